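# Shared small helpers. Coordinates are 0-based half-open everywhere inside the
# package; GTF import/export converts at the boundary.

chain_key <- function(chain) paste(chain, collapse = ",")

chain_from_key <- function(key) as.integer(strsplit(key, ",", fixed = TRUE)[[1]])

#' @keywords internal
is_strictly_increasing <- function(x) length(x) < 2L || all(diff(x) > 0L)

# is `a` a contiguous infix of `b`? (proper or not)
chain_is_infix <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na > nb) return(FALSE)
  hits <- which(b == a[1L])
  for (h in hits) {
    if (h + na - 1L <= nb && all(b[h:(h + na - 1L)] == a)) return(TRUE)
  }
  FALSE
}

# length of the longest proper suffix of `a` equal to a proper prefix of `b`;
# 0 if none.  Used for overlap edges.
chain_overlap_len <- function(a, b) {
  na <- length(a); nb <- length(b)
  kmax <- min(na - 1L, nb - 1L)
  if (kmax < 1L) return(0L)
  for (k in seq(kmax, 1L)) {
    if (all(a[(na - k + 1L):na] == b[1L:k])) return(k)
  }
  0L
}

merge_chains_at <- function(left, right) {
  # concatenate two chains sharing one element at the junction point
  stopifnot(length(left) == 0L || length(right) == 0L ||
              left[length(left)] == right[1L])
  if (length(left) == 0L) return(right)
  if (length(right) == 0L) return(left)
  c(left, right[-1L])
}

# deterministic lexicographic comparison of integer vectors:
# -1 if a < b, 0 if equal, 1 if a > b
chain_compare <- function(a, b) {
  n <- min(length(a), length(b))
  if (n > 0L) {
    d <- a[seq_len(n)] - b[seq_len(n)]
    i <- which(d != 0L)
    if (length(i)) return(sign(d[i[1L]]))
  }
  sign(length(a) - length(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
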