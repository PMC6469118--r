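---
title: "Assembling transcripts with exon-bin graphs and network flows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling transcripts with exon-bin graphs and network flows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binflow)
```

# The problem

Given spliced paired-end alignments of RNA-seq reads against a reference
genome, transcript assembly reconstructs the set of expressed isoforms of
each gene and estimates their abundances.  Two classical graph frameworks
attack this problem from opposite sides.  Overlap graphs keep each read
fragment as a node, preserving multi-splice and mate-pair information but
discarding the per-base coverage signal.  Splice graphs use exons as nodes
and splices as edges, exposing coverage for flow-based quantification but
collapsing any read that spans more than two exons onto independent edges.
`binflow` implements a generalized exon-bin graph that keeps both: long
reads stay intact as maximal edge chains, and every node and edge carries a
coverage value a network flow can act on.

# From alignments to bins

Reads are streamed from coordinate-sorted SAM/BAM (secondary, supplementary
and unmapped records skipped), their CIGAR strings decomposed into aligned
blocks, and reference gaps of at least `min_intron` (default 30 bp) recorded
as splice junctions with the strand taken from the XS tag.  Base-level
coverage is stored as sparse gain/loss events per chromosome, so depth
queries at any interval are prefix sums.  Junctions are 1D-clustered within
a bandwidth (default 3 bp) to absorb alignment jitter; the member with
maximal support names the cluster.

The covered genome partitions into loci (coverage islands merged across
bridging junctions).  Within a locus, the boundary set — coverage edges
plus every clustered donor and acceptor — induces the smallest ordered set
of *exon ranges* explaining all splice sites; an exon of one isoform that
contains another isoform's splice site is handled as two ranges.  Every
fragment becomes a *bin*: the ordered list of ranges its blocks overlap.
Mates merge into one bin when their chains overlap (the shared region must
agree exactly) or abut in range-index space; otherwise the pairing is kept
as a *paired link* for the phasing step.

# The bin graph

Bins are consolidated in an auxiliary graph with *overlap* edges (a proper
suffix of one chain equals a proper prefix of another) and *containment*
edges (one chain is a contiguous infix of another; a non-contiguous subset
would assert a contradictory splice structure).  Contained bins surrender
their overlap edges, transitive edges are removed (exact DAG transitive
reduction — the brute-force semantics our tests verify against), and bins
joined by an overlap edge that is the only one on both sides merge into one
longer bin.  What remains marks genuine ambiguity.

The final graph has source and sink plus at most one node per exon range
(labels injective); edges carry maximal exon chains.  Four conditions
characterize it: every source-sink path spells a unique well-formed
transcript; every retained bin maps to a unique path whose end nodes carry
the bin's first and last exon; the node count is minimal for that; and edge
chains are maximal.  Construction processes maximal bins in genomic order
(ties: longer first).  A bin without incoming overlaps becomes a single
edge; otherwise its predecessors' paths are split at the bin's first exon
and joined along the shared chain, with the residual chain appended as a
new edge.  Bins contained in two or more maximal bins are classified
lazily: if their containers already share one path over the bin's span the
bin is absorbed (when the span is a bare node, its reads are already
accounted for by the node's own coverage and credit no edge); otherwise the
containers' paths are joined along the bin, which is what creates nodes at
genuinely ambiguous exons.  Bins hold their current path as shared edge
ids, so splitting an edge updates every owner at once.  With only one- and
two-exon bins and dense alternative splicing the result degenerates to the
basic splice graph, its worst case.

# Coverage and the flow solve

Node coverage is the mean depth of the labeled range.  Edge coverage is
estimated from the features unique to the edge, all on the same local-depth
scale: the sequenced crossing-read count of each junction only that edge
contains, and the mean depth of interior exons only that edge contains.  A
naive aligned-bases-over-length average would halve junction-only edges
(crossing reads paint a triangular profile), and crossing counts are taken
at the mate level so that a merged pair whose unsequenced insert spans a
junction does not count.  When an edge has no unique feature, the owners'
aligned bases averaged over the chain serve as fallback.

Before solving, coverage is pre-corrected for non-uniformity: per node the
forward overhead (windowed-maximum depth minus the depth at the last bases)
and the reverse overhead (versus the first bases) are computed, discounted
by twice the counting-noise standard error of a windowed mean,
`2 * sqrt(c * r / (w + r))` with window `w = 25` and read span `r` — at
typical depths the raw per-base maximum sits well above any boundary mean
through noise alone, and undiscounted overheads would inject phantom
corrections.  A forward pass in topological order hands each node its
predecessors' overhead mass apportioned by relative edge coverage, a
reverse pass mirrors it, and each feature gains the larger of its two
corrections, so perfectly uniform coverage is left unchanged and no value
ever decreases.

Each node *v* then becomes an arc from *v.in* to *v.out* with its coverage
as the observed value; graph edges connect the split halves; source and
sink arcs are free.  A conserving flow *f* is scored with convex deviation
costs `(c - f)^2 / c` on node arcs and `(c - f)^2 (L - 1) / c` on an edge
arc with chain length `L` and observed value `c`; arcs observed at zero
carry the locus's median per-unit cost so they stay unattractive but
usable.  The minimizer is the denoised expression cover.  We solve it
exactly: deviations are linearized at unit breakpoints and routed as a
minimum-cost b-flow on the offset network by successive shortest paths,
which yields an integral optimum.  The deviation range starts at 16 units
and doubles whenever an artificial bound is hit, up to four times the
observed value — beyond that a deviation always costs more than explaining
the locus from zero, so the cap cannot bind at an optimum.  We chose unit
breakpoints over a coarser geometric ladder because the solver is also our
reference against a brute-force enumeration oracle, and only an exact
linearization makes that comparison meaningful; the doubling schedule keeps
the arc count small on deep loci.  The cost function is homogeneous of
degree one (`c(kx; kc) = k c(x; c)`), so scaling all coverages scales any
flow's cost exactly; the integral *optimum* scales exactly whenever the
continuous optimum is integral, and within one flow unit otherwise.

# Phasing resolution and extraction

Flow conservation lets tree nodes and composite paths contract until every
interior node has at least two in- and two out-edges.  These unresolved
nodes — reported per locus as diagnostics — are resolved with phasing
evidence: bins spanning the node and paired links bridging it connect
specific in-edges to out-edges.  Sub-chains of a longer spanning bin are
dropped; evidence that fits inside a single edge elsewhere (a bypass path)
is not counted; and a mate lying beyond an edge that ends at an interior
node only weakly supports that edge, since the fragment may continue past
it — such observations stay ambiguous rather than minting false specific
connections.

Each node is resolved by two linear programs: the first finds connection
flows minimizing the total absolute deviation from the observed support
counts, the second fixes those optima as lower bounds and maximizes the
used flow by minimizing the per-edge residuals.  The used-flow optimum is
usually degenerate, so a third stage selects, among its solutions, the one
closest in L1 to an evidence-proportional allocation `x = alpha * n` with
the scalar `alpha` free — without it the solver parks entire transcripts on
single connections.  Ambiguous evidence is admitted only where the specific
connections cannot sufficiently explain it: its count must exceed what its
specifically covered sibling pairs already carry, and both edges of an
admitted pair must hold residual flow above the Poisson noise scale
`2 * sqrt(f)`.  Edges untouched by any connection keep their full flow for
later decomposition (incomplete evidence must not erase real transcripts);
on covered edges, leftover flow is estimation noise and is dropped.  Nodes
resolve in order of increasing degree — settling the well-determined nodes
first lengthens the chains the harder nodes see — then by evidence
specificity and error per flow.

Between steps, unevidenced edges below 30% of another transcript edge at a
shared vertex (75% where the vertex has no evidence at all) are removed and
the flow re-balanced, with removals that would disconnect the graph rolled
back; an edge counts as evidenced if read bins map onto it or phasing
created it, and residual stubs are explicitly unevidenced.  Retained
introns — edge chains running contiguously across another edge's splice
gap — are removed unless the intronic median depth reaches `ir_frac`
(default 0.35) of the weaker flanking exon.  Finally the residual flow is
decomposed by repeatedly taking the source-sink path with the most exons
(ties: larger bottleneck, then leftmost), emitting it with its bottleneck
flow; decomposition stops below one flow unit.  We prefer longest-first
over heaviest-first because minimal path covers optimize parsimony, not
biological plausibility.  Abundances are reported in flow units and as
FPKM, `flow * 1e9 / (length * fragments)`.

With a guide annotation, guides map to graph paths (or are dropped as
incompatible), per-node bias factors propagate each guide's largest
feasible coverage along its path, and if the explained fraction *F* of
total coverage reaches `trust/100` the coverage labels are replaced by the
guide sum, otherwise raised toward it proportionally to *F* — a linear
interpolation, the mildest reading of an otherwise open mapping.  Guided
transcripts are extracted first; unannotated transcripts below
`0.05 * (trust/100) * (trust/20)` of the locus maximum are dropped, so
trust 0 disables the filter entirely and trust 100 demands a quarter of the
maximum.

# The synthetic-data generator

The simulator builds loci as exon layouts plus isoform chains and samples
paired fragments directly as alignments (sequence content is irrelevant to
the method, so SEQ is an N-run).  Its defaults define the study conditions
of the package's own benchmark:

* read length 100 bp, fragment length normal with mean 280 and sd 25;
* exons 50–200 bp (terminal exons at least 170 bp), introns 80–300 bp;
* per-isoform depth 20–40x, equal across isoforms unless distinct
  (geometrically spaced) abundances are requested;
* fragment starts uniform over a window extended beyond the transcript by
  one fragment length, with overhanging mates clipped (at least 30 aligned
  bases) — so the noiseless condition really is uniform coverage over the
  whole transcript, including terminal exons, matching a benchmark design
  of equal coverage without sequencing errors;
* junction jitter (rate and +-bp), a 5'→3' log2 coverage trend, and
  fragment dropout as explicit noise knobs, all off by default;
* a fixed seed makes the SAM byte-reproducible.

Generated isoform sets are screened for identifiability: all isoforms span
the locus end to end (the source/sink wiring recognizes transcript starts
only at ranges without predecessors, so mid-exon start sites are out of the
model), splice chains are pairwise distinct, and every interior stretch
shared by two isoforms that diverge on both sides must be bridgeable by a
fragment.  The screen is pairwise: with many isoforms on few exons, joint
ambiguity can survive it, and on such loci no method — this one included —
can guarantee a perfect call set.  Passing the recovery tests therefore
shows correctness under identifiable, uniform-coverage conditions; real
libraries add positional bias, misalignment and incomplete fragmentation
the trend/jitter/dropout knobs only caricature.

# Numerical choices and limitations

* Coverages are rounded to integers (minimum 1 on covered arcs) before the
  flow solve; connection flows are rounded to integers after the LPs with
  per-edge feasibility repair.
* The LPs run in continuous relaxation through a dense simplex
  (`pracma::linprog`); their constraint matrices are network matrices, so
  vertices are integral.  The solver consults the session RNG on degenerate
  vertices, which is why `run_pipeline` pins the RNG from its `seed`
  argument — the documented contract is byte-identical output for fixed
  input, configuration and seed.
* Worst-case complexities are quadratic in places where the underlying
  ideas admit near-linear algorithms (suffix/prefix scanning, reduction by
  reachability, per-edge path updates); loci of a few dozen exon ranges
  keep this immaterial.
* The acceptance workloads (and their problem sizes: 50-locus benchmark at
  1–8 isoforms, 200 random graph loci with at most 8 exons, 100 oracle
  networks, 100 LP instances) are the package's own choice of desk-scale
  study conditions; they are generated in code, never stored.
* Trans-splicing, circular transcripts and mid-exon start/end sites are out
  of scope; multi-mapping reads contribute only their primary alignments.
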