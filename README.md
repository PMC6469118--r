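# binflow

Reference-guided transcript assembly and quantification from spliced
paired-end RNA-seq alignments.

Transcript assembly must reconcile two kinds of evidence that classical
graph models keep apart: splice graphs (exons as nodes, splices as edges)
expose per-base coverage for flow-based quantification but dissolve every
read spanning more than two exons, while overlap graphs preserve
multi-splice and mate-pair phasing but hide the coverage signal.  `binflow`
builds a generalized **exon-bin graph** that keeps both.  Reads become
*bins* — ordered chains of exon ranges x₁ < x₂ < … — and the graph places a
node only where bins genuinely conflict, so that every source–sink path
spells a unique transcript, every retained bin maps to a unique path, the
node count is minimal, and edge chains are maximal.

On that graph the package:

1. estimates per-node and per-edge coverage (junction-crossing counts and
   unique interior exon depths, on one local-depth scale) and pre-corrects
   it for non-uniformity via per-exon coverage overheads b⁺, b⁻ propagated
   in topological order;
2. solves a convex-cost minimum-cost flow — minimize
   Σ_v (cov(v) − f_v)²/cov(v) + Σ_uv (cov(uv) − f_uv)²·(|l(uv)|−1)/cov(uv)
   over conserving flows f — exactly, by unit-breakpoint linearization and
   successive shortest paths on the offset network (the denoised
   "expression cover" of the locus);
3. contracts the flow-annotated graph until only genuinely ambiguous nodes
   remain and resolves those with phasing evidence (multi-splice bins and
   mate pairs) through a two-step linear program: minimal deviation from
   the evidence counts, then maximal used flow, with an
   evidence-proportional tie-break;
4. filters weak unevidenced edges (30%/75% rules) and unsupported retained
   introns, then decomposes the residual flow longest-path-first into
   transcripts with flow and FPKM abundances, written as GTF2.2.

A deterministic synthetic-data module (exon layouts, isoform chains,
paired-end sampling with coverage-trend / junction-jitter / dropout noise
knobs, SAM + truth GTF emission) makes the whole pipeline testable without
any external data.

## A worked example

Three isoforms over eight exons A–H, where exon D sits at the crossing
point of all three (the only genuinely ambiguous exon) while E and F are
shared with identical context and stay inside one maximal edge:

```r
library(binflow)

loc  <- fig_locus()                      # isoforms ACDEFG, BDEFG, ACDH
recs <- sample_reads(loc, seed = 7)      # paired-end fragments
sam  <- file.path(tempdir(), "example.sam")
emit_sam(recs, sam)

res <- run_pipeline(assembly_config(sam, out = "assembled.gtf",
                                    verbose = TRUE))
#> locus chrF:1000-2560[+]: 21 bins, 5 nodes, 1 unresolved, 3 transcripts

for (tx in res$transcripts)
  cat(sprintf("%s:%d-%d [%s]  flow %.0f\n", tx$chrom,
      min(tx$exons$start) + 1L, max(tx$exons$end), tx$strand, tx$abundance))
#> chrF:1001-2260 [+]  flow 14
#> chrF:1241-2260 [+]  flow 7
#> chrF:1001-2560 [+]  flow 17
```

All three isoforms are recovered (simulated at depths 12, 8 and 20; the
locus's 115 fragments support flows 14, 7 and 17), the graph used 5 nodes
for 8 exons, and the one unresolved node — exon D — was settled by mate
pairs.  The GTF carries `gene_id`, `transcript_id`, `FPKM` and `cov`
attributes:

```
chrF  binflow  transcript  1001  2260  .  +  .  gene_id "BINFLOW.1"; transcript_id "BINFLOW.1.1"; FPKM "135462.0223"; cov "14.0000";
```

A shell entry point wrapping the same pipeline lives at
`inst/scripts/assemble.R`:

```sh
Rscript assemble.R --bam aligned.bam [--guide ann.gtf --trust 60] \
    [--min-edge-frac 0.30] [--no-evidence-frac 0.75] [--ir-frac 0.35] \
    [--bandwidth 3] [--seed 1] -o out.gtf
```

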