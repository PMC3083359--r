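# bessurvey

Genome surveys from BAC-end sequences (BES), in R.

Before a genome is assembled, end reads from a large-insert BAC library
already answer useful questions: how repetitive is the genome, what
microsatellite markers does it offer, and how does it relate to an
assembled genome of a close relative? `bessurvey` implements that survey
end to end:

* **Cleanup** — modified-Mott quality trimming (per-base score
  `t − 10^(−Q/10)`, maximal-sum segment), end-anchored vector trimming,
  a 50-bp length floor, and redundancy filtering (a read fully covered
  by another at >95% identity is dropped), with survey statistics
  (totals, mean length, GC%, mate-pair counts).
* **Repeats** — non-redundant library merging (≥95% identity over ≥95%
  of the shorter sequence), masking with per-hit divergence
  (substitutions per aligned non-gap column), six-frame
  transposon-protein scanning, and a simple frequent-k-mer de novo
  repeat discoverer.
* **Microsatellites** — maximal perfect runs of atomic 2–6 bp motifs
  with ≥5 units, canonical motifs (minimum over rotations and
  reverse-complement rotations), flank checks for primer design, and a
  census by unit length and motif.
* **Anchoring** — a seed-and-extend local aligner (exact 14-mer seeds,
  diagonal banding, affine-gap DP; match +1 / mismatch −2 / gap open 5 /
  extend 2) with BLAST-style 12-column tabular interchange,
  deterministic top-hit selection, and a site-weighted identity summary
  (`Σ identical / Σ aligned` columns).
* **Synteny** — mate-pair classification (paired ends / long pair /
  mate-reverse / unmate / singleton / unmapped; "consistent
  orientation" = inward-facing ends, facing gap ≤ 300 kb), microsynteny
  typing against gene annotation (coding / noncoding / intergenic end
  pairs), and per-chromosome physical coverage as a union of clone
  spans.
* **Simulation** — a ground-truthed generator for reference genomes,
  diverged sample genomes (per-site substitution, optional segmental
  duplication) and clone-end reads (inward mates, two-segment quality
  model, vector contamination), so the whole pipeline is testable
  without external data.

## Worked example

Simulate a 350-kb two-chromosome reference, derive a 10%-diverged
sample genome, sequence 60 clones from both ends, clean the reads and
anchor them back:

```r
library(bessurvey)

ref <- simulate_reference(c(chr1 = 200000, chr2 = 150000), n_genes = 10,
                          n_repeat_copies = 15, n_ssrs = 10, seed = 42)
smp <- derive_sample_genome(ref, divergence = 0.1, seed = 43)
vec <- withr::with_seed(9, random_dna(800))
be  <- simulate_bac_ends(smp, n_clones = 60, insert_mean = 50000,
                         insert_sd = 8000, vector = vec,
                         contamination_rate = 0.2, seed = 44)

cl <- clean_reads(be$reads, vectors = c(vec = vec))
cl$stats
#> BES survey statistics
#>   reads in                   120
#>   after trimming             120
#>   redundant removed            2
#>   final reads                118
#>   total bp                 70338
#>   mean length (bp)           596
#>   GC% / AT%           38.6 / 61.4
#>   mate pairs                  58

top <- select_top_hits(align_bes(cl$reads, build_index(ref)))
top
#> top_hits: 118 queries with a passing hit ( 118 unique )
identity_summary(top)$mean_identity_percent
#> [1] 89.9

cls <- classify_clones(top)
ms  <- build_microsyntenies(cls$classifications, ref$genes)
chromosome_coverage(ms$microsyntenies, nchar(ref$seqs))
#> # A tibble: 3 × 5
#>   chrom size_bp covered_bp n_clones coverage_percent
#>   <chr>   <int>      <dbl>    <int>            <dbl>
#> 1 chr1   200000     186371       31             93.2
#> 2 chr2   150000     144438       27             96.3
#> 3 Total  350000     330809       58             94.5
```

Reading the output: all 120 simulated reads survive trimming, two are
removed as redundant; the mean identity of the anchored reads (89.9%)
recovers the simulated 10% divergence; 58 of 60 clones classify as
paired ends (both ends on one chromosome, inward, ≤ 300 kb apart), and
the union of their spans covers ~94% of the reference.

The same stages run as one orchestrated pipeline with
`run_pipeline(list(simulate = TRUE, seed = 5, out_dir = "out", ...))`,
which writes cleaned reads, all stage TSVs and a checksum manifest; a
thin CLI wrapper lives at `inst/scripts/bes-survey`.

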