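---
title: "Methods: BAC-end sequence surveys with bessurvey"
author: "bessurvey authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BAC-end sequence surveys with bessurvey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

BAC-end sequences (BES) are single Sanger reads taken from both termini
of large-insert (~100–200 kb) genomic clones. Before a genome is
assembled, a few tens of thousands of BES already support a useful
genome survey: base composition, repeat content and age structure,
microsatellite (SSR) marker discovery, and — when a closely related
reference genome exists — comparative anchoring, where the two mate
reads of a clone constrain its placement and define conserved
*microsyntenies*. The motivating setting is a large, recently duplicated
(tetraploid-like) cyprinid genome surveyed against the assembled genome
of a close diploid relative, but nothing in the package is specific to
that pair.

`bessurvey` implements the whole survey as composable stages — cleanup,
repeat annotation, SSR census, alignment anchoring, mate-pair
classification/synteny, reporting — plus a simulator that generates a
reference genome, a diverged sample genome and ground-truthed clone-end
reads, so every stage is testable without external data.

## Read cleanup

**Quality trimming** uses the modified-Mott rule: each base with Phred
quality $Q$ contributes a score $t - 10^{-Q/10}$, where $t$ is the
error-probability threshold (default $t = 0.01$, the conventional Q20
operating point), and the read is trimmed to the contiguous segment with
the maximal score sum. Ties are broken toward the smallest end position,
then the smallest start; a read whose best segment is non-positive is
discarded. The implementation is the linear-time prefix-minimum scan;
the test suite checks it against an exhaustive $O(n^2)$ best-window
oracle on 1,000 random quality strings.

**Vector trimming** aligns each read locally against the supplied
vector/contaminant sequences (match +1, mismatch −2, gap open 5, gap
extend 2 — the scoring used throughout the nucleotide stages). Hits with
score ≥ 16 at ≥ 90% identity that touch within 25 bp of either read end
are extended to that end and removed; the longest clean interior
segment is kept. These thresholds follow common vector-screening
defaults; end-anchoring reflects end-read chemistry, where vector
carryover is terminal.

**Redundancy filtering** removes a read when a local alignment against
another retained read covers its *full* length at more than 95%
identity on either strand. Of a mutually covering pair the longer read
is kept (maximising retained genome representation), with the
lexicographically earlier id as the final tie-break. Candidate pairs are
prefiltered by shared 16-mers; a stride-sampled k-mer set is joined
against an every-position k-mer table so that sampling phase can never
hide a true pair.

**Survey statistics** report totals, the rounded-integer mean read
length, GC/AT percentages computed over unambiguous bases only, a 50-bp
length histogram, and the number of clones with both ends surviving
("mate pairs"). `survey_stats_from_totals()` reproduces the same
arithmetic from published totals, which is how the package's reporting
is validated against a printed survey table.

## Repeat annotation

Repeat libraries are tibbles of (id, family, sequence) with the family
classes DNA / LINE / SINE / LTR / Satellite / Simple / LowComplexity /
Unknown. `merge_repeat_libraries()` drops the shorter member of any pair
aligning at ≥ 95% identity over ≥ 95% of the *shorter* sequence's
length. Coverage is measured on the shorter sequence because the rule's
action is to discard it; measured on the longer one the rule would
almost never fire.

`mask_repeats()` aligns every library entry against every read (k-mer
prefiltered, both strands); alignments scoring ≥ `min_score` (default
30) become hits, hit intervals are unioned per read before masking and
before any bp accounting, so family totals can never exceed the masked
total. Divergence is substitutions per aligned non-gap column — gap
columns are excluded because divergence is meant to proxy substitutional
age. The default `min_score = 30` was chosen from the alignment score
statistics (a score-30 local alignment between unrelated ~650-bp
sequences is vanishingly rare); a property test verifies that a shuffled
library masks < 0.1% of random reads.

`transposon_protein_scan()` translates unmasked reads in six frames,
breaks frames at stop codons into fragments of ≥ 20 aa, and aligns
fragments against a transposon-protein set with BLOSUM62 (gap open 11 /
extend 1), reporting the best per-read hit with score ≥ 60. A 4-mer
amino-acid word prefilter keeps the all-vs-all cost down.

`discover_repeats_kmer()` is a deliberately simple de novo discoverer:
the most frequent ≥ `min_copies` k-mer seeds a candidate that is
extended column-by-column while the consensus base keeps ≥ `min_copies`
support, candidates are emitted as family `Unknown`, and the merge rule
above removes redundancy. It recovers abundant interspersed elements; it
is not a substitute for a full repeat-discovery suite (no tandem/LTR
structure modelling, no family refinement).

## Microsatellites

`find_ssrs()` reports maximal perfect tandem runs of atomic 2–6 bp
motifs with ≥ 5 complete units (defaults). Design choices worth
stating:

* *Perfect runs only*: no mismatches inside a run — the only reading
  consistent with counting exact repeat units.
* *Atomicity*: an `ACAC` tetramer call is forbidden where `AC` explains
  the run; mononucleotide runs are excluded (motif range starts at 2),
  which also silences poly-A tails.
* *Truncation*: a 5.5-unit run is reported as 5 units over exactly
  `units × unit_len` bp.
* *Overlap resolution*: candidates from different unit lengths are
  resolved leftmost-longest, greedily.
* Runs break at `N`.

The scanner is validated against an exhaustive brute-force oracle
(every position × every unit length) on adversarial fixtures and on
2,000 random 500-bp sequences. `canonical_motif()` maps a motif to the
lexicographic minimum over all rotations of itself and of its reverse
complement, so `TG`, `GT`, `CA`, `AC` share the class `AC`.
`flank_check()` calls an SSR primer-designable when both flanks are
≥ `min_flank_bp` (default 50 — a deliberate knob, since "sufficient
flanking sequence" has no universal definition) and neither flank is
repeat-masked over half its length.

## Alignment anchoring

`build_index()` indexes exact k-mers (default k = 14) of the reference
plus strand; k-mers occurring more than 50 times are dropped (repeat
seeds). `align_bes()` samples query k-mers every 10 bp on both strands,
groups seed matches into diagonal bands per chromosome, and extends each
band by exact local dynamic programming of the query against the banded
reference window (band ± 100 bp margin). Window-bounded exact DP was
chosen over x-drop extension: at survey problem sizes it finds the same
hits, is exactly reproducible, and reuses one well-tested alignment
kernel. At 10% divergence a sampled 14-mer is error-free with
probability $0.9^{14} \approx 0.23$, so a 650-bp read yields ~15 exact
seeds — sensitivity is not limiting.

Each hit carries an e-value-like expectation
$K m n e^{-\lambda S}$ with fixed $K = 0.71$, $\lambda = 1.37$. Only its
cutoff behaviour matters (default cutoff $10^{-5}$); it is not a
calibrated BLAST e-value. `select_top_hits()` ranks per query by score,
then e-value, aligned columns, subject name and position — a fully
deterministic tie-break, since ties are otherwise arbitrary.
`identity_summary()` reports the *site-weighted* mean (total identical
over total aligned columns): printed counts of identical sites imply
site weighting, and that is the convention adopted. The 12-column
tabular interchange uses 1-based inclusive coordinates with the minus
strand encoded as reversed subject coordinates; internal coordinates
are 0-based half-open with an explicit strand.

## Mate-pair classification and microsynteny

With one top hit per end, a clone is classified: no hits → unmapped;
one → singleton; two chromosomes → unmate; same chromosome but
orientation-inconsistent → mate_reverse; consistent and facing-end gap
≤ 300 kb → paired_ends; consistent but farther → long_pair.
"Consistent orientation" is implemented as *inward-facing opposite
strands* (leftmost hit on plus, rightmost on minus): this is the only
physically coherent layout of the two ends of one insert, and the
existence of a separate mate-reverse class presupposes an
orientation-violating configuration. The gap is measured between the
facing ends of the two hit intervals (clone geometry), the span
outermost-to-outermost.

Each paired_ends clone yields one microsynteny, typed by the unordered
pair of end annotations against the gene models: 1 coding/coding,
2 coding/noncoding, 3 noncoding/noncoding, 4 coding/intergenic,
5 noncoding/intergenic, and 6 intergenic/intergenic. Type 6 is reported
even though five-type schemes often omit it: the five named types do
not partition the paired clones, and a partition is required for the
counts to reconcile. An end is *coding* when its interval overlaps ≥ 1
bp of a protein-coding gene span, introns included; coding takes
precedence over noncoding.

`chromosome_coverage()` reports per-chromosome physical coverage as the
union of paired-end spans (overlaps counted once) with a Total row
recomputed from the summed columns; the union is validated against a
per-base boolean-array oracle. `exon_gene_hits()` counts genes with at
least one BES overlapping an exon, each gene once.

## The simulator

`simulate_reference()` draws A/T-rich random chromosomes (default
63.2% A/T, typical of teleost genomes) and plants non-overlapping gene
models (with exons), repeat-family copies (each copy substituted at 10%
by default, giving the divergence histogram something to measure) and
perfect SSRs. `derive_sample_genome()` models the surveyed genome as
the reference plus independent per-site substitutions — no indels
unless `indel_rate > 0`, keeping identity arithmetic analytic — and
optional segmental duplications appended as extra contigs (re-diverged
at 2%), so that in a truth-aware alignment against the sample genome a
read from a duplicated segment has two homologous loci, emulating a
recently duplicated genome. `simulate_bac_ends()` draws clone loci
(insert length Normal, default mean 141 kb — a typical BAC library —
with a free 20 kb sd, since library-specific variance is rarely
published), sequences the two termini inward, assigns a two-segment
quality model (Q40 core, linear decay to Q8 over the final 15%; the
decay gives the Mott trimmer something real to cut), introduces
sequencing errors at the rate the qualities imply, and optionally
prepends 20–120 bp of vector to a fraction of reads (prefix-only, as in
end-read chemistry). A truth table records the error-free origin of
every read.

What the simulator does *not* emulate: chromatogram-level noise and
realistic Sanger error profiles, true tetraploid inheritance, indel
divergence by default, GC-dependent coverage bias, and chimeric clones.
Passing tests on synthetic data therefore demonstrate algorithmic
correctness under the stated model, not robustness to every artefact of
real trace data.

## Numerical choices and degenerate inputs

* All internal coordinates are 0-based half-open; interval unions use
  `IRanges::reduce`.
* Rounding follows survey-table precision: mean read length to an
  integer, masked fraction and GC% to 1 decimal, coverage and census
  percentages to 2 decimals.
* Empty inputs return typed empty results (zero-row tibbles, all-zero
  censuses, flagged undefined means) rather than errors; an empty
  repeat library warns and masks nothing; an empty reference is an
  error.
* Determinism: every stochastic function takes a `seed`; a fixed seed
  reproduces byte-identical FASTA/TSV outputs, and `run_pipeline()`
  writes a manifest (parameters + input/output checksums) that is
  identical across reruns of the same config.

## Validation problem sizes

The shipped validation exercises the package at sizes chosen to finish
in minutes on one CPU while keeping every estimate well-conditioned: a
5-Mb two-chromosome reference with 1,000 clones (2,000 reads) for the
end-to-end recovery run (divergence 0.10: the identity histogram peaks
in the 89–91% bin and ≥ 95% of clones whose ends both map correctly
classify as paired_ends); 100-kb chromosomes for coverage-union
oracles; 2,000 random 500-bp reads for the SSR oracle; 1,000 random
quality strings for the trimmer oracle. Published-table worked examples
(mean read length, trimming success, repeat fraction, SSR percentages,
site-weighted identity, chromosome coverage, mate-pair counts) are
reproduced exactly by the reporting operations from the printed totals.

## Known limitations

The aligner is a survey anchoring tool, not a general-purpose mapper:
no spliced or translated alignment, uncalibrated e-values, and seeding
that assumes queries of at least a few times the seed length. Repeat
discovery is frequency-based and blind to low-copy or highly diverged
families. Synteny classification trusts the single top hit per end;
near-equal paralogous hits (common in duplicated genomes) can misplace
a clone even when classification logic is correct. Coverage is physical
clone coverage, not sequence coverage, and uses paired-end spans only.
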