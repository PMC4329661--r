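---
title: "Methods: comparative metagenome profiling and fragment recruitment"
author: "metacompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative metagenome profiling and fragment recruitment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacompare)
```

## Scope

metacompare compares two shotgun metagenome samples end to end. It was
built around the analysis style used for 454-pyrosequenced biogas-reactor
microbiomes — two communities of bacteria and methanogenic archaea
sequenced to unequal depth and compared at every level: read quality,
taxonomic and functional (Pfam) profiles, rarefaction, and fragment
recruitment against reference genomes. The classifiers that produce
per-read taxonomic or Pfam assignments are *not* part of the package;
their outputs are consumed as plain TSV tables. Likewise, external BLASTn
hits can be supplied in tabular (outfmt 6) form, while a small internal
aligner makes fully self-contained runs possible.

## The synthetic community generator

Every stage is validated against simulated data with known ground truth,
so the generator is first-class code, not a test fixture.

* **Genomes** are i.i.d. base draws at a target GC content
  (`generate_genome()`); related "strains" at a known average nucleotide
  divergence are derived by i.i.d. substitutions (`mutate_genome()`).
* **Reads** (`simulate_reads()`) pick a source genome with probability
  equal to its abundance, a uniform start, and a length from a normal
  distribution truncated to [50 bp, 2 × mean]. Only the means of real
  454 read-length distributions are typically reported, so the truncated
  normal is a stand-in shape honouring them, not a calibrated model; the
  default mean of 387 bp matches the regime of a typical GS FLX run.
* **Errors** are substitution-only by default: each base is flipped to
  one of the three other bases with the genome's divergence rate, so the
  per-read mismatch count is exactly binomial — which is what makes the
  recruitment-identity oracle computable in closed form. 454-style
  homopolymer indels can be switched on (`homopolymer_indel_rate`), but
  no downstream statistic here depends on indels, only on identity
  fractions.
* **Artifacts**: emulsion-PCR duplicates copy a parent read's genome,
  start and length and redraw its errors independently; parents are
  chosen with weight `exp(gc_dup_coupling × GC)`, coupling duplication
  to GC content as observed in pyrosequencing libraries. Originals are
  emitted before their duplicates; read order carries no other signal,
  and the duplicate count is `round(duplicate_rate × n_reads)` exactly.

What the simulator does **not** emulate: flowgrams/SFF structure,
quality-coupled errors, chimeras, strand of origin (reads are
forward-strand; every identity statistic is strand-symmetric and the
aligner is exercised on explicit reverse complements). Passing tests on
synthetic data therefore demonstrate correctness of the *computations*,
not robustness to every artifact of real 454 data.

## Read quality control

Two filters, always composed duplicates-first (the order is recorded in
the `QCReport`):

1. **Duplicate removal** (`remove_duplicates()`). Emulsion-PCR
   replicates share their 5' start, so reads with an identical
   `prefix_len = 50` bp prefix (case-insensitive) and lengths within
   `length_tolerance = 2%` are clustered; each cluster keeps its longest
   member (earliest on ties). Reads with `N` in the prefix never
   cluster — conservative toward retention. Keeping one representative
   per cluster (rather than discarding whole clusters) is the default
   because the replicate class being removed is an amplification
   artifact of a real template.
2. **GC-bias filtering** (`filter_gc_bias()`). Reads whose GC fraction
   lies more than `z_cutoff = 3` sample standard deviations from the
   sample mean are removed. The trim iterates to a fixed point by
   default — mean and SD are recomputed after each pass until nothing
   moves — because a single pass is not idempotent (removing outliers
   shrinks the SD, so a rerun could remove more). Iterative 3-sigma
   trimming is a standard robust outlier procedure and makes "apply the
   filter twice = apply it once" hold by construction; `iterate = FALSE`
   restores the literal single pass.

On simulated libraries with a 10% duplicate rate from a 2-Mb genome
(realistic microbial genome scale), duplicate removal attains
sensitivity ≈ 1 and a false-positive rate ≈ 0 against ground-truth
labels. The genome must not be made much smaller in such experiments: on
a 100-kb genome, thousands of reads coincidentally share start
positions, which are genuine sequence duplicates of position and would
conflate the false-positive measurement.

## Profiles and their comparison

A `Profile` is a named count vector at one rank plus the dataset total
it is relative to — the totals matter because the two samples are
sequenced to different depths.

* **E-value filter**: assignments with E-value ≤ 1e-5 are considered
  (boundary inclusive).
* **Smallest-dataset normalization** (`normalize_to_smallest()`): all
  counts are scaled by `N_min / total`; the smallest sample passes
  through unchanged and within-sample relative abundances are preserved
  exactly. Normalized counts are real-valued and kept at full precision;
  only reported percentages are rounded (half-up, two decimals, via
  `percentage_of_total()`, whose denominator is always the minimum
  total for *every* sample — the only convention under which published
  recruited-read percentages reproduce from their printed counts).
* **Scatter data** (`scatter_points()`): per family,
  `log10(normalized count + 1)` for each sample. The pseudocount of one
  maps absences to 0 and guarantees non-negative coordinates. Families
  are kept only when the sum over both samples of each sample's own
  relative abundance is ≥ 0.01% (`min_rel_sum = 1e-4`), suppressing
  noise-level families.
* **Unique gene tags** (`unique_egts()`): a taxon/Pfam is unique to one
  sample when the other sample's count is exactly zero (a raw zero
  scales to zero, so the test is on the raw zero) and its normalized
  count is ≥ 5, inclusive.
* **Rarefaction** (`rarefy_assignments()`): Monte-Carlo subsampling
  without replacement, default 10 replicates and 10 evenly spaced
  depths, seeded. Each replicate is one random permutation read as a
  collector's curve, so every replicate is non-decreasing in depth while
  each depth remains a uniform without-replacement subsample; the mean
  therefore follows the hypergeometric closed form
  `E[S_n] = Σ_i (1 − C(N−N_i, n)/C(N, n))`, available as
  `rarefaction_expected()` and cross-checked against `vegan::rarefy`.
* **Methanogenesis comparison** (`methanogenesis_comparison()`):
  functional records are restricted to superkingdom *Archaea* and to a
  curated Pfam map covering the acetyl-CoA pathway (AckA, Pta),
  methanogenesis proper (MCR subunits, Ftr, Mch, Mtd, Hmd, Mer, HdrB)
  and the Wood–Ljungdahl pathway (CODH/ACS subunits, Fdh family). The
  map is a judgement call shipped as an editable TSV; any
  `pfam_acc → pathway` table can be substituted.

## Fragment recruitment

The identity of a hit is **identical bases divided by the full read
length** (`compute_identity()`), *not* the usual aligned-span identity:
a short local alignment of a long read scores low by construction, so a
read must align near-globally to a close relative to approach 1. Hits
below 55% identity are discarded and reads at ≥ 90% are counted per
reference genome (both thresholds inclusive; the retention floor
follows the "below 55% discarded" convention, and a config switch can
flip to exclusive). Counts are read counts, so hits are reduced to the
best hit per (read, genome) first — ties broken by score, then lower
subject start, then genome id. Flooring before or after best-hit
selection is provably equivalent under best-by-identity selection and is
asserted by a property test. Outputs are the ranking table
(genome, n ≥ 90%, percentage of the smallest total), recruitment-plot
points (identity vs alignment midpoint, a recorded choice among
start/midpoint/end), and a 1%-bin histogram over [55, 100] whose last
bin is closed so 100% identity is counted; histogram counts are scaled
by `N_min / sample_total`, leaving the smallest sample raw.

External BLASTn hits enter via `read_blast6()`; identical bases are
reconstructed as `round(pident × length / 100)` and the read length is
taken from the read file, never the alignment span. The internal
aligner (`align_reads()`) uses exact non-overlapping k-mer seeds
(k = 15) on both strands with ungapped full-read verification; an exact
substring is guaranteed a 1.0-identity hit at the true coordinates. At
5% divergence and ~400 bp reads, the chance that all ~26 seeds of a
read are hit by an error is ≈ 1e-7, so effectively every read is
recovered, and every verified placement's identical-base count equals a
direct base-by-base comparison. `align_reads_exhaustive()` is the
quadratic reference implementation used to validate the seeded path on
small instances. Coordinates are 1-based inclusive externally
(outfmt-6 convention), 0-based internally in the simulator's
`truth_start`.

## Numerical and statistical choices

* Percentages are rounded half away from zero to two decimals
  (`round_half_up()`); base R's half-to-even would turn 0.285 into 0.28.
* All randomness in a call flows from one integer seed via a scoped RNG,
  so identical specs give byte-identical FASTA/FASTQ and identical
  pipeline manifests.
* Test tolerances for Monte-Carlo quantities are 3 standard errors with
  two calibration guards. First, when a replicate spread collapses to
  exactly zero (near-exhaustive rarefaction depths where every draw sees
  all taxa) the tolerance is floored at the rule-of-three bound
  `3/reps`, the upper confidence bound for an event never observed in
  `reps` trials. Second, where the checked quantity is a small expected
  count (≈ 0.25 reads below 90% identity in the recruitment
  validation), a ±3·SE normal band would cover only ~97% of seeds, so
  the suite asserts the calibrated equivalent: the observed count must
  lie in the central 99.7% region of its exact Poisson-binomial
  distribution, computed by direct convolution.
* Degenerate inputs are defined, not errors: zero reads give empty
  outputs and zeroed reports; zero GC variance removes nothing; an
  infinite z-cutoff is the identity; empty hit lists produce empty
  rankings.

## Problem sizes

The validation suite runs entirely on synthetic data sized for a
workstation: recruitment recovery uses 10,000 reads of ~400 bp against
a 100-kb reference at 5% divergence; QC recovery uses 5,000 reads from
a 2-Mb genome with a 10% duplicate rate; rarefaction is checked on a
100-read, 5-taxon toy profile with 200 replicates; aligner equivalence
on 50 reads × 5 kb. These sizes make the statistical checks sharp (the
binomial and hypergeometric oracles are exact at any size) while the
full suite completes in a few minutes.

## Known limitations

* The read simulator's length distribution and error model are
  idealized; no quality scores inform any stage.
* The GC-bias filter is an operationalization of a briefly described
  filtering step whose original details are not public; defaults are
  overridable and the report records exactly what was removed.
* The internal aligner performs no gapped extension; with indel-bearing
  reads (`homopolymer_indel_rate > 0`), placements downstream of an
  indel count as mismatches, exactly as the read-length identity
  statistic prescribes, but sensitivity drops relative to a gapped
  aligner.
* `unique_egts()` tests absence on the *observed* zero; it cannot
  distinguish true absence from insufficient depth — rarefaction curves
  are the companion diagnostic for that question.
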