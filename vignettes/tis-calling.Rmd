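---
title: "Calling translation initiation sites and measuring antigen ORF detection sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling translation initiation sites and measuring antigen ORF detection sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribotis)
library(dplyr)
```

## The problem

Harringtonine arrests initiating ribosomes at start codons while
cycloheximide freezes elongating ones, so ribosome-profiling libraries
prepared this way concentrate footprint signal on translation initiation
sites (TISs). Given such footprints aligned to a transcriptome, ribotis

1. calibrates **P-site offsets** per read length by metagene enrichment at
   annotated start codons,
2. converts reads to per-nucleotide **P-site count tracks**,
3. calls codon positions with statistically significant initiation signal
   using a **negative-binomial (NB) test** against a per-transcript
   background with transcriptome-wide FDR control,
4. extends each significant TIS to an in-frame stop and **classifies the
   ORF** relative to the annotated CDS (annotated, upstream, internal
   in/out-of-frame, downstream, lncRNA),
5. **matches a catalog of T-cell antigen ORFs** (epitope peptide plus
   encoding gene) against the per-sample calls, and
6. reports **class-wise detection sensitivity**, detection-count histograms
   across samples, and expression-stratified cross-tabs.

A first-class synthetic-data generator plants ORFs of every class with
known ground truth so each stage can be validated without access to
restricted sequencing data.

## The statistical model

### P-site offsets

For each read length $L$ with at least `min_reads_per_length` reads
(default 100), the offset $d^\*(L)$ maximises the number of reads whose
shifted 5' end $x + d$ lands on one of the three nucleotides of an
annotated CDS start codon, aggregated over all coding transcripts, with
$d$ searched over `search_window` (default 10–15 nt). Ties resolve to the
smaller offset, deterministically. The 3-nt target (rather than a single
nucleotide) tolerates ±1 jitter in digestion. The full score profile is
retained in the `profile` attribute for audit.

### The initiation test

Candidates are all positions whose codon belongs to the configured start
set — default ATG plus its nine single-substitution neighbours, since
upstream ORFs frequently initiate at near-cognates — and whose P-site
count summed over the codon's three nucleotides reaches `min_count`
(default 5). For each transcript, counts are binned per codon, bins within
`exclusion_radius` codons of any candidate are excluded, and the
background is summarised by its mean $\mu$ and a method-of-moments NB size
$\hat k = \mu^2/(s^2 - \mu)$, floored at 0.1; when $s^2 \le \mu$ the
Poisson limit is used. The candidate p-value is the NB upper tail
$P(X \ge \text{count})$.

**Multiplicity.** Benjamini–Hochberg correction is applied across the
whole sample with the multiplicity set to the number of *scanned*
codon-set positions, not just the prefiltered candidates. This choice is
deliberate: the count prefilter selects positions with large counts, so
the p-values of surviving candidates are conditionally inflated by
$1/P(\text{count} \ge \text{min\_count})$; dividing the BH budget only
among survivors would then inflate the false discovery rate, while
counting every scanned position (treating sub-threshold positions as
tests at $p = 1$) keeps BH valid and makes the prefilter a pure pruning of
hopeless tests. `mt_scope = "candidates"` exposes the narrower convention
for comparison. A site is significant when $q < \alpha$ (default 0.05).

### ORF building, classification and resolution

Each significant TIS is extended codon by codon to the first in-frame
stop; ORFs with no stop before the transcript end are kept and flagged
incomplete (they are excluded from mean-length summaries but not from
counts — discarding them would silently bias length statistics). The
initiator is reported as methionine regardless of a near-cognate start,
matching how such peptides are synthesised. No minimum ORF length is
imposed by default. Classification is purely positional; an
upstream-initiating ORF that runs into the CDS keeps class `upstream`,
with the overlap and its relative frame recorded separately, because
antigen catalogs may file the same ORF under `out_of_frame`. When one TIS
is carried by several transcripts of a gene, the in-frame ORF is
preferred, then the longest peptide, then the lexicographically smallest
transcript id.

### Antigen matching

Because published detection counts do not pin down whether detection
required the exact initiation nucleotide, both criteria are implemented:
`peptide_containment` (default) counts an antigen ORF as detected when any
significant ORF call on its gene contains the epitope as an in-frame
substring of the called peptide; `exact_tis` requires a significant call
at the expected TIS (± a tolerance, default 0). Matching never compares
class labels. Antigens sharing one encoding ORF are collapsed to ORF
level, and an ORF absent from a sample's genotype can never be detected
there (presence gating, enforced as an invariant of the detection
matrix). Percentages are rounded half-away-from-zero to one decimal, the
convention all reported figures follow.

## The synthetic study

`sim_config()` defines the conditions; generation is a pure function of
the seed.

* **Transcripts.** Coding transcripts have a random 5' UTR (90–240 nt), an
  ATG-initiated CDS (300–900 nt, multiple of 3, no internal in-frame
  stop) and a 3' UTR (60–200 nt); lncRNAs are length-matched and carry no
  CDS. Per transcript one ORF of each non-annotated class is planted by
  default: upstream ORFs wholly inside the 5' UTR (an option allows
  CDS-overlapping, out-of-frame uORFs), internal starts by writing a start
  codon at an in-frame or frame-shifted CDS position (rejecting writes
  that would truncate the annotated protein), downstream ORFs in the 3'
  UTR, and free-standing ORFs on lncRNAs. Ground truth records each
  planted TIS with the peptide and stop the final sequence actually
  encodes.
* **Expression** is log10-normal (default mean 1, sd 1 — roughly 0.1 to
  1000 RPKM), one value per gene.
* **Footprints.** Per-nucleotide P-site intensity is proportional to
  expression; the three nucleotides of each active TIS codon are
  multiplied by `initiation_enrichment`. The magnitude of
  harringtonine enrichment is not quantified in published protocols, so
  the default (50-fold) is a declared free parameter chosen to represent
  strong arrest; power analyses in the test suite use 20-fold.
  Counts are drawn NB with size `nb_dispersion`; each count becomes reads
  with lengths drawn from `read_length_weights` and 5' ends placed
  `offset_map[length]` nt upstream of the P-site. Run-off depletion of
  elongating ribosomes is modelled only as a uniform `background_scale`
  factor (no positional decay profile is published to emulate).
* **Dispersion default.** `nb_dispersion = 2` models the moderate
  positional overdispersion of counts within a single library (variance
  $\mu + \mu^2/2$). Much smaller sizes (e.g. 0.5) correspond to
  between-replicate biological variability; applying that noise to every
  position would give a 3-nt TIS sum a coefficient of variation of
  $\approx\sqrt{1/(3\,\text{size})} \approx 0.8$ even at infinite depth,
  i.e. a measurement process in which strong initiation sites routinely
  emit a small fraction of their expected signal — not how a single
  arrested-initiation library behaves.

What the generator does *not* emulate: splicing and genome-space
alignment, sequence-composition or ligation biases, sequencing errors,
multimapping, UMI duplication, and positional run-off decay. Passing
tests therefore demonstrate correctness of the statistical machinery on
an idealised library, not robustness to alignment artifacts.

## Validation design and problem sizes

The test suite validates every stage against independent oracles: a
hand-written codon table and 3-frame start-to-stop enumerator (ORF
building and translation on 100 random transcripts), brute-force pmf
summation (NB tails to 1e-9 over a mu/size/count grid), a manual BH
implementation, exhaustive candidate rescans, and read-count conservation
identities. Published ratios are reproduced exactly by feeding the
printed per-class counts through the report functions. Stochastic
properties use fixed seeds: type-I control runs 200 null samples
(20 coding transcripts, 30k reads each) and checks the mean false
discovery proportion against $\alpha + 2\,\mathrm{SE}$; power runs three
simulations (30 coding transcripts, 200k reads) at 20-fold enrichment
with all genes above 10 RPKM and requires ≥90% recovery of planted
annotated TISs; the expression association runs six samples at the
default log-spread expression and requires detection counts to rise
monotonically across the <1, 1–10 and >10 RPKM bins with a positive
Spearman correlation. These sizes were chosen to make each property
measurable with comfortable margins while keeping the default test run
fast.

## Worked example

```{r, eval = FALSE}
library(ribotis)

sim <- simulate_transcriptome(sim_config(seed = 1))
fp  <- simulate_footprints(sim)

offsets <- estimate_psite_offsets(fp, sim$transcripts)
tracks  <- psite_tracks(fp, sim$transcripts, offsets)
calls   <- call_tis(tracks, sim$transcripts, alpha = 0.05)
orfs    <- build_orfs(calls, sim$transcripts) |>
  classify_orfs(sim$transcripts)

catalog <- plant_antigens(sim, class_mix = c(annotated = 5, upstream = 3),
                          seed = 1)
dm <- detection_matrix(catalog, list(s1 = orfs))
detection_sensitivity(dm)
```

`run_pipeline()` drives the same stages from one schema-validated config,
writing per-stage TSVs and JSON provenance records, and
`inst/scripts/ribotis.R` exposes each stage as a shell subcommand.

## Known limitations

* The initiation test is a per-candidate NB tail test against a
  transcript-level background, not a regression with covariates; the
  module isolates it behind `test_tis_candidates()` so a GLM could be
  substituted.
* Overlapping reading frames convolve initiation signal: codons
  overlapping a strong TIS in another frame can reach significance at
  shifted positions. Matching by peptide containment is robust to this;
  exact-TIS matching is not.
* Offsets are global per read length, not per transcript or sample
  condition.
* Incomplete ORFs (no in-frame stop) are retained but their biological
  interpretation is ambiguous.
* The detection-sensitivity machinery assumes the catalog's epitopes are
  faithful substrings of the encoded peptides; it performs no HLA-binding
  or immunogenicity reasoning.
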