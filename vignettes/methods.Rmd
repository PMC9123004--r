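---
title: "Methods: MSI, TMB and structural-variant calling on a targeted pan-tumor panel"
author: "oncoprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSI, TMB and structural-variant calling on a targeted pan-tumor panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoprofiler)
```

`oncoprofiler` implements the analysis core of a targeted-panel
comprehensive genomic profiling workflow for solid tumors: microsatellite
instability (MSI) detection, tumor mutational burden (TMB) estimation,
in silico panel design, simplified structural-variant calling, and the
agreement statistics used to validate such assays. This vignette explains
the models, the tunable parameters and their defaults, the choices made
where the design was genuinely open, and what the synthetic-data generators
do and do not emulate.

## MSI from mononucleotide tract length distributions

MSI is read out from 68 mononucleotide repeat tracts of reference length
13–30 bp. Standard aligners misplace indels inside homopolymers, so tract
length is re-measured per read by local realignment: the exact 5' and 3'
anchor sequences (seeds, ≥ 8 bp) flanking the tract are located in the read
and the bases between them are counted. When an anchor matches more than
once (periodic anchors can be extended by flanking sequence), the
occurrences adjacent to the tract are used — the last 5' match before the
3' anchor and the first 3' match after it.

A read contributes a fragment to the tract's length distribution only if
all of the following hold, checked in order (the rejection reason records
the first failure):

1. the tract lies strictly more than 8 bases inside both read ends;
2. the measured indel is at most 12 bp from the reference length;
3. no single-base change occurs inside the realigned repeat segment
   (checked on the segment only, not the whole read);
4. mapping quality equals 60 (an exact, configurable value — the usual
   aligner maximum);
5. at most 20 bases of the read are soft-clipped.

Fragments are deduplicated by coordinates (read start, mate start, measured
offset); no molecular barcodes are assumed. The resulting error-corrected
histogram of indel offsets is scanned for alleles: an offset is an allele
when its count is a *strict* local maximum against all four neighbors at
±1 and ±2 bp, exceeds 5 distinct fragments (strict, i.e. ≥ 6), and holds at
least 8% of the absolute coverage. Absolute coverage is defined as the
total number of distinct eligible fragments at the tract — the only
self-contained denominator available. Ties between adjacent counts
disqualify both candidates, a deliberate bias toward calling stability.

A tract exhibits instability when an allele is ≥ 2 bp *shorter* than the
reference; insertions never mark instability. A sample is tract-level MSI-H
when more than 10 of the 68 evaluated tracts are unstable. Tracts with no
eligible fragments are reported non-evaluable rather than failing the
sample; whether the reference-length allele itself must be detected for a
tract to count is not specified anywhere, so any tract with at least one
eligible fragment is evaluated.

`select_tracts()` reproduces the panel-curation logic on labeled cohorts:
tracts are dropped when covered (≥ 20 fragments by default) in fewer than
80% of samples, when polymorphic across the MSS subset (more than one
distinct allele length observed — a specificity risk), or when their
unstable-call rates differ between classes by less than 0.2.

## The mutation-context signature

Mismatch-repair deficiency leaves a characteristic substitution-context
signature. Each substitution is canonicalized to a pyrimidine reference
(six classes C>A, C>G, C>T, T>A, T>C, T>G; purine events are
reverse-complemented together with their context) and scored against a
position weight matrix over the nine overlapping reference triplets inside
an 11-bp window centered on the mutated base. Matrix entries are
log-likelihood ratios of the triplet probability under an MMR-deficient
versus an MMR-proficient training catalog, each estimated per class and
position with additive smoothing.

Numerical choices:

* **Log base**: natural log, the log-odds convention. Any other base would
  rescale all scores and the fitted decision boundary jointly, so nothing
  observable depends on it.
* **Pseudocount**: 0.5 per triplet per position, keeping every entry
  finite; configurable.
* **Class conditioning**: matrices are class-conditional only; no shared
  background distribution is estimated.
* **Scope**: substitutions only; indels never contribute to the signature.
* The proficient-tumor catalog must exclude POLE/POLD1 hypermutators, so
  the matrices measure the MMR context signature rather than raw mutation
  load — the caller takes pre-filtered catalogs.

The per-sample signature score is the plain sum of per-substitution scores,
deliberately *not* normalized by mutation count (a per-mutation mean is
available as a diagnostic); an empty catalog scores 0. Windows containing
non-ACGT characters are skipped with a warning.

## The ensemble MSI classifier

The final call combines the fraction of unstable tracts with the signature
total on a 2-D plane via a maximum-margin linear boundary
(`fit_boundary()`, features standardized internally, soft-margin cost high
enough to behave as a hard margin on separable data; non-separable input
yields a soft-margin fit with a warning listing violators). When
per-sample flags for deleterious mutations in MMR genes (MLH1, MSH2, MSH6,
PMS2 — supplied as input annotation, never curated here) are available,
samples within a band around the initial boundary (default 10% of the
training margin; no value is published, so the band is configurable) are
relabeled by that flag before one refit. A sample is MSI-H when its
combined score is strictly positive; a point exactly on the boundary is
called MSS, favoring specificity.

## TMB estimation

Panel TMB is the count of eligible coding variants divided by the 1.3 Mb
of coding sequence evaluated. The eligibility filter keeps synonymous and
nonsynonymous variants alike with caller confidence above threshold, more
than 3 supporting observations, and MAF strictly above 5%, then removes:

* recurrent cancer-database variants (≥ 25 observations by default,
  mirroring the usual hotspot definition);
* common germline variants — population frequency ≥ 1% in any `pop_*`
  column (the databases are named in the assay description but no cutoff
  is, so 1% is the configurable default);
* private germline variants, flagged by allele fraction in
  [0.40, 0.60] ∪ [0.90, 1.00] without further evidence (again only the
  principle is published; the band is configurable).

Missing annotations never exclude a variant. The exome-equivalent value is
`eTMB = 10^(−0.944 + 1.397·log10(pTMB))`, with eTMB defined as 0 at
pTMB = 0 where the log model is undefined — a mutation-free panel must map
to zero burden. `fit_etmb_model()` re-derives such coefficients by ordinary
least squares on the log10–log10 scale and recovers them exactly on
noise-free data.

Clinical reporting uses tiered thresholds: 4 observations and MAF > 0.4%
for high-actionability variants, 6 observations and MAF > 5% otherwise —
the two endpoints of the published 0.4–5.0% range; intermediate tiers are
configurable. Deleterious BRCA1/BRCA2 variants bypass the germline
exclusion.

The limit of blank follows the CLSI EP17-A nonparametric convention:
sort the blank measurements, take rank `0.5 + 0.95·n`, interpolate
linearly between bracketing order statistics, clamp to the observed range.

## Panel-size simulation

`evaluate_panel_sizes()` rebuilds the panel-design experiment: random
panels are assembled by sampling exons without replacement until the
cumulative size first reaches the target (the last exon may overshoot;
rates use the realized size, which keeps the estimator unbiased), each
tumor's qualifying mutations (nonsynonymous, MAF ≥ 10%) are counted inside
the panel, and the panel mutation rate is correlated with the reference
exome TMB (qualifying mutations over a 33.4 Mb exome). Correlations are
computed per replicate and summarized per size by the median with a
5th–95th percentile band (the choice of summary is ours; only the
distributions are published). Population reweighting to the metastatic
case mix (lung 64.3%, colorectal 15.0%, melanoma 1.8%, bladder 1.6%, head
and neck 5.9%, liver 3.7%, gastric 2.6%, uterine/endometrial 5.1%) is
offered in two modes: weighted resampling of the cohort followed by a
pooled correlation (default), or a weighted mean of per-type correlations.

## Structural variants

Amplifications are called from normalized coverage against a
panel-of-normals baseline (≥ 2, routinely 20 control profiles). Per ROI,
the coverage ratio `r` is converted through the mixture model
`CN = (2r − 2(1 − p))/p` at tumor purity `p`, and fold change `CN/2` must
exceed a gene-specific threshold (externally configured; the shipped
default is 2) in more than 25% of evaluated ROIs. ROIs are masked when the
baseline is low or the deviation from it is insignificant under a z-test at
α = 0.01 (the filter is described qualitatively in the assay literature;
the test and level are our choice, and `alpha = NA` disables it). Purity
itself is estimated as twice the median clonal-variant MAF, clamped to 1 —
the diploid-heterozygous relation, the simplest estimator consistent with
"estimated from somatic sequence mutations"; it is documented and
swappable. With undetermined purity a gene that would pass at a
hypothetical 20% purity is reported indeterminate.

Translocations are called from read pairs that map more than 2 kb apart,
to different chromosomes, or in improper orientation (orientation-only
anomalies below 2 kb are included), after removing low-mapping-quality
reads. Fragments are deduplicated by coordinates and clustered within a
500 bp window (unpublished; configurable). A cluster is reported only when
both breakpoints are in annotated genes, the join maintains a coding
strand, the event is absent from the noncancerous control database, and at
least 5 distinct fragments support it (the published description names a
"fusion-specific read count threshold" without a value).

## Agreement statistics

`ppa_npa()` computes positive/negative percent agreement with explicit
`NA` (never 0) for undefined metrics. `wilson_ci()` implements Wilson's
score interval with a continuity correction, clamped to [0, 1].
`average_agreement()` enumerates every unordered replicate pair in both
directions (each replicate serving as reference once — the symmetric
APA/ANA convention; direction is unspecified in the source description)
and averages all defined directional agreements.
`variance_component_cv()` uses the closed-form nested-ANOVA method of
moments (site / operator / day, optionally instrument as its own
component, with within-run residual), truncating negative moment
estimates to zero; the design is assumed near-balanced, as precision
studies are, and REML via a mixed-model backend would be a drop-in
alternative we deliberately avoid for dependency-lightness.
`observed_dilution_purity()` and `clonality_score()` implement the median
MAF-ratio purity and median-MAF/purity clonality definitions.

## What the synthetic data emulates — and what it does not

The generators produce every input the callers consume, with truth
records:

* **Tract reads** (`simulate_tract_reads`): a tumor/normal mixture where a
  fraction `purity × unstable_fraction` of fragments carries a planted
  deletion, plus per-read ±1 bp slippage at a configurable stutter rate
  (symmetric by default, with a configurable deletion bias — real PCR
  stutter is deletion-biased and multi-step, which we do not model). Reads
  carry MAPQ 60 and clean CIGARs; base-level sequencing error, soft-clip
  artifacts and FFPE deamination are not simulated, so the read-level
  eligibility filters are exercised structurally rather than stressed.
* **Mutation catalogs** (`simulate_mutation_catalog`): window flanks are
  drawn i.i.d. from a per-signature base composition, so triplet
  probabilities at flank positions are analytic products and trained PWM
  entries have known expectations. Real mutational signatures have
  position-dependent, correlated context preferences; passing tests show
  parameter recovery and class separation under the model's own
  assumptions, not performance on real tumors.
* **Tumor cohorts** (`simulate_tumor_cohort`): types drawn from the
  metastatic weights; per-type log-normal TMB with median 4 mutations/Mb
  and log10-sd 0.6, melanoma and lung medians doubled — values chosen once
  as a realistic pan-cancer burden distribution with a heavy right tail
  (hypermutators up to ~100 mutations/Mb); mutations placed uniformly over
  a ~30 Mb exon catalog. Real cohorts have per-gene hotspots and
  covariation between type and clonality that this does not reproduce, so
  panel-size correlations on synthetic cohorts are upper-bound-flavored.
* **Coverage profiles and fusion reads** complete the structural-variant
  inputs with log-normal noise and planted events.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use a 4,000-tumor cohort with
10 random panels at 1.0 Mb (and 10 models per size across the 0.1–2.5 Mb
grid), and 10 dilution replicates per purity level at 5 levels × 68 tracts
× 500 fragments — sizes we consider sufficient for stable medians while
keeping a full run in the low minutes on one core. Peak-finder equivalence
is checked against brute force on 1,000 random distributions.

## Known limitations

* The caller is mononucleotide-only at runtime, as the final 68-tract
  panel is; the selection helper reasons about di-/trinucleotide tracts
  but the shipped classifier does not call them.
* Variant caller confidence scores are consumed as inputs; no re-scoring
  model is included.
* Published cohort-level results that depend on restricted clinical data
  (cross-validated correlations, the 829-observation precision study,
  per-gene PPA/NPA) are represented by property tests on synthetic data,
  not reproduced.
* The purity estimator assumes diploid heterozygous clonal variants;
  copy-number-altered or subclonal variant sets bias it low or high.
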