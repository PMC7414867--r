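---
title: "Genomic-scar HRD scoring and cross-platform agreement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic-scar HRD scoring and cross-platform agreement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdscar)
library(dplyr)
```

## The problem

Tumours deficient in homologous-recombination (HR) DNA repair — classically
through biallelic *BRCA1*/*BRCA2* inactivation — accumulate characteristic
chromosome-scale copy-number "scars". Three scar counts, computed from a
tumour's allele-specific copy-number segmentation, are summed into the HRD
score, and an HRD score of 42 or more conventionally classifies the tumour
as HR deficient, which is informative for platinum and PARP-inhibitor
therapy. The allele-specific segmentation itself comes from upstream callers
(ASCAT for SNP arrays, ascatNgs for whole-genome sequencing); this package
consumes their per-segment major/minor allele counts and does everything
downstream: scar scoring, HR classification, signal-quality metrics, a full
paired-platform agreement battery, and a synthetic paired-platform
generator so the whole analysis can be exercised and tested without access
to controlled patient data.

## The three scar components

All coordinates are 1-based and fully closed, the convention of the
segmentation tables we consume. Only autosomes 1–22 are scored. Allelic
imbalance (AI) means `n_major != n_minor`; loss of heterozygosity (LOH)
means `n_minor == 0` with `n_major >= 1` (a homozygous deletion retains no
allele and is not LOH).

* **NtAI** — the number of AI segments extending to a telomere. Per
  chromosome, only the first and the last segment of the profile are
  candidates; a candidate counts if it does not cross the centromere, does
  not span the whole chromosome, and is at least `ntai_min_len` long
  (default 0). Terminality is profile-relative: real segmentations rarely
  reach literal base 1, so "touches the telomere" is read as "is the outer
  segment of the profile". Whether the original scoring scripts applied a
  minimum segment length is not documented anywhere we could find; we
  default to none and expose the knob.

* **HRD-LOH** — the number of LOH regions strictly longer than 15 Mb that
  do not span a whole chromosome. Maximal runs of LOH segments are joined
  across zero-length gaps regardless of changes in `n_major` (`1+0`
  adjacent to `2+0` is one region), and across the centromere; runs are
  not joined across intervening non-LOH segments.

* **LST** — large-scale state transitions: breakpoints between two adjacent
  segments of different allele-specific state, each flank at least 10 Mb,
  with at most 3 Mb of genomic gap between them, counted per chromosome arm
  after smoothing. Smoothing iteratively removes segments shorter than 3 Mb
  (shortest first) and re-joins same-state neighbours separated by less
  than 3 Mb, until stable. We apply no ploidy-specific LST cutoff: the
  summed score is compared against the fixed threshold of 42, ties
  classifying as deficient.

The 15 Mb / 10 Mb / 3 Mb / 42 constants all live in `scoring_params()`, so
alternative conventions are one configuration away.

### Normalisation and the centromere

`normalize_profile()` drops chromosomes absent from the build, clips
segments at the centromere (bases inside the centromere interval belong to
neither arm and are removed), and merges gap-free same-state runs within
each arm side. Scoring is invariant to whether the caller normalised first:
internally NtAI and HRD-LOH are computed on a *coalesced* view in which
same-state segments are re-joined across zero gaps and across the
centromere, so a whole-chromosome event is recognised as such no matter how
the upstream caller (or our own normalisation) split it. The key
correctness property — splitting any segment into same-state pieces never
changes any score — is property-tested, and all three components are
checked against independent brute-force rule enumerators on random
profiles.

## Reference coordinates

The bundled GRCh37 build carries the 22 autosome lengths and one centromere
interval per chromosome, taken from the UCSC gap table and collapsed to a
single interval. No authoritative statement exists on which centromere
table upstream pipelines used; any consistent table preserves the score
semantics, and the asset is a swappable two-file TSV (`load_build()`).
`make_bins()` tiles the autosomes with fixed-width bins — at the default
10 kb this yields exactly 288,113 bins, the grid on which cross-platform
Log2-ratio comparisons are made.

```{r}
build <- load_build("GRCh37")
make_bins(build, 10000)$total
```

## Signal-quality metrics

For probe-level Log2-ratio tracks, `dlrs()` is the derivative Log Ratio
Spread: the standard deviation of differences between genomically adjacent
probes, divided by sqrt(2), so that for independent probe noise it
estimates the per-probe standard deviation. The phrase "standard deviation
of Log2 ratios" is sometimes used loosely for this quantity; the
non-derivative reading is available as `dlrs(track, plain_sd = TRUE)`.
`mapd()` is the robust counterpart (median absolute adjacent difference).
Differences never span chromosome boundaries — a choice we make explicit
because descriptions of MAPD rarely state it.

Cross-platform Log2 comparisons first project each platform onto the
common 10 kb grid (`bin_median()`): in segmented mode each segment
contributes its Log2 value once to every bin it overlaps (not
length-weighted — the simplest faithful reading of "values mapping to this
region"); in probe mode each probe contributes to the bin containing its
position. Per-bin medians use the usual midpoint convention for ties. Bins
without data stay missing and are excluded pairwise, never imputed.
`binned_deviation()` is the median absolute between-platform difference,
`binned_spearman()` the rank correlation over jointly covered bins. When a
segment table carries no Log2 column, segment values are derived as
`log2(max(n_major + n_minor, 0.5) / ploidy)`.

## The agreement battery

`build_agreement_report()` compares two platforms' score tables the way a
paired-platform method comparison is normally run:

* **Correlation and regression** (`pearson_with_regression()`): OLS of the
  array-like response on the WGS-like explanatory variable; for a simple
  regression R² is the squared Pearson r (asserted to 1e-12 in tests).
* **Bland-Altman** (`bland_altman()`): differences are WGS minus array;
  bias, 1.96-sd limits of agreement, t-based confidence interval of the
  bias, and limit confidence intervals with the `sd * sqrt(3/n)` standard
  error convention of the common Bland-Altman plotting implementations.
  With Gaussian differences the limits cover ~95% of pairs; a 10,000-pair
  simulation in the test suite checks 0.95 ± 0.03.
* **ICC(3,1)** (`icc3()`): two-way mixed, single measure, consistency form,
  `(MS_rows − MS_error) / (MS_rows + MS_error)` for two raters — a fixed
  between-platform offset does not reduce it. Cross-checked against R's
  `aov()` decomposition.
* **Fleiss kappa** (`fleiss_kappa_binary()`): chance-corrected agreement of
  the two platforms' deficient/proficient calls (for two raters this equals
  Scott's pi), with the standard large-sample z-test; exact small-sample
  inference is out of scope. Verified against a direct contingency-table
  computation over all 2×2 tables with cells up to 10.
* **Classification concordance** (`classification_concordance()`): percent
  agreement plus the discordant samples with both scores and the direction
  of disagreement.
* **Contribution comparison** (`compare_contributions()`): per-component
  percentage contributions to the HRD score, compared with a Wilcoxon
  signed-rank test between platforms (paired). For the HR-deficient versus
  HR-proficient grouping the samples are unpaired, so a rank-sum test is
  the statistically appropriate form and is what we run — reports that
  label that comparison "signed-rank" cannot be literally reproduced for
  unpaired groups, and we document the choice instead of guessing.
* **Distribution comparison** (`ks_compare()`): two-sample two-sided
  Kolmogorov-Smirnov with the asymptotic p-value (score counts are heavily
  tied, so the exact p is unavailable anyway).

No multiple-testing correction is applied anywhere; the battery reports raw
p-values, as such method-comparison analyses conventionally do.

## The synthetic paired-platform generator

`simulate_true_profile()` builds a ground-truth tumour genome on an
all-`1+1` diploid background by injecting three event classes with known
counts: interstitial LOH (`1+0`, Uniform(16, 40) Mb), terminal AI (`2+1` or
`3+1`, Uniform(5, 30) Mb, confined to one arm), and interstitial
state switches (`2+2`, Uniform(12, 25) Mb) whose two boundaries are LSTs.
Counts are Poisson with archetype means (15/12/12 for HR-deficient, giving
expected scores around 85; 1.5/1/1 for HR-proficient, around 8 — matching
the separation seen between clearly proficient and clearly deficient
tumours). Events are placed with 13 Mb clearance from each other, from arm
boundaries and from the centromere: comfortably above every rule margin, so
that under zero noise the truth's component scores equal the injected
counts exactly (LST is bounded below by the injected break count, since LOH
boundaries and long terminal AI events legitimately add transitions). Event
lengths and rates are artifact choices — no published values exist for
them.

`render_platform_view()` distorts the truth per platform: each event is
missed outright with probability `p_miss_event`; surviving breakpoints are
jittered by Gaussian noise (the telomere-anchored edge of a terminal event
is the edge of the data, not a breakpoint, and stays fixed); and spurious
breakpoints arrive as a Poisson process, each perturbing the allele state
(major allele incremented) over a run of 0.5–3 Mb. A fraction of the
spurious runs (10% by default) anchors at a chromosome end, reflecting the
concentration of coverage artefacts in poorly mappable subtelomeric
sequence; these create artefactual telomeric AI. This is the mechanism by
which the shallow-coverage presets inflate scores on average, reproducing
the direction observed when real WGS is downsampled: interior spurious runs
are mostly removed by LST smoothing (and occasionally disqualify a true
transition by widening its gap beyond 3 Mb), while telomeric ones add NtAI.

The shipped presets (`platform_presets()`) encode an array tier, a deep
(~70x) WGS tier and three downsampled tiers (~30x/15x/10x). Lower nominal
coverage never decreases the spurious-breakpoint rate or the probe-level
Log2 noise; the per-event miss probability stays flat across WGS tiers
because multi-megabase events remain visible at 10x — coverage loss
manifests as noise, not blindness. The array tier has a slightly higher
miss probability (limited dynamic range) and coarser breakpoint jitter.
Magnitudes were chosen once to give cross-platform agreement of the order
seen in real array-versus-WGS comparisons (correlations and ICC well above
0.9, concordance near 100%) and were fixed before being used in any
assertion about direction.

What the generator deliberately does *not* model: purity/ploidy
mis-estimation, subclonal (non-integer) copy number, read-level artefacts,
GC-content-dependent noise, and correlated breakpoint errors between
platforms. Passing agreement tests on synthetic cohorts therefore
demonstrates the correctness of the scoring and agreement machinery under
the stated noise model, not the field performance of any platform.

```{r}
cohort <- simulate_cohort(build, n_samples = 8, deficient_fraction = 0.5,
                          seed = 1)
report <- build_agreement_report(cohort$scores$array, cohort$scores$wgs70x)
glance(report)
```

## Numerical and design choices

* Coordinates: 1-based closed intervals everywhere; `n_minor > n_major`
  rows are swapped (with a warning), since allele labels are arbitrary.
* Non-integer copy numbers are rejected by default (`round_cn = TRUE`
  rounds half away from zero); the scar definitions are stated on integer
  allele counts.
* Gaps between segments are permitted and preserved; merging is never
  implicit outside the documented coalescing rules.
* LST smoothing removes the shortest offending segment first; this makes
  the iteration order deterministic. A segment of exactly 3 Mb survives
  smoothing (strict inequality), and the inter-flank gap rule is inclusive
  at 3 Mb.
* The HRD-LOH length rule is exclusive at 15 Mb (`> 15 Mb`), the LST flank
  rule inclusive at 10 Mb, both per their published definitions.
* Degenerate inputs: a score of 0 has all component contributions defined
  as 0; a constant input makes the Spearman correlation `NA` with a
  warning; single-category classifications make Fleiss kappa `NA` with a
  warning; identical paired contributions give a signed-rank p of exactly 1.
* Randomness: one global integer seed; per-sample and per-platform
  sub-streams are derived arithmetically from it, all below 2^31, and the
  caller's RNG state is restored afterwards.

## Problem sizes used in the shipped checks

The packaged tests exercise the scoring oracles on ~1,000 random toy-genome
profiles, the agreement oracles on all small 2×2 tables and 10,000
simulated Gaussian pairs, and the synthetic study at the 67-sample cohort
size over 20 replicate seeds for the agreement statistics, with 16-sample
cohorts over a few seeds for the coverage-tier direction check — sizes at
which every quantity stabilises well inside the asserted margins while the
whole suite stays quick to run.

## Known limitations

Scores are only as good as the upstream allele-specific segmentation:
purity/ploidy errors propagate directly and are not modelled here. The
terminality rule is profile-relative, so profiles truncated far from the
telomere can still contribute NtAI. The Fleiss kappa p-value is a
large-sample approximation, unreliable for very small cohorts. The
synthetic generator's noise model is mechanistic rather than fitted to any
real platform.
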