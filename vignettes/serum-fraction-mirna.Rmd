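---
title: "Methods: fraction-resolved circulating miRNA analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fraction-resolved circulating miRNA analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agomir)
```

## The measurement model

A qRT-PCR panel reports, for each miRNA *m* and sample *s*, the cycle
threshold Ct(*m*, *s*): the PCR cycle at which amplification fluorescence
crosses a fixed threshold. Ct is approximately log2-linear in template
amount — one cycle less means roughly twice as much input — so throughout
the package *expression* is the inverted Ct, `50 − Ct`, a log2-like scale
on which higher means more abundant. Measurements that never amplify, or
amplify at or beyond the instrument's reliable range, are *censored*: they
are flagged undetected and stored at the censor limit (default Ct 40).
Downstream estimators include censored entries at that stored value
(limit substitution). This keeps medians and group contrasts defined even
under heavy censoring, at the cost of biasing abundance toward the limit
for barely-detectable miRNAs; exclusion can be chosen instead where an
analysis warrants it, but the defaults favour always-defined statistics.

Samples come from distinct serum fractions of the same donors — whole
serum, an exosome-enriched precipitate, Ago1 and Ago2 RNA
immunoprecipitates (and their combination), and blood-cell fractions
(RBC, WBC, platelet) — annotated with the donor, the clinical group
(control, heart failure, or calibration), and the serum volume used for
the preparation.

## Normalization

Per-sample loading differences are removed by reference-subset mean
normalization: for a chosen set *N* of reference miRNAs,

`x(m, s) ← x(m, s) − mean_{n ∈ N} x(n, s) + G`,

where `G` is the grand mean over samples of the per-sample reference
means. The anchoring constant keeps normalized values on the inverted-Ct
scale, which matters because the differential stage applies an *absolute*
abundance gate (normalized median expression > 12): after pure centering
(`anchor = "none"`) such a threshold would be meaningless. The choice of
interpretation — treating the published abundance gate as a threshold on
anchored normalized expression units — is deliberate and configurable.

Two consequences are worth stating precisely. Normalization is
idempotent, and it is invariant to per-sample additive shifts *up to the
mean of the shifts*: a zero-sum pattern of loading differences is removed
exactly, while a common shift of every sample moves the anchored scale
with it (by design — absolute abundance information is retained). The
pure-centering mode is exactly invariant to arbitrary per-sample shifts.
Near the detection limit neither statement holds exactly, because
censoring clips shifted values at the limit; the invariance tests
therefore operate on fractions whose values sit well inside the detected
range.

Reference selection (`select_normalizers`) starts from a candidate list
and removes (i) miRNAs flagged as group-differential, blood-fraction
specific, or Ago-selective, (ii) candidates whose median raw Ct across
the in-scope samples exceeds 37.5 cycles, and (iii) candidates undetected
in any in-scope sample (the last because normalization refuses undetected
references rather than silently imputing them). The identity of the
reference set is data- and scope-dependent and is recorded in the run
manifest.

## Fraction specificity

Blood-cell specificity works on the single-donor RBC/WBC/platelet
profiles: an RBC call requires the miRNA to sit at or above the 80th
percentile (linear-interpolation definition) of the RBC profile *and*
exceed both the platelet and WBC expression by strictly more than 2
cycles; a WBC call requires the 80th percentile of the WBC profile and a
> 2-cycle margin over RBC only. There is deliberately no platelet rule.

Ago1-vs-Ago2 association is paired within donor:
`Δ_d = x(ago1, d) − x(ago2, d)` on normalized expression, summarized as
the signed fold change of the median Δ. Significance uses a paired t-test
on the Δs by default: with three calibration donors a rank test cannot
reach *P* < .05 (the smallest attainable two-sided signed-rank *P* at
n = 3 is 0.25), so a rank-based default would make the stage vacuous at
the design's own sample size; the Wilcoxon option remains available for
larger cohorts. A call further requires |median fold change| > 2
(strictly) and raw Ct < 37.5 in every in-scope sample. The signed
fold-change convention is negative-reciprocal: `d ≥ 0 → 2^d`,
`d < 0 → −2^(−d)`, so values never fall strictly inside (−1, 1) and a
1.8-fold down-regulation reads −1.8.

An alternative reading of "median fold change" — the median of per-donor
signed fold changes rather than the signed fold change of the median Δ —
is exposed as `fc_from = "median_fc"`; the default transforms the median,
which is the more robust of the two at three donors.

## Clustering

Samples are clustered on the 40 miRNAs with the highest coefficient of
variation (sd/mean across samples, ties broken by panel order), each
standardized to zero mean and unit variance, using
`d(i, j) = 1 − Pearson(i, j)` as the sample distance and average-linkage
agglomeration. Average linkage is the package default because no linkage
is canonical for correlation-distance expression clustering and average
linkage is the common choice; complete and single linkage are one
argument away. CV ranking operates on normalized expression by default
(configurable), and because Pearson correlation is invariant to
per-sample location shifts, the distance matrix is unaffected by that
choice of normalization anchor.

## Differential calling and scores

Within a fraction, each miRNA passing the abundance gate is tested
HF-vs-control with a two-sided Mann-Whitney test. At these group sizes
the test is exact: for untied data the exact U null distribution is used;
tied data (which arise, for example, in noiseless simulations) are
handled by enumerating U over all label assignments of the mid-ranked
pooled sample whenever `choose(n, n1) ≤ 2e5`, with the two-sided *P*
defined as twice the smaller tail, capped at 1 — the same convention as
the untied exact test. Beyond that enumeration bound the tie-corrected
normal approximation is used. A call requires |signed fold change| > 1.5
(strict, computed from group medians) and *P* < .05 on the raw *P*;
Benjamini–Hochberg q-values are reported alongside but never gate,
matching the stated selection criteria of the emulated design.

Composite scores sum normalized expression over a fixed marker panel with
signs: the Ago1-HF panel enters let-7a-5p with weight −1 because it is
down-regulated, and an unsigned sum would cancel part of the signal; the
literal unsigned summation is retained as `signed = FALSE`. Diagnostic
performance is summarized by the empirical ROC (HF positive, higher score
more positive, classification at `score ≥ threshold` over all distinct
scores), trapezoidal AUC — which equals the Mann-Whitney `U/(n₁n₂)`
identity, a property the tests verify against an independent pairwise
count — and the Youden-optimal operating point
(max sensitivity + specificity − 1, lowest threshold on ties).

## What the generator emulates

`default_study_config()` encodes the emulated study design: an 84-miRNA
panel; three calibration donors measured in whole serum, exosomes, Ago1,
Ago2, and Ago1+Ago2 RIP; one blood-cell control donor (RBC, WBC,
platelet); and a 10-control / 8-HF cohort measured in whole serum and
Ago1 RIP. Ct values are generated as

`Ct(m, s) = baseline(m) + offset(fraction) − carrier(m, fraction) −
hf(m, fraction)·[group = hf] + donor(s) + ε`,

with `ε ~ N(0, noise_sd²)` i.i.d. on the Ct scale and censoring at Ct 40.
One log2 unit of planted effect equals one cycle (the perfect-doubling
assumption). The defaults, chosen once as a realistic rendering of the
design and not revisited:

- **Fraction offsets** (cycles; larger = less abundant): serum 0,
  exosome 0.3, Ago1+Ago2 1.0, Ago2 1.5, Ago1 5.0, RBC −1, WBC and
  platelet 0.5. Ago1 is by far the least loaded fraction, and
  volume-adjusted global expression reproduces that ordering.
- **Carrier profiles**: five RBC-type miRNAs (miR-451a, miR-486-5p,
  miR-16-5p, miR-92a-3p, miR-25-3p) enriched in RBC (+6 log2) and carried
  by Ago2 (+3, with +2.5 in Ago1+Ago2 and +1.5 in serum/exosome); five
  WBC-type miRNAs (miR-223-3p, miR-150-5p, miR-155-5p, miR-142-3p,
  miR-146a-5p) enriched in WBC and carried by Ago1 (+3); five
  Ago1-preferring, five Ago2-preferring, and six vesicle-carried miRNAs.
  The planted Ago1-side and Ago2-side contrasts are balanced (27.5 log2
  units each) so per-sample mean normalization does not bias the paired
  Ago contrast. These interaction profiles, not the global offsets, are
  what drive the three-cluster sample structure (Ago1 | Ago2 & Ago1+Ago2
  | serum & exosome), since correlation distance is blind to per-sample
  constants.
- **HF effects** (log2, positive = up in HF): miR-222-3p +log2(1.7),
  miR-497-5p +log2(1.8), miR-21-5p +log2(1.6), let-7a-5p −log2(1.8) in
  the Ago1 fraction, each attenuated ×0.4 in whole serum with sign
  preserved — strong enough to keep the serum trend visible but (at the
  default noise) usually below the significance gate. The four
  serum-panel markers (miR-22-3p, miR-423-5p, miR-320a, miR-92b-3p) are
  planted up in both fractions (+0.8 log2 in Ago1, +0.5 in serum), sized
  so Ago1 discriminates better than serum; no effect sizes are published
  for these, only their relative performance.
- **Noise**: `noise_sd = 0.3` Ct per measurement (0.25 in the
  fold-change-recovery protocol), a plausible technical-replicate scale
  for serum qPCR; the emulated study publishes no variance estimates, so
  this is a modeling default, not an inference. The optional per-donor
  random effect defaults to 0.
- **Volumes**: serum 0.2 mL, exosome 0.5 mL, RIP fractions 1 mL, so
  log-additive adjustment to 1 mL adds log2(5) and log2(2) — the familiar
  ×5 / ×2 global-expression correction; the literal multiplicative mode
  is retained for figure reproduction.

What the generator does **not** emulate: donor-level biological
covariance between miRNAs (noise is independent across the panel),
PCR-efficiency differences between assays, spike-in recovery, plate or
batch effects, and any correlation between a miRNA's abundance and its
measurement noise. Passing tests therefore demonstrate that the pipeline
recovers what it assumes — planted additive Ct-scale structure under
Gaussian noise and censoring — not that real serum cohorts will behave
this way.

## Validation scale and numerical choices

The validation suites run at desk scale: fold-change recovery uses 200
simulated cohorts (median recovered signed fold change per Ago1 marker,
tolerance ±0.1 around the planted values); type-I control uses 1000 null
panels of 20 miRNAs (observed pass rate of the joint fold-change +
significance gate ≤ 5% + 1.5%; the joint gate is far more conservative
than its *P*-component alone); cluster-structure recovery uses 100 seeds
(three-way fraction separation at `k = 3` required in ≥ 95%); oracle
equivalence uses 100 random instances each for the exact Mann-Whitney
enumeration and the AUC–U identity. The acceptance script derives every
replicate seed from a single root seed.

Remaining numerical conventions: percentiles use R's default
linear-interpolation definition; CV ties resolve by panel order (stable
sort); `hclust` resolves distance ties deterministically by merge index;
Youden ties take the lowest threshold; strict inequalities are used at
every published threshold (a fold change of exactly 2, or 1.5, fails).

## Known limitations

The pipeline evaluates discovery and diagnosis on the same cohort, as the
emulated design does — there is no cross-validation, and AUC estimates
from 18 samples are optimistic and unstable. The abundance gate's
interpretation on the anchored normalized scale is one of two defensible
readings of "normalized median Ct > 12". With three calibration donors,
the paired t-test's normality assumption is unverifiable; its use is a
pragmatic necessity at that sample size. Censored entries contribute at
the detection limit, which attenuates fold changes for weakly expressed
miRNAs rather than excluding them.
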