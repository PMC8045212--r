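---
title: "Methods: CNV calling, CNVR mapping and case/control validation in cnvcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV calling, CNVR mapping and case/control validation in cnvcohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvcohort)
```

This vignette is the package's account of the models and procedures it
implements, the parameters that matter, the numerical conventions, and
what the synthetic-data validation does and does not establish.

## The measurement model

aCGH co-hybridises test and reference DNA and reports, per probe, the
log2 ratio of their intensities. Under ideal diploid arithmetic a
heterozygous deletion (one copy) gives log2(1/2) = −1.0 and a
single-copy duplication (three copies) gives log2(3/2) ≈ +0.58; diploid
loci sit at 0 plus measurement noise. The package assumes its input is
already normalised log2 ratios (the vendor extraction pipeline's job)
and makes no attempt to model dye bias, GC waves or mosaicism.

## CNV calling: a thresholded run-length scan

`call_cnvs()` declares a gain over a maximal run of consecutive probes
whose ratios are all ≥ `gain_threshold`, and a loss over a maximal run
all ≤ `loss_threshold`, keeping runs of at least `min_probes` probes.
Parameters:

* `min_probes = 3` — the classical minimum probe support for reporting
  an array CNV; one or two deviant probes are indistinguishable from
  outliers.
* `gain_threshold = +0.25`, `loss_threshold = −0.25` (log2 units) — a
  conventional aberration cutoff for arrays of this noise class. The
  literal reporting rule for such data ("above zero is a duplication,
  below zero a deletion") is noise-degenerate: with any noise, half of
  all diploid probes deviate from zero, and every third probe would
  seed a spurious run. Setting both thresholds to 0 ("sign mode")
  recovers the literal rule; it is intended for noiseless or
  pre-segmented input. In sign mode a probe exactly at 0 counts as
  neither gain nor loss (with nonzero thresholds, a probe exactly at a
  threshold qualifies — closed boundaries, so behaviour is deterministic
  at the cut).
* `max_probe_gap = NULL` — "consecutive" means adjacent in probe order;
  optionally a bp cap breaks runs across probe deserts (e.g.
  centromeres). Disabled by default to match the plain reading of the
  run-length rule.

Call boundaries are the first and last probe positions of the run, not
midpoints to the flanking probes: the simplest defensible convention,
and the one that makes downstream region lengths reproducible from the
call table alone. Consequently a call can never extend beyond the
outermost supporting probes, which slightly under-covers the true event
(about half a probe spacing per side, ~6.5 kb at 13 kb spacing).

## CNVR mapping

`build_cnvrs()` merges calls across samples into copy-number-variable
regions (CNVRs) as the connected components of the interval-overlap
graph: two calls belong to the same region if they overlap by ≥ 1 bp
(closed 1-based intervals), directly or through intermediates. This
union-merge is the standard CNVR construction; no reciprocal-overlap
fraction is imposed. Properties relied on by the tests: the regions on a
chromosome are pairwise disjoint, their total length equals the bp
union of the input calls, and re-merging the output is a no-op.

Region attributes follow the field's conventions: *shared* means ≥ 2
distinct samples contribute; the *trend* is `gain` or `loss` when every
contributing call agrees, `inconsistent` otherwise; singleton calls are
retained as unshared regions (so region counts interpolate between call
counts and the number of distinct loci).

Published maps sometimes split long merged fragments at internal
breakpoints. Because the splitting algorithm is rarely specified, the
package offers both behaviours: the default plain union, and
`split_mode = TRUE`, which partitions each merged component at every
distinct contributing call start/end so that sub-regions tile the
component exactly and inherit only the calls covering them. Which
variant a given published region count corresponds to generally cannot
be determined after the fact; analyses should state the mode used.

Sex chromosomes are excluded by default (`include_sex = FALSE`): in
mixed-sex cohorts, X/Y dosage differences between test and reference
swamp genuine CNVs. Summaries report genome coverage against the sum of
*autosomal* chromosome lengths, mean region length in kb, total in Mb,
and the gain:loss ratio counted over calls (not regions) — the ratio is
a statement about call abundance, and counting regions would erase
multiplicity. Percentages are reported on the 0–100 scale and rounded
half-up to 2 decimals; raw values are kept internally.

## Gene annotation

`annotate_cnvrs()` lists a gene for a region when their closed intervals
share ≥ 1 bp on the same chromosome, over the whole gene span
(exon-level resolution would overstate precision for events tens of kb
wide) and ignoring strand (dosage is strand-agnostic). BED input is
converted from 0-based half-open to 1-based inclusive on read. Interval
intersection is delegated to `GenomicRanges::findOverlaps()`; the tests
check it against an all-pairs scan. Pathway or disease enrichment is
out of scope: it depends on versioned external databases.

## qPCR copy number by comparative ΔΔCt

For TaqMan copy-number assays run in replicate (quadruplicate by
convention), `aggregate_replicates()` computes ΔCt = target Ct −
reference Ct per well, drops wells more than `outlier_ct = 0.5` cycles
from the sample's median ΔCt (median-based so a single wild well cannot
mask itself), and averages the survivors. A sample losing all wells is
flagged, never silently dropped. Then

cn = cn_calibrator × 2^(−ΔΔCt),  ΔΔCt = ΔCt_sample − ΔCt_calibrator,

so the calibrator self-calls at exactly its known copy number.
`categorize_copy_number()` integerises half-up (2.5 → 3; deterministic
at the boundary, unlike round-half-even) and applies the diploid rule:
< 2 loss, = 2 normal, > 2 gain. Estimates more than 0.35 from the
nearest integer are flagged low-confidence. Commercial callers add a
proprietary confidence model on top of the same comparative-Ct core;
only the core is implemented, which suffices for integer categories.
Efficiency-corrected (standard-curve) quantification is out of scope.

## Association statistics

* **Pearson χ²** — `sum((O−E)²/E)`, *no* continuity correction by
  default: published case/control tables are routinely the uncorrected
  statistic, and Yates' correction would change the printed values.
  It is available behind a flag. When an expected cell is < 5 a Fisher
  exact p is reported alongside, never silently substituted.
* **Odds ratio** — a·d/(b·c) with the Wald interval
  exp(ln OR ± z·√(1/a+1/b+1/c+1/d)) and z = 1.959964 (the exact 97.5%
  normal quantile; using 1.96 shifts bounds at the second decimal for
  small tables). Any zero cell triggers the Haldane–Anscombe +0.5
  correction, flagged; two zeros sharing a margin leave the OR
  undefined and raise an error.
* **Logistic regression** — maximum likelihood via IRLS (`glm`,
  binomial), categorical covariates referenced to their first level.
  The design matrix's rank is checked up front and collinear columns
  named. A fitted |coefficient| > 15 on the log scale is treated as
  (quasi-)separation and flagged; with all outcomes identical the fit
  is refused outright. Wald CIs per term; `exp(coefficient)` is the
  adjusted OR.
* **Mann–Whitney U** — rank sums with midranks, tie-corrected variance,
  0.5 continuity correction, two-sided normal p. This matches
  `wilcox.test(exact = FALSE, correct = TRUE)`; for groups smaller than
  ~6 the normal approximation is crude (deviations from the exact
  permutation p can exceed 0.2 with heavy ties) and an exact test is
  preferable — the package keeps the approximation because that is what
  standard software reports for cohort-scale tables.

Reported percentages round half-up (e.g. 15/297 → 5.1%).

## The synthetic-data module

The generators emulate the study designs above with known ground truth:

* `make_probe_map()` emits exactly `floor(length/spacing)` probes per
  chromosome; inter-probe gaps are exponential with the target mean and
  rescaled to the chromosome, approximating irregular array designs. At
  13 kb spacing a full hg19 genome yields a ~180k-array-scale map.
* `simulate_sample_array()` adds i.i.d. Gaussian noise (default sd
  0.15, a mid-grade array) to a piecewise-constant mean: the planted
  shift inside events (−1.0 loss, +0.58 gain by default — ideal diploid
  arithmetic), 0 elsewhere.
* `simulate_case_control_arrays()` draws event carriers per group
  frequency (12 case/control pairs by default) and records every
  planted event in a truth table. Planted regions must be disjoint per
  chromosome so per-sample truth never self-overlaps.
* `simulate_qpcr_plate()` encodes copy number in the target assay's Ct
  (reference assay centred at a fixed 25 cycles; the calibrator's ΔCt
  is an arbitrary fixed 1.0 — only differences carry information), with
  independent Gaussian Ct noise (default 0.1 cycles) on both assays of
  every well.
* `simulate_cohort_table()` draws carrier status and five covariates
  (gender, age, BMI class, blood-pressure class, diabetes history)
  independently within each group, with defaults matching a large
  validation cohort's baseline profile (297 cases / 260 controls,
  carrier frequencies 15/297 and 4/260, cases shifted toward high BMI
  and blood pressure). Because carrier status is independent of the
  covariates within groups, the true covariate-adjusted exposure OR
  equals the one implied by the two carrier frequencies — the joint
  model is exactly logistic-additive, with no non-collapsibility gap.

What the generators deliberately do **not** model: wave/GC artefacts,
dye bias, batch effects, probe-specific variances, mosaicism, qPCR
efficiency differences, covariate–exposure correlation. Passing
recovery benchmarks therefore shows the algorithms are correct under
clean-but-noisy conditions, not that real arrays of any vintage will
behave as well.

All generators take one integer seed and are bit-reproducible; the
pipeline derives per-stage sub-seeds from its global seed with a fixed
linear-congruential step, so stages are independently reproducible.

## Recovery benchmarks and their design

`evaluate_caller_recovery()` plants probe-aligned events of 8–10 probes
(both directions, frequencies 0.5 in cases / 0.25 in controls) on six
mid-sized hg19 chromosomes (~470 Mb, ~36k probes) for 12 pairs, and
scores recovery at reciprocal (Jaccard) overlap ≥ 0.8 against
same-sample, same-direction calls. Events are probe-aligned because the
caller's boundaries cannot extend past the outermost probes: with
arbitrary event boundaries the achievable Jaccard is capped below 1 by
boundary jitter, which would measure the probe grid, not the caller.
Gains (+0.58 shift, per-probe exceedance probability ≈ 0.986 at the
default threshold) are the binding case; losses at −1.0 are essentially
always recovered. A noiseless null array must yield zero calls.

`evaluate_qpcr_recovery()` runs 200 samples per true copy number 1–3 in
quadruplicate at 0.1-cycle noise. The ΔΔCt margins between adjacent
integer copy numbers are ≥ 0.4 cycles, i.e. ≥ 5 standard errors of a
quadruplicate mean, so near-perfect categorisation is the correct
expectation, not an optimistic one.

`evaluate_logistic_recovery()` simulates 500 cohorts of 297/260 and
fits the five-covariate model. Its default carrier frequencies are 0.5
vs 0.2 — odds 1 vs 1/4, true OR exactly 4 — rather than the rare-carrier
regime of the cohort generator's defaults. This is deliberate: a
parameter-recovery benchmark must operate where the Wald machinery it
checks is applicable. With ~15 vs ~4 expected carriers, the
arithmetic mean of the OR estimate is inflated by the log-normal-like
skew of exp(β̂) (E[exp(X)] ≈ exp(μ + σ²/2) with σ² ≈ 0.13 there), a
property of the OR scale rather than of the estimator's correctness.
Separately, the sparse BMI extreme class (expected count 1 in controls)
quasi-separates in a sizeable fraction of replicates; the benchmark
scores the exposure term, which remains well-behaved, and reports the
covariate separations rather than discarding those fits.

## Problem sizes and determinism in the shipped tests

The test suite simulates at reduced scale — toy chromosomes of 1–100 Mb
for unit tests, the ~470 Mb six-chromosome cohort for caller recovery,
200 seeds for frequency-calibration checks, 500 replicates for the
logistic benchmark — with all seeds fixed in the test code, so the suite
is deterministic. Oracles are independent implementations: an O(n²)
maximal-run scanner for the caller, pairwise union-find and
`GenomicRanges::reduce()` for the map, an all-pairs scan for
annotation, the algebraic 2×2 identity N(ad−bc)²/(row·col margins) for
χ², exact permutation enumeration for Mann–Whitney, and closed forms
for ΔΔCt and the Wald OR.

## Known limitations

* The run-length caller is intentionally simple; it is not a
  replacement for segmentation (CBS/HMM) on noisy real arrays, where
  its false-positive rate at ±0.25 and sd 0.15 is non-negligible (a
  three-probe fluke passes at ≈ 10⁻⁴ per probe triple).
* Region counts depend on the merge mode; cross-study comparisons of
  "number of CNVRs" are only meaningful with the mode stated.
* The qPCR module assumes equal amplification efficiencies of target
  and reference assays.
* The association module covers unmatched designs; conditional
  (matched-pair) logistic regression is out of scope.
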