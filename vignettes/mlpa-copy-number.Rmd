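---
title: "Copy-number calling and ligation-site indel genotyping from MLPA dosage ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number calling and ligation-site indel genotyping from MLPA dosage ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlpacnv)
```

## The measurement model

Multiplex ligation-dependent probe amplification (MLPA) measures gene dosage
with pairs of half-probes that hybridize adjacently on a target sequence.
Only when both halves anneal with a perfectly apposed nick can a ligase join
them, and only the joined probe amplifies; the fluorescence peak height is
therefore proportional to the number of target copies in the sample. The
*FCGR3B* promoter assay this package is built around uses three such probe
pairs in the promoter of *FCGR3B* — a low-affinity Fc gamma receptor gene on
chromosome 1q23 that exhibits common copy-number variation (CNV) — plus
three control genes (*CREBBP*, *EXT1*, *EP300*) chosen because their dosage
is expected to be constant at two copies.

The analysis chain is:

1. **Dosage ratios** (`compute_ratios()`): each target peak height is
   divided by the sum of the three control peaks of the same sample,
   cancelling sample-to-sample differences in DNA input and amplification
   efficiency. A sample whose control sum is not positive fails QC; it is
   kept in the output with a flag so that downstream accounting is
   auditable, but contributes to nothing else.
2. **Median anchoring** (`normalize_ratios()`): within each assay batch,
   each probe's ratios are rescaled so that the cohort median equals 2 —
   the assumption being that the median individual is diploid at the
   measured site. Ties and even counts use the midpoint of the two central
   values. The operation is idempotent and invariant to rescaling all peaks
   of one sample.
3. **Integer copy number** (`fit_cn_model()` / `predict()`): see below.
4. **Indel genotyping** (`derive_genotypes()`): see below.
5. **Association statistics** (`odds_ratio()`, `pearson_chi2()`,
   `mantel_haenszel()`, `allelic_test()`).

## The copy-number mixture

Cluster assignment of normalized ratios is formalized as a one-dimensional
Gaussian mixture. For K = 1..`max_cn`+1 candidate components the model is
fitted by EM (k-means++ initialization on the data, deterministic under the
`seed` argument) and K is selected by BIC, with ties of less than 2 units
resolved toward the smaller K. Two guards keep the likelihood honest:

* an absolute variance floor, `(1e-3 * sd(x))^2` by default, which keeps
  the likelihood finite on noiseless (degenerate) clusters; and
* a relative floor — no component variance may fall below 5% of the
  mixture's weighted-average variance — which prevents the classic
  spurious solution in which a single outlying point is captured by a
  near-zero-variance spike that wins BIC. The relative floor is inactive
  on noiseless data, where every variance sits at the absolute floor.

**Labelling.** The highest-weight (modal) component is anchored at CN 2,
consistent with the median-to-2 normalization, giving a provisional unit
spacing u = modal mean / 2. That anchor alone is wrong for a probe that
counts only a *subset* of copies: for the WT-only probe below, the modal
individual carries one countable copy, so after median anchoring its
clusters land at 0, 2, 4, ... and the naive rule would label them 0, 2,
4, ... Two refinements fix this reproducibly:

* the unit is re-estimated from the median spacing of adjacent non-zero
  component means whenever that spacing lies within [0.6, 2.5] of the
  anchor unit (spacings outside this band are sub-structure or skipped
  states and are not trusted); and
* if the final integer labels still share a common factor g >= 2, states
  are assumed adjacent and labels are divided by g.

Components whose mean is below 0.3 u are labeled CN 0 (homozygous
deletion); components whose labels collide are merged moment-matched with
a warning. A model that collapses to a single component is flagged
`no_cnv` (`is_no_cnv()`) and yields constant CN 2 calls — the behavior of
the third promoter probe in the reference assay, whose ratios show no
copy-number structure.

**Calling.** Ratios are assigned by the decision boundaries where adjacent
weighted component densities cross, which makes calls non-decreasing in
the ratio even with unequal variances; the posterior probability of the
assigned component is recorded, and calls below `posterior_threshold`
(default 0.9) are flagged low-confidence rather than suppressed. A ratio
exactly midway between two equal-variance, equal-weight components has
posterior 0.5 and is flagged.

## The ligation model and the -256A>TG indel

The reference assay's first probe behaves anomalously because a previously
unreported indel — deletion of the adenine 256 bases upstream of the
transcription start followed by a TG insertion, written -256A>TG — falls
exactly at its ligation site. `ligation_success()` models this with a
binary rule: ligation succeeds iff the `w` bases ending at the junction and
the `w` bases starting at it match the allele exactly and contiguously
(default `w = 10`, configurable; the package's tests exercise w = 4, 8,
10). Any substitution, insertion or deletion inside the 2w-base window
abolishes signal; variants outside it are tolerated. No thermodynamic
model (Tm, free energy) is attempted: nick-sealing failure is the modeled
mechanism, and the binary rule reproduces every qualitative behavior of
the assay — probe 1 is silent on indel-carrier copies, probes 2 and 3 are
unaffected.

`expected_probe_signal()` counts ligation-competent copies, so for an
individual carrying `wt` wild-type and `mt` indel copies, probe 1 reads
`wt`, probe 2 reads `wt + mt`, and their difference reads `mt`. That
algebra is the premise of the genotyper: `derive_genotypes()` sets
`mt = cn_total - cn_wt`, classifies individuals as WT>MT / WT=MT / WT<MT,
and marks physically impossible pairs (`cn_wt > cn_total`) invalid. Invalid
samples are reported and excluded from association tables — never
"repaired" — and `exclusion_report()` expresses them as a technical error
rate. Allele totals in `cohort_allele_table()` are sums of per-copy
counts, not twice the number of individuals, because CNV makes the total
allele count differ from 2n.

The bundled promoter reference (`synthetic_promoter()`) is a synthetic
stand-in: the published half-probe sequences are placed adjacently at
their declared junction coordinates and all other bases are deterministic
filler. Probe-binding sites and the indel context are faithful; the rest
of the sequence is not, and the object's id says so.

## Association statistics

Counts are compared with the conventions that match the reference
cohort's published analysis: odds ratios with Woolf (log-normal)
confidence intervals, the Haldane–Anscombe +0.5 correction when a cell is
zero, Pearson chi-square without continuity correction (2 df for the 3x2
genotype table), and the continuity-uncorrected Cochran–Mantel–Haenszel
statistic, whose single-stratum form is (N-1)/N times the Pearson
statistic. No multiple-testing correction is applied, matching the source
analysis. One caveat found while validating: the published allelic CI
upper bound (1.03) is the Woolf half-width exponentiated around the
*rounded* OR (0.82 x 1.253 = 1.03); the exact Woolf bound from the
unrounded OR is 1.024. The package reports the exact bound.

The published CI for the low-CN odds ratio (0.45–1.76 around OR 0.89) is
not a Woolf interval (it is most likely Cornfield, from the original
software); the package reports Woolf throughout and validates only the
interval that Woolf reproduces.

## The synthetic cohort generator

`sim_params()` defaults *are* the study conditions the package is
validated under, chosen once:

| parameter | default | meaning |
|---|---|---|
| `n_cases`, `n_controls` | 518 / 304 | reference cohort sizes |
| `cn_probs` | 1: 0.067, 2: 0.839, 3: 0.08, 4: 0.01, 5: 0.004 | control copy-number distribution; the high tail (9.4%) split 3:4:5 as mostly three copies with few 4–5-copy individuals |
| `class_or` | 1 | per-class case:control odds ratios (1 = null); case probabilities come from odds-rescaling the control distribution and renormalizing, so null and alternative runs share one code path |
| `mt_freq` | 0.407 | per-copy indel probability, i.i.d. across copies |
| `mlpa_cv` | 0.07 | lognormal sigma of multiplicative peak noise (dimensionless); the true dispersion of the reference data is unpublished, so this is a plausible assay CV, swept in tests rather than asserted |
| `ct_sd` | 0.15 | replicate Ct noise, cycles |
| `probe_behavior` | probe1 WT-only, probe2 all copies, probe3 no-CNV | per-probe read-out |
| `seed` | 1 | master seed; renders derive sub-seeds from it |

Peak heights are `signal x control_sum x exp(N(0, mlpa_cv))`, so the raw
ratio is centred on the true copy signal; zero-signal samples leave a
half-normal background peak proportional to the noise level (exactly zero
in the noiseless limit). The no-CNV probe always reads 2: the reference
assay's third probe could not be explained mechanistically, so it is
emulated phenomenologically, not modeled. qPCR target replicates follow
`baseline - log2(copies / 2)` with Gaussian cycle noise and a 0.5-copy
floor for zero-copy samples.

What the generator does *not* emulate: linkage between CNV state and the
indel (none is known, so per-copy indel status is independent), batch
drift beyond the per-assay median anchor, paralog cross-hybridization,
allele-specific amplification bias, and the heavy-tailed artifacts of real
capillary traces. Passing tests therefore demonstrate internal
consistency of the pipeline under its own noise model, not performance on
any real cohort; in particular the published qPCR-vs-MLPA correlation of
0.65 on 24 real samples is *not* reproducible from these simulations
(synthetic 24-sample runs give r near 0.95 at 0.15-cycle noise), and no
claim about it is made.

## ΔΔCt quantification

Relative quantities Q = 2^(-ΔCt) are anchored so the cohort mean copy
number is exactly 2, the convention of the reference analysis, rather than
to a designated calibrator sample; a `calibrator` argument provides the
textbook variant. Amplification efficiency is fixed at perfect doubling
(no efficiency correction was published). Replicates are averaged
arithmetically with a QC flag at replicate SD > 0.5 cycles and no outlier
rejection — a deliberately conservative reading. Platform concordance
(`correlate_platforms()`) correlates *continuous* qPCR estimates against
integer MLPA calls by default, since whether the original comparison
rounded first is unstated.

## Numerical choices and degenerate inputs

* EM: at most 500 iterations, relative log-likelihood tolerance 1e-8;
  candidate K capped at n/2 and at the number of distinct values, with a
  warning.
* BIC ties (< 2 units) go to the smaller K, favoring parsimony.
* Decision boundaries are found by root-finding between adjacent means
  and fall back to the midpoint for pathological weight/variance
  combinations.
* An explicit peak height of 0 is a biological zero (candidate homozygous
  deletion), never missing data; missing heights must be absent rows.
* A probe whose batch median ratio is nonpositive fails for that batch; a
  batch with no passing samples is an error.
* All simulator randomness derives from one integer seed; identical
  parameters give byte-identical cohorts.

## Problem sizes used by the test suite

The suite validates the statistics directly on the reference cohort's
printed counts (sub-second), the noiseless round trip on a full 518/304
cohort, noisy parameter recovery at n = 800 and CV 0.07, null calibration
on 500 simulated cohorts, and effect recovery (low-CN OR 2.0) over 200
replicates at the reference sample sizes. These sizes were chosen to make
sampling error small relative to the asserted tolerances while keeping
the whole suite around a minute.

## Known limitations

* Integer calls near cluster boundaries are flagged, not suppressed;
  downstream tables include low-confidence calls exactly as the original
  analysis included by-eye assignments.
* The unit-spacing labelling resolves, but cannot prove, the harmonic
  ambiguity of a probe whose clusters are evenly spaced with no zero
  cluster (ratios 2/4 could be one or two countable copies); the
  adjacent-states assumption is documented and matches the reference
  assay's behavior.
* Phase (which physical chromosome carries which copy) is unidentifiable
  from dosage data and is not modeled.
* ACPA-stratified machinery (`mantel_haenszel()` over strata) is provided,
  but no stratified reference values exist to validate against.
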