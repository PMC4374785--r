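---
title: "Methods: qRT-PCR screening analysis in ctscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qRT-PCR screening analysis in ctscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctscreen)
```

# The assay and its data model

ctscreen analyzes single-dose transcriptional screens read out by
quantitative RT-PCR on 384-well plates. Each well reports two threshold
cycles (Ct): one for the screened target transcript and one for a
housekeeping calibrator (GAPDH or B2M in the campaign this package models).
Ct is a log2-scale quantity — one cycle corresponds to one doubling of
template — which is what makes the arithmetic below exact.

A plate is described by two tables: a *plate map* (well → DMSO vehicle,
compound + concentration, or empty) and a *Ct table* (well × gene → Ct).
Reactions that never cross the detection threshold are exported by
thermocyclers as `Undetermined`; ctscreen right-censors them at the cycle
ceiling (default 55, the screening protocol's cycle count) rather than
dropping them. The rationale: a target reaction that fails outright is a
strong *downregulation* signal whose direction is worth preserving, whereas
a failed **calibrator** reaction invalidates the well's normalization
entirely — such wells are excluded at validation with a warning. This
censoring behavior is a design decision (instrument vendors do not
standardize it) and is surfaced in the `censored` flag of every Ct record.

# Relative quantification

For each analyzable well,

$$\Delta Ct = Ct_\text{target} - Ct_\text{calibrator}, \qquad
\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_\text{DMSO}, \qquad
\text{fold} = 2^{-\Delta\Delta Ct},$$

the Livak method with the plate's own DMSO wells as calibrator condition.
Under this sign convention upregulation gives negative ΔΔCt and fold > 1.
Screening write-ups sometimes print the subtraction in the opposite order
while simultaneously thresholding the Z-score at < −2 for *up*regulation;
the two are only coherent under the Livak order, which ctscreen therefore
adopts throughout. Two consequences are used as exact test invariants:
vehicle-well ΔΔCt averages zero by construction, and any additive
per-plate, per-gene Ct offset cancels identically.

The vehicle reference uses the **mean** ΔCt over all DMSO wells (not a
designated control well) and the **sample** (n−1) standard deviation, since
the null is estimated from a finite set of 32 wells. ΔΔCt is a constant
shift of ΔCt within a plate, so the DMSO ΔCt SD is also the ΔΔCt SD; the
Z-score is `ddct / sd`. A robust median/MAD alternative was considered and
rejected as the default because the screen's published criteria are
mean/SD-based; with 32 control wells the efficiency loss of MAD is not
justified absent evidence of control-well contamination.

# Hit calling

A compound well is a hit when all three criteria hold, with **strict**
inequalities (boundary values are non-hits, matching the literal "> 2-fold"
and "< −2" phrasing):

| criterion | default | unit | purpose |
|---|---|---|---|
| `fold > min_fold` | 2 | dimensionless | effect size |
| `ddct_z < max_ddct_z` | −2 | vehicle SDs | statistical depth |
| `−bound < calibrator_z < bound` | 10 | vehicle SDs | housekeeping sanity |

The calibrator gate reads "between 10 and −10" literally as the open
interval. Hits are always called per plate against that plate's own
vehicle wells — plates are never pooled, so plate-to-plate shifts cannot
masquerade as effects. Campaign-level calls reconcile the duplicate
replicates; the default rule `"both"` (hit in every replicate) is the
conservative choice for a triage funnel that feeds expensive confirmation
assays, and `"any"` is available where sensitivity matters more. No
multiple-testing correction is applied across the campaign: the screening
design controls false positives through the duplicate requirement and the
downstream confirmation cascade, not through per-well error rates.

# Dose–response confirmation

Confirmation series are fitted with the four-parameter logistic in Hill
form,

$$\text{fold}(d) = b + \frac{t - b}{1 + (EC_{50}/d)^{h}},$$

the default sigmoid of Prism-style analysis, by least squares over the
individual replicate points (no pre-averaging — fitting should use all
information; the MEC summary below averages per dose because it mirrors a
per-dose summary table). The optimizer is bounded Levenberg–Marquardt
(`minpack.lm::nlsLM`) with EC50 fitted on the log scale. Numerical
choices:

* **Initialization**: `bottom`/`top` from the mean response at the lowest
  and highest tested dose (this handles induction and inhibition
  symmetrically), EC50 at the geometric-mean dose, Hill slope 1, plus 5
  restarts with lognormally jittered EC50 and Hill; best RSS wins.
* **Bounds**: EC50 ∈ [min dose/100, max dose × 100]; Hill ∈ [0.1, 10].
  The bounds prevent pathological fits while still allowing extrapolated
  EC50s, which are flagged (`ec50_in_range = FALSE`) and warned about by
  `ec50()`.
* **Canonicalization**: the Hill slope is kept positive; inhibition data
  are represented by `top < bottom` rather than a sign-flipped slope.
* **Degenerate inputs**: series with zero response range skip the
  optimizer and return `converged = FALSE` with `ec50 = NA` — EC50 is
  unidentifiable on flat data, and an error would be the wrong interface
  for batch confirmation runs. Optimizer failure likewise never raises.
* At the fitted EC50 the curve equals `(bottom + top)/2` exactly; fits are
  equivariant under dose-unit rescaling. Both are exercised as test
  invariants, and fits are cross-checked against an independent
  grid-search oracle (coarse grid over log-EC50 × Hill with the linear
  parameters solved analytically per grid point).

The **minimal effective concentration** (MEC) is the lowest *tested* dose
whose per-dose mean fold reaches the threshold (default 2, `>=`
comparison); series that never reach it are reported inactive together
with their maximal mean fold, rendered `IA [max]` in summary tables.

# Landmark profiling

Expression matrices (GCT 1.2/1.3) are quantile-normalized
(`limma::normalizeQuantiles`: every column's sorted values are replaced by
the rank-wise mean across columns), log2-transformed, and summarized as
replicate-averaged log2 fold change (LFC) versus the vehicle samples of
the same timepoint stratum. Two-class contrasts (e.g. target-gene
inducers versus inhibitors) are ranked by the signal-to-noise ratio

$$s_g = \frac{\bar{x}_{A,g} - \bar{x}_{B,g}}{sd_{A,g} + sd_{B,g}},$$

the default marker-selection statistic of the GENE-E/Morpheus lineage of
tools; a Welch-type t statistic is available (`method = "tlike"`). Each
group SD is floored at `max(0.2 · |group mean|, 1e-8)` — the standard SNR
regularization — so near-constant genes cannot dominate the ranking
through vanishing denominators. Ties are broken by raw mean difference,
then gene label, making ranks a deterministic permutation.
Sample-permutation p-values are available (`n_perm`) but no pipeline
conclusion depends on them.

# What the simulators emulate — and what they do not

The generators exist because raw screening data of this design are
typically not deposited; they encode the campaign's *stated* design plus
explicitly assumed noise magnitudes:

| parameter | default | unit | status |
|---|---|---|---|
| wells per plate / DMSO wells | 384 / 32 | — | screen design |
| screening dose | 12 | µM | screen design |
| replicates per compound | 2 | plates | screen design |
| active fold at dose | 3.5 | fold | reported effect scale |
| baseline Ct target/calibrator | 24 / 18 | cycles | assumption (realistic) |
| `sigma_ct` | 0.25 | cycles | assumption |
| `plate_shift_sd` | 0.5 | cycles | assumption |
| `dr_cv` | 0.10 | CV | assumption |

Ct noise is Gaussian on the cycle scale (log-normal on abundance),
independent across genes and wells; plate effects are additive per gene —
chosen deliberately because ΔΔCt is provably invariant to them, which
turns the invariance into a testable property. Active compounds shift the
target Ct by −log2(fold), with the fold realized at the plated dose
through the compound's own 4PL curve; the calibrator is untouched unless
an off-target shift is requested (the knob that exercises the
calibrator-Z gate). Dose–response noise is multiplicative unit-mean
lognormal (`sdlog = sqrt(log(1+cv²))`, `meanlog = −sdlog²/2`). Profile
intensities are lognormal with N(7, 1) baseline log2 levels and N(0,
0.25) per-sample noise.

Passing tests on these simulations therefore demonstrate *algorithmic*
correctness and statistical calibration under the stated model — they do
not certify behavior on real plates, which additionally show spatial
(edge/gradient) artifacts, dispensing failures, amplification-efficiency
differences between primer pairs, and heavier-tailed noise. Spatial
correction (B-scores) and efficiency-corrected (Pfaffl) quantification
are out of scope by design.

All generators are pure functions of (parameters, seed); campaign plates
derive per-plate seeds from the campaign seed, so regeneration is
byte-identical.

# Validation studies and their problem sizes

The test suite runs four simulation studies, sized to give comfortable
Monte-Carlo margins while keeping the default run fast:

* **Parameter recovery**: 200 seeded dose–response datasets per reference
  curve (8 two-fold dilutions from 25 µM, triplicates, 10% CV); the
  median fitted EC50 must land within ±15% of the generating value (2.3
  µM for the target-induction curve, 3.3 µM for the LDL-uptake curve) and
  the median top within ±10% of 3.5.
* **Oracle equivalence**: 50 simulated plates with actives spanning folds
  1.5–4; every per-well `is_hit` must equal an independent brute-force
  evaluation of the three criteria from raw Ct values.
* **Null calibration**: a 20-plate campaign with no actives; the per-well
  hit rate must stay at or below the one-sided P(Z < −2) ≈ 0.0228 bound
  (the conjunction of criteria can only reduce it — the empirical rate
  is far lower because fold > 2 requires ΔΔCt < −1, about 2.8 vehicle
  SDs at default noise) within 3 binomial SDs, and vehicle ΔΔCt Z-scores
  must have mean ≈ 0 and SD ≈ 1.
* **Power**: 352 actives spiked at fold 3.5 across 8 plates under the
  duplicate rule must be recalled above 0.95. At default noise the
  per-well detection probability is ≈ 0.99 (the fold gate binds, not the
  Z gate), giving ≈ 0.97 expected recall for duplicates.

# Known limitations

* Single target/calibrator pair per analysis pass; multi-gene panels are
  run as repeated passes (the time-course and multi-cell-line analyses
  this supports are groupings of the same operation).
* No amplification-curve processing: Ct values are taken as exported.
* The 4PL fitter reports no confidence intervals; profile-likelihood
  intervals and 5PL asymmetry are out of scope.
* The run manifest records configuration and output digests but not
  timestamps — a deliberate trade so that re-running an identical
  configuration is byte-identical, which the tests assert.
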