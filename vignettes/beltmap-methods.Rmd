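---
title: "Methods: split-belt adaptation metrics and voxelwise brain-behavior mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: split-belt adaptation metrics and voxelwise brain-behavior mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beltmap)
```

# Overview

`beltmap` chains two analyses that are usually run with separate tools:
the behavioral quantification of split-belt treadmill adaptation
(per-step gait parameters → percent change → between-feet symmetry →
plateau), and mass-univariate structural brain mapping of the resulting
per-subject symmetry scores (voxelwise GLM → TFCE → permutation FWE →
atlas-labelled clusters). A synthetic-cohort generator with known ground
truth closes the loop, so every stage is validated by construction
rather than by eyeballing.

This vignette is the package's methodological record: the models and
their assumptions, the defaults and why they are what they are, the
numerical choices, and the limits of what the synthetic validation can
show.

# The behavioral model

## Trial structure and gait parameters

The paradigm walks a subject through baseline trials at a slow
(0.7 m/s) and fast (1.4 m/s) belt speed and then a *split* trial with
the left belt fast and the right belt slow. All ML quantities are signed
positive toward the slow-belt (right) side. Four per-step outcome
variables are computed at each heel strike, with marker values at event
times obtained by linear interpolation between samples:

* **CoM** — the ML position of the posterior-hip-marker midpoint, the
  package-wide CoM proxy, at heel strike (mm);
* **intCoPCoM** — the CoP−CoM ML displacement integrated over the
  striking foot's single-stance interval, by the trapezoidal rule on the
  recorded sampling grid (mm·s);
* **StepCoM** — striking-foot heel ML minus CoM at heel strike (mm);
* **StepLength** — leading minus trailing heel AP position at the
  leading foot's heel strike (mm).

Two definitional ambiguities had to be resolved. First, the stance
integral's reference: we compute the per-step integral from the trial's
own CoP and CoM-proxy traces, and the baseline-slow condition enters
only through the percent-change normalisation below; the choice is
recorded in each step-record table's `int_cop_com_reading` attribute.
Second, step attribution: each record is attributed to the foot that
strikes (the newly leading foot), and "slow stance" steps are
right-foot steps.

## Event detection

Heel strikes are detected as local maxima of a heel marker's AP position
relative to the hip-midpoint AP position — the foot is maximally forward
of the pelvis at contact. Candidates from the two feet are merged and
forced to alternate (of two consecutive same-foot candidates, the more
forward wins). No toe-off information is available from this marker set,
so the single-stance interval of the striking foot is taken from its
strike to the next contralateral strike; this includes the initial
double-support phase, a known approximation that is applied identically
to every step and condition. Externally detected event tables can be
supplied directly, bypassing the detector.

## From steps to one score per subject

For each parameter and foot, the split-condition series is converted to
percent change from the baseline-slow mean of the same foot,
$\Delta_k = 100\,(x_k - \bar b)/\bar b$ (an error is raised when
$\bar b = 0$). Symmetry pairs the $k$-th step of each foot by
within-condition ordinal — unmatched trailing steps are dropped — and is
the raw difference $s_k = \Delta_{slow,k} - \Delta_{fast,k}$, not a
normalised ratio; zero means symmetric, positive means the slow-stance
steps changed more.

The plateau of a series is the mean of its final 50 values, and the
series has *reached* plateau at the first index whose next 9 consecutive
values all lie within 2 SD of the plateau, where the SD is also taken
from the final 50 values (the rule names no other candidate, and this
makes the band self-consistent with the plateau estimate). Two readings
of the rule are possible — test only the single "next 9" window after a
candidate threshold, or scan every candidate forward — and we implement
the forward scan with the first qualifying index winning, which makes
tie-breaking deterministic. When the band SD is zero the criterion
collapses to exact equality; when no index qualifies, the series is
flagged as not reaching plateau and steps-to-plateau is the series
length. All three parameters (`n_last = 50`, `n_consec = 9`,
`k_sd = 2`) are configurable.

The **magnitude-at-plateau** of the split-condition symmetry series is
the per-subject behavioral score passed to the brain models; only the
split condition is scored, as that is where the group differences of
interest arise.

# The brain-behavior model

## Design matrices

Two model families answer two questions. *Q1* (shared association):
intercept, one column per behavioral score, group, sex, and TIV when the
metric is volumetric; the contrast puts unit weight on one score. *Q2*
(group interaction): intercept, group, sex (TIV when configured), and
for each score two group-split slope columns; the contrast is the young
minus old slope difference. All scores enter each model jointly, so
multiplicity across gait parameters is absorbed by the joint fit, and
the default score set is the three ML balance parameters (CoM, StepCoM,
intCoPCoM) with the regressor list fully configurable (the fourth
parameter, step length, can simply be added). Rank deficiency is
detected at build time and reported with the offending columns.

## GLM, TFCE, permutation

Each in-mask voxel gets the same OLS fit; the contrast t is
$t = c^\top\hat\beta / \sqrt{\hat\sigma^2 c^\top (X^\top X)^{-1} c}$
with $df = n - \mathrm{rank}(X)$. Voxels with numerically zero residual
variance are set to $t = 0$ and counted.

TFCE integrates cluster support across all thresholds,
$\mathrm{TFCE}(v) = \int_0^{h_v} e_v(h)^E\,h^H\,dh$. The exponents
default to the literature-standard volumetric choice $H = 2$,
$E = 0.5$ with 26-connectivity; only the enhancement toolbox and its
5,000-permutation default are prescribed by the study design, so the
exponents remain configurable. Two numerical schemes are provided:

* **exact** (default of `tfce_enhance()`): between consecutive voxel
  activation heights the component structure is constant, so each
  interval contributes $e^E (h_{hi}^{H+1} - h_{lo}^{H+1})/(H+1)$ in
  closed form — the $dh \to 0$ limit, with no discretisation error;
* **discrete**: the conventional Riemann sum at a step `dh`, default
  `max(|stat|)/100` chosen adaptively from the map. The permutation
  engine uses this scheme with `dh` frozen from the observed map and
  reused for every permutation, so observed and null enhancements share
  one quadrature and the discretisation bias cancels in the comparison.

Negative statistics are enhanced on the negated map and re-signed.

Family-wise error is controlled by the permutation distribution of the
image-wide maximum enhanced statistic under the Freedman–Lane scheme:
the response is residualized against the nuisance columns (all columns
with zero contrast weight), residual rows are permuted, the full model
is refit, and the maximum is recorded. The corrected p-value is
$p(v) = (1 + \#\{\max_j \ge \mathrm{TFCE}_{obs}(v)\})/(n_{perm}+1)$;
the two $+1$s are the unpermuted data counted as one member of the null
ensemble, which guarantees $p \ge 1/(n_{perm}+1)$. Two-sided inference
(the default) enhances both signs and takes the null maximum over both,
so the two-directional family is controlled at the nominal level
jointly. Permutation indices are a pure function of `(seed, n, n_perm)`;
when every distinguishable permutation can be enumerated the sampler is
replaced by exact enumeration with a warning. Whether the original
study's toolbox permutes this way is not documented; Freedman–Lane is
the scheme with the best general support and is stated here explicitly
so results are interpreted against it.

## Clusters and atlas labels

Significant voxels (`p < alpha`, default 0.05) are grouped into
connected components; each cluster reports its extent $K_E$, its
minimum-p voxel as peak (first in array order on ties), and the peak's
world coordinates through the NIfTI affine (0-based voxel convention).
Atlas labels on the same grid are attached as the percentage of cluster
voxels per label, suppressing labels under 5% (configurable), matching
the usual reporting convention.

# The synthetic cohort

The generator emulates the study conditions so that recovery is
checkable: two groups of 31 (younger) and 19 (older) subjects, female
proportions 17/31 and 10/19, per-parameter plateau-symmetry
distributions (% units) of

| parameter | younger | older |
|---|---|---|
| CoM | −4.6 ± 5.2 | −1.7 ± 6.0 |
| intCoPCoM | −63.3 ± 68.1 | 11.4 ± 51.9 |
| StepCoM | 29.0 ± 16.0 | 3.2 ± 23.4 |
| StepLength | 11.7 ± 8.0 | 16.6 ± 15.0 |

Each subject's drawn symmetry $s^*$ is split evenly between feet
($p_{slow} = +s^*/2$, $p_{fast} = -s^*/2$) and approached by a
dual-rate exponential transient — amplitudes $A_{fast} = 15$%,
$A_{slow} = 5$%, time constants 15 and 100 steps, opposite signs on the
two feet — plus i.i.d. Gaussian step noise (SD 3%). The functional form
is a modeling choice: the behavioral pipeline only requires that series
reach a plateau, and the dual-rate shape provides known ground truth
with realistic fast-then-slow dynamics. The number of steps per trial
is not part of the study record; the default of 600 split steps
approximates a 10-minute trial at about one step per second per foot,
with 120 baseline steps for the 2-minute baselines, and both are
documented assumptions. Baseline series fluctuate around the raw
baseline with no systematic asymmetry, so Δ and symmetry are
interpretable against zero. Raw step values are
$b\,(1 + \Delta/100)$ with per-parameter baseline magnitudes
(CoM 20 mm, intCoPCoM 30 mm·s, StepCoM 80 mm, StepLength 700 mm) chosen
as plausible scales whose only functional role is to be nonzero under
percent-change normalisation.

## Marker-level trials

`simulate_marker_trial()` renders a subject's step series as continuous
trajectories engineered for exact round trips: heel-strike times fall
exactly on the 100 Hz sampling grid (stride periods 1.4/1.2/1.0 s for
baseline-slow/split/baseline-fast); heel AP signals are antiphase
sinusoids peaking at the planted strikes plus a piecewise-linear
amplitude drift encoding per-step step length; hip markers straddle a
piecewise-linear CoM track through the per-step CoM targets; and the CoP
carries one triangular displacement pulse per single-stance interval
whose trapezoidal integral equals the target stance integral exactly.
In the zero-noise case the extraction stage reproduces the generator's
step-level truth to machine precision (the tests assert 1e-6 relative
tolerance). These trials validate the extraction code path; they are
not biomechanical simulations.

## Brain maps

`simulate_brain_maps()` produces per-subject volumes
`baseline + slope·score·1[voxel ∈ ROI] + nuisance + smoothed noise`,
with additive group and sex shifts, a slope on standardized TIV, and
Gaussian noise smoothed by a separable kernel
($\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$, truncated at $3\sigma$,
zero-padded). The maps stand in for preprocessed gray-matter intensity,
cerebellar volume, or FA-skeleton images; they share those maps' GLM
structure but none of their spatial statistics (no anatomy, no
tissue-dependent variance, no registration error).

# What the validation does and does not show

The test suite checks, among others: plateau detection against a
literal brute-force scan of the rule on 1,000 random series; recovery
of the configured plateau-symmetry distributions from a default-size
cohort; voxelwise t against the closed-form correlation t at 1e-10;
TFCE against the isolated-voxel closed form $h^3/3$ and against a
fine-step brute-force oracle (igraph components) on random 12³ maps;
family-wise error calibration on 200 pure-noise cohorts (n = 40, 10³
mask, 500 permutations) against the binomial band around 0.05; ≥80%
detection of a planted 27-voxel ROI effect at per-voxel R² ≈ 0.3
(n = 50, 1,000 permutations) with correctly signed peaks; and exact
atlas-overlap arithmetic including the 5% suppression rule. Problem
sizes were chosen as the smallest that make the statistical assertions
sharp.

Passing these tests demonstrates correctness of the algorithms under
the generator's assumptions — Gaussian i.i.d. step noise without
autocorrelation, exchangeable subjects, stationary smooth-noise brain
maps. Real motion-capture data have autocorrelated step series, missing
markers and event-detection ambiguity, and real brain maps have
spatially varying smoothness, which TFCE+max-statistic permutation
tolerates but the calibration here does not probe. Surface (vertexwise)
statistics, washout/readaptation trials and acquisition/preprocessing
are out of scope.

# Parameter reference

| parameter | default | unit | role |
|---|---|---|---|
| `n_last` | 50 | steps | plateau window |
| `n_consec` | 9 | steps | consecutive in-band steps to reach plateau |
| `k_sd` | 2 | SD | plateau band half-width |
| `H`, `E` | 2, 0.5 | – | TFCE exponents (volumetric standard) |
| `dh` | exact / max·0.01 | stat units | TFCE quadrature step |
| `connectivity` | 26 | – | voxel neighborhood |
| `n_perm` | 5000 | – | permutations (study default) |
| `alpha` | 0.05 | – | FWE threshold |
| `min_overlap` | 5 | % | atlas label suppression |
| `A_fast`, `A_slow` | 15, 5 | % | transient amplitudes |
| `tau_fast`, `tau_slow` | 15, 100 | steps | transient time constants |
| `step_noise_sd` | 3 | % | per-step noise |
| `n_steps_split` | 600 | steps | ~10 min split trial (assumption) |
| `fs` | 100 | Hz | marker sampling rate |
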