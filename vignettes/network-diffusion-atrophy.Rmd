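---
title: "Network-diffusion models of atrophy spread: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-diffusion models of atrophy spread: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atrophynet)
```

## The scientific question

In temporal lobe epilepsy (TLE), gray-matter atrophy is not confined to the
seizure focus: it appears in a stereotyped set of regions connected to the
mesial temporal lobe by white-matter tracts. Two mechanisms could produce
this topography:

* **Spread of activity (excitotoxicity).** Epileptogenic hyperactivity
  diffuses outward along tracts; each region's atrophy is proportional to
  the hyperactivity it accumulates over a lifetime of seizures.
* **Spread of atrophy (progressive degeneration).** Neuronal death at the
  focus deafferents connected regions, which then degenerate in turn; the
  atrophy front itself propagates, and the process is frozen at a finite
  "diffusion depth" at the time of imaging.

Both mechanisms reduce, at a macroscopic level, to the same linear
dynamics on the brain's structural connectivity graph — a network
diffusion driven by the symmetric normalized Laplacian. They differ only
in how the diffusing quantity is integrated into atrophy, and that single
difference has a testable signature. This package implements both models,
the group-atrophy derivation they are fitted to, the fitting sweeps, the
peak-versus-monotone comparison criterion, and a permutation null — plus a
synthetic connectome/cohort generator so that the whole pipeline is
validated end-to-end without any patient data.

## The models

Let $C$ be the $N \times N$ symmetric nonnegative connectivity matrix,
$\delta_i = \sum_j c_{ij}$ the weighted degrees, $\Delta =
\mathrm{diag}(\delta)$, and
$$\mathcal{L} = I - \Delta^{-1/2} C \Delta^{-1/2}$$
the normalized Laplacian with eigenvalues $0 = \lambda_1 < \lambda_2 \le
\dots \le \lambda_N \le 2$ and orthonormal eigen-modes $u_i$. Diffusion of
a quantity $x$ follows $\dot{x} = -\beta \mathcal{L} x$, with closed form
$x(t) = \sum_i e^{-\lambda_i \beta t} u_i (u_i' x_0)$.

**Model 1** integrates activity to $t = \infty$:
$$\Phi_1 = \sum_{i=2}^{K} \frac{1}{\lambda_i} u_i (u_i' x_0),$$
the partial eigen-mode expansion of the Laplacian pseudo-inverse applied
to the seed. **Model 2** integrates the diffusing degeneration only to a
finite depth $t$:
$$\Phi_2(t) = \sum_{i=2}^{N} \frac{1 - e^{-\lambda_i t}}{\lambda_i}
u_i (u_i' y_0).$$
Model 1 is exactly Model 2 at $t = \infty$ (for $K = N$), which yields the
model-comparison criterion: if the correlation between $\Phi_2(t)$ and
measured atrophy peaks at an intermediate $t$, the degenerative model is
the better description; if it increases monotonically toward the plateau,
the activity model is.

### Why the first eigen-mode is excluded

The $\lambda_1 = 0$ mode is $u_1 \propto \sqrt{\delta}$ — a uniform,
topography-free activation of the whole network. Its Model 1 integral
diverges, and its Model 2 closed-form term is the unbounded analytic
limit $t\, u_1 (u_1' y_0)$. Both models therefore exclude $i = 1$ by
default, which also preserves the exact $t = \infty$ equivalence between
them. For sensitivity analysis, `model2_atrophy(..., include_first_mode =
TRUE)` re-adds the analytic limit term; for Model 1 no finite surrogate
exists and the option is a documented no-op.

### Rate constants and units

The diffusivities $\beta$ (activity) and $\gamma$ (degeneration) only
rescale the time axis, and every reported statistic is a Pearson
correlation, invariant to positive scaling of the estimate. Both
constants are therefore fixed to 1: `t` is in units of $1/\beta$
(respectively $1/\gamma$) and is treated as dimensionless throughout.

## Measured atrophy

Group atrophy is the per-region unpooled two-sample t-statistic
$$s = \frac{\bar{x} - \bar{y}}{\sqrt{\sigma_x^2 / n + \sigma_y^2 / m}}$$
with $x$ the healthy controls and $y$ the patients, so positive $s$
means volume loss in patients. Sample variances use the $n-1$
denominator. $s$ is used as a spatial *pattern*, never for subject-level
inference, so no degrees-of-freedom correction is applied. Patients with
a right-sided focus are first mirrored by swapping homotopic region
columns (`side_flip()`), aligning every focus to the left ("ipsilateral")
hemisphere; the swap is an involution and preserves each subject's
multiset of volumes. ICV normalization (`icv_normalize()`) is available
but off by default — the synthetic cohorts need none.

## Fitting

* **Model 1** (`fit_model1`): the seed is fixed (by default ones on all
  temporal regions of both hemispheres); the single free parameter is the
  number of eigen-modes $K$, swept over $[2, N]$. The $K$ maximizing $R$
  wins; exact ties go to the smaller $K$ for reproducibility.
* **Model 2** (`fit_model2`): for each candidate seed region (all $N$ by
  default, or a subset such as the ipsilateral subcortical regions), a
  unit seed is swept over the diffusion-depth grid and the best depth is
  selected by `select_tcrit()`; the seed with the highest selected $R$
  wins, ties to the lowest region index.

The default depth grid is 900 evenly spaced points on $[0, 100]$ plus 100
on $[100.01, 500]$: dense where correlation curves peak, sparse on the
asymptotic plateau. $\Phi_2(0) = 0$ makes $R$ undefined at $t = 0$; it is
recorded as missing, not zero, so it can never masquerade as a minimum.

**Depth selection.** A global maximum at $t < 3$ is discarded — the
diffusion has not propagated meaningfully into the network — and the
highest strict discrete local maximum with $t \ge 3$ is taken instead.
The threshold is on the *value* of $t$, not on a count of grid points,
and is configurable (`t_min`). A monotone nondecreasing curve selects the
last grid point, flagged `"monotone"`; if the admissible region contains
neither a local maximum nor a monotone tail, the restricted argmax is
returned flagged `"boundary"`. Local maxima are strict and unsmoothed:
any smoothing choice would be an unstated reconstruction.

**Curve classification.** `classify_curve()` calls a depth curve
`monotone_increasing` iff $R(\mathrm{last}) \ge \max R - \varepsilon$
with $\varepsilon = 10^{-3}$ of the curve's $R$ range, else
`peak_at_intermediate_t`; a flat curve is monotone by convention and
flagged degenerate. This $\varepsilon$ is deliberately strict. A known
consequence, quantified during development and worth restating: under
measurement noise a truly monotone (Model-1-generated) curve acquires
interior bumps of order 0.1–2% of its range, so with noisy data the
classifier calls a substantial minority of Model-1 curves "peaked". The
classifier is therefore sharp evidence *for* Model 2 when data are clean,
but asymmetric under noise; the discrimination checks in the test suite
use noiseless planted patterns, where the $t=\infty$ limit law makes the
classification exact, and the noisy-regime asymmetry is documented here
as a limitation rather than silently absorbed into a looser tolerance.

**Per-eigen-mode correlations** (`eigenmode_correlations`) report
$|R(u_i, s)|$ for $i \ge 2$; the absolute value is used because an
eigenvector's sign is arbitrary, and all model quantities depend only on
the outer products $u_i u_i'$ (verified by sign-flip invariance tests).

**Log-scale correlation** (`log_estimate_correlation`) correlates
$\log(\Phi + c)$ with the measured atrophy as an outlier-robustness
check. The offset $c$ is 0 when the estimate is already positive;
otherwise the estimate is shifted so its minimum lands at the smallest
positive spacing of the shifted values — shifting by machine epsilon
instead would manufacture an extreme negative outlier at the minimum,
defeating the purpose of the check. No ordering between linear and log
$R$ is asserted anywhere: none is guaranteed.

## Permutation null

`permutation_null_model1/2` shuffle the measured atrophy uniformly over
all regions and re-run the *entire* sweep — re-optimizing $K$ or $t$
inside every permutation — recording the best $R$ per permutation.
Re-optimization makes the null conservative relative to fixing the
parameter (the fixed-parameter null is stochastically dominated; asserted
empirically in the tests on a shared permutation stream). Exceedance uses
strict inequality; because the literature defines the permutation p-value
both ways, the raw fraction $k/n$ and the add-one estimator
$(k+1)/(n+1)$ are both reported. The default is 1000 iterations with a
single documented RNG seed.

## The synthetic world

`synthetic_spec()` fixes the stated world once:

| parameter | default | rationale |
|---|---|---|
| `n_regions` | 86 | bilateral Desikan-Killiany-style parcellation: 43 per hemisphere (11 frontal, 5 parietal, 4 occipital, 9 temporal, 5 cingulate, 9 subcortical) |
| `n_healthy`, `n_patient` | 61, 29 | typical healthy / TLE-MTS cohort sizes |
| `true_model`, `true_seed`, `true_t` | model2, Hippocampus-L, 5 | hippocampal degenerative spread at a depth in the empirically plausible range |
| `kappa` | 0.2 | 20% volume loss at the seed, the scale of hippocampal atrophy in MTS |
| `baseline_range` | 3000–9000 mm³ | span of regional gray-matter volumes |
| `baseline_cv` | 0.05 | per-subject measurement variability of regional volumetry |
| `pattern_noise_frac` | 0.25 | per-patient heterogeneity of the atrophy pattern, 25% of the pattern SD |
| `frac_right` | 0.5 | even laterality mix, so side-flipping is actually exercised |
| `subcortical_boost` | 2 | subcortical structures are connectivity hubs |

The connectome generator draws continuous log-normal weights on a
bilateral modular skeleton (dense intra-lobe blocks, sparser inter-lobe
edges, always-present homotopic edges, sparse non-homotopic crossings),
guaranteeing a simple Laplacian spectrum with probability one, and
regenerates until connected. Two deliberate departures from pure
independence are worth flagging:

* **Homotopically symmetric baselines.** Baseline volumes are averaged
  with their homotopic partner. Real regional volumes are near-symmetric
  across hemispheres; with fully independent baselines, side-flipping a
  right-focus patient injects the left–right baseline difference into the
  group t-map and drowns the planted signal — an artifact of the
  generator, not a property of the pipeline.
* **Per-patient pattern noise.** The planted pattern is perturbed
  independently per patient, so heterogeneity averages out across the
  group, exactly like subject-level noise in real cohorts. Group-level
  (shared) perturbations are *not* simulated; a green recovery test
  therefore establishes robustness to subject-level noise, not to
  systematic disease heterogeneity.

What the generator does **not** emulate: tractography noise and false
tracts, subject-specific connectomes, spatially correlated measurement
error, multiple or distributed seeds, and any nonlinear or time-varying
dynamics. Green tests say the pipeline recovers its own generative
process — a necessary self-consistency condition, not evidence about
real cohorts.

## Numerical conventions

* Eigenvalues with $|\lambda| < 10^{-10}$ are treated as exactly zero;
  more than one zero mode means a disconnected graph, which warns with
  the component count. Fitting proceeds (the eigen-mode formulas remain
  valid per component) but additional zero modes are skipped in both
  model sums.
* Eigenvector signs are fixed by making the first component of magnitude
  $> 10^{-8}$ positive — purely for run-to-run reproducibility; every
  downstream quantity is sign-invariant, and the synthetic generator's
  continuous weights make repeated eigenvalues a probability-zero event.
* Asymmetric connectivity input is an error, never silently symmetrized;
  only float-level asymmetry (relative magnitude below $10^{-8}$) is
  averaged away.
* Region identity travels by explicit 0-based index shared between the
  atlas, matrix, and volumetrics files — never by name matching —
  because silent misalignment is the worst failure mode of this
  pipeline.

## Known limitations

* The peak-versus-monotone classifier is asymmetric under noise (see
  above): "peaked" verdicts on noisy data warrant inspection of the
  actual decline magnitude before concluding against the activity model.
* The t-statistic pattern has an intrinsic noise floor of order 1 per
  region regardless of cohort precision, so correlations reachable on
  cohort-derived data are bounded away from 1 even when the generative
  model is exact.
* Diffusion depth is dimensionless here; calibrating it to years would
  require longitudinal data the models are not fitted to.
* Directed or signed networks, nonlinear neural-mass dynamics, and
  connectome construction from diffusion imaging are out of scope.
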