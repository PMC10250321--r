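---
title: "Models and methods: viscoelastic creep, Hertz indentation, and chemotactic motility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: viscoelastic creep, Hertz indentation, and chemotactic motility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmech)
```

`cellmech` implements the three quantitative pipelines of a macrophage
mechanobiology experiment — micropipette aspiration, spherical
nanoindentation, and chemotaxis/wound planimetry — together with seeded
synthetic-data generators that let every fitting stage be validated by
parameter recovery. This vignette is the package's account of the models,
the numerical choices, and what the synthetic validation does and does not
demonstrate about real measurements.

## The standard linear solid and aspiration creep

A cell partially aspirated into a micropipette of radius $R_p$ under
constant pressure $\Delta P$ creeps according to the standard linear solid
(SLS): a spring $k_1$ in parallel with a Maxwell arm (spring $k_2$ in
series with dashpot $\mu$), the cell treated as a semi-infinite medium with
no wall corrections. The aspirated length is

$$L(t) = \frac{2 R_p \Delta P}{\pi k_1}
  \left[1 + \left(\frac{k_1}{k_1+k_2} - 1\right)
  e^{-k_1 k_2 t / \mu (k_1+k_2)}\right],$$

an instantaneous elastic jump to $2R_p\Delta P/\pi(k_1+k_2)$ followed by a
single-exponential rise to the plateau $L_{\max} = 2R_p\Delta P/\pi k_1$
with time constant $\tau = \mu(k_1+k_2)/k_1 k_2$. The three parameters are
therefore identifiable from three features of one curve: the plateau
($k_1$), the extrapolated jump ($k_1+k_2$, hence $k_2$), and the transient
rate ($\mu$).

`fit_two_point()` implements exactly that algebra, made deterministic and
noise-robust:

* $L_{\max}$ starts as the mean of the trailing 20% of samples
  (`plateau_fraction`), accepted only if the window's least-squares slope
  is below 1% of the transient rate scale $(L_{\max}-L_0)/\hat\tau$ —
  otherwise the fit is flagged `converged = FALSE` rather than returning
  silently wrong numbers.
* $L(0)$ is *not* read from the first frame (the pressure-application
  transient makes the first frames unreliable at ~1 s resolution); it is
  the intercept of the regression of $\log(L_{\max} - L(t))$ on $t$. That
  regression is weighted by $(L_{\max}-L)^2$, the delta-method weights for
  the log transform, so near-plateau points whose logs explode under noise
  do not dominate. With exactly two transient points the regression
  reduces to the classical two-point selection.
* The trailing mean is biased low by the unfinished transient (of order
  $e^{-8}$ of the amplitude on a $10\tau$ window), which matters when you
  ask for recovery at $10^{-6}$ relative. A residual-guarded fixed-point
  refinement removes it: alternate a linear fit of $L$ on
  $e^{-t/\hat\tau}$ (updating $L_{\max}$ and the amplitude) with the
  log-linear regression (updating $\tau$), keeping the lowest-residual
  state and stopping after three non-improving steps. On noiseless data
  this converges to the generating parameters; under noise the guard
  prevents the plateau/time-constant feedback from drifting.

`fit_nls()` is the statistically efficient refinement: Levenberg–Marquardt
least squares on $(\log k_1, \log k_2, \log\mu)$ (positivity is
structural), initialized from the two-point fit, with per-parameter
variances from the Jacobian. Calibration at 1% additive noise and 200
samples shows the division of labor plainly: the algebraic route pins
$k_1$ to a fraction of a percent but estimates $k_2$ and $\mu$ only to
~20–35% worst case, while the nonlinear fit recovers all three parameters
within 10% in every calibration replicate. Use `fit_two_point()` for
initialization and quick screens; report `fit_nls()` estimates.

Units are SI throughout (m, Pa, s); the file readers convert the
`time_s, length_um` columns and `# delta_p_pa= / # rp_um=` headers on
input (default pipette radius 3.5 um, i.e. a 7 um-diameter pipette),
because the creep equation is unit-consistent only in a coherent system.

## Hertz spherical indentation

A ferrule-top nanoindenter records load against tip position while driving
a spherical probe into the cell (defaults: spring constant 0.048 N/m,
5 um depth-controlled indents, 2 s loading). For a sphere of radius $R$
at indentation $\delta$,

$$F = \tfrac{4}{3} E^* \sqrt{R}\, \delta^{3/2},$$

with $E^*$ the reduced Young's modulus. Three numerical choices matter:

* **Tip size.** Probe datasheets quote a single "9 um" tip whose
  radius-versus-diameter convention is ambiguous, and either reading
  strains Hertz validity at 5 um depth. The default is
  `tip_radius = 9e-6` with the 4.5 um alternate one argument away; every
  analysis in this package pins the config it used. Since $E^* \propto
  R^{-1/2}$ at fixed data, the two conventions differ by a factor
  $\sqrt{2}$ — a systematic, not statistical, uncertainty.
* **Contact point.** The recording has no marked contact. It is found by
  exhaustive piecewise model comparison: for every candidate sample, fit
  (linearly) a constant baseline plus a $3/2$-power rise starting there,
  and keep the global least-squares winner — deterministic, with a
  no-contact error when the piecewise model fails to beat a flat baseline
  by 20% of its squared error. Calibration at 2% additive load noise
  places the detected index within ±5 samples of truth in >90% of
  replicates; sample-exact localization is impossible at that noise
  because the force within a couple of samples of contact is ~10⁻³ of the
  noise sd. The fitted modulus is insensitive to this slack (<5% error),
  because the deep part of the curve dominates the regression; a
  sensitivity test in the suite documents the monotone bias that a
  deliberately mislocated contact induces.
* **Fit range.** Only the loading segment is fitted (unloading carries
  viscoelastic hysteresis), over the full controlled depth by default
  (`depth_fraction` restricts it for Hertz-validity studies). The modulus
  is the slope of load on $\delta^{3/2}$ through the origin — a linear
  problem solved in closed form; the suite verifies it agrees with
  brute-force nonlinear minimization to $10^{-9}$.

The package reports $E^*$ and makes the Poisson conversion explicit
(`young_from_reduced()`, default $\nu = 0.5$) instead of conflating
reduced and Young's moduli. `aggregate_moduli()` reproduces the standard
reporting unit — per-group mean ± SEM over 20–30 single indents — with
non-converged fits excluded and counted.

## Chemotaxis metrics and wound closure

Tracked positions (µm, 3-min frames by convention, 1–6 h) with a declared
gradient axis yield per-cell metrics:

* **velocity** — curvilinear speed, total path length over elapsed time
  (µm/min). Tracking tools conventionally report curvilinear speed; the
  straight-line alternative is exposed as `fmi_velocity`.
* **directionality** — the net displacement projected on the gradient
  axis, divided by path length: a signed chemotactic index in $[-1, 1]$,
  bounded and dimensionless, matching the plotted range semantics of
  chemotaxis panels. The forward-migration-index-per-time alternative is
  `fmi_velocity`. A stationary cell is defined to have directionality 0.

Tracks shorter than 5 frames are excluded from cohort summaries (flagged
and counted) because both metrics are unstable there; the threshold is an
argument. Times stay in minutes and positions in µm end-to-end — the
units the instruments export — rather than converting to SI and back.

Wound planimetry is a single normalization: area on each day as a
percentage of the day-0 area, exactly 100 at day 0.

## The synthetic-data generators

The generators define the package's study conditions:

* `simulate_creep()` — the SLS forward model on an even grid (default
  200 points over $10\tau$) plus noise. Default noise: additive Gaussian
  at 2% of the signal ceiling, a typical optical-tracking precision; true
  instrument noise magnitudes are not published, so this is a calibration
  choice, flagged as such.
* `simulate_indentation()` — flat zero-load baseline (50 samples over
  0.5 um of pre-contact travel) then Hertzian loading to the controlled
  depth (200 samples), with the contact index recorded as ground truth;
  raw mode emits (piezo, deflection) channels that `reduce_raw()` inverts
  exactly.
* `simulate_trajectories()` — a biased persistent random walk: each step
  is a drift component `drift_fraction * speed_scale * step_time` toward
  the source plus an AR(1)-heading random component (coefficient
  `persistence`, default 0.5; macrophage tracks are visibly persistent,
  so pure Brownian motion would be the wrong null), scaled so the mean
  random step length is `(1 - drift_fraction) * speed_scale * step_time`.
  The expected curvilinear speed equals `speed_scale` exactly at
  `drift_fraction` 0 and 1 and is approximate (within ~30%) between,
  since the mean norm of a sum is less than the sum of mean norms.
* `simulate_cohort_mechanics()` — between-cell variability drawn
  log-normally around group means (moduli are positive with heavy right
  tails — reported SDs approach the means — so a Gaussian would be
  wrong), with `cv` the coefficient of variation; `cv = 0` collapses to
  identical cells.

All generators are seeded (bit-identical for a fixed seed), match their
forward models exactly at zero noise, and attach ground truth as an
attribute so recovery is assertable mechanically.

**What passing recovery tests shows — and does not.** The generators
reproduce the *statistical* structure each fitter assumes: exponential
creep with stationary noise, a clean power-law loading curve, independent
per-cell parameters. Real recordings add what the generators omit:
pressure-application transients, cell–pipette friction, viscoelastic
(rate-dependent) indentation response, substrate and bottom effects,
tracking errors and cell division in trajectories. Passing recovery at
these conditions therefore validates the estimators' correctness and
precision, not the adequacy of the SLS or Hertz models for any particular
cell.

## Problem sizes and reproducibility

The validation suite uses desk-scale problems chosen to make sampling
error negligible relative to the tolerances tested: 50–1000 parameter
sets for noiseless identities, 200-curve cohorts for modulus recovery
(cohort-mean standard error ~0.2% at 3% per-curve noise, against a 3%
tolerance), 100 seeded repetitions for the two-cohort comparison, and
500 tracks for the unbiased-directionality calibration. Every stochastic
step takes an explicit seed, and `write_results()` emits a JSON manifest
(package version, seed, config echo, input checksums) sufficient to
reproduce a run byte-for-byte.

One statistical caveat is worth stating: the two-cohort comparison
property asks that an unchanged $k_2$ be flagged *not* significant at
$\alpha = 0.05$ in ≥95 of 100 repetitions, but 5% of repetitions are
expected to reject by construction — the bar sits exactly at the type-I
boundary, so occasional counts of 94 under reseeding are sampling noise,
not regression.

## Known limitations

* No image analysis: inputs are pre-extracted lengths, curves, and
  coordinates.
* No half-space corrections for aspiration (wall thickness, fillet
  radius) and no bottom-effect correction for indentation.
* The Hertz fit assumes elastic response; fitted moduli from a
  viscoelastic cell are loading-rate-dependent effective values.
* The directionality definition follows the bounded chemotactic-index
  convention; tools that report forward migration index per time will
  differ by a factor with units.
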