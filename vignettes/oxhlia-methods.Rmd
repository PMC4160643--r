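---
title: "Time-dose modelling of oxidative hemolysis kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-dose modelling of oxidative hemolysis kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxhlia)
```

## The assay and the model

In the oxidative hemolysis inhibition assay (OxHLIA), erythrocytes are
exposed to peroxyl radicals generated by thermal decomposition of AAPH;
the fraction of intact cells is followed over time, usually by turbidity
in a 96-well plate read every 10 min for about 3 h. An antioxidant delays
the lysis wave; a prooxidant, a surfactant, salt or temperature shifts it
in other characteristic ways. The raw endpoint traditionally reported is
the delay of the hemolytic half-life, $\Delta t = \tau_S - \tau_C$.

`oxhlia` models the surviving population $P$ (percent, 0–100 scale) with a
Weibull survival kinetic reparameterized so the half-life is an explicit
parameter:

$$P(t) = K \exp\!\left[-\ln 2 \left(\frac{t}{\tau}\right)^{\alpha}\right],$$

where $K$ is the asymptote (percent of the population that is ultimately
lysed; in an open system with excess initiator, 100), $\tau$ the time at
which survival has dropped to $K/2$ (minutes), and $\alpha$ a
dimensionless shape parameter: $\alpha < 1$ gives power-law-like decay,
$\alpha = 1$ first-order decay, $\alpha > 1$ the sigmoidal profiles
observed in practice. By construction $P(\tau) = K/2$ for every valid
triple, which is what makes $\tau$ directly and robustly estimable.

### Derived parameters

With $G = (\alpha-1)/\alpha$, closed forms give the other quantities used
to characterize a curve:

* rate at the half-life: $v_\tau = K\alpha\ln 2 / (2\tau)$ (percent/min);
* maximum hemolysis rate:
  $v_m = (K\alpha/\tau)\,(\ln 2)^{1/\alpha} G^{G} e^{-G}$;
* lag phase:
  $\lambda = \tau (\ln 2)^{1/\alpha}\left[G^{1/\alpha} +
  \dfrac{e^{-G}-1}{\alpha G^{G} e^{-G}}\right]$ (minutes);
* time of maximum rate: $t^* = \tau (G/\ln 2)^{1/\alpha}$.

$v_m$, $\lambda$ and $t^*$ exist only in the sigmoidal regime
($\alpha > 1$); `derived_kinetics()` returns them as explicit `NA`s with
`defined` markers otherwise, so report generation never branches or
throws. The formulas are validated in the test suite in two independent
ways: against a dense finite-difference derivative of $P$ (maximum rate,
its location, and the rate at $\tau$), and against the published trolox
reference table bundled as `trolox_kinetics()`, every cell of which they
reproduce within final-digit rounding of the printed inputs.

A lag phase can also be defined geometrically, as the intersection of the
tangent at the inflection point with the plateau $P = K$. That
construction yields a different multiplier
($(\ln 2)^{-1/\alpha}$ in place of $(\ln 2)^{+1/\alpha}$, about 46.8 min
instead of 39.92 min for the reference control curve). This package
implements the convention above because it is the one the reference
values follow; the discrepancy is noted here deliberately and not
resolved.

### Reparameterized forms

Three alternative parameterizations make $v_m$, $v_\tau$ or $\lambda$ an
explicit fitted parameter, so its confidence interval comes straight out
of the fit instead of requiring error propagation. Rather than carrying
separately typeset formulas for each form, `oxhlia` evaluates them by
exact closed-form inversion: the half-life implied by the explicit
parameter is recovered (`tau_from_vm()`, `tau_from_vtau()`,
`tau_from_lag()`) and the native form evaluated with it. This guarantees
the round-trip identity — all four forms are pointwise identical curves
and reach identical least-squares optima — which the test suite asserts
to $10^{-8}$ relative error on randomized parameters and to $10^{-6}$ on
fitted SSE.

## Effector modifiers and the bivariate surface

An effector at level $e$ perturbs a parameter $\theta$ multiplicatively,

$$m_\theta(e) = \theta_C\,[1 + f(e)],$$

leaving the control value $\theta_C$ (and its statistical meaning)
intact. Four phenomenological shapes for $f$ cover the perturbations
reported across hemolysis assays:

| shape | form | typical effector |
|---|---|---|
| linear | $L(e) = l_1 e + l_2$ | antioxidant dose on $\tau$, $\alpha$ |
| hyperbolic | $H(e) = h_1[1 - \exp(h_2 e)]$ | prooxidant (AAPH) on $\tau$ |
| sigmoidal | $S(e) = s_1 \exp[-\ln 2\,(e/s_2)^{s_3}]$ | surfactant/NaCl |
| bell | $B(e) = b_1 \exp\!\big\{\frac{b_3}{b_2}[1 - r + \ln r]\big\},\ r = (e/b_4)^{b_2}$ | temperature |

Substituting the modified parameters into the kinetic model gives the
bivariate surface fitted simultaneously to a whole panel:

$$P(t, e) = m_K \exp\!\left[-\ln 2 \left(\frac{t}{m_\tau}\right)^{m_\alpha}\right].$$

Two design choices deserve comment.

**The bell form.** The literature states the bell modifier's defining
properties (maximum $b_1$ attained at $e = b_4$, $b_2$ width-related,
$b_3$ asymmetry-related) more reliably than its exact algebra. `oxhlia`
uses the asymmetric log-bell above, which satisfies all of them
analytically: its exponent vanishes at $e = b_4$ (so $B(b_4) = b_1$
exactly) and its derivative changes sign only there for $b_2, b_3 > 0$.
This exact algebraic form is a documented package choice; anyone
comparing coefficients fitted by other software should check which bell
was used.

**Linear intercepts.** For antioxidant panels the intercepts $l_2$
default to 0 (fixed), so $f(0) = 0$ and the control curve anchors the
surface exactly; published potency tables report only slopes, consistent
with this. `free_l2 = TRUE` frees them when the zero-dose curve should
not be privileged. Similarly, $K$ carries no modifier in the antioxidant
preset: with excess initiator, hemolysis is eventually complete at every
dose, so an apparent dose effect on $K$ would signal a normalization
problem rather than chemistry.

Modifiers may also target a derived parameter ($v_m$, $v_\tau$,
$\lambda$): the control derived value is perturbed and the implied
half-life recovered in closed form, with $K$- and $\alpha$-modifiers
applied first. The `temperature-B` preset uses this to put the bell on
$v_\tau$, whose temperature optimum is the biologically meaningful
quantity.

## Estimation and inference

Parameters are estimated by unweighted nonlinear least squares —
matching the additive, approximately homoscedastic noise of normalized
plate readings — using Levenberg–Marquardt (`minpack.lm::nls.lm`) with
tight tolerances (`ftol = ptol = 1e-10`, up to 1000 iterations). The
contract is the optimum, not the algorithm.

**Initialization** is deterministic and data-driven: $K_0$ is the
maximum observed response; $\tau_0$ the linearly interpolated time of the
first crossing of $K_0/2$ (the end of the series if no crossing);
$\alpha_0 = 4$, mid-range of the shapes seen in practice. For
simultaneous fits, each dose level is first fitted separately; the level
nearest $e = 0$ initializes the control triple, and the per-level
relative perturbations $\hat\theta(e)/\hat\theta_C - 1$ initialize the
modifier coefficients through shape-specific least squares (slope through
the origin for $L$, plateau value and rate $-2/e_{max}$ for $H$, and so
on). Box constraints keep iterates in the model's domain without
constraining the biology: $K \in (0, 120]$, $\tau \in (0, 10\,t_{max}]$,
$\alpha \in (0.05, 50]$ (lower bound 1.01 when a derived-parameter form
or target requires the sigmoidal regime); modifier coefficients are
unbounded except positivity of $s_2, s_3, b_2, b_4$. If an iterate
strays where the surface is undefined, the residual vector is replaced
by a large flat penalty; with the initialization above this is not
reached in any tested scenario.

**Inference** is the classical linearization at the optimum: with $J$
the numerically differentiated (central differences) Jacobian of
predictions, $\mathrm{cov} = (J^\top J)^{-1}\,SSE/(n-p)$; standard errors
are the root diagonal; two-sided Student-$t$ intervals at
$\alpha = 0.05$; per-parameter $t$ tests; Fisher's $F$ for model
consistency, computed as regression mean square over residual mean
square, $F = \frac{(SS_{tot}-SSE)/(p-1)}{SSE/(n-p)}$; and the adjusted
determination coefficient
$R^2_{adj} = 1 - (1-R^2)\frac{n-1}{n-p-1}$, in which $p$ counts every
fitted parameter (note this denominator is $n-p-1$, not the $n-p$ used
by `summary.lm`). A singular $J^\top J$ raises a rank-deficiency error
naming the unidentifiable direction. Degenerate inputs fail loudly and
early: constant series, fewer observations than parameters, or a single
effector level are classed errors, and a modifier coefficient whose
interval spans zero triggers an identifiability warning rather than
silent acceptance.

Residual diagnostics (`residual_diagnostics()`) report a Shapiro–Wilk
normality p-value and the lag-1 autocorrelation; they are informational
and never gate a fit.

### Why fit simultaneously

The traditional two-step analysis fits each curve separately and then
regresses the fitted half-lives on dose. Its second stage sees one
number per curve: with six doses and two parameters it has four residual
degrees of freedom, so its interval for the potency slope $l_1$ is both
wide on average and highly variable — on occasional panels it collapses
below its nominal width by pure chance. The simultaneous fit uses every
observation for every parameter; across simulated panels its $l_1$
interval is narrower in mean and median (and in the large majority of
individual panels), while remaining correctly calibrated. This aggregate
comparison, not a per-panel one, is the meaningful rendering of the
precision claim, and is what the test suite asserts.

## The synthetic-data generator

`simulation_scenario()` + `simulate_panel()` generate percent-survival
panels as the model surface plus additive Gaussian noise, with the
ground truth attached to the data so tests never re-fit to learn it. The
defaults are the reference study conditions, chosen once: readings every
10 min from 0 to 180 (19 time points), trolox doses 0–125 µM in 25 µM
steps (6 levels), noise SD 1.5 percentage points on the percent scale,
one replicate, and the published trolox time-dose model
(`trolox_dose_model()`: control $(100, 70.5, 4.83)$, $l_1 = 0.0086$ on
$\tau$, $l_1 = 0.0121$ on $\alpha$) as generating truth.
`simulate_od_panel()` maps the same panels onto the optical-density
scale (noise applied on the percent scale first), so the preprocessing
arithmetic is testable end to end by exact inversion.

What the generator emulates: the sampling design, the homoscedastic
percent-scale noise the unweighted estimator assumes, and dose effects
exactly of the modifier families the fitter estimates. What it does not:
heteroscedastic or multiplicative error, plate-position (edge) effects,
replicate correlation, drift of the complete-lysis reference, model
misspecification (real dose effects need not be exactly linear), or the
digitization error present when curves are recovered from published
figures. Passing recovery and calibration tests therefore demonstrates
correctness of the estimator under its own assumptions — not robustness
to everything real plates do.

Simulation sizes used by the checks are deliberately modest: 200 panels
of $6 \times 19 = 114$ observations for coverage and slope-accuracy
calibration, 200 single curves for the Monte-Carlo standard-error
comparison, 25 panels for the simultaneous-versus-two-step contrast.
Each panel fits in well under 50 ms, so the whole suite runs in seconds.

## Numerical conventions

* All percent-scale quantities use the 0–100 scale, never fractions.
* $t = 0$ evaluates to $K$ for every $\alpha$ (continuity convention);
  rate functions refuse $t = 0$ when $\alpha < 1$, where the rate is
  singular.
* Survival values outside $[0, 100]$ produced by noise are retained,
  never clipped — clipping biases the asymptote — and the OD-to-percent
  conversion (`survival_percent()`) is applied per well, with the
  complete-lysis reference taken from dedicated wells by default (a
  per-series plateau fallback is available).
* Derived quantities undefined at $\alpha \le 1$ are explicit `NA`s with
  `defined` flags, not exceptions.
* Randomness exists only in the generator and is seed-controlled with
  the caller's RNG state restored; every fit is deterministic given data
  and starting values.

## Limitations

The model is phenomenological: its parameters summarize, but do not
mechanistically explain, membrane oxidation and lysis. Single-population
Weibull kinetics cannot represent bimodal lysis (mixed erythrocyte
populations). Linearized confidence intervals are first-order
approximations — adequate here (coverage of nominal 95% intervals over
simulated panels falls in the 90–99% band) but not exact in small
samples or near parameter bounds. Three-or-more-variable surfaces (time
× antioxidant × surfactant) are out of scope, though the modifier
algebra is written so that extension is mostly bookkeeping.
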