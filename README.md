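# oxhlia

Time-dose quantification of erythrocyte survival kinetics for the
oxidative hemolysis inhibition assay (OxHLIA) and related hemolytic
bioassays.

In OxHLIA, erythrocytes are lysed by peroxyl radicals generated from
AAPH, and an antioxidant delays the lysis wave. The assay is usually
quantified graphically — read the half-life off each curve, then regress
it on dose — which discards the kinetic information and its statistics.
`oxhlia` is for assay developers and antioxidant researchers who want
that quantification done as parametric regression: every curve, every
dose, one model, with confidence intervals on the numbers that get
compared between compounds.

## The model

The surviving population (percent, 0–100) follows a Weibull survival
kinetic with an explicit half-life:

    P(t) = K exp[ -ln2 (t/τ)^α ]

with asymptote `K` (%), half-life `τ` (min; `P(τ) = K/2` exactly) and
shape `α` (sigmoidal for `α > 1`). Closed forms derive the rate at the
half-life `v_τ = Kα ln2/(2τ)`, the maximum rate
`v_m = (Kα/τ)(ln2)^(1/α) G^G e^(-G)` with `G = (α-1)/α`, the lag phase
`λ`, and the time of maximum rate `t*`; three reparameterized forms make
`v_m`, `v_τ` or `λ` a directly fitted parameter.

An effector at level `e` (antioxidant dose, AAPH, surfactant,
temperature…) perturbs parameters multiplicatively,
`m_θ(e) = θ_C [1 + f(e)]`, with `f` linear, hyperbolic, sigmoidal or
bell-shaped. Substituted into the kinetic model this gives a bivariate
surface `P(t, e)` that is fitted **simultaneously** to the whole panel
by Levenberg–Marquardt least squares, with linearized inference
(Student-t intervals, Fisher F consistency test, adjusted R², residual
diagnostics). For an antioxidant, the linear slope `l1` on `τ`
(min delay per µM, as a fraction of the control half-life) is the
headline potency coefficient.

## Worked example

Derived parameters of the reference trolox control curve
(`K = 100, τ = 68.12, α = 4.59`):

```r
library(oxhlia)
derived_kinetics(kinetic_params(K = 100, tau = 68.12, alpha = 4.59))
#> Derived kinetic parameters:
#>   v_tau (rate at half-life): 2.335 %/min
#>   v_m   (maximum rate):      2.348 %/min
#>   lag   (lag phase):         39.92 min
#>   t*    (time of max rate):  69.94 min
```

So at dose zero half the population is lysed at 68 min, the lysis wave
peaks at about 2.35 %/min shortly after, and essentially nothing happens
for the first 40 min (the lag attributed to endogenous membrane
antioxidants).

Simultaneous time-dose fit of a simulated trolox panel (6 doses × 19
time points, noise SD 1.5 %):

```r
panel <- simulate_panel(simulation_scenario(noise_sd = 1.5, seed = 42))
fit <- fit_bivariate(panel, preset = "antioxidant-L")
fit
#> Simultaneous time-effector survival-kinetics fit (eq5 base)
#>  parameter  estimate std_error ci_halfwidth t_value    p_value significant
#>          K 99.950000 2.195e-01    0.4350000  455.40 1.411e-180        TRUE
#>        tau 70.780000 2.745e-01    0.5441000  257.80 1.125e-153        TRUE
#>      alpha  4.762000 1.348e-01    0.2671000   35.33  1.618e-61        TRUE
#>     tau_l1  0.008561 7.752e-05    0.0001536  110.40 1.026e-113        TRUE
#>   alpha_l1  0.012830 8.332e-04    0.0016510   15.39  4.217e-29        TRUE
#> n = 114, dof = 109, SSE = 251.527, R2_adj = 0.998832
#> F = 24389 (p = 6.96e-160), converged in 4 iterations
```

Five parameters describe all six curves: the control triple plus one
slope per perturbed parameter. The fitted `tau_l1 = 0.00856 ± 0.00015`
(95% CI) covers the generating value 0.0086; each µM of trolox extends
the half-life by 0.86% of its control value. The per-level table gives
the classical delay endpoint at every dose:

```r
fit$level_table
#>   effector      m_K     m_tau   m_alpha  delta_t
#> 1        0 99.94657  70.77893  4.761962  0.00000
#> 2       25 99.94657  85.92756  6.288806 15.14863
#> ...
#> 6      125 99.94657 146.52209 12.396182 75.74317
```

i.e. 125 µM trolox delays the hemolytic half-life by ~76 min.

## Command line

A thin CLI wraps the same functions (`exec/oxhlia`, or call
`oxhlia_cli()` in-process):

```sh
oxhlia derive --K 100 --tau 68.12 --alpha 4.59
oxhlia simulate --seed 42 --out panel.csv --truth-out truth.json
oxhlia fit --input panel.csv --base vtau
oxhlia dose-fit --input panel.csv --preset antioxidant-L --out report.json
```

Exit codes: 0 success, 2 input error, 3 non-convergence. Input mode
(`--mode percent|od`) is always explicit, never autodetected.

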