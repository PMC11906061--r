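# sinegph

Fully parametric proportional-hazards (PH) regression for right-censored
survival data, with **Sine-G** trigonometric families as baseline hazards.

Clinical time-to-event data show hazard shapes — increasing, decreasing,
unimodal, bathtub — that a single classical family rarely covers.  The
Sine-G construction turns any baseline CDF `G(t; θ)` into

    F(t) = sin( (π/2) · G(t; θ) ),     f(t) = (π/2) · g(t; θ) · cos( (π/2) · G(t; θ) ),

bending the baseline's hazard shape without adding parameters.  The package
implements five such baselines — sine-exponential (SE), sine-Weibull (SW),
sine-Lomax (SL), sine-exponentiated-exponential (SEE) and sine-Gompertz
(SG), each with scale `λ > 0` and (except SE) shape `α > 0` — inside the PH
model

    h(t | x) = h0(t; θ) · exp(x'β),    S(t | x) = S0(t; θ)^exp(x'β),

and the right-censored log-likelihood

    ℓ(θ, β) = Σ δi [ log h0(ti) + xi'β ] − Σ H0(ti) · exp(xi'β).

It is aimed at biostatisticians comparing parametric baseline-hazard
families for censored cohort or trial data, and at methodologists who need
a reproducible simulation-and-recovery bench for such models.

**What's inside**

- closed-form CDF/PDF/SF/hazard/cumulative-hazard/odds/quantile and inverse
  cumulative hazard for all five families, evaluated in log space through a
  half-angle identity so the right tail never cancels;
- inversion-method simulation `T = H0⁻¹(−log(1−U)·e^{−x'β})` with
  deterministic calibration of uniform censoring to a target fraction, and
  `synthetic_trial()` presets emulating the structure of two classic
  oncology cohorts (n = 90, 45/45 arms; n = 101, 50/51 groups, ~half
  censored);
- maximum likelihood (BFGS + Newton polish, observed-information SEs) and
  Bayesian inference (Hamiltonian Monte Carlo with dual-averaged step size,
  or adaptive Metropolis) under Gamma(10, 10) priors on `λ, α` and
  Normal(0, 10²) on `β`, with split R-hat, autocorrelation ESS and Monte
  Carlo SE diagnostics;
- WAIC and importance-sampling LOOIC (with a generalised-Pareto tail
  diagnostic and optional smoothing) from pointwise log-likelihood
  matrices, and `compare_models()` ranking;
- total-time-on-test (TTT) hazard-shape diagnostics, tidy `tibble` outputs,
  `tidy()`/`glance()` methods, `autoplot()` ggplot2 graphics, and a
  `simulate / fit / compare / ttt` command-line interface
  (`inst/cli/sinegph`).

## Worked example

```r
library(sinegph)

d <- synthetic_trial("gastric", seed = 7)   # n = 90, 45/45 treatment arms
fit <- fit_sine_ph_bayes(d, "sw", seed = 7) # 4 chains x 2000 (1000 warmup)
summarize_posterior(fit)
#> # A tibble: 3 × 9
#>   term   estimate     mcse     sd   q2.5   median q97.5   ess  rhat
#> 1 lambda  0.343   0.000670 0.0463  0.257  0.341   0.441 4773. 1.000
#> 2 alpha   1.01    0.00105  0.0825  0.857  1.01    1.18  6201. 1.000
#> 3 treat  -0.00314 0.00281  0.210  -0.431 -0.00451 0.413 5620. 1.00
```

The data were generated from a sine-Weibull PH truth (λ = 0.34, α = 0.95,
β = −0.06); the posterior means recover it, every split R-hat is at 1.00,
and with ESS in the thousands the Monte Carlo error (`mcse`) is far below
the posterior sd — the fit passes the usual convergence contract
(R-hat ≤ 1.01, ESS > 400, MCSE < 0.05·sd).  Model choice is by WAIC/LOOIC,
lower is better:

```r
fit_sl <- fit_sine_ph_bayes(d, "sl", seed = 7)
compare_models(`SW-PH` = pointwise_loglik_matrix(fit),
               `SL-PH` = pointwise_loglik_matrix(fit_sl))
#> # A tibble: 2 × 8
#>   model  lppd p_waic  waic elpd_loo looic n_high_pareto_k delta
#> 1 SW-PH -132.   2.76  270.    -135.  271.               0  0
#> 2 SL-PH -137.   1.26  277.    -138.  277.               0  6.29
```

The generating SW family ranks first, 6.3 WAIC points ahead; `p_waic` is
the effective parameter count and `n_high_pareto_k` counts observations
whose importance-weight tail index exceeds 0.7 (none here, so the LOO
estimate is trustworthy).  The same workflow is available from a shell:

```sh
Rscript inst/cli/sinegph simulate --preset gastric --seed 7 --out d.csv
Rscript inst/cli/sinegph fit --data d.csv --family sw --seed 7 --out sw.json
Rscript inst/cli/sinegph fit --data d.csv --family sl --seed 7 --out sl.json
Rscript inst/cli/sinegph compare --out ranking.csv sw.json sl.json
Rscript inst/cli/sinegph ttt --data d.csv --out ttt.csv
```

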