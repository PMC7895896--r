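# oudecode

Closed-form Fisher linear discriminant (LDA) decoding error for a
two-population leaky-integrator model of neural activity, with a Monte-Carlo
decoder that verifies every formula and a sweep engine for parameter studies.

## The problem

A downstream readout must decide which of two constant stimuli drove a pair
of neural populations, given one noisy sample of their firing rates. Each
population is a leaky linear integrator

```
tau_u dx/dt = -alpha_u x + nu_{i,u} + beta_u xi_u(t),    u in {x, y},
```

an Ornstein–Uhlenbeck process whose stationary rate is Gaussian with mean
`nu_i/alpha` and variance `sigma_u^2 = beta_u^2 / (2 tau_u alpha_u)`. The
readout sees `Z ~ N(mu_i, Sigma)` with noise correlation `rho` on the
off-diagonal of `Sigma`. For two classes with equal covariance, Fisher LDA
has the closed-form optimal weights `W = (2 Sigma)^{-1} (mu_2 - mu_1)` and
misclassification probability

```
eps = 1/2 erfc( d / (2 sqrt(2)) ),     d^2 = dmu' Sigma^{-1} dmu
    = (r_x^2 + r_y^2 - 2 rho r_x r_y) / (1 - rho^2),
```

where `r_u = dmu_u / sigma_u` is each population's signed signal-to-noise
ratio. The error-maximizing correlation has the closed form
`rho* = min(r_x^2, r_y^2) / (r_x r_y)` when `|r_x| != |r_y|` and
`r_x r_y != 0`. The package computes all of these exactly from the model
parameters, estimates the same error empirically (stationary sampling,
stratified 80/20 split, pooled-covariance LDA fit, held-out
misclassification), simulates the underlying SDEs, and packages the four
canonical tuning scenarios and the parameter sweeps that show when noise
correlation — and even extra noise — helps or hurts decoding.

It is aimed at computational neuroscientists studying population coding and
noise correlations, and at anyone who wants a compact, fully testable
reference implementation of two-class LDA error in closed form.

## Worked example

The gain-mismatch scenario: population x receives drives (11, 13),
population y (11, 14), all dynamical constants 1.

```r
library(oudecode)

sc <- scenario_preset("gain_mismatch")
snr_ratios(sc$px, sc$py)
#>      r_x      r_y
#> 2.828427 4.242641

rho_star(snr_ratios(sc$px, sc$py))   # closed form: r_x / r_y
#> [1] 0.6666667

rho_argmax_numeric(sc$px, sc$py)     # grid search + refinement
#> [1] 0.6666666

error_vs_rho(sc, c(-0.5, 0, 0.5, 2/3, 0.9), empirical = TRUE, seed = 1)
#>      rho error_analytic error_empirical std_err n_test
#> 1 -0.500       0.000186          0.0000 0.00000   2000
#> 2  0.000       0.005394          0.0045 0.00150   2000
#> 3  0.500       0.015377          0.0210 0.00321   2000
#> 4  0.667       0.016947          0.0125 0.00248   2000
#> 5  0.900       0.008061          0.0065 0.00180   2000
```

The signal-to-noise ratios are `2 sqrt(2)` and `3 sqrt(2)`, so the error
peaks at `rho* = 2/3` — noise correlation below 2/3 hurts discrimination,
while pushing it beyond 2/3 helps, and the error vanishes at `|rho| -> 1`.
The empirical column (5000 samples per class, 80/20 stratified split, 2000
held-out points) tracks the closed form within binomial noise.

Qualitative structure is available as named, checkable claims:

```r
check_claim("gain_mismatch_beta_x_rho_star_decreasing")$passed
#> [1] TRUE
```

A thin command-line front end is installed with the package:

```sh
Rscript exec/oudecode scenario --scenario gain_mismatch --empirical --seed 1 --out out/
Rscript exec/oudecode sweep --scenario offset_tuning --parameter tau_x --values 1,2,4 --out out/
Rscript exec/oudecode simulate --scenario identical_tuning --seed 1 --out out/
```

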