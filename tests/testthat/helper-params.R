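# Shared fixtures: random-but-reasonable parameter draws used by the
# property-style tests. All draws happen under the caller's seed.

random_population <- function(nu_range = c(8, 15)) {
  population_params(tau = runif(1, 0.5, 2), alpha = runif(1, 0.5, 2),
                    beta = runif(1, 0.5, 2),
                    nu1 = runif(1, nu_range[1], nu_range[2]),
                    nu2 = runif(1, nu_range[1], nu_range[2]))
}

# population pair with unit dynamical constants and drives chosen to hit the
# requested signal-to-noise ratios (r = dnu * sqrt(2) when tau=alpha=beta=1)
pair_with_snr <- function(r_x, r_y, nu_base = 10) {
  list(px = population_params(1, 1, 1, nu_base, nu_base + r_x / sqrt(2)),
       py = population_params(1, 1, 1, nu_base, nu_base + r_y / sqrt(2)))
}
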