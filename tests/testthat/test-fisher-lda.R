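# Closed-form LDA: feature model, weights, error routes, rho-star.

test_that("feature model carries the stationary moments and rho", {
  sc <- scenario_preset("identical_tuning")
  fm <- feature_model_from_params(sc$px, sc$py, rho = 0.9)
  expect_equal(fm$mu1, c(11, 11))
  expect_equal(fm$mu2, c(14, 14))
  expect_equal(fm$sigma_x2, 0.5)
  expect_equal(fm$sigma_y2, 0.5)
  expect_equal(fm$rho, 0.9)
  expect_error(feature_model_from_params(sc$px, sc$py, 1.5),
               "invalid correlation")
  # covariance singular exactly at |rho| = 1
  expect_equal(det(feature_cov(feature_model_from_params(sc$px, sc$py, 1))), 0)
  expect_gt(det(feature_cov(fm)), 0)
})

test_that("lda weights match the hand-inverted 2x2 solution", {
  # scenario with dmu = (3,3), sigma^2 = 0.5 both, rho = 0.5:
  # (2 Sigma) w = dmu  =>  w = (2, 2) by explicit inversion
  sc <- scenario_preset("identical_tuning")
  sol <- lda_weights(feature_model_from_params(sc$px, sc$py, 0.5))
  expect_equal(sol$w, c(2, 2))
  expect_equal(sol$eta1, -sol$eta2)
  expect_lt(sol$eta1, 0)           # class 1 on the negative side
  expect_gt(sol$zeta2, 0)
  # isotropic rho = 0 case: w proportional to dmu scaled by 1/(2 sigma^2)
  sol0 <- lda_weights(feature_model_from_params(sc$px, sc$py, 0))
  expect_equal(sol0$w, c(3, 3) / (2 * 0.5))
})

test_that("matrix solve agrees with the network-parameter expansion of W", {
  # expansion: w = (1/(2(1-rho^2))) [dmx/sx2 - rho dmy/(sx sy),
  #                                  dmy/sy2 - rho dmx/(sx sy)]
  set.seed(42)
  for (i in 1:200) {
    px <- random_population(); py <- random_population()
    rho <- runif(1, -0.95, 0.95)
    fm <- feature_model_from_params(px, py, rho)
    dm <- fm$mu2 - fm$mu1
    sx <- sqrt(fm$sigma_x2); sy <- sqrt(fm$sigma_y2)
    w_exp <- c(dm[1] / sx^2 - rho * dm[2] / (sx * sy),
               dm[2] / sy^2 - rho * dm[1] / (sx * sy)) / (2 * (1 - rho^2))
    expect_equal(lda_weights(fm)$w, w_exp, tolerance = 1e-12)
  }
})

test_that("degenerate lda inputs behave as contracted", {
  fm_eq <- feature_model(c(11, 11), c(11, 11), 0.5, 0.5, 0.3)
  sol <- lda_weights(fm_eq)
  expect_equal(sol$w, c(0, 0))
  expect_equal(c(sol$eta1, sol$eta2), c(0, 0))
  expect_equal(analytic_error_via_projection(sol), 0.5)  # chance level
  expect_error(lda_weights(feature_model(c(11, 11), c(14, 14), 0.5, 0.5, 1)),
               "singular covariance")
})

test_that("signed signal-to-noise ratios follow the scenario structure", {
  scA <- scenario_preset("identical_tuning")
  rA <- snr_ratios(scA$px, scA$py)
  expect_equal(unname(rA), rep(3 / sqrt(0.5), 2))   # dmu/sigma = 3/sqrt(0.5)
  rB <- snr_ratios(scenario_preset("offset_tuning")$px,
                   scenario_preset("offset_tuning")$py)
  expect_equal(rB[["r_x"]], -rB[["r_y"]])
  rC <- snr_ratios(scenario_preset("flat_tuning_x")$px,
                   scenario_preset("flat_tuning_x")$py)
  expect_equal(rC[["r_x"]], 0)
  # sign equals sign of nu2 - nu1
  expect_lt(snr_ratios(population_params(1, 1, 1, 14, 11),
                       population_params(1, 1, 1, 11, 14))[["r_x"]], 0)
})

test_that("squared Mahalanobis distance handles interior and boundary rho", {
  r <- c(3, 4)
  expect_equal(mahalanobis_sq(r, 0), 25)            # diagonal case
  # matches the matrix definition dmu' Sigma^{-1} dmu
  set.seed(7)
  for (i in 1:100) {
    px <- random_population(); py <- random_population()
    rho <- runif(1, -0.95, 0.95)
    fm <- feature_model_from_params(px, py, rho)
    dm <- fm$mu2 - fm$mu1
    d2_matrix <- drop(t(dm) %*% solve(feature_cov(fm)) %*% dm)
    expect_equal(mahalanobis_sq(snr_ratios(px, py), rho), d2_matrix,
                 tolerance = 1e-10)
  }
  # label-swap symmetry: d^2 invariant under dmu -> -dmu
  expect_equal(mahalanobis_sq(c(-3, -4), 0.4), mahalanobis_sq(c(3, 4), 0.4))
  # equal-ratio factorized limit 2 r^2/(1+rho), finite at rho = 1
  r_eq <- c(2, 2)
  expect_equal(mahalanobis_sq(r_eq, 1 - 1e-8), 2 * 4 / (2 - 1e-8),
               tolerance = 1e-6)
  expect_equal(mahalanobis_sq(r_eq, 1), 4)
  expect_equal(mahalanobis_sq(c(2, -2), -1), 4)
  expect_identical(mahalanobis_sq(c(2, 3), 1), Inf)
  expect_identical(mahalanobis_sq(c(2, 2), -1), Inf)
  expect_equal(mahalanobis_sq(c(0, 0), 1), 0)
  expect_error(mahalanobis_sq(r, 1.01), "invalid correlation")
})

test_that("analytic error maps d^2 to [0, 0.5], decreasing", {
  expect_equal(analytic_error(0), 0.5)
  expect_equal(analytic_error(Inf), 0)
  # frozen oracle: numerical integration of the two shifted Gaussian tail
  # areas for d^2 = 36 gives 1.3498980e-03 (= pnorm(-3))
  expect_equal(analytic_error(36), 1.349898031630095e-03, tolerance = 1e-12)
  d2 <- seq(0, 50, by = 0.5)
  expect_true(all(diff(analytic_error(d2)) < 0))
  expect_error(analytic_error(-1), "non-negative")
})

test_that("projection and Mahalanobis error routes agree to 1e-10 relative", {
  set.seed(123)
  n_ok <- 0
  while (n_ok < 1000) {
    px <- random_population(); py <- random_population()
    rho <- runif(1, -0.99, 0.99)
    d2 <- mahalanobis_sq(snr_ratios(px, py), rho)
    if (d2 > 1000) next  # keep both routes in the representable range
    fm <- feature_model_from_params(px, py, rho)
    e_proj <- analytic_error_via_projection(lda_weights(fm))
    e_maha <- analytic_error(d2)
    expect_equal(e_proj, e_maha, tolerance = 1e-10)
    n_ok <- n_ok + 1
  }
})

test_that("rho_star covers interior, zero-signal and boundary cases", {
  # gain-mismatch preset: |r_x| < |r_y|, rho* = r_x/r_y = 2/3
  rD <- snr_ratios(scenario_preset("gain_mismatch")$px,
                   scenario_preset("gain_mismatch")$py)
  expect_equal(as.numeric(rho_star(rD)), 2 / 3)
  expect_false(attr(rho_star(rD), "boundary"))
  expect_equal(as.numeric(rho_star(c(0, 3))), 0)
  expect_equal(as.numeric(rho_star(c(2, 2))), 1)
  expect_true(attr(rho_star(c(2, 2)), "boundary"))
  expect_equal(as.numeric(rho_star(c(2, -2))), -1)
  # swapped magnitudes use the other branch: rho* = r_y/r_x
  expect_equal(as.numeric(rho_star(c(4, 2))), 0.5)
})

test_that("numeric argmax matches the closed form on random interior cases", {
  set.seed(99)
  for (i in 1:50) {
    repeat {
      r <- runif(2, -4, 4)
      if (all(abs(r) > 0.3) && abs(abs(r[1]) - abs(r[2])) > 0.1) break
    }
    p <- pair_with_snr(r[1], r[2])
    expect_lt(abs(rho_argmax_numeric(p$px, p$py, grid_n = 801) -
                    as.numeric(rho_star(r))), 1e-3)
  }
})

test_that("numeric argmax lands on 0 for flat tuning and the boundary for identical tuning", {
  scC <- scenario_preset("flat_tuning_x")
  expect_lt(abs(rho_argmax_numeric(scC$px, scC$py)), 1e-4)
  scA <- scenario_preset("identical_tuning")
  expect_equal(rho_argmax_numeric(scA$px, scA$py), 1 - 1e-6, tolerance = 1e-5)
})

test_that("error monotonicity and symmetry across the scenarios", {
  grid <- seq(-0.99, 0.99, by = 0.01)
  rA <- snr_ratios(scenario_preset("identical_tuning")$px,
                   scenario_preset("identical_tuning")$py)
  expect_true(all(diff(analytic_error(mahalanobis_sq(rA, grid))) > 0))
  rB <- snr_ratios(scenario_preset("offset_tuning")$px,
                   scenario_preset("offset_tuning")$py)
  expect_true(all(diff(analytic_error(mahalanobis_sq(rB, grid))) < 0))
  rC <- snr_ratios(scenario_preset("flat_tuning_x")$px,
                   scenario_preset("flat_tuning_x")$py)
  eC <- analytic_error(mahalanobis_sq(rC, grid))
  expect_equal(eC, rev(eC))                      # symmetric in rho
  expect_lt(analytic_error(mahalanobis_sq(rC, 0.999)), 1e-6)
  expect_lt(analytic_error(mahalanobis_sq(rC, -0.999)), 1e-6)
})
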