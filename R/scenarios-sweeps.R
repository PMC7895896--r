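# Scenario presets, error-vs-correlation curves, rho-star factorizations,
# parameter sweeps, and a registry of qualitative claims.

#' Canonical two-population tuning scenarios
#'
#' Four presets with \eqn{\tau = \alpha = \beta = 1} for both populations and
#' drives:
#' \describe{
#'   \item{`identical_tuning`}{x: (11, 14), y: (11, 14) — \eqn{r_x = r_y};
#'     error increases monotonically with correlation.}
#'   \item{`offset_tuning`}{x: (11, 14), y: (14, 11) — \eqn{r_x = -r_y};
#'     error decreases monotonically with correlation.}
#'   \item{`flat_tuning_x`}{x: (11, 11), y: (11, 14) — \eqn{r_x = 0};
#'     symmetric error curve peaking at \eqn{\rho_* = 0}.}
#'   \item{`gain_mismatch`}{x: (11, 13), y: (11, 14) —
#'     \eqn{|r_x| \neq |r_y|}; interior maximal-error correlation
#'     \eqn{\rho_* = \min(r_x^2, r_y^2)/(r_x r_y)}.}
#' }
#'
#' @param label scenario name (see above), or `"custom"` with `px`, `py`
#'   supplied.
#' @param px,py [population_params()] for `label = "custom"`.
#' @param rho noise correlation attached to the configuration (default 0).
#' @return An object of class `scenario_config`: list with `px`, `py`,
#'   `rho`, `label`.
#' @export
scenario_preset <- function(label, px = NULL, py = NULL, rho = 0) {
  presets <- list(
    identical_tuning = list(x = c(11, 14), y = c(11, 14)),
    offset_tuning    = list(x = c(11, 14), y = c(14, 11)),
    flat_tuning_x    = list(x = c(11, 11), y = c(11, 14)),
    gain_mismatch    = list(x = c(11, 13), y = c(11, 14))
  )
  if (identical(label, "custom")) {
    assert_population_params(px); assert_population_params(py)
  } else if (label %in% names(presets)) {
    nus <- presets[[label]]
    px <- population_params(1, 1, 1, nus$x[1], nus$x[2])
    py <- population_params(1, 1, 1, nus$y[1], nus$y[2])
  } else {
    stop("invalid scenario: unknown label '", label, "'", call. = FALSE)
  }
  if (abs(rho) > 1)
    stop("invalid correlation: `rho` must lie in [-1, 1]", call. = FALSE)
  structure(list(px = px, py = py, rho = rho, label = label),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  r <- snr_ratios(x$px, x$py)
  cat(sprintf("<scenario_config> %s  r_x=%.4g r_y=%.4g rho=%g\n",
              x$label, r[["r_x"]], r[["r_y"]], x$rho))
  invisible(x)
}

#' Analytic (and optionally empirical) error across a correlation grid
#'
#' @param sc a [scenario_preset()] configuration.
#' @param rho_grid correlations, each within \eqn{[-1 + 10^{-6}, 1 - 10^{-6}]}.
#' @param empirical also run the full sample/split/fit/error chain at each
#'   grid point (default `FALSE`).
#' @param n_per_class samples per class for the empirical chain.
#' @param train_fraction training proportion for the empirical chain.
#' @param seed base seed; grid point `i` uses `seed + 10 * i` derived seeds.
#' @return A data frame with columns `rho`, `error_analytic`, and when
#'   `empirical` is set, `error_empirical`, `std_err`, `n_test`.
#' @examples
#' sc <- scenario_preset("gain_mismatch")
#' error_vs_rho(sc, seq(-0.9, 0.9, by = 0.1))
#' @export
error_vs_rho <- function(sc, rho_grid, empirical = FALSE,
                         n_per_class = 5000L, train_fraction = 0.8,
                         seed = 1L) {
  stopifnot(inherits(sc, "scenario_config"))
  lim <- 1 - 1e-6
  if (any(abs(rho_grid) > lim))
    stop("grid values must lie within [-1 + 1e-6, 1 - 1e-6]", call. = FALSE)
  r <- snr_ratios(sc$px, sc$py)
  out <- data.frame(rho = rho_grid,
                    error_analytic = analytic_error(mahalanobis_sq(r, rho_grid)))
  if (empirical) {
    est <- lapply(seq_along(rho_grid), function(i) {
      fm <- feature_model_from_params(sc$px, sc$py, rho_grid[i])
      empirical_error(fm, n_per_class, train_fraction,
                      seed = seed + 10L * i)
    })
    out$error_empirical <- vapply(est, `[[`, numeric(1), "error")
    out$std_err <- vapply(est, `[[`, numeric(1), "std_err")
    out$n_test <- vapply(est, `[[`, integer(1), "n_test")
  }
  out
}

# rho* via Eq.-style factorization f(g) * c_g.  tau and alpha enter the
# signal-to-noise ratio under a square root (r_x/r_y =
# (dnu_x/dnu_y)(beta_y/beta_x) sqrt(tau_x alpha_y / (tau_y alpha_x))), so the
# varying factors are sqrt(tau_x) and 1/sqrt(alpha_x); beta enters linearly.
factorization_table <- function(p) {
  dnx <- p$px$nu2 - p$px$nu1; dny <- p$py$nu2 - p$py$nu1
  with(list(tx = p$px$tau, ty = p$py$tau, ax = p$px$alpha, ay = p$py$alpha,
            bx = p$px$beta, by = p$py$beta), list(
    beta_pair = list(
      f = function(g) g[["beta_y"]] / g[["beta_x"]],
      g = c(beta_x = bx, beta_y = by),
      c_g = (dnx / dny) * sqrt(tx * ay) / sqrt(ty * ax)),
    beta_x = list(
      f = function(g) 1 / g[["beta_x"]],
      g = c(beta_x = bx),
      c_g = by * dnx * sqrt(tx * ay) / (dny * sqrt(ty * ax))),
    tau_x = list(
      f = function(g) sqrt(g[["tau_x"]]),
      g = c(tau_x = tx),
      c_g = by * dnx * sqrt(ay) / (bx * dny * sqrt(ty * ax))),
    alpha_x = list(
      f = function(g) 1 / sqrt(g[["alpha_x"]]),
      g = c(alpha_x = ax),
      c_g = by * dnx * sqrt(tx * ay) / (bx * dny * sqrt(ty)))
  ))
}

#' Factorized maximal-error correlation
#'
#' Splits \eqn{\rho_*} into a factor that varies with the chosen parameter(s)
#' and a constant: on the branch \eqn{|r_x| < |r_y|},
#' \eqn{\rho_* = r_x/r_y = f(g)\, c_g}; on \eqn{|r_x| > |r_y|} it is
#' \eqn{(f(g)\, c_g)^{-1}}. Supported `varied` sets: `"beta_pair"`
#' (\eqn{f = \beta_y/\beta_x}), `"beta_x"` (\eqn{f = 1/\beta_x}), `"tau_x"`
#' (\eqn{f = \sqrt{\tau_x}}), `"alpha_x"` (\eqn{f = 1/\sqrt{\alpha_x}}); the
#' square roots follow from how \eqn{\tau} and \eqn{\alpha} enter
#' \eqn{r_u = \Delta\nu_u\sqrt{2\tau_u/(\beta_u^2\alpha_u)}}.
#'
#' @param sc a [scenario_preset()] configuration.
#' @param varied one of `"beta_pair"`, `"beta_x"`, `"tau_x"`, `"alpha_x"`.
#' @return An object of class `rho_star_factorization`: list with `varied`,
#'   `f` (the varying-factor function of a named vector `g`), `g` (current
#'   parameter values), `f_of_g` (f evaluated at `g`), `c_g`, `branch`
#'   (`"rx_lt_ry"` or `"rx_gt_ry"`), and `rho_star` (the branch-adjusted
#'   product, equal to [rho_star()] on the same parameters).
#' @export
rho_star_factorized <- function(sc, varied = c("beta_pair", "beta_x",
                                               "tau_x", "alpha_x")) {
  stopifnot(inherits(sc, "scenario_config"))
  varied <- match.arg(varied)
  r <- snr_ratios(sc$px, sc$py)
  if (r[["r_x"]] * r[["r_y"]] == 0 || abs(r[["r_x"]]) == abs(r[["r_y"]]))
    stop("branch undefined: requires r_x * r_y != 0 and |r_x| != |r_y|",
         call. = FALSE)
  entry <- factorization_table(sc)[[varied]]
  branch <- if (abs(r[["r_x"]]) < abs(r[["r_y"]])) "rx_lt_ry" else "rx_gt_ry"
  prod <- entry$f(entry$g) * entry$c_g
  structure(
    list(varied = varied, f = entry$f, g = entry$g,
         f_of_g = entry$f(entry$g), c_g = entry$c_g, branch = branch,
         rho_star = if (branch == "rx_lt_ry") prod else 1 / prod),
    class = "rho_star_factorization"
  )
}

set_scenario_parameter <- function(sc, parameter, value) {
  if (value <= 0) stop("sweep values must be strictly positive", call. = FALSE)
  upd <- function(p, field, v) {
    p[[field]] <- v
    do.call(population_params, p[c("tau", "alpha", "beta", "nu1", "nu2")])
  }
  px <- sc$px; py <- sc$py
  switch(parameter,
    beta_x = px <- upd(px, "beta", value),
    beta_y = py <- upd(py, "beta", value),
    beta_joint = { px <- upd(px, "beta", value); py <- upd(py, "beta", value) },
    tau_x = px <- upd(px, "tau", value),
    tau_y = py <- upd(py, "tau", value),
    alpha_x = px <- upd(px, "alpha", value),
    alpha_y = py <- upd(py, "alpha", value),
    stop("unknown sweep parameter '", parameter, "'", call. = FALSE)
  )
  scenario_preset("custom", px = px, py = py, rho = sc$rho)
}

#' Sweep one model parameter and tabulate error curves and rho-star
#'
#' For each swept value, computes the full analytic \eqn{\varepsilon(\rho)}
#' curve (optionally with the empirical chain), the closed-form
#' \eqn{\rho_*} and its numeric argmax.
#'
#' @param sc a [scenario_preset()] configuration.
#' @param parameter one of `beta_x`, `beta_y`, `beta_joint`, `tau_x`,
#'   `tau_y`, `alpha_x`, `alpha_y`.
#' @param values strictly positive swept values.
#' @param rho_grid correlation grid for the curves.
#' @param empirical,n_per_class,train_fraction,seed as in [error_vs_rho()].
#' @return An object of class `sweep_result`: list with `curves` (tidy data
#'   frame, one row per (value, rho)), `summary` (one row per value with
#'   `rho_star_closed`, `rho_star_boundary`, `rho_star_numeric`), `parameter`,
#'   `label`, `seed`.
#' @examples
#' sw <- sweep_parameter(scenario_preset("gain_mismatch"), "beta_x",
#'                       values = c(1, 2, 4), rho_grid = seq(-0.9, 0.9, 0.1))
#' sw$summary
#' @export
sweep_parameter <- function(sc, parameter, values, rho_grid,
                            empirical = FALSE, n_per_class = 5000L,
                            train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(sc, "scenario_config"))
  if (length(values) == 0L) stop("`values` must be non-empty", call. = FALSE)
  curves <- list(); summ <- list()
  for (k in seq_along(values)) {
    sck <- set_scenario_parameter(sc, parameter, values[k])
    cur <- error_vs_rho(sck, rho_grid, empirical = empirical,
                        n_per_class = n_per_class,
                        train_fraction = train_fraction,
                        seed = seed + 1000L * k)
    cur <- cbind(parameter = parameter, value = values[k], cur,
                 stringsAsFactors = FALSE)
    rs <- rho_star(snr_ratios(sck$px, sck$py))
    summ[[k]] <- data.frame(
      parameter = parameter, value = values[k],
      rho_star_closed = as.numeric(rs),
      rho_star_boundary = isTRUE(attr(rs, "boundary")),
      rho_star_numeric = rho_argmax_numeric(sck$px, sck$py),
      stringsAsFactors = FALSE)
    curves[[k]] <- cur
  }
  structure(
    list(curves = do.call(rbind, curves), summary = do.call(rbind, summ),
         parameter = parameter, label = sc$label, seed = seed),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> scenario '%s', parameter %s over {%s}\n",
              x$label, x$parameter, paste(x$summary$value, collapse = ", ")))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Plot error-vs-correlation curves of a sweep
#'
#' @param x a `sweep_result`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.sweep_result <- function(x, ...) {
  vals <- unique(x$curves$value)
  m <- sapply(vals, function(v)
    x$curves$error_analytic[x$curves$value == v])
  rho <- unique(x$curves$rho)
  graphics::matplot(rho, m, type = "l", lty = 1, xlab = "noise correlation",
                    ylab = "classification error",
                    main = sprintf("%s sweep (%s)", x$parameter, x$label), ...)
  graphics::legend("topleft", legend = sprintf("%s = %g", x$parameter, vals),
                   col = seq_along(vals), lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Export a sweep result as tidy CSV with a metadata sidecar
#'
#' @param sw a `sweep_result`.
#' @param path CSV path for the curves; the summary goes to
#'   `sub(".csv", "_summary.csv", path)` and metadata to
#'   `paste0(path, ".meta")`.
#' @return `path`, invisibly.
#' @export
write_sweep_result <- function(sw, path) {
  stopifnot(inherits(sw, "sweep_result"))
  utils::write.csv(sw$curves, path, row.names = FALSE)
  utils::write.csv(sw$summary, sub("\\.csv$", "_summary.csv", path),
                   row.names = FALSE)
  writeLines(c(sprintf("scenario = %s", sw$label),
               sprintf("parameter = %s", sw$parameter),
               sprintf("values = %s", paste(sw$summary$value, collapse = ",")),
               sprintf("seed = %d", sw$seed)),
             paste0(path, ".meta"))
  invisible(path)
}

# ---- qualitative claims registry ------------------------------------------

strictly_increasing <- function(v) all(diff(v) > 0)
strictly_decreasing <- function(v) all(diff(v) < 0)
nonmonotonic <- function(v) any(diff(v) > 0) && any(diff(v) < 0)

default_rho_grid <- function() seq(-0.9, 0.9, by = 0.1)

claim_registry <- function() {
  list(
    identical_error_increasing = list(
      needs = "data.frame",
      about = "identical tuning: error strictly increases with correlation",
      build = function() error_vs_rho(scenario_preset("identical_tuning"),
                                      default_rho_grid()),
      check = function(res) strictly_increasing(res$error_analytic)),
    offset_error_decreasing = list(
      needs = "data.frame",
      about = "offset tuning: error strictly decreases with correlation",
      build = function() error_vs_rho(scenario_preset("offset_tuning"),
                                      default_rho_grid()),
      check = function(res) strictly_decreasing(res$error_analytic)),
    flat_x_symmetric_peak_zero = list(
      needs = "data.frame",
      about = "flat tuning in x: error symmetric in rho, peak at 0, vanishing at |rho| -> 1",
      build = function() error_vs_rho(scenario_preset("flat_tuning_x"),
                                      c(-0.999, default_rho_grid(), 0.999)),
      check = function(res) {
        e <- res$error_analytic[order(res$rho)]
        r <- sort(res$rho)
        sym <- max(abs(e - rev(e))) < 1e-12
        peak <- which.max(e) == which.min(abs(r))
        tails <- e[1] < 1e-6 && e[length(e)] < 1e-6
        sym && peak && tails
      }),
    gain_mismatch_interior_peak = list(
      needs = "scenario_config",
      about = "gain mismatch: maximal error at an interior rho* = min(r^2)/(rx ry)",
      build = function() scenario_preset("gain_mismatch"),
      check = function(res) {
        rs <- rho_star(snr_ratios(res$px, res$py))
        abs(rs) < 1 && !attr(rs, "boundary") &&
          abs(rho_argmax_numeric(res$px, res$py) - rs) < 1e-3
      }),
    joint_beta_rho_star_invariant = list(
      needs = "sweep_result",
      about = "scaling both noise gains together leaves rho* unchanged",
      build = function() sweep_parameter(scenario_preset("identical_tuning"),
                                         "beta_joint", c(1, 2, 3, 4),
                                         default_rho_grid()),
      check = function(res) {
        s <- res$summary
        all(s$rho_star_closed == s$rho_star_closed[1]) &&
          max(abs(s$rho_star_numeric - s$rho_star_numeric[1])) < 1e-3
      }),
    joint_beta_error_increasing = list(
      needs = "sweep_result",
      about = "scaling both noise gains up increases error pointwise",
      build = function() sweep_parameter(scenario_preset("identical_tuning"),
                                         "beta_joint", c(1, 2, 3, 4),
                                         default_rho_grid()),
      check = function(res) {
        m <- sapply(unique(res$curves$value), function(v)
          res$curves$error_analytic[res$curves$value == v])
        all(diff(t(m)) > 0)  # increasing across values at every rho
      }),
    offset_beta_x_rho_star_nonmonotonic = list(
      needs = "sweep_result",
      about = "offset tuning: rho*(beta_x) falls to -1 at beta_x = 1 then rises",
      build = function() sweep_parameter(scenario_preset("offset_tuning"),
                                         "beta_x", c(0.5, 1, 2, 4),
                                         default_rho_grid()),
      check = function(res) nonmonotonic(res$summary$rho_star_closed)),
    gain_mismatch_beta_x_rho_star_decreasing = list(
      needs = "sweep_result",
      about = "gain mismatch: rho* strictly decreasing in beta_x",
      build = function() sweep_parameter(scenario_preset("gain_mismatch"),
                                         "beta_x", c(1, 2, 3, 4, 10),
                                         default_rho_grid()),
      check = function(res) strictly_decreasing(res$summary$rho_star_closed)),
    offset_large_beta_x_lowers_error = list(
      needs = "sweep_result",
      about = "offset tuning: beta_x = 10 gives lower error than beta_x = 3 or 4 at rho = -0.5",
      build = function() sweep_parameter(scenario_preset("offset_tuning"),
                                         "beta_x", c(3, 4, 10), -0.5),
      check = function(res) {
        e <- res$curves$error_analytic[match(c(3, 4, 10), res$curves$value)]
        e[3] < e[1] && e[3] < e[2]
      }),
    offset_tau_x_rho_star_up_error_down = list(
      needs = "sweep_result",
      about = "offset tuning: larger tau_x raises rho* and lowers error pointwise",
      build = function() sweep_parameter(scenario_preset("offset_tuning"),
                                         "tau_x", c(1, 2, 4),
                                         default_rho_grid()),
      check = function(res) {
        m <- sapply(unique(res$curves$value), function(v)
          res$curves$error_analytic[res$curves$value == v])
        strictly_increasing(res$summary$rho_star_closed) &&
          all(diff(t(m)) < 0)
      }),
    offset_alpha_x_rho_star_down_error_up = list(
      needs = "sweep_result",
      about = "offset tuning: larger alpha_x lowers rho* and raises error pointwise (alpha_x <= 1 branch)",
      build = function() sweep_parameter(scenario_preset("offset_tuning"),
                                         "alpha_x", c(0.25, 0.5, 1),
                                         default_rho_grid()),
      check = function(res) {
        m <- sapply(unique(res$curves$value), function(v)
          res$curves$error_analytic[res$curves$value == v])
        strictly_decreasing(res$summary$rho_star_closed) &&
          all(diff(t(m)) > 0)
      }),
    identical_tau_x_rho_star_nonmonotonic = list(
      needs = "sweep_result",
      about = "identical tuning: rho*(tau_x) rises to 1 at tau_x = 1 then falls",
      build = function() sweep_parameter(scenario_preset("identical_tuning"),
                                         "tau_x", c(0.25, 0.5, 1, 2, 4),
                                         default_rho_grid()),
      check = function(res) nonmonotonic(res$summary$rho_star_closed)),
    gain_mismatch_alpha_x_rho_star_nonmonotonic = list(
      needs = "sweep_result",
      about = "gain mismatch: rho*(alpha_x) non-monotonic across the |r_x| = |r_y| branch switch",
      build = function() sweep_parameter(scenario_preset("gain_mismatch"),
                                         "alpha_x", c(0.1, 0.25, 1, 4),
                                         default_rho_grid()),
      check = function(res) nonmonotonic(res$summary$rho_star_closed)),
    identical_error_decreasing_negative_control = list(
      needs = "data.frame",
      about = "negative control: identical tuning error does NOT decrease with correlation",
      build = function() error_vs_rho(scenario_preset("identical_tuning"),
                                      default_rho_grid()),
      check = function(res) strictly_decreasing(res$error_analytic))
  )
}

#' Names of the registered qualitative claims
#' @return Character vector of claim names.
#' @export
list_claims <- function() names(claim_registry())

#' Check one registered qualitative claim
#'
#' Each claim pairs a default sweep (built from the canonical scenario
#' parameters) with a boolean check. Supplying `results` overrides the
#' default sweep; it must cover what the claim needs (a `sweep_result` for
#' sweep claims, an [error_vs_rho()] frame for curve claims, a
#' `scenario_config` for the interior-peak claim).
#'
#' @param claim a name from [list_claims()].
#' @param results optional precomputed evidence.
#' @return A list with `claim`, `about`, `passed` (logical) and `evidence`
#'   (the results object the check ran on).
#' @examples
#' check_claim("identical_error_increasing")$passed
#' @export
check_claim <- function(claim, results = NULL) {
  reg <- claim_registry()
  if (!claim %in% names(reg))
    stop("unknown claim '", claim, "'; see list_claims()", call. = FALSE)
  entry <- reg[[claim]]
  if (is.null(results)) results <- entry$build()
  if (!inherits(results, entry$needs))
    stop("insufficient sweep coverage for claim '", claim, "': expected a ",
         entry$needs, call. = FALSE)
  passed <- tryCatch(isTRUE(entry$check(results)), error = function(e) {
    stop("insufficient sweep coverage for claim '", claim, "': ",
         conditionMessage(e), call. = FALSE)
  })
  list(claim = claim, about = entry$about, passed = passed,
       evidence = results)
}

#' Check every registered qualitative claim
#'
#' @return Data frame with columns `claim`, `passed`, `about`.
#' @export
check_all_claims <- function() {
  nm <- list_claims()
  res <- lapply(nm, check_claim)
  data.frame(claim = nm,
             passed = vapply(res, `[[`, logical(1), "passed"),
             about = vapply(res, `[[`, character(1), "about"),
             stringsAsFactors = FALSE)
}
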