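# Leaky linear integrator model: parameter containers, OU reparametrization,
# closed-form moments, and a time-stepped stochastic simulator.

#' Parameters of one integrator population
#'
#' A leaky linear integrator describes one population's firing rate \eqn{x(t)}:
#' \deqn{\tau \frac{dx}{dt} = -\alpha x + \nu_i + \beta \xi(t),}
#' where \eqn{\nu_i} is the constant drive under stimulus \eqn{i \in \{1,2\}},
#' \eqn{\alpha} a leak, \eqn{\tau} a time constant, and \eqn{\xi(t)} standard
#' Gaussian white noise with gain \eqn{\beta}. After reparametrization with
#' \eqn{\theta = \alpha/\tau} and \eqn{\lambda = \beta/\tau} this is an
#' Ornstein-Uhlenbeck process reverting to \eqn{\mu_i = \nu_i/\alpha}.
#'
#' @param tau time constant (time units, > 0).
#' @param alpha leak (dimensionless rate factor, > 0).
#' @param beta noise gain (rate x time units, > 0).
#' @param nu1,nu2 constant drives under stimulus 1 and 2 (rate units).
#' @return An object of class `population_params`.
#' @examples
#' population_params(tau = 1, alpha = 1, beta = 1, nu1 = 11, nu2 = 14)
#' @export
population_params <- function(tau, alpha, beta, nu1, nu2) {
  for (nm in c("tau", "alpha", "beta", "nu1", "nu2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  if (tau <= 0 || alpha <= 0 || beta <= 0)
    stop("invalid parameter: tau, alpha and beta must be strictly positive",
         call. = FALSE)
  structure(
    list(tau = tau, alpha = alpha, beta = beta, nu1 = nu1, nu2 = nu2),
    class = "population_params"
  )
}

#' @export
print.population_params <- function(x, ...) {
  dr <- derived_rates(x)
  cat(sprintf(
    "<population_params> tau=%g alpha=%g beta=%g nu=(%g, %g)  [theta=%g, lambda=%g]\n",
    x$tau, x$alpha, x$beta, x$nu1, x$nu2, dr[["theta"]], dr[["lambda"]]))
  invisible(x)
}

assert_population_params <- function(p, arg = deparse(substitute(p))) {
  if (!inherits(p, "population_params"))
    stop("`", arg, "` must be a `population_params` object", call. = FALSE)
  invisible(p)
}

stimulus_drive <- function(p, stimulus) {
  if (!(length(stimulus) == 1L && stimulus %in% c(1, 2)))
    stop("`stimulus` must be 1 or 2", call. = FALSE)
  if (stimulus == 1) p$nu1 else p$nu2
}

#' OU rates derived from integrator parameters
#'
#' @param p a [population_params()] object.
#' @return Named numeric vector with `theta = alpha/tau` (mean-reversion rate)
#'   and `lambda = beta/tau` (diffusion gain).
#' @examples
#' derived_rates(population_params(2, 1, 4, 11, 14))  # theta 0.5, lambda 2
#' @export
derived_rates <- function(p) {
  assert_population_params(p)
  c(theta = p$alpha / p$tau, lambda = p$beta / p$tau)
}

#' Stationary mean and variance of one population
#'
#' In the stationary regime the rate is Gaussian with mean \eqn{\nu_i/\alpha}
#' and variance \eqn{\beta^2 / (2 \tau \alpha)}.
#'
#' @inheritParams derived_rates
#' @param stimulus which stimulus drive to use, 1 or 2.
#' @return Named numeric vector `c(mean, variance)`.
#' @examples
#' stationary_moments(population_params(1, 1, 1, 11, 14), stimulus = 1)
#' @export
stationary_moments <- function(p, stimulus) {
  assert_population_params(p)
  nu <- stimulus_drive(p, stimulus)
  c(mean = nu / p$alpha, variance = p$beta^2 / (2 * p$tau * p$alpha))
}

#' Transient mean and variance of one population
#'
#' Starting from a deterministic rate `x0`, the OU solution has
#' \eqn{E[x(t)] = \mu + (x_0-\mu) e^{-\theta t}} and
#' \eqn{Var(x(t)) = \frac{\lambda^2}{2\theta}(1 - e^{-2\theta t})}.
#'
#' @inheritParams stationary_moments
#' @param x0 initial rate.
#' @param t elapsed time, >= 0.
#' @return Named numeric vector `c(mean, variance)`.
#' @export
transient_moments <- function(p, x0, t, stimulus) {
  assert_population_params(p)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("`t` must be a single non-negative time", call. = FALSE)
  dr <- derived_rates(p)
  st <- stationary_moments(p, stimulus)
  mu <- st[["mean"]]
  c(mean = mu + (x0 - mu) * exp(-dr[["theta"]] * t),
    variance = st[["variance"]] * (1 - exp(-2 * dr[["theta"]] * t)))
}

#' Configuration for a simulated trajectory pair
#'
#' @param dt integration step (time units, > 0).
#' @param n_steps number of retained steps (> 0).
#' @param burn_in_steps steps discarded before statistics (>= 0). The burn-in
#'   is simulated in addition to `n_steps` and dropped from the output series
#'   marked by the `burn_in_steps` field downstream summaries use.
#' @param x0 initial rate for both populations (length 1 or 2).
#' @param seed RNG seed (integer).
#' @return An object of class `trajectory_config`.
#' @export
trajectory_config <- function(dt, n_steps, burn_in_steps = 0L, x0 = c(0, 0),
                              seed = 1L) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive step", call. = FALSE)
  if (n_steps < 1 || n_steps != round(n_steps))
    stop("`n_steps` must be a positive integer", call. = FALSE)
  if (burn_in_steps < 0 || burn_in_steps != round(burn_in_steps))
    stop("`burn_in_steps` must be a non-negative integer", call. = FALSE)
  if (length(x0) == 1L) x0 <- rep(x0, 2L)
  structure(
    list(dt = dt, n_steps = as.integer(n_steps),
         burn_in_steps = as.integer(burn_in_steps),
         x0 = as.numeric(x0), seed = as.integer(seed)),
    class = "trajectory_config"
  )
}

#' Default trajectory configuration for a population pair
#'
#' Chooses `dt` so that `dt * max(theta) = 0.01` and a burn-in covering
#' `10 / min(theta)` of simulated time (at least ten of the slowest
#' relaxation times), then `t_total` of retained time.
#'
#' @param px,py [population_params()] for the two populations.
#' @param t_total retained (post burn-in) simulated time.
#' @param seed RNG seed.
#' @export
default_trajectory_config <- function(px, py, t_total = 100, seed = 1L) {
  thx <- derived_rates(px)[["theta"]]
  thy <- derived_rates(py)[["theta"]]
  dt <- 0.01 / max(thx, thy)
  burn <- ceiling((10 / min(thx, thy)) / dt)
  trajectory_config(dt = dt, n_steps = ceiling(t_total / dt),
                    burn_in_steps = burn,
                    x0 = c(stationary_moments(px, 1)[["mean"]],
                           stationary_moments(py, 1)[["mean"]]),
                    seed = seed)
}

# Lower-triangular factor of [[1, rho], [rho, 1]]; valid (rank-1) at |rho| = 1.
corr_factor <- function(rho) {
  matrix(c(1, rho, 0, sqrt(max(0, 1 - rho^2))), 2L, 2L)
}

#' Simulate a correlated pair of integrator trajectories
#'
#' Integrates the two-population model under one stimulus with per-step noise
#' increments that are bivariate standard normal with correlation `rho`
#' (lower-triangular factor of the 2x2 correlation matrix applied to
#' independent draws), scaled by \eqn{\lambda \sqrt{dt}}. Two schemes are
#' available: Euler-Maruyama (default) and the exact OU transition kernel.
#' Both are AR(1) recursions and are evaluated with [stats::filter()].
#'
#' Driving the increments at correlation `rho` yields stationary *rate*
#' correlation `rho` only when the two mean-reversion rates are equal
#' (`theta_x == theta_y`); otherwise the rate correlation is attenuated by
#' \eqn{2\sqrt{\theta_x\theta_y}/(\theta_x+\theta_y)}. For decoding the
#' canonical sampling route is [sample_stationary()], which draws directly
#' from the stationary feature distribution.
#'
#' @param px,py [population_params()] for populations x and y.
#' @param rho input noise-increment correlation, in \eqn{[-1, 1]}.
#' @param stimulus which stimulus drive to use, 1 or 2.
#' @param cfg a [trajectory_config()]. The step must satisfy
#'   `dt * theta <= 0.1` for both populations.
#' @param method `"euler"` (Euler-Maruyama) or `"exact"` (exact transition).
#' @return An object of class `trajectory_pair`: a list with `times`, `x`,
#'   `y` (each of length `n_steps`, the post burn-in retained steps),
#'   `rho_in`, `seed`, `burn_in_steps`, `dt` and the parameters used.
#' @examples
#' px <- population_params(1, 1, 1, 11, 14)
#' cfg <- trajectory_config(dt = 0.01, n_steps = 2000, burn_in_steps = 1000,
#'                          x0 = 11, seed = 42)
#' tp <- simulate_ou(px, px, rho = 0.5, stimulus = 1, cfg = cfg)
#' @export
simulate_ou <- function(px, py, rho, stimulus, cfg,
                        method = c("euler", "exact")) {
  assert_population_params(px); assert_population_params(py)
  method <- match.arg(method)
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || abs(rho) > 1)
    stop("invalid correlation: `rho` must lie in [-1, 1]", call. = FALSE)
  if (!inherits(cfg, "trajectory_config"))
    stop("`cfg` must be a `trajectory_config`", call. = FALSE)
  drx <- derived_rates(px); dry <- derived_rates(py)
  if (cfg$dt * max(drx[["theta"]], dry[["theta"]]) > 0.1 + 1e-12)
    stop("configuration error: dt * theta exceeds 0.1 for at least one population",
         call. = FALSE)

  n_total <- cfg$n_steps + cfg$burn_in_steps
  set.seed(cfg$seed)
  eps <- matrix(stats::rnorm(2L * n_total), n_total, 2L) %*% t(corr_factor(rho))

  one_pop <- function(p, dr, z, x0) {
    mu <- stimulus_drive(p, stimulus) / p$alpha
    th <- dr[["theta"]]; lam <- dr[["lambda"]]
    if (method == "euler") {
      a <- 1 - th * cfg$dt
      input <- th * mu * cfg$dt + lam * sqrt(cfg$dt) * z
    } else {
      a <- exp(-th * cfg$dt)
      sd_exact <- lam * sqrt((1 - exp(-2 * th * cfg$dt)) / (2 * th))
      input <- mu * (1 - a) + sd_exact * z
    }
    as.numeric(stats::filter(input, a, method = "recursive", init = x0))
  }

  x <- one_pop(px, drx, eps[, 1L], cfg$x0[1L])
  y <- one_pop(py, dry, eps[, 2L], cfg$x0[2L])
  keep <- seq.int(cfg$burn_in_steps + 1L, n_total)
  structure(
    list(times = cfg$dt * keep, x = x[keep], y = y[keep],
         rho_in = rho, seed = cfg$seed, dt = cfg$dt,
         burn_in_steps = cfg$burn_in_steps, stimulus = stimulus,
         method = method, px = px, py = py),
    class = "trajectory_pair"
  )
}

#' Summarize a simulated trajectory pair against the stationary solution
#'
#' Computes post burn-in (the retained series is already post burn-in) sample
#' means, variances and the x-y correlation, together with standard errors
#' that account for the AR(1) autocorrelation of the sampled path: with
#' per-step autocorrelation \eqn{\phi = e^{-\theta dt}}, the variance of the
#' sample mean is inflated by \eqn{(1+\phi)/(1-\phi)} and second-moment
#' statistics use the effective sample size \eqn{n(1-\phi^2)/(1+\phi^2)}.
#'
#' @param tp a `trajectory_pair` from [simulate_ou()].
#' @return A data frame with one row per population plus a `cor` attribute:
#'   columns `population, mean, mean_se, variance, variance_se,
#'   mean_expected, variance_expected`. The attribute `cor` holds
#'   `c(estimate, se, expected)` (expected = input rho when theta_x == theta_y,
#'   otherwise the attenuated value).
#' @export
ou_summary <- function(tp) {
  stopifnot(inherits(tp, "trajectory_pair"))
  pops <- list(x = tp$px, y = tp$py)
  series <- list(x = tp$x, y = tp$y)
  n <- length(tp$x)
  rows <- lapply(names(pops), function(nm) {
    p <- pops[[nm]]
    st <- stationary_moments(p, tp$stimulus)
    th <- derived_rates(p)[["theta"]]
    phi <- exp(-th * tp$dt)
    ess_mean <- n * (1 - phi) / (1 + phi)
    ess_var <- n * (1 - phi^2) / (1 + phi^2)
    s <- series[[nm]]
    data.frame(
      population = nm,
      mean = mean(s), mean_se = sqrt(st[["variance"]] / ess_mean),
      variance = stats::var(s),
      variance_se = st[["variance"]] * sqrt(2 / ess_var),
      mean_expected = st[["mean"]], variance_expected = st[["variance"]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  thx <- derived_rates(tp$px)[["theta"]]; thy <- derived_rates(tp$py)[["theta"]]
  atten <- 2 * sqrt(thx * thy) / (thx + thy)
  rho_exp <- tp$rho_in * atten
  phi2 <- exp(-(thx + thy) * tp$dt)
  ess_c <- n * (1 - phi2) / (1 + phi2)
  r_hat <- stats::cor(tp$x, tp$y)
  attr(out, "cor") <- c(estimate = r_hat,
                        se = (1 - rho_exp^2) / sqrt(ess_c),
                        expected = rho_exp)
  out
}

#' Write a trajectory pair to CSV with a metadata sidecar
#'
#' The trajectory goes to `path` as a plain CSV with header `time,x,y`; run
#' metadata (parameters, rho, seed, dt, scheme) goes to `paste0(path, ".meta")`
#' as `key = value` lines.
#'
#' @param tp a `trajectory_pair`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(tp, path) {
  stopifnot(inherits(tp, "trajectory_pair"))
  utils::write.csv(data.frame(time = tp$times, x = tp$x, y = tp$y),
                   path, row.names = FALSE)
  meta <- c(
    sprintf("tau_x = %.17g", tp$px$tau), sprintf("alpha_x = %.17g", tp$px$alpha),
    sprintf("beta_x = %.17g", tp$px$beta),
    sprintf("nu1_x = %.17g", tp$px$nu1), sprintf("nu2_x = %.17g", tp$px$nu2),
    sprintf("tau_y = %.17g", tp$py$tau), sprintf("alpha_y = %.17g", tp$py$alpha),
    sprintf("beta_y = %.17g", tp$py$beta),
    sprintf("nu1_y = %.17g", tp$py$nu1), sprintf("nu2_y = %.17g", tp$py$nu2),
    sprintf("rho = %.17g", tp$rho_in), sprintf("stimulus = %d", tp$stimulus),
    sprintf("dt = %.17g", tp$dt), sprintf("seed = %d", tp$seed),
    sprintf("burn_in_steps = %d", tp$burn_in_steps),
    sprintf("method = %s", tp$method)
  )
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}
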