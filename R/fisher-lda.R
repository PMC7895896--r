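# Closed-form two-class Fisher LDA in network-parameter space.
#
# Feature space: Z ~ N(mu_i, Sigma), equal class covariance
#   Sigma = [[sx2, rho*sx*sy], [rho*sx*sy, sy2]],
# optimal projection W = (2 Sigma)^{-1} (mu2 - mu1), midpoint threshold, and
# error  eps = 1/2 erfc(d / (2 sqrt(2)))  with d^2 = dmu' Sigma^{-1} dmu.
# erfc is evaluated through pnorm: 1/2 erfc(d/(2 sqrt 2)) = pnorm(-d/2),
# which keeps full tail accuracy.

#' Bivariate Gaussian feature model for the LDA readout
#'
#' @param mu1,mu2 length-2 class mean vectors (rates for populations x, y).
#' @param sigma_x2,sigma_y2 marginal variances (> 0).
#' @param rho noise correlation in \eqn{[-1, 1]}. The covariance is singular
#'   exactly at `|rho| = 1`.
#' @return An object of class `feature_model`.
#' @export
feature_model <- function(mu1, mu2, sigma_x2, sigma_y2, rho) {
  if (length(mu1) != 2L || length(mu2) != 2L)
    stop("`mu1` and `mu2` must be length-2 mean vectors", call. = FALSE)
  if (sigma_x2 <= 0 || sigma_y2 <= 0)
    stop("marginal variances must be strictly positive", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || abs(rho) > 1)
    stop("invalid correlation: `rho` must lie in [-1, 1]", call. = FALSE)
  structure(
    list(mu1 = as.numeric(mu1), mu2 = as.numeric(mu2),
         sigma_x2 = sigma_x2, sigma_y2 = sigma_y2, rho = rho),
    class = "feature_model"
  )
}

#' @export
print.feature_model <- function(x, ...) {
  cat(sprintf(
    "<feature_model> mu1=(%g, %g) mu2=(%g, %g) var=(%g, %g) rho=%g\n",
    x$mu1[1], x$mu1[2], x$mu2[1], x$mu2[2], x$sigma_x2, x$sigma_y2, x$rho))
  invisible(x)
}

#' Shared covariance matrix of a feature model
#'
#' @param fm a [feature_model()].
#' @return The 2x2 covariance matrix.
#' @export
feature_cov <- function(fm) {
  off <- fm$rho * sqrt(fm$sigma_x2 * fm$sigma_y2)
  matrix(c(fm$sigma_x2, off, off, fm$sigma_y2), 2L, 2L)
}

#' Feature model induced by two integrator populations
#'
#' Class means are the stationary means under each stimulus,
#' \eqn{\mu_{i} = (\nu_{i,x}/\alpha_x,\ \nu_{i,y}/\alpha_y)}; marginal
#' variances are the stationary variances \eqn{\beta^2/(2\tau\alpha)}; `rho`
#' is installed directly as the off-diagonal correlation.
#'
#' @param px,py [population_params()] for populations x and y.
#' @param rho noise correlation in \eqn{[-1, 1]}.
#' @return A [feature_model()].
#' @examples
#' sc <- scenario_preset("identical_tuning")
#' feature_model_from_params(sc$px, sc$py, rho = 0.9)
#' @export
feature_model_from_params <- function(px, py, rho) {
  assert_population_params(px); assert_population_params(py)
  s1x <- stationary_moments(px, 1); s2x <- stationary_moments(px, 2)
  s1y <- stationary_moments(py, 1); s2y <- stationary_moments(py, 2)
  feature_model(mu1 = c(s1x[["mean"]], s1y[["mean"]]),
                mu2 = c(s2x[["mean"]], s2y[["mean"]]),
                sigma_x2 = s1x[["variance"]], sigma_y2 = s1y[["variance"]],
                rho = rho)
}

#' Closed-form Fisher LDA solution
#'
#' Solves \eqn{(2\Sigma) w = \mu_2 - \mu_1} for the optimal projection, with
#' midpoint threshold \eqn{c = w \cdot \tfrac12(\mu_1 + \mu_2) + b}, shifted
#' projected class means \eqn{\eta_i = w \cdot \mu_i + b - c}, and projected
#' variance \eqn{\zeta^2 = w^\top \Sigma w}. The bias `b` cancels out of the
#' shifted means and is fixed at 0. Orientation: class 1 projects to the
#' negative side, so `eta1 <= 0 <= eta2` whenever \eqn{w \cdot \Delta\mu > 0}
#' (always true for nonzero signal), and `eta1 == -eta2`.
#'
#' @param fm a [feature_model()] with `|rho| < 1`.
#' @return An object of class `lda_solution`: list with `w` (length-2
#'   weights), `b` (0), `c` (unshifted threshold), `eta1`, `eta2` (shifted
#'   projected class means) and `zeta2` (projected variance).
#' @export
lda_weights <- function(fm) {
  stopifnot(inherits(fm, "feature_model"))
  if (abs(fm$rho) >= 1)
    stop("singular covariance: |rho| = 1; use the factorized error limit instead",
         call. = FALSE)
  S <- feature_cov(fm)
  dmu <- fm$mu2 - fm$mu1
  w <- solve(2 * S, dmu)
  b <- 0
  cc <- sum(w * (fm$mu1 + fm$mu2) / 2) + b
  structure(
    list(w = w, b = b, c = cc,
         eta1 = sum(w * fm$mu1) + b - cc,
         eta2 = sum(w * fm$mu2) + b - cc,
         zeta2 = drop(t(w) %*% S %*% w)),
    class = "lda_solution"
  )
}

#' Signed signal-to-noise ratios of the two populations
#'
#' For population \eqn{u}, \eqn{r_u = \Delta\mu_u / \sigma_u}, the stationary
#' mean separation in units of the stationary standard deviation:
#' \deqn{r_u = \Delta\nu_u \sqrt{2 \tau_u / (\beta_u^2 \alpha_u)},}
#' with the *signed* drive difference \eqn{\Delta\nu_u = \nu_2 - \nu_1}, so
#' that populations whose tuning runs in opposite directions get opposite
#' signs (the offset-tuning scenario requires \eqn{r_x = -r_y}).
#'
#' @param px,py [population_params()] for populations x and y.
#' @return Named numeric vector `c(r_x, r_y)`.
#' @export
snr_ratios <- function(px, py) {
  r_one <- function(p) {
    (p$nu2 - p$nu1) * sqrt(2 * p$tau / (p$beta^2 * p$alpha))
  }
  assert_population_params(px); assert_population_params(py)
  c(r_x = r_one(px), r_y = r_one(py))
}

#' Squared Mahalanobis distance between the two classes
#'
#' For \eqn{|\rho| < 1},
#' \deqn{d^2 = \frac{r_x^2 + r_y^2 - 2 \rho r_x r_y}{1 - \rho^2} \ge 0.}
#' At \eqn{\rho = 1} the analytic limit is finite only when \eqn{r_x = r_y}
#' (value \eqn{r_x^2}, via the factorized equal-ratio form
#' \eqn{2 r^2/(1+\rho)}); at \eqn{\rho = -1} only when \eqn{r_x = -r_y}
#' (again \eqn{r_x^2}); otherwise the limit is `Inf`. No division-by-zero is
#' ever performed at the boundary.
#'
#' @param r a vector `c(r_x, r_y)` as from [snr_ratios()].
#' @param rho noise correlation in \eqn{[-1, 1]} (vectorized).
#' @return Squared Mahalanobis distance(s), possibly `Inf`.
#' @export
mahalanobis_sq <- function(r, rho) {
  if (length(r) != 2L || any(!is.finite(r)))
    stop("`r` must be two finite signal-to-noise ratios", call. = FALSE)
  if (any(is.na(rho)) || any(abs(rho) > 1))
    stop("invalid correlation: `rho` must lie in [-1, 1]", call. = FALSE)
  rx <- r[[1L]]; ry <- r[[2L]]
  d2 <- numeric(length(rho))
  interior <- abs(rho) < 1
  d2[interior] <-
    (rx^2 + ry^2 - 2 * rho[interior] * rx * ry) / (1 - rho[interior]^2)
  hi <- !interior & rho > 0
  lo <- !interior & rho < 0
  d2[hi] <- if (rx == ry) rx^2 else Inf
  d2[lo] <- if (rx == -ry) rx^2 else Inf
  # zero signal: d2 = 0 at every rho, including the boundaries
  if (rx == 0 && ry == 0) d2[] <- 0
  d2
}

#' Classification error from the squared Mahalanobis distance
#'
#' \deqn{\varepsilon = \tfrac12\,\mathrm{erfc}\!\left(\frac{\sqrt{d^2}}{2\sqrt2}\right)
#'   = \Phi(-d/2),}
#' the total-probability misclassification rate of the optimal linear readout
#' under equal priors. Strictly decreasing in `d2`, with
#' \eqn{\varepsilon(0) = 1/2} and \eqn{\varepsilon(\infty) = 0}.
#'
#' @param d2 squared Mahalanobis distance(s), >= 0 (may be `Inf`).
#' @return Error probability in \eqn{[0, 1/2]}.
#' @examples
#' analytic_error(36)  # = pnorm(-3)
#' @export
analytic_error <- function(d2) {
  if (any(is.na(d2)) || any(d2 < 0))
    stop("`d2` must be non-negative", call. = FALSE)
  stats::pnorm(-sqrt(d2) / 2)
}

#' Classification error from the projected LDA statistics
#'
#' The projection route: \eqn{\varepsilon = \tfrac12\,
#' \mathrm{erfc}(|\eta_1| / \sqrt{2\zeta^2})}. With the class-1-negative
#' orientation convention, \eqn{|\eta_1|} is used so either orientation of
#' `w` yields the same error. Agrees with
#' `analytic_error(mahalanobis_sq(...))` to machine accuracy.
#'
#' @param sol an `lda_solution` from [lda_weights()].
#' @return Error probability in \eqn{[0, 1/2]}.
#' @export
analytic_error_via_projection <- function(sol) {
  stopifnot(inherits(sol, "lda_solution"))
  if (!is.finite(sol$zeta2) || sol$zeta2 <= 0) {
    if (sol$eta1 == 0 && sol$eta2 == 0 && sol$zeta2 == 0) return(0.5)
    stop("invalid solution: projected variance must be positive", call. = FALSE)
  }
  stats::pnorm(-abs(sol$eta1) / sqrt(sol$zeta2))
}

#' Noise correlation of maximal readout error (closed form)
#'
#' In the interior case (\eqn{r_x r_y \neq 0}, \eqn{|r_x| \neq |r_y|}),
#' \deqn{\rho_* = \frac{\min(r_x^2, r_y^2)}{r_x r_y} \in (-1, 1).}
#' Degenerate cases: `r_x = 0` or `r_y = 0` gives a symmetric error curve
#' peaking at \eqn{\rho_* = 0}; `r_x = r_y != 0` gives a monotonically
#' increasing curve whose supremum is at the boundary \eqn{\rho_* = 1};
#' `r_x = -r_y != 0` a decreasing curve with supremum at \eqn{\rho_* = -1}.
#' Boundary suprema are flagged by the `"boundary"` attribute.
#'
#' @param r a vector `c(r_x, r_y)` as from [snr_ratios()].
#' @return The maximizing correlation, with logical attribute `boundary`
#'   (`TRUE` when the supremum sits at `|rho| = 1` and is not attained).
#' @export
rho_star <- function(r) {
  if (length(r) != 2L || any(!is.finite(r)))
    stop("`r` must be two finite signal-to-noise ratios", call. = FALSE)
  rx <- r[[1L]]; ry <- r[[2L]]
  if (rx == 0 || ry == 0) return(structure(0, boundary = FALSE))
  if (rx == ry)  return(structure(1,  boundary = TRUE))
  if (rx == -ry) return(structure(-1, boundary = TRUE))
  structure(min(rx^2, ry^2) / (rx * ry), boundary = FALSE)
}

#' Noise correlation of maximal readout error (numeric)
#'
#' Grid search of the closed-form error over an even grid on
#' \eqn{[-1 + 10^{-6},\ 1 - 10^{-6}]}, refined by bracketed maximization
#' ([stats::optimize()]) to tolerance 1e-6. Ties break toward smaller
#' \eqn{|\rho|}.
#'
#' @param px,py [population_params()] for the two populations.
#' @param grid_n grid size, >= 3.
#' @return The maximizing correlation.
#' @export
rho_argmax_numeric <- function(px, py, grid_n = 2001L) {
  if (grid_n < 3) stop("`grid_n` must be at least 3", call. = FALSE)
  r <- snr_ratios(px, py)
  lo <- -1 + 1e-6; hi <- 1 - 1e-6
  grid <- seq(lo, hi, length.out = grid_n)
  err <- analytic_error(mahalanobis_sq(r, grid))
  # ties toward smaller |rho|
  best <- which(err >= max(err) - .Machine$double.xmin)
  i <- best[which.min(abs(grid[best]))]
  bl <- grid[max(1L, i - 1L)]; bu <- grid[min(grid_n, i + 1L)]
  opt <- stats::optimize(function(p) analytic_error(mahalanobis_sq(r, p)),
                         lower = bl, upper = bu, maximum = TRUE, tol = 1e-6)
  if (opt$objective >= err[i]) opt$maximum else grid[i]
}
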