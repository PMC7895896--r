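# Monte-Carlo verification of the closed-form error: stationary sampling,
# train/test split, pooled-covariance LDA fit, held-out misclassification.

#' Labeled samples from the stationary feature distribution
#'
#' Draws `n_per_class` points per class from the bivariate Gaussian
#' \eqn{N(\mu_i, \Sigma)} of the feature model. Sampling applies the
#' closed-form lower-triangular factor of \eqn{\Sigma} to independent
#' standard normals, which remains valid (rank-1 scatter) at the singular
#' boundary `|rho| = 1`.
#'
#' @param fm a [feature_model()].
#' @param n_per_class draws per class, >= 1.
#' @param seed RNG seed.
#' @return An object of class `sample_set`: list with `features`
#'   (2n x 2 matrix, columns `x`, `y`), `labels` (integer, 1 or 2), `seed`.
#' @examples
#' fm <- feature_model(c(11, 11), c(14, 14), 0.5, 0.5, rho = 0.9)
#' s <- sample_stationary(fm, n_per_class = 100, seed = 7)
#' @export
sample_stationary <- function(fm, n_per_class, seed) {
  stopifnot(inherits(fm, "feature_model"))
  if (n_per_class < 1 || n_per_class != round(n_per_class))
    stop("`n_per_class` must be a positive integer", call. = FALSE)
  n <- as.integer(n_per_class)
  L <- diag(c(sqrt(fm$sigma_x2), sqrt(fm$sigma_y2))) %*% corr_factor(fm$rho)
  set.seed(seed)
  z <- matrix(stats::rnorm(2L * 2L * n), 2L * n, 2L) %*% t(L)
  feats <- z + rbind(matrix(fm$mu1, n, 2L, byrow = TRUE),
                     matrix(fm$mu2, n, 2L, byrow = TRUE))
  colnames(feats) <- c("x", "y")
  structure(
    list(features = feats, labels = rep(c(1L, 2L), each = n), seed = seed),
    class = "sample_set"
  )
}

new_sample_set <- function(features, labels, seed = NA_integer_) {
  colnames(features) <- c("x", "y")
  structure(list(features = features, labels = as.integer(labels), seed = seed),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d rows (%s)\n", nrow(x$features),
              paste(sprintf("class %d: %d", sort(unique(x$labels)),
                            tabulate(x$labels)[sort(unique(x$labels))]),
                    collapse = ", ")))
  invisible(x)
}

#' Train/test split of a sample set
#'
#' By default the split is stratified per class: each class contributes
#' `round(train_fraction * n_class)` training rows. A non-stratified mode
#' draws the training rows from the pooled set instead.
#'
#' @param s a `sample_set`.
#' @param train_fraction proportion in (0, 1).
#' @param seed RNG seed; the split is deterministic given the seed.
#' @param stratified stratify per class (default `TRUE`).
#' @return List with elements `train` and `test`, both `sample_set`s; the two
#'   are disjoint and exhaustive.
#' @export
split_samples <- function(s, train_fraction, seed, stratified = TRUE) {
  stopifnot(inherits(s, "sample_set"))
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  n <- nrow(s$features)
  set.seed(seed)
  if (stratified) {
    idx_train <- unlist(lapply(sort(unique(s$labels)), function(k) {
      rows <- which(s$labels == k)
      sample(rows, round(train_fraction * length(rows)))
    }), use.names = FALSE)
  } else {
    idx_train <- sample.int(n, round(train_fraction * n))
  }
  idx_test <- setdiff(seq_len(n), idx_train)
  if (length(idx_train) == 0L || length(idx_test) == 0L)
    stop("degenerate split: one side is empty", call. = FALSE)
  list(train = new_sample_set(s$features[idx_train, , drop = FALSE],
                              s$labels[idx_train], seed),
       test = new_sample_set(s$features[idx_test, , drop = FALSE],
                             s$labels[idx_test], seed))
}

#' Fit a two-class LDA from data
#'
#' Sample analogue of the closed-form solution: class means are per-class
#' sample means, the pooled covariance is the within-class scatter divided by
#' `n - 2` (unbiased, two classes), and the weights solve
#' \eqn{(2 \hat\Sigma)\, \hat w = \hat m_2 - \hat m_1}. The orientation is
#' normalized so \eqn{\hat w \cdot (\hat m_2 - \hat m_1) > 0}.
#'
#' @param train a `sample_set` with >= 2 rows in each of classes 1 and 2.
#' @return An object of class `empirical_fit`: list with `w_hat`, `c_hat`,
#'   `class_means` (2x2 matrix, one row per class) and `pooled_cov`.
#' @export
fit_lda <- function(train) {
  stopifnot(inherits(train, "sample_set"))
  f <- train$features; lab <- train$labels
  if (sum(lab == 1L) < 2L || sum(lab == 2L) < 2L)
    stop("need at least two training samples per class", call. = FALSE)
  m1 <- colMeans(f[lab == 1L, , drop = FALSE])
  m2 <- colMeans(f[lab == 2L, , drop = FALSE])
  ctr <- f - rbind(m1, m2)[lab, ]
  pooled <- crossprod(ctr) / (nrow(f) - 2L)
  pooled <- (pooled + t(pooled)) / 2
  w <- tryCatch(solve(2 * pooled, m2 - m1),
                error = function(e) stop("singular fit: pooled covariance is not invertible",
                                         call. = FALSE))
  if (rcond(pooled) < .Machine$double.eps * 100)
    stop("singular fit: pooled covariance is not invertible", call. = FALSE)
  if (sum(w * (m2 - m1)) < 0) w <- -w
  structure(
    list(w_hat = w, c_hat = sum(w * (m1 + m2) / 2),
         class_means = rbind(`1` = m1, `2` = m2), pooled_cov = pooled),
    class = "empirical_fit"
  )
}

#' Held-out misclassification of a fitted decoder
#'
#' Assigns label 2 when \eqn{\hat w \cdot z > \hat c} (the fit's orientation
#' guarantees class 2 sits on the positive side); points exactly on the
#' boundary go to class 1 (a deterministic rule for a measure-zero event).
#'
#' @param fit an `empirical_fit`.
#' @param test a non-empty `sample_set`.
#' @return An object of class `error_estimate`: list with `error`
#'   (misclassified proportion), `n_test` and `std_err`
#'   (\eqn{\sqrt{\varepsilon(1-\varepsilon)/n}}).
#' @export
classify_and_error <- function(fit, test) {
  stopifnot(inherits(fit, "empirical_fit"), inherits(test, "sample_set"))
  if (nrow(test$features) == 0L) stop("`test` must be non-empty", call. = FALSE)
  pred <- ifelse(drop(test$features %*% fit$w_hat) > fit$c_hat, 2L, 1L)
  err <- mean(pred != test$labels)
  structure(
    list(error = err, n_test = length(pred),
         std_err = sqrt(err * (1 - err) / length(pred))),
    class = "error_estimate"
  )
}

#' @export
print.error_estimate <- function(x, ...) {
  cat(sprintf("<error_estimate> %.4f (n_test = %d, se = %.4g)\n",
              x$error, x$n_test, x$std_err))
  invisible(x)
}

#' Full empirical decoding chain for one feature model
#'
#' sample -> split -> fit -> held-out error, with the sampling conditions
#' used throughout: 5000 points per class and an 80/20 stratified split.
#'
#' @param fm a [feature_model()].
#' @param n_per_class samples per class (default 5000).
#' @param train_fraction training proportion (default 0.8).
#' @param seed RNG seed (sampling uses `seed`, the split `seed + 1`).
#' @param stratified stratified split (default `TRUE`).
#' @return An `error_estimate`.
#' @export
empirical_error <- function(fm, n_per_class = 5000L, train_fraction = 0.8,
                            seed = 1L, stratified = TRUE) {
  s <- sample_stationary(fm, n_per_class, seed)
  sp <- split_samples(s, train_fraction, seed + 1L, stratified = stratified)
  classify_and_error(fit_lda(sp$train), sp$test)
}

#' Read and write labeled sample sets as CSV
#'
#' Plain CSV with header `x,y,label`.
#'
#' @param s a `sample_set`.
#' @param path CSV path.
#' @return `write_samples()` returns `path` invisibly; `read_samples()`
#'   returns a `sample_set`.
#' @export
write_samples <- function(s, path) {
  stopifnot(inherits(s, "sample_set"))
  utils::write.csv(data.frame(x = s$features[, 1L], y = s$features[, 2L],
                              label = s$labels),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("x", "y", "label") %in% names(d)))
  new_sample_set(cbind(x = d$x, y = d$y), d$label)
}
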