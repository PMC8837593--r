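#' Flexible least squares configuration
#'
#' @param mu Lagrange-multiplier weight on the dynamic (coefficient-increment)
#'   error; `mu >= 0`. Default 100, the conventional TR-independent setting.
#' @param direction_rule which region of an unordered pair acts as the
#'   predictor x: `"lower"` (lower-index region, default) or `"average"`
#'   (average of the two directed coefficient series).
#' @return object of class `fls_config`.
#' @export
fls_config <- function(mu = 100, direction_rule = c("lower", "average")) {
  if (!is_scalar_number(mu) || mu < 0) stop_invalid("mu must be a non-negative number")
  structure(list(mu = mu, direction_rule = match.arg(direction_rule)),
            class = "fls_config")
}

# Vectorized symmetric tridiagonal solve (Thomas algorithm) for the FLS
# normal equations of many pairs at once.
#
# For each row p, minimizes over beta
#   sum_t (Y[p,t] - X[p,t] beta_t)^2 + mu * sum_{t<T} (beta_{t+1} - beta_t)^2,
# whose stationarity condition is a symmetric tridiagonal system with
# diagonal X^2 + mu * (1[t>1] + 1[t<T]), off-diagonal -mu and right-hand side
# X * Y. The matrix is positive definite whenever mu > 0 and the row of X is
# not identically zero, so the sweep needs no pivoting.
fls_solve <- function(X, Y, mu) {
  T <- ncol(X); n <- nrow(X)
  d <- X^2
  if (T >= 2L) {
    d[, 1L] <- d[, 1L] + mu
    d[, T] <- d[, T] + mu
    if (T > 2L) d[, 2:(T - 1L)] <- d[, 2:(T - 1L)] + 2 * mu
  }
  B <- X * Y
  e <- -mu
  cp <- matrix(0, n, T)
  bp <- matrix(0, n, T)
  cp[, 1L] <- e / d[, 1L]
  bp[, 1L] <- B[, 1L] / d[, 1L]
  for (t in 2:T) {
    denom <- d[, t] - e * cp[, t - 1L]
    cp[, t] <- e / denom
    bp[, t] <- (B[, t] - e * bp[, t - 1L]) / denom
  }
  beta <- matrix(0, n, T)
  beta[, T] <- bp[, T]
  for (t in (T - 1L):1L) beta[, t] <- bp[, t] - cp[, t] * beta[, t + 1L]
  beta
}

#' Flexible least squares for one region pair
#'
#' Computes the framewise time-varying regression coefficient series beta(t)
#' of y on x by minimizing the cost-incompatibility function
#' \deqn{C(\beta; \mu) = \sum_t (y_t - x_t \beta_t)^2 +
#'       \mu \sum_{t<T} (\beta_{t+1} - \beta_t)^2,}
#' the weighted sum of the measurement fit error and the dynamic error. The
#' unique global minimizer solves a symmetric tridiagonal linear system and is
#' obtained exactly in O(T). Small `mu` admits erratic solutions with large
#' dynamic error; as `mu` grows the solution tends to the constant ordinary
#' least squares slope.
#'
#' @param x predictor series (frames; not identically zero).
#' @param y response series (same length, T >= 2).
#' @param mu non-negative dynamic-error weight; default 100.
#' @return list with `beta` (length-T coefficient series) and `cost`, a list
#'   with `measurement_error`, `dynamic_error` and
#'   `total = measurement_error + mu * dynamic_error` evaluated at the
#'   solution.
#' @export
#' @examples
#' x <- c(1, 1, 1, 1); y <- c(1, 2, 2, 1)
#' fls_pair(x, y, mu = 1)$beta   # 4/3 5/3 5/3 4/3
fls_pair <- function(x, y, mu = 100) {
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  T <- length(x)
  if (T < 2L) stop_invalid("need at least 2 frames")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_invalid("inputs must be finite")
  if (!is_scalar_number(mu) || mu < 0) stop_invalid("mu must be a non-negative number")
  if (all(x == 0)) stop_invalid("x is identically zero: beta is unidentified")
  if (mu == 0 && any(x == 0))
    stop_invalid("mu = 0 with zero entries in x: solution is non-unique")
  beta <- drop(fls_solve(matrix(x, 1L), matrix(y, 1L), mu))
  rm2 <- sum((y - x * beta)^2)
  rd2 <- sum(diff(beta)^2)
  list(beta = beta,
       cost = list(measurement_error = rm2, dynamic_error = rd2,
                   total = mu * rd2 + rm2))
}

#' FLS dynamic connectivity for all region pairs
#'
#' Runs [fls_pair()] for every unordered pair of regions in a recording, in
#' the canonical lexicographic pair order ((1,2), (1,3), ..., (R-1,R)). With
#' `direction_rule = "lower"` the lower-index region is the predictor; with
#' `"average"` the two directed coefficient series are averaged.
#'
#' @param recording a `subject_recording`, typically residualized and
#'   standardized by [regress_confounds()].
#' @param config an [fls_config()].
#' @return object of class `dfc_tensor`: list with `beta` (pairs x frames
#'   coefficient matrix), `pairs` (pair index table), `subject_id`,
#'   `condition`, `mu`, `direction_rule`.
#' @export
fls_all_pairs <- function(recording, config = fls_config()) {
  stopifnot(inherits(recording, "subject_recording"),
            inherits(config, "fls_config"))
  ts <- recording$timeseries
  R <- nrow(ts)
  pairs <- pair_index(R)
  zero <- rowSums(ts != 0) == 0L
  if (any(zero)) {
    bad <- pairs[zero[pairs$i] | zero[pairs$j], , drop = FALSE]
    stop_invalid("identically-zero region(s) make pairs unidentified: %s",
                 paste(sprintf("(%d,%d)", bad$i, bad$j), collapse = " "))
  }
  Xi <- ts[pairs$i, , drop = FALSE]
  Xj <- ts[pairs$j, , drop = FALSE]
  beta <- fls_solve(Xi, Xj, config$mu)
  if (config$direction_rule == "average")
    beta <- (beta + fls_solve(Xj, Xi, config$mu)) / 2
  structure(list(beta = beta, pairs = pairs,
                 subject_id = recording$subject_id,
                 condition = recording$condition,
                 mu = config$mu, direction_rule = config$direction_rule),
            class = "dfc_tensor")
}

#' Static (time-averaged) functional connectivity
#'
#' Pearson correlation between every pair of regional time series, in the
#' canonical pair order. Constant regions yield `NA` correlations with a
#' warning naming the regions.
#'
#' @param recording a `subject_recording`.
#' @return data.frame with columns `i`, `j`, `r`.
#' @export
static_fc <- function(recording) {
  stopifnot(inherits(recording, "subject_recording"))
  ts <- recording$timeseries
  pairs <- pair_index(nrow(ts))
  sds <- apply(ts, 1L, stats::sd)
  flat <- sds == 0
  if (any(flat))
    warning(sprintf("constant region(s) %s: their correlations are NA",
                    paste(rownames(ts)[flat], collapse = ", ")))
  C <- suppressWarnings(stats::cor(t(ts)))
  pairs$r <- C[cbind(pairs$i, pairs$j)]
  pairs$r[flat[pairs$i] | flat[pairs$j]] <- NA_real_
  pairs
}

#' @export
print.dfc_tensor <- function(x, ...) {
  cat(sprintf("dfc_tensor %s (%s): %d pairs x %d frames, mu = %g, predictor = %s\n",
              x$subject_id, x$condition, nrow(x$beta), ncol(x$beta), x$mu,
              x$direction_rule))
  invisible(x)
}
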