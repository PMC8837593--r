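# Independent oracles used to freeze expected values. These deliberately take
# generic, brute-force routes (dense solves, generic optimizers, textbook
# formulas) so they share no code with the implementation they check.

# Dense solve of the FLS normal equations: build the full T x T tridiagonal
# matrix and call solve().
dense_fls <- function(x, y, mu) {
  T <- length(x)
  A <- diag(x^2 + mu * c(1, rep(2, max(T - 2, 0)), 1)[seq_len(T)])
  for (t in seq_len(T - 1)) A[t, t + 1] <- A[t + 1, t] <- -mu
  solve(A, x * y)
}

# Generic convex optimizer for the L2 logistic objective (unpenalized
# intercept), via BFGS at tight tolerance.
brute_logistic <- function(X, y, C = 1) {
  obj <- function(th) {
    m <- drop(cbind(1, X) %*% th) * (2 * y - 1)
    0.5 * sum(th[-1]^2) + C * sum(log1p(exp(-abs(m))) + pmax(-m, 0))
  }
  o <- stats::optim(rep(0, ncol(X) + 1), obj, method = "BFGS",
                    control = list(reltol = 1e-15, maxit = 2000))
  list(intercept = o$par[1], weights = o$par[-1])
}

# First-order partial correlation from pairwise correlations (textbook
# recursion), single covariate z.
partial_r_recursive <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Direct O(n m) discrete convolution, truncated to length n.
direct_convolve <- function(signal, kernel) {
  n <- length(signal)
  out <- numeric(n)
  for (t in seq_len(n)) {
    k <- seq_len(min(t, length(kernel)))
    out[t] <- sum(kernel[k] * signal[t - k + 1])
  }
  out
}

# Sliding-window Pearson correlation (window w, centered on each frame where
# the full window fits).
sliding_cor <- function(x, y, w = 30) {
  T <- length(x)
  half <- w %/% 2
  out <- rep(NA_real_, T)
  for (t in seq.int(half + 1, T - half)) {
    idx <- (t - half):(t + half)
    out[t] <- cor(x[idx], y[idx])
  }
  out
}

# Small planted cohort used by several classifier tests.
small_planted_cohort <- function(n_subjects = 40, n_regions = 6, n_frames = 80,
                                 seed = 1, ...) {
  simulate_cohort(cohort_spec(n_subjects = n_subjects, n_regions = n_regions,
                              n_frames = n_frames,
                              planted_pairs = rbind(c(1, 2), c(3, 4)),
                              seed = seed, ...))
}
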