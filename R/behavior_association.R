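#' Per-subject task identifiability
#'
#' For each subject, the mean probability estimate of the subject's task
#' sample over all region pairs whose network block is suprathreshold in the
#' given configuration. Training subjects contribute out-of-fold
#' probabilities and test subjects held-out probabilities, so every subject
#' gets a score. Optionally the rest sample enters as `1 - p(rest)` averaged
#' in, giving a symmetric two-condition variant.
#'
#' @param results an `mtpa_results` from [run_all_connections()].
#' @param config a nonempty `thresholded_config` from [threshold_matrix()].
#' @param assignment the [network_assignment()] used to build the
#'   configuration.
#' @param include_rest if TRUE, average `1 - p` of the rest sample together
#'   with `p` of the task sample.
#' @return data.frame with `subject_id`, `score`, `n_connections`,
#'   `partition`.
#' @export
task_identifiability <- function(results, config, assignment,
                                 include_rest = FALSE) {
  stopifnot(inherits(results, "mtpa_results"),
            inherits(config, "thresholded_config"),
            inherits(assignment, "network_assignment"))
  if (!any(config$mask[upper.tri(config$mask, diag = TRUE)] != 0))
    stop_invalid("empty configuration: task identifiability is undefined")
  net_of <- stats::setNames(assignment$table$network, assignment$table$region)
  nets <- rownames(config$mask)
  pr <- results$pairs
  keep <- !(pr$i %in% assignment$drop) & !(pr$j %in% assignment$drop)
  a <- net_of[as.character(pr$i)]
  b <- net_of[as.character(pr$j)]
  supra <- keep & !is.na(a) & !is.na(b) &
    config$mask[cbind(match(a, nets), match(b, nets))] != 0
  if (!any(supra))
    stop_invalid("no region pair contributes to the suprathreshold configuration")
  sm <- results$samples
  task_rows <- which(sm$condition == "task")
  p_task <- results$prob[task_rows, supra, drop = FALSE]
  score <- rowMeans(p_task, na.rm = TRUE)
  if (include_rest) {
    rest_rows <- match(sm$subject[task_rows], sm$subject[sm$condition == "rest"])
    p_rest <- results$prob[which(sm$condition == "rest")[rest_rows], supra,
                           drop = FALSE]
    score <- (score + rowMeans(1 - p_rest, na.rm = TRUE)) / 2
  }
  data.frame(subject_id = sm$subject[task_rows], score = score,
             n_connections = sum(supra),
             partition = sm$partition[task_rows])
}

#' Pearson partial correlation with covariate control
#'
#' Correlation between the residuals of `x` and `y` after each is regressed
#' (with intercept) on the covariates; with no covariates this is exactly the
#' plain Pearson correlation. The p-value comes from the t distribution with
#' `n - 2 - k` degrees of freedom, k the number of covariates. Rows with any
#' missing value are dropped (pairwise-complete analysis).
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates optional numeric matrix/data.frame of covariate columns.
#' @return list with `r`, `p`, `n` (rows used).
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  Z <- if (is.null(covariates)) matrix(nrow = length(x), ncol = 0L)
       else as.matrix(covariates)
  ok <- stats::complete.cases(x, y, Z)
  x <- x[ok]; y <- y[ok]; Z <- Z[ok, , drop = FALSE]
  n <- length(x); k <- ncol(Z)
  if (n < k + 3L) stop_invalid("need at least %d complete rows, got %d", k + 3L, n)
  D <- cbind(1, Z)
  qrD <- qr(D)
  rx <- qr.resid(qrD, x)
  ry <- qr.resid(qrD, y)
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12)
    stop_invalid("zero residual variance after partialling: correlation undefined")
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df), n = n)
}

#' Screen behavioral measures against identifiability scores
#'
#' One Pearson partial correlation per behavior column, controlling for the
#' named covariates; a measure is flagged significant iff its Bonferroni-
#' corrected p-value passes (`p < alpha / m`) AND its effect size passes
#' (`|r| > r_min`). `m` is the configured width of the measure battery (192
#' in the canonical layout) and stays fixed even if some columns are skipped,
#' matching the printed divisor.
#'
#' @param scores data.frame with `subject_id` and `score` (e.g. from
#'   [task_identifiability()]).
#' @param behavior data.frame with `subject_id`, measure columns and
#'   covariate columns.
#' @param covariates names of covariate columns in `behavior`
#'   (default `c("age", "sex")`).
#' @param alpha family-wise error rate, default 0.05.
#' @param m Bonferroni divisor, default 192.
#' @param r_min minimum absolute effect size, default 0.1.
#' @param extra_covariates optional numeric matrix of additional covariate
#'   columns aligned with `behavior` rows (used by [pc_partial()]).
#' @return data.frame of class `association_results` with columns `measure`,
#'   `r`, `p`, `n`, `significant`, sorted by decreasing `|r|`.
#' @export
screen_measures <- function(scores, behavior, covariates = c("age", "sex"),
                            alpha = 0.05, m = 192, r_min = 0.1,
                            extra_covariates = NULL) {
  stopifnot(is.data.frame(scores), is.data.frame(behavior))
  if (!all(covariates %in% names(behavior)))
    stop_invalid("covariate column(s) missing from behavior table: %s",
                 paste(setdiff(covariates, names(behavior)), collapse = ", "))
  merged <- merge(scores[, c("subject_id", "score")], behavior,
                  by = "subject_id", sort = TRUE)
  Z <- as.matrix(merged[, covariates, drop = FALSE])
  if (!is.null(extra_covariates)) {
    extra <- as.matrix(extra_covariates)
    Z <- cbind(Z, extra[match(merged$subject_id, behavior$subject_id), ,
                        drop = FALSE])
  }
  measures <- setdiff(names(behavior), c("subject_id", covariates))
  rows <- list()
  for (mm in measures) {
    v <- merged[[mm]]
    if (!is.numeric(v)) {
      warning(sprintf("non-numeric measure '%s' skipped", mm))
      next
    }
    pc <- tryCatch(partial_correlation(merged$score, v, Z),
                   error = function(e) {
                     warning(sprintf("measure '%s' skipped: %s", mm,
                                     conditionMessage(e)))
                     NULL
                   })
    if (is.null(pc)) next
    rows[[mm]] <- data.frame(measure = mm, r = pc$r, p = pc$p, n = pc$n)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(measure = character(), r = numeric(),
                                      p = numeric(), n = integer())
  out$significant <- out$p < alpha / m & abs(out$r) > r_min
  out <- out[order(-abs(out$r)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("association_results", class(out))
  out
}

#' Behavioral screen with principal-component covariates
#'
#' Extracts the top principal components of a named set of cognition columns
#' and a named set of task-performance columns (each standardized first),
#' appends the component scores to the covariate matrix, and re-runs
#' [screen_measures()]. With `n_components = 0` this is identical to the
#' plain screen.
#'
#' @inheritParams screen_measures
#' @param cognition_cols,performance_cols names of behavior columns forming
#'   each set (nonempty when `n_components > 0`).
#' @param n_components number of leading components per set.
#' @return an `association_results` data.frame.
#' @export
pc_partial <- function(scores, behavior, cognition_cols, performance_cols,
                       n_components = 1, covariates = c("age", "sex"),
                       alpha = 0.05, m = 192, r_min = 0.1) {
  n_components <- as.integer(n_components)
  if (n_components == 0L)
    return(screen_measures(scores, behavior, covariates, alpha, m, r_min))
  pc_set <- function(cols, prefix) {
    if (length(cols) == 0L) stop_invalid("empty column set for %s", prefix)
    if (!all(cols %in% names(behavior)))
      stop_invalid("column(s) missing from behavior table: %s",
                   paste(setdiff(cols, names(behavior)), collapse = ", "))
    M <- as.matrix(behavior[, cols, drop = FALSE])
    if (nrow(M) <= n_components)
      stop_invalid("fewer rows than requested components")
    M <- scale(M)
    M <- M[, colSums(!is.finite(M)) < nrow(M), drop = FALSE]  # drop constants
    pc <- stats::prcomp(M[stats::complete.cases(M), , drop = FALSE],
                        center = FALSE, scale. = FALSE)
    sc <- matrix(NA_real_, nrow(M), n_components)
    sc[stats::complete.cases(M), ] <-
      pc$x[, seq_len(n_components), drop = FALSE]
    colnames(sc) <- sprintf("%s_pc%d", prefix, seq_len(n_components))
    sc
  }
  extra <- cbind(pc_set(cognition_cols, "cognition"),
                 pc_set(performance_cols, "performance"))
  screen_measures(scores, behavior, covariates, alpha, m, r_min,
                  extra_covariates = extra)
}
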