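#' Confound regression specification
#'
#' Selects which nuisance terms enter the per-region GLM. An intercept is
#' always included. The `raw` profile (all flags off) reproduces the
#' no-additional-preprocessing variant of the pipeline.
#'
#' @param use_fd include the framewise-displacement confound row.
#' @param use_tissue_means include the tissue-mean confound rows.
#' @param use_task_regressors include HRF-convolved condition regressors when
#'   the recording carries a block design.
#' @param standardize_output re-standardize each region's residuals to zero
#'   mean, unit variance (makes downstream FLS coefficients comparable across
#'   pairs and subjects).
#' @return object of class `regression_spec`.
#' @export
regression_spec <- function(use_fd = TRUE, use_tissue_means = TRUE,
                            use_task_regressors = TRUE,
                            standardize_output = TRUE) {
  structure(list(use_fd = isTRUE(use_fd),
                 use_tissue_means = isTRUE(use_tissue_means),
                 use_task_regressors = isTRUE(use_task_regressors),
                 add_intercept = TRUE,
                 standardize_output = isTRUE(standardize_output)),
            class = "regression_spec")
}

#' Regress confound and mean task-activation variance out of a recording
#'
#' Fits one ordinary-least-squares GLM per region on
#' \[intercept | selected confound rows | HRF-convolved condition regressors\]
#' and replaces the time series by the residuals, which are orthogonal to all
#' retained regressors. Task regressors are only used when the recording has a
#' block design (rest recordings are residualized on confounds alone).
#'
#' @param recording a `subject_recording`.
#' @param spec a [regression_spec()].
#' @param hrf optional HRF kernel for the task regressors; default
#'   [canonical_hrf()] at the design's TR.
#' @return the recording with residualized (and, by default, re-standardized)
#'   `timeseries`.
#' @export
regress_confounds <- function(recording, spec = regression_spec(), hrf = NULL) {
  stopifnot(inherits(recording, "subject_recording"),
            inherits(spec, "regression_spec"))
  ts <- recording$timeseries
  T <- ncol(ts)
  conf <- recording$confounds
  if (!is.null(conf) && ncol(conf) != T)
    stop_invalid("confound rows must have the same frame count as the time series")
  cols <- list(intercept = rep(1, T))
  if (spec$use_fd && "fd" %in% rownames(conf)) cols$fd <- conf["fd", ]
  if (spec$use_tissue_means && !is.null(conf)) {
    for (nm in rownames(conf)[startsWith(rownames(conf), "tissue")])
      cols[[nm]] <- conf[nm, ]
  }
  if (spec$use_task_regressors && !is.null(recording$design)) {
    design <- recording$design
    if (design$n_frames != T)
      stop_invalid("design has %d frames but recording has %d", design$n_frames, T)
    if (is.null(hrf)) hrf <- canonical_hrf(design$tr)
    regs <- convolve_design(design, hrf)
    for (r in seq_len(nrow(regs)))
      cols[[paste0("task_", rownames(regs)[r])]] <- regs[r, ]
  }
  X <- do.call(cbind, cols)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop_invalid("rank-deficient design matrix; offending column(s): %s",
                 paste(bad, collapse = ", "))
  }
  resid <- t(qr.resid(qrX, t(ts)))
  if (spec$standardize_output) {
    sds <- apply(resid, 1L, stats::sd)
    flat <- sds < 1e-10
    if (any(flat))
      warning(sprintf("region(s) %s have (near-)constant residuals; left unscaled",
                      paste(rownames(ts)[flat], collapse = ", ")))
    keep <- !flat
    resid[keep, ] <- (resid[keep, , drop = FALSE] -
                        rowMeans(resid[keep, , drop = FALSE])) /
      apply(resid[keep, , drop = FALSE], 1L, stats::sd)
  }
  dimnames(resid) <- dimnames(ts)
  recording$timeseries <- resid
  recording$preprocessed <- TRUE
  recording
}

#' Standardize a series to zero mean and unit sample variance
#'
#' @param x numeric vector with finite values and nonzero variance.
#' @return `(x - mean(x)) / sd(x)`.
#' @export
standardize <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop_invalid("input must be finite numeric")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop_invalid("constant series: zero variance")
  (x - mean(x)) / s
}

#' Trim a rest recording to the task length
#'
#' Keeps the first `t_task` frames of the time series, confounds and
#' ground-truth coupling so rest and task feature vectors have equal length.
#'
#' @param rest a `subject_recording` with at least `t_task` frames.
#' @param t_task number of frames to retain (>= 1).
#' @return the trimmed recording.
#' @export
trim_rest <- function(rest, t_task) {
  stopifnot(inherits(rest, "subject_recording"))
  t_task <- as.integer(t_task)
  if (t_task < 1L) stop_invalid("t_task must be >= 1")
  T <- ncol(rest$timeseries)
  if (t_task > T)
    stop_invalid("rest recording has %d frames, fewer than the requested %d", T, t_task)
  keep <- seq_len(t_task)
  rest$timeseries <- rest$timeseries[, keep, drop = FALSE]
  rest$confounds <- rest$confounds[, keep, drop = FALSE]
  if (!is.null(rest$true_coupling))
    rest$true_coupling <- rest$true_coupling[, keep, drop = FALSE]
  rest
}

#' Preprocess every recording of a cohort
#'
#' Applies [regress_confounds()] to each task and rest recording (task
#' regressors only where a design is present) and trims rest recordings to
#' the task length.
#'
#' @param cohort an `mtpa_cohort` from [simulate_cohort()].
#' @param spec a [regression_spec()]; use
#'   `regression_spec(FALSE, FALSE, FALSE, FALSE)` for the raw variant.
#' @return the cohort with residualized recordings.
#' @export
preprocess_cohort <- function(cohort, spec = regression_spec()) {
  stopifnot(inherits(cohort, "mtpa_cohort"))
  raw <- !spec$use_fd && !spec$use_tissue_means && !spec$use_task_regressors &&
    !spec$standardize_output
  for (s in seq_along(cohort$recordings)) {
    task <- cohort$recordings[[s]]$task
    rest <- cohort$recordings[[s]]$rest
    if (!raw) {
      task <- regress_confounds(task, spec)
      rest <- regress_confounds(rest, spec)
    }
    cohort$recordings[[s]]$task <- task
    cohort$recordings[[s]]$rest <- trim_rest(rest, ncol(task$timeseries))
  }
  cohort
}
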