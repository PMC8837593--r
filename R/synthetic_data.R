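#' Task block design
#'
#' Describes a block paradigm on the acquisition frame grid: a set of events,
#' each with a condition label, an onset and a duration in seconds.
#'
#' @param conditions character vector, condition label per event.
#' @param onsets numeric vector, event onsets in seconds (non-negative,
#'   strictly increasing within each condition).
#' @param durations numeric vector, event durations in seconds (> 0).
#' @param tr repetition time in seconds per frame (> 0).
#' @param n_frames number of acquired frames.
#' @return object of class `block_design`.
#' @export
#' @examples
#' block_design(c("A", "B"), onsets = c(10, 40), durations = c(18, 18),
#'              tr = 0.72, n_frames = 120)
block_design <- function(conditions, onsets, durations, tr, n_frames) {
  if (!is_scalar_number(tr) || tr <= 0) stop_invalid("tr must be a positive number")
  n_frames <- as.integer(n_frames)
  if (length(conditions) != length(onsets) || length(onsets) != length(durations))
    stop_invalid("conditions, onsets and durations must have equal length")
  if (any(onsets < 0)) stop_invalid("onsets must be non-negative")
  if (any(durations <= 0)) stop_invalid("durations must be positive")
  for (cond in unique(conditions)) {
    o <- onsets[conditions == cond]
    if (length(o) > 1L && any(diff(o) <= 0))
      stop_invalid("onsets must be strictly increasing within condition '%s'", cond)
  }
  if (any(onsets + durations > n_frames * tr + 1e-9))
    stop_invalid("an event extends beyond the acquisition (onset + duration > n_frames * tr)")
  structure(list(condition_names = unique(conditions),
                 events = data.frame(condition = as.character(conditions),
                                     onset = as.numeric(onsets),
                                     duration = as.numeric(durations)),
                 tr = tr, n_frames = n_frames),
            class = "block_design")
}

#' Default alternating two-condition block design
#'
#' Convenience constructor used by the cohort simulator: 18 s blocks of two
#' alternating conditions separated by 12 s rest gaps, starting 10 s into the
#' acquisition, for as many blocks as fit.
#'
#' @inheritParams block_design
#' @return a [block_design()].
#' @export
default_block_design <- function(n_frames, tr = 0.72) {
  total <- n_frames * tr
  block <- 18; gap <- 12; start <- 10
  if (total < start + block) {
    # short acquisitions: scale the paradigm to fit
    start <- 0.1 * total; block <- 0.35 * total; gap <- 0.15 * total
  }
  onsets <- seq(start, by = block + gap, length.out = 64L)
  onsets <- onsets[onsets + block <= total]
  conds <- rep(c("A", "B"), length.out = length(onsets))
  block_design(conds, onsets, rep(block, length(onsets)), tr, n_frames)
}

#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style canonical HRF: a gamma density peaking at ~5-6 s minus a later
#' undershoot gamma (peak 16 s) scaled by 1/6, sampled on the frame grid.
#'
#' @param tr sampling interval in seconds (> 0).
#' @param duration kernel support in seconds (>= 20).
#' @return numeric kernel sampled at `t = 0, tr, 2 tr, ...` up to `duration`;
#'   first sample is exactly 0.
#' @export
#' @examples
#' h <- canonical_hrf(0.72)
#' which.max(h)   # peak near t = 5 s
canonical_hrf <- function(tr, duration = 32) {
  if (!is_scalar_number(tr) || tr <= 0) stop_invalid("tr must be a positive number")
  if (!is_scalar_number(duration) || duration < 20)
    stop_invalid("duration must be at least 20 s to cover the undershoot")
  t <- seq(0, duration, by = tr)
  stats::dgamma(t, shape = 6, rate = 1) - stats::dgamma(t, shape = 16, rate = 1) / 6
}

#' Convolve a block design with an HRF kernel
#'
#' Builds one boxcar per condition on the frame grid (1 while a block of that
#' condition is on, 0 elsewhere), convolves it with the kernel, and truncates
#' to the acquisition length.
#'
#' @param design a [block_design()].
#' @param hrf sampled kernel (same grid spacing as `design$tr`), e.g. from
#'   [canonical_hrf()].
#' @return matrix conditions x frames with condition row names.
#' @export
convolve_design <- function(design, hrf) {
  stopifnot(inherits(design, "block_design"))
  n <- design$n_frames
  ft <- (seq_len(n) - 1L) * design$tr
  out <- matrix(0, nrow = length(design$condition_names), ncol = n,
                dimnames = list(design$condition_names, NULL))
  for (cond in design$condition_names) {
    ev <- design$events[design$events$condition == cond, , drop = FALSE]
    box <- rep(0, n)
    for (k in seq_len(nrow(ev)))
      box[ft >= ev$onset[k] & ft < ev$onset[k] + ev$duration[k]] <- 1
    # discrete convolution, causal, truncated to the acquisition
    full <- stats::convolve(box, rev(hrf), type = "open")
    out[cond, ] <- full[seq_len(n)]
  }
  out
}

#' Synthetic cohort specification
#'
#' Fixes the generative world for a paired task/rest cohort: independent AR(1)
#' regional signals, a set of "planted" region pairs whose instantaneous
#' coupling w(t) is modulated during task by a slow non-block-locked raised
#' cosine scaled by a per-subject engagement factor, weakly mixed-in nuisance
#' confounds, and a behavior table whose "performance" column loads on
#' engagement.
#'
#' @param n_subjects number of subjects (each contributes one task and one
#'   rest recording).
#' @param n_regions number of regions (>= 4).
#' @param n_frames frames per recording (>= 10).
#' @param baseline_coupling constant coupling of planted pairs at rest scale
#'   reference, in (-1, 1).
#' @param modulation_amplitude peak task modulation of coupling on the
#'   correlation scale; `abs(baseline_coupling) + modulation_amplitude < 1`.
#' @param planted_pairs two-column integer matrix of region pairs carrying
#'   the coupling signal; regions may appear in at most one planted pair.
#'   Default: pairs (1,2), (3,4), ..., up to 5 pairs.
#' @param engagement_sd standard deviation of the per-subject engagement
#'   factor (mean 1).
#' @param noise_sd observation noise standard deviation (signal units; the
#'   latent signals have unit-scale innovations).
#' @param behavior_loading loading of the behavioral "performance" measure on
#'   engagement (measure = loading * engagement + N(0,1)).
#' @param n_null_measures number of additional behavior columns independent
#'   of engagement.
#' @param tr repetition time in seconds.
#' @param rest_drift if TRUE, rest coupling slowly drifts (one cosine cycle,
#'   amplitude `modulation_amplitude / 4`) instead of staying constant.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 200, n_regions = 20, n_frames = 150,
                        baseline_coupling = 0.2, modulation_amplitude = 0.5,
                        planted_pairs = NULL, engagement_sd = 0.2,
                        noise_sd = 0.3, behavior_loading = 2,
                        n_null_measures = 11, tr = 0.72,
                        rest_drift = FALSE, seed = 1) {
  if (n_regions < 4) stop_invalid("n_regions must be >= 4")
  if (n_frames < 10) stop_invalid("n_frames must be >= 10")
  if (abs(baseline_coupling) >= 1) stop_invalid("baseline_coupling must be in (-1, 1)")
  if (modulation_amplitude < 0) stop_invalid("modulation_amplitude must be non-negative")
  if (abs(baseline_coupling) + modulation_amplitude >= 1)
    stop_invalid("|baseline_coupling| + modulation_amplitude must be < 1")
  if (engagement_sd < 0 || noise_sd < 0) stop_invalid("standard deviations must be non-negative")
  if (is.null(planted_pairs)) {
    k <- min(5L, n_regions %/% 2L)
    planted_pairs <- cbind(seq(1L, by = 2L, length.out = k),
                           seq(2L, by = 2L, length.out = k))
  }
  planted_pairs <- matrix(as.integer(planted_pairs), ncol = 2L)
  if (nrow(planted_pairs) > 0L) {
    planted_pairs <- t(apply(planted_pairs, 1L, sort))
    if (any(planted_pairs < 1L) || any(planted_pairs > n_regions))
      stop_invalid("planted pair indices out of range 1..%d", n_regions)
    if (anyDuplicated(as.vector(planted_pairs)))
      stop_invalid("a region may belong to at most one planted pair")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_regions = as.integer(n_regions),
                 n_frames = as.integer(n_frames),
                 baseline_coupling = baseline_coupling,
                 modulation_amplitude = modulation_amplitude,
                 planted_pairs = planted_pairs,
                 engagement_sd = engagement_sd, noise_sd = noise_sd,
                 behavior_loading = behavior_loading,
                 n_null_measures = as.integer(n_null_measures),
                 tr = tr, rest_drift = rest_drift,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Slow non-block-locked modulation profile: raised cosine, two cycles over T,
# range [0, 1].
modulation_profile <- function(n_frames) {
  (1 - cos(4 * pi * (seq_len(n_frames) - 1L) / n_frames)) / 2
}

# Ground-truth coupling series for one planted pair.
#
# Task: w(t) = baseline + engagement * amplitude * m(t) with m(t) in [0, 1].
# Rest: constant at baseline + amplitude / 2, the expected time average of the
# task series at engagement 1, so the two conditions are mean-matched and the
# decodable signal lives purely in the dynamics (static FC stays at chance).
coupling_series <- function(spec, condition, engagement) {
  T <- spec$n_frames
  if (condition == "task") {
    w <- spec$baseline_coupling +
      engagement * spec$modulation_amplitude * modulation_profile(T)
  } else {
    w <- rep(spec$baseline_coupling + spec$modulation_amplitude / 2, T)
    if (isTRUE(spec$rest_drift))
      w <- w + spec$modulation_amplitude / 4 *
        cos(2 * pi * (seq_len(T) - 1L) / T)
  }
  pmin(pmax(w, -0.99), 0.99)
}

# Stationary AR(1) rows: coefficient phi, innovation sd 1.
ar1_rows <- function(n, T, phi = 0.3) {
  z <- matrix(0, n, T)
  z[, 1L] <- stats::rnorm(n, sd = 1 / sqrt(1 - phi^2))
  for (t in 2:T) z[, t] <- phi * z[, t - 1L] + stats::rnorm(n)
  z
}

#' Simulate one subject recording
#'
#' Draws one task or rest recording under a [cohort_spec()]. Regions carry
#' independent stationary AR(1) latents (coefficient 0.3, innovation sd 1).
#' For each planted pair (i, j), the latent of region j is replaced by
#' `w(t) * z_i(t) + sqrt(1 - w(t)^2) * eta(t)` with `eta` an independent AR(1)
#' of the same law, so the instantaneous correlation of the pair is exactly
#' w(t). Three confound series (an FD-like motion summary and two slow
#' tissue-mean-like series) are mixed into all regions with loading 0.1, and
#' task recordings additionally receive a block-locked HRF-convolved
#' activation (loading 0.5, removed later by the preprocessing GLM).
#'
#' Uses the current RNG state; seed it (or call via [simulate_cohort()]) for
#' reproducibility.
#'
#' @param spec a [cohort_spec()].
#' @param subject_id subject label.
#' @param condition `"task"` or `"rest"`.
#' @param engagement per-subject engagement factor (finite scalar).
#' @param design optional [block_design()] for task recordings; default
#'   [default_block_design()].
#' @return object of class `subject_recording` with fields `timeseries`
#'   (regions x frames), `confounds` (3 x frames, rows `fd`, `tissue_wm`,
#'   `tissue_csf`), `design` (task only), and `true_coupling`
#'   (pairs x frames ground truth, zero rows for unplanted pairs).
#' @export
simulate_subject <- function(spec, subject_id, condition = c("task", "rest"),
                             engagement = 1, design = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  condition <- match.arg(condition)
  if (!is_scalar_number(engagement)) stop_invalid("engagement must be a finite number")
  R <- spec$n_regions; T <- spec$n_frames
  pairs <- pair_index(R)

  z <- ar1_rows(R, T)
  true_w <- matrix(0, nrow(pairs), T)
  if (nrow(spec$planted_pairs) > 0L) {
    for (k in seq_len(nrow(spec$planted_pairs))) {
      i <- spec$planted_pairs[k, 1L]; j <- spec$planted_pairs[k, 2L]
      w <- coupling_series(spec, condition, engagement)
      eta <- drop(ar1_rows(1L, T))
      z[j, ] <- w * z[i, ] + sqrt(1 - w^2) * eta
      true_w[pair_row(i, j, R), ] <- w
    }
  }

  # confounds: spiky FD-like series, two slow tissue-mean series
  fd <- abs(0.15 + 0.05 * stats::rnorm(T) +
              ifelse(stats::runif(T) < 0.05, stats::rexp(T, rate = 4), 0))
  tw <- drop(ar1_rows(1L, T, phi = 0.95)) * sqrt(1 - 0.95^2)
  tc <- drop(ar1_rows(1L, T, phi = 0.95)) * sqrt(1 - 0.95^2)
  confounds <- rbind(fd = fd, tissue_wm = tw, tissue_csf = tc)
  conf_std <- t(apply(confounds, 1L, function(v) (v - mean(v)) / stats::sd(v)))
  ts <- z + 0.1 * matrix(colSums(conf_std), R, T, byrow = TRUE)

  if (condition == "task") {
    if (is.null(design)) design <- default_block_design(T, spec$tr)
    act <- convolve_design(design, canonical_hrf(design$tr))
    ts <- ts + 0.5 * matrix(colSums(act), R, T, byrow = TRUE)
  } else design <- NULL

  if (spec$noise_sd > 0) ts <- ts + spec$noise_sd * matrix(stats::rnorm(R * T), R, T)
  rownames(ts) <- paste0("r", seq_len(R))

  structure(list(subject_id = as.character(subject_id), condition = condition,
                 timeseries = ts, confounds = confounds, design = design,
                 true_coupling = true_w, pairs = pairs,
                 engagement = engagement),
            class = "subject_recording")
}

#' Simulate a full paired task/rest cohort
#'
#' Per subject s, draws engagement_s ~ Normal(1, `engagement_sd`), one task
#' and one rest recording via [simulate_subject()], and a behavior row with
#' `performance = behavior_loading * engagement_s + Normal(0, 1)`,
#' `n_null_measures` null measures independent of engagement, integer age in
#' 22..37 and binary sex. Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `mtpa_cohort`: list with `recordings` (per subject,
#'   `$task` and `$rest` [simulate_subject()] outputs), `behavior`
#'   (data.frame), `engagement` (named vector), and `spec`.
#' @export
#' @examples
#' co <- simulate_cohort(cohort_spec(n_subjects = 4, n_regions = 6,
#'                                   n_frames = 60, seed = 7))
#' dim(co$recordings[[1]]$task$timeseries)
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    ids <- sprintf("sub%03d", seq_len(n))
    engagement <- stats::rnorm(n, mean = 1, sd = spec$engagement_sd)
    names(engagement) <- ids
    design <- default_block_design(spec$n_frames, spec$tr)
    recordings <- vector("list", n)
    names(recordings) <- ids
    for (s in seq_len(n)) {
      recordings[[s]] <- list(
        task = simulate_subject(spec, ids[s], "task", engagement[s], design),
        rest = simulate_subject(spec, ids[s], "rest", engagement[s]))
    }
    behavior <- data.frame(
      subject_id = ids,
      performance = spec$behavior_loading * engagement + stats::rnorm(n))
    if (spec$n_null_measures > 0L) {
      nulls <- matrix(stats::rnorm(n * spec$n_null_measures), n)
      colnames(nulls) <- sprintf("null_%02d", seq_len(spec$n_null_measures))
      behavior <- cbind(behavior, as.data.frame(nulls))
    }
    behavior$age <- sample(22:37, n, replace = TRUE)
    behavior$sex <- stats::rbinom(n, 1L, 0.5)
    structure(list(recordings = recordings, behavior = behavior,
                   engagement = engagement, spec = spec),
              class = "mtpa_cohort")
  })
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("cohort_spec: %d subjects, %d regions, %d frames\n",
                     "  coupling %.2f + engagement * %.2f * m(t) on %d planted pair(s)\n",
                     "  engagement sd %.2f, noise sd %.2f, seed %d\n"),
              x$n_subjects, x$n_regions, x$n_frames, x$baseline_coupling,
              x$modulation_amplitude, nrow(x$planted_pairs),
              x$engagement_sd, x$noise_sd, x$seed))
  invisible(x)
}

#' @export
print.subject_recording <- function(x, ...) {
  cat(sprintf("subject_recording %s (%s): %d regions x %d frames\n",
              x$subject_id, x$condition, nrow(x$timeseries), ncol(x$timeseries)))
  invisible(x)
}
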