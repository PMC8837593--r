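#' Subject-level split specification
#'
#' Controls the train/test partition and the cross-validation folds. Both
#' samples (task and rest) of a subject always land on the same side of every
#' partition, so no subject leaks across the boundary.
#'
#' @param train_fraction fraction of subjects assigned to the training set
#'   (in (0, 1)); the training count is `floor(train_fraction * n)`.
#' @param n_folds number of cross-validation folds (>= 2), grouped by subject.
#' @param seed integer seed controlling the split and fold assignment.
#' @param group_by_subject must be TRUE; ungrouped splitting would leak
#'   subjects between partitions and is rejected.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.7, n_folds = 10, seed = 1,
                       group_by_subject = TRUE) {
  if (!is_scalar_number(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop_invalid("train_fraction must be in (0, 1)")
  if (n_folds < 2) stop_invalid("n_folds must be >= 2")
  if (!isTRUE(group_by_subject))
    stop_invalid("group_by_subject = FALSE would leak subjects across partitions")
  structure(list(train_fraction = train_fraction, n_folds = as.integer(n_folds),
                 seed = as.integer(seed), group_by_subject = TRUE),
            class = "split_spec")
}

#' Split subjects into training and test sets
#'
#' Randomly assigns `floor(train_fraction * n)` subjects to the training set
#' and the rest to the test set, reproducibly from the spec's seed.
#'
#' @param subject_ids character vector of unique subject ids (>= 10).
#' @param spec a [split_spec()].
#' @return list with `train` and `test` character vectors (disjoint,
#'   exhaustive).
#' @export
split_subjects <- function(subject_ids, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  subject_ids <- unique(as.character(subject_ids))
  n <- length(subject_ids)
  if (n < 10L) stop_invalid("need at least 10 subjects, got %d", n)
  n_train <- floor(spec$train_fraction * n)
  train <- with_seed(spec$seed, sample(subject_ids, n_train))
  list(train = train, test = setdiff(subject_ids, train))
}

# Deterministic subject -> fold assignment: shuffle subjects under the spec
# seed (offset so the fold shuffle differs from the split shuffle), then deal
# round-robin into n_folds groups.
assign_folds <- function(subject_ids, spec) {
  shuffled <- with_seed(spec$seed + 1L, sample(subject_ids))
  folds <- rep(seq_len(spec$n_folds), length.out = length(shuffled))
  stats::setNames(folds[order(match(subject_ids, shuffled))], subject_ids)
}

# Training-set feature standardization: center/scale per feature; constant
# features get scale 1 so they map to zero rather than NaN.
feature_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl,
       apply = function(M) sweep(sweep(M, 2L, ctr), 2L, scl, "/"))
}

#' Fit an L2-regularized linear logistic classifier
#'
#' Minimizes the LIBLINEAR-style convex objective
#' \deqn{f(w, b) = \tfrac12 \|w\|^2 + C \sum_i \log(1 + e^{-\hat y_i (w \cdot x_i + b)})}
#' with \eqn{\hat y_i \in \{-1, +1\}} and an unpenalized intercept, by damped
#' Newton iterations until the gradient norm falls below `tol`. The objective
#' is strictly convex in `w`, so the minimizer is unique.
#'
#' @param x feature matrix, samples x features (standardize with training-set
#'   statistics before fitting; penalized objectives are scale-sensitive).
#' @param y labels in {0, 1} (1 = task); both classes must be present.
#' @param reg_strength the loss weight C (> 0); larger C means weaker
#'   regularization. Default 1.
#' @param tol convergence tolerance on the Euclidean gradient norm.
#' @param max_iter Newton iteration cap.
#' @return object of class `mtpa_logistic` with `weights`, `intercept`,
#'   `reg_strength`, `converged`, `iterations`.
#' @export
fit_logistic <- function(x, y, reg_strength = 1, tol = 1e-6, max_iter = 200) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop_invalid("x and y disagree on sample count")
  if (!all(y %in% c(0L, 1L))) stop_invalid("labels must be 0 (rest) or 1 (task)")
  if (length(unique(y)) < 2L)
    stop_invalid("both classes must be present in the training data")
  if (!is_scalar_number(reg_strength) || reg_strength <= 0)
    stop_invalid("reg_strength must be positive")
  n <- nrow(x); p <- ncol(x)
  Z <- cbind(1, x)                      # column 1 = intercept, unpenalized
  pen <- c(0, rep(1, p))
  theta <- numeric(p + 1L)
  obj <- function(th) {
    m <- drop(Z %*% th) * (2 * y - 1)   # margins
    0.5 * sum(pen * th^2) + reg_strength * sum(log1p(exp(-abs(m))) + pmax(-m, 0))
  }
  f <- obj(theta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(Z %*% theta)
    prob <- stats::plogis(eta)
    g <- pen * theta + reg_strength * drop(crossprod(Z, prob - y))
    if (sqrt(sum(g^2)) < tol) { converged <- TRUE; break }
    Wv <- pmax(prob * (1 - prob), 1e-10)
    H <- diag(pen, p + 1L) + reg_strength * crossprod(Z, Z * Wv)
    step <- solve(H, g)
    # backtracking line search on the convex objective
    lam <- 1
    repeat {
      cand <- theta - lam * step
      fc <- obj(cand)
      if (fc <= f + 1e-4 * lam * (-sum(g * step)) || lam < 1e-8) break
      lam <- lam / 2
    }
    theta <- cand; f <- fc
  }
  structure(list(weights = theta[-1L], intercept = theta[1L],
                 reg_strength = reg_strength, converged = converged,
                 iterations = iter),
            class = "mtpa_logistic")
}

#' Posterior task probability of a fitted classifier
#'
#' `p = 1 / (1 + exp(-(w . x + b)))`; the predicted label is 1 (task) iff
#' `p >= 0.5`.
#'
#' @param model an `mtpa_logistic` from [fit_logistic()].
#' @param x feature matrix (samples x features) or a single feature vector.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "mtpa_logistic"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model$weights))
    stop_invalid("feature count %d does not match model dimension %d",
                 ncol(x), length(model$weights))
  stats::plogis(drop(x %*% model$weights) + model$intercept)
}

#' Predicted labels (1 = task iff probability >= 0.5)
#' @inheritParams predict_proba
#' @return integer vector of 0/1 labels.
#' @export
predict_label <- function(model, x) as.integer(predict_proba(model, x) >= 0.5)

#' Subject-grouped k-fold cross-validation for one connection
#'
#' Splits the training subjects into `n_folds` groups, fits on the
#' out-of-fold samples (features standardized on the fold-training part) and
#' scores the held-out fold. Each subject receives out-of-fold probabilities
#' exactly once. Folds whose training part contains a single class are
#' skipped with a warning.
#'
#' @param x feature matrix samples x features (training partition only).
#' @param y 0/1 labels per sample.
#' @param subjects subject id per sample.
#' @param spec a [split_spec()] (its `n_folds` and `seed` are used).
#' @param reg_strength passed to [fit_logistic()].
#' @param folds optional precomputed subject -> fold assignment (named
#'   integer vector), e.g. shared across connections.
#' @return list with `cv_accuracy` (mean fold accuracy), `oof_prob`
#'   (out-of-fold probability per sample) and `fold_accuracy`.
#' @export
cross_validate <- function(x, y, subjects, spec = split_spec(),
                           reg_strength = 1, folds = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  subjects <- as.character(subjects)
  if (is.null(folds)) folds <- assign_folds(unique(subjects), spec)
  fold_of <- folds[subjects]
  accs <- rep(NA_real_, spec$n_folds)
  oof <- rep(NA_real_, length(y))
  for (k in seq_len(spec$n_folds)) {
    hold <- fold_of == k
    if (!any(hold)) next
    if (length(unique(y[!hold])) < 2L) {
      warning(sprintf("fold %d skipped: single-class training partition", k))
      next
    }
    sc <- feature_scaler(x[!hold, , drop = FALSE])
    fit <- fit_logistic(sc$apply(x[!hold, , drop = FALSE]), y[!hold], reg_strength)
    pr <- predict_proba(fit, sc$apply(x[hold, , drop = FALSE]))
    oof[hold] <- pr
    accs[k] <- mean(as.integer(pr >= 0.5) == y[hold])
  }
  list(cv_accuracy = mean(accs, na.rm = TRUE), oof_prob = oof,
       fold_accuracy = accs)
}

#' Assemble per-connection feature sets from a preprocessed cohort
#'
#' Computes either the T-dimensional FLS coefficient series (features =
#' beta(t), one classifier feature per frame) or the 1-dimensional static
#' Pearson correlation for every recording and stacks them into a
#' pairs x samples x features array.
#'
#' @param cohort a preprocessed `mtpa_cohort` (see [preprocess_cohort()]).
#' @param type `"dfc"` (FLS temporal features) or `"static"`.
#' @param config an [fls_config()] (used for `type = "dfc"`).
#' @return object of class `mtpa_features`: list with `X` (pairs x samples x
#'   features array), `subject` and `condition` per sample, `label` (1 =
#'   task), `pairs`, `type`.
#' @export
collect_features <- function(cohort, type = c("dfc", "static"),
                             config = fls_config()) {
  stopifnot(inherits(cohort, "mtpa_cohort"))
  type <- match.arg(type)
  recs <- unlist(unname(lapply(cohort$recordings,
                               function(p) list(p$task, p$rest))),
                 recursive = FALSE)
  n_samp <- length(recs)
  pairs <- pair_index(nrow(recs[[1L]]$timeseries))
  nfeat <- if (type == "dfc") ncol(recs[[1L]]$timeseries) else 1L
  X <- array(NA_real_, dim = c(nrow(pairs), n_samp, nfeat))
  for (s in seq_len(n_samp)) {
    X[, s, ] <- if (type == "dfc") fls_all_pairs(recs[[s]], config)$beta
                else matrix(static_fc(recs[[s]])$r, ncol = 1L)
  }
  structure(list(X = X,
                 subject = vapply(recs, `[[`, "", "subject_id"),
                 condition = vapply(recs, `[[`, "", "condition"),
                 label = as.integer(vapply(recs, `[[`, "", "condition") == "task"),
                 pairs = pairs, type = type),
            class = "mtpa_features")
}

#' Train and evaluate one classifier per connection
#'
#' For every region pair: 10-fold subject-grouped cross-validation on the
#' training partition, a final model fitted on the full training partition,
#' and out-of-sample accuracy on the held-out test subjects. The same
#' subject-level 70/30 split and the same fold assignment are reused across
#' all pairs. Per-sample probability estimates are retained: out-of-fold
#' probabilities for training subjects, final-model probabilities for test
#' subjects.
#'
#' @param features an `mtpa_features` from [collect_features()].
#' @param spec a [split_spec()].
#' @param reg_strength loss weight C of [fit_logistic()].
#' @param pairs optional integer vector of pair rows to evaluate (default:
#'   all pairs).
#' @return object of class `mtpa_results`: list with `results` (data.frame
#'   `i`, `j`, `cv_accuracy`, `test_accuracy`), `prob` (samples x pairs
#'   probability matrix), `samples` (data.frame `subject`, `condition`,
#'   `partition`), `pairs`, `split`, `type`.
#' @export
run_all_connections <- function(features, spec = split_spec(),
                                reg_strength = 1, pairs = NULL) {
  stopifnot(inherits(features, "mtpa_features"), inherits(spec, "split_spec"))
  subj <- features$subject
  # every subject must contribute exactly one task and one rest sample
  tab <- table(factor(subj),
               factor(features$condition, levels = c("rest", "task")))
  bad <- rownames(tab)[tab[, "task"] != 1L | tab[, "rest"] != 1L]
  keep_samp <- !(subj %in% bad)
  if (length(bad) > 0L)
    warning(sprintf("dropping subject(s) without both conditions: %s",
                    paste(bad, collapse = ", ")))
  subj <- subj[keep_samp]
  y <- features$label[keep_samp]
  if (is.null(pairs)) pairs <- seq_len(nrow(features$pairs))

  split <- split_subjects(unique(subj), spec)
  in_train <- subj %in% split$train
  folds <- assign_folds(split$train, spec)

  n_pair <- length(pairs)
  cv_acc <- test_acc <- rep(NA_real_, n_pair)
  prob <- matrix(NA_real_, length(subj), n_pair)
  for (q in seq_len(n_pair)) {
    Xp <- features$X[pairs[q], keep_samp, , drop = FALSE]
    Xp <- matrix(Xp, dim(Xp)[2L], dim(Xp)[3L])
    cv <- cross_validate(Xp[in_train, , drop = FALSE], y[in_train],
                         subj[in_train], spec, reg_strength, folds = folds)
    sc <- feature_scaler(Xp[in_train, , drop = FALSE])
    fit <- fit_logistic(sc$apply(Xp[in_train, , drop = FALSE]), y[in_train],
                        reg_strength)
    pr_test <- predict_proba(fit, sc$apply(Xp[!in_train, , drop = FALSE]))
    cv_acc[q] <- cv$cv_accuracy
    test_acc[q] <- mean(as.integer(pr_test >= 0.5) == y[!in_train])
    prob[in_train, q] <- cv$oof_prob
    prob[!in_train, q] <- pr_test
  }
  structure(list(results = data.frame(i = features$pairs$i[pairs],
                                      j = features$pairs$j[pairs],
                                      cv_accuracy = cv_acc,
                                      test_accuracy = test_acc),
                 prob = prob,
                 samples = data.frame(subject = subj,
                                      condition = features$condition[keep_samp],
                                      partition = ifelse(in_train, "train", "test")),
                 pairs = features$pairs[pairs, , drop = FALSE],
                 split = split, type = features$type),
            class = "mtpa_results")
}

#' @export
print.mtpa_results <- function(x, ...) {
  cat(sprintf(paste0("mtpa_results (%s features): %d connections, %d samples\n",
                     "  mean CV accuracy %.3f, mean test accuracy %.3f\n"),
              x$type, nrow(x$results), nrow(x$samples),
              mean(x$results$cv_accuracy, na.rm = TRUE),
              mean(x$results$test_accuracy, na.rm = TRUE)))
  invisible(x)
}
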