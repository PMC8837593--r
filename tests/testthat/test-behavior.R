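# Minimal hand-built mtpa_results: 2 subjects x {task, rest}, 3 connections
# among 4 regions grouped into two networks.
fake_results <- function(prob) {
  pairs <- data.frame(i = c(1, 1, 3), j = c(2, 3, 4))
  structure(list(results = data.frame(i = pairs$i, j = pairs$j,
                                      cv_accuracy = 0.8, test_accuracy = 0.8),
                 prob = prob,
                 samples = data.frame(subject = rep(c("s1", "s2"), each = 2),
                                      condition = rep(c("task", "rest"), 2),
                                      partition = "train"),
                 pairs = pairs, split = NULL, type = "dfc"),
            class = "mtpa_results")
}

two_net <- network_assignment(1:4, c("N1", "N1", "N2", "N2"))

config_for <- function(blocks) {
  m <- matrix(0, 2, 2, dimnames = list(c("N1", "N2"), c("N1", "N2")))
  for (b in blocks) m[b[1], b[2]] <- m[b[2], b[1]] <- 1
  structure(list(mask = m, threshold = 0.7), class = "thresholded_config")
}

test_that("task_identifiability averages task probabilities over the config", {
  prob <- matrix(0.9, 4, 3)
  sc <- task_identifiability(fake_results(prob), config_for(list(c(1, 1))),
                             two_net)
  expect_equal(sc$score, c(0.9, 0.9))
  expect_equal(sc$n_connections, c(1L, 1L))  # only pair (1,2) is in N1-N1

  # two contributing connections with probabilities 0.6 and 0.8 -> 0.7
  prob2 <- matrix(rep(c(0.6, 0.7, 0.8), each = 4), 4, 3)
  sc2 <- task_identifiability(fake_results(prob2),
                              config_for(list(c(1, 1), c(2, 2))), two_net)
  expect_equal(sc2$score, c(0.7, 0.7))
  expect_equal(sc2$n_connections, c(2L, 2L))

  # empty configuration: identifiability undefined
  expect_error(task_identifiability(fake_results(prob), config_for(list()),
                                    two_net),
               "empty configuration")
})

test_that("partial_correlation matches its formula oracles", {
  set.seed(13)
  x <- rnorm(30)
  z <- rnorm(30)
  # y = x: perfect correlation survives partialling an unrelated covariate
  pc <- partial_correlation(x, x, cbind(z))
  expect_equal(pc$r, 1, tolerance = 1e-12)

  # y equal to the covariate: zero residual variance -> error path
  expect_error(partial_correlation(x, z, cbind(z)), "zero residual variance")

  # 12-row toy vs the recursive pairwise-correlation formula
  set.seed(14)
  x12 <- rnorm(12); z12 <- rnorm(12)
  y12 <- 0.5 * x12 + 0.8 * z12 + rnorm(12)
  pc12 <- partial_correlation(x12, y12, cbind(z12))
  expect_equal(pc12$r, partial_r_recursive(x12, y12, z12), tolerance = 1e-10)
  expect_equal(pc12$n, 12L)

  # no covariates: exactly the plain Pearson correlation, p from t on n - 2 df
  pc0 <- partial_correlation(x12, y12)
  expect_equal(pc0$r, cor(x12, y12), tolerance = 1e-14)
  expect_equal(pc0$p, cor.test(x12, y12)$p.value, tolerance = 1e-12)

  # missing rows are dropped pairwise-complete
  xm <- c(x12, NA)
  ym <- c(y12, 1)
  expect_equal(partial_correlation(xm, ym)$n, 12L)
  expect_error(partial_correlation(1:4, c(2, 1, 4, 3), cbind(rnorm(4), rnorm(4))),
               "at least")
})

test_that("screen_measures applies the Bonferroni and effect-size filters", {
  set.seed(15)
  n <- 400
  e <- rnorm(n, 1, 0.2)
  scores <- data.frame(subject_id = sprintf("s%03d", 1:n),
                       score = e + rnorm(n, sd = 0.1))
  behavior <- data.frame(subject_id = sprintf("s%03d", 1:n),
                         strong = 2 * e + rnorm(n),          # true association
                         weak = 0.05 * scale(e)[, 1] + rnorm(n),
                         null_measure = rnorm(n),
                         text_col = sample(letters, n, TRUE),
                         age = sample(22:37, n, TRUE),
                         sex = rbinom(n, 1, 0.5))
  expect_warning(res <- screen_measures(scores, behavior, m = 192),
                 "non-numeric")
  expect_true(res$significant[res$measure == "strong"])
  expect_false(res$significant[res$measure == "null_measure"])
  # the 'weak' column has tiny effect size; even a small p cannot rescue it
  rw <- res[res$measure == "weak", ]
  expect_false(rw$significant && abs(rw$r) <= 0.1)
  # flag logic: significant iff p < alpha/m AND |r| > r_min
  expect_equal(res$significant, res$p < 0.05 / 192 & abs(res$r) > 0.1)
  expect_equal(res$r, res$r[order(-abs(res$r))])  # sorted by effect size
})

test_that("pc_partial attenuates associations driven by the partialled set", {
  set.seed(16)
  n <- 300
  e <- rnorm(n, 1, 0.2)
  scores <- data.frame(subject_id = sprintf("s%03d", 1:n),
                       score = e + rnorm(n, sd = 0.2))
  behavior <- data.frame(subject_id = sprintf("s%03d", 1:n),
                         performance = 2 * e + rnorm(n),
                         perf_b = 2 * e + rnorm(n),
                         cognition_a = e + rnorm(n),
                         cognition_b = e + rnorm(n),
                         age = sample(22:37, n, TRUE),
                         sex = rbinom(n, 1, 0.5))
  plain <- screen_measures(scores, behavior, m = 192)
  pc <- pc_partial(scores, behavior,
                   cognition_cols = c("cognition_a", "cognition_b"),
                   performance_cols = c("performance", "perf_b"),
                   n_components = 1, m = 192)
  r_plain <- plain$r[plain$measure == "performance"]
  r_pc <- pc$r[pc$measure == "performance"]
  expect_lt(abs(r_pc), abs(r_plain))  # strictly attenuated

  # n_components = 0 is a no-op
  expect_equal(pc_partial(scores, behavior, "cognition_a", "performance",
                          n_components = 0, m = 192),
               plain)

  # PC1 of a single column is that column up to sign
  one <- behavior$cognition_a
  M <- scale(one)
  p1 <- prcomp(M, center = FALSE)$x[, 1]
  expect_equal(abs(cor(p1, one)), 1, tolerance = 1e-12)

  expect_error(pc_partial(scores, behavior, character(), "performance", 1),
               "empty column set")
})

test_that("higher engagement never lowers a subject's identifiability", {
  # train per-connection models on a fixed planted cohort, then probe them
  # with recordings simulated at increasing engagement under common random
  # numbers: mean task probability over planted connections must be monotone
  co <- small_planted_cohort(n_subjects = 40, n_frames = 100, seed = 21)
  co <- preprocess_cohort(co)
  f <- collect_features(co, "dfc")
  planted <- pair_row(c(1, 3), c(2, 4), 6)
  res <- run_all_connections(f, split_spec(seed = 4), pairs = planted)

  # refit final models to reuse on probe recordings
  spec <- co$spec
  probe_score <- function(engagement, seed) {
    set.seed(seed)
    rec <- simulate_subject(spec, "probe", "task", engagement,
                            design = co$recordings[[1]]$task$design)
    rec <- regress_confounds(rec, regression_spec())
    beta <- fls_all_pairs(rec)$beta
    subj <- f$subject; y <- f$label
    in_train <- subj %in% res$split$train
    mean(vapply(seq_along(planted), function(q) {
      Xtr <- matrix(f$X[planted[q], in_train, ], sum(in_train))
      sc <- mtpa:::feature_scaler(Xtr)
      fit <- fit_logistic(sc$apply(Xtr), y[in_train])
      predict_proba(fit, sc$apply(matrix(beta[planted[q], ], 1)))
    }, 0))
  }
  mean_probe <- function(eng)
    mean(vapply(1:5, function(k) probe_score(eng, 1000 + k), 0))
  p_lo <- mean_probe(0.4)
  p_mid <- mean_probe(1.0)
  p_hi <- mean_probe(1.6)
  expect_lte(p_lo, p_mid + 1e-9)
  expect_lte(p_mid, p_hi + 1e-9)
})
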