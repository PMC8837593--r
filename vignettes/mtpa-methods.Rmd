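---
title: "Methods: time-varying connectivity, temporal decoding, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-varying connectivity, temporal decoding, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements: the
estimators and their assumptions, every tunable parameter with its default
and rationale, what the synthetic-data generator does and does not emulate,
and the numerical conventions that a careful user (or reviewer) would want
pinned down.

## 1. The problem

Task engagement changes how brain regions talk to each other, not only how
active they are. Time-averaged ("static") functional connectivity — one
Pearson correlation per region pair — barely differs between task and rest
once the mean evoked response is removed. The hypothesis behind this package
is that the *temporal pattern* of coupling still separates the two states.
The pipeline therefore (i) estimates a framewise coupling series per region
pair, (ii) treats that series as a feature vector for a supervised
classifier of task vs. rest, (iii) summarizes where in the brain's network
structure decoding succeeds, and (iv) asks whose task state is easy to
decode, relating that to behavior.

## 2. Preprocessing GLM

Each region's series is residualized, per recording, on an intercept, a
framewise-displacement (FD) motion summary, two tissue-mean series, and —
for task recordings — one HRF-convolved boxcar per task condition. The
condition regressors absorb the *block-locked* mean activation, so whatever
the classifier later exploits is not a trivial evoked-response artifact.
Choices:

* One GLM per region with all regressors fitted jointly; rest recordings
  use confounds only (they have no design).
* FD enters as a single regressor, without expansions (the simplest reading
  of the method; expansions are a documented non-goal).
* Convolution regressors are not mean-centered — an intercept is always
  present, so centering would not change the residuals.
* Residuals are re-standardized to unit variance by default. The source
  method is silent on scaling; standardization makes the FLS coefficients
  comparable across pairs and subjects (they become correlation-like), and
  is the assumption under which omitting the FLS intercept is benign.
  Near-constant residuals (variance below 1e-10) are left unscaled with a
  warning rather than producing NaNs.
* `regression_spec(FALSE, FALSE, FALSE, FALSE)` (or `--raw` on the CLI)
  skips everything, reproducing the "no additional preprocessing" variant.
* Rest recordings are trimmed to the first T task frames so feature vectors
  have equal length.

## 3. Flexible least squares (FLS)

For a pair (x, y) the coupling series minimizes

$$C(\beta;\mu) = \sum_{t=1}^{T} (y_t - x_t\beta_t)^2
  \;+\; \mu \sum_{t=1}^{T-1} (\beta_{t+1}-\beta_t)^2 .$$

The first term is the measurement fit error, the second the dynamic error; μ
arbitrates between erratic solutions (small μ) and the constant ordinary
least squares slope (μ → ∞). The stationarity conditions form a symmetric
tridiagonal, positive-definite linear system (diagonal
$x_t^2 + \mu([t>1]+[t<T])$, off-diagonal $-\mu$, right-hand side $x_ty_t$),
which `fls_pair()` solves exactly with a Thomas sweep in O(T) — no toolbox,
no iterative optimizer. `fls_all_pairs()` vectorizes the sweep across all
R(R−1)/2 pairs at once. The tests verify the solver against a dense
`solve()` oracle to 1e−8, the μ → ∞ OLS limit to 1e−4, the exact `y = 2x`
zero-cost case, monotonicity of the two error terms in μ, and exact scale
covariance in y.

Conventions:

* **μ = 100** by default: the conventional TR-independent setting of the
  framewise method; exposed everywhere as a parameter.
* **No intercept** in the measurement equation, as the objective is stated;
  inputs are standardized upstream, which is what makes this harmless.
* **Regression direction**: the objective is asymmetric in (x, y) and the
  source method never states which region predicts which. The default takes
  the lower-index region as predictor (`direction_rule = "lower"`);
  `"average"` averages the two directed solutions for symmetry-sensitive
  uses. Neither convention is asserted to be the original one.
* The β stack is kept in memory as a pairs × frames matrix (~90 MB at 200
  subjects × 190 pairs × 150 frames) and written as TSV on request. The
  natural at-scale container would be HDF5, but no R HDF5 binding is
  available in the supported environment, so the package deliberately stays
  with in-memory arrays plus delimited text.

## 4. The classifier (MTPA proper)

One classifier per connection, features either the T framewise β values or
the single static correlation. The objective is the LIBLINEAR-style
L2-regularized logistic loss

$$f(w,b) = \tfrac12\lVert w\rVert^2 + C\sum_i \log\!\big(1+e^{-\hat y_i(w\cdot x_i+b)}\big),
\qquad \hat y_i\in\{-1,+1\},$$

with an unpenalized intercept, minimized by damped Newton iterations to a
gradient norm below 1e−6. A generic BFGS optimizer serves as the test oracle
(agreement to 1e−4 on probabilities). Probability estimates are the plain
logistic sigmoid — no Platt recalibration, since only "probability
estimates" are called for — and the label is task iff p ≥ 0.5.

* **C = 1** by default (no penalty value is printed anywhere; exposed as a
  flag).
* **Features are z-scored with training-partition statistics only** —
  penalized objectives are scale-sensitive and test leakage must be avoided.
  Constant features get scale 1.
* **Split**: `floor(0.7 n)` subjects train, the rest test (floor fixed for
  determinism); both samples of a subject stay together; ungrouped splitting
  is rejected outright as a leakage hazard. The same split and the same
  10-fold subject-grouped CV assignment are reused across all connections.
* **Probabilities per subject**: training subjects contribute out-of-fold CV
  probabilities, test subjects final-model probabilities. The original
  method does not say which individuals enter downstream identifiability;
  this package uses all of them, under the above convention, and documents
  rather than asserts it.
* Folds whose training part degenerates to one class are skipped with a
  warning; subjects missing a condition are dropped with a warning.

## 5. Network summarization and dice

Region-pair accuracies are block-averaged over a region → network assignment
(20 networks in the canonical layout; any table works), diagonal blocks
averaging intranetwork pairs. A configuration keeps blocks whose mean
accuracy reaches the **inclusive** 70% threshold (`>= 0.70`; published
entries such as 70.2–70.7% survive under either convention, but the choice
is documented and tested). Dice similarity between two configurations is
computed over the upper triangle including the diagonal, so each symmetric
block counts once; two empty configurations raise an error instead of
returning a misleading 0. A count-weighted conservation property (network
mean reproduces the global pair mean) guards the bookkeeping. Dropped
regions (e.g. brain-stem regions of an atlas) are excluded before averaging
via the assignment's drop list.

## 6. Identifiability and behavior

Task identifiability of a subject = mean probability estimate of the
subject's *task* sample over all region pairs inside the suprathreshold
configuration (an empty configuration is an error — some tasks genuinely
yield none). A flag (`include_rest`) also averages in 1 − p of the rest
sample for a symmetric variant; the task-only definition is the default
because the measure is task identifiability.

Associations use the Pearson partial correlation: residuals of score and
measure after OLS on an intercept plus covariates (age, sex by default),
p-value from t with n − 2 − k df, pairwise-complete deletion per measure
with n reported. Significance requires both `p < alpha/m` (`alpha = .05`,
`m = 192` — the divisor stays at the configured battery width even if
columns are skipped) and `|r| > 0.1`. `pc_partial()` additionally partials
the top principal components of named cognition and performance column sets
(columns standardized before extraction).

## 7. The synthetic world

The generator exists because the original recordings are access-restricted.
It emulates what the downstream stages *assume*, with closed-form ground
truth:

* **Latent signals**: independent stationary AR(1) per region, coefficient
  0.3 (a mild, fixed stand-in for BOLD autocorrelation), innovation sd 1.
* **Planted coupling**: for a planted pair (i, j), region j's latent is
  rebuilt as $w(t)z_i(t) + \sqrt{1-w(t)^2}\,\eta(t)$ with η an independent
  copy of the same process, so the instantaneous correlation is *exactly*
  w(t) — the mixture construction gives recovery tests an analytic target.
* **Task coupling**: $w(t) = b + e \cdot a \cdot m(t)$ with baseline
  b = 0.2, amplitude a = 0.5, per-subject engagement e ~ N(1, 0.2), and m(t)
  a raised cosine with two cycles over T, range [0, 1] — deliberately **not
  block-locked**, because the preprocessing removes block-locked structure
  and the decodable signal must survive it.
* **Rest coupling**: constant at $b + a/2$, the expected time average of
  the task series. This mean-matching is load-bearing: with rest pinned at
  the bare baseline, task and rest would differ in *time-averaged*
  correlation and static FC would decode them trivially, contradicting both
  the static-chance acceptance criterion and the stated mean-preserving
  character of the planted world. The package treats the constant-rest
  description and the mean-preservation requirement as conflicting and
  resolves in favor of the latter (the scientific point of the exercise);
  with amplitude 0 the two conditions coincide exactly, preserving the null
  degeneracy. An optional slow rest drift (`rest_drift`) exists, off by
  default, as the chosen null is constant rest coupling.
* w(t) is clipped to |w| ≤ 0.99; with the validated constraint
  |b| + a < 1 clipping only engages for extreme engagement draws (|e| > ~1.6
  at the defaults). Aborting instead would kill a few percent of honest
  cohorts on Gaussian tail draws, so clipping is silent and documented.
* **Confounds**: a spiky nonnegative FD-like series and two slow AR(1)
  tissue-mean-like series, each mixed into all regions with loading 0.1 —
  enough to make confound regression consequential, not enough to drown the
  signal. Task recordings add a block-locked HRF-convolved activation
  (loading 0.5) that the preprocessing GLM must remove.
* **HRF**: SPM-style double gamma (response gamma shape 6, undershoot shape
  16, ratio 1/6, unit rate), sampled at TR; peak ≈ 5–6 s, value 0 at t = 0.
* **Behavior**: performance = 2·e + N(0, 1) (`behavior_loading = 2`; no
  value is stated anywhere, and 2 yields a true score–performance
  correlation ≈ 0.35 at engagement sd 0.2 — a realistic, clearly nonzero
  behavioral effect that still needs hundreds of subjects to clear a
  .05/192 Bonferroni bar); plus independent null measures, integer ages
  22–37, binary sex.
* Everything is reproducible from the single cohort seed.

**What a green test does not establish.** The generator has Gaussian AR(1)
sources, three clean confounds, and a single smooth modulation profile; real
recordings have structured physiological noise, spatially correlated
parcels, heteroscedastic motion artifacts, and unknown w(t). Passing the
acceptance suite shows the *pipeline* is correct and well-calibrated under
its stated assumptions — it does not certify effect sizes or accuracies on
real data, and the published network-level accuracies and behavioral r
values are explicitly out of desk-scale reach.

## 8. Scaled-down and emulated checks

Two properties are verified at reduced cost, by design rather than
necessity:

* The behavioral power/family-wise-error property (planted measure
  significant in ≥ 90% of 25 replicates at n = 400) feeds
  `screen_measures()` with an *emulated* identifiability score —
  a logistic readout of engagement, `plogis(1 + 3(e−1) + N(0, 0.3))` —
  instead of 25 full classifier pipelines at 400 subjects each (hours of
  compute for no additional coverage: the score→screen path is what the
  property tests, and the classifier→score path is tested elsewhere). The
  logit-scale noise 0.3 was chosen once as a generous estimate of score
  estimation noise at T = 150 features.
* The identifiability-monotonicity property (more engagement never lowers a
  subject's identifiability) is tested by probing fixed trained models with
  recordings simulated at increasing engagement under common random
  numbers, averaged over replicates — a unit-level restatement of the same
  claim.

The full-scale criteria (chance-level static FC on a 200-subject null
cohort; ≥ 70% DFC accuracy on planted pairs at 200 subjects, T = 150) run
uncut in `tests/testthat/test-acceptance.R` and `scripts/acceptance.R`.

## 9. Known limitations

* No motion scrubbing, bandpass filtering, or FIR task modeling; no
  sliding-window/HMM DFC alternatives; no nonlinear or multi-connection
  classifiers; no task-vs-task decoding. All are declared non-goals.
* The FLS direction convention is a genuine unknown of the source method;
  results for strongly asymmetric pairs can differ between `"lower"` and
  `"average"`.
* At small n (tens of subjects) per-connection test accuracies are coarse
  (quantized by the test-set size) and the 70% threshold behaves noisily;
  the package reports CV and test accuracy side by side so users can see
  the agreement (they match within 5 points on well-powered cohorts).
* `read_cohort()` cannot restore ground-truth coupling (it is not written
  to disk); recovery tests must work from freshly simulated objects.
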