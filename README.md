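# mtpa — multi-timepoint pattern analysis of dynamic functional connectivity

`mtpa` asks a simple question of paired task/rest fMRI recordings: *after the
mean evoked response is regressed away, does the moment-to-moment dynamics of
inter-regional coupling still carry enough information to tell whether a
person was doing a task or resting?* It answers it by

1. estimating **framewise time-varying connectivity** for every region pair
   with **flexible least squares (FLS)** — the coefficient series
   `beta(t)` minimizing

   ```
   C(beta; mu) = sum_t (y_t - x_t beta_t)^2  +  mu * sum_{t<T} (beta_{t+1} - beta_t)^2
   ```

   (measurement fit error plus `mu` times the dynamic error; `mu = 100` by
   default, solved exactly in O(T) via the symmetric tridiagonal normal
   equations);
2. training one **L2-regularized linear logistic classifier per connection**
   on the T-dimensional temporal pattern `beta(1..T)` (or on the
   1-dimensional static Pearson correlation, for comparison), with a
   subject-level 70/30 split and 10-fold subject-grouped cross-validation
   (multi-timepoint pattern analysis, MTPA);
3. **summarizing decoding accuracy at network level** (block means over a
   region-to-network assignment, inclusive threshold at 70% accuracy) and
   comparing task configurations with the **dice coefficient**
   `2|A∩B| / (|A|+|B|)`;
4. relating per-subject **task identifiability** (mean task-sample
   probability over suprathreshold connections) to behavioral measures via
   **Pearson partial correlation** with age/sex control, Bonferroni
   correction (`p < alpha/m`, `m = 192`) and an effect-size filter
   (`|r| > 0.1`).

Because the neuroimaging data this methodology was designed for are access
restricted, the package ships a first-class **synthetic cohort generator**
with known ground-truth time-varying coupling, so every stage is testable
end to end on a laptop. See `vignettes/mtpa-methods.Rmd` for the generative
model and all numerical conventions.

## Worked example

```r
library(mtpa)

spec   <- cohort_spec(n_subjects = 40, n_regions = 20, n_frames = 120, seed = 1)
cohort <- preprocess_cohort(simulate_cohort(spec))     # GLM residuals, trimmed
res    <- run_all_connections(collect_features(cohort, "dfc"), split_spec(seed = 1))
res
#> mtpa_results (dfc features): 190 connections, 80 samples
#>   mean CV accuracy 0.497, mean test accuracy 0.511
```

The cohort plants time-varying coupling on five region pairs — (1,2), (3,4),
…, (9,10) — whose task recordings modulate coupling with a slow,
non-block-locked profile scaled by each subject's latent engagement. Grouping
consecutive regions into ten two-region networks isolates each planted pair
in one diagonal block:

```r
asg <- network_assignment(1:20, rep(sprintf("net%02d", 1:10), each = 2))
net <- downsample_accuracy(res, asg)
round(diag(net$accuracy), 2)
#> net01 net02 net03 net04 net05 net06 net07 net08 net09 net10
#>  0.75  0.62  0.83  0.79  0.71  0.46  0.46  0.46  0.42  0.50
```

The five planted blocks decode far above the unplanted ones; four of them
clear the 70% threshold even at this small n (the mean *over all 190 pairs*
stays at chance because 185 pairs carry no signal). Identifiability and the
behavioral screen then run on the suprathreshold configuration:

```r
cfg <- threshold_matrix(net, 0.70)
sc  <- task_identifiability(res, cfg, asg)
head(screen_measures(sc, cohort$behavior, m = 192), 3)
#>       measure      r     p  n significant
#> 1 performance  0.252 0.128 40       FALSE
#> 2     null_09 -0.199 0.232 40       FALSE
#> 3     null_11  0.158 0.344 40       FALSE
```

The planted `performance` measure (which loads on engagement) tops the
ranking, but 40 subjects cannot survive a Bonferroni bar of `.05/192`; the
power properties in `tests/testthat/test-acceptance.R` demonstrate reliable
recovery at n = 400.

A command-line wrapper over the same functions lives at
`inst/cli/mtpa.R` (`simulate`, `preprocess`, `dfc`, `staticfc`, `classify`,
`summarize`, `dice`, `behavior`, `run`).

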