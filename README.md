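# emocascade

Emotion-labelled reshare cascade propagation analysis.

After a shocking public event, social-media reactions arrive as **reshare
cascades**: an original post plus the time-ordered series of its reshares
within a fixed observation window (21 days by default). emocascade is for
computational social scientists and public-health analysts who want to ask
how the *emotion* expressed in a post relates to how far, how long, how
fast and how intensely it propagates — and who need every step of that
analysis to be testable without access to proprietary platform data.

The package covers the full pipeline:

1. **Ingest** — read reshare event logs (JSONL/CSV) and author covariate
   tables, validate the seven-way emotion probability scores, and assemble
   time-ordered cascades under the window rule (`read_events()`,
   `build_cascades()`).
2. **Metrics** — five per-cascade propagation measures: size (reshares + 1),
   lifetime, median inter-reshare delay, time to the fifth reshare, and
   burstiness as the coefficient of variation CV = σ/μ of inter-event
   delays, where CV ≈ 1 is the memoryless (Poisson) baseline and CV > 1
   means temporally clustered resharing (`summarize_features()`).
3. **Emotion** — dominant-emotion assignment by argmax of the probability
   scores, frequency and intensity tables, and support-weighted
   precision/recall/F1 for validating a scorer against human annotation
   (`dominant_emotion()`, `weighted_prf()`).
4. **Regression** — the model battery

   y_i = β0 + β1ᵀ emotion_i + β2ᵀ event_i + β3ᵀ controls_i + ε_i

   with neutral as the emotion base: negative binomial for cascade size,
   OLS for log lifetime, log median delay, log time-to-fifth and CV, each
   with and without emotion dummies and with event-clustered CR1 robust
   standard errors (t with G−1 df; the package warns when clusters are few)
   (`run_model_battery()`, `sign_pattern()`).
5. **Synthetic data & recovery** — a seeded generator whose defaults
   reproduce the study conditions (67% of cascades at size 2, mean size
   5.36, heavy-tailed author covariates, regular vs bursty reshare timing),
   plus a parameter-recovery harness that simulates, re-assembles, re-fits
   and reports bias and CI coverage against the known truth
   (`gen_event_stream()`, `recovery_experiment()`).

All user-facing functions take data frames and return tibbles; fitted
models have `tidy()`/`glance()` methods and `autoplot()` coefficient plots.

## Worked example

Simulate a scenario in which disgust-laden posts propagate more strongly
than neutral ones, run the pipeline, and read off the results:

```r
library(emocascade)

cfg      <- scenario_signs(n_cascades = 5000, seed = 42)
sim      <- gen_event_stream(cfg)
cascades <- build_cascades(sim$events, cfg$event_start_s, cfg$window_days)
features <- summarize_features(cascades, sim$authors)

cohort_summary(features)[, c("group", "n", "size_mean", "size_sd",
                             "lifetime_min_mean", "cv_mean")]
#> # A tibble: 5 × 6
#>   group     n size_mean size_sd lifetime_min_mean cv_mean
#>   <chr> <int>     <dbl>   <dbl>             <dbl>   <dbl>
#> 1 DC     1458      6.34   20.9               256.   0.924
#> 2 JS     1875      6.61   19.5               274.   0.880
#> 3 LTY     695      4.41    9.77              172.   0.855
#> 4 TS      972      6.73   21.7               282.   0.889
#> 5 ALL    5000      6.25   19.4               256.   0.892
```

Per event stratum and pooled (`ALL`): cascades average ~6 posts with a
right-skewed spread (SD ≈ 19), live ~4 hours, and their inter-reshare
delays are slightly more regular than a memoryless process (CV < 1).

```r
battery <- run_model_battery(features)
td <- tidy(battery[["size_min2_emotions"]])
td[grepl("emotion", td$term), c("term", "estimate", "std.error", "p.value")]
#> # A tibble: 6 × 4
#>   term             estimate std.error p.value
#>   <chr>               <dbl>     <dbl>   <dbl>
#> 1 emotion_anger      0.267     0.0697 0.0312
#> 2 emotion_disgust    1.42      0.126  0.00150
#> 3 emotion_fear       0.0357    0.0828 0.696
#> 4 emotion_joy        0.0779    0.122  0.568
#> 5 emotion_sadness    0.0119    0.0663 0.869
#> 6 emotion_surprise   0.0926    0.204  0.681
```

In the negative binomial size model, a disgust post multiplies the
expected cascade size by exp(1.42) ≈ 4.1 relative to a neutral post
(cluster-robust p ≈ 0.002 on 3 df). Condensing the whole battery into
per-emotion sign calls:

```r
sign_pattern(battery)
#> # A tibble: 6 × 5
#>   emotion  size  lifetime speed burstiness
#>   <chr>    <chr> <chr>    <chr> <chr>
#> 1 anger    +     0        0     +
#> 2 disgust  +     +        +     +
#> 3 fear     0     0        0     0
#> 4 joy      0     0        0     0
#> 5 sadness  0     0        0     0
#> 6 surprise 0     0        0     0
```

Disgust shows the full positive signature — larger, longer-lived, faster
(speed inverts the median-delay sign) and burstier — exactly the structure
this scenario was generated with; at this modest sample size the weaker
generated effects of the other emotions mostly do not clear the
four-cluster significance bar.

The same pipeline runs from a single YAML config via `run_simulate()` /
`run_analyze()` / `run_recover()` or the thin CLI wrapper in
`inst/cli.R`; see the vignette in `vignettes/cascade-propagation.Rmd` for
the models, assumptions and design choices.

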