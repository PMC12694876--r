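# Synthetic reshare-stream generator.

test_that("gen_authors is deterministic and matches its marginal targets", {
  a1 <- gen_authors(1, seed = 7)
  a2 <- gen_authors(1, seed = 7)
  expect_identical(a1, a2)

  big <- gen_authors(10000, seed = 42)
  expect_lt(abs(mean(big$verified) - 0.04), 0.01)
  expect_equal(min(big$followers), 0)   # point mass at the legal minimum
  expect_equal(min(big$likes), 0)
  expect_true(min(big$statuses) >= 1)
  expect_true(max(big$followers) > 1e5)     # heavy tail
  expect_error(gen_authors(0), "positive")
})

test_that("emotion score vectors live on the simplex with the requested argmax", {
  s <- gen_emotion_scores("sadness", concentration = 8, seed = 1)
  expect_named(s, emotion_labels())
  expect_equal(sum(s), 1, tolerance = 1e-9)
  expect_true(all(s >= 0))

  set.seed(99)
  draws <- replicate(1000, gen_emotion_scores("fear", concentration = 4))
  expect_true(all(apply(draws, 2, function(x) names(which.max(x))) == "fear"))
  expect_true(all(abs(colSums(draws) - 1) < 1e-9))

  # degenerate concentration limit: mass collapses on the dominant label
  s_inf <- gen_emotion_scores("sadness", concentration = 1e6, seed = 3)
  expect_gt(s_inf[["sadness"]], 0.999)
  expect_error(gen_emotion_scores("boredom"), "must be one of")
})

test_that("regular-regime reshare times behave like a memoryless process", {
  set.seed(11)
  cvs <- replicate(1000, {
    offs <- gen_cascade_times(5, mean_delay_s = 60, regime = "regular")
    g <- diff(c(0, offs))
    sd(g) / mean(g)
  })
  # small-sample CV under exponential gaps is biased below 1
  expect_gt(mean(cvs), 0.7)
  expect_lt(mean(cvs), 1.1)

  one <- gen_cascade_times(1, mean_delay_s = 60, seed = 5)
  expect_length(one, 1)
  expect_gt(one, 0)
  many <- gen_cascade_times(500, mean_delay_s = 60, seed = 5)
  expect_true(all(diff(many) > 0))
})

test_that("bursty-regime reshare times are overdispersed in time", {
  set.seed(12)
  bp <- list(burst_rate_ratio = 20, burst_switch_prob = 0.1)
  cv_gt1 <- replicate(1000, {
    offs <- gen_cascade_times(100, mean_delay_s = 60, regime = "bursty",
                              burst_params = bp)
    g <- diff(c(0, offs))
    sd(g) / mean(g) > 1
  })
  expect_gte(mean(cv_gt1), 0.95)
})

test_that("gen_event_stream is reproducible and respects its contracts", {
  cfg <- scenario_config(n_cascades = 200, n_authors = 100, seed = 5)
  sim1 <- gen_event_stream(cfg)
  sim2 <- gen_event_stream(cfg)
  expect_identical(sim1$events, sim2$events)
  expect_identical(sim1$authors, sim2$authors)

  ev <- sim1$events
  expect_true(all(abs(rowSums(as.matrix(ev[paste0("score_", emotion_labels())])) - 1) < 1e-9))

  # every root has at least one reshare, and reshares carry the root fields
  roots <- ev[ev$root_id == "", ]
  rts <- ev[ev$root_id != "", ]
  expect_true(all(roots$event_id %in% rts$root_id))
  j <- match(rts$root_id, roots$event_id)
  expect_true(all(rts$score_fear == roots$score_fear[j]))
  expect_true(all(rts$word_count == roots$word_count[j]))
  expect_true(all(rts$time_s >= roots$time_s[j]))

  # all timestamps inside the window of their event stratum
  start <- cfg$event_start_s[ev$event_label]
  expect_true(all(ev$time_s >= start))
  expect_true(all(ev$time_s <= start + cfg$window_days * 86400))
})

test_that("generated sizes match the 2 + negative binomial target", {
  mu <- 3.36
  cfg <- scenario_config(n_cascades = 4000, n_authors = 500,
                         size_betas = c(`(Intercept)` = log(mu)), seed = 21)
  sim <- gen_event_stream(cfg)
  sizes <- table(sim$events$root_id[sim$events$root_id != ""])
  excess <- as.numeric(sizes) - 1 # (size - 2) = reshares - 1
  mcse <- sd(excess) / sqrt(length(excess))
  expect_lt(abs(mean(excess) - mu), 3 * mcse)
})

test_that("ground truth round-trips through JSON", {
  cfg <- scenario_signs(n_cascades = 20, seed = 9)
  sim <- gen_event_stream(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$dominant_emotion, sim$truth$dominant_emotion)
  expect_equal(back$size_betas, sim$truth$size_betas)
  expect_equal(back$size_theta, sim$truth$size_theta)
  expect_equal(unclass(back$config), unclass(sim$truth$config),
               tolerance = 1e-12)
})

test_that("scenario validation rejects broken configurations", {
  bad_probs <- setNames(rep(0.2, 7), emotion_labels())
  expect_error(scenario_config(10, emotion_probs = bad_probs), "sum to 1")
  expect_error(scenario_config(10, size_betas = c(happiness = 1)),
               "unrecognised")
  expect_error(scenario_config(10, burst_params = list(burst_rate_ratio = 0.5)),
               "burst_rate_ratio")
})
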