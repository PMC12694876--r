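# Design matrices, model fits, clustered errors, battery, recovery.

test_that("build_design lays out responses, dummies and filters", {
  feats <- fake_features(300, seed = 21)
  d <- build_design(feats, dv = "size", min_size = 2)
  expect_equal(nrow(d$data), 300)
  expect_equal(d$data$response, as.numeric(feats$size))
  expect_true(all(paste0("emotion_", setdiff(emotion_labels(), "neutral"))
                  %in% names(d$data)))
  expect_true(all(paste0("event_", c("B", "C", "D")) %in% names(d$data)))
  expect_false("event_A" %in% names(d$data)) # base stratum
  # emotion dummies are mutually exclusive
  emo <- as.matrix(d$data[grep("^emotion_", names(d$data))])
  expect_true(all(rowSums(emo) <= 1))

  dl <- build_design(feats, dv = "log_lifetime", min_size = 3)
  expect_equal(dl$data$response,
               log1p(feats$lifetime_s[feats$size >= 3] / 60))

  expect_message(dcv <- build_design(feats, dv = "cv", min_size = 2),
                 "undefined response")
  expect_equal(nrow(dcv$data), sum(!is.na(feats$cv)))
  d5 <- build_design(feats, dv = "log_time5rt", min_size = 6)
  expect_equal(nrow(d5$data), sum(feats$size >= 6))

  neutral_only <- feats
  neutral_only$dominant_emotion <- "neutral"
  expect_message(dn <- build_design(neutral_only, "size", 2),
                 "all-zero design column")
  expect_false(any(grepl("^emotion_", names(dn$data))))

  one_cluster <- feats
  one_cluster$event_label <- "A"
  expect_error(build_design(one_cluster, "size", 2), "insufficient")
})

test_that("count models recover known generating parameters", {
  set.seed(22)
  n <- 10000
  x <- rnorm(n)
  y <- rpois(n, exp(1.0 + 0.5 * x))
  g <- sample(c("a", "b", "c", "d"), n, replace = TRUE)
  d <- fake_design(y, data.frame(x = x), g)
  fit <- fit_count_model(d, family = "poisson")
  se <- fit$se_model
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - 1.0), 3 * se[["(Intercept)"]])
  expect_lt(abs(fit$coefficients[["x"]] - 0.5), 3 * se[["x"]])

  # NB on equidispersed data: huge theta, likelihood pinned to the Poisson
  nb <- suppressWarnings(fit_count_model(d, family = "negative_binomial"))
  expect_gt(nb$theta, 100)
  expect_lt(abs(nb$loglik - fit$loglik), 1)
  expect_gte(nb$loglik, fit$loglik - 1e-6) # nesting
  expect_equal(nb$aic, 2 * (length(nb$coefficients) + 1) - 2 * nb$loglik)
})

test_that("an intercept-only count model reproduces the sample mean", {
  set.seed(23)
  y <- rnbinom(500, mu = 4, size = 1)
  d <- fake_design(y, data.frame(), rep(c("a", "b"), 250))
  fit <- fit_count_model(d)
  expect_equal(exp(fit$coefficients[["(Intercept)"]]), mean(y),
               tolerance = 1e-6)
  expect_error(
    fit_count_model(fake_design(c(0.5, 1.2, 3), data.frame(), c("a", "a", "b"))),
    "integer"
  )
})

test_that("OLS matches the normal-equation oracle", {
  set.seed(24)
  n <- 60
  X <- data.frame(x1 = rnorm(n), x2 = runif(n))
  y <- 2 + 1.5 * X$x1 - 0.7 * X$x2 + rnorm(n)
  d <- fake_design(y, X, rep(letters[1:3], 20))
  fit <- fit_ols(d)
  Xm <- cbind(1, X$x1, X$x2)
  beta_oracle <- solve(t(Xm) %*% Xm, t(Xm) %*% y)
  expect_equal(unname(fit$coefficients), as.numeric(beta_oracle),
               tolerance = 1e-10)
  expect_lte(fit$adj_r2, fit$r2)

  # exact linear response: zero residuals, R^2 = 1
  y_exact <- 1 + 2 * X$x1
  fit_exact <- suppressWarnings(
    fit_ols(fake_design(y_exact, X["x1"], rep(letters[1:3], 20)))
  )
  expect_equal(max(abs(fit_exact$residuals)), 0, tolerance = 1e-10)
  expect_equal(fit_exact$r2, 1)

  X$dup <- X$x1 # collinear column
  expect_error(fit_ols(fake_design(y, X, rep(letters[1:3], 20))), "collinear")
})

test_that("cluster-robust SEs equal the hand-rolled sandwich", {
  set.seed(25)
  n <- 30
  X <- data.frame(x1 = rnorm(n), x2 = runif(n))
  cl <- rep(c("c1", "c2", "c3"), each = 10)
  y <- 1 + 0.5 * X$x1 + rnorm(n) * (1 + (cl == "c2"))
  fit <- fit_ols(fake_design(y, X, cl))
  expect_warning(fit <- cluster_robust_se(fit), class = "emocascade_small_G")
  Xm <- cbind(1, X$x1, X$x2)
  V <- bf_cluster_vcov_ols(Xm, fit$residuals, cl)
  expect_equal(unname(fit$se_cluster), sqrt(diag(V)), tolerance = 1e-8)

  # and for the negative binomial through its estimating-equation scores
  yc <- rnbinom(n, mu = exp(0.5 + 0.4 * X$x1), size = 2)
  nb <- fit_count_model(fake_design(yc, X["x1"], cl))
  nb <- cluster_robust_se(nb, warn_small_G = FALSE)
  mu <- fitted(nb$model)
  Vnb <- bf_cluster_vcov_nb(cbind(1, X$x1), yc, mu, nb$theta, cl)
  expect_equal(unname(nb$se_cluster), sqrt(diag(Vnb)), tolerance = 1e-8)

  expect_error(cluster_robust_se(fit, clusters = rep("one", n)), ">= 2")
})

test_that("degenerate clustering reduces to heteroskedasticity-robust SEs", {
  set.seed(26)
  n <- 40
  X <- data.frame(x = rnorm(n))
  y <- 1 + 0.3 * X$x + rnorm(n) * exp(X$x / 2)
  fit <- fit_ols(fake_design(y, X, paste0("u", 1:n)))
  fit <- cluster_robust_se(fit, warn_small_G = FALSE)
  Xm <- cbind(1, X$x)
  e <- fit$residuals
  # HC1 by hand: n/(n-k) * bread X' diag(e^2) X bread
  bread <- solve(t(Xm) %*% Xm)
  Vhc1 <- n / (n - 2) * bread %*% (t(Xm) %*% (Xm * e^2)) %*% bread
  expect_equal(unname(fit$se_cluster), sqrt(diag(Vhc1)), tolerance = 1e-8)
})

test_that("duplicating rows within clusters leaves t-ratios stable", {
  set.seed(27)
  n <- 200
  X <- data.frame(x = rnorm(n))
  cl <- sample(paste0("g", 1:5), n, replace = TRUE)
  u <- rnorm(5)[match(cl, paste0("g", 1:5))] # within-cluster correlation
  y <- 1 + 0.5 * X$x + u + rnorm(n)
  f1 <- cluster_robust_se(fit_ols(fake_design(y, X, cl)), warn_small_G = FALSE)
  f2 <- cluster_robust_se(
    fit_ols(fake_design(rep(y, 2), data.frame(x = rep(X$x, 2)), rep(cl, 2))),
    warn_small_G = FALSE
  )
  t1 <- f1$coefficients / f1$se_cluster
  t2 <- f2$coefficients / f2$se_cluster
  expect_equal(unname(t2), unname(t1), tolerance = 0.05)
})

test_that("the battery enumerates the full model grid reproducibly", {
  cfg <- scenario_signs(n_cascades = 2500, seed = 17)
  sim <- gen_event_stream(cfg)
  cas <- suppressMessages(build_cascades(sim$events, cfg$event_start_s,
                                         cfg$window_days))
  feats <- summarize_features(cas, sim$authors)
  bat <- suppressMessages(run_model_battery(feats))
  expect_length(bat, 14)
  expect_setequal(
    names(bat),
    c(t(outer(c("size_min2", "size_min3", "log_lifetime_min2",
                "log_lifetime_min3", "log_median_delay_min6",
                "log_time5rt_min6", "cv_min6"),
              c("_base", "_emotions"), paste0)))
  )
  controls <- c("log_followers", "log_friends", "log_statuses", "log_likes",
                "verified", "word_count", "has_hashtag")
  for (f in bat) {
    expect_true(all(controls %in% names(f$coefficients)))
    expect_false(is.null(f$se_cluster))
  }
  funnel <- attr(bat, "funnel")
  expect_true(funnel[["min2"]] >= funnel[["min3"]])
  expect_true(funnel[["min3"]] >= funnel[["min6"]])

  bat2 <- suppressMessages(run_model_battery(feats))
  expect_identical(lapply(bat, coef), lapply(bat2, coef))

  sp <- sign_pattern(bat)
  expect_setequal(sp$emotion, setdiff(emotion_labels(), "neutral"))
  expect_true(all(unlist(sp[-1]) %in% c("+", "-", "0")))
  # with an impossibly strict alpha nothing is called
  sp0 <- sign_pattern(bat, alpha = 1e-300)
  expect_true(all(unlist(sp0[-1]) == "0"))

  td <- tidy(bat[["size_min2_emotions"]])
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(bat[["size_min2_emotions"]])
  expect_equal(gl$family, "negative_binomial")
  expect_false(is.na(gl$theta))
})

test_that("a small recovery run produces coherent diagnostics", {
  cfg <- scenario_recovery(n_cascades = 400, seed = 19)
  rep <- recovery_experiment(cfg, n_reps = 4, seed = 19)
  s <- rep$summary
  expect_equal(nrow(s), 6)
  expect_true(all(is.finite(s$bias)))
  expect_true(all(s$coverage >= 0 & s$coverage <= 1))
  expect_equal(s$mean_estimate - s$true, s$bias, tolerance = 1e-12)
  expect_equal(tidy(rep), s)
  expect_equal(glance(rep)$n_reps, 4)
})
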