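# Design construction and the regression battery: negative binomial for
# cascade size, OLS for the log-duration and burstiness outcomes, with
# event-clustered robust standard errors throughout.

dv_choices <- function() {
  c("size", "size_minus2", "log_lifetime", "log_median_delay",
    "log_time5rt", "cv")
}

# response on the model scale; durations are log(1 + x) to admit the zero
# minima observed in the data (lifetime in minutes, delays in seconds)
dv_response <- function(features, dv) {
  switch(dv,
    size = as.numeric(features$size),
    size_minus2 = as.numeric(features$size) - 2,
    log_lifetime = log1p(features$lifetime_s / 60),
    log_median_delay = log1p(features$median_delay_s),
    log_time5rt = log1p(features$time5rt_s),
    cv = features$cv,
    abort(paste0("unknown dv: ", dv))
  )
}

#' Build a regression design for one propagation outcome
#'
#' Applies the size filter, computes the response for the chosen outcome
#' (counts untransformed for the NB models; `log(1 + x)` for durations; CV
#' raw), and lays out the predictor columns: six emotion dummies with
#' neutral as the base category, event-stratum dummies with the first
#' stratum as base, and the controls (log author covariates, verified,
#' word count, hashtag flag). Rows with an undefined response are dropped
#' and counted. Dummy columns that are identically zero in the filtered
#' subset (an emotion or stratum absent) are removed with a message so the
#' design stays full rank.
#'
#' @param features A `cascade_features` tibble.
#' @param dv One of `"size"`, `"size_minus2"`, `"log_lifetime"`,
#'   `"log_median_delay"`, `"log_time5rt"`, `"cv"`.
#' @param min_size Size filter applied before fitting (>= 2).
#' @param include_emotions Include the six emotion dummies? (The battery
#'   fits each outcome with and without them.)
#' @return An object of class `cascade_design`: list with `data` (response
#'   plus predictors), `response`, `clusters` (event label per row), `dv`,
#'   `min_size`, `include_emotions`, `n_dropped_response`.
#' @export
build_design <- function(features, dv, min_size = 2, include_emotions = TRUE) {
  dv <- match.arg(dv, dv_choices())
  feats <- filter_by_size(features, min_size)
  if (nrow(feats) == 0) abort("no cascades left after the size filter.")
  y <- dv_response(feats, dv)
  keep <- !is.na(y)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(paste0("build_design(", dv, "): dropped ", n_dropped,
                  " row(s) with undefined response."))
  }
  feats <- feats[keep, , drop = FALSE]
  y <- y[keep]

  data <- tibble(response = y)
  if (include_emotions) {
    for (e in setdiff(emotion_labels(), "neutral")) {
      data[[paste0("emotion_", e)]] <- as.numeric(feats$dominant_emotion == e)
    }
  }
  ev_levels <- sort(unique(features$event_label))
  for (ev in ev_levels[-1]) {
    data[[paste0("event_", ev)]] <- as.numeric(feats$event_label == ev)
  }
  data$log_followers <- feats$log_followers
  data$log_friends <- feats$log_friends
  data$log_statuses <- feats$log_statuses
  data$log_likes <- feats$log_likes
  data$verified <- as.numeric(feats$verified)
  data$word_count <- as.numeric(feats$word_count)
  data$has_hashtag <- as.numeric(feats$has_hashtag)

  zero <- names(data)[-1][vapply(data[-1], function(x) all(x == 0), logical(1))]
  if (length(zero)) {
    inform(paste0("dropping all-zero design column(s): ",
                  paste(zero, collapse = ", ")))
    data <- data[setdiff(names(data), zero)]
  }
  clusters <- feats$event_label
  k <- ncol(data) # predictors + intercept
  if (length(unique(clusters)) < 2 || nrow(data) < k + 2) {
    abort("insufficient data: need >= 2 clusters and n >= k + 2 rows.")
  }
  structure(
    list(data = data, response = y, clusters = clusters, dv = dv,
         min_size = min_size, include_emotions = include_emotions,
         n_dropped_response = n_dropped),
    class = "cascade_design"
  )
}

new_cascade_fit <- function(model, design, family) {
  s <- sqrt(diag(vcov(model)))
  # count-model likelihoods through the stable density evaluators: the
  # glm.nb internal loglik loses precision when theta runs away on
  # equidispersed data
  y <- design$data$response
  ll <- switch(family,
    negative_binomial = sum(stats::dnbinom(y, size = model$theta,
                                           mu = stats::fitted(model),
                                           log = TRUE)),
    poisson = sum(stats::dpois(y, stats::fitted(model), log = TRUE)),
    NULL
  )
  # +1 parameter for theta in the NB model
  k <- length(coef(model)) + (family == "negative_binomial")
  aic <- if (is.null(ll)) NULL else 2 * k - 2 * ll
  structure(
    list(
      model = model,
      coefficients = coef(model),
      se_model = s[names(coef(model))],
      se_cluster = NULL,
      n_clusters = NULL,
      theta = if (family == "negative_binomial") model$theta else NULL,
      loglik = ll,
      aic = aic,
      adj_r2 = if (family == "ols") summary(model)$adj.r.squared else NULL,
      r2 = if (family == "ols") summary(model)$r.squared else NULL,
      residuals = resid(model),
      n_obs = nrow(design$data),
      family = family,
      dv = design$dv,
      min_size = design$min_size,
      include_emotions = design$include_emotions,
      clusters = design$clusters
    ),
    class = "cascade_fit"
  )
}

#' Fit a count model (negative binomial or Poisson) for cascade size
#'
#' A log-link GLM of the count response on the design's predictors. The
#' negative binomial dispersion `theta` is estimated by maximum likelihood
#' (via `MASS::glm.nb`); the Poisson model is the equidispersed comparison
#' fit. Non-convergence is an error.
#'
#' @param design A `cascade_design` whose response is a non-negative
#'   integer count.
#' @param family `"negative_binomial"` (default) or `"poisson"`.
#' @param maxit Maximum IRLS iterations (default 100).
#' @return A `cascade_fit` (model-based SEs only; add clustered SEs with
#'   [cluster_robust_se()]).
#' @export
fit_count_model <- function(design,
                            family = c("negative_binomial", "poisson"),
                            maxit = 100) {
  stopifnot(inherits(design, "cascade_design"))
  family <- match.arg(family)
  y <- design$data$response
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8)) {
    abort("count models need a non-negative integer response.")
  }
  form <- if (ncol(design$data) == 1) response ~ 1 else response ~ .
  if (family == "negative_binomial") {
    model <- MASS::glm.nb(form, data = design$data,
                          control = stats::glm.control(maxit = maxit))
    if (!isTRUE(model$converged)) {
      abort(paste0("negative binomial fit did not converge in ", maxit,
                   " iterations (theta trace: ",
                   paste(signif(model$twologlik, 6), collapse = ", "), ")"))
    }
  } else {
    model <- glm(form, data = design$data, family = poisson(),
                 control = stats::glm.control(maxit = maxit))
    if (!isTRUE(model$converged)) {
      abort("Poisson fit did not converge.")
    }
  }
  new_cascade_fit(model, design, family)
}

#' Fit an ordinary least squares model
#'
#' @param design A `cascade_design`.
#' @return A `cascade_fit` with coefficients, model SEs and adjusted R^2.
#'   Rank deficiency is an error naming the collinear columns.
#' @export
fit_ols <- function(design) {
  stopifnot(inherits(design, "cascade_design"))
  form <- if (ncol(design$data) == 1) response ~ 1 else response ~ .
  model <- lm(form, data = design$data)
  if (anyNA(coef(model))) {
    bad <- names(coef(model))[is.na(coef(model))]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  new_cascade_fit(model, design, "ols")
}

#' Add event-clustered robust standard errors to a fit
#'
#' Sandwich estimator with cluster-level score sums and the CR1
#' small-sample factor `G/(G-1) * (n-1)/(n-k)`, applied to OLS directly and
#' to the GLMs through their estimating-equation scores. With one cluster
#' per observation this reduces to heteroskedasticity-robust (HC1-type)
#' standard errors. A warning is emitted when there are fewer than 10
#' clusters: with so few clusters the estimator is noisy, and inference
#' below uses t references with G - 1 degrees of freedom.
#'
#' @param fit A `cascade_fit`.
#' @param clusters Optional replacement cluster labels (defaults to the
#'   event labels stored in the fit).
#' @param warn_small_G Emit the few-clusters warning? (default `TRUE`).
#' @return The fit with `se_cluster` and `n_clusters` filled in.
#' @export
cluster_robust_se <- function(fit, clusters = NULL, warn_small_G = TRUE) {
  stopifnot(inherits(fit, "cascade_fit"))
  cl <- clusters %||% fit$clusters
  G <- length(unique(cl))
  if (G < 2) abort("clustered standard errors need >= 2 clusters.")
  if (G < 10 && warn_small_G) {
    warn(paste0("only ", G, " clusters: cluster-robust SEs are noisy ",
                "(CR1 with t(G-1) reference)"),
         class = "emocascade_small_G")
  }
  V <- sandwich::vcovCL(fit$model, cluster = cl, type = "HC1", cadjust = TRUE)
  fit$se_cluster <- sqrt(diag(V))[names(fit$coefficients)]
  fit$vcov_cluster <- V
  fit$n_clusters <- G
  fit$clusters <- cl
  fit
}

#' @export
print.cascade_fit <- function(x, ...) {
  cat("<cascade_fit> dv:", x$dv, " family:", x$family,
      " n:", x$n_obs, " min_size:", x$min_size, "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a cascade regression fit
#'
#' @param x A `cascade_fit`.
#' @param se `"cluster"` (default; falls back to model SEs when clustered
#'   SEs have not been computed) or `"model"`. Clustered inference uses a
#'   t reference with G - 1 degrees of freedom.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @method tidy cascade_fit
#' @export
tidy.cascade_fit <- function(x, se = c("cluster", "model"),
                             conf_level = 0.95, ...) {
  se <- match.arg(se)
  est <- x$coefficients
  if (se == "cluster" && !is.null(x$se_cluster)) {
    s <- x$se_cluster
    df <- x$n_clusters - 1
  } else {
    s <- x$se_model
    df <- if (x$family == "ols") x$model$df.residual else Inf
  }
  stat <- est / s
  p <- 2 * pt(abs(stat), df = df, lower.tail = FALSE)
  q <- qt(1 - (1 - conf_level) / 2, df = df)
  tibble(term = names(est), estimate = unname(est), std.error = unname(s),
         statistic = unname(stat), p.value = unname(p),
         conf.low = unname(est - q * s), conf.high = unname(est + q * s))
}

#' One-row model summary for a cascade regression fit
#'
#' @param x A `cascade_fit`.
#' @param ... Unused.
#' @return A tibble with the outcome, family, sample and cluster counts,
#'   dispersion, log-likelihood / AIC (count models) and adjusted R^2 (OLS).
#' @method glance cascade_fit
#' @export
glance.cascade_fit <- function(x, ...) {
  tibble(
    dv = x$dv, family = x$family, n_obs = x$n_obs,
    min_size = x$min_size,
    n_clusters = x$n_clusters %||% NA_integer_,
    theta = x$theta %||% NA_real_,
    logLik = x$loglik %||% NA_real_,
    AIC = x$aic %||% NA_real_,
    adj.r.squared = x$adj_r2 %||% NA_real_
  )
}

#' Run the full regression battery over the propagation outcomes
#'
#' Fits the full threshold battery: negative binomial size models at size
#' thresholds 2 and 3; OLS log-lifetime at thresholds 2 and 3; OLS log
#' median delay, log time-to-fifth-reshare and burstiness CV at threshold 6
#' -- each once without and once with the emotion dummies, for 14 fits in
#' total. Every fit carries event-clustered robust standard errors.
#'
#' @param features A `cascade_features` tibble.
#' @return A named list of `cascade_fit` objects of class
#'   `cascade_battery`, named `<dv>_min<size>_<base|emotions>`, with a
#'   `funnel` attribute giving the cascade counts at each size threshold.
#' @export
run_model_battery <- function(features) {
  plan <- list(
    list(dv = "size", min_size = 2), list(dv = "size", min_size = 3),
    list(dv = "log_lifetime", min_size = 2),
    list(dv = "log_lifetime", min_size = 3),
    list(dv = "log_median_delay", min_size = 6),
    list(dv = "log_time5rt", min_size = 6),
    list(dv = "cv", min_size = 6)
  )
  fits <- list()
  for (p in plan) {
    for (emo in c(FALSE, TRUE)) {
      d <- build_design(features, p$dv, min_size = p$min_size,
                        include_emotions = emo)
      f <- if (p$dv == "size") fit_count_model(d) else fit_ols(d)
      f <- cluster_robust_se(f, warn_small_G = FALSE)
      fits[[paste0(p$dv, "_min", p$min_size,
                   if (emo) "_emotions" else "_base")]] <- f
    }
  }
  G <- length(unique(features$event_label))
  if (G < 10) {
    inform(paste0("battery fitted with ", G, " clusters; ",
                  "cluster-robust inference uses t(", G - 1, ")."))
  }
  funnel <- c(min2 = nrow(filter_by_size(features, 2)),
              min3 = nrow(filter_by_size(features, 3)),
              min6 = nrow(filter_by_size(features, 6)))
  structure(fits, class = "cascade_battery", funnel = funnel)
}

#' @export
print.cascade_battery <- function(x, ...) {
  cat("<cascade_battery> ", length(x), " fits\n", sep = "")
  print(dplyr::bind_rows(purrr::imap(x, function(f, nm) {
    dplyr::mutate(glance(f), fit = nm, .before = 1)
  })), n = Inf)
  invisible(x)
}

#' Summarise emotion effects as a sign pattern
#'
#' For each emotion (relative to neutral) and each propagation dimension,
#' reports `"+"`, `"-"` or `"0"` from the coefficient sign and its
#' cluster-robust significance at `alpha`. Size and lifetime come from the
#' threshold-2 emotion fits; speed and burstiness from the threshold-6
#' fits. The speed sign is inverted from the median-delay coefficient: a
#' negative delay effect means faster resharing, reported as `"+"`.
#'
#' @param battery A `cascade_battery` from [run_model_battery()].
#' @param alpha Significance level for calling a sign (default 0.05).
#' @return A tibble with columns `emotion`, `size`, `lifetime`, `speed`,
#'   `burstiness`.
#' @export
sign_pattern <- function(battery, alpha = 0.05) {
  stopifnot(inherits(battery, "cascade_battery"))
  pick <- c(size = "size_min2_emotions", lifetime = "log_lifetime_min2_emotions",
            speed = "log_median_delay_min6_emotions", burstiness = "cv_min6_emotions")
  missing <- setdiff(unname(pick), names(battery))
  if (length(missing)) {
    abort(paste0("battery is missing fit(s): ", paste(missing, collapse = ", ")))
  }
  emotions <- setdiff(emotion_labels(), "neutral")
  one <- function(fit_name, invert = FALSE) {
    td <- tidy(battery[[fit_name]], se = "cluster")
    vapply(emotions, function(e) {
      row <- td[td$term == paste0("emotion_", e), ]
      if (nrow(row) == 0 || row$p.value >= alpha) return("0")
      s <- sign(row$estimate)
      if (invert) s <- -s
      if (s > 0) "+" else "-"
    }, character(1))
  }
  tibble(
    emotion = emotions,
    size = one(pick[["size"]]),
    lifetime = one(pick[["lifetime"]]),
    speed = one(pick[["speed"]], invert = TRUE),
    burstiness = one(pick[["burstiness"]])
  )
}
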