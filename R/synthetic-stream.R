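# Seed plumbing -----------------------------------------------------------

# Per-cascade substream seeds, derived by counter from one master seed so the
# stream is order-independent: seed_i = (seed + i * step) mod (2^31 - 1).
# The prime modulus keeps all products exact in doubles.
substream_seeds <- function(seed, n) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m + seq_len(n) * 979693) %% m)
}

# Evaluate a scoped block with its own RNG stream, restoring global RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Authors ------------------------------------------------------------------

#' Generate a synthetic author covariate table
#'
#' Follower, friend, status and like counts are drawn as the floor of
#' log-normal variables (heavy-tailed, with a point mass at the legal
#' minimum: zero for followers/friends/likes, one for statuses), and
#' verified status as Bernoulli(0.04). Location/scale parameters are chosen
#' so the means and heavy tails resemble reported author summaries
#' (e.g. mean follower count in the tens of thousands with a maximum in the
#' millions, 4% verified).
#'
#' @param n_authors Number of authors (positive integer).
#' @param seed Integer seed; the table is deterministic given the seed.
#' @param p_verified Probability of verified status (default 0.04).
#' @return A tibble with columns `author_id`, `followers`, `friends`,
#'   `statuses`, `likes`, `verified`.
#' @export
#' @examples
#' gen_authors(5, seed = 7)
gen_authors <- function(n_authors, seed = 1L, p_verified = 0.04) {
  if (length(n_authors) != 1 || is.na(n_authors) || n_authors < 1) {
    abort("`n_authors` must be a positive integer.")
  }
  n_authors <- as.integer(n_authors)
  with_local_seed(seed, {
    tibble(
      author_id = sprintf("a%07d", seq_len(n_authors)),
      followers = floor(rlnorm(n_authors, meanlog = 4.0, sdlog = 3.5)),
      friends   = floor(rlnorm(n_authors, meanlog = 4.3, sdlog = 2.5)),
      statuses  = pmax(1, floor(rlnorm(n_authors, meanlog = 9.1, sdlog = 1.2))),
      likes     = floor(rlnorm(n_authors, meanlog = 1.4, sdlog = 3.0)),
      verified  = runif(n_authors) < p_verified
    )
  })
}

# Emotion scores -----------------------------------------------------------

#' Generate a seven-way emotion probability vector with a given dominant label
#'
#' Scores are drawn from a Dirichlet distribution placing weight
#' `concentration` on the dominant label and 1 on each other label, and
#' rejection-sampled until the dominant label is the strict maximum, so the
#' argmax property holds by construction. Components are non-negative and
#' sum to 1 within 1e-9.
#'
#' @param dominant_label One of [emotion_labels()].
#' @param concentration Positive real; larger values concentrate mass on the
#'   dominant label.
#' @param seed Optional integer seed for a self-contained draw; if `NULL`
#'   the current RNG stream is used.
#' @return Named numeric vector over [emotion_labels()].
#' @export
#' @examples
#' gen_emotion_scores("sadness", concentration = 8, seed = 1)
gen_emotion_scores <- function(dominant_label, concentration = 8, seed = NULL) {
  labs <- emotion_labels()
  if (!is.character(dominant_label) || length(dominant_label) != 1 ||
      !(dominant_label %in% labs)) {
    abort(paste0("`dominant_label` must be one of: ", paste(labs, collapse = ", ")))
  }
  if (!is.numeric(concentration) || concentration <= 0) {
    abort("`concentration` must be a positive real.")
  }
  draw <- function() {
    alpha <- setNames(rep(1, 7), labs)
    alpha[dominant_label] <- concentration
    repeat {
      g <- rgamma(7, shape = alpha)
      s <- g / sum(g)
      if (which.max(s) == match(dominant_label, labs)) {
        return(setNames(s, labs))
      }
    }
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

# Reshare timing -----------------------------------------------------------

#' Generate reshare time offsets for one cascade
#'
#' Offsets are measured from the root post at time 0 and are the cumulative
#' sum of positive inter-event gaps. In the `"regular"` regime gaps are
#' i.i.d. exponential with mean `mean_delay_s`, the memoryless baseline with
#' coefficient of variation 1. In the `"bursty"` regime gaps come from a
#' two-state Markov-modulated exponential: a slow and a fast state whose
#' rates differ by `burst_rate_ratio`, switching after each event with
#' probability `burst_switch_prob`. Runs of fast gaps produce temporal
#' clustering, pushing the inter-event CV above 1 while keeping the
#' marginal mean gap at `mean_delay_s`.
#'
#' @param n_retweets Number of reshares (>= 1).
#' @param mean_delay_s Mean inter-event gap in seconds (> 0).
#' @param regime `"regular"` or `"bursty"`.
#' @param burst_params List with `burst_rate_ratio` (> 1) and
#'   `burst_switch_prob` (in (0, 1)); only used in the bursty regime.
#' @param seed Optional integer seed for a self-contained draw.
#' @return Strictly increasing numeric vector of `n_retweets` offsets (s).
#' @export
#' @examples
#' gen_cascade_times(5, mean_delay_s = 60, regime = "regular", seed = 1)
gen_cascade_times <- function(n_retweets, mean_delay_s,
                              regime = c("regular", "bursty"),
                              burst_params = list(burst_rate_ratio = 20,
                                                  burst_switch_prob = 0.1),
                              seed = NULL) {
  if (length(n_retweets) != 1 || is.na(n_retweets) || n_retweets < 1) {
    abort("`n_retweets` must be >= 1.")
  }
  if (!is.numeric(mean_delay_s) || mean_delay_s <= 0) {
    abort("`mean_delay_s` must be > 0.")
  }
  regime <- match.arg(regime)
  n <- as.integer(n_retweets)
  draw <- function() {
    if (regime == "regular") {
      gaps <- rexp(n, rate = 1 / mean_delay_s)
    } else {
      r <- burst_params$burst_rate_ratio
      p <- burst_params$burst_switch_prob
      stopifnot(r > 1, p > 0, p < 1)
      # symmetric switching => stationary 50/50 occupancy; pick the slow rate
      # so the marginal mean gap is mean_delay_s: 0.5 (1/ls + 1/(r ls)) = m
      lambda_slow <- (1 + 1 / r) / (2 * mean_delay_s)
      state <- (runif(1) < 0.5) # TRUE = fast
      switches <- runif(n) < p
      states <- logical(n)
      for (i in seq_len(n)) {
        states[i] <- state
        if (switches[i]) state <- !state
      }
      rate <- ifelse(states, r * lambda_slow, lambda_slow)
      gaps <- rexp(n, rate = rate)
    }
    cumsum(gaps)
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

# Event stream -------------------------------------------------------------

beta_lookup <- function(betas, name) {
  if (name %in% names(betas)) unname(betas[[name]]) else 0
}

# linear predictor for one cascade given its features
cascade_lp <- function(betas, emotion, event_label, covs) {
  lp <- beta_lookup(betas, "(Intercept)")
  if (emotion != "neutral") lp <- lp + beta_lookup(betas, emotion)
  lp <- lp + beta_lookup(betas, paste0("event_", event_label))
  for (nm in names(covs)) lp <- lp + beta_lookup(betas, nm) * covs[[nm]]
  lp
}

regime_for <- function(burst_params, emotion) {
  reg <- burst_params$regime
  if (length(reg) == 1 && is.null(names(reg))) return(unname(reg))
  if (emotion %in% names(reg)) unname(reg[[emotion]]) else "regular"
}

#' Generate a full synthetic reshare event stream
#'
#' For each cascade a root author, event stratum, dominant emotion, emotion
#' scores, word count and hashtag flag are drawn from its own counter-derived
#' substream; cascade size is `2 + NB(exp(x . size_betas), size_theta)`, so
#' every cascade has at least one reshare; reshare offsets come from
#' [gen_cascade_times()] with an emotion-dependent mean delay and regime.
#' The root time is uniform in the first quarter of the observation window
#' after its event start and, in the rare case the drawn offsets would
#' overflow the window, all offsets are compressed by one scale factor so
#' every timestamp stays within `window_days` of the event start (this
#' preserves cascade size and the delay CV exactly). One record is emitted
#' for the root (`root_id = ""`) and one per reshare, reshares carrying the
#' root's emotion scores and text features. The stream is deterministic
#' given the scenario seed and independent of generation order.
#'
#' @param config A [scenario_config()].
#' @return A list with `events` (tibble, one row per post or reshare),
#'   `authors` (tibble, as [gen_authors()]) and `truth` (a `ground_truth`
#'   object holding the realised scenario and true coefficient vectors).
#' @export
#' @examples
#' sim <- gen_event_stream(scenario_config(n_cascades = 5, seed = 42))
#' sim$events
gen_event_stream <- function(config) {
  if (!inherits(config, "scenario_config")) {
    abort("`config` must be a `scenario_config`.")
  }
  n <- config$n_cascades
  authors <- gen_authors(config$n_authors, seed = config$seed)
  # pre-compute log1p covariates used in the linear predictors
  author_covs <- with(authors, list(
    log_followers = log1p(followers), log_friends = log1p(friends),
    log_statuses = log1p(statuses), log_likes = log1p(likes),
    verified = as.numeric(verified)
  ))
  seeds <- substream_seeds(config$seed, n)
  window_s <- config$window_days * 86400
  labs <- emotion_labels()

  cascade_emotion <- character(n)
  cascade_label <- character(n)
  cascade_author <- integer(n)
  cascade_wc <- integer(n)
  cascade_hash <- logical(n)
  cascade_root_t <- numeric(n)
  cascade_scores <- matrix(0, n, 7, dimnames = list(NULL, labs))
  offsets_list <- vector("list", n)

  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })

  for (i in seq_len(n)) {
    set.seed(seeds[i])
    lab_idx <- sample.int(length(config$event_labels), 1,
                          prob = config$event_weights)
    ev <- config$event_labels[lab_idx]
    au <- sample.int(config$n_authors, 1)
    emo <- sample(labs, 1, prob = config$emotion_probs)
    scores <- gen_emotion_scores(emo, config$dirichlet_concentration)
    wc <- as.integer(pmin(37, pmax(3, round(rnorm(1, 16.3, 7.2)))))
    hash <- runif(1) < 0.28
    covs <- list(
      log_followers = author_covs$log_followers[au],
      log_friends = author_covs$log_friends[au],
      log_statuses = author_covs$log_statuses[au],
      log_likes = author_covs$log_likes[au],
      verified = author_covs$verified[au],
      word_count = wc, has_hashtag = as.numeric(hash)
    )
    mu_size <- exp(cascade_lp(config$size_betas, emo, ev, covs))
    n_rt <- 1L + rnbinom(1, mu = mu_size, size = config$size_theta)
    mean_delay <- exp(cascade_lp(config$delay_scale_betas, emo, ev, covs))
    offs <- gen_cascade_times(n_rt, mean_delay,
                              regime = regime_for(config$burst_params, emo),
                              burst_params = config$burst_params)
    root_t <- config$event_start_s[[ev]] + runif(1) * 0.25 * window_s
    budget <- config$event_start_s[[ev]] + window_s - root_t
    if (max(offs) > budget) offs <- offs * (budget / max(offs))

    cascade_emotion[i] <- emo
    cascade_label[i] <- ev
    cascade_author[i] <- au
    cascade_wc[i] <- wc
    cascade_hash[i] <- hash
    cascade_root_t[i] <- root_t
    cascade_scores[i, ] <- scores
    offsets_list[[i]] <- offs
  }

  n_rt_vec <- lengths(offsets_list)
  set.seed(substream_seeds(config$seed, n + 1L)[n + 1L])
  rt_authors <- sample.int(config$n_authors, sum(n_rt_vec), replace = TRUE)

  root_ids <- sprintf("c%06d", seq_len(n))
  idx <- rep.int(seq_len(n), n_rt_vec)
  rt_seq <- sequence(n_rt_vec)
  score_mat <- rbind(cascade_scores, cascade_scores[idx, , drop = FALSE])
  colnames(score_mat) <- score_cols()

  events <- tibble(
    event_id = c(root_ids, sprintf("%s_r%04d", root_ids[idx], rt_seq)),
    root_id = c(rep("", n), root_ids[idx]),
    author_id = authors$author_id[c(cascade_author, rt_authors)],
    time_s = c(cascade_root_t, cascade_root_t[idx] + unlist(offsets_list))
  )
  events <- dplyr::bind_cols(events, as_tibble(score_mat))
  events$word_count <- c(cascade_wc, cascade_wc[idx])
  events$has_hashtag <- c(cascade_hash, cascade_hash[idx])
  events$event_label <- c(cascade_label, cascade_label[idx])
  events <- arrange(events, .data$time_s, .data$event_id)

  truth <- structure(
    list(
      config = config,
      dominant_emotion = setNames(cascade_emotion, root_ids),
      size_betas = config$size_betas,
      size_theta = config$size_theta,
      delay_scale_betas = config$delay_scale_betas,
      seed = config$seed
    ),
    class = "ground_truth"
  )
  list(events = events, authors = authors, truth = truth)
}

# Ground truth serialisation ------------------------------------------------

#' Write / read generator ground truth as JSON
#'
#' Ground truth round-trips losslessly: every scenario parameter, the true
#' coefficient vectors and the per-cascade dominant emotions are preserved.
#'
#' @param truth A `ground_truth` object from [gen_event_stream()].
#' @param path File path for the JSON document.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns a `ground_truth` object.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  cfg <- unclass(truth$config)
  cfg$event_start_s <- as.list(cfg$event_start_s)
  cfg$emotion_probs <- as.list(cfg$emotion_probs)
  cfg$size_betas <- as.list(cfg$size_betas)
  cfg$delay_scale_betas <- as.list(cfg$delay_scale_betas)
  cfg$burst_params$regime <- as.list(cfg$burst_params$regime)
  payload <- list(
    config = cfg,
    dominant_emotion = as.list(truth$dominant_emotion),
    size_betas = as.list(truth$size_betas),
    size_theta = truth$size_theta,
    delay_scale_betas = as.list(truth$delay_scale_betas),
    seed = truth$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- x$config
  config <- scenario_config(
    n_cascades = cfg$n_cascades, n_authors = cfg$n_authors,
    event_labels = cfg$event_labels, event_weights = cfg$event_weights,
    event_start_s = unlist(cfg$event_start_s),
    emotion_probs = unlist(cfg$emotion_probs),
    dirichlet_concentration = cfg$dirichlet_concentration,
    size_betas = unlist(cfg$size_betas), size_theta = cfg$size_theta,
    delay_scale_betas = unlist(cfg$delay_scale_betas),
    burst_params = list(
      regime = unlist(cfg$burst_params$regime),
      burst_rate_ratio = cfg$burst_params$burst_rate_ratio,
      burst_switch_prob = cfg$burst_params$burst_switch_prob
    ),
    window_days = cfg$window_days, seed = cfg$seed
  )
  structure(
    list(
      config = config,
      dominant_emotion = unlist(x$dominant_emotion),
      size_betas = unlist(x$size_betas),
      size_theta = x$size_theta,
      delay_scale_betas = unlist(x$delay_scale_betas),
      seed = x$seed
    ),
    class = "ground_truth"
  )
}
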