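# Independent brute-force oracles (naive loops; no shared code with the
# implementation paths they check) and small fixture builders.

bf_gaps <- function(times, include_root = TRUE) {
  seq_times <- if (include_root) times else times[-1]
  gaps <- numeric(0)
  if (length(seq_times) >= 2) {
    for (i in 2:length(seq_times)) gaps <- c(gaps, seq_times[i] - seq_times[i - 1])
  }
  gaps
}

bf_lifetime <- function(times) {
  lo <- times[1]
  hi <- times[1]
  for (t in times) {
    if (t > hi) hi <- t
  }
  hi - lo
}

bf_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

bf_time_to_nth <- function(times, n) {
  n_rt <- length(times) - 1
  if (n_rt < n) return(NA_real_)
  times[1 + n] - times[1]
}

bf_cv <- function(gaps) {
  n <- length(gaps)
  if (n < 2) return(NA_real_)
  m <- 0
  for (g in gaps) m <- m + g
  m <- m / n
  if (m == 0) return(NA_real_)
  ss <- 0
  for (g in gaps) ss <- ss + (g - m)^2
  sqrt(ss / (n - 1)) / m
}

# random toy cascade: sorted event times (root first), integer-valued so
# exact ties occur
random_cascade_times <- function(max_rt = 12) {
  n_rt <- sample(1:max_rt, 1)
  root <- runif(1, 0, 100)
  sort(c(root, root + sample(0:500, n_rt, replace = TRUE)))
}

# CR1 cluster sandwich from scratch for a linear model: scores X'e per
# cluster, bread (X'X)^-1
bf_cluster_vcov_ols <- function(X, e, clusters) {
  k <- ncol(X)
  n <- nrow(X)
  meat <- matrix(0, k, k)
  for (g in unique(clusters)) {
    sg <- t(X[clusters == g, , drop = FALSE]) %*% e[clusters == g]
    meat <- meat + sg %*% t(sg)
  }
  G <- length(unique(clusters))
  bread <- solve(t(X) %*% X)
  (G / (G - 1)) * ((n - 1) / (n - k)) * bread %*% meat %*% bread
}

# CR1 sandwich for a log-link negative binomial with fixed theta:
# score_i = x_i (y_i - mu_i) / (1 + mu_i / theta), bread (X' W X)^-1 with
# working weights w_i = mu_i / (1 + mu_i / theta)
bf_cluster_vcov_nb <- function(X, y, mu, theta, clusters) {
  k <- ncol(X)
  n <- nrow(X)
  s <- X * ((y - mu) / (1 + mu / theta))
  meat <- matrix(0, k, k)
  for (g in unique(clusters)) {
    sg <- colSums(s[clusters == g, , drop = FALSE])
    meat <- meat + outer(sg, sg)
  }
  G <- length(unique(clusters))
  W <- mu / (1 + mu / theta)
  bread <- solve(t(X) %*% (X * W))
  (G / (G - 1)) * ((n - 1) / (n - k)) * bread %*% meat %*% bread
}

# brute-force weighted precision/recall/F1 from per-class tallies
bf_weighted_prf <- function(pred, truth) {
  classes <- sort(unique(c(pred, truth)))
  P <- R <- F1 <- W <- numeric(0)
  for (cl in classes) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    P <- c(P, p); R <- c(R, r); F1 <- c(F1, f)
    W <- c(W, sum(truth == cl))
  }
  W <- W / sum(W)
  c(precision = sum(W * P), recall = sum(W * R), f1 = sum(W * F1))
}

# minimal hand-built cascade_design for estimator-level tests
fake_design <- function(y, X, clusters, dv = "size") {
  data <- tibble::tibble(response = y)
  if (NCOL(X) > 0 && nrow(as.data.frame(X)) > 0) {
    data <- dplyr::bind_cols(data, tibble::as_tibble(as.data.frame(X)))
  }
  structure(
    list(data = data, response = y, clusters = clusters, dv = dv,
         min_size = 2, include_emotions = FALSE, n_dropped_response = 0L),
    class = "cascade_design"
  )
}

# small hand-built feature table with every column summarize_features emits
fake_features <- function(n, seed = 1) {
  set.seed(seed)
  emo <- sample(emotion_labels(), n, replace = TRUE)
  tibble::tibble(
    cascade_id = sprintf("c%04d", seq_len(n)),
    event_label = sample(c("A", "B", "C", "D"), n, replace = TRUE),
    size = 2L + stats::rnbinom(n, mu = 3, size = 1),
    lifetime_s = stats::rexp(n, 1 / 1000),
    median_delay_s = stats::rexp(n, 1 / 500),
    time5rt_s = stats::rexp(n, 1 / 2000),
    cv = stats::rgamma(n, 2, 2),
    dominant_emotion = emo,
    log_followers = log1p(stats::rlnorm(n, 4, 2)),
    log_friends = log1p(stats::rlnorm(n, 4, 1.5)),
    log_statuses = log1p(stats::rlnorm(n, 8, 1)),
    log_likes = log1p(stats::rlnorm(n, 2, 2)),
    verified = stats::runif(n) < 0.05,
    word_count = sample(3:37, n, replace = TRUE),
    has_hashtag = stats::runif(n) < 0.3
  ) |>
    dplyr::mutate(
      time5rt_s = ifelse(size >= 6, time5rt_s, NA_real_),
      cv = ifelse(size >= 4, cv, NA_real_)
    )
}

# tiny well-formed event stream built by hand (one root + its reshares)
hand_events <- function() {
  mk_scores <- function(dom) {
    s <- setNames(rep(0.02, 7), paste0("score_", emotion_labels()))
    s[paste0("score_", dom)] <- 1 - 0.02 * 6
    as.list(s)
  }
  rows <- list(
    c(list(event_id = "t1", root_id = "", author_id = "u1", time_s = 0),
      mk_scores("sadness"),
      list(word_count = 10L, has_hashtag = TRUE, event_label = "E1")),
    c(list(event_id = "t1_r1", root_id = "t1", author_id = "u2", time_s = 10),
      mk_scores("sadness"),
      list(word_count = 10L, has_hashtag = TRUE, event_label = "E1")),
    c(list(event_id = "t1_r2", root_id = "t1", author_id = "u3", time_s = 160),
      mk_scores("sadness"),
      list(word_count = 10L, has_hashtag = TRUE, event_label = "E1"))
  )
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}
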