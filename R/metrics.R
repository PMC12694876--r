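# Per-cascade propagation metrics.
#
# The scalar functions all take `times`: the cascade's event times in
# seconds, root first, sorted non-decreasingly (offsets or epoch times --
# every metric only uses differences).

#' Cascade size
#'
#' The number of reshares plus one, counting every node in the cascade
#' including the original post: a root with three reshares is a cascade of
#' four posts.
#'
#' @param times Numeric vector of event times, root first.
#' @return Integer size (>= 1).
#' @export
#' @examples
#' cascade_size(c(0, 10, 20, 40))
cascade_size <- function(times) {
  length(times)
}

#' Cascade lifetime
#'
#' Elapsed time between the original post and its last reshare, in the
#' units of `times` (seconds throughout this package).
#'
#' @inheritParams cascade_size
#' @return Non-negative real.
#' @export
cascade_lifetime <- function(times) {
  times[length(times)] - times[1]
}

#' Inter-event delay series
#'
#' Gaps between consecutive events of the cascade's chronological sequence.
#' With `include_root = TRUE` (the default) the root is event zero, so the
#' first gap is the root-to-first-reshare latency; with `FALSE` only gaps
#' between consecutive reshares are returned.
#'
#' @inheritParams cascade_size
#' @param include_root Include the root as the first event of the sequence?
#' @return Numeric vector of non-negative gaps (length = events - 1).
#' @export
#' @examples
#' inter_event_delays(c(0, 10, 20, 40, 80, 160))
inter_event_delays <- function(times, include_root = TRUE) {
  if (!include_root) times <- times[-1]
  diff(times)
}

#' Median inter-reshare delay
#'
#' The median of the gaps between each two consecutive events within a
#' cascade (mean of the middle two for even-length series). A small median
#' delay indicates a fast resharing cadence.
#'
#' @inheritParams inter_event_delays
#' @return Median gap in seconds, or `NA` when the delay series is empty.
#' @export
median_delay <- function(times, include_root = TRUE) {
  gaps <- inter_event_delays(times, include_root = include_root)
  if (length(gaps) == 0) return(NA_real_)
  median(gaps)
}

#' Time to the nth reshare
#'
#' Elapsed time from the original post until its nth reshare; defined only
#' for cascades with at least `n` reshares (for the default `n = 5`, size
#' at least 6), otherwise `NA`.
#'
#' @inheritParams cascade_size
#' @param n Which reshare to reach (default 5).
#' @return Non-negative real or `NA`.
#' @export
time_to_nth_retweet <- function(times, n = 5) {
  if (length(times) - 1 < n) return(NA_real_)
  times[n + 1] - times[1]
}

#' Burstiness as the coefficient of variation of inter-event delays
#'
#' The ratio of the standard deviation to the mean of the cascade's
#' inter-event delays (sigma / mu), using the sample (n - 1) standard
#' deviation. Values above 1 indicate temporal clustering beyond a
#' memoryless (Poisson) process; values below 1 indicate more uniform
#' spacing; constant gaps give exactly 0. Undefined (`NA`) when there are
#' fewer than two gaps or the mean gap is zero.
#'
#' @inheritParams inter_event_delays
#' @return Non-negative real or `NA`.
#' @export
#' @examples
#' burstiness_cv(c(0, 10, 20, 40, 80, 160))
burstiness_cv <- function(times, include_root = TRUE) {
  gaps <- inter_event_delays(times, include_root = include_root)
  if (length(gaps) < 2) return(NA_real_)
  m <- mean(gaps)
  if (m == 0) return(NA_real_)
  sd(gaps) / m
}

# one pass over the time vector, for the feature builder
metric_row <- function(times, include_root = TRUE, n_rt = 5) {
  c(size = length(times),
    lifetime_s = cascade_lifetime(times),
    median_delay_s = median_delay(times, include_root),
    time5rt_s = time_to_nth_retweet(times, n_rt),
    cv = burstiness_cv(times, include_root))
}

#' Build the per-cascade feature table fed to the regressions
#'
#' Joins each cascade's root-author covariates to its five propagation
#' metrics and its dominant emotion. Author covariates enter as
#' `log(1 + x)` (their minima are zero). Undefined metrics (time to fifth
#' reshare below size 6; CV with fewer than two gaps) propagate as `NA` and
#' are dropped listwise per model downstream.
#'
#' @param cascades A `cascade_tbl` from [build_cascades()].
#' @param authors Author tibble covering every root author (an error names
#'   any missing ids).
#' @param include_root Treat the root as event zero of the delay series
#'   (default `TRUE`).
#' @param n_rt Which reshare the time-to-nth metric targets (default 5).
#' @return A tibble of class `cascade_features`, one row per cascade.
#' @export
summarize_features <- function(cascades, authors, include_root = TRUE,
                               n_rt = 5) {
  missing <- setdiff(unique(cascades$root_author_id), authors$author_id)
  if (length(missing)) {
    abort(paste0("root author(s) absent from author table: ",
                 paste(head(missing, 10), collapse = ", ")))
  }
  times <- purrr::map2(cascades$root_time_s, cascades$retweets,
                       function(t0, rt) c(t0, rt$time_s))
  m <- vapply(times, metric_row, numeric(5),
              include_root = include_root, n_rt = n_rt)
  sc <- as.matrix(cascades[score_cols()])
  feats <- tibble(
    cascade_id = cascades$cascade_id,
    event_label = cascades$event_label,
    size = as.integer(m["size", ]),
    lifetime_s = m["lifetime_s", ],
    median_delay_s = m["median_delay_s", ],
    time5rt_s = m["time5rt_s", ],
    cv = m["cv", ],
    dominant_emotion = dominant_emotion(sc)
  )
  au <- authors[match(cascades$root_author_id, authors$author_id), ]
  feats$log_followers <- log1p(au$followers)
  feats$log_friends <- log1p(au$friends)
  feats$log_statuses <- log1p(au$statuses)
  feats$log_likes <- log1p(au$likes)
  feats$verified <- au$verified
  feats$word_count <- cascades$word_count
  feats$has_hashtag <- cascades$has_hashtag
  class(feats) <- c("cascade_features", class(feats))
  feats
}

#' Per-event summary of the propagation measures
#'
#' Mean and standard deviation of each propagation metric per event stratum
#' plus a pooled `ALL` row. Lifetime is reported in minutes and the delay
#' metrics in seconds, matching the usual presentation; `NA` metrics are
#' excluded pairwise and their contributing counts reported. Groups with a
#' single cascade report SD as 0 and are flagged.
#'
#' @param features A `cascade_features` tibble.
#' @param group_by Grouping column (default `"event_label"`).
#' @return A tibble, one row per group plus `ALL`, with `<metric>_mean` /
#'   `<metric>_sd` columns, `n`, `n_time5rt`, `n_cv`, and a `degenerate`
#'   flag for single-cascade groups.
#' @export
cohort_summary <- function(features, group_by = "event_label") {
  if (nrow(features) == 0) abort("`features` is empty.")
  one <- function(df, label) {
    msd <- function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0) return(c(NA_real_, NA_real_))
      c(mean(x), if (length(x) > 1) sd(x) else 0)
    }
    s <- msd(df$size); lt <- msd(df$lifetime_s / 60)
    md <- msd(df$median_delay_s); t5 <- msd(df$time5rt_s); cv <- msd(df$cv)
    tibble(
      group = label, n = nrow(df),
      size_mean = s[1], size_sd = s[2],
      lifetime_min_mean = lt[1], lifetime_min_sd = lt[2],
      median_delay_s_mean = md[1], median_delay_s_sd = md[2],
      time5rt_s_mean = t5[1], time5rt_s_sd = t5[2],
      cv_mean = cv[1], cv_sd = cv[2],
      n_time5rt = sum(!is.na(df$time5rt_s)), n_cv = sum(!is.na(df$cv)),
      degenerate = nrow(df) < 2
    )
  }
  groups <- split(features, features[[group_by]])
  out <- dplyr::bind_rows(c(
    unname(purrr::imap(groups, function(df, g) one(df, g))),
    list(one(features, "ALL"))
  ))
  if (any(out$degenerate)) {
    inform(paste0("group(s) with a single cascade report SD = 0: ",
                  paste(out$group[out$degenerate], collapse = ", ")))
  }
  out
}
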