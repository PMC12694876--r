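# Event and author I/O, validation, and cascade assembly.

required_event_cols <- function() {
  c("event_id", "root_id", "author_id", "time_s", score_cols(),
    "word_count", "has_hashtag", "event_label")
}

guess_format <- function(path) {
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl"
  else if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
  else abort("cannot guess format from extension; pass `format` explicitly.")
}

#' Read and validate a reshare event stream
#'
#' Events arrive as JSONL (one record per line) or CSV with one row per
#' original post or reshare. Roots are rows whose `root_id` is empty;
#' reshares point at their root via `root_id`. Validation enforces the
#' schema (all required columns, no stray `score_*` columns) and checks that
#' each row's seven emotion scores sum to 1 within `tol`; rows that fail are
#' either rejected (`score_policy = "strict"`) or rescaled to sum to 1
#' (`"renormalize"`). Zero-sum score rows are always rejected. Malformed
#' JSONL lines are reported with their line numbers.
#'
#' @param path Path to the events file.
#' @param format `"auto"` (by extension), `"jsonl"` or `"csv"`.
#' @param score_policy `"strict"` or `"renormalize"`.
#' @param tol Tolerance on the emotion-score sum (default 1e-6).
#' @return A validated tibble of events.
#' @export
read_events <- function(path, format = c("auto", "jsonl", "csv"),
                        score_policy = c("strict", "renormalize"),
                        tol = 1e-6) {
  format <- match.arg(format)
  score_policy <- match.arg(score_policy)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "auto") format <- guess_format(path)
  df <- if (format == "jsonl") read_jsonl(path) else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  validate_events(as_tibble(df), score_policy = score_policy, tol = tol)
}

read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- tryCatch(
    jsonlite::stream_in(textConnection(lines), verbose = FALSE),
    error = function(e) NULL
  )
  if (is.null(out)) {
    bad <- which(vapply(lines, function(l) {
      inherits(tryCatch(jsonlite::fromJSON(l), error = function(e) e), "error")
    }, logical(1), USE.NAMES = FALSE))
    abort(paste0("malformed JSONL at line(s): ",
                 paste(head(bad, 20), collapse = ", ")))
  }
  out
}

#' Validate an in-memory event table
#'
#' @param events Data frame of events.
#' @inheritParams read_events
#' @return A validated tibble (scores possibly renormalised).
#' @export
validate_events <- function(events, score_policy = c("strict", "renormalize"),
                            tol = 1e-6) {
  score_policy <- match.arg(score_policy)
  events <- as_tibble(events)
  missing <- setdiff(required_event_cols(), names(events))
  if (length(missing)) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  stray <- setdiff(grep("^score_", names(events), value = TRUE), score_cols())
  if (length(stray)) {
    abort(paste0("unknown emotion score column(s): ", paste(stray, collapse = ", ")))
  }
  events$root_id[is.na(events$root_id)] <- ""
  if (!is.numeric(events$time_s) || any(!is.finite(events$time_s))) {
    abort("`time_s` must be finite numeric.")
  }
  if (anyDuplicated(events$event_id)) {
    abort("duplicate `event_id` values in event stream.")
  }
  events$has_hashtag <- parse_logical_col(events$has_hashtag, "has_hashtag")

  sc <- as.matrix(events[score_cols()])
  if (any(sc < 0)) abort("negative emotion scores are not allowed.")
  sums <- rowSums(sc)
  if (any(sums <= 0)) {
    abort(paste0("all-zero emotion scores at row(s): ",
                 paste(head(which(sums <= 0), 20), collapse = ", ")))
  }
  off <- abs(sums - 1) > tol
  if (any(off)) {
    if (score_policy == "strict") {
      abort(paste0("emotion scores do not sum to 1 at row(s): ",
                   paste(head(which(off), 20), collapse = ", "),
                   " (use score_policy = 'renormalize' to rescale)"))
    }
    sc[off, ] <- sc[off, , drop = FALSE] / sums[off]
    events[score_cols()] <- as_tibble(sc)
    inform(paste0("renormalized emotion scores on ", sum(off), " row(s)."))
  }
  events
}

parse_logical_col <- function(x, name) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out) && !anyNA(x)) {
    abort(paste0("cannot parse `", name, "` as logical."))
  }
  out
}

#' Write a reshare event stream
#'
#' @param events Validated event tibble.
#' @param path Output path (`.jsonl` or `.csv` decide the format when
#'   `format = "auto"`). Timestamps are written at full precision.
#' @inheritParams read_events
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "jsonl") {
    con <- file(path, open = "w")
    on.exit(close(con))
    jsonlite::stream_out(as.data.frame(events), con, verbose = FALSE,
                         digits = I(17))
  } else {
    readr::write_csv(events, path)
  }
  invisible(path)
}

#' Read a CSV author covariate table
#'
#' Requires columns `author_id`, `followers`, `friends`, `statuses`,
#' `likes`, `verified`; `verified` accepts logical, 0/1 and "true"/"false"
#' dialects. Duplicate author ids are an error; an empty table is returned
#' with a warning.
#'
#' @param path CSV path.
#' @return A tibble of author records.
#' @export
read_authors <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("author_id", "followers", "friends", "statuses", "likes", "verified")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) {
    warn("author table is empty.")
    return(as_tibble(df))
  }
  if (anyDuplicated(df$author_id)) {
    dup <- unique(df$author_id[duplicated(df$author_id)])
    abort(paste0("duplicate author_id(s): ", paste(head(dup, 10), collapse = ", ")))
  }
  df$verified <- parse_logical_col(df$verified, "verified")
  if (any(df$followers < 0) || any(df$friends < 0) || any(df$likes < 0) ||
      any(df$statuses < 1)) {
    abort("author covariates out of range (counts must be non-negative, statuses >= 1).")
  }
  as_tibble(df)
}

#' Write an author covariate table as CSV
#' @param authors Author tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_authors <- function(authors, path) {
  readr::write_csv(authors, path)
  invisible(path)
}

# Cascade assembly ----------------------------------------------------------

#' Assemble time-ordered cascades under the observation-window rule
#'
#' Groups reshares to their root post by `root_id`, keeping only events that
#' fall inside `[event_start, event_start + window_days]` for their event
#' stratum. Reshares whose root is absent (or itself outside the window) are
#' dropped, not promoted to roots, because a cascade requires its original
#' post; drop counts are reported and attached as an attribute. Reshares are
#' sorted by `(time_s, event_id)` -- ties broken by id so the order is
#' deterministic, and zero gaps are legal. Only cascades with at least one
#' reshare (size >= 2) are returned.
#'
#' @param events Validated event tibble (see [read_events()]).
#' @param event_start_s Event start time(s) in epoch seconds: a single
#'   number applied to all strata, or a named vector keyed by `event_label`.
#' @param window_days Length of the observation window (default 21 days).
#' @return A tibble of class `cascade_tbl`, one row per cascade, with the
#'   root's fields, `size`, and a nested `retweets` tibble
#'   (`event_id`, `author_id`, `time_s`). Attribute `dropped` holds counts
#'   of discarded events (`outside_window`, `orphan_retweets`,
#'   `rootless_roots`).
#' @export
build_cascades <- function(events, event_start_s, window_days = 21) {
  events <- as_tibble(events)
  labs <- unique(events$event_label)
  if (length(event_start_s) == 1 && is.null(names(event_start_s))) {
    event_start_s <- setNames(rep(event_start_s, length(labs)), labs)
  }
  missing_lab <- setdiff(labs, names(event_start_s))
  if (length(missing_lab)) {
    abort(paste0("no event start time for label(s): ",
                 paste(missing_lab, collapse = ", ")))
  }
  start <- unname(event_start_s[events$event_label])
  in_window <- events$time_s >= start &
    events$time_s <= start + window_days * 86400
  n_outside <- sum(!in_window)
  events <- events[in_window, , drop = FALSE]

  roots <- filter(events, .data$root_id == "")
  rts <- filter(events, .data$root_id != "")
  orphan <- !(rts$root_id %in% roots$event_id)
  n_orphan <- sum(orphan)
  rts <- rts[!orphan, , drop = FALSE]

  rts_nested <- rts %>%
    select("root_id", "event_id", "author_id", "time_s") %>%
    arrange(.data$root_id, .data$time_s, .data$event_id) %>%
    tidyr::nest(retweets = c("event_id", "author_id", "time_s"))

  cascades <- roots %>%
    rename(cascade_id = "event_id", root_author_id = "author_id",
           root_time_s = "time_s") %>%
    select(-"root_id") %>%
    dplyr::inner_join(rts_nested, by = c(cascade_id = "root_id"))
  n_rootless <- nrow(roots) - nrow(cascades)

  cascades <- cascades %>%
    mutate(size = vapply(.data$retweets, nrow, integer(1)) + 1L) %>%
    select("cascade_id", "event_label", "root_author_id", "root_time_s",
           "size", all_of(score_cols()), "word_count", "has_hashtag",
           "retweets")
  dropped <- c(outside_window = n_outside, orphan_retweets = n_orphan,
               rootless_roots = n_rootless)
  if (any(dropped > 0)) {
    inform(paste0("build_cascades dropped events -- outside window: ",
                  n_outside, ", orphan reshares: ", n_orphan,
                  ", roots without reshares: ", n_rootless))
  }
  attr(cascades, "dropped") <- dropped
  class(cascades) <- c("cascade_tbl", class(cascades))
  cascades
}

#' Flatten assembled cascades back to an event table
#'
#' Inverse of [build_cascades()] for the retained events: emits one root
#' record per cascade plus its reshare records (reshares carry the root's
#' emotion scores and text features).
#'
#' @param cascades A `cascade_tbl`.
#' @return An event tibble in the [read_events()] schema.
#' @export
cascade_events <- function(cascades) {
  n_rt <- vapply(cascades$retweets, nrow, integer(1))
  idx <- rep.int(seq_len(nrow(cascades)), n_rt)
  rts <- dplyr::bind_rows(cascades$retweets)
  roots <- tibble(
    event_id = cascades$cascade_id, root_id = "",
    author_id = cascades$root_author_id, time_s = cascades$root_time_s
  )
  rt_rows <- tibble(
    event_id = rts$event_id, root_id = cascades$cascade_id[idx],
    author_id = rts$author_id, time_s = rts$time_s
  )
  out <- dplyr::bind_rows(roots, rt_rows)
  carried <- cascades[c(score_cols(), "word_count", "has_hashtag", "event_label")]
  out <- dplyr::bind_cols(out, dplyr::bind_rows(carried, carried[idx, ]))
  arrange(out, .data$time_s, .data$event_id)
}

#' Keep cascades at or above a minimum size
#'
#' Size thresholds mirror the analysis subsets: `min_size = 2` keeps all
#' cascades, `3` keeps cascades with at least two reshares, and `6` keeps
#' cascades with at least five reshares (the subset on which time-to-fifth
#' reshare and burstiness are defined).
#'
#' @param cascades A `cascade_tbl` or cascade-features tibble with a
#'   `size` column.
#' @param min_size Minimum cascade size (>= 2).
#' @return The filtered tibble, original order preserved.
#' @export
filter_by_size <- function(cascades, min_size) {
  if (min_size < 2) abort("`min_size` must be >= 2.")
  filter(cascades, .data$size >= min_size)
}
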