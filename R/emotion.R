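# Dominant-emotion assignment and emotion summary tables.

#' Assign the dominant emotion from probability scores
#'
#' The dominant emotion is the label with the highest probability score.
#' Exact ties are resolved deterministically by `tie_break_order`
#' (alphabetical by default); ties have essentially measure zero on real
#' scores but the rule keeps results reproducible. A message with an anger
#' score of 0.30 and a sadness score of 0.70 is categorised as sadness.
#'
#' @param scores A numeric vector of 7 scores (named by emotion or in
#'   [emotion_labels()] order), a numeric matrix with 7 columns, or a data
#'   frame carrying the `score_<label>` columns.
#' @param tie_break_order Label order used to resolve exact ties.
#' @return A character vector of dominant labels (length = rows of input).
#' @export
#' @examples
#' dominant_emotion(c(anger = 0.3, sadness = 0.7, fear = 0, joy = 0,
#'                    disgust = 0, surprise = 0, neutral = 0))
dominant_emotion <- function(scores, tie_break_order = emotion_labels()) {
  if (!setequal(tie_break_order, emotion_labels())) {
    abort("`tie_break_order` must be a permutation of the 7 emotion labels.")
  }
  m <- score_matrix(scores)
  if (any(m < 0)) abort("emotion scores must be non-negative.")
  if (any(rowSums(m) <= 0)) {
    abort(paste0("all-zero score vector at row(s): ",
                 paste(head(which(rowSums(m) <= 0), 20), collapse = ", ")))
  }
  m <- m[, tie_break_order, drop = FALSE]
  tie_break_order[max.col(m, ties.method = "first")]
}

# coerce the accepted score inputs to an n x 7 matrix with label colnames
score_matrix <- function(scores) {
  labs <- emotion_labels()
  if (is.data.frame(scores)) {
    cols <- if (all(score_cols() %in% names(scores))) score_cols() else labs
    if (!all(cols %in% names(scores))) {
      abort("data frame must carry the 7 `score_<label>` (or label-named) columns.")
    }
    m <- as.matrix(scores[cols])
    colnames(m) <- labs
    return(m)
  }
  if (is.matrix(scores)) {
    if (ncol(scores) != 7) abort("score matrix must have 7 columns.")
    if (!is.null(colnames(scores))) {
      cn <- sub("^score_", "", colnames(scores))
      if (!setequal(cn, labs)) abort("unrecognised score column names.")
      colnames(scores) <- cn
      return(scores[, labs, drop = FALSE])
    }
    colnames(scores) <- labs
    return(scores)
  }
  if (is.numeric(scores) && length(scores) == 7) {
    if (!is.null(names(scores))) {
      nm <- sub("^score_", "", names(scores))
      if (!setequal(nm, labs)) abort("unrecognised score names.")
      scores <- setNames(scores, nm)[labs]
    }
    return(matrix(scores, nrow = 1, dimnames = list(NULL, labs)))
  }
  abort("`scores` must be a length-7 vector, 7-column matrix, or data frame.")
}

#' Percentage of cascades labelled with each dominant emotion
#'
#' One column per group (event stratum) plus a pooled `ALL` column; each
#' column sums to 100 up to rounding of the underlying percentages.
#'
#' @param features A `cascade_features` tibble (or any data frame with a
#'   `dominant_emotion` column and the grouping column).
#' @param group_by Grouping column name (default `"event_label"`).
#' @return A tibble with an `emotion` column and one percentage column per
#'   group plus `ALL`.
#' @export
emotion_frequency_table <- function(features, group_by = "event_label") {
  if (nrow(features) == 0) abort("`features` is empty.")
  labs <- emotion_labels()
  pct <- function(x) {
    100 * as.vector(table(factor(x, levels = labs))) / length(x)
  }
  groups <- split(features$dominant_emotion, features[[group_by]])
  out <- tibble(emotion = labs)
  for (g in names(groups)) out[[g]] <- pct(groups[[g]])
  out$ALL <- pct(features$dominant_emotion)
  out
}

#' Mean emotion probability scores (emotion intensity)
#'
#' The mean probability score of each emotion across records, per group and
#' pooled. Computed over all posts (roots and reshares alike, reshares
#' carrying the root's scores); pass a cascade table's root rows to average
#' over cascades instead.
#'
#' @param events An event tibble carrying the `score_<label>` columns.
#' @param group_by Grouping column name (default `"event_label"`).
#' @return A tibble with an `emotion` column and one mean-score column per
#'   group plus `ALL`; each column sums to 1.
#' @export
emotion_intensity <- function(events, group_by = "event_label") {
  if (nrow(events) == 0) abort("`events` is empty.")
  m <- as.matrix(events[score_cols()])
  colnames(m) <- emotion_labels()
  out <- tibble(emotion = emotion_labels())
  for (g in unique(events[[group_by]])) {
    out[[g]] <- unname(colMeans(m[events[[group_by]] == g, , drop = FALSE]))
  }
  out$ALL <- unname(colMeans(m))
  out
}

#' Support-weighted precision, recall and F1
#'
#' Per-class precision, recall and F1 are averaged with weights equal to
#' each class's share of the true labels; classes never observed in the
#' truth carry zero weight. Per-class precision (or F1) is defined as 0
#' when its denominator is 0.
#'
#' @param pred_labels,true_labels Equal-length, non-empty character vectors.
#' @return A one-row tibble with `precision`, `recall`, `f1`.
#' @export
#' @examples
#' weighted_prf(c("a", "a", "b"), c("a", "b", "b"))
weighted_prf <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels)) {
    abort("`pred_labels` and `true_labels` must have equal length.")
  }
  if (length(true_labels) == 0) abort("label vectors must be non-empty.")
  classes <- sort(unique(c(pred_labels, true_labels)))
  tab <- table(factor(true_labels, classes), factor(pred_labels, classes))
  tp <- diag(tab)
  support <- rowSums(tab)         # true-class counts
  pred_n <- colSums(tab)
  prec <- ifelse(pred_n > 0, tp / pred_n, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- support / sum(support)
  tibble(precision = sum(w * prec), recall = sum(w * rec), f1 = sum(w * f1))
}
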