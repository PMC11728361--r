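#' Top-k and bottom-k images for one feature
#'
#' Orders the cohort from the highest to the lowest value of the feature and
#' returns the image ids at both extremes. Ties are broken by ascending
#' image id so the ranking is deterministic.
#'
#' @param table data frame with an `image_id` column and the feature column.
#' @param feature feature column name.
#' @param k extreme size (default 10).
#' @return list with character vectors `top` and `bottom` (each of length k,
#'   disjoint).
#' @export
rank_extremes <- function(table, feature, k = 10L) {
  if (!feature %in% names(table)) {
    stop(sprintf("feature '%s' not present in table", feature), call. = FALSE)
  }
  if (nrow(table) < 2L * k) {
    stop(sprintf("need at least %d rows for k = %d extremes (got %d)",
                 2L * k, k, nrow(table)), call. = FALSE)
  }
  o <- order(-table[[feature]], table$image_id)
  ids <- table$image_id[o]
  list(top = ids[seq_len(k)], bottom = rev(ids)[seq_len(k)])
}

#' Simulated rater impairment labels
#'
#' Stands in for a blinded human rater: an image is labelled "more affected"
#' when its grade is 3 or 4, and each label is flipped independently with the
#' given disagreement rate.
#'
#' @param grades integer vector of grades 1-4.
#' @param disagreement_rate flip probability in [0, 1).
#' @return logical vector, `TRUE` = more affected.
#' @export
simulate_rater <- function(grades, disagreement_rate = 0) {
  stopifnot(all(grades %in% 1:4),
            disagreement_rate >= 0, disagreement_rate < 1)
  affected <- grades >= 3L
  if (disagreement_rate > 0) {
    flip <- stats::runif(length(grades)) < disagreement_rate
    affected <- xor(affected, flip)
  }
  affected
}

#' Tally rater agreement at the feature extremes
#'
#' For each feature, counts how many of the top-k and bottom-k images each
#' rater labelled "more affected" — the tabular form produced by the two-rater
#' extreme-image evaluation protocol.
#'
#' @param table cohort data frame including feature columns.
#' @param labels list of per-rater logical label vectors (aligned with
#'   `table` rows; `TRUE` = more affected).
#' @param features feature columns to assess (default all 21).
#' @param k extreme size.
#' @return data frame with columns `feature`, `top_r1`, `top_r2`,
#'   `bottom_r1`, `bottom_r2`, `k`.
#' @export
assess_extremes <- function(table, labels, features = feature_names(), k = 10L) {
  stopifnot(length(labels) == 2L,
            all(vapply(labels, length, 1L) == nrow(table)))
  rows <- lapply(features, function(f) {
    ex <- rank_extremes(table, f, k)
    top_i <- match(ex$top, table$image_id)
    bot_i <- match(ex$bottom, table$image_id)
    data.frame(feature = f,
               top_r1 = sum(labels[[1L]][top_i]),
               top_r2 = sum(labels[[2L]][top_i]),
               bottom_r1 = sum(labels[[1L]][bot_i]),
               bottom_r2 = sum(labels[[2L]][bot_i]),
               k = k)
  })
  do.call(rbind, rows)
}

#' Apply the 100%-at-opposite-extremes selection criterion
#'
#' A feature is informative only when, for both raters, one extreme is
#' unanimously "more affected" (k of k) and the opposite extreme unanimously
#' "less affected" (0 of k). Any intermediate count for either rater at
#' either extreme — including both extremes unanimously affected — excludes
#' the feature. The direction records which extreme carried the affected
#' images. Raters disagreeing on the direction also excludes the feature.
#'
#' @param assessments data frame as returned by [assess_extremes()] (or read
#'   from a CSV with the same columns).
#' @return list with `selected` (character vector) and `direction` (named
#'   character vector, `"high_values_affected"` or `"low_values_affected"`).
#' @export
apply_selection_criterion <- function(assessments) {
  req <- c("feature", "top_r1", "top_r2", "bottom_r1", "bottom_r2", "k")
  missing_cols <- setdiff(req, names(assessments))
  if (length(missing_cols)) {
    stop(sprintf("assessment table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(assessments$feature)) {
    stop("duplicate feature names in assessments", call. = FALSE)
  }
  counts <- assessments[c("top_r1", "top_r2", "bottom_r1", "bottom_r2")]
  if (any(counts < 0) || any(counts > assessments$k)) {
    stop("assessment counts must lie in 0..k", call. = FALSE)
  }
  k <- assessments$k
  high <- assessments$top_r1 == k & assessments$top_r2 == k &
    assessments$bottom_r1 == 0L & assessments$bottom_r2 == 0L
  low <- assessments$top_r1 == 0L & assessments$top_r2 == 0L &
    assessments$bottom_r1 == k & assessments$bottom_r2 == k
  sel <- high | low
  direction <- ifelse(high, "high_values_affected", "low_values_affected")[sel]
  names(direction) <- assessments$feature[sel]
  list(selected = assessments$feature[sel], direction = direction)
}

#' Read a rater-assessment table from CSV
#'
#' Expects columns `feature, top_r1, top_r2, bottom_r1, bottom_r2, k`. The
#' package ships an example at
#' `system.file("extdata", "rater_assessments.csv", package = "echotex")`:
#' the counts recorded by two physiotherapists evaluating the extreme images
#' of each of the 21 features in a 130-image post-stroke cohort.
#'
#' @param path CSV path.
#' @return data frame in the [assess_extremes()] format.
#' @export
read_assessments <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("feature", "top_r1", "top_r2", "bottom_r1", "bottom_r2", "k")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("assessment CSV is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  tab
}
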