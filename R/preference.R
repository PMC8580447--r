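#' Select representative-track candidates
#'
#' Same directional rule as [build_training_set()], but with the threshold
#' pushed 10% of the subdivision's feature standard deviation further out
#' (added when the subdivision mean exceeds the grand mean, subtracted
#' otherwise), so only tracks from the extremes of each subdivision's
#' feature distributions qualify. With `margin = 0` this reduces exactly to
#' the training-set qualification rule.
#'
#' @inheritParams build_training_set
#' @param margin Fraction of the subdivision s.d. added to the threshold
#'   (default 0.10).
#' @return Candidate tracks with a `subdivision` column. Subdivisions with
#'   no candidates produce a warning, not an error.
#' @export
select_representative_candidates <- function(catalog, model, margin = 0.10) {
  out <- assign_by_threshold(catalog, model, margin = margin)
  got <- unique(out$subdivision)
  empty <- setdiff(unique(model$centroids$subdivision), got)
  if (length(empty) > 0) {
    warning("no candidate tracks for subdivision(s): ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  out
}

#' PCA-based shortlist of representative tracks
#'
#' Within each subdivision's candidate set, a principal component analysis
#' on standardized audio features orders tracks along the first component;
#' the five highest, the five nearest the median and the five lowest scores
#' are short-listed (15 per subdivision, disjoint thirds, ties broken by
#' track id). Subdivisions with fewer than 15 candidates are returned whole,
#' with a warning.
#'
#' @param candidates Output of [select_representative_candidates()].
#' @param n_per_band Tracks per band (default 5).
#' @return Tibble of short-listed tracks with columns `subdivision`,
#'   `track_id`, `band` (`"top"`, `"middle"`, `"bottom"`) and `pc1`.
#' @export
pca_select <- function(candidates, n_per_band = 5) {
  feats <- intersect(feature_names(), names(candidates))
  out <- lapply(split(candidates, candidates$subdivision), function(cc) {
    cc <- cc[order(cc$track_id), ]
    if (nrow(cc) < 3 * n_per_band) {
      warning("only ", nrow(cc), " candidates for ", cc$subdivision[1],
              "; returning all", call. = FALSE)
      return(tibble::tibble(subdivision = cc$subdivision,
                            track_id = cc$track_id,
                            band = NA_character_, pc1 = NA_real_))
    }
    x <- as.matrix(cc[feats])
    keep <- apply(x, 2, stats::sd) > 0
    pc <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE,
                        scale. = TRUE)
    pc1 <- pc$x[, 1]
    ord <- order(pc1, cc$track_id) # ascending, ties by track id
    bottom <- ord[seq_len(n_per_band)]
    top <- rev(ord)[seq_len(n_per_band)]
    rest <- setdiff(ord, c(top, bottom))
    med <- stats::median(pc1)
    middle <- rest[order(abs(pc1[rest] - med),
                         cc$track_id[rest])][seq_len(n_per_band)]
    idx <- c(top, middle, bottom)
    tibble::tibble(
      subdivision = cc$subdivision[idx],
      track_id = cc$track_id[idx],
      band = rep(c("top", "middle", "bottom"), each = n_per_band),
      pc1 = pc1[idx])
  })
  dplyr::bind_rows(out)
}

#' Exclude under-participating raters
#'
#' Drops participants who provided no ratings at all or who rated fewer than
#' 66% of the distinct tracks in the table.
#'
#' @param ratings Ratings tibble (`participant_id`, `track_id`,
#'   `track_subdivision`, `rated_subdivision`, `rating`).
#' @param min_frac Minimum rated-track fraction (default 0.66).
#' @return The filtered ratings; excluded participant ids are recorded in
#'   the `"excluded"` attribute.
#' @export
exclude_participants <- function(ratings, min_frac = 0.66) {
  n_tracks <- dplyr::n_distinct(ratings$track_id)
  keep_tbl <- ratings |>
    dplyr::filter(!is.na(.data$rating)) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(frac = dplyr::n_distinct(.data$track_id) / n_tracks,
                     .groups = "drop")
  keep <- keep_tbl$participant_id[keep_tbl$frac >= min_frac]
  out <- ratings |>
    dplyr::filter(!is.na(.data$rating),
                  .data$participant_id %in% keep)
  attr(out, "excluded") <- setdiff(unique(ratings$participant_id), keep)
  out
}

#' Per-participant preference-difference scores
#'
#' For each participant and subdivision S, the mean rating of S's own tracks
#' at S's rating slot minus the mean rating of the other four subdivisions'
#' tracks at that same slot. Positive scores indicate a preference for
#' listening to the tracks at their model-predicted subdivision. Missing
#' individual ratings are ignored within the means; a participant with no
#' own-subdivision ratings at a slot gets a missing score there.
#'
#' @param ratings Ratings tibble, exclusions already applied.
#' @return Tibble with columns `participant_id`, `subdivision`, `score`.
#' @export
preference_differences <- function(ratings) {
  slot <- ratings |>
    dplyr::filter(!is.na(.data$rating)) |>
    dplyr::group_by(.data$participant_id, .data$rated_subdivision) |>
    dplyr::summarise(
      own = mean(.data$rating[.data$track_subdivision ==
                                .data$rated_subdivision[1]]),
      other = mean(.data$rating[.data$track_subdivision !=
                                  .data$rated_subdivision[1]]),
      .groups = "drop")
  tibble::tibble(
    participant_id = slot$participant_id,
    subdivision = slot$rated_subdivision,
    score = slot$own - slot$other
  ) |>
    dplyr::filter(!is.na(.data$score)) |>
    dplyr::arrange(.data$participant_id,
                   match(.data$subdivision, subdivision_levels()))
}

#' One-sample t-tests of preference scores against zero
#'
#' Per subdivision: `t = mean / (s.d. / sqrt(n))` with sample s.d., df =
#' n - 1, a two-sided p-value Bonferroni-corrected by `n_comparisons`
#' (capped at 1), and the 95% confidence interval
#' `mean +/- t_{0.975, df} * s.d. / sqrt(n)`.
#'
#' @param scores Output of [preference_differences()] (columns `subdivision`,
#'   `score`), or any data frame with those columns.
#' @param n_comparisons Bonferroni multiplier (default 5).
#' @param conf_level Confidence level (default 0.95).
#' @return A `preference_stats` tibble: `subdivision`, `mean`, `sd`, `n`,
#'   `t`, `df`, `p` (corrected), `conf_low`, `conf_high`.
#' @export
ttest_vs_zero <- function(scores, n_comparisons = 5, conf_level = 0.95) {
  out <- scores |>
    dplyr::group_by(.data$subdivision) |>
    dplyr::summarise(mean = mean(.data$score), sd = stats::sd(.data$score),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(match(.data$subdivision, subdivision_levels()))
  if (any(out$n < 2)) {
    stop("need at least two scores per subdivision", call. = FALSE)
  }
  res <- preference_stats_from_summary(out$mean, out$sd, out$n,
                                       n_comparisons, conf_level)
  out <- dplyr::bind_cols(out, res)
  if (any(out$sd == 0 & out$mean != 0)) {
    warning("zero score s.d. with nonzero mean: p is degenerate",
            call. = FALSE)
  }
  class(out) <- c("preference_stats", class(out))
  out
}

#' Preference statistics from summary rows
#'
#' The same arithmetic as [ttest_vs_zero()], starting from printed summary
#' statistics (mean, s.d., n) instead of raw scores.
#'
#' @param mean,sd,n Vectors of per-group summaries.
#' @param n_comparisons Bonferroni multiplier (default 5).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with columns `t`, `df`, `p` (Bonferroni-corrected,
#'   capped at 1), `conf_low`, `conf_high`.
#' @export
preference_stats_from_summary <- function(mean, sd, n, n_comparisons = 5,
                                          conf_level = 0.95) {
  se <- sd / sqrt(n)
  t <- ifelse(sd == 0 & mean == 0, 0, mean / se)
  df <- n - 1
  p <- pmin(2 * stats::pt(abs(t), df, lower.tail = FALSE) * n_comparisons, 1)
  # zero spread with a nonzero mean: t is infinite, p collapses towards 0
  p[sd == 0 & mean != 0] <- .Machine$double.xmin
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  tibble::tibble(t = t, df = df, p = p,
                 conf_low = mean - tcrit * se,
                 conf_high = mean + tcrit * se)
}
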