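#' Audio feature registry
#'
#' The 15 per-track audio features used throughout the package, with their
#' documented valid ranges. Most features are bounded scores in \[0, 1\];
#' `dyn_range_mean` and `loudness` are in decibels and `tempo` in beats per
#' minute. Loudness is nominally bounded above by 0 dBFS but positive values
#' occur in real streaming catalogs, so the enforced upper bound is open.
#'
#' @return A tibble with columns `feature`, `min`, `max` and `unit`. `min`/
#'   `max` are the bounds enforced on ingest; `Inf` means unbounded above.
#' @export
#' @examples
#' audio_features()
audio_features <- function() {
  tibble::tribble(
    ~feature,           ~min, ~max, ~unit,
    "energy",            0,    1,   "score",
    "danceability",      0,    1,   "score",
    "acousticness",      0,    1,   "score",
    "dyn_range_mean",    0,    Inf, "dB",
    "beat_strength",     0,    1,   "score",
    "liveness",          0,    1,   "score",
    "organism",          0,    1,   "score",
    "mechanism",         0,    1,   "score",
    "valence",           0,    1,   "score",
    "bounciness",        0,    1,   "score",
    "flatness",          0,    1,   "score",
    "loudness",        -60,    Inf, "dB",
    "speechiness",       0,    1,   "score",
    "instrumentalness",  0,    1,   "score",
    "tempo",             0,    Inf, "BPM"
  )
}

#' Names of the audio features
#'
#' @return Character vector of the 15 feature names, in canonical column order.
#' @export
feature_names <- function() audio_features()$feature

#' The six classifier input features
#'
#' Speechiness, acousticness and instrumentalness are excluded from
#' classification because their distributions are highly non-normal.
#'
#' @return Character vector of six feature names.
#' @export
classifier_features <- function() {
  c("danceability", "energy", "loudness", "liveness", "valence", "tempo")
}

#' Check a track table against the documented feature ranges
#'
#' @param tracks A data frame with one row per track and the 15 feature
#'   columns of [audio_features()].
#' @param strict If `TRUE` (default), out-of-range values raise an error;
#'   otherwise a tibble of violations is returned.
#' @return `tracks` invisibly when valid (strict mode), else a tibble with
#'   columns `row`, `feature`, `value`, `min`, `max` describing violations.
#' @export
validate_features <- function(tracks, strict = TRUE) {
  reg <- audio_features()
  missing_cols <- setdiff(reg$feature, names(tracks))
  if (length(missing_cols) > 0) {
    stop("track table is missing feature columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- purrr::map_dfr(seq_len(nrow(reg)), function(i) {
    f <- reg$feature[i]
    x <- tracks[[f]]
    out <- which(!is.na(x) & (x < reg$min[i] | x > reg$max[i]))
    if (length(out) == 0) return(NULL)
    tibble::tibble(row = out, feature = f, value = x[out],
                   min = reg$min[i], max = reg$max[i])
  })
  if (nrow(bad) > 0 && strict) {
    stop("feature values outside documented ranges, e.g. ",
         bad$feature[1], " = ", signif(bad$value[1], 4),
         " outside [", bad$min[1], ", ", bad$max[1], "] (",
         nrow(bad), " violation(s))", call. = FALSE)
  }
  if (strict) invisible(tracks) else bad
}
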