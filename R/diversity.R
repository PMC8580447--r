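#' Hourly audio-feature variability
#'
#' Measures the relative diversity of music being listened to across the
#' day: each feature's 168 hourly standard deviations are z-normalized
#' across the hours of the week, averaged over the seven days per hour of
#' the day, and then averaged over features, giving one value per hour of
#' the day.
#'
#' @param table A complete hourly feature table from [aggregate_hourly()].
#' @return A tibble with columns `hour` (0..23) and `variability`.
#' @export
feature_variability <- function(table) {
  assert_complete_hourly(table)
  feats <- feature_names()
  sd_cols <- paste0("sd_", feats)
  sd_cols <- sd_cols[sd_cols %in% names(table)]
  if (length(sd_cols) == 0) stop("no sd_ columns found", call. = FALSE)
  hod <- (table$hour_of_week - 1) %% 24
  z <- vapply(sd_cols, function(cl) {
    x <- table[[cl]]
    if (anyNA(x)) stop("missing hourly s.d. values in ", cl, call. = FALSE)
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) {
      stop("hourly s.d. of '", sub("^sd_", "", cl),
           "' is constant; cannot normalize", call. = FALSE)
    }
    (x - mean(x)) / s
  }, numeric(nrow(table)))
  per_hour <- rowsum(rowMeans(z), hod) / as.vector(table(hod))
  tibble::tibble(hour = sort(unique(hod)),
                 variability = as.vector(per_hour))
}

#' Preprocess activity diaries to hourly activities
#'
#' Rounds each record's start time down to the full hour, forward-fills so
#' every hour of the day carries the activity in progress, then removes
#' sleep-related codes (010101, 010199, 010102) and missing-data codes
#' (500101 and higher). Hours whose filled code was removed contribute
#' nothing; persons with no remaining valid hours are dropped (counted in
#' the `"dropped_persons"` attribute).
#'
#' @param diaries A tibble with `person_id`, `start_minute` (0..1439) and
#'   `activity_code`.
#' @param sleep_codes Integer codes treated as sleep.
#' @param missing_min Codes `>=` this value are treated as missing data.
#' @return A tibble `person_id` / `hour` (0..23) / `activity_code` holding
#'   only valid person-hours.
#' @export
preprocess_diaries <- function(diaries,
                               sleep_codes = c(10101L, 10199L, 10102L),
                               missing_min = 500101L) {
  stopifnot(all(c("person_id", "start_minute", "activity_code") %in%
                  names(diaries)))
  if (nrow(diaries) == 0) {
    return(tibble::tibble(person_id = character(0), hour = integer(0),
                          activity_code = integer(0)))
  }
  d <- diaries |>
    dplyr::mutate(hour = as.integer(.data$start_minute %/% 60)) |>
    dplyr::arrange(.data$person_id, .data$start_minute) |>
    # several records rounding into one hour: the latest one occupies it
    dplyr::group_by(.data$person_id, .data$hour) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup()
  filled <- d |>
    dplyr::group_by(.data$person_id) |>
    tidyr::complete(hour = 0:23) |>
    tidyr::fill("activity_code", .direction = "down") |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$activity_code))
  valid <- filled |>
    dplyr::filter(!.data$activity_code %in% sleep_codes,
                  .data$activity_code < missing_min) |>
    dplyr::select("person_id", "hour", "activity_code")
  dropped <- setdiff(unique(diaries$person_id), unique(valid$person_id))
  attr(valid, "dropped_persons") <- dropped
  valid
}

#' Descending proportion differences for one hour
#'
#' The building block of the activity-diversity index: activity proportions
#' are sorted in descending order, the top 50 are taken (padded with zeros
#' when fewer than 50 activities occur), and the 49 consecutive differences
#' (next minus current, hence all `<= 0`) are returned.
#'
#' @param counts Numeric vector of per-activity counts (or proportions) for
#'   one hour; names are irrelevant.
#' @param top_n Number of top activities considered (default 50).
#' @return Numeric vector of `top_n - 1` non-positive differences.
#' @export
diversity_differences <- function(counts, top_n = 50) {
  total <- sum(counts)
  if (length(counts) == 0 || total <= 0) {
    stop("counts must contain at least one positive value", call. = FALSE)
  }
  p <- sort(counts / total, decreasing = TRUE)
  p <- c(p, rep(0, max(0, top_n - length(p))))[seq_len(top_n)]
  diff(p)
}

#' Activity-diversity index for one hour
#'
#' The median of the 49 descending proportion differences among the hour's
#' top-50 activities. Lies in `[-1, 0]`; values near 0 indicate a more
#' uniform (diverse) spread of activity.
#'
#' @inheritParams diversity_differences
#' @return A single value in `[-1, 0]`.
#' @export
#' @examples
#' activity_diversity_index(c(40, 30, 20, 10))
activity_diversity_index <- function(counts, top_n = 50) {
  stats::median(diversity_differences(counts, top_n))
}

#' Activity-diversity series over the day
#'
#' Applies [activity_diversity_index()] to each hour of a preprocessed
#' hourly activity table, counting activity instances (person-hours).
#'
#' @param hourly Output of [preprocess_diaries()].
#' @param top_n Number of top activities considered per hour (default 50).
#' @return A tibble with columns `hour` (0..23) and `diversity` (`NA` for
#'   hours with no valid activity).
#' @export
activity_diversity <- function(hourly, top_n = 50) {
  idx <- vapply(0:23, function(h) {
    counts <- table(hourly$activity_code[hourly$hour == h])
    if (length(counts) == 0) return(NA_real_)
    activity_diversity_index(as.numeric(counts), top_n)
  }, numeric(1))
  tibble::tibble(hour = 0:23, diversity = idx)
}

#' Circular moving average
#'
#' Centered moving average over a 24-hour series with wrap-around, for
#' smoothed daily profiles.
#'
#' @param series Numeric vector (typically length 24).
#' @param window Odd window width `<=` the series length.
#' @return Numeric vector of the same length.
#' @export
moving_average <- function(series, window = 3) {
  n <- length(series)
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (window > n) stop("window exceeds series length", call. = FALSE)
  half <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    mean(series[((i - 1 + (-half:half)) %% n) + 1])
  }, numeric(1))
}

#' Correlate activity diversity with feature variability
#'
#' Pearson correlation between the 24-hour activity-diversity series and the
#' 24-hour mean audio-feature-variability series, with a two-sided p-value
#' from the t transform on 22 degrees of freedom.
#'
#' @param diversity Numeric length-24 series (or tibble with a `diversity`
#'   column).
#' @param variability Numeric length-24 series (or tibble with a
#'   `variability` column).
#' @return A tibble with columns `r`, `p`, `n`, `df`.
#' @export
correlate_diversity_variability <- function(diversity, variability) {
  if (is.data.frame(diversity)) diversity <- diversity$diversity
  if (is.data.frame(variability)) variability <- variability$variability
  if (length(diversity) != length(variability)) {
    stop("series lengths differ", call. = FALSE)
  }
  if (anyNA(diversity) || anyNA(variability)) {
    stop("series contain missing values", call. = FALSE)
  }
  if (stats::sd(diversity) == 0 || stats::sd(variability) == 0) {
    stop("zero variance in a series; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(diversity, variability, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value,
                 n = length(diversity), df = unname(ct$parameter))
}
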