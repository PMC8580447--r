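#' Filter streaming events
#'
#' Keeps only events where the listener listened to most of the track,
#' performed at most one seek-forward or seek-backward operation, and whose
#' date/hour information is intact. Rows with missing values in any of the
#' three filter fields are rejected as malformed rather than crashing the
#' filter; per-reason rejection counts are attached as the `"filter_log"`
#' attribute. The operation is idempotent and preserves row order.
#'
#' @param log An event-log tibble with logical `listened_most`, integer
#'   `n_seek_ops`, logical `valid_timestamp` (and any other columns).
#' @return The kept rows, with attribute `filter_log`: a tibble of
#'   `reason`/`n` for every rejection reason.
#' @export
filter_events <- function(log) {
  need <- c("listened_most", "n_seek_ops", "valid_timestamp")
  missing_cols <- setdiff(need, names(log))
  if (length(missing_cols) > 0) {
    stop("event log lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  malformed <- is.na(log$listened_most) | is.na(log$n_seek_ops) |
    (is.na(log$valid_timestamp))
  skipped <- !malformed & !log$listened_most
  seeky <- !malformed & log$listened_most & log$n_seek_ops > 1
  corrupt <- !malformed & log$listened_most & log$n_seek_ops <= 1 &
    (!log$valid_timestamp | is.na(log$hour) | is.na(log$weekday))
  keep <- !(malformed | skipped | seeky | corrupt)
  reasons <- tibble::tibble(
    reason = c("malformed_row", "not_listened_most", "too_many_seek_ops",
               "corrupt_timestamp"),
    n = c(sum(malformed), sum(skipped), sum(seeky), sum(corrupt))
  )
  out <- log[keep, , drop = FALSE]
  attr(out, "filter_log") <- reasons[reasons$n > 0, ]
  out
}

#' Hour-of-week coordinate
#'
#' Maps (weekday, hour-of-day) to the hour-of-week index `h` in 1..168, with
#' hour 1 being Monday 00:00 and hour 168 Sunday 23:00. Vectorized and
#' bijective; [hour_of_week_inverse()] is its inverse.
#'
#' @param weekday Integer 0..6, Monday = 0.
#' @param hour Integer 0..23.
#' @return Integer vector in 1..168.
#' @export
#' @examples
#' hour_of_week(0, 0)   # Monday 00:00 -> 1
#' hour_of_week(6, 23)  # Sunday 23:00 -> 168
hour_of_week <- function(weekday, hour) {
  if (any(is.na(weekday) | is.na(hour)) ||
      any(weekday < 0 | weekday > 6 | hour < 0 | hour > 23) ||
      any(weekday != trunc(weekday) | hour != trunc(hour))) {
    stop("weekday must be in 0..6 and hour in 0..23", call. = FALSE)
  }
  as.integer(24 * weekday + hour + 1)
}

#' @rdname hour_of_week
#' @param h Hour-of-week index 1..168.
#' @return For the inverse: a tibble with columns `weekday` and `hour`.
#' @export
hour_of_week_inverse <- function(h) {
  if (any(is.na(h)) || any(h < 1 | h > 168) || any(h != trunc(h))) {
    stop("h must be in 1..168", call. = FALSE)
  }
  tibble::tibble(weekday = as.integer((h - 1) %/% 24),
                 hour = as.integer((h - 1) %% 24))
}

#' Aggregate audio features per unique hour of the week
#'
#' Computes, for each of the 168 hours of the week, the event-weighted mean
#' and standard deviation of every audio feature over the (already filtered)
#' events falling in that hour: a track streamed twice counts twice. Hours
#' with no events appear with `n = 0` and missing summaries.
#'
#' @param log A filtered event log (columns `track_id`, `weekday`, `hour`).
#' @param catalog Track catalog with `track_id` and the 15 feature columns.
#' @param sd_type `"population"` (divide by n, the default, matching the
#'   z-normalization convention used downstream) or `"sample"` (n - 1).
#' @return An hourly feature table: a tibble with 168 rows and columns
#'   `hour_of_week`, `n`, then `mean_<feature>` and `sd_<feature>` for each
#'   feature, in registry order.
#' @export
aggregate_hourly <- function(log, catalog,
                             sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  feats <- intersect(feature_names(), names(catalog))
  if (length(feats) == 0) stop("catalog carries no known feature columns",
                               call. = FALSE)
  unresolved <- setdiff(unique(log$track_id), catalog$track_id)
  if (length(unresolved) > 0) {
    stop("event log references unknown track ids: ",
         paste(utils::head(unresolved, 5), collapse = ", "),
         if (length(unresolved) > 5) ", ...", call. = FALSE)
  }
  how <- hour_of_week(log$weekday, log$hour)
  j <- match(log$track_id, catalog$track_id)
  out <- tibble::tibble(hour_of_week = 1:168,
                        n = as.integer(tabulate(how, nbins = 168)))
  denom <- function(n) if (sd_type == "population") n else pmax(n - 1, 0)
  for (f in feats) {
    x <- catalog[[f]][j]
    s1 <- rep(0, 168)
    agg1 <- rowsum(x, how)
    hrs <- as.integer(rownames(agg1))
    s1[hrs] <- agg1[, 1]
    m <- ifelse(out$n > 0, s1 / out$n, NA_real_)
    # two-pass variance: exact enough for oracle-equivalence checks
    ss <- rep(0, 168)
    agg2 <- rowsum((x - m[how])^2, how)
    ss[hrs] <- agg2[, 1]
    v <- ifelse(out$n > 0, ss / denom(out$n), NA_real_)
    v[out$n > 0 & denom(out$n) == 0] <- NA_real_
    out[[paste0("mean_", f)]] <- m
    out[[paste0("sd_", f)]] <- sqrt(v)
  }
  out
}
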