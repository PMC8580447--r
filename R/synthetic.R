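#' Canonical subdivision order
#'
#' The five within-day subdivisions in their cyclic order, anchored at
#' morning. This ordering defines class indices 1..5 wherever a numeric
#' class is needed (e.g. the circular error metric).
#'
#' @return Character vector of length 5.
#' @export
subdivision_levels <- function() {
  c("morning", "afternoon", "evening", "night", "late_night")
}

# inverse-CDF truncated normal draw; sd = 0 collapses to the mean
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Regime feature profiles
#'
#' A regime profile gives, per audio feature, the mean and standard deviation
#' of the (truncated normal) distribution tracks of that regime are drawn
#' from. Two presets are provided:
#'
#' * `"diurnal5"` — five regimes named after the subdivisions of the day,
#'   with mean shifts mirroring the qualitative structure of population
#'   listening data: mornings louder and more positive but slower, tempo and
#'   danceability peaking in the evening, night quietest and slowest, late
#'   night like night but with more energy and valence.
#' * `"separated5"` — five regimes pulled far apart (>= 4 s.d.) on the six
#'   classifier features; used to exercise classification under planted,
#'   clearly separable structure.
#'
#' @param preset `"diurnal5"` (default) or `"separated5"`.
#' @return A tibble with columns `regime`, `feature`, `mean`, `sd`. Regimes
#'   are ordered per [subdivision_levels()].
#' @export
regime_profiles <- function(preset = c("diurnal5", "separated5")) {
  preset <- match.arg(preset)
  levs <- subdivision_levels()
  if (preset == "diurnal5") {
    means <- tibble::tribble(
      ~feature,           ~morning, ~afternoon, ~evening, ~night, ~late_night,
      "energy",               0.65,       0.55,     0.60,   0.35,       0.45,
      "danceability",         0.50,       0.55,     0.70,   0.40,       0.45,
      "acousticness",         0.35,       0.40,     0.35,   0.60,       0.55,
      "dyn_range_mean",       8.0,        7.0,      6.0,   10.0,        9.0,
      "beat_strength",        0.50,       0.55,     0.70,   0.40,       0.45,
      "liveness",             0.20,       0.25,     0.30,   0.15,       0.28,
      "organism",             0.45,       0.40,     0.35,   0.60,       0.55,
      "mechanism",            0.50,       0.55,     0.65,   0.40,       0.45,
      "valence",              0.60,       0.55,     0.48,   0.35,       0.48,
      "bounciness",           0.50,       0.55,     0.70,   0.40,       0.45,
      "flatness",             0.45,       0.45,     0.40,   0.55,       0.50,
      "loudness",            -7.0,       -8.0,     -8.0,  -14.0,      -12.0,
      "speechiness",          0.08,       0.10,     0.12,   0.06,       0.07,
      "instrumentalness",     0.15,       0.20,     0.20,   0.45,       0.35,
      "tempo",              112,        124,      128,    102,        106
    )
    sds <- c(
      energy = 0.15, danceability = 0.15, acousticness = 0.15,
      dyn_range_mean = 2, beat_strength = 0.15, liveness = 0.10,
      organism = 0.15, mechanism = 0.15, valence = 0.15, bounciness = 0.15,
      flatness = 0.15, loudness = 4, speechiness = 0.05,
      instrumentalness = 0.15, tempo = 25
    )
  } else {
    means <- tibble::tribble(
      ~feature,           ~morning, ~afternoon, ~evening, ~night, ~late_night,
      "energy",               0.85,       0.15,     0.50,   0.70,       0.30,
      "danceability",         0.15,       0.85,     0.50,   0.30,       0.70,
      "acousticness",         0.50,       0.50,     0.50,   0.50,       0.50,
      "dyn_range_mean",       8.0,        8.0,      8.0,    8.0,        8.0,
      "beat_strength",        0.50,       0.50,     0.50,   0.50,       0.50,
      "liveness",             0.10,       0.50,     0.30,   0.70,       0.90,
      "organism",             0.50,       0.50,     0.50,   0.50,       0.50,
      "mechanism",            0.50,       0.50,     0.50,   0.50,       0.50,
      "valence",              0.80,       0.60,     0.20,   0.40,       0.95,
      "bounciness",           0.50,       0.50,     0.50,   0.50,       0.50,
      "flatness",             0.50,       0.50,     0.50,   0.50,       0.50,
      "loudness",            -5,        -25,      -15,    -10,        -20,
      "speechiness",          0.08,       0.08,     0.08,   0.08,       0.08,
      "instrumentalness",     0.20,       0.20,     0.20,   0.20,       0.20,
      "tempo",               80,        180,      130,    200,        105
    )
    sds <- c(
      energy = 0.05, danceability = 0.05, acousticness = 0.10,
      dyn_range_mean = 1.5, beat_strength = 0.10, liveness = 0.05,
      organism = 0.10, mechanism = 0.10, valence = 0.05, bounciness = 0.10,
      flatness = 0.10, loudness = 1.5, speechiness = 0.03,
      instrumentalness = 0.10, tempo = 6
    )
  }
  out <- tidyr::pivot_longer(means, -"feature",
                             names_to = "regime", values_to = "mean")
  out$sd <- unname(sds[out$feature])
  out$regime <- factor(out$regime, levels = levs)
  out <- dplyr::arrange(out, .data$regime, .data$feature)
  out$regime <- as.character(out$regime)
  validate_profiles(out)
  dplyr::select(out, "regime", "feature", "mean", "sd")
}

#' Validate a regime profile table
#'
#' @param profiles A tibble with columns `regime`, `feature`, `mean`, `sd`.
#' @return `profiles`, invisibly; errors if a mean lies outside the feature's
#'   documented range, an s.d. is negative, or a feature is unknown.
#' @export
validate_profiles <- function(profiles) {
  stopifnot(all(c("regime", "feature", "mean", "sd") %in% names(profiles)))
  reg <- audio_features()
  unknown <- setdiff(unique(profiles$feature), reg$feature)
  if (length(unknown) > 0) {
    stop("unknown features in profile: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(profiles$sd < 0)) stop("profile s.d. must be >= 0", call. = FALSE)
  j <- match(profiles$feature, reg$feature)
  bad <- profiles$mean < reg$min[j] | profiles$mean > reg$max[j]
  if (any(bad)) {
    i <- which(bad)[1]
    stop("profile mean outside feature range: ", profiles$feature[i], " = ",
         profiles$mean[i], " for regime ", profiles$regime[i], call. = FALSE)
  }
  invisible(profiles)
}

#' Weekly listening schedule
#'
#' Maps each hour of the week (1..168, hour 1 = Monday 00:00) to a mixture
#' over regimes. The `"diurnal5"` preset assigns each hour entirely to one of
#' the five subdivisions, with onsets following the canonical within-day
#' structure: morning at 06:00 and afternoon at 12:00 every day; evening at
#' 20:00, extended past midnight on Friday and Saturday nights; night at
#' 23:00 on weekdays but 03:00/04:00 after the extended weekend evenings;
#' late night/early morning at 04:00 on weekdays and 05:00 on Saturday and
#' Sunday. These onset hours are illustrative defaults, not measurements.
#'
#' @param preset Currently only `"diurnal5"`.
#' @return A tibble with columns `hour` (1..168), `regime`, `weight`;
#'   weights sum to 1 within each hour.
#' @export
weekly_schedule <- function(preset = "diurnal5") {
  preset <- match.arg(preset, "diurnal5")
  day_labels <- function(day) { # day: 0 = Monday .. 6 = Sunday
    lab <- character(24)
    if (day <= 4) {            # Mon-Fri small hours
      lab[1:4] <- "night"      # 00-03
      lab[5:6] <- "late_night" # 04-05
    } else if (day == 5) {     # Saturday
      lab[1:3] <- "evening"    # 00-02 (Friday evening extended)
      lab[4:5] <- "night"      # 03-04
      lab[6]   <- "late_night" # 05
    } else {                   # Sunday
      lab[1:4] <- "evening"    # 00-03 (Saturday evening extended)
      lab[5]   <- "night"      # 04
      lab[6]   <- "late_night" # 05
    }
    lab[7:12]  <- "morning"    # 06-11
    lab[13:20] <- "afternoon"  # 12-19
    if (day %in% c(4, 5)) {    # Fri, Sat evenings run to midnight
      lab[21:24] <- "evening"  # 20-23
    } else {
      lab[21:23] <- "evening"  # 20-22
      lab[24]    <- "night"    # 23
    }
    lab
  }
  regime <- unlist(lapply(0:6, day_labels))
  tibble::tibble(hour = 1:168, regime = regime, weight = 1)
}

#' Planted schedule ground truth
#'
#' Convenience accessor for recovery tests: the majority regime per hour and
#' the onset hour-of-day structure implied by a schedule.
#'
#' @param schedule A schedule tibble from [weekly_schedule()].
#' @return A list with `labels` (length-168 character vector, majority regime
#'   per hour) and `mode_onsets` (named integer vector: modal onset
#'   hour-of-day per regime, ties to the earliest hour).
#' @export
schedule_truth <- function(schedule) {
  lab <- schedule |>
    dplyr::group_by(.data$hour) |>
    dplyr::slice_max(.data$weight, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$hour) |>
    dplyr::pull(.data$regime)
  runs <- label_runs(lab)
  onsets <- vapply(split(runs$onset_hod, runs$label), mode_hour, numeric(1))
  list(labels = lab, mode_onsets = onsets)
}

#' Generate a synthetic track catalog
#'
#' Each track is assigned a hidden ground-truth regime (uniformly unless
#' `regime_weights` is given) and its 15 audio features are drawn from that
#' regime's truncated-normal profile, truncated to the documented feature
#' ranges.
#'
#' @param n_tracks Number of tracks (>= 0).
#' @param profiles Regime profile tibble, e.g. [regime_profiles()].
#' @param seed Integer seed; output is deterministic given the seed.
#' @param regime_weights Optional named numeric vector of sampling weights
#'   per regime.
#' @return A tibble with `track_id`, the 15 feature columns, and a
#'   ground-truth column `gt_regime`.
#' @export
generate_track_catalog <- function(n_tracks, profiles, seed,
                                   regime_weights = NULL) {
  stopifnot(n_tracks >= 0)
  validate_profiles(profiles)
  regimes <- unique(profiles$regime)
  reg <- audio_features()
  feats <- feature_names()
  empty <- tibble::as_tibble(
    c(list(track_id = character(0)),
      stats::setNames(rep(list(numeric(0)), length(feats)), feats),
      list(gt_regime = character(0))))
  if (n_tracks == 0) return(empty)
  if (is.null(regime_weights)) {
    regime_weights <- stats::setNames(rep(1, length(regimes)), regimes)
  }
  withr::local_seed(seed)
  gt <- sample(regimes, n_tracks, replace = TRUE,
               prob = regime_weights[regimes])
  cols <- lapply(feats, function(f) {
    x <- numeric(n_tracks)
    lo <- reg$min[reg$feature == f]
    hi <- reg$max[reg$feature == f]
    for (r in regimes) {
      idx <- which(gt == r)
      if (length(idx) == 0) next
      p <- profiles[profiles$regime == r & profiles$feature == f, ]
      x[idx] <- rtrunc_norm(length(idx), p$mean, p$sd, lo, hi)
    }
    x
  })
  names(cols) <- feats
  tibble::as_tibble(c(
    list(track_id = sprintf("tr%06d", seq_len(n_tracks))),
    cols,
    list(gt_regime = gt)))
}

#' Generate a synthetic streaming-event log
#'
#' Events are placed uniformly over the 168 hours of the week; each event
#' draws its track from the catalog according to the hour's regime mixture.
#' A fraction `invalid_frac` of events is planted to fail exactly one of the
#' three validity filters (not listened to the most, more than one seek
#' operation, or a corrupt timestamp), chosen uniformly.
#'
#' @param catalog Track catalog from [generate_track_catalog()] (must carry
#'   `gt_regime`).
#' @param schedule Schedule tibble from [weekly_schedule()].
#' @param n_events Number of events.
#' @param invalid_frac Proportion in `[0, 1)` of filter-failing events.
#' @param seed Integer seed.
#' @return A tibble with columns `session_id`, `track_id`, `weekday` (0..6,
#'   Monday = 0), `hour` (0..23, `NA` when the timestamp is corrupt),
#'   `listened_most`, `n_seek_ops`, `valid_timestamp`, plus ground truth
#'   `gt_regime` and `gt_valid`.
#' @export
generate_streaming_events <- function(catalog, schedule, n_events,
                                      invalid_frac = 0, seed = 1L) {
  stopifnot(invalid_frac >= 0, invalid_frac < 1, n_events >= 0)
  if (n_events > 0 && nrow(catalog) == 0) {
    stop("cannot generate events from an empty catalog", call. = FALSE)
  }
  withr::local_seed(seed)
  how <- sample.int(168, n_events, replace = TRUE)
  # regime per event from the hour's mixture
  sched <- split(schedule[c("regime", "weight")], schedule$hour)
  regime <- character(n_events)
  for (h in unique(how)) {
    idx <- which(how == h)
    mix <- sched[[as.character(h)]]
    if (nrow(mix) == 1) {
      regime[idx] <- mix$regime
    } else {
      regime[idx] <- sample(mix$regime, length(idx), replace = TRUE,
                            prob = mix$weight)
    }
  }
  # track per event, sampled within the event's regime
  by_regime <- split(catalog$track_id, catalog$gt_regime)
  track <- character(n_events)
  for (r in unique(regime)) {
    pool <- by_regime[[r]]
    if (is.null(pool) || length(pool) == 0) {
      stop("catalog has no tracks for regime ", r, call. = FALSE)
    }
    idx <- which(regime == r)
    track[idx] <- pool[sample.int(length(pool), length(idx), replace = TRUE)]
  }
  valid <- stats::runif(n_events) >= invalid_frac
  fail_mode <- sample.int(3, n_events, replace = TRUE) # only used when !valid
  listened <- rep(TRUE, n_events)
  seeks <- stats::rbinom(n_events, 1, 0.3) # valid events have 0 or 1 seeks
  ts_ok <- rep(TRUE, n_events)
  bad <- which(!valid)
  listened[bad[fail_mode[bad] == 1]] <- FALSE
  seeks[bad[fail_mode[bad] == 2]] <- 2L + stats::rbinom(
    sum(fail_mode[bad] == 2), 3, 0.5)
  ts_ok[bad[fail_mode[bad] == 3]] <- FALSE
  weekday <- (how - 1) %/% 24
  hod <- (how - 1) %% 24
  hod[!ts_ok] <- NA_integer_
  new_session <- if (n_events > 0) {
    c(TRUE, stats::runif(n_events - 1) < 0.2)
  } else logical(0)
  tibble::tibble(
    session_id = sprintf("s%07d", cumsum(new_session)),
    track_id = track,
    weekday = as.integer(weekday),
    hour = as.integer(hod),
    listened_most = listened,
    n_seek_ops = as.integer(seeks),
    valid_timestamp = ts_ok,
    gt_regime = regime,
    gt_valid = valid
  )
}

#' Diary generation profile
#'
#' Controls the synthetic activity diaries: the pool of activity codes, the
#' per-hour concentration of the activity distribution (higher = more skewed
#' towards the hour's top activities; `Inf` collapses each hour to a single
#' activity), the per-hour probability of sleeping, and the probability of a
#' missing-data code. The defaults emulate a time-use survey: a broad
#' activity lexicon with geometrically decaying frequencies, decay gentle
#' enough that the hourly top-50 proportions are informative rather than
#' tied, heavy night-time sleep, and a flatter (more diverse) activity
#' distribution in the small hours.
#'
#' @param n_codes Number of distinct non-sleep activity codes.
#' @param concentration Length-24 positive vector (recycled if length 1) of
#'   geometric decay rates for the ranked activity frequencies.
#' @param sleep_prob Length-24 vector of sleep probabilities per hour.
#' @param missing_prob Scalar probability of a missing-data record.
#' @param record_prob Probability that a new diary record starts in a given
#'   hour (otherwise the previous activity carries on).
#' @return A `diary_profile` list.
#' @export
diary_profile <- function(n_codes = 120,
                          concentration = c(rep(0.03, 6), rep(0.12, 18)),
                          sleep_prob = c(rep(0.85, 6), rep(0.02, 16),
                                         rep(0.35, 2)),
                          missing_prob = 0.03,
                          record_prob = 0.8) {
  concentration <- rep_len(concentration, 24)
  sleep_prob <- rep_len(sleep_prob, 24)
  stopifnot(all(concentration > 0), all(sleep_prob >= 0 & sleep_prob <= 1),
            missing_prob >= 0, missing_prob < 1)
  structure(list(
    activity_codes = 110000 + seq_len(n_codes) * 101,
    sleep_codes = c(10101L, 10199L, 10102L),
    missing_codes = c(500101L, 500103L, 500105L),
    concentration = concentration,
    sleep_prob = sleep_prob,
    missing_prob = missing_prob,
    record_prob = record_prob
  ), class = "diary_profile")
}

#' Generate synthetic activity diaries
#'
#' One diary day per person, with records at sub-hour start times (so the
#' round-to-hour and forward-fill steps of diary preprocessing are
#' exercised). Sleep and missing-data codes are planted per the profile, so
#' downstream filtering always has something to remove.
#'
#' @param n_people Number of diarists (>= 0).
#' @param profile A [diary_profile()].
#' @param seed Integer seed.
#' @return A tibble with columns `person_id`, `start_minute` (0..1439) and
#'   `activity_code`.
#' @export
generate_activity_diaries <- function(n_people, profile = diary_profile(),
                                      seed = 1L) {
  stopifnot(n_people >= 0, inherits(profile, "diary_profile"))
  empty <- tibble::tibble(person_id = character(0),
                          start_minute = integer(0),
                          activity_code = integer(0))
  if (n_people == 0) return(empty)
  withr::local_seed(seed)
  m <- length(profile$activity_codes)
  # a fixed (per call) activity ranking per hour, so hours differ in which
  # activities dominate
  hour_order <- lapply(1:24, function(h) sample.int(m))
  draw_codes <- function(h, n) {
    c0 <- profile$concentration[h + 1]
    if (is.infinite(c0)) {
      ranked <- rep(1L, n)
    } else {
      w <- exp(-c0 * (seq_len(m) - 1))
      ranked <- sample.int(m, n, replace = TRUE, prob = w)
    }
    profile$activity_codes[hour_order[[h + 1]][ranked]]
  }
  rows <- lapply(0:23, function(h) {
    # which people start a new record this hour
    starts <- if (h == 0) rep(TRUE, n_people) else
      stats::runif(n_people) < profile$record_prob
    idx <- which(starts)
    n <- length(idx)
    if (n == 0) return(NULL)
    u <- stats::runif(n)
    code <- integer(n)
    asleep <- u < profile$sleep_prob[h + 1]
    missing <- !asleep &
      u < profile$sleep_prob[h + 1] + profile$missing_prob
    code[asleep] <- sample(profile$sleep_codes, sum(asleep), replace = TRUE)
    code[missing] <- sample(profile$missing_codes, sum(missing),
                            replace = TRUE)
    awake <- !(asleep | missing)
    code[awake] <- draw_codes(h, sum(awake))
    tibble::tibble(
      person_id = sprintf("p%05d", idx),
      start_minute = as.integer(60 * h +
                                  sample.int(60, n, replace = TRUE) - 1L),
      activity_code = code
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$person_id, .data$start_minute)
}

#' Generate a synthetic ratings table
#'
#' Emulates a single-track preference survey: 15 tracks (three per
#' subdivision), each rated by every participant for every subdivision slot
#' on a continuous slider from 1 to 101. A planted preference effect is added
#' when a track is rated at its own subdivision's slot, so the expected
#' preference-difference score per subdivision equals the planted effect (up
#' to slight attenuation from clipping at the slider bounds).
#'
#' @param n_participants Number of participants.
#' @param effects Named numeric vector of planted mean preferences, one per
#'   subdivision (names per [subdivision_levels()]).
#' @param noise_sd Rating noise s.d. in slider units.
#' @param missing_frac Probability that a participant skips a track entirely
#'   (all five of its slot ratings missing).
#' @param seed Integer seed.
#' @param baseline Baseline rating (default 51, the slider midpoint).
#' @return A tibble with columns `participant_id`, `track_id`,
#'   `track_subdivision`, `rated_subdivision`, `rating` (clipped to
#'   `[1, 101]`).
#' @export
generate_ratings <- function(n_participants,
                             effects = stats::setNames(
                               rep(0, 5), subdivision_levels()),
                             noise_sd = 20, missing_frac = 0, seed = 1L,
                             baseline = 51) {
  levs <- subdivision_levels()
  stopifnot(n_participants >= 0, all(levs %in% names(effects)),
            noise_sd >= 0, missing_frac >= 0, missing_frac < 1)
  tracks <- tibble::tibble(
    track_id = sprintf("rep_%s_%d", rep(levs, each = 3), rep(1:3, 5)),
    track_subdivision = rep(levs, each = 3)
  )
  if (n_participants == 0) {
    return(tibble::tibble(participant_id = character(0),
                          track_id = character(0),
                          track_subdivision = character(0),
                          rated_subdivision = character(0),
                          rating = numeric(0)))
  }
  withr::local_seed(seed)
  grid <- tidyr::expand_grid(
    participant_id = sprintf("sub%04d", seq_len(n_participants)),
    tracks,
    rated_subdivision = levs
  )
  planted <- ifelse(grid$track_subdivision == grid$rated_subdivision,
                    effects[grid$track_subdivision], 0)
  grid$rating <- pmin(101, pmax(1, baseline + planted +
                                  stats::rnorm(nrow(grid), 0, noise_sd)))
  if (missing_frac > 0) {
    pt <- dplyr::distinct(grid, .data$participant_id, .data$track_id)
    pt$skip <- stats::runif(nrow(pt)) < missing_frac
    grid <- grid |>
      dplyr::left_join(pt, by = c("participant_id", "track_id")) |>
      dplyr::filter(!.data$skip) |>
      dplyr::select(-"skip")
  }
  grid
}
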