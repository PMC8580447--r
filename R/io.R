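# CSV dialect everywhere: comma-separated, UTF-8, mandatory header, '.'
# decimal. Column orders are fixed by the writers below.

event_cols <- function() {
  readr::cols(
    session_id = readr::col_character(),
    track_id = readr::col_character(),
    weekday = readr::col_integer(),
    hour = readr::col_integer(),
    listened_most = readr::col_logical(),
    n_seek_ops = readr::col_integer(),
    valid_timestamp = readr::col_logical(),
    .default = readr::col_guess()
  )
}

#' Read / write the standard CSV schemas
#'
#' Thin readr wrappers fixing column types for the package's four input
#' schemas (event logs, track catalogs, activity diaries, ratings) and the
#' hourly feature table. NDJSON event logs (one JSON object per line) are
#' also accepted by [read_event_log()].
#'
#' @param path File path.
#' @return A tibble with typed columns.
#' @name io
NULL

#' @rdname io
#' @export
read_event_log <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("^\\s*\\{", first)) {
    rows <- jsonlite::stream_in(file(path), verbose = FALSE)
    out <- tibble::as_tibble(rows)
    out$weekday <- as.integer(out$weekday)
    out$hour <- as.integer(out$hour)
    out$n_seek_ops <- as.integer(out$n_seek_ops)
    return(out)
  }
  readr::read_csv(path, col_types = event_cols(), progress = FALSE)
}

#' @rdname io
#' @param log Event log tibble.
#' @param format `"csv"` or `"ndjson"`.
#' @export
write_event_log <- function(log, path, format = c("csv", "ndjson")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(log, path, progress = FALSE)
  } else {
    con <- file(path, open = "w")
    on.exit(close(con))
    jsonlite::stream_out(as.data.frame(log), con, verbose = FALSE)
  }
  invisible(path)
}

#' @rdname io
#' @export
read_track_catalog <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    track_id = readr::col_character(), .default = readr::col_guess()),
    progress = FALSE)
  validate_features(out)
  out
}

#' @rdname io
#' @param catalog Track catalog tibble.
#' @export
write_track_catalog <- function(catalog, path) {
  cols <- c("track_id", intersect(feature_names(), names(catalog)),
            intersect("gt_regime", names(catalog)))
  readr::write_csv(catalog[cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_diaries <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    person_id = readr::col_character(),
    start_minute = readr::col_integer(),
    activity_code = readr::col_integer()), progress = FALSE)
}

#' @rdname io
#' @export
read_ratings <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    track_id = readr::col_character(),
    track_subdivision = readr::col_character(),
    rated_subdivision = readr::col_character(),
    rating = readr::col_double()), progress = FALSE)
}

#' @rdname io
#' @param table Hourly feature table.
#' @export
write_hourly_table <- function(table, path) {
  feats <- intersect(feature_names(),
                     sub("^mean_", "", grep("^mean_", names(table),
                                            value = TRUE)))
  cols <- c("hour_of_week", "n", paste0("mean_", feats), paste0("sd_", feats))
  readr::write_csv(table[cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_hourly_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    hour_of_week = readr::col_integer(), n = readr::col_integer(),
    .default = readr::col_double()), progress = FALSE)
}

#' Serialize a subdivision model to JSON
#'
#' @param model A `subdivision_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subdivision_model <- function(model, path) {
  payload <- list(
    k = model$k,
    labels = model$labels,
    clusters = model$clusters,
    centroids = model$centroids,
    scaler = model$scaler,
    cyclic_order_ok = model$cyclic_order_ok,
    inertia = model$inertia,
    restarts = model$restarts,
    seed = model$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_subdivision_model
#' @export
read_subdivision_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("labels", "clusters", "centroids", "scaler")) {
    raw[[nm]] <- tibble::as_tibble(raw[[nm]])
  }
  structure(raw, class = "subdivision_model")
}

#' Validate an input file against a named schema
#'
#' Per-row schema and range checks: feature ranges for catalogs,
#' weekday/hour/flag ranges for event logs, minute and code ranges for
#' diaries, the 1..101 slider range for ratings.
#'
#' @param path File path.
#' @param schema_name One of `"events"`, `"catalog"`, `"diaries"`,
#'   `"ratings"`.
#' @return A validation report: list with `n_rows`, `n_rejected` and a
#'   `rejections` tibble (`row`, `reason`).
#' @export
validate_inputs <- function(path,
                            schema_name = c("events", "catalog", "diaries",
                                            "ratings")) {
  schema_name <- match.arg(schema_name)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  rej <- tibble::tibble(row = integer(0), reason = character(0))
  add <- function(rows, reason) {
    if (length(rows) > 0) {
      rej <<- dplyr::bind_rows(rej, tibble::tibble(row = rows,
                                                   reason = reason))
    }
  }
  n_rows <- 0L
  if (schema_name == "events") {
    d <- read_event_log(path)
    n_rows <- nrow(d)
    add(which(!is.na(d$weekday) & (d$weekday < 0 | d$weekday > 6)),
        "weekday out of range")
    add(which(!is.na(d$hour) & (d$hour < 0 | d$hour > 23)),
        "hour out of range")
    add(which(d$valid_timestamp & is.na(d$hour)),
        "valid_timestamp but missing hour")
    add(which(!is.na(d$n_seek_ops) & d$n_seek_ops < 0),
        "negative seek count")
  } else if (schema_name == "catalog") {
    d <- readr::read_csv(path, col_types = readr::cols(
      track_id = readr::col_character(), .default = readr::col_guess()),
      progress = FALSE)
    n_rows <- nrow(d)
    bad <- validate_features(d, strict = FALSE)
    if (nrow(bad) > 0) {
      add(bad$row, paste0(bad$feature, " outside documented range [",
                          bad$min, ", ", bad$max, "]"))
    }
    add(which(is.na(d$track_id) | d$track_id == ""), "missing track_id")
  } else if (schema_name == "diaries") {
    d <- read_diaries(path)
    n_rows <- nrow(d)
    add(which(is.na(d$start_minute) | d$start_minute < 0 |
                d$start_minute > 1439), "start_minute out of range")
    add(which(is.na(d$activity_code) | d$activity_code <= 0),
        "invalid activity code")
  } else {
    d <- read_ratings(path)
    n_rows <- nrow(d)
    add(which(!is.na(d$rating) & (d$rating < 1 | d$rating > 101)),
        "rating outside slider range")
    add(which(!d$rated_subdivision %in% subdivision_levels()),
        "unknown rated subdivision")
  }
  list(n_rows = n_rows, n_rejected = nrow(rej), rejections = rej)
}
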