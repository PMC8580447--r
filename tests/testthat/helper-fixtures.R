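# shared fixtures, all built in code

# a tiny catalog carrying only a couple of features (aggregate_hourly and the
# oracles work on any subset of the registry)
toy_catalog <- function() {
  tibble::tibble(
    track_id = c("a", "b", "c", "d"),
    energy = c(0.2, 0.4, 0.6, 0.8),
    tempo = c(100, 110, 120, 130)
  )
}

toy_log <- function(track_ids, weekday, hour) {
  tibble::tibble(
    session_id = paste0("s", seq_along(track_ids)),
    track_id = track_ids,
    weekday = as.integer(weekday),
    hour = as.integer(hour),
    listened_most = TRUE,
    n_seek_ops = 0L,
    valid_timestamp = TRUE
  )
}

# a complete 168-row hourly table whose per-feature means are supplied as a
# 168 x f matrix (sds default to |means| / 10)
make_hourly_table <- function(means, sds = NULL, features = NULL) {
  means <- as.matrix(means)
  if (is.null(features)) features <- feature_names()[seq_len(ncol(means))]
  if (is.null(sds)) sds <- abs(means) / 10
  out <- tibble::tibble(hour_of_week = 1:168, n = 100L)
  for (j in seq_along(features)) {
    out[[paste0("mean_", features[j])]] <- means[, j]
    out[[paste0("sd_", features[j])]] <- as.matrix(sds)[, j]
  }
  out
}

# minimal subdivision_model stand-in for threshold rules: per-subdivision
# raw means / sds for the four threshold features, plus a scaler giving the
# grand mean
make_toy_model <- function(centroids, grand_means, hourly_sd = 1) {
  feats <- unique(centroids$feature)
  cen <- centroids
  if (!"hourly_sd" %in% names(cen)) cen$hourly_sd <- hourly_sd
  if (!"normalized" %in% names(cen)) cen$normalized <- NA_real_
  if (!"relative" %in% names(cen)) {
    cen$relative <- cen$raw - grand_means[cen$feature]
  }
  structure(list(
    k = length(unique(cen$subdivision)),
    centroids = cen,
    scaler = tibble::tibble(feature = feats,
                            u = unname(grand_means[feats]), s = 1)
  ), class = "subdivision_model")
}

# independent brute-force hourly aggregation (two-pass, per cell)
oracle_aggregate <- function(log, catalog, features) {
  out <- tibble::tibble(hour_of_week = 1:168)
  vals <- lapply(features, function(f) {
    catalog[[f]][match(log$track_id, catalog$track_id)]
  })
  names(vals) <- features
  h <- 24 * log$weekday + log$hour + 1
  for (f in features) {
    m <- sd_ <- rep(NA_real_, 168)
    for (hh in unique(h)) {
      x <- vals[[f]][h == hh]
      m[hh] <- sum(x) / length(x)
      sd_[hh] <- sqrt(sum((x - m[hh])^2) / length(x))
    }
    out[[paste0("mean_", f)]] <- m
    out[[paste0("sd_", f)]] <- sd_
  }
  out$n <- as.integer(tabulate(h, 168))
  out
}
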