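# ---- helpers on circular hour labels ----

# maximal runs of identical labels around the circular 1..168 week
label_runs <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 1)
  if (length(unique(labels)) == 1) {
    return(tibble::tibble(label = labels[1], start_hour = 1L,
                          end_hour = as.integer(n),
                          onset_hod = 0, offset_hod = (n - 1) %% 24))
  }
  prev <- labels[c(n, seq_len(n - 1))]
  starts <- which(labels != prev)
  ends <- c(starts[-1] - 1L, starts[1] - 1L)
  ends[ends == 0L] <- n
  tibble::tibble(
    label = labels[starts],
    start_hour = as.integer(starts),
    end_hour = as.integer(ends),
    onset_hod = (starts - 1) %% 24,
    offset_hod = (ends - 1) %% 24
  )
}

# modal value; ties broken towards the earliest hour
mode_hour <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)][1])
}

# circular standard deviation of hours-of-day, reported in hours
circular_sd_hours <- function(hods) {
  ang <- hods * 2 * pi / 24
  r <- sqrt(mean(cos(ang))^2 + mean(sin(ang))^2)
  r <- min(r, 1)
  sqrt(pmax(-2 * log(r), 0)) * 24 / (2 * pi)
}

# circular distance between hours-of-day
circ_hod_dist <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}

mean_cols <- function(table) {
  feats <- feature_names()
  pref <- paste0("mean_", feats)
  present <- pref %in% names(table)
  if (any(present)) {
    stats::setNames(pref[present], feats[present])
  } else {
    got <- intersect(feats, names(table))
    if (length(got) == 0) stop("no feature columns found", call. = FALSE)
    stats::setNames(got, got)
  }
}

assert_complete_hourly <- function(table) {
  if (nrow(table) != 168) {
    stop("hourly table must have exactly 168 rows", call. = FALSE)
  }
  cols <- mean_cols(table)
  bad <- names(cols)[vapply(cols, function(cl) anyNA(table[[cl]]), logical(1))]
  if (length(bad) > 0) {
    stop("hourly table has missing values (empty hours?) in: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(table)
}

# ---- normalization ----

#' Z-normalize an hourly feature table
#'
#' Standardizes each feature's 168 hourly means by removing the mean and
#' scaling to unit variance: z = (x - u) / s with u, s the mean and
#' (population) standard deviation over the 168 hours.
#'
#' @param table An hourly feature table from [aggregate_hourly()] (complete:
#'   no missing hours).
#' @return A list with `scaled` (tibble: `hour_of_week` plus one z-scored
#'   column per feature, named by feature) and `scaler` (tibble: `feature`,
#'   `u`, `s`).
#' @seealso [inverse_zscore()]
#' @export
zscore_hourly <- function(table) {
  assert_complete_hourly(table)
  cols <- mean_cols(table)
  scaled <- tibble::tibble(hour_of_week = table$hour_of_week)
  scaler <- tibble::tibble(feature = names(cols),
                           u = NA_real_, s = NA_real_)
  for (i in seq_along(cols)) {
    x <- table[[cols[i]]]
    u <- mean(x)
    s <- sqrt(mean((x - u)^2))
    if (s == 0) {
      stop("feature '", names(cols)[i],
           "' is constant across hours; cannot z-normalize", call. = FALSE)
    }
    scaler$u[i] <- u
    scaler$s[i] <- s
    scaled[[names(cols)[i]]] <- (x - u) / s
  }
  list(scaled = scaled, scaler = scaler)
}

#' Invert a z-normalization
#'
#' @param scaled Tibble of z-scored feature columns (as from
#'   [zscore_hourly()]).
#' @param scaler The matching scaler tibble.
#' @return A tibble with the original scales restored.
#' @export
inverse_zscore <- function(scaled, scaler) {
  out <- scaled
  for (i in seq_len(nrow(scaler))) {
    f <- scaler$feature[i]
    if (f %in% names(out)) out[[f]] <- out[[f]] * scaler$s[i] + scaler$u[i]
  }
  out
}

#' Grand mean feature profile
#'
#' The per-feature mean over the 168 hourly means (unweighted by event
#' counts); the reference against which cluster centroids are compared.
#'
#' @param table An hourly feature table (raw or z-scored).
#' @return A tibble with columns `feature` and `grand_mean`.
#' @export
grand_mean_profile <- function(table) {
  assert_complete_hourly(table)
  cols <- mean_cols(table)
  tibble::tibble(
    feature = names(cols),
    grand_mean = unname(vapply(cols, function(cl) mean(table[[cl]]),
                               numeric(1)))
  )
}

# ---- clustering ----

scaled_matrix <- function(scaled) {
  feats <- intersect(feature_names(), names(scaled))
  as.matrix(scaled[, feats, drop = FALSE])
}

# best-of-restarts k-means with retry on degenerate starts
kmeans_best <- function(x, k, restarts, max_iter) {
  ux <- unique(x)
  if (k == nrow(ux)) {
    # closed form: every distinct row is its own centroid
    cl <- match(data.frame(t(x)), data.frame(t(ux)))
    withinss <- vapply(seq_len(k), function(ci) {
      sum(sweep(x[cl == ci, , drop = FALSE], 2, ux[ci, ])^2)
    }, numeric(1))
    return(list(cluster = cl, centers = ux, size = tabulate(cl, k),
                tot.withinss = sum(withinss)))
  }
  for (attempt in 1:5) {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = k, nstart = restarts,
                                     iter.max = max_iter)),
      error = function(e) NULL)
    if (!is.null(km) && all(km$size > 0)) return(km)
  }
  stop("k-means failed to produce ", k, " non-empty clusters", call. = FALSE)
}

#' Scan k for the elbow curve
#'
#' Runs k-means for each k in `k_range` on the z-scored hourly table,
#' keeping the best (lowest) within-cluster sum of squares (inertia) over
#' `restarts` random starts.
#'
#' @param scaled Z-scored hourly table (the `scaled` element of
#'   [zscore_hourly()]).
#' @param k_range Integer vector of candidate k (default 2..24).
#' @param restarts Random starts per k (default 20).
#' @param max_iter Maximum k-means iterations per start (default 100).
#' @param seed Integer seed; the scan is deterministic given the seed.
#' @return An inertia curve: tibble with columns `k` and `inertia`, with
#'   `restarts` and `seed` recorded as attributes.
#' @export
kmeans_scan <- function(scaled, k_range = 2:24, restarts = 20,
                        max_iter = 100, seed = 1L) {
  x <- scaled_matrix(scaled)
  ndistinct <- nrow(unique(x))
  if (any(k_range > ndistinct)) {
    stop("k exceeds the number of distinct rows (", ndistinct, ")",
         call. = FALSE)
  }
  withr::local_seed(seed)
  inertia <- vapply(sort(unique(as.integer(k_range))), function(k) {
    kmeans_best(x, k, restarts, max_iter)$tot.withinss
  }, numeric(1))
  out <- tibble::tibble(k = sort(unique(as.integer(k_range))),
                        inertia = inertia)
  attr(out, "restarts") <- restarts
  attr(out, "seed") <- seed
  out
}

#' Select k by the elbow rule
#'
#' Automates elbow inspection: after min-max scaling both axes to `[0, 1]`,
#' returns the k whose point lies farthest (perpendicular distance) from the
#' chord joining the curve's endpoints. Ties go to the smallest such k; a
#' straight-line curve therefore returns the smallest interior k.
#'
#' @param curve Inertia curve from [kmeans_scan()] (>= 3 points).
#' @return The selected k (integer).
#' @export
select_k_elbow <- function(curve) {
  stopifnot(nrow(curve) >= 3)
  k <- curve$k
  inert <- curve$inertia
  xs <- (k - min(k)) / (max(k) - min(k))
  ys <- if (max(inert) > min(inert)) {
    (inert - min(inert)) / (max(inert) - min(inert))
  } else rep(0, length(inert))
  n <- length(k)
  x1 <- xs[1]; y1 <- ys[1]; x2 <- xs[n]; y2 <- ys[n]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  d <- abs((x2 - x1) * (y1 - ys) - (x1 - xs) * (y2 - y1)) / len
  interior <- 2:(n - 1)
  dmax <- max(d[interior])
  as.integer(k[interior][which(d[interior] >= dmax - 1e-12)[1]])
}

# The clusters occur "sequentially" when the circular sequence of label
# runs over the whole week is a periodic repetition of a single cyclic
# order of the k clusters (day boundaries may split an occurrence, e.g.
# a weekend evening running past midnight, so the check works on runs,
# not on calendar days).
sequential_runs <- function(run_labels, k) {
  r <- length(run_labels)
  if (r %% k != 0) return(FALSE)
  if (length(unique(run_labels[seq_len(k)])) != k) return(FALSE)
  all(run_labels == rep(run_labels[seq_len(k)], r / k))
}

#' Fit the subdivision model
#'
#' Clusters the 168 z-scored hourly feature rows into k subdivisions and
#' derives the full subdivision structure: canonical labels (clusters ordered
#' by modal onset, anchored at the cluster whose onset is nearest 06:00, and
#' named morning/afternoon/evening/night/late_night when k = 5), modal onset
#' and offset hours with circular onset s.d., normalized / raw
#' (inverse-transformed) / relative (centroid minus grand mean) feature
#' profiles, and a check that the clusters always occur sequentially: the
#' circular sequence of label runs over the week must repeat a single cyclic
#' order of the k clusters (day boundaries may split an occurrence, so the
#' check works on runs rather than calendar days).
#'
#' @param scaled Z-scored hourly table (the `scaled` element of
#'   [zscore_hourly()]).
#' @param scaler The matching scaler (for inverse-transforming centroids).
#' @param k Number of subdivisions.
#' @param restarts Random starts (default 20; the best partition is kept).
#' @param max_iter Maximum k-means iterations (default 1000).
#' @param seed Integer seed.
#' @return A `subdivision_model` object: a list with elements `k`, `labels`
#'   (tibble `hour_of_week` / `cluster` / `subdivision`), `clusters` (per
#'   subdivision: `n_hours`, `n_occurrences`, `mode_onset`, `onset_sd`,
#'   `mode_offset`), `centroids` (long tibble: `subdivision`, `feature`,
#'   `normalized`, `raw`, `relative`, `hourly_sd`), `scaler`,
#'   `cyclic_order_ok`, `inertia`, `restarts`, `seed`.
#' @export
fit_subdivisions <- function(scaled, scaler, k, restarts = 20,
                             max_iter = 1000, seed = 1L) {
  x <- scaled_matrix(scaled)
  if (k > nrow(unique(x))) {
    stop("k exceeds the number of distinct rows", call. = FALSE)
  }
  withr::local_seed(seed)
  km <- kmeans_best(x, k, restarts, max_iter)
  raw_labels <- km$cluster

  runs <- label_runs(as.character(raw_labels))
  onset_tbl <- runs |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      mode_onset = mode_hour(.data$onset_hod),
      onset_sd = circular_sd_hours(.data$onset_hod),
      mode_offset = mode_hour(.data$offset_hod),
      n_occurrences = dplyr::n(),
      .groups = "drop")

  # canonical order: anchor at the cluster with onset nearest 06:00, then
  # follow the cyclic order of modal onsets
  d6 <- circ_hod_dist(onset_tbl$mode_onset, 6)
  anchor <- onset_tbl$mode_onset[order(d6, onset_tbl$mode_onset)][1]
  cyc_pos <- (onset_tbl$mode_onset - anchor) %% 24
  ord <- order(cyc_pos, onset_tbl$mode_onset)
  onset_tbl <- onset_tbl[ord, ]
  subdiv_names <- if (k == 5) subdivision_levels() else
    paste0("subdivision_", seq_len(k))
  onset_tbl$subdivision <- subdiv_names
  onset_tbl$cluster <- seq_len(k)

  remap <- stats::setNames(seq_len(k), onset_tbl$label) # old label -> new id
  new_cluster <- unname(remap[as.character(raw_labels)])
  labels <- tibble::tibble(
    hour_of_week = scaled$hour_of_week,
    cluster = as.integer(new_cluster),
    subdivision = subdiv_names[new_cluster])

  sizes <- tabulate(new_cluster, nbins = k)
  feats <- colnames(x)
  centers_norm <- km$centers[as.integer(onset_tbl$label), , drop = FALSE]
  u <- scaler$u[match(feats, scaler$feature)]
  s <- scaler$s[match(feats, scaler$feature)]
  centers_raw <- sweep(sweep(centers_norm, 2, s, `*`), 2, u, `+`)
  # grand mean on the raw scale, from the data (equals u when the input is
  # genuinely z-scored)
  grand_raw <- u + s * colMeans(x)
  centers_rel <- sweep(centers_raw, 2, grand_raw, `-`)
  # spread of a cluster's raw hourly means around its centroid
  hourly_sd <- t(vapply(seq_len(k), function(ci) {
    xr <- sweep(sweep(x[new_cluster == ci, , drop = FALSE], 2, s, `*`),
                2, u, `+`)
    apply(xr, 2, stats::sd)
  }, numeric(length(feats))))

  centroids <- tibble::tibble(
    subdivision = rep(subdiv_names, times = length(feats)),
    feature = rep(feats, each = k),
    normalized = as.vector(centers_norm),
    raw = as.vector(centers_raw),
    relative = as.vector(centers_rel),
    hourly_sd = as.vector(hourly_sd))

  cyclic_ok <- sequential_runs(unname(remap[runs$label]), k)

  structure(list(
    k = as.integer(k),
    labels = labels,
    clusters = tibble::tibble(
      subdivision = subdiv_names,
      cluster = seq_len(k),
      n_hours = as.integer(sizes),
      n_occurrences = onset_tbl$n_occurrences,
      mode_onset = onset_tbl$mode_onset,
      onset_sd = onset_tbl$onset_sd,
      mode_offset = onset_tbl$mode_offset),
    centroids = centroids,
    scaler = scaler,
    cyclic_order_ok = cyclic_ok,
    inertia = km$tot.withinss,
    restarts = restarts,
    seed = seed
  ), class = "subdivision_model")
}

#' @export
print.subdivision_model <- function(x, ...) {
  cat("Subdivision model: k =", x$k,
      "| inertia =", signif(x$inertia, 5),
      "| cyclic order", if (x$cyclic_order_ok) "consistent" else
        "NOT consistent", "\n")
  print(x$clusters)
  invisible(x)
}

#' Relative centroid profile matrix
#'
#' The subdivision-by-feature matrix of centroid minus grand mean values
#' (positive = the subdivision sits above the weekly average for that
#' feature).
#'
#' @param model A `subdivision_model`.
#' @return A tibble: one row per subdivision, one column per feature.
#' @export
relative_profiles <- function(model) {
  stopifnot(inherits(model, "subdivision_model"))
  tidyr::pivot_wider(
    model$centroids[c("subdivision", "feature", "relative")],
    names_from = "feature", values_from = "relative")
}
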