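#' Feature remapping bounds
#'
#' Linear remap of the six classifier features to the open interval (-1, 1):
#' loudness is clamped to \[-60, 12\] dB and tempo to \[40, 220\] BPM before
#' the affine map; the four 0-1 features map as x -> 2x - 1.
#'
#' @return A tibble with columns `feature`, `lo`, `hi`.
#' @export
remap_bounds <- function() {
  tibble::tribble(
    ~feature,       ~lo, ~hi,
    "danceability",   0,   1,
    "energy",         0,   1,
    "loudness",     -60,  12,
    "liveness",       0,   1,
    "valence",        0,   1,
    "tempo",         40, 220
  )
}

#' Remap classifier features to (-1, 1)
#'
#' @param tracks A data frame with (at least) the six classifier feature
#'   columns.
#' @param bounds Remap bounds, normally [remap_bounds()].
#' @return A tibble with the six features remapped; values outside the
#'   bounds are clamped to -1 / 1.
#' @export
#' @examples
#' remap_features(data.frame(danceability = 0.75, energy = 0.5,
#'   loudness = -24, liveness = 0.1, valence = 0.5, tempo = 130))
remap_features <- function(tracks, bounds = remap_bounds()) {
  missing_cols <- setdiff(bounds$feature, names(tracks))
  if (length(missing_cols) > 0) {
    stop("missing classifier features: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(tracks[bounds$feature])
  for (i in seq_len(nrow(bounds))) {
    f <- bounds$feature[i]
    x <- pmin(pmax(out[[f]], bounds$lo[i]), bounds$hi[i])
    out[[f]] <- 2 * (x - bounds$lo[i]) / (bounds$hi[i] - bounds$lo[i]) - 1
  }
  out
}

#' Balanced class weights
#'
#' `weight_c = N / (K * n_c)`: the weighted mean of the weights over samples
#' is 1, and rarer classes weigh more.
#'
#' @param counts Named vector (or table) of per-class sample counts, all > 0.
#' @return Named numeric vector of weights.
#' @export
class_weights <- function(counts) {
  counts <- c(counts)
  if (any(counts <= 0)) stop("all class counts must be > 0", call. = FALSE)
  n <- sum(counts)
  k <- length(counts)
  stats::setNames(n / (k * as.numeric(counts)), names(counts))
}

# ---- training-set construction ----

threshold_features <- function() c("danceability", "energy", "liveness",
                                   "valence")

# per-subdivision threshold table: mean, direction sign, hourly sd
subdivision_thresholds <- function(model) {
  feats <- threshold_features()
  cen <- model$centroids[model$centroids$feature %in% feats, ]
  u <- model$scaler$u[match(cen$feature, model$scaler$feature)]
  cen$sign <- ifelse(cen$raw > u, 1, -1)
  cen[c("subdivision", "feature", "raw", "sign", "hourly_sd")]
}

# assign tracks to subdivisions by directional thresholds; multi-qualifying
# tracks go to the subdivision with the largest mean standardized margin
assign_by_threshold <- function(catalog, model, margin = 0) {
  feats <- threshold_features()
  thr <- subdivision_thresholds(model)
  subs <- unique(thr$subdivision)
  x <- as.matrix(catalog[feats])
  feat_sd <- apply(x, 2, stats::sd)
  qualifies <- matrix(FALSE, nrow(catalog), length(subs),
                      dimnames = list(NULL, subs))
  margins <- matrix(-Inf, nrow(catalog), length(subs),
                    dimnames = list(NULL, subs))
  for (s in subs) {
    ts <- thr[thr$subdivision == s, ]
    ts <- ts[match(feats, ts$feature), ]
    sdv <- ifelse(is.na(ts$hourly_sd), 0, ts$hourly_sd)
    cut <- ts$raw + ts$sign * margin * sdv
    # signed distance past the threshold, per feature
    m <- sweep(x, 2, cut, `-`) * rep(ts$sign, each = nrow(x))
    qualifies[, s] <- rowSums(m > 0) == length(feats)
    margins[, s] <- rowMeans(sweep(m, 2, feat_sd, `/`))
  }
  margins[!qualifies] <- -Inf
  any_q <- rowSums(qualifies) > 0
  pick <- subs[max.col(margins[any_q, , drop = FALSE],
                       ties.method = "first")]
  out <- catalog[any_q, , drop = FALSE]
  out$subdivision <- pick
  tibble::as_tibble(out)
}

#' Build the thresholded training set
#'
#' For each subdivision, a track qualifies when each of danceability,
#' energy, liveness and valence lies strictly beyond the subdivision's mean
#' in the direction of that subdivision's deviation from the grand mean
#' (above when the subdivision mean exceeds the grand mean, below
#' otherwise). Speechiness, acousticness and instrumentalness are ignored
#' because of their highly non-normal distributions. Tracks qualifying for
#' several subdivisions are assigned to the one with the largest mean
#' standardized margin past its thresholds.
#'
#' @param catalog Track catalog (tibble with the feature columns).
#' @param model A fitted `subdivision_model` (supplies subdivision means and
#'   the grand mean).
#' @return The qualifying tracks with an added `subdivision` label column.
#'   Errors if any subdivision ends up with zero qualifying tracks.
#' @export
build_training_set <- function(catalog, model) {
  out <- assign_by_threshold(catalog, model, margin = 0)
  got <- unique(out$subdivision)
  empty <- setdiff(unique(model$centroids$subdivision), got)
  if (length(empty) > 0) {
    stop("no qualifying tracks for subdivision(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  out
}

# ---- the feed-forward network ----

#' Classifier hyperparameters
#'
#' The network takes the six remapped features into four fully connected
#' hidden layers of 64, 128, 64 and 32 sigmoid units and a 5-way softmax
#' output. Training uses Adam (initial learning rate 1e-4), categorical
#' cross-entropy with balanced class weights, batches of 32 shuffled
#' between epochs, 30% dropout between the hidden layers, an L1 penalty of
#' 0.01 on the last three hidden layers, an 80/20 train/validation split
#' inside the training portion, and early stopping once validation accuracy
#' has not improved for 30 epochs.
#'
#' @param hidden Hidden layer widths.
#' @param dropout Dropout rate between hidden layers.
#' @param l1 L1 penalty on the last three hidden layers' weights.
#' @param learning_rate Adam initial learning rate.
#' @param batch_size Mini-batch size.
#' @param patience Early-stopping patience in epochs.
#' @param max_epochs Upper bound on training epochs.
#' @param holdout_frac Fraction held out for final evaluation.
#' @param validation_frac Fraction of the training portion used for
#'   validation / early stopping.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(hidden = c(64, 128, 64, 32), dropout = 0.30,
                            l1 = 0.01, learning_rate = 1e-4,
                            batch_size = 32, patience = 30,
                            max_epochs = 400, holdout_frac = 0.20,
                            validation_frac = 0.20) {
  structure(list(hidden = hidden, dropout = dropout, l1 = l1,
                 learning_rate = learning_rate, batch_size = batch_size,
                 patience = patience, max_epochs = max_epochs,
                 holdout_frac = holdout_frac,
                 validation_frac = validation_frac),
            class = "classifier_spec")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_init <- function(sizes) {
  nl <- length(sizes) - 1
  w <- vector("list", nl)
  b <- vector("list", nl)
  for (l in seq_len(nl)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    w[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(w = w, b = b)
}

mlp_forward <- function(par, x) {
  nl <- length(par$w)
  a <- x
  for (l in seq_len(nl - 1)) {
    a <- sigmoid(sweep(a %*% par$w[[l]], 2, par$b[[l]], `+`))
  }
  softmax_rows(sweep(a %*% par$w[[nl]], 2, par$b[[nl]], `+`))
}

# one Adam step over a mini-batch; returns updated parameters and optimizer
# state. l1_layers indexes weight matrices carrying the L1 penalty.
mlp_batch_step <- function(par, opt, x, y_onehot, wts, spec, l1_layers) {
  nl <- length(par$w)
  nb <- nrow(x)
  acts <- vector("list", nl + 1)
  masks <- vector("list", nl - 1)
  acts[[1]] <- x
  for (l in seq_len(nl - 1)) {
    a <- sigmoid(sweep(acts[[l]] %*% par$w[[l]], 2, par$b[[l]], `+`))
    if (l < nl - 1 && spec$dropout > 0) { # dropout between hidden layers
      m <- matrix(stats::rbinom(length(a), 1, 1 - spec$dropout) /
                    (1 - spec$dropout), nrow(a), ncol(a))
      a <- a * m
      masks[[l]] <- m
    }
    acts[[l + 1]] <- a
  }
  p <- softmax_rows(sweep(acts[[nl]] %*% par$w[[nl]], 2, par$b[[nl]], `+`))
  dz <- (p - y_onehot) * (wts / nb)
  gw <- vector("list", nl)
  gb <- vector("list", nl)
  for (l in nl:1) {
    gw[[l]] <- crossprod(acts[[l]], dz)
    gb[[l]] <- colSums(dz)
    if (l > 1) {
      da <- dz %*% t(par$w[[l]])
      if (!is.null(masks[[l - 1]])) da <- da * masks[[l - 1]]
      a <- acts[[l]]
      dz <- da * a * (1 - a)
    }
  }
  # Adam
  opt$t <- opt$t + 1
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- spec$learning_rate
  for (l in seq_len(nl)) {
    opt$mw[[l]] <- b1 * opt$mw[[l]] + (1 - b1) * gw[[l]]
    opt$vw[[l]] <- b2 * opt$vw[[l]] + (1 - b2) * gw[[l]]^2
    opt$mb[[l]] <- b1 * opt$mb[[l]] + (1 - b1) * gb[[l]]
    opt$vb[[l]] <- b2 * opt$vb[[l]] + (1 - b2) * gb[[l]]^2
    mhat <- opt$mw[[l]] / (1 - b1^opt$t)
    vhat <- opt$vw[[l]] / (1 - b2^opt$t)
    par$w[[l]] <- par$w[[l]] - lr * mhat / (sqrt(vhat) + eps)
    mhat <- opt$mb[[l]] / (1 - b1^opt$t)
    vhat <- opt$vb[[l]] / (1 - b2^opt$t)
    par$b[[l]] <- par$b[[l]] - lr * mhat / (sqrt(vhat) + eps)
    if (l %in% l1_layers && spec$l1 > 0) {
      # decoupled proximal (soft-threshold) step for the L1 penalty: with an
      # adaptive optimizer, a subgradient implementation would rescale the
      # constant-magnitude L1 gradient into full-size steps and collapse the
      # sigmoid stack to a constant predictor
      thr <- lr * spec$l1
      par$w[[l]] <- sign(par$w[[l]]) * pmax(abs(par$w[[l]]) - thr, 0)
    }
  }
  list(par = par, opt = opt)
}

#' Train the subdivision classifier
#'
#' Trains the feed-forward network of [classifier_spec()] on a labelled
#' track set (as produced by [build_training_set()]). The data are split
#' 80/20 into training and holdout portions; the training portion is split
#' again 80/20 into fitting and validation subsets for early stopping on
#' validation accuracy. Balanced class weights compensate for class
#' imbalance. Deterministic given the seed (single-threaded).
#'
#' @param trainset Tibble with the six classifier feature columns and a
#'   `subdivision` label column containing all five classes.
#' @param spec A [classifier_spec()].
#' @param seed Integer seed.
#' @param quiet Suppress the per-run message.
#' @return A `diurnal_mlp` object with elements `par` (weights), `spec`,
#'   `classes`, `bounds`, `metrics` (holdout accuracy/loss, per-class
#'   accuracy, epochs run, best epoch) and `seed`.
#' @export
train_classifier <- function(trainset, spec = classifier_spec(), seed = 1L,
                             quiet = TRUE) {
  classes <- subdivision_levels()
  if (!all(classes %in% trainset$subdivision)) {
    stop("training set must contain all five subdivisions", call. = FALSE)
  }
  bounds <- remap_bounds()
  x_all <- as.matrix(remap_features(trainset, bounds))
  y_all <- match(trainset$subdivision, classes)
  n <- nrow(x_all)

  withr::local_seed(seed)
  hold <- sample.int(n, round(spec$holdout_frac * n))
  tr <- setdiff(seq_len(n), hold)
  val <- sample(tr, round(spec$validation_frac * length(tr)))
  fit <- setdiff(tr, val)

  cw <- class_weights(stats::setNames(tabulate(y_all[tr], 5), classes))
  wts_fit <- unname(cw[y_all[fit]])
  onehot <- diag(5)[y_all, , drop = FALSE]

  sizes <- c(ncol(x_all), spec$hidden, 5)
  par <- mlp_init(sizes)
  nl <- length(par$w)
  l1_layers <- 2:4  # weights into the last three hidden layers
  opt <- list(
    t = 0,
    mw = lapply(par$w, function(m) m * 0), vw = lapply(par$w, function(m) m * 0),
    mb = lapply(par$b, function(v) v * 0), vb = lapply(par$b, function(v) v * 0))

  x_fit <- x_all[fit, , drop = FALSE]
  y_fit <- onehot[fit, , drop = FALSE]
  x_val <- x_all[val, , drop = FALSE]
  y_val <- y_all[val]

  best <- list(acc = -Inf, par = par, epoch = 0)
  stale <- 0
  epoch <- 0
  while (epoch < spec$max_epochs) {
    epoch <- epoch + 1
    ord <- sample.int(nrow(x_fit))
    starts <- seq(1, length(ord), by = spec$batch_size)
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + spec$batch_size - 1, length(ord))]
      step <- mlp_batch_step(par, opt, x_fit[idx, , drop = FALSE],
                             y_fit[idx, , drop = FALSE], wts_fit[idx],
                             spec, l1_layers)
      par <- step$par
      opt <- step$opt
    }
    val_acc <- mean(max.col(mlp_forward(par, x_val),
                            ties.method = "first") == y_val)
    if (val_acc > best$acc) {
      best <- list(acc = val_acc, par = par, epoch = epoch)
      stale <- 0
    } else {
      stale <- stale + 1
      if (stale >= spec$patience) break
    }
  }
  par <- best$par

  p_hold <- mlp_forward(par, x_all[hold, , drop = FALSE])
  y_hold <- y_all[hold]
  pred_hold <- max.col(p_hold, ties.method = "first")
  acc <- mean(pred_hold == y_hold)
  loss <- -mean(log(pmax(p_hold[cbind(seq_along(y_hold), y_hold)], 1e-12)))
  per_class <- tibble::tibble(
    subdivision = classes,
    n = as.integer(tabulate(y_hold, 5)),
    accuracy = vapply(1:5, function(c0) {
      idx <- y_hold == c0
      if (!any(idx)) NA_real_ else mean(pred_hold[idx] == c0)
    }, numeric(1)))
  if (!quiet) {
    message("holdout accuracy ", round(100 * acc, 2), "% after ",
            epoch, " epochs (best validation epoch ", best$epoch, ")")
  }
  structure(list(
    par = par, spec = spec, classes = classes, bounds = bounds,
    metrics = list(holdout_accuracy = acc, holdout_loss = loss,
                   per_class_accuracy = per_class,
                   validation_accuracy = best$acc,
                   epochs_run = epoch, best_epoch = best$epoch),
    seed = seed
  ), class = "diurnal_mlp")
}

#' @export
print.diurnal_mlp <- function(x, ...) {
  cat("Feed-forward subdivision classifier (",
      paste(x$spec$hidden, collapse = "-"), " sigmoid units)\n", sep = "")
  cat("holdout accuracy:", round(100 * x$metrics$holdout_accuracy, 2),
      "% | loss:", signif(x$metrics$holdout_loss, 4),
      "| epochs:", x$metrics$epochs_run, "\n")
  invisible(x)
}

#' Predict subdivision probabilities for tracks
#'
#' @param object A `diurnal_mlp`.
#' @param newdata Data frame with the six classifier feature columns (raw
#'   scales; remapping happens internally).
#' @param ... Unused.
#' @return A tibble of class probabilities, one row per track, columns named
#'   by subdivision; rows sum to 1.
#' @export
predict.diurnal_mlp <- function(object, newdata, ...) {
  x <- as.matrix(remap_features(newdata, object$bounds))
  p <- mlp_forward(object$par, x)
  colnames(p) <- object$classes
  tibble::as_tibble(p)
}

#' Classify a playlist
#'
#' Classifies each track separately, averages the per-track probability
#' vectors and predicts the subdivision with the highest mean probability
#' (ties broken towards the earlier subdivision in canonical order).
#'
#' @param model A trained `diurnal_mlp`.
#' @param tracks Non-empty data frame of track features.
#' @return A `playlist_prediction` list: `track_probs` (tibble),
#'   `mean_prob` (named numeric), `predicted` (character).
#' @export
classify_playlist <- function(model, tracks) {
  if (is.null(tracks) || nrow(tracks) == 0) {
    stop("playlist is empty", call. = FALSE)
  }
  probs <- predict(model, tracks)
  mp <- colMeans(probs)
  structure(list(
    track_probs = probs,
    mean_prob = mp,
    predicted = model$classes[which.max(mp)]
  ), class = "playlist_prediction")
}

#' @export
print.playlist_prediction <- function(x, ...) {
  cat("Playlist of", nrow(x$track_probs), "tracks -> predicted:",
      x$predicted, "\n")
  print(round(x$mean_prob, 3))
  invisible(x)
}

# ---- agreement scoring ----

#' Circular error between subdivisions
#'
#' The shortest step distance between two of the five cyclically ordered
#' subdivisions: `min(|res - pred|, 5 - |res - pred|)`. Ranges from 0 (equal)
#' to 2. Vectorized.
#'
#' @param res,pred Integer classes in 1..5 (order per
#'   [subdivision_levels()]), or subdivision names.
#' @return Integer vector of errors in 0..2.
#' @export
#' @examples
#' circular_error(1, 5) # morning vs late night are adjacent on the cycle
circular_error <- function(res, pred) {
  to_idx <- function(v) {
    if (is.character(v) || is.factor(v)) {
      v <- match(as.character(v), subdivision_levels())
    }
    v
  }
  res <- to_idx(res); pred <- to_idx(pred)
  if (anyNA(res) || anyNA(pred) ||
      any(res < 1 | res > 5 | pred < 1 | pred > 5) ||
      any(res != trunc(res) | pred != trunc(pred))) {
    stop("classes must be integers in 1..5 or subdivision names",
         call. = FALSE)
  }
  d <- abs(res - pred)
  as.integer(pmin(d, 5 - d))
}

#' Agreement report for playlist predictions
#'
#' Summarizes response/prediction pairs: per predicted subdivision and
#' overall, the percentage of exact agreement (circular error 0) and the
#' mean circular error.
#'
#' @param responses Data frame with columns `pred` and `res` (classes 1..5
#'   or subdivision names).
#' @return A tibble with columns `pred`, `n`, `agreement_pct`, `mean_error`;
#'   the final row (`pred = "overall"`) covers the whole sample. Empty input
#'   yields an empty report.
#' @export
agreement_report <- function(responses) {
  empty <- tibble::tibble(pred = character(0), n = integer(0),
                          agreement_pct = numeric(0),
                          mean_error = numeric(0))
  if (is.null(responses) || nrow(responses) == 0) return(empty)
  levs <- subdivision_levels()
  err <- circular_error(responses$res, responses$pred)
  pred <- responses$pred
  if (!is.character(pred) && !is.factor(pred)) pred <- levs[pred]
  per <- tibble::tibble(pred = as.character(pred), err = err) |>
    dplyr::group_by(.data$pred) |>
    dplyr::summarise(n = dplyr::n(),
                     agreement_pct = 100 * mean(.data$err == 0),
                     mean_error = mean(.data$err), .groups = "drop") |>
    dplyr::arrange(match(.data$pred, levs))
  dplyr::bind_rows(per, tibble::tibble(
    pred = "overall", n = length(err),
    agreement_pct = 100 * mean(err == 0), mean_error = mean(err)))
}
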