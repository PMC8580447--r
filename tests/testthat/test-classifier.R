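# toy centroid structure for threshold rules: grand mean 0.5 everywhere,
# "hi" sits above it and "lo" below it on all four threshold features
toy_threshold_model <- function() {
  feats <- c("danceability", "energy", "liveness", "valence")
  cen <- tidyr::expand_grid(subdivision = c("hi", "lo"), feature = feats)
  cen$raw <- ifelse(cen$subdivision == "hi", 0.7, 0.3)
  make_toy_model(cen, grand_means = stats::setNames(rep(0.5, 4), feats),
                 hourly_sd = 0.1)
}

toy_tracks <- function(dance, energy, live, val) {
  n <- length(dance)
  tibble::tibble(
    track_id = sprintf("t%02d", seq_len(n)),
    danceability = dance, energy = energy, liveness = live, valence = val)
}

test_that("threshold qualification follows the directional rule", {
  m <- toy_threshold_model()
  tracks <- toy_tracks(
    dance = c(0.8, 0.2, 0.7, 0.8, 0.75, 0.1, 0.9, 0.5),
    energy = c(0.9, 0.1, 0.7, 0.8, 0.72, 0.2, 0.1, 0.5),
    live = c(0.8, 0.2, 0.7, 0.9, 0.71, 0.25, 0.8, 0.5),
    val = c(0.8, 0.2, 0.7, 0.9, 0.74, 0.15, 0.8, 0.5))
  got <- build_training_set(tracks, m)
  # t1: all four above 0.7 -> hi; t2: all below 0.3 -> lo
  # t3: exactly at hi's means -> strict inequality, and fails lo too
  # t8: at the grand mean: above lo's means... qualifies for "lo"? no:
  #     for lo the rule needs values BELOW 0.3; 0.5 fails. not assigned.
  expect_equal(got$subdivision[got$track_id == "t01"], "hi")
  expect_equal(got$subdivision[got$track_id == "t02"], "lo")
  expect_false("t03" %in% got$track_id)   # boundary: strict inequality
  expect_false("t08" %in% got$track_id)
  expect_true(all(c("t04", "t05") %in%
                    got$track_id[got$subdivision == "hi"]))
  expect_equal(got$subdivision[got$track_id == "t06"], "lo")
  expect_false("t07" %in% got$track_id)   # energy on the wrong side of hi
})

test_that("an empty subdivision aborts training-set construction", {
  m <- toy_threshold_model()
  only_hi <- toy_tracks(0.9, 0.9, 0.9, 0.9)
  expect_error(build_training_set(only_hi, m), "lo")
})

test_that("the representative margin tightens the threshold", {
  m <- toy_threshold_model()
  # hourly_sd = 0.1 so the 10% margin moves hi's cut from 0.70 to 0.71
  tracks <- toy_tracks(dance = c(0.705, 0.72), energy = c(0.705, 0.72),
                       live = c(0.705, 0.72), val = c(0.705, 0.72))
  expect_warning(
    cand <- select_representative_candidates(tracks, m, margin = 0.10),
    "lo")                                 # no lo candidates exist here
  expect_equal(cand$track_id, "t02")      # 0.705 < 0.71 no longer qualifies
  expect_equal(cand$subdivision, "hi")
  # margin 0 reduces to the training-set rule
  cand0 <- suppressWarnings(
    select_representative_candidates(tracks, m, margin = 0))
  expect_setequal(cand0$track_id, c("t01", "t02"))
})

test_that("feature remapping hits the documented anchor points", {
  tr <- tibble::tibble(
    danceability = c(0.75, 0, 1), energy = c(0.5, 0, 1),
    loudness = c(-24, -60, 12), liveness = c(0.5, 0, 1),
    valence = c(0.5, 0, 1), tempo = c(130, 40, 220))
  z <- remap_features(tr)
  expect_equal(z$loudness, c(0, -1, 1))
  expect_equal(z$tempo, c(0, -1, 1))
  expect_equal(z$danceability[1], 0.5)
  # clamping beyond the bounds
  extreme <- tr[1, ]
  extreme$loudness <- -100; extreme$tempo <- 300
  ze <- remap_features(extreme)
  expect_equal(ze$loudness, -1)
  expect_equal(ze$tempo, 1)
  # monotone per feature
  xs <- seq(0, 1, 0.1)
  mono <- remap_features(tibble::tibble(
    danceability = xs, energy = xs, loudness = seq(-60, 12, length.out = 11),
    liveness = xs, valence = xs, tempo = seq(40, 220, length.out = 11)))
  expect_true(all(vapply(mono, function(cl) all(diff(cl) > 0), logical(1))))
})

test_that("class weights balance the loss", {
  expect_equal(unname(class_weights(c(a = 10, b = 10, c = 10))), rep(1, 3))
  w <- class_weights(c(10, 10, 10, 10, 60))
  expect_equal(unname(w), c(2, 2, 2, 2, 1 / 3))
  counts <- c(3, 14, 25, 8, 50)
  expect_equal(sum(class_weights(counts) * counts) / sum(counts), 1)
  expect_error(class_weights(c(1, 0)), "> 0")
})

test_that("circular error is the ring distance on the five subdivisions", {
  expect_equal(circular_error(3, 3), 0L)
  expect_equal(circular_error(1, 5), 1L)
  expect_equal(circular_error(2, 5), 2L)
  expect_equal(circular_error("morning", "late_night"), 1L)
  expect_error(circular_error(0, 3), "1..5")
  expect_error(circular_error(1, 6), "1..5")
})

test_that("training contract: shapes, determinism, class checks", {
  set.seed(31)
  n <- 120
  lab <- rep(subdivision_levels(), length.out = n)
  centers <- stats::setNames(seq(0.1, 0.9, 0.2), subdivision_levels())
  ts <- tibble::tibble(
    danceability = pmin(pmax(centers[lab] + rnorm(n, 0, 0.03), 0), 1),
    energy = pmin(pmax(rev(centers)[lab] + rnorm(n, 0, 0.03), 0), 1),
    loudness = -30 + 25 * centers[lab] + rnorm(n),
    liveness = runif(n), valence = runif(n),
    tempo = 60 + 150 * centers[lab] + rnorm(n, 0, 3),
    subdivision = lab)
  small <- classifier_spec(max_epochs = 15, patience = 5)
  clf <- train_classifier(ts, small, seed = 4)
  probs <- predict(clf, ts)
  expect_equal(dim(probs), c(n, 5))
  expect_lt(max(abs(rowSums(probs) - 1)), 1e-6)
  expect_true(all(probs >= 0))

  clf2 <- train_classifier(ts, small, seed = 4)
  expect_identical(clf$par, clf2$par)
  expect_identical(clf$metrics$holdout_accuracy,
                   clf2$metrics$holdout_accuracy)

  expect_error(train_classifier(ts[ts$subdivision != "night", ], small, 1),
               "all five subdivisions")
})

test_that("playlist prediction averages track probabilities", {
  set.seed(32)
  n <- 100
  lab <- rep(subdivision_levels(), length.out = n)
  centers <- stats::setNames(seq(0.1, 0.9, 0.2), subdivision_levels())
  ts <- tibble::tibble(
    danceability = pmin(pmax(centers[lab] + rnorm(n, 0, 0.02), 0), 1),
    energy = pmin(pmax(rev(centers)[lab] + rnorm(n, 0, 0.02), 0), 1),
    loudness = -30 + 25 * centers[lab], liveness = 0.2, valence = 0.5,
    tempo = 60 + 150 * centers[lab], subdivision = lab)
  clf <- train_classifier(ts, classifier_spec(max_epochs = 10, patience = 3),
                          seed = 9)
  one <- classify_playlist(clf, ts[3, ])
  expect_equal(one$predicted,
               clf$classes[which.max(as.numeric(predict(clf, ts[3, ])))])
  ten <- classify_playlist(clf, ts[1:10, ])
  expect_equal(unname(ten$mean_prob),
               unname(colMeans(as.matrix(predict(clf, ts[1:10, ])))),
               tolerance = 1e-12)
  expect_error(classify_playlist(clf, ts[0, ]), "empty")
})

test_that("uniform probabilities break ties towards the earlier class", {
  # all-zero weights give a uniform softmax: every class ties
  sizes <- c(6, 4, 4, 4, 4, 5)
  par <- list(
    w = lapply(1:5, function(l) matrix(0, sizes[l], sizes[l + 1])),
    b = lapply(1:5, function(l) rep(0, sizes[l + 1])))
  fake <- structure(list(par = par, classes = subdivision_levels(),
                         bounds = remap_bounds()),
                    class = "diurnal_mlp")
  pl <- classify_playlist(fake, toy_tracks(0.5, 0.5, 0.5, 0.5) |>
                            dplyr::mutate(loudness = -10, tempo = 120))
  expect_equal(unname(pl$mean_prob), rep(0.2, 5))
  expect_equal(pl$predicted, "morning")
})

test_that("agreement reports summarize circular errors", {
  expect_equal(nrow(agreement_report(data.frame(pred = integer(0),
                                                res = integer(0)))), 0)

  perfect <- data.frame(pred = 1:5, res = 1:5)
  rep1 <- agreement_report(perfect)
  overall <- rep1[rep1$pred == "overall", ]
  expect_equal(overall$agreement_pct, 100)
  expect_equal(overall$mean_error, 0)

  # responses uniform over classes for a fixed prediction
  unif <- data.frame(pred = rep(2, 5), res = 1:5)
  rep2 <- agreement_report(unif)
  expect_equal(rep2$mean_error[rep2$pred == "afternoon"], 1.2)
  expect_equal(rep2$agreement_pct[rep2$pred == "afternoon"], 20)

  toy <- data.frame(pred = c(1, 1, 2, 3, 4, 5, 5, 2, 3, 1),
                    res = c(1, 2, 2, 5, 4, 5, 1, 4, 3, 1))
  rep3 <- agreement_report(toy)
  ov <- rep3[rep3$pred == "overall", ]
  # hand-computed ring errors: 0,1,0,2,0,0,1,2,0,0
  expect_equal(ov$mean_error, 0.6)
  expect_equal(ov$agreement_pct, 60)
})
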