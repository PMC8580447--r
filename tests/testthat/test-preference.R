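test_that("PCA shortlist takes top, middle and bottom of the first axis", {
  # one dominant axis: all three features move together, so PC1 is (up to
  # sign) the shared axis and selection reduces to sorting on it
  set.seed(21)
  n <- 41
  energy <- sort(runif(n))
  cand <- tibble::tibble(
    subdivision = "morning",
    track_id = sprintf("t%02d", 1:n),
    energy = energy,
    danceability = pmin(pmax(energy + rnorm(n, 0, 1e-4), 0), 1),
    valence = pmin(pmax(energy + rnorm(n, 0, 1e-4), 0), 1))
  sl <- pca_select(cand)
  expect_equal(nrow(sl), 15)
  expect_equal(unname(table(sl$band)[c("top", "middle", "bottom")]),
               rep(5L, 3), ignore_attr = TRUE)
  expect_false(any(duplicated(sl$track_id)))
  ord <- order(cand$energy)
  extremes <- c(cand$track_id[ord[1:5]], cand$track_id[rev(ord)[1:5]])
  expect_setequal(sl$track_id[sl$band %in% c("top", "bottom")], extremes)
  rest <- ord[6:(n - 5)]
  mid <- cand$track_id[rest[order(abs(energy[rest] -
                                        median(energy)))][1:5]]
  expect_setequal(sl$track_id[sl$band == "middle"], mid)

  # sign flip of the dominant axis leaves the selected set unchanged
  cand2 <- cand
  for (f in c("energy", "danceability", "valence")) cand2[[f]] <- 1 - cand2[[f]]
  sl2 <- pca_select(cand2)
  expect_setequal(sl2$track_id, sl$track_id)

  # exactly 15 candidates: the identity partition by PC1 order
  sl15 <- pca_select(cand[1:15, ])
  expect_setequal(sl15$track_id, cand$track_id[1:15])

  expect_warning(pca_select(cand[1:10, ]), "returning all")
})

test_that("participant exclusion uses the 66% rated-track rule", {
  levs <- subdivision_levels()
  full <- generate_ratings(3, noise_sd = 0, seed = 1)
  # p1 complete, p2 rates 10/15 tracks (66.7%), p3 rates 9/15 (60%)
  tracks <- unique(full$track_id)
  r <- dplyr::bind_rows(
    full[full$participant_id == "sub0001", ],
    full[full$participant_id == "sub0002" &
           full$track_id %in% tracks[1:10], ],
    full[full$participant_id == "sub0003" &
           full$track_id %in% tracks[1:9], ])
  kept <- exclude_participants(r)
  expect_setequal(unique(kept$participant_id), c("sub0001", "sub0002"))
  expect_equal(attr(kept, "excluded"), "sub0003")

  # participant with zero ratings
  r2 <- r
  r2$rating[r2$participant_id == "sub0001"] <- NA
  kept2 <- exclude_participants(r2)
  expect_setequal(unique(kept2$participant_id), "sub0002")

  # all complete: unchanged
  kept3 <- exclude_participants(full)
  expect_equal(nrow(kept3), nrow(full))
})

test_that("preference differences compare matched rating slots", {
  levs <- subdivision_levels()
  flat <- generate_ratings(4, noise_sd = 0, seed = 2)
  s <- preference_differences(flat)
  expect_true(all(s$score == 0))

  # translation invariance per participant
  shifted <- flat
  shifted$rating <- shifted$rating +
    ifelse(shifted$participant_id == "sub0001", 7, 0)
  expect_equal(preference_differences(shifted)$score, s$score)

  # two-participant toy table, hand-computed
  toy <- tidyr::expand_grid(
    participant_id = c("a", "b"),
    track_id = c("m1", "m2", "m3", "n1", "n2", "n3"),
    rated_subdivision = c("morning", "night"))
  toy$track_subdivision <- ifelse(grepl("^m", toy$track_id),
                                  "morning", "night")
  # participant a: morning tracks rated 80 at the morning slot, night
  # tracks 60 there; everything 50 at the night slot
  toy$rating <- 50
  toy$rating[toy$participant_id == "a" &
               toy$rated_subdivision == "morning"] <-
    ifelse(grepl("^m", toy$track_id[toy$participant_id == "a" &
                                      toy$rated_subdivision == "morning"]),
           80, 60)
  got <- preference_differences(toy)
  expect_equal(got$score[got$participant_id == "a" &
                           got$subdivision == "morning"], 20)
  expect_equal(got$score[got$participant_id == "a" &
                           got$subdivision == "night"], 0)
  expect_true(all(got$score[got$participant_id == "b"] == 0))

  # missing own-subdivision ratings yield a missing score, not a crash
  drop_own <- toy[!(toy$participant_id == "a" &
                      toy$track_subdivision == "morning" &
                      toy$rated_subdivision == "morning"), ]
  got2 <- preference_differences(drop_own)
  expect_equal(nrow(got2[got2$participant_id == "a" &
                           got2$subdivision == "morning", ]), 0)
})

test_that("one-sample t machinery agrees with stats::t.test", {
  set.seed(3)
  scores <- tibble::tibble(
    subdivision = rep(subdivision_levels(), each = 30),
    score = rnorm(150, mean = rep(c(2, 0, -1, 0.5, 4), each = 30), sd = 5))
  got <- ttest_vs_zero(scores)
  for (s in subdivision_levels()) {
    x <- scores$score[scores$subdivision == s]
    tt <- t.test(x)
    row <- got[got$subdivision == s, ]
    expect_equal(row$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(row$p, min(tt$p.value * 5, 1), tolerance = 1e-10)
    expect_equal(c(row$conf_low, row$conf_high),
                 unname(tt$conf.int), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(row$df, unname(tt$parameter))
  }

  zeros <- tibble::tibble(subdivision = rep("morning", 10), score = 0)
  z <- ttest_vs_zero(zeros)
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)   # Bonferroni-capped

  const <- tibble::tibble(subdivision = rep("morning", 10), score = 3)
  zc <- suppressWarnings(ttest_vs_zero(const))
  expect_true(is.infinite(zc$t))
  expect_lt(zc$p, 1e-100)
  expect_warning(ttest_vs_zero(const), "zero score s.d.")

  expect_error(ttest_vs_zero(tibble::tibble(subdivision = "x", score = 1)),
               "at least two")
})

test_that("tidiers expose model summaries", {
  set.seed(6)
  scores <- tibble::tibble(subdivision = rep(subdivision_levels(), each = 20),
                           score = rnorm(100))
  ps <- ttest_vs_zero(scores)
  expect_s3_class(ps, "preference_stats")
  td <- tidy(ps)
  expect_false(inherits(td, "preference_stats"))
  gl <- glance(ps)
  expect_equal(gl$n_subdivisions, 5)
  p <- autoplot(ps)
  expect_s3_class(p, "ggplot")
})
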