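test_that("feature variability z-scores hourly spreads per feature", {
  # one feature whose hourly s.d. is the hour-of-day index, every day
  hod <- (1:168 - 1) %% 24
  ht <- make_hourly_table(cbind(rep(0.5, 168)), sds = cbind(hod),
                          features = "energy")
  ht$mean_energy <- seq(0, 1, length.out = 168) # non-constant means
  v <- feature_variability(ht)
  u <- mean(hod); s <- sqrt(mean((hod - u)^2))
  expect_equal(v$variability, (0:23 - u) / s, tolerance = 1e-12)

  # constant hourly s.d. cannot be normalized
  ht2 <- make_hourly_table(cbind(seq(0, 1, length.out = 168)),
                           sds = cbind(rep(0.2, 168)), features = "energy")
  expect_error(feature_variability(ht2), "constant")
})

test_that("night-time spread inflation shows up as a night peak", {
  sd_night <- ifelse((1:168 - 1) %% 24 %in% c(0:5, 23), 0.4, 0.1)
  set.seed(8)
  ht <- make_hourly_table(cbind(rep(0.5, 168)),
                          sds = cbind(sd_night + runif(168, 0, 0.01)),
                          features = "energy")
  ht$mean_energy <- runif(168)
  v <- feature_variability(ht)
  night <- v$variability[v$hour %in% c(0:5, 23)]
  day <- v$variability[!v$hour %in% c(0:5, 23)]
  expect_gt(min(night), max(day))
})

test_that("diary preprocessing rounds, forward-fills and filters", {
  # single activity starting at minute 0 covers all 24 hours
  one <- tibble::tibble(person_id = "p1", start_minute = 0L,
                        activity_code = 120101L)
  h1 <- preprocess_diaries(one)
  expect_equal(nrow(h1), 24)
  expect_true(all(h1$activity_code == 120101L))

  # record at minute 75 lands in hour 1 and fills onward to the next record
  two <- tibble::tibble(person_id = "p1",
                        start_minute = c(75L, 300L),
                        activity_code = c(120101L, 130101L))
  h2 <- preprocess_diaries(two)
  expect_false(0 %in% h2$hour)                      # nothing before hour 1
  expect_equal(h2$activity_code[h2$hour %in% 1:4], rep(120101L, 4))
  expect_equal(unique(h2$activity_code[h2$hour >= 5]), 130101L)

  # sleep-only diary contributes nothing and the person is dropped
  asleep <- tibble::tibble(person_id = "p2", start_minute = 0L,
                           activity_code = 10101L)
  h3 <- preprocess_diaries(asleep)
  expect_equal(nrow(h3), 0)
  expect_equal(attr(h3, "dropped_persons"), "p2")

  # missing codes (>= 500101) are filtered too
  miss <- tibble::tibble(person_id = "p3", start_minute = c(0L, 720L),
                         activity_code = c(500101L, 120101L))
  h4 <- preprocess_diaries(miss)
  expect_true(all(h4$hour >= 12))
})

test_that("preprocess + index equals a minute-level brute-force oracle", {
  diary <- tibble::tibble(
    person_id = rep(c("a", "b", "c"), times = c(3, 2, 2)),
    start_minute = c(0L, 400L, 900L, 30L, 610L, 0L, 59L),
    activity_code = c(110101L, 120101L, 110101L,
                      120101L, 10101L,          # b falls asleep at 610
                      130101L, 110101L))
  got <- activity_diversity(preprocess_diaries(diary))

  # oracle: expand each person's day minute by minute, take the activity in
  # force at the start of each hour's rounded record, then count
  oracle_hour_codes <- function(d) {
    out <- list()
    for (p in unique(d$person_id)) {
      dd <- d[d$person_id == p, ]
      dd <- dd[order(dd$start_minute), ]
      hrs <- rep(NA_integer_, 24)
      for (i in seq_len(nrow(dd))) {
        h0 <- dd$start_minute[i] %/% 60
        hrs[(h0 + 1):24] <- dd$activity_code[i]
      }
      out[[p]] <- hrs
    }
    out
  }
  codes <- oracle_hour_codes(diary)
  for (h in 0:23) {
    at_h <- unlist(lapply(codes, `[`, h + 1))
    at_h <- at_h[!is.na(at_h) & !at_h %in% c(10101L, 10199L, 10102L) &
                   at_h < 500101L]
    if (length(at_h) == 0) {
      expect_true(is.na(got$diversity[got$hour == h]))
    } else {
      expect_equal(got$diversity[got$hour == h],
                   activity_diversity_index(as.numeric(table(at_h))))
    }
  }
})

test_that("the diversity index follows its worked definition", {
  # descending difference between proportions 0.4 and 0.3 is -0.1
  d <- diversity_differences(c(40, 30, 20, 10))
  expect_equal(d[1], -0.1)
  expect_length(d, 49)
  expect_true(all(d <= 0))

  # 50 equally common activities: perfectly diverse, index 0
  expect_equal(activity_diversity_index(rep(2, 50)), 0)

  # (0.5, 0.3, 0.2) padded to 50: differences (-0.2, -0.1, -0.2, 0 x 46)
  expect_equal(activity_diversity_index(c(5, 3, 2)), 0)
  expect_equal(diversity_differences(c(5, 3, 2))[1:3], c(-0.2, -0.1, -0.2))

  # invariant to relabelling and count scaling
  x <- c(7, 3, 2, 2, 1)
  expect_equal(activity_diversity_index(x),
               activity_diversity_index(rev(x) * 1000))

  # with full top-50 support, more uniform proportions move the index
  # towards 0 (nested majorization: uniform > gentle slope > steep slope)
  uniform <- rep(2, 50)
  gentle <- seq(100, 2, length.out = 50)
  steep <- seq(200, 2, length.out = 50)
  expect_equal(activity_diversity_index(uniform), 0)
  expect_gt(activity_diversity_index(gentle),
            activity_diversity_index(steep))
  expect_gt(0, activity_diversity_index(gentle))

  expect_error(activity_diversity_index(numeric(0)), "positive")
})

test_that("circular moving average wraps around midnight", {
  x <- rnorm(24)
  expect_equal(moving_average(x, 1), x)
  expect_equal(moving_average(rep(2, 24), 5), rep(2, 24))
  imp <- c(1, rep(0, 23))
  sm <- moving_average(imp, 3)
  expect_equal(sm[c(24, 1, 2)], rep(1 / 3, 3))
  expect_equal(sum(sm), 1)
  expect_error(moving_average(x, 4), "odd")
})

test_that("diversity-variability correlation matches the closed form", {
  d <- c(0.1, 0.4, 0.2, 0.8, 0.6, 0.9)
  expect_equal(correlate_diversity_variability(d, d)$r, 1)
  expect_equal(correlate_diversity_variability(d, -d)$r, -1)

  v <- c(0.3, 0.1, 0.5, 0.2, 0.9, 0.4)
  got <- correlate_diversity_variability(d, v)
  r <- sum((d - mean(d)) * (v - mean(v))) /
    sqrt(sum((d - mean(d))^2) * sum((v - mean(v))^2))
  tt <- r * sqrt(4 / (1 - r^2))
  expect_equal(got$r, r, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(abs(tt), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(got$df, 4)

  expect_error(correlate_diversity_variability(rep(1, 6), v), "variance")
})
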