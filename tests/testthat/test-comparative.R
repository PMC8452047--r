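traj_at <- function(t, v, a) tibble::tibble(t = t, v = v, a = a)

test_that("edge-presence filter and pair enumeration follow the 10% rule", {
  words <- tibble::tibble(
    movie_id = "m1",
    speaker = c("A", "A", "B", "B", "C", "C", "D"),
    t = c(0.05, 0.95, 0.02, 0.99, 0.08, 0.93, 0.6) # D: second half only
  )
  pairs <- eligible_pairs(words, 0.10)
  expect_equal(nrow(pairs), 3L) # C(3, 2)
  expect_false("D" %in% c(pairs$speaker_a, pairs$speaker_b))
  expect_true(all(pairs$speaker_a < pairs$speaker_b))

  solo <- tibble::tibble(movie_id = "m2", speaker = "X", t = c(0.01, 0.99))
  expect_equal(nrow(eligible_pairs(solo)), 0L)
})

test_that("discordance of identical trajectories is zero and constant offsets give the exact distance", {
  t <- seq(0.005, 0.995, by = 0.01)
  a1 <- traj_at(t, rep(0.2, length(t)), rep(0.2, length(t)))
  a2 <- traj_at(t, rep(0.5, length(t)), rep(0.6, length(t)))
  same <- discordance_series(a1, a1, 100L)
  expect_true(all(same$distance == 0))
  offs <- discordance_series(a1, a2, 100L)
  expect_equal(offs$distance, rep(0.5, 100)) # 3-4-5 triangle
  expect_equal(offs$t, (1:100 - 0.5) / 100)
})

test_that("discordance is symmetric in the pair and matches direct recomputation", {
  withr::with_seed(43, {
    ta <- traj_at(sort(runif(300)), runif(300), runif(300))
    tb <- traj_at(sort(runif(250)), runif(250), runif(250))
  })
  ab <- discordance_series(ta, tb, 50L)
  ba <- discordance_series(tb, ta, 50L)
  expect_equal(ab$distance, ba$distance, tolerance = 1e-12)
  # direct recomputation for a bin where both speakers have points
  k <- which(ab$n_a > 0 & ab$n_b > 0)[5]
  in_bin <- function(tr) tr$t > (k - 1) / 50 & tr$t <= k / 50
  va <- mean(ta$v[in_bin(ta)]); aa <- mean(ta$a[in_bin(ta)])
  vb <- mean(tb$v[in_bin(tb)]); ab2 <- mean(tb$a[in_bin(tb)])
  expect_equal(ab$distance[k], sqrt((va - vb)^2 + (aa - ab2)^2), tolerance = 1e-12)
})

test_that("interior gaps are interpolated, edge gaps stay missing, empty trajectories error", {
  # speaker occupies bins 2 and 4 of 5; bin 3 interpolated; bins 1, 5 missing
  ta <- traj_at(c(0.25, 0.65), c(0.2, 0.6), c(0.2, 0.6))
  tb <- traj_at(c(0.25, 0.45, 0.65), rep(0.2, 3), rep(0.2, 3))
  d <- discordance_series(ta, tb, 5L)
  expect_true(is.na(d$distance[1]) && is.na(d$distance[5]))
  expect_equal(d$v_a[3], 0.4) # linear midpoint between 0.2 and 0.6
  expect_error(discordance_series(traj_at(numeric(0), numeric(0), numeric(0)), tb),
               "no time bins")
})

test_that("discordance obeys the per-bin triangle inequality", {
  withr::with_seed(47, {
    mk <- function() traj_at(seq(0.005, 0.995, by = 0.01), runif(100), runif(100))
    A <- mk(); B <- mk(); C <- mk()
  })
  ab <- discordance_series(A, B, 20L)$distance
  bc <- discordance_series(B, C, 20L)$distance
  ac <- discordance_series(A, C, 20L)$distance
  expect_true(all(ac <= ab + bc + 1e-12, na.rm = TRUE))
})

test_that("density arcs are rolling category percentages over all tokens", {
  emo <- tiny_emolex()
  toks <- c(rep("rage", 3), rep("x", 27), rep("y", 10))
  words <- tibble::tibble(token = toks, t = seq_along(toks) / length(toks))
  arc <- density_arc(words, emo, "negative", window = 30L)
  expect_equal(arc$density[1], 10) # 3 of first 30
  expect_equal(nrow(arc), length(toks) - 30L + 1L)
  expect_equal(arc$density[nrow(arc)], 0)
  # brute-force recount on a random fixture
  withr::with_seed(53, {
    toks2 <- sample(c("rage", "party", "blah"), 100, replace = TRUE)
  })
  words2 <- tibble::tibble(token = toks2, t = seq_len(100) / 100)
  arc2 <- density_arc(words2, emo, "anger", window = 10L)
  brute <- vapply(1:91, function(i) 100 * sum(toks2[i:(i + 9)] == "rage") / 10, 0)
  expect_equal(arc2$density, brute, tolerance = 1e-12)
  # absent category: all-zero arc
  zero <- density_arc(words2, emo, "sadness", window = 10L)
  expect_true(all(zero$density == 0))
  expect_warning(density_arc(words2[1:5, ], emo, "anger", window = 10L), "Fewer tokens")
})

test_that("trend fitting recovers a noiseless parabola's extremum at 0.9", {
  x <- seq(0, 1, length.out = 200)
  y <- -(x - 0.9)^2
  tr <- fit_trend(x, y)
  ex <- locate_extremum(tr, "max")
  expect_equal(ex$t, 0.9, tolerance = 0.02)
  expect_false(ex$boundary)
  expect_true(ex$distinct)
})

test_that("flat and monotone inputs produce flagged extrema", {
  x <- seq(0, 1, length.out = 100)
  flat <- fit_trend(x, rep(0.3, 100))
  ev <- evaluate_trend(flat)
  expect_equal(ev$fitted, rep(0.3, 1001), tolerance = 1e-6)
  expect_false(locate_extremum(flat, "max")$distinct)

  mono <- fit_trend(x, 2 * x + 1)
  exm <- locate_extremum(mono, "max")
  expect_equal(exm$t, 1.0)
  expect_true(exm$boundary)
  expect_error(fit_trend(rep(0.5, 30), rnorm(30)), "Degenerate")
  expect_error(fit_trend(x[1:10], x[1:10]), "20 points")
})

test_that("trend fitting recovers a generating smooth curve under noise", {
  withr::with_seed(59, {
    x <- runif(400)
    f <- function(x) 0.2 + 0.1 * sin(2 * pi * x)
    y <- f(x) + rnorm(400, 0, 0.02)
  })
  tr <- fit_trend(x, y)
  grid <- seq(0.05, 0.95, by = 0.05)
  fitted <- evaluate_trend(tr, grid)$fitted
  expect_lt(max(abs(fitted - f(grid))), 0.02) # well within the noise scale
})

test_that("correlation matches the covariance formula and handles degenerate input", {
  x <- seq(0.1, 1, by = 0.1)
  expect_equal(correlate_series(x, 2 * x + 1), 1.0, tolerance = 1e-12)
  expect_equal(correlate_series(x, -x), -1.0, tolerance = 1e-12)
  withr::with_seed(61, { u <- runif(40); w <- runif(40) })
  expect_equal(correlate_series(u, w), oracle_pearson(u, w), tolerance = 1e-12)
  expect_warning(r <- correlate_series(rep(1, 10), u[1:10]), "Constant")
  expect_true(is.na(r))
  expect_warning(r2 <- correlate_series(c(1, 2), c(2, 1)), "Fewer than 3")
  expect_true(is.na(r2))
})

test_that("permutation slope check flags a real trend and passes a null", {
  withr::with_seed(67, {
    x <- runif(200)
    trend <- trend_permutation(x, 0.5 * x + rnorm(200, 0, 0.05), seed = 2L)
    null <- trend_permutation(x, rnorm(200), seed = 2L)
  })
  expect_lt(trend$p_value, 0.01)
  expect_gt(null$p_value, 0.05)
})
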