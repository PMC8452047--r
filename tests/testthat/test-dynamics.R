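test_that("emotion word density counts category words over ALL tokens", {
  emo <- tiny_emolex()
  toks <- c("party", "rage", rep("filler", 8)) # 10 tokens, 1 joy, 1 anger
  d <- emotion_word_density(toks, emo, c("joy", "anger", "negative", "surprise"))
  expect_equal(d$density, c(10, 10, 10, 0))
  two_joy <- c("party", "party", rep("x", 8))
  expect_equal(emotion_word_density(two_joy, emo, "joy")$density, 20)
  expect_true(is.na(emotion_word_density(character(0), emo, "joy")$density))
  expect_error(emotion_word_density(toks, emo, "happiness"), "Unknown")
})

test_that("dimensional density is the plain mean over covered words", {
  s <- tibble::tibble(valence = c(0.2, 0.8), arousal = c(0.3, 0.5))
  dd <- dimensional_density(s)
  expect_equal(dd$mean_valence, 0.5)
  expect_equal(dd$mean_arousal, 0.4)
  one <- dimensional_density(tibble::tibble(valence = 0.7, arousal = 0.1))
  expect_equal(one$mean_valence, 0.7)
  empty <- dimensional_density(tibble::tibble(valence = double(), arousal = double()))
  expect_true(is.na(empty$mean_valence))
  withr::with_seed(3, {
    v <- runif(37); a <- runif(37)
  })
  dd2 <- dimensional_density(tibble::tibble(valence = v, arousal = a))
  expect_equal(dd2$mean_valence, sum(v) / 37, tolerance = 1e-14)
})

test_that("variability is the population SD; 2-D variability averages the components", {
  expect_equal(emo_variability(c(0.4, 0.6)), 0.1)
  expect_equal(emo_variability(rep(0.3, 9)), 0)
  withr::with_seed(17, x <- runif(50))
  expect_equal(emo_variability(x), oracle_pop_sd(x), tolerance = 1e-14)
  traj <- tibble::tibble(v = c(0.1, 0.5), a = c(0.4, 0.6)) # SDs 0.2 and 0.1
  expect_equal(emo_variability_2d(traj), 0.15)
})

test_that("a constructed excursion yields the expected indices, lengths and rates", {
  circ <- unit_circle_ellipse()
  v <- c(rep(0, 10), 1.1, 1.2, 1.3, 1.2, 1.1, rep(0, 10))
  traj <- tibble::tibble(index = 0:24, v = v, a = 0)
  disp <- detect_displacements(traj, circ)
  expect_equal(nrow(disp), 1L)
  expect_equal(disp$length, 5L)
  expect_equal(disp$peak_distance, 0.3, tolerance = 1e-12)
  expect_equal(disp$exit_index, 9L)
  expect_equal(disp$first_out_index, 10L)
  expect_equal(disp$peak_index, 12L)
  expect_equal(disp$return_index, 15L)
  expect_equal(disp$rise_words, 3L)
  expect_equal(disp$recovery_words, 3L)
  expect_equal(disp$rise_rate, 0.1, tolerance = 1e-12)
  expect_equal(disp$recovery_rate, 0.1, tolerance = 1e-12)
  expect_false(disp$truncated)
})

test_that("fully-inside trajectories and truncated runs are handled per contract", {
  circ <- unit_circle_ellipse()
  inside <- tibble::tibble(index = 0:9, v = rep(0.1, 10), a = 0)
  expect_equal(nrow(detect_displacements(inside, circ)), 0L)

  v <- c(rep(0, 10), 1.5, 2.0) # outside run touches the trajectory end
  traj <- tibble::tibble(index = 0:11, v = v, a = 0)
  disp <- detect_displacements(traj, circ)
  expect_equal(nrow(disp), 1L)
  expect_true(disp$truncated)
  expect_true(is.na(disp$return_index))
  expect_true(is.na(disp$recovery_rate))
  expect_equal(disp$peak_distance, 1.0, tolerance = 1e-12)
})

test_that("peak ties break to the earliest index", {
  circ <- unit_circle_ellipse()
  v <- c(rep(0, 3), 1.2, 1.3, 1.3, 1.2, rep(0, 3))
  traj <- tibble::tibble(index = 0:9, v = v, a = 0)
  disp <- detect_displacements(traj, circ)
  expect_equal(disp$peak_index, 4L)
})

test_that("rates swap under time reversal of a symmetric excursion", {
  circ <- unit_circle_ellipse()
  v <- c(rep(0, 5), 1.1, 1.3, 1.2, 1.1, rep(0, 5)) # asymmetric peak position
  traj <- tibble::tibble(index = 0:13, v = v, a = 0)
  fwd <- detect_displacements(traj, circ)
  rev_traj <- tibble::tibble(index = 0:13, v = rev(v), a = 0)
  bwd <- detect_displacements(rev_traj, circ)
  expect_equal(fwd$rise_words, bwd$recovery_words)
  expect_equal(fwd$recovery_words, bwd$rise_words)
  expect_equal(fwd$rise_rate, bwd$recovery_rate)
  expect_equal(fwd$peak_distance, bwd$peak_distance)
})

test_that("displacement bookkeeping is internally consistent on random trajectories", {
  withr::with_seed(37, {
    for (rep in 1:5) {
      traj <- tibble::tibble(index = 0:299,
                             v = 0.5 + cumsum(rnorm(300, 0, 0.02)),
                             a = 0.5 + cumsum(rnorm(300, 0, 0.02)))
      ell <- home_base_2d(traj)
      disp <- detect_displacements(traj, ell)
      expect_lte(sum(disp$length), nrow(traj))
      # completed displacements = inside->outside transitions followed by a return
      inside <- ellipse_contains(ell, traj$v, traj$a)
      exits <- which(inside[-length(inside)] & !inside[-1])
      completed <- sum(vapply(exits, function(i) any(inside[(i + 1):length(inside)]), TRUE))
      expect_equal(sum(!disp$truncated), completed)
      expect_true(all(disp$peak_distance >= 0))
      ok <- !disp$truncated
      expect_true(all(disp$exit_index[ok] < disp$first_out_index[ok]))
      expect_true(all(disp$first_out_index[ok] <= disp$peak_index[ok]))
      expect_true(all(disp$peak_index[ok] < disp$return_index[ok]))
    }
  })
})

test_that("shrinking the confidence level never decreases displacement count", {
  # well-separated excursions, so a smaller home base can only add excursions
  lex <- make_lexicon(2500L)
  sim <- simulate_narrative(narrative_spec(seed = 42L), lex)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_transcript(sim$turns, tf)
  words <- build_narratives(read_transcript(tf, "tsv"))
  scored <- score_words(words[words$speaker == "HERO", ], lex$vad)
  traj <- rolling_trajectory(scored, 10L)
  counts <- vapply(c(0.95, 0.68, 0.3), function(cf) {
    ell <- home_base_2d(traj, confidence = cf)
    nrow(detect_displacements(traj, ell))
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("profiles report displacement averages only with enough usable displacements", {
  lex <- make_lexicon(2500L)
  spec <- narrative_spec(seed = 9L) # 3 well-separated events
  sim <- simulate_narrative(spec, lex)
  turns <- read_transcript(write_transcript(sim$turns, tempfile(fileext = ".tsv")), "tsv")
  words <- build_narratives(turns)
  hero <- words[words$speaker == "HERO", ]
  prof <- summarize_profile(hero, lex$vad, lex$emotions)
  expect_equal(prof$displacement_count, 3L)
  expect_true(is.na(prof$mean_peak_distance)) # 3 < min_displacements = 5
  prof2 <- summarize_profile(hero, lex$vad, lex$emotions, min_displacements = 3L)
  expect_false(is.na(prof2$mean_peak_distance))
  expect_gt(prof2$mean_peak_distance, 0)
})
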