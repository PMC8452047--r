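#' Generate a synthetic lexicon pair
#'
#' Builds a dimensional lexicon of `n_words` synthetic words (`w0001`, ...)
#' whose (valence, arousal) scores form a uniform `m x m` lattice over
#' \[0.05, 0.95\]^2 (`n_words` must be a perfect square, at least 25), plus a
#' categorical lexicon derived from deterministic thresholds: valence >= 0.7
#' flags `positive` and `joy`; valence <= 0.3 flags `negative`; arousal >=
#' 0.7 together with valence <= 0.3 additionally flags `anger` and `fear`.
#' Dominance is a constant 0.5 placeholder. The construction is fully
#' deterministic; `seed` is accepted for interface symmetry with the other
#' generators.
#'
#' @param n_words Number of words; a perfect square >= 25 (default 2500, a
#'   50 x 50 lattice whose spacing keeps word-score quantization error well
#'   below typical trajectory noise).
#' @param seed Unused; the lattice is deterministic.
#' @return A list with elements `vad` (a `vad_lexicon`) and `emotions` (an
#'   `emotion_lexicon`).
#' @export
make_lexicon <- function(n_words = 2500L, seed = NULL) {
  m <- as.integer(round(sqrt(n_words)))
  if (m * m != n_words || n_words < 25L) {
    abort("`n_words` must be a perfect square >= 25 (an exact score lattice).")
  }
  vals <- seq(0.05, 0.95, length.out = m)
  grid <- expand.grid(arousal = vals, valence = vals)[, c("valence", "arousal")]
  width <- max(4L, nchar(as.character(n_words)))
  words <- sprintf(paste0("w%0", width, "d"), seq_len(n_words))
  vad <- new_vad_lexicon(tibble::tibble(
    word = words,
    valence = grid$valence,
    arousal = grid$arousal,
    dominance = 0.5
  ), source = "synthetic-lattice")
  pos <- grid$valence >= 0.7
  neg <- grid$valence <= 0.3
  ang <- grid$arousal >= 0.7 & grid$valence <= 0.3
  entries <- dplyr::bind_rows(
    tibble::tibble(word = words[pos], emotion = "positive"),
    tibble::tibble(word = words[pos], emotion = "joy"),
    tibble::tibble(word = words[neg], emotion = "negative"),
    tibble::tibble(word = words[ang], emotion = "anger"),
    tibble::tibble(word = words[ang], emotion = "fear")
  )
  emotions <- new_emotion_lexicon(entries, words = words,
                                  source = "synthetic-lattice")
  list(vad = vad, emotions = emotions)
}

#' An empty displacement-event table
#'
#' Convenience for specifying a baseline-only narrative (no injected
#' displacements) in [narrative_spec()].
#'
#' @return A zero-row event tibble.
#' @export
no_events <- function() {
  tibble::tibble(onset = integer(), dv = double(), da = double(),
                 rise = integer(), hold = integer(), recovery = integer())
}

#' Specification of a synthetic narrative
#'
#' Describes one speaker's ground-truth emotional path: a mean-reverting
#' baseline at `center` with iid Gaussian noise (`sigma` per word and
#' coordinate) and injected displacement events. Each event is a
#' piecewise-linear bump: over `rise` words the path ramps from the center to
#' `center + (dv, da)`, holds there for `hold` words, and ramps back over
#' `recovery` words. Linear ramps make the injected rise/recovery word counts
#' exact integers, which the recovery tests rely on. Events must be separated
#' from each other and from both narrative ends by at least `3 * window`
#' words, and the displaced path must stay inside \[0, 1\]^2.
#'
#' @param center Length-2 home center (valence, arousal); default
#'   `c(0.55, 0.45)`.
#' @param sigma Baseline noise SD per word and coordinate (default 0.02).
#' @param n_words Number of focal-speaker words (default 1500).
#' @param events A tibble with columns `onset` (0-based word ordinal of the
#'   first ramp word), `dv`, `da`, `rise`, `hold`, `recovery`; default three
#'   well-separated events of amplitude 0.3 at 20%, 47% and 73% of the
#'   narrative.
#' @param turn_words Mean turn length in words; turn lengths are geometric
#'   (default 8).
#' @param window Rolling window the narrative is designed for, used only to
#'   validate event separation (default 10).
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @return A `narrative_spec` list.
#' @export
narrative_spec <- function(center = c(0.55, 0.45), sigma = 0.02,
                           n_words = 1500L, events = NULL, turn_words = 8,
                           window = 10L, seed = 1L) {
  if (is.null(events)) {
    events <- tibble::tibble(
      onset = as.integer(round(n_words * c(0.20, 0.47, 0.73))),
      dv = c(0.30, -0.30, 0),
      da = c(0, 0, 0.25),
      rise = 15L, hold = 9L, recovery = 15L
    )
  }
  spec <- structure(
    list(center = center, sigma = sigma, n_words = as.integer(n_words),
         events = events, turn_words = turn_words,
         window = as.integer(window), seed = as.integer(seed)),
    class = "narrative_spec"
  )
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  ev <- spec$events
  if (nrow(ev) > 0L) {
    end <- ev$onset + ev$rise + ev$hold + ev$recovery - 1L
    if (any(ev$onset < 3L * spec$window) ||
        any(end > spec$n_words - 1L - 3L * spec$window)) {
      abort("Events must be at least 3 * window words away from both narrative ends.")
    }
    if (nrow(ev) > 1L) {
      o <- order(ev$onset)
      gaps <- ev$onset[o][-1] - end[o][-nrow(ev)]
      if (any(gaps < 3L * spec$window)) {
        abort("Events must be separated by at least 3 * window words.")
      }
    }
    peak_v <- spec$center[1] + ev$dv
    peak_a <- spec$center[2] + ev$da
    if (any(peak_v < 0 | peak_v > 1 | peak_a < 0 | peak_a > 1)) {
      abort("Displaced path leaves [0, 1]^2; shrink the event amplitudes.")
    }
  }
  invisible(spec)
}

# noiseless target path implied by a spec: n_words x 2 matrix
spec_path <- function(spec) {
  path <- matrix(rep(spec$center, each = spec$n_words), ncol = 2)
  ev <- spec$events
  for (i in seq_len(nrow(ev))) {
    amp <- c(ev$dv[i], ev$da[i])
    prof <- c(seq_len(ev$rise[i]) / ev$rise[i],
              rep(1, ev$hold[i]),
              (ev$recovery[i] - seq_len(ev$recovery[i])) / ev$recovery[i])
    idx <- ev$onset[i] + seq_along(prof) # 1-based rows for 0-based ordinals
    path[idx, 1] <- path[idx, 1] + amp[1] * prof
    path[idx, 2] <- path[idx, 2] + amp[2] * prof
  }
  path
}

# ground-truth event table with peak/offset ordinals (0-based)
spec_events <- function(spec) {
  ev <- spec$events
  tibble::tibble(
    onset = ev$onset,
    peak = ev$onset + ev$rise - 1L,
    offset = ev$onset + ev$rise + ev$hold + ev$recovery - 1L,
    dv = ev$dv, da = ev$da,
    rise = ev$rise, hold = ev$hold, recovery = ev$recovery
  )
}

# emit the lexicon word nearest (Euclidean) to each target point, lowest
# index on ties; chunked to bound memory
nearest_words <- function(targets, vad, chunk = 512L) {
  lv <- vad$valence
  la <- vad$arousal
  idx <- integer(nrow(targets))
  for (s in seq(1L, nrow(targets), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(targets))
    d2 <- outer(targets[s:e, 1], lv, "-")^2 + outer(targets[s:e, 2], la, "-")^2
    idx[s:e] <- max.col(-d2, ties.method = "first")
  }
  vad$word[idx]
}

# draw geometric turn lengths (mean `mean_words`) until `total` is consumed
draw_turn_lengths <- function(total, mean_words) {
  lens <- integer(0)
  used <- 0L
  p <- 1 / max(mean_words, 1)
  while (used < total) {
    l <- 1L + stats::rgeom(1L, p)
    l <- min(l, total - used)
    lens <- c(lens, l)
    used <- used + l
  }
  lens
}

# interleave two token streams into alternating-speaker turns
interleave_streams <- function(tokens_list, speakers, movie_id, turn_words) {
  stopifnot(length(tokens_list) == 2L)
  lens <- lapply(tokens_list, function(x) draw_turn_lengths(length(x), turn_words))
  pos <- c(1L, 1L)
  ti <- c(1L, 1L)
  rows <- list()
  turn <- 0L
  who <- 1L
  while (any(ti <= lengths(lens))) {
    if (ti[who] > length(lens[[who]])) { who <- 3L - who; next }
    l <- lens[[who]][ti[who]]
    toks <- tokens_list[[who]][pos[who]:(pos[who] + l - 1L)]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      movie_id = movie_id, turn_order = turn, speaker = speakers[who],
      text = paste(toks, collapse = " ")
    )
    pos[who] <- pos[who] + l
    ti[who] <- ti[who] + 1L
    turn <- turn + 1L
    if (ti[3L - who] <= length(lens[[3L - who]])) who <- 3L - who
  }
  dplyr::bind_rows(rows)
}

# one focal word stream (tokens + truth) for a spec; assumes RNG already seeded
gen_stream <- function(spec, lexicons) {
  path <- spec_path(spec)
  noise <- matrix(stats::rnorm(2L * spec$n_words, 0, spec$sigma), ncol = 2)
  target <- pmin(pmax(path + noise, 0), 1)
  tokens <- nearest_words(target, lexicons$vad)
  list(
    tokens = tokens,
    path = tibble::tibble(ordinal = seq_len(spec$n_words) - 1L,
                          v = path[, 1], a = path[, 2]),
    events = spec_events(spec)
  )
}

#' Simulate one synthetic narrative
#'
#' Generates a turn-structured transcript for one focal speaker whose
#' emotional path follows `spec`, interleaved with a filler speaker (constant
#' home at (0.5, 0.5), same noise, no events) so the transcript is
#' multi-speaker. Each word's target (v, a) is the spec path plus Gaussian
#' noise; the emitted token is the lexicon word nearest in (v, a). Fully
#' reproducible from `spec$seed`.
#'
#' @param spec A [narrative_spec()].
#' @param lexicons A lexicon pair from [make_lexicon()].
#' @param movie_id Movie identifier (default `"m1"`).
#' @param focal_speaker,filler_speaker Speaker names.
#' @return A list with `turns` (transcript tibble with `movie_id`,
#'   `turn_order`, `speaker`, `text`) and `truth` (list with the focal
#'   speaker's noiseless `path`, the injected `events` with 0-based `onset`,
#'   `peak`, `offset` ordinals, and the `spec`).
#' @export
simulate_narrative <- function(spec, lexicons, movie_id = "m1",
                               focal_speaker = "HERO",
                               filler_speaker = "OTHER") {
  validate_spec(spec)
  withr::with_seed(spec$seed, {
    focal <- gen_stream(spec, lexicons)
    filler_spec <- spec
    filler_spec$center <- c(0.5, 0.5)
    filler_spec$events <- spec$events[0, ]
    filler <- gen_stream(filler_spec, lexicons)
    turns <- interleave_streams(
      list(focal$tokens, filler$tokens),
      c(focal_speaker, filler_speaker), movie_id, spec$turn_words
    )
    list(
      turns = turns,
      truth = list(speaker = focal_speaker, path = focal$path,
                   events = focal$events, spec = spec)
    )
  })
}

#' Simulate a synthetic corpus
#'
#' One movie per pair of focal speakers (`n_speakers` must be even): the two
#' speakers of a movie alternate turns, each following an independently drawn
#' variant of `template` (home center jittered by up to 0.03 per coordinate,
#' independent noise and seed). With `identical_specs = TRUE` both speakers
#' of a movie share the template spec and seed exactly, so their word
#' streams coincide and their discordance is near zero by construction.
#'
#' When `dir` is given, the transcript (TSV dialect), both lexicons (TSV) and
#' a ground-truth JSON sidecar (`events: [{onset, peak, offset, dv, da}]` per
#' speaker) are written there.
#'
#' @param n_speakers Even number of focal speakers (default 4).
#' @param lexicons From [make_lexicon()].
#' @param template A [narrative_spec()] used as the base for every speaker.
#' @param seed Master integer seed; per-speaker seeds are derived from it.
#' @param dir Optional output directory.
#' @param identical_specs Give both speakers of each movie identical specs
#'   and seeds (default `FALSE`).
#' @return A list with `turns` (all movies), `truth` (list keyed by
#'   `movie/speaker`), and `files` (paths, when `dir` was given).
#' @export
simulate_corpus <- function(n_speakers = 4L, lexicons = make_lexicon(),
                            template = narrative_spec(), seed = 1L,
                            dir = NULL, identical_specs = FALSE) {
  if (n_speakers < 2L || n_speakers %% 2L != 0L) {
    abort("`n_speakers` must be an even number >= 2.")
  }
  n_movies <- n_speakers %/% 2L
  master <- withr::with_seed(seed, {
    list(
      speaker_seeds = sample.int(.Machine$integer.max - 1L, n_speakers),
      jitter = matrix(stats::runif(2L * n_speakers, -0.03, 0.03), ncol = 2)
    )
  })
  turns <- list()
  truth <- list()
  for (mv in seq_len(n_movies)) {
    ids <- c(2L * mv - 1L, 2L * mv)
    speakers <- sprintf("CHAR_%02d", ids)
    movie_id <- sprintf("movie_%02d", mv)
    specs <- lapply(seq_along(ids), function(j) {
      sp <- template
      if (identical_specs) {
        sp$seed <- master$speaker_seeds[ids[1]]
      } else {
        sp$center <- template$center + master$jitter[ids[j], ]
        sp$seed <- master$speaker_seeds[ids[j]]
      }
      validate_spec(sp)
      sp
    })
    streams <- lapply(specs, function(sp) {
      withr::with_seed(sp$seed, gen_stream(sp, lexicons))
    })
    mv_turns <- withr::with_seed(master$speaker_seeds[ids[1]] %% 1000003L, {
      interleave_streams(
        list(streams[[1]]$tokens, streams[[2]]$tokens),
        speakers, movie_id, template$turn_words
      )
    })
    turns[[mv]] <- mv_turns
    for (j in 1:2) {
      truth[[paste(movie_id, speakers[j], sep = "/")]] <- list(
        movie_id = movie_id, speaker = speakers[j],
        path = streams[[j]]$path, events = streams[[j]]$events,
        spec = specs[[j]]
      )
    }
  }
  out <- list(turns = dplyr::bind_rows(turns), truth = truth, files = NULL)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list(
      transcript = file.path(dir, "transcript.tsv"),
      vad = file.path(dir, "vad_lexicon.tsv"),
      emotions = file.path(dir, "emotion_lexicon.tsv"),
      truth = file.path(dir, "ground_truth.json")
    )
    write_transcript(out$turns, files$transcript)
    write_vad_lexicon(lexicons$vad, files$vad)
    write_emotion_lexicon(lexicons$emotions, files$emotions)
    sidecar <- lapply(truth, function(tr) {
      list(movie_id = tr$movie_id, speaker = tr$speaker,
           events = tr$events[, c("onset", "peak", "offset", "dv", "da")])
    })
    jsonlite::write_json(sidecar, files$truth, auto_unbox = TRUE, digits = NA)
    out$files <- files
  }
  out
}
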