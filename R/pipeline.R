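#' Analysis run configuration
#'
#' Bundles the inputs and tuning parameters of a full analysis run. The
#' defaults are the framework's standard settings: main characters need at
#' least 50 turns, trajectories use a 10-word rolling window, density arcs a
#' 30-word window, home bases 68% coverage, discordance 100 narrative-time
#' bins with a 10% edge-presence filter, and displacement averages require 5
#' usable displacements.
#'
#' @param transcripts Character vector of transcript paths.
#' @param vad Path to the dimensional lexicon TSV.
#' @param emolex Path to the categorical lexicon TSV (optional).
#' @param min_turns,window,density_window,confidence,n_bins,min_displacements,edge_fraction
#'   Tuning parameters; see the respective metric functions.
#' @param stat_basis `"trajectory"` or `"raw"` statistics basis.
#' @param out Output directory for CSV/JSON artifacts.
#' @param seed Integer seed for any randomized step (e.g. permutation
#'   checks).
#' @return A `ued_config` list.
#' @export
ued_config <- function(transcripts, vad, emolex = NULL, min_turns = 50L,
                       window = 10L, density_window = 30L, confidence = 0.68,
                       n_bins = 100L, min_displacements = 5L,
                       edge_fraction = 0.10,
                       stat_basis = c("trajectory", "raw"),
                       out = ".", seed = 1L) {
  stat_basis <- match.arg(stat_basis)
  check_window(window); check_window(density_window); check_window(n_bins)
  check_confidence(confidence)
  for (p in c(transcripts, vad, emolex)) {
    if (!file.exists(p)) abort(sprintf("Input file '%s' does not exist.", p))
  }
  structure(
    list(transcripts = transcripts, vad = vad, emolex = emolex,
         min_turns = as.integer(min_turns), window = as.integer(window),
         density_window = as.integer(density_window),
         confidence = confidence, n_bins = as.integer(n_bins),
         min_displacements = as.integer(min_displacements),
         edge_fraction = edge_fraction, stat_basis = stat_basis,
         out = out, seed = as.integer(seed)),
    class = "ued_config"
  )
}

read_config_inputs <- function(config) {
  vad <- read_vad_lexicon(config$vad)
  emolex <- if (!is.null(config$emolex)) read_emotion_lexicon(config$emolex) else NULL
  turns <- purrr::map_dfr(config$transcripts, function(p) {
    dialect <- if (grepl("\\.jsonl$", p)) "jsonl" else "tsv"
    read_transcript(p, dialect)
  })
  inform(sprintf("stage=read movies=%d turns=%d",
                 length(unique(turns$movie_id)), nrow(turns)))
  list(vad = vad, emolex = emolex, turns = turns)
}

#' Run the per-speaker profile pipeline
#'
#' Reads the configured lexicons and transcripts, computes a UED profile per
#' main character, and writes `profiles.csv` (one row per speaker) and
#' `displacements.csv` (one row per displacement) to the output directory.
#' Stage counters (movies read, turns merged, characters selected, VAD
#' coverage) are logged via `message()` in a machine-parsable
#' `stage=... key=value` form. Deterministic given inputs and config.
#'
#' @param config A [ued_config()].
#' @return Invisibly, a list with `profiles` and `displacements` tibbles.
#' @export
run_profiles <- function(config) {
  stopifnot(inherits(config, "ued_config"))
  inp <- read_config_inputs(config)
  mains <- select_main_characters(inp$turns, config$min_turns)
  inform(sprintf("stage=select characters=%d min_turns=%d",
                 nrow(mains), config$min_turns))
  profiles <- ued_profiles(
    inp$turns, inp$vad, inp$emolex, min_turns = config$min_turns,
    window = config$window, confidence = config$confidence,
    min_displacements = config$min_displacements,
    stat_basis = config$stat_basis
  )
  if (nrow(profiles) > 0L && "n_vad_words" %in% names(profiles)) {
    inform(sprintf("stage=score vad_coverage=%.4f",
                   sum(profiles$n_vad_words) / sum(profiles$n_tokens)))
  }
  if (!dir.exists(config$out)) dir.create(config$out, recursive = TRUE)
  disp <- if (nrow(profiles) > 0L && "displacements" %in% names(profiles)) {
    profiles |>
      dplyr::select("movie_id", "speaker", "displacements") |>
      tidyr::unnest("displacements")
  } else {
    tibble::tibble()
  }
  flat <- profiles[, setdiff(names(profiles), "displacements")]
  readr::write_csv(flat, file.path(config$out, "profiles.csv"))
  readr::write_csv(disp, file.path(config$out, "displacements.csv"))
  inform(sprintf("stage=write profiles=%d displacements=%d out=%s",
                 nrow(flat), nrow(disp), config$out))
  invisible(list(profiles = profiles, displacements = disp))
}

#' Run the pairwise discordance pipeline
#'
#' Restricts each movie to main characters present in both the first and last
#' `edge_fraction` of narrative time, computes the binned discordance series
#' for every eligible pair, fits an aggregate penalized-spline trend of
#' discordance on narrative time, and locates its maximum. Writes
#' `discordance.csv` (`movie,speaker_a,speaker_b,bin,t,distance`),
#' `discordance_trend.csv` (`t,fitted`) and `discordance_extremum.json`.
#' With no eligible pairs the report states `"none"` and the run still
#' succeeds.
#'
#' @param config A [ued_config()].
#' @return Invisibly, a list with `discordance`, `trend` and `extremum`.
#' @export
run_discordance <- function(config) {
  stopifnot(inherits(config, "ued_config"))
  inp <- read_config_inputs(config)
  mains <- select_main_characters(inp$turns, config$min_turns)
  words <- build_narratives(inp$turns, mains)
  pairs <- eligible_pairs(words, config$edge_fraction)
  inform(sprintf("stage=pairs eligible=%d", nrow(pairs)))
  if (!dir.exists(config$out)) dir.create(config$out, recursive = TRUE)
  if (nrow(pairs) == 0L) {
    readr::write_csv(
      tibble::tibble(movie = character(), speaker_a = character(),
                     speaker_b = character(), bin = integer(), t = double(),
                     distance = double()),
      file.path(config$out, "discordance.csv")
    )
    jsonlite::write_json(list(extremum = "none"),
                         file.path(config$out, "discordance_extremum.json"),
                         auto_unbox = TRUE)
    return(invisible(list(discordance = tibble::tibble(), trend = NULL,
                          extremum = "none")))
  }
  scored <- score_words(words, inp$vad)
  traj <- suppressWarnings(rolling_trajectory(scored, config$window))
  disc <- purrr::pmap_dfr(pairs, function(movie_id, speaker_a, speaker_b) {
    ta <- traj[traj$movie_id == movie_id & traj$speaker == speaker_a, ]
    tb <- traj[traj$movie_id == movie_id & traj$speaker == speaker_b, ]
    if (nrow(ta) == 0L || nrow(tb) == 0L) return(tibble::tibble())
    discordance_series(ta, tb, config$n_bins) |>
      dplyr::transmute(movie = movie_id, speaker_a = speaker_a,
                       speaker_b = speaker_b, bin = .data$bin, t = .data$t,
                       distance = .data$distance)
  })
  readr::write_csv(disc, file.path(config$out, "discordance.csv"))
  ok <- !is.na(disc$distance)
  trend <- NULL
  extremum <- "none"
  if (sum(ok) >= 20L && diff(range(disc$t[ok])) >= 0.5) {
    trend <- fit_trend(disc$t[ok], disc$distance[ok])
    readr::write_csv(evaluate_trend(trend),
                     file.path(config$out, "discordance_trend.csv"))
    extremum <- locate_extremum(trend, "max")
    jsonlite::write_json(
      list(category = "discordance", argmax_t = extremum$t,
           boundary = extremum$boundary, distinct = extremum$distinct),
      file.path(config$out, "discordance_extremum.json"),
      auto_unbox = TRUE, digits = NA
    )
  } else {
    jsonlite::write_json(list(extremum = "none"),
                         file.path(config$out, "discordance_extremum.json"),
                         auto_unbox = TRUE)
  }
  inform(sprintf("stage=discordance rows=%d", nrow(disc)))
  invisible(list(discordance = disc, trend = trend, extremum = extremum))
}
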