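#' Read a turn-structured dialogue transcript
#'
#' Reads dialogue records (`movie_id`, `turn_order`, `speaker`, `text`) from
#' TSV (with header) or JSON-Lines (one object per line with those keys) and
#' groups them into turns. A turn is a maximal run of uninterrupted records
#' by the same speaker: consecutive records by one speaker are merged, their
#' text concatenated with a single space. Applying the reader to already
#' merged turns changes nothing.
#'
#' @param path Path to the transcript file.
#' @param dialect `"tsv"` or `"jsonl"`.
#' @return A tibble of turns with columns `movie_id`, `turn_index` (0-based,
#'   movie-global), `speaker`, `text`, `n_merged` (records merged into the
#'   turn), ordered by movie and turn.
#' @export
read_transcript <- function(path, dialect = c("tsv", "jsonl")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("Transcript file '%s' not found.", path))
  if (dialect == "tsv") {
    recs <- readr::read_tsv(path, col_types = readr::cols(
      movie_id = readr::col_character(),
      turn_order = readr::col_double(),
      speaker = readr::col_character(),
      text = readr::col_character()
    ), progress = FALSE)
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) abort(sprintf("Transcript file '%s' is empty.", path))
    recs <- purrr::map_dfr(seq_along(lines), function(i) {
      obj <- jsonlite::fromJSON(lines[i])
      tibble::tibble(
        movie_id = as.character(obj$movie_id %||% NA_character_),
        turn_order = as.numeric(obj$turn_order %||% NA_real_),
        speaker = as.character(obj$speaker %||% NA_character_),
        text = as.character(obj$text %||% NA_character_)
      )
    })
  }
  if (nrow(recs) == 0L) abort(sprintf("Transcript file '%s' is empty.", path))
  missing_fields <- c("movie_id", "turn_order", "speaker", "text")
  for (f in missing_fields) {
    bad <- which(is.na(recs[[f]]))
    if (length(bad) > 0L) {
      abort(sprintf("Record %d of '%s' is missing required field '%s'.",
                    bad[1], path, f))
    }
  }
  group_turns(recs)
}

# Merge consecutive same-speaker records into turns, per movie.
group_turns <- function(records) {
  records |>
    dplyr::arrange(.data$movie_id, .data$turn_order) |>
    dplyr::group_by(.data$movie_id) |>
    dplyr::mutate(
      .run = cumsum(c(TRUE, .data$speaker[-1] != .data$speaker[-dplyr::n()]))
    ) |>
    dplyr::group_by(.data$movie_id, .data$.run) |>
    dplyr::summarise(
      speaker = .data$speaker[1],
      text = paste(.data$text, collapse = " "),
      n_merged = dplyr::n(),
      .groups = "drop_last"
    ) |>
    dplyr::mutate(turn_index = .data$.run - 1L) |>
    dplyr::ungroup() |>
    dplyr::select("movie_id", "turn_index", "speaker", "text", "n_merged")
}

#' Tokenize utterance text
#'
#' Lowercases, splits on every non-alphanumeric character (so punctuation is
#' stripped and apostrophes split words into separate fragments; one-character
#' fragments are retained — lexicon lookup simply misses non-words), and
#' passes each token through `lemmatizer`. The default lemmatizer is the
#' identity, keeping the pipeline free of external model downloads; plug in
#' any `function(tokens) tokens` normalizer (e.g. a WordNet-style
#' lemmatizer) to match your lexicon's conventions.
#'
#' @param text Character vector of utterances.
#' @param lemmatizer A vectorized `function(character) character`, or `NULL`
#'   for the identity.
#' @return A list of character vectors (one per input element).
#' @examples
#' tokenize_text("I'm so happy!")  # list(c("i", "m", "so", "happy"))
#' @export
tokenize_text <- function(text, lemmatizer = NULL) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")
  toks <- lapply(toks, function(x) x[nzchar(x)])
  if (!is.null(lemmatizer)) toks <- lapply(toks, lemmatizer)
  toks
}

#' Select main characters by turn count
#'
#' Speakers with at least `min_turns` turns in a movie; the threshold is
#' inclusive.
#'
#' @param turns A turns tibble from [read_transcript()].
#' @param min_turns Minimum turn count (default 50).
#' @return A tibble with columns `movie_id`, `speaker`, `n_turns` for the
#'   qualifying speakers.
#' @export
select_main_characters <- function(turns, min_turns = 50L) {
  if (length(min_turns) != 1L || is.na(min_turns) || min_turns < 1) {
    abort("`min_turns` must be a single integer >= 1.")
  }
  turns |>
    dplyr::count(.data$movie_id, .data$speaker, name = "n_turns") |>
    dplyr::filter(.data$n_turns >= min_turns)
}

#' Build per-speaker word narratives
#'
#' Tokenizes every turn, assigns each token its movie-global 0-based word
#' position (enumerating all tokens of the movie in turn order), and returns
#' the long word table for the selected speakers. Word positions of
#' non-selected speakers still advance the global counter, so positions and
#' normalized times refer to the full movie.
#'
#' @param turns A turns tibble from [read_transcript()].
#' @param speakers Optional tibble with `movie_id`, `speaker` (e.g. from
#'   [select_main_characters()]); `NULL` keeps all speakers.
#' @param lemmatizer Passed to [tokenize_text()].
#' @return A tibble with columns `movie_id`, `speaker`, `turn_index`,
#'   `token`, `global_pos` (0-based, movie-global), `word_ordinal` (0-based
#'   within speaker), `t` (normalized narrative time on the movie-global
#'   axis), `movie_total_tokens`.
#' @export
build_narratives <- function(turns, speakers = NULL, lemmatizer = NULL) {
  toks <- tokenize_text(turns$text, lemmatizer)
  words <- turns |>
    dplyr::mutate(token = toks) |>
    tidyr::unnest("token") |>
    dplyr::group_by(.data$movie_id) |>
    dplyr::mutate(
      global_pos = seq_len(dplyr::n()) - 1L,
      movie_total_tokens = dplyr::n()
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(t = (.data$global_pos + 0.5) / .data$movie_total_tokens)
  if (!is.null(speakers)) {
    words <- dplyr::semi_join(words, speakers, by = c("movie_id", "speaker"))
  }
  words |>
    dplyr::group_by(.data$movie_id, .data$speaker) |>
    dplyr::mutate(word_ordinal = seq_len(dplyr::n()) - 1L) |>
    dplyr::ungroup() |>
    dplyr::select("movie_id", "speaker", "turn_index", "token",
                  "global_pos", "word_ordinal", "t", "movie_total_tokens")
}

#' Write a transcript in the TSV dialect
#'
#' @param turns A turns tibble (or raw records with a `turn_order` column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(turns, path) {
  out <- turns
  if (!"turn_order" %in% names(out) && "turn_index" %in% names(out)) {
    out <- dplyr::rename(out, turn_order = "turn_index")
  }
  readr::write_tsv(out[, c("movie_id", "turn_order", "speaker", "text")], path)
  invisible(path)
}
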