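#' @title Word-emotion lexicons
#' @description Readers, writers and query helpers for the two tab-separated
#'   lexicon dialects used throughout the package: the dimensional dialect
#'   (`word<TAB>valence<TAB>arousal<TAB>dominance`, scores in \[0, 1\]) and
#'   the categorical long dialect (`word<TAB>emotion<TAB>flag` with binary
#'   flags over eight basic emotions plus negative/positive sentiment).
#' @name lexicons
NULL

#' The fixed categorical emotion label set
#'
#' Eight basic emotions plus the two sentiment polarities. Categorical
#' lexicon rows must use labels from this set.
#'
#' @export
EMOTION_CATEGORIES <- c(
  "anger", "anticipation", "disgust", "fear", "joy",
  "sadness", "surprise", "trust", "negative", "positive"
)

new_vad_lexicon <- function(entries, source = NA_character_) {
  out <- tibble::new_tibble(entries, class = "vad_lexicon")
  attr(out, "source") <- source
  out
}

new_emotion_lexicon <- function(entries, words, source = NA_character_) {
  out <- tibble::new_tibble(entries, class = "emotion_lexicon")
  attr(out, "words") <- words
  attr(out, "source") <- source
  out
}

# A first row whose numeric columns fail to parse is treated as a header;
# both lexicon dialects circulate with and without headers.
read_tsv_raw <- function(path, n_cols) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(NULL)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != n_cols)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Line %d of '%s': expected %d tab-separated fields, found %d.",
      bad[1], path, n_cols, length(parts[[bad[1]]])
    ))
  }
  mat <- matrix(unlist(parts), ncol = n_cols, byrow = TRUE)
  tibble::tibble(line = seq_along(lines), mat = mat)
}

#' Read a dimensional (valence-arousal-dominance) lexicon
#'
#' Reads the tab-separated dimensional dialect
#' `word<TAB>valence<TAB>arousal<TAB>dominance`. A header row, if present, is
#' auto-detected (its numeric columns fail to parse) and skipped. Scores must
#' lie in \[0, 1\]. Duplicated words keep their first occurrence, with one
#' warning reporting the count. Dominance is parsed and stored but not used
#' by any downstream metric.
#'
#' @param path Path to the TSV file.
#' @return A `vad_lexicon`: a tibble with columns `word`, `valence`,
#'   `arousal`, `dominance`, one row per unique word (lowercased).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines("nice\t0.93\t0.44\t0.65", tf)
#' lex <- read_vad_lexicon(tf)
#' get_scores(lex, "nice")
#' @export
read_vad_lexicon <- function(path) {
  raw <- read_tsv_raw(path, 4L)
  if (is.null(raw)) {
    warn(sprintf("'%s' is empty; returning an empty lexicon.", path))
    return(new_vad_lexicon(
      tibble::tibble(word = character(), valence = double(),
                     arousal = double(), dominance = double()),
      source = path
    ))
  }
  mat <- raw$mat
  num1 <- suppressWarnings(as.numeric(mat[1, 2:4]))
  if (anyNA(num1)) { # header row
    mat <- mat[-1, , drop = FALSE]
    raw <- raw[-1, , drop = FALSE]
    if (nrow(mat) == 0L) {
      warn(sprintf("'%s' contains only a header; returning an empty lexicon.", path))
      return(new_vad_lexicon(
        tibble::tibble(word = character(), valence = double(),
                       arousal = double(), dominance = double()),
        source = path
      ))
    }
  }
  scores <- suppressWarnings(matrix(as.numeric(mat[, 2:4]), ncol = 3L))
  bad <- which(rowSums(is.na(scores)) > 0L)
  if (length(bad) > 0L) {
    abort(sprintf("Line %d of '%s': unparsable numeric score.",
                  raw$line[bad[1]], path))
  }
  oob <- which(scores < 0 | scores > 1, arr.ind = TRUE)
  if (nrow(oob) > 0L) {
    i <- oob[1, 1]
    abort(sprintf(
      "Line %d of '%s': score %s outside [0, 1].",
      raw$line[i], path,
      format(scores[i, oob[1, 2]])
    ))
  }
  words <- tolower(mat[, 1])
  dup <- duplicated(words)
  if (any(dup)) {
    warn(sprintf("%d duplicated word(s) in '%s'; keeping first occurrences.",
                 sum(dup), path))
  }
  keep <- !dup
  new_vad_lexicon(
    tibble::tibble(word = words[keep], valence = scores[keep, 1],
                   arousal = scores[keep, 2], dominance = scores[keep, 3]),
    source = path
  )
}

#' Read a categorical word-emotion lexicon
#'
#' Reads the long tab-separated dialect `word<TAB>emotion<TAB>flag`, where
#' `emotion` is one of [EMOTION_CATEGORIES] and `flag` is 0 or 1. A word's
#' category set is the set of labels flagged 1; a word whose rows are all 0
#' is still recorded as covered (empty category set).
#'
#' @param path Path to the TSV file.
#' @return An `emotion_lexicon`: a tibble with columns `word`, `emotion`
#'   containing the flagged (word, label) pairs; the full set of covered
#'   words (including all-zero words) is kept in `attr(, "words")`.
#' @export
read_emotion_lexicon <- function(path) {
  raw <- read_tsv_raw(path, 3L)
  if (is.null(raw)) {
    warn(sprintf("'%s' is empty; returning an empty lexicon.", path))
    return(new_emotion_lexicon(
      tibble::tibble(word = character(), emotion = character()),
      words = character(), source = path
    ))
  }
  mat <- raw$mat
  flag1 <- suppressWarnings(as.numeric(mat[1, 3]))
  if (is.na(flag1)) { # header row: its flag column fails to parse
    mat <- mat[-1, , drop = FALSE]
    raw <- raw[-1, , drop = FALSE]
  }
  if (nrow(mat) == 0L) {
    warn(sprintf("'%s' contains only a header; returning an empty lexicon.", path))
    return(new_emotion_lexicon(
      tibble::tibble(word = character(), emotion = character()),
      words = character(), source = path
    ))
  }
  emo <- tolower(mat[, 2])
  unknown <- which(!emo %in% EMOTION_CATEGORIES)
  if (length(unknown) > 0L) {
    abort(sprintf("Line %d of '%s': unknown emotion label '%s'.",
                  raw$line[unknown[1]], path, mat[unknown[1], 2]))
  }
  flags <- suppressWarnings(as.numeric(mat[, 3]))
  badflag <- which(is.na(flags) | !(flags %in% c(0, 1)))
  if (length(badflag) > 0L) {
    abort(sprintf("Line %d of '%s': flag '%s' is not 0 or 1.",
                  raw$line[badflag[1]], path, mat[badflag[1], 3]))
  }
  words <- tolower(mat[, 1])
  entries <- tibble::tibble(word = words, emotion = emo)[flags == 1, ]
  entries <- dplyr::distinct(entries)
  new_emotion_lexicon(entries, words = unique(words), source = path)
}

#' Look up valence and arousal scores
#'
#' Case-normalized lookup in a dimensional lexicon. Words without an entry
#' are returned with `NA` scores (an explicit "no entry", never a default
#' score) and `covered = FALSE`.
#'
#' @param lexicon A `vad_lexicon`.
#' @param words Character vector of words.
#' @return A tibble with columns `word`, `valence`, `arousal`, `covered`,
#'   one row per input word, in input order.
#' @export
get_scores <- function(lexicon, words) {
  stopifnot(inherits(lexicon, "vad_lexicon"))
  w <- tolower(words)
  idx <- match(w, lexicon$word)
  tibble::tibble(
    word = w,
    valence = lexicon$valence[idx],
    arousal = lexicon$arousal[idx],
    covered = !is.na(idx)
  )
}

#' Look up categorical emotion labels
#'
#' @param lexicon An `emotion_lexicon`.
#' @param word A single word.
#' @return Character vector of flagged categories (possibly empty), or `NULL`
#'   if the word is not covered by the lexicon at all.
#' @export
get_categories <- function(lexicon, word) {
  stopifnot(inherits(lexicon, "emotion_lexicon"), length(word) == 1L)
  w <- tolower(word)
  if (!w %in% attr(lexicon, "words")) return(NULL)
  sort(lexicon$emotion[lexicon$word == w])
}

#' Lexicon coverage of a token stream
#'
#' Fraction of tokens that have a lexicon entry.
#'
#' @param lexicon A `vad_lexicon` or `emotion_lexicon`.
#' @param tokens Character vector of tokens.
#' @return A single value in \[0, 1\]; `NA` for an empty token stream.
#' @export
lexicon_coverage <- function(lexicon, tokens) {
  if (length(tokens) == 0L) return(NA_real_)
  vocab <- if (inherits(lexicon, "vad_lexicon")) lexicon$word else attr(lexicon, "words")
  mean(tolower(tokens) %in% vocab)
}

#' Remove words from a lexicon
#'
#' Editing hook for curating lexicons before analysis (for example dropping
#' entries whose dominant sense or bias does not suit the target domain).
#'
#' @param lexicon A `vad_lexicon` or `emotion_lexicon`.
#' @param words Character vector of words to drop (case-insensitive).
#' @return The lexicon without those words.
#' @export
remove_words <- function(lexicon, words) {
  w <- tolower(words)
  if (inherits(lexicon, "vad_lexicon")) {
    new_vad_lexicon(lexicon[!lexicon$word %in% w, ],
                    source = attr(lexicon, "source"))
  } else if (inherits(lexicon, "emotion_lexicon")) {
    new_emotion_lexicon(lexicon[!lexicon$word %in% w, ],
                        words = setdiff(attr(lexicon, "words"), w),
                        source = attr(lexicon, "source"))
  } else {
    abort("`lexicon` must be a vad_lexicon or emotion_lexicon.")
  }
}

#' Write lexicons back to their TSV dialects
#'
#' Round-trip companions to [read_vad_lexicon()] and
#' [read_emotion_lexicon()]; reloading a written lexicon reproduces the
#' entry map exactly.
#'
#' @param lexicon The lexicon object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vad_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "vad_lexicon"))
  readr::write_tsv(as.data.frame(lexicon), path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_vad_lexicon
#' @export
write_emotion_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "emotion_lexicon"))
  full <- tidyr::expand_grid(word = attr(lexicon, "words"),
                             emotion = EMOTION_CATEGORIES)
  full$flag <- as.integer(
    paste(full$word, full$emotion) %in% paste(lexicon$word, lexicon$emotion)
  )
  readr::write_tsv(full, path, col_names = FALSE)
  invisible(path)
}
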