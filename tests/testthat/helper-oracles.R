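# Independent brute-force oracles. Each recomputes a quantity directly from
# its definition, without sharing code with the implementation under test.

oracle_rolling_mean <- function(x, w) {
  n <- length(x)
  if (n < w) return(numeric(0))
  vapply(seq_len(n - w + 1L), function(i) sum(x[i:(i + w - 1L)]) / w, 0)
}

oracle_pop_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / length(x))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Radial point-to-ellipse distance by dense sampling of the ray from the
# center through the point: finds the quadratic-form crossing q = 1 among
# 1e5 samples and interpolates on sqrt(q) (linear along the ray).
oracle_radial_distance <- function(ellipse, p) {
  ctr <- ellipse$center
  d <- p - ctr
  len <- sqrt(sum(d^2))
  if (len == 0) return(0)
  s <- seq(0, 2 * len + 10 * max(ellipse$semi_major, len), length.out = 1e5)
  e <- ellipse$eigenvectors
  q <- vapply(s, function(si) {
    x <- si * d / len
    u1 <- x[1] * e[1, 1] + x[2] * e[2, 1]
    u2 <- x[1] * e[1, 2] + x[2] * e[2, 2]
    u1^2 / (ellipse$psi * ellipse$eigenvalues[1]) +
      u2^2 / (ellipse$psi * ellipse$eigenvalues[2])
  }, 0)
  i <- which(q >= 1)[1]
  r <- if (i == 1L) 0 else {
    s[i - 1] + (s[i] - s[i - 1]) * (1 - sqrt(q[i - 1])) / (sqrt(q[i]) - sqrt(q[i - 1]))
  }
  max(0, len - r)
}

# minimal in-memory fixtures --------------------------------------------------

tiny_vad <- function() {
  tf <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c(
    "nice\t0.93\t0.44\t0.65",
    "bad\t0.10\t0.60\t0.40",
    "calm\t0.70\t0.10\t0.50",
    "rage\t0.05\t0.95\t0.30"
  ), tf)
  read_vad_lexicon(tf)
}

tiny_emolex <- function() {
  tf <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c(
    "party\tjoy\t1", "party\tpositive\t1", "party\tanger\t0",
    "rage\tanger\t1", "rage\tnegative\t1",
    "table\tjoy\t0", "table\tanger\t0"
  ), tf)
  read_emotion_lexicon(tf)
}

make_turns <- function(records) {
  # records: list of c(movie, speaker, text); turn_order = sequence
  tf <- tempfile(fileext = ".tsv")
  df <- data.frame(
    movie_id = vapply(records, `[`, "", 1),
    turn_order = seq_along(records),
    speaker = vapply(records, `[`, "", 2),
    text = vapply(records, `[`, "", 3)
  )
  readr::write_tsv(df, tf)
  on.exit(unlink(tf))
  read_transcript(tf, "tsv")
}

# a unit circle "ellipse" centered at the origin, for closed-form checks
unit_circle_ellipse <- function(center = c(0, 0), r = 1) {
  structure(
    list(center = stats::setNames(center, c("v", "a")),
         eigenvalues = c(r^2, r^2) / stats::qchisq(0.68, 2),
         eigenvectors = diag(2),
         psi = stats::qchisq(0.68, 2),
         semi_major = r, semi_minor = r, theta = 0,
         confidence = 0.68, n = 0L),
    class = "home_base_ellipse"
  )
}

# arbitrary ellipse with given semi-axes and rotation, bypassing fitting
manual_ellipse <- function(center, A, B, theta = 0) {
  psi <- stats::qchisq(0.68, 2)
  e1 <- c(cos(theta), sin(theta))
  e2 <- c(-sin(theta), cos(theta))
  structure(
    list(center = stats::setNames(center, c("v", "a")),
         eigenvalues = c(A^2, B^2) / psi,
         eigenvectors = cbind(e1, e2, deparse.level = 0),
         psi = psi, semi_major = A, semi_minor = B, theta = theta,
         confidence = 0.68, n = 0L),
    class = "home_base_ellipse"
  )
}
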