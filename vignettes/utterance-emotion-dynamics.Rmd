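---
title: "Utterance emotion dynamics: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Utterance emotion dynamics: models, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uedyn)
library(dplyr)
```

## The model

Utterance emotion dynamics (UED) treats the words a speaker utters, in
order, as repeated indirect measurements of their emotional state. Each
word is scored on two dimensions from a word–emotion lexicon: *valence*
(0 = extremely unpleasant, 1 = extremely pleasant) and *arousal* (0 =
sluggish, 1 = activated). Only words with a lexicon entry ("VAD words")
carry information; everything else is ignored. A dominance score is parsed
and stored but not used by any metric.

Single word scores are noisy, so the speaker's *location* in
valence–arousal space at word $k$ is defined as the trailing rolling mean of
the last $w$ scored words (default $w = 10$). The path of this location over
narrative time is the speaker's *emotional trajectory*. All higher-level
metrics are functionals of this trajectory:

* **Home base.** The high-probability region of the trajectory. In one
  dimension it is the confidence band
  $\bar v \pm t_{1-(1-c)/2,\,N-1}\sqrt{\sigma^2/N}$, with $\sigma^2$ the
  population (divide-by-$N$) variance of the series and $c$ the coverage
  (default 0.68, roughly one standard error). In two dimensions it is the
  covariance confidence ellipse: center at the component means, axes along
  the eigenvectors of the population covariance matrix, semi-axes
  $\sqrt{\psi\lambda_j}$ with $\psi$ the $\chi^2_2$ quantile at coverage $c$
  ($\approx 2.2789$ at 0.68). A point is inside when its quadratic form in
  principal-axis coordinates is at most 1.
* **Emotional variability.** The population standard deviation of the
  trajectory component; in two dimensions, the mean of the valence and
  arousal SDs.
* **Displacements.** Maximal runs of consecutive trajectory points outside
  the home base, bounded by inside points on both sides. The *peak* is the
  outside point farthest from the home-base perimeter (earliest index on
  ties); *rise words* count from the last inside point to the peak and
  *recovery words* from the peak to the first inside point after, so both
  are at least 1; the *rise/recovery rates* divide peak distance by those
  counts. Runs touching a trajectory end are flagged truncated and excluded
  from averages.
* **Emotion word density.** The percentage of a speaker's tokens (all
  tokens, not just VAD words) carrying a categorical emotion label
  (eight basic emotions plus negative/positive sentiment).
* **Discordance.** For two speakers of the same narrative, the Euclidean
  distance between their binned trajectory positions at matched normalized
  narrative time.

## Statistical conventions the package fixes

Several conventions in this framework are genuinely open; the package fixes
them as follows and exposes options where both readings are defensible.

* **Population variance everywhere.** The variability definition uses the
  $1/N$ denominator, and the same convention is used in the 1-D band and
  the 2-D covariance for internal consistency. For the trajectory lengths
  involved (hundreds of points) the difference from $1/(N-1)$ is
  negligible.
* **Two-sided critical values.** Coverage $c$ maps to the $t$ quantile at
  $1 - (1-c)/2$ with $N-1$ degrees of freedom, and to the $\chi^2_2$
  quantile at $c$. Monte-Carlo coverage checks in the test suite (1-D band
  over 1000 replicates of $N = 50$; 2-D ellipse over $n = 2000$ bivariate
  Gaussian points) confirm both hit their nominal 68%.
* **Trajectory-based statistics.** Home bases and variability are computed
  over the rolling trajectory points by default (the home base is where the
  *location* — a windowed average — is likely to be), with
  `stat_basis = "raw"` available to use raw word scores instead.
* **Radial perimeter distance.** Distance from a point to the ellipse is
  measured along the ray from the ellipse center through the point:
  $\max(0,\,\lVert p - c\rVert - r(u))$ where $r(u)$ is the boundary radius
  in the point's direction. This is a deterministic closed form, continuous,
  exact in the circular limit, and order-preserving along a single
  excursion, which is what peak selection needs. The exact nearest-boundary
  distance (root-solved to ~1e-9) is available via `method = "nearest"`.
* **Full windows only, trailing anchor.** Rolling means are emitted only
  for full windows and anchored at the window's last word. Partial leading
  windows have inflated variance and would fabricate early displacements;
  the trailing anchor keeps the trajectory causal (it uses only words
  already uttered).
* **Normalized time on the movie-global axis.** A word at 0-based position
  $p$ of a movie with $T$ tokens sits at $t = (p + 0.5)/T$, so a
  single-token movie lands at 0.5 rather than a boundary, and different
  speakers' trajectories are directly comparable — which the discordance
  analysis requires. (Per-character normalization can be obtained by
  passing a per-speaker token axis to `normalized_time()`.)
* **Discordance binning.** The grid has 100 bins with centers at
  $(k - 0.5)/100$, matching the percentage-of-narrative resolution in which
  results in this area are usually described. Interior empty bins of a
  speaker are filled by linear interpolation between occupied neighbours;
  bins before a speaker's first or after their last occupied bin stay
  missing — no emotional state is invented where the character is absent.
* **Displacement reporting threshold.** Rate and distance averages are
  reported only when a speaker has at least `min_displacements = 5`
  non-truncated displacements; below that the averages are unstable. The
  threshold is configurable.
* **Trend inference.** Trends of density or discordance on narrative time
  are fitted as penalized cubic regression splines (`mgcv::gam`, smoothing
  parameter by generalized cross-validation), and summarized descriptively
  by the extremum location on a 1001-point grid, with boundary and
  degenerate (range < 1e-9) cases flagged. A seeded permutation check of
  the linear slope (`trend_permutation()`) is provided instead of formal
  mixed-model inference, which is off-the-shelf machinery rather than part
  of this method.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_turns` | 50 | turn count for "main character" status (inclusive) |
| `window` | 10 words | rolling window of the v–a trajectory |
| `density_window` | 30 words | rolling window of categorical density arcs |
| `confidence` | 0.68 | home-base coverage (≈ one SD) |
| `n_bins` | 100 | narrative-time bins for discordance |
| `edge_fraction` | 0.10 | presence filter for pair eligibility |
| `min_displacements` | 5 | usable displacements required to report averages |

All windows are in words, not turns; a *turn* is a maximal uninterrupted
run of records by one speaker, merged by the transcript reader.

## Text handling

The tokenizer lowercases, splits on every non-alphanumeric character
(apostrophes split contractions into fragments; one-character fragments are
kept — lexicon lookup simply misses non-words), and passes tokens through a
pluggable lemmatizer whose default is the identity. A real analysis should
plug in the lemmatizer matching its lexicon's conventions; the identity
default keeps the package free of external model downloads and makes the
test suite deterministic.

## What the synthetic generator emulates — and what it does not

`make_lexicon()`, `narrative_spec()`, `simulate_narrative()` and
`simulate_corpus()` generate data with known ground truth so every metric
can be validated without third-party corpora or lexicons:

* the lexicon is an exact $m \times m$ lattice of (valence, arousal) scores
  over $[0.05, 0.95]^2$ with threshold-derived categorical flags, so word
  emission (nearest lattice point to the target state) has quantization
  error bounded by half a lattice diagonal;
* a speaker's path is a mean-reverting baseline (home center plus iid
  Gaussian noise) with injected piecewise-linear displacement events whose
  onset, peak, offset and amplitude are recorded; linear ramps make the
  injected rise/recovery word counts exact integers;
* words are grouped into alternating-speaker turns with geometric lengths,
  and all randomness flows from a single spec-level seed.

Defaults were chosen once as realistic study conditions: a 2500-word
lattice lexicon (spacing ≈ 0.018, so quantization noise is well below the
0.02 baseline noise SD), home center (0.55, 0.45) — mildly pleasant, mildly
calm, where dialogue tends to sit — 1500 focal words per narrative, three
events of amplitude 0.3 (about 15 baseline SDs, i.e. clearly intended
displacements) with 15-word ramps and a 9-word hold (one full window minus
one, giving a unique full-amplitude trajectory point), and a mean turn
length of 8 words.

The generator does **not** emulate several properties of real dialogue:
Zipfian word frequencies, partial lexicon coverage (every synthetic token
is a VAD word), sense ambiguity, autocorrelated baseline drift, or
speaker interaction effects. Passing the recovery tests therefore shows
the estimators are correct under the stated generative model, not that
lexicon-based scores are valid measurements of human emotion — the usual
caveats about lexicon coverage and dominant-sense priors apply to any real
corpus.

## Validation design and problem sizes

The test suite validates each layer against an independent route: rolling
means, variances, densities and correlations against brute-force
recomputation on 100 random fixtures (tolerance 1e-10); ellipse geometry
against a hand-computed 4-point eigendecomposition, the circle closed form
(1e-12) and a dense ray-sampling distance oracle (1e-6); coverage by Monte
Carlo as above; displacement recovery on 50 seeded 1500-word narratives
(count matched exactly in ≥ 95% of replicates, peak distances within 25% of
the injected geometry, rise/recovery timing within ±2 words of the same
detector applied to the noiseless path with the same home base — the
noiseless reference isolates estimator noise from the dependence of
exit/peak indices on the fitted ellipse size); trend extremum location on a
noiseless parabola (±0.02); and end-to-end byte-identical determinism of
the pipeline outputs. These problem sizes keep the whole suite to a few
minutes while leaving each check statistically sharp.

## Degenerate inputs

Zero-variance narratives yield variability 0, a degenerate (unreported)
ellipse, and zero displacements rather than an error; narratives shorter
than the window yield an empty trajectory plus a warning; empty lexicons
and empty token streams yield explicit "not available" values. Eigenvalues
below 1e-12 are treated as degenerate geometry, and `home_base_2d()` names
the deficient axis in its error.

## Known limitations

* Word-level lexicon scoring ignores context, negation and sarcasm; it is
  a strong baseline, not a sentence-level emotion model.
* The radial perimeter distance slightly exceeds the orthogonal distance
  off-axis; rankings along one excursion are unaffected, but absolute peak
  distances from very eccentric home bases differ between the two
  conventions.
* Discordance depends on a binning/alignment scheme; the binned-trajectory
  scheme here is one concrete realization of "distance between emotional
  states at the same narrative time". Matched-time comparison is also
  sensitive to small time-axis offsets between speakers (e.g. from turn
  alternation) wherever a trajectory changes steeply: two speakers on
  identical emotional paths shifted by a few turns show near-zero
  discordance on flat stretches but transiently large discordance at sharp
  transitions.
* UED metrics must not be used to draw mental-health or personality
  inferences about individuals; see the ethics section of the package
  documentation.
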