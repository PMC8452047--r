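# uedyn — utterance emotion dynamics from dialogue transcripts

`uedyn` quantifies how an individual speaker's use of emotion-associated
words changes over the course of a narrative — movie dialogue, interview
transcripts, long-running social-media threads — using only a
turn-structured transcript and two word–emotion lexicons. It is aimed at
computational psycholinguists, digital-humanities researchers, and
affective scientists who want per-speaker *utterance emotion dynamics
(UED)* metrics rather than a single document-level sentiment score.

## The method

Each word a speaker utters is scored on **valence** ($v$) and **arousal**
($a$), both in $[0,1]$, from a dimensional lexicon (the common
`word<TAB>valence<TAB>arousal<TAB>dominance` TSV dialect). The speaker's
emotional *trajectory* is the trailing 10-word rolling mean of these
scores, placed on normalized narrative time $t = (p + 0.5)/T$ for word
position $p$ in a $T$-token narrative. From the trajectory, per speaker:

- **Home base**: the high-probability region of the trajectory. 1-D:
  $\bar v \pm t_{1-(1-c)/2,\,N-1}\sqrt{\sigma^2/N}$ (population variance,
  coverage $c = 0.68$ by default). 2-D: the covariance confidence ellipse
  with semi-axes $\sqrt{\psi\lambda_{1,2}}$, where $\lambda_{1,2}$ are the
  covariance eigenvalues and $\psi$ is the $\chi^2_2$ quantile at $c$.
- **Emotional variability**: the population SD of the trajectory (mean of
  the $v$ and $a$ SDs in 2-D).
- **Displacements**: completed excursions outside the home base, each with
  a peak distance (Euclidean distance from the ellipse perimeter), rise
  rate (peak distance / words from exit to peak) and recovery rate (peak
  distance / words from peak to return) — proxies for emotional reactivity
  and regulation.
- **Emotion word density**: percent of all tokens flagged for each of the
  eight basic emotions and the two sentiment polarities in a categorical
  lexicon (`word<TAB>emotion<TAB>flag` TSV dialect).
- **Discordance**: for speaker pairs present in both the first and last
  10% of a narrative, the Euclidean distance between their binned
  trajectory positions at matched narrative time, with penalized-spline
  trend curves (`mgcv`) and extremum location.

A synthetic generator (`make_lexicon()`, `simulate_narrative()`,
`simulate_corpus()`) produces lattice lexicons and narratives with known
home centers and injected displacement events, so the whole pipeline is
testable without any third-party corpus or lexicon.

## Worked example

```r
library(uedyn)
library(dplyr)

lex  <- make_lexicon(2500)                     # 50 x 50 synthetic lattice lexicon
sim  <- simulate_narrative(narrative_spec(seed = 42), lex)
tf   <- tempfile(fileext = ".tsv"); write_transcript(sim$turns, tf)

words <- read_transcript(tf, "tsv") |> build_narratives()
hero  <- filter(words, speaker == "HERO")
traj  <- hero |> score_words(lex$vad) |> rolling_trajectory(window = 10)
home  <- home_base_2d(traj, confidence = 0.68)
home
#> Home base ellipse (68%): center (0.5494, 0.4540), semi-axes 0.0709 / 0.0433, theta 0.022 rad, n 1491
```

The fitted home base sits at the speaker's typical emotional state
(valence 0.55, arousal 0.45 — the generator's home center) with a 68%
ellipse about 0.07 wide in valence and 0.04 in arousal. The narrative was
generated with three displacement events of amplitude 0.3; the detector
finds exactly those three:

```r
detect_displacements(traj, home) |>
  select(peak_index, length, peak_distance, rise_words, recovery_words)
#>   peak_index length peak_distance rise_words recovery_words
#> 1        315     32         0.231         18             15
#> 2        719     33         0.227         17             17
#> 3       1110     34         0.207         19             16
```

Each excursion peaks about 0.21–0.23 beyond the home-base perimeter
(amplitude 0.3 minus the ellipse's ~0.07 radius in the event direction)
within ±2 words of the injected timing. `summarize_profile()` collects
everything into one row per speaker:

```r
summarize_profile(hero, lex$vad, lex$emotions, min_displacements = 3) |>
  select(speaker, n_vad_words, variability_2d, displacement_count, mean_peak_distance)
#>   speaker n_vad_words variability_2d displacement_count mean_peak_distance
#> 1 HERO           1500         0.0378                  3              0.221
```

`ued_profiles()` runs the same computation for every main character
(≥ 50 turns by default) of a multi-movie transcript, and `run_profiles()` /
`run_discordance()` wrap the full pipeline with CSV/JSON outputs. Plots:
`plot_trajectory(traj, home)`, `autoplot(home)`, `plot_discordance()`.

## Ethical use

UED metrics describe word usage. Do not use them to infer mental health or
personality of real individuals without consent and clinical context;
prefer aggregate-level analyses. Lexicons encode crowd-sourced
associations for a word's dominant sense and may carry inappropriate
biases — inspect the most frequent words in your data and prune unsuitable
entries with `remove_words()` before analysis.
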