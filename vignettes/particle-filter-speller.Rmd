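---
title: "Decoding the P300 speller with a language-model particle filter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding the P300 speller with a language-model particle filter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfspeller)
```

## The problem

The row/column P300 speller presents a 6x6 character grid and flashes its
six rows and six columns in random order. When the row or column holding
the attended character flashes, the EEG contains an evoked response (the
P300, and for face-overlay stimuli also the N170/N400f); because the
single-trial signal-to-noise ratio is low, many flashes must be combined
before a character can be selected. `pfspeller` implements a decoder that
shortens this process in two complementary ways: it integrates a
character-level language model into the classifier, and it stops flashing
as soon as the posterior over the current character is confident enough
(dynamic stopping).

## From epochs to scores

Each flash is followed by a fixed 600 ms window of multichannel EEG.
`preprocess_epoch()` block-averages each channel over windows of 12
samples (moving-average anti-aliasing followed by downsampling, 256 Hz to
about 21 Hz) and flattens channel-major. The decimation factor is a
package default: it keeps the stepwise design matrix well-conditioned at
typical training-set sizes, and is conventional for P300 feature
extraction; the window length is the only quantity fixed by the recording
protocol itself.

`fit_swlda()` performs stepwise linear discriminant analysis: ordinary
least-squares regression of the binary target/non-target label on the
features, adding the candidate with the smallest partial p-value while it
is below `p_enter = 0.10`, removing included features whose p-value rises
above `p_remove = 0.15`, until `max_features = 60` are held or nothing
changes. These three thresholds are the values in common use for P300
SWLDA; the stepwise procedure itself, not the thresholds, is what matters
for the decoder downstream. Forward p-values are computed by
residualizing the label and all candidates on the current design
(Frisch-Waugh), which is algebraically identical to the full-model
partial t-test but costs one QR decomposition per step instead of one
regression per candidate. Ties are broken towards the lowest feature
index so refitting is deterministic.

A stimulus score is the dot product of the fitted coefficients with the
epoch (`score_epoch()`), and `fit_score_model()` summarizes training
scores by per-class means and unbiased variances
(mu_target, var_target, mu_nontarget, var_nontarget). These four numbers
are the whole interface between signal processing and inference: the
decoding likelihood of a flash score is the target Gaussian when the
flashed group contains the hypothesized character and the non-target
Gaussian otherwise.

## The language model

`build_language_model()` counts, for every prefix of every corpus word,
how many words begin with it. The transition probability of continuing a
word fragment `h` with character `v` is the count ratio
`c(h + v) / c(h)`; the word separator receives mass proportional to the
number of words exactly equal to `h`, and after a separator the fragment
resets to empty. This makes the separator a first-class grid character —
the speller must be able to type spaces — while keeping the model a pure
word-prefix model.

Two normalization choices are deliberately simple and documented rather
than configurable: corpus text is folded to upper case, and any character
outside the vocabulary acts as a word boundary (reported once via a
warning). Zero-count characters receive a uniform smoothing floor
(default 0.05 total mass) mixed into every transition distribution;
without it a character absent from the corpus could never be typed,
because no amount of EEG evidence can rescue a particle that is never
proposed. A history with no corpus support at all falls back to the
uniform distribution. The packaged default corpus is a small plain
English text written for this package; any UTF-8 file can be used
instead, and absolute probabilities will of course depend on that
choice — it is the mechanism, not the corpus, that the package fixes.

## The particle filter

A particle is a hypothesis of the whole typed string with an importance
weight; `P = 1000` particles are used by default (the number is a
configurable accuracy/cost dial, and the oracle tests use more). At each
character period every particle draws its next character from the
language model conditioned on its own word fragment — the proposal equals
the prior, so the weights need only absorb the likelihood. After every
flash, `update_weights()` multiplies each weight by the Gaussian density
of the observed score under that particle's current character and
renormalizes; accumulation is in the log domain with max-subtraction,
since up to 120 densities multiply into a weight within one character.
`character_posterior()` is then the weight histogram over final
characters.

Dynamic stopping (`decode_character()`): flashing ends at the first flash
where some character's posterior reaches the threshold (0.95 by default,
the value used for online operation), or at the 120-flash cap. The
stopping rule may not fire before one full 12-flash sequence has been
seen; this floor prevents a decision driven by the language prior alone
before any row and column has flashed, and is consistent with observed
online selection times. It is configurable (`min_flashes`).

After each selection the particle set is resampled systematically —
one uniform offset and `P` evenly spaced strata, so a particle with
weight `w` survives either `floor(P w)` or `ceiling(P w)` times — and
weights reset to `1/P`. Systematic resampling is the minimum-variance
member of the standard resampling family; the alternative multinomial
scheme satisfies the same expectation but adds Monte-Carlo noise.
Resampling happens per selection, not per flash: within a character the
weights are exact likelihood products and resampling would only discard
information. By default every particle's current character is then
overwritten with the selected one (`commit_selected`), so all particles
agree with the single string the speller displays; turning this off keeps
alternative histories alive across selections, which is closer to pure
filtering but lets the displayed string and the particle population
diverge.

One master seed drives proposals and resampling through R's RNG in a
fixed consumption order, so a decode is bit-reproducible given the seed,
the stream and the configuration.

## The simulator

`simulate_session()` runs the decoding likelihood generatively: for each
target character it draws a randomized schedule of full 12-flash
sequences and samples each flash's score from the target Gaussian when
the flashed group contains the target, the non-target Gaussian otherwise.
Scores are conditionally independent given the target — exactly the
factorization the decoder assumes. The default generating separation is
1.25 standard deviations between target and non-target means, a
calibration chosen so decoded speeds and accuracies land in the range
reported for able-bodied online spelling; stronger stimulus paradigms
(face overlays versus inverting characters) are emulated purely as larger
separations.

What the simulator does *not* model, and what passing tests therefore do
not establish about real EEG: overlapping evoked responses at 125 ms SOA
(consecutive epochs share samples and are correlated), refractory and
habituation effects, non-Gaussian artifacts, and the difference in
evoked-component topography between stimulus types. Simulation-based
results here validate the inference machinery, not signal-processing
performance on recordings.

`simulate_epoch_features()` inverts the scoring step for pipeline tests:
it injects the class mean along a given weight vector and adds isotropic
noise scaled so the induced score distribution matches the configured
Gaussians exactly, letting SWLDA refitting and cross-validation be
exercised end to end.

## Evaluation

`session_metrics()` computes the standard quantities: selection rate
(selections per minute, from flash counts times the 125 ms SOA plus any
configured inter-character pause — zero by default, since published
online rates are consistent with negligible overhead), accuracy
(positional matches against the target, cycling the target when the
subject finished and restarted the phrase), CCPM (correct characters per
minute, discarding errors) and the Wolpaw information transfer rate with
`N = 36` choices. `threshold_sweep()` replays sessions over a grid of
stopping thresholds (0 to 1 in steps of 0.01 by default) and reports the
CCPM-maximizing threshold, ties to the lower value; `crossfold_offline()`
reproduces the three-session cross-validated training analysis.

The packaged per-subject tables (`load_subject_table()`) carry the
published offline and online results for the ten subjects. Their column
means and the famous-faces-over-inverting improvement percentages are
recomputed by `summarize_table()`; improvements are computed on the means
rounded to two decimals, the reproducible convention given that only
rounded per-subject data are available. One caveat found while packaging:
the online inverting-condition CCPM column averages to 7.34 from its
printed per-subject entries while the published average row prints 7.33,
so that average (and percentages built on it) can only be reproduced to
the tables' printed precision.

## Numerical and degenerate-input choices

- Weights live in log space end to end; an all-zero weight vector (every
  density underflowed) raises an error rather than renormalizing noise.
- Zero generating variances are allowed in the simulator (noise-free
  sessions are useful fixtures) but rejected by the decoder and by
  `fit_score_model()`, where they indicate degenerate training data.
- Posterior argmax ties break in grid row-major order; stepwise-selection
  ties break towards the lower feature index; sweep ties towards the
  lower threshold.
- Problem sizes in the test suite are chosen to make Monte-Carlo bounds
  meaningful at interactive runtimes: the exact-Bayes comparison uses a
  2x2 grid, three-character strings and 50,000 particles; mechanism
  checks (threshold monotonicity, language-model benefit) average 20
  seeded sessions of a 15-character in-corpus phrase at 300 particles.

## Limitations

- The decoder consumes stimulus scores, not raw EEG files; acquisition
  formats and artifact handling are out of scope, with features entering
  through a documented tabular format.
- The word-prefix model has no cross-word context: the first character of
  each word is proposed from unconditional word-start frequencies.
- Published per-subject speeds and accuracies depend on recordings that
  are not redistributable, so they enter only as packaged summary tables;
  simulation reproduces mechanisms (speed-accuracy trade-off, language
  model benefit), not subject-level values.
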