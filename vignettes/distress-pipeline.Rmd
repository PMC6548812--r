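---
title: "Regime-segmented acoustics and perception of infant vocal distress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regime-segmented acoustics and perception of infant vocal distress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryregimes)
```

## The problem

Newborn vocalizations form a continuum from intensely distressful cries
("wails") through fussy "whines" to speech-precursor "vocants" that express
little or no distress. Adult listeners rate distress along this continuum
with striking consistency, yet the acoustic basis of those judgments is not
obvious: infant phonation chains several *vibratory regimes* — modal
vibration, aperiodic (chaotic/biphonated) stretches, subharmonic
(period-doubled) episodes, and pulse register — and much of the predictive
information lives inside individual regime segments rather than in
whole-utterance averages.

`cryregimes` implements the full analysis pipeline for this problem:
regime-aware acoustic profiling of phonation-only utterances, rater-panel
agreement analytics, a distress-prediction regression with backward-AIC
selection, per-listener dynamics statistics (trend, prevalence,
heterogeneity, experience contrasts), and a synthetic-data module that
stands in for audio and listener data that cannot be redistributed.

## The acoustic model

Nine parameters are computed per utterance. Three are whole-utterance
quantities plus duration:

* **duration** (ms), rounded to the nearest millisecond;
* **average and maximum pitch** (Hz): mean and maximum of the voiced f0
  track. Tracking is by normalized autocorrelation with parabolic peak
  interpolation, a 40 ms frame, 10 ms hop, search range 150–1000 Hz
  (the stimuli of interest span roughly 300–510 Hz; the margin absorbs
  octave-safe tracking at both ends), and a voicing decision combining an
  autocorrelation floor (0.35) with a relative silence gate (5% of peak
  RMS);
* **maximum RMS amplitude**: peak of a 30 ms sliding RMS, in full-scale
  linear units (WAV amplitudes are normalized to [-1, 1]; no absolute
  calibration is assumed).

The remaining five are measured *within each regime segment* and aggregated
by the extremum that marks distress:

* **spectral ratio** (dB): `10 log10` of energy below 2 kHz over energy
  above it, computed from a Welch long-term average spectrum (Hann 25 ms,
  50% overlap, next-power-of-two FFT); utterance value = **minimum** over
  segments. The high-band power is floored at `1e-10` of total power and
  the ratio capped at ±60 dB so an all-low-band tone is finite.
* **spectral mean and dispersion** (kHz): power-weighted mean and SD of the
  LTAS; utterance values = **maximum** over segments.
* **periodicity** (dB): cepstral peak prominence — the cepstral peak in the
  quefrency band [1/f0max, 1/f0min] above a linear baseline fitted across
  the analyzed quefrency band (0.5 ms upward), frames of 40 ms averaged
  before peak picking; utterance value = **minimum** over segments.
* **number of regimes**: the segment count of the tier.

These windows, the pitch algorithm and the dB convention for the spectral
ratio are package choices, documented here because the source material does
not specify them; the packaged stimulus table's spectral-ratio column
(-15.1 to 34.8) is consistent with a dB scale.

## Regime tiers and automatic segmentation

Tiers are ordered, non-overlapping, half-open `[start, end)` intervals
labeled modal / aperiodic / subharmonic / pulse, with optional trill and
flutter modulation flags carried from manual annotation (they are never
auto-detected: no quantitative criterion for them is established). By
default tiers must tile the phonated span.

`auto_segment_regimes()` automates segmentation so the pipeline runs
end-to-end without manual tiers. Frames (25 ms / 10 ms hop) are classified
and then smoothed:

1. frames below 5% of peak RMS inherit their nearest neighbor's label;
2. **aperiodic**: no autocorrelation periodicity (peak < 0.30), or a flat
   cepstrum (CPP < 20 dB) *and* weak periodicity (< 0.55) — the guard keeps
   pulse register, which is periodic but CPP-poor at 25 ms, out of the
   aperiodic class;
3. **subharmonic**: the tracked f0 sits near half the utterance's carrier
   f0 (ratio 0.42–0.58 against the median f0 of confidently periodic
   frames), and the spectrally *whitened* frame spectrum carries energy at
   half-integer multiples of the carrier exceeding the
   subharmonic-to-harmonic ratio threshold (default 0.25). Whitening by a
   smooth spectral envelope makes the ratio a property of the vocal-fold
   source rather than of whichever harmonic happens to sit on a formant;
4. **pulse**: tracked f0 below 180 Hz;
5. otherwise **modal**. Ties resolve aperiodic > subharmonic > pulse >
   modal (the marked, rarer categories win).

Labels are mode-filtered (5 frames) and runs shorter than 50 ms are merged
into their longer neighbor — the same rule under which very short
subharmonic events are not annotated manually. The detector is validated
*only* against the package's synthesizer: on 100 random schedules it
recovers segment counts and labels with ≥ 90% success and a median boundary
error around 3 ms (the acceptance suite asserts < 30 ms). A green detector
test establishes fidelity to the synthesizer's regime events, not parity
with expert annotation of real infant audio.

## The synthetic world

`synth_utterance()` is a source-filter synthesizer: a glottal impulse train
follows a flat / rise-fall / rise-flat / custom f0 contour (0.5% jitter, 3%
shimmer), passes through three formant resonators (defaults 1000 / 3200 /
5200 Hz, approximating a newborn tract) and a spectral-tilt filter, with a
-35 dB aspiration floor. Scheduled events modify the source: subharmonic
segments alternate successive pulse amplitudes with depth 0.6 (a salient
f0/2 component, matching the "abrupt appearance" character of subharmonics);
aperiodic segments use 12% jitter plus strong (-5 dB) noise; pulse segments
drop f0 to 120 Hz. Every utterance is reproducible from (spec, seed).

`build_stimulus_set()` mirrors the published design — 7 infants x
{wail, whine, vocant} x 2 ages = 42 records — with class templates
calibrated to the published per-stimulus ranges (durations 452–2000 ms,
pitch 298–510 Hz, 1–5 regimes): wails are long (1–2 s), shallow-tilted
(more high-frequency energy) and multi-regime; vocants short, steeply
tilted and modal-only; whines intermediate. Durations are filtered to the
400–2000 ms selection bounds.

`simulate_panel()` generates listener ratings as
`clip(intercept + sum_p (w_lp + drift_lp * t) z_p(s) + bias_l + noise)`:
listener-specific weights on standardized features (defaults: mean 6 rating
points per SD, between-listener SD 1.5), listener bias (SD 7.2, matching
the published between-listener spread of grand means), rating noise (SD
10), optional linear-in-trial drift (the simplest model consistent with the
monotone-trend alternative of the Cox–Stuart test), and an optional
experience effect added to chosen (by default spectral) feature weights of
the inexperienced group. Defaults keep clipping below 5% of ratings, which
each run asserts, so linear-model recovery stays valid. The simulator does
not emulate scale-usage nonlinearity, stimulus-order effects, or listener
fatigue; green panel tests certify the statistics against this linear
world only.

## Statistical pipeline

* **Agreement**: pairwise inter-rater correlations of the mean individual
  ratings (C(39,2) = 741 pairs), leave-one-out correlations, intra-rater
  correlations over all C(10,2) = 45 trial-block pairs, and the CV
  analysis (inter-listener CV of grand means vs mean within-listener CV of
  trial-block means — the trial-block-mean reading is a package choice, as
  is the use of the sample SD). Undefined (zero-variance) correlations are
  excluded, never imputed. The scale-usage histogram uses bins
  `(0,5], ..., (95,100]` with exact 0 in the first bin; integer-labeled
  published bins are not well-defined for real-valued means, so the edges
  are exposed in the output.
* **Regression**: `fit_ols()` reports raw and standardized coefficients
  (z-scored predictors, raw response, so the standardized intercept is the
  mean rating), R², adjusted R², VIFs (reported, not enforced), and a
  Gaussian AIC `n log(RSS/n) + 2k` with k counting all mean parameters —
  the same scale `stats::extractAIC` uses, so backward selection agrees
  with the reference stepwise implementation (asserted in the suite
  against `MASS::stepAIC`). Ties between candidate drops fall to the
  predictor with the larger p-value.
* **Listener dynamics**: the trial x parameter correlation cube feeds (a)
  the Cox–Stuart trend battery with a chi-square prevalence test against a
  configurable chance proportion p0 (default alpha) and effect size
  `w = sqrt(chi2/n)`; (b) a bootstrap permutation test of across-listener
  heterogeneity comparing Fisher-z means of two with-replacement listener
  subgroups (size `floor(n/2)`) by a two-sample z-test whose standard
  error is the known sampling error of a correlation over `n_stimuli`
  items (`1/sqrt(n_stimuli - 3)`), reporting the proportion of
  permutations failing to reject — an empirical-variance test would be
  calibrated under any exchangeable listener population and blind to
  heterogeneity, whereas the fixed-error form rejects at `alpha` only when
  listeners differ by no more than correlation sampling noise; and (c) the
  experience contrast:
  per-parameter Wilcoxon rank-sum tests, Bonferroni-corrected over the
  parameter family, plus a rating-level contrast.

### Numerical and design notes

* With 10 trial blocks the Cox–Stuart test compares 5 pairs, so the
  smallest attainable two-sided p is 0.0625: no listener can be flagged at
  alpha = 0.05 two-sided. The published per-listener counts therefore
  cannot arise from the two-sided variant; `cox_stuart()` defaults to the
  stated two-sided form and exposes one-sided alternatives. Power
  properties in the suite use 14 trial blocks, where the two-sided test can
  reject.
* The published prevalence chi-squares and permutation proportions could
  not be reconciled with a goodness-of-fit against chance at alpha (the
  construction lives in unavailable supplementary material); the package
  implements the documented default with configurable p0 and validates the
  permutation machinery by calibration (fail-to-reject near 1 - alpha
  under homogeneity) and power (planted opposite-weight subpopulations),
  not against the published table values.
* The stimulus table is shipped as printed, with a flagged corrected
  variant: stimulus 12's printed 73 ms duration violates the stated
  400–2000 ms inclusion rule, and 738 ms is the unique single-cell repair
  reproducing the published duration mean (SD) of 1030.6 (450.9) exactly —
  so the published regression used 738 ms. Reproduction functions default
  to the corrected variant. Because all predictor columns are printed
  rounded, reproduction is judged at printed precision, within one unit in
  the last printed decimal place; the recomputed regimes coefficient (7.1)
  sits one last-place unit from the printed 7.0, and R² (0.83) one unit
  from 0.84, consistent with input rounding.
* The full nine-parameter model is implemented and exercised on synthetic
  panels; it cannot be validated against published numbers because only
  four predictor columns were printed.

## Worked example

```{r example, eval = FALSE}
library(cryregimes)

# published-table reproduction
reproduce_table2()

# a fully synthetic end-to-end run
recs <- build_stimulus_set(seed = 1)
feats <- do.call(rbind, lapply(recs, function(r)
  profile_row(extract_profile(r))))
sim <- simulate_panel(panel_spec(seed = 1), load_table3())
bundle <- analyze_panel(sim$panel, load_table3(), n_perm = 2000, seed = 1)
print(bundle)
```

## Limitations

The synthesizer produces schematic, not perceptually realistic, infant
phonation (no glottal bursts, catch breaths, loft register, or supraglottal
articulation — all excluded from the stimulus design it emulates). The
automatic segmenter is a testing instrument calibrated to that synthesizer;
applying it to real recordings should be preceded by validation against
manual tiers. Chaos and biphonation are not subdivided within "aperiodic"
(no numeric criterion separates them), and the published Tables of
prevalence chi-squares and permutation proportions are out of reach without
the raw listener data.
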