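---
title: "Methods: simulating and analysing affect perception from vocalizations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing affect perception from vocalizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(vocaffect)
```

This vignette documents the design decisions behind each module, the
verification strategy, and one substantive methodological finding about the
calibration of the hit-rate analysis.

## The study being emulated

The emulated design has two listener experiments over a corpus of 155
chimpanzee call-bout recordings from 10 behavioural contexts and 66 callers.
In experiment 1, participants assign each stimulus to one of the 10 contexts
and rate arousal and valence; performance per context is scored with Hu
unbiased hit rates compared against Wagner chance rates by exact Wilcoxon
signed-rank tests (Bonferroni alpha 0.05/10). In experiment 2, participants
answer yes/no "was this recorded in context X?" questions, scored with
d-prime. Acoustic features of the stimuli then predict context and affect
(multinomial/binomial models) and listener accuracy (binomial GLMMs with
crossed participant and caller random intercepts, AICc selection).

## Power analysis

`power_n_ttest()` searches for the smallest n where the noncentral-t power
of a one-sample test reaches the target:

```{r power}
power_n_ttest(d = 0.2, alpha = 0.005, power = 0.80, tail = "one")
power_n_ttest(d = 0.2, alpha = 0.05, power = 0.80, tail = "one")
```

The first drives the experiment 1 sample (310 recruited for 296 required);
the second drives experiment 2, where each stimulus must collect at least
156 matching judgments, giving 312 participants per context (each stimulus
is a "match" trial for half of them) and 3120 in total. `validate_design()`
re-derives this arithmetic for any configuration.

## Synthetic corpus

`generate_corpus()` builds each stimulus with `synthesize_call_bout()`: a
harmonic stack with per-context f0 centre, spectral tilt, amplitude
envelope, frequency modulation, noise fraction, call count and duration, set
by `context_profiles("paper")`. Caller identity perturbs the profile so the
66 callers are acoustically distinguishable. Because the modulation rate and
phase are random, the nominal f0 centre is not the generating truth; the
duration-weighted mean of the actually generated contour is stored as
`f0_true` and is the oracle the feature tests recover against.

Listener behaviour is a parametric model (`listener_model()`): context
choice via softmax weights, affect ratings via latent Gaussians with
arousal/valence gains and a negativity bias, yes/no matching via a probit
rule with per-context sensitivity, all diluted by a lapse rate. The `"null"`
preset (lapse rate 1) gives the exact guessing distribution used for
calibration; `"perfect"` gives a ceiling check.

## Acoustic analysis

Segmentation thresholds a 1-ms-hop RMS envelope relative to its peak, with
window-smear compensation and merging of sub-threshold gaps. The f0 tracker
uses frame autocorrelation (40 ms Hann frames, 10 ms hop) normalized by the
window autocorrelation, restricts candidates to lags past the first
zero-crossing of the autocorrelation (excluding the lag-0 shoulder, whose
noise ripples otherwise masquerade as low-f0 peaks), applies a 0.05-per-
octave cost against subharmonic picks, and refines the winning lag by
parabolic interpolation. HNR is `10*log10(r/(1-r))` at the chosen lag.
Jitter and shimmer come from period marks placed by peak-picking successive
periods. SCoG is the power-spectral centroid over concatenated call
segments, zero-padded to a (2,3,5)-smooth FFT length. Tests verify each
feature against constructed signals with closed-form answers (pure tones,
glides, pulse trains with known perturbation, two-tone spectra) and check
gain and time-shift invariance.

Tracker accuracy over an 80–1500 Hz grid crossed with noise fractions 0,
0.25 and 0.5 stays within 2% of the realized contour mean; this grid is an
acceptance test.

## Feature selection

`pca_varimax()` retains components explaining more than 10% of variance,
varimax-rotates them, and canonicalizes loading signs so results are
invariant to row order. `vif()` flags collinearity; `select_features()`
implements both the fixed six-feature set used by the emulated analysis
(SCoG, duration, f0 mean and s.d., HNR mean and max) and a data-driven
policy (top rotated loadings subject to a VIF ceiling). On the synthetic
corpus the fixed set violates the VIF ceiling — `hnr_max` tracks `hnr_mean`
almost perfectly because the generator holds the noise level constant within
a bout — which is a known limitation of the generator, not of the selection
code; the data-driven policy satisfies the ceiling by construction.

## Perception statistics

`hu_scores()` computes per-participant Hu unbiased hit rates (recall times
precision) and Wagner chance rates from individual confusion matrices,
arcsine-transformed; `wilcoxon_vs_chance()` runs the exact signed-rank test
per category with Bonferroni correction. `dprime()` applies the standard
extreme-rate adjustment (0 to 0.5/n, 1 to (n-0.5)/n). Supporting checks
reproduce the analysis pipeline's screening: rating recoding, valence bias,
fatigue (early/late accuracy), and s.d.-based outlier exclusion.

## A calibration finding: the signed-rank test is anti-conservative here

Calibration against the null listener is part of the test suite: simulate
the full experiment with a guessing listener many times and measure how
often each test rejects. The d-prime t-tests hold their level. The Wilcoxon
tests do not:

```{r wilcox-calibration, eval = FALSE}
corpus <- generate_corpus(context_profiles("paper"), seed = 1,
                          out_dir = tempdir())
rej <- replicate(200, {
  r <- simulate_exp1(corpus, 310, listener_model("null"))
  mean(wilcoxon_vs_chance(hu_scores(r, corpus), alpha = 0.05)$significant)
})
mean(rej)  # ~0.027 at a nominal per-test alpha of 0.005
```

The cause is structural. The signed-rank test assumes the paired differences
are symmetric about zero under the null. For a guessing participant the
difference between the Hu hit rate and the Wagner chance rate has mean zero
but is right-skewed (skewness about 0.55 at 155 trials): the same chance
fluctuation that inflates a category's hit count also inflates its column
marginal, coupling the two terms. With 310 participants the test has enough
power to detect that skew as a location shift, inflating the false-positive
rate roughly five-fold. The skew shrinks as the number of trials per
participant grows, so studies with longer sessions are less affected; a sign
test or a permutation test of the mean difference would be calibrated
alternatives. The corresponding acceptance test in this package is
deliberately left failing, as the implementation faithfully reproduces the
published procedure.

## Predictive models

`fit_classifier()` wraps a multinomial (or binomial) logit with per-feature
likelihood-ratio tests; `fit_accuracy_glmm()` fits the binomial GLMM with
crossed participant/caller intercepts; `glmm_candidates()` plus
`aic_select()` perform leave-one-feature-out AICc selection, with exact ties
broken toward the larger model and a `improves_fit` flag for margins above 2
AICc units. Recovery of a planted +0.5 per-SD log-odds effect (within 0.15
averaged over 20 replicates) is an acceptance test.

## Reproducibility

`run_all()` derives an independent sub-seed per stage from the master seed,
so re-running any stage in isolation reproduces its outputs byte for byte;
the manifest records package version, configuration hash, row counts and
stage status, and marks the run invalid if a stage fails. Identical
configurations produce identical CSVs and sample-identical WAVs.
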