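#' Context profiles for the synthetic stimulus corpus
#'
#' The `"paper"` preset encodes the study design this package emulates: 10
#' behavioural contexts (`c1`..`c10`) with fixed stimulus counts summing to
#' 155, each labelled with an arousal class (high/medium/low) and a valence
#' class (positive/negative/none), plus per-context synthesis parameters for
#' the harmonic-plus-noise call generator. Synthesis parameters are presets of
#' this package, chosen so that negative and high-arousal contexts are
#' acoustically more extreme (longer, higher-pitched, noisier); they are not
#' claims about real chimpanzee acoustics.
#'
#' Per-context caller pools lie in \[4, 21\] and the corpus-wide caller count
#' is 66. Valence marginals are derived from the per-context counts
#' (69 positive / 75 negative / 11 none).
#'
#' @param preset Currently only `"paper"`.
#' @return A data frame with one row per context: identifiers, labels, design
#'   counts and synthesis parameters. The preset name is kept in
#'   `attr(, "preset")`.
#' @export
context_profiles <- function(preset = "paper") {
  preset <- match.arg(preset)
  profiles <- data.frame(
    context_id = paste0("c", 1:10),
    context_label = c(
      "eating high value food", "eating low value food", "copulating",
      "being separated from mother", "discovering a large food source",
      "being refused access to food", "being tickled",
      "being attacked by another chimpanzee",
      "threatening an aggressive chimpanzee", "discovering something scary"),
    call_type = c(
      "rough grunt", "rough grunt", "copulation call", "whimper", "pant hoot",
      "tantrum scream", "laughter", "victim scream", "waa bark", "alarm call"),
    valence = c("positive", "positive", "none", "negative", "positive",
                "negative", "positive", "negative", "negative", "negative"),
    arousal = c("medium", "low", "medium", "medium", "high",
                "medium", "medium", "high", "high", "high"),
    n_stimuli = c(19L, 22L, 11L, 10L, 12L, 15L, 16L, 21L, 16L, 13L),
    caller_pool = c(10L, 11L, 6L, 5L, 7L, 8L, 8L, 12L, 9L, 7L),
    # synthesis parameters: f0 base distribution (Hz), relative f0 modulation
    # depth, broadband-noise power fraction, calls per bout, call duration (s),
    # inter-call silence (s), spectral tilt (dB/octave)
    f0_mean = c(120, 100, 450, 380, 500, 900, 180, 1200, 700, 650),
    f0_sd = c(25, 20, 80, 60, 90, 150, 40, 180, 120, 110),
    f0_mod_depth = c(0.08, 0.06, 0.15, 0.18, 0.20, 0.15, 0.10, 0.12, 0.12, 0.12),
    noise_frac = c(0.45, 0.50, 0.25, 0.20, 0.15, 0.35, 0.55, 0.30, 0.40, 0.45),
    calls_min = c(2L, 1L, 1L, 2L, 3L, 2L, 3L, 2L, 2L, 1L),
    calls_max = c(6L, 4L, 3L, 5L, 8L, 5L, 8L, 6L, 5L, 4L),
    dur_min = c(0.15, 0.12, 0.30, 0.20, 0.20, 0.40, 0.10, 0.50, 0.30, 0.25),
    dur_max = c(0.40, 0.35, 0.80, 0.50, 0.60, 0.90, 0.30, 1.00, 0.70, 0.60),
    sil_min = rep(0.05, 10),
    sil_max = rep(0.25, 10),
    tilt_db_oct = c(-9, -10, -6, -8, -6, -4, -8, -3, -5, -5),
    stringsAsFactors = FALSE
  )
  attr(profiles, "preset") <- preset
  profiles
}

#' Listener response models for the experiment simulators
#'
#' A listener model collects the parameters of the generative response model
#' used by [simulate_exp1()] and [simulate_exp2()]:
#'
#' * `context_weights`: per-context log-odds evidence for the true context in
#'   the 10-way softmax choice rule; 0 means chance-level discrimination.
#' * `arousal_gain` / `valence_gain`: mean of the latent rating (on the
#'   recoded -2..2 scale) for each true arousal/valence class.
#' * `valence_bias`: additive shift of all valence ratings (rating points;
#'   negative values model a negativity bias).
#' * `rating_sd`: s.d. of the latent Gaussian ratings before discretization.
#' * `exp2_sensitivity`: per-context probit sensitivity of the yes/no matching
#'   rule; without lapses the nominal d-prime equals this value.
#' * `exp2_criterion`: probit response criterion (positive = conservative).
#' * `lapse_rate`: probability that a response is replaced by a uniform draw.
#'
#' Presets: `"qualitative"` reproduces the study's qualitative findings
#' (above-chance affect judgments, negativity bias, higher sensitivity for
#' negative contexts); `"null"` responds uniformly at random (`lapse_rate =
#' 1`); `"perfect"` always picks the true context.
#'
#' @param preset One of `"qualitative"`, `"null"`, `"perfect"`.
#' @param ... Named fields overriding the preset values.
#' @return An object of class `listener_model`.
#' @export
listener_model <- function(preset = c("qualitative", "null", "perfect"), ...) {
  preset <- match.arg(preset)
  ctx <- paste0("c", 1:10)
  base <- list(
    context_weights = setNames(rep(0.4, 10), ctx),
    arousal_gain = c(high = 0.8, medium = 0, low = -0.8),
    valence_gain = c(positive = 0.35, negative = -0.55, none = 0),
    valence_bias = -0.3,
    rating_sd = 1.1,
    exp2_sensitivity = setNames(
      c(0.28, 0.55, 0.00, 0.16, 0.31, 0.74, 0.10, 1.29, 0.64, -0.60), ctx),
    exp2_criterion = 0.2,
    lapse_rate = 0.05
  )
  if (preset == "null") {
    base$lapse_rate <- 1
    base$context_weights[] <- 0
    base$exp2_sensitivity[] <- 0
    base$exp2_criterion <- 0
    base$valence_bias <- 0
    base$arousal_gain[] <- 0
    base$valence_gain[] <- 0
  } else if (preset == "perfect") {
    base$lapse_rate <- 0
    base$context_weights[] <- Inf
    base$exp2_sensitivity[] <- 6
  }
  override <- list(...)
  for (nm in names(override)) {
    if (!nm %in% names(base)) stop("unknown listener_model field: ", nm)
    if (length(override[[nm]]) == 1 && length(base[[nm]]) > 1 &&
        is.null(names(override[[nm]]))) {
      base[[nm]][] <- override[[nm]]
    } else if (!is.null(names(override[[nm]]))) {
      base[[nm]][names(override[[nm]])] <- override[[nm]]
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  if (base$lapse_rate < 0 || base$lapse_rate > 1)
    stop("lapse_rate must lie in [0, 1]")
  structure(base, class = "listener_model", preset = preset)
}

#' Nominal d-prime implied by a listener model
#'
#' Closed form of the sensitivity the yes/no matching simulator generates for
#' one context: hit and false-alarm probabilities follow the equal-variance
#' signal-detection model `hit = pnorm(d/2 - c)`, `fa = pnorm(-d/2 - c)`,
#' mixed with a uniform lapse, and the nominal d-prime is
#' `qnorm(hit) - qnorm(fa)` of the lapse-mixed rates.
#'
#' @param listener A [listener_model()].
#' @param context Context id, e.g. `"c1"`.
#' @return Nominal d-prime (numeric scalar).
#' @export
nominal_dprime <- function(listener, context) {
  stopifnot(inherits(listener, "listener_model"))
  d <- listener$exp2_sensitivity[[context]]
  cc <- listener$exp2_criterion
  lam <- listener$lapse_rate
  hit <- (1 - lam) * pnorm(d / 2 - cc) + lam * 0.5
  fa <- (1 - lam) * pnorm(-d / 2 - cc) + lam * 0.5
  qnorm(hit) - qnorm(fa)
}
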