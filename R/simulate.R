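#' Simulate the 10-way forced-choice categorization experiment
#'
#' For each simulated participant the stimulus order is randomized, a context
#' choice is drawn from a softmax over context evidence (the true context
#' receives its `context_weights` log-odds, all others 0), floored by the
#' lapse rate, and 5-point arousal and valence ratings are drawn from
#' discretized Gaussians centred on the listener's class means (valence
#' shifted by `valence_bias`). With `lapse_rate = 1` every response — choice
#' and ratings — is uniform.
#'
#' @param corpus Stimulus metadata from [generate_corpus()].
#' @param n_participants Number of simulated participants (>= 1).
#' @param listener A [listener_model()].
#' @param seed Integer seed.
#' @return Data frame with one row per trial: `participant_id`,
#'   `stimulus_id`, `trial_index`, `chosen_context`, `arousal_rating`,
#'   `valence_rating`.
#' @export
simulate_exp1 <- function(corpus, n_participants,
                          listener = listener_model("qualitative"), seed = 1) {
  stopifnot(inherits(listener, "listener_model"))
  if (n_participants < 1) stop("n_participants must be >= 1")
  set.seed(seed)
  contexts <- sort(unique(corpus$context_id))
  k <- length(contexts)
  n_stim <- nrow(corpus)
  lam <- listener$lapse_rate

  # probability that a non-lapsed choice hits the true context under the
  # one-hot evidence softmax: exp(w) / (exp(w) + k - 1)
  w <- listener$context_weights[corpus$context_id]
  p_true <- ifelse(is.infinite(w), 1, exp(w) / (exp(w) + k - 1))
  p_true_mix <- (1 - lam) * p_true + lam / k

  ar_mu <- listener$arousal_gain[corpus$arousal]
  va_mu <- listener$valence_gain[corpus$valence] + listener$valence_bias

  draw_rating <- function(mu, n) {
    r <- round(rnorm(n, mu, listener$rating_sd))
    pmin(2, pmax(-2, r)) + 3L
  }

  true_idx <- match(corpus$context_id, contexts)
  out <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    ord <- sample.int(n_stim)
    hit <- runif(n_stim) < p_true_mix[ord]
    # a missed choice is uniform over the k - 1 other contexts
    r <- sample.int(k - 1, n_stim, replace = TRUE)
    other_idx <- r + (r >= true_idx[ord])
    chosen <- ifelse(hit, corpus$context_id[ord], contexts[other_idx])
    lapse_ar <- runif(n_stim) < lam
    lapse_va <- runif(n_stim) < lam
    ar <- draw_rating(ar_mu[ord], n_stim)
    va <- draw_rating(va_mu[ord], n_stim)
    ar[lapse_ar] <- sample.int(5, sum(lapse_ar), replace = TRUE)
    va[lapse_va] <- sample.int(5, sum(lapse_va), replace = TRUE)
    out[[p]] <- data.frame(
      participant_id = sprintf("p%04d", p),
      stimulus_id = corpus$stimulus_id[ord],
      trial_index = seq_len(n_stim),
      chosen_context = chosen,
      arousal_rating = ar,
      valence_rating = va,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate the yes/no match-to-context experiment for one context
#'
#' Each participant hears a random half of the target context's stimuli as
#' matching trials and three times as many non-matching stimuli drawn from
#' the other contexts, in randomized order. Yes-responses follow the
#' equal-variance signal-detection rule `P(yes | match) = pnorm(d/2 - c)`,
#' `P(yes | non-match) = pnorm(-d/2 - c)` with the listener's per-context
#' sensitivity `d` and criterion `c`, mixed with a uniform lapse.
#'
#' @inheritParams simulate_exp1
#' @param condition_context Target context id (one of the corpus contexts).
#' @return Data frame with `participant_id`, `condition_context`,
#'   `stimulus_id`, `is_match`, `response_yes`, `trial_index`.
#' @export
simulate_exp2 <- function(corpus, condition_context, n_participants,
                          listener = listener_model("qualitative"), seed = 1) {
  stopifnot(inherits(listener, "listener_model"))
  if (!condition_context %in% corpus$context_id)
    stop("unknown condition_context: ", condition_context)
  in_ctx <- corpus$stimulus_id[corpus$context_id == condition_context]
  out_ctx <- corpus$stimulus_id[corpus$context_id != condition_context]
  if (length(in_ctx) < 2)
    stop("context ", condition_context,
         " has fewer than 2 stimuli; cannot take half")
  set.seed(seed)
  n_match <- floor(length(in_ctx) / 2)
  n_non <- 3 * n_match
  if (n_non > length(out_ctx))
    stop("not enough non-matching stimuli for a 3:1 ratio")

  d <- listener$exp2_sensitivity[[condition_context]]
  cc <- listener$exp2_criterion
  lam <- listener$lapse_rate
  p_yes_match <- (1 - lam) * pnorm(d / 2 - cc) + lam * 0.5
  p_yes_non <- (1 - lam) * pnorm(-d / 2 - cc) + lam * 0.5

  n_trials <- n_match + n_non
  is_match0 <- c(rep(TRUE, n_match), rep(FALSE, n_non))
  stim_col <- character(n_participants * n_trials)
  match_col <- logical(n_participants * n_trials)
  for (p in seq_len(n_participants)) {
    stim <- c(sample(in_ctx, n_match), sample(out_ctx, n_non))
    ord <- sample.int(n_trials)
    at <- (p - 1L) * n_trials + seq_len(n_trials)
    stim_col[at] <- stim[ord]
    match_col[at] <- is_match0[ord]
  }
  p_yes <- ifelse(match_col, p_yes_match, p_yes_non)
  data.frame(
    participant_id = rep(sprintf("p%04d", seq_len(n_participants)),
                         each = n_trials),
    condition_context = condition_context,
    stimulus_id = stim_col,
    is_match = match_col,
    response_yes = runif(length(stim_col)) < p_yes,
    trial_index = rep(seq_len(n_trials), n_participants),
    stringsAsFactors = FALSE)
}
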