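#' Build a stimulus-by-response confusion matrix
#'
#' Counts trials with true category `i` and response `j` for one participant
#' (or any set of trials passed in). Rows are the true stimulus categories,
#' columns the responses.
#'
#' @param responses Trial table with a response column; if it lacks a truth
#'   column, `corpus` is joined on `stimulus_id` to supply it.
#' @param corpus Optional stimulus metadata with `stimulus_id` and the truth
#'   column.
#' @param participant Optional participant id to filter on.
#' @param categories Category levels (default the 10 contexts `c1`..`c10`).
#' @param truth_col,response_col Column names for truth and response.
#' @return A `k x k` integer matrix of class `confusion_matrix` with
#'   attribute `N`.
#' @export
confusion_matrix <- function(responses, corpus = NULL, participant = NULL,
                             categories = paste0("c", 1:10),
                             truth_col = "context_id",
                             response_col = "chosen_context") {
  if (!is.null(participant)) {
    responses <- responses[responses$participant_id == participant, , drop = FALSE]
  }
  if (!truth_col %in% names(responses)) {
    if (is.null(corpus)) stop("responses lack '", truth_col,
                              "' and no corpus was given to join on")
    responses[[truth_col]] <-
      corpus[[truth_col]][match(responses$stimulus_id, corpus$stimulus_id)]
  }
  bad <- setdiff(unique(responses[[response_col]]), categories)
  if (length(bad) > 0)
    stop("response label(s) outside the categories: ", paste(bad, collapse = ", "))
  cm <- table(factor(responses[[truth_col]], categories),
              factor(responses[[response_col]], categories))
  cm <- unclass(cm)
  structure(cm, class = "confusion_matrix", N = sum(cm))
}

#' Unbiased hit rate (Hu score) per category
#'
#' `Hu_i = counts\[i,i\]^2 / (row_i * col_i)`: the product of the hit rate
#' and the precision for category `i`, correcting raw accuracy for response
#' bias. Defined as 0 when the category was never presented or never chosen.
#'
#' @param cm A [confusion_matrix()] (any square matrix works).
#' @return Named numeric vector of Hu scores in \[0, 1\].
#' @export
unbiased_hit_rate <- function(cm) {
  rowm <- rowSums(cm)
  colm <- colSums(cm)
  d <- diag(as.matrix(cm))
  hu <- ifelse(rowm * colm > 0, d^2 / (rowm * colm), 0)
  setNames(hu, rownames(cm))
}

#' Wagner chance level per category
#'
#' The Hu score expected under random responding:
#' `chance_i = (row_i * col_i) / N^2`, using the participant's own response
#' marginals.
#'
#' @inheritParams unbiased_hit_rate
#' @return Named numeric vector of chance proportions.
#' @export
wagner_chance <- function(cm) {
  N <- sum(cm)
  if (N == 0) stop("empty confusion matrix")
  setNames(rowSums(cm) * colSums(cm) / N^2, rownames(cm))
}

#' Arcsine-square-root transform of a proportion
#'
#' `asin(sqrt(p))`, the standard variance-stabilizing transform for
#' proportions, mapping \[0, 1\] to \[0, pi/2\].
#'
#' @param p Proportion(s) in \[0, 1\].
#' @return Radians.
#' @export
arcsine_transform <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

#' Per-participant Hu and chance scores for the categorization task
#'
#' Vectorized over participants: tabulates (participant, truth, response)
#' in one pass and applies the Hu and Wagner formulas per participant and
#' category, returning both raw and arcsine-transformed values.
#'
#' @inheritParams confusion_matrix
#' @return Data frame: `participant_id`, `category`, `hu`, `chance`,
#'   `hu_arcsine`, `chance_arcsine`.
#' @export
hu_scores <- function(responses, corpus = NULL,
                      categories = paste0("c", 1:10),
                      truth_col = "context_id",
                      response_col = "chosen_context") {
  if (!truth_col %in% names(responses)) {
    if (is.null(corpus)) stop("responses lack '", truth_col,
                              "' and no corpus was given to join on")
    responses[[truth_col]] <-
      corpus[[truth_col]][match(responses$stimulus_id, corpus$stimulus_id)]
  }
  bad <- setdiff(unique(responses[[response_col]]), categories)
  if (length(bad) > 0)
    stop("response label(s) outside the categories: ", paste(bad, collapse = ", "))
  tab <- table(responses$participant_id,
               factor(responses[[truth_col]], categories),
               factor(responses[[response_col]], categories))
  parts <- dimnames(tab)[[1]]
  k <- length(categories)
  rowm <- apply(tab, c(1, 2), sum)           # participants x truth
  colm <- apply(tab, c(1, 3), sum)           # participants x response
  diag_idx <- cbind(rep(seq_along(parts), k),
                    rep(seq_len(k), each = length(parts)),
                    rep(seq_len(k), each = length(parts)))
  d <- matrix(tab[diag_idx], nrow = length(parts))
  N <- rowSums(rowm)
  prod_m <- rowm * colm
  hu <- ifelse(prod_m > 0, d^2 / prod_m, 0)
  chance <- prod_m / N^2
  out <- data.frame(
    participant_id = rep(parts, k),
    category = rep(categories, each = length(parts)),
    hu = as.vector(hu), chance = as.vector(chance),
    stringsAsFactors = FALSE)
  out$hu_arcsine <- arcsine_transform(out$hu)
  out$chance_arcsine <- arcsine_transform(out$chance)
  out[order(out$participant_id, out$category), ]
}

#' Paired signed-rank tests of Hu scores against chance
#'
#' For each category, a two-sided paired Wilcoxon signed-rank test of the
#' arcsine-transformed Hu scores against the arcsine-transformed chance
#' levels across participants, Bonferroni-corrected by the number of
#' categories. The exact null distribution is used for n <= `exact_max`
#' pairs without ties or zero differences; otherwise the normal approximation
#' with continuity correction. Zero differences are dropped (Wilcoxon's
#' policy); if all differences are zero the p-value is 1 by convention.
#'
#' @param scores Output of [hu_scores()] (or any data frame with
#'   `participant_id`, `category`, `hu_arcsine`, `chance_arcsine`).
#' @param alpha Family alpha before Bonferroni correction.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return Data frame: `category`, `n`, `statistic` (V), `p`,
#'   `alpha_corrected`, `significant`, `direction`.
#' @export
wilcoxon_vs_chance <- function(scores, alpha = 0.05, exact_max = 25) {
  cats <- unique(scores$category)
  k <- length(cats)
  alpha_c <- alpha / k
  rows <- lapply(cats, function(cc) {
    s <- scores[scores$category == cc, ]
    d <- s$hu_arcsine - s$chance_arcsine
    n <- length(d)
    if (n < 5) stop("need at least 5 pairs per category")
    d_nz <- d[d != 0]
    if (length(d_nz) == 0) {
      return(data.frame(category = cc, n = n, statistic = 0, p = 1,
                        alpha_corrected = alpha_c, significant = FALSE,
                        direction = "none"))
    }
    use_exact <- length(d_nz) <= exact_max && !any(duplicated(abs(d_nz)))
    wt <- suppressWarnings(
      wilcox.test(d, exact = use_exact, correct = TRUE))
    data.frame(category = cc, n = n, statistic = unname(wt$statistic),
               p = wt$p.value, alpha_corrected = alpha_c,
               significant = wt$p.value < alpha_c,
               direction = if (median(d) > 0) "above" else
                 if (median(d) < 0) "below" else "none",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Recode 5-point ratings and score their correctness
#'
#' Ratings 1–5 are recoded to -2..2 (`value = rating - 3`). A response is
#' correct when the sign of the recoded value matches the stimulus class:
#' high arousal needs `value > 0`, low `value < 0`, medium `value = 0`;
#' positive valence needs `value > 0`, negative `value < 0`. Stimuli with no
#' specific valence are excluded from valence scoring (`correct = NA`).
#'
#' @param rating Integer vector of raw ratings in 1..5.
#' @param truth Character vector of stimulus classes (arousal: high, medium,
#'   low; valence: positive, negative, none).
#' @param scale `"arousal"` or `"valence"`.
#' @return Data frame with `value`, `truth_class`, `correct`.
#' @export
recode_and_score_ratings <- function(rating, truth,
                                     scale = c("arousal", "valence")) {
  scale <- match.arg(scale)
  if (any(!rating %in% 1:5)) stop("ratings must be integers in 1..5")
  value <- as.integer(rating) - 3L
  correct <- switch(scale,
    arousal = (truth == "high" & value > 0) |
      (truth == "low" & value < 0) |
      (truth == "medium" & value == 0),
    valence = ifelse(truth == "none", NA,
                     (truth == "positive" & value > 0) |
                       (truth == "negative" & value < 0)))
  data.frame(value = value, truth_class = truth, correct = correct,
             stringsAsFactors = FALSE)
}

# response class implied by a recoded rating value
rating_response_class <- function(value, scale) {
  if (scale == "arousal") {
    ifelse(value > 0, "high", ifelse(value < 0, "low", "medium"))
  } else {
    ifelse(value > 0, "positive", ifelse(value < 0, "negative", "neutral"))
  }
}

#' Per-participant Hu and chance scores for rating judgments
#'
#' The forced-choice Hu machinery needs a stimulus-by-response table, which
#' the 5-point rating scales do not directly provide. Each recoded rating is
#' mapped to a response class by its sign (arousal: high/medium/low; valence:
#' positive/neutral/negative) and a class-by-class confusion table is built
#' per participant; Hu and Wagner chance then follow the usual formulas over
#' the named row/column pairs. Stimuli without a specific valence are
#' excluded from the valence table's rows.
#'
#' @param responses Experiment-1 trial table (needs `arousal_rating`,
#'   `valence_rating`).
#' @param corpus Stimulus metadata (for `arousal` and `valence` classes).
#' @param scale `"arousal"` or `"valence"`.
#' @return As [hu_scores()], with `category` the arousal/valence classes.
#' @export
hu_scores_ratings <- function(responses, corpus,
                              scale = c("arousal", "valence")) {
  scale <- match.arg(scale)
  truth <- corpus[[scale]][match(responses$stimulus_id, corpus$stimulus_id)]
  rating <- responses[[paste0(scale, "_rating")]]
  value <- as.integer(rating) - 3L
  resp_class <- rating_response_class(value, scale)
  keep <- truth != "none"
  stim_classes <- if (scale == "arousal") c("high", "medium", "low")
                  else c("positive", "negative")
  resp_classes <- if (scale == "arousal") c("high", "medium", "low")
                  else c("positive", "negative", "neutral")
  tab <- table(responses$participant_id[keep],
               factor(truth[keep], stim_classes),
               factor(resp_class[keep], resp_classes))
  parts <- dimnames(tab)[[1]]
  rowm <- apply(tab, c(1, 2), sum)
  colm <- apply(tab, c(1, 3), sum)[, stim_classes, drop = FALSE]
  d <- vapply(seq_along(stim_classes), function(i) tab[, i, i],
              numeric(length(parts)))
  N <- rowSums(rowm)
  prod_m <- rowm * colm
  hu <- ifelse(prod_m > 0, d^2 / prod_m, 0)
  chance <- prod_m / N^2
  out <- data.frame(
    participant_id = rep(parts, length(stim_classes)),
    category = rep(stim_classes, each = length(parts)),
    hu = as.vector(hu), chance = as.vector(chance),
    stringsAsFactors = FALSE)
  out$hu_arcsine <- arcsine_transform(out$hu)
  out$chance_arcsine <- arcsine_transform(out$chance)
  out[order(out$participant_id, out$category), ]
}

#' Negativity bias in valence ratings
#'
#' Mean recoded valence rating per participant across stimuli with positive
#' or negative valence, and a one-sample signed-rank test of these means
#' against zero. Negative means indicate a bias toward judging vocalizations
#' as negative.
#'
#' @inheritParams hu_scores_ratings
#' @return List with `participant_means`, `mean`, `statistic`, `p`.
#' @export
valence_bias <- function(responses, corpus) {
  truth <- corpus$valence[match(responses$stimulus_id, corpus$stimulus_id)]
  keep <- truth %in% c("positive", "negative")
  value <- responses$valence_rating[keep] - 3L
  means <- tapply(value, responses$participant_id[keep], mean)
  if (all(means == 0)) {
    return(list(participant_means = means, mean = 0, statistic = 0, p = 1))
  }
  wt <- suppressWarnings(wilcox.test(as.numeric(means), exact = FALSE,
                                     correct = TRUE))
  list(participant_means = means, mean = mean(means),
       statistic = unname(wt$statistic), p = wt$p.value)
}

#' Early-versus-late accuracy (fatigue check)
#'
#' Compares per-participant accuracy in the first `n_window` and the last
#' `n_window` trials of the session, separately for the context choice and
#' the arousal and valence rating judgments, with paired signed-rank tests.
#'
#' @inheritParams hu_scores_ratings
#' @param n_window Number of trials in each window (default 30).
#' @return Data frame: `judgment`, `early_mean`, `late_mean`, `statistic`,
#'   `p`.
#' @export
fatigue_check <- function(responses, corpus, n_window = 30) {
  if (!"trial_index" %in% names(responses)) stop("trial_index is required")
  n_trials <- max(responses$trial_index)
  if (n_trials < 2 * n_window)
    stop("participants need at least ", 2 * n_window, " trials")
  m <- match(responses$stimulus_id, corpus$stimulus_id)
  correct <- data.frame(
    context = responses$chosen_context == corpus$context_id[m],
    arousal = recode_and_score_ratings(responses$arousal_rating,
                                       corpus$arousal[m], "arousal")$correct,
    valence = recode_and_score_ratings(responses$valence_rating,
                                       corpus$valence[m], "valence")$correct)
  early <- responses$trial_index <= n_window
  late <- responses$trial_index > n_trials - n_window
  rows <- lapply(names(correct), function(j) {
    acc_e <- tapply(correct[[j]][early], responses$participant_id[early],
                    mean, na.rm = TRUE)
    acc_l <- tapply(correct[[j]][late], responses$participant_id[late],
                    mean, na.rm = TRUE)
    d <- acc_e - acc_l
    if (all(d == 0)) {
      return(data.frame(judgment = j, early_mean = mean(acc_e),
                        late_mean = mean(acc_l), statistic = 0, p = 1,
                        stringsAsFactors = FALSE))
    }
    wt <- suppressWarnings(wilcox.test(as.numeric(d), exact = FALSE,
                                       correct = TRUE))
    data.frame(judgment = j, early_mean = mean(acc_e), late_mean = mean(acc_l),
               statistic = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Screen participants for outlying accuracy
#'
#' Excludes participants whose accuracy is `n_sd` standard deviations or more
#' below the sample mean (mean and s.d. computed once on the full sample).
#'
#' @param accuracy Named numeric vector of per-participant accuracies.
#' @param n_sd Exclusion threshold in standard deviations (default 3).
#' @return List with `retained`, `excluded` (names), and `threshold`.
#' @export
screen_outliers <- function(accuracy, n_sd = 3) {
  if (length(accuracy) < 3) stop("need at least 3 participants")
  s <- sd(accuracy)
  thr <- mean(accuracy) - n_sd * s
  excluded <- if (s == 0) character(0) else names(accuracy)[accuracy <= thr]
  list(retained = setdiff(names(accuracy), excluded),
       excluded = excluded, threshold = thr)
}

#' A priori sample size for a one-sample t-test
#'
#' Smallest `n` such that the one-sample (or paired) t-test with standardized
#' effect size `d` attains the target power: at each `n` the power is the
#' upper tail of the noncentral t distribution with `df = n - 1` and
#' noncentrality `d * sqrt(n)` beyond the alpha critical value (split for the
#' two-tailed case).
#'
#' @param d Standardized effect size (> 0).
#' @param alpha Significance level.
#' @param power Target power.
#' @param tail `"one"` or `"two"`.
#' @param n_max Search bound.
#' @return The minimal integer `n`.
#' @export
power_n_ttest <- function(d, alpha, power, tail = c("one", "two"),
                          n_max = 1e6) {
  tail <- match.arg(tail)
  if (d <= 0) stop("d must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must lie in (0, 1)")
  pow <- function(n) {
    df <- n - 1
    ncp <- d * sqrt(n)
    if (tail == "one") {
      1 - pt(qt(1 - alpha, df), df, ncp)
    } else {
      crit <- qt(1 - alpha / 2, df)
      1 - pt(crit, df, ncp) + pt(-crit, df, ncp)
    }
  }
  for (n in 2:n_max) {
    if (pow(n) >= power) return(n)
  }
  stop("power ", power, " not attainable with n <= ", n_max)
}
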