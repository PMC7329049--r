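#' Signal-detection sensitivity (d-prime) per participant
#'
#' Hit rate is the proportion of matching ("signal") trials answered yes,
#' false-alarm rate the proportion of non-matching ("noise") trials answered
#' yes. Rates of exactly 0 are replaced by `0.5 / n` and rates of exactly 1
#' by `(n - 0.5) / n`, with `n` that participant's own signal (respectively
#' noise) trial count, so the normal quantile is always finite;
#' `d' = qnorm(hit_adj) - qnorm(fa_adj)`.
#'
#' @param responses Yes/no trial table from [simulate_exp2()] (columns
#'   `participant_id`, `condition_context`, `is_match`, `response_yes`).
#' @param participant Optional single participant id to filter on.
#' @return Data frame of class `sdt_result`, one row per participant:
#'   `participant_id`, `condition_context`, `n_signal`, `n_noise`,
#'   `hit_rate`, `fa_rate`, `hit_adj`, `fa_adj`, `dprime`.
#' @export
dprime <- function(responses, participant = NULL) {
  if (!is.null(participant)) {
    responses <- responses[responses$participant_id == participant, , drop = FALSE]
  }
  key <- interaction(responses$participant_id, responses$condition_context,
                     drop = TRUE)
  agg <- function(x, f) as.numeric(tapply(x, key, f))
  n_signal <- agg(responses$is_match, sum)
  n_noise <- agg(!responses$is_match, sum)
  if (any(n_signal < 1) || any(n_noise < 1))
    stop("every participant needs at least one signal and one noise trial")
  hits <- agg(responses$response_yes & responses$is_match, sum)
  fas <- agg(responses$response_yes & !responses$is_match, sum)
  first <- !duplicated(key)
  hit_rate <- hits / n_signal
  fa_rate <- fas / n_noise
  adjust <- function(rate, n) {
    ifelse(rate == 0, 0.5 / n, ifelse(rate == 1, (n - 0.5) / n, rate))
  }
  hit_adj <- adjust(hit_rate, n_signal)
  fa_adj <- adjust(fa_rate, n_noise)
  out <- data.frame(
    participant_id = responses$participant_id[first][order(key[first])],
    condition_context = responses$condition_context[first][order(key[first])],
    n_signal = n_signal, n_noise = n_noise,
    hit_rate = hit_rate, fa_rate = fa_rate,
    hit_adj = hit_adj, fa_adj = fa_adj,
    dprime = qnorm(hit_adj) - qnorm(fa_adj),
    stringsAsFactors = FALSE)
  class(out) <- c("sdt_result", "data.frame")
  out
}

#' One-sample t-tests of d-prime against chance
#'
#' Random guessing corresponds to d-prime 0; each context's participant
#' d-primes are tested against 0 with a one-sample t-test at the
#' Bonferroni-corrected level (default 0.005 = 0.05/10).
#'
#' @param sdt A [dprime()] table over many participants.
#' @param alpha Per-test significance level after correction.
#' @return Data frame: `context`, `n`, `mean_dprime`, `t`, `df`, `p`,
#'   `ci_lo`, `ci_hi`, `significant`, `zero_variance`.
#' @export
dprime_vs_chance <- function(sdt, alpha = 0.005) {
  rows <- lapply(split(sdt, sdt$condition_context), function(s) {
    if (nrow(s) < 2) stop("need at least 2 participants per context")
    if (sd(s$dprime) == 0) {
      return(data.frame(context = s$condition_context[1], n = nrow(s),
                        mean_dprime = mean(s$dprime), t = NA_real_,
                        df = nrow(s) - 1, p = NA_real_,
                        ci_lo = mean(s$dprime), ci_hi = mean(s$dprime),
                        significant = FALSE, zero_variance = TRUE,
                        stringsAsFactors = FALSE))
    }
    tt <- t.test(s$dprime, mu = 0)
    data.frame(context = s$condition_context[1], n = nrow(s),
               mean_dprime = mean(s$dprime), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
               significant = tt$p.value < alpha, zero_variance = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare accuracy for negative versus positive vocalizations
#'
#' Experiment-1 mode: per participant, the arcsine-transformed Hu scores are
#' averaged over the negative and over the positive categories and compared
#' with a paired signed-rank test. Experiment-2 mode: a one-way ANOVA of
#' participant d-primes by the valence of their condition context. Stimuli
#' or contexts without a specific valence are excluded.
#'
#' @param x For `design = "exp1"`, a [hu_scores()]-style table plus
#'   `valence_of`, a named vector mapping category to valence; for
#'   `design = "exp2"`, a [dprime()] table plus `valence_of` mapping context
#'   to valence.
#' @param valence_of Named character vector: category/context -> valence.
#' @param design `"exp1"` or `"exp2"`.
#' @return List with `design`, `direction`, test statistics and `p`.
#' @export
valence_accuracy_contrast <- function(x, valence_of,
                                      design = c("exp1", "exp2")) {
  design <- match.arg(design)
  if (design == "exp1") {
    val <- valence_of[x$category]
    keep <- val %in% c("positive", "negative")
    x <- x[keep, ]
    val <- val[keep]
    if (length(unique(val)) < 2) stop("need both valence groups")
    neg <- tapply(x$hu_arcsine[val == "negative"],
                  x$participant_id[val == "negative"], mean)
    pos <- tapply(x$hu_arcsine[val == "positive"],
                  x$participant_id[val == "positive"], mean)
    pos <- pos[names(neg)]
    d <- as.numeric(neg - pos)
    if (all(d == 0)) {
      return(list(design = design, direction = "none", statistic = 0, p = 1,
                  mean_negative = mean(neg), mean_positive = mean(pos)))
    }
    wt <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = TRUE))
    list(design = design,
         direction = if (median(d) > 0) "negative > positive"
                     else if (median(d) < 0) "positive > negative" else "none",
         statistic = unname(wt$statistic), p = wt$p.value,
         mean_negative = mean(neg), mean_positive = mean(pos))
  } else {
    val <- valence_of[x$condition_context]
    keep <- val %in% c("positive", "negative")
    x <- x[keep, ]
    val <- factor(val[keep], c("positive", "negative"))
    if (nlevels(droplevels(val)) < 2) stop("need both valence groups")
    fit <- aov(x$dprime ~ val)
    s <- summary(fit)[[1]]
    means <- tapply(x$dprime, val, mean)
    list(design = design,
         direction = if (means["negative"] > means["positive"])
           "negative > positive" else "positive > negative",
         F = s$`F value`[1], df1 = s$Df[1], df2 = s$Df[2],
         p = s$`Pr(>F)`[1],
         mean_negative = unname(means["negative"]),
         mean_positive = unname(means["positive"]))
  }
}
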