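test_that("confusion_matrix tallies trials exactly", {
  resp <- data.frame(
    participant_id = "p1",
    stimulus_id = paste0("s", 1:5),
    chosen_context = c("c1", "c2", "c2", "c1", "c3"),
    stringsAsFactors = FALSE)
  corp <- data.frame(stimulus_id = paste0("s", 1:5),
                     context_id = c("c1", "c1", "c2", "c2", "c3"),
                     stringsAsFactors = FALSE)
  cm <- confusion_matrix(resp, corp, categories = paste0("c", 1:3))
  expect_equal(unclass(cm)[1:3, 1:3],
               matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, byrow = TRUE,
                      dimnames = list(paste0("c", 1:3), paste0("c", 1:3))),
               ignore_attr = TRUE)
  expect_equal(rownames(cm), paste0("c", 1:3))
  expect_equal(colnames(cm), paste0("c", 1:3))
  expect_equal(attr(cm, "N"), 5)
  # perfect responding gives a diagonal matrix with equal marginals
  resp2 <- resp
  resp2$chosen_context <- corp$context_id
  cm2 <- confusion_matrix(resp2, corp, categories = paste0("c", 1:3))
  expect_equal(rowSums(cm2), colSums(cm2))
  expect_equal(sum(diag(cm2)), 5)
  # out-of-category response is rejected
  resp$chosen_context[1] <- "zebra"
  expect_error(confusion_matrix(resp, corp, categories = paste0("c", 1:3)),
               "zebra")
})

test_that("Hu and Wagner chance match the hand-worked example", {
  cm <- matrix(c(3, 1, 2, 4), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  hu <- unbiased_hit_rate(cm)
  expect_equal(unname(hu), c(9 / 20, 16 / 30))
  ch <- wagner_chance(cm)
  expect_equal(unname(ch), c(0.20, 0.30))
  # perfect diagonal: all 1; zero correct: 0
  expect_equal(unname(unbiased_hit_rate(diag(c(4, 6)))), c(1, 1))
  cm0 <- matrix(c(0, 2, 1, 3), 2)
  expect_equal(unname(unbiased_hit_rate(cm0))[1], 0)
})

test_that("Hu identities hold on random confusion matrices", {
  set.seed(1)
  for (i in 1:200) {
    k <- sample(2:10, 1)
    cm <- matrix(rpois(k * k, 3), k, dimnames = list(paste0("r", 1:k),
                                                     paste0("r", 1:k)))
    if (sum(cm) == 0) next
    hu <- unbiased_hit_rate(cm)
    rec <- diag(cm) / pmax(1e-12, rowSums(cm))
    prec <- diag(cm) / pmax(1e-12, colSums(cm))
    expect_equal(unname(hu), unname(rec * prec), tolerance = 1e-12)
    expect_lte(sum(wagner_chance(cm)), 1 + 1e-12)
  }
})

test_that("a uniform guesser's Hu approaches Wagner chance", {
  set.seed(2)
  k <- 5
  truth <- sample(k, 1e5, replace = TRUE)
  resp <- sample(k, 1e5, replace = TRUE)
  cm <- table(truth, resp)
  hu <- unbiased_hit_rate(cm)
  ch <- wagner_chance(cm)
  expect_true(all(abs(hu - ch) / ch < 0.05))
})

test_that("arcsine transform hits its anchors and rejects bad input", {
  expect_equal(arcsine_transform(c(0, 0.5, 1)), c(0, pi / 4, pi / 2))
  expect_error(arcsine_transform(1.2), "0, 1")
  expect_error(arcsine_transform(-0.1), "0, 1")
})

test_that("exact Wilcoxon p-values match full sign enumeration", {
  set.seed(3)
  for (i in 1:25) {
    n <- sample(5:10, 1)
    repeat {
      d <- round(rnorm(n), 3)
      if (!any(d == 0) && !any(duplicated(abs(d)))) break
    }
    res <- wilcoxon_vs_chance(scores_from_diffs(matrix(d, ncol = 1)))
    expect_equal(res$p, enumerate_signrank_p(d), tolerance = 1e-12)
  }
})

test_that("wilcoxon_vs_chance handles degenerate and null inputs", {
  # hu identical to chance: all-zero differences -> p = 1, not significant
  res <- wilcoxon_vs_chance(scores_from_diffs(matrix(0, 8, 3)))
  expect_equal(res$p, rep(1, 3))
  expect_false(any(res$significant))
  expect_equal(res$alpha_corrected, rep(0.05 / 3, 3))
  expect_error(wilcoxon_vs_chance(scores_from_diffs(matrix(1, 4, 1))),
               "at least 5")
  # a clearly positive shift is detected and labelled
  res2 <- wilcoxon_vs_chance(scores_from_diffs(matrix(0.2 + 0.01 * 1:12,
                                                      ncol = 1)))
  expect_true(res2$significant)
  expect_equal(res2$direction, "above")
})

test_that("rating recoding and correctness follow the scale rules", {
  r <- recode_and_score_ratings(c(5, 3, 4), c("high", "medium", "low"),
                                "arousal")
  expect_equal(r$value, c(2L, 0L, 1L))
  expect_equal(r$correct, c(TRUE, TRUE, FALSE))
  v <- recode_and_score_ratings(c(4, 2, 4), c("negative", "negative", "none"),
                                "valence")
  expect_equal(v$correct, c(FALSE, TRUE, NA))
  expect_error(recode_and_score_ratings(6, "high", "arousal"), "1..5")
})

test_that("valence_bias detects a shift and is null on symmetric ratings", {
  corp <- data.frame(stimulus_id = paste0("s", 1:4),
                     valence = c("positive", "negative", "positive",
                                 "negative"),
                     stringsAsFactors = FALSE)
  sym <- expand.grid(participant_id = sprintf("p%02d", 1:8),
                     stimulus_id = paste0("s", 1:4),
                     stringsAsFactors = FALSE)
  sym$valence_rating <- rep(c(2L, 4L), length.out = nrow(sym))
  vb <- valence_bias(sym, corp)
  expect_equal(vb$mean, 0)
  expect_equal(vb$p, 1)
  neg <- sym
  neg$valence_rating <- 2L  # every rating one point negative
  vbn <- valence_bias(neg, corp)
  expect_equal(vbn$mean, -1)
  expect_lt(vbn$p, 0.05)
})

test_that("fatigue_check compares the first and last trial windows", {
  mk <- function(n_trials, late_flip) {
    corp <- data.frame(stimulus_id = paste0("s", 1:n_trials),
                       context_id = "c1", arousal = "medium",
                       valence = "positive", stringsAsFactors = FALSE)
    resp <- expand.grid(participant_id = sprintf("p%02d", 1:8),
                        trial_index = 1:n_trials, stringsAsFactors = FALSE)
    resp$stimulus_id <- paste0("s", resp$trial_index)
    resp$chosen_context <- "c1"
    resp$arousal_rating <- 3L
    resp$valence_rating <- 4L
    if (late_flip) {
      late <- resp$trial_index > n_trials - 30
      resp$chosen_context[late] <- "c2"
      resp$arousal_rating[late] <- 5L
    }
    list(resp = resp, corp = corp)
  }
  s <- mk(60, late_flip = FALSE)           # stationary, exactly 60 trials
  f <- fatigue_check(s$resp, s$corp)
  expect_equal(f$p, rep(1, 3))
  expect_equal(f$early_mean, f$late_mean)
  d <- mk(80, late_flip = TRUE)            # accuracy collapses late
  fd <- fatigue_check(d$resp, d$corp)
  ctx <- fd[fd$judgment == "context", ]
  expect_gt(ctx$early_mean, ctx$late_mean)
  expect_lt(ctx$p, 0.05)
  expect_error(fatigue_check(s$resp[s$resp$trial_index <= 40, ], s$corp),
               "at least 60")
  s$resp$trial_index <- NULL
  expect_error(fatigue_check(s$resp, s$corp), "trial_index")
})

test_that("dprime matches its worked examples and adjustment rule", {
  mk_resp <- function(hits, n_sig, fas, n_noise) {
    data.frame(
      participant_id = "p1", condition_context = "c1",
      is_match = c(rep(TRUE, n_sig), rep(FALSE, n_noise)),
      response_yes = c(rep(TRUE, hits), rep(FALSE, n_sig - hits),
                       rep(TRUE, fas), rep(FALSE, n_noise - fas)),
      stringsAsFactors = FALSE)
  }
  # hit = fa = 0.5 -> 0
  expect_equal(dprime(mk_resp(10, 20, 10, 20))$dprime, 0)
  # hit 0.69146 / fa 0.30854 -> 1.000 (z quantiles +/- 0.5); use counts
  # 69146/100000 and 30854/100000 to realize those exact rates
  r <- mk_resp(69146, 100000, 30854, 100000)
  expect_equal(dprime(r)$dprime, 1, tolerance = 1e-3)
  # 8 signal trials all yes, 24 noise trials all no -> adjusted rates
  r2 <- dprime(mk_resp(8, 8, 0, 24))
  expect_equal(r2$hit_adj, 7.5 / 8)
  expect_equal(r2$fa_adj, 0.5 / 24)
  expect_equal(r2$dprime, qnorm(7.5 / 8) - qnorm(0.5 / 24))
  # antisymmetry: swapping hits and false alarms negates d-prime
  a <- dprime(mk_resp(15, 20, 5, 20))$dprime
  b <- dprime(mk_resp(5, 20, 15, 20))$dprime
  expect_equal(a, -b)
  expect_error(dprime(mk_resp(3, 3, 0, 0)), "at least one")
})

test_that("dprime_vs_chance flags zero variance and tests against zero", {
  sdt <- data.frame(participant_id = sprintf("p%02d", 1:10),
                    condition_context = "c1", dprime = 0)
  res <- dprime_vs_chance(sdt)
  expect_true(res$zero_variance)
  expect_false(res$significant)
  sdt2 <- sdt
  set.seed(4)
  sdt2$dprime <- 1 + rnorm(10, sd = 0.1)
  res2 <- dprime_vs_chance(sdt2)
  expect_true(res2$significant)
  expect_equal(res2$mean_dprime, mean(sdt2$dprime))
})

test_that("valence_accuracy_contrast works in both designs", {
  val <- c(c1 = "negative", c2 = "positive", c3 = "none")
  scores <- expand.grid(participant_id = sprintf("p%02d", 1:12),
                        category = c("c1", "c2", "c3"),
                        stringsAsFactors = FALSE)
  scores$hu_arcsine <- 0.5
  same <- valence_accuracy_contrast(scores, val, "exp1")
  expect_equal(same$p, 1)
  expect_equal(same$direction, "none")
  up <- scores
  up$hu_arcsine[up$category == "c1"] <-
    0.6 + 0.005 * seq_len(sum(up$category == "c1"))
  res <- valence_accuracy_contrast(up, val, "exp1")
  expect_equal(res$direction, "negative > positive")
  expect_lt(res$p, 0.05)
  # exp2: ANOVA on d-prime by context valence
  set.seed(5)
  sdt <- data.frame(
    participant_id = sprintf("p%03d", 1:60),
    condition_context = rep(c("c1", "c2", "c3"), each = 20),
    dprime = c(rnorm(20, 1.2, 0.3), rnorm(20, 0.4, 0.3), rnorm(20, 5, 1)))
  r2 <- valence_accuracy_contrast(sdt, val, "exp2")
  expect_equal(r2$direction, "negative > positive")
  expect_lt(r2$p, 0.01)
  expect_equal(r2$df1, 1)  # "none" contexts are excluded
  expect_error(valence_accuracy_contrast(scores[scores$category == "c1", ],
                                         val, "exp1"), "both valence")
})

test_that("screen_outliers applies the 3-sd rule on the full sample", {
  acc <- setNames(rep(0.8, 10), sprintf("p%02d", 1:10))
  expect_equal(screen_outliers(acc)$excluded, character(0))  # sd = 0
  set.seed(6)
  acc2 <- setNames(c(rnorm(30, 0.8, 0.02), NA), sprintf("p%02d", 1:31))
  acc2[31] <- mean(acc2[1:30]) - 4 * sd(acc2[1:30])
  scr <- screen_outliers(acc2)
  # verify the threshold arithmetic directly on the full sample
  thr <- mean(acc2) - 3 * sd(acc2)
  expect_equal(scr$threshold, thr)
  expect_equal(scr$excluded, names(acc2)[acc2 <= thr])
  expect_true("p31" %in% scr$excluded)
  expect_error(screen_outliers(acc[1:2]), "at least 3")
})

test_that("power_n_ttest reproduces the design n's and is monotone", {
  expect_equal(power_n_ttest(0.2, 0.005, 0.80, "one"), 296)
  expect_equal(power_n_ttest(0.2, 0.05, 0.80, "one"), 156)
  # d = 1 case against a brute-force noncentral-t search
  brute <- NULL
  for (n in 2:50) {
    if (1 - pt(qt(0.95, n - 1), n - 1, ncp = sqrt(n)) >= 0.8) {
      brute <- n
      break
    }
  }
  expect_equal(power_n_ttest(1, 0.05, 0.80, "one"), brute)
  expect_equal(brute, 8)
  # monotone in d, alpha (non-increasing) and power (non-decreasing)
  for (d in c(0.2, 0.5)) {
    expect_gte(power_n_ttest(d, 0.01, 0.8, "one"),
               power_n_ttest(d, 0.05, 0.8, "one"))
    expect_gte(power_n_ttest(d, 0.05, 0.9, "one"),
               power_n_ttest(d, 0.05, 0.8, "one"))
  }
  expect_gte(power_n_ttest(0.2, 0.05, 0.8, "one"),
             power_n_ttest(0.5, 0.05, 0.8, "one"))
  # two-tailed needs more than one-tailed
  expect_gte(power_n_ttest(0.2, 0.05, 0.8, "two"),
             power_n_ttest(0.2, 0.05, 0.8, "one"))
  expect_error(power_n_ttest(-1, 0.05, 0.8), "positive")
  expect_error(power_n_ttest(0.2, 1.5, 0.8), "alpha")
  expect_error(power_n_ttest(0.2, 0.05, 2), "power")
  expect_error(power_n_ttest(5, 0.05, 0.8, n_max = 2), "not attainable")
})

test_that("hu_scores agrees with per-participant confusion matrices", {
  corp <- cached_paper_corpus()
  resp <- simulate_exp1(corp, 3, listener_model("qualitative"), seed = 9)
  hs <- hu_scores(resp, corp)
  for (p in unique(resp$participant_id)) {
    cm <- confusion_matrix(resp, corp, participant = p)
    hu <- unbiased_hit_rate(cm)
    ch <- wagner_chance(cm)
    sub <- hs[hs$participant_id == p, ]
    expect_equal(sub$hu[match(names(hu), sub$category)], unname(hu))
    expect_equal(sub$chance[match(names(ch), sub$category)], unname(ch))
  }
})

test_that("hu_scores_ratings builds class-level Hu tables", {
  corp <- cached_paper_corpus()
  resp <- simulate_exp1(corp, 5, listener_model("qualitative"), seed = 10)
  ha <- hu_scores_ratings(resp, corp, "arousal")
  expect_setequal(unique(ha$category), c("high", "medium", "low"))
  expect_equal(nrow(ha), 5 * 3)
  expect_true(all(ha$hu >= 0 & ha$hu <= 1))
  hv <- hu_scores_ratings(resp, corpus = corp, "valence")
  expect_setequal(unique(hv$category), c("positive", "negative"))
  expect_true(all(hv$chance > 0 & hv$chance < 1))
})
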