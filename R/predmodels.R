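#' Classify stimulus labels from acoustic features
#'
#' Multinomial logistic regression (binomial when the outcome has two
#' levels, both fit by maximum likelihood through [nnet::multinom()]) of a
#' stimulus label on the selected acoustic features, z-scored so
#' coefficients are per standard deviation. Reports per-predictor
#' likelihood-ratio chi-squares (deviance difference against the model
#' without that predictor, df = classes - 1), the overall model chi-square
#' against the intercept-only model, and the in-sample classification
#' agreement. If the fit shows signs of separation (unbounded coefficients)
#' it is refit with a small ridge penalty and flagged.
#'
#' @param features Data frame of predictors (rows = stimuli).
#' @param labels Vector of class labels (length `nrow(features)`).
#' @param feature_set Character vector of predictor columns (default the six
#'   canonical features present in `features`).
#' @param standardize Z-score predictors before fitting (default TRUE).
#' @param ridge_decay Weight-decay penalty used only for the separation
#'   fallback.
#' @return Object of class `classification_fit`: `coefficients`,
#'   `lr_tests` (term, chisq, df, p), `overall_chisq`, `overall_df`,
#'   `overall_p`, `agreement` (percent), `predicted`, `n`, `ridged`.
#' @export
fit_classifier <- function(features, labels,
                           feature_set = intersect(the_six_features,
                                                   names(features)),
                           standardize = TRUE, ridge_decay = 0.01) {
  dat <- features[feature_set]
  ok <- complete.cases(dat) & !is.na(labels)
  dat <- dat[ok, , drop = FALSE]
  labels <- factor(labels[ok])
  if (any(table(labels) < 2)) stop("every class needs at least 2 stimuli")
  if (standardize) dat[] <- lapply(dat, function(z) as.numeric(scale(z)))
  dat$.y <- labels
  k <- nlevels(labels)

  fit_one <- function(form, decay = 0) {
    nnet::multinom(form, data = dat, trace = FALSE, maxit = 500,
                   decay = decay, MaxNWts = 5000)
  }
  full_form <- as.formula(paste(".y ~", paste(feature_set, collapse = " + ")))
  fit <- fit_one(full_form)
  ridged <- FALSE
  if (any(abs(coef(fit)) > 25)) {
    fit <- fit_one(full_form, decay = ridge_decay)
    ridged <- TRUE
    warning("possible quasi-separation; refit with ridge decay ", ridge_decay)
  }
  null_fit <- fit_one(.y ~ 1, decay = if (ridged) ridge_decay else 0)

  lr <- lapply(feature_set, function(f) {
    red <- fit_one(as.formula(paste(".y ~", paste(setdiff(feature_set, f),
                                                  collapse = " + "))),
                   decay = if (ridged) ridge_decay else 0)
    chisq <- max(0, red$deviance - fit$deviance)
    df <- k - 1
    data.frame(term = f, chisq = chisq, df = df,
               p = pchisq(chisq, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  lr_tests <- do.call(rbind, lr)
  overall_chisq <- max(0, null_fit$deviance - fit$deviance)
  overall_df <- (k - 1) * length(feature_set)
  pred <- predict(fit, newdata = dat)
  structure(list(
    coefficients = coef(fit), lr_tests = lr_tests,
    overall_chisq = overall_chisq, overall_df = overall_df,
    overall_p = pchisq(overall_chisq, overall_df, lower.tail = FALSE),
    agreement = 100 * mean(pred == labels),
    predicted = pred, n = nrow(dat), classes = levels(labels),
    feature_set = feature_set, ridged = ridged), class = "classification_fit")
}

#' @export
print.classification_fit <- function(x, ...) {
  cat("Classification fit (", length(x$classes), " classes, n = ", x$n, ")\n",
      sep = "")
  cat(sprintf("overall chi-square = %.2f (df = %d, p = %.3g)\n",
              x$overall_chisq, x$overall_df, x$overall_p))
  cat(sprintf("classification agreement = %.1f%%\n", x$agreement))
  print(x$lr_tests, row.names = FALSE)
  invisible(x)
}

#' Mixed model for trial-level listener accuracy
#'
#' Binomial GLMM of per-trial correctness on z-scored acoustic features, with
#' crossed random intercepts for participant and caller identity, fit by
#' maximum likelihood (Laplace approximation) with the bobyqa optimizer. On
#' non-convergence the fit is retried from the first fit's estimates and
#' with the Nelder-Mead optimizer before failing.
#'
#' @param trials Data frame with `correct` (logical/0-1), `participant_id`,
#'   `chimp_id`, and the feature columns.
#' @param feature_set Character vector of fixed-effect features.
#' @param standardize Z-score the features before fitting.
#' @return Object of class `glmm_fit`: `coefficients` (term, estimate_logodds,
#'   se, z, p), `ranef_variance` (participant, chimp), `aic`, `aicc`,
#'   `loglik`, `n`, `n_params`, `converged`, and the `lme4` fit in `model`.
#' @export
fit_accuracy_glmm <- function(trials, feature_set = the_six_features,
                              standardize = TRUE) {
  if (length(unique(trials$participant_id)) < 2 ||
      length(unique(trials$chimp_id)) < 2)
    stop("need at least 2 participants and 2 callers")
  dat <- trials[c("correct", "participant_id", "chimp_id", feature_set)]
  dat <- dat[complete.cases(dat), ]
  if (standardize)
    dat[feature_set] <- lapply(dat[feature_set],
                               function(z) as.numeric(scale(z)))
  form <- as.formula(paste("correct ~", paste(feature_set, collapse = " + "),
                           "+ (1 | participant_id) + (1 | chimp_id)"))
  ctrl <- lme4::glmerControl(optimizer = "bobyqa",
                             calc.derivs = FALSE,
                             check.conv.singular = "ignore")
  fit <- suppressWarnings(
    lme4::glmer(form, data = dat, family = stats::binomial, control = ctrl))
  conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0
  if (!conv) {
    ctrl2 <- lme4::glmerControl(optimizer = "Nelder_Mead",
                                calc.derivs = FALSE,
                                check.conv.singular = "ignore")
    fit2 <- try(suppressWarnings(
      lme4::glmer(form, data = dat, family = stats::binomial,
                  control = ctrl2,
                  start = list(theta = lme4::getME(fit, "theta"),
                               fixef = lme4::fixef(fit)))), silent = TRUE)
    if (!inherits(fit2, "try-error")) {
      fit <- fit2
      conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0
    }
  }
  sm <- summary(fit)$coefficients
  co <- data.frame(term = rownames(sm), estimate_logodds = sm[, 1],
                   se = sm[, 2], z = sm[, 3], p = sm[, 4],
                   row.names = NULL, stringsAsFactors = FALSE)
  vc <- lme4::VarCorr(fit)
  n <- nrow(dat)
  k <- length(feature_set) + 1 + 2  # fixed effects + 2 variance components
  aic <- AIC(fit)
  structure(list(
    coefficients = co,
    ranef_variance = c(participant = as.numeric(vc$participant_id),
                       chimp = as.numeric(vc$chimp_id)),
    aic = aic, aicc = aic + 2 * k * (k + 1) / (n - k - 1),
    loglik = as.numeric(logLik(fit)), n = n, n_params = k,
    feature_set = feature_set, converged = conv, model = fit),
    class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Binomial GLMM of trial accuracy (n = ", x$n, ")\n", sep = "")
  print(x$coefficients, row.names = FALSE, digits = 3)
  cat(sprintf("random intercept variances: participant %.3f, caller %.3f\n",
              x$ranef_variance["participant"], x$ranef_variance["chimp"]))
  cat(sprintf("AIC = %.1f, AICc = %.1f\n", x$aic, x$aicc))
  invisible(x)
}

#' Fit the full model and all leave-one-feature-out candidates
#'
#' @inheritParams fit_accuracy_glmm
#' @return Named list of [fit_accuracy_glmm()] fits; the first element
#'   (`"full"`) uses all features, the others drop one feature each.
#' @export
glmm_candidates <- function(trials, feature_set = the_six_features,
                            standardize = TRUE) {
  fits <- list(full = fit_accuracy_glmm(trials, feature_set, standardize))
  for (f in feature_set) {
    fits[[paste0("minus_", f)]] <-
      fit_accuracy_glmm(trials, setdiff(feature_set, f), standardize)
  }
  fits
}

#' AICc model selection over candidate feature sets
#'
#' Candidates must be fit on identical trial sets. The chosen model minimizes
#' AICc; exact ties are broken toward the model with more parameters, so a
#' variable is dropped only when dropping it strictly lowers the criterion.
#' `improves_fit` flags candidates beating the runner-up criterion value by
#' more than two units, the conventional reading of a meaningful improvement.
#'
#' @param fits Named list of [fit_accuracy_glmm()] objects (e.g. from
#'   [glmm_candidates()]).
#' @return Data frame of class `model_selection`: `candidate`, `n_params`,
#'   `aic`, `aicc`, `delta_aicc`, `chosen`, `improves_fit`.
#' @export
aic_select <- function(fits) {
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1)
    stop("candidates were fit on differing trial sets (n: ",
         paste(unique(ns), collapse = ", "), ")")
  tab <- data.frame(
    candidate = names(fits),
    n_params = vapply(fits, function(f) f$n_params, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  ties <- which(tab$delta_aicc < 1e-8)
  chosen_idx <- ties[which.max(tab$n_params[ties])]
  tab$chosen <- seq_len(nrow(tab)) == chosen_idx
  second <- sort(tab$aicc)[2]
  tab$improves_fit <- tab$aicc < second - 2
  class(tab) <- c("model_selection", "data.frame")
  tab
}

#' Forest plot of GLMM fixed effects
#'
#' Log-odds estimates with 95% Wald intervals, one row per acoustic feature,
#' optionally faceted over several fitted models.
#'
#' @param fits A single [fit_accuracy_glmm()] object or a named list of them.
#' @return A ggplot object.
#' @export
plot_forest <- function(fits) {
  if (inherits(fits, "glmm_fit")) fits <- list(model = fits)
  dat <- do.call(rbind, lapply(names(fits), function(nm) {
    co <- fits[[nm]]$coefficients
    co <- co[co$term != "(Intercept)", ]
    data.frame(model = nm, term = co$term, est = co$estimate_logodds,
               lo = co$estimate_logodds - 1.96 * co$se,
               hi = co$estimate_logodds + 1.96 * co$se,
               stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$est, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "log-odds per SD of feature", y = NULL) +
    ggplot2::theme_minimal()
}
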