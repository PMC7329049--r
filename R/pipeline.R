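#' Configuration for a full pipeline run
#'
#' Defaults reproduce the emulated study design: 155 stimuli in 10 contexts,
#' 310 participants in the 10-way categorization experiment, 312 participants
#' per context (3120 total) in the yes/no matching experiment, alpha 0.005
#' for the context and d-prime tests (Bonferroni 0.05/10) and 0.05 elsewhere.
#'
#' @param out_dir Output directory.
#' @param seed Master seed; each stage derives its own sub-seed from it.
#' @param corpus_preset Corpus preset name (see [context_profiles()]).
#' @param listener_preset Listener preset (see [listener_model()]).
#' @param n_participants_exp1 Participants in experiment 1.
#' @param n_participants_per_context_exp2 Participants per context in
#'   experiment 2.
#' @param alpha_context Alpha for context categorization and d-prime tests.
#' @param alpha_other Alpha for the remaining tests.
#' @param sample_rate Synthesis sampling rate (Hz).
#' @param stages Stages to run, in order; upstream outputs are read from
#'   `out_dir` when a stage is skipped.
#' @param profiles Optional explicit context profile table overriding
#'   `corpus_preset`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, corpus_preset = "paper",
                       listener_preset = "qualitative",
                       n_participants_exp1 = 310,
                       n_participants_per_context_exp2 = 312,
                       alpha_context = 0.005, alpha_other = 0.05,
                       sample_rate = 44100,
                       stages = c("corpus", "features", "featsel", "exp1",
                                  "exp1_stats", "exp2", "exp2_stats",
                                  "classify", "glmm"),
                       profiles = NULL) {
  if (n_participants_exp1 < 1) stop("n_participants_exp1 must be >= 1")
  if (n_participants_per_context_exp2 < 1)
    stop("n_participants_per_context_exp2 must be >= 1")
  structure(list(
    out_dir = out_dir, seed = as.integer(seed),
    corpus_preset = corpus_preset, listener_preset = listener_preset,
    n_participants_exp1 = n_participants_exp1,
    n_participants_per_context_exp2 = n_participants_per_context_exp2,
    alpha_context = alpha_context, alpha_other = alpha_other,
    sample_rate = sample_rate, stages = stages,
    profiles = profiles), class = "run_config")
}

#' Deterministic sub-seed for a pipeline stage
#'
#' Mixes the master seed with a polynomial hash of the stage name, so adding
#' a stage never perturbs another stage's random stream.
#'
#' @param seed Master seed (integer).
#' @param stage Stage name.
#' @return Integer sub-seed in \[0, 2^31).
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147480009
  as.integer((seed %% 2147480009 * 2654435 + h) %% 2147480009)
}

#' Validate the design arithmetic of a configuration
#'
#' Report-only checks: the corpus preset's counts, the matching-experiment
#' arithmetic (each stimulus is judged as matching by half the context's
#' participants, so judgments per stimulus = participants per context / 2),
#' and consistency of the configured sample sizes with the a priori power
#' requirements (d = 0.2, power 0.80, one-tailed; alpha 0.005 for the 10-way
#' task, 0.05 for the matching task).
#'
#' @param config A [run_config()].
#' @return Data frame with one row per check: `check`, `value`, `ok`.
#' @export
validate_design <- function(config) {
  profiles <- config$profiles %||% context_profiles(config$corpus_preset)
  judgments <- config$n_participants_per_context_exp2 / 2
  n_req_exp1 <- power_n_ttest(0.2, config$alpha_context, 0.80, "one")
  n_req_exp2 <- power_n_ttest(0.2, config$alpha_other, 0.80, "one")
  data.frame(
    check = c("corpus_total", "corpus_contexts", "judgments_per_stimulus",
              "exp1_n_vs_power", "judgments_vs_power",
              "exp2_total_participants"),
    value = c(sum(profiles$n_stimuli), nrow(profiles), judgments,
              config$n_participants_exp1,
              judgments,
              config$n_participants_per_context_exp2 * nrow(profiles)),
    ok = c(!identical(attr(profiles, "preset"), "paper") ||
             sum(profiles$n_stimuli) == 155,
           nrow(profiles) >= 2,
           judgments >= 1,
           config$n_participants_exp1 >= n_req_exp1,
           judgments >= n_req_exp2,
           TRUE),
    stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes corpus generation, feature extraction, feature selection, both
#' experiment simulations, the perception statistics, the acoustic
#' classifiers and (optionally) the accuracy GLMMs, writing CSV outputs under
#' `out_dir/{stimuli,features,exp1,exp2,models}` and a JSON run manifest.
#' Every stochastic stage consumes a sub-seed derived from the master seed,
#' so identical configurations give identical outputs. A failing stage aborts
#' the run and the manifest marks the run invalid with the failing stage
#' named.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (a list; also written as `manifest.json`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dirs <- file.path(out, c("stimuli", "features", "exp1", "exp2", "models"))
  for (d in dirs) dir.create(d, showWarnings = FALSE, recursive = TRUE)
  profiles <- config$profiles %||% context_profiles(config$corpus_preset)
  listener <- listener_model(config$listener_preset)
  contexts <- profiles$context_id
  valence_of <- setNames(profiles$valence, profiles$context_id)

  manifest <- list(
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    package_version = as.character(packageVersion("vocaffect")),
    seed = config$seed, stages = list(), row_counts = list(), valid = TRUE)
  path <- list(
    stimuli = file.path(out, "stimuli", "stimuli.csv"),
    features = file.path(out, "features", "features.csv"),
    loadings = file.path(out, "features", "pca_loadings.csv"),
    selected = file.path(out, "features", "selected_features.csv"),
    exp1 = file.path(out, "exp1", "exp1_responses.csv"),
    hu = file.path(out, "exp1", "hu_scores.csv"),
    tests1 = file.path(out, "exp1", "tests.csv"),
    exp2 = file.path(out, "exp2", "exp2_responses.csv"),
    dprime = file.path(out, "exp2", "dprime.csv"),
    tests2 = file.path(out, "exp2", "tests.csv"),
    classify = file.path(out, "models", "classification_fits.csv"),
    glmm = file.path(out, "models", "glmm_fits.csv"),
    selection = file.path(out, "models", "model_selection.csv"))

  record <- function(stage, rows) {
    manifest$stages[[stage]] <<- TRUE
    manifest$row_counts[[stage]] <<- rows
  }
  run_stage <- function(stage, f) {
    if (!stage %in% config$stages) return(invisible(NULL))
    tryCatch(f(), error = function(e) {
      manifest$valid <<- FALSE
      manifest$failed_stage <<- stage
      write_manifest(manifest, out)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  run_stage("corpus", function() {
    corpus <- generate_corpus(profiles, seed = derive_seed(config$seed, "corpus"),
                              out_dir = file.path(out, "stimuli"),
                              sample_rate = config$sample_rate)
    record("corpus", nrow(corpus))
  })
  corpus <- if (file.exists(path$stimuli)) {
    read.csv(path$stimuli, stringsAsFactors = FALSE)
  } else NULL

  run_stage("features", function() {
    feats <- extract_features_corpus(corpus, quiet = TRUE)
    write.csv(feats, path$features, row.names = FALSE)
    record("features", nrow(feats))
  })

  run_stage("featsel", function() {
    feats <- read.csv(path$features)
    pca <- pca_varimax(feats[setdiff(names(feats), "stimulus_id")])
    write.csv(data.frame(feature = rownames(pca$loadings), pca$loadings),
              path$loadings, row.names = FALSE)
    sel <- select_features(policy = "paper")
    write.csv(data.frame(feature = sel), path$selected, row.names = FALSE)
    record("featsel", length(sel))
  })

  run_stage("exp1", function() {
    resp <- simulate_exp1(corpus, config$n_participants_exp1, listener,
                          seed = derive_seed(config$seed, "exp1"))
    write.csv(resp, path$exp1, row.names = FALSE)
    record("exp1", nrow(resp))
  })

  run_stage("exp1_stats", function() {
    resp <- read.csv(path$exp1, stringsAsFactors = FALSE)
    m <- match(resp$stimulus_id, corpus$stimulus_id)
    acc <- tapply(resp$chosen_context == corpus$context_id[m],
                  resp$participant_id, mean)
    scr <- screen_outliers(acc)
    resp <- resp[resp$participant_id %in% scr$retained, ]
    hs <- hu_scores(resp, corpus, categories = contexts)
    write.csv(hs, path$hu, row.names = FALSE)
    tests <- list(
      cbind(task = "context",
            wilcoxon_vs_chance(hs, alpha = config$alpha_context * length(contexts))),
      cbind(task = "arousal",
            wilcoxon_vs_chance(hu_scores_ratings(resp, corpus, "arousal"),
                               alpha = config$alpha_other)),
      cbind(task = "valence",
            wilcoxon_vs_chance(hu_scores_ratings(resp, corpus, "valence"),
                               alpha = config$alpha_other)))
    write.csv(do.call(rbind, tests), path$tests1, row.names = FALSE)
    record("exp1_stats", nrow(hs))
    manifest$row_counts$exp1_excluded <<- length(scr$excluded)
  })

  run_stage("exp2", function() {
    resp <- lapply(contexts, function(cc) {
      simulate_exp2(corpus, cc, config$n_participants_per_context_exp2,
                    listener, seed = derive_seed(config$seed,
                                                 paste0("exp2_", cc)))
    })
    resp <- do.call(rbind, resp)
    resp$participant_id <- paste(resp$condition_context,
                                 resp$participant_id, sep = "_")
    write.csv(resp, path$exp2, row.names = FALSE)
    record("exp2", nrow(resp))
  })

  run_stage("exp2_stats", function() {
    resp <- read.csv(path$exp2, stringsAsFactors = FALSE)
    sdt <- dprime(resp)
    # outlier screening against the context-specific mean
    excluded <- unlist(lapply(split(sdt, sdt$condition_context), function(s) {
      screen_outliers(setNames(s$dprime, s$participant_id))$excluded
    }))
    sdt <- sdt[!sdt$participant_id %in% excluded, ]
    scr <- list(excluded = excluded)
    write.csv(sdt, path$dprime, row.names = FALSE)
    tests <- dprime_vs_chance(sdt, alpha = config$alpha_context)
    anova_res <- valence_accuracy_contrast(sdt, valence_of, "exp2")
    write.csv(tests, path$tests2, row.names = FALSE)
    record("exp2_stats", nrow(sdt))
    manifest$row_counts$exp2_excluded <<- length(scr$excluded)
    manifest$exp2_valence_anova <<- anova_res[c("direction", "F", "p")]
  })

  run_stage("classify", function() {
    feats <- read.csv(path$features)
    m <- match(feats$stimulus_id, corpus$stimulus_id)
    fits <- list(
      context = fit_classifier(feats, corpus$context_id[m]),
      arousal = fit_classifier(feats, corpus$arousal[m]),
      valence = fit_classifier(
        feats[corpus$valence[m] != "none", ],
        corpus$valence[m][corpus$valence[m] != "none"]))
    tab <- do.call(rbind, lapply(names(fits), function(nm) {
      data.frame(outcome = nm, agreement = fits[[nm]]$agreement,
                 overall_chisq = fits[[nm]]$overall_chisq,
                 overall_df = fits[[nm]]$overall_df,
                 overall_p = fits[[nm]]$overall_p,
                 stringsAsFactors = FALSE)
    }))
    write.csv(tab, path$classify, row.names = FALSE)
    record("classify", nrow(tab))
  })

  run_stage("glmm", function() {
    feats <- read.csv(path$features)
    resp1 <- read.csv(path$exp1, stringsAsFactors = FALSE)
    resp2 <- read.csv(path$exp2, stringsAsFactors = FALSE)
    m1 <- match(resp1$stimulus_id, corpus$stimulus_id)
    m2 <- match(resp2$stimulus_id, corpus$stimulus_id)
    mk_trials <- function(resp, correct, m) {
      cbind(data.frame(correct = correct,
                       participant_id = resp$participant_id,
                       chimp_id = corpus$caller_id[m]),
            feats[match(resp$stimulus_id, feats$stimulus_id),
                  the_six_features])
    }
    trials <- list(
      arousal = mk_trials(resp1, recode_and_score_ratings(
        resp1$arousal_rating, corpus$arousal[m1], "arousal")$correct, m1),
      valence = mk_trials(resp1, recode_and_score_ratings(
        resp1$valence_rating, corpus$valence[m1], "valence")$correct, m1),
      match = mk_trials(resp2, resp2$response_yes == resp2$is_match, m2))
    all_fits <- list(); all_sel <- list()
    for (nm in names(trials)) {
      cand <- glmm_candidates(trials[[nm]])
      sel <- aic_select(cand)
      all_sel[[nm]] <- cbind(outcome = nm, sel)
      co <- cand$full$coefficients
      all_fits[[nm]] <- cbind(outcome = nm, co,
                              aic = cand$full$aic, aicc = cand$full$aicc)
    }
    write.csv(do.call(rbind, all_fits), path$glmm, row.names = FALSE)
    write.csv(do.call(rbind, all_sel), path$selection, row.names = FALSE)
    record("glmm", length(trials))
  })

  write_manifest(manifest, out)
  invisible(manifest)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
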