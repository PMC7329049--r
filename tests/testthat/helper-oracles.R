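# Brute-force oracle for the exact two-sided one-sample Wilcoxon signed-rank
# p-value, enumerating all 2^n sign assignments. Replicates the standard
# exact convention: double the smaller tail of the V+ distribution, capped
# at 1. Zero differences are dropped first (Wilcoxon's policy).
enumerate_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 12, !any(duplicated(abs(d))))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  p <- if (v_obs > n * (n + 1) / 4) 2 * mean(v_all >= v_obs)
       else 2 * mean(v_all <= v_obs)
  min(1, p)
}

# A hu_scores()-shaped table whose per-category differences
# (hu_arcsine - chance_arcsine) equal the rows of `diffs` (a participants x
# categories matrix), for driving wilcoxon_vs_chance with known differences.
scores_from_diffs <- function(diffs) {
  n <- nrow(diffs)
  k <- ncol(diffs)
  data.frame(
    participant_id = rep(sprintf("p%03d", seq_len(n)), k),
    category = rep(paste0("c", seq_len(k)), each = n),
    hu_arcsine = 0.5 + as.vector(diffs),
    chance_arcsine = 0.5,
    stringsAsFactors = FALSE)
}

# The full "paper"-preset corpus, generated once per test session.
.corpus_cache <- new.env(parent = emptyenv())
cached_paper_corpus <- function() {
  if (is.null(.corpus_cache$corpus)) {
    dir <- file.path(tempdir(), "vocaffect-test-corpus")
    .corpus_cache$corpus <- generate_corpus(context_profiles("paper"),
                                            seed = 1, out_dir = dir)
  }
  .corpus_cache$corpus
}

# A one-context profile table for fast corpus tests.
mini_profiles <- function(n_stimuli = 3L, caller_pool = 2L, f0_mean = 300,
                          noise_frac = 0.1) {
  data.frame(
    context_id = "c1", context_label = "test context", call_type = "test",
    valence = "positive", arousal = "medium",
    n_stimuli = as.integer(n_stimuli), caller_pool = as.integer(caller_pool),
    f0_mean = f0_mean, f0_sd = 10, f0_mod_depth = 0.05,
    noise_frac = noise_frac, calls_min = 2L, calls_max = 3L,
    dur_min = 0.15, dur_max = 0.3, sil_min = 0.08, sil_max = 0.2,
    tilt_db_oct = -6, stringsAsFactors = FALSE)
}

# Six-feature table of independent standard normals (for model tests).
random_feature_table <- function(n, seed) {
  set.seed(seed)
  out <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(out) <- c("scog", "duration", "f0_mean", "f0_sd", "hnr_mean",
                  "hnr_max")
  out
}
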