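#' Synthesize one call bout
#'
#' Generates a call bout as a concatenation of amplitude-enveloped call
#' segments separated by silences. Each call is a harmonic stack (first
#' `n_harmonics` harmonics with a fixed spectral tilt) whose fundamental
#' follows a slow sinusoidal contour, mixed with Gaussian broadband noise so
#' that `noise_frac` is the noise fraction of total power. Calls get 10 ms
#' Hann on/off ramps. Deterministic given the arguments and `seed`.
#'
#' @param f0 Fundamental frequency base in Hz (> 0).
#' @param n_calls Number of calls in the bout (>= 1).
#' @param call_dur Call duration(s) in seconds; scalar or length `n_calls`.
#' @param silence Inter-call silence(s) in seconds; scalar or length
#'   `n_calls - 1`.
#' @param noise_frac Noise power fraction in \[0, 1\].
#' @param mod_depth Relative depth of the sinusoidal f0 contour (0 = flat).
#' @param tilt_db_oct Spectral tilt of the harmonic stack in dB/octave.
#' @param n_harmonics Number of harmonics (those above Nyquist are dropped).
#' @param sample_rate Sampling rate in Hz.
#' @param seed Optional integer seed for the noise and contour draws.
#' @return Numeric waveform (unit peak not guaranteed; see
#'   [peak_normalize()]). Attribute `"f0_realized"` holds the
#'   duration-weighted mean of the actual f0 contour across the calls (the
#'   contour's random phase makes this differ slightly from `f0`).
#' @export
synthesize_call_bout <- function(f0, n_calls = 1, call_dur = 0.5,
                                 silence = 0.1, noise_frac = 0,
                                 mod_depth = 0, tilt_db_oct = -6,
                                 n_harmonics = 12, sample_rate = 44100,
                                 seed = NULL) {
  if (f0 <= 0) stop("f0 must be positive")
  if (n_calls < 1) stop("a bout needs at least one call")
  if (any(call_dur <= 0)) stop("call duration must be positive")
  if (noise_frac < 0 || noise_frac > 1) stop("noise_frac must lie in [0, 1]")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  durs <- rep_len(call_dur, n_calls)
  sils <- if (n_calls > 1) rep_len(silence, n_calls - 1) else numeric(0)
  harm_amp <- 10^(tilt_db_oct * log2(seq_len(n_harmonics)) / 20)

  f0_sum <- 0; f0_n <- 0
  calls <- lapply(seq_len(n_calls), function(i) {
    n <- max(8L, round(durs[i] * sample_rate))
    t <- seq_len(n) / sample_rate
    # slow sinusoidal pitch contour with random rate and phase
    rate <- runif(1, 1, 4)
    phase0 <- runif(1, 0, 2 * pi)
    f0_t <- f0 * (1 + mod_depth * sin(2 * pi * rate * t + phase0))
    f0_sum <<- f0_sum + sum(f0_t); f0_n <<- f0_n + n
    phi <- 2 * pi * cumsum(f0_t) / sample_rate
    harm <- numeric(n)
    for (k in seq_len(n_harmonics)) {
      if (k * max(f0_t) >= sample_rate / 2) break
      harm <- harm + harm_amp[k] * sin(k * phi)
    }
    harm <- if (sd(harm) > 0) harm / sqrt(mean(harm^2)) else harm
    noise <- rnorm(n)
    noise <- noise / sqrt(mean(noise^2))
    x <- sqrt(1 - noise_frac) * harm + sqrt(noise_frac) * noise
    ramp <- min(round(0.01 * sample_rate), floor(n / 2))
    if (ramp > 0) {
      w <- 0.5 - 0.5 * cos(pi * seq_len(ramp) / ramp)
      x[seq_len(ramp)] <- x[seq_len(ramp)] * w
      x[n - ramp + seq_len(ramp)] <- x[n - ramp + seq_len(ramp)] * rev(w)
    }
    x
  })
  out <- calls[[1]]
  if (n_calls > 1) {
    for (i in 2:n_calls) {
      out <- c(out, numeric(round(sils[i - 1] * sample_rate)), calls[[i]])
    }
  }
  attr(out, "f0_realized") <- f0_sum / f0_n
  out
}

#' Peak-normalize a waveform
#'
#' @param x Numeric waveform.
#' @param target Peak absolute amplitude after scaling (full scale = 1).
#' @return Scaled waveform; an all-zero input is returned unchanged.
#' @export
peak_normalize <- function(x, target = 0.9) {
  peak <- max(abs(x))
  if (peak == 0) return(x)
  x * (target / peak)
}

#' Generate a synthetic stimulus corpus
#'
#' Builds the full stimulus set described by a table of context profiles:
#' draws per-stimulus synthesis parameters from each context's distributions,
#' synthesizes every call bout, peak-normalizes it, writes one WAV per
#' stimulus and a `stimuli.csv` metadata table. Caller identities are
#' assigned from per-context caller pools carved out of a corpus-wide pool so
#' that (under the `"paper"` preset) exactly 66 distinct callers appear and
#' every per-context pool member contributes at least one stimulus.
#'
#' @param profiles Context profile table, see [context_profiles()].
#' @param seed Integer seed; identical seeds give byte-identical metadata and
#'   sample-identical audio.
#' @param out_dir Directory for WAV files and `stimuli.csv` (created if
#'   needed).
#' @param sample_rate Sampling rate in Hz (default 44.1 kHz, 16-bit mono PCM).
#' @param peak_target Peak-normalization target amplitude (full scale = 1).
#' @param n_callers Total distinct callers across the corpus.
#' @return Data frame of stimulus metadata (one row per stimulus) with
#'   attribute `preset`.
#' @export
generate_corpus <- function(profiles = context_profiles("paper"), seed = 1,
                            out_dir = tempfile("corpus"),
                            sample_rate = 44100, peak_target = 0.9,
                            n_callers = 66) {
  preset <- attr(profiles, "preset") %||% "custom"
  if (identical(preset, "paper") && sum(profiles$n_stimuli) != 155) {
    stop("the 'paper' preset requires per-context stimulus counts summing to 155")
  }
  if (any(profiles$caller_pool > profiles$n_stimuli)) {
    bad <- profiles$context_id[profiles$caller_pool > profiles$n_stimuli]
    stop("caller_pool exceeds n_stimuli for context(s): ",
         paste(bad, collapse = ", "))
  }
  if (any(profiles$caller_pool < 1)) stop("caller_pool must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  total_pool <- sum(profiles$caller_pool)
  n_callers <- min(n_callers, total_pool)
  callers <- sprintf("ch%02d", seq_len(n_callers))
  # fill per-context pools with fresh callers until the corpus pool is
  # exhausted, then reuse already-seen callers for the remaining slots
  pools <- vector("list", nrow(profiles))
  nxt <- 1L
  for (i in seq_len(nrow(profiles))) {
    want <- profiles$caller_pool[i]
    fresh <- min(want, n_callers - nxt + 1L)
    pool <- if (fresh > 0) callers[nxt:(nxt + fresh - 1L)] else character(0)
    nxt <- nxt + fresh
    if (fresh < want) {
      seen <- callers[seq_len(nxt - 1L)]
      pool <- c(pool, sample(setdiff(seen, pool), want - fresh))
    }
    pools[[i]] <- pool
  }

  rows <- list()
  idx <- 0L
  for (i in seq_len(nrow(profiles))) {
    pr <- profiles[i, ]
    n <- pr$n_stimuli
    # every pool member gets at least one stimulus; remainder drawn at random
    caller_ids <- c(pools[[i]],
                    sample(pools[[i]], n - length(pools[[i]]), replace = TRUE))
    caller_ids <- sample(caller_ids)
    for (j in seq_len(n)) {
      idx <- idx + 1L
      stimulus_id <- sprintf("s%03d", idx)
      f0 <- max(60, rnorm(1, pr$f0_mean, pr$f0_sd))
      n_calls <- sample(pr$calls_min:pr$calls_max, 1)
      durs <- runif(n_calls, pr$dur_min, pr$dur_max)
      sils <- if (n_calls > 1) runif(n_calls - 1, pr$sil_min, pr$sil_max) else 0
      nf <- min(1, max(0, rnorm(1, pr$noise_frac, 0.05)))
      wav <- synthesize_call_bout(
        f0 = f0, n_calls = n_calls, call_dur = durs, silence = sils,
        noise_frac = nf, mod_depth = pr$f0_mod_depth,
        tilt_db_oct = pr$tilt_db_oct, sample_rate = sample_rate)
      f0_realized <- attr(wav, "f0_realized")
      wav <- peak_normalize(wav, peak_target)
      wav_path <- file.path(out_dir, paste0(stimulus_id, ".wav"))
      write_wav(wav, sample_rate, wav_path)
      rows[[idx]] <- data.frame(
        stimulus_id = stimulus_id, caller_id = caller_ids[j],
        context_id = pr$context_id, context_label = pr$context_label,
        arousal = pr$arousal, valence = pr$valence,
        wav_path = wav_path, sample_rate = sample_rate,
        duration_s = length(wav) / sample_rate,
        f0_true = f0_realized, n_calls_true = n_calls, noise_frac_true = nf,
        stringsAsFactors = FALSE)
    }
  }
  corpus <- do.call(rbind, rows)
  attr(corpus, "preset") <- preset
  write.csv(corpus, file.path(out_dir, "stimuli.csv"), row.names = FALSE)
  corpus
}
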