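#' Acoustic analysis settings
#'
#' Defaults are sized for great-ape vocalizations: 40 ms analysis frames with
#' a 10 ms hop, a pitch search range of 70–1800 Hz, a voicing threshold of
#' 0.45 on the normalized autocorrelation, amplitude segmentation at 25 dB
#' below the bout's peak envelope with 50 ms minimum silences and 30 ms
#' minimum calls, and an HNR cap of 40 dB (a noiseless synthetic tone has an
#' autocorrelation of essentially 1, which would otherwise give an infinite
#' ratio).
#'
#' @param frame_len Analysis frame length in seconds.
#' @param hop Frame hop in seconds.
#' @param f0_floor,f0_ceiling Pitch search range in Hz (floor < ceiling).
#' @param voicing_threshold Minimum normalized autocorrelation for a frame to
#'   count as voiced.
#' @param octave_cost Lag penalty (per octave above the minimum lag) used to
#'   resolve period-multiple ambiguity in the pitch candidate choice.
#' @param seg_threshold_db Segmentation threshold below peak envelope (dB).
#' @param seg_window Envelope RMS window in seconds.
#' @param min_silence Gaps shorter than this are merged (s).
#' @param min_call Segments shorter than this are dropped (s).
#' @param hnr_cap Upper bound on per-frame HNR (dB).
#' @return A list of class `acoustic_config`.
#' @export
acoustic_config <- function(frame_len = 0.040, hop = 0.010,
                            f0_floor = 70, f0_ceiling = 1800,
                            voicing_threshold = 0.45, octave_cost = 0.05,
                            seg_threshold_db = 25, seg_window = 0.010,
                            min_silence = 0.050, min_call = 0.030,
                            hnr_cap = 40) {
  if (f0_floor >= f0_ceiling) stop("f0_floor must be below f0_ceiling")
  structure(list(
    frame_len = frame_len, hop = hop, f0_floor = f0_floor,
    f0_ceiling = f0_ceiling, voicing_threshold = voicing_threshold,
    octave_cost = octave_cost, seg_threshold_db = seg_threshold_db,
    seg_window = seg_window, min_silence = min_silence, min_call = min_call,
    hnr_cap = hnr_cap), class = "acoustic_config")
}

#' Segment a bout into calls by its amplitude envelope
#'
#' Computes a short-window RMS envelope on a 1 ms grid, marks grid points
#' whose envelope exceeds the bout's peak envelope minus
#' `config$seg_threshold_db`, merges active runs separated by gaps shorter
#' than `min_silence`, drops runs shorter than `min_call`, and compensates
#' the half-window smear at run edges.
#'
#' @param waveform Numeric vector.
#' @param sample_rate Hz.
#' @param config An [acoustic_config()].
#' @return Data frame with columns `start` and `end` (seconds); zero rows for
#'   an all-silent input.
#' @export
segment_calls <- function(waveform, sample_rate, config = acoustic_config()) {
  if (length(waveform) == 0) stop("empty waveform")
  w <- max(2L, round(config$seg_window * sample_rate))
  step <- max(1L, round(0.001 * sample_rate))
  n <- length(waveform)
  if (n < w) w <- n
  e2 <- cumsum(c(0, waveform^2))
  starts <- seq(1L, n - w + 1L, by = step)
  rms <- sqrt((e2[starts + w] - e2[starts]) / w)
  peak <- max(rms)
  if (peak == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  active <- rms > peak * 10^(-config$seg_threshold_db / 20)
  centers <- (starts - 1 + w / 2) / sample_rate

  r <- rle(active)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  seg <- data.frame(start = centers[starts_i[r$values]],
                    end = centers[ends_i[r$values]])
  if (nrow(seg) == 0) return(seg)
  # edge compensation first (so gap lengths are unbiased before merging):
  # the envelope window triggers as soon as it touches a call, smearing each
  # run by ~w/2 per side
  half <- w / 2 / sample_rate
  start <- seg$start + half
  end <- seg$end - half
  bad <- end <= start
  start[bad] <- (seg$start[bad] + seg$end[bad]) / 2 - 1 / sample_rate
  end[bad] <- (seg$start[bad] + seg$end[bad]) / 2 + 1 / sample_rate
  seg <- data.frame(start = pmax(0, start), end = pmin(n / sample_rate, end))
  # merge gaps shorter than min_silence
  keep <- list(seg[1, ])
  if (nrow(seg) > 1) {
    for (i in 2:nrow(seg)) {
      last <- keep[[length(keep)]]
      if (seg$start[i] - last$end < config$min_silence) {
        keep[[length(keep)]]$end <- seg$end[i]
      } else {
        keep[[length(keep) + 1]] <- seg[i, ]
      }
    }
  }
  seg <- do.call(rbind, keep)
  seg[seg$end - seg$start >= config$min_call, , drop = FALSE]
}

# normalized autocorrelation of every frame, computed batch-wise via FFT.
# Frames are Hann-windowed and the raw autocorrelation is divided by the
# window's own autocorrelation, which removes the taper-induced decay
# (reliable for lags up to about half the frame).
frame_autocorr <- function(waveform, sample_rate, config, max_lag) {
  flen <- round(config$frame_len * sample_rate)
  hop <- max(1L, round(config$hop * sample_rate))
  n <- length(waveform)
  if (n < flen) return(NULL)
  starts <- seq(1L, n - flen + 1L, by = hop)
  idx <- outer(seq_len(flen) - 1L, starts, "+")
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(flen) - 0.5) / flen)
  X <- matrix(waveform[idx], nrow = flen)
  X <- sweep(X, 2, colMeans(X)) * win
  nfft <- 2^ceiling(log2(flen + max_lag + 1L))
  pad <- function(M) rbind(M, matrix(0, nfft - flen, ncol(M)))
  S <- mvfft(pad(X))
  ac <- Re(mvfft(Mod(S)^2, inverse = TRUE)) / nfft
  acw <- Re(fft(Mod(fft(c(win, numeric(nfft - flen))))^2, inverse = TRUE)) / nfft
  ac0 <- ac[1L, ]
  ac0[ac0 == 0] <- Inf  # silent frame: r = 0 everywhere
  lags <- seq_len(max_lag)
  r <- sweep(ac[lags + 1L, , drop = FALSE], 2, ac0, "/") /
    (acw[lags + 1L] / acw[1L])
  list(r = r, times = (starts - 1) / sample_rate, flen = flen,
       frame_times = (starts - 1 + flen / 2) / sample_rate)
}

#' Track fundamental frequency across a bout
#'
#' Per 40 ms frame, finds local maxima of the bias-corrected normalized
#' autocorrelation within the configured lag range, picks the candidate
#' maximizing strength minus an octave cost (so the shortest of equally
#' strong period multiples wins), and refines the lag by parabolic
#' interpolation. A frame is voiced iff its candidate strength reaches the
#' voicing threshold *and* its centre lies inside a call segment.
#'
#' @inheritParams segment_calls
#' @param segments Optional call segments (computed if missing).
#' @return A list of class `frame_track`: `frame_times` (frame centres, s),
#'   `f0` (Hz, `NA` when unvoiced), `voiced_flag`, `strength` (normalized
#'   autocorrelation at the chosen lag), `in_segment`, plus the frame
#'   geometry.
#' @export
track_f0 <- function(waveform, sample_rate, config = acoustic_config(),
                     segments = NULL) {
  if (is.null(segments)) segments <- segment_calls(waveform, sample_rate, config)
  lag_min <- max(2L, floor(sample_rate / config$f0_ceiling))
  lag_max <- ceiling(sample_rate / config$f0_floor)
  fa <- frame_autocorr(waveform, sample_rate, config, lag_max + 1L)
  if (is.null(fa)) stop("waveform shorter than one analysis frame")
  nf <- ncol(fa$r)
  f0 <- rep(NA_real_, nf)
  strength <- numeric(nf)
  for (j in seq_len(nf)) {
    r <- fa$r[, j]
    # candidate peaks must lie beyond the first zero crossing, which excises
    # the lag-0 shoulder (its noise ripples would otherwise pose as maxima)
    nonpos <- which(r <= 0)
    if (length(nonpos) == 0) next
    first_dip <- nonpos[1]
    cand <- which(diff(sign(diff(r))) == -2) + 1L
    cand <- cand[cand >= max(lag_min, first_dip) & cand <= lag_max]
    if (length(cand) == 0) next
    score <- r[cand] - config$octave_cost * log2(cand / lag_min)
    best <- cand[which.max(score)]
    # parabolic refinement of lag and strength
    y1 <- r[best - 1L]; y2 <- r[best]; y3 <- r[best + 1L]
    denom <- y1 - 2 * y2 + y3
    delta <- if (denom != 0) 0.5 * (y1 - y3) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
    lag_star <- best + delta
    strength[j] <- min(1 - 1e-9, y2 - 0.25 * (y1 - y3) * delta)
    f0[j] <- sample_rate / lag_star
  }
  centre <- fa$frame_times
  in_seg <- rep(FALSE, nf)
  if (nrow(segments) > 0) {
    for (i in seq_len(nrow(segments))) {
      in_seg <- in_seg | (centre >= segments$start[i] & centre <= segments$end[i])
    }
  }
  voiced <- in_seg & strength >= config$voicing_threshold & !is.na(f0) &
    f0 >= config$f0_floor & f0 <= config$f0_ceiling
  f0[!voiced] <- NA_real_
  structure(list(frame_times = centre, f0 = f0, voiced_flag = voiced,
                 strength = strength, in_segment = in_seg,
                 frame_len = config$frame_len, hop = config$hop,
                 sample_rate = sample_rate, segments = segments),
            class = "frame_track")
}

#' Harmonics-to-noise ratio of the voiced frames
#'
#' Per voiced frame, `HNR = 10 log10(r / (1 - r))` where `r` is the
#' normalized autocorrelation at the fundamental's lag, capped at
#' `config$hnr_cap`. Returns `NA`s when no frame is voiced (the feature is
#' missing, not zero).
#'
#' @param track A [track_f0()] result.
#' @param config An [acoustic_config()].
#' @return List with `hnr_mean`, `hnr_max` (dB) and the per-frame `hnr`.
#' @export
harmonicity <- function(track, config = acoustic_config()) {
  stopifnot(inherits(track, "frame_track"))
  v <- track$voiced_flag
  if (!any(v)) return(list(hnr_mean = NA_real_, hnr_max = NA_real_,
                           hnr = rep(NA_real_, length(v))))
  r <- pmin(pmax(track$strength, 1e-9), 1 - 1e-9)
  hnr <- pmin(10 * log10(r / (1 - r)), config$hnr_cap)
  hnr[!v] <- NA_real_
  list(hnr_mean = mean(hnr[v]), hnr_max = max(hnr[v]), hnr = hnr)
}

# locate pitch-period peaks in one time range by stepping one expected
# period at a time from the strongest peak
period_marks <- function(waveform, sample_rate, t0, t1, period_s) {
  i0 <- max(1L, floor(t0 * sample_rate) + 1L)
  i1 <- min(length(waveform), ceiling(t1 * sample_rate))
  if (i1 - i0 < 2 * period_s * sample_rate) return(integer(0))
  Tn <- period_s * sample_rate
  seg <- waveform[i0:i1]
  anchor <- i0 - 1L + which.max(seg)
  cap <- ceiling((i1 - i0) / (0.75 * Tn)) + 2L
  fwd <- integer(cap); nf <- 0L
  cur <- anchor
  repeat {
    lo <- cur + round(0.75 * Tn); hi <- cur + round(1.25 * Tn)
    if (hi > i1) break
    cur <- lo - 1L + which.max(waveform[lo:hi])
    nf <- nf + 1L; fwd[nf] <- cur
  }
  bwd <- integer(cap); nb <- 0L
  cur <- anchor
  repeat {
    hi <- cur - round(0.75 * Tn); lo <- cur - round(1.25 * Tn)
    if (lo < i0) break
    cur <- lo - 1L + which.max(waveform[lo:hi])
    nb <- nb + 1L; bwd[nb] <- cur
  }
  c(rev(bwd[seq_len(nb)]), anchor, fwd[seq_len(nf)])
}

#' Jitter and shimmer (local, percent)
#'
#' Pitch periods are marked by peak-picking within each voiced span (run of
#' consecutive voiced frames), stepping one expected period at a time.
#' Jitter(local) is the mean absolute difference of consecutive periods over
#' the mean period, shimmer(local) the same ratio for consecutive peak
#' amplitudes, both in percent and pooled across voiced spans (differences
#' never straddle a span boundary).
#'
#' @inheritParams harmonicity
#' @param waveform,sample_rate The analysed signal.
#' @param f0_hint Optional fundamental (Hz) overriding the track's per-span
#'   median f0 when stepping between peaks; used for calibration signals
#'   whose autocorrelation period is a multiple of the pulse rate.
#' @return List with `jitter` and `shimmer` (percent; `NA` when fewer than 3
#'   consecutive periods are found).
#' @export
perturbation <- function(waveform, sample_rate, track, f0_hint = NULL) {
  stopifnot(inherits(track, "frame_track"))
  v <- track$voiced_flag
  periods <- list(); amps <- list()
  if (any(v)) {
    r <- rle(v)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (s in which(r$values)) {
      i <- starts[s]:ends[s]
      t0 <- track$frame_times[i[1]] - track$frame_len / 2
      t1 <- track$frame_times[i[length(i)]] + track$frame_len / 2
      f0s <- if (!is.null(f0_hint)) f0_hint else median(track$f0[i], na.rm = TRUE)
      if (!is.finite(f0s) || f0s <= 0) next
      m <- period_marks(waveform, sample_rate, t0, t1, 1 / f0s)
      if (length(m) >= 3) {
        periods[[length(periods) + 1]] <- diff(m) / sample_rate
        amps[[length(amps) + 1]] <- waveform[m]
      }
    }
  }
  all_p <- unlist(periods)
  if (length(all_p) < 3) return(list(jitter = NA_real_, shimmer = NA_real_))
  dT <- unlist(lapply(periods, function(p) abs(diff(p))))
  dA <- unlist(lapply(amps, function(a) abs(diff(a))))
  all_a <- unlist(amps)
  list(jitter = 100 * mean(dT) / mean(all_p),
       shimmer = 100 * mean(dA) / mean(abs(all_a)))
}

#' Spectral centre of gravity and peak-frequency timing
#'
#' SCoG is the power-weighted mean frequency of the magnitude spectrum of the
#' concatenated call segments (so leading/trailing silence cannot dilute it).
#' The peak time is the centre of the spectrogram frame holding the global
#' maximum magnitude; its relative position divides by the bout span (first
#' segment start to last segment end).
#'
#' @inheritParams segment_calls
#' @param segments Call segments from [segment_calls()].
#' @return List with `scog` (Hz), `time_max_peak_freq` (s) and
#'   `rel_peak_position` (0–1); all `NA` if there are no segments.
#' @export
spectral_features <- function(waveform, sample_rate, segments,
                              config = acoustic_config()) {
  if (is.null(segments) || nrow(segments) == 0) {
    return(list(scog = NA_real_, time_max_peak_freq = NA_real_,
                rel_peak_position = NA_real_))
  }
  # boundaries come from the analysis grid, so they sit on (or within one
  # ulp of) exact sample positions; round() keeps the conversion stable
  idx <- unlist(lapply(seq_len(nrow(segments)), function(i) {
    seq(max(1L, round(segments$start[i] * sample_rate) + 1L),
        min(length(waveform), round(segments$end[i] * sample_rate)))
  }))
  x <- waveform[idx]
  x <- x - mean(x)
  # zero-pad to a highly composite length: R's mixed-radix fft degrades to
  # O(n^2) on lengths with large prime factors
  nfft <- stats::nextn(length(x), c(2, 3, 5))
  spec <- Mod(fft(c(x, numeric(nfft - length(x)))))^2
  nh <- floor(nfft / 2)
  freqs <- (seq_len(nh) - 1) * sample_rate / nfft
  p <- spec[seq_len(nh)]
  scog <- if (sum(p) > 0) sum(freqs * p) / sum(p) else NA_real_

  # spectrogram frame with the global maximum magnitude
  flen <- round(config$frame_len * sample_rate)
  hop <- max(1L, round(config$hop * sample_rate))
  n <- length(waveform)
  if (n < flen) {
    t_peak <- which.max(abs(waveform)) / sample_rate
  } else {
    starts <- seq(1L, n - flen + 1L, by = hop)
    fidx <- outer(seq_len(flen) - 1L, starts, "+")
    X <- matrix(waveform[fidx], nrow = flen) *
      (0.5 - 0.5 * cos(2 * pi * seq_len(flen) / flen))
    S <- Mod(mvfft(X))
    peak_frame <- which.max(apply(S[seq_len(floor(flen / 2)), , drop = FALSE], 2, max))
    t_peak <- (starts[peak_frame] - 1 + flen / 2) / sample_rate
  }
  span0 <- segments$start[1]
  span1 <- segments$end[nrow(segments)]
  rel <- (t_peak - span0) / (span1 - span0)
  list(scog = scog, time_max_peak_freq = t_peak,
       rel_peak_position = max(0, min(1, rel)))
}

#' Extract the full acoustic feature set from one call bout
#'
#' Composes [segment_calls()], [track_f0()], [harmonicity()],
#' [perturbation()] and [spectral_features()] into one record: number of
#' calls, summed call duration, peak-frequency timing, percent voiced frames
#' (of frames inside calls), jitter, shimmer, SCoG, and min/max/mean/s.d. of
#' f0 plus mean/max HNR. Voiced-dependent fields are `NA` when no voiced
#' frame exists; everything is `NA` except `n_calls = 0` and `duration = 0`
#' for silent input. Deterministic for fixed config.
#'
#' @param wav Path to a WAV file, or a numeric waveform (then `sample_rate`
#'   is required).
#' @param sample_rate Hz, when `wav` is a numeric vector.
#' @param config An [acoustic_config()].
#' @return One-row data frame of the feature set; per-call durations are kept
#'   in `attr(, "call_durations")`.
#' @export
extract_features <- function(wav, sample_rate = NULL,
                             config = acoustic_config()) {
  if (is.character(wav)) {
    audio <- read_wav(wav)
    waveform <- audio$samples
    sample_rate <- audio$sample_rate
  } else {
    if (is.null(sample_rate)) stop("sample_rate required for a raw waveform")
    waveform <- as.numeric(wav)
  }
  if (length(waveform) == 0) stop("empty audio")

  seg <- segment_calls(waveform, sample_rate, config)
  empty <- data.frame(
    n_calls = nrow(seg), duration = sum(seg$end - seg$start),
    time_max_peak_freq = NA_real_, rel_peak_position = NA_real_,
    percent_voiced = NA_real_, jitter = NA_real_, shimmer = NA_real_,
    scog = NA_real_, f0_min = NA_real_, f0_max = NA_real_,
    f0_mean = NA_real_, f0_sd = NA_real_,
    hnr_mean = NA_real_, hnr_max = NA_real_)
  attr(empty, "call_durations") <- seg$end - seg$start
  if (nrow(seg) == 0) return(empty)

  track <- track_f0(waveform, sample_rate, config, segments = seg)
  sp <- spectral_features(waveform, sample_rate, seg, config)
  out <- empty
  out$time_max_peak_freq <- sp$time_max_peak_freq
  out$rel_peak_position <- sp$rel_peak_position
  out$scog <- sp$scog
  if (any(track$in_segment)) {
    out$percent_voiced <- 100 * sum(track$voiced_flag) / sum(track$in_segment)
  }
  if (any(track$voiced_flag)) {
    f0v <- track$f0[track$voiced_flag]
    out$f0_min <- min(f0v); out$f0_max <- max(f0v)
    out$f0_mean <- mean(f0v)
    out$f0_sd <- if (length(f0v) > 1) sd(f0v) else 0
    h <- harmonicity(track, config)
    out$hnr_mean <- h$hnr_mean; out$hnr_max <- h$hnr_max
    pert <- perturbation(waveform, sample_rate, track)
    out$jitter <- pert$jitter; out$shimmer <- pert$shimmer
  }
  out
}

#' Extract features for a whole corpus
#'
#' @param corpus Stimulus metadata from [generate_corpus()] (needs
#'   `stimulus_id` and `wav_path`).
#' @param config An [acoustic_config()].
#' @param quiet Suppress the missing-feature message.
#' @return Data frame: `stimulus_id` plus the feature columns of
#'   [extract_features()].
#' @export
extract_features_corpus <- function(corpus, config = acoustic_config(),
                                    quiet = FALSE) {
  if (is.null(corpus) || nrow(corpus) == 0 || is.null(corpus$wav_path))
    stop("no corpus table with wav paths available")
  feats <- lapply(seq_len(nrow(corpus)), function(i) {
    f <- extract_features(corpus$wav_path[i], config = config)
    cbind(stimulus_id = corpus$stimulus_id[i], f)
  })
  out <- do.call(rbind, feats)
  n_missing <- sum(!complete.cases(out))
  if (!quiet && n_missing > 0) {
    message(n_missing, " stimulus/stimuli with undefined voiced features ",
            "(excluded listwise by downstream models)")
  }
  out
}
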