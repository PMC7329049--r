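#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the uncompressed 16-bit mono files this
#' package writes. Chunks other than `fmt ` and `data` are skipped.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric vector scaled to \[-1, 1\]) and
#'   `sample_rate` (Hz).
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # overall size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  sample_rate <- NULL
  bits <- NULL
  channels <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      audio_format <- fmt[1]
      channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, 2, endian = "little")  # block align
      bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      if (audio_format != 1L) stop("only PCM WAV is supported")
      if (channels != 1L) stop("only mono WAV is supported")
      if (bits != 16L) stop("only 16-bit WAV is supported")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(id, "data")) {
      n <- size %/% 2L
      samples <- readBin(con, "integer", n, 2, endian = "little") / 32767
      break
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  list(samples = samples, sample_rate = sample_rate)
}

#' Write a mono PCM WAV file
#'
#' @param samples Numeric vector in \[-1, 1\]; values outside are clipped.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  x <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  data_size <- 2L * length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                     # PCM
  writeBin(1L, con, 2, endian = "little")                     # mono
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  writeBin(x, con, 2, endian = "little")
  invisible(path)
}
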