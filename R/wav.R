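#' Read a mono WAV file as a target signal
#'
#' Reads a PCM WAV file (8/16/24/32-bit integer or 32/64-bit IEEE float) and
#' returns its samples scaled to `[-1, 1]`, as a single-trial [target_set()]
#' with modality `"envelope"`. Audio targets recorded alongside the neural
#' data (e.g. the speech waveform) are read this way and then epoched and
#' enveloped by the caller.
#'
#' @param path path to a RIFF/WAVE file.
#' @return A `target_set` with one trial at the file's sampling rate.
#' @export
read_target_wav <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file")
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file")

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1L, size = 2L,
                               endian = "little", signed = FALSE),
        n_channels = readBin(raw_fmt[3:4], "integer", 1L, size = 2L,
                             endian = "little", signed = FALSE),
        fs = readBin(raw_fmt[5:8], "integer", 1L, size = 4L, endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1L, size = 2L,
                       endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      samples <- decode_wav_data(readBin(con, "raw", sz), fmt)
      if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1L))
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2L)))
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) stop("malformed WAV: no data chunk found")
  if (fmt$n_channels != 1L) {
    stop(sprintf("mono required: file has %d channels", fmt$n_channels))
  }
  target_set(matrix(samples, nrow = 1L), fs = fmt$fs, modality = "envelope")
}

decode_wav_data <- function(raw, fmt) {
  if (fmt$audio_format == 1L) {          # integer PCM
    if (fmt$bits == 8L) {
      # 8-bit PCM is unsigned, midpoint 128
      (as.integer(raw) - 128) / 128
    } else if (fmt$bits == 16L) {
      readBin(raw, "integer", length(raw) %/% 2L, size = 2L,
              endian = "little", signed = TRUE) / 32768
    } else if (fmt$bits == 24L) {
      n <- length(raw) %/% 3L
      b <- matrix(as.integer(raw[seq_len(3L * n)]), nrow = 3L)
      v <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    } else if (fmt$bits == 32L) {
      readBin(raw, "integer", length(raw) %/% 4L, size = 4L,
              endian = "little") / 2147483648
    } else {
      stop(sprintf("unsupported PCM encoding: %d-bit", fmt$bits))
    }
  } else if (fmt$audio_format == 3L) {   # IEEE float
    sz <- fmt$bits %/% 8L
    readBin(raw, "double", length(raw) %/% sz, size = sz, endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding (format tag %d); PCM or IEEE float required",
                 fmt$audio_format))
  }
}

#' Write a mono 16-bit PCM WAV file
#'
#' Companion writer to [read_target_wav()]; samples are clipped to
#' `[-1, 1]` and quantized to 16-bit PCM.
#'
#' @param x numeric vector of samples in `[-1, 1]`.
#' @param fs sampling rate in Hz.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, fs, path) {
  x <- pmax(-1, pmin(1, as.numeric(x)))
  q <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(q)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_bytes, con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")      # PCM
  writeBin(1L, con, size = 2L, endian = "little")      # mono
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs) * 2L, con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")      # block align
  writeBin(16L, con, size = 2L, endian = "little")     # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4L, endian = "little")
  writeBin(q, con, size = 2L, endian = "little")
  invisible(path)
}
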