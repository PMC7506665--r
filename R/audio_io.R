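#' Audio recordings
#'
#' An `audio_recording` is the package's in-memory representation of a mono
#' auscultation signal: a numeric vector of amplitudes in `[-1, 1]` together
#' with its sample rate and the bit depth it was (or will be) stored at.
#' All downstream processing is bit-depth independent because integer PCM
#' samples are rescaled to `[-1, 1]` at read time.
#'
#' @param samples Numeric vector of amplitudes in `[-1, 1]`.
#' @param sample_rate_hz Positive integer sample rate (reference recorder:
#'   192000 Hz).
#' @param bit_depth Integer bit depth of the source/target PCM encoding
#'   (reference recorder: 24).
#' @return An object of class `audio_recording` with fields `samples`,
#'   `sample_rate_hz`, `bit_depth` and derived `duration_s`.
#' @export
audio_recording <- function(samples, sample_rate_hz, bit_depth = 24L) {
  samples <- as.numeric(samples)
  if (length(samples) && (anyNA(samples) ||
      max(abs(samples)) > 1 + 1e-12)) {
    stop("audio_recording: amplitudes must lie in [-1, 1] and be finite")
  }
  sample_rate_hz <- as.integer(sample_rate_hz)
  if (is.na(sample_rate_hz) || sample_rate_hz <= 0L) {
    stop("audio_recording: sample_rate_hz must be a positive integer")
  }
  structure(
    list(
      samples = samples,
      sample_rate_hz = sample_rate_hz,
      bit_depth = as.integer(bit_depth),
      duration_s = length(samples) / sample_rate_hz
    ),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf(
    "<audio_recording: %.3f s, %d Hz, %d-bit source, %d samples>\n",
    x$duration_s, x$sample_rate_hz, x$bit_depth, length(x$samples)
  ))
  invisible(x)
}

# little-endian unsigned int from a raw matrix column block
.u32 <- function(con) readBin(con, "integer", 1L, size = 4L, endian = "little")
.u16 <- function(con) readBin(con, "integer", 1L, size = 2L, endian = "little",
                              signed = FALSE)

#' Read a RIFF/WAVE PCM file
#'
#' Supports 16- and 24-bit integer PCM and 32-bit IEEE float, the encodings
#' produced by electronic stethoscope recorders. Integer samples are scaled
#' to `[-1, 1]` by division by `2^(bits-1)`; multi-channel audio is downmixed
#' to mono by channel averaging.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_recording()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("read_wav: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(riff, "RIFF")) stop("read_wav: not a RIFF file: ", path)
  .u32(con) # total size, unused
  wave <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(wave, "WAVE")) stop("read_wav: not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id_raw <- readBin(con, "raw", 4L)
    if (length(id_raw) < 4L) break
    id <- rawToChar(id_raw)
    size <- .u32(con)
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1, 256)),
        n_channels   = sum(as.integer(body[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(body[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      seek(con, size, origin = "current")
    }
    if (size %% 2L == 1L) seek(con, 1L, origin = "current") # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("read_wav: missing fmt chunk")
  if (is.null(data_raw)) data_raw <- raw(0)

  enc_name <- c(`1` = "PCM", `3` = "IEEE float")
  if (!fmt$audio_format %in% c(1L, 3L)) {
    stop(sprintf(
      "read_wav: unsupported encoding (format tag %d); only PCM and IEEE float are supported",
      fmt$audio_format
    ))
  }
  if (fmt$audio_format == 1L && !fmt$bits %in% c(16L, 24L)) {
    stop("read_wav: unsupported PCM bit depth: ", fmt$bits)
  }
  if (fmt$audio_format == 3L && fmt$bits != 32L) {
    stop("read_wav: unsupported float bit depth: ", fmt$bits)
  }

  x <- .decode_pcm(data_raw, fmt$audio_format, fmt$bits)
  if (fmt$n_channels > 1L) {
    n <- length(x) %/% fmt$n_channels
    dim(x) <- c(fmt$n_channels, n)
    x <- colMeans(x)
  }
  audio_recording(x, fmt$sample_rate, bit_depth = fmt$bits)
}

.decode_pcm <- function(data_raw, audio_format, bits) {
  if (audio_format == 3L) {
    return(readBin(data_raw, "double", length(data_raw) %/% 4L, size = 4L,
                   endian = "little"))
  }
  if (bits == 16L) {
    v <- readBin(data_raw, "integer", length(data_raw) %/% 2L, size = 2L,
                 endian = "little", signed = TRUE)
    return(v / 32768)
  }
  # 24-bit little-endian: assemble from byte triples
  n <- length(data_raw) %/% 3L
  if (n == 0L) return(numeric(0))
  b <- matrix(as.integer(data_raw[seq_len(3L * n)]), nrow = 3L)
  v <- b[1L, ] + 256 * b[2L, ] + 65536 * b[3L, ]
  v <- ifelse(v >= 8388608, v - 16777216, v)
  v / 8388608
}

#' Write a RIFF/WAVE PCM file
#'
#' Amplitudes outside `[-1, 1]` are an error, not silent saturation: a
#' clipped write would corrupt downstream envelope and spectrogram values.
#'
#' @param recording An [audio_recording()].
#' @param path Output path.
#' @param bit_depth 16 or 24 (integer PCM).
#' @return `path`, invisibly.
#' @export
write_wav <- function(recording, path, bit_depth = recording$bit_depth) {
  stopifnot(inherits(recording, "audio_recording"))
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(16L, 24L)) {
    stop("write_wav: bit_depth must be 16 or 24")
  }
  x <- recording$samples
  if (length(x) && max(abs(x)) > 1 + 1e-12) {
    stop("write_wav: amplitudes outside [-1, 1]; refusing to clip")
  }
  full <- 2^(bit_depth - 1L)
  q <- pmin(pmax(round(x * full), -full), full - 1)

  n <- length(q)
  bytes_per_sample <- bit_depth %/% 8L
  data_size <- n * bytes_per_sample
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("RIFF"), con)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeBin(charToRaw("WAVEfmt "), con)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")              # PCM
  writeBin(1L, con, size = 2L, endian = "little")              # mono
  writeBin(recording$sample_rate_hz, con, size = 4L, endian = "little")
  byte_rate <- recording$sample_rate_hz * bytes_per_sample
  writeBin(as.integer(byte_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(bytes_per_sample), con, size = 2L, endian = "little")
  writeBin(bit_depth, con, size = 2L, endian = "little")
  writeBin(charToRaw("data"), con)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (n) {
    if (bit_depth == 16L) {
      writeBin(as.integer(q), con, size = 2L, endian = "little")
    } else {
      v <- ifelse(q < 0, q + 16777216, q)
      b <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
      writeBin(as.raw(as.integer(b)), con)
    }
  }
  invisible(path)
}

#' Extract a time interval from a recording
#'
#' Sample indexing is half-open and zero-based in time: the returned samples
#' are those at indices `floor(start_s * rate)` up to but excluding
#' `floor(end_s * rate)`.
#'
#' @param recording An [audio_recording()].
#' @param start_s,end_s Interval bounds in seconds, `0 <= start_s < end_s <=
#'   duration_s`.
#' @return An [audio_recording()] at the same sample rate.
#' @export
slice_audio <- function(recording, start_s, end_s) {
  stopifnot(inherits(recording, "audio_recording"))
  if (!(start_s >= 0 && start_s < end_s &&
        end_s <= recording$duration_s + 1e-9)) {
    stop(sprintf(
      "slice_audio: invalid interval [%g, %g) for a %.3f s recording",
      start_s, end_s, recording$duration_s
    ))
  }
  r <- recording$sample_rate_hz
  i0 <- floor(start_s * r)       # 0-based inclusive
  i1 <- floor(end_s * r)         # 0-based exclusive
  i1 <- min(i1, length(recording$samples))
  audio_recording(recording$samples[(i0 + 1L):i1][seq_len(i1 - i0)],
                  r, recording$bit_depth)
}

.rms <- function(x) sqrt(mean(x^2))
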