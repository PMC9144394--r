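#' Read a mono 16-bit PCM WAV file
#'
#' Reads a RIFF/WAVE file and scales the integer samples to floats in
#' \[-1, 1\] (division by 32768, so full-scale positive is 32767/32768).
#' Multi-channel files are rejected rather than silently downmixed, and
#' only uncompressed integer PCM is supported: the recording chain this
#' package targets stores mono 16-bit PCM.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_clip()] with the file's sample rate.
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format    = readBin(con, "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels      = readBin(con, "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate     = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate       = readBin(con, "integer", 1, 4, endian = "little"),
        block_align     = readBin(con, "integer", 1, 2, signed = FALSE, endian = "little"),
        bits_per_sample = readBin(con, "integer", 1, 2, signed = FALSE, endian = "little")
      )
      extra <- size - 16L
      if (extra > 0L) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$audio_format != 1L) {
        stop("unsupported WAV encoding (only integer PCM is supported)")
      }
      if (fmt$n_channels != 1L) {
        stop("multi-channel WAV rejected (", fmt$n_channels,
             " channels); this package handles mono recordings only")
      }
      if (fmt$bits_per_sample != 16L) {
        stop("unsupported sample depth: ", fmt$bits_per_sample, " bit")
      }
      n <- size %/% 2L
      samples <- readBin(con, "integer", n, 2, signed = TRUE, endian = "little")
      break
    } else {
      # skip unknown chunk (LIST, fact, ...), padded to even size
      invisible(readBin(con, "raw", size + (size %% 2L)))
    }
  }
  if (is.null(samples)) stop("malformed WAV: no data chunk found")
  audio_clip(samples / 32768, fmt$sample_rate)
}

#' Write a clip as a mono 16-bit PCM WAV file
#'
#' Quantizes the float samples to 16-bit integers (round to nearest,
#' clamped to \[-32768, 32767\]). Quantization at write time is the only
#' place amplitude resolution is lost; all in-memory processing is double
#' precision.
#'
#' @param clip An [audio_clip()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- round(clip$samples * 32768)
  x <- pmin(pmax(x, -32768), 32767)
  n <- length(x)
  data_size <- 2L * n

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                       # PCM
  writeBin(1L, con, 2, endian = "little")                       # mono
  writeBin(as.integer(clip$rate), con, 4, endian = "little")
  writeBin(as.integer(clip$rate * 2L), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")                       # block align
  writeBin(16L, con, 2, endian = "little")                      # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  writeBin(as.integer(x), con, 2, endian = "little")
  invisible(path)
}
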