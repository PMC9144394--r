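#' Short-time Fourier transform with non-centered Hann framing
#'
#' Frames the clip with a periodic Hann window without padding or
#' centering: frame `j` covers samples `(j-1)*hop + 1 ... (j-1)*hop +
#' window`, so a clip of length `L` yields `floor((L - window)/hop) + 1`
#' frames and `window/2 + 1` one-sided frequency bins (DC and Nyquist
#' included). A 2-s clip at 16 kHz with window 256 / hop 128 gives a
#' 129 x 249 spectrogram.
#'
#' @param clip An [audio_clip()] with at least `window_size` samples.
#' @param window_size Analysis window length in samples (even).
#' @param hop_size Hop between frame starts in samples.
#' @return A `spectrogram` object: complex matrix `values` (bins x
#'   frames) plus window/hop/rate metadata and `kind = "complex"`.
#' @export
stft <- function(clip, window_size = 256, hop_size = 128) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- clip$samples
  L <- length(x)
  if (L < window_size) {
    stop("clip (", L, " samples) shorter than one window (", window_size, ")")
  }
  n_frames <- (L - window_size) %/% hop_size + 1L
  w <- hann_window(window_size)
  idx <- outer(seq_len(window_size), (seq_len(n_frames) - 1L) * hop_size, "+")
  frames <- matrix(x[idx], nrow = window_size) * w
  Z <- stats::mvfft(frames)[seq_len(window_size %/% 2L + 1L), , drop = FALSE]
  spectrogram(Z, window_size, hop_size, clip$rate, kind = "complex")
}

# periodic Hann window (COLA at hop = window/2)
hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)
}

#' Construct a spectrogram object
#'
#' @param values Matrix, frequency bins x frames (complex or real).
#' @param window_size,hop_size Framing metadata in samples.
#' @param rate Sample rate in Hz.
#' @param kind `"complex"`, `"magnitude"` or `"power"`.
#' @return A `spectrogram`.
#' @export
spectrogram <- function(values, window_size, hop_size, rate,
                        kind = c("complex", "magnitude", "power")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values))
  if (nrow(values) != window_size %/% 2L + 1L) {
    stop("bins (", nrow(values), ") inconsistent with window_size (",
         window_size, "): expected ", window_size %/% 2L + 1L)
  }
  structure(
    list(values = values, window_size = window_size, hop_size = hop_size,
         rate = rate, kind = kind),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram %s> %d bins x %d frames (window %d, hop %d, %g Hz)\n",
              x$kind, nrow(x$values), ncol(x$values),
              x$window_size, x$hop_size, x$rate))
  invisible(x)
}

#' Magnitude of a spectrogram
#'
#' @param spec A complex `spectrogram`.
#' @return A `spectrogram` with `kind = "magnitude"`.
#' @export
spec_magnitude <- function(spec) {
  stopifnot(inherits(spec, "spectrogram"))
  out <- spec
  out$values <- Mod(spec$values)
  out$kind <- "magnitude"
  out
}

#' Phase of a spectrogram
#'
#' @param spec A complex `spectrogram`.
#' @return Matrix of phases in radians (bins x frames).
#' @export
spec_phase <- function(spec) {
  stopifnot(inherits(spec, "spectrogram"), spec$kind == "complex")
  Arg(spec$values)
}

#' Power spectrum of a spectrogram
#'
#' Element-wise squared magnitude, floored at `eps` so logarithms of
#' silent bins stay defined (the log-spectral distance divides and logs
#' these values).
#'
#' @param spec A complex or magnitude `spectrogram`.
#' @param eps Floor applied to every power value.
#' @return A `spectrogram` with `kind = "power"`.
#' @export
power_spec <- function(spec, eps = 1e-10) {
  stopifnot(inherits(spec, "spectrogram"))
  p <- switch(spec$kind,
              complex = Mod(spec$values)^2,
              magnitude = spec$values^2,
              power = spec$values)
  out <- spec
  out$values <- pmax(p, eps)
  out$kind <- "power"
  out
}

#' Inverse STFT by normalized overlap-add
#'
#' Reconstructs a waveform from a complex spectrogram produced by
#' [stft()] with the same window and hop: each frame is inverse-DFT'd,
#' weighted by the synthesis (= analysis) window, overlap-added, and
#' normalized by the accumulated squared window. With a periodic Hann
#' window at hop = window/2 this is a perfect-reconstruction pair on the
#' fully covered interior (error below 1e-6); the outermost part-covered
#' samples are approximate.
#'
#' @param spec A complex `spectrogram`.
#' @param length_out Optional output length; the waveform is trimmed or
#'   zero-padded to it.
#' @return An [audio_clip()] at the spectrogram's rate.
#' @export
istft <- function(spec, length_out = NULL) {
  stopifnot(inherits(spec, "spectrogram"))
  if (spec$kind != "complex") stop("istft needs a complex spectrogram")
  win <- spec$window_size
  hop <- spec$hop_size
  Z <- spec$values
  n_frames <- ncol(Z)
  # restore the conjugate-symmetric full spectrum
  full <- rbind(Z, Conj(Z[(win %/% 2L):2L, , drop = FALSE]))
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / win
  w <- hann_window(win)
  L <- (n_frames - 1L) * hop + win
  y <- numeric(L)
  den <- numeric(L)
  for (j in seq_len(n_frames)) {
    i <- ((j - 1L) * hop + 1L):((j - 1L) * hop + win)
    y[i] <- y[i] + frames[, j] * w
    den[i] <- den[i] + w^2
  }
  # floor the normalizer at 10% of its peak: the interior (where
  # overlapping windows sum to O(1)) is untouched, while the outermost
  # samples — covered only by the near-zero tail of a single window —
  # are attenuated instead of amplified, which keeps modified (e.g.
  # masked) spectrograms from exploding at the clip edges
  y <- y / pmax(den, 0.1 * max(den))
  if (!is.null(length_out)) {
    if (length(y) >= length_out) y <- y[seq_len(length_out)]
    else y <- c(y, numeric(length_out - length(y)))
  }
  audio_clip(y, spec$rate)
}
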