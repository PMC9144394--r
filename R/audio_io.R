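#' Resample a clip to a new rate
#'
#' Band-limited polyphase resampling (via [signal::resample()]). The
#' output length is `round(n * target_rate / rate)`; when the target rate
#' equals the current rate the clip is returned unchanged.
#'
#' @param clip An [audio_clip()].
#' @param target_rate Target sample rate in Hz.
#' @return An [audio_clip()] at `target_rate`.
#' @examples
#' clip <- audio_clip(rnorm(44100), 44100)
#' n_samples(resample_clip(clip, 16000))  # 16000
#' @export
resample_clip <- function(clip, target_rate) {
  stopifnot(inherits(clip, "audio_clip"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0) {
    stop("`target_rate` must be a single positive number")
  }
  if (target_rate == clip$rate) return(clip)

  # reduce target/rate to an integer up/down factor pair
  r <- rational_ratio(target_rate, clip$rate)
  y <- signal::resample(clip$samples, r$p, r$q)
  n_out <- round(length(clip$samples) * target_rate / clip$rate)
  if (length(y) >= n_out) y <- y[seq_len(n_out)] else y <- c(y, numeric(n_out - length(y)))
  audio_clip(y, target_rate, clip$label)
}

rational_ratio <- function(a, b, tol = 1e-9) {
  # exact for integer rates; continued-fraction fallback otherwise
  if (a == round(a) && b == round(b)) {
    g <- gcd_int(round(a), round(b))
    return(list(p = round(a) / g, q = round(b) / g))
  }
  # fall back on a fine rational approximation
  q <- 1
  while (abs(a / b * q - round(a / b * q)) > tol && q < 1e6) q <- q + 1
  list(p = round(a / b * q), q = q)
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Partition a clip into fixed-length pieces
#'
#' Splits a clip into non-overlapping contiguous pieces of exactly
#' `piece_seconds`; a trailing remainder shorter than one piece is
#' discarded. This mirrors the slicing used to build the training and
#' test sets (5-min segments cut into 2-s slices, 150 slices per
#' segment).
#'
#' @param clip An [audio_clip()].
#' @param piece_seconds Piece length in seconds (positive).
#' @return A list of [audio_clip()] pieces (possibly empty).
#' @examples
#' seg <- audio_clip(numeric(5 * 8000), 8000)
#' length(partition(seg, 2))  # 2 pieces, 1 s discarded
#' @export
partition <- function(clip, piece_seconds) {
  stopifnot(inherits(clip, "audio_clip"))
  if (!is.numeric(piece_seconds) || length(piece_seconds) != 1L || piece_seconds <= 0) {
    stop("`piece_seconds` must be a single positive number")
  }
  piece_n <- round(piece_seconds * clip$rate)
  n_pieces <- length(clip$samples) %/% piece_n
  if (n_pieces == 0L) return(list())
  lapply(seq_len(n_pieces), function(i) {
    audio_clip(clip$samples[((i - 1L) * piece_n + 1L):(i * piece_n)],
               clip$rate, clip$label)
  })
}
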