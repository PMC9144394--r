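#' Construct an audio clip
#'
#' An `audio_clip` is the package's basic container: a mono sequence of
#' amplitude samples (dimensionless, nominally in \[-1, 1\]) together with
#' its sample rate and an optional class label. All denoisers, generators
#' and metrics consume and return `audio_clip` objects.
#'
#' @param samples Numeric vector of amplitudes.
#' @param rate Sample rate in Hz (positive scalar).
#' @param label Optional class tag, one of `"feeding"`, `"noise"`,
#'   `"ambient"`, or `NULL`.
#' @return An object of class `audio_clip`.
#' @examples
#' clip <- audio_clip(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), 8000)
#' duration(clip)
#' @export
audio_clip <- function(samples, rate, label = NULL) {
  if (!is.numeric(samples)) stop("`samples` must be numeric")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number")
  }
  if (!is.null(label)) {
    label <- match.arg(label, c("feeding", "noise", "ambient"))
  }
  structure(
    list(samples = as.numeric(samples), rate = rate, label = label),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf(
    "<audio_clip> %d samples @ %g Hz (%.3f s)%s\n",
    length(x$samples), x$rate, duration(x),
    if (is.null(x$label)) "" else paste0(" [", x$label, "]")
  ))
  invisible(x)
}

#' Duration of a clip in seconds
#'
#' @param clip An [audio_clip()].
#' @return Duration in seconds, `length(samples) / rate` exactly.
#' @export
duration <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  length(clip$samples) / clip$rate
}

#' Number of samples in a clip
#'
#' @param clip An [audio_clip()].
#' @return Integer sample count.
#' @export
n_samples <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  length(clip$samples)
}

#' Root-mean-square amplitude of a clip
#'
#' @param clip An [audio_clip()].
#' @return RMS amplitude (dimensionless).
#' @export
clip_rms <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  sqrt(mean(clip$samples^2))
}

# internal: check two clips are comparable sample-wise
check_aligned <- function(a, b) {
  stopifnot(inherits(a, "audio_clip"), inherits(b, "audio_clip"))
  if (length(a$samples) != length(b$samples)) {
    stop("clips have different lengths (", length(a$samples), " vs ",
         length(b$samples), ")")
  }
  if (a$rate != b$rate) stop("clips have different sample rates")
  invisible(TRUE)
}
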