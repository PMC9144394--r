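#' SNR increment achieved by denoising
#'
#' `delta_snr = SNR(pure, denoised) - SNR(pure, noisy)`: how many dB of
#' signal-to-noise ratio the denoiser gained. Positive means
#' improvement; the identity denoiser scores exactly 0. If the denoised
#' clip equals the pure clip (infinite after-SNR) the value is capped at
#' `cap` dB and flagged with attribute `capped = TRUE`.
#'
#' @param pure,noisy,denoised [audio_clip()]s of equal length and rate.
#' @param cap Cap applied when the after-denoising residual is zero.
#' @return SNR increment in dB.
#' @examples
#' p <- audio_clip(c(1, 1, 1, 1), 8000)
#' s <- audio_clip(p$samples + c(1, -1, 1, -1), 8000)
#' d <- audio_clip(p$samples + c(.1, -.1, .1, -.1), 8000)
#' delta_snr(p, s, d)  # 20 dB
#' @export
delta_snr <- function(pure, noisy, denoised, cap = 120) {
  before <- measure_snr(pure, noisy, infinite = "inf")
  after <- measure_snr(pure, denoised, infinite = "inf")
  if (!is.finite(after)) {
    out <- cap - min(before, cap)
    attr(out, "capped") <- TRUE
    return(out)
  }
  after - before
}

# frame-wise SNR per the global SNR definition; silent-pure frames give NA
frame_snrs <- function(pure, noisy, window, shift) {
  L <- length(pure)
  f <- (L - window) %/% shift + 1L
  vapply(seq_len(f), function(j) {
    i <- ((j - 1L) * shift + 1L):((j - 1L) * shift + window)
    es <- sum(pure[i]^2)
    if (es == 0) return(NA_real_)
    er <- sum((noisy[i] - pure[i])^2)
    if (er == 0) return(Inf)
    10 * log10(es / er)
  }, numeric(1))
}

#' Segmental-SNR increment achieved by denoising
#'
#' SegSNR is the mean of frame-wise SNRs over 256-sample windows shifted
#' by 128 samples (feeding sounds are short transients, so frame-wise
#' averaging weights the pulses rather than the silence between them).
#' The increment is SegSNR after minus before. Frames where the pure
#' signal has zero energy are excluded (their frame SNR is undefined);
#' if every frame is excluded an error is raised.
#'
#' @inheritParams delta_snr
#' @param window,shift Frame length and shift in samples.
#' @param exclude_silent Exclude zero-pure-energy frames (default). With
#'   `FALSE`, such frames raise an error immediately.
#' @return SegSNR increment in dB, with attribute `n_excluded`.
#' @export
delta_segsnr <- function(pure, noisy, denoised, window = 256, shift = 128,
                         exclude_silent = TRUE) {
  check_aligned(pure, noisy)
  check_aligned(pure, denoised)
  if (length(pure$samples) < window) stop("clip shorter than one frame")
  before <- frame_snrs(pure$samples, noisy$samples, window, shift)
  after <- frame_snrs(pure$samples, denoised$samples, window, shift)
  silent <- is.na(before) | is.na(after)
  if (any(silent) && !exclude_silent) {
    stop(sum(silent), " frame(s) with zero pure energy")
  }
  keep <- !silent & is.finite(before) & is.finite(after)
  if (!any(keep)) stop("no frames with defined SNR")
  out <- mean(after[keep]) - mean(before[keep])
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Log-spectral distance between pure and denoised clips
#'
#' Frame-averaged root-mean-square distance between log power spectra:
#' for each STFT frame, the root of the mean over bins of
#' `(10 log10(P_pure / P_denoised))^2`, averaged over frames. Power
#' spectra use the package STFT (Hann 256/128, non-centered) with the
#' epsilon floor of [power_spec()]. Zero for identical clips; symmetric
#' under swapping the two inputs.
#'
#' @param pure,denoised [audio_clip()]s of equal length (at least one
#'   window).
#' @param window,hop STFT framing in samples.
#' @return LSD in dB.
#' @export
lsd <- function(pure, denoised, window = 256, hop = 128) {
  check_aligned(pure, denoised)
  Pp <- power_spec(stft(pure, window, hop))$values
  Pd <- power_spec(stft(denoised, window, hop))$values
  d <- 10 * log10(Pp / Pd)
  mean(sqrt(colMeans(d^2)))
}

#' Relative improvement of a candidate over a reference, in percent
#'
#' `100 * (candidate - reference) / reference` for metrics where larger
#' is better; with `decreasing = TRUE` (e.g. LSD, where a fall is the
#' improvement) the sign convention flips to
#' `100 * (reference - candidate) / reference`.
#'
#' @param candidate,reference Metric values; `reference` must be nonzero.
#' @param decreasing Is a smaller candidate the improvement?
#' @param digits If non-`NULL`, round to this many decimals with
#'   half-away-from-zero rounding (the convention that reproduces
#'   printed report tables).
#' @return Percent improvement.
#' @examples
#' relative_improvement(16.97, 14.40, digits = 2)  # 17.85
#' @export
relative_improvement <- function(candidate, reference, decreasing = FALSE,
                                 digits = NULL) {
  if (any(reference == 0)) stop("`reference` must be nonzero")
  out <- if (decreasing) 100 * (reference - candidate) / reference
         else 100 * (candidate - reference) / reference
  if (!is.null(digits)) out <- round_half_away(out, digits)
  out
}

#' Round half away from zero
#'
#' Decimal rounding where exact halves move away from zero (2.345 ->
#' 2.35), matching how report tables print percentages; R's `round()`
#' uses round-half-even instead.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  # the 1e-9 guard keeps values that are mathematically exact halves but
  # sit a few ulps below them (e.g. 100*(18.13-15.68)/15.68) on the
  # away-from-zero side
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Evaluate a denoiser over a mixture dataset
#'
#' Runs `denoiser` on every mixed clip and reports per-clip Delta-SNR,
#' Delta-SegSNR and LSD, per-SNR-bucket means, and overall (unweighted
#' per-clip) means.
#'
#' @param records List of `mixture_record`s with audio.
#' @param denoiser Either a function `audio_clip -> audio_clip` or a
#'   pre-computed list of denoised [audio_clip()]s aligned with
#'   `records`.
#' @param window,shift Framing for SegSNR and LSD.
#' @return A `metrics_report`: list with `per_clip` (data.frame),
#'   `per_bucket` (data.frame of bucket means) and `overall` (named
#'   means).
#' @export
evaluate_denoiser <- function(records, denoiser, window = 256, shift = 128) {
  denoised <- if (is.function(denoiser)) {
    lapply(records, function(r) denoiser(r$mixed))
  } else {
    stopifnot(length(denoiser) == length(records))
    denoiser
  }
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    data.frame(
      clip = i,
      snr_bucket = r$target_snr,
      delta_snr = as.numeric(delta_snr(r$pure, r$mixed, denoised[[i]])),
      delta_segsnr = as.numeric(delta_segsnr(r$pure, r$mixed, denoised[[i]],
                                             window, shift)),
      lsd = lsd(r$pure, denoised[[i]], window, shift)
    )
  })
  per_clip <- do.call(rbind, rows)
  per_bucket <- do.call(rbind, lapply(split(per_clip, per_clip$snr_bucket),
    function(d) data.frame(snr_bucket = d$snr_bucket[1],
                           delta_snr = mean(d$delta_snr),
                           delta_segsnr = mean(d$delta_segsnr),
                           lsd = mean(d$lsd), n = nrow(d))))
  per_bucket <- per_bucket[order(per_bucket$snr_bucket), ]
  rownames(per_bucket) <- NULL
  overall <- c(delta_snr = mean(per_clip$delta_snr),
               delta_segsnr = mean(per_clip$delta_segsnr),
               lsd = mean(per_clip$lsd))
  structure(list(per_clip = per_clip, per_bucket = per_bucket,
                 overall = overall),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n overall: dSNR ",
      sprintf("%.2f dB, dSegSNR %.2f dB, LSD %.2f dB over %d clips\n",
              x$overall["delta_snr"], x$overall["delta_segsnr"],
              x$overall["lsd"], nrow(x$per_clip)))
  print(x$per_bucket, ...)
  invisible(x)
}
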