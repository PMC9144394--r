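#' Measure the signal-to-noise ratio of a noisy clip against its pure source
#'
#' SNR in dB of a noisy clip `S` relative to the pure clip `C` it was
#' built from:
#' \deqn{SNR = 10 \log_{10}\left[\frac{\sum_t C_t^2}{\sum_t (S_t - C_t)^2}\right]}
#' The residual `S - C` is the noise actually present, so this is exact
#' for additive mixtures, before or after denoising.
#'
#' @param pure Pure [audio_clip()] (`C`).
#' @param noisy Noisy or denoised [audio_clip()] (`S`), same length/rate.
#' @param infinite What to do when the residual is identically zero:
#'   `"error"` (default) or `"inf"` to return `+Inf`.
#' @return SNR in dB.
#' @examples
#' p <- audio_clip(c(1, 1, 1, 1), 8000)
#' s <- audio_clip(c(2, 0, 2, 0), 8000)
#' measure_snr(p, s)  # 0 dB: equal signal and residual energy
#' @export
measure_snr <- function(pure, noisy, infinite = c("error", "inf")) {
  infinite <- match.arg(infinite)
  check_aligned(pure, noisy)
  e_sig <- sum(pure$samples^2)
  if (e_sig == 0) stop("pure clip has zero energy; SNR undefined")
  e_res <- sum((noisy$samples - pure$samples)^2)
  if (e_res == 0) {
    if (infinite == "error") stop("residual is identically zero (infinite SNR)")
    return(Inf)
  }
  10 * log10(e_sig / e_res)
}

#' Mix a pure clip with noise at an exact target SNR
#'
#' Scales the noise (never the pure signal) so that the mixture
#' `pure + scale * noise` measures exactly `target` dB against the pure
#' clip:
#' \deqn{scale = \sqrt{\frac{\sum C_t^2}{10^{target/10} \sum N_t^2}}}
#'
#' @param pure Pure [audio_clip()].
#' @param noise Noise [audio_clip()], same length/rate.
#' @param target Target SNR in dB (finite).
#' @return A `mixture_record`: list with `pure`, `noise`, `target_snr`,
#'   `noise_scale`, `mixed`.
#' @export
mix_at_snr <- function(pure, noise, target) {
  check_aligned(pure, noise)
  if (!is.finite(target)) stop("`target` must be a finite SNR in dB")
  e_sig <- sum(pure$samples^2)
  e_noi <- sum(noise$samples^2)
  if (e_sig == 0) stop("pure clip has zero energy")
  if (e_noi == 0) stop("noise clip has zero energy")
  scale <- sqrt(e_sig / (10^(target / 10) * e_noi))
  mixed <- audio_clip(pure$samples + scale * noise$samples, pure$rate)
  structure(
    list(pure = pure, noise = noise, target_snr = target,
         noise_scale = scale, mixed = mixed),
    class = "mixture_record"
  )
}

#' @export
print.mixture_record <- function(x, ...) {
  cat(sprintf("<mixture_record> target %g dB, noise scale %.4g, %d samples\n",
              x$target_snr, x$noise_scale,
              if (inherits(x$mixed, "audio_clip")) n_samples(x$mixed) else NA_integer_))
  invisible(x)
}

#' SNR grids used for mixture construction
#'
#' Training mixtures use -20 to 5 dB in 5 dB steps; the test grid is
#' widened to -24 to 6 dB in 6 dB steps to probe beyond the training
#' range.
#'
#' @param which `"training"` or `"test"`.
#' @return Ordered numeric vector of dB levels.
#' @export
snr_grid <- function(which = c("training", "test")) {
  which <- match.arg(which)
  switch(which,
         training = c(-20, -15, -10, -5, 0, 5),
         test = c(-24, -18, -12, -6, 0, 6))
}

#' Build a balanced SNR-graded mixture dataset
#'
#' Pairs pure and noise slices at random (seeded) and assigns each pair
#' one SNR from the grid so that every level receives exactly
#' `length(pures) / length(grid)` mixtures — balanced assignment, which
#' is what exact per-level counts (e.g. 1050 of 6300 training mixtures
#' per level) require. If a mixture's peak amplitude exceeds 1, the
#' record's `pure`, `noise` and `mixed` clips are renormalized jointly so
#' the measured SNR is untouched while WAV export cannot clip.
#'
#' @param pures List of pure [audio_clip()]s.
#' @param noises List of noise [audio_clip()]s, same length as `pures`.
#' @param grid Numeric vector of SNR levels (see [snr_grid()]).
#' @param seed Integer seed for pairing and level assignment.
#' @param keep_audio If `FALSE`, records store indices into the input
#'   lists instead of clips (memory-light bookkeeping mode).
#' @return List of `mixture_record`s with attribute `"assignment"`, a
#'   data.frame of (pure_index, noise_index, snr_db, noise_scale).
#' @export
build_mixture_dataset <- function(pures, noises, grid, seed = 1L,
                                  keep_audio = TRUE) {
  stopifnot(is.list(pures), is.list(noises))
  if (length(pures) != length(noises)) {
    stop("`pures` and `noises` must have the same length")
  }
  ok_p <- vapply(pures, function(c) sum(c$samples^2) > 0, logical(1))
  ok_n <- vapply(noises, function(c) sum(c$samples^2) > 0, logical(1))
  if (!all(ok_p) || !all(ok_n)) {
    warning("dropping ", sum(!ok_p | !ok_n), " zero-energy slice pair(s)")
    keep <- ok_p & ok_n
    pures <- pures[keep]; noises <- noises[keep]
  }
  n <- length(pures)
  g <- length(grid)
  if (n %% g != 0L) {
    warning("count ", n, " not divisible by grid size ", g,
            "; truncating to ", (n %/% g) * g)
    n <- (n %/% g) * g
    pures <- pures[seq_len(n)]; noises <- noises[seq_len(n)]
  }
  set.seed(as.integer(seed))
  noise_order <- sample.int(n)
  snr_assign <- sample(rep(grid, each = n %/% g))

  records <- vector("list", n)
  assignment <- data.frame(pure_index = seq_len(n),
                           noise_index = noise_order,
                           snr_db = snr_assign,
                           noise_scale = NA_real_)
  for (i in seq_len(n)) {
    rec <- mix_at_snr(pures[[i]], noises[[noise_order[i]]], snr_assign[i])
    peak <- max(abs(rec$mixed$samples))
    if (peak > 1) {
      # joint renormalization: SNR is a ratio, so it is preserved
      f <- 1 / peak
      rec$pure$samples <- rec$pure$samples * f
      rec$noise$samples <- rec$noise$samples * f
      rec$mixed$samples <- rec$mixed$samples * f
    }
    assignment$noise_scale[i] <- rec$noise_scale
    if (!keep_audio) {
      rec$pure <- i
      rec$noise <- noise_order[i]
      rec$mixed <- NULL
    }
    records[[i]] <- rec
  }
  attr(records, "assignment") <- assignment
  records
}

#' Manifest of a mixture dataset
#'
#' @param records Output of [build_mixture_dataset()].
#' @return data.frame with one row per mixture (indices, SNR, scale).
#' @export
mixture_manifest <- function(records) {
  attr(records, "assignment")
}
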