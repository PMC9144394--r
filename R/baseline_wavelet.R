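#' Configuration for the wavelet-shrinkage baseline
#'
#' The traditional comparison method: multilevel db1 (Haar)
#' decomposition, a minimax shrinkage threshold scaled by a noise level
#' estimated from the finest detail band, and soft thresholding of all
#' detail bands. The decomposition depth defaults to 5 so that at 16 kHz
#' the coarsest detail band (250-500 Hz) sits well below the ~5 kHz
#' feeding-sound band.
#'
#' @param basis Wavelet family; only `"db1"` (Haar) is implemented.
#' @param threshold_rule Threshold selection rule; only `"minimax"`.
#' @param threshold_mode Threshold function; only `"soft"`.
#' @param level Decomposition depth (positive integer).
#' @return A list of class `wavelet_config`.
#' @export
wavelet_config <- function(basis = "db1", threshold_rule = "minimax",
                           threshold_mode = "soft", level = 5L) {
  basis <- match.arg(basis)
  threshold_rule <- match.arg(threshold_rule)
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(level >= 1)
  structure(
    list(basis = basis, threshold_rule = threshold_rule,
         threshold_mode = threshold_mode, level = as.integer(level)),
    class = "wavelet_config"
  )
}

#' Soft-thresholding operator
#'
#' `sign(x) * max(|x| - t, 0)`: shrinks every coefficient toward zero by
#' `t` and kills those below `t`.
#'
#' @param x Numeric vector of coefficients.
#' @param t Non-negative threshold.
#' @return Shrunk coefficients.
#' @examples
#' soft_threshold(c(1.5, -0.3), 1)  # 0.5, 0
#' @export
soft_threshold <- function(x, t) {
  if (!is.numeric(t) || length(t) != 1L || t < 0) {
    stop("`t` must be a single non-negative number")
  }
  sign(x) * pmax(abs(x) - t, 0)
}

#' Minimax shrinkage threshold
#'
#' The minimax-risk threshold for `n` samples, scaled by the robust
#' noise estimate from the finest detail coefficients:
#' `sigma_hat = median(|d1|) / 0.6745` and
#' `lambda(n) = 0.3936 + 0.1829 * log2(n)` for `n > 32`, else 0
#' (no shrinkage for very short signals). For `sigma_hat = 1` and
#' `n = 1024` the threshold is 2.2226.
#'
#' @param detail_coeffs Finest-level detail coefficients, used for the
#'   noise estimate.
#' @param n Signal length the risk factor is computed for.
#' @return Non-negative threshold `sigma_hat * lambda(n)`.
#' @export
minimax_threshold <- function(detail_coeffs, n) {
  if (length(detail_coeffs) == 0L) stop("empty detail coefficients")
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    stop("`n` must be a single positive integer")
  }
  sigma <- stats::median(abs(detail_coeffs)) / 0.6745
  lambda <- if (n > 32) 0.3936 + 0.1829 * log2(n) else 0
  sigma * lambda
}

# one Haar analysis step; odd-length inputs are extended symmetrically
# by one sample (recorded so synthesis can undo it)
haar_step <- function(x) {
  n <- length(x)
  padded <- n %% 2L == 1L
  if (padded) x <- c(x, x[n])
  even <- x[seq(2L, length(x), by = 2L)]
  odd <- x[seq(1L, length(x), by = 2L)]
  list(approx = (odd + even) / sqrt(2), detail = (odd - even) / sqrt(2),
       padded = padded)
}

haar_unstep <- function(approx, detail, padded) {
  odd <- (approx + detail) / sqrt(2)
  even <- (approx - detail) / sqrt(2)
  x <- as.numeric(rbind(odd, even))
  if (padded) x <- x[-length(x)]
  x
}

#' Multilevel Haar (db1) wavelet decomposition
#'
#' @param x Numeric signal.
#' @param level Decomposition depth; must not exceed `floor(log2(n))`.
#' @return List with `approx` (coarsest approximation), `details` (list
#'   of detail bands, finest first) and `padded` flags per level.
#' @export
haar_dwt <- function(x, level) {
  n <- length(x)
  if (n < 2L) stop("signal too short for a wavelet decomposition")
  max_level <- floor(log2(n))
  if (level > max_level) {
    stop("level ", level, " exceeds maximum depth ", max_level,
         " for length ", n)
  }
  details <- vector("list", level)
  padded <- logical(level)
  a <- x
  for (l in seq_len(level)) {
    s <- haar_step(a)
    details[[l]] <- s$detail
    padded[l] <- s$padded
    a <- s$approx
  }
  list(approx = a, details = details, padded = padded)
}

#' Multilevel Haar (db1) wavelet reconstruction
#'
#' Exact inverse of [haar_dwt()] (perfect-reconstruction filter bank).
#'
#' @param dec Decomposition as returned by [haar_dwt()].
#' @return Reconstructed numeric signal.
#' @export
haar_idwt <- function(dec) {
  a <- dec$approx
  for (l in rev(seq_along(dec$details))) {
    a <- haar_unstep(a, dec$details[[l]], dec$padded[l])
  }
  a
}

#' Wavelet soft-threshold denoising
#'
#' Decomposes the clip to `config$level`, estimates the noise level from
#' the finest detail band, soft-thresholds every detail band with the
#' minimax threshold (computed for the clip length), reconstructs, and
#' returns a clip of the input length.
#'
#' @param clip A non-empty [audio_clip()].
#' @param config A [wavelet_config()].
#' @return Denoised [audio_clip()].
#' @export
wavelet_denoise <- function(clip, config = wavelet_config()) {
  stopifnot(inherits(clip, "audio_clip"))
  if (length(clip$samples) == 0L) stop("empty clip")
  dec <- haar_dwt(clip$samples, config$level)
  t <- minimax_threshold(dec$details[[1L]], length(clip$samples))
  dec$details <- lapply(dec$details, soft_threshold, t = t)
  audio_clip(haar_idwt(dec), clip$rate, clip$label)
}
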