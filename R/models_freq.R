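#' Configuration for a frequency-domain denoising network (FDD-Net)
#'
#' FDD-Nets estimate a non-negative time-frequency mask from the
#' magnitude spectrogram of a noisy clip: three recurrent layers read
#' the frame sequence (frequency bins are the features, frames the
#' recurrence axis), a dropout layer precedes a fully connected layer
#' with ReLU that maps back to one mask value per bin. The denoised
#' magnitude is the element-wise product of the noisy magnitude and the
#' mask. Variants by recurrent cell and direction:
#' R/G/L (unidirectional RNN/GRU/LSTM) and BR/BG/BL (bidirectional).
#'
#' @param cell `"RNN"`, `"GRU"` or `"LSTM"`.
#' @param bidirectional Logical; bidirectional layers double the feature
#'   width feeding the final projection.
#' @param hidden_size Hidden units per direction.
#' @param n_layers Number of recurrent layers (3).
#' @param dropout_rate Dropout probability before the fully connected
#'   layer, in \[0, 1).
#' @param n_bins Spectrogram bins (129 for window 256).
#' @param window_size,hop_size STFT framing the model operates on.
#' @return A list of class `fdd_config`.
#' @export
fdd_config <- function(cell = c("LSTM", "RNN", "GRU"), bidirectional = TRUE,
                       hidden_size = 256, n_layers = 3L, dropout_rate = 0.2,
                       n_bins = 129L, window_size = 256L, hop_size = 128L) {
  cell <- match.arg(cell)
  stopifnot(hidden_size >= 1, n_layers >= 1,
            dropout_rate >= 0, dropout_rate < 1)
  structure(
    list(cell = cell, bidirectional = isTRUE(bidirectional),
         hidden_size = as.integer(hidden_size), n_layers = as.integer(n_layers),
         dropout_rate = dropout_rate, n_bins = as.integer(n_bins),
         window_size = as.integer(window_size), hop_size = as.integer(hop_size)),
    class = "fdd_config"
  )
}

#' Map an FDD variant name to its configuration
#'
#' @param variant One of `"R"`, `"G"`, `"L"`, `"BR"`, `"BG"`, `"BL"`.
#' @param ... Passed to [fdd_config()].
#' @return An `fdd_config`.
#' @export
fdd_variant <- function(variant = c("BL", "R", "G", "L", "BR", "BG"), ...) {
  variant <- match.arg(variant)
  bidir <- startsWith(variant, "B")
  cell <- switch(sub("^B", "", variant), R = "RNN", G = "GRU", L = "LSTM")
  fdd_config(cell = cell, bidirectional = bidir, ...)
}

#' Build an FDD-Net mask estimator
#'
#' @param config An [fdd_config()].
#' @param seed Integer seed for weight initialisation.
#' @param rate Sample rate (Hz) the model is intended for.
#' @return An object of class `fdd_net`. Its per-bin input
#'   standardisation statistics (`$bin_mean`, `$bin_sd`) are fitted by
#'   [train_fdd()]; the mask and loss always operate on unstandardised
#'   magnitudes.
#' @export
build_fdd <- function(config = fdd_config(), seed = 1L, rate = 16000) {
  stopifnot(inherits(config, "fdd_config"))
  set.seed(as.integer(seed))
  h <- config$hidden_size
  width <- if (config$bidirectional) 2L * h else h
  params <- list()
  din <- config$n_bins
  for (l in seq_len(config$n_layers)) {
    params[[paste0("rec", l)]] <- if (config$bidirectional) {
      list(fwd = rnn_cell_init(din, h, config$cell),
           bwd = rnn_cell_init(din, h, config$cell))
    } else {
      rnn_cell_init(din, h, config$cell)
    }
    din <- width
  }
  # near-zero mask head: the untrained estimator masks everything out,
  # which is already a strong denoiser at low SNR; training recovers the
  # signal-carrying cells from there
  params$fc <- linear_init(width, config$n_bins)
  params$fc$W <- params$fc$W * 0.01
  structure(
    list(config = config, params = params, rate = rate,
         bin_mean = numeric(config$n_bins), bin_sd = rep(1, config$n_bins),
         trained = FALSE, loss_history = numeric(0)),
    class = "fdd_net"
  )
}

#' @export
print.fdd_net <- function(x, ...) {
  cat(sprintf("<fdd_net %s%s> hidden %d x %d layers, %d bins, %s\n",
              if (x$config$bidirectional) "Bi" else "", x$config$cell,
              x$config$hidden_size, x$config$n_layers, x$config$n_bins,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# forward: Xstd is (T, B, bins) standardized magnitudes
fdd_forward <- function(model, Xstd, training = FALSE) {
  cfg <- model$config
  p <- model$params
  caches <- list()
  H <- Xstd
  for (l in seq_len(cfg$n_layers)) {
    nm <- paste0("rec", l)
    r <- if (cfg$bidirectional) bicell_fwd(p[[nm]], H, cfg$cell)
         else cell_fwd(p[[nm]], H, cfg$cell)
    caches[[nm]] <- list(cache = r$cache, X = H)
    H <- r$out
  }
  Tn <- dim(H)[1]; B <- dim(H)[2]; Fh <- dim(H)[3]
  Hm <- matrix(H, Tn * B, Fh)
  if (training && cfg$dropout_rate > 0) {
    keep <- (stats::runif(length(Hm)) >= cfg$dropout_rate) / (1 - cfg$dropout_rate)
    Hm <- Hm * keep
    caches$drop <- keep
  }
  fc <- linear_fwd(p$fc, Hm)
  ac <- relu_fwd(fc$out)
  caches$fc <- fc$cache
  caches$relu <- ac$cache
  caches$dims <- c(Tn, B, Fh)
  list(out = array(ac$out, dim = c(Tn, B, cfg$n_bins)), cache = caches)
}

fdd_backward <- function(model, cache, dM) {
  cfg <- model$config
  p <- model$params
  dims <- cache$dims
  Tn <- dims[1]; B <- dims[2]; Fh <- dims[3]
  dOut <- matrix(dM, Tn * B, cfg$n_bins)
  dFc <- relu_bwd(cache$relu, dOut)
  bw <- linear_bwd(p$fc, cache$fc, dFc)
  grads <- list(fc = bw$grads)
  dH <- bw$dx
  if (!is.null(cache$drop)) dH <- dH * cache$drop
  dH <- array(dH, dim = c(Tn, B, Fh))
  for (l in rev(seq_len(cfg$n_layers))) {
    nm <- paste0("rec", l)
    cc <- cache[[nm]]
    r <- if (cfg$bidirectional) {
      bicell_bwd(p[[nm]], cc$cache, cc$X, dH, cfg$cell)
    } else {
      cell_bwd(p[[nm]], cc$cache, cc$X, dH, cfg$cell)
    }
    grads[[nm]] <- r$grads
    dH <- r$dx
  }
  grads
}

#' Apply a time-frequency mask to a magnitude spectrogram
#'
#' Element-wise product `F_denoised = F_noisy * M`.
#'
#' @param noisy_spec A magnitude `spectrogram`.
#' @param mask Non-negative matrix of the same shape (a `MaskMatrix`).
#' @return A magnitude `spectrogram`.
#' @export
apply_mask <- function(noisy_spec, mask) {
  stopifnot(inherits(noisy_spec, "spectrogram"))
  if (noisy_spec$kind == "complex") noisy_spec <- spec_magnitude(noisy_spec)
  if (!all(dim(mask) == dim(noisy_spec$values))) {
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match spectrogram ",
         paste(dim(noisy_spec$values), collapse = "x"))
  }
  if (any(mask < 0)) stop("mask must be non-negative")
  out <- noisy_spec
  out$values <- noisy_spec$values * mask
  out
}

#' Masked-spectrogram MSE loss
#'
#' \deqn{Loss = \frac{1}{N}\sum (F_{noisy} \hat M - F_{pure})^2}
#' with `N` the number of points (bins x frames) in the spectrogram.
#'
#' @param noisy_spec,pure_spec Magnitude `spectrogram`s (or matrices) of
#'   equal shape.
#' @param mask Estimated mask matrix of the same shape.
#' @return Scalar loss.
#' @export
fdd_loss <- function(noisy_spec, mask, pure_spec) {
  Fn <- if (inherits(noisy_spec, "spectrogram")) noisy_spec$values else noisy_spec
  Fp <- if (inherits(pure_spec, "spectrogram")) pure_spec$values else pure_spec
  if (!all(dim(Fn) == dim(mask)) || !all(dim(Fn) == dim(Fp))) {
    stop("shape mismatch between spectrograms and mask")
  }
  mean((Fn * mask - Fp)^2)
}

#' Phase-sensitive "oracle" mask
#'
#' The non-negative real mask that, per spectrogram cell, minimises the
#' error of masked-noisy-magnitude reconstruction under the noisy phase:
#' `M* = max(0, Re(F_pure conj(F_noisy)) / |F_noisy|^2)`, clipped to
#' `[0, clip_max]`. Because the all-ones mask lies inside the feasible
#' set, this oracle dominates it cell by cell — an upper-bound harness
#' for trained mask estimators. (The plain magnitude ratio
#' `|F_pure|/|F_noisy|` is not an upper bound here: in noise-dominated
#' cells it keeps the pure magnitude but the wrong phase, which can
#' double the residual.)
#'
#' @param pure_spec,noisy_spec Complex `spectrogram`s of equal shape
#'   (plain complex matrices are accepted).
#' @param clip_max Upper clip for cells where the noisy magnitude is
#'   tiny.
#' @return Mask matrix.
#' @export
oracle_mask <- function(pure_spec, noisy_spec, clip_max = 10) {
  Fp <- if (inherits(pure_spec, "spectrogram")) pure_spec$values else pure_spec
  Fn <- if (inherits(noisy_spec, "spectrogram")) noisy_spec$values else noisy_spec
  if (!is.complex(Fp) || !is.complex(Fn)) {
    stop("oracle_mask needs complex spectrograms (phase-sensitive mask)")
  }
  m <- Re(Fp * Conj(Fn)) / pmax(Mod(Fn)^2, 1e-24)
  pmin(pmax(m, 0), clip_max)
}

#' Train an FDD-Net on mixture records
#'
#' Fits per-bin standardisation statistics from the training noisy
#' magnitudes, then minimises the masked-spectrogram MSE with Adam under
#' the plateau learning-rate schedule (initial 1e-4, x0.7 after any
#' epoch whose training loss does not decrease).
#'
#' @inheritParams train_tdd
#' @param schedule A [train_schedule()]; defaults to the FDD schedule.
#' @return The trained `fdd_net` with `$loss_history`.
#' @export
train_fdd <- function(model, records, epochs = 5, batch_size = 16,
                      schedule = train_schedule("fdd"), seed = 1L,
                      verbose = FALSE) {
  stopifnot(inherits(model, "fdd_net"))
  cfg <- model$config
  mags_noisy <- lapply(records, function(r) {
    Mod(stft(r$mixed, cfg$window_size, cfg$hop_size)$values)
  })
  mags_pure <- lapply(records, function(r) {
    Mod(stft(r$pure, cfg$window_size, cfg$hop_size)$values)
  })
  Tn <- unique(vapply(mags_noisy, ncol, integer(1)))
  if (length(Tn) != 1L) stop("all training clips must have equal length")
  n <- length(records)

  # per-bin standardisation from the training noisy magnitudes
  all_noisy <- do.call(cbind, mags_noisy)
  model$bin_mean <- rowMeans(all_noisy)
  model$bin_sd <- pmax(apply(all_noisy, 1, stats::sd), 1e-8)

  opt <- adam_init(model$params)
  set.seed(as.integer(seed))
  history <- model$loss_history

  for (ep in seq_len(epochs)) {
    lr <- lr_at_epoch(schedule, length(history), history)
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      ids <- ord[start:min(start + batch_size - 1L, n)]
      B <- length(ids)
      # (T, B, bins): recurrence over frames, bins are features
      X <- array(0, dim = c(Tn, B, cfg$n_bins))
      Fn <- array(0, dim = c(Tn, B, cfg$n_bins))
      Fp <- array(0, dim = c(Tn, B, cfg$n_bins))
      for (j in seq_len(B)) {
        mn <- mags_noisy[[ids[j]]]
        X[, j, ] <- t((mn - model$bin_mean) / model$bin_sd)
        Fn[, j, ] <- t(mn)
        Fp[, j, ] <- t(mags_pure[[ids[j]]])
      }
      fw <- fdd_forward(model, X, training = TRUE)
      diff <- Fn * fw$out - Fp
      loss <- mean(diff^2)
      ep_loss <- ep_loss + loss * B
      dM <- 2 * Fn * diff / length(diff)
      grads <- fdd_backward(model, fw$cache, dM)
      stp <- adam_step(model$params, grads, opt, lr)
      model$params <- stp$params
      opt <- stp$state
    }
    history <- c(history, ep_loss / n)
    if (verbose) {
      message(sprintf("epoch %d: loss %.6g (lr %.2g)", length(history),
                      ep_loss / n, lr))
    }
  }
  model$loss_history <- history
  model$trained <- TRUE
  model
}

#' Denoise a waveform with an FDD-Net
#'
#' STFT of the noisy clip, mask estimation, element-wise masking of the
#' noisy magnitude, reconstruction with the noisy phase via [istft()],
#' trimmed/padded to the input length. An optional `forced_mask`
#' bypasses the network (e.g. the [oracle_mask()] or an all-ones mask).
#'
#' @param model An `fdd_net`.
#' @param noisy Noisy [audio_clip()] at the model's rate, at least one
#'   STFT window long.
#' @param forced_mask Optional mask matrix used instead of the network
#'   output.
#' @return Denoised [audio_clip()] of the same length.
#' @export
denoise_freq <- function(model, noisy, forced_mask = NULL) {
  stopifnot(inherits(model, "fdd_net"), inherits(noisy, "audio_clip"))
  if (noisy$rate != model$rate) {
    stop("clip rate (", noisy$rate, " Hz) differs from the model's training rate (",
         model$rate, " Hz)")
  }
  cfg <- model$config
  Z <- stft(noisy, cfg$window_size, cfg$hop_size)
  mag <- Mod(Z$values)
  if (is.null(forced_mask)) {
    Xstd <- array(t((mag - model$bin_mean) / model$bin_sd),
                  dim = c(ncol(mag), 1L, cfg$n_bins))
    fw <- fdd_forward(model, Xstd, training = FALSE)
    mask <- t(matrix(fw$out, ncol(mag), cfg$n_bins))
  } else {
    mask <- forced_mask
  }
  den <- mag * mask
  rec <- Z
  rec$values <- den * exp(1i * Arg(Z$values))
  istft(rec, length_out = length(noisy$samples))
}
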