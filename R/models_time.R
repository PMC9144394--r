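#' Configuration for a time-domain denoising network (TDD-Net)
#'
#' TDD-Nets are waveform-in/waveform-out denoisers: an input convolution
#' (1 -> channels), eight convolution blocks, an output convolution and a
#' final 1x1 convolution back to one channel. Every convolution except
#' the final 1x1 is followed by batch normalization and a leaky ReLU.
#' The four variants differ only in the blocks:
#' * `"C"` - standard convolutions (dilation 1);
#' * `"D"` - dilated convolutions, dilation `2^k` in block `k`;
#' * `"DS"` - dilated convolutions with an identity shortcut per block;
#' * `"DC"` - dilated convolutions with a convolutional (dilation-1)
#'   shortcut per block, capturing local correlation on the bypass path.
#'
#' In a block the shortcut is added to the batch-normalized convolution
#' output and the sum passes through the leaky ReLU.
#'
#' @param variant One of `"C"`, `"D"`, `"DS"`, `"DC"`.
#' @param channels Channel width of all internal convolutions.
#' @param kernel_size Odd kernel size of all non-1x1 convolutions.
#' @param leaky_slope Negative slope of the leaky ReLU.
#' @param n_blocks Number of convolution blocks (8).
#' @param dilation_base Base of the dilation schedule (2, so block `k`
#'   dilates by `2^k`).
#' @return A list of class `tdd_config`.
#' @export
tdd_config <- function(variant = c("DC", "C", "D", "DS"), channels = 64,
                       kernel_size = 3, leaky_slope = 0.01, n_blocks = 8L,
                       dilation_base = 2L) {
  variant <- match.arg(variant)
  stopifnot(channels >= 1, kernel_size %% 2 == 1, kernel_size >= 1,
            leaky_slope > 0, leaky_slope < 1, n_blocks >= 1)
  structure(
    list(variant = variant, channels = as.integer(channels),
         kernel_size = as.integer(kernel_size), leaky_slope = leaky_slope,
         n_blocks = as.integer(n_blocks),
         dilation_base = as.integer(dilation_base)),
    class = "tdd_config"
  )
}

#' Dilation schedule of a TDD-Net
#'
#' @param config A [tdd_config()].
#' @return Integer vector of per-block dilations: all 1 for variant
#'   `"C"`, otherwise `2^k` for block `k = 1..n_blocks`.
#' @export
tdd_dilations <- function(config) {
  stopifnot(inherits(config, "tdd_config"))
  if (config$variant == "C") rep(1L, config$n_blocks)
  else config$dilation_base^seq_len(config$n_blocks)
}

#' Build a TDD-Net waveform denoiser
#'
#' @param config A [tdd_config()].
#' @param seed Integer seed for weight initialisation.
#' @param rate Sample rate (Hz) the model is intended for; checked at
#'   denoising time.
#' @return An object of class `tdd_net` holding parameters, batch-norm
#'   running statistics and the config. Untrained until passed through
#'   [train_tdd()].
#' @export
build_tdd <- function(config = tdd_config(), seed = 1L, rate = 16000) {
  stopifnot(inherits(config, "tdd_config"))
  set.seed(as.integer(seed))
  C <- config$channels
  k <- config$kernel_size
  has_sc <- config$variant == "DC"
  params <- list(conv_in = conv1d_init(1L, C, k), bn_in = bn_init(C))
  stats <- list(bn_in = bn_stats_init(C))
  for (b in seq_len(config$n_blocks)) {
    params[[paste0("conv_b", b)]] <- conv1d_init(C, C, k)
    params[[paste0("bn_b", b)]] <- bn_init(C)
    stats[[paste0("bn_b", b)]] <- bn_stats_init(C)
    if (has_sc) {
      params[[paste0("conv_s", b)]] <- conv1d_init(C, C, k)
      params[[paste0("bn_s", b)]] <- bn_init(C)
      stats[[paste0("bn_s", b)]] <- bn_stats_init(C)
    }
  }
  params$conv_out <- conv1d_init(C, C, k)
  params$bn_out <- bn_init(C)
  stats$bn_out <- bn_stats_init(C)
  # near-zero final projection: the untrained network is then a near-null
  # denoiser (a strong baseline at low SNR) and short training runs move
  # it monotonically toward signal recovery
  params$conv_final <- conv1d_init(C, 1L, 1L)
  params$conv_final$W <- params$conv_final$W * 0.01
  structure(
    list(config = config, params = params, bn_stats = stats, rate = rate,
         trained = FALSE, loss_history = numeric(0)),
    class = "tdd_net"
  )
}

#' @export
print.tdd_net <- function(x, ...) {
  cat(sprintf("<tdd_net %s> %d channels, kernel %d, %d blocks%s, %s\n",
              x$config$variant, x$config$channels, x$config$kernel_size,
              x$config$n_blocks,
              if (x$config$variant == "C") "" else
                sprintf(" (dilations %s)", paste(tdd_dilations(x$config), collapse = ",")),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Number of trainable parameters of a model
#'
#' @param model A `tdd_net`, `fdd_net` or `fsrnet` model.
#' @return Integer count of scalar parameters.
#' @export
n_parameters <- function(model) {
  cnt <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else cnt <<- cnt + length(x)
    invisible(NULL)
  }
  walk(model$params)
  cnt
}

#' Receptive field of a TDD-Net, by graph traversal
#'
#' Accumulates `(kernel - 1) * dilation` over the deepest path of the
#' layer graph (the shortcut path of variant DC is shallower and never
#' dominates).
#'
#' @param model A `tdd_net`.
#' @return Receptive field in samples.
#' @export
tdd_receptive_field <- function(model) {
  stopifnot(inherits(model, "tdd_net"))
  k <- model$config$kernel_size
  d <- tdd_dilations(model$config)
  # input conv + blocks + output conv (final conv is 1x1)
  1L + (k - 1L) * 1L + sum((k - 1L) * d) + (k - 1L) * 1L
}

# forward pass; X is array (1, L, B) or matrix (1, L*B) with dims given
tdd_forward <- function(model, X, training = FALSE, dims = NULL) {
  cfg <- model$config
  p <- model$params
  st <- model$bn_stats
  k <- cfg$kernel_size
  dil <- tdd_dilations(cfg)
  has_sc <- cfg$variant == "DC"
  add_sc <- cfg$variant %in% c("DS", "DC")
  cache <- list()
  if (is.null(dims)) {
    stopifnot(length(dim(X)) == 3L)
    dims <- c(dim(X)[2], dim(X)[3])
  }
  dim(X) <- c(dim(X)[1], prod(dims))

  cv <- conv1d_fwd(p$conv_in, X, dims, 1L, k)
  bn <- bn_fwd(p$bn_in, cv$out, st$bn_in, training)
  st$bn_in <- bn$stats
  ac <- lrelu_fwd(bn$out, cfg$leaky_slope)
  cache$inp <- list(cv = cv$cache, bn = bn$cache, ac = ac$cache)
  h <- ac$out

  for (b in seq_len(cfg$n_blocks)) {
    x_in <- h
    cv <- conv1d_fwd(p[[paste0("conv_b", b)]], x_in, dims, dil[b], k)
    bn <- bn_fwd(p[[paste0("bn_b", b)]], cv$out, st[[paste0("bn_b", b)]], training)
    st[[paste0("bn_b", b)]] <- bn$stats
    pre <- bn$out
    blk <- list(cv = cv$cache, bn = bn$cache)
    if (has_sc) {
      cvs <- conv1d_fwd(p[[paste0("conv_s", b)]], x_in, dims, 1L, k)
      bns <- bn_fwd(p[[paste0("bn_s", b)]], cvs$out, st[[paste0("bn_s", b)]], training)
      st[[paste0("bn_s", b)]] <- bns$stats
      pre <- pre + bns$out
      blk$cvs <- cvs$cache
      blk$bns <- bns$cache
    } else if (add_sc) {
      pre <- pre + x_in
    }
    ac <- lrelu_fwd(pre, cfg$leaky_slope)
    blk$ac <- ac$cache
    cache[[paste0("b", b)]] <- blk
    h <- ac$out
  }

  cv <- conv1d_fwd(p$conv_out, h, dims, 1L, k)
  bn <- bn_fwd(p$bn_out, cv$out, st$bn_out, training)
  st$bn_out <- bn$stats
  ac <- lrelu_fwd(bn$out, cfg$leaky_slope)
  cache$outp <- list(cv = cv$cache, bn = bn$cache, ac = ac$cache)
  fin <- conv1d_fwd(p$conv_final, ac$out, dims, 1L, 1L)
  cache$fin <- fin$cache

  list(out = fin$out, dims = dims, cache = cache, bn_stats = st)
}

tdd_backward <- function(model, cache, dY) {
  cfg <- model$config
  p <- model$params
  grads <- list()

  bw <- conv1d_bwd(p$conv_final, cache$fin, dY)
  grads$conv_final <- bw$grads
  d <- lrelu_bwd(cache$outp$ac, bw$dx)
  bw <- bn_bwd(p$bn_out, cache$outp$bn, d)
  grads$bn_out <- bw$grads
  bw2 <- conv1d_bwd(p$conv_out, cache$outp$cv, bw$dx)
  grads$conv_out <- bw2$grads
  d <- bw2$dx

  has_sc <- cfg$variant == "DC"
  add_sc <- cfg$variant %in% c("DS", "DC")
  for (b in rev(seq_len(cfg$n_blocks))) {
    blk <- cache[[paste0("b", b)]]
    dpre <- lrelu_bwd(blk$ac, d)
    bw <- bn_bwd(p[[paste0("bn_b", b)]], blk$bn, dpre)
    grads[[paste0("bn_b", b)]] <- bw$grads
    bw2 <- conv1d_bwd(p[[paste0("conv_b", b)]], blk$cv, bw$dx)
    grads[[paste0("conv_b", b)]] <- bw2$grads
    d_in <- bw2$dx
    if (has_sc) {
      bws <- bn_bwd(p[[paste0("bn_s", b)]], blk$bns, dpre)
      grads[[paste0("bn_s", b)]] <- bws$grads
      bws2 <- conv1d_bwd(p[[paste0("conv_s", b)]], blk$cvs, bws$dx)
      grads[[paste0("conv_s", b)]] <- bws2$grads
      d_in <- d_in + bws2$dx
    } else if (add_sc) {
      d_in <- d_in + dpre
    }
    d <- d_in
  }

  d <- lrelu_bwd(cache$inp$ac, d)
  bw <- bn_bwd(p$bn_in, cache$inp$bn, d)
  grads$bn_in <- bw$grads
  bw2 <- conv1d_bwd(p$conv_in, cache$inp$cv, bw$dx)
  grads$conv_in <- bw2$grads
  grads
}

#' Mean-squared-error loss between denoised and pure waveforms
#'
#' \deqn{Loss = \frac{1}{n}\sum_t (C_t - D_t)^2}
#'
#' @param denoised Denoised [audio_clip()] or numeric vector.
#' @param pure Pure [audio_clip()] or numeric vector of equal length.
#' @return Scalar loss.
#' @export
tdd_loss <- function(denoised, pure) {
  d <- if (inherits(denoised, "audio_clip")) denoised$samples else denoised
  c_ <- if (inherits(pure, "audio_clip")) pure$samples else pure
  if (length(d) != length(c_)) stop("length mismatch: ", length(d), " vs ", length(c_))
  if (length(d) == 0L) stop("empty input")
  mean((c_ - d)^2)
}

#' Train a TDD-Net on mixture records
#'
#' Minimises waveform MSE between the network output for the mixed clip
#' and the pure clip, with Adam and the step learning-rate schedule
#' (initial 0.001 halved every 20 epochs by default, see
#' [train_schedule()]).
#'
#' @param model An untrained or previously trained `tdd_net`.
#' @param records List of `mixture_record`s with audio
#'   (see [build_mixture_dataset()]). All clips must share one length.
#' @param epochs Number of passes over the data.
#' @param batch_size Mini-batch size.
#' @param schedule A [train_schedule()]; defaults to the TDD schedule.
#' @param seed Integer seed controlling shuffling.
#' @param verbose Print per-epoch mean loss.
#' @return The trained `tdd_net` with `$loss_history` per epoch.
#' @export
train_tdd <- function(model, records, epochs = 5, batch_size = 16,
                      schedule = train_schedule("tdd"), seed = 1L,
                      verbose = FALSE) {
  stopifnot(inherits(model, "tdd_net"))
  pures <- lapply(records, function(r) r$pure$samples)
  mixes <- lapply(records, function(r) r$mixed$samples)
  L <- unique(vapply(mixes, length, integer(1)))
  if (length(L) != 1L) stop("all training clips must have equal length")
  n <- length(records)
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
      X <- matrix(unlist(mixes[ids]), nrow = 1L)
      Yt <- matrix(unlist(pures[ids]), nrow = 1L)
      fw <- tdd_forward(model, X, training = TRUE, dims = c(L, B))
      model$bn_stats <- fw$bn_stats
      diff <- fw$out - Yt
      loss <- mean(diff^2)
      ep_loss <- ep_loss + loss * B
      dY <- 2 * diff / length(diff)
      grads <- tdd_backward(model, fw$cache, dY)
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

#' Denoise a waveform with a TDD-Net
#'
#' Evaluation-mode forward pass (batch-norm running statistics, no
#' stochastic components): deterministic, same output length and rate as
#' the input.
#'
#' @param model A `tdd_net`.
#' @param noisy Noisy [audio_clip()] at the model's sample rate.
#' @return Denoised [audio_clip()].
#' @export
denoise_time <- function(model, noisy) {
  stopifnot(inherits(model, "tdd_net"), inherits(noisy, "audio_clip"))
  if (noisy$rate != model$rate) {
    stop("clip rate (", noisy$rate, " Hz) differs from the model's training rate (",
         model$rate, " Hz)")
  }
  X <- array(noisy$samples, dim = c(1L, length(noisy$samples), 1L))
  fw <- tdd_forward(model, X, training = FALSE)
  audio_clip(as.numeric(fw$out), noisy$rate)
}
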