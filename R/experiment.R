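#' Training schedule for the denoising networks
#'
#' Both network families train with Adam, batch size 16, for 50 epochs
#' at full scale. The time-domain nets start at learning rate 0.001 with
#' a step policy (x0.5 every 20 epochs); the frequency-domain nets start
#' at 0.0001 with a plateau policy (x0.7 after any epoch whose training
#' loss did not decrease).
#'
#' @param net `"tdd"` or `"fdd"`, selecting the defaults; every field
#'   can be overridden.
#' @param epochs,batch_size Optimisation defaults carried with the
#'   schedule.
#' @param lr_init Initial learning rate.
#' @param lr_policy `"step"` or `"plateau"`.
#' @param step_every,step_factor Step policy: decay factor applied every
#'   `step_every` epochs.
#' @param plateau_factor Plateau policy: factor applied per
#'   non-decreasing epoch.
#' @return A list of class `train_schedule`.
#' @export
train_schedule <- function(net = c("tdd", "fdd"), epochs = 50,
                           batch_size = 16, lr_init = NULL, lr_policy = NULL,
                           step_every = 20, step_factor = 0.5,
                           plateau_factor = 0.7) {
  net <- match.arg(net)
  if (is.null(lr_init)) lr_init <- if (net == "tdd") 0.001 else 0.0001
  if (is.null(lr_policy)) lr_policy <- if (net == "tdd") "step" else "plateau"
  lr_policy <- match.arg(lr_policy, c("step", "plateau"))
  structure(
    list(net = net, epochs = epochs, batch_size = batch_size,
         lr_init = lr_init, lr_policy = lr_policy, step_every = step_every,
         step_factor = step_factor, plateau_factor = plateau_factor),
    class = "train_schedule"
  )
}

#' Learning rate at a given epoch
#'
#' Step policy: `lr_init * step_factor^floor(epoch / step_every)`.
#' Plateau policy: `lr_init * plateau_factor^k` where `k` counts the
#' epochs in `loss_history` whose mean training loss did not decrease
#' relative to the previous epoch.
#'
#' @param schedule A [train_schedule()].
#' @param epoch Zero-based epoch index about to run.
#' @param loss_history Numeric vector of completed per-epoch mean
#'   training losses (required by the plateau policy once `epoch > 1`).
#' @return Learning rate.
#' @examples
#' s <- train_schedule("tdd")
#' lr_at_epoch(s, 0)   # 0.001
#' lr_at_epoch(s, 20)  # 0.0005
#' lr_at_epoch(s, 40)  # 0.00025
#' @export
lr_at_epoch <- function(schedule, epoch, loss_history = numeric(0)) {
  stopifnot(inherits(schedule, "train_schedule"), epoch >= 0)
  if (schedule$lr_policy == "step") {
    return(schedule$lr_init * schedule$step_factor^(epoch %/% schedule$step_every))
  }
  if (epoch > 1 && length(loss_history) < epoch) {
    stop("plateau policy needs the loss history of all ", epoch,
         " completed epochs")
  }
  h <- loss_history[seq_len(min(epoch, length(loss_history)))]
  k <- if (length(h) >= 2) sum(diff(h) >= 0) else 0L
  schedule$lr_init * schedule$plateau_factor^k
}

#' Configuration of a desk-scale benchmark experiment
#'
#' Defines an end-to-end seeded run: synthesize disjoint train/test
#' sources, build SNR-graded mixtures, train the selected denoisers,
#' evaluate everything (plus the wavelet baseline) with the three-metric
#' suite. The default profile is an honest smoke scale (200 training and
#' 60 test mixtures of 0.5 s, 5 epochs, slim networks); paper-scale
#' results are not promised at this size.
#'
#' @param seed Global seed; train and test generators draw from disjoint
#'   derived-seed ranges to avoid leakage.
#' @param n_train,n_test Mixture counts (divisible by 6).
#' @param clip_seconds Slice length in seconds (0.25 s in the smoke
#'   profile: a few feeding pulses per clip, and comfortably longer than
#'   the widest network receptive field).
#' @param rate Sample rate in Hz.
#' @param variants Character vector of denoisers to run: any of
#'   `"tdd_dc"`, `"tdd_c"`, `"tdd_d"`, `"tdd_ds"`, `"fdd_bl"`,
#'   `"fdd_r"`, `"fdd_g"`, `"fdd_l"`, `"fdd_br"`, `"fdd_bg"`,
#'   `"wavelet"`.
#' @param epochs Training epochs for the networks.
#' @param tdd_channels,fdd_hidden Network widths for this run.
#' @param noise_level RMS of generated noise sources.
#' @return A list of class `experiment_config` carrying a config hash.
#' @export
experiment_config <- function(seed = 1L, n_train = 198L, n_test = 60L,
                              clip_seconds = 0.25, rate = 16000,
                              variants = c("tdd_dc", "fdd_bl", "wavelet"),
                              epochs = 5L, tdd_channels = 16L,
                              fdd_hidden = 32L, noise_level = 0.05) {
  cfg <- list(seed = as.integer(seed), n_train = as.integer(n_train),
              n_test = as.integer(n_test), clip_seconds = clip_seconds,
              rate = rate, variants = variants, epochs = as.integer(epochs),
              tdd_channels = as.integer(tdd_channels),
              fdd_hidden = as.integer(fdd_hidden), noise_level = noise_level)
  cfg$hash <- rlang::hash(cfg)
  structure(cfg, class = "experiment_config")
}

# synthesize n equal-length pure/noise slice pairs from segment generators
make_mixture_set <- function(n, clip_seconds, rate, grid, seed, noise_level,
                             seed_offset = 0L) {
  pures <- gen_segments("feeding", n, clip_seconds, rate,
                        seed = seed + seed_offset)
  noises <- gen_segments("noise", n, clip_seconds, rate,
                         seed = seed + seed_offset + 1L,
                         noise_level = noise_level)
  build_mixture_dataset(pures, noises, grid, seed = seed + seed_offset + 2L)
}

#' Run a seeded end-to-end denoising benchmark
#'
#' Generates synthetic sources, builds balanced train/test mixtures on
#' the training and test SNR grids, trains the requested network
#' variants, and evaluates every method (networks and/or wavelet) with
#' [evaluate_denoiser()]. Fully deterministic given the config. The
#' default profile uses 198 training mixtures (33 per SNR level) so the
#' balanced assignment divides evenly.
#'
#' @param config An [experiment_config()].
#' @param verbose Print progress.
#' @return A list of class `benchmark_result`: `reports` (named list of
#'   `metrics_report`s), `summary` (data.frame of overall means per
#'   method), `models` (trained models), `config`, and the config hash.
#' @export
run_benchmark <- function(config = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  note <- function(...) if (verbose) message(sprintf(...))

  note("synthesizing %d training and %d test mixtures",
       config$n_train, config$n_test)
  train <- make_mixture_set(config$n_train, config$clip_seconds, config$rate,
                            snr_grid("training"), config$seed,
                            config$noise_level, seed_offset = 0L)
  test <- make_mixture_set(config$n_test, config$clip_seconds, config$rate,
                           snr_grid("test"), config$seed,
                           config$noise_level, seed_offset = 7919L)

  models <- list()
  denoisers <- list()
  for (v in config$variants) {
    if (startsWith(v, "tdd_")) {
      variant <- toupper(sub("tdd_", "", v))
      note("training TDD-Net-%s (%d epochs)", variant, config$epochs)
      m <- build_tdd(tdd_config(variant, channels = config$tdd_channels),
                     seed = config$seed, rate = config$rate)
      m <- train_tdd(m, train, epochs = config$epochs,
                     seed = config$seed, verbose = verbose)
      models[[v]] <- m
      denoisers[[v]] <- local({
        mm <- m
        function(clip) denoise_time(mm, clip)
      })
    } else if (startsWith(v, "fdd_")) {
      variant <- toupper(sub("fdd_", "", v))
      note("training FDD-Net-%s (%d epochs)", variant, config$epochs)
      m <- build_fdd(fdd_variant(variant, hidden_size = config$fdd_hidden),
                     seed = config$seed, rate = config$rate)
      m <- train_fdd(m, train, epochs = config$epochs,
                     seed = config$seed, verbose = verbose)
      models[[v]] <- m
      denoisers[[v]] <- local({
        mm <- m
        function(clip) denoise_freq(mm, clip)
      })
    } else if (v == "wavelet") {
      denoisers[[v]] <- function(clip) wavelet_denoise(clip)
    } else {
      stop("unknown variant: ", v)
    }
  }

  note("evaluating %d method(s) on %d test mixtures",
       length(denoisers), length(test))
  reports <- lapply(denoisers, function(f) evaluate_denoiser(test, f))
  summary <- do.call(rbind, lapply(names(reports), function(nm) {
    data.frame(method = nm,
               delta_snr = reports[[nm]]$overall["delta_snr"],
               delta_segsnr = reports[[nm]]$overall["delta_segsnr"],
               lsd = reports[[nm]]$overall["lsd"])
  }))
  rownames(summary) <- NULL
  structure(list(reports = reports, summary = summary, models = models,
                 config = config, hash = config$hash,
                 n_train = length(train), n_test = length(test)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d train / %d test mixtures (hash %s)\n",
              x$n_train, x$n_test, substr(x$hash, 1, 8)))
  print(x$summary, ...)
  invisible(x)
}

#' Reproduce report percentage columns from mean metric values
#'
#' Given a table of per-method mean Delta-SNR, Delta-SegSNR and LSD, adds
#' the percentage-improvement columns relative to a reference method
#' (improvement for the dB metrics, fall for LSD), rounded to two
#' decimals half-away-from-zero as report tables print them.
#'
#' @param summary data.frame with columns `method`, `delta_snr`,
#'   `delta_segsnr`, `lsd`.
#' @param reference Method name the percentages are computed against.
#' @return The data.frame with `delta_snr_pct`, `delta_segsnr_pct`,
#'   `lsd_pct` columns added.
#' @export
improvement_table <- function(summary, reference) {
  ref <- summary[summary$method == reference, ]
  if (nrow(ref) != 1L) stop("reference method not found: ", reference)
  summary$delta_snr_pct <- relative_improvement(summary$delta_snr,
                                                ref$delta_snr, digits = 2)
  summary$delta_segsnr_pct <- relative_improvement(summary$delta_segsnr,
                                                   ref$delta_segsnr, digits = 2)
  summary$lsd_pct <- relative_improvement(summary$lsd, ref$lsd,
                                          decreasing = TRUE, digits = 2)
  summary
}
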