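#' Specification for surrogate larval feeding sound
#'
#' Larval feeding (mouthparts rasping wood) registers on a piezoelectric
#' probe as a sparse train of short broadband "biting" pulses over a near
#' silent background, with dominant spectral energy near 5 kHz. The
#' surrogate models each bite as an exponentially damped band-limited
#' burst with Poisson arrivals.
#'
#' @param pulse_rate Expected pulses per second.
#' @param pulse_duration_ms Mean pulse length in milliseconds.
#' @param center_freq Dominant band centre in Hz.
#' @param bandwidth Width of the carrier-frequency band in Hz.
#' @param amplitude_jitter Relative standard deviation of pulse amplitude.
#' @param amplitude Nominal peak amplitude of a pulse.
#' @param background_rms RMS of the near-zero noise floor behind pulses.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class `feeding_spec`.
#' @export
feeding_spec <- function(pulse_rate = 10, pulse_duration_ms = 6,
                         center_freq = 5000, bandwidth = 2000,
                         amplitude_jitter = 0.3, amplitude = 0.5,
                         background_rms = 0.002, seed = 1L) {
  stopifnot(pulse_rate > 0, pulse_duration_ms > 0, center_freq > 0,
            bandwidth >= 0, amplitude > 0)
  structure(
    list(pulse_rate = pulse_rate, pulse_duration_ms = pulse_duration_ms,
         center_freq = center_freq, bandwidth = bandwidth,
         amplitude_jitter = amplitude_jitter, amplitude = amplitude,
         background_rms = background_rms, seed = as.integer(seed)),
    class = "feeding_spec"
  )
}

#' Generate a surrogate feeding-sound clip
#'
#' @param spec A [feeding_spec()].
#' @param duration Clip length in seconds.
#' @param rate Sample rate in Hz.
#' @return An [audio_clip()] labelled `"feeding"`.
#' @examples
#' clip <- gen_feeding(feeding_spec(seed = 7), duration = 2, rate = 16000)
#' n_samples(clip)  # 32000
#' @export
gen_feeding <- function(spec, duration, rate) {
  stopifnot(inherits(spec, "feeding_spec"), duration > 0, rate > 0)
  if (spec$center_freq >= rate / 2) {
    stop("center_freq (", spec$center_freq, " Hz) must be below Nyquist (",
         rate / 2, " Hz)")
  }
  n <- round(duration * rate)
  set.seed(spec$seed)
  x <- stats::rnorm(n, sd = spec$background_rms)

  n_pulses <- stats::rpois(1, spec$pulse_rate * duration)
  if (n_pulses > 0) {
    starts <- sort(stats::runif(n_pulses, 0, duration))
    tau <- spec$pulse_duration_ms / 1000 / 3  # ~3 time constants per pulse
    for (s in starts) {
      len <- round(spec$pulse_duration_ms / 1000 * rate)
      i0 <- floor(s * rate) + 1L
      if (i0 + len - 1L > n) len <- n - i0 + 1L
      if (len < 2L) next
      t <- (seq_len(len) - 1) / rate
      f <- spec$center_freq + stats::runif(1, -spec$bandwidth / 2, spec$bandwidth / 2)
      a <- spec$amplitude * max(0.05, 1 + spec$amplitude_jitter * stats::rnorm(1))
      phase <- stats::runif(1, 0, 2 * pi)
      x[i0:(i0 + len - 1L)] <- x[i0:(i0 + len - 1L)] +
        a * exp(-t / tau) * sin(2 * pi * f * t + phase)
    }
  }
  audio_clip(x, rate, "feeding")
}

#' Specification for surrogate environmental noise
#'
#' The noise vocabulary mirrors what a probe in a grove or at a roadside
#' picks up: vehicle rumble, whistles/honks, bird song, wind, dripping
#' water, human speech, plus white and pink reference noises.
#'
#' @param kind One of `"bird_chirp"`, `"vehicle"`, `"whistle"`, `"wind"`,
#'   `"speech_like"`, `"dripping"`, `"white"`, `"pink"`.
#' @param level Target RMS amplitude of the generated clip.
#' @param seed Integer seed.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(kind = "bird_chirp", level = 0.05, seed = 1L) {
  kind <- match.arg(kind, c("bird_chirp", "vehicle", "whistle", "wind",
                            "speech_like", "dripping", "white", "pink"))
  stopifnot(level >= 0)
  structure(list(kind = kind, level = level, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Generate a surrogate environmental-noise clip
#'
#' Each kind uses a distinct synthesis recipe: FM chirp trains
#' (`bird_chirp`), low-frequency rumble plus engine harmonics
#' (`vehicle`), a vibrato narrowband tone (`whistle`), 1/f noise with
#' slow gusting (`wind`), band-passed noise bursts with a syllabic
#' envelope (`speech_like`), sparse decaying clicks (`dripping`), and
#' flat/1-over-f reference noise (`white`, `pink`). All outputs are
#' rescaled to RMS equal to `spec$level`.
#'
#' @param spec A [noise_spec()].
#' @param duration Clip length in seconds.
#' @param rate Sample rate in Hz.
#' @return An [audio_clip()] labelled `"noise"`.
#' @export
gen_noise <- function(spec, duration, rate) {
  stopifnot(inherits(spec, "noise_spec"), duration > 0, rate > 0)
  n <- round(duration * rate)
  set.seed(spec$seed)
  t <- (seq_len(n) - 1) / rate

  x <- switch(spec$kind,
    white = stats::rnorm(n),
    pink = one_over_f(n),
    wind = one_over_f(n) * (1 + 0.6 * sin(2 * pi * stats::runif(1, 0.1, 0.4) * t +
                                            stats::runif(1, 0, 2 * pi))),
    vehicle = {
      rumble <- fft_bandpass(stats::rnorm(n), rate, 0, 300)
      f0 <- stats::runif(1, 60, 110)
      harm <- rowSums(sapply(1:4, function(h) {
        sin(2 * pi * h * f0 * t + stats::runif(1, 0, 2 * pi)) / h
      }))
      rumble / stats::sd(rumble) + 0.4 * harm
    },
    whistle = {
      f0 <- stats::runif(1, 1800, 3200)
      sin(2 * pi * f0 * t + 3 * sin(2 * pi * 5 * t))
    },
    bird_chirp = {
      x <- numeric(n)
      n_chirps <- max(1L, stats::rpois(1, 3 * duration))
      for (i in seq_len(n_chirps)) {
        len <- round(stats::runif(1, 0.05, 0.2) * rate)
        i0 <- sample.int(max(1L, n - len), 1)
        tt <- (seq_len(len) - 1) / rate
        fa <- stats::runif(1, 2000, 5000)
        fb <- fa + stats::runif(1, -1500, 1500)
        inst <- fa + (fb - fa) * tt / max(tt)
        env <- 0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1))
        x[i0:(i0 + len - 1L)] <- x[i0:(i0 + len - 1L)] +
          env * sin(2 * pi * cumsum(inst) / rate)
      }
      if (all(x == 0)) x <- sin(2 * pi * 3000 * t)
      x
    },
    speech_like = {
      env <- pmax(0, sin(2 * pi * 4 * t + stats::runif(1, 0, 2 * pi)))^2
      fft_bandpass(stats::rnorm(n), rate, 300, 3000) * env
    },
    dripping = {
      x <- numeric(n)
      n_drops <- max(1L, stats::rpois(1, 2 * duration))
      for (i in seq_len(n_drops)) {
        len <- min(round(0.03 * rate), n)
        i0 <- sample.int(max(1L, n - len), 1)
        tt <- (seq_len(len) - 1) / rate
        f0 <- stats::runif(1, 800, 1500)
        x[i0:(i0 + len - 1L)] <- x[i0:(i0 + len - 1L)] +
          exp(-tt / 0.005) * sin(2 * pi * f0 * tt)
      }
      if (all(x == 0)) x[1] <- 1
      x
    },
    stop("unknown noise kind: ", spec$kind)
  )

  r <- sqrt(mean(x^2))
  if (r > 0) x <- x * (spec$level / r)
  audio_clip(x, rate, "noise")
}

#' Generate quiet non-infested wood ambience
#'
#' A surrogate for recordings from non-infested logs at the same site:
#' very low-level coloured noise with no biting pulses and no structured
#' events, hence a flatter spectrum than feeding clips.
#'
#' @param duration Clip length in seconds.
#' @param rate Sample rate in Hz.
#' @param seed Integer seed.
#' @param level RMS amplitude (default well below a feeding-pulse peak).
#' @return An [audio_clip()] labelled `"ambient"`.
#' @export
gen_ambient <- function(duration, rate, seed = 1L, level = 0.005) {
  stopifnot(duration > 0, rate > 0, level >= 0)
  n <- round(duration * rate)
  set.seed(as.integer(seed))
  # mild 1/f tilt over a white floor: quiet room tone
  x <- 0.5 * one_over_f(n) + stats::rnorm(n)
  r <- sqrt(mean(x^2))
  if (r > 0) x <- x * (level / r)
  audio_clip(x, rate, "ambient")
}

# 1/f (pink-ish) noise via spectral shaping
one_over_f <- function(n) {
  w <- stats::rnorm(n)
  z <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # symmetric frequency index
  z <- z / sqrt(f)
  Re(stats::fft(z, inverse = TRUE)) / n
}

# zero-phase FFT band-pass
fft_bandpass <- function(x, rate, lo, hi) {
  n <- length(x)
  z <- stats::fft(x)
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f)
  keep <- f >= lo & f <= hi
  z[!keep] <- 0
  Re(stats::fft(z, inverse = TRUE)) / n
}

#' Derive a per-clip seed from a global seed and counter
#'
#' One global seed reproduces an entire dataset: clip `i` of a run uses
#' `derive_seed(seed, i)`. Kept below 2^31 so it is always a valid R
#' integer seed.
#'
#' @param seed Global integer seed.
#' @param counter Positive integer index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 1000003) %% 2147483647)
}

#' Generate a set of labelled segments
#'
#' Convenience generator for fixture datasets: `n` segments of one class,
#' each `seconds` long, with per-segment seeds derived from one global
#' seed. Noise segments cycle through the environmental-noise vocabulary.
#'
#' @param class `"feeding"`, `"noise"` or `"ambient"`.
#' @param n Number of segments.
#' @param seconds Segment length in seconds.
#' @param rate Sample rate in Hz.
#' @param seed Global seed.
#' @param noise_level RMS level used for noise segments.
#' @return A list of [audio_clip()]s.
#' @export
gen_segments <- function(class = c("feeding", "noise", "ambient"), n,
                         seconds, rate = 16000, seed = 1L,
                         noise_level = 0.05) {
  class <- match.arg(class)
  kinds <- c("bird_chirp", "vehicle", "whistle", "wind", "speech_like",
             "dripping", "pink", "white")
  lapply(seq_len(n), function(i) {
    s <- derive_seed(seed, i)
    switch(class,
      feeding = gen_feeding(feeding_spec(seed = s), seconds, rate),
      noise = gen_noise(noise_spec(kinds[(i - 1L) %% length(kinds) + 1L],
                                   level = noise_level, seed = s),
                        seconds, rate),
      ambient = gen_ambient(seconds, rate, seed = s)
    )
  })
}

#' Write a synthetic dataset of WAV files with a manifest
#'
#' Files are named `<class>_<segmentid>_<sliceid>.wav`; the manifest CSV
#' records path, class, seed and generation parameters.
#'
#' @param out_dir Output directory (created if missing).
#' @param class Signal class to generate.
#' @param n Number of segments.
#' @param seconds Segment length in seconds.
#' @param rate Sample rate in Hz.
#' @param seed Global seed.
#' @param slice_seconds If not `NULL`, each segment is partitioned into
#'   slices of this length before export.
#' @return The manifest as a data.frame, invisibly; also written as
#'   `manifest.csv` in `out_dir`.
#' @export
synth_dataset <- function(out_dir, class = "feeding", n = 4, seconds = 10,
                          rate = 16000, seed = 1L, slice_seconds = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  segs <- gen_segments(class, n, seconds, rate, seed)
  rows <- list()
  for (i in seq_along(segs)) {
    pieces <- if (is.null(slice_seconds)) list(segs[[i]]) else
      partition(segs[[i]], slice_seconds)
    for (j in seq_along(pieces)) {
      fn <- file.path(out_dir, sprintf("%s_%03d_%03d.wav", class, i, j))
      write_wav(pieces[[j]], fn)
      rows[[length(rows) + 1L]] <- data.frame(
        path = fn, class = class, segment = i, slice = j,
        seed = derive_seed(seed, i), rate = rate,
        seconds = duration(pieces[[j]])
      )
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
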