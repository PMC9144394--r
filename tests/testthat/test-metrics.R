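test_that("delta_snr measures the SNR increment", {
  p <- audio_clip(c(1, 1, 1, 1), 8000)
  s <- audio_clip(p$samples + c(1, -1, 1, -1), 8000)
  d <- audio_clip(p$samples + c(0.1, -0.1, 0.1, -0.1), 8000)
  expect_equal(delta_snr(p, s, d), 20)
  # identity denoiser scores exactly zero
  expect_equal(delta_snr(p, s, s), 0)
  # residual x10 costs 20 dB
  d10 <- audio_clip(p$samples + c(1, -1, 1, -1) * 10, 8000)
  expect_equal(delta_snr(p, s, d10), -20)
  # perfect reconstruction is capped and flagged
  out <- delta_snr(p, s, p)
  expect_true(isTRUE(attr(out, "capped")))
})

test_that("delta_segsnr averages frame SNRs and handles silent frames", {
  set.seed(3)
  p <- audio_clip(stats::rnorm(512), 16000)
  noise <- stats::rnorm(512)
  s <- audio_clip(p$samples + noise, 16000)
  d <- audio_clip(p$samples + noise / 2, 16000)
  # halving the residual in every frame adds exactly 20*log10(2) dB
  expect_equal(as.numeric(delta_segsnr(p, s, d, 256, 128)), 20 * log10(2),
               tolerance = 1e-9)
  expect_equal(as.numeric(delta_segsnr(p, s, s)), 0)

  # a residual identical in every frame makes SegSNR equal SNR
  resid <- rep(stats::rnorm(128), 4)
  s2 <- audio_clip(p$samples + resid, 16000)
  d2 <- audio_clip(p$samples + resid * 0.3, 16000)
  expect_equal(as.numeric(delta_segsnr(p, s2, d2, 128, 128)),
               delta_snr(p, s2, d2), tolerance = 1e-9)

  # silent pure frames are excluded and counted
  p3 <- audio_clip(c(numeric(256), stats::rnorm(256)), 16000)
  s3 <- audio_clip(p3$samples + stats::rnorm(512) * 0.1, 16000)
  out <- delta_segsnr(p3, s3, s3, 256, 256)
  expect_equal(attr(out, "n_excluded"), 1L)
})

test_that("delta_segsnr uses all frames when the pure signal is active", {
  p <- audio_clip(stats::rnorm(512), 16000)
  s <- audio_clip(p$samples + stats::rnorm(512), 16000)
  out <- delta_segsnr(p, s, s, 256, 128)
  expect_equal(attr(out, "n_excluded"), 0L)
})

test_that("lsd is zero at identity, 10 dB for a uniform power ratio, symmetric", {
  x <- fix_feeding(seed = 71L)
  expect_equal(lsd(x, x), 0)
  # scaling amplitude by 1/sqrt(10) scales power by 1/10 at every bin
  y <- audio_clip(x$samples / sqrt(10), x$rate)
  expect_equal(lsd(x, y), 10, tolerance = 1e-6)
  expect_equal(lsd(y, x), lsd(x, y))
})

test_that("metrics are invariant to joint global scaling", {
  pure <- fix_feeding(seed = 81L)
  rec <- mix_at_snr(pure, fix_noise(seed = 82L), -6)
  den <- wavelet_denoise(rec$mixed)
  g <- 3.7
  sp <- audio_clip(g * pure$samples, pure$rate)
  ss <- audio_clip(g * rec$mixed$samples, pure$rate)
  sd_ <- audio_clip(g * den$samples, pure$rate)
  expect_equal(delta_snr(sp, ss, sd_), delta_snr(pure, rec$mixed, den),
               tolerance = 1e-9)
  expect_equal(as.numeric(delta_segsnr(sp, ss, sd_)),
               as.numeric(delta_segsnr(pure, rec$mixed, den)), tolerance = 1e-9)
  # LSD is ratio-based up to the epsilon floor on near-silent bins,
  # which a global gain moves across; equality is approximate
  expect_equal(lsd(sp, sd_), lsd(pure, den), tolerance = 1e-3)
})

test_that("relative improvement matches reported-percentage conventions", {
  expect_equal(relative_improvement(16.97, 14.40, digits = 2), 17.85)
  expect_equal(relative_improvement(17.53, 3.12, digits = 2), 461.86)
  expect_equal(relative_improvement(5, 5), 0)
  expect_equal(relative_improvement(0.85, 0.96, decreasing = TRUE, digits = 2),
               11.46)
  expect_error(relative_improvement(1, 0), "nonzero")
  # half-away rounding, not banker's
  expect_equal(round_half_away(15.625, 2), 15.63)
  expect_equal(round_half_away(-15.625, 2), -15.63)
})

test_that("evaluate_denoiser aggregates per clip, bucket and overall", {
  recs <- fix_mixtures(n = 6, seed = 404L)
  rep_id <- evaluate_denoiser(recs, function(clip) clip)
  expect_equal(nrow(rep_id$per_clip), 6)
  expect_true(all(rep_id$per_clip$delta_snr == 0))
  expect_true(all(rep_id$per_clip$delta_segsnr == 0))
  expect_equal(unname(rep_id$overall["delta_snr"]), 0)
  expect_equal(rep_id$per_bucket$snr_bucket, sort(snr_grid("test")))
  # overall mean is the unweighted mean of per-clip values
  rep_wav <- evaluate_denoiser(recs, wavelet_denoise)
  expect_equal(unname(rep_wav$overall["lsd"]), mean(rep_wav$per_clip$lsd))
})
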