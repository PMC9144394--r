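test_that("soft thresholding shrinks toward zero", {
  expect_equal(soft_threshold(1.5, 1.0), 0.5)
  expect_equal(soft_threshold(-0.3, 1.0), 0)
  x <- c(-2, -0.5, 0, 0.5, 2)
  expect_equal(soft_threshold(x, 0), x)
  expect_error(soft_threshold(1, -0.1), "non-negative")
})

test_that("minimax threshold reproduces the published risk factor", {
  # detail coefficients with median(|d|) = 0.6745 give sigma_hat = 1
  d <- c(-0.6745, 0.6745, 0.6745)
  expect_equal(minimax_threshold(d, 1024), 0.3936 + 0.1829 * 10)
  expect_equal(minimax_threshold(d, 1024), 2.2226)
  expect_equal(minimax_threshold(d, 32), 0)
  expect_equal(minimax_threshold(d, 16), 0)
  # threshold scales linearly with the noise estimate
  expect_equal(minimax_threshold(3 * d, 1024), 3 * 2.2226)
  expect_error(minimax_threshold(numeric(0), 10), "empty")
})

test_that("Haar analysis/synthesis is a perfect-reconstruction pair", {
  set.seed(9)
  for (n in c(32, 100, 1024, 777)) {
    x <- stats::rnorm(n)
    lev <- min(5, floor(log2(n)))
    expect_lt(max(abs(haar_idwt(haar_dwt(x, lev)) - x)), 1e-8)
  }
  expect_error(haar_dwt(stats::rnorm(16), 10), "exceeds")
})

test_that("wavelet denoising behaves on canonical inputs", {
  z <- wavelet_denoise(audio_clip(numeric(4096), 16000))
  expect_true(all(z$samples == 0))
  expect_equal(n_samples(z), 4096)

  # clean low-frequency square wave passes nearly unchanged
  sq <- audio_clip(rep(rep(c(0.5, -0.5), each = 256), 8), 16000)
  den <- wavelet_denoise(sq)
  expect_gt(stats::cor(den$samples, sq$samples), 0.99)

  # pure white noise loses energy under shrinkage
  wn <- gen_noise(noise_spec("white", level = 0.1, seed = 44L), 0.5, 16000)
  den <- wavelet_denoise(wn)
  expect_lt(sum(den$samples^2), sum(wn$samples^2))
})

test_that("shrinkage never increases detail-band energy", {
  rec <- mix_at_snr(fix_feeding(seed = 61L), fix_noise(seed = 62L), -6)
  cfg <- wavelet_config()
  before <- haar_dwt(rec$mixed$samples, cfg$level)
  den <- wavelet_denoise(rec$mixed, cfg)
  after <- haar_dwt(den$samples, cfg$level)
  e <- function(d) sum(vapply(d$details, function(v) sum(v^2), numeric(1)))
  expect_lte(e(after), e(before))
})
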