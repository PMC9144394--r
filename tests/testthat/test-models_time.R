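test_that("dilation schedule is 2^k per block for dilated variants", {
  for (v in c("D", "DS", "DC")) {
    expect_equal(tdd_dilations(tdd_config(v)), 2^(1:8))
  }
  expect_equal(tdd_dilations(tdd_config("C")), rep(1L, 8))
  expect_equal(tdd_dilations(tdd_config("D"))[5], 32)
})

test_that("C and D variants share parameter counts but not receptive fields", {
  mC <- build_tdd(tdd_config("C", channels = 8), seed = 1L)
  mD <- build_tdd(tdd_config("D", channels = 8), seed = 1L)
  expect_equal(n_parameters(mC), n_parameters(mD))
  # oracle: receptive field accumulates (k-1)*dilation over the deepest
  # path; for kernel 3 the dilated path spans 1 + 2*(2+4+...+256) + 4
  expect_equal(tdd_receptive_field(mD), 1 + 2 + 2 * sum(2^(1:8)) + 2)
  expect_gte(tdd_receptive_field(mD), 1 + 2 * sum(2^(1:8)))
  expect_lt(tdd_receptive_field(mC), tdd_receptive_field(mD))
  # the convolutional shortcut adds parameters
  mDC <- build_tdd(tdd_config("DC", channels = 8), seed = 1L)
  expect_gt(n_parameters(mDC), n_parameters(mD))
})

test_that("tdd_loss is the mean squared error", {
  a <- audio_clip(c(1, 1), 8000)
  z <- audio_clip(c(0, 0), 8000)
  expect_equal(tdd_loss(a, a), 0)
  expect_equal(tdd_loss(a, z), 1)
  set.seed(2)
  x <- stats::rnorm(50); y <- stats::rnorm(50)
  perm <- sample(50)
  expect_equal(tdd_loss(x, y), tdd_loss(x[perm], y[perm]))
  expect_error(tdd_loss(x, y[1:10]), "mismatch")
})

test_that("denoising preserves length and is deterministic in eval mode", {
  m <- build_tdd(tdd_config("DC", channels = 4), seed = 3L)
  for (L in c(1100, 4000, 8001)) {
    clip <- audio_clip(stats::rnorm(L), 16000)
    out <- denoise_time(m, clip)
    expect_equal(n_samples(out), L)
    expect_equal(out$rate, 16000)
    out2 <- denoise_time(m, clip)
    expect_identical(out$samples, out2$samples)
  }
  expect_error(denoise_time(m, audio_clip(stats::rnorm(100), 8000)), "rate")
})

test_that("smoke training reduces the loss on a small mixture set", {
  recs <- fix_mixtures(n = 24, seconds = 0.25, seed = 505L)
  m <- build_tdd(tdd_config("DC", channels = 8), seed = 4L)
  m <- train_tdd(m, recs, epochs = 3, batch_size = 8, seed = 5L)
  expect_length(m$loss_history, 3)
  expect_lt(m$loss_history[3], m$loss_history[1])
  expect_true(m$trained)
})
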