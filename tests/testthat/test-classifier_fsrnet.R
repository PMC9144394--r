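test_that("classifier features use the wide framing and scale linearly", {
  clip <- fix_feeding(seconds = 2, seed = 901L)
  feats <- fsrnet_features(clip)
  expect_equal(dim(feats$values), c(241, 198))
  z <- fsrnet_features(audio_clip(numeric(32000), 16000))
  expect_true(all(z$values == 0))
  scaled <- fsrnet_features(audio_clip(2 * clip$samples, 16000))
  expect_equal(scaled$values, 2 * feats$values)
  expect_error(fsrnet_features(audio_clip(numeric(16000), 16000)), "duration")
})

test_that("softmax probabilities are valid and evaluation is deterministic", {
  m <- build_fsrnet(seed = 1L)
  clip <- fix_feeding(seconds = 2, seed = 902L)
  p1 <- predict_fsrnet(m, clip)
  expect_equal(dim(p1), c(1, 3))
  expect_lt(abs(sum(p1) - 1), 1e-6)
  expect_true(all(p1 >= 0))
  p2 <- predict_fsrnet(m, clip)
  expect_identical(p1, p2)
  # global average pooling fixes the logit input width at conv2_filters
  expect_equal(nrow(m$params$fc$W), m$config$conv2_filters)
  expect_equal(ncol(m$params$fc$W), 3)
})

test_that("the three clean classes are separable at small training scale", {
  rate <- 16000
  n_per <- 100
  n_test <- 15
  make_class <- function(cls, seed0) {
    gen_segments(cls, n_per + n_test, 2, rate, seed = seed0)
  }
  feeding <- make_class("feeding", 11L)
  ambient <- make_class("ambient", 22L)
  noise <- make_class("noise", 33L)
  train_clips <- c(feeding[1:n_per], ambient[1:n_per], noise[1:n_per])
  train_labels <- rep(c("feeding", "ambient", "noise"), each = n_per)
  held <- (n_per + 1):(n_per + n_test)
  test_clips <- c(feeding[held], ambient[held], noise[held])
  test_labels <- rep(c("feeding", "ambient", "noise"), each = n_test)

  m <- build_fsrnet(seed = 2L)
  m <- train_fsrnet(m, train_clips, train_labels, epochs = 6,
                    batch_size = 16, seed = 3L)
  acc <- mean(classify_clips(m, test_clips) == test_labels)
  expect_gt(acc, 0.9)

  # denoising-benefit harness: identity column reproduces noisy exactly
  recs <- fix_mixtures(n = 6, seconds = 2, seed = 909L)
  bench <- evaluate_denoising_benefit(m, recs,
                                      denoisers = list(identity = function(x) x,
                                                       wavelet = wavelet_denoise))
  expect_equal(bench$per_bucket$identity, bench$per_bucket$noisy)
  expect_true(all(unlist(bench$per_bucket[, -(1:2)]) >= 0))
  expect_true(all(unlist(bench$per_bucket[, -(1:2)]) <= 1))
  expect_equal(unname(bench$mean["identity"]), unname(bench$mean["noisy"]))
})
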