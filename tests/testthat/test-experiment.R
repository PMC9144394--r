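test_that("step schedule halves the rate every 20 epochs", {
  s <- train_schedule("tdd")
  expect_equal(s$lr_init, 0.001)
  expect_equal(lr_at_epoch(s, 0), 0.001)
  expect_equal(lr_at_epoch(s, 19), 0.001)
  expect_equal(lr_at_epoch(s, 20), 0.0005)
  expect_equal(lr_at_epoch(s, 40), 0.00025)
})

test_that("plateau schedule decays only on non-decreasing loss", {
  s <- train_schedule("fdd")
  expect_equal(s$lr_init, 0.0001)
  dec <- c(1, 0.9, 0.8, 0.7)
  expect_equal(lr_at_epoch(s, 4, dec), 0.0001)
  one_up <- c(1, 0.9, 0.95, 0.7)
  expect_equal(lr_at_epoch(s, 4, one_up), 0.0001 * 0.7)
  expect_equal(lr_at_epoch(s, 4, c(1, 1, 1, 1)), 0.0001 * 0.7^3)
  expect_error(lr_at_epoch(s, 4, c(1, 0.9)), "history")
})

test_that("config hashing is stable and seed-sensitive", {
  a <- experiment_config(seed = 1L)
  b <- experiment_config(seed = 1L)
  c_ <- experiment_config(seed = 2L)
  expect_identical(a$hash, b$hash)
  expect_false(identical(a$hash, c_$hash))
})

test_that("improvement_table reproduces printed percentage columns", {
  tab <- data.frame(method = c("wavelet", "tdd_dc", "fdd_bl"),
                    delta_snr = c(3.12, 17.53, 11.10),
                    delta_segsnr = c(3.62, 18.59, 12.04),
                    lsd = c(0.96, 0.85, 0.84))
  out <- improvement_table(tab, "wavelet")
  expect_equal(out$delta_snr_pct, c(0, 461.86, 255.77))
  expect_equal(out$delta_segsnr_pct, c(0, 413.54, 232.60))
  expect_equal(out$lsd_pct, c(0, 11.46, 12.50))
})

test_that("a tiny benchmark run has the expected structure and determinism", {
  cfg <- experiment_config(seed = 5L, n_train = 12L, n_test = 12L,
                           clip_seconds = 0.25, epochs = 1L,
                           tdd_channels = 4L, fdd_hidden = 8L,
                           variants = c("tdd_dc", "fdd_bl", "wavelet"))
  res <- run_benchmark(cfg)
  expect_equal(nrow(res$summary), 3)
  expect_setequal(res$summary$method, c("tdd_dc", "fdd_bl", "wavelet"))
  expect_equal(res$reports$wavelet$per_bucket$snr_bucket, sort(snr_grid("test")))
  expect_equal(res$hash, cfg$hash)

  res2 <- run_benchmark(cfg)
  expect_identical(res$reports$wavelet$per_clip, res2$reports$wavelet$per_clip)
  expect_identical(res$summary, res2$summary)
})
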