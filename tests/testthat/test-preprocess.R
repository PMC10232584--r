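fs <- 512

test_that("a clean in-range sinusoid raises no artifact flags", {
  t <- (0:(2 * fs - 1)) / fs
  x <- cbind(50 * sin(2 * pi * 10 * t))
  expect_false(any(detect_artifacts(x, fs)))
  expect_error(detect_artifacts(x), "fs")
  expect_error(detect_artifacts(cbind(c(x[, 1], NA)), fs), "finite")
})

test_that("a gradient-violating step is flagged with exactly +-200 ms padding", {
  # 150 uV single-sample step: gradient 150 * 0.512 = 76.8 uV/ms > 50, but
  # range stays under 200 uV and the ripple keeps activity above 0.5 uV
  n <- 3 * fs
  k <- 800L
  t <- (0:(n - 1)) / fs
  x <- 5 * sin(2 * pi * 10 * t)
  x[k:n] <- x[k:n] + 150
  mask <- detect_artifacts(cbind(x), fs)
  pad <- round(0.2 * fs) # 102 samples
  expect_identical(which(mask), (k - pad):(k + pad))
})

test_that("flat channels are fully flagged by the low-activity criterion", {
  x <- cbind(numeric(2 * fs), rnorm(2 * fs, sd = 20))
  expect_true(all(detect_artifacts(x, fs)))
})

test_that("gradient detection is translation-equivariant", {
  # windowed criteria disabled via extreme thresholds so the mask is purely
  # gradient-driven, where equivariance holds exactly for any shift
  crit <- artifact_criteria(max_gradient = 50, max_range = 1e9,
                            min_activity = 1e-9, tag_pad_ms = 200)
  set.seed(42)
  x <- cumsum(rnorm(3 * fs, sd = 5))
  x[700] <- x[700] + 400
  k <- 137L
  prefix <- cumsum(rnorm(k, sd = 5)) # non-flat prefix: shifts content without
  m1 <- detect_artifacts(cbind(x), fs, crit) # adding its own artifacts
  m2 <- detect_artifacts(cbind(c(prefix, x)), fs, crit)
  zone <- 400:1100 # window around the injected artifact, clear of the seam
  expect_identical(intersect(which(m2) - k, zone), intersect(which(m1), zone))
})

test_that("loosening every threshold never flags more samples", {
  set.seed(7)
  x <- cbind(cumsum(rnorm(8 * fs, sd = 8)))
  x[1000] <- x[1000] + 500
  x[3000:3100] <- 0
  tight <- artifact_criteria(max_gradient = 20, max_range = 100,
                             min_activity = 2, tag_pad_ms = 200)
  loose <- artifact_criteria(max_gradient = 50, max_range = 200,
                             min_activity = 0.5, tag_pad_ms = 200)
  m_tight <- detect_artifacts(x, fs, tight)
  m_loose <- detect_artifacts(x, fs, loose)
  expect_false(any(m_loose & !m_tight))
})

test_that("epoching yields floor(6.2 s * fs) samples and drops artifact epochs", {
  n <- 600 * fs # 10-minute recording
  set.seed(1)
  x <- cbind(5 * sin(2 * pi * 10 * (0:(n - 1)) / fs) + rnorm(n))
  triggers <- 10 + (0:32) * 15
  es <- make_epochs(x, fs, triggers, window = c(-0.2, 6))
  expect_s3_class(es, "epoch_set")
  expect_equal(dim(es)[1], 33)
  expect_equal(dim(es)[3], 3174) # floor(6.2 * 512)
  # artifact inside epoch 5 only -> 32 epochs survive
  mask <- logical(n)
  mask[round((triggers[5] + 1) * fs)] <- TRUE
  es2 <- make_epochs(x, fs, triggers, window = c(-0.2, 6), artifact_mask = mask)
  expect_equal(dim(es2)[1], 32)
  expect_equal(attr(es2, "n_dropped_artifact"), 1L)
  # trigger before the recording start -> skipped with warning
  expect_warning(es3 <- make_epochs(x, fs, c(-5, triggers[1]), window = c(-0.2, 6)),
                 "outside")
  expect_equal(dim(es3)[1], 1)
})

test_that("average re-referencing zeroes the channel mean", {
  # two-channel toy: (a, b) -> ((a - b) / 2, (b - a) / 2)
  a <- c(4, 8, 2, 6)
  b <- c(2, 2, 2, 2)
  es <- epoch_set(array(rbind(a, b), dim = c(1, 2, 4)), fs, c("A", "B"))
  out <- rereference_average(es)
  expect_equal(out$data[1, 1, ], (a - b) / 2)
  expect_equal(out$data[1, 2, ], (b - a) / 2)
  # already zero-mean montage unchanged
  es0 <- epoch_set(array(rbind(a - (a + b) / 2, b - (a + b) / 2), dim = c(1, 2, 4)),
                   fs, c("A", "B"))
  expect_equal(rereference_average(es0)$data, es0$data)
})

test_that("epoch sets round-trip through the delimited format", {
  set.seed(3)
  es <- epoch_set(array(rnorm(2 * 3 * 200), dim = c(2, 3, 200)), fs,
                  c("A", "B", "C"), participant = "P001", condition = "control")
  path <- tempfile(fileext = ".tsv")
  write_epoch_set(es, path)
  back <- read_epoch_set(path)
  expect_equal(back$data, es$data, tolerance = 1e-12)
  expect_identical(back$channel_labels, es$channel_labels)
  expect_identical(back$condition, "control")
  unlink(c(path, paste0(path, ".json")))
})
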