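test_that("waveform length matches closed forms and a brute-force oracle", {
  expect_identical(waveform_length(c(5, 5, 5, 5)), 0)
  expect_identical(waveform_length(c(0, 1, 0, 1)), 3)
  expect_error(waveform_length(3), "at least 2")

  wl_loop <- function(x) {
    acc <- 0
    for (r in 2:length(x)) acc <- acc + abs(x[r] - x[r - 1])
    acc
  }
  set.seed(11)
  for (i in 1:100) {
    x <- rnorm(256, sd = runif(1, 0.1, 10))
    expect_equal(waveform_length(x), wl_loop(x), tolerance = 1e-12)
  }
})

test_that("rms matches closed forms, including the sine amplitude limit", {
  expect_identical(rms_amplitude(rep(-3, 10)), 3)
  expect_equal(rms_amplitude(c(3, 4)), sqrt(12.5))
  expect_error(rms_amplitude(numeric(0)), "non-empty")

  rms_loop <- function(x) {
    acc <- 0
    for (v in x) acc <- acc + v^2
    sqrt(acc / length(x))
  }
  set.seed(12)
  for (i in 1:100) {
    x <- rnorm(64, mean = runif(1, -2, 2))
    expect_equal(rms_amplitude(x), rms_loop(x), tolerance = 1e-12)
  }

  # sine of amplitude A over whole periods -> A / sqrt(2)
  for (A in c(0.5, 1, 7.3)) {
    t <- seq(0, 4, length.out = 4 * 1024 + 1)[-(4 * 1024 + 1)] # 4 periods
    x <- A * sin(2 * pi * t)
    expect_equal(rms_amplitude(x), A / sqrt(2), tolerance = 1e-6)
  }
})

test_that("AR coefficient estimation recovers known processes", {
  # white noise: all coefficients near zero
  x <- simulate_ar_process(c(0, 0, 0, 0), n = 4096, seed = 3)
  expect_true(all(abs(ar_coefficients(x, 4)) < 0.08))

  # AR(1) with q1 = 0.9
  x1 <- simulate_ar_process(c(0.9, 0, 0, 0), n = 8192, seed = 4)
  q1 <- ar_coefficients(x1, 4)[1]
  expect_gt(q1, 0.85)
  expect_lt(q1, 0.95)

  # AR(4) round trip within +/- 0.05 elementwise
  q <- c(0.55, -0.25, 0.10, -0.05)
  x4 <- simulate_ar_process(q, n = 8192, seed = 5)
  for (m in c("burg", "yule_walker")) {
    qhat <- ar_coefficients(x4, 4, method = m)
    expect_true(all(abs(qhat - q) < 0.05), info = m)
  }
})

test_that("AR estimation rejects degenerate input and bad orders", {
  expect_error(ar_coefficients(rep(2, 100)), "constant")
  expect_error(ar_coefficients(rnorm(4), order = 4), "more samples")
  expect_error(ar_coefficients(rnorm(100), order = 0))
})

test_that("simulated AR process validates stationarity and is seeded", {
  expect_error(simulate_ar_process(c(1.0), 100), "not stationary")
  expect_error(simulate_ar_process(c(0.5, 0.6), 100), "not stationary")
  a <- simulate_ar_process(c(0.9), 500, seed = 1)
  b <- simulate_ar_process(c(0.9), 500, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, simulate_ar_process(c(0.9), 500, seed = 2)))
  # lag-1 autocorrelation ~ q1 for AR(1); ~0 for white noise
  x <- simulate_ar_process(c(0.9), n = 10000, seed = 6)
  expect_equal(cor(x[-1], x[-length(x)]), 0.9, tolerance = 0.02)
  w <- simulate_ar_process(c(0, 0, 0, 0), n = 10000, seed = 7)
  expect_lt(abs(cor(w[-1], w[-length(w)])), 0.03)
})

test_that("AR estimator bias shrinks with sample size", {
  q <- c(0.55, -0.25, 0.10, -0.05)
  mean_abs_err <- sapply(c(512, 2048, 8192), function(n) {
    errs <- sapply(1:20, function(s) {
      x <- simulate_ar_process(q, n = n, seed = 1000 + s)
      mean(abs(ar_coefficients(x, 4) - q))
    })
    mean(errs)
  })
  expect_true(all(diff(mean_abs_err) < 0))
})

test_that("feature extraction yields 24 named features per window", {
  rec <- quick_recording()
  seg <- assign_labels(segment_recording(rec, 256L, 128L), rec$labels, "pure")
  f <- extract_features(seg)
  expect_identical(
    setdiff(names(f), c("subject_id", "window_index", "label")),
    c(
      "ED_wl", "ED_rms", "ED_ar1", "ED_ar2", "ED_ar3", "ED_ar4",
      "PL_wl", "PL_rms", "PL_ar1", "PL_ar2", "PL_ar3", "PL_ar4",
      "FCU_wl", "FCU_rms", "FCU_ar1", "FCU_ar2", "FCU_ar3", "FCU_ar4",
      "ECR_wl", "ECR_rms", "ECR_ar1", "ECR_ar2", "ECR_ar3", "ECR_ar4"
    )
  )
  expect_identical(nrow(f), length(seg$labels))
  expect_true(all(is.finite(as.matrix(f[, -(1:3)]))))
  expect_true(all(f$ED_rms >= 0) && all(f$ED_wl >= 0))
  # determinism: identical segments give identical features
  expect_identical(extract_features(seg), f)
  # active windows have larger rms than rest windows in an active muscle
  expect_gt(
    min(f$FCU_rms[f$label == 4L]),
    max(f$FCU_rms[f$label == 1L])
  )
})

test_that("scaling the signal scales wl/rms and leaves AR coefficients unchanged", {
  rec <- quick_recording()
  seg <- assign_labels(segment_recording(rec, 256L, 128L), rec$labels, "pure")
  f1 <- extract_features(seg)
  a <- 3.7
  seg2 <- seg
  seg2$data <- lapply(seg$data, function(m) a * m)
  f2 <- extract_features(seg2)
  for (m in c("ED", "PL", "FCU", "ECR")) {
    expect_equal(f2[[paste0(m, "_wl")]], a * f1[[paste0(m, "_wl")]], tolerance = 1e-9)
    expect_equal(f2[[paste0(m, "_rms")]], a * f1[[paste0(m, "_rms")]], tolerance = 1e-9)
    for (j in 1:4) {
      expect_equal(f2[[paste0(m, "_ar", j)]], f1[[paste0(m, "_ar", j)]], tolerance = 1e-6)
    }
  }
})
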