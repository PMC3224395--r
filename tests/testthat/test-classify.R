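test_that("stratified split produces exact, disjoint, reproducible partitions", {
  # 4230 balanced segments at fraction 0.1 -> exactly 423 test segments
  big <- data.frame(
    subject_id = "s", window_index = 1:4230,
    label = rep(1:15, each = 282), f1 = rnorm(4230)
  )
  parts <- split_train_test(big, 0.1, seed = 1)
  expect_identical(nrow(parts$test), 423L)
  expect_identical(nrow(parts$train), 3807L)
  expect_length(intersect(parts$train$window_index, parts$test$window_index), 0)
  expect_setequal(c(parts$train$window_index, parts$test$window_index), 1:4230)
  # all classes represented proportionally in the test partition
  expect_true(all(table(parts$test$label) %in% 28:29))

  # balanced 2-class toy at fraction 0.5 -> 5/5 with both classes in each
  toy <- data.frame(
    subject_id = "s", window_index = 1:10,
    label = rep(1:2, each = 5), f1 = rnorm(10)
  )
  half <- split_train_test(toy, 0.5, seed = 2)
  expect_identical(nrow(half$test), 5L)
  expect_setequal(unique(half$test$label), 1:2)
  expect_setequal(unique(half$train$label), 1:2)

  # determinism
  parts2 <- split_train_test(big, 0.1, seed = 1)
  expect_identical(parts$test$window_index, parts2$test$window_index)
  expect_false(identical(
    parts$test$window_index,
    split_train_test(big, 0.1, seed = 99)$test$window_index
  ))

  # single-instance class under stratification is an error
  bad <- data.frame(subject_id = "s", window_index = 1:11, label = c(rep(1, 10), 2), f1 = rnorm(11))
  expect_error(split_train_test(bad, 0.1, seed = 1), "at least 2 instances")
})

test_that("standardization centers/scales on train and transfers to test", {
  f <- toy_features()
  out <- standardize_features(f)
  x <- as.matrix(out$train[, c("f1", "f2", "f3", "f4")])
  expect_equal(unname(colMeans(x)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(x, 2, sd)), rep(1, 4), tolerance = 1e-9)

  # test set scaled with train statistics keeps its shift
  shifted <- f
  shifted[, c("f1", "f2", "f3", "f4")] <- shifted[, c("f1", "f2", "f3", "f4")] + 5
  out2 <- standardize_features(f, test = shifted)
  xs <- as.matrix(out2$test[, c("f1", "f2", "f3", "f4")])
  expect_true(all(colMeans(xs) > 1))

  # constant column: centered, unscaled, with warning
  f$f1 <- 7
  expect_warning(out3 <- standardize_features(f), "zero-spread.*f1")
  expect_equal(unique(out3$train$f1), 0)
})

test_that("grid search finds separating hyperparameters on Gaussian classes", {
  f <- toy_features(n_per_class = 24, gap = 8)
  gs <- grid_search_cv(f, folds = 4, seed = 3)
  expect_identical(gs$cv_folds, 4L)
  expect_identical(nrow(gs$grid), length(default_c_grid()) * length(default_gamma_grid()))
  expect_equal(max(gs$grid$cv_accuracy), 100)
  # tie-break: the best point is the smallest (c, gamma) among the maxima
  top <- gs$grid[gs$grid$cv_accuracy == max(gs$grid$cv_accuracy), ]
  expect_identical(gs$best$c, min(top$c))
  expect_identical(gs$best$gamma, min(top$gamma[top$c == gs$best$c]))

  # single-point grid returns that point
  one <- grid_search_cv(f, c_grid = 10, gamma_grid = 0.5, folds = 4, seed = 3)
  expect_identical(one$best, list(c = 10, gamma = 0.5))

  # too few per-class instances for the fold count
  small <- toy_features(n_per_class = 5)
  expect_error(grid_search_cv(small, folds = 8), "fewer instances")

  # identical seeds give identical surfaces
  gs2 <- grid_search_cv(f, folds = 4, seed = 3)
  expect_identical(gs$grid, gs2$grid)
})

test_that("trained SVM separates toy problems including XOR", {
  f <- toy_features(n_per_class = 20, gap = 6)
  m <- train_svm(f, list(c = 100, gamma = 0.5))
  expect_identical(predict(m, f), f$label)

  # XOR: linearly inseparable, solvable with the RBF kernel
  xor <- data.frame(
    subject_id = "x", window_index = 1:4,
    label = c(1L, 2L, 2L, 1L),
    f1 = c(0, 0, 1, 1), f2 = c(0, 1, 0, 1)
  )
  mx <- train_svm(xor, list(c = 100, gamma = 1), standardize = FALSE)
  expect_identical(predict(mx, xor), xor$label)

  expect_error(train_svm(f[f$label == 1, ], list(c = 1, gamma = 1)), "2 classes")
})

test_that("predictions are invariant to training-set row order", {
  f <- toy_features(n_per_class = 15, gap = 3, n_feat = 3)
  probe <- toy_features(n_per_class = 30, gap = 3, n_feat = 3, seed = 9)
  m1 <- train_svm(f, list(c = 10, gamma = 0.4))
  set.seed(31)
  m2 <- train_svm(f[sample(nrow(f)), ], list(c = 10, gamma = 0.4))
  expect_identical(predict(m1, probe), predict(m2, probe))
})

test_that("prediction validates feature dimensions", {
  f <- toy_features()
  m <- train_svm(f, list(c = 10, gamma = 0.5))
  expect_error(predict(m, matrix(0, 2, 3)), "dimension mismatch")
  bad <- f
  names(bad)[names(bad) == "f4"] <- "zz"
  expect_error(predict(m, bad), "missing columns")
})

test_that("hyperparameter bounds follow the search interval", {
  f <- toy_features(n_per_class = 16)
  expect_error(grid_search_cv(f, c_grid = c(10, 200), folds = 4), "c_grid")
  expect_error(grid_search_cv(f, gamma_grid = c(0.5, 5), folds = 4), "gamma_grid")
})
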