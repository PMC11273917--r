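test_that("rmse: closed forms, naive oracle and metric axioms", {
  a <- array(0.2, c(8, 8, 3))
  expect_equal(rmse(a, a), 0)
  expect_equal(rmse(a, a + 0.1), 0.1)
  set.seed(19)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  y <- array(runif(8 * 8 * 3), c(8, 8, 3))
  z <- array(runif(8 * 8 * 3), c(8, 8, 3))
  expect_equal(rmse(x, y), naive_rmse(x, y), tolerance = 1e-12)
  expect_equal(rmse(x, y), rmse(y, x))                      # symmetry
  expect_lte(rmse(x, z), rmse(x, y) + rmse(y, z) + 1e-12)   # triangle
  # 8-bit inputs are rescaled to [0, 1]
  expect_equal(rmse(array(0L, c(4, 4, 3)), array(255L, c(4, 4, 3))), 1)
  expect_error(rmse(x, array(0, c(4, 4, 3))), class = "eberstain_format_error")
})

test_that("psnr: closed forms, logarithm identity, infinite flag", {
  a <- array(0.5, c(8, 8, 3))
  expect_equal(as.numeric(psnr(a, a + 0.1)), 20)
  expect_equal(as.numeric(psnr(a, a + 0.01)), 40)
  # halving the error adds 20 log10(2) dB
  expect_equal(as.numeric(psnr(a, a + 0.05)) - as.numeric(psnr(a, a + 0.1)),
               20 * log10(2))
  p <- psnr(a, a)
  expect_true(is.infinite(p))
  expect_true(attr(p, "identical"))
  # strictly decreasing in rmse
  set.seed(2)
  r <- sort(runif(5, 0.01, 0.5))
  ps <- vapply(r, function(e) as.numeric(psnr(a, a + e)), numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("ssim: identity, constant-image closed form, reference values", {
  set.seed(123)
  x <- matrix(runif(64 * 64), 64)
  y <- pmin(pmax(x + 0.1 * matrix(rnorm(64 * 64), 64), 0), 1)
  expect_equal(ssim(x, x), 1)
  # zero-variance closed form: (2 v1 v2 + C1) / (v1^2 + v2^2 + C1)
  v1 <- 0.3; v2 <- 0.5; C1 <- 1e-4
  expect_equal(ssim(matrix(v1, 32, 32), matrix(v2, 32, 32)),
               (2 * v1 * v2 + C1) / (v1^2 + v2^2 + C1), tolerance = 1e-12)
  # frozen values from an independent implementation (scikit-image
  # structural_similarity, Gaussian weights, sigma 1.5, win 11)
  expect_equal(ssim(x, y), 0.9464035106, tolerance = 1e-6)
  set.seed(7)
  a <- array(runif(32 * 32 * 3), c(32, 32, 3))
  b <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_equal(ssim(a, b), 0.0355001790, tolerance = 1e-6)
  expect_error(ssim(matrix(0.1, 8, 8), matrix(0.2, 8, 8), window_size = 11),
               class = "eberstain_format_error")
})

test_that("classification metrics reproduce the published worked examples", {
  # 8617/8686 negatives and 8480/8481 positives classified correctly
  m <- classification_metrics(confusion_counts(TP = 8480, TN = 8617,
                                               FP = 69, FN = 1))
  expect_equal(round(100 * m[["accuracy"]], 2), 99.59)
  expect_gte(100 * m[["recall"]], 99.98)
  # F1 as the harmonic mean of printed precision/recall pairs
  expect_equal(round(f1_score(0.8948, 0.9347), 4), 0.9143)
  expect_equal(round(f1_score(0.8711, 0.8845), 4), 0.8777)
  expect_equal(round(f1_score(0.7251, 0.9530), 4), 0.8236)
  m1 <- classification_metrics(confusion_counts(1, 1, 1, 1))
  expect_true(all(m1 == 0.5))
})

test_that("metrics handle undefined rates and are scale invariant", {
  m <- classification_metrics(confusion_counts(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_true(is.na(m[["precision"]]))
  expect_true(is.na(m[["recall"]]))
  expect_equal(m[["accuracy"]], 1)
  expect_error(confusion_counts(-1, 1, 1, 1), class = "eberstain_format_error")
  set.seed(3)
  for (i in 1:5) {
    cnt <- as.list(sample(1:50, 4))
    a <- classification_metrics(do.call(confusion_counts, cnt))
    b <- classification_metrics(do.call(confusion_counts,
                                        lapply(cnt, function(v) 7L * v)))
    expect_equal(a, b)
  }
})

test_that("F1 lies between precision and recall (harmonic mean)", {
  set.seed(4)
  for (i in 1:20) {
    p <- runif(1, 0.05, 1); r <- runif(1, 0.05, 1)
    f <- f1_score(p, r)
    expect_gte(f, min(p, r) - 1e-12)
    expect_lte(f, max(p, r) + 1e-12)
  }
})

test_that("confusion tallies partition the sample", {
  truth <- rbinom(1000, 1, 0.4); pred <- rbinom(1000, 1, 0.5)
  cc <- confusion_from_labels(pred, truth)
  ref <- naive_confusion(pred, truth)
  expect_equal(unlist(cc)[names(ref)], ref)
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 1000L)
  same <- confusion_from_labels(truth, truth)
  expect_equal(same$FP + same$FN, 0L)
  inv <- confusion_from_labels(1 - truth, truth)
  expect_equal(inv$TP + inv$TN, 0L)
  expect_error(confusion_from_labels(c(0, 1), c(0, 1, 1)),
               class = "eberstain_format_error")
})

test_that("pair evaluation averages per-image metrics", {
  set.seed(9)
  gen <- lapply(1:3, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  ref <- lapply(gen, function(g) pmin(pmax(g + 0.05, 0), 1))
  ev <- evaluate_pairs(gen, ref)
  expect_equal(nrow(ev$per_image), 3L)
  expect_equal(ev$mean[["rmse"]], mean(ev$per_image$rmse))
  expect_equal(ev$mean[["psnr"]], mean(ev$per_image$psnr))
})
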