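test_that("SSIM is 1 for identical images and matches a direct windowed oracle", {
  img <- matrix(runif(40 * 40, 10, 80), 40, 40)
  expect_equal(ssim(img, img), 1)

  # independent oracle: direct evaluation of the windowed definition
  ssim_oracle <- function(a, b, L = 70, w = 11, sig = 1.5) {
    g1 <- exp(-((seq_len(w) - (w + 1) / 2)^2) / (2 * sig^2))
    W <- outer(g1, g1); W <- W / sum(W)
    C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
    vals <- c()
    for (i in seq_len(nrow(a) - w + 1)) {
      for (j in seq_len(ncol(a) - w + 1)) {
        pa <- a[i + seq_len(w) - 1, j + seq_len(w) - 1]
        pb <- b[i + seq_len(w) - 1, j + seq_len(w) - 1]
        m1 <- sum(W * pa); m2 <- sum(W * pb)
        v1 <- sum(W * pa^2) - m1^2; v2 <- sum(W * pb^2) - m2^2
        cv <- sum(W * pa * pb) - m1 * m2
        vals <- c(vals, ((2 * m1 * m2 + C1) * (2 * cv + C2)) /
                          ((m1^2 + m2^2 + C1) * (v1 + v2 + C2)))
      }
    }
    mean(vals)
  }
  # checkerboard against its inversion: structure anti-correlated
  ch <- 35 * (outer(1:24, 1:24, `+`) %% 2) + 20
  inv <- 90 - ch
  s_pkg <- ssim(ch, inv)
  expect_lt(s_pkg, 0)
  expect_equal(s_pkg, ssim_oracle(ch, inv), tolerance = 1e-10)

  a <- matrix(runif(24 * 24, 10, 80), 24, 24)
  b <- a + matrix(rnorm(24 * 24, sd = 5), 24, 24)
  expect_equal(ssim(a, b), ssim_oracle(a, b), tolerance = 1e-10)

  # luminance sensitivity: small constant offsets barely move SSIM
  expect_lt(abs(ssim(a, a + 0.5) - 1), 0.01)

  # symmetry under the shared dynamic range
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-12)
  expect_error(ssim(a, matrix(0, 3, 3)), "identical shape")
})

test_that("NRMSE normalizes RMSE by the reference range", {
  expect_equal(nrmse(matrix(c(0, 12), 1), matrix(c(0, 10), 1)),
               sqrt(4 / 2) / 10, tolerance = 1e-12)
  a <- matrix(runif(100, 10, 80), 10, 10)
  expect_equal(nrmse(a, a), 0)
  b <- a + rnorm(100)
  expect_equal(nrmse(3 * b, 3 * a), nrmse(b, a), tolerance = 1e-12)
  expect_error(nrmse(a, matrix(5, 10, 10)), "constant reference")
})

test_that("PSNR follows its closed form with a finite cap", {
  ref <- matrix(c(0, 10), 1)
  expect_equal(psnr(matrix(c(0, 12), 1), ref),
               20 * log10(10 / sqrt(2)), tolerance = 1e-12)
  expect_equal(psnr(ref, ref), 100)
  a <- matrix(runif(64, 10, 80), 8, 8)
  e <- matrix(rnorm(64), 8, 8)
  expect_equal(psnr(a + e / 2, a) - psnr(a + e, a), 20 * log10(2),
               tolerance = 1e-10)
  # NRMSE and PSNR are monotone transforms of each other
  expect_equal(psnr(a + e, a), -20 * log10(nrmse(a + e, a)),
               tolerance = 1e-10)
})

test_that("metrics are invariant under simultaneous pixel permutation", {
  a <- matrix(runif(144, 10, 80), 12, 12)
  b <- a + matrix(rnorm(144, sd = 3), 12, 12)
  pr <- sample(12); pc <- sample(12)
  expect_equal(nrmse(b[pr, pc], a[pr, pc]), nrmse(b, a), tolerance = 1e-12)
  expect_equal(psnr(b[pr, pc], a[pr, pc]), psnr(b, a), tolerance = 1e-12)
})

test_that("summaries report means, sds and threshold proportions", {
  one <- data.frame(case_id = "c1", ssim = 0.95, nrmse = 0.1, psnr = 35)
  s <- summarize_metrics(one)
  expect_equal(c(s$ssim_gt_0.9, s$nrmse_lt_0.2, s$psnr_gt_30), c(1, 1, 1))
  expect_equal(c(s$ssim_sd, s$nrmse_sd, s$psnr_sd), c(0, 0, 0))

  two <- data.frame(case_id = c("a", "b"), ssim = c(0.85, 0.95),
                    nrmse = c(0.1, 0.3), psnr = c(25, 35))
  s2 <- summarize_metrics(two)
  expect_equal(c(s2$ssim_gt_0.9, s2$nrmse_lt_0.2, s2$psnr_gt_30),
               c(0.5, 0.5, 0.5))

  # large-sample agreement with an independent accumulation order
  set.seed(9)
  rec <- data.frame(case_id = as.character(1:1000), ssim = runif(1000),
                    nrmse = runif(1000), psnr = runif(1000, 20, 40))
  s3 <- summarize_metrics(rec)
  expect_equal(s3$ssim_mean, sum(sort(rec$ssim)) / 1000, tolerance = 1e-12)
  expect_equal(s3$psnr_sd, sqrt(sum(sort((rec$psnr - mean(rec$psnr))^2)) / 999),
               tolerance = 1e-12)
  expect_error(summarize_metrics(rec[0, ]), "empty")
})

test_that("evaluate_cases assembles per-case records", {
  refs <- replicate(3, matrix(runif(400, 10, 80), 20, 20), simplify = FALSE)
  preds <- lapply(refs, function(r) r + rnorm(400, sd = 2))
  ev <- evaluate_cases(preds, refs)
  expect_equal(nrow(ev), 3)
  expect_true(all(ev$ssim <= 1 & ev$nrmse >= 0 & is.finite(ev$psnr)))
  expect_error(evaluate_cases(preds[1:2], refs), "differ in length")
})
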