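# evaluation metrics and their nodule-region variants

test_that("PSNR follows its closed form for constant offsets", {
  ref <- rand_vol(c(10, 10, 10), seed = 1, lo = -0.5, hi = 0.5)
  expect_equal(psnr(ref + 0.02, ref), 20 * log10(2 / 0.02), tolerance = 1e-9)
  expect_equal(psnr(ref + 0.02, ref), 40, tolerance = 1e-9)
  # halving the error adds 20*log10(2) dB
  expect_equal(psnr(ref + 0.01, ref) - psnr(ref + 0.02, ref),
               20 * log10(2), tolerance = 1e-9)
  # identical images hit the capped sentinel
  expect_equal(psnr(ref, ref), 100)
  expect_error(psnr(ref, ref, max_val = 0), "positive")
})

test_that("PSNR is strictly decreasing in MSE", {
  ref <- rand_vol(c(8, 8, 8), seed = 2)
  offs <- c(0.005, 0.01, 0.05, 0.2)
  vals <- sapply(offs, function(o) psnr(ref + o, ref))
  expect_true(all(diff(vals) < 0))
})

test_that("SSIM: self-similarity, oracle equivalence, anticorrelation", {
  a <- rand_vol(c(8, 8, 8), seed = 3)
  expect_equal(ssim(a, a), 1, tolerance = 1e-12)
  b <- rand_vol(c(8, 8, 8), seed = 4)
  expect_equal(ssim(a, b, window = 3L), oracle_ssim(a, b, 3L),
               tolerance = 1e-6)
  # zero-mean anticorrelated windows push SSIM negative
  z <- array(rep(c(-0.5, 0.5), 256), c(8, 8, 8))
  expect_lt(ssim(z, -z), 0)
})

test_that("DSC: fixed points, arithmetic, symmetry, empty-mask rule", {
  m <- rand_mask(c(8, 8, 8), seed = 5)
  expect_equal(dsc(m, m), 1)
  expect_equal(dsc(m, 1 - m), 0)
  a <- array(0, c(10, 10, 10)); a[1:100] <- 1
  b <- array(0, c(10, 10, 10)); b[21:120] <- 1  # overlap 80 of 100 each
  expect_equal(dsc(a, b), 0.8)
  expect_equal(dsc(a, b), dsc(b, a))
  expect_equal(dsc(array(0, c(4, 4, 4)), array(0, c(4, 4, 4))), 1)
})

test_that("region restriction is honoured and monotone", {
  ref <- rand_vol(c(10, 10, 10), seed = 6)
  region <- array(0, c(10, 10, 10))
  region[4:6, 4:6, 4:6] <- 1
  pred <- ref + 0.02
  expect_equal(psnr(pred, ref, region = region), 40, tolerance = 1e-9)
  # corrupting voxels outside the region changes psnr but not psnr*
  pred2 <- pred
  pred2[region == 0] <- pred2[region == 0] + 0.5
  expect_lt(psnr(pred2, ref), psnr(pred, ref))
  expect_equal(psnr(pred2, ref, region = region),
               psnr(pred, ref, region = region))
  # a one-voxel region reduces to that voxel's squared error
  r1 <- array(0, c(10, 10, 10)); r1[5, 5, 5] <- 1
  pred3 <- ref; pred3[5, 5, 5] <- ref[5, 5, 5] + 0.1
  expect_equal(psnr(pred3, ref, region = r1), 20 * log10(2 / 0.1),
               tolerance = 1e-9)
  expect_error(psnr(pred, ref, region = array(0, c(10, 10, 10))), "empty")
  expect_error(ssim(pred, ref, region = array(0, c(10, 10, 10))), "empty")
})

test_that("starred metrics equal bounding-box restricted computation", {
  ref <- rand_vol(c(12, 12, 12), seed = 7)
  pred <- ref + array(rnorm(12^3, sd = 0.05), c(12, 12, 12))
  region <- array(0, c(12, 12, 12))
  region[5:8, 5:8, 5:8] <- 1
  direct <- psnr(pred, ref, region = region)
  crop <- psnr(pred[5:8, 5:8, 5:8], ref[5:8, 5:8, 5:8])
  expect_equal(direct, crop, tolerance = 1e-9)
})

test_that("evaluate_pair assembles the full report", {
  pr <- small_phantom_pair(seed = 6, interval = 150)
  bundle <- list(y_hat = unclass(pr$followup), seg_mask = pr$followup_mask)
  rep_ <- evaluate_pair(bundle, pr)
  expect_equal(rep_$ssim, 1, tolerance = 1e-12)
  expect_equal(rep_$ssim_star, 1, tolerance = 1e-12)
  expect_equal(rep_$psnr, 100)
  expect_equal(rep_$dsc, 1)
  expect_equal(rep_$n_voxels_region, sum(pr$followup_mask))

  bundle2 <- list(y_hat = unclass(pr$followup) * 0.9,
                  seg_mask = pr$baseline_mask)
  rep2 <- evaluate_pair(bundle2, pr)
  expect_lt(rep2$psnr, 100)
  expect_lt(rep2$dsc, 1)
  # uniform offset: psnr and psnr* coincide
  bundle3 <- list(y_hat = pmin(unclass(pr$followup) + 0.02, 1.02),
                  seg_mask = pr$followup_mask)
  rep3 <- evaluate_pair(bundle3, pr)
  expect_equal(rep3$psnr, rep3$psnr_star, tolerance = 1e-9)
  # empty truth mask: starred metrics missing, not zero
  pr0 <- pr
  pr0$followup_mask <- array(0, dim(pr$followup_mask))
  rep0 <- evaluate_pair(bundle, pr0)
  expect_true(is.na(rep0$psnr_star))
  expect_true(is.na(rep0$ssim_star))
})
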