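# volume I/O and the preprocessing chain

test_that("identity and constant resampling are fixed points", {
  v <- rand_vol(c(8, 8, 8), seed = 1, lo = -1000, hi = 400)
  sc <- raw_scan(v, c(1, 1, 1))
  out <- resample_isotropic(sc, c(1, 1, 1))
  expect_identical(out$intensities, v)

  const <- raw_scan(array(-500, c(10, 10, 10)), c(0.5, 0.5, 0.5))
  out2 <- resample_isotropic(const, c(1, 1, 1))
  expect_equal(dim(out2$intensities), c(5, 5, 5))
  expect_true(all(out2$intensities == -500))
  expect_equal(out2$spacing, c(1, 1, 1))
})

test_that("ramp resampling matches a direct linear-interpolation oracle", {
  n <- 21
  ramp <- array(seq(0, 100, length.out = n), c(n, 1, 1))
  sc <- raw_scan(ramp, c(0.5, 1, 1))
  out <- resample_isotropic(sc, c(1, 1, 1))
  m <- dim(out$intensities)[1]
  # output voxel j (0-based) sits at physical j mm -> input voxel 2j
  oracle <- approx(x = (seq_len(n) - 1) * 0.5, y = ramp[, 1, 1],
                   xout = pmin((seq_len(m) - 1) * 1, (n - 1) * 0.5))$y
  expect_equal(as.vector(out$intensities[, 1, 1]), oracle, tolerance = 1e-12)
})

test_that("resampling validates spacing", {
  v <- raw_scan(array(0, c(4, 4, 4)), c(1, 1, 1))
  expect_error(resample_isotropic(v, c(0, 1, 1)), "positive")
  expect_error(raw_scan(array(0, c(4, 4, 4)), c(-1, 1, 1)), "positive")
})

test_that("interior crops equal the corresponding sub-block", {
  v <- array(as.numeric(seq_len(10^3)), c(10, 10, 10))
  sc <- raw_scan(v, c(1, 1, 1))
  out <- crop_voi(sc, center = c(5, 5, 5), size = c(4, 4, 4))
  # centre voxel index floor(4/2)=2 (0-based) must land on voxel 5 (0-based)
  expect_identical(out$intensities, v[4:7, 4:7, 4:7])
})

test_that("out-of-scan voxels are padded with the window floor", {
  v <- array(100, c(6, 6, 6))
  sc <- raw_scan(v, c(1, 1, 1))
  out <- crop_voi(sc, center = c(0, 0, 0), size = c(6, 6, 6))
  expect_equal(dim(out$intensities), c(6, 6, 6))
  expect_true(any(out$intensities == -1024))
  expect_true(any(out$intensities == 100))
  # voxels before the scan start must be padding
  expect_true(all(out$intensities[1:2, , ] == -1024))
})

test_that("crop index arithmetic matches an explicit offset oracle", {
  d <- c(9, 8, 7)
  v <- array(as.numeric(seq_len(prod(d))), d)
  sc <- raw_scan(v, c(1, 1, 1))
  center <- c(6, 3, 4)
  size <- c(3, 4, 5)
  out <- crop_voi(sc, center, size)
  start <- round(center) - size %/% 2  # 0-based
  for (a in sample(prod(size), 10)) {
    idx <- arrayInd(a, size)
    src <- start + idx  # 1-based back-conversion: start(0-based) + idx(1-based)
    expected <- if (all(src >= 1 & src <= d)) v[src[1], src[2], src[3]] else -1024
    expect_identical(out$intensities[idx[1], idx[2], idx[3]], expected)
  }
})

test_that("window normalization maps endpoints, midpoint and clips", {
  v <- array(c(-1024, 400, -312, 2000, -2000, 0), c(6, 1, 1))
  out <- window_normalize(raw_scan(v, c(1, 1, 1)))
  expect_equal(as.vector(out)[1:5], c(-1, 1, 0, 1, -1))
  expect_true(all(out >= -1 & out <= 1))
  expect_error(window_normalize(raw_scan(v, c(1, 1, 1)), lo = 10, hi = 10),
               "lo < hi")
})

test_that("window normalization is monotone in HU", {
  hu <- sort(runif(50, -2000, 2000))
  out <- window_normalize(array(hu, c(50, 1, 1)))
  expect_true(all(diff(as.vector(out)) >= 0))
})

test_that("NIfTI round trip reproduces intensities and spacing", {
  v <- rand_vol(c(7, 6, 5), seed = 3, lo = -1000, hi = 400)
  sc <- raw_scan(v, c(0.5, 0.75, 1.5))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(sc, path)
  back <- read_volume(path)
  expect_identical(back$intensities, v)
  expect_equal(back$spacing, c(0.5, 0.75, 1.5))
  unlink(path)
})

test_that("missing and truncated files raise I/O errors naming the path", {
  expect_error(read_volume("/nonexistent/vol.nii.gz"), "no such file")
  path <- tempfile(fileext = ".nii.gz")
  write_volume(array(rnorm(4^3), c(4, 4, 4)), path)
  raw <- readBin(path, "raw", file.info(path)$size)
  writeBin(raw[1:20], path)
  expect_error(read_volume(path), "nii")
  unlink(path)
})

test_that("the preprocessing chain is deterministic and stays in [-1, 1]", {
  for (seed in 1:3) {
    v <- rand_vol(c(20, 18, 16), seed = seed, lo = -2000, hi = 2500)
    sc <- raw_scan(v, c(0.7, 1.1, 1.3))
    a <- preprocess_voi(sc, center = c(7, 9, 10), size = c(12, 12, 12))
    b <- preprocess_voi(sc, center = c(7, 9, 10), size = c(12, 12, 12))
    expect_identical(a, b)
    expect_equal(dim(a), c(12L, 12L, 12L))
    expect_true(all(a >= -1 & a <= 1))
  }
})
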