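# architecture contracts: untrained identity, fusion algebra, parameter
# counting, covariance and numeric health

test_that("an untrained network is the identity transform", {
  net <- tiny_net(16L, 4L)
  x <- rand_vol(c(16, 16, 16), seed = 1)
  s <- rand_mask(c(16, 16, 16), seed = 2)
  b <- predict_bundle(net, x, s, 6L)
  expect_equal(b$x_warp, x, tolerance = 1e-12)
  expect_equal(b$s_warp, s, tolerance = 1e-12)
  expect_true(all(abs(b$u) == 0))
})

test_that("with a zeroed texture head the model is deformation-only", {
  net <- tiny_net(16L, 4L)
  net$cfg$deep_supervision <- FALSE
  net$params$head_tex$w[] <- 0
  net$params$head_tex$b[] <- 0
  x <- rand_vol(c(16, 16, 16), seed = 3)
  s <- rand_mask(c(16, 16, 16), seed = 4)
  b <- predict_bundle(net, x, s, 3L, clamp = FALSE)
  expect_true(all(b$x_res == 0))
  expect_equal(b$y_hat, b$x_warp, tolerance = 1e-12)
})

test_that("fusion formulas obey their mask algebra", {
  d <- c(6, 6, 6)
  xw <- rand_vol(d, seed = 5)
  xr <- rand_vol(d, seed = 6)
  xt <- rand_vol(d, seed = 7)
  s0 <- array(0, d)
  s1 <- array(1, d)
  expect_equal(fuse_residual(xw, xr, s0), xw)
  expect_equal(fuse_direct(xw, xt, s0), xw)
  expect_equal(fuse_direct(xw, xt, s1), xt)
  # binary mask: constant residual adds only inside
  sb <- rand_mask(d, seed = 8)
  y <- fuse_residual(xw, array(0.3, d), sb)
  expect_equal(y[sb == 1], xw[sb == 1] + 0.3)
  expect_equal(y[sb == 0], xw[sb == 0])
})

test_that("residual and direct fusion agree when x_texture = x_warp + x_res", {
  for (seed in 1:3) {
    d <- c(8, 8, 8)
    xw <- rand_vol(d, seed = seed)
    xr <- rand_vol(d, seed = seed + 10)
    withr_seed(seed + 20)
    sw <- array(runif(prod(d)), d)  # soft mask
    xt <- xw + xr
    expect_equal(fuse_direct(xw, xt, sw), fuse_residual(xw, xr, sw),
                 tolerance = 1e-12)
  }
})

test_that("parameter counts follow the convolution scaling law", {
  n8 <- count_parameters(network_config(voi_size = 16, base_channels = 8))
  n16 <- count_parameters(network_config(voi_size = 16, base_channels = 16))
  expect_gt(n16 / n8, 3.2)
  expect_lt(n16 / n8, 4.3)
  expect_identical(n8, count_parameters(network_config(voi_size = 16,
                                                       base_channels = 8)))
})

test_that("sharing the encoder beats three single-task networks", {
  net <- tiny_net(16L, 8L)
  groups <- nogrownet:::.param_groups(net$params)
  size_of <- function(nms) sum(vapply(net$params[nms], function(l)
    length(l$w) + length(l$b), numeric(1)))
  enc <- size_of(groups$encoder)
  dec <- vapply(groups[c("warp", "tex", "seg")], size_of, numeric(1))
  shared_total <- enc + sum(dec)
  separate_total <- sum(enc + dec)  # one encoder per task
  expect_lt(shared_total, separate_total)
  expect_equal(shared_total, count_parameters(net$cfg))
})

test_that("the untrained warp output is translation-covariant", {
  net <- tiny_net(16L, 4L)
  x <- array(0, c(16, 16, 16))
  x[5:8, 5:8, 5:8] <- 0.7
  s <- array(0, c(16, 16, 16))
  s[5:8, 5:8, 5:8] <- 1
  b1 <- predict_bundle(net, x, s, 6L)
  xs <- array(0, c(16, 16, 16))
  xs[9:12, 9:12, 9:12] <- 0.7
  ss <- array(0, c(16, 16, 16))
  ss[9:12, 9:12, 9:12] <- 1
  b2 <- predict_bundle(net, xs, ss, 6L)
  expect_equal(b2$x_warp[9:12, 9:12, 9:12], b1$x_warp[5:8, 5:8, 5:8],
               tolerance = 1e-12)
})

test_that("all bundle outputs are finite and in their declared ranges", {
  net <- tiny_net(16L, 4L, seed = 9)
  # break the identity so the warp actually does something
  withr_seed(10)
  net$params$head_warp$w[] <- rnorm(length(net$params$head_warp$w), sd = 0.05)
  x <- rand_vol(c(16, 16, 16), seed = 11)
  s <- rand_mask(c(16, 16, 16), seed = 12)
  b <- predict_bundle(net, x, s, 12L)
  for (f in c("u", "x_warp", "s_warp", "x_res", "y_hat", "seg_mask"))
    expect_true(all(is.finite(b[[f]])), info = f)
  expect_true(all(b$seg_mask >= 0 & b$seg_mask <= 1))
  expect_true(all(b$s_warp >= -1e-9 & b$s_warp <= 1 + 1e-9))
  expect_true(all(b$x_res >= -2 & b$x_res <= 2))
  expect_true(all(b$y_hat >= -1 & b$y_hat <= 1))  # clamped on export
})

test_that("shape and conditioning contracts are validated", {
  expect_error(network_config(voi_size = 15), "divisible")
  expect_error(network_config(base_channels = 3), "even")
  net <- tiny_net(16L, 4L)
  x <- rand_vol(c(16, 16, 16), seed = 13)
  s <- rand_mask(c(16, 16, 16), seed = 14)
  expect_error(predict_bundle(net, x, s, 25L), "\\[0, 20\\]")
  expect_error(predict_bundle(net, rand_vol(c(8, 8, 8)), s, 5L), "shape")
})
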