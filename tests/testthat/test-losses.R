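# training objectives and their algebraic properties

test_that("local NCC: self-similarity, affine invariance, loop oracle", {
  a <- rand_vol(c(10, 10, 10), seed = 1)
  expect_equal(local_ncc(a, a, 5L), 1, tolerance = 1e-6)
  expect_equal(baseline_consistency_loss(a, a, 5L), 0, tolerance = 1e-6)

  b <- 2 * a + 0.1  # positive affine map
  expect_equal(local_ncc(a, b, 5L), 1, tolerance = 1e-4)

  b2 <- rand_vol(c(8, 8, 8), seed = 2)
  a2 <- rand_vol(c(8, 8, 8), seed = 3)
  expect_equal(local_ncc(a2, b2, 3L), oracle_local_ncc(a2, b2, 3L),
               tolerance = 1e-5)
  # shifted copy is penalized
  ash <- a
  ash[1:9, , ] <- a[2:10, , ]
  expect_gt(baseline_consistency_loss(a, ash, 5L), 0)
})

test_that("Tversky loss: fixed points, Dice equivalence, monotonicity", {
  m <- rand_mask(c(8, 8, 8), seed = 4)
  expect_equal(tversky_loss(m, m, 0.2, 0.8), 0, tolerance = 1e-9)

  disj <- array(0, dim(m))
  disj[m == 0] <- 1
  expect_equal(tversky_loss(m, disj, 0.2, 0.8), 1, tolerance = 1e-6)

  for (seed in 1:5) {
    t_ <- rand_mask(c(8, 8, 8), seed = seed, p = 0.35)
    p_ <- rand_mask(c(8, 8, 8), seed = seed + 50, p = 0.35)
    ti <- 1 - tversky_loss(t_, p_, 0.5, 0.5)
    dice <- 2 * sum(t_ & p_) / (sum(t_) + sum(p_))
    expect_equal(ti, dice, tolerance = 1e-6)
    expect_equal(ti, oracle_tversky_index(t_, p_, 0.5, 0.5), tolerance = 1e-6)
  }

  # adding a false positive never decreases the loss
  t_ <- rand_mask(c(6, 6, 6), seed = 7, p = 0.3)
  p_ <- t_
  l0 <- tversky_loss(t_, p_, 0.2, 0.8)
  idx <- which(t_ == 0 & p_ == 0)[1]
  p_[idx] <- 1
  expect_gte(tversky_loss(t_, p_, 0.2, 0.8), l0)

  # raising beta with FN > 0 and FP = 0 increases the loss (recall pressure)
  t2 <- array(0, c(6, 6, 6)); t2[2:5, 2:5, 2:5] <- 1
  p2 <- array(0, c(6, 6, 6)); p2[3:4, 3:4, 3:4] <- 1  # subset: FN only
  expect_gt(tversky_loss(t2, p2, 0.2, 0.8), tversky_loss(t2, p2, 0.2, 0.5))
})

test_that("Dice loss agrees with the Tversky index at alpha = beta = 0.5", {
  for (seed in 1:4) {
    a <- rand_mask(c(7, 7, 7), seed = seed, p = 0.4)
    b <- rand_mask(c(7, 7, 7), seed = seed + 20, p = 0.4)
    expect_equal(dice_loss(a, b), tversky_loss(b, a, 0.5, 0.5),
                 tolerance = 1e-5)
  }
  m <- rand_mask(c(6, 6, 6), seed = 9)
  expect_equal(dice_loss(m, m), 0, tolerance = 1e-6)
  inv <- 1 - m
  expect_equal(dice_loss(m, inv), 1, tolerance = 1e-6)
})

test_that("texture losses: constants and loop oracles", {
  a <- rand_vol(c(9, 9, 9), seed = 10)
  expect_equal(texture_l1_loss(a, a), 0)
  expect_equal(texture_l1_loss(a, a + 0.2), 0.2, tolerance = 1e-12)
  b <- rand_vol(c(9, 9, 9), seed = 11)
  expect_equal(texture_l1_loss(a, b), mean(abs(b - a)), tolerance = 1e-12)

  expect_equal(texture_reg_loss(array(0, c(5, 5, 5))), 0)
  expect_equal(texture_reg_loss(array(0.5, c(5, 5, 5))), 0.25)
  expect_equal(texture_reg_loss(b), sum(b^2) / length(b), tolerance = 1e-12)
})

test_that("task totals combine terms with the configured weights", {
  w <- warp_loss_weights()
  expect_equal(w$lambda1, 0.5)
  expect_equal(w$lambda2, 10)
  expect_equal(w$lambda3, 1)
  expect_equal(w$tversky_alpha, 0.2)
  expect_equal(w$tversky_beta, 0.8)
  expect_equal(warp_total_loss(0, 0, 0, 0, w), 0)
  expect_equal(warp_total_loss(1, 1, 1, 1, w), 12.5)
  # linear in the smoothness weight
  t1 <- warp_total_loss(0.3, 0.2, 0.1, 0.05, warp_loss_weights(lambda2 = 10))
  t2 <- warp_total_loss(0.3, 0.2, 0.1, 0.05, warp_loss_weights(lambda2 = 20))
  expect_equal(t2 - t1, 10 * 0.1)

  tw <- texture_loss_weights()
  expect_equal(texture_total_loss(0, 0, tw), 0)
  expect_equal(texture_total_loss(0.3, 0.2, tw), 0.5)
  expect_equal(texture_total_loss(0.3, 0.2, texture_loss_weights(0)), 0.3)
  expect_error(warp_loss_weights(lambda1 = -1), "non-negative")
})

test_that("losses are permutation-covariant under joint voxel permutation", {
  d <- c(6, 6, 6)
  a <- rand_vol(d, seed = 12)
  b <- rand_vol(d, seed = 13)
  m1 <- rand_mask(d, seed = 14)
  m2 <- rand_mask(d, seed = 15)
  withr_seed(16)
  perm <- sample(prod(d))
  pa <- array(a[perm], d); pb <- array(b[perm], d)
  pm1 <- array(m1[perm], d); pm2 <- array(m2[perm], d)
  expect_equal(texture_l1_loss(a, b), texture_l1_loss(pa, pb))
  expect_equal(tversky_loss(m1, m2, 0.2, 0.8), tversky_loss(pm1, pm2, 0.2, 0.8))
  expect_equal(dice_loss(m1, m2), dice_loss(pm1, pm2))
  expect_equal(texture_reg_loss(a), texture_reg_loss(pa))
})

test_that("every loss vanishes at its perfect-prediction fixed point", {
  a <- rand_vol(c(8, 8, 8), seed = 17)
  m <- rand_mask(c(8, 8, 8), seed = 18)
  expect_equal(1 - local_ncc(a, a), 0, tolerance = 1e-6)
  expect_equal(tversky_loss(m, m), 0, tolerance = 1e-9)
  expect_equal(dice_loss(m, m), 0, tolerance = 1e-6)
  expect_equal(texture_l1_loss(a, a), 0)
  expect_equal(smoothness_penalty(array(0, c(8, 8, 8, 3))), 0)
})
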