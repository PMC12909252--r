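# shared fixtures and independent loop oracles used across the suite

rand_vol <- function(d, seed = 1, lo = -1, hi = 1) {
  withr_seed(seed)
  array(runif(prod(d), lo, hi), d)
}

rand_mask <- function(d, seed = 1, p = 0.3) {
  withr_seed(seed)
  array(rbinom(prod(d), 1, p), d)
}

withr_seed <- function(seed) set.seed(seed)

# brute-force local squared-correlation similarity: per-voxel window Pearson^2
# over in-volume neighbours (population sums), epsilon-stabilized like the
# implementation but computed with explicit loops
oracle_local_ncc <- function(a, b, window, eps = 1e-5) {
  d <- dim(a)
  r <- (window - 1) %/% 2
  acc <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    zi <- max(1, i - r):min(d[1], i + r)
    yi <- max(1, j - r):min(d[2], j + r)
    xi <- max(1, k - r):min(d[3], k + r)
    wa <- a[zi, yi, xi]
    wb <- b[zi, yi, xi]
    n <- length(wa)
    cross <- sum(wa * wb) - sum(wa) * sum(wb) / n
    va <- sum(wa^2) - sum(wa)^2 / n
    vb <- sum(wb^2) - sum(wb)^2 / n
    acc <- acc + cross^2 / (va * vb + eps)
  }
  acc / prod(d)
}

# brute-force SSIM map mean with uniform window, population statistics
oracle_ssim <- function(a, b, window, max_val = 2) {
  d <- dim(a)
  r <- (window - 1) %/% 2
  c1 <- (0.01 * max_val)^2
  c2 <- (0.03 * max_val)^2
  acc <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    zi <- max(1, i - r):min(d[1], i + r)
    yi <- max(1, j - r):min(d[2], j + r)
    xi <- max(1, k - r):min(d[3], k + r)
    wa <- a[zi, yi, xi]
    wb <- b[zi, yi, xi]
    n <- length(wa)
    mx <- mean(wa); my <- mean(wb)
    vx <- sum((wa - mx)^2) / n
    vy <- sum((wb - my)^2) / n
    cxy <- sum((wa - mx) * (wb - my)) / n
    acc <- acc + ((2 * mx * my + c1) * (2 * cxy + c2)) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
  }
  acc / prod(d)
}

# set-arithmetic Tversky index on binary masks
oracle_tversky_index <- function(target, pred, alpha, beta) {
  tp <- sum(target == 1 & pred == 1)
  fp <- sum(pred == 1 & target == 0)
  fn <- sum(target == 1 & pred == 0)
  tp / (tp + alpha * fp + beta * fn)
}

small_phantom_pair <- function(seed = 5, interval = 200, radius = 5,
                               vdt = 250) {
  simulate_pair(phantom_params(seed = seed, voi_size = 24,
                               baseline_radius = radius,
                               volume_doubling_time = vdt,
                               interval_days = interval))
}

tiny_net <- function(voi = 16L, c0 = 4L, seed = 1L) {
  init_network(network_config(voi_size = voi, base_channels = c0), seed = seed)
}
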