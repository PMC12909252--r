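# Synthetic longitudinal nodule phantoms. Each phantom is a centred ellipsoid
# with a fixed low-order spherical-harmonic radial perturbation (so the shape
# is irregular but carried unchanged through growth), embedded in smoothed
# parenchyma-like noise with optional bright tube distractors standing in for
# vessels. Growth is exponential in volume with a volume-doubling-time
# parameter -- the standard clinical model of nodule growth -- and interior
# density drifts linearly with elapsed time. Everything is deterministic given
# the seed, so paired baseline/follow-up samples with known ground truth can
# be regenerated at will.

#' Parameters of a synthetic nodule phantom
#'
#' Units: radii in voxels (1 voxel = 1 mm at the standard preprocessing),
#' doubling time and interval in days, densities on the normalized [-1, 1]
#' intensity scale, drift per 100 days.
#'
#' @param seed Integer RNG seed; fully determines the phantom.
#' @param voi_size Integer length-3 VOI shape.
#' @param baseline_radius Mean nodule radius at baseline, voxels.
#' @param volume_doubling_time Days for the nodule volume to double.
#' @param density_baseline Interior density at baseline, in (-0.2, 0.6).
#' @param density_drift_rate Density change per 100 days.
#' @param boundary_irregularity Amplitude of the radial perturbation as a
#'   fraction of the radius, in [0, 0.3].
#' @param background_noise_sd SD of the smoothed background noise.
#' @param vessel_count Number of bright tube distractors.
#' @param interval_days Follow-up interval in days.
#' @return A \code{phantom_params} list.
#' @export
phantom_params <- function(seed = 1L, voi_size = c(48L, 48L, 48L),
                           baseline_radius = 6, volume_doubling_time = 180,
                           density_baseline = 0.2, density_drift_rate = 0.04,
                           boundary_irregularity = 0.15,
                           background_noise_sd = 0.05, vessel_count = 2L,
                           interval_days = 180L) {
  if (length(voi_size) == 1L) voi_size <- rep(voi_size, 3L)
  p <- list(seed = as.integer(seed), voi_size = as.integer(voi_size),
            baseline_radius = baseline_radius,
            volume_doubling_time = volume_doubling_time,
            density_baseline = density_baseline,
            density_drift_rate = density_drift_rate,
            boundary_irregularity = boundary_irregularity,
            background_noise_sd = background_noise_sd,
            vessel_count = as.integer(vessel_count),
            interval_days = as.integer(interval_days))
  if (p$baseline_radius <= 0) stop("baseline_radius must be positive")
  if (p$volume_doubling_time <= 0) stop("volume_doubling_time must be positive")
  if (p$interval_days < 0) stop("interval_days must be non-negative")
  structure(p, class = "phantom_params")
}

# run code with a private, restored RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# real spherical harmonics of degree 2 evaluated at unit directions (n x 3)
.sh2 <- function(dirs) {
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  cbind(x * y, y * z, x * z, x^2 - y^2, 3 * z^2 - 1)
}

# deterministic unit-sphere sample used to normalize the perturbation
.fib_sphere <- function(n = 400L) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# frozen per-nodule randomness: perturbation coefficients, background field,
# texture field, vessels. Everything time-independent lives here.
.phantom_scene <- function(p) {
  with_seed(p$seed, {
    d <- p$voi_size
    coef <- rnorm(5)
    fmax <- max(abs(.sh2(.fib_sphere()) %*% coef), 1e-8)
    coef <- coef / fmax  # perturbation now bounded by 1 in magnitude
    parenchyma <- -0.75
    noise <- array(rnorm(prod(d)), d)
    # box-smoothed noise rescaled to the requested SD
    ncf <- array(noise, c(1L, d))
    sm <- .boxsum3d(ncf, as.integer(c(1L, d)), 1L)
    sm <- array(sm, d)
    sm <- sm / max(sd(sm), 1e-8) * p$background_noise_sd
    bg <- parenchyma + sm
    cen <- (d - 1) / 2
    ax <- lapply(1:3, function(a) seq_len(d[a]) - 1 - cen[a])
    gz <- array(rep(ax[[1]], times = d[2] * d[3]), d)
    gy <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d)
    gx <- array(rep(ax[[3]], each = d[1] * d[2]), d)
    if (p$vessel_count > 0) {
      for (v in seq_len(p$vessel_count)) {
        pt <- runif(3, -1, 1) * (d / 2 - 2)
        dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
        rad <- runif(1, 0.8, 1.4)
        val <- runif(1, 0.2, 0.5)
        # distance from voxel to the line pt + t*dirv
        rz <- gz - pt[1]; ry <- gy - pt[2]; rx <- gx - pt[3]
        t_ <- rz * dirv[1] + ry * dirv[2] + rx * dirv[3]
        dist2 <- (rz - t_ * dirv[1])^2 + (ry - t_ * dirv[2])^2 +
          (rx - t_ * dirv[3])^2
        bg <- bg + (val - parenchyma) * exp(-dist2 / (2 * rad^2))
      }
    }
    texcf <- array(rnorm(prod(d)), c(1L, d))
    tex <- array(.boxsum3d(texcf, as.integer(c(1L, d)), 1L), d)
    tex <- tex / max(sd(tex), 1e-8) * 0.06
    rr <- sqrt(gz^2 + gy^2 + gx^2)
    safe <- pmax(rr, 1e-8)
    dirs <- cbind(as.vector(gz / safe), as.vector(gy / safe),
                  as.vector(gx / safe))
    pert <- array(.sh2(dirs) %*% coef, d)  # in [-1, 1]
    list(bg = bg, tex = tex, rr = rr, pert = pert)
  })
}

# nodule state after `elapsed` days: volume (ct_volume) + binary mask
.phantom_state <- function(p, scene, elapsed) {
  scale <- 2^(elapsed / p$volume_doubling_time / 3)  # radius growth factor
  radius_field <- p$baseline_radius * scale *
    (1 + p$boundary_irregularity * scene$pert)
  max_r <- p$baseline_radius * scale * (1 + p$boundary_irregularity)
  if (max_r + 1.5 > min(p$voi_size) / 2)
    stop("nodule outgrows the VOI (radius ", signif(max_r, 4),
         " voxels); use a larger voi_size or smaller growth")
  density <- min(max(p$density_baseline +
                       p$density_drift_rate * elapsed / 100, -1), 1)
  # 1-voxel smoothstep across the analytic surface (partial volume)
  signed <- radius_field - scene$rr
  w <- pmin(pmax(signed + 0.5, 0), 1)
  vol <- scene$bg * (1 - w) + (density + scene$tex) * w
  vol <- pmin(pmax(vol, -1), 1)
  mask <- (scene$rr <= radius_field) * 1
  list(volume = structure(vol, class = c("ct_volume", "array")), mask = mask)
}

#' Simulate one baseline/follow-up nodule pair
#'
#' Builds the baseline nodule and its follow-up after
#' \code{params$interval_days}: the volume grows exponentially
#' (\code{V(t) = V0 * 2^(t / volume_doubling_time)}, realized on the voxel
#' grid as an isotropic, shape-preserving radius scaling), and interior
#' density drifts by \code{density_drift_rate * t / 100}. The background
#' scene (noise, vessels, texture) is frozen per nodule, so a zero-day
#' interval reproduces the baseline exactly.
#'
#' @param params A \code{\link{phantom_params}} object.
#' @param patient_id,nodule_id Identifier tokens carried into the pair.
#' @return A \code{nodule_pair} list with fields \code{baseline},
#'   \code{baseline_mask}, \code{followup}, \code{followup_mask},
#'   \code{interval_days}, \code{patient_id}, \code{nodule_id}.
#' @export
simulate_pair <- function(params, patient_id = "P001", nodule_id = "N001") {
  stopifnot(inherits(params, "phantom_params"))
  scene <- .phantom_scene(params)
  s0 <- .phantom_state(params, scene, 0)
  s1 <- .phantom_state(params, scene, params$interval_days)
  structure(list(baseline = s0$volume, baseline_mask = s0$mask,
                 followup = s1$volume, followup_mask = s1$mask,
                 interval_days = params$interval_days,
                 patient_id = patient_id, nodule_id = nodule_id,
                 params = params),
            class = "nodule_pair")
}

#' Cohort configuration for the phantom generator
#'
#' The defaults emulate the clinical cohort structure the model targets:
#' baseline radii spanning small to large nodules, volume doubling times of
#' 60--720 days, follow-up intervals of 8--1392 days drawn from a gamma
#' distribution with mean 376 days (matching the reported average follow-up),
#' and a fraction of patients with three timepoints contributing the pair
#' sets \{T0&T1, T0&T2, T1&T2\}. The \code{"small"} preset (24^3 VOI, radii
#' 2--6) keeps CPU training in the minutes range.
#'
#' @param preset \code{"full"} (48^3) or \code{"small"} (24^3).
#' @param voi_size,radius_range,vdt_range,interval_range,density_range,
#'   drift_range,irregularity_range,noise_sd,vessel_max Overrides.
#' @param p_three_timepoints Fraction of patients with a second follow-up.
#' @return A \code{phantom_cohort_config} list.
#' @export
phantom_cohort_config <- function(preset = c("small", "full"),
                                  voi_size = NULL, radius_range = NULL,
                                  vdt_range = c(60, 720),
                                  interval_range = c(8, 1392),
                                  density_range = c(-0.2, 0.6),
                                  drift_range = c(0, 0.08),
                                  irregularity_range = c(0, 0.3),
                                  noise_sd = 0.05, vessel_max = 3L,
                                  p_three_timepoints = 0.3) {
  preset <- match.arg(preset)
  if (is.null(voi_size)) voi_size <- if (preset == "full") 48L else 24L
  if (is.null(radius_range))
    radius_range <- if (preset == "full") c(2, 12) else c(2, 6)
  structure(list(preset = preset, voi_size = rep(as.integer(voi_size), 3L)[1:3],
                 radius_range = radius_range, vdt_range = vdt_range,
                 interval_range = interval_range,
                 density_range = density_range, drift_range = drift_range,
                 irregularity_range = irregularity_range, noise_sd = noise_sd,
                 vessel_max = as.integer(vessel_max),
                 p_three_timepoints = p_three_timepoints),
            class = "phantom_cohort_config")
}

# mean-376-day interval draw truncated to the configured range
.draw_interval <- function(cfg) {
  t <- stats::rgamma(1, shape = 1.6, scale = 376 / 1.6)
  as.integer(round(min(max(t, cfg$interval_range[1]), cfg$interval_range[2])))
}

#' Simulate a longitudinal phantom cohort
#'
#' Draws \code{n_patients} nodules (one per patient). A configurable fraction
#' get three timepoints, yielding the pair sets \{T0&T1, T0&T2, T1&T2\}; the
#' rest contribute one T0&T1 pair. Doubling times and intervals are redrawn
#' (deterministically under the seed) when the follow-up nodule would outgrow
#' the VOI. The manifest carries \code{patient_id} so splits can be made at
#' patient level, plus the ground-truth phantom parameters for recovery
#' tests.
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer master seed; two runs with the same seed are
#'   bit-identical.
#' @param config A \code{\link{phantom_cohort_config}}.
#' @return A list with \code{pairs} (list of \code{nodule_pair}) and
#'   \code{manifest} (data.frame, one row per pair).
#' @export
simulate_cohort <- function(n_patients, seed = 1L,
                            config = phantom_cohort_config()) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  cfg <- config
  draws <- with_seed(seed, {
    lapply(seq_len(n_patients), function(i) {
      has3 <- runif(1) < cfg$p_three_timepoints
      capacity <- min(cfg$voi_size) / 2 - 1.5
      for (try in 1:80) {
        r0 <- runif(1, cfg$radius_range[1], cfg$radius_range[2])
        vdt <- runif(1, cfg$vdt_range[1], cfg$vdt_range[2])
        irr <- runif(1, cfg$irregularity_range[1], cfg$irregularity_range[2])
        t1 <- .draw_interval(cfg)
        t2 <- if (has3) t1 + .draw_interval(cfg) else NA_integer_
        tmax <- if (has3) t2 else t1
        rmax <- r0 * 2^(tmax / vdt / 3) * (1 + irr)
        if (rmax < capacity) break
      }
      if (rmax >= capacity) {  # last resort: slow the growth to fit
        vdt <- tmax / (3 * log2(capacity / (r0 * (1 + irr))))
      }
      list(seed = sample.int(2147483646L, 1), has3 = has3, r0 = r0,
           vdt = vdt, irr = irr, t1 = t1, t2 = t2,
           dens = runif(1, cfg$density_range[1], cfg$density_range[2]),
           drift = runif(1, cfg$drift_range[1], cfg$drift_range[2]),
           nves = sample.int(cfg$vessel_max + 1L, 1) - 1L)
    })
  })
  pairs <- list()
  rows <- list()
  for (i in seq_len(n_patients)) {
    dr <- draws[[i]]
    pid <- sprintf("P%03d", i)
    nid <- sprintf("N%03d", i)
    p <- phantom_params(seed = dr$seed, voi_size = cfg$voi_size,
                        baseline_radius = dr$r0,
                        volume_doubling_time = dr$vdt,
                        density_baseline = dr$dens,
                        density_drift_rate = dr$drift,
                        boundary_irregularity = dr$irr,
                        background_noise_sd = cfg$noise_sd,
                        vessel_count = dr$nves, interval_days = dr$t1)
    scene <- .phantom_scene(p)
    states <- list(T0 = .phantom_state(p, scene, 0),
                   T1 = .phantom_state(p, scene, dr$t1))
    combos <- list(c("T0", "T1"))
    if (dr$has3) {
      states$T2 <- .phantom_state(p, scene, dr$t2)
      combos <- list(c("T0", "T1"), c("T0", "T2"), c("T1", "T2"))
    }
    elapsed <- c(T0 = 0, T1 = dr$t1, T2 = if (dr$has3) dr$t2 else NA)
    for (cb in combos) {
      a <- states[[cb[1]]]; b <- states[[cb[2]]]
      itv <- as.integer(elapsed[cb[2]] - elapsed[cb[1]])
      pair <- structure(list(baseline = a$volume, baseline_mask = a$mask,
                             followup = b$volume, followup_mask = b$mask,
                             interval_days = itv, patient_id = pid,
                             nodule_id = nid, params = p),
                        class = "nodule_pair")
      pairs[[length(pairs) + 1L]] <- pair
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = sprintf("%s_%s_%s", nid, cb[1], cb[2]),
        patient_id = pid, nodule_id = nid,
        baseline_label = cb[1], followup_label = cb[2],
        interval_days = itv, baseline_radius = dr$r0,
        volume_doubling_time = dr$vdt, density_baseline = dr$dens,
        density_drift_rate = dr$drift, boundary_irregularity = dr$irr,
        vessel_count = dr$nves, seed = dr$seed,
        stringsAsFactors = FALSE)
    }
  }
  list(pairs = pairs, manifest = do.call(rbind, rows))
}

#' Write a simulated cohort to disk
#'
#' Writes baseline/follow-up volumes and masks as NIfTI-1 files, a CSV
#' manifest, and a JSON file of the ground-truth phantom parameters.
#'
#' @param cohort Result of \code{\link{simulate_cohort}}.
#' @param dir Output directory (created if missing).
#' @return The manifest data.frame augmented with file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  paths <- lapply(seq_along(cohort$pairs), function(i) {
    pr <- cohort$pairs[[i]]
    id <- man$pair_id[i]
    f <- file.path(dir, paste0(id, c("_baseline.nii.gz", "_baseline_mask.nii.gz",
                                     "_followup.nii.gz", "_followup_mask.nii.gz")))
    write_volume(unclass(pr$baseline), f[1])
    write_volume(pr$baseline_mask, f[2], datatype = "uint8")
    write_volume(unclass(pr$followup), f[3])
    write_volume(pr$followup_mask, f[4], datatype = "uint8")
    setNames(as.list(f), c("baseline_path", "baseline_mask_path",
                           "followup_path", "followup_mask_path"))
  })
  man <- cbind(man, do.call(rbind.data.frame, paths))
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  gt <- lapply(cohort$pairs, function(pr) pr$params[setdiff(names(pr$params), "voi_size")])
  names(gt) <- man$pair_id
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(man)
}
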