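# Training orchestration: two-stage optimization with AdamW, patient-level
# k-fold splitting, the ablation grid, and inference. Stage 1 trains the
# shared encoder and all three decoders jointly on the sum of the task
# losses; stage 2 freezes the encoder and fine-tunes each decoder separately
# (sequentially, warp -> texture -> segmentation). Every optimization step
# also runs a zero-interval pass feeding the baseline-consistency and
# zero-residual regularizers.

#' Training configuration
#'
#' The reference recipe is the default (AdamW; learning rate 0.001 for the
#' deformation/segmentation path and 0.0005 for the texture path; batch 8;
#' 200 + 200-per-task epochs). The \code{"small"} preset scales this to a
#' desk-size run: batch 2, short schedules. Ablation flags:
#' \code{use_deep_supervision} (auxiliary direct texture prediction),
#' \code{use_tversky} (Tversky mask loss, else soft Dice) and \code{use_l1}
#' (L1 texture similarity, else mean-square).
#'
#' @param preset \code{"full"} or \code{"small"}.
#' @param lr_warp,lr_texture Learning rates.
#' @param batch_size Gradient-accumulation batch.
#' @param stage1_epochs,stage2_epochs_per_task Schedule lengths.
#' @param seed RNG seed covering initialization and shuffling.
#' @param weight_decay,beta1,beta2 AdamW settings.
#' @param use_deep_supervision,use_tversky,use_l1,cascade Ablation switches;
#'   \code{cascade} trains the warp and texture branches sequentially as two
#'   single-task models instead of jointly.
#' @param warp_weights,texture_weights Loss-weight containers.
#' @return A \code{train_config} list.
#' @export
train_config <- function(preset = c("small", "full"), lr_warp = 0.001,
                         lr_texture = 0.0005, batch_size = NULL,
                         stage1_epochs = NULL, stage2_epochs_per_task = NULL,
                         seed = 1L, weight_decay = 0.01, beta1 = 0.9,
                         beta2 = 0.999, use_deep_supervision = TRUE,
                         use_tversky = TRUE, use_l1 = TRUE, cascade = FALSE,
                         warp_weights = warp_loss_weights(),
                         texture_weights = texture_loss_weights()) {
  preset <- match.arg(preset)
  small <- preset == "small"
  cfg <- list(preset = preset, lr_warp = lr_warp, lr_texture = lr_texture,
              batch_size = batch_size %||% (if (small) 2L else 8L),
              stage1_epochs = stage1_epochs %||% (if (small) 5L else 200L),
              stage2_epochs_per_task = stage2_epochs_per_task %||%
                (if (small) 2L else 200L),
              seed = as.integer(seed), weight_decay = weight_decay,
              beta1 = beta1, beta2 = beta2,
              use_deep_supervision = isTRUE(use_deep_supervision),
              use_tversky = isTRUE(use_tversky), use_l1 = isTRUE(use_l1),
              cascade = isTRUE(cascade),
              warp_weights = warp_weights, texture_weights = texture_weights)
  if (cfg$lr_warp <= 0 || cfg$lr_texture <= 0)
    stop("learning rates must be positive")
  if (cfg$stage1_epochs < 0 || cfg$stage2_epochs_per_task < 0)
    stop("epoch counts must be non-negative")
  structure(cfg, class = "train_config")
}

#' Patient-level k-fold split
#'
#' Partitions patients (not pairs) into k mutually exclusive folds, so every
#' sample pair of a patient lands on one side of each split and no imaging
#' data leaks between train and test.
#'
#' @param manifest data.frame with a \code{patient_id} column.
#' @param k Number of folds.
#' @param seed Shuffle seed.
#' @return List of \code{fold_split} objects with \code{fold_id},
#'   \code{train_patients}, \code{test_patients}.
#' @export
make_folds <- function(manifest, k = 5L, seed = 1L) {
  patients <- unique(manifest$patient_id)
  if (k > length(patients))
    stop("k (", k, ") exceeds the number of patients (", length(patients), ")")
  shuffled <- with_seed(seed, sample(patients))
  assign_ <- rep_len(seq_len(k), length(shuffled))
  lapply(seq_len(k), function(f) {
    structure(list(fold_id = f - 1L,
                   train_patients = sort(shuffled[assign_ != f]),
                   test_patients = sort(shuffled[assign_ == f])),
              class = "fold_split")
  })
}

## ---- loss assembly ---------------------------------------------------------

# per-sample task losses as tape nodes; returns scalars too for logging
.sample_losses <- function(tape, net, pair, tcfg, tasks = .tasks,
                           detach_encoder = FALSE) {
  cfg <- net$cfg
  d <- dim(pair$baseline)
  P <- .param_nodes(tape, net$params)
  xcf <- ag_leaf(tape, array(unclass(pair$baseline), c(1L, d)))
  scf <- ag_leaf(tape, array(pair$baseline_mask, c(1L, d)))
  ycf <- ag_node(tape, array(unclass(pair$followup), c(1L, d)))
  stcf <- ag_node(tape, array(pair$followup_mask, c(1L, d)))
  t_itv <- quantize_interval(pair$interval_days)
  ds_on <- tcfg$use_deep_supervision && all(c("warp", "tex") %in% tasks)
  enc <- .encode_nodes(tape, cfg, P, xcf, scf, tasks = tasks,
                       detach_encoder = detach_encoder)
  nd <- .decode_nodes(tape, cfg, P, enc, t_itv, tasks = tasks,
                      deep_supervision = ds_on)
  t0tasks <- intersect(tasks, c("warp", "tex"))
  nd0 <- if (length(t0tasks))
    .decode_nodes(tape, cfg, P, enc, 0L, tasks = t0tasks,
                  deep_supervision = FALSE)
  ww <- tcfg$warp_weights
  out <- list(P = P)
  if ("warp" %in% tasks) {
    sim <- ag_local_ncc_loss(tape, ycf, nd$x_warp, cfg$ncc_window)
    maskl <- if (tcfg$use_tversky)
      ag_tversky_loss(tape, stcf, nd$s_warp, ww$tversky_alpha, ww$tversky_beta)
    else ag_dice_loss(tape, nd$s_warp, stcf)
    smooth <- ag_smoothness(tape, nd$u)
    reg <- ag_local_ncc_loss(tape, xcf, nd0$x_warp, cfg$ncc_window)
    out$warp <- ag_add(tape, sim,
                       ag_add(tape, ag_scale(tape, maskl, ww$lambda1),
                              ag_add(tape, ag_scale(tape, smooth, ww$lambda2),
                                     ag_scale(tape, reg, ww$lambda3))))
    out$warp_terms <- c(sim = sim$value, mask = maskl$value,
                        smooth = smooth$value, reg = reg$value)
  }
  if ("tex" %in% tasks && !is.null(nd$y_hat)) {
    simt <- if (tcfg$use_l1) ag_l1_loss(tape, nd$y_hat, ycf)
    else ag_msq_loss(tape, nd$y_hat, ycf)
    regt <- ag_mean(tape, ag_square(tape, nd0$x_res))
    tex <- ag_add(tape, simt,
                  ag_scale(tape, regt, tcfg$texture_weights$lambda1_prime))
    if (ds_on && !is.null(nd$y_ds)) {
      dsl <- if (tcfg$use_l1) ag_l1_loss(tape, nd$y_ds, ycf)
      else ag_msq_loss(tape, nd$y_ds, ycf)
      tex <- ag_add(tape, tex, dsl)
    }
    out$tex <- tex
  }
  if ("seg" %in% tasks) {
    out$seg <- ag_dice_loss(tape, nd$seg, stcf)
  }
  out
}

## ---- AdamW -----------------------------------------------------------------

.adamw_state <- function(params) {
  lapply(params, function(l) list(
    mw = array(0, dim(l$w)), vw = array(0, dim(l$w)),
    mb = numeric(length(l$b)), vb = numeric(length(l$b)), t = 0L))
}

.adamw_step <- function(params, grads, state, names_upd, lr, tcfg) {
  b1 <- tcfg$beta1; b2 <- tcfg$beta2; wd <- tcfg$weight_decay
  eps <- 1e-8
  for (nm in names_upd) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st <- state[[nm]]
    st$t <- st$t + 1L
    corr1 <- 1 - b1^st$t
    corr2 <- 1 - b2^st$t
    st$mw <- b1 * st$mw + (1 - b1) * g$w
    st$vw <- b2 * st$vw + (1 - b2) * g$w^2
    params[[nm]]$w <- params[[nm]]$w -
      lr * ((st$mw / corr1) / (sqrt(st$vw / corr2) + eps) +
              wd * params[[nm]]$w)
    st$mb <- b1 * st$mb + (1 - b1) * g$b
    st$vb <- b2 * st$vb + (1 - b2) * g$b^2
    params[[nm]]$b <- params[[nm]]$b -
      lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

# one optimization pass over `pairs` for the given loss task set
.run_epoch <- function(net, pairs, tcfg, state, update_names, lr, tasks,
                       detach_encoder, order) {
  total <- 0
  nb <- 0
  bs <- tcfg$batch_size
  idx <- split(order, ceiling(seq_along(order) / bs))
  for (batch in idx) {
    grads <- NULL
    bloss <- 0
    for (i in batch) {
      tape <- ag_tape()
      ls <- .sample_losses(tape, net, pairs[[i]], tcfg, tasks, detach_encoder)
      lnode <- NULL
      for (t in intersect(c("warp", "tex", "seg"), names(ls))) {
        lnode <- if (is.null(lnode)) ls[[t]] else ag_add(tape, lnode, ls[[t]])
      }
      if (!is.finite(lnode$value)) {
        terms <- if (!is.null(ls$warp_terms))
          paste(names(ls$warp_terms), signif(ls$warp_terms, 4),
                sep = "=", collapse = ", ") else ""
        stop("non-finite training loss (", terms, ")")
      }
      bloss <- bloss + lnode$value
      ag_backward(tape, lnode)
      gs <- lapply(ls$P, function(nd) list(
        w = nd$w$grad %||% array(0, dim(nd$w$value)),
        b = nd$b$grad %||% numeric(length(nd$b$value))))
      if (is.null(grads)) grads <- gs
      else for (nm in names(gs)) {
        grads[[nm]]$w <- grads[[nm]]$w + gs[[nm]]$w
        grads[[nm]]$b <- grads[[nm]]$b + gs[[nm]]$b
      }
    }
    nsamp <- length(batch)
    for (nm in names(grads)) {
      grads[[nm]]$w <- grads[[nm]]$w / nsamp
      grads[[nm]]$b <- grads[[nm]]$b / nsamp
    }
    upd <- .adamw_step(net$params, grads, state, update_names, lr, tcfg)
    net$params <- upd$params
    state <- upd$state
    total <- total + bloss
    nb <- nb + nsamp
  }
  list(net = net, state = state, mean_loss = total / nb)
}

#' Train the multi-task growth-prediction model
#'
#' Stage 1 jointly optimizes the deformation, texture and segmentation losses
#' (unweighted sum across tasks) with AdamW; stage 2 freezes the shared
#' encoder and fine-tunes each decoder separately in the fixed order warp,
#' texture, segmentation, each with its own task loss and learning rate.
#' Every step includes the zero-interval regularization pass. All randomness
#' (initialization, shuffling) derives from \code{config$seed}; runs are
#' bit-reproducible in this single-threaded implementation.
#'
#' @param pairs List of \code{nodule_pair} training samples (or a cohort list
#'   with a \code{pairs} element).
#' @param net_cfg A \code{\link{network_config}} matching the pair shapes.
#' @param config A \code{\link{train_config}}.
#' @param verbose Print per-epoch losses.
#' @return A list: \code{net} (trained \code{growth_net}), \code{history}
#'   (data.frame of stage/epoch/task mean losses).
#' @export
train_growth_model <- function(pairs, net_cfg, config = train_config(),
                               verbose = FALSE) {
  if (!is.null(pairs$pairs)) pairs <- pairs$pairs
  tcfg <- config
  net <- init_network(net_cfg, seed = tcfg$seed)
  if (!tcfg$use_deep_supervision) net$cfg$deep_supervision <- FALSE
  state <- .adamw_state(net$params)
  groups <- .param_groups(net$params)
  hist <- list()
  log_row <- function(stage, epoch, task, loss) {
    hist[[length(hist) + 1L]] <<- data.frame(stage = stage, epoch = epoch,
                                             task = task, loss = loss)
    if (verbose) message(sprintf("stage %d epoch %d [%s] loss %.5f",
                                 stage, epoch, task, loss))
  }
  orders <- with_seed(tcfg$seed + 1L, {
    n_ep <- tcfg$stage1_epochs + 3L * tcfg$stage2_epochs_per_task + 3L
    lapply(seq_len(n_ep), function(e) sample(length(pairs)))
  })
  oi <- 0L
  next_order <- function() {
    oi <<- oi + 1L
    orders[[oi]]
  }
  stage1_tasks <- if (tcfg$cascade) "warp" else c("warp", "tex", "seg")
  for (e in seq_len(tcfg$stage1_epochs)) {
    upd_names <- unlist(groups[c("encoder", intersect(names(groups),
                                                      stage1_tasks))])
    r <- .run_epoch(net, pairs, tcfg, state, upd_names, tcfg$lr_warp,
                    stage1_tasks, FALSE, next_order())
    net <- r$net; state <- r$state
    log_row(1L, e, "joint", r$mean_loss)
  }
  if (tcfg$cascade) {
    # cascade comparator: texture branch trained afterwards on the frozen rest
    for (e in seq_len(max(tcfg$stage1_epochs, 1L))) {
      r <- .run_epoch(net, pairs, tcfg, state, groups$tex, tcfg$lr_texture,
                      c("warp", "tex"), TRUE, next_order())
      net <- r$net; state <- r$state
      log_row(1L, e, "cascade_tex", r$mean_loss)
    }
  }
  enc_before <- net$params[groups$encoder]
  lrs <- c(warp = tcfg$lr_warp, tex = tcfg$lr_texture, seg = tcfg$lr_warp)
  for (task in c("warp", "tex", "seg")) {
    for (e in seq_len(tcfg$stage2_epochs_per_task)) {
      tasks <- if (task == "tex") c("warp", "tex") else task
      r <- .run_epoch(net, pairs, tcfg, state, groups[[task]], lrs[[task]],
                      tasks, TRUE, next_order())
      net <- r$net; state <- r$state
      log_row(2L, e, task, r$mean_loss)
    }
  }
  # freeze contract: stage 2 must not touch the shared encoder
  drift <- max(vapply(groups$encoder, function(nm)
    max(abs(net$params[[nm]]$w - enc_before[[nm]]$w)), numeric(1)))
  attr(net, "encoder_drift_stage2") <- drift
  list(net = net, history = do.call(rbind, hist))
}

#' Predict the follow-up appearance of a nodule
#'
#' Runs inference for a requested horizon of 1--20 months. If no baseline
#' mask is supplied, a preliminary zero-interval pass of the segmentation
#' decoder (with an empty mask channel) provides one, so manual annotation is
#' not required at inference time.
#'
#' @param net A trained \code{growth_net}.
#' @param baseline_vol Baseline VOI in [-1, 1].
#' @param baseline_mask Optional binary baseline mask.
#' @param months Integer follow-up horizon in months, 1--20.
#' @return A \code{prediction_bundle}; the mask actually used is attached as
#'   \code{baseline_mask_used}.
#' @export
predict_growth <- function(net, baseline_vol, baseline_mask = NULL, months) {
  if (!is.numeric(months) || length(months) != 1 || months < 1 || months > 20)
    stop("months must be a single integer in the prediction range 1-20")
  x <- unclass(baseline_vol)
  if (is.null(baseline_mask)) {
    pre <- predict_bundle(net, x, array(0, dim(x)), 0L)
    baseline_mask <- (pre$seg_mask > 0.5) * 1
  }
  out <- predict_bundle(net, x, baseline_mask, as.integer(months))
  out$baseline_mask_used <- baseline_mask
  out
}

#' Evaluate a model on a set of held-out pairs
#'
#' @param net A trained \code{growth_net}.
#' @param pairs List of \code{nodule_pair} test samples.
#' @return data.frame with one row per pair: the metric report plus predicted
#'   and true follow-up mask volumes (voxel counts).
#' @export
evaluate_cohort <- function(net, pairs) {
  if (!is.null(pairs$pairs)) pairs <- pairs$pairs
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    b <- predict_bundle(net, unclass(pr$baseline), pr$baseline_mask,
                        quantize_interval(pr$interval_days))
    rep_ <- evaluate_pair(b, pr)
    rep_$pred_volume <- sum(b$seg_mask > 0.5)
    rep_$true_volume <- sum(pr$followup_mask > 0.5)
    rep_$baseline_volume <- sum(pr$baseline_mask > 0.5)
    rep_$patient_id <- pr$patient_id
    rep_
  })
  do.call(rbind, rows)
}

#' Predicted nodule volume across prediction horizons
#'
#' @param net A trained \code{growth_net}.
#' @param pair A \code{nodule_pair} supplying the baseline.
#' @param months Integer vector of horizons.
#' @return Numeric vector of thresholded segmentation volumes (voxels).
#' @export
predicted_volume_curve <- function(net, pair, months = c(1L, 6L, 12L, 18L)) {
  vapply(months, function(m) {
    b <- predict_bundle(net, unclass(pair$baseline), pair$baseline_mask,
                        as.integer(m))
    sum(b$seg_mask > 0.5)
  }, numeric(1))
}

#' Run the ablation grid
#'
#' Trains and evaluates each configuration on identical data, seeds and
#' splits, over the standard ablation grid: \code{"cascade"}
#' (sequential single-task warp then texture), \code{"base"} (multi-task,
#' mean-square texture loss, Dice mask loss, no deep supervision),
#' \code{"+DS"}, \code{"+TL"}, \code{"+L1"} and \code{"+TL+L1"} (additive
#' flags on top of \code{+DS}).
#'
#' @param grid Character vector of configuration names.
#' @param train_pairs,test_pairs Training and held-out pair lists.
#' @param net_cfg A \code{\link{network_config}}.
#' @param config Base \code{\link{train_config}} whose flags are overridden
#'   per row.
#' @return data.frame with one row per configuration: mean metrics over the
#'   test pairs and a hash of the evaluation set for controlled comparison.
#' @export
run_ablation <- function(grid, train_pairs, test_pairs, net_cfg,
                         config = train_config()) {
  flags <- list(
    cascade = list(cascade = TRUE, use_deep_supervision = FALSE,
                   use_tversky = FALSE, use_l1 = FALSE),
    base = list(cascade = FALSE, use_deep_supervision = FALSE,
                use_tversky = FALSE, use_l1 = FALSE),
    "+DS" = list(cascade = FALSE, use_deep_supervision = TRUE,
                 use_tversky = FALSE, use_l1 = FALSE),
    "+TL" = list(cascade = FALSE, use_deep_supervision = TRUE,
                 use_tversky = TRUE, use_l1 = FALSE),
    "+L1" = list(cascade = FALSE, use_deep_supervision = TRUE,
                 use_tversky = FALSE, use_l1 = TRUE),
    "+TL+L1" = list(cascade = FALSE, use_deep_supervision = TRUE,
                    use_tversky = TRUE, use_l1 = TRUE))
  unknown <- setdiff(grid, names(flags))
  if (length(unknown)) stop("unknown ablation flag(s): ",
                            paste(unknown, collapse = ", "))
  eval_hash <- paste(vapply(test_pairs, function(p) p$patient_id,
                            character(1)), collapse = "|")
  rows <- lapply(grid, function(g) {
    tc <- config
    for (nm in names(flags[[g]])) tc[[nm]] <- flags[[g]][[nm]]
    fit <- train_growth_model(train_pairs, net_cfg, tc)
    ev <- evaluate_cohort(fit$net, test_pairs)
    data.frame(config = g, psnr = mean(ev$psnr),
               psnr_star = mean(ev$psnr_star, na.rm = TRUE),
               ssim = mean(ev$ssim),
               ssim_star = mean(ev$ssim_star, na.rm = TRUE),
               dsc = mean(ev$dsc), eval_hash = eval_hash,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
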