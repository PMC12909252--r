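# Training objectives: local squared NCC similarity, Tversky / Dice mask
# overlap, displacement smoothness, L1 / mean-square texture terms, and the
# weighted task totals. Each loss exists twice: a plain numeric function on 3D
# arrays (evaluation, tests) and an ag_* counterpart on tape nodes (training).
# All losses are means over voxels, so the stated weight coefficients are
# resolution-independent.

#' Loss weights for the deformation task
#'
#' Defaults follow the training recipe: mask weight 0.5, smoothness weight 10
#' (highest, prioritising physiologically smooth displacement fields),
#' baseline-consistency weight 1, and Tversky coefficients alpha = 0.2 /
#' beta = 0.8 (penalising false negatives harder, which matters for growth
#' detection).
#'
#' @param lambda1 Mask (Tversky) term weight.
#' @param lambda2 Smoothness term weight.
#' @param lambda3 Baseline-consistency term weight.
#' @param tversky_alpha,tversky_beta False-positive / false-negative weights.
#' @return A \code{warp_loss_weights} list.
#' @export
warp_loss_weights <- function(lambda1 = 0.5, lambda2 = 10, lambda3 = 1,
                              tversky_alpha = 0.2, tversky_beta = 0.8) {
  w <- list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
            tversky_alpha = tversky_alpha, tversky_beta = tversky_beta)
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative")
  if (tversky_alpha + tversky_beta <= 0) stop("alpha + beta must be positive")
  structure(w, class = "warp_loss_weights")
}

#' Loss weights for the texture task
#' @param lambda1_prime Weight of the zero-interval residual regularizer.
#' @return A \code{texture_loss_weights} list.
#' @export
texture_loss_weights <- function(lambda1_prime = 1) {
  if (lambda1_prime < 0) stop("lambda1_prime must be non-negative")
  structure(list(lambda1_prime = lambda1_prime),
            class = "texture_loss_weights")
}

.ncc_eps <- 1e-5
.tversky_eps <- 1e-7

# shared numeric core: mean over voxels of squared local correlation
.local_ncc_value <- function(a, b, window) {
  if (window %% 2 != 1) stop("window must be odd")
  d <- dim(a)
  r <- (window - 1L) %/% 2L
  cf <- function(x) array(x, c(1L, d))
  dims <- as.integer(c(1L, d))
  n <- .boxsum3d(cf(array(1, d)), dims, r)
  sa <- .boxsum3d(cf(a), dims, r)
  sb <- .boxsum3d(cf(b), dims, r)
  saa <- .boxsum3d(cf(a * a), dims, r)
  sbb <- .boxsum3d(cf(b * b), dims, r)
  sab <- .boxsum3d(cf(a * b), dims, r)
  cross <- sab - sa * sb / n
  va <- saa - sa * sa / n
  vb <- sbb - sb * sb / n
  mean(cross^2 / (va * vb + .ncc_eps))
}

#' Local normalized cross-correlation similarity
#'
#' Mean over voxels of the squared local Pearson correlation between the two
#' images, computed in a \code{window^3} neighbourhood (zero-padded at the
#' borders, with per-voxel counts). The squared form keeps the value in
#' [0, 1]; windows that are constant in either image contribute 0 through an
#' epsilon-stabilized denominator. The similarity is invariant to positive
#' affine intensity maps within each window. The associated loss is
#' \code{1 - local_ncc}.
#'
#' @param a,b 3D arrays of equal shape.
#' @param window Odd window edge length (default 9).
#' @return Similarity in [0, 1].
#' @export
local_ncc <- function(a, b, window = 9L) {
  if (!identical(dim(a), dim(b))) stop("shapes must agree")
  .local_ncc_value(a, b, as.integer(window))
}

#' Baseline-consistency loss
#'
#' \code{1 - local_ncc(x, warped_at_t0)}: a forward pass conditioned on a
#' zero follow-up interval should reproduce the input image.
#'
#' @param x Input volume.
#' @param warped_at_t0 Deformation output of a zero-interval pass.
#' @param window NCC window.
#' @return Non-negative scalar.
#' @export
baseline_consistency_loss <- function(x, warped_at_t0, window = 9L) {
  1 - local_ncc(x, warped_at_t0, window)
}

#' Tversky loss between a target mask and a warped mask
#'
#' Soft Tversky index \code{TI = TP / (TP + alpha*FP + beta*FN)} with
#' \code{TP = sum(s_t * s_w)}, \code{FP = sum(s_w * (1 - s_t))},
#' \code{FN = sum(s_t * (1 - s_w))}, epsilon-stabilized so two empty masks
#' count as perfect agreement; the loss is \code{1 - TI}. At
#' \code{alpha = beta = 0.5} on binary masks the index equals the Dice
#' coefficient. Raising \code{beta} penalises false negatives more, trading
#' precision for recall.
#'
#' @param target_mask,warped_mask Arrays with values in [0, 1].
#' @param alpha,beta False-positive / false-negative weights.
#' @return Loss in [0, 1].
#' @export
tversky_loss <- function(target_mask, warped_mask, alpha = 0.2, beta = 0.8) {
  if (!identical(dim(target_mask), dim(warped_mask))) stop("shapes must agree")
  tp <- sum(target_mask * warped_mask)
  fp <- sum(warped_mask * (1 - target_mask))
  fn <- sum(target_mask * (1 - warped_mask))
  ti <- (tp + .tversky_eps) / (tp + alpha * fp + beta * fn + .tversky_eps)
  1 - ti
}

#' Soft Dice loss
#'
#' \code{1 - 2*sum(p*q) / (sum(p) + sum(q) + eps)}; used to supervise the
#' segmentation decoder.
#'
#' @param pred_mask,target_mask Arrays with values in [0, 1].
#' @return Loss in [0, 1].
#' @export
dice_loss <- function(pred_mask, target_mask) {
  if (!identical(dim(pred_mask), dim(target_mask))) stop("shapes must agree")
  1 - 2 * sum(pred_mask * target_mask) /
    (sum(pred_mask) + sum(target_mask) + .tversky_eps)
}

#' Mean absolute (L1) texture similarity loss
#' @param pred,target Arrays of equal shape.
#' @return Mean over voxels of \code{|target - pred|}.
#' @export
texture_l1_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target))) stop("shapes must agree")
  mean(abs(target - pred))
}

#' Zero-interval texture residual regularizer
#'
#' Mean squared residual of a zero-interval pass: when no time has elapsed
#' the texture branch should predict no density change.
#'
#' @param residual_at_t0 Residual volume from a zero-interval forward pass.
#' @return Non-negative scalar.
#' @export
texture_reg_loss <- function(residual_at_t0) {
  mean(residual_at_t0^2)
}

#' Total deformation-task loss
#'
#' \code{sim + lambda1*mask + lambda2*smooth + lambda3*reg} with the weights
#' of \code{\link{warp_loss_weights}}; with unit components and default
#' weights the total is 12.5.
#'
#' @param sim NCC similarity loss term.
#' @param mask Tversky mask term.
#' @param smooth Displacement smoothness term.
#' @param reg Baseline-consistency term.
#' @param weights A \code{warp_loss_weights} object.
#' @return Scalar total.
#' @export
warp_total_loss <- function(sim, mask, smooth, reg,
                            weights = warp_loss_weights()) {
  sim + weights$lambda1 * mask + weights$lambda2 * smooth +
    weights$lambda3 * reg
}

#' Total texture-task loss
#'
#' \code{sim + lambda1_prime * reg}. The similarity term defaults to the L1
#' loss between the fused prediction and the true follow-up; a mean-square
#' variant is selectable through the training configuration's ablation flag.
#'
#' @param sim Similarity term value.
#' @param reg Zero-interval residual regularizer value.
#' @param weights A \code{texture_loss_weights} object.
#' @return Scalar total.
#' @export
texture_total_loss <- function(sim, reg, weights = texture_loss_weights()) {
  sim + weights$lambda1_prime * reg
}

## ---- tape-node counterparts used during training ---------------------------

ag_local_ncc_loss <- function(tape, a, b, window = 9L) {
  d <- dim(a$value)
  r <- (as.integer(window) - 1L) %/% 2L
  n <- .boxsum3d(array(1, d), as.integer(d), r)
  sa <- ag_boxsum(tape, a, r)
  sb <- ag_boxsum(tape, b, r)
  saa <- ag_boxsum(tape, ag_square(tape, a), r)
  sbb <- ag_boxsum(tape, ag_square(tape, b), r)
  sab <- ag_boxsum(tape, ag_mul(tape, a, b), r)
  ninv <- ag_node(tape, 1 / n)  # constant
  cross <- ag_sub(tape, sab, ag_mul(tape, ag_mul(tape, sa, sb), ninv))
  va <- ag_sub(tape, saa, ag_mul(tape, ag_mul(tape, sa, sa), ninv))
  vb <- ag_sub(tape, sbb, ag_mul(tape, ag_mul(tape, sb, sb), ninv))
  cc <- ag_div(tape, ag_square(tape, cross),
               ag_adds(tape, ag_mul(tape, va, vb), .ncc_eps))
  ag_sub(tape, ag_node(tape, 1), ag_mean(tape, cc))
}

ag_tversky_loss <- function(tape, target, warped, alpha, beta) {
  tp <- ag_sum(tape, ag_mul(tape, target, warped))
  one <- ag_node(tape, array(1, dim(target$value)))
  fp <- ag_sum(tape, ag_mul(tape, warped, ag_sub(tape, one, target)))
  fn <- ag_sum(tape, ag_mul(tape, target, ag_sub(tape, one, warped)))
  num <- ag_adds(tape, tp, .tversky_eps)
  den <- ag_adds(tape, ag_add(tape, tp, ag_add(tape, ag_scale(tape, fp, alpha),
                                               ag_scale(tape, fn, beta))),
                 .tversky_eps)
  ag_sub(tape, ag_node(tape, 1), ag_div(tape, num, den))
}

ag_dice_loss <- function(tape, pred, target) {
  num <- ag_scale(tape, ag_sum(tape, ag_mul(tape, pred, target)), 2)
  den <- ag_adds(tape, ag_add(tape, ag_sum(tape, pred), ag_sum(tape, target)),
                 .tversky_eps)
  ag_sub(tape, ag_node(tape, 1), ag_div(tape, num, den))
}

ag_l1_loss <- function(tape, pred, target) {
  ag_mean(tape, ag_abs(tape, ag_sub(tape, target, pred)))
}

ag_msq_loss <- function(tape, pred, target) {
  ag_mean(tape, ag_square(tape, ag_sub(tape, target, pred)))
}
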