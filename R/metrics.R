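# Image-fidelity metrics: PSNR, SSIM and DSC, each with a nodule-region
# variant (starred in the reporting convention) restricted to the voxels of
# the ground-truth follow-up mask. Images live on the normalized [-1, 1]
# scale, so the dynamic range constant is max_val = 2.

#' Peak signal-to-noise ratio
#'
#' \code{20 * log10(max_val / sqrt(MSE))} in dB, with the MSE averaged over
#' the whole volume or over \code{region} voxels only. Identical inputs have
#' infinite PSNR, reported as a capped sentinel (100 dB) for serializability.
#'
#' @param pred,ref 3D arrays of equal shape.
#' @param max_val Dynamic range (default 2, the span of [-1, 1]).
#' @param region Optional mask; if given, MSE uses only voxels where
#'   \code{region > 0}.
#' @param cap Sentinel for zero MSE.
#' @return PSNR in dB.
#' @export
psnr <- function(pred, ref, max_val = 2, region = NULL, cap = 100) {
  if (!identical(dim(pred), dim(ref))) stop("shapes must agree")
  if (max_val <= 0) stop("max_val must be positive")
  err <- (pred - ref)^2
  if (!is.null(region)) {
    keep <- region > 0
    if (!any(keep)) stop("region is empty")
    mse <- mean(err[keep])
  } else {
    mse <- mean(err)
  }
  if (mse == 0) return(cap)
  min(20 * log10(max_val / sqrt(mse)), cap)
}

#' Structural similarity index
#'
#' Sliding-window SSIM with a uniform \code{window^3} box, the standard
#' simplified form with unit exponents and \code{c3 = c2/2}:
#' \code{SSIM = (2*mu_x*mu_y + c1)(2*sigma_xy + c2) /
#' ((mu_x^2 + mu_y^2 + c1)(sigma_x^2 + sigma_y^2 + c2))} with
#' \code{c1 = (0.01 L)^2}, \code{c2 = (0.03 L)^2}, \code{L = max_val}.
#' Window statistics use the population convention (divide by the in-volume
#' window count). The scalar score is the mean of the per-voxel map over the
#' whole volume, or over \code{region} voxels for the nodule-region variant.
#' Anticorrelated content can push the score below 0; the upper bound 1 is
#' attained exactly for identical images.
#'
#' @param pred,ref 3D arrays of equal shape.
#' @param max_val Dynamic range L (default 2).
#' @param window Odd window edge (default 7).
#' @param region Optional mask restricting the average.
#' @return SSIM in [-1, 1].
#' @export
ssim <- function(pred, ref, max_val = 2, window = 7L, region = NULL) {
  if (!identical(dim(pred), dim(ref))) stop("shapes must agree")
  m <- ssim_map(pred, ref, max_val, window)
  if (!is.null(region)) {
    keep <- region > 0
    if (!any(keep)) stop("region is empty")
    mean(m[keep])
  } else {
    mean(m)
  }
}

#' Per-voxel SSIM map
#' @rdname ssim
#' @export
ssim_map <- function(pred, ref, max_val = 2, window = 7L) {
  d <- dim(pred)
  r <- (as.integer(window) - 1L) %/% 2L
  cf <- function(x) array(x, c(1L, d))
  dims <- as.integer(c(1L, d))
  n <- .boxsum3d(cf(array(1, d)), dims, r)
  mx <- .boxsum3d(cf(pred), dims, r) / n
  my <- .boxsum3d(cf(ref), dims, r) / n
  vx <- .boxsum3d(cf(pred^2), dims, r) / n - mx^2
  vy <- .boxsum3d(cf(ref^2), dims, r) / n - my^2
  cxy <- .boxsum3d(cf(pred * ref), dims, r) / n - mx * my
  c1 <- (0.01 * max_val)^2
  c2 <- (0.03 * max_val)^2
  m <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  array(m, d)
}

#' Dice similarity coefficient between binary masks
#'
#' \code{2 |A intersect B| / (|A| + |B|)}; two empty masks count as perfect
#' agreement (DSC 1). Inputs are binarized at 0.5.
#'
#' @param pred_mask,ref_mask Arrays of equal shape.
#' @return DSC in [0, 1].
#' @export
dsc <- function(pred_mask, ref_mask) {
  if (!identical(dim(pred_mask), dim(ref_mask))) stop("shapes must agree")
  a <- pred_mask > 0.5
  b <- ref_mask > 0.5
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Evaluate a prediction bundle against the true follow-up
#'
#' Plain metrics are computed over the full VOI; starred (nodule-region)
#' metrics restrict PSNR/SSIM to the voxels of the ground-truth follow-up
#' mask; DSC compares the thresholded segmentation-decoder mask with that
#' ground truth. An empty truth mask yields \code{NA} starred metrics rather
#' than zeros.
#'
#' @param bundle A \code{prediction_bundle} (see \code{\link{predict_bundle}}).
#' @param truth A \code{nodule_pair} (or any list with \code{followup} and
#'   \code{followup_mask}).
#' @param max_val Dynamic range.
#' @param window SSIM window.
#' @return A one-row data.frame: psnr, psnr_star, ssim, ssim_star, dsc,
#'   n_voxels_region.
#' @export
evaluate_pair <- function(bundle, truth, max_val = 2, window = 7L) {
  y <- truth$followup
  m <- truth$followup_mask
  nreg <- sum(m > 0)
  star_psnr <- if (nreg > 0) psnr(bundle$y_hat, y, max_val, region = m) else NA_real_
  star_ssim <- if (nreg > 0) ssim(bundle$y_hat, y, max_val, window, region = m) else NA_real_
  data.frame(psnr = psnr(bundle$y_hat, y, max_val),
             psnr_star = star_psnr,
             ssim = ssim(bundle$y_hat, y, max_val, window),
             ssim_star = star_ssim,
             dsc = dsc(bundle$seg_mask, m),
             n_voxels_region = nreg)
}
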