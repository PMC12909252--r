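# Displacement fields and spatial transformation. A displacement field u is a
# (D, H, W, 3) array in voxel units; the warp phi = id + u resamples the input
# at p + u(p) with trilinear interpolation and border clamping. The network
# keeps fields channel-first internally; these user-facing functions take the
# spatial-last layout natural for 3D arrays in R.

#' Apply a displacement-field warp to a volume or mask
#'
#' Computes \code{out(p) = vol(p + u(p))} by trilinear interpolation,
#' border-clamping samples that fall outside the grid (so no artificial air is
#' introduced at the VOI edge). The same operation is used differentiably
#' inside the network; warped binary masks come back with soft boundary values
#' in [0, 1] and are thresholded at 0.5 only for evaluation and export.
#'
#' @param vol 3D array (volume or mask).
#' @param u Displacement field, array of dim \code{c(dim(vol), 3)} in voxel
#'   units; component order matches the axis order (z, y, x).
#' @return A 3D array of the same shape as \code{vol}.
#' @export
apply_warp <- function(vol, u) {
  d <- dim(vol)
  if (length(d) != 3L) stop("vol must be a 3D array")
  if (!identical(dim(u), c(d, 3L)) && !identical(dim(u), as.integer(c(d, 3))))
    stop("displacement field shape must be c(dim(vol), 3)")
  if (any(!is.finite(u))) stop("displacement field must be finite")
  ucf <- aperm(u, c(4, 1, 2, 3))  # channel-first for the kernel
  vcf <- array(vol, c(1L, d))
  out <- .warp_fwd(vcf, as.integer(c(1L, d)), ucf)
  array(out, d)
}

#' Displacement-field smoothness penalty
#'
#' Mean squared forward-difference gradient of the field: for each of the nine
#' component/axis partial derivatives the squared forward differences are
#' averaged over the valid positions, and the nine averages are summed. A pure
#' linear ramp with slope \code{s} in one component along one axis scores
#' exactly \code{s^2}; a constant field scores 0. Averaging (rather than
#' summing) over voxels keeps the loss weight resolution-independent.
#'
#' @param u Displacement field, dim \code{c(D, H, W, 3)}.
#' @return Non-negative scalar.
#' @export
smoothness_penalty <- function(u) {
  d <- dim(u)
  if (length(d) != 4L || d[4] != 3L) stop("u must have dim c(D, H, W, 3)")
  total <- 0
  for (axis in 1:3) {
    n <- d[axis]
    if (n < 2L) next
    hi <- switch(axis, u[2:n, , , , drop = FALSE],
                 u[, 2:n, , , drop = FALSE],
                 u[, , 2:n, , drop = FALSE])
    lo <- switch(axis, u[1:(n - 1), , , , drop = FALSE],
                 u[, 1:(n - 1), , , drop = FALSE],
                 u[, , 1:(n - 1), , drop = FALSE])
    df <- hi - lo
    # one mean per component/axis, then summed
    total <- total + sum(apply(df^2, 4, mean))
  }
  total
}

# channel-first smoothness penalty as an autodiff node (training path)
ag_smoothness <- function(tape, u_cf) {
  terms <- NULL
  for (axis in 1:3) {
    df <- ag_fdiff(tape, u_cf, axis)
    m <- ag_mean(tape, ag_square(tape, df))
    # mean over (3, n-1 slice) block = mean over all 3 components jointly;
    # multiply by 3 to recover the sum of per-component means
    m3 <- ag_scale(tape, m, 3)
    terms <- if (is.null(terms)) m3 else ag_add(tape, terms, m3)
  }
  terms
}

#' Export a displacement field as a 4D NIfTI
#'
#' @param u Displacement field, dim \code{c(D, H, W, 3)}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_field <- function(u, path) {
  img <- RNifti::asNifti(u, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
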