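#' Raw CT scan container
#'
#' A minimal container for a 3D CT block in Hounsfield units together with its
#' voxel spacing. Axis order is (z, y, x) with 0-based voxel indices in all
#' coordinate arithmetic; voxel \code{i} sits at physical position
#' \code{i * spacing} mm along its axis. This convention is held fixed across
#' the whole package.
#'
#' @param intensities 3D numeric array of CT numbers (HU).
#' @param spacing Numeric length-3, mm per voxel along (z, y, x). Must be
#'   positive.
#' @param origin Numeric length-3 physical offset in mm (metadata only).
#' @return An object of class \code{raw_scan}.
#' @export
raw_scan <- function(intensities, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers")
  if (any(!is.finite(intensities)))
    stop("intensities must be finite")
  structure(list(intensities = intensities, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "raw_scan")
}

#' @export
print.raw_scan <- function(x, ...) {
  cat("<raw_scan> ", paste(dim(x$intensities), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "x"),
      " mm, HU range [", signif(min(x$intensities), 5), ", ",
      signif(max(x$intensities), 5), "]\n", sep = "")
  invisible(x)
}

#' Resample a scan to a target voxel spacing
#'
#' Resamples onto an isotropic (or any) target grid, preserving the physical
#' extent to within one voxel. Image intensities use trilinear interpolation;
#' masks should use \code{method = "nearest"} so they stay binary.
#'
#' @param scan A \code{raw_scan}.
#' @param target_spacing Numeric length-3, mm per voxel (default 1 mm
#'   isotropic).
#' @param method \code{"linear"} (images) or \code{"nearest"} (masks).
#' @return A \code{raw_scan} on the target grid.
#' @export
resample_isotropic <- function(scan, target_spacing = c(1, 1, 1),
                               method = c("linear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(scan, "raw_scan"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3L)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0))
    stop("target_spacing must be positive")
  idim <- dim(scan$intensities)
  odim <- pmax(1L, as.integer(round(idim * scan$spacing / target_spacing)))
  if (all(odim == idim) && all(abs(scan$spacing - target_spacing) < 1e-12))
    return(scan)
  out <- .resample3d(scan$intensities, as.integer(idim), scan$spacing,
                     target_spacing, odim, method == "nearest")
  raw_scan(out, target_spacing, scan$origin)
}

#' Crop a fixed-size volume of interest around a physical centre
#'
#' Extracts a \code{size} block whose centre voxel (index
#' \code{floor(size/2)}, 0-based) lands on the voxel nearest the requested
#' physical centre. Voxels falling outside the scan are padded with the
#' air value -1024 HU, matching the window floor.
#'
#' @param scan A \code{raw_scan}.
#' @param center Numeric length-3 physical centre in mm (z, y, x).
#' @param size Integer length-3 VOI shape (default 48^3).
#' @param pad_value Fill for out-of-scan voxels (default -1024).
#' @return A \code{raw_scan} of exactly the requested shape.
#' @export
crop_voi <- function(scan, center, size = c(48L, 48L, 48L),
                     pad_value = -1024) {
  stopifnot(inherits(scan, "raw_scan"))
  size <- as.integer(size)
  if (length(size) == 1L) size <- rep(size, 3L)
  if (any(size <= 0)) stop("size must be positive")
  idim <- dim(scan$intensities)
  cidx <- as.integer(round(as.numeric(center) / scan$spacing))  # 0-based
  start <- cidx - size %/% 2L                                   # 0-based
  out <- array(pad_value, size)
  # overlap between [start, start+size) and [0, idim) per axis
  lo <- pmax(start, 0L)
  hi <- pmin(start + size, idim)
  if (all(hi > lo)) {
    src <- lapply(1:3, function(a) (lo[a] + 1L):hi[a])
    dst <- lapply(1:3, function(a) (lo[a] - start[a] + 1L):(hi[a] - start[a]))
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      scan$intensities[src[[1]], src[[2]], src[[3]]]
  }
  raw_scan(out, scan$spacing, scan$origin + start * scan$spacing)
}

#' Window and normalize a scan to [-1, 1]
#'
#' Clips CT numbers to the window \code{[lo, hi]} (default the lung window
#' [-1024, 400] HU used throughout the package) and maps it affinely so that
#' \code{lo} becomes -1 and \code{hi} becomes +1.
#'
#' @param scan A \code{raw_scan} (or bare 3D array of HU values).
#' @param lo,hi Window bounds in HU; \code{lo < hi}.
#' @return A 3D numeric array of class \code{ct_volume} with values in
#'   [-1, 1].
#' @export
window_normalize <- function(scan, lo = -1024, hi = 400) {
  if (lo >= hi) stop("window bounds require lo < hi")
  v <- if (inherits(scan, "raw_scan")) scan$intensities else scan
  v <- pmin(pmax(v, lo), hi)
  out <- 2 * (v - lo) / (hi - lo) - 1
  structure(out, class = c("ct_volume", "array"))
}

#' Read a volume from a NIfTI-1 file
#'
#' @param path Path to a \code{.nii} or \code{.nii.gz} file.
#' @return A \code{raw_scan}; spacing is taken from the NIfTI pixdim.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("failed to read NIfTI file '",
                                           path, "': ", conditionMessage(e)))
  arr <- as.array(img)
  arr <- array(as.numeric(arr), dim(arr))  # plain numeric, no NIfTI attributes
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
  raw_scan(arr, RNifti::pixdim(img)[1:3])
}

#' Write a volume to a NIfTI-1 file
#'
#' Volumes are stored as float64 so that a write/read round trip reproduces
#' intensities bit-exactly; binary masks should be written with
#' \code{datatype = "uint8"}.
#'
#' @param vol A \code{raw_scan}, \code{ct_volume} or bare 3D array.
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @param spacing Voxel spacing in mm; defaults to the scan's own, else 1 mm.
#' @param datatype NIfTI storage type (\code{"double"} or \code{"uint8"}).
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(vol, path, spacing = NULL, datatype = "double") {
  if (inherits(vol, "raw_scan")) {
    spacing <- spacing %||% vol$spacing
    vol <- vol$intensities
  }
  spacing <- spacing %||% c(1, 1, 1)
  arr <- array(as.numeric(vol), dim(vol))
  attr(arr, "pixdim") <- spacing
  img <- RNifti::asNifti(arr, datatype = datatype)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Full preprocessing chain: resample, crop, window, normalize
#'
#' Applies the standard preparation used for every nodule VOI: resample to
#' 1 mm isotropic voxels, crop a 48^3 block centred on the nodule, clip to the
#' [-1024, 400] HU window and rescale to [-1, 1].
#'
#' @param scan A \code{raw_scan}.
#' @param center Nodule centre in mm.
#' @param size VOI shape (default 48^3).
#' @param target_spacing Isotropic spacing (default 1 mm).
#' @param lo,hi HU window.
#' @param method Interpolation for the resampling step.
#' @return A \code{ct_volume} in [-1, 1].
#' @export
preprocess_voi <- function(scan, center, size = c(48L, 48L, 48L),
                           target_spacing = c(1, 1, 1), lo = -1024, hi = 400,
                           method = "linear") {
  s <- resample_isotropic(scan, target_spacing, method = method)
  s <- crop_voi(s, center, size, pad_value = lo)
  window_normalize(s, lo, hi)
}
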