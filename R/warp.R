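#' Readout sequence parameters
#'
#' @param bandwidth_hz_per_px readout bandwidth in Hz/pixel (> 0).
#' @param freq_axis frequency-encoding axis, 1..3.
#' @param polarity +1 or -1; sign convention of the shift (positive
#'   off-resonance shifts signal toward increasing index when +1). The
#'   gradient polarity is acquisition-dependent and not encoded in NIfTI.
#' @return object of class `seq_params`.
#' @export
sequence_params <- function(bandwidth_hz_per_px, freq_axis = 1, polarity = 1) {
  if (!(bandwidth_hz_per_px > 0))
    stop("sequence_params: bandwidth must be > 0 Hz/pixel")
  freq_axis <- as.integer(freq_axis)
  if (!(freq_axis %in% 1:3)) stop("sequence_params: freq_axis must be 1..3")
  if (!(polarity %in% c(-1, 1))) stop("sequence_params: polarity must be +1/-1")
  structure(list(bandwidth_hz_per_px = bandwidth_hz_per_px,
                 freq_axis = freq_axis, polarity = polarity),
            class = "seq_params")
}

#' Displacement field along the frequency-encoding axis
#'
#' Off-resonance translates into a voxel shift along the readout direction:
#' `shift_px = polarity * delta_f / BW` (equivalently
#' `gamma*delta_B / (2*pi*BW)`).
#'
#' @param fm a [fieldmap].
#' @param seq a [sequence_params].
#' @param mask optional [mask3d]; when supplied, the shift is validated for
#'   finiteness inside the mask and set to zero outside it.
#' @return object of class `disp3d` with elements `shift_px` ([vol3d], pixels)
#'   and `freq_axis`; the mm view is available via [disp_mm()].
#' @export
displacement_from_fieldmap <- function(fm, seq, mask = NULL) {
  stopifnot(inherits(fm, "fieldmap"), inherits(seq, "seq_params"))
  hz <- fm$offres_hz$data
  if (!is.null(mask)) {
    stop_if_lattice_mismatch(fm$offres_hz, mask, "field map and mask")
    if (any(!is.finite(hz[mask$data > 0])))
      stop("displacement_from_fieldmap: non-finite field values inside mask")
    hz[mask$data == 0] <- 0
  } else if (any(!is.finite(hz))) {
    stop("displacement_from_fieldmap: non-finite field values")
  }
  shift <- seq$polarity * hz / seq$bandwidth_hz_per_px
  v <- vol_like(shift, fm$offres_hz)
  v$freq_axis <- seq$freq_axis
  structure(list(shift_px = v, freq_axis = seq$freq_axis),
            class = "disp3d")
}

#' Construct a displacement field from a pixel-shift volume
#'
#' @param shift_px [vol3d] of shifts in pixels along `freq_axis`.
#' @param freq_axis frequency-encoding axis, 1..3.
#' @return a `disp3d`.
#' @export
displacement_field <- function(shift_px, freq_axis) {
  stopifnot(inherits(shift_px, "vol3d"))
  freq_axis <- as.integer(freq_axis)
  if (!(freq_axis %in% 1:3))
    stop("displacement_field: freq_axis must be 1..3")
  if (any(!is.finite(shift_px$data)))
    stop("displacement_field: non-finite shift values")
  v <- shift_px; v$freq_axis <- freq_axis
  structure(list(shift_px = v, freq_axis = freq_axis), class = "disp3d")
}

#' Displacement in millimetres
#'
#' @param disp a `disp3d`.
#' @return [vol3d] of shifts in mm (`shift_px * spacing[freq_axis]`).
#' @export
disp_mm <- function(disp) {
  stopifnot(inherits(disp, "disp3d"))
  sp <- disp$shift_px$spacing[disp$freq_axis]
  vol_like(disp$shift_px$data * sp, disp$shift_px)
}

# Derivative along one axis in index units: central differences at interior
# voxels, one-sided at the two boundary slices.
deriv_along_axis <- function(x, axis) {
  d <- dim(x)
  n <- d[axis]
  if (n < 2) return(array(0, d))
  idx <- function(i) {
    a <- vector("list", 3); for (k in 1:3) a[[k]] <- seq_len(d[k])
    a[[axis]] <- i; a
  }
  get <- function(i) do.call(`[`, c(list(x), idx(i), list(drop = FALSE)))
  out <- array(0, d)
  asn <- function(i, val) {
    a <- idx(i)
    out[a[[1]], a[[2]], a[[3]]] <<- val
  }
  if (n > 2) asn(2:(n - 1), (get(3:n) - get(1:(n - 2))) / 2)
  asn(1, get(2) - get(1))
  asn(n, get(n) - get(n - 1))
  out
}

# Resample `arr` along `axis`: output voxel i takes the value of the input at
# position i + delta(i, ...) (index units), by 1D Catmull-Rom cubic or linear
# interpolation; samples outside the grid contribute zero.
resample_shift <- function(arr, delta, axis, method = c("cubic", "linear")) {
  method <- match.arg(method)
  d <- dim(arr)
  ord <- c(axis, setdiff(1:3, axis))
  ap <- aperm(arr, ord)
  dl <- aperm(delta, ord)
  n1 <- dim(ap)[1]
  ncol <- prod(dim(ap)) / n1
  dim(ap) <- c(n1, ncol)
  p <- as.vector(dl) + rep.int(seq_len(n1), ncol)
  colbase <- rep(0:(ncol - 1), each = n1) * n1
  i0 <- floor(p)
  t <- p - i0
  tap <- function(off) {
    i <- i0 + off
    ok <- i >= 1 & i <= n1
    v <- numeric(length(p))
    v[ok] <- ap[i[ok] + colbase[ok]]
    v
  }
  if (method == "linear") {
    out <- tap(0) * (1 - t) + tap(1) * t
  } else {
    t2 <- t * t; t3 <- t2 * t
    out <- tap(-1) * (-0.5 * t3 + t2 - 0.5 * t) +
           tap(0)  * (1.5 * t3 - 2.5 * t2 + 1) +
           tap(1)  * (-1.5 * t3 + 2 * t2 + 0.5 * t) +
           tap(2)  * (0.5 * t3 - 0.5 * t2)
  }
  dim(out) <- dim(aperm(arr, ord))
  aperm(out, order(ord))
}

fold_over_stop <- function(factor_arr, label) {
  bad <- which(factor_arr <= 0)
  if (length(bad)) {
    v <- arrayInd(bad[1], dim(factor_arr))
    stop(sprintf("%s: fold-over (non-positive Jacobian) at voxel (%d, %d, %d)",
                 label, v[1], v[2], v[3]))
  }
  invisible(TRUE)
}

#' Jacobian determinant of a 1D displacement field
#'
#' For distortion restricted to the frequency-encoding axis the Jacobian
#' matrix is diagonal and its determinant reduces to
#' `1 + d(shift)/dx` along that axis, computed with central differences
#' (one-sided at the boundaries); the other axes contribute nothing.
#'
#' @param disp a `disp3d`.
#' @return [vol3d] of unitless determinant values.
#' @export
jacobian_determinant <- function(disp) {
  stopifnot(inherits(disp, "disp3d"))
  s <- disp$shift_px$data
  if (any(!is.finite(s))) stop("jacobian_determinant: non-finite displacement")
  vol_like(1 + deriv_along_axis(s, disp$freq_axis), disp$shift_px)
}

#' Simulate susceptibility distortion (forward warp)
#'
#' Applies the distortion that the scanner would produce: signal at true
#' position x appears at `x + shift(x)`. Implemented as 1D resampling of each
#' line along the frequency-encoding axis at `x - shift(x)` with intensity
#' scaled by the exact Jacobian of that sampling map (`1 - d(shift)/dx`), so
#' that total signal per line is conserved to interpolation accuracy.
#'
#' @param img [vol3d] to distort.
#' @param disp `disp3d` displacement field (pixels).
#' @param method interpolation, `"cubic"` (default) or `"linear"`.
#' @return distorted [vol3d].
#' @export
forward_warp <- function(img, disp, method = "cubic") {
  stopifnot(inherits(img, "vol3d"), inherits(disp, "disp3d"))
  stop_if_lattice_mismatch(img, disp$shift_px, "image and displacement")
  s <- disp$shift_px$data
  if (max(abs(s)) >= dim(img$data)[disp$freq_axis])
    stop("forward_warp: displacement exceeds image extent along freq_axis")
  fac <- 1 - deriv_along_axis(s, disp$freq_axis)
  fold_over_stop(fac, "forward_warp")
  out <- resample_shift(img$data, -s, disp$freq_axis, method) * fac
  vol_like(out, img)
}

#' Correct susceptibility distortion (inverse warp)
#'
#' The correction step: the distorted image is resampled back to undistorted
#' coordinates (sampling at `x + shift(x)` along the frequency-encoding axis)
#' and multiplied by the Jacobian determinant `1 + d(shift)/dx` so that
#' stretched or compressed signal is restored, inverting [forward_warp()] up
#' to interpolation error.
#'
#' @param img_distorted distorted [vol3d].
#' @param disp `disp3d` displacement field (pixels).
#' @param method interpolation, `"cubic"` (default) or `"linear"`.
#' @return corrected [vol3d].
#' @export
unwarp <- function(img_distorted, disp, method = "cubic") {
  stopifnot(inherits(img_distorted, "vol3d"), inherits(disp, "disp3d"))
  stop_if_lattice_mismatch(img_distorted, disp$shift_px,
                           "image and displacement")
  s <- disp$shift_px$data
  detj <- 1 + deriv_along_axis(s, disp$freq_axis)
  fold_over_stop(detj, "unwarp")
  out <- resample_shift(img_distorted$data, s, disp$freq_axis, method) * detj
  vol_like(out, img_distorted)
}

# Transport fractional (partial-volume) mask weights with the geometric
# transform, without Jacobian scaling or re-binarization. Used by the
# evaluation pipeline for sub-voxel centroid measurements, mirroring contours
# drawn on continuous images.
warp_soft <- function(weights, disp, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  stopifnot(inherits(weights, "vol3d"), inherits(disp, "disp3d"))
  stop_if_lattice_mismatch(weights, disp$shift_px, "weights and displacement")
  s <- disp$shift_px$data
  der <- deriv_along_axis(s, disp$freq_axis)
  fold_over_stop(if (direction == "forward") 1 - der else 1 + der, "warp_soft")
  delta <- if (direction == "forward") -s else s
  w <- resample_shift(weights$data + 0, delta, disp$freq_axis, "linear")
  vol_like(pmin(pmax(w, 0), 1), weights)
}

# Intensity-weighted centroid of a soft mask, physical mm.
centroid_mm_soft <- function(weights) {
  w <- as.vector(weights$data)
  if (sum(w) <= 0) stop("centroid_mm_soft: empty weights")
  idx <- which(w > 0)
  mm <- voxel_to_mm(weights, idx)
  colSums(mm * w[idx]) / sum(w[idx])
}

#' Warp a binary mask
#'
#' Applies the same geometric transform as [forward_warp()] (direction
#' `"forward"`) or [unwarp()] (direction `"inverse"`) without Jacobian
#' intensity scaling, using linear interpolation, then re-binarizes at 0.5.
#'
#' @param mask [mask3d] to transport.
#' @param disp `disp3d` displacement field.
#' @param direction `"forward"` (distort) or `"inverse"` (correct).
#' @return warped [mask3d].
#' @export
warp_mask <- function(mask, disp, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  stopifnot(inherits(mask, "mask3d"), inherits(disp, "disp3d"))
  stop_if_lattice_mismatch(mask, disp$shift_px, "mask and displacement")
  s <- disp$shift_px$data
  der <- deriv_along_axis(s, disp$freq_axis)
  fold_over_stop(if (direction == "forward") 1 - der else 1 + der, "warp_mask")
  delta <- if (direction == "forward") -s else s
  w <- resample_shift(mask$data + 0, delta, disp$freq_axis, "linear")
  mask3d(w >= 0.5, template = mask)
}
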