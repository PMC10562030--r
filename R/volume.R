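#' 3D volume with voxel spacing, affine and frequency-encoding axis
#'
#' `vol3d` is the carrier for every per-voxel quantity in the package:
#' anatomical images, field maps (Hz), displacement fields, dose grids and
#' masks. Voxel indices are 1-based; physical coordinates are millimetres,
#' obtained by applying the affine to 0-based indices (NIfTI convention).
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3, voxel size in mm (strictly positive).
#' @param affine 4x4 voxel-to-mm matrix; defaults to a diagonal scaling by
#'   `spacing` centred at the origin of the first voxel.
#' @param freq_axis index of the frequency-encoding (readout) axis, 1..3, or
#'   `NA` when not applicable (e.g. dose grids).
#' @return object of class `vol3d`.
#' @export
vol3d <- function(data, spacing = c(1, 1, 1), affine = NULL, freq_axis = NA) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("vol3d: 'data' must be a 3-dimensional array, got ",
         length(dim(data)), " dimension(s)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("vol3d: 'spacing' must be 3 strictly positive values")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) ||
      abs(det(affine[1:3, 1:3, drop = FALSE])) < 1e-12)
    stop("vol3d: affine must be an invertible 4x4 matrix")
  if (!is.na(freq_axis)) {
    freq_axis <- as.integer(freq_axis)
    if (!(freq_axis %in% 1:3))
      stop("vol3d: freq_axis must be 1, 2 or 3 (got ", freq_axis, ")")
  }
  structure(list(data = data, spacing = spacing, affine = affine,
                 freq_axis = freq_axis),
            class = "vol3d")
}

#' Binary mask on the lattice of a `vol3d`
#'
#' @param data logical or 0/1 numeric 3D array.
#' @param template optional `vol3d` supplying spacing/affine.
#' @inheritParams vol3d
#' @return object of class `c("mask3d", "vol3d")`.
#' @export
mask3d <- function(data, template = NULL, spacing = c(1, 1, 1),
                   affine = NULL, freq_axis = NA) {
  if (is.logical(data)) {
    stor <- array(as.integer(data), dim(data))
  } else {
    if (!all(data %in% c(0, 1)))
      stop("mask3d: values must be 0/1")
    stor <- array(as.integer(data), dim(data))
  }
  if (!is.null(template)) {
    stopifnot(inherits(template, "vol3d"))
    if (!all(dim(stor) == dim(template$data)))
      stop("mask3d: grid shape does not match template")
    spacing <- template$spacing; affine <- template$affine
    freq_axis <- template$freq_axis
  }
  v <- vol3d(stor, spacing = spacing, affine = affine, freq_axis = freq_axis)
  class(v) <- c("mask3d", "vol3d")
  v
}

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d, spacing %s mm, freq_axis %s\n",
              class(x)[1], d[1], d[2], d[3],
              paste(format(x$spacing, digits = 3), collapse = "x"),
              ifelse(is.na(x$freq_axis), "-", x$freq_axis)))
  r <- range(x$data)
  cat(sprintf("  range [%g, %g]\n", r[1], r[2]))
  invisible(x)
}

# Replace the data of a volume, keeping its lattice.
vol_like <- function(data, template) {
  v <- vol3d(data, spacing = template$spacing, affine = template$affine,
             freq_axis = template$freq_axis)
  v
}

mask_like <- function(data, template) {
  mask3d(data, template = template)
}

#' Check that two volumes share one lattice
#'
#' @param a,b `vol3d` objects.
#' @param tol tolerance on spacing/affine entries.
#' @return logical.
#' @export
same_lattice <- function(a, b, tol = 1e-5) {
  all(dim(a$data) == dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$affine - b$affine)) <= tol
}

stop_if_lattice_mismatch <- function(a, b, what = "volumes") {
  if (!same_lattice(a, b))
    stop("lattice mismatch: ", what, " must share shape, spacing and affine")
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file with 3 spatial dimensions.
#' @param freq_axis readout axis (1..3) to record on the volume; `NA` if not
#'   applicable. The axis is supplied by the caller because NIfTI headers do
#'   not reliably encode the readout direction.
#' @return a [vol3d].
#' @export
read_volume <- function(path, freq_axis = NA) {
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("read_volume: expected a 3D volume, file has ", length(d),
         " dimensions: ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  sp <- abs(RNifti::pixdim(img))[1:3]
  vol3d(array(as.numeric(img), d), spacing = sp, affine = aff,
        freq_axis = freq_axis)
}

#' Read a NIfTI-1 mask
#'
#' Values are binarized at 0.5.
#' @inheritParams read_volume
#' @return a [mask3d].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  mask3d(v$data >= 0.5, template = v)
}

#' Write a volume or mask as NIfTI-1
#'
#' Volumes are stored as 32-bit float, masks as 8-bit unsigned integer.
#'
#' @param vol a [vol3d] or [mask3d].
#' @param path output file path (`.nii` or `.nii.gz`); parent must exist.
#' @param datatype NIfTI storage type; default `"float"` (`"uint8"` for masks).
#' @export
write_volume <- function(vol, path, datatype = NULL) {
  stopifnot(inherits(vol, "vol3d"))
  if (!dir.exists(dirname(path)))
    stop("write_volume: directory does not exist: ", dirname(path))
  if (is.null(datatype))
    datatype <- if (inherits(vol, "mask3d")) "uint8" else "float"
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# ---- morphology / connectivity helpers (6-connectivity) --------------------

# Logical array of same dim: TRUE where all 6 face neighbours (and self) are
# TRUE; out-of-volume counts as FALSE.
erode6 <- function(m) {
  d <- dim(m)
  out <- m
  shift_and <- function(acc, ax, by) {
    idx <- vector("list", 3); for (i in 1:3) idx[[i]] <- seq_len(d[i])
    src <- idx; dst <- idx
    if (by > 0) { dst[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
    else        { dst[[ax]] <- 2:d[ax];       src[[ax]] <- 1:(d[ax] - 1) }
    sh <- array(FALSE, d)
    sh[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    acc & sh
  }
  for (ax in 1:3) { out <- shift_and(out, ax, +1); out <- shift_and(out, ax, -1) }
  out
}

# 6-neighbour linear indices (0-based arithmetic) of a set of voxels,
# returned with the border handled; duplicates allowed.
neighbors6 <- function(idx, d) {
  i0 <- idx - 1L
  ix <- i0 %% d[1]
  iy <- (i0 %/% d[1]) %% d[2]
  iz <- i0 %/% (d[1] * d[2])
  out <- c(
    idx[ix > 0] - 1L, idx[ix < d[1] - 1L] + 1L,
    idx[iy > 0] - d[1], idx[iy < d[2] - 1L] + d[1],
    idx[iz > 0] - d[1] * d[2], idx[iz < d[3] - 1L] + d[1] * d[2]
  )
  out
}

# Label connected components (6-connectivity) of a logical array.
# Returns an integer array, 0 = background.
label_components <- function(m) {
  d <- dim(m)
  lab <- array(0L, d)
  remaining <- which(m)
  cur <- 0L
  seen <- array(FALSE, d)
  for (s in remaining) {
    if (seen[s]) next
    cur <- cur + 1L
    frontier <- s
    seen[s] <- TRUE
    lab[s] <- cur
    while (length(frontier)) {
      nb <- neighbors6(frontier, d)
      nb <- nb[m[nb] & !seen[nb]]
      if (!length(nb)) break
      nb <- unique(nb)
      seen[nb] <- TRUE
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

# Fill interior holes: background voxels not connected to the volume border.
fill_holes <- function(m) {
  d <- dim(m)
  bg <- !m
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  frontier <- which(bg & border)
  outside <- array(FALSE, d)
  outside[frontier] <- TRUE
  while (length(frontier)) {
    nb <- neighbors6(frontier, d)
    nb <- nb[bg[nb] & !outside[nb]]
    if (!length(nb)) break
    nb <- unique(nb)
    outside[nb] <- TRUE
    frontier <- nb
  }
  m | (bg & !outside)
}

#' Head mask by robust thresholding
#'
#' A light-weight stand-in for skull stripping: voxels at or above
#' `fraction` times the robust maximum (99.9th percentile) are kept, the
#' largest 6-connected component is selected, and interior holes are filled.
#'
#' @param magnitude a non-negative [vol3d] (e.g. magnitude or T1 image).
#' @param fraction threshold as a fraction of the robust maximum, in (0,1).
#' @return a [mask3d].
#' @export
threshold_mask <- function(magnitude, fraction = 0.2) {
  stopifnot(inherits(magnitude, "vol3d"))
  if (fraction <= 0 || fraction >= 1)
    stop("threshold_mask: fraction must be in (0,1)")
  x <- magnitude$data
  if (min(x) < 0) stop("threshold_mask: magnitude must be non-negative")
  rmax <- stats::quantile(x, 0.999, names = FALSE)
  if (rmax <= 0)
    stop("threshold_mask: empty mask after thresholding (no signal)")
  m <- x >= fraction * rmax
  if (!any(m)) stop("threshold_mask: empty mask after thresholding")
  lab <- label_components(m)
  if (max(lab) > 1L) {
    sizes <- tabulate(lab[lab > 0L])
    m <- lab == which.max(sizes)
  }
  m <- fill_holes(m)
  mask3d(m, template = magnitude)
}

# Physical (mm) coordinates of given voxel linear indices via the affine
# (0-based index convention).
voxel_to_mm <- function(vol, idx) {
  d <- dim(vol$data)
  i0 <- idx - 1
  ix <- i0 %% d[1]
  iy <- (i0 %/% d[1]) %% d[2]
  iz <- i0 %/% (d[1] * d[2])
  v <- rbind(ix, iy, iz, 1)
  t(vol$affine %*% v)[, 1:3, drop = FALSE]
}
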