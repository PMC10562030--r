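as_data3 <- function(x) if (inherits(x, "vol3d")) x$data else x

#' Normalized mean square error
#'
#' `NMSE = ||pred - ref||^2 / ||ref||^2`, elementwise over the (optional)
#' mask. Reported as a fraction; multiply by 100 for percent. No hidden
#' normalization: scaling both images by the same factor leaves it unchanged,
#' scaling only the prediction does not.
#'
#' @param pred,ref [vol3d] or arrays on one lattice.
#' @param mask optional [mask3d] restricting the comparison.
#' @return non-negative scalar; 0 iff identical inside the mask.
#' @export
nmse <- function(pred, ref, mask = NULL) {
  p <- as_data3(pred); r <- as_data3(ref)
  if (!all(dim(p) == dim(r))) stop("nmse: shape mismatch")
  if (!is.null(mask)) {
    m <- as_data3(mask) > 0
    p <- p[m]; r <- r[m]
  }
  den <- sum(r^2)
  if (den == 0) stop("nmse: reference has zero norm inside the mask")
  sum((p - r)^2) / den
}

#' Structural similarity index
#'
#' Two modes are provided. `"global"` evaluates the SSIM formula once over
#' the whole volume with stabilizers `c1 = c1_factor * L` and
#' `c2 = c2_factor * L` (constants linear in the dynamic range `L`).
#' `"windowed"` is the conventional local form: the formula is evaluated in a
#' cubic moving window with the squared stabilizers `c1 = (c1_factor * L)^2`,
#' `c2 = (c2_factor * L)^2` and averaged over the volume.
#'
#' @param pred,ref [vol3d] or arrays on one lattice.
#' @param L dynamic range; defaults to the maximum voxel intensity of `ref`.
#' @param mode `"global"` (default) or `"windowed"`.
#' @param window window edge length in voxels (windowed mode).
#' @param c1_factor,c2_factor stabilizer factors (defaults 0.01 and 0.03).
#' @return scalar in `[-1, 1]`; 1 iff the images are identical.
#' @export
ssim <- function(pred, ref, L = NULL, mode = c("global", "windowed"),
                 window = 7, c1_factor = 0.01, c2_factor = 0.03) {
  mode <- match.arg(mode)
  p <- as_data3(pred); r <- as_data3(ref)
  if (!all(dim(p) == dim(r))) stop("ssim: shape mismatch")
  if (is.null(L)) L <- max(r)
  if (L <= 0) stop("ssim: dynamic range L must be positive")
  if (mode == "global") {
    c1 <- c1_factor * L; c2 <- c2_factor * L
    mx <- mean(r); my <- mean(p)
    vx <- mean((r - mx)^2); vy <- mean((p - my)^2)
    cxy <- mean((r - mx) * (p - my))
    (2 * mx * my + c1) * (2 * cxy + c2) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
  } else {
    c1 <- (c1_factor * L)^2; c2 <- (c2_factor * L)^2
    bm <- function(x) box_mean(x, window)
    mx <- bm(r); my <- bm(p)
    vx <- bm(r * r) - mx^2; vy <- bm(p * p) - my^2
    cxy <- bm(r * p) - mx * my
    s <- (2 * mx * my + c1) * (2 * cxy + c2) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
    mean(s)
  }
}

# Separable moving-average (box) filter with edge renormalization.
box_mean <- function(x, w) {
  h <- floor(w / 2)
  d <- dim(x)
  ones <- array(1, d)
  f1 <- function(a, ax) {
    ord <- c(ax, setdiff(1:3, ax))
    m <- aperm(a, ord)
    dm <- dim(m); dim(m) <- c(dm[1], prod(dm[-1]))
    cs <- apply(m, 2, cumsum)
    n1 <- dm[1]
    hi <- pmin(seq_len(n1) + h, n1)
    lo <- pmax(seq_len(n1) - h, 1) - 1
    res <- cs[hi, , drop = FALSE] -
      rbind(matrix(0, sum(lo == 0), ncol(cs)),
            cs[lo[lo > 0], , drop = FALSE])
    dim(res) <- dm
    aperm(res, order(ord))
  }
  num <- x; den <- ones
  for (ax in 1:3) { num <- f1(num, ax); den <- f1(den, ax) }
  num / den
}

#' Sorensen-Dice coefficient of two masks
#'
#' @param a,b [mask3d] on one lattice.
#' @return `2|A.B| / (|A| + |B|)` in `[0, 1]`.
#' @export
dice <- function(a, b) {
  ma <- as_data3(a) > 0; mb <- as_data3(b) > 0
  if (!all(dim(ma) == dim(mb))) stop("dice: shape mismatch")
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0) stop("dice: both masks empty (undefined)")
  2 * sum(ma & mb) / (na + nb)
}

surface_voxels <- function(m) {
  s <- m & !erode6(m)
  if (!any(s)) s <- m   # single voxels / thin structures
  which(s)
}

#' Hausdorff distance between two masks (mm)
#'
#' Surface-to-surface distances in physical millimetres; surfaces are the
#' mask voxels minus their 6-neighbourhood erosion. Both the maximum (HD) and
#' the 95th-percentile (HD95) of the directed distances are reported, the
#' latter as the larger of the two directed 95th percentiles.
#'
#' @param a,b non-empty [mask3d] on one lattice.
#' @return named numeric vector `c(hd = , hd95 = )` in mm.
#' @export
hausdorff <- function(a, b) {
  stopifnot(inherits(a, "mask3d"), inherits(b, "mask3d"))
  stop_if_lattice_mismatch(a, b, "masks")
  ma <- a$data > 0; mb <- b$data > 0
  if (!any(ma) || !any(mb)) stop("hausdorff: empty mask")
  pa <- voxel_to_mm(a, surface_voxels(ma))
  pb <- voxel_to_mm(b, surface_voxels(mb))
  dmin <- function(p, q) {
    # min distance from each row of p to q, chunked to bound memory
    out <- numeric(nrow(p))
    step <- max(1L, floor(2e7 / nrow(q)))
    qs <- rowSums(q^2)
    for (i in seq(1, nrow(p), by = step)) {
      j <- i:min(i + step - 1, nrow(p))
      g <- p[j, , drop = FALSE]
      d2 <- outer(rowSums(g^2), qs, "+") - 2 * g %*% t(q)
      out[j] <- sqrt(pmax(0, apply(d2, 1, min)))
    }
    out
  }
  dab <- dmin(pa, pb)
  dba <- dmin(pb, pa)
  c(hd = max(dab, dba),
    hd95 = max(stats::quantile(dab, 0.95, names = FALSE),
               stats::quantile(dba, 0.95, names = FALSE)))
}

#' Centroid of a mask in physical mm
#' @param m non-empty [mask3d].
#' @return numeric length-3, mm.
#' @export
centroid_mm <- function(m) {
  stopifnot(inherits(m, "mask3d"))
  idx <- which(m$data > 0)
  if (!length(idx)) stop("centroid_mm: empty mask")
  colMeans(voxel_to_mm(m, idx))
}

#' Centroid shift between two masks
#'
#' Difference of intensity-unweighted centroids, `centroid(b) - centroid(a)`,
#' per axis in physical mm.
#'
#' @param a,b non-empty [mask3d] on one lattice.
#' @return numeric length-3, mm.
#' @export
centroid_shift <- function(a, b) {
  stop_if_lattice_mismatch(a, b, "masks")
  centroid_mm(b) - centroid_mm(a)
}

#' Mask volume in cc
#'
#' @param a [mask3d].
#' @return voxel count times voxel volume, in cubic centimetres.
#' @export
volume_cc <- function(a) {
  stopifnot(inherits(a, "vol3d"))
  sum(a$data > 0) * prod(a$spacing) / 1000
}
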