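#' Proton gyromagnetic ratio over 2*pi, Hz per Tesla
#' @export
GAMMA_OVER_2PI_HZ_PER_T <- 42577478.518

#' Dual-echo phase pair
#'
#' Bundles two phase volumes (radians) with their echo times. The off-resonance
#' field is obtained from the phase evolution between the echoes:
#' `delta_B = delta_phi / (gamma * delta_TE)`, i.e. in frequency units
#' `delta_f = delta_phi / (2*pi*delta_TE)`.
#'
#' @param phase_te1,phase_te2 [vol3d] phase volumes in radians, one lattice.
#' @param te1,te2 echo times in ms, `te2 > te1 > 0`.
#' @return object of class `phase_pair`.
#' @export
phase_pair <- function(phase_te1, phase_te2, te1, te2) {
  stopifnot(inherits(phase_te1, "vol3d"), inherits(phase_te2, "vol3d"))
  if (!(te2 > te1 && te1 > 0))
    stop("phase_pair: echo times must satisfy te2 > te1 > 0 (ms)")
  stop_if_lattice_mismatch(phase_te1, phase_te2, "phase volumes")
  structure(list(phase_te1 = phase_te1, phase_te2 = phase_te2,
                 te1 = te1, te2 = te2),
            class = "phase_pair")
}

#' Off-resonance field map
#'
#' Stored in Hz (`delta_f = gamma/(2*pi) * delta_B`); the Tesla view is derived
#' through the gyromagnetic ratio. Storing Hz avoids carrying gamma through
#' the displacement computation, whose bandwidth is quoted in Hz/pixel.
#'
#' @param offres_hz [vol3d] of off-resonance values in Hz.
#' @param b0 main field strength in Tesla (metadata).
#' @param gamma_over_2pi gyromagnetic ratio / 2*pi in Hz/T.
#' @return object of class `fieldmap`.
#' @export
fieldmap <- function(offres_hz, b0 = 3,
                     gamma_over_2pi = GAMMA_OVER_2PI_HZ_PER_T) {
  stopifnot(inherits(offres_hz, "vol3d"), b0 > 0, gamma_over_2pi > 0)
  structure(list(offres_hz = offres_hz, b0 = b0,
                 gamma_over_2pi = gamma_over_2pi),
            class = "fieldmap")
}

#' @export
print.fieldmap <- function(x, ...) {
  cat(sprintf("<fieldmap> B0 = %g T, off-resonance range [%.2f, %.2f] Hz\n",
              x$b0, min(x$offres_hz$data), max(x$offres_hz$data)))
  invisible(x)
}

#' Field map in Tesla
#'
#' @param fm a [fieldmap].
#' @return [vol3d] of `delta_B` in Tesla.
#' @export
fieldmap_tesla <- function(fm) {
  stopifnot(inherits(fm, "fieldmap"))
  vol_like(fm$offres_hz$data / fm$gamma_over_2pi, fm$offres_hz)
}

# Wrap angles to (-pi, pi].
wrap_phase <- function(x) x - 2 * pi * ceiling((x - pi) / (2 * pi))

#' Wrapped phase difference of a dual-echo pair
#'
#' Elementwise `phase(TE2) - phase(TE1)`, re-wrapped to `(-pi, pi]` (the
#' difference of two wrapped phases is itself wrapped).
#'
#' @param pair a [phase_pair].
#' @return [vol3d] in radians, wrapped.
#' @export
phase_difference <- function(pair) {
  stopifnot(inherits(pair, "phase_pair"))
  vol_like(wrap_phase(pair$phase_te2$data - pair$phase_te1$data),
           pair$phase_te1)
}

#' Spatial phase unwrapping by seeded region growing
#'
#' Starting from a seed voxel, the wrapped phase difference is unwrapped by
#' growing a front through the mask; each new voxel receives the 2*pi multiple
#' that brings it within pi of the mean of its already-unwrapped neighbours.
#' The output is defined up to one global 2*pi multiple. The seed is the
#' highest-magnitude voxel when a magnitude image is supplied, otherwise the
#' mask voxel nearest the mask centroid.
#'
#' @param dphi [vol3d] wrapped phase difference, values in `(-pi, pi]`.
#' @param mask [mask3d] region to unwrap (e.g. brain mask).
#' @param magnitude optional [vol3d] used to pick the seed voxel.
#' @return [vol3d] of unwrapped phase (radians); voxels outside the mask keep
#'   their input value.
#' @export
unwrap_delta_phi <- function(dphi, mask, magnitude = NULL) {
  stopifnot(inherits(dphi, "vol3d"), inherits(mask, "mask3d"))
  stop_if_lattice_mismatch(dphi, mask, "phase and mask")
  m <- mask$data > 0
  if (!any(m)) stop("unwrap_delta_phi: empty mask")
  d <- dim(m)
  x <- dphi$data
  if (!is.null(magnitude)) {
    stop_if_lattice_mismatch(dphi, magnitude, "phase and magnitude")
    mag <- magnitude$data
    mag[!m] <- -Inf
    seed <- which.max(mag)
  } else {
    idx <- which(m)
    ctr <- colMeans(voxel_to_mm(dphi, idx))
    mm <- voxel_to_mm(dphi, idx)
    seed <- idx[which.min(rowSums(sweep(mm, 2, ctr)^2))]
  }
  out <- x
  visited <- array(FALSE, d)
  visited[seed] <- TRUE
  frontier <- seed
  while (length(frontier)) {
    nb <- neighbors6(frontier, d)
    nb <- unique(nb[m[nb] & !visited[nb]])
    if (!length(nb)) {
      # disconnected region of the mask: restart from an unvisited voxel
      left <- which(m & !visited)
      if (!length(left)) break
      frontier <- left[1]
      visited[frontier] <- TRUE
      next
    }
    # mean unwrapped value over the visited 6-neighbours of each new voxel
    refsum <- numeric(length(nb))
    refcnt <- numeric(length(nb))
    i0 <- nb - 1L
    ix <- i0 %% d[1]; iy <- (i0 %/% d[1]) %% d[2]; iz <- i0 %/% (d[1] * d[2])
    offs <- list(c(-1L, ix > 0), c(1L, ix < d[1] - 1L),
                 c(-d[1], iy > 0), c(d[1], iy < d[2] - 1L),
                 c(-d[1] * d[2], iz > 0), c(d[1] * d[2], iz < d[3] - 1L))
    for (o in offs) {
      ok <- as.logical(o[-1])
      cand <- nb[ok] + o[1]
      use <- visited[cand]
      w <- which(ok)[use]
      refsum[w] <- refsum[w] + out[cand[use]]
      refcnt[w] <- refcnt[w] + 1
    }
    ref <- refsum / pmax(refcnt, 1)
    out[nb] <- x[nb] + 2 * pi * round((ref - x[nb]) / (2 * pi))
    visited[nb] <- TRUE
    frontier <- nb
  }
  vol_like(out, dphi)
}

#' Field map from an unwrapped phase difference
#'
#' Converts phase evolution between two echoes into off-resonance frequency:
#' `delta_f = delta_phi / (2*pi * (TE2 - TE1))`, with echo times in ms
#' (converted internally to seconds). Equivalently
#' `delta_B = delta_phi / (gamma * delta_TE)` in Tesla.
#'
#' @param dphi_unwrapped [vol3d], unwrapped phase difference in radians.
#' @param te1,te2 echo times in ms, `te2 > te1`.
#' @param b0 main field strength in Tesla (metadata on the result).
#' @param gamma_over_2pi gyromagnetic ratio / 2*pi in Hz/T.
#' @return a [fieldmap] in Hz.
#' @export
fieldmap_from_phase <- function(dphi_unwrapped, te1, te2, b0 = 3,
                                gamma_over_2pi = GAMMA_OVER_2PI_HZ_PER_T) {
  stopifnot(inherits(dphi_unwrapped, "vol3d"))
  if (!(te2 > te1)) stop("fieldmap_from_phase: te2 must exceed te1")
  dte_s <- (te2 - te1) * 1e-3
  hz <- dphi_unwrapped$data / (2 * pi * dte_s)
  fieldmap(vol_like(hz, dphi_unwrapped), b0 = b0,
           gamma_over_2pi = gamma_over_2pi)
}
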