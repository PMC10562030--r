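#' Configuration for the synthetic susceptibility head phantom
#'
#' The phantom emulates, at natural scale, the anatomy that makes
#' vestibular-schwannoma imaging distortion-sensitive: an ellipsoidal head
#' (soft tissue) with a thin skull shell; on each side an auditory canal
#' entering laterally, a middle-ear cavity and petrous air cells at its
#' medial end, and a mastoid air-cell complex behind it (together the
#' pneumatized temporal bone, the dominant susceptibility load near the
#' target); a nasal cavity; and a roughly spherical hyperintense target
#' abutting the medial end of the right canal, the
#' cerebellopontine-angle position of a vestibular schwannoma.
#' Susceptibility defaults are SI volume susceptibilities in ppm (air +0.36,
#' soft tissue -9.05, cortical bone -11.4).
#'
#' @param n grid size, length 3 (each >= 32).
#' @param spacing voxel size in mm, each within 0.5..2.
#' @param b0 main field strength, Tesla.
#' @param b0_axis grid axis aligned with the main field (default 3).
#' @param chi_air,chi_tissue,chi_bone susceptibilities, ppm.
#' @param head_frac head ellipsoid semi-axes as fractions of the half-FOV.
#' @param skull_mm skull shell thickness, mm.
#' @param canal_radius_mm,canal_length_mm auditory canal tube geometry, mm.
#' @param mastoid_mm semi-axes of the mastoid air-cell complex behind each
#'   canal entry, mm.
#' @param middle_ear_mm radius of the middle-ear cavity at the canal's
#'   medial end, mm.
#' @param petrous_mm radius of the petrous air cells between middle ear and
#'   mastoid, mm.
#' @param nasal_mm nasal cavity semi-axes, mm.
#' @param target_cc nominal target volume, cc (randomized +/- `target_jitter`).
#' @param target_jitter relative jitter on the target volume.
#' @param target_abut gap between the canal end and the target centre, as a
#'   fraction of the target equivalent radius (small = abutting the canal).
#' @param head_jitter relative jitter (uniform, +/-) on the head semi-axes.
#'   Kept smaller than `geom_jitter`: the head's shape sets a global
#'   demagnetization field, and natural inter-subject variation of it is
#'   modest.
#' @param geom_jitter relative jitter (uniform, +/-) applied per case to the
#'   air-cavity geometry, so that every seed produces a distinct anatomy and
#'   induced field.
#' @param noise_sd Gaussian noise s.d. on the anatomical image (intensity
#'   units; tissue = 1).
#' @param bias_amp amplitude of the smooth multiplicative bias field.
#' @param smooth_mm Gaussian smoothing applied to the piecewise anatomical
#'   contrast, mm (keeps the image band-limited).
#' @param chi_smooth_mm Gaussian smoothing applied to the susceptibility map
#'   before the dipole convolution, mm. Models the partial-volume
#'   band-limiting of real air-tissue interfaces at voxel scale; the stored
#'   `chi` map itself stays exactly piecewise.
#' @param pad_voxels zero-padding per side for the Fourier dipole convolution.
#' @return a list of class `phantom_config`.
#' @export
phantom_config <- function(n = c(96, 96, 96), spacing = c(1.25, 1.25, 1.25),
                           b0 = 3, b0_axis = 3,
                           chi_air = 0.36, chi_tissue = -9.05,
                           chi_bone = -11.4,
                           head_frac = c(0.72, 0.86, 0.78),
                           skull_mm = 2.5,
                           canal_radius_mm = 3.5, canal_length_mm = 22,
                           mastoid_mm = c(8, 12, 10),
                           middle_ear_mm = 4.8, petrous_mm = 4,
                           nasal_mm = c(7, 10, 7),
                           target_cc = 2.7, target_jitter = 0.25,
                           target_abut = 0.35,
                           head_jitter = 0.06, geom_jitter = 0.12,
                           noise_sd = 0.02, bias_amp = 0.1,
                           smooth_mm = 1.0, chi_smooth_mm = 1.6,
                           pad_voxels = 32) {
  structure(as.list(environment()), class = "phantom_config")
}

# FFT sample frequencies in cycles/mm for n samples at spacing d.
fftfreqs <- function(n, d = 1) {
  i <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  i / (n * d)
}

# Expand a per-axis vector to a full 3D array along `ax`.
axis_array <- function(v, d, ax) {
  others <- setdiff(1:3, ax)
  a <- array(rep(v, times = prod(d[others])), c(d[ax], d[others]))
  aperm(a, order(c(ax, others)))
}

# Gaussian smoothing via FFT (periodic boundaries; sigma in mm).
gaussian_smooth <- function(x, spacing, sigma_mm) {
  if (sigma_mm <= 0) return(x)
  d <- dim(x)
  H <- array(1, d)
  for (ax in 1:3) {
    f <- fftfreqs(d[ax], spacing[ax])
    H <- H * axis_array(exp(-2 * pi^2 * sigma_mm^2 * f^2), d, ax)
  }
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / prod(d)
}

#' Generate a synthetic susceptibility head phantom
#'
#' Deterministic under a seed: the same seed and configuration reproduce the
#' phantom bit for bit. The target is placed medially to the end of the right
#' ear canal (the vestibular-schwannoma position), with volume randomized
#' within `target_jitter` of `target_cc`.
#'
#' @param config a [phantom_config].
#' @param seed integer seed.
#' @return object of class `psd_phantom` with elements `chi` (ppm, [vol3d]),
#'   `anat` (arbitrary units), `head_mask`, `target_mask`, `air_mask`
#'   ([mask3d]), `b0`, `b0_axis`, `seed`, `config`.
#' @export
make_head_phantom <- function(config = phantom_config(), seed = 1) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$n; sp <- config$spacing
  if (any(n < 32)) stop("make_head_phantom: grid must be at least 32^3")
  if (any(sp < 0.5 | sp > 2))
    stop("make_head_phantom: voxel spacing must be within 0.5..2 mm")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  # mm coordinates centred on the grid
  X <- axis_array((seq_len(n[1]) - (n[1] + 1) / 2) * sp[1], n, 1)
  Y <- axis_array((seq_len(n[2]) - (n[2] + 1) / 2) * sp[2], n, 2)
  Z <- axis_array((seq_len(n[3]) - (n[3] + 1) / 2) * sp[3], n, 3)

  jit <- function(k = 1) 1 + stats::runif(k, -config$geom_jitter,
                                          config$geom_jitter)
  half_fov <- n * sp / 2
  ax <- config$head_frac * half_fov *
    (1 + stats::runif(3, -config$head_jitter, config$head_jitter))
  ell <- function(a) (X / a[1])^2 + (Y / a[2])^2 + (Z / a[3])^2
  head <- ell(ax) <= 1
  inner <- ell(pmax(ax - config$skull_mm, 1)) <= 1
  skull <- head & !inner

  # auditory canals: tubes along +x/-x, slightly posterior of centre
  canal_r <- config$canal_radius_mm * jit()
  canal_len <- config$canal_length_mm * jit()
  yc <- 0.08 * ax[2] * jit(); zc <- 0
  tube_r2 <- (Y - yc)^2 + (Z - zc)^2
  x_surf <- ax[1] * sqrt(pmax(0, 1 - (yc / ax[2])^2 - (zc / ax[3])^2))
  end_x <- x_surf - canal_len           # medial canal end (right side)
  canal_R <- tube_r2 <= canal_r^2 & X >= end_x & X <= ax[1]
  canal_L <- tube_r2 <= canal_r^2 & X <= -end_x & X >= -ax[1]
  # pneumatized temporal bone: middle ear at the canal end, petrous cells,
  # and the mastoid complex behind the canal entry
  me_r <- config$middle_ear_mm * jit()
  pe_r <- config$petrous_mm * jit()
  mas <- config$mastoid_mm * jit(3)
  sphere <- function(cx, cy, cz, r)
    (X - cx)^2 + (Y - cy)^2 + (Z - cz)^2 <= r^2
  tb <- function(sgn) {
    sphere(sgn * (end_x + 5), yc + 5.5, zc, me_r) |
      sphere(sgn * (end_x + 10), yc + 9, zc - 2, pe_r) |
      (((X - sgn * (x_surf - 8)) / mas[1])^2 + ((Y - (yc + 11)) / mas[2])^2 +
         ((Z - (zc - 2)) / mas[3])^2 <= 1)
  }
  # nasal cavity: anterior midline pocket
  nc <- c(0, -0.75 * ax[2], -0.15 * ax[3])
  nas <- config$nasal_mm * jit(3)
  nasal <- ((X - nc[1]) / nas[1])^2 + ((Y - nc[2]) / nas[2])^2 +
    ((Z - nc[3]) / nas[3])^2 <= 1
  air <- (canal_R | canal_L | tb(1) | tb(-1) | nasal) & inner

  # target: ellipsoid of randomized volume medial to the right canal end
  vol_cc <- config$target_cc * (1 + stats::runif(1, -config$target_jitter,
                                                 config$target_jitter))
  r_eq <- (3 * vol_cc * 1000 / (4 * pi))^(1 / 3)   # mm
  ar <- stats::runif(3, 0.85, 1.15)
  ar <- ar / prod(ar)^(1 / 3)
  tc <- c(end_x - config$target_abut * r_eq, yc, zc)
  tgt <- ((X - tc[1]) / (r_eq * ar[1]))^2 +
    ((Y - tc[2]) / (r_eq * ar[2]))^2 +
    ((Z - tc[3]) / (r_eq * ar[3]))^2 <= 1
  tgt <- tgt & inner & !air
  got_cc <- sum(tgt) * prod(sp) / 1000
  if (got_cc < (1 - 0.25) * vol_cc || got_cc > (1 + 0.25) * vol_cc)
    stop(sprintf(
      "make_head_phantom: target volume %.2f cc not realizable on this grid (wanted %.2f cc)",
      got_cc, vol_cc))

  chi <- array(config$chi_air, n)
  chi[head] <- config$chi_tissue
  chi[skull & !air] <- config$chi_bone
  chi[air] <- config$chi_air

  anat <- array(0, n)
  anat[head] <- 1
  anat[skull & !air] <- 0.25
  anat[air] <- 0
  anat[tgt] <- 1.6
  anat <- gaussian_smooth(anat, sp, config$smooth_mm)
  bias <- gaussian_smooth(array(stats::rnorm(prod(n)), n), sp, 12)
  bias <- bias / max(abs(bias)) * config$bias_amp
  anat <- anat * (1 + bias)
  if (config$noise_sd > 0)
    anat <- anat + stats::rnorm(prod(n), sd = config$noise_sd)
  anat <- pmax(anat, 0)

  tv <- function(d) vol3d(d, spacing = sp)
  structure(list(
    chi = tv(chi),
    anat = tv(anat),
    head_mask = mask3d(head, template = tv(chi)),
    target_mask = mask3d(tgt, template = tv(chi)),
    air_mask = mask3d(air, template = tv(chi)),
    air_masks = list(canal_right = mask3d(canal_R & inner, template = tv(chi)),
                     canal_left = mask3d(canal_L & inner, template = tv(chi)),
                     temporal_right = mask3d(tb(1) & inner, template = tv(chi)),
                     temporal_left = mask3d(tb(-1) & inner, template = tv(chi)),
                     nasal = mask3d(nasal & inner, template = tv(chi))),
    b0 = config$b0, b0_axis = config$b0_axis,
    seed = seed, config = config), class = "psd_phantom")
}

#' @export
print.psd_phantom <- function(x, ...) {
  cat(sprintf("<psd_phantom> %s @ %s mm, B0 = %g T, target %.2f cc (seed %d)\n",
              paste(dim(x$chi$data), collapse = "x"),
              paste(format(x$chi$spacing, digits = 3), collapse = "x"),
              x$b0, volume_cc(x$target_mask), x$seed))
  invisible(x)
}

#' Susceptibility-induced B0 field by Fourier dipole convolution
#'
#' Computes the static field perturbation of a susceptibility distribution in
#' k-space: `dB(k) = B0 * chi(k) * (1/3 - kz^2/|k|^2)` with the k = 0 term set
#' to zero (the field is defined up to a constant; this convention makes it
#' zero-mean over the padded grid). The volume is padded with the background
#' susceptibility before the FFT to suppress the periodic-boundary artifact.
#'
#' @param chi [vol3d] of susceptibility in ppm, or a `psd_phantom`.
#' @param b0 field strength, Tesla (taken from the phantom if given one).
#' @param b0_axis grid axis along the main field.
#' @param pad_voxels zero-padding per side (default 32; 0 disables).
#' @param pad_value background susceptibility used for padding, ppm.
#' @param gamma_over_2pi gyromagnetic ratio / 2*pi, Hz/T.
#' @return a [fieldmap] in Hz on the unpadded lattice.
#' @export
field_from_susceptibility <- function(chi, b0 = 3, b0_axis = 3,
                                      pad_voxels = 32, pad_value = NULL,
                                      gamma_over_2pi = GAMMA_OVER_2PI_HZ_PER_T) {
  if (inherits(chi, "psd_phantom")) {
    ph <- chi
    b0 <- ph$b0; b0_axis <- ph$b0_axis
    pad_voxels <- ph$config$pad_voxels
    if (is.null(pad_value)) pad_value <- ph$config$chi_air
    chi <- ph$chi
    if (ph$config$chi_smooth_mm > 0)
      chi <- vol_like(gaussian_smooth(chi$data, chi$spacing,
                                      ph$config$chi_smooth_mm), chi)
  }
  stopifnot(inherits(chi, "vol3d"))
  if (!(b0 > 0)) stop("field_from_susceptibility: b0 must be positive")
  if (any(!is.finite(chi$data)))
    stop("field_from_susceptibility: non-finite susceptibility")
  sp <- chi$spacing
  if (max(sp) / min(sp) > 4)
    warning("field_from_susceptibility: severe spacing anisotropy (> 4:1)")
  if (is.null(pad_value)) pad_value <- chi$data[1]
  d <- dim(chi$data)
  dp <- d + 2L * pad_voxels
  x <- array(pad_value, dp)
  i1 <- pad_voxels + seq_len(d[1])
  i2 <- pad_voxels + seq_len(d[2])
  i3 <- pad_voxels + seq_len(d[3])
  x[i1, i2, i3] <- chi$data

  K1 <- axis_array(fftfreqs(dp[1], sp[1]), dp, 1)
  K2 <- axis_array(fftfreqs(dp[2], sp[2]), dp, 2)
  K3 <- axis_array(fftfreqs(dp[3], sp[3]), dp, 3)
  Ksq <- K1^2 + K2^2 + K3^2
  Kpar <- switch(b0_axis, K1, K2, K3)
  Dk <- 1 / 3 - Kpar^2 / Ksq
  Dk[Ksq == 0] <- 0
  fld <- Re(stats::fft(stats::fft(x) * Dk, inverse = TRUE)) / prod(dp)
  fld <- fld[i1, i2, i3]
  hz <- gamma_over_2pi * b0 * 1e-6 * fld
  fieldmap(vol_like(hz, chi), b0 = b0, gamma_over_2pi = gamma_over_2pi)
}

#' Ground-truth distorted/undistorted pair from a phantom
#'
#' Composes the forward physics: dipole field from the susceptibility map,
#' displacement at the stated bandwidth, Jacobian-compensated forward warp of
#' the anatomical image and geometric warp of the target mask.
#'
#' @param phantom a `psd_phantom`.
#' @param seq a [sequence_params].
#' @return list of class `psd_case`: `anat` (true), `anat_distorted`,
#'   `fieldmap_true`, `disp_true`, `target_mask` (true), `target_distorted`
#'   (binary), `target_distorted_soft` (fractional partial-volume weights,
#'   for sub-voxel centroid measurements), `head_mask`, `seq`, `seed`.
#' @export
make_distorted_pair <- function(phantom, seq) {
  stopifnot(inherits(phantom, "psd_phantom"), inherits(seq, "seq_params"))
  fm <- field_from_susceptibility(phantom)
  disp <- displacement_from_fieldmap(fm, seq)
  anat_d <- tryCatch(forward_warp(phantom$anat, disp),
                     error = function(e) {
                       if (grepl("fold-over", conditionMessage(e)))
                         stop("make_distorted_pair: fold-over; increase the readout bandwidth",
                              call. = FALSE)
                       stop(e)
                     })
  tgt_soft <- warp_soft(vol_like(phantom$target_mask$data + 0,
                                 phantom$target_mask), disp, "forward")
  tgt_d <- mask3d(tgt_soft$data >= 0.5, template = phantom$target_mask)
  structure(list(anat = phantom$anat, anat_distorted = anat_d,
                 fieldmap_true = fm, disp_true = disp,
                 target_mask = phantom$target_mask,
                 target_distorted = tgt_d,
                 target_distorted_soft = tgt_soft,
                 head_mask = phantom$head_mask,
                 seq = seq, seed = phantom$seed),
            class = "psd_case")
}
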