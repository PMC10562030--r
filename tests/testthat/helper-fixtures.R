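# Shared fixtures, built in code. Heavyweight objects are memoised so the
# suite constructs them once.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

# displacement field object from a raw shift array (pixels)
disp_from_array <- function(shift, freq_axis = 1, spacing = c(1, 1, 1)) {
  displacement_field(vol3d(shift, spacing = spacing, freq_axis = freq_axis),
                     freq_axis)
}

# smooth compactly supported 3D blob
smooth_blob <- function(n = 32, width = 5, spacing = c(1, 1, 1)) {
  x <- seq_len(n) - (n + 1) / 2
  g1 <- exp(-x^2 / (2 * width^2))
  a <- outer(outer(g1, g1), g1)
  vol3d(array(a, c(n, n, n)), spacing = spacing, freq_axis = 1)
}

# anti-aliased sphere susceptibility volume for the dipole oracle
aa_sphere <- function(n, fov = 64, a_mm = 10.3, chi_in = 9) {
  sp <- fov / n
  ctr <- (n + 1) / 2
  x <- ((1:n) - ctr) * sp
  X <- array(rep(x, n * n), c(n, n, n))
  Y <- aperm(X, c(2, 1, 3)); Z <- aperm(X, c(3, 2, 1))
  r <- sqrt(X^2 + Y^2 + Z^2)
  m <- array(0, c(n, n, n))
  m[r <= a_mm - sp] <- 1
  shell <- which(abs(r - a_mm) <= sp)
  ai <- arrayInd(shell, c(n, n, n))
  off <- as.matrix(expand.grid(dx = c(-1, 0, 1) / 3, dy = c(-1, 0, 1) / 3,
                               dz = c(-1, 0, 1) / 3))
  frac <- numeric(length(shell))
  for (o in seq_len(nrow(off))) {
    rr <- sqrt(((ai[, 1] - ctr + off[o, 1]) * sp)^2 +
               ((ai[, 2] - ctr + off[o, 2]) * sp)^2 +
               ((ai[, 3] - ctr + off[o, 3]) * sp)^2)
    frac <- frac + (rr <= a_mm)
  }
  m[shell] <- frac / nrow(off)
  list(chi = vol3d(m * chi_in, spacing = rep(sp, 3)),
       r = r, Z = Z, a_mm = a_mm, chi_in = chi_in, sp = sp)
}

# RMS relative error of the dipole field against the exterior closed form
sphere_dipole_rel_err <- function(n, fov = 64, a_mm = 10.3, b0 = 3) {
  s <- aa_sphere(n, fov, a_mm)
  fm <- field_from_susceptibility(s$chi, b0 = b0, b0_axis = 3,
                                  pad_voxels = n %/% 2, pad_value = 0)
  cst <- GAMMA_OVER_2PI_HZ_PER_T * b0 * 1e-6 * s$chi_in
  ana <- cst * a_mm^3 * (3 * (s$Z / s$r)^2 - 1) / (3 * s$r^3)
  ext <- s$r > a_mm + 2 * s$sp
  err <- fm$offres_hz$data[ext] - ana[ext]
  sqrt(mean(err^2)) / sqrt(mean(ana[ext]^2))
}

default_case <- function(seed = 1) {
  memo(paste0("case", seed), {
    ph <- make_head_phantom(phantom_config(), seed = seed)
    make_distorted_pair(ph, sequence_params(220, 1))
  })
}

# One shared desk-scale experiment for the learning/dominance checks.
shared_experiment <- function() {
  memo("experiment", {
    run_experiment(run_config(seed = 20260919))
  })
}

# fractional mask transport (test-local composition helper)
warp_soft2 <- function(arr, disp, direction) {
  ws <- getFromNamespace("warp_soft", "psdcorrect")
  ws(vol3d(arr), disp, direction)$data
}

# Brute-force two-sided exact signed-rank p-value by enumerating all 2^n sign
# assignments (midranks for ties) — independent oracle for the DP version.
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% r
  p_le <- mean(Ws <= W + 1e-12)
  p_ge <- mean(Ws >= W - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}
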