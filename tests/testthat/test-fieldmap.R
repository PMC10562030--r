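test_that("phase difference wraps into (-pi, pi]", {
  d <- c(8, 8, 8)
  p1 <- vol3d(array(0.1, d)); p2 <- vol3d(array(0.4, d))
  pair <- phase_pair(p1, p2, 2.5, 5.0)
  expect_equal(phase_difference(pair)$data, array(0.3, d))

  expect_equal(phase_difference(phase_pair(p1, p1, 2.5, 5.0))$data,
               array(0, d))

  # wrap case, oracle = argument of the complex phasor ratio
  a <- 3.0; b <- -3.0
  pw <- phase_difference(phase_pair(vol3d(array(a, d)), vol3d(array(b, d)),
                                    2.5, 5.0))
  oracle <- Arg(exp(1i * b) * exp(-1i * a))
  expect_equal(pw$data[1], oracle, tolerance = 1e-12)
  expect_equal(pw$data[1], 2 * pi - 6, tolerance = 1e-12)

  # random wrapped differences match the phasor oracle everywhere
  set.seed(4)
  q1 <- array(runif(prod(d), -pi, pi), d)
  q2 <- array(runif(prod(d), -pi, pi), d)
  got <- phase_difference(phase_pair(vol3d(q1), vol3d(q2), 1, 2))$data
  expect_equal(got, Arg(exp(1i * q2) * exp(-1i * q1)), tolerance = 1e-10)
})

test_that("phase_pair validates echo times and lattices", {
  p <- vol3d(array(0, c(4, 4, 4)))
  expect_error(phase_pair(p, p, 5, 2), "te2 > te1")
  expect_error(phase_pair(p, p, -1, 2), "te2 > te1")
  q <- vol3d(array(0, c(5, 4, 4)))
  expect_error(phase_pair(p, q, 1, 2), "lattice")
})

test_that("unwrapping recovers a wrapped ramp up to a global 2*pi multiple", {
  n <- 32
  ramp <- array(rep(seq(0, 3 * pi, length.out = n), n * n), c(n, n, n))
  wrapped <- ramp - 2 * pi * ceiling((ramp - pi) / (2 * pi))
  mask <- mask3d(array(TRUE, c(n, n, n)))
  un <- unwrap_delta_phi(vol3d(wrapped), mask)
  # 1D Itoh oracle along the ramp axis
  itoh <- function(w) { d <- diff(w); d <- d - 2 * pi * round(d / (2 * pi))
                        cumsum(c(w[1], d)) }
  oracle <- itoh(wrapped[, 1, 1])
  resid <- un$data[, 1, 1] - oracle
  expect_lt(diff(range(resid)), 1e-9)                      # same shape
  expect_equal(resid[1] %% (2 * pi), 0, tolerance = 1e-9)  # global 2*pi k
  # smooth ramp with small excursion passes through unchanged
  small <- vol3d(array(rep(seq(0, 2, length.out = n), n * n), c(n, n, n)))
  expect_equal(unwrap_delta_phi(small, mask)$data, small$data,
               tolerance = 1e-12)
})

test_that("unwrapping adds no spurious jumps to noisy constant phase", {
  set.seed(7)
  n <- 24
  x <- array(rnorm(n^3, mean = 0.5, sd = 0.1), c(n, n, n))
  mask <- mask3d(array(TRUE, c(n, n, n)))
  un <- unwrap_delta_phi(vol3d(x), mask)
  expect_equal(un$data, x)  # no voxel needed a 2*pi correction
})

test_that("unwrapping is gauge-invariant under interior 2*pi offsets", {
  n <- 24
  base <- array(rep(seq(-1, 1, length.out = n), n * n), c(n, n, n))
  mask <- mask3d(array(TRUE, c(n, n, n)))
  u0 <- unwrap_delta_phi(vol3d(base), mask)$data
  shifted <- base
  shifted[8:16, 8:16, 8:16] <- shifted[8:16, 8:16, 8:16] + 2 * pi
  shifted <- shifted - 2 * pi * ceiling((shifted - pi) / (2 * pi))
  u1 <- unwrap_delta_phi(vol3d(shifted), mask)$data
  resid <- (u1 - u0) / (2 * pi)
  expect_lt(max(abs(resid - round(mean(resid)))), 1e-9)
  expect_error(unwrap_delta_phi(vol3d(base),
                                mask3d(array(FALSE, c(n, n, n)))), "empty")
})

test_that("field map from phase uses delta-phi / (2*pi*dTE) with TE in ms", {
  d <- c(6, 6, 6)
  expect_equal(fieldmap_from_phase(vol3d(array(0, d)), 2, 3)$offres_hz$data,
               array(0, d))
  expect_equal(
    fieldmap_from_phase(vol3d(array(2 * pi, d)), 2, 3)$offres_hz$data[1],
    1000)
  expect_equal(
    fieldmap_from_phase(vol3d(array(pi, d)), 1, 3.5)$offres_hz$data[1], 200)
  expect_error(fieldmap_from_phase(vol3d(array(0, d)), 3, 2), "te2")
})

test_that("field map is linear in phase and Hz<->Tesla is a bijection", {
  set.seed(2)
  d <- c(6, 6, 6)
  dphi <- vol3d(array(rnorm(prod(d)), d))
  f1 <- fieldmap_from_phase(dphi, 2, 4.3)
  f3 <- fieldmap_from_phase(vol3d(3 * dphi$data), 2, 4.3)
  expect_equal(f3$offres_hz$data, 3 * f1$offres_hz$data, tolerance = 1e-12)
  tesla <- fieldmap_tesla(f1)
  expect_equal(tesla$data * f1$gamma_over_2pi, f1$offres_hz$data,
               tolerance = 1e-12)
})
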