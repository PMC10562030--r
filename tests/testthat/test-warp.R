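test_that("displacement is polarity * field / bandwidth, with mm view", {
  d <- c(8, 8, 8)
  fm <- fieldmap(vol3d(array(440, d), spacing = c(1, 1, 1)))
  disp <- displacement_from_fieldmap(fm, sequence_params(440, 1))
  expect_equal(disp$shift_px$data, array(1, d))

  fm0 <- fieldmap(vol3d(array(0, d)))
  expect_equal(displacement_from_fieldmap(fm0, sequence_params(440, 1))$shift_px$data,
               array(0, d))

  fm2 <- fieldmap(vol3d(array(110, d), spacing = c(1, 1, 1)))
  d2 <- displacement_from_fieldmap(fm2, sequence_params(220, 2, polarity = -1))
  expect_equal(d2$shift_px$data[1], -0.5)
  expect_equal(disp_mm(d2)$data[1], -0.5)

  # linear in the field map
  set.seed(5)
  f <- array(rnorm(prod(d)), d)
  da <- displacement_from_fieldmap(fieldmap(vol3d(f)), sequence_params(100, 1))
  db <- displacement_from_fieldmap(fieldmap(vol3d(2 * f)), sequence_params(100, 1))
  expect_equal(db$shift_px$data, 2 * da$shift_px$data, tolerance = 1e-14)

  fm_bad <- fieldmap(vol3d(array(c(NaN, rep(0, prod(d) - 1)), d)))
  expect_error(displacement_from_fieldmap(fm_bad, sequence_params(100, 1)),
               "non-finite")
  m <- mask3d(array(c(FALSE, rep(TRUE, prod(d) - 1)), d))
  dm <- displacement_from_fieldmap(fm_bad, sequence_params(100, 1), mask = m)
  expect_equal(dm$shift_px$data[1], 0)  # zero outside mask, NaN excluded
})

test_that("Jacobian determinant is 1 + d(shift)/dx along the readout axis", {
  d <- c(16, 8, 8)
  expect_equal(jacobian_determinant(disp_from_array(array(0.7, d)))$data,
               array(1, d))
  lin <- disp_from_array(array(0.1 * (1:16), d))
  j <- jacobian_determinant(lin)$data
  expect_equal(j[2:15, , ], array(1.1, c(14, 8, 8)), tolerance = 1e-12)
  # independent second implementation of the stencil
  set.seed(8)
  s <- array(rnorm(prod(d), sd = 0.1), d)
  j2 <- jacobian_determinant(disp_from_array(s))$data
  oracle <- array(NA_real_, d)
  for (y in 1:8) for (z in 1:8) {
    line <- s[, y, z]
    g <- c(line[2] - line[1], (line[3:16] - line[1:14]) / 2,
           line[16] - line[15])
    oracle[, y, z] <- 1 + g
  }
  expect_equal(j2, oracle, tolerance = 1e-12)
})

test_that("forward warp: identity, translation, conservation", {
  img <- smooth_blob(32)
  zero <- disp_from_array(array(0, c(32, 32, 32)))
  expect_identical(forward_warp(img, zero)$data, img$data)

  k <- disp_from_array(array(3, c(32, 32, 32)))
  fw <- forward_warp(img, k)
  expect_lt(max(abs(fw$data[4:32, , ] - img$data[1:29, , ])), 1e-9)
  expect_true(all(abs(fw$data[1:3, , ]) < 1e-9))  # zero-filled edge

  # sinusoidal shift of 1.5 px amplitude conserves per-line totals
  sh <- array(1.5 * sin(2 * pi * (1:32) / 32), c(32, 32, 32))
  fs <- forward_warp(img, disp_from_array(sh))
  expect_lt(abs(sum(fs$data) - sum(img$data)) / sum(img$data), 0.005)
  line_in <- apply(img$data, c(2, 3), sum)
  line_out <- apply(fs$data, c(2, 3), sum)
  core <- line_in > 0.05 * max(line_in)
  expect_lt(max(abs(line_out[core] - line_in[core]) / line_in[core]), 0.005)
})

test_that("unwarp inverts forward_warp within interpolation error", {
  img <- smooth_blob(32)
  sh <- array(1.2 * sin(2 * pi * (1:32) / 32), c(32, 32, 32))
  dsp <- disp_from_array(sh)
  rt <- unwarp(forward_warp(img, dsp), dsp)
  expect_lt(nmse(rt, img), 0.02)

  zero <- disp_from_array(array(0, c(32, 32, 32)))
  expect_identical(unwarp(img, zero)$data, img$data)

  k <- disp_from_array(array(2, c(32, 32, 32)))
  rtk <- unwarp(forward_warp(img, k), k)
  interior <- rtk$data[5:28, , ] - img$data[5:28, , ]
  expect_lt(max(abs(interior)), 1e-9)
})

test_that("fold-over raises an error naming the voxel", {
  sh <- array(0, c(16, 8, 8))
  sh[7, , ] <- 2.5   # central difference at voxels 6 and 8 is +/-1.25
  img <- vol3d(array(1, c(16, 8, 8)), freq_axis = 1)
  expect_error(forward_warp(img, disp_from_array(sh)), "fold-over.*voxel")
  expect_error(unwarp(img, disp_from_array(sh)), "fold-over")
  expect_error(warp_mask(mask3d(array(TRUE, c(16, 8, 8))),
                         disp_from_array(sh)), "fold-over")
})

test_that("mask warping moves the centroid and round-trips", {
  n <- 32
  x <- seq_len(n) - (n + 1) / 2
  r <- sqrt(outer(outer(x^2, x^2, "+"), x^2, "+"))
  m <- mask3d(array(r <= 5, c(n, n, n)))
  zero <- disp_from_array(array(0, c(n, n, n)))
  expect_identical(warp_mask(m, zero, "forward")$data, m$data)

  one <- disp_from_array(array(1, c(n, n, n)))
  wf <- warp_mask(m, one, "forward")
  expect_equal(centroid_shift(m, wf), c(1, 0, 0), tolerance = 1e-9)

  # round trip of a 10 mm sphere under a smooth field with |dx| <= 2 px:
  # the composed geometric transform is near-identity; the voxelized round
  # trip (one re-binarization in between) additionally pays rasterization
  sh <- disp_from_array(array(1.8 * sin(2 * pi * (1:n) / n), c(n, n, n)))
  soft <- warp_soft2(warp_soft2(m$data + 0, sh, "forward"), sh, "inverse")
  expect_gte(dice(mask3d(soft >= 0.5), m), 0.99)
  rt <- warp_mask(warp_mask(m, sh, "forward"), sh, "inverse")
  expect_gte(dice(rt, m), 0.95)
})
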