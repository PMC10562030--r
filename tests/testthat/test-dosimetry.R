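grid_template <- function(n = 64, sp = 1) {
  aff <- diag(c(sp, sp, sp, 1)); aff[1:3, 4] <- -sp * (n - 1) / 2
  vol3d(array(0, c(n, n, n)), spacing = rep(sp, 3), affine = aff)
}

single_shot <- function(sigma = 5, rx = 12) {
  plan_spec(data.frame(x = 0, y = 0, z = 0, sigma_mm = sigma, weight = 1),
            rx_dose = rx)
}

test_that("Gaussian shot dose: normalization and isodose geometry", {
  tpl <- grid_template(96, 0.5)
  dg <- simulate_gk_dose(single_shot(5), tpl)
  expect_equal(max(dg$dose$data), 24)
  # 12 Gy isosurface is a sphere of radius sigma*sqrt(2 ln 2)
  r12 <- 5 * sqrt(2 * log(2))
  v12 <- sum(dg$dose$data >= 12) * 0.5^3
  expect_equal(v12, 4 / 3 * pi * r12^3, tolerance = 0.02)

  # weight rescaling cancels out
  p2 <- plan_spec(data.frame(x = 0, y = 0, z = 0, sigma_mm = 5, weight = 7),
                  rx_dose = 12)
  expect_equal(simulate_gk_dose(p2, tpl)$dose$data, dg$dose$data,
               tolerance = 1e-12)

  # two far-separated equal shots give two identical lobes
  p3 <- plan_spec(data.frame(x = c(-15, 15), y = 0, z = 0, sigma_mm = 3,
                             weight = 1), rx_dose = 12)
  d3 <- simulate_gk_dose(p3, tpl)$dose$data
  expect_equal(d3, d3[96:1, , ], tolerance = 1e-9)

  p4 <- plan_spec(data.frame(x = 500, y = 0, z = 0, sigma_mm = 3, weight = 1))
  expect_error(simulate_gk_dose(p4, tpl), "outside")
})

test_that("DVH metrics: order statistics and the oversampled oracle", {
  d <- c(10, 10, 10)
  tgt <- mask3d(array(c(rep(TRUE, 50), rep(FALSE, 950)), d))
  uni <- vol3d(array(12, d))
  dv <- dvh_metrics(uni, tgt)
  expect_equal(unname(dv), c(12, 12, 12, 12))

  two <- vol3d(array(0, d)); two$data[1] <- 10; two$data[2] <- 20
  t2 <- mask3d(array(c(TRUE, TRUE, rep(FALSE, 998)), d))
  dv2 <- dvh_metrics(two, t2)
  expect_equal(unname(dv2), c(15, 20, 10, 10))
  expect_error(dvh_metrics(uni, mask3d(array(FALSE, d))), "empty")

  # Gaussian dose over a spherical target vs a 10x-oversampled DVH oracle
  tpl <- grid_template(40, 1)
  dg <- simulate_gk_dose(single_shot(6), tpl)
  x <- ((1:40) - 20.5)
  r <- sqrt(outer(outer(x^2, x^2, "+"), x^2, "+"))
  sph <- mask3d(array(r <= 7, c(40, 40, 40)), template = tpl)
  got <- dvh_metrics(dg, sph)
  set.seed(1)
  # dense sampling inside the continuum sphere
  pts <- matrix(runif(3 * 2e5, -7, 7), ncol = 3)
  pts <- pts[rowSums(pts^2) <= 49, ]
  dose_pts <- 24 * exp(-rowSums(pts^2) / (2 * 36))
  expect_equal(unname(got["d_mean"]), mean(dose_pts), tolerance = 0.01)
  expect_equal(unname(got["d95"]), quantile(dose_pts, 0.05, names = FALSE),
               tolerance = 0.01)

  # ordering invariant on random cases
  set.seed(2)
  for (i in 1:100) {
    doses <- vol3d(array(runif(27, 0, 25), c(3, 3, 3)))
    tm <- mask3d(array(runif(27) < 0.6, c(3, 3, 3)))
    if (!any(tm$data > 0)) next
    m <- dvh_metrics(doses, tm)
    expect_true(m["d_min"] <= m["d95"] + 1e-12)
    expect_true(m["d95"] <= m["d_max"] + 1e-12)
    expect_true(m["d_mean"] <= m["d_max"] + 1e-12)
  }
})

test_that("coverage, Paddick CI and their identity", {
  d <- c(10, 10, 10)
  dose <- vol3d(array(0, d)); dose$data[1:500] <- 20
  tin <- mask3d(array(c(rep(TRUE, 100), rep(FALSE, 900)), d))
  tout <- mask3d(array(c(rep(FALSE, 900), rep(TRUE, 100)), d))
  expect_equal(coverage_tc(dose, tin, 12), 1)
  expect_equal(coverage_tc(dose, tout, 12), 0)
  half <- mask3d(array(c(rep(TRUE, 50), rep(FALSE, 450),
                         rep(TRUE, 50), rep(FALSE, 450)), d))
  expect_equal(coverage_tc(dose, half, 12), 0.5)

  # TV = 100, PIV = 150, TV_PIV = 90 -> PCI = 90^2/(100*150) = 0.54
  dd <- vol3d(array(0, d)); dd$data[1:90] <- 20; dd$data[101:160] <- 20
  tt <- mask3d(array(c(rep(TRUE, 100), rep(FALSE, 900)), d))
  expect_equal(paddick_ci(dd, tt, 12), 0.54)
  expect_equal(paddick_ci(dd, tt, 12),
               coverage_tc(dd, tt, 12) * (90 / 150), tolerance = 1e-12)

  # identity PCI = TC * (TV_PIV / PIV) on random plans
  set.seed(9)
  tpl <- grid_template(32, 1)
  for (i in 1:10) {
    ns <- sample(1:3, 1)
    pl <- plan_spec(data.frame(x = runif(ns, -6, 6), y = runif(ns, -6, 6),
                               z = runif(ns, -6, 6),
                               sigma_mm = runif(ns, 3, 6),
                               weight = runif(ns, 0.5, 2)))
    dg <- simulate_gk_dose(pl, tpl)
    x <- ((1:32) - 16.5)
    r <- sqrt(outer(outer(x^2, x^2, "+"), x^2, "+"))
    tm <- mask3d(array(r <= runif(1, 4, 8), c(32, 32, 32)), template = tpl)
    piv <- sum(dg$dose$data >= 12)
    tvpiv <- sum(dg$dose$data[tm$data > 0] >= 12)
    lhs <- paddick_ci(dg, tm, 12)
    rhs <- coverage_tc(dg, tm, 12) * (tvpiv / piv)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  expect_error(paddick_ci(vol3d(array(1, d)), tin, 12), "isodose")
})

test_that("gradient index: closed forms and scale invariance", {
  # single Gaussian prescribed at 50%: GI = 2*sqrt(2), independent of sigma
  for (sig in c(3, 5, 8)) {
    tpl <- grid_template(round(14 * sig), 0.5)
    gi <- gradient_index(simulate_gk_dose(single_shot(sig), tpl), 12)
    expect_equal(gi, 2 * sqrt(2), tolerance = 0.02 * 2 * sqrt(2))
  }
  # linear radial falloff D = Dmax (1 - r/R), rx = Dmax/2 -> (0.75/0.5)^3
  n <- 80
  x <- ((1:n) - (n + 1) / 2) * 0.5
  r <- sqrt(outer(outer(x^2, x^2, "+"), x^2, "+"))
  R <- 15
  lin <- vol3d(array(pmax(24 * (1 - r / R), 0), c(n, n, n)),
               spacing = c(0.5, 0.5, 0.5))
  expect_equal(gradient_index(lin, 12), 3.375, tolerance = 0.02 * 3.375)
  # voxel-count ratio
  synth <- vol3d(array(c(rep(24, 100), rep(7, 120), rep(0, 80)), c(10, 10, 3)))
  expect_equal(gradient_index(synth, 12), 2.2)
  expect_error(gradient_index(synth, 100), "isodose")
})

test_that("homogeneity index: default and ICRU variants", {
  tpl <- grid_template(48, 1)
  dg <- simulate_gk_dose(single_shot(6), tpl)
  x <- ((1:48) - 24.5)
  r <- sqrt(outer(outer(x^2, x^2, "+"), x^2, "+"))
  tgt <- mask3d(array(r <= 6 * sqrt(2 * log(2)), c(48, 48, 48)),
                template = tpl)
  expect_equal(homogeneity_index(dg, tgt, 12), 2, tolerance = 1e-9)

  d <- c(8, 8, 8)
  uni <- vol3d(array(12, d)); um <- mask3d(array(TRUE, d))
  expect_equal(homogeneity_index(uni, um, 12), 1)
  expect_equal(homogeneity_index(uni, um, 12, mode = "icru"), 0)
})

test_that("paired Wilcoxon comparison matches exhaustive enumeration", {
  # n = 5, all differences positive: exact two-sided p = 2/32
  before <- data.frame(case = 1:5, m = c(1, 2, 3, 4, 5))
  after <- data.frame(case = 1:5, m = c(2, 3, 5, 6, 9))
  out <- compare_plans(before, after)
  expect_equal(out$p_value, 0.0625)
  expect_equal(out$n_informative, 5)

  # agreement with sign-flip enumeration for n <= 10, random data with ties;
  # the oracle sees the same realized differences as the implementation
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    d <- round(rnorm(n), sample(0:1, 1))   # rounding creates ties
    d[d == 0] <- 0.5
    b <- data.frame(case = 1:n, m = rnorm(n))
    a <- data.frame(case = 1:n, m = b$m + d)
    got <- compare_plans(b, a)$p_value
    expect_equal(got, enum_signed_rank_p(a$m - b$m), tolerance = 1e-12)
  }

  # degenerate and error cases
  same <- data.frame(case = 1:6, m = 1:6)
  expect_error(compare_plans(same, same), "informative")
  expect_error(compare_plans(before[1:4, ], after[1:4, ]), "at least 5")
  expect_error(compare_plans(before, data.frame(case = 6:10, m = 1:5)),
               "case ids")

  # symmetry under relabeling before/after
  expect_equal(compare_plans(before, after)$p_value,
               compare_plans(after, before)$p_value)
})
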