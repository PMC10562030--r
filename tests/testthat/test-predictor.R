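tiny_cases <- function(n, grid = 32, seed0 = 100, field_fun = NULL) {
  lapply(seq_len(n), function(i) {
    set.seed(seed0 + i)
    anat <- vol3d(array(rnorm(grid^3, mean = 1), rep(grid, 3)))
    f <- if (is.null(field_fun)) array(0, rep(grid, 3)) else field_fun(grid, i)
    list(anat = anat, field = vol3d(f))
  })
}

test_that("patch sampling: counts, shapes, determinism, preconditions", {
  set.seed(1)
  anat <- vol3d(array(rnorm(128^3), c(128, 128, 128)))
  fld <- vol3d(array(rnorm(128^3), c(128, 128, 128)))
  ps <- sample_patches(anat, fld, n = 16, size = 64, seed = 5)
  expect_length(ps, 16)
  expect_true(all(vapply(ps, function(p) all(dim(p$x) == c(64, 64, 64)),
                         logical(1))))
  # aligned pairs: patch content matches the volume at the stated corner
  p1 <- ps[[1]]
  sl <- lapply(1:3, function(a) p1$corner[a]:(p1$corner[a] + 63))
  expect_identical(p1$x, anat$data[sl[[1]], sl[[2]], sl[[3]]])
  expect_identical(p1$y, fld$data[sl[[1]], sl[[2]], sl[[3]]])

  ps2 <- sample_patches(anat, fld, n = 16, size = 64, seed = 5)
  expect_identical(lapply(ps, `[[`, "corner"), lapply(ps2, `[[`, "corner"))

  small <- vol3d(array(0, c(32, 32, 32)))
  expect_error(sample_patches(small, small, n = 1, size = 64, seed = 1),
               "smaller than patch")
})

test_that("patch sampler covers the head bounding box", {
  set.seed(2)
  n <- 48
  anat <- vol3d(array(rnorm(n^3), rep(n, 3)))
  hm <- array(FALSE, rep(n, 3)); hm[9:40, 9:40, 9:40] <- TRUE
  head <- mask3d(hm)
  ps <- sample_patches(anat, anat, n = 100, size = 16, seed = 3,
                       head_mask = head)
  corners <- do.call(rbind, lapply(ps, `[[`, "corner"))
  centers <- corners + 8
  mid <- c(24.5, 24.5, 24.5)
  octant <- (centers[, 1] > mid[1]) + 2 * (centers[, 2] > mid[2]) +
    4 * (centers[, 3] > mid[3])
  expect_setequal(unique(octant), 0:7)
})

test_that("network maps patches to same-shape patches", {
  net <- build_unet(net_config(levels = 3, base_channels = 4, patch = 32),
                    seed = 1)
  out <- unet_apply(net, array(rnorm(32^3), c(32, 32, 32)))
  expect_equal(dim(out), c(32, 32, 32))
  out64 <- unet_apply(net, array(rnorm(64^3), c(64, 64, 64)))
  expect_equal(dim(out64), c(64, 64, 64))
  expect_error(unet_apply(net, array(0, c(20, 20, 20))), "divisible")
  expect_error(net_config(levels = 3, patch = 20), "divisible")

  # doubling base channels roughly quadruples the parameter count
  n1 <- n_params(build_unet(net_config(3, 4, 32), seed = 1))
  n2 <- n_params(build_unet(net_config(3, 8, 32), seed = 1))
  expect_gt(n2 / n1, 3.5)
  expect_lt(n2 / n1, 4.2)
})

test_that("training drives the loss to zero on constant-zero targets", {
  cases <- tiny_cases(3, grid = 16)
  net <- net_config(levels = 3, base_channels = 4, patch = 16)
  tc <- train_config(lr = 2e-3, epochs = 5, patches_per_volume = 4, seed = 2)
  fit <- train_predictor(cases[1:2], cases[3], netcfg = net, traincfg = tc)
  expect_lt(tail(fit$history$train_l1, 1), 0.01)
  expect_true(fit$manifest$trained)
})

test_that("training is deterministic under the seed", {
  fld <- function(grid, i) array(sin(seq_len(grid^3) / 500), rep(grid, 3))
  cases <- tiny_cases(3, grid = 16, field_fun = fld)
  net <- net_config(levels = 3, base_channels = 4, patch = 16)
  tc <- train_config(lr = 1e-3, epochs = 2, patches_per_volume = 2, seed = 9)
  f1 <- train_predictor(cases[1:2], cases[3], netcfg = net, traincfg = tc)
  f2 <- train_predictor(cases[1:2], cases[3], netcfg = net, traincfg = tc)
  expect_identical(f1$history, f2$history)
  expect_identical(weight_hash(f1), weight_hash(f2))
})

test_that("whole-volume prediction: tiling identity, lattice, masking", {
  fld <- function(grid, i) array(0, rep(grid, 3))
  cases <- tiny_cases(3, grid = 16, field_fun = fld)
  net <- net_config(levels = 3, base_channels = 4, patch = 16)
  tc <- train_config(lr = 2e-3, epochs = 5, patches_per_volume = 4, seed = 4)
  fit <- train_predictor(cases[1:2], cases[3], netcfg = net, traincfg = tc)

  # volume of exactly one patch: stitched output equals the single tile
  # (away from the 3-voxel feathered rim of the head mask)
  anat <- cases[[3]]$anat
  hm <- mask3d(array(TRUE, c(16, 16, 16)))
  pred <- predict_fieldmap(fit, anat, head_mask = hm)
  expect_true(same_lattice(pred$offres_hz, anat))
  ns <- (anat$data - median(anat$data)) /
    IQR(anat$data)
  single <- unet_apply(fit, ns) * fit$manifest$target_scale
  core <- 4:13
  expect_equal(pred$offres_hz$data[core, core, core],
               single[core, core, core], tolerance = 1e-10)

  # trained on zero fields, prediction is ~0; zero outside the head mask
  expect_lt(max(abs(pred$offres_hz$data)), 0.05 * fit$manifest$target_scale +
              0.05)
  hm2 <- array(TRUE, c(16, 16, 16)); hm2[1:4, , ] <- FALSE
  pred2 <- predict_fieldmap(fit, anat, head_mask = mask3d(hm2))
  expect_true(all(pred2$offres_hz$data[1:4, , ] == 0))

  # scale-mismatch warning for un-normalized input
  big <- vol3d(anat$data * 1000)
  expect_warning(predict_fieldmap(fit, big, head_mask = hm), "scale")
})

test_that("backpropagation matches central finite differences", {
  fwd <- getFromNamespace("unet_forward", "psdcorrect")
  bwd <- getFromNamespace("unet_backward", "psdcorrect")
  net <- build_unet(net_config(levels = 2, base_channels = 2, patch = 8),
                    seed = 3)
  set.seed(1)
  x <- array(rnorm(8^3), c(8, 8, 8, 1))
  tgt <- array(rnorm(8^3), c(8, 8, 8, 1))
  fw <- fwd(net$params, x, 2)
  dy <- array(sign(fw$y - tgt) / length(fw$y), dim(fw$y))
  g <- unlist(bwd(dy, fw, net$params, 2), use.names = FALSE)
  theta <- unlist(net$params, use.names = FALSE)
  loss_at <- function(v) {
    p <- utils::relist(v, net$params)
    mean(abs(fwd(p, x, 2)$y - tgt))
  }
  set.seed(9)
  idx <- sample(length(theta), 12)
  eps <- 3e-3   # large enough that float32 forward noise is negligible
  num <- vapply(idx, function(i) {
    a <- theta; a[i] <- a[i] + eps
    b <- theta; b[i] <- b[i] - eps
    (loss_at(a) - loss_at(b)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(num - g[idx])) / max(abs(num)), 0.01)
})

test_that("fused single-precision convolution matches the double-precision lowering", {
  im2col <- getFromNamespace("im2col3", "psdcorrect")
  fwd <- getFromNamespace("conv3f_forward", "psdcorrect")
  set.seed(12)
  for (stride in c(1L, 2L)) {
    d <- c(10L, 9L, 8L, 3L)
    x <- array(rnorm(prod(d)), d)
    co <- 4L
    W <- matrix(rnorm(27 * d[4] * co, sd = 0.2), 27 * d[4], co)
    b <- rnorm(co)
    got <- fwd(x, d, W, b, stride)
    M <- im2col(x, d, stride)
    ref <- M %*% W
    ref <- array(sweep(ref, 2, b, "+"), dim(got))
    expect_equal(got, ref, tolerance = 1e-5)
  }
})
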