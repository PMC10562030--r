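# Patch sampling, training loop and whole-volume prediction for the
# field-map predictor.

robust_norm_stats <- function(x, mask = NULL) {
  v <- if (is.null(mask)) as.vector(x) else x[mask > 0]
  ctr <- stats::median(v)
  scl <- stats::IQR(v)
  if (scl < 1e-8) scl <- stats::sd(v)
  if (!is.finite(scl) || scl < 1e-8) scl <- 1
  list(center = ctr, scale = scl)
}

#' Sample aligned anatomical/field patch pairs
#'
#' Patch corners are drawn uniformly at random inside the head bounding box
#' (clipped so patches stay inside the volume); sampling is deterministic
#' under the seed.
#'
#' @param anat [vol3d] anatomical image.
#' @param target_field [vol3d] or [fieldmap] on the same lattice.
#' @param n number of patch pairs (>= 1).
#' @param size patch edge length in voxels.
#' @param seed integer seed.
#' @param head_mask optional [mask3d] defining the head bounding box.
#' @return list of `n` elements, each `list(x =, y =, corner =)` with `x`
#'   and `y` arrays of dim `size^3`.
#' @export
sample_patches <- function(anat, target_field, n, size, seed,
                           head_mask = NULL) {
  stopifnot(inherits(anat, "vol3d"), n >= 1)
  y <- if (inherits(target_field, "fieldmap")) target_field$offres_hz else target_field
  stop_if_lattice_mismatch(anat, y, "anatomy and field")
  d <- dim(anat$data)
  if (any(d < size))
    stop("sample_patches: volume (", paste(d, collapse = "x"),
         ") smaller than patch size ", size)
  lo <- c(1L, 1L, 1L); hi <- d
  if (!is.null(head_mask)) {
    idx <- which(head_mask$data > 0)
    if (length(idx)) {
      ai <- arrayInd(idx, d)
      lo <- apply(ai, 2, min); hi <- apply(ai, 2, max)
    }
  }
  cmin <- pmax(lo, 1L)
  cmax <- pmin(hi - size + 1L, d - size + 1L)
  bad <- cmax < cmin
  cmin[bad] <- 1L
  cmax[bad] <- d[bad] - size + 1L
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    crn <- vapply(1:3, function(ax)
      if (cmax[ax] > cmin[ax]) sample(cmin[ax]:cmax[ax], 1) else cmin[ax],
      numeric(1))
    sl <- lapply(1:3, function(ax) crn[ax]:(crn[ax] + size - 1))
    list(x = anat$data[sl[[1]], sl[[2]], sl[[3]]],
         y = y$data[sl[[1]], sl[[2]], sl[[3]]],
         corner = as.integer(crn))
  })
}

case_field_vol <- function(case) {
  f <- case$fieldmap_true
  if (is.null(f)) f <- case$field
  if (inherits(f, "fieldmap")) f$offres_hz else f
}

case_input_vol <- function(case) {
  a <- case$anat_distorted
  if (is.null(a)) a <- case$anat
  a
}

#' Train the field-map predictor
#'
#' L1 regression of the off-resonance field (Hz) from the anatomical image
#' with Adam. Inputs are normalized per volume by a robust z-score
#' (median/IQR); field targets are scaled to unit spread by a single global
#' factor computed on the training set and recorded in the model manifest.
#' Patches are re-drawn each epoch; the weights with the best validation L1
#' are retained. Fully deterministic under the training seed.
#'
#' @param train_cases,val_cases lists of cases; each case is a list with an
#'   anatomical [vol3d] (element `anat_distorted` or `anat`), a target field
#'   (`fieldmap_true` or `field`, [fieldmap] or [vol3d]) and optionally
#'   `head_mask`.
#' @param netcfg a [net_config].
#' @param traincfg a [train_config].
#' @param verbose print per-epoch losses.
#' @return trained `psd_unet` with `history` (per-epoch train/validation L1)
#'   and a manifest recording normalization, seed and configuration.
#' @export
train_predictor <- function(train_cases, val_cases,
                            netcfg = net_config(),
                            traincfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(netcfg, "net_config"), inherits(traincfg, "train_config"))
  if (length(train_cases) < 1 || length(val_cases) < 1)
    stop("train_predictor: need at least one training and one validation volume")

  prep <- function(case) {
    a <- case_input_vol(case)
    y <- case_field_vol(case)
    hm <- if (!is.null(case$head_mask)) case$head_mask$data else NULL
    ns <- robust_norm_stats(a$data, hm)
    list(x = vol_like((a$data - ns$center) / ns$scale, a), y = y,
         head_mask = case$head_mask, norm = ns)
  }
  tr <- lapply(train_cases, prep)
  va <- lapply(val_cases, prep)
  pooled <- unlist(lapply(tr, function(cs) {
    if (is.null(cs$head_mask)) as.vector(cs$y$data)
    else cs$y$data[cs$head_mask$data > 0]
  }))
  target_scale <- stats::sd(pooled)
  if (!is.finite(target_scale) || target_scale <= 0) target_scale <- 1
  for (i in seq_along(tr)) tr[[i]]$y <- vol_like(tr[[i]]$y$data / target_scale, tr[[i]]$y)
  for (i in seq_along(va)) va[[i]]$y <- vol_like(va[[i]]$y$data / target_scale, va[[i]]$y)

  seed <- traincfg$seed
  model <- build_unet(netcfg, seed = seed)
  m <- tree_zeros(model$params); v <- m
  b1 <- traincfg$betas[1]; b2 <- traincfg$betas[2]
  lr <- traincfg$lr
  step <- 0L
  L <- netcfg$levels; psz <- netcfg$patch

  # validation: L1 over the head on a fixed non-overlapping tile grid (a
  # random patch-subsample estimate is too noisy to select the best epoch);
  # tiles with little head coverage carry no information and are skipped
  val_tiles <- lapply(va, function(cs) {
    d <- dim(cs$x$data)
    corners <- function(n) unique(c(seq(1L, n - psz + 1L, by = psz),
                                    n - psz + 1L))
    hm <- if (!is.null(cs$head_mask)) cs$head_mask$data > 0
          else array(TRUE, d)
    tiles <- list()
    for (i in corners(d[1])) for (j in corners(d[2])) for (k in corners(d[3])) {
      sx <- i:(i + psz - 1); sy <- j:(j + psz - 1); sz <- k:(k + psz - 1)
      m <- hm[sx, sy, sz]
      if (mean(m) < 0.25) next
      tiles[[length(tiles) + 1]] <-
        list(x = cs$x$data[sx, sy, sz], y = cs$y$data[sx, sy, sz], m = m)
    }
    tiles
  })

  val_l1 <- function(params) {
    tot <- 0; nvox <- 0
    for (tiles in val_tiles) for (tl in tiles) {
      fw <- unet_forward(params, array(tl$x, c(psz, psz, psz, 1)), L)
      pred <- array(fw$y, c(psz, psz, psz))
      tot <- tot + sum(abs(pred[tl$m] - tl$y[tl$m]))
      nvox <- nvox + sum(tl$m)
    }
    tot / nvox
  }

  hist_train <- numeric(traincfg$epochs)
  hist_val <- numeric(traincfg$epochs)
  best <- Inf; best_params <- model$params

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  for (ep in seq_len(traincfg$epochs)) {
    lr_ep <- lr * traincfg$lr_decay^(ep - 1)
    set.seed(seed + 100 * ep)
    ord <- sample(seq_along(tr))
    ep_loss <- 0; n_pat <- 0L
    for (vi in ord) {
      cs <- tr[[vi]]
      pats <- sample_patches(cs$x, cs$y, n = traincfg$patches_per_volume,
                             size = psz, seed = seed + 100 * ep + 13 * vi,
                             head_mask = cs$head_mask)
      for (pp in pats) {
        x <- array(pp$x, c(dim(pp$x), 1))
        fw <- unet_forward(model$params, x, L)
        r <- fw$y - array(pp$y, dim(fw$y))
        loss <- mean(abs(r))
        if (!is.finite(loss))
          stop("train_predictor: non-finite loss at epoch ", ep,
               " (diverged); reduce the learning rate")
        ep_loss <- ep_loss + loss; n_pat <- n_pat + 1L
        dy <- array(sign(r) / length(r), dim(r))
        g <- unet_backward(dy, fw, model$params, L)
        step <- step + 1L
        upd <- adam_step(model$params, g, m, v, lr_ep, b1, b2, step)
        model$params <- upd$p; m <- upd$m; v <- upd$v
      }
    }
    hist_train[ep] <- ep_loss / n_pat
    hist_val[ep] <- val_l1(model$params)
    if (hist_val[ep] < best) {
      best <- hist_val[ep]
      best_params <- model$params
    }
    if (verbose)
      message(sprintf("epoch %d/%d  train L1 %.4f  val L1 %.4f",
                      ep, traincfg$epochs, hist_train[ep], hist_val[ep]))
  }

  model$params <- best_params
  model$history <- data.frame(epoch = seq_len(traincfg$epochs),
                              train_l1 = hist_train, val_l1 = hist_val)
  model$manifest <- list(
    trained = TRUE, seed = seed,
    target_scale = target_scale,
    input_norm = "per-volume robust z-score (median/IQR)",
    typical_input_iqr = stats::median(vapply(tr, function(cs) cs$norm$scale,
                                             numeric(1))),
    lr = lr, betas = traincfg$betas, epochs = traincfg$epochs,
    patches_per_volume = traincfg$patches_per_volume,
    patch = psz, levels = L, base_channels = netcfg$base_channels,
    n_train = length(tr), n_val = length(va))
  model
}

#' Predict a whole-volume field map
#'
#' The volume is normalized as in training, tiled with overlapping patches at
#' 50% stride, patch predictions are averaged in overlap regions, and the
#' result is rescaled to Hz. Values outside the head mask are set to zero.
#'
#' @param model trained `psd_unet`.
#' @param anat [vol3d] anatomical image.
#' @param head_mask optional [mask3d]; if `NULL` a robust threshold mask of
#'   `anat` is used.
#' @param b0 field strength (metadata on the returned [fieldmap]).
#' @param tiling `"overlap"` (50%-stride patches, overlap-averaged) or
#'   `"whole"` (one fully convolutional pass over the volume; requires
#'   dimensions divisible by `2^levels`, otherwise falls back to overlap).
#' @return predicted [fieldmap] in Hz on the lattice of `anat`.
#' @export
predict_fieldmap <- function(model, anat, head_mask = NULL, b0 = 3,
                             tiling = c("overlap", "whole")) {
  tiling <- match.arg(tiling)
  stopifnot(inherits(model, "psd_unet"), inherits(anat, "vol3d"))
  if (!isTRUE(model$manifest$trained))
    warning("predict_fieldmap: model has not been trained")
  if (is.null(head_mask)) head_mask <- threshold_mask(anat, 0.2)
  d <- dim(anat$data)
  psz <- model$netcfg$patch
  if (any(d < psz))
    stop("predict_fieldmap: volume smaller than the model patch size")
  ns <- robust_norm_stats(anat$data, head_mask$data)
  tiqr <- model$manifest$typical_input_iqr
  if (!is.null(tiqr) && is.finite(tiqr) &&
      (ns$scale > 10 * tiqr || ns$scale < tiqr / 10))
    warning("predict_fieldmap: input intensity scale differs more than ",
            "10-fold from the training scale; is the volume normalized?")
  xn <- (anat$data - ns$center) / ns$scale

  if (tiling == "whole" && all(d %% 2^model$netcfg$levels == 0)) {
    fw <- unet_forward(model$params, array(xn, c(d, 1)),
                       model$netcfg$levels)
    out <- array(fw$y, d) * model$manifest$target_scale
  } else {
    corners <- function(n) unique(c(seq(1L, n - psz + 1L, by = psz %/% 2L),
                                    n - psz + 1L))
    hm <- head_mask$data > 0
    acc <- array(0, d); cnt <- array(0, d)
    for (i in corners(d[1])) for (j in corners(d[2])) for (k in corners(d[3])) {
      sx <- i:(i + psz - 1); sy <- j:(j + psz - 1); sz <- k:(k + psz - 1)
      if (!any(hm[sx, sy, sz])) next    # all-air tile: output is masked anyway
      x <- array(xn[sx, sy, sz], c(psz, psz, psz, 1))
      fw <- unet_forward(model$params, x, model$netcfg$levels)
      acc[sx, sy, sz] <- acc[sx, sy, sz] + array(fw$y, c(psz, psz, psz))
      cnt[sx, sy, sz] <- cnt[sx, sy, sz] + 1
    }
    out <- acc / pmax(cnt, 1) * model$manifest$target_scale
  }
  # zero outside the head, feathered over a 3-voxel inward ramp: a hard step
  # at the head boundary would put an artificial spike in d(shift)/dx and can
  # fold the Jacobian during correction
  m <- head_mask$data > 0
  e1 <- erode6(m)
  w <- (m + e1 + erode6(e1)) / 3
  fieldmap(vol_like(out * w, anat), b0 = b0)
}

#' @export
#' @rdname predict_fieldmap
#' @param object trained `psd_unet` (S3 `predict` method).
#' @param ... passed to [predict_fieldmap()].
predict.psd_unet <- function(object, anat, ...) {
  predict_fieldmap(object, anat, ...)
}
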