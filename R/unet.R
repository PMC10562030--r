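# 3D U-Net with ResNet encoder blocks, implemented directly on R arrays:
# convolutions are lowered to matrix multiplications (im2col in C++, GEMM via
# BLAS), with hand-written backpropagation and Adam. Data layout is
# channels-last: (nx, ny, nz, c).

#' Network configuration
#'
#' The encoder is `levels` ResNet stages with stride-2 3x3x3 convolutions
#' (channel width doubling per stage); the decoder mirrors them with
#' nearest-neighbour upsampling followed by convolution (no transposed
#' convolution, avoiding checkerboard artifacts) and skip connections. Output
#' shape equals input shape.
#'
#' @param levels number of resolution levels (default 3).
#' @param base_channels channels after the stem convolution.
#' @param patch training patch edge length in voxels; must be divisible by
#'   `2^levels`.
#' @return object of class `net_config`.
#' @export
net_config <- function(levels = 3, base_channels = 8, patch = 32) {
  if (levels < 1) stop("net_config: levels must be >= 1")
  if (patch %% 2^levels != 0)
    stop("net_config: patch must be divisible by 2^levels")
  structure(list(levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 patch = as.integer(patch)),
            class = "net_config")
}

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 2e-4 and
#' betas (0.9, 0.999), L1 loss, 16 patches per volume. Epochs default to a
#' desk-scale 10.
#'
#' @param lr learning rate (> 0).
#' @param betas Adam exponential decay rates, both in (0, 1).
#' @param epochs number of epochs.
#' @param patches_per_volume patches sampled from each volume per epoch.
#' @param lr_decay multiplicative learning-rate decay per epoch (1 = none).
#' @param loss only `"l1"` is supported.
#' @param seed integer seed controlling initialization and sampling.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 2e-4, betas = c(0.9, 0.999), epochs = 10,
                         patches_per_volume = 16, lr_decay = 1,
                         loss = "l1", seed = 1) {
  if (!(lr > 0)) stop("train_config: lr must be positive")
  if (length(betas) != 2 || any(betas <= 0) || any(betas >= 1))
    stop("train_config: betas must be two values in (0,1)")
  if (!(lr_decay > 0 && lr_decay <= 1))
    stop("train_config: lr_decay must be in (0, 1]")
  if (!identical(loss, "l1")) stop("train_config: only the L1 loss is supported")
  structure(list(lr = lr, betas = betas, epochs = as.integer(epochs),
                 patches_per_volume = as.integer(patches_per_volume),
                 lr_decay = lr_decay, loss = loss, seed = as.integer(seed)),
            class = "train_config")
}

init_conv3 <- function(ci, co) {
  list(W = matrix(stats::rnorm(27 * ci * co, sd = sqrt(2 / (27 * ci))),
                  27 * ci, co),
       b = numeric(co))
}
init_conv1 <- function(ci, co) {
  list(W = matrix(stats::rnorm(ci * co, sd = sqrt(2 / ci)), ci, co),
       b = numeric(co))
}

# leaky rectifier (slope 0.1): avoids dead units in small batch-1 training
lrelu <- function(x) pmax(x, 0) + 0.1 * pmin(x, 0)
lrelu_grad <- function(x) ifelse(x > 0, 1, 0.1)

conv3_f <- function(x, p, stride) {
  d <- dim(x)
  y <- conv3f_forward(x, as.integer(d), p$W, p$b, as.integer(stride))
  list(y = y, x = x, stride = stride)
}

conv3_b <- function(dy, cache, p) {
  r <- conv3f_backward(cache$x, as.integer(dim(cache$x)), p$W, dy,
                       as.integer(cache$stride))
  list(dx = r$dx, g = list(W = r$dW, b = r$db))
}

conv1_f <- function(x, p, stride) {
  d <- dim(x)
  i1 <- seq(1L, d[1], stride); i2 <- seq(1L, d[2], stride)
  i3 <- seq(1L, d[3], stride)
  xs <- x[i1, i2, i3, , drop = FALSE]
  ds <- dim(xs)
  M <- matrix(xs, prod(ds[1:3]), ds[4])
  y <- M %*% p$W
  y <- y + rep(p$b, each = nrow(y))
  list(y = array(y, c(ds[1:3], ncol(p$W))), xdim = d, xs = xs,
       stride = stride)
}

conv1_b <- function(dy, cache, p) {
  ds <- dim(cache$xs)
  co <- ncol(p$W)
  M <- matrix(cache$xs, prod(ds[1:3]), ds[4])
  dY <- matrix(dy, ncol = co)
  dW <- crossprod(M, dY)
  db <- colSums(dY)
  dxs <- array(tcrossprod(dY, p$W), ds)
  dx <- array(0, cache$xdim)
  d <- cache$xdim
  i1 <- seq(1L, d[1], cache$stride); i2 <- seq(1L, d[2], cache$stride)
  i3 <- seq(1L, d[3], cache$stride)
  dx[i1, i2, i3, ] <- dxs
  list(dx = dx, g = list(W = dW, b = db))
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
    rep(seq_len(d[3]), each = 2), , drop = FALSE]
}

# adjoint of nearest-neighbour x2 upsampling: sum over 2x2x2 blocks
downsum2 <- function(dy) {
  d <- dim(dy)
  n <- d[1:3] / 2
  a <- dy
  dim(a) <- c(2, prod(d) / 2)
  a <- a[1, ] + a[2, ]
  dim(a) <- c(n[1], 2, n[2] * 2 * n[3] * d[4])
  a <- a[, 1, ] + a[, 2, ]
  dim(a) <- c(n[1] * n[2], 2, n[3] * d[4])
  a <- a[, 1, ] + a[, 2, ]
  array(a, c(n, d[4]))
}

cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

enc_f <- function(x, pb) {
  c1 <- conv3_f(x, pb$c1, 2L)
  a1 <- lrelu(c1$y)
  c2 <- conv3_f(a1, pb$c2, 1L)
  pj <- conv1_f(x, pb$proj, 2L)
  s <- c2$y + pj$y
  list(y = lrelu(s), c1 = c1, a1 = a1, c2 = c2, pj = pj, s = s)
}

enc_b <- function(dy, cache, pb) {
  ds <- dy * lrelu_grad(cache$s)
  b2 <- conv3_b(ds, cache$c2, pb$c2)
  da1 <- b2$dx * lrelu_grad(cache$c1$y)
  b1 <- conv3_b(da1, cache$c1, pb$c1)
  bp <- conv1_b(ds, cache$pj, pb$proj)
  list(dx = b1$dx + bp$dx,
       g = list(c1 = b1$g, c2 = b2$g, proj = bp$g))
}

dec_f <- function(u, skip, pb) {
  up <- upsample2(u)
  z <- cat_ch(up, skip)
  c1 <- conv3_f(z, pb$c1, 1L)
  a1 <- lrelu(c1$y)
  c2 <- conv3_f(a1, pb$c2, 1L)
  list(y = lrelu(c2$y), cu = dim(u)[4], c1 = c1, a1 = a1, c2 = c2)
}

dec_b <- function(dy, cache, pb) {
  da2 <- dy * lrelu_grad(cache$c2$y)
  b2 <- conv3_b(da2, cache$c2, pb$c2)
  da1 <- b2$dx * lrelu_grad(cache$c1$y)
  b1 <- conv3_b(da1, cache$c1, pb$c1)
  dz <- b1$dx
  cu <- cache$cu
  dup <- dz[, , , seq_len(cu), drop = FALSE]
  dskip <- dz[, , , cu + seq_len(dim(dz)[4] - cu), drop = FALSE]
  list(du = downsum2(dup), dskip = dskip,
       g = list(c1 = b1$g, c2 = b2$g))
}

# nested-list parameter tree helpers (leaves are numeric vectors/matrices)
tree_zeros <- function(p) if (is.list(p)) lapply(p, tree_zeros) else p * 0

# one Adam update, walking the parameter/gradient/state trees leaf by leaf
adam_step <- function(params, grads, m, v, lr, b1, b2, t, eps = 1e-8) {
  if (is.list(params)) {
    for (i in seq_along(params)) {
      r <- adam_step(params[[i]], grads[[i]], m[[i]], v[[i]],
                     lr, b1, b2, t, eps)
      params[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
    }
    list(p = params, m = m, v = v)
  } else {
    m <- b1 * m + (1 - b1) * grads
    v <- b2 * v + (1 - b2) * grads * grads
    params <- params - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
    list(p = params, m = m, v = v)
  }
}

unet_init_params <- function(cfg) {
  C <- cfg$base_channels; L <- cfg$levels
  enc <- vector("list", L)
  for (l in seq_len(L)) {
    ci <- C * 2^(l - 1); co <- C * 2^l
    enc[[l]] <- list(c1 = init_conv3(ci, co), c2 = init_conv3(co, co),
                     proj = init_conv1(ci, co))
  }
  dec <- vector("list", L)
  for (l in seq_len(L)) {
    cs <- C * 2^(l - 1)
    cu <- if (l == L) C * 2^L else C * 2^l
    dec[[l]] <- list(c1 = init_conv3(cu + cs, cs), c2 = init_conv3(cs, cs))
  }
  list(stem = init_conv3(1, C), enc = enc, dec = dec, head = init_conv3(C, 1))
}

unet_forward <- function(params, x, levels) {
  st <- conv3_f(x, params$stem, 1L)
  acts <- vector("list", levels + 1)
  acts[[1]] <- lrelu(st$y)
  ec <- vector("list", levels)
  for (l in seq_len(levels)) {
    ec[[l]] <- enc_f(acts[[l]], params$enc[[l]])
    acts[[l + 1]] <- ec[[l]]$y
  }
  u <- acts[[levels + 1]]
  dc <- vector("list", levels)
  for (l in rev(seq_len(levels))) {
    dc[[l]] <- dec_f(u, acts[[l]], params$dec[[l]])
    u <- dc[[l]]$y
  }
  hd <- conv3_f(u, params$head, 1L)
  list(y = hd$y, st = st, acts = acts, ec = ec, dc = dc, hd = hd)
}

unet_backward <- function(dy, fw, params, levels) {
  bh <- conv3_b(dy, fw$hd, params$head)
  du <- bh$dx
  gdec <- vector("list", levels)
  dskips <- vector("list", levels)
  for (l in seq_len(levels)) {
    bd <- dec_b(du, fw$dc[[l]], params$dec[[l]])
    gdec[[l]] <- bd$g
    dskips[[l]] <- bd$dskip
    du <- bd$du
  }
  genc <- vector("list", levels)
  dcur <- du
  for (l in rev(seq_len(levels))) {
    be <- enc_b(dcur, fw$ec[[l]], params$enc[[l]])
    genc[[l]] <- be$g
    dcur <- be$dx + dskips[[l]]
  }
  da0 <- dcur * lrelu_grad(fw$st$y)
  bs <- conv3_b(da0, fw$st, params$stem)
  list(stem = bs$g, enc = genc, dec = gdec, head = bh$g)
}

#' Build an untrained field-map prediction network
#'
#' @param cfg a [net_config].
#' @param seed seed for weight initialization (He-scaled Gaussian).
#' @return object of class `psd_unet` (untrained; see [train_predictor()]).
#' @export
build_unet <- function(cfg = net_config(), seed = 1) {
  stopifnot(inherits(cfg, "net_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  structure(list(params = unet_init_params(cfg), netcfg = cfg,
                 manifest = list(seed = seed, trained = FALSE),
                 history = NULL),
            class = "psd_unet")
}

#' Run the network on a single patch
#'
#' @param model a `psd_unet`.
#' @param patch 3D array whose edges are divisible by `2^levels`.
#' @return 3D array of the same shape.
#' @export
unet_apply <- function(model, patch) {
  stopifnot(inherits(model, "psd_unet"))
  d <- dim(patch)
  if (any(d %% 2^model$netcfg$levels != 0))
    stop("unet_apply: patch dimensions must be divisible by 2^levels")
  x <- array(as.double(patch), c(d, 1))
  fw <- unet_forward(model$params, x, model$netcfg$levels)
  array(fw$y, d)
}

#' Number of trainable parameters
#' @param model a `psd_unet`.
#' @return integer count.
#' @export
n_params <- function(model) length(unlist(model$params, use.names = FALSE))

#' @export
print.psd_unet <- function(x, ...) {
  cat(sprintf(
    "<psd_unet> levels %d, base channels %d, patch %d, %s parameters (%s)\n",
    x$netcfg$levels, x$netcfg$base_channels, x$netcfg$patch,
    format(n_params(x), big.mark = ","),
    if (isTRUE(x$manifest$trained)) "trained" else "untrained"))
  if (!is.null(x$history)) {
    h <- x$history
    cat(sprintf("  final train L1 %.4g, best val L1 %.4g (epoch %d)\n",
                h$train_l1[nrow(h)], min(h$val_l1), which.min(h$val_l1)))
  }
  invisible(x)
}

# MD5 over the serialized weights; used for reproducibility checks.
#' Hash of the model weights
#' @param model a `psd_unet`.
#' @return character MD5 digest.
#' @export
weight_hash <- function(model) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(model$params, f, compress = FALSE)
  unname(tools::md5sum(f))
}
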