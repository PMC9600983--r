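# Small CNN engine: parameter trees, Adam, and the two architectures used
# by the pipeline (a 3-block classification CNN and an encoder-decoder
# segmenter with skip connections).  Compiled kernels do the heavy lifting;
# this file orchestrates forward/backward passes and keeps caches.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

he_conv <- function(cin, cout) {
  fan_in <- cin * 9
  list(
    w = matrix(rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in),
    b = numeric(cout)
  )
}

as_cube <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

# ---- parameter trees ------------------------------------------------------

tree_map <- function(a, f) {
  if (is.list(a)) lapply(a, tree_map, f = f) else f(a)
}

tree_map2 <- function(a, b, f) {
  if (is.list(a)) Map(tree_map2, a, b, MoreArgs = list(f = f)) else f(a, b)
}

tree_size <- function(a) {
  if (is.list(a)) sum(vapply(a, tree_size, numeric(1))) else length(a)
}

# Global-norm gradient clipping, the usual stabilizer when heavily
# weighted losses produce occasional very large batch gradients.
clip_grads <- function(grads, max_norm) {
  if (!is.finite(max_norm) || max_norm <= 0) return(grads)
  sq <- 0
  walk <- function(a) {
    if (is.list(a)) lapply(a, walk) else sq <<- sq + sum(a^2)
    invisible(NULL)
  }
  walk(grads)
  nrm <- sqrt(sq)
  if (nrm <= max_norm) return(grads)
  tree_map(grads, function(x) x * (max_norm / nrm))
}

adam_init <- function(params) {
  zeros <- tree_map(params, function(x) x * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v, function(m, v) {
    lr * (m / c1) / (sqrt(v / c2) + eps)
  })
  list(params = tree_map2(params, upd, `-`), state = state)
}

# ---- softmax / cross-entropy ---------------------------------------------

softmax2_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# z: array (H, W, 2) of logits -> per-pixel class probabilities.
softmax2_map <- function(z) {
  m <- pmax(z[, , 1], z[, , 2])
  e1 <- exp(z[, , 1] - m)
  e2 <- exp(z[, , 2] - m)
  s <- e1 + e2
  array(c(e1 / s, e2 / s), dim = dim(z))
}

# Weighted softmax cross-entropy on a pixel map, computed from logits for
# numerical stability.  target: 0/1 matrix; weights: c(background, foreground).
# Returns loss (mean over pixels) and the gradient wrt logits.
wce_from_logits <- function(z, target, weights) {
  p <- softmax2_map(z)
  n <- length(target)
  wmat <- ifelse(target == 1, weights[2], weights[1])
  py <- ifelse(target == 1, p[, , 2], p[, , 1])
  loss <- mean(-wmat * log(pmax(py, 1e-12)))
  dz <- array(0, dim = dim(z))
  dz[, , 1] <- wmat * (p[, , 1] - (target == 0)) / n
  dz[, , 2] <- wmat * (p[, , 2] - (target == 1)) / n
  list(loss = loss, dz = dz, prob = p)
}

# ---- classification CNN ---------------------------------------------------
# conv3x3(1->b) relu pool / conv3x3(b->2b) relu pool / conv3x3(2b->4b) relu
# global average pool / dense -> 2 logits.

tiny_cnn_init <- function(base_channels = 8L) {
  b <- as.integer(base_channels)
  list(
    conv1 = he_conv(1L, b),
    conv2 = he_conv(b, 2L * b),
    conv3 = he_conv(2L * b, 4L * b),
    fc = list(
      w = matrix(rnorm(2L * 4L * b, sd = sqrt(2 / (4 * b))), 2L, 4L * b),
      b = numeric(2L)
    )
  )
}

tiny_cnn_forward <- function(params, x) {
  x <- as_cube(x)
  if (any(dim(x)[1:2] %% 4L != 0L)) {
    stop_arg("classifier input size must be divisible by 4, got ",
             dim(x)[1], "x", dim(x)[2])
  }
  z1 <- conv3x3_fwd(x, params$conv1$w, params$conv1$b)
  a1 <- relu(z1)
  p1 <- maxpool2_fwd(a1)
  z2 <- conv3x3_fwd(p1$out, params$conv2$w, params$conv2$b)
  a2 <- relu(z2)
  p2 <- maxpool2_fwd(a2)
  z3 <- conv3x3_fwd(p2$out, params$conv3$w, params$conv3$b)
  a3 <- relu(z3)
  feat <- apply(a3, 3, mean)
  logits <- drop(params$fc$w %*% feat) + params$fc$b
  list(
    logits = logits,
    cache = list(x = x, z1 = z1, p1 = p1, z2 = z2, p2 = p2, z3 = z3,
                 a3dim = dim(a3), feat = feat)
  )
}

tiny_cnn_backward <- function(params, cache, dlogits) {
  feat <- cache$feat
  dfc_w <- dlogits %o% feat
  dfc_b <- dlogits
  dfeat <- drop(t(params$fc$w) %*% dlogits)
  hd <- cache$a3dim
  npx <- hd[1] * hd[2]
  da3 <- array(rep(dfeat / npx, each = npx), dim = hd)
  dz3 <- da3 * (cache$z3 > 0)
  g3 <- conv3x3_bwd(cache$p2$out, params$conv3$w, dz3)
  dp2 <- maxpool2_bwd(g3$dx, cache$p2$arg, dim(cache$z2)[1], dim(cache$z2)[2])
  dz2 <- dp2 * (cache$z2 > 0)
  g2 <- conv3x3_bwd(cache$p1$out, params$conv2$w, dz2)
  dp1 <- maxpool2_bwd(g2$dx, cache$p1$arg, dim(cache$z1)[1], dim(cache$z1)[2])
  dz1 <- dp1 * (cache$z1 > 0)
  g1 <- conv3x3_bwd(cache$x, params$conv1$w, dz1)
  list(
    conv1 = list(w = g1$dw, b = as.numeric(g1$db)),
    conv2 = list(w = g2$dw, b = as.numeric(g2$db)),
    conv3 = list(w = g3$dw, b = as.numeric(g3$db)),
    fc = list(w = dfc_w, b = dfc_b)
  )
}

# ---- encoder-decoder segmenter -------------------------------------------
# depth encoder levels with two 3x3 convs each and 2x2 maxpool between
# levels; decoder mirrors with nearest-neighbour upsampling, a 3x3
# "up-conv", skip concatenation and two 3x3 convs; final 1x1 conv to 2
# per-pixel class logits.

unet_channels <- function(depth, base) as.integer(base * 2^(seq_len(depth) - 1))

unet_init <- function(depth = 3L, base_channels = 8L) {
  ch <- unet_channels(depth, base_channels)
  enc <- vector("list", depth)
  cin <- 1L
  for (l in seq_len(depth)) {
    enc[[l]] <- list(a = he_conv(cin, ch[l]), b = he_conv(ch[l], ch[l]))
    cin <- ch[l]
  }
  dec <- vector("list", depth - 1L)
  for (l in seq_len(depth - 1L)) {       # dec[[l]] produces level-l maps
    dec[[l]] <- list(
      up = he_conv(ch[l + 1L], ch[l]),
      a = he_conv(2L * ch[l], ch[l]),
      b = he_conv(ch[l], ch[l])
    )
  }
  out <- list(
    w = matrix(rnorm(2L * ch[1], sd = sqrt(2 / ch[1])), 2L, ch[1]),
    b = numeric(2L)
  )
  list(enc = enc, dec = dec, out = out, depth = as.integer(depth))
}

# 1x1 convolution expressed as a matrix product over flattened pixels.
conv1x1_fwd <- function(x, w, b) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  out <- xm %*% t(w)
  out <- sweep(out, 2, b, "+")
  array(out, c(d[1], d[2], nrow(w)))
}

cat_channels <- function(a, b) {
  array(c(a, b), dim = c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

unet_forward <- function(params, x) {
  x <- as_cube(x)
  depth <- params$depth
  div <- 2L^(depth - 1L)
  if (any(dim(x)[1:2] %% div != 0L)) {
    stop_cfg("segmenter input size must be divisible by ", div,
             " for depth ", depth, ", got ", dim(x)[1], "x", dim(x)[2])
  }
  enc_cache <- vector("list", depth)
  cur <- x
  for (l in seq_len(depth)) {
    p <- params$enc[[l]]
    za <- conv3x3_fwd(cur, p$a$w, p$a$b); aa <- relu(za)
    zb <- conv3x3_fwd(aa, p$b$w, p$b$b); ab <- relu(zb)
    pool <- if (l < depth) maxpool2_fwd(ab) else NULL
    enc_cache[[l]] <- list(input = cur, za = za, aa = aa, zb = zb, ab = ab,
                           pool = pool)
    cur <- if (l < depth) pool$out else ab
  }
  dec_cache <- vector("list", depth - 1L)
  for (l in rev(seq_len(depth - 1L))) {
    p <- params$dec[[l]]
    up_in <- upsample2_fwd(cur)
    zu <- conv3x3_fwd(up_in, p$up$w, p$up$b); au <- relu(zu)
    skip <- enc_cache[[l]]$ab
    cat_in <- cat_channels(au, skip)
    za <- conv3x3_fwd(cat_in, p$a$w, p$a$b); aa <- relu(za)
    zb <- conv3x3_fwd(aa, p$b$w, p$b$b); ab <- relu(zb)
    dec_cache[[l]] <- list(up_in = up_in, zu = zu, cat_in = cat_in,
                           za = za, aa = aa, zb = zb, ab = ab)
    cur <- ab
  }
  logits <- conv1x1_fwd(cur, params$out$w, params$out$b)
  list(logits = logits,
       cache = list(enc = enc_cache, dec = dec_cache, final = cur))
}

unet_backward <- function(params, cache, dlogits) {
  depth <- params$depth
  d <- dim(cache$final)
  fm <- matrix(cache$final, d[1] * d[2], d[3])
  dm <- matrix(dlogits, d[1] * d[2], dim(dlogits)[3])
  dout_w <- t(dm) %*% fm
  dout_b <- colSums(dm)
  dcur <- array(dm %*% params$out$w, d)

  grads <- list(enc = vector("list", depth), dec = vector("list", depth - 1L),
                out = list(w = dout_w, b = dout_b), depth = depth)
  dskip <- vector("list", depth)   # gradient flowing into each encoder skip

  for (l in seq_len(depth - 1L)) {
    p <- params$dec[[l]]
    cc <- cache$dec[[l]]
    dzb <- dcur * (cc$zb > 0)
    gb <- conv3x3_bwd(cc$aa, p$b$w, dzb)
    dza <- gb$dx * (cc$za > 0)
    ga <- conv3x3_bwd(cc$cat_in, p$a$w, dza)
    cu <- dim(cc$zu)[3]
    dcat <- ga$dx
    dau <- dcat[, , seq_len(cu), drop = FALSE]
    dskip[[l]] <- dcat[, , cu + seq_len(dim(dcat)[3] - cu), drop = FALSE]
    dzu <- dau * (cc$zu > 0)
    gu <- conv3x3_bwd(cc$up_in, p$up$w, dzu)
    dcur <- upsample2_bwd(gu$dx)
    grads$dec[[l]] <- list(
      up = list(w = gu$dw, b = as.numeric(gu$db)),
      a = list(w = ga$dw, b = as.numeric(ga$db)),
      b = list(w = gb$dw, b = as.numeric(gb$db))
    )
  }

  for (l in rev(seq_len(depth))) {
    p <- params$enc[[l]]
    cc <- cache$enc[[l]]
    dab <- if (l == depth) dcur else {
      g <- maxpool2_bwd(dcur, cc$pool$arg, dim(cc$ab)[1], dim(cc$ab)[2])
      g + dskip[[l]]
    }
    dzb <- dab * (cc$zb > 0)
    gb <- conv3x3_bwd(cc$aa, p$b$w, dzb)
    dza <- gb$dx * (cc$za > 0)
    ga <- conv3x3_bwd(cc$input, p$a$w, dza)
    dcur <- ga$dx
    grads$enc[[l]] <- list(
      a = list(w = ga$dw, b = as.numeric(ga$db)),
      b = list(w = gb$dw, b = as.numeric(gb$db))
    )
  }
  grads
}

# Trainable parameters only (depth bookkeeping excluded).
nn_param_tree <- function(params) params[setdiff(names(params), "depth")]

#' Number of trainable parameters of a fitted or initialized model
#'
#' @param model A `slice_classifier` or `seg_model` object.
#' @return Integer scalar.
#' @export
n_parameters <- function(model) {
  stopifnot(is.list(model), !is.null(model$params))
  as.integer(tree_size(nn_param_tree(model$params)))
}

#' Save or load a fitted model
#'
#' Models are plain R lists of numeric arrays and serialize losslessly.
#'
#' @param model A `slice_classifier` or `seg_model`.
#' @param path File path for the serialized model.
#' @return `load_model()` returns the model; `save_model()` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_arg("no model file at '", path, "'")
  readRDS(path)
}
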