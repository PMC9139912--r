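# Minimal seeded CNN engine.
#
# Feature maps are arrays (H, W, C, N); dense activations are matrices
# (features x N). Each layer is a list with a class tag and a $params list
# of numeric arrays; forward passes return (out, cache, layer) — the layer
# comes back so stateful layers (batch-norm running moments) can update —
# and backward passes return (gin, grads) with grads shaped like $params.
# Convolution is im2col + BLAS matrix multiply. All stochastic pieces
# (init, shuffling, dropout) draw from the caller-seeded RNG stream.

he_init <- function(fan_in, n) stats::rnorm(n, sd = sqrt(2 / fan_in))

nn_conv <- function(in_ch, out_ch, k, stride = 1L, pad = 0L) {
  structure(list(
    params = list(W = matrix(he_init(k * k * in_ch, k * k * in_ch * out_ch),
                             k * k * in_ch, out_ch),
                  b = numeric(out_ch)),
    in_ch = in_ch, out_ch = out_ch, k = k, stride = stride, pad = pad),
    class = c("nn_conv", "nn_layer"))
}

nn_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  structure(list(params = list(gamma = rep(1, ch), beta = numeric(ch)),
                 running_mean = numeric(ch), running_var = rep(1, ch),
                 momentum = momentum, eps = eps, ch = ch),
            class = c("nn_bn", "nn_layer"))
}

nn_relu <- function() structure(list(params = NULL), class = c("nn_relu", "nn_layer"))
nn_avgpool <- function(k = 2L) structure(list(params = NULL, k = as.integer(k)),
                                         class = c("nn_avgpool", "nn_layer"))
nn_maxpool <- function(k = 3L, stride = 2L, pad = 1L)
  structure(list(params = NULL, k = k, stride = stride, pad = pad),
            class = c("nn_maxpool", "nn_layer"))
nn_gap <- function() structure(list(params = NULL), class = c("nn_gap", "nn_layer"))
nn_flatten <- function() structure(list(params = NULL), class = c("nn_flatten", "nn_layer"))
nn_dense <- function(in_dim, out_dim) {
  structure(list(params = list(W = matrix(he_init(in_dim, in_dim * out_dim),
                                          out_dim, in_dim),
                               b = numeric(out_dim)),
                 in_dim = in_dim, out_dim = out_dim),
            class = c("nn_dense", "nn_layer"))
}
nn_dropout <- function(p) structure(list(params = NULL, p = p),
                                    class = c("nn_dropout", "nn_layer"))
# Residual block: out = relu(main(x) + shortcut(x)); identity shortcut if NULL
nn_res <- function(main, shortcut = NULL)
  structure(list(params = NULL, main = main, shortcut = shortcut),
            class = c("nn_res", "nn_layer"))

pad4d <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  xp
}

# Linear indices for im2col over one image of (Hp, Wp, C): rows ordered
# (ki, kj, c), columns ordered (oh, ow) column-major.
im2col_idx <- function(Hp, Wp, C, k, stride) {
  outH <- (Hp - k) %/% stride + 1L
  outW <- (Wp - k) %/% stride + 1L
  i0 <- (seq_len(outH) - 1L) * stride + 1L
  j0 <- (seq_len(outW) - 1L) * stride + 1L
  starts <- as.vector(outer(i0, (j0 - 1L) * Hp, "+"))
  offs <- as.vector(outer(as.vector(outer(0:(k - 1L), (0:(k - 1L)) * Hp, "+")),
                          (0:(C - 1L)) * Hp * Wp, "+"))
  list(idx = outer(offs, starts, "+"), outH = outH, outW = outW)
}

forward.nn_conv <- function(layer, x, train) {
  d <- dim(x)
  xp <- pad4d(x, layer$pad)
  dp <- dim(xp)
  ii <- im2col_idx(dp[1], dp[2], dp[3], layer$k, layer$stride)
  per_img <- dp[1] * dp[2] * dp[3]
  full <- outer(as.vector(ii$idx), (0:(d[4] - 1L)) * per_img, "+")
  cols <- matrix(xp[as.vector(full)], nrow = nrow(ii$idx))
  out <- crossprod(cols, layer$params$W)
  out <- out + matrix(layer$params$b, nrow(out), length(layer$params$b), byrow = TRUE)
  out <- aperm(array(out, c(ii$outH, ii$outW, d[4], layer$out_ch)), c(1, 2, 4, 3))
  list(out = out,
       cache = list(cols = cols, full = full, dp = dp, din = d,
                    outH = ii$outH, outW = ii$outW),
       layer = layer)
}

backward.nn_conv <- function(layer, cache, gout, need_gin = TRUE) {
  n <- cache$din[4]
  gm <- matrix(aperm(gout, c(1, 2, 4, 3)), ncol = layer$out_ch)
  grads <- list(W = cache$cols %*% gm, b = colSums(gm))
  gin <- NULL
  if (need_gin) {
    gcols <- tcrossprod(layer$params$W, gm)      # (k*k*C) x M
    acc <- rowsum(as.vector(gcols), group = as.vector(cache$full))
    gxp <- numeric(prod(cache$dp))
    gxp[as.integer(rownames(acc))] <- acc[, 1]
    gxp <- array(gxp, cache$dp)
    p <- layer$pad
    gin <- if (p > 0)
      gxp[p + seq_len(cache$din[1]), p + seq_len(cache$din[2]), , , drop = FALSE]
    else gxp
    dim(gin) <- cache$din
  }
  list(gin = gin, grads = grads)
}

forward.nn_bn <- function(layer, x, train) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = layer$ch)
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean + layer$momentum * mu
    layer$running_var <- (1 - layer$momentum) * layer$running_var + layer$momentum * v
  } else {
    mu <- layer$running_mean; v <- layer$running_var
  }
  ivstd <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, ivstd, `*`)
  outm <- sweep(sweep(xhat, 2, layer$params$gamma, `*`), 2, layer$params$beta, `+`)
  out <- aperm(array(outm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(out = out, cache = list(xhat = xhat, ivstd = ivstd, d = d, train = train),
       layer = layer)
}

backward.nn_bn <- function(layer, cache, gout, need_gin = TRUE) {
  d <- cache$d
  gm <- matrix(aperm(gout, c(1, 2, 4, 3)), ncol = layer$ch)
  grads <- list(gamma = colSums(gm * cache$xhat), beta = colSums(gm))
  gin <- NULL
  if (need_gin) {
    m <- nrow(gm)
    dxhat <- sweep(gm, 2, layer$params$gamma, `*`)
    if (cache$train) {
      t1 <- sweep(dxhat, 2, colMeans(dxhat))
      t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
      gxm <- sweep(t1 - t2, 2, cache$ivstd, `*`)
    } else {
      gxm <- sweep(dxhat, 2, cache$ivstd, `*`)
    }
    gin <- aperm(array(gxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  }
  list(gin = gin, grads = grads)
}

forward.nn_relu <- function(layer, x, train) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, cache = mask, layer = layer)
}
backward.nn_relu <- function(layer, cache, gout, need_gin = TRUE) {
  gout[!cache] <- 0
  list(gin = gout, grads = NULL)
}

forward.nn_avgpool <- function(layer, x, train) {
  k <- layer$k; d <- dim(x)
  y <- array(colMeans(matrix(x, nrow = k)), c(d[1] %/% k, d[2], d[3], d[4]))
  y <- aperm(y, c(2, 1, 3, 4))
  y <- array(colMeans(matrix(y, nrow = k)), c(d[2] %/% k, d[1] %/% k, d[3], d[4]))
  list(out = aperm(y, c(2, 1, 3, 4)), cache = d, layer = layer)
}
backward.nn_avgpool <- function(layer, cache, gout, need_gin = TRUE) {
  k <- layer$k
  g <- gout[rep(seq_len(dim(gout)[1]), each = k),
            rep(seq_len(dim(gout)[2]), each = k), , , drop = FALSE] / (k * k)
  list(gin = g, grads = NULL)
}

forward.nn_maxpool <- function(layer, x, train) {
  d <- dim(x)
  xr <- x; dim(xr) <- c(d[1], d[2], 1L, d[3] * d[4])   # channels as images
  xp <- pad4d(xr, layer$pad)
  # padding with -Inf semantics: zeros are wrong if activations are negative
  if (layer$pad > 0) {
    dp <- dim(xp)
    m <- array(TRUE, dp)
    m[layer$pad + seq_len(d[1]), layer$pad + seq_len(d[2]), , ] <- FALSE
    xp[m] <- -Inf
  }
  dp <- dim(xp)
  ii <- im2col_idx(dp[1], dp[2], 1L, layer$k, layer$stride)
  per_img <- dp[1] * dp[2]
  full <- outer(as.vector(ii$idx), (0:(dp[4] - 1L)) * per_img, "+")
  cols <- matrix(xp[as.vector(full)], nrow = nrow(ii$idx))
  which_max <- max.col(t(cols), ties.method = "first")
  mx <- cols[cbind(which_max, seq_len(ncol(cols)))]
  out <- array(mx, c(ii$outH, ii$outW, d[3], d[4]))
  list(out = out,
       cache = list(full = full, which_max = which_max, dp = dp, din = d),
       layer = layer)
}
backward.nn_maxpool <- function(layer, cache, gout, need_gin = TRUE) {
  dp <- cache$dp; d <- cache$din
  fullm <- matrix(as.vector(cache$full), nrow = layer$k * layer$k)
  sel <- fullm[cbind(cache$which_max, seq_len(ncol(fullm)))]
  acc <- rowsum(as.vector(gout), group = sel)
  gxp <- numeric(prod(dp))
  gxp[as.integer(rownames(acc))] <- acc[, 1]
  gxp <- array(gxp, dp)
  p <- layer$pad
  g <- if (p > 0) gxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE] else gxp
  dim(g) <- d
  list(gin = g, grads = NULL)
}

forward.nn_gap <- function(layer, x, train) {
  d <- dim(x)
  out <- matrix(colMeans(matrix(x, nrow = d[1] * d[2])), d[3], d[4])
  list(out = out, cache = d, layer = layer)
}
backward.nn_gap <- function(layer, cache, gout, need_gin = TRUE) {
  d <- cache
  g <- array(rep(as.vector(gout), each = d[1] * d[2]) / (d[1] * d[2]), d)
  list(gin = g, grads = NULL)
}

forward.nn_flatten <- function(layer, x, train) {
  d <- dim(x)
  list(out = matrix(x, ncol = d[4]), cache = d, layer = layer)
}
backward.nn_flatten <- function(layer, cache, gout, need_gin = TRUE) {
  dim(gout) <- cache
  list(gin = gout, grads = NULL)
}

forward.nn_dense <- function(layer, x, train) {
  out <- layer$params$W %*% x + layer$params$b
  list(out = out, cache = x, layer = layer)
}
backward.nn_dense <- function(layer, cache, gout, need_gin = TRUE) {
  grads <- list(W = tcrossprod(gout, cache), b = rowSums(gout))
  gin <- if (need_gin) crossprod(layer$params$W, gout) else NULL
  list(gin = gin, grads = grads)
}

forward.nn_dropout <- function(layer, x, train) {
  if (!train || layer$p == 0)
    return(list(out = x, cache = NULL, layer = layer))
  keep <- 1 - layer$p
  mask <- array((stats::runif(length(x)) < keep) / keep, dim(x) %||% length(x))
  list(out = x * mask, cache = mask, layer = layer)
}
backward.nn_dropout <- function(layer, cache, gout, need_gin = TRUE) {
  list(gin = if (is.null(cache)) gout else gout * cache, grads = NULL)
}

forward.nn_res <- function(layer, x, train) {
  fm <- seq_forward(layer$main, x, train)
  layer$main <- fm$layers
  if (is.null(layer$shortcut)) {
    sc_out <- x; fs <- NULL
  } else {
    fs <- seq_forward(layer$shortcut, x, train)
    layer$shortcut <- fs$layers
    sc_out <- fs$out
  }
  s <- fm$out + sc_out
  mask <- s > 0
  s[!mask] <- 0
  list(out = s,
       cache = list(main = fm$caches, shortcut = if (is.null(fs)) NULL else fs$caches,
                    mask = mask),
       layer = layer)
}
backward.nn_res <- function(layer, cache, gout, need_gin = TRUE) {
  gout[!cache$mask] <- 0
  bm <- seq_backward(layer$main, cache$main, gout, need_gin = TRUE)
  if (is.null(layer$shortcut)) {
    g_sc <- gout; grads_sc <- NULL
  } else {
    bs <- seq_backward(layer$shortcut, cache$shortcut, gout, need_gin = TRUE)
    g_sc <- bs$gin; grads_sc <- bs$grads
  }
  list(gin = bm$gin + g_sc, grads = list(main = bm$grads, shortcut = grads_sc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

forward <- function(layer, x, train) UseMethod("forward")
backward <- function(layer, cache, gout, need_gin = TRUE) UseMethod("backward")

seq_forward <- function(layers, x, train) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    f <- forward(layers[[i]], x, train)
    x <- f$out
    caches[[i]] <- f$cache
    layers[[i]] <- f$layer
  }
  list(out = x, caches = caches, layers = layers)
}

seq_backward <- function(layers, caches, gout, need_gin = FALSE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    b <- backward(layers[[i]], caches[[i]], gout,
                  need_gin = need_gin || i > 1)
    if (!is.null(b$grads)) grads[[i]] <- b$grads
    gout <- b$gin
  }
  list(gin = gout, grads = grads)
}

# ---- parameter trees ------------------------------------------------------

layer_params <- function(layer) {
  if (inherits(layer, "nn_res"))
    list(main = lapply(layer$main, layer_params),
         shortcut = if (is.null(layer$shortcut)) NULL
                    else lapply(layer$shortcut, layer_params))
  else layer$params
}

set_layer_params <- function(layer, p) {
  if (inherits(layer, "nn_res")) {
    layer$main <- Map(set_layer_params, layer$main, p$main)
    if (!is.null(layer$shortcut))
      layer$shortcut <- Map(set_layer_params, layer$shortcut, p$shortcut)
  } else layer$params <- p
  layer
}

is_param_leaf <- function(x) is.numeric(x)

tree_map <- function(f, ...) {
  trees <- list(...)
  a <- trees[[1]]
  if (is.null(a)) return(NULL)
  if (is_param_leaf(a)) return(do.call(f, trees))
  out <- vector("list", length(a))
  names(out) <- names(a)
  for (i in seq_along(a)) {
    v <- do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    if (!is.null(v)) out[[i]] <- v   # plain assignment of NULL would drop the slot
  }
  out
}

tree_flatten <- function(x) {
  if (is.null(x)) return(numeric(0))
  if (is_param_leaf(x)) return(as.numeric(x))
  unlist(lapply(x, tree_flatten), use.names = FALSE)
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) list(m = tree_map(function(p) p * 0, params),
                                   v = tree_map(function(p) p * 0, params),
                                   t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                     params, state$m, state$v)
  list(params = params, state = state)
}

# ---- loss -----------------------------------------------------------------

softmax_xent <- function(logits, y) {
  mx <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, mx))
  p <- sweep(e, 2, colSums(e), `/`)
  n <- ncol(logits)
  idx <- cbind(y + 1L, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = g / n, prob = p)
}
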