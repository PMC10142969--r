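# Minimal convolutional-network engine used by the OCT image classifiers.
# Convolutions are evaluated as im2col patch-matrix products; gradients are
# exact (backpropagation); optimisation is Adam with decoupled L2 handled as
# a gradient penalty. All randomness flows through R's RNG so a single seed
# fixes initialisation, data order, dropout and augmentation draws.

.nn_cache <- new.env(parent = emptyenv())

# patch-index matrix for 2D convolution on a padded H x W x cin input
conv2d_index <- function(H, W, cin, k, stride, pad) {
  key <- paste("c2", H, W, cin, k, stride, pad, sep = "_")
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  oh <- (Hp - k) %/% stride + 1L; ow <- (Wp - k) %/% stride + 1L
  pos <- expand.grid(i = seq_len(oh), j = seq_len(ow))
  r0 <- (pos$i - 1L) * stride + 1L
  c0 <- (pos$j - 1L) * stride + 1L
  off <- expand.grid(kr = 0:(k - 1), kc = 0:(k - 1), ch = seq_len(cin))
  idx <- matrix(0L, nrow(pos), nrow(off))
  for (m in seq_len(nrow(off)))
    idx[, m] <- (r0 + off$kr[m]) + (c0 + off$kc[m] - 1L) * Hp +
      (off$ch[m] - 1L) * Hp * Wp
  out <- list(idx = idx, oh = oh, ow = ow, Hp = Hp, Wp = Wp)
  .nn_cache[[key]] <- out
  out
}

conv2d_forward <- function(x, Wmat, b, k, stride, pad) {
  d <- dim(x); H <- d[1]; W <- d[2]; cin <- d[3]
  ix <- conv2d_index(H, W, cin, k, stride, pad)
  xp <- array(0, c(ix$Hp, ix$Wp, cin))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  P <- matrix(xp[ix$idx], nrow(ix$idx), ncol(ix$idx))
  Y <- P %*% Wmat
  Y <- sweep(Y, 2, b, "+")
  list(out = array(Y, c(ix$oh, ix$ow, ncol(Wmat))),
       cache = list(P = P, ix = ix, H = H, W = W, cin = cin, pad = pad))
}

conv2d_backward <- function(dout, Wmat, cache) {
  ix <- cache$ix
  dY <- matrix(dout, nrow(ix$idx), ncol(Wmat))
  dW <- crossprod(cache$P, dY)
  db <- colSums(dY)
  dP <- dY %*% t(Wmat)
  dxp <- numeric(ix$Hp * ix$Wp * cache$cin)
  for (m in seq_len(ncol(ix$idx)))
    dxp[ix$idx[, m]] <- dxp[ix$idx[, m]] + dP[, m]
  dxp <- array(dxp, c(ix$Hp, ix$Wp, cache$cin))
  dx <- dxp[cache$pad + seq_len(cache$H), cache$pad + seq_len(cache$W), ,
            drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# patch-index matrix for 3D convolution on a padded D x H x W x cin input
conv3d_index <- function(D, H, W, cin, k, stride, pad) {
  key <- paste("c3", D, H, W, cin, k, paste(stride, collapse = "."), pad,
               sep = "_")
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Dp <- D + 2 * pad; Hp <- H + 2 * pad; Wp <- W + 2 * pad
  od <- (Dp - k) %/% stride[1] + 1L
  oh <- (Hp - k) %/% stride[2] + 1L
  ow <- (Wp - k) %/% stride[3] + 1L
  pos <- expand.grid(d = seq_len(od), i = seq_len(oh), j = seq_len(ow))
  d0 <- (pos$d - 1L) * stride[1] + 1L
  r0 <- (pos$i - 1L) * stride[2] + 1L
  c0 <- (pos$j - 1L) * stride[3] + 1L
  off <- expand.grid(kd = 0:(k - 1), kr = 0:(k - 1), kc = 0:(k - 1),
                     ch = seq_len(cin))
  idx <- matrix(0L, nrow(pos), nrow(off))
  for (m in seq_len(nrow(off)))
    idx[, m] <- (d0 + off$kd[m]) + (r0 + off$kr[m] - 1L) * Dp +
      (c0 + off$kc[m] - 1L) * Dp * Hp + (off$ch[m] - 1L) * Dp * Hp * Wp
  out <- list(idx = idx, od = od, oh = oh, ow = ow, Dp = Dp, Hp = Hp, Wp = Wp)
  .nn_cache[[key]] <- out
  out
}

conv3d_forward <- function(x, Wmat, b, k, stride, pad) {
  d <- dim(x)
  ix <- conv3d_index(d[1], d[2], d[3], d[4], k, stride, pad)
  xp <- array(0, c(ix$Dp, ix$Hp, ix$Wp, d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  P <- matrix(xp[ix$idx], nrow(ix$idx), ncol(ix$idx))
  Y <- sweep(P %*% Wmat, 2, b, "+")
  list(out = array(Y, c(ix$od, ix$oh, ix$ow, ncol(Wmat))),
       cache = list(P = P, ix = ix, dims = d, pad = pad))
}

conv3d_backward <- function(dout, Wmat, cache) {
  ix <- cache$ix
  dY <- matrix(dout, nrow(ix$idx), ncol(Wmat))
  dW <- crossprod(cache$P, dY)
  db <- colSums(dY)
  dP <- dY %*% t(Wmat)
  dxp <- numeric(ix$Dp * ix$Hp * ix$Wp * cache$dims[4])
  for (m in seq_len(ncol(ix$idx)))
    dxp[ix$idx[, m]] <- dxp[ix$idx[, m]] + dP[, m]
  dxp <- array(dxp, c(ix$Dp, ix$Hp, ix$Wp, cache$dims[4]))
  p <- cache$pad
  list(dx = dxp[p + seq_len(cache$dims[1]), p + seq_len(cache$dims[2]),
                p + seq_len(cache$dims[3]), , drop = FALSE],
       dW = dW, db = db)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

he_init <- function(fan_in, cout) {
  matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout)
}

# --- architectures ---------------------------------------------------------

init_resnet2p5d <- function(channels, n_blocks, k = 3L) {
  C <- channels
  p <- list(stem.W = he_init(k * k * 1L, C), stem.b = numeric(C),
            reduce.W = he_init(k * k * C, C), reduce.b = numeric(C))
  for (bi in seq_len(n_blocks)) {
    p[[sprintf("block%d.conv1.W", bi)]] <- he_init(k * k * C, C)
    p[[sprintf("block%d.conv1.b", bi)]] <- numeric(C)
    p[[sprintf("block%d.conv2.W", bi)]] <- he_init(k * k * C, C)
    p[[sprintf("block%d.conv2.b", bi)]] <- numeric(C)
  }
  p$head.W <- matrix(stats::rnorm(C, 0, 1 / sqrt(C)), C, 1)
  p$head.b <- 0
  p
}

# forward pass of the shared 2D backbone on one scan -> feature vector
resnet_scan_forward <- function(scan, p, n_blocks, k = 3L, keep = FALSE) {
  x <- array(scan, c(dim(scan), 1L))
  caches <- list()
  s <- conv2d_forward(x, p$stem.W, p$stem.b, k, 2L, 1L)
  h <- relu(s$out); if (keep) caches$stem <- list(c = s$cache, pre = s$out)
  r <- conv2d_forward(h, p$reduce.W, p$reduce.b, k, 2L, 1L)
  h <- relu(r$out); if (keep) caches$reduce <- list(c = r$cache, pre = r$out,
                                                   inp = NULL)
  for (bi in seq_len(n_blocks)) {
    c1 <- conv2d_forward(h, p[[sprintf("block%d.conv1.W", bi)]],
                         p[[sprintf("block%d.conv1.b", bi)]], k, 1L, 1L)
    a <- relu(c1$out)
    c2 <- conv2d_forward(a, p[[sprintf("block%d.conv2.W", bi)]],
                         p[[sprintf("block%d.conv2.b", bi)]], k, 1L, 1L)
    pre <- h + c2$out
    if (keep) caches[[sprintf("block%d", bi)]] <-
        list(c1 = c1$cache, pre1 = c1$out, c2 = c2$cache, pre = pre)
    h <- relu(pre)
  }
  npos <- dim(h)[1] * dim(h)[2]
  feat <- apply(h, 3, mean)
  if (keep) caches$pool <- list(dims = dim(h), npos = npos)
  list(feat = feat, caches = caches)
}

resnet_scan_backward <- function(dfeat, p, n_blocks, caches, k = 3L) {
  g <- list()
  dims <- caches$pool$dims
  dh <- array(rep(dfeat / caches$pool$npos, each = caches$pool$npos), dims)
  for (bi in rev(seq_len(n_blocks))) {
    cb <- caches[[sprintf("block%d", bi)]]
    dpre <- dh * (cb$pre > 0)
    b2 <- conv2d_backward(dpre, p[[sprintf("block%d.conv2.W", bi)]], cb$c2)
    g[[sprintf("block%d.conv2.W", bi)]] <- b2$dW
    g[[sprintf("block%d.conv2.b", bi)]] <- b2$db
    da <- b2$dx * (cb$pre1 > 0)
    b1 <- conv2d_backward(da, p[[sprintf("block%d.conv1.W", bi)]], cb$c1)
    g[[sprintf("block%d.conv1.W", bi)]] <- b1$dW
    g[[sprintf("block%d.conv1.b", bi)]] <- b1$db
    dh <- dpre + b1$dx           # residual skip
  }
  dpre <- dh * (caches$reduce$pre > 0)
  br <- conv2d_backward(dpre, p$reduce.W, caches$reduce$c)
  g$reduce.W <- br$dW; g$reduce.b <- br$db
  dpre <- br$dx * (caches$stem$pre > 0)
  bs <- conv2d_backward(dpre, p$stem.W, caches$stem$c)
  g$stem.W <- bs$dW; g$stem.b <- bs$db
  g
}

cam3d_plan <- function(width) {
  list(channels = c(width, width, 2L * width, 2L * width, 4L * width,
                    4L * width),
       strides = list(c(1L, 2L, 2L), c(2L, 2L, 2L), c(1L, 2L, 2L),
                      c(2L, 2L, 2L), c(1L, 2L, 2L), c(1L, 1L, 1L)))
}

init_cam3d <- function(width, k = 3L) {
  plan <- cam3d_plan(width)
  cin <- 1L
  p <- list()
  for (l in 1:6) {
    cout <- plan$channels[l]
    p[[sprintf("conv%d.W", l)]] <- he_init(k^3 * cin, cout)
    p[[sprintf("conv%d.b", l)]] <- numeric(cout)
    cin <- cout
  }
  p$head.W <- matrix(stats::rnorm(cin, 0, 1 / sqrt(cin)), cin, 1)
  p$head.b <- 0
  p
}

cam3d_forward <- function(vol, p, width, k = 3L, keep = FALSE) {
  plan <- cam3d_plan(width)
  x <- array(vol, c(dim(vol), 1L))
  caches <- list()
  for (l in 1:6) {
    cv <- conv3d_forward(x, p[[sprintf("conv%d.W", l)]],
                         p[[sprintf("conv%d.b", l)]], k, plan$strides[[l]], 1L)
    if (keep) caches[[l]] <- list(c = cv$cache, pre = cv$out)
    x <- relu(cv$out)
  }
  npos <- prod(dim(x)[1:3])
  feat <- apply(x, 4, mean)
  if (keep) caches$pool <- list(dims = dim(x), npos = npos)
  list(feat = feat, caches = caches)
}

cam3d_backward <- function(dfeat, p, width, caches, k = 3L) {
  g <- list()
  dims <- caches$pool$dims
  dx <- array(rep(dfeat / caches$pool$npos, each = caches$pool$npos), dims)
  for (l in 6:1) {
    dpre <- dx * (caches[[l]]$pre > 0)
    bk <- conv3d_backward(dpre, p[[sprintf("conv%d.W", l)]], caches[[l]]$c)
    g[[sprintf("conv%d.W", l)]] <- bk$dW
    g[[sprintf("conv%d.b", l)]] <- bk$db
    dx <- bk$dx
  }
  g
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

accumulate_grads <- function(total, g, scale = 1) {
  if (is.null(total)) return(lapply(g, function(x) x * scale))
  for (nm in names(g)) total[[nm]] <- total[[nm]] + g[[nm]] * scale
  total
}
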