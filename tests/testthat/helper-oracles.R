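# Independent oracles used across tests. These deliberately avoid the code
# paths they check: brute-force enumeration, direct formula evaluation, and
# a from-scratch resampler.

# AUROC as the explicit fraction of concordant positive/negative pairs,
# ties counted half. O(n^2).
auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Benjamini-Hochberg step-up applied by hand: sort ascending, q_i =
# min_{j >= i} p_(j) * m / j, capped at 1, mapped back to input order.
bh_step_up <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration.
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Bilinear resampler for the augmentation map: p_out = A (p_in - C) + C + t
# with pixel-centre coordinates (centre of pixel i at i - 0.5) and C the
# geometric image centre. Inverse mapping, zero fill.
affine_oracle <- function(img, rotation = 0, translation = c(0, 0),
                          hflip = FALSE, scale = 1) {
  H <- nrow(img); W <- ncol(img)
  th <- rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Fm <- diag(c(1, if (hflip) -1 else 1))
  A <- scale * R %*% Fm
  Ai <- solve(A)
  C <- c(H / 2, W / 2)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    pin <- Ai %*% (c(i - 0.5, j - 0.5) - C - translation) + C
    r <- pin[1] + 0.5; cc <- pin[2] + 0.5   # back to 1-based index space
    r0 <- floor(r); c0 <- floor(cc)
    fr <- r - r0; fc <- cc - c0
    px <- function(rr, ccx) if (rr >= 1 && rr <= H && ccx >= 1 && ccx <= W)
      img[rr, ccx] else 0
    out[i, j] <- (1 - fr) * (1 - fc) * px(r0, c0) +
      (1 - fr) * fc * px(r0, c0 + 1) +
      fr * (1 - fc) * px(r0 + 1, c0) +
      fr * fc * px(r0 + 1, c0 + 1)
  }
  out
}

# Grid-search maximum likelihood for a univariate logistic regression.
logit_mle_grid <- function(x, y, b0_range = c(-4, 4), b1_range = c(-4, 4),
                           n_grid = 161) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  b0s <- seq(b0_range[1], b0_range[2], length.out = n_grid)
  b1s <- seq(b1_range[1], b1_range[2], length.out = n_grid)
  best <- c(NA, NA); best_ll <- -Inf
  for (b0 in b0s) for (b1 in b1s) {
    v <- ll(b0, b1)
    if (v > best_ll) { best_ll <- v; best <- c(b0, b1) }
  }
  c(b0 = best[1], b1 = best[2])
}

# Round-robin per-stratum fold counts: the balanced reference that a
# stratified fold assignment must match in distribution.
round_robin_counts <- function(n, n_folds = 5) {
  counts <- rep(n %/% n_folds, n_folds)
  if (n %% n_folds > 0) counts[seq_len(n %% n_folds)] <- counts[1] + 1
  sort(counts, decreasing = TRUE)
}
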