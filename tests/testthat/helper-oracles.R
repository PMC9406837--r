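# Brute-force reference implementations used as independent oracles.
# These deliberately use naive explicit loops, not the package's vectorised
# code paths.

rand_gray <- function(h, w) matrix(runif(h * w, 0, 255), h, w)

rand_rgb <- function(h, w) array(runif(h * w * 3, 0, 255), dim = c(h, w, 3))

# valid cross-correlation with zero padding, quadruple loop
oracle_conv2 <- function(x, filt, stride = 1L, pad = 0L) {
  h <- nrow(x); w <- ncol(x)
  xp <- matrix(0, h + 2 * pad, w + 2 * pad)
  xp[pad + seq_len(h), pad + seq_len(w)] <- x
  kh <- nrow(filt); kw <- ncol(filt)
  oh <- (nrow(xp) - kh) %/% stride + 1L
  ow <- (ncol(xp) - kw) %/% stride + 1L
  out <- matrix(NA_real_, oh, ow)
  for (oi in seq_len(oh)) for (oj in seq_len(ow)) {
    s <- 0
    for (a in seq_len(kh)) for (b in seq_len(kw)) {
      s <- s + xp[(oi - 1) * stride + a, (oj - 1) * stride + b] * filt[a, b]
    }
    out[oi, oj] <- s
  }
  out
}

oracle_pool <- function(x, k, stride = k, fun = max) {
  oh <- (nrow(x) - k) %/% stride + 1L
  ow <- (ncol(x) - k) %/% stride + 1L
  out <- matrix(NA_real_, oh, ow)
  for (oi in seq_len(oh)) for (oj in seq_len(ow)) {
    vals <- c()
    for (a in seq_len(k)) for (b in seq_len(k)) {
      vals <- c(vals, x[(oi - 1) * stride + a, (oj - 1) * stride + b])
    }
    out[oi, oj] <- fun(vals)
  }
  out
}

# convolution with edge-inclusive symmetric padding, same size as input
oracle_conv_reflect <- function(x, kernel) {
  h <- nrow(x); w <- ncol(x)
  kh <- nrow(kernel); kw <- ncol(kernel)
  rh <- (kh - 1) / 2; rw <- (kw - 1) / 2
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    s <- 0
    for (a in seq_len(kh)) for (b in seq_len(kw)) {
      ii <- refl(i + a - 1 - rh, h)
      jj <- refl(j + b - 1 - rw, w)
      s <- s + x[ii, jj] * kernel[a, b]
    }
    out[i, j] <- s
  }
  out
}

# Eq-style 24-term LBP code by explicit neighbour enumeration
oracle_lbp_code <- function(g, i, j) {
  gc <- g[i, j]
  code <- 0
  p <- 0
  for (di in -2:2) for (dj in -2:2) {
    if (di == 0 && dj == 0) next
    gp <- g[i + di, j + dj]
    if (gp - gc >= 0) code <- code + 2^p
    p <- p + 1
  }
  code
}

# 2x2 block Haar transform by explicit block loops
oracle_haar <- function(g) {
  if (nrow(g) %% 2 == 1) g <- rbind(g, g[nrow(g), ])
  if (ncol(g) %% 2 == 1) g <- cbind(g, g[, ncol(g)])
  nh <- nrow(g) / 2; nw <- ncol(g) / 2
  LL <- LH <- HL <- HH <- matrix(NA_real_, nh, nw)
  for (bi in seq_len(nh)) for (bj in seq_len(nw)) {
    a <- g[2 * bi - 1, 2 * bj - 1]; b <- g[2 * bi - 1, 2 * bj]
    cc <- g[2 * bi, 2 * bj - 1]; d <- g[2 * bi, 2 * bj]
    LL[bi, bj] <- (a + b + cc + d) / 2
    LH[bi, bj] <- (a + b - cc - d) / 2
    HL[bi, bj] <- (a - b + cc - d) / 2
    HH[bi, bj] <- (a - b - cc + d) / 2
  }
  list(LL = LL, LH = LH, HL = HL, HH = HH)
}

# symmetric normalised co-occurrence matrix by per-pixel pair enumeration;
# q holds integer levels 0..L-1
oracle_glcm <- function(q, L, off) {
  M <- matrix(0, L, L)
  h <- nrow(q); w <- ncol(q)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 >= 1 && i2 <= h && j2 >= 1 && j2 <= w) {
      M[q[i, j] + 1, q[i2, j2] + 1] <- M[q[i, j] + 1, q[i2, j2] + 1] + 1
      M[q[i2, j2] + 1, q[i, j] + 1] <- M[q[i2, j2] + 1, q[i, j] + 1] + 1
    }
  }
  M / sum(M)
}

# Haralick's 13 statistics by naive double sums over matrix cells
oracle_haralick <- function(P) {
  L <- nrow(P)
  lg <- function(x) if (x > 0) log2(x) else 0
  px <- sapply(seq_len(L), function(i) sum(P[i, ]))
  mu <- sum(seq_len(L) * px)
  sg2 <- sum((seq_len(L) - mu)^2 * px)

  asm <- contrast <- corr_num <- variance <- idm <- entropy <- 0
  psum <- numeric(2 * L); pdiff <- numeric(L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    p <- P[i, j]
    asm <- asm + p^2
    contrast <- contrast + (i - j)^2 * p
    corr_num <- corr_num + (i - mu) * (j - mu) * p
    variance <- variance + (i - mu)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    entropy <- entropy - p * lg(p)
    psum[i + j] <- psum[i + j] + p
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p
  }
  correlation <- if (sg2 > 0) corr_num / sg2 else 0
  sum_avg <- sum((1:(2 * L)) * psum)
  sum_var <- sum(((1:(2 * L)) - sum_avg)^2 * psum)
  sum_ent <- -sum(sapply(psum, function(p) p * lg(p)))
  mu_d <- sum((0:(L - 1)) * pdiff)
  diff_var <- sum(((0:(L - 1)) - mu_d)^2 * pdiff)
  diff_ent <- -sum(sapply(pdiff, function(p) p * lg(p)))
  hx <- -sum(sapply(px, function(p) p * lg(p)))
  hxy1 <- hxy2 <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) {
    hxy1 <- hxy1 - P[i, j] * lg(px[i] * px[j])
    hxy2 <- hxy2 - px[i] * px[j] * lg(px[i] * px[j])
  }
  imc1 <- if (hx > 0) (entropy - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  c(asm, contrast, correlation, variance, idm, sum_avg, sum_var, sum_ent,
    entropy, diff_var, diff_ent, imc1, imc2)
}

oracle_glcm13 <- function(q, L) {
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  rowMeans(sapply(offs, function(o) oracle_haralick(oracle_glcm(q, L, o))))
}

# regularised hinge-loss objective for the 2-D SVM toy, for grid search
hinge_objective <- function(w1, b, X, y, C) {
  f <- X[, 1] * w1 + b
  C * sum(pmax(0, 1 - y * f)) + w1^2 / 2
}
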