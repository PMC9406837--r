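#' Luminance gray conversion
#'
#' Converts an H x W x 3 RGB array to a gray matrix with the fixed weights
#' 0.299 R + 0.587 G + 0.114 B. All gray-level texture descriptors (DWT,
#' LBP, GLCM) operate on this conversion.
#'
#' @param img H x W x 3 array in 0..255 (a matrix passes through).
#' @return H x W numeric matrix.
#' @export
rgb_to_gray <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# --- Haar wavelet subband statistics (12) ---------------------------------

# one-level orthonormal 2x2 Haar block transform; odd sizes are
# reflect-padded (last row/column duplicated) to even first
haar_subbands <- function(g) {
  h <- nrow(g); w <- ncol(g)
  if (h < 2L || w < 2L) stop("image must be at least 2x2 for the wavelet transform")
  if (h %% 2L == 1L) g <- rbind(g, g[h, , drop = FALSE])
  if (w %% 2L == 1L) g <- cbind(g, g[, ncol(g), drop = FALSE])
  a <- g[seq(1, nrow(g), 2), seq(1, ncol(g), 2), drop = FALSE]  # top-left
  b <- g[seq(1, nrow(g), 2), seq(2, ncol(g), 2), drop = FALSE]  # top-right
  cc <- g[seq(2, nrow(g), 2), seq(1, ncol(g), 2), drop = FALSE] # bottom-left
  d <- g[seq(2, nrow(g), 2), seq(2, ncol(g), 2), drop = FALSE]  # bottom-right
  list(
    LL = (a + b + cc + d) / 2,
    LH = (a + b - cc - d) / 2,   # horizontal edges (vertical difference)
    HL = (a - b + cc - d) / 2,   # vertical edges
    HH = (a - b - cc + d) / 2    # diagonal detail
  )
}

#' Wavelet subband statistics
#'
#' One-level 2-D orthonormal Haar decomposition into approximation (LL) and
#' horizontal/vertical/diagonal detail subbands (LH, HL, HH); for each
#' subband the mean, population variance and standard deviation are
#' reported, in subband order LL, LH, HL, HH — 12 features. The orthonormal
#' convention preserves total energy (Parseval), so a constant image of
#' value c has LL coefficients equal to 2c and zero detail energy.
#'
#' @param g Gray image matrix, at least 2x2 (odd sizes are reflect-padded).
#' @return Named numeric vector of length 12.
#' @export
dwt_features <- function(g) {
  sb <- haar_subbands(g)
  out <- unlist(lapply(sb, function(s) {
    v <- mean((s - mean(s))^2)
    c(mean = mean(s), var = v, sd = sqrt(v))
  }))
  names(out) <- paste0("dwt_", seq_along(out))
  out
}

# --- 24-neighbour local binary patterns (203) -----------------------------

#' Local binary pattern code at one pixel
#'
#' The 24 neighbours are all pixels of the 5x5 window centred on the target
#' pixel, minus the centre, scanned row-major. Neighbour p (0-based)
#' contributes `2^p` when its gray value is greater than or equal to the
#' centre (ties count as 1), giving a code in `[0, 2^24)`.
#'
#' @param g Gray image matrix.
#' @param i,j Centre position, at least 2 px from every border.
#' @return The integer code as a double (codes exceed 32-bit integers).
#' @export
lbp_code <- function(g, i, j) {
  if (i < 3L || j < 3L || i > nrow(g) - 2L || j > ncol(g) - 2L)
    stop("centre must be at least 2 px from every border")
  win <- g[(i - 2):(i + 2), (j - 2):(j + 2)]
  gc <- win[3, 3]
  neigh <- as.numeric(t(win))[-13L]  # row-major scan, centre removed
  sum((neigh >= gc) * 2^(0:23))
}

lbp_code_matrix <- function(g) {
  h <- nrow(g); w <- ncol(g)
  if (h < 5L || w < 5L) stop("image must be at least 5x5 for LBP")
  ci <- 3:(h - 2L); cj <- 3:(w - 2L)
  centre <- g[ci, cj, drop = FALSE]
  codes <- matrix(0, length(ci), length(cj))
  p <- 0L
  for (di in -2:2) {          # row-major over the 5x5 window
    for (dj in -2:2) {
      if (di == 0L && dj == 0L) next
      codes <- codes + (g[ci + di, cj + dj, drop = FALSE] >= centre) * 2^p
      p <- p + 1L
    }
  }
  codes
}

#' Local binary pattern histogram
#'
#' Computes the 24-bit LBP code at every valid centre and bins the code
#' space `[0, 2^24)` into 203 equal-width bins (the last bin absorbs the
#' division remainder), L1-normalised. Codes depend only on the sign of
#' gray differences, so the histogram is invariant to adding a constant to
#' every pixel.
#'
#' @param g Gray image matrix, at least 5x5.
#' @return Named numeric vector of length 203 summing to 1.
#' @export
lbp_features <- function(g) {
  codes <- lbp_code_matrix(g)
  width <- (2^24) %/% 203          # 82646; last bin absorbs the remainder
  bins <- pmin(floor(codes / width) + 1L, 203L)
  h <- tabulate(bins, nbins = 203L)
  out <- h / sum(h)
  names(out) <- paste0("lbp_", seq_len(203L))
  out
}

# --- fuzzy colour histogram over hue (16) ---------------------------------

rgb_to_hue <- function(img) {
  r <- img[, , 1] / 255; g <- img[, , 2] / 255; b <- img[, , 3] / 255
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  hdeg <- matrix(0, nrow(r), ncol(r))
  idx <- d > 0 & mx == r
  hdeg[idx] <- 60 * (((g - b) / d)[idx] %% 6)
  idx <- d > 0 & mx == g & !(mx == r)
  hdeg[idx] <- 60 * (((b - r) / d)[idx] + 2)
  idx <- d > 0 & mx == b & !(mx == r) & !(mx == g)
  hdeg[idx] <- 60 * (((r - g) / d)[idx] + 4)
  list(hue = hdeg %% 360, achromatic = d == 0)
}

#' Fuzzy colour histogram
#'
#' Each pixel's hue distributes a unit of mass between its two nearest of
#' 16 bin centres spaced evenly on the hue circle (triangular membership
#' with circular wraparound), instead of a hard single-bin assignment; the
#' result is L1-normalised over the image. Achromatic pixels (zero
#' saturation, where hue is undefined) assign their whole mass to bin 1 by
#' convention.
#'
#' @param img H x W x 3 RGB array in 0..255.
#' @return Named numeric vector of length 16 summing to 1.
#' @export
fch_features <- function(img) {
  stopifnot(length(dim(img)) == 3L)
  hu <- rgb_to_hue(img)
  step <- 360 / 16
  pos <- hu$hue / step                   # in [0, 16)
  lo <- floor(pos)                       # lower centre index, 0-based
  frac <- pos - lo
  hist <- numeric(16)
  lo1 <- (lo %% 16) + 1L
  hi1 <- ((lo + 1) %% 16) + 1L
  w_lo <- (1 - frac); w_hi <- frac
  # achromatic pixels: all mass to bin 1
  w_lo[hu$achromatic] <- 1; w_hi[hu$achromatic] <- 0
  lo1[hu$achromatic] <- 1L
  for (k in 1:16) {
    hist[k] <- sum(w_lo[lo1 == k]) + sum(w_hi[hi1 == k & !hu$achromatic])
  }
  out <- hist / sum(hist)
  names(out) <- paste0("fch_", 1:16)
  out
}

# --- Haralick co-occurrence statistics (13) -------------------------------

glcm_offset <- function(theta, d) {
  switch(as.character(theta),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("theta must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pairs of quantised gray levels at the offset implied by
#' direction `theta` and distance `d`, then symmetrises (adds the
#' transpose) and normalises to sum 1. Offsets follow the usual rule: d = 1
#' along rows/columns for theta 0 and 90, the diagonal unit offset
#' (distance sqrt 2 per step) for theta 45 and 135. By default intensities
#' in 0..255 are quantised into `levels` equal-width bins; set
#' `pre_quantized = TRUE` when `g` already holds integer levels in
#' `0..levels-1`.
#'
#' @param g Gray image matrix.
#' @param theta Direction in degrees: 0, 45, 90 or 135.
#' @param d Offset distance in pixels (diagonal steps count 1 per step).
#' @param levels Number of gray levels L (default 8).
#' @param pre_quantized Interpret `g` as ready-made levels.
#' @return An L x L matrix of class `glcm_matrix`, symmetric, summing to 1.
#' @export
glcm_matrix <- function(g, theta = 0, d = 1L, levels = 8L,
                        pre_quantized = FALSE) {
  q <- if (pre_quantized) {
    if (any(g < 0 | g > levels - 1)) stop("pre-quantised levels out of range")
    g
  } else {
    pmin(floor(g / (256 / levels)), levels - 1)
  }
  off <- glcm_offset(theta, as.integer(d))
  h <- nrow(q); w <- ncol(q)
  ri <- seq_len(h); ci <- seq_len(w)
  ri2 <- ri + off[1]; ci2 <- ci + off[2]
  keep_r <- ri2 >= 1L & ri2 <= h
  keep_c <- ci2 >= 1L & ci2 <= w
  if (!any(keep_r) || !any(keep_c))
    stop("image too small for offset (", off[1], ",", off[2], ")")
  a <- q[ri[keep_r], ci[keep_c], drop = FALSE]
  b <- q[ri2[keep_r], ci2[keep_c], drop = FALSE]
  idx <- a * levels + b + 1
  counts <- tabulate(idx, nbins = levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE)
  P <- P + t(P)
  P <- P / sum(P)
  structure(P, theta = theta, d = d, class = c("glcm_matrix", "matrix"))
}

# Haralick's 13 statistics from a normalised symmetric GLCM.
# 0 log 0 is taken as 0; correlation and the first information measure are
# defined as 0 when their denominators vanish (constant image).
haralick13 <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P)                 # == colSums for symmetric P
  mu <- sum(seq_len(L) * px)
  sg2 <- sum((seq_len(L) - mu)^2 * px)
  sg <- sqrt(sg2)

  slog <- function(x) ifelse(x > 0, log2(x), 0)

  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sg2 > 0) sum((i - mu) * (j - mu) * P) / sg2 else 0
  variance <- sum((i - mu)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))

  # p_{x+y}(k), k = 2..2L and p_{x-y}(k), k = 0..L-1
  psum <- vapply(2:(2 * L), function(k) sum(P[i + j == k]), numeric(1))
  pdiff <- vapply(0:(L - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * L); kd <- 0:(L - 1)

  sum_avg <- sum(ks * psum)
  sum_ent <- -sum(psum * slog(psum))
  sum_var <- sum((ks - sum_avg)^2 * psum)
  entropy <- -sum(P * slog(P))
  mu_d <- sum(kd * pdiff)
  diff_var <- sum((kd - mu_d)^2 * pdiff)
  diff_ent <- -sum(pdiff * slog(pdiff))

  hx <- -sum(px * slog(px))
  pxy <- outer(px, px)
  hxy1 <- -sum(P * slog(pxy))
  hxy2 <- -sum(pxy * slog(pxy))
  imc1 <- if (hx > 0) (entropy - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))

  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_avg = sum_avg, sum_var = sum_var,
    sum_ent = sum_ent, entropy = entropy, diff_var = diff_var,
    diff_ent = diff_ent, imc1 = imc1, imc2 = imc2)
}

#' Direction-averaged Haralick texture features
#'
#' Builds the co-occurrence matrix at each of the four directions (0, 45,
#' 90, 135 degrees; d = 1 for the axial, the unit diagonal offset for the
#' diagonal directions), computes Haralick's 13 statistics per direction
#' (angular second moment, contrast, correlation, sum-of-squares variance,
#' inverse difference moment, sum average, sum variance, sum entropy,
#' entropy, difference variance, difference entropy, and the two
#' information measures of correlation) and averages them over the four
#' directions — 13 features total.
#'
#' @inheritParams glcm_matrix
#' @return Named numeric vector of length 13.
#' @export
glcm_features <- function(g, levels = 8L, pre_quantized = FALSE) {
  thetas <- c(0, 45, 90, 135)
  feats <- vapply(thetas, function(th) {
    haralick13(glcm_matrix(g, theta = th, d = 1L, levels = levels,
                           pre_quantized = pre_quantized))
  }, numeric(13))
  out <- rowMeans(feats)
  names(out) <- paste0("glcm_", names(out))
  out
}

# --- the 244-feature concatenation ----------------------------------------

#' Handcrafted 244-feature descriptor
#'
#' Concatenates the four descriptor blocks in the fixed order
#' DWT (12) || LBP (203) || FCH (16) || GLCM (13), length 244. The gray
#' conversion is computed once and shared by the three gray-level blocks;
#' the fuzzy colour histogram uses the RGB pixels directly.
#'
#' @param img H x W x 3 RGB array in 0..255, at least 5x5.
#' @return Named numeric vector of length 244 with a `blocks` attribute
#'   giving the block layout.
#' @export
handcrafted_features <- function(img) {
  g <- rgb_to_gray(img)
  out <- c(dwt_features(g), lbp_features(g), fch_features(img),
           glcm_features(g))
  attr(out, "blocks") <- c(dwt = 12L, lbp = 203L, fch = 16L, glcm = 13L)
  out
}

#' Handcrafted feature matrix for a set of images
#'
#' @param images List of RGB arrays.
#' @param ids Optional row names.
#' @return n x 244 matrix, rows named by `ids`.
#' @export
handcrafted_matrix <- function(images, ids = NULL) {
  X <- do.call(rbind, lapply(images, handcrafted_features))
  if (!is.null(ids)) rownames(X) <- ids
  X
}
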