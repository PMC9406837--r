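#' @title Slide-image enhancement
#' @description Colour consistency and contrast enhancement for stained
#'   tissue-slide images: gray-world channel scaling, Gaussian smoothing,
#'   a 4-neighbour Laplacian response, and their signed combination.
#' @name preprocessing
NULL

# 2-D convolution with symmetric (edge-reflecting) padding, implemented as a
# shift-and-add over kernel taps so large images stay vectorised.
conv2_reflect <- function(x, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)
  ri <- reflect_index(h, ph)
  ci <- reflect_index(w, pw)
  xp <- x[ri, ci, drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      if (kernel[i, j] == 0) next
      out <- out + kernel[i, j] * xp[i:(i + h - 1L), j:(j + w - 1L)]
    }
  }
  out
}

# index vector 1..n padded by p on both sides with edge-inclusive reflection
reflect_index <- function(n, p) {
  if (p == 0L) return(seq_len(n))
  c(rev(seq_len(min(p, n))), seq_len(n), n + 1L - seq_len(min(p, n)))[
    seq_len(n + 2L * p)]
}

per_channel <- function(img, f) {
  if (length(dim(img)) == 2L) return(f(img))
  out <- img
  for (ch in seq_len(dim(img)[3])) out[, , ch] <- f(img[, , ch])
  out
}

#' Gray-world colour normalisation
#'
#' Scales each RGB channel by (target mean / channel mean), where the target
#' is the mean of the three channel means, then clamps to 0..255. Slides
#' stained or lit unevenly are pulled to a common colour balance; an
#' already-gray image passes through unchanged.
#'
#' @param img H x W x 3 array of intensities in 0..255.
#' @return Image of the same shape, clamped to 0..255.
#' @export
gray_world_normalize <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  mu <- vapply(1:3, function(ch) mean(img[, , ch]), numeric(1))
  if (any(mu == 0)) stop("degenerate input: a channel mean is zero")
  target <- mean(mu)
  out <- img
  for (ch in 1:3) out[, , ch] <- img[, , ch] * (target / mu[ch])
  clamp255(out)
}

# normalised isotropic 2-D Gaussian sampled on a size x size grid
gaussian_kernel <- function(sigma, size = 5L) {
  stopifnot(size %% 2L == 1L)
  r <- (size - 1L) %/% 2L
  g1 <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

#' Gaussian smoothing
#'
#' Per-channel convolution with a normalised isotropic 2-D Gaussian kernel
#' (entries sum to 1) under reflect padding, so constant images are
#' preserved exactly.
#'
#' @param img H x W x 3 array (or H x W matrix).
#' @param sigma Kernel standard deviation in pixels, > 0.
#' @param size Odd kernel side length; default 5.
#' @return Smoothed image, same shape, not clamped.
#' @export
gaussian_smooth <- function(img, sigma = 1, size = 5L) {
  if (sigma <= 0) stop("sigma must be > 0")
  k <- gaussian_kernel(sigma, size)
  per_channel(img, function(ch) conv2_reflect(ch, k))
}

#' Laplacian response
#'
#' Applies the 4-neighbour discrete Laplacian `[[0,1,0],[1,-4,1],[0,1,0]]`
#' per channel under reflect padding. The result is a signed map (not
#' clamped): zero on constant or linear regions, large at edges.
#'
#' @param img H x W x 3 array (or H x W matrix).
#' @return Signed array of the same shape.
#' @export
laplacian_response <- function(img) {
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  per_channel(img, function(ch) conv2_reflect(ch, k))
}

#' Combined enhancement
#'
#' Computes `gaussian_smooth(img, sigma) - laplacian_response(img)` per
#' channel in signed arithmetic, then clamps to 0..255. Subtracting the
#' Laplacian from the smoothed image accentuates edges (unsharp-mask
#' behaviour) while the Gaussian term suppresses pixel noise. `sign = -1`
#' flips the combination to `laplacian - gaussian` for users who prefer the
#' opposite convention.
#'
#' @inheritParams gaussian_smooth
#' @param sign `+1` (default) for smooth minus Laplacian, `-1` to flip.
#' @return Enhanced image, clamped to 0..255.
#' @export
enhance <- function(img, sigma = 1, size = 5L, sign = 1) {
  out <- gaussian_smooth(img, sigma, size) - laplacian_response(img)
  if (sign < 0) out <- -out
  clamp255(out)
}

#' Full preprocessing stage
#'
#' Gray-world normalisation followed by [enhance()]; the per-image pipeline
#' stage applied before any feature extraction.
#'
#' @inheritParams enhance
#' @export
preprocess_image <- function(img, sigma = 1, size = 5L, sign = 1) {
  enhance(gray_world_normalize(img), sigma = sigma, size = size, sign = sign)
}
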