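#' Fit a PCA model on training-phase features
#'
#' Computes the top-k principal components of the training feature matrix
#' (rows centred on the training mean; components are the leading
#' eigenvectors of the training covariance, obtained by singular value
#' decomposition). The requested k is silently lowered to
#' `min(k, n - 1, d)`. To make outputs reproducible each component's
#' largest-magnitude coordinate is made positive. The default k of 1024
#' compresses 4096-dim deep features to the width the fused descriptor
#' expects. Fitting on training rows only (rather than all rows) avoids
#' information leaking from validation/test into the projection; pass all
#' rows explicitly if the leaky variant is wanted.
#'
#' @param train_features n x d numeric matrix, n >= 2.
#' @param k Number of components requested (default 1024).
#' @return A `pca_model`: list with `mean` (length d), `components`
#'   (k_eff x d, orthonormal rows), `ev_share` (explained-variance shares),
#'   `k`, `d`.
#' @export
pca_fit <- function(train_features, k = 1024L) {
  X <- as.matrix(train_features)
  n <- nrow(X); d <- ncol(X)
  if (n < 2L) stop("PCA needs at least 2 training rows")
  k_eff <- min(k, n - 1L, d)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- La.svd(Xc, nu = 0L, nv = min(n, d))
  comp <- sv$vt[seq_len(k_eff), , drop = FALSE]
  # sign convention: largest-magnitude coordinate positive
  for (r in seq_len(k_eff)) {
    m <- which.max(abs(comp[r, ]))
    if (comp[r, m] < 0) comp[r, ] <- -comp[r, ]
  }
  ev <- sv$d^2
  total <- sum(ev)
  structure(
    list(mean = mu, components = comp,
         ev_share = if (total > 0) ev[seq_len(k_eff)] / total
                    else rep(0, k_eff),
         k = k_eff, d = d, n_train = n),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA model: %d -> %d (fit on %d rows); top-5 variance shares: %s\n",
              x$d, x$k, x$n_train,
              paste(signif(utils::head(x$ev_share, 5), 3), collapse = " ")))
  invisible(x)
}

#' Project features onto a fitted PCA model
#'
#' Centres rows on the training mean and projects onto the component rows.
#' Transforming the training mean itself yields the zero vector.
#'
#' @param model A `pca_model`.
#' @param features n x d matrix with d equal to the model's input width.
#' @return n x k matrix.
#' @export
pca_transform <- function(model, features) {
  X <- as.matrix(features)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$d)
    stop("feature width ", ncol(X), " does not match PCA input width ", model$d)
  out <- sweep(X, 2L, model$mean) %*% t(model$components)
  colnames(out) <- paste0("deep_pca_", seq_len(ncol(out)))
  rownames(out) <- rownames(X)
  out
}

#' @export
predict.pca_model <- function(object, newdata, ...) pca_transform(object, newdata)

#' Fuse PCA-reduced deep features with handcrafted features
#'
#' Column-wise concatenation `deep_pca || handcrafted` with block labels;
#' with the default 1024 components and the 244 handcrafted features the
#' fused width is 1268. Rows must align: equal counts and, when both carry
#' row names, identical ids.
#'
#' @param deep_reduced n x k matrix of PCA-reduced deep features.
#' @param handcrafted n x 244 matrix of handcrafted features.
#' @return n x (k + 244) matrix with attribute `blocks = c(deep_pca = k,
#'   handcrafted = 244)`.
#' @export
fuse <- function(deep_reduced, handcrafted) {
  deep_reduced <- as.matrix(deep_reduced)
  handcrafted <- as.matrix(handcrafted)
  if (nrow(deep_reduced) != nrow(handcrafted))
    stop("row counts differ: ", nrow(deep_reduced), " vs ", nrow(handcrafted))
  rd <- rownames(deep_reduced); rh <- rownames(handcrafted)
  if (!is.null(rd) && !is.null(rh) && !identical(rd, rh))
    stop("row ids of the deep and handcrafted blocks are misaligned")
  out <- cbind(deep_reduced, handcrafted)
  attr(out, "blocks") <- c(deep_pca = ncol(deep_reduced),
                           handcrafted = ncol(handcrafted))
  out
}
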