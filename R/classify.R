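#' Train the linear SVM head
#'
#' Fits a maximum-margin linear separator (regularised hinge loss, soft
#' margin constant `C`) on standardised features; standardisation
#' parameters are estimated from the training rows and stored inside the
#' model so prediction stays leak-free. The optimisation is delegated to
#' libsvm (via e1071) behind this interface; the decision function is
#' oriented so that positive scores mean the positive class (malignant).
#'
#' @param X n x d numeric feature matrix.
#' @param y Binary labels; `positive` names the positive class (default
#'   `"malignant"` when present, else the second factor level).
#' @param C Soft-margin cost, > 0 (default 1).
#' @param positive Positive class label.
#' @return A `linear_svm` model with fields `w`, `b`, `center`, `scale`,
#'   `levels`, `positive`, usable with [svm_predict()] / `predict()`.
#' @export
train_linear_svm <- function(X, y, C = 1, positive = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2L)
    stop("need exactly two classes in y, got ", length(lev))
  if (is.null(positive))
    positive <- if ("malignant" %in% lev) "malignant" else lev[2]
  stopifnot(positive %in% lev)
  negative <- setdiff(lev, positive)

  ctr <- colMeans(X)
  scl <- pop_sd(X)
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")

  fit <- e1071::svm(Xs, factor(y, levels = c(negative, positive)),
                    kernel = "linear", cost = C, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # orient: positive class scores above negative on the training data
  sc <- drop(Xs %*% w) + b
  if (mean(sc[y == positive]) < mean(sc[y == negative])) {
    w <- -w; b <- -b
  }
  structure(list(w = w, b = b, center = ctr, scale = scl,
                 C = C, positive = positive, negative = negative),
            class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("Linear SVM head: %d features, C = %g, positive class '%s'\n",
              length(x$w), x$C, x$positive))
  invisible(x)
}

#' @export
coef.linear_svm <- function(object, ...) c(bias = object$b, object$w)

#' Predict with the linear SVM head
#'
#' Standardises with the stored training parameters and thresholds the
#' affine score at zero; a score of exactly zero is assigned to the
#' positive class.
#'
#' @param model A `linear_svm`.
#' @param X Feature matrix with the training width.
#' @param type `"class"` for labels, `"score"` for the signed decision
#'   values.
#' @return Character labels or numeric scores (empty input gives an empty
#'   vector).
#' @export
svm_predict <- function(model, X, type = c("class", "score")) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (nrow(X) == 0L) return(if (type == "class") character(0) else numeric(0))
  if (ncol(X) != length(model$w))
    stop("feature width ", ncol(X), " does not match model width ",
         length(model$w))
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  sc <- drop(Xs %*% model$w) + model$b
  if (type == "score") return(sc)
  ifelse(sc >= 0, model$positive, model$negative)
}

#' @export
predict.linear_svm <- function(object, newdata, type = c("class", "score"), ...) {
  svm_predict(object, newdata, type = match.arg(type))
}

# --- the ANN head ---------------------------------------------------------

#' Training configuration for the ANN head
#'
#' @param max_epochs Maximum full-batch gradient-descent epochs.
#' @param patience Consecutive validation checks without improvement before
#'   stopping (default 6).
#' @param learning_rate Fixed step size (default 0.01).
#' @param seed Seed for the weight initialisation.
#' @param hidden_layout Integer vector of hidden-layer widths. The default
#'   is one hidden layer of 15 units; `rep(10, 10)` or any other layout is
#'   accepted.
#' @param loss `"cross_entropy"` (default) or `"mse"`.
#' @return A `train_config` list.
#' @export
train_config <- function(max_epochs = 200L, patience = 6L,
                         learning_rate = 0.01, seed = 1L,
                         hidden_layout = 15L,
                         loss = c("cross_entropy", "mse")) {
  stopifnot(patience >= 1L, max_epochs >= 1L, learning_rate > 0,
            all(hidden_layout >= 1L))
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 hidden_layout = as.integer(hidden_layout),
                 loss = match.arg(loss)),
            class = "train_config")
}

# population standard deviation per column (duplication-invariant, unlike
# the n-1 sample estimate); zero-variance columns get scale 1
pop_sd <- function(X) {
  s <- sqrt(colMeans(sweep(X, 2L, colMeans(X))^2))
  s[s == 0] <- 1
  s
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

ann_forward <- function(W, B, X) {
  A <- list(X)
  L <- length(W)
  for (l in seq_len(L - 1L)) {
    A[[l + 1L]] <- tanh(sweep(A[[l]] %*% W[[l]], 2L, B[[l]], "+"))
  }
  Z <- sweep(A[[L]] %*% W[[L]], 2L, B[[L]], "+")
  list(A = A, P = softmax_rows(Z))
}

ann_loss <- function(P, Y, loss) {
  if (loss == "cross_entropy") -mean(rowSums(Y * log(pmax(P, 1e-12))))
  else mean((P - Y)^2)
}

#' Train the ANN head
#'
#' A fully connected network — input layer matching the feature width,
#' tanh hidden layer(s) (default one layer of 15 units), and a 2-unit
#' softmax output — trained by full-batch gradient descent on
#' cross-entropy (or squared error). After every epoch the validation loss
#' is checked; when it fails to improve for `patience` consecutive checks,
#' training stops and the best-validation weights are restored. Features
#' are standardised internally on the training rows.
#'
#' @param X,y Training features and binary labels.
#' @param cfg A [train_config()].
#' @param X_val,y_val Non-empty validation set used for early stopping.
#' @param positive Positive class label (default `"malignant"` if present).
#' @return An `ann_model` with the weights, the standardisation parameters,
#'   a per-epoch `log` (train loss, validation loss, gradient norm) and a
#'   `stop_reason` of `"patience"` or `"max_epochs"`.
#' @export
train_ann <- function(X, y, cfg = train_config(), X_val, y_val,
                      positive = NULL) {
  X <- as.matrix(X); X_val <- as.matrix(X_val)
  y <- as.character(y); y_val <- as.character(y_val)
  if (nrow(X_val) == 0L) stop("validation set must be non-empty")
  lev <- sort(unique(y))
  if (length(lev) != 2L) stop("need exactly two classes in y")
  if (is.null(positive))
    positive <- if ("malignant" %in% lev) "malignant" else lev[2]
  negative <- setdiff(lev, positive)
  classes <- c(negative, positive)

  ctr <- colMeans(X)
  scl <- pop_sd(X)
  std <- function(M) sweep(sweep(M, 2L, ctr), 2L, scl, "/")
  Xs <- std(X); Xvs <- std(X_val)
  Y <- outer(y, classes, "==") * 1
  Yv <- outer(y_val, classes, "==") * 1

  sizes <- c(ncol(X), cfg$hidden_layout, 2L)
  L <- length(sizes) - 1L
  W <- vector("list", L); B <- vector("list", L)
  with_seed(cfg$seed, {
    for (l in seq_len(L)) {
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                    sd = sqrt(1 / sizes[l])),
                       sizes[l], sizes[l + 1L])
      B[[l]] <- rep(0, sizes[l + 1L])
    }
  })

  n <- nrow(Xs)
  best <- list(loss = Inf, W = W, B = B, epoch = 0L)
  bad_checks <- 0L
  log_df <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric(), grad_norm = numeric())
  stop_reason <- "max_epochs"

  for (epoch in seq_len(cfg$max_epochs)) {
    fw <- ann_forward(W, B, Xs)
    tl <- ann_loss(fw$P, Y, cfg$loss)
    if (!is.finite(tl))
      stop("training diverged (non-finite loss) at epoch ", epoch)

    # backprop; delta at the softmax output
    delta <- if (cfg$loss == "cross_entropy") (fw$P - Y) / n
             else {
               G <- 2 * (fw$P - Y) / (n * 2)
               (G - rowSums(G * fw$P)) * fw$P  # through softmax jacobian
             }
    gW <- vector("list", L); gB <- vector("list", L)
    for (l in L:1) {
      gW[[l]] <- crossprod(fw$A[[l]], delta)
      gB[[l]] <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(W[[l]])) * (1 - fw$A[[l]]^2)
      }
    }
    gnorm <- sqrt(sum(vapply(seq_len(L), function(l)
      sum(gW[[l]]^2) + sum(gB[[l]]^2), numeric(1))))
    for (l in seq_len(L)) {
      W[[l]] <- W[[l]] - cfg$learning_rate * gW[[l]]
      B[[l]] <- B[[l]] - cfg$learning_rate * gB[[l]]
    }

    vl <- ann_loss(ann_forward(W, B, Xvs)$P, Yv, cfg$loss)
    if (!is.finite(vl))
      stop("training diverged (non-finite validation loss) at epoch ", epoch)
    log_df[epoch, ] <- list(epoch, tl, vl, gnorm)

    if (vl < best$loss - 1e-12) {
      best <- list(loss = vl, W = W, B = B, epoch = epoch)
      bad_checks <- 0L
    } else {
      bad_checks <- bad_checks + 1L
      if (bad_checks >= cfg$patience) { stop_reason <- "patience"; break }
    }
  }

  structure(list(W = best$W, B = best$B, center = ctr, scale = scl,
                 classes = classes, positive = positive, negative = negative,
                 sizes = sizes, cfg = cfg, log = log_df,
                 best_epoch = best$epoch, best_val_loss = best$loss,
                 stop_reason = stop_reason),
            class = "ann_model")
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf(
    "ANN head: layers [%s], stopped by %s at epoch %d (best val loss %.5g at epoch %d)\n",
    paste(x$sizes, collapse = " -> "), x$stop_reason, nrow(x$log),
    x$best_val_loss, x$best_epoch))
  invisible(x)
}

#' @export
summary.ann_model <- function(object, ...) {
  cat("Feed-forward classifier, softmax output, loss:", object$cfg$loss, "\n")
  print(object)
  cat("Last epochs of the training log:\n")
  print(utils::tail(object$log, 5), row.names = FALSE)
  invisible(object$log)
}

#' Predict with the ANN head
#'
#' @param model An `ann_model`.
#' @param X Feature matrix with the training width.
#' @return A list with `labels` (argmax of the softmax) and `scores`
#'   (n x 2 matrix of class probabilities, columns named by class; rows sum
#'   to 1). The second column is the positive-class probability used for
#'   ROC curves.
#' @export
ann_predict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$sizes[1])
    stop("feature width ", ncol(X), " does not match model input width ",
         model$sizes[1])
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  P <- ann_forward(model$W, model$B, Xs)$P
  colnames(P) <- model$classes
  labels <- model$classes[max.col(P, ties.method = "last")]
  list(labels = labels, scores = P)
}

#' @export
predict.ann_model <- function(object, newdata, type = c("class", "prob"), ...) {
  out <- ann_predict(object, newdata)
  if (match.arg(type) == "class") out$labels else out$scores
}
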