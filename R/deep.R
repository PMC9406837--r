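#' Convolutional primitives
#'
#' `conv2d()` computes a valid cross-correlation of a 2-D input with a 2-D
#' filter after zero padding; output side length per axis is
#' `floor((n + 2*pad - k)/stride) + 1`. `max_pool()` and `avg_pool()` apply
#' windowed max / arithmetic mean. `relu()` is element-wise `max(0, x)`.
#' These are the primitive operators the test backbones are built from.
#'
#' @param x Numeric matrix (H x W).
#' @param filt Numeric filter matrix (kh x kw).
#' @param stride Positive integer step.
#' @param pad Nonnegative zero-padding width on every side.
#' @return A numeric matrix of the output size.
#' @examples
#' conv2d(matrix(1, 3, 3), matrix(1, 2, 2))  # all entries 4
#' max_pool(matrix(1:4, 2, 2), k = 2)        # 4
#' @export
conv2d <- function(x, filt, stride = 1L, pad = 0L) {
  stopifnot(stride >= 1L, pad >= 0L)
  kh <- nrow(filt); kw <- ncol(filt)
  h <- nrow(x) + 2L * pad; w <- ncol(x) + 2L * pad
  if (kh > h || kw > w) stop("filter larger than padded input")
  if (pad > 0L) {
    xp <- matrix(0, h, w)
    xp[pad + seq_len(nrow(x)), pad + seq_len(ncol(x))] <- x
    x <- xp
  }
  oh <- (h - kh) %/% stride + 1L
  ow <- (w - kw) %/% stride + 1L
  out <- matrix(0, oh, ow)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      if (filt[i, j] == 0) next
      rows <- seq.int(i, by = stride, length.out = oh)
      cols <- seq.int(j, by = stride, length.out = ow)
      out <- out + filt[i, j] * x[rows, cols, drop = FALSE]
    }
  }
  out
}

pool2d <- function(x, k, stride, op) {
  stopifnot(stride >= 1L)
  h <- nrow(x); w <- ncol(x)
  if (k > h || k > w) stop("pooling window larger than input")
  oh <- (h - k) %/% stride + 1L
  ow <- (w - k) %/% stride + 1L
  out <- matrix(if (identical(op, max)) -Inf else 0, oh, ow)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      rows <- seq.int(i, by = stride, length.out = oh)
      cols <- seq.int(j, by = stride, length.out = ow)
      win <- x[rows, cols, drop = FALSE]
      out <- if (identical(op, max)) pmax(out, win) else out + win
    }
  }
  if (identical(op, max)) out else out / (k * k)
}

#' @rdname conv2d
#' @param k Pooling window side length.
#' @export
max_pool <- function(x, k, stride = k) pool2d(x, k, stride, max)

#' @rdname conv2d
#' @export
avg_pool <- function(x, k, stride = k) pool2d(x, k, stride, mean)

#' @rdname conv2d
#' @export
relu <- function(x) pmax(x, 0)

# --- backbones ------------------------------------------------------------

adapter_registry <- new.env(parent = emptyenv())

#' Register a deep-backbone adapter
#'
#' Adapters plug external feature extractors (e.g. pretrained AlexNet or
#' ResNet-18 via an external runtime) into the fixed-width feature contract.
#' An adapter is a function `(images, output_dim) -> n x output_dim matrix`.
#' Pretrained weights are never required by the package's own tests; note
#' that ResNet-18's natural penultimate width is 512, not 4096, so adapters
#' must state which layer they tap.
#'
#' @param id Adapter identifier (used as `backbone_spec("adapter:<id>")`).
#' @param fun The extraction function.
#' @export
register_backbone_adapter <- function(id, fun) {
  stopifnot(is.character(id), is.function(fun))
  assign(id, fun, envir = adapter_registry)
  invisible(id)
}

#' Deep-feature backbone specification
#'
#' Defines which extractor produces the fixed-width (default 4096) deep
#' feature vectors. `"stub"` is a seeded fixed linear map from 32x32
#' down-sampled pixels; `"minicnn"` is a small conv/relu/maxpool stack
#' (channels 8, 16, 32, 3x3 filters) pooled to a 4x4 grid, flattened and
#' passed through a seeded fixed linear map; `"adapter:<id>"` dispatches to
#' a registered adapter. Stub and mini-CNN are fully determined by
#' `weights_seed`, making feature extraction a pure function of the pixels
#' and the spec.
#'
#' @param name `"stub"`, `"minicnn"`, or `"adapter:<id>"`.
#' @param weights_seed Integer seed fixing the random (untrained) weights.
#' @param output_dim Feature width, >= 1; default 4096.
#' @param input_size Side length images are resized to for minicnn
#'   (bilinear); default 227.
#' @return An object of class `backbone_spec`.
#' @export
backbone_spec <- function(name = c("stub", "minicnn"), weights_seed = 1L,
                          output_dim = 4096L, input_size = 227L) {
  if (length(name) > 1L) name <- name[1]
  if (!grepl("^adapter:", name)) name <- match.arg(name, c("stub", "minicnn"))
  stopifnot(output_dim >= 1L)
  structure(list(name = name, weights_seed = as.integer(weights_seed),
                 output_dim = as.integer(output_dim),
                 input_size = as.integer(input_size)),
            class = "backbone_spec")
}

#' @export
print.backbone_spec <- function(x, ...) {
  cat(sprintf("Backbone '%s': output_dim %d, weights seed %d\n",
              x$name, x$output_dim, x$weights_seed))
  invisible(x)
}

# bilinear resize of a matrix to th x tw
resize_bilinear <- function(m, th, tw) {
  h <- nrow(m); w <- ncol(m)
  if (h == th && w == tw) return(m)
  ys <- (seq_len(th) - 0.5) * h / th + 0.5
  xs <- (seq_len(tw) - 0.5) * w / tw + 0.5
  y0 <- pmin(pmax(floor(ys), 1L), h); y1 <- pmin(y0 + 1L, h)
  x0 <- pmin(pmax(floor(xs), 1L), w); x1 <- pmin(x0 + 1L, w)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE] * ((1 - fy) %o% (1 - fx))
  b <- m[y0, x1, drop = FALSE] * ((1 - fy) %o% fx)
  cc <- m[y1, x0, drop = FALSE] * (fy %o% (1 - fx))
  d <- m[y1, x1, drop = FALSE] * (fy %o% fx)
  a + b + cc + d
}

resize_image <- function(img, side) {
  apply_to_channels(img, function(m) resize_bilinear(m, side, side))
}

# seeded Gaussian weight matrix, scaled like Xavier init
seeded_linear_map <- function(d_in, d_out, seed) {
  with_seed(seed, matrix(stats::rnorm(d_in * d_out, sd = sqrt(1 / d_in)),
                         d_in, d_out))
}

# multichannel 3x3 conv via shift-and-add; x is H x W x Cin, w is array
# (3, 3, Cin, Cout); zero padding 1 keeps the spatial size
conv3x3_mc <- function(x, w) {
  h <- dim(x)[1]; wd <- dim(x)[2]
  cin <- dim(w)[3]; cout <- dim(w)[4]
  out <- array(0, dim = c(h, wd, cout))
  xp <- array(0, dim = c(h + 2L, wd + 2L, cin))
  xp[2:(h + 1L), 2:(wd + 1L), ] <- x
  for (co in seq_len(cout)) {
    acc <- matrix(0, h, wd)
    for (ci in seq_len(cin)) {
      for (i in 1:3) for (j in 1:3) {
        wij <- w[i, j, ci, co]
        if (wij == 0) next
        acc <- acc + wij * xp[i:(i + h - 1L), j:(j + wd - 1L), ci]
      }
    }
    out[, , co] <- acc
  }
  out
}

pool_channels <- function(x, k, stride = k) {
  chans <- lapply(seq_len(dim(x)[3]), function(c) max_pool(x[, , c], k, stride))
  array(unlist(chans), dim = c(dim(chans[[1]]), dim(x)[3]))
}

minicnn_weights <- function(seed) {
  with_seed(seed, {
    chans <- c(3L, 8L, 16L, 32L)
    lapply(1:3, function(b) {
      cin <- chans[b]; cout <- chans[b + 1L]
      array(stats::rnorm(9L * cin * cout, sd = sqrt(2 / (9 * cin))),
            dim = c(3L, 3L, cin, cout))
    })
  })
}

minicnn_forward <- function(img, weights) {
  x <- img / 255
  for (b in 1:3) {
    x <- conv3x3_mc(x, weights[[b]])
    x <- relu(x)
    x <- pool_channels(x, 2L)
  }
  # adaptive max pool to a 4x4 grid before flattening
  side <- dim(x)[1]
  k <- max(1L, side %/% 4L)
  x <- pool_channels(x, k, k)
  x <- x[1:min(4L, dim(x)[1]), 1:min(4L, dim(x)[2]), , drop = FALSE]
  as.numeric(x)
}

#' Extract deep features for a set of images
#'
#' Runs the backbone over every image and returns an n x `output_dim`
#' feature matrix with image ids as row names. Deterministic for fixed
#' `(images, backbone)`.
#'
#' @param images List of H x W x 3 arrays in 0..255.
#' @param backbone A [backbone_spec()].
#' @param ids Optional row names.
#' @return Numeric matrix, one row per image.
#' @export
extract_deep_features <- function(images, backbone = backbone_spec(),
                                  ids = NULL) {
  stopifnot(inherits(backbone, "backbone_spec"))
  n <- length(images)
  if (grepl("^adapter:", backbone$name)) {
    id <- sub("^adapter:", "", backbone$name)
    fun <- if (exists(id, envir = adapter_registry)) get(id, envir = adapter_registry)
    if (is.null(fun)) stop("unknown backbone adapter '", id, "'")
    out <- fun(images, backbone$output_dim)
  } else if (backbone$name == "stub") {
    d_in <- 32L * 32L * 3L
    W <- seeded_linear_map(d_in, backbone$output_dim, backbone$weights_seed)
    X <- matrix(0, n, d_in)
    for (i in seq_len(n)) X[i, ] <- as.numeric(resize_image(images[[i]], 32L)) / 255
    out <- X %*% W
  } else {  # minicnn
    weights <- minicnn_weights(backbone$weights_seed)
    feats <- lapply(images, function(img) {
      minicnn_forward(resize_image(img, backbone$input_size), weights)
    })
    d_in <- length(feats[[1]])
    W <- seeded_linear_map(d_in, backbone$output_dim,
                           backbone$weights_seed + 1L)
    out <- do.call(rbind, feats) %*% W
  }
  if (!is.null(ids)) rownames(out) <- ids
  colnames(out) <- paste0("deep_", seq_len(ncol(out)))
  out
}
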