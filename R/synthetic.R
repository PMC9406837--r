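#' Synthetic two-class histology-like image specification
#'
#' Builds the parameter object consumed by [generate_dataset()]. The two
#' classes emulate H&E-stained tissue at the level the downstream descriptors
#' care about: a per-class base colour (eosin-pink stroma for normal tissue,
#' a darker hematoxylin purple for malignant), dark nucleus-like blobs with
#' Gaussian-soft edges placed by a seeded uniform process, a sinusoidal
#' texture modulation, and additive Gaussian pixel noise. Identical
#' `(spec, seed)` pairs reproduce identical pixel arrays bit for bit.
#'
#' Two named presets are provided. `"separable"` places the class parameters
#' far apart in colour and texture so that colour and texture descriptors
#' separate the classes almost perfectly; `"hard"` moves the base colours
#' close together and raises the noise so the classes overlap.
#'
#' @param preset Either `"separable"` (default) or `"hard"`, or `NULL` when
#'   `class_params` is supplied directly.
#' @param image_size Integer height/width in pixels, length 1 or 2. Default
#'   227x227, the conventional deep-backbone input size.
#' @param class_params Optional named list with elements `normal` and
#'   `malignant`, each a list with fields `base_color` (RGB triple in
#'   0..255), `blob_density` (expected blobs per 10^4 pixels, >= 0),
#'   `blob_radius_range` (min/max radius in px), `texture_freq` (cycles per
#'   image), `texture_amp` (intensity units), `noise_sd` (intensity units,
#'   >= 0). Overrides the preset.
#' @param seed Integer seed controlling every random draw of the generator.
#' @return An object of class `synthetic_spec`.
#' @examples
#' spec <- synthetic_spec("separable", image_size = 64, seed = 7)
#' ds <- generate_dataset(spec, n_per_class = 2)
#' sapply(ds$images, dim)
#' @export
synthetic_spec <- function(preset = "separable", image_size = c(227L, 227L),
                           class_params = NULL, seed = 1L) {
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  image_size <- as.integer(image_size)
  if (any(image_size < 8L)) stop("image_size must be at least 8 px per side")

  if (is.null(class_params)) {
    class_params <- switch(match.arg(preset, c("separable", "hard")),
      separable = list(
        normal = list(
          base_color = c(235, 180, 210),     # pale eosin pink
          blob_density = 4,                   # blobs per 10^4 px
          blob_radius_range = c(3, 6),
          texture_freq = 4,
          texture_amp = 8,
          noise_sd = 4
        ),
        malignant = list(
          base_color = c(140, 85, 150),       # darker hematoxylin purple
          blob_density = 12,
          blob_radius_range = c(2, 5),
          texture_freq = 12,
          texture_amp = 14,
          noise_sd = 6
        )
      ),
      hard = list(
        normal = list(
          base_color = c(200, 150, 180),
          blob_density = 8,
          blob_radius_range = c(2, 5),
          texture_freq = 8,
          texture_amp = 8,
          noise_sd = 18
        ),
        malignant = list(
          base_color = c(185, 135, 170),
          blob_density = 10,
          blob_radius_range = c(2, 5),
          texture_freq = 10,
          texture_amp = 8,
          noise_sd = 18
        )
      )
    )
  }
  for (cl in c("normal", "malignant")) {
    p <- class_params[[cl]]
    if (is.null(p)) stop("class_params must define class '", cl, "'")
    if (p$blob_density < 0) stop("blob_density must be >= 0")
    if (p$noise_sd < 0) stop("noise_sd must be >= 0")
    if (is.null(p$texture_amp)) class_params[[cl]]$texture_amp <- 8
  }
  structure(
    list(image_size = image_size, class_params = class_params,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic H&E-like image spec:", x$image_size[1], "x", x$image_size[2],
      "px, seed", x$seed, "\n")
  for (cl in names(x$class_params)) {
    p <- x$class_params[[cl]]
    cat(sprintf("  %-9s base RGB (%s)  blobs/1e4px %.1f  texture %g cyc  noise sd %g\n",
                cl, paste(p$base_color, collapse = ","), p$blob_density,
                p$texture_freq, p$noise_sd))
  }
  invisible(x)
}

# Evaluate a function with a private RNG stream, restoring global state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Render one image from class parameters; returns H x W x 3 integers 0..255.
render_image <- function(p, h, w) {
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- p$base_color[ch]

  # sinusoidal texture shared by all channels
  if (p$texture_freq > 0 && p$texture_amp > 0) {
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    tex <- p$texture_amp * sin(2 * pi * p$texture_freq * xx / w) *
      sin(2 * pi * p$texture_freq * yy / h)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + tex
  }

  # nucleus-like blobs: dark disks with Gaussian-soft edges
  n_blobs <- round(p$blob_density * h * w / 1e4)
  if (n_blobs > 0) {
    cy <- runif(n_blobs, 1, h)
    cx <- runif(n_blobs, 1, w)
    rr <- runif(n_blobs, p$blob_radius_range[1], p$blob_radius_range[2])
    blob_color <- p$base_color * 0.45  # darker chromatin tone
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (b in seq_len(n_blobs)) {
      d2 <- (yy - cy[b])^2 + (xx - cx[b])^2
      alpha <- exp(-d2 / (2 * (rr[b] / 1.5)^2))
      alpha[d2 > (3 * rr[b])^2] <- 0
      for (ch in 1:3) {
        img[, , ch] <- (1 - alpha) * img[, , ch] + alpha * blob_color[ch]
      }
    }
  }

  if (p$noise_sd > 0) {
    img <- img + array(stats::rnorm(h * w * 3, sd = p$noise_sd), dim = c(h, w, 3))
  }
  clamp255(round(img))
}

clamp255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

#' Generate a seeded two-class synthetic image set
#'
#' Draws `n_per_class` images per class from the spec's class parameters.
#' All randomness comes from `spec$seed`: the same `(spec, n_per_class)`
#' reproduces identical pixel arrays. Pixels are rounded to integers in
#' 0..255 so PNG round-trips are lossless.
#'
#' @param spec A [synthetic_spec()] object.
#' @param n_per_class Number of images per class, >= 1.
#' @return A `labeled_image_set`: list with `images` (list of H x W x 3
#'   arrays), `labels` (character, `"normal"`/`"malignant"`) and unique `ids`.
#' @export
generate_dataset <- function(spec, n_per_class) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(n_per_class) != 1L || n_per_class < 1)
    stop("n_per_class must be a positive count")
  n_per_class <- as.integer(n_per_class)
  h <- spec$image_size[1]; w <- spec$image_size[2]

  images <- vector("list", 2L * n_per_class)
  labels <- character(2L * n_per_class)
  ids <- character(2L * n_per_class)
  with_seed(spec$seed, {
    k <- 0L
    for (cl in c("normal", "malignant")) {
      p <- spec$class_params[[cl]]
      for (i in seq_len(n_per_class)) {
        k <- k + 1L
        images[[k]] <- render_image(p, h, w)
        labels[k] <- cl
        ids[k] <- sprintf("%s_%04d", cl, i)
      }
    }
  })
  structure(list(images = images, labels = labels, ids = ids),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat("Labeled image set:", length(x$images), "images (",
      paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Read and write RGB images
#'
#' `read_image()` reads a PNG or JPEG file into an H x W x 3 array of
#' intensities in 0..255; `write_image()` writes one. PNG round-trips are
#' lossless for integer-valued images. JPEG support requires the EBImage
#' package.
#'
#' @param path File path ending in `.png`, `.jpg` or `.jpeg`.
#' @param img H x W x 3 numeric array with values in 0..255 (a gray H x W
#'   matrix is promoted to three equal channels on write).
#' @return `read_image()` returns the pixel array; `write_image()` returns
#'   `path` invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("JPEG support requires the EBImage package; cannot read ", path)
    px <- EBImage::imageData(EBImage::readImage(path))
    # EBImage stores x,y(,c); transpose back to row = y
    px <- if (length(dim(px)) == 3L) aperm(px, c(2, 1, 3)) else t(px)
  } else {
    stop("unsupported image format '", ext, "' for ", path)
  }
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  round(px * 255)
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  ext <- tolower(tools::file_ext(path))
  scaled <- clamp255(img) / 255
  if (ext == "png") {
    png::writePNG(scaled, target = path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("JPEG support requires the EBImage package; cannot write ", path)
    EBImage::writeImage(EBImage::Image(aperm(scaled, c(2, 1, 3)),
                                       colormode = "Color"), path)
  } else {
    stop("unsupported image format '", ext, "' for ", path)
  }
  invisible(path)
}

#' Write a labeled image set to disk with a manifest
#'
#' Writes each image as `<id>.png` under `dir` and a `manifest.csv` with
#' columns `id,path,label`, the on-disk interchange format of the pipeline.
#'
#' @param ds A `labeled_image_set`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_image_set <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(ds$ids, ".png"))
  for (i in seq_along(ds$images)) write_image(ds$images[[i]], paths[i])
  manifest <- data.frame(id = ds$ids, path = paths, label = ds$labels,
                         stringsAsFactors = FALSE)
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}

#' Read a labeled image set from a manifest CSV
#'
#' @param manifest Path to a CSV with columns `id,path,label`; relative image
#'   paths are resolved against the manifest's directory.
#' @return A `labeled_image_set`.
#' @export
read_image_set <- function(manifest) {
  if (!file.exists(manifest)) stop("cannot read manifest: ", manifest)
  m <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "path", "label") %in% names(m)))
  paths <- ifelse(file.exists(m$path), m$path,
                  file.path(dirname(manifest), m$path))
  images <- lapply(paths, read_image)
  structure(list(images = images, labels = m$label, ids = m$id),
            class = "labeled_image_set")
}
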