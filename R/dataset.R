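#' Stratified train/validation/test split
#'
#' Splits image ids into phases with the floor-based two-level 80/20 rule,
#' stratified by class: per class of size N, the test phase holds
#' `N - floor(0.8 N)` images; the remaining `floor(0.8 N)` are split again
#' so the train phase holds `floor(0.8 * floor(0.8 N))` and validation the
#' rest. Membership within a class is a seeded uniform permutation. With
#' class sizes 2494/2698 this reproduces counts 1596/399/499 (normal) and
#' 1726/432/540 (malignant).
#'
#' @param labels Character/factor class labels, one per image.
#' @param seed Integer seed for the permutation.
#' @param ids Optional unique id per image; defaults to `img_<i>`.
#' @return A `split_assignment`: data frame with columns `id`, `label`,
#'   `phase` (train/val/test) and attribute `seed`.
#' @examples
#' sp <- stratified_split(rep(c("normal", "malignant"), c(10, 10)), seed = 1)
#' table(sp$label, sp$phase)
#' @export
stratified_split <- function(labels, seed = 1L, ids = NULL) {
  labels <- as.character(labels)
  if (is.null(ids)) ids <- sprintf("img_%05d", seq_along(labels))
  stopifnot(length(ids) == length(labels), !anyDuplicated(ids))
  tab <- table(labels)
  if (any(tab < 2)) stop("every class needs at least 2 images to split")

  phase <- character(length(labels))
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      n <- length(idx)
      n_trainval <- floor(0.8 * n)
      n_train <- floor(0.8 * n_trainval)
      n_val <- n_trainval - n_train
      perm <- sample(idx)
      phase[perm[seq_len(n_train)]] <- "train"
      phase[perm[n_train + seq_len(n_val)]] <- "val"
      phase[perm[(n_trainval + 1):n]] <- "test"
    }
  })
  structure(
    data.frame(id = ids, label = labels, phase = phase,
               stringsAsFactors = FALSE),
    seed = as.integer(seed),
    class = c("split_assignment", "data.frame")
  )
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("Stratified split (seed", attr(x, "seed"), "):\n")
  print(table(x$label, factor(x$phase, c("train", "val", "test"))))
  invisible(x)
}

# --- the fixed 12-variant augmentation menu -------------------------------

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

apply_to_channels <- function(img, f) {
  chans <- lapply(seq_len(dim(img)[3]), function(ch) f(img[, , ch]))
  array(unlist(chans), dim = c(dim(chans[[1]]), length(chans)))
}

shift_reflect <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  # reading index i - d with edge-inclusive reflection implements a shift by d
  ri <- reflect_shift_index(h, dy)
  ci <- reflect_shift_index(w, dx)
  m[ri, ci, drop = FALSE]
}

reflect_shift_index <- function(n, d) {
  idx <- seq_len(n) - d
  idx <- ifelse(idx < 1L, 1L - idx + 0L, idx)       # reflect below: 0 -> 1, -1 -> 2
  idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)    # reflect above
  pmin(pmax(idx, 1L), n)
}

#' The 12 deterministic augmentation transforms
#'
#' Named list of image transforms applied to every training image:
#' rotations by 90/180/270 degrees, horizontal and vertical flips, shifts by
#' +/-10% along x and y with reflect fill, and the three 90-degree rotations
#' of the horizontally flipped image.
#'
#' @return Named list of functions, each mapping an H x W x 3 array to a
#'   transformed array.
#' @export
augmentation_menu <- function() {
  fliph <- function(m) m[, ncol(m):1, drop = FALSE]
  flipv <- function(m) m[nrow(m):1, , drop = FALSE]
  mk <- function(f) function(img) apply_to_channels(img, f)
  list(
    rot90  = mk(rot90cw),
    rot180 = mk(function(m) rot90cw(rot90cw(m))),
    rot270 = mk(function(m) rot90cw(rot90cw(rot90cw(m)))),
    fliph  = mk(fliph),
    flipv  = mk(flipv),
    shiftxp = function(img) apply_to_channels(img, function(m)
      shift_reflect(m, 0L, as.integer(round(0.1 * ncol(m))))),
    shiftxm = function(img) apply_to_channels(img, function(m)
      shift_reflect(m, 0L, -as.integer(round(0.1 * ncol(m))))),
    shiftyp = function(img) apply_to_channels(img, function(m)
      shift_reflect(m, as.integer(round(0.1 * nrow(m))), 0L)),
    shiftym = function(img) apply_to_channels(img, function(m)
      shift_reflect(m, -as.integer(round(0.1 * nrow(m))), 0L)),
    fliph_rot90  = mk(function(m) rot90cw(fliph(m))),
    fliph_rot180 = mk(function(m) rot90cw(rot90cw(fliph(m)))),
    fliph_rot270 = mk(function(m) rot90cw(rot90cw(rot90cw(fliph(m)))))
  )
}

#' Deterministic 12-fold training-set augmentation
#'
#' Expands every training image into exactly 12 derived variants (see
#' [augmentation_menu()]). Only training-phase images may be augmented;
#' validation and test images are left untouched by design, and passing one
#' is an error. With 1596 and 1726 training images per class this produces
#' the 19,152 / 20,712 augmented counts.
#'
#' @param images List of H x W x 3 arrays (training images only).
#' @param ids Character ids of the source images.
#' @param labels Class labels of the source images.
#' @param split Optional `split_assignment`; when given, every id must be in
#'   its train phase.
#' @return An `augmented_set`: list with `images`, `labels`, `ids`
#'   (`<source id>.<transform>`), and `provenance` (data frame of source id
#'   and transform name).
#' @export
augment_training_set <- function(images, ids, labels, split = NULL) {
  stopifnot(length(images) == length(ids), length(ids) == length(labels))
  if (!is.null(split)) {
    train_ids <- split$id[split$phase == "train"]
    bad <- setdiff(ids, train_ids)
    if (length(bad))
      stop("augmentation is restricted to training images; not in train phase: ",
           paste(utils::head(bad, 3), collapse = ", "))
  }
  menu <- augmentation_menu()
  n <- length(images)
  out_images <- vector("list", 12L * n)
  out_ids <- character(12L * n)
  out_labels <- character(12L * n)
  src <- character(12L * n)
  tname <- character(12L * n)
  k <- 0L
  for (i in seq_len(n)) {
    for (tn in names(menu)) {
      k <- k + 1L
      out_images[[k]] <- menu[[tn]](images[[i]])
      out_ids[k] <- paste(ids[i], tn, sep = ".")
      out_labels[k] <- as.character(labels[i])
      src[k] <- ids[i]
      tname[k] <- tn
    }
  }
  structure(
    list(images = out_images, labels = out_labels, ids = out_ids,
         provenance = data.frame(source_id = src, transform = tname,
                                 stringsAsFactors = FALSE)),
    class = "augmented_set"
  )
}

#' @export
print.augmented_set <- function(x, ...) {
  cat("Augmented set:", length(x$images), "images from",
      length(unique(x$provenance$source_id)), "sources (x12)\n")
  invisible(x)
}
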