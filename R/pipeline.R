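#' Pipeline configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]. Either a
#' synthetic data source (preset + images per class) or a manifest CSV of
#' existing images must be named. The head/feature pairing follows the
#' method's design: the SVM head takes PCA-reduced deep features, the ANN
#' head takes fused (default), deep, or handcrafted features; `head = "svm"`
#' with `features = "fused"` is rejected unless `allow_any_pairing = TRUE`.
#'
#' @param data List describing the source: either
#'   `list(synthetic = list(preset, n_per_class, image_size, seed))` or
#'   `list(manifest = "path/to/manifest.csv")`.
#' @param features `"deep"`, `"handcrafted"` or `"fused"`.
#' @param head `"svm"` or `"ann"`.
#' @param backbone A [backbone_spec()] (or list of its arguments).
#' @param preprocessing List: `sigma`, `kernel_size`, `enhance_sign`.
#' @param split_seed Seed of the stratified split.
#' @param augment Apply the 12-fold training-set augmentation.
#' @param pca List: `k` (components, default 1024), `fit_on`
#'   (`"train"`, default, or `"all"`).
#' @param ann A [train_config()] for the ANN head.
#' @param svm_C Soft-margin constant of the SVM head.
#' @param shuffle_labels Permute training (and validation) labels before
#'   head training — a negative-control diagnostic.
#' @param allow_any_pairing Permit head/feature pairings outside the
#'   method's design.
#' @param out_dir Optional directory for artifacts (split CSV, feature
#'   CSVs, model file, metrics JSON, log).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(data = list(synthetic = list(preset = "separable",
                                                         n_per_class = 100L,
                                                         image_size = 64L,
                                                         seed = 1L)),
                            features = c("fused", "deep", "handcrafted"),
                            head = c("ann", "svm"),
                            backbone = backbone_spec("stub"),
                            preprocessing = list(sigma = 1, kernel_size = 5L,
                                                 enhance_sign = 1),
                            split_seed = 1L,
                            augment = TRUE,
                            pca = list(k = 1024L, fit_on = "train"),
                            ann = train_config(),
                            svm_C = 1,
                            shuffle_labels = FALSE,
                            allow_any_pairing = FALSE,
                            out_dir = NULL) {
  features <- match.arg(features)
  head <- match.arg(head)
  if (head == "svm" && features != "deep" && !allow_any_pairing)
    stop("the SVM head is paired with PCA-reduced deep features; ",
         "set allow_any_pairing = TRUE to override")
  if (is.list(backbone) && !inherits(backbone, "backbone_spec"))
    backbone <- do.call(backbone_spec, backbone)
  if (is.list(ann) && !inherits(ann, "train_config"))
    ann <- do.call(train_config, ann)
  structure(list(data = data, features = features, head = head,
                 backbone = backbone, preprocessing = preprocessing,
                 split_seed = split_seed, augment = augment, pca = pca,
                 ann = ann, svm_C = svm_C, shuffle_labels = shuffle_labels,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

stage <- function(name, expr, log) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  log(sprintf("stage %-12s %6.2f s", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full classification pipeline
#'
#' Executes enhance -> split -> augment(train) -> features -> (PCA) ->
#' fuse -> train -> evaluate, fully reproducible from the configuration
#' (every random draw is seeded). Evaluation is on the held-out test
#' phase; the validation phase steers the ANN's early stopping.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage timings.
#' @return A `pipeline_run`: list with `metrics` (including `roc_auc`),
#'   `confusion`, `model`, `split`, `pca` (when used), `config`, and the
#'   test-set predictions.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    if (verbose) message(msg)
  }

  ds <- stage("load", {
    if (!is.null(config$data$synthetic)) {
      s <- config$data$synthetic
      spec <- synthetic_spec(preset = s$preset %||% "separable",
                             image_size = s$image_size %||% 227L,
                             class_params = s$class_params,
                             seed = s$seed %||% 1L)
      generate_dataset(spec, s$n_per_class %||% 100L)
    } else if (!is.null(config$data$manifest)) {
      read_image_set(config$data$manifest)
    } else stop("config$data must name a synthetic spec or a manifest")
  }, log)

  pp <- config$preprocessing
  ds$images <- stage("enhance", lapply(ds$images, preprocess_image,
                                       sigma = pp$sigma %||% 1,
                                       size = pp$kernel_size %||% 5L,
                                       sign = pp$enhance_sign %||% 1), log)

  sp <- stage("split", stratified_split(ds$labels, seed = config$split_seed,
                                           ids = ds$ids), log)
  idx <- split(seq_along(ds$ids), sp$phase)

  tr_images <- ds$images[idx$train]
  tr_ids <- ds$ids[idx$train]
  tr_labels <- ds$labels[idx$train]
  if (isTRUE(config$augment)) {
    aug <- stage("augment",
                 augment_training_set(tr_images, tr_ids, tr_labels, sp),
                 log)
    tr_images <- c(tr_images, aug$images)
    tr_ids <- c(tr_ids, aug$ids)
    tr_labels <- c(tr_labels, aug$labels)
  }

  featurize <- function(images, ids) {
    deep <- hand <- NULL
    if (config$features %in% c("deep", "fused"))
      deep <- extract_deep_features(images, config$backbone, ids)
    if (config$features %in% c("handcrafted", "fused"))
      hand <- handcrafted_matrix(images, ids)
    list(deep = deep, hand = hand)
  }
  f_tr <- stage("features_tr", featurize(tr_images, tr_ids), log)
  f_val <- stage("features_val",
                 featurize(ds$images[idx$val], ds$ids[idx$val]), log)
  f_te <- stage("features_te",
                featurize(ds$images[idx$test], ds$ids[idx$test]), log)

  pca_model <- NULL
  assemble <- function(f) {
    dr <- NULL
    if (!is.null(f$deep)) dr <- pca_transform(pca_model, f$deep)
    if (config$features == "deep") dr
    else if (config$features == "handcrafted") f$hand
    else fuse(dr, f$hand)
  }
  if (config$features %in% c("deep", "fused")) {
    pca_model <- stage("pca", {
      fit_X <- if (identical(config$pca$fit_on, "all"))
        rbind(f_tr$deep, f_val$deep, f_te$deep) else f_tr$deep
      pca_fit(fit_X, k = config$pca$k %||% 1024L)
    }, log)
  }
  X_tr <- assemble(f_tr); X_val <- assemble(f_val); X_te <- assemble(f_te)

  y_tr <- tr_labels
  y_val <- ds$labels[idx$val]
  y_te <- ds$labels[idx$test]
  if (isTRUE(config$shuffle_labels)) {
    with_seed(config$split_seed + 1L, {
      y_tr <- sample(y_tr)
      y_val <- sample(y_val)
    })
  }

  model <- stage("train", {
    if (config$head == "svm") train_linear_svm(X_tr, y_tr, C = config$svm_C)
    else train_ann(X_tr, y_tr, cfg = config$ann, X_val = X_val,
                   y_val = y_val)
  }, log)

  res <- stage("evaluate", {
    if (config$head == "svm") {
      pred <- svm_predict(model, X_te)
      scores <- svm_predict(model, X_te, type = "score")
    } else {
      p <- ann_predict(model, X_te)
      pred <- p$labels
      scores <- p$scores[, model$positive]
    }
    cm <- confusion(y_te, pred)
    mt <- metrics(cm)
    mt$roc_auc <- roc_auc(y_te, scores)
    list(pred = pred, scores = scores, cm = cm, metrics = mt)
  }, log)

  run <- structure(
    list(metrics = res$metrics, confusion = res$cm, model = model,
         split = sp, pca = pca_model, config = config,
         predictions = data.frame(id = ds$ids[idx$test], label = y_te,
                                  predicted = res$pred, score = res$scores,
                                  stringsAsFactors = FALSE),
         log = log_lines),
    class = "pipeline_run")

  if (!is.null(config$out_dir)) write_run_artifacts(run, f_tr, config$out_dir)
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_run_artifacts <- function(run, f_tr, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(run$split), file.path(dir, "split.csv"),
                   row.names = FALSE)
  if (!is.null(f_tr$hand))
    utils::write.csv(data.frame(id = rownames(f_tr$hand), f_tr$hand),
                     file.path(dir, "features_handcrafted_train.csv"),
                     row.names = FALSE)
  saveRDS(run$model, file.path(dir, "model.rds"))
  m <- run$metrics
  jsonlite::write_json(
    list(accuracy = m$accuracy, specificity = m$specificity,
         sensitivity = m$sensitivity, precision = m$precision,
         auc_ratio = m$auc_ratio, roc_auc = m$roc_auc),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  writeLines(run$log, file.path(dir, "run.log"))
  utils::write.csv(run$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("Pipeline run: features '%s', head '%s'\n",
              x$config$features, x$config$head))
  print(x$confusion)
  print(x$metrics)
  invisible(x)
}

#' @export
summary.pipeline_run <- function(object, ...) {
  print(object)
  cat("\nStage timings:\n")
  cat(paste0("  ", object$log), sep = "\n")
  invisible(object)
}
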