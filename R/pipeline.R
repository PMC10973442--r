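#' List a class-per-directory image folder
#'
#' Expects the layout used by public histopathology collections such as
#' BreakHis: a root directory with one subdirectory per class (`benign/`,
#' `malignant/`), optionally containing subtype subdirectories; images are
#' PNG, TIFF or JPEG. Listing order is lexicographic, so repeated calls are
#' deterministic. Directories that are not a known class are skipped and
#' reported in the `skipped` attribute rather than aborting the run.
#'
#' @param root Path to the dataset root.
#' @param classes Recognized class directory names.
#'   Default `c("benign", "malignant")`.
#' @return A data.frame (`labeled_image_set`) with columns `path`, `label`,
#'   `subtype` (NA when the image sits directly in the class directory) and
#'   `image_id`; attribute `skipped` lists ignored entries.
#' @export
load_image_folder <- function(root, classes = c("benign", "malignant")) {
  if (!dir.exists(root)) stop("no such directory: ", root, call. = FALSE)
  entries <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  known <- intersect(entries, classes)
  skipped <- setdiff(entries, classes)
  exts <- "\\.(png|tif|tiff|jpg|jpeg)$"
  recs <- list()
  for (cl in known) {
    files <- sort(list.files(file.path(root, cl), pattern = exts,
                             recursive = TRUE, ignore.case = TRUE))
    if (!length(files)) next
    subtype <- ifelse(dirname(files) == ".", NA_character_, dirname(files))
    recs[[cl]] <- data.frame(path = file.path(root, cl, files),
                             label = cl, subtype = subtype,
                             image_id = file.path(cl, files),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  if (is.null(out) || nrow(out) == 0L)
    stop("no images found under ", root, call. = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("labeled_image_set", "data.frame")
  out
}

# Read an image file to a grayscale [0,1] matrix (rows = image rows).
# RGB is reduced by the ITU-R 601 luma weighting.
.read_gray <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3L) {
    nch <- dim(a)[3L]
    a <- if (nch >= 3L) {
      0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
    } else {
      a[, , 1L]
    }
  }
  t(a)  # EBImage stores x (width) first
}

#' Preprocess one image to a quantized square gray image
#'
#' Grayscale conversion (ITU-R 601 luma for RGB), bilinear resize to
#' `resolution` x `resolution`, then uniform quantization to `n_levels`
#' gray levels. Deterministic: identical input and settings give
#' bit-identical output.
#'
#' @param x Path to a PNG/TIFF/JPEG file, or a numeric matrix in \[0, 1\].
#' @param resolution Target side length in pixels (>= 8). Default 40.
#' @param n_levels Gray levels for quantization. Default 8.
#' @return A `gray_image`.
#' @export
preprocess_image <- function(x, resolution = 40L, n_levels = 8L) {
  if (resolution < 8L) stop("'resolution' must be >= 8", call. = FALSE)
  m <- if (is.character(x)) .read_gray(x) else x
  if (!is.matrix(m)) stop("'x' must be a file path or numeric matrix",
                          call. = FALSE)
  if (nrow(m) != resolution || ncol(m) != resolution) {
    img <- EBImage::Image(t(m))                 # bilinear by default
    m <- t(EBImage::imageData(EBImage::resize(img, w = resolution,
                                              h = resolution)))
  }
  m <- pmin(pmax(m, 0), 1)
  quantize_image(m, n_levels)
}

#' Experiment configuration
#'
#' Bundles every knob of an end-to-end run: preprocessing resolution, GLCM
#' settings, clusterer settings, the train/test split used by the supervised
#' baselines, and the feature scaling applied before clustering.
#'
#' @param resolution Square preprocessing size in pixels. Default 40.
#' @param glcm A [glcm_params()].
#' @param udlm A [udlm_config()].
#' @param include_optional Extract entropy and coarseness too. Default FALSE.
#' @param split_fraction Training fraction for the baselines, in (0, 1).
#'   Default 0.8.
#' @param split_seed Seed for the stratified split. Default 1.
#' @param feature_scaling One of `"minmax"`, `"zscore"`, `"none"`. Min-max
#'   scaling to \[0, 1\] per feature is the default: contrast is unbounded
#'   and would otherwise dominate the Euclidean clustering geometry.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(resolution = 40L, glcm = glcm_params(),
                              udlm = udlm_config(),
                              include_optional = FALSE,
                              split_fraction = 0.8, split_seed = 1L,
                              feature_scaling = c("minmax", "zscore",
                                                  "none")) {
  feature_scaling <- match.arg(feature_scaling)
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("'split_fraction' must be in (0, 1)", call. = FALSE)
  structure(list(resolution = as.integer(resolution), glcm = glcm,
                 udlm = udlm, include_optional = isTRUE(include_optional),
                 split_fraction = split_fraction,
                 split_seed = as.integer(split_seed),
                 feature_scaling = feature_scaling),
            class = "experiment_config")
}

#' Extract the per-image texture feature table
#'
#' Runs [preprocess_image()] and [extract_features()] over every record of a
#' labeled image set. Unreadable files are collected into the `errors`
#' attribute rather than aborting the batch.
#'
#' @param images A `labeled_image_set` (see [load_image_folder()]).
#' @param config An [experiment_config()].
#' @return Data.frame with columns `image_id`, `resolution`, `asm`, `con`,
#'   `idm`, `cor` (+ `ent`, `coarseness` when configured) and `label`.
#' @export
extract_feature_table <- function(images, config = experiment_config()) {
  stopifnot(is.data.frame(images), nrow(images) >= 1L)
  errors <- character()
  rows <- vector("list", nrow(images))
  for (k in seq_len(nrow(images))) {
    feat <- tryCatch({
      img <- preprocess_image(images$path[k], config$resolution,
                              config$glcm$n_levels)
      suppressWarnings(extract_features(img, config$glcm,
                                        config$include_optional))
    }, error = function(e) {
      errors[[length(errors) + 1L]] <<- paste0(images$path[k], ": ",
                                               conditionMessage(e))
      NULL
    })
    if (!is.null(feat))
      rows[[k]] <- data.frame(image_id = images$image_id[k],
                              resolution = config$resolution,
                              as.list(feat),
                              label = images$label[k],
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no image could be processed", call. = FALSE)
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  out
}

.feature_cols <- c("asm", "con", "idm", "cor")

.is_feature_table <- function(x) {
  is.data.frame(x) && all(.feature_cols %in% names(x))
}

# Per-feature scaling applied before clustering; constant columns map to 0.
.scale_features <- function(X, method) {
  switch(method,
         none = X,
         minmax = apply(X, 2L, function(v) {
           r <- max(v) - min(v)
           if (r == 0) rep(0, length(v)) else (v - min(v)) / r
         }),
         zscore = apply(X, 2L, function(v) {
           s <- stats::sd(v)
           if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
         }),
         stop("unknown scaling method: ", method, call. = FALSE))
}

#' Run the full unsupervised classification pipeline
#'
#' Texture features are extracted for every image (or taken from a supplied
#' feature table), scaled, and clustered into two groups by [run_udlm()] —
#' no label is read before the evaluation stage. When ground-truth labels
#' are present, clusters are aligned to classes by [align_clusters()] and
#' the full metrics report is produced, along with a continuous-score ROC
#' from [margin_score()].
#'
#' @param x A `labeled_image_set` or a feature table
#'   (see [extract_feature_table()]).
#' @param config An [experiment_config()].
#' @return A `bcicm_run` list: `features` (the table), `centers` (2 x D, in
#'   scaled feature space), `objective`, `history`, `assignments`
#'   (data.frame `image_id`, `cluster`, `mapped_label`, `margin_score`),
#'   `mapping`, `metrics` (a [metrics_report()]; `NULL` without labels),
#'   `roc` (margin-score ROC; `NULL` without labels), `config`, `timings`
#'   (seconds per stage).
#' @export
run_bcicm <- function(x, config = experiment_config()) {
  timings <- c()
  tic <- function() Sys.time()
  lap <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))
  t0 <- tic()
  feats <- if (.is_feature_table(x)) x else extract_feature_table(x, config)
  timings["features"] <- lap(t0)
  X <- as.matrix(feats[, .feature_cols])
  Xs <- .scale_features(X, config$feature_scaling)
  t0 <- tic()
  fit <- run_udlm(Xs, config$udlm)
  timings["udlm"] <- lap(t0)
  clusters <- assign_labels(Xs, fit$centers)
  have_labels <- "label" %in% names(feats) &&
    any(!is.na(feats$label) & nzchar(feats$label))
  mapping <- metrics <- roc <- NULL
  mapped <- rep(NA_character_, length(clusters))
  margins <- rep(NA_real_, length(clusters))
  if (have_labels) {
    y <- feats$label
    if (length(unique(y)) < 2L) {
      warning("only one class present; metrics restricted", call. = FALSE)
      mapping <- c("0" = unique(y), "1" = unique(y))
      mapped <- mapping[as.character(clusters)]
    } else {
      mapping <- align_clusters(clusters, y)
      mapped <- unname(mapping[as.character(clusters)])
      b_idx <- which(mapping == "benign") - 1L  # cluster index mapped benign
      bc <- fit$centers[b_idx + 1L, ]
      mc <- fit$centers[2L - b_idx, ]
      margins <- margin_score(Xs, bc, mc)
      cm <- confusion_matrix(y, mapped)
      metrics <- metrics_report(cm)
      roc <- roc_curve(margins, y)
    }
  } else {
    bc <- fit$centers[1L, ]; mc <- fit$centers[2L, ]
    margins <- margin_score(Xs, bc, mc)
  }
  assignments <- data.frame(image_id = if ("image_id" %in% names(feats))
    feats$image_id else seq_len(nrow(feats)),
    cluster = clusters, mapped_label = mapped,
    margin_score = margins, stringsAsFactors = FALSE)
  structure(list(features = feats, centers = fit$centers,
                 objective = fit$objective, history = fit$state$history,
                 assignments = assignments, mapping = mapping,
                 metrics = metrics, roc = roc, config = config,
                 timings = timings),
            class = "bcicm_run")
}

#' @export
print.bcicm_run <- function(x, ...) {
  cat(sprintf("<bcicm_run: %d samples, objective %.4f>\n",
              nrow(x$assignments), x$objective))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

# Stratified train/test index split; retries with a shifted seed if a class
# is missing from either side (possible only for tiny classes).
.stratified_split <- function(labels, fraction, seed) {
  for (attempt in 0:4) {
    set.seed(seed + attempt)
    train <- unlist(lapply(split(seq_along(labels), labels), function(idx) {
      n_tr <- max(1L, floor(length(idx) * fraction))
      if (n_tr >= length(idx)) n_tr <- length(idx) - 1L
      sample(idx, n_tr)
    }), use.names = FALSE)
    test <- setdiff(seq_along(labels), train)
    if (length(unique(labels[train])) == length(unique(labels)) &&
        length(unique(labels[test])) == length(unique(labels)))
      return(list(train = sort(train), test = sort(test)))
    warning("class missing from a split; resplitting", call. = FALSE)
  }
  stop("could not produce a split containing every class", call. = FALSE)
}

#' Supervised baselines: random forest and SVM
#'
#' The comparison protocol for the unsupervised pipeline: the same texture
#' features are split into a stratified train/test partition
#' (`split_fraction`, default 80/20), a random forest and an RBF-kernel SVM
#' are trained with library-default hyperparameters (recorded in the
#' result), and the test-split metrics are reported with the same
#' hard-classifier AUC convention as the unsupervised run.
#'
#' @param x A `labeled_image_set` or feature table with labels.
#' @param config An [experiment_config()].
#' @return List with one element per method (`rf`, `svm`), each holding
#'   `metrics`, `predictions` and `hyperparameters`; plus `split` indices.
#' @export
run_baselines <- function(x, config = experiment_config()) {
  feats <- if (.is_feature_table(x)) x else extract_feature_table(x, config)
  if (!"label" %in% names(feats) || anyNA(feats$label))
    stop("baselines require labels for every sample", call. = FALSE)
  y <- factor(feats$label, levels = c("benign", "malignant"))
  if (nlevels(droplevels(y)) < 2L)
    stop("baselines require both classes", call. = FALSE)
  X <- as.data.frame(.scale_features(as.matrix(feats[, .feature_cols]),
                                     config$feature_scaling))
  sp <- .stratified_split(as.character(y), config$split_fraction,
                          config$split_seed)
  out <- list(split = sp)
  set.seed(config$split_seed)
  rf <- randomForest::randomForest(X[sp$train, ], y[sp$train])
  rf_pred <- as.character(predict(rf, X[sp$test, ]))
  out$rf <- list(metrics = metrics_report(
    confusion_matrix(as.character(y)[sp$test], rf_pred)),
    predictions = rf_pred,
    hyperparameters = list(ntree = rf$ntree, mtry = rf$mtry))
  sv <- e1071::svm(X[sp$train, ], y[sp$train])
  sv_pred <- as.character(predict(sv, X[sp$test, ]))
  out$svm <- list(metrics = metrics_report(
    confusion_matrix(as.character(y)[sp$test], sv_pred)),
    predictions = sv_pred,
    hyperparameters = list(kernel = "radial", cost = sv$cost,
                           gamma = sv$gamma))
  out
}

#' Feature behavior and accuracy across preprocessing resolutions
#'
#' For each resolution: mean core feature values (plus entropy), wall time
#' of the feature-extraction stage in milliseconds, and — when labels are
#' present — the unsupervised pipeline's accuracy at that resolution.
#'
#' @param images A `labeled_image_set`.
#' @param resolutions Integer vector of square sizes, e.g.
#'   `c(40, 100, 200, 400)`.
#' @param config An [experiment_config()]; its `resolution` is overridden
#'   per row.
#' @return Data.frame with one row per resolution: `resolution`, `asm`,
#'   `con`, `idm`, `ent`, `time_ms`, `acc`.
#' @export
resolution_sweep <- function(images, resolutions,
                             config = experiment_config()) {
  stopifnot(length(resolutions) >= 1L)
  rows <- lapply(resolutions, function(r) {
    cfg <- config
    cfg$resolution <- as.integer(r)
    cfg$include_optional <- TRUE
    t0 <- Sys.time()
    feats <- extract_feature_table(images, cfg)
    ms <- as.numeric(difftime(Sys.time(), t0, units = "secs")) * 1000
    acc_val <- NA_real_
    if ("label" %in% names(feats) && length(unique(feats$label)) == 2L) {
      run <- run_bcicm(feats, cfg)
      acc_val <- run$metrics$acc
    }
    data.frame(resolution = as.integer(r), asm = mean(feats$asm),
               con = mean(feats$con), idm = mean(feats$idm),
               ent = mean(feats$ent), time_ms = ms, acc = acc_val)
  })
  do.call(rbind, rows)
}
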