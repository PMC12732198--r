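# Configuration, image-folder datasets, checkpoints and report output.

#' Default run configuration
#'
#' Nested defaults for every stage of the pipeline: backbone geometry,
#' augmentation, self-supervised pretraining (AdamW 3e-4 / weight decay
#' 1e-4, batch 64 with gradient accumulation over 4 mini-batches for an
#' effective batch of 256, 125 epochs with patience 25, cosine annealing
#' over 100 epochs, EMA decay 0.996, equal loss weighting), and two-phase
#' fine-tuning (batch 32, phase-1 learning rate 1e-3 reduced by 90% for
#' phase 2, reduce-on-plateau factor 0.5 / patience 3, gradient clipping
#' at norm 1.0).
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    backbone = list(blocks = c(3L, 4L, 6L, 3L), base_width = 64L),
    augment = list(scale = c(0.6, 1.0), flip_p = 0.5, jitter = 0.2,
                   blur_p = c(0.5, 0.1)),
    ssl = list(lr = 3e-4, weight_decay = 1e-4, batch = 64L,
               accum_steps = 4L, epochs = 125L, patience = 25L,
               tau = 0.996, lambda_spatial = 0.5, cosine_horizon = 100L,
               clip = 1.0, size = 224L, seed = NULL,
               proj_hidden = 4096L, proj_dim = 256L,
               spatial_mid = 256L, spatial_dim = 128L,
               augment = NULL),
    finetune = list(batch = 32L, lr_phase1 = 1e-3, weight_decay = 1e-4,
                    clip = 1.0, plateau_factor = 0.5, plateau_patience = 3L,
                    epochs_phase1 = 30L, epochs_phase2 = 30L,
                    test_frac = 0.2, val_frac = 0.1,
                    hidden = 1280L, dropout = 0.5, size = 224L,
                    class_weights = NULL)
  )
}

check_config_keys <- function(cfg, defaults, path = "") {
  extra <- setdiff(names(cfg), names(defaults))
  if (length(extra) > 0) {
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", extra)), collapse = ", "))
  }
  for (nm in names(cfg)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      check_config_keys(cfg[[nm]], defaults[[nm]], paste0(path, ".", nm))
    }
  }
  invisible(TRUE)
}

#' Load and validate a YAML run configuration
#'
#' Reads a YAML file, rejects keys not present in [default_config()], and
#' merges the values over the defaults.
#'
#' @param path Path to a YAML file.
#' @return The merged configuration list.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_config()
  check_config_keys(cfg, defaults)
  utils::modifyList(defaults, cfg)
}

# ---- image reading ----------------------------------------------------------

#' Read a single image as a 3-channel array
#'
#' Decodes PNG or TIFF, converts to grayscale-replicated 3 channels (the
#' encoder expects 3-channel input), and drops any alpha channel.
#'
#' @param path Image file path.
#' @return An `(H, W, 3)` array in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, " (", path, ")")
  )
  if (length(dim(img)) == 2) {
    img <- array(rep(img, 3), dim = c(dim(img), 3L))
  } else if (dim(img)[3] == 1) {
    img <- array(rep(img[, , 1], 3), dim = c(dim(img)[1:2], 3L))
  } else if (dim(img)[3] >= 3) {
    # color input: collapse to luminance, then replicate
    g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    img <- array(rep(g, 3), dim = c(dim(img)[1:2], 3L))
  }
  img
}

#' Open a folder-per-class image dataset
#'
#' Scans `root` for class subdirectories (alphabetical class indexing),
#' verifies each image decodes, and returns a lazy dataset handle; images
#' are read and resized on demand by [dataset_batch()]. Unreadable files
#' are skipped with a warning naming the path; empty class folders
#' produce a warning.
#'
#' @param root Dataset root directory.
#' @param class_names Optional explicit class subset; defaults to all
#'   subdirectories, sorted.
#' @param size Side length images are resized to when materialized.
#' @return An object of class `sbyol_dataset` with a `manifest` tibble
#'   (path, label, class_index).
#' @export
load_image_folder <- function(root, class_names = NULL, size = 224L) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  classes <- class_names %||% sort(list.dirs(root, recursive = FALSE,
                                             full.names = FALSE))
  if (length(classes) == 0) stop("no class subdirectories under ", root)
  rows <- list()
  for (i in seq_along(classes)) {
    files <- sort(list.files(file.path(root, classes[i]),
                             pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) {
      warning("empty class folder: ", classes[i])
      next
    }
    ok <- vapply(files, function(f) {
      tryCatch({ read_image(f); TRUE },
               error = function(e) {
                 warning("skipping unreadable image: ", f, call. = FALSE)
                 FALSE
               })
    }, logical(1))
    if (any(ok)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        path = files[ok], label = classes[i], class_index = i)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  structure(list(manifest = manifest, classes = classes,
                 size = as.integer(size)),
            class = "sbyol_dataset")
}

#' @export
print.sbyol_dataset <- function(x, ...) {
  cat(sprintf("<sbyol_dataset> %d images, %d classes (%s)\n",
              nrow(x$manifest), length(x$classes),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

dataset_length <- function(x) {
  if (inherits(x, "sbyol_dataset")) nrow(x$manifest)
  else dim(x)[4]
}

# Materialize a batch as a (size, size, 3, n) array.
dataset_batch <- function(x, idx) {
  if (inherits(x, "sbyol_dataset")) {
    out <- array(0, dim = c(x$size, x$size, 3L, length(idx)))
    for (j in seq_along(idx)) {
      img <- read_image(x$manifest$path[idx[j]])
      out[, , , j] <- resize_image(img, x$size)
    }
    out
  } else {
    x[, , , idx, drop = FALSE]
  }
}

# ---- checkpoints ------------------------------------------------------------

config_hash <- function(obj) rlang::hash(obj)

#' Save a model checkpoint
#'
#' Serializes any of the package's model objects together with a hash of
#' its configuration-defining fields, verified on load.
#'
#' @param object A model object (`sbyol_model`, `sbyol_pretrain`,
#'   `sbyol_classifier`, `sbyol_finetune`, ...).
#' @param path Destination file path.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(object, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  payload <- list(object = object,
                  hash = config_hash(checkpoint_signature(object)),
                  package_version = as.character(utils::packageVersion("spatialbyol")))
  ok <- tryCatch({ saveRDS(payload, path); TRUE },
                 error = function(e) stop("checkpoint write failed: ",
                                          conditionMessage(e)))
  invisible(path)
}

# Fields that define the architecture (not the weights) for hash checking.
checkpoint_signature <- function(object) {
  if (inherits(object, "sbyol_pretrain")) object <- object$model
  if (inherits(object, "sbyol_model")) {
    list(class = "sbyol_model", blocks = object$encoder$blocks,
         base_width = object$encoder$base_width, dims = object$dims)
  } else if (inherits(object, "sbyol_classifier")) {
    list(class = "sbyol_classifier", blocks = object$encoder$blocks,
         base_width = object$encoder$base_width, hidden = object$hidden,
         n_classes = object$n_classes)
  } else if (inherits(object, "sbyol_finetune")) {
    checkpoint_signature(object$classifier)
  } else {
    list(class = class(object))
  }
}

#' Load a model checkpoint
#'
#' Restores the serialized object; if the stored configuration hash no
#' longer matches (e.g. the file was produced by a different architecture
#' description), a warning is emitted and loading proceeds.
#'
#' @param path Checkpoint file path.
#' @return The restored object.
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  actual <- config_hash(checkpoint_signature(payload$object))
  if (!identical(actual, payload$hash)) {
    warning("checkpoint config hash mismatch; loading anyway")
  }
  payload$object
}

# Verify two parameter trees are structurally identical; error names the
# first mismatched parameter.
check_param_compat <- function(a, b, path = "") {
  if (is.list(a) != is.list(b)) {
    stop("parameter mismatch at '", sub("^/", "", path), "'")
  }
  if (is.list(a)) {
    if (!setequal(names(a), names(b))) {
      miss <- c(setdiff(names(a), names(b)), setdiff(names(b), names(a)))[1]
      stop("parameter mismatch at '", sub("^/", "", paste0(path, "/", miss)), "'")
    }
    for (nm in names(a)) check_param_compat(a[[nm]], b[[nm]],
                                            paste0(path, "/", nm))
  } else if (!is.null(a)) {
    da <- dim(a) %||% length(a)
    db <- dim(b) %||% length(b)
    if (!identical(da, db)) {
      stop(sprintf("parameter mismatch at '%s': dims (%s) vs (%s)",
                   sub("^/", "", path), paste(da, collapse = "x"),
                   paste(db, collapse = "x")))
    }
  }
  invisible(TRUE)
}

#' Load pretrained encoder weights into a classifier
#'
#' Copies the online encoder parameters and batch-norm state of a saved
#' pretraining checkpoint into an existing classifier, after verifying
#' the parameter trees match (the first divergent parameter is named on
#' error).
#'
#' @param clf An `sbyol_classifier`.
#' @param checkpoint Path to a pretraining checkpoint, or an
#'   `sbyol_model` / `sbyol_pretrain` object.
#' @return The classifier with encoder weights replaced.
#' @export
load_encoder_weights <- function(clf, checkpoint) {
  obj <- if (is.character(checkpoint)) load_checkpoint(checkpoint) else checkpoint
  if (inherits(obj, "sbyol_pretrain")) obj <- obj$model
  if (!inherits(obj, "sbyol_model")) stop("checkpoint does not hold an sbyol_model")
  check_param_compat(clf$params$encoder, obj$online$params$encoder)
  clf$params$encoder <- obj$online$params$encoder
  clf$state$encoder <- obj$online$state$encoder
  clf
}

# ---- report output ----------------------------------------------------------

#' Write a classification report as JSON
#'
#' @param report An `sbyol_report`.
#' @param path Destination `.json` path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(
    confusion = as.list(report$confusion),
    accuracy = report$accuracy,
    sensitivity = report$sensitivity,
    specificity = report$specificity,
    precision_weighted = report$precision_weighted,
    recall_weighted = report$recall_weighted,
    f1_weighted = report$f1_weighted,
    n = report$n, positive = report$positive),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
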