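# Synthetic OCT B-scan phantoms: horizontal retinal bands with a foveal
# depression, multiplicative gamma speckle, and an optional DRIL-like
# lesion that locally erases inner-layer boundary contrast.

#' Configuration for the OCT phantom generator
#'
#' @param size Image side length in pixels (default 224).
#' @param n_layers Number of horizontal retinal bands (default 7).
#' @param layer_intensities Per-band mean reflectivity in `[0, 1]`;
#'   defaults alternate bright/dark so layer boundaries are detectable.
#' @param fovea_depth Depth of the central foveal dip in pixels.
#' @param fovea_width Width (FWHM-like scale) of the dip in pixels.
#' @param speckle_shape Gamma shape of the unit-mean multiplicative
#'   speckle (default 4; larger is smoother).
#' @param dril_extent Horizontal width of the DRIL-like lesion in pixels
#'   (must be smaller than `size`).
#' @param dril_blur_sigma Vertical Gaussian blur strength inside the
#'   lesion, in pixels; 0 disables the lesion entirely.
#' @param seed Integer seed; together with the config it fully determines
#'   the phantom.
#' @return A list of class `sbyol_phantom_config`.
#' @export
phantom_config <- function(size = 224L, n_layers = 7L,
                           layer_intensities = NULL,
                           fovea_depth = NULL, fovea_width = NULL,
                           speckle_shape = 4, dril_extent = NULL,
                           dril_blur_sigma = 3, seed = 1L) {
  size <- as.integer(size)
  if (size < 16) stop("phantom size must be at least 16 pixels")
  if (is.null(layer_intensities)) {
    bright <- c(0.55, 0.5, 0.6, 0.52)
    dark <- c(0.18, 0.24, 0.15, 0.2)
    layer_intensities <- as.vector(rbind(bright, dark))[seq_len(n_layers)]
  }
  if (length(layer_intensities) != n_layers) {
    stop("layer_intensities must have n_layers entries")
  }
  fovea_depth <- fovea_depth %||% round(size * 0.12)
  fovea_width <- fovea_width %||% round(size * 0.25)
  dril_extent <- dril_extent %||% round(size * 0.35)
  if (dril_extent >= size) stop("dril_extent must be smaller than size")
  structure(list(size = size, n_layers = as.integer(n_layers),
                 layer_intensities = layer_intensities,
                 fovea_depth = fovea_depth, fovea_width = fovea_width,
                 speckle_shape = speckle_shape, dril_extent = dril_extent,
                 dril_blur_sigma = dril_blur_sigma, seed = as.integer(seed)),
            class = "sbyol_phantom_config")
}

# 1-d Gaussian blur of each column restricted to rows `rows`, columns `cols`.
blur_columns <- function(img, rows, cols, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, as.integer(ceiling(2 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  sub <- img[rows, cols, drop = FALSE]
  n <- nrow(sub)
  M <- matrix(0, n, n)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx <- seq_len(n)
    src <- pmin(pmax(idx + off, 1L), n)
    M[cbind(idx, src)] <- M[cbind(idx, src)] + k[j]
  }
  img[rows, cols] <- M %*% sub
  img
}

#' Generate one synthetic OCT phantom
#'
#' Draws `n_layers` horizontal reflectivity bands with a smooth central
#' foveal depression, multiplies by unit-mean gamma speckle, and — when
#' `dril_present` — vertically blurs the inner-layer boundaries over a
#' centered horizontal span of `dril_extent` pixels before the speckle is
#' applied, so matched seeds give images that are pixelwise identical
#' outside the lesion mask.
#'
#' @param config An `sbyol_phantom_config` from [phantom_config()].
#' @param dril_present Add the DRIL-like lesion?
#' @return A list with `image` (`(size, size)` matrix in `[0, 1]`),
#'   `label` (`"DRIL"` or `"NO_DRIL"`), and `lesion_mask` (logical
#'   matrix; all-FALSE when absent).
#' @examples
#' ph <- generate_phantom(phantom_config(size = 64, seed = 7), TRUE)
#' ph$label
#' @export
generate_phantom <- function(config, dril_present = FALSE) {
  stopifnot(inherits(config, "sbyol_phantom_config"))
  S <- config$size
  set.seed(config$seed)

  # band boundaries: retina occupies the central vertical band, with the
  # inner (upper) boundaries dipping at the fovea
  top <- 0.22 * S
  bottom <- 0.78 * S
  nb <- config$n_layers + 1L
  base_rows <- seq(top, bottom, length.out = nb)
  xs <- seq_len(S)
  center <- (S + 1) / 2
  dip <- exp(-((xs - center)^2) / (2 * (config$fovea_width / 2.355)^2))
  boundaries <- matrix(0, nb, S)
  for (k in seq_len(nb)) {
    # inner boundaries dip most; the outermost barely moves
    w <- (nb - k) / (nb - 1)
    boundaries[k, ] <- base_rows[k] + config$fovea_depth * dip * w +
      stats::rnorm(1, 0, S * 0.005)
  }

  clean <- matrix(0.04, S, S)
  rows <- seq_len(S)
  for (k in seq_len(config$n_layers)) {
    for (x in xs) {
      r0 <- max(1L, ceiling(boundaries[k, x]))
      r1 <- min(S, floor(boundaries[k + 1L, x]))
      if (r0 <= r1) clean[r0:r1, x] <- config$layer_intensities[k]
    }
  }

  # lesion: centered span, inner-layer rows (first ~half of the bands)
  mask <- matrix(FALSE, S, S)
  half <- round(config$dril_extent / 2)
  x0 <- max(1L, round(center) - half)
  x1 <- min(S, round(center) + half - 1L)
  inner_top <- max(1L, floor(min(boundaries[1, x0:x1])) - 2L)
  inner_bot <- min(S, ceiling(max(boundaries[ceiling(nb / 2), x0:x1])) + 2L)
  if (dril_present && config$dril_blur_sigma > 0) {
    clean <- blur_columns(clean, inner_top:inner_bot, x0:x1,
                          config$dril_blur_sigma)
  }
  if (dril_present) mask[inner_top:inner_bot, x0:x1] <- TRUE

  speckle <- matrix(
    stats::rgamma(S * S, shape = config$speckle_shape,
                  rate = config$speckle_shape), S, S)
  img <- clean * speckle
  img[img > 1] <- 1
  img[img < 0] <- 0

  list(image = img, label = if (dril_present) "DRIL" else "NO_DRIL",
       lesion_mask = mask)
}

# Mean vertical gradient magnitude inside a mask — the boundary-contrast
# statistic used to verify that lesions erase layer edges.
vertical_gradient_energy <- function(img, mask) {
  g <- abs(diff(img))
  m <- mask[-1, , drop = FALSE] & mask[-nrow(mask), , drop = FALSE]
  if (!any(m)) return(NA_real_)
  mean(g[m])
}

#' Generate an in-memory phantom batch
#'
#' Builds `n_per_class` DRIL-positive and `n_per_class` DRIL-negative
#' phantoms with per-image seeds derived from `seed`, replicated to 3
#' channels for the encoder.
#'
#' @param n_per_class Images per class.
#' @param config Base [phantom_config()]; per-image seeds and slight
#'   geometry jitter are derived from `seed`.
#' @param seed Integer master seed.
#' @return A list with `images` (`(S, S, 3, 2 n)` array), `labels`
#'   (character), and `masks` (list of lesion masks).
#' @export
phantom_batch <- function(n_per_class, config = phantom_config(), seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  seeds <- sample.int(.Machine$integer.max, n)
  labels <- rep(c("DRIL", "NO_DRIL"), each = n_per_class)
  S <- config$size
  images <- array(0, dim = c(S, S, 3L, n))
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- seeds[i]
    ph <- generate_phantom(cfg_i, dril_present = labels[i] == "DRIL")
    images[, , 1, i] <- ph$image
    images[, , 2, i] <- ph$image
    images[, , 3, i] <- ph$image
    masks[[i]] <- ph$lesion_mask
  }
  list(images = images, labels = labels, masks = masks)
}

#' Write a phantom dataset to disk
#'
#' In `"finetune"` mode writes PNGs under `DRIL/` and `NO_DRIL/`
#' subfolders plus a `manifest.csv` with columns `path,label`. In
#' `"pretrain"` mode writes four pseudo-classes (`CNV`, `DME`, `DRUSEN`,
#' `NORMAL`) with varied phantom parameters, mirroring the folder-per-class
#' layout of public OCT corpora.
#'
#' @param n_per_class Images per class.
#' @param config Base [phantom_config()].
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; the same seed reproduces byte-identical
#'   manifests and images.
#' @param mode `"finetune"` (two classes) or `"pretrain"` (four
#'   pseudo-classes).
#' @return Invisibly, the manifest tibble.
#' @export
generate_dataset <- function(n_per_class, config = phantom_config(),
                             out_dir, seed = 1L,
                             mode = c("finetune", "pretrain")) {
  mode <- match.arg(mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)

  if (mode == "finetune") {
    classes <- c("DRIL", "NO_DRIL")
    variants <- list(
      DRIL = function(cfg) cfg,
      NO_DRIL = function(cfg) cfg)
  } else {
    # pseudo-pathologies: parameter variations of the same phantom family
    classes <- c("CNV", "DME", "DRUSEN", "NORMAL")
    variants <- list(
      CNV = function(cfg) { cfg$fovea_depth <- round(cfg$size * 0.2); cfg },
      DME = function(cfg) { cfg$speckle_shape <- 2; cfg },
      DRUSEN = function(cfg) { cfg$n_layers <- 5L
        cfg$layer_intensities <- cfg$layer_intensities[1:5]; cfg },
      NORMAL = function(cfg) cfg)
  }

  rows <- list()
  for (cl in classes) {
    dir.create(file.path(out_dir, cl), showWarnings = FALSE)
    seeds <- sample.int(.Machine$integer.max, n_per_class)
    for (i in seq_len(n_per_class)) {
      cfg_i <- variants[[cl]](config)
      cfg_i$seed <- seeds[i]
      dril <- (mode == "finetune" && cl == "DRIL")
      ph <- generate_phantom(cfg_i, dril_present = dril)
      rel <- file.path(cl, sprintf("%s_%04d.png", tolower(cl), i))
      png::writePNG(ph$image, file.path(out_dir, rel))
      rows[[length(rows) + 1L]] <- tibble::tibble(path = rel, label = cl)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
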