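# Grad-CAM saliency maps for classifier decisions.

GRADCAM_LAYERS <- c("stage4", "stage3")

# Channel weights are the spatial means of the class-score gradient on the
# chosen feature map; the map is the rectified weighted channel sum.
gradcam_from_grads <- function(fmap, grad) {
  d <- dim(fmap)
  hw <- d[1] * d[2]
  gm <- matrix(grad[, , , 1], nrow = hw)   # (HW, C)
  fm <- matrix(fmap[, , , 1], nrow = hw)
  w <- colMeans(gm)
  cam <- fm %*% w
  cam[cam < 0] <- 0
  matrix(cam, d[1], d[2])
}

minmax_norm <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] < 1e-12) return(m * 0)  # flat (e.g. all-zero) maps stay zero
  (m - rng[1]) / (rng[2] - rng[1])
}

#' Grad-CAM heatmap for a classifier decision
#'
#' Computes the gradient of the target-class logit with respect to a
#' convolutional feature map of the encoder, weights each channel by the
#' spatial mean of its gradient, rectifies the weighted channel sum, and
#' bilinearly upsamples the result to the input size, min-max normalized
#' to `[0, 1]` (an all-zero map stays all-zero).
#'
#' @param clf An `sbyol_classifier`.
#' @param image A single image: `(H, W, 3)` or `(H, W, 3, 1)` array,
#'   already transformed/normalized for the encoder (see
#'   [finetune_transform()]).
#' @param target_class Class index (1-based) or class name; defaults to the
#'   predicted class.
#' @param layer Which feature map to visualize: `"stage4"` (deepest,
#'   default) or `"stage3"`.
#' @return An object of class `sbyol_heatmap`: list with `values` (an
#'   `(H, W)` matrix in `[0, 1]` at the input resolution), `target_class`,
#'   `layer_name`, and the class `probs`.
#' @export
gradcam <- function(clf, image, target_class = NULL, layer = "stage4") {
  if (!layer %in% GRADCAM_LAYERS) {
    stop(sprintf("unknown layer '%s'; valid layers: %s", layer,
                 paste(GRADCAM_LAYERS, collapse = ", ")))
  }
  d <- dim(image)
  if (length(d) == 3) dim(image) <- c(d, 1)
  d <- dim(image)

  enc <- encoder_forward(clf$encoder, clf$params$encoder, clf$state$encoder,
                         image, training = FALSE, keep_cache = TRUE)
  feats <- global_pool(enc$s2)
  hd <- nn_forward(clf$head_arch, clf$params$head, clf$state$head, feats,
                   training = FALSE)
  probs <- softmax_rows(hd$out)[1, ]
  if (is.null(target_class)) {
    target_class <- which.max(probs)
  } else if (is.character(target_class)) {
    target_class <- match(target_class, clf$class_levels)
    if (is.na(target_class)) stop("unknown class name")
  }

  glogits <- matrix(0, 1, clf$n_classes)
  glogits[1, target_class] <- 1
  hb <- nn_backward(clf$head_arch, clf$params$head, hd$cache, glogits,
                    need_gx = TRUE)
  s2d <- dim(enc$s2)
  hw <- s2d[1] * s2d[2]
  gs2 <- array(rep(as.vector(t(hb$gx / hw)), each = hw), dim = s2d)

  if (layer == "stage4") {
    fmap <- enc$s2
    grad <- gs2
  } else {
    r <- nn_backward(clf$encoder$arch$stages$stage4,
                     clf$params$encoder$stages$stage4,
                     enc$cache$stages$stage4, gs2, need_gx = TRUE)
    fmap <- enc$s1
    grad <- r$gx
  }

  cam <- gradcam_from_grads(fmap, grad)
  up <- affine_image(array(cam, dim = c(dim(cam), 1L)), d[1], d[2],
                     c((dim(cam)[1] - 1) / max(d[1] - 1, 1), 0, 0,
                       (dim(cam)[2] - 1) / max(d[2] - 1, 1), 0, 0))
  values <- minmax_norm(matrix(up, d[1], d[2]))
  structure(list(values = values,
                 target_class = clf$class_levels[target_class],
                 layer_name = layer, probs = probs),
            class = "sbyol_heatmap")
}

#' @export
print.sbyol_heatmap <- function(x, ...) {
  cat(sprintf("<sbyol_heatmap> %dx%d, class '%s', layer %s\n",
              nrow(x$values), ncol(x$values), x$target_class, x$layer_name))
  invisible(x)
}

#' Render a Grad-CAM heatmap over its image
#'
#' Blends a jet-style colormap of the heatmap with the grayscale image
#' using alpha compositing.
#'
#' @param image `(H, W)` matrix or `(H, W, C)` array in `[0, 1]`.
#' @param heatmap An `sbyol_heatmap` or an `(H, W)` matrix in `[0, 1]`.
#' @param alpha Heatmap opacity (default 0.4).
#' @return An `(H, W, 3)` RGB array in `[0, 1]`.
#' @export
gradcam_overlay <- function(image, heatmap, alpha = 0.4) {
  if (inherits(heatmap, "sbyol_heatmap")) heatmap <- heatmap$values
  if (length(dim(image)) == 3) image <- image[, , 1]
  stopifnot(all(dim(image) == dim(heatmap)))
  ramp <- grDevices::colorRamp(c("navy", "cyan", "yellow", "red"))
  cols <- ramp(as.vector(heatmap)) / 255
  out <- array(0, dim = c(dim(image), 3L))
  for (ch in 1:3) {
    out[, , ch] <- (1 - alpha) * image +
      alpha * matrix(cols[, ch], nrow(image), ncol(image))
  }
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}
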