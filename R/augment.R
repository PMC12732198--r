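# Stochastic augmented views for self-supervised pretraining and the
# lighter train/eval pipeline used during fine-tuning.
#
# All geometric transforms are built from one bilinear affine sampler with
# border replication. OCT B-scans are grayscale and anatomically oriented:
# hue/solarization operations are pointless and vertical flips would invert
# the fixed retinal layer order, so neither is ever applied.

IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_STD <- c(0.229, 0.224, 0.225)

# Affine transform of a single (H, W, C) image to (Hout, Wout).
# `A` maps output pixel (row, col) to input coordinates.
affine_image <- function(img, Hout, Wout, A) {
  cpp_affine_sample(img, as.integer(Hout), as.integer(Wout), as.numeric(A))
}

resize_image <- function(img, size) {
  d <- dim(img)
  A <- c((d[1] - 1) / max(size - 1, 1), 0, 0,
         (d[2] - 1) / max(size - 1, 1), 0, 0)
  affine_image(img, size, size, A)
}

crop_resize_image <- function(img, top, left, h, w, size) {
  A <- c((h - 1) / max(size - 1, 1), 0, 0,
         (w - 1) / max(size - 1, 1), top, left)
  affine_image(img, size, size, A)
}

rotate_image <- function(img, angle_deg) {
  d <- dim(img)
  th <- angle_deg * pi / 180
  cy <- (d[1] - 1) / 2; cx <- (d[2] - 1) / 2
  # output (r, c) -> rotate about center by -theta to find source pixel
  A <- c(cos(th), -sin(th), sin(th), cos(th),
         cy - cos(th) * cy - sin(th) * cx,
         cx + sin(th) * cy - cos(th) * cx)
  affine_image(img, d[1], d[2], A)
}

hflip_image <- function(img) img[, rev(seq_len(dim(img)[2])), , drop = FALSE]

gauss_blur_image <- function(img, sigma) {
  if (sigma <= 0) return(img)
  d <- dim(img)
  r <- max(1L, as.integer(ceiling(2 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  band <- function(n) {
    M <- matrix(0, n, n)
    for (j in seq_along(k)) {
      off <- j - r - 1L
      idx <- seq_len(n)
      src <- pmin(pmax(idx + off, 1L), n)  # replicate borders
      M[cbind(idx, src)] <- M[cbind(idx, src)] + k[j]
    }
    M
  }
  Kv <- band(d[1]); Kh <- band(d[2])
  out <- img
  for (ch in seq_len(d[3])) out[, , ch] <- Kv %*% img[, , ch] %*% t(Kh)
  out
}

jitter_image <- function(img, strength) {
  if (strength <= 0) return(img)
  fb <- stats::runif(1, 1 - strength, 1 + strength)
  fc <- stats::runif(1, 1 - strength, 1 + strength)
  img <- img * fb
  m <- mean(img)
  img <- m + fc * (img - m)
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

normalize_batch <- function(x, mean = IMAGENET_MEAN, std = IMAGENET_STD) {
  d <- dim(x)
  for (ch in seq_len(d[3])) {
    x[, , ch, ] <- (x[, , ch, ] - mean[ch]) / std[ch]
  }
  x
}

random_resized_crop_params <- function(H, W, scale, aspect) {
  area <- H * W
  for (i in 1:10) {
    target <- area * stats::runif(1, scale[1], scale[2])
    logr <- stats::runif(1, log(aspect[1]), log(aspect[2]))
    ar <- exp(logr)
    w <- sqrt(target * ar)
    h <- sqrt(target / ar)
    if (h <= H && w <= W) {
      top <- stats::runif(1, 0, H - h)
      left <- stats::runif(1, 0, W - w)
      return(c(top, left, h, w))
    }
  }
  c(0, 0, H, W)  # fall back to the full frame
}

augment_one_view <- function(img, size, scale, aspect, flip_p, jitter, blur_p) {
  d <- dim(img)
  cp <- random_resized_crop_params(d[1], d[2], scale, aspect)
  out <- crop_resize_image(img, cp[1], cp[2], cp[3], cp[4], size)
  if (flip_p > 0 && stats::runif(1) < flip_p) out <- hflip_image(out)
  out <- jitter_image(out, jitter)
  if (blur_p > 0 && stats::runif(1) < blur_p) {
    out <- gauss_blur_image(out, stats::runif(1, 0.1, 2.0))
  }
  out
}

#' Generate two augmented views of an image batch
#'
#' Produces the stochastic view pair consumed by the self-supervised
#' objective. Each view independently applies a random resized crop
#' (area scale 0.6-1.0), horizontal flip (p = 0.5), brightness/contrast
#' jitter (strength 0.2), and Gaussian blur (p = 0.5 for view 1, 0.1 for
#' view 2), then normalizes with the ImageNet statistics. Vertical flips
#' and hue operations are never applied (grayscale anatomy with fixed
#' layer order).
#'
#' @param images A `(H, W, 3, N)` array with values in `[0, 1]`.
#' @param size Output side length in pixels (default 224; must be >= 32).
#' @param seed Optional integer seed; with a fixed seed the pair is
#'   bit-reproducible.
#' @param scale Random-resized-crop area range.
#' @param aspect Aspect-ratio range of the crop.
#' @param flip_p Horizontal flip probability.
#' @param jitter Brightness/contrast jitter strength.
#' @param blur_p Length-2 vector: blur probability for view 1 and view 2.
#' @param normalize Apply ImageNet normalization (default TRUE).
#' @return An object of class `sbyol_views`: list with `view1`, `view2`
#'   (`(size, size, 3, N)` arrays) and `seed_state`.
#' @export
make_views <- function(images, size = 224L, seed = NULL,
                       scale = c(0.6, 1.0), aspect = c(3 / 4, 4 / 3),
                       flip_p = 0.5, jitter = 0.2, blur_p = c(0.5, 0.1),
                       normalize = TRUE) {
  if (size < 32) stop(sprintf("view size %d is below the minimum of 32", size))
  d <- dim(images)
  if (is.null(d) || length(d) != 4) stop("images must be (H, W, C, N)")
  if (!is.null(seed)) set.seed(seed)
  seed_state <- .Random.seed
  N <- d[4]
  v1 <- array(0, dim = c(size, size, d[3], N))
  v2 <- v1
  for (n in seq_len(N)) {
    img <- images[, , , n, drop = FALSE]
    dim(img) <- d[1:3]
    v1[, , , n] <- augment_one_view(img, size, scale, aspect, flip_p,
                                    jitter, blur_p[1])
    v2[, , , n] <- augment_one_view(img, size, scale, aspect, flip_p,
                                    jitter, blur_p[2])
  }
  if (normalize) {
    v1 <- normalize_batch(v1)
    v2 <- normalize_batch(v2)
  }
  structure(list(view1 = v1, view2 = v2, seed_state = seed_state),
            class = "sbyol_views")
}

#' Fine-tuning input transform
#'
#' Train mode: resize to `size`, random horizontal flip, random rotation
#' within +/- 15 degrees, brightness/contrast jitter, ImageNet
#' normalization. Eval mode: resize and normalization only (deterministic).
#'
#' @param images A `(H, W, 3, N)` array in `[0, 1]`.
#' @param train_mode Apply stochastic augmentation (TRUE) or the
#'   deterministic eval pipeline (FALSE).
#' @param size Output side length (default 224).
#' @param seed Optional seed for reproducible train-mode augmentation.
#' @return A normalized `(size, size, 3, N)` array.
#' @export
finetune_transform <- function(images, train_mode = FALSE, size = 224L,
                               seed = NULL) {
  d <- dim(images)
  if (is.null(d) || length(d) != 4) stop("images must be (H, W, C, N)")
  if (!is.null(seed)) set.seed(seed)
  N <- d[4]
  out <- array(0, dim = c(size, size, d[3], N))
  for (n in seq_len(N)) {
    img <- images[, , , n, drop = FALSE]
    dim(img) <- d[1:3]
    x <- resize_image(img, size)
    if (train_mode) {
      if (stats::runif(1) < 0.5) x <- hflip_image(x)
      x <- rotate_image(x, stats::runif(1, -15, 15))
      x <- jitter_image(x, 0.2)
    }
    out[, , , n] <- x
  }
  normalize_batch(out)
}
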