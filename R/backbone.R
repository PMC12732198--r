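#' Convolutional encoder with a two-level feature pyramid
#'
#' Builds a ResNet-50-style encoder (7x7 stem, max pool, four stages of
#' bottleneck blocks with expansion 4) without any classifier head, exposing
#' feature maps at two depths: `s1`, the stage-3 output at stride 16, and
#' `s2`, the stage-4 output at stride 32. With the default configuration a
#' square input of side S yields `s1` with 1024 channels on an (S/16)^2 grid
#' and `s2` with 2048 channels on an (S/32)^2 grid — for S = 224 that is
#' 1024 x 14 x 14 (196 spatial locations) and 2048 x 7 x 7.
#'
#' @param blocks Integer vector of length 4: bottleneck blocks per stage
#'   (default `c(3, 4, 6, 3)`, the ResNet-50 layout).
#' @param base_width Width of the first stage's bottleneck (default 64).
#'   Stage output channels are `4 * base_width * c(1, 2, 4, 8)`; reduced
#'   widths give small encoders for desk-scale experiments.
#' @param seed Optional integer seed for reproducible random initialization.
#' @return An object of class `sbyol_encoder`: a list with the architecture
#'   (`arch`), initial parameters (`params`) and batch-norm state (`state`),
#'   plus the channel counts `c_s1` and `c_s2`.
#' @examples
#' enc <- build_encoder(blocks = c(1, 1, 1, 1), base_width = 4, seed = 1)
#' x <- array(stats::rnorm(64 * 64 * 3), dim = c(64, 64, 3, 1))
#' fp <- extract_pyramid(enc, x)
#' dim(fp$s1)
#' @export
build_encoder <- function(blocks = c(3L, 4L, 6L, 3L), base_width = 64L, seed = NULL) {
  stopifnot(length(blocks) == 4, all(blocks >= 1))
  base_width <- as.integer(base_width)
  widths <- base_width * c(1L, 2L, 4L, 8L)
  strides <- c(1L, 2L, 2L, 2L)

  stem <- nn_seq(
    conv = nn_conv(3L, base_width, 7L, stride = 2L, pad = 3L, bias = FALSE),
    bn = nn_bn2d(base_width),
    relu = nn_relu(),
    pool = nn_maxpool(3L, 2L, 1L)
  )

  in_ch <- base_width
  stages <- vector("list", 4L)
  for (s in 1:4) {
    blks <- vector("list", blocks[s])
    for (b in seq_len(blocks[s])) {
      stride <- if (b == 1L) strides[s] else 1L
      blks[[b]] <- nn_bottleneck(in_ch, widths[s], stride)
      in_ch <- 4L * widths[s]
    }
    names(blks) <- sprintf("b%02d", seq_len(blocks[s]))
    stages[[s]] <- list(type = "seq", layers = blks)
  }
  names(stages) <- sprintf("stage%d", 1:4)

  arch <- list(stem = stem, stages = stages)
  if (!is.null(seed)) set.seed(seed)
  init <- list(stem = nn_init(stem), stages = lapply(stages, nn_init))

  structure(list(
    arch = arch,
    params = list(stem = init$stem$params,
                  stages = lapply(init$stages, `[[`, "params")),
    state = list(stem = init$stem$state,
                 stages = lapply(init$stages, `[[`, "state")),
    blocks = as.integer(blocks),
    base_width = base_width,
    c_s1 = 4L * widths[3],
    c_s2 = 4L * widths[4]
  ), class = "sbyol_encoder")
}

#' @export
print.sbyol_encoder <- function(x, ...) {
  cat(sprintf("<sbyol_encoder> blocks [%s], base width %d\n",
              paste(x$blocks, collapse = ", "), x$base_width))
  cat(sprintf("  s1: %d channels (stride 16)   s2: %d channels (stride 32)\n",
              x$c_s1, x$c_s2))
  cat(sprintf("  parameters: %s\n", format(param_count(x$params), big.mark = ",")))
  invisible(x)
}

check_image_batch <- function(images) {
  d <- dim(images)
  if (is.null(d) || length(d) != 4) {
    stop("images must be a 4-d array (H, W, C, N)")
  }
  if (d[3] != 3) {
    stop(sprintf("images must have 3 channels, got %d", d[3]))
  }
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0) {
    stop(sprintf("input spatial size %dx%d is not divisible by 32", d[1], d[2]))
  }
  invisible(d)
}

# Forward pass through the encoder; returns s1, s2 and (optionally) the
# caches needed for backpropagation.
encoder_forward <- function(encoder, params, state, images, training = FALSE,
                            keep_cache = FALSE) {
  check_image_batch(images)
  arch <- encoder$arch
  caches <- list(stages = list())
  r <- nn_forward(arch$stem, params$stem, state$stem, images, training)
  x <- r$out
  new_state <- list(stem = r$state, stages = list())
  if (keep_cache) caches$stem <- r$cache
  s1 <- NULL
  for (s in 1:4) {
    nm <- sprintf("stage%d", s)
    r <- nn_forward(arch$stages[[nm]], params$stages[[nm]], state$stages[[nm]],
                    x, training)
    x <- r$out
    new_state$stages[[nm]] <- r$state
    if (keep_cache) caches$stages[[nm]] <- r$cache
    if (s == 3) s1 <- x
  }
  list(s1 = s1, s2 = x, state = new_state,
       cache = if (keep_cache) caches else NULL)
}

# Backward through the encoder given gradients flowing into s1 and/or s2.
encoder_backward <- function(encoder, params, cache, gs1 = NULL, gs2 = NULL,
                             need_gx = FALSE) {
  arch <- encoder$arch
  grads <- list(stages = list())
  g <- gs2
  for (s in 4:1) {
    nm <- sprintf("stage%d", s)
    if (s == 3 && !is.null(gs1)) {
      g <- if (is.null(g)) gs1 else g + gs1
    }
    r <- nn_backward(arch$stages[[nm]], params$stages[[nm]],
                     cache$stages[[nm]], g, need_gx = TRUE)
    grads$stages[[nm]] <- r$grads
    g <- r$gx
  }
  r <- nn_backward(arch$stem, params$stem, cache$stem, g, need_gx = need_gx)
  grads$stem <- r$grads
  # preserve stage order stage1..stage4 for tree alignment
  grads$stages <- grads$stages[sprintf("stage%d", 1:4)]
  list(grads = grads[c("stem", "stages")], gx = r$gx)
}

#' Extract the two-level feature pyramid from an image batch
#'
#' Runs a forward pass of the encoder in inference mode and returns the two
#' feature maps used by the spatially-aware self-supervised objective.
#'
#' @param encoder An `sbyol_encoder` from [build_encoder()], or a model
#'   bundle exposing `$arch`/`$params`/`$state` of the same shape.
#' @param images A `(H, W, C, N)` array with `C = 3` and `H`, `W` divisible
#'   by 32. Grayscale inputs should be replicated to 3 channels at load time
#'   (see [load_image_folder()]).
#' @param params,state Optional parameter/state trees overriding the ones
#'   stored in `encoder` (used internally during training).
#' @return An object of class `sbyol_pyramid` with elements `s1`
#'   (stride-16 map, `(H/16, W/16, C1, N)`), `s2` (stride-32 map,
#'   `(H/32, W/32, C2, N)`) and `input_size`.
#' @examples
#' enc <- build_encoder(blocks = c(1, 1, 1, 1), base_width = 4, seed = 1)
#' fp <- extract_pyramid(enc, array(0.5, dim = c(64, 64, 3, 2)))
#' dim(fp$s2)
#' @export
extract_pyramid <- function(encoder, images, params = NULL, state = NULL) {
  params <- params %||% encoder$params
  state <- state %||% encoder$state
  r <- encoder_forward(encoder, params, state, images, training = FALSE)
  structure(list(s1 = r$s1, s2 = r$s2, input_size = dim(images)[1:2]),
            class = "sbyol_pyramid")
}

#' Global average pooling of a feature map
#'
#' Reduces a `(H, W, C, N)` feature map to an `(N, C)` matrix by averaging
#' over the spatial grid — the pooled representation used by the global
#' branch of the objective.
#'
#' @param s A 4-d feature map array `(H, W, C, N)`.
#' @return An `(N, C)` numeric matrix.
#' @examples
#' global_pool(array(2, dim = c(7, 7, 16, 1)))[1, 1:3]
#' @export
global_pool <- function(s) {
  d <- dim(s)
  if (is.null(d) || length(d) != 4) stop("global_pool expects a 4-d array")
  m <- matrix(s, nrow = d[1] * d[2])  # (H*W) x (C*N)
  pooled <- colMeans(m)
  t(matrix(pooled, nrow = d[3], ncol = d[4]))  # (N, C)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
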