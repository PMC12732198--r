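# Shared fixtures: small encoders, models and phantom batches built in code.

sb <- asNamespace("spatialbyol")

tiny_encoder <- function(seed = 1, base_width = 4L) {
  build_encoder(blocks = c(1L, 1L, 1L, 1L), base_width = base_width,
                seed = seed)
}

tiny_ssl_model <- function(seed = 1, base_width = 4L) {
  build_ssl_model(tiny_encoder(seed, base_width),
                  proj_hidden = 32L, proj_dim = 16L,
                  spatial_mid = 16L, spatial_dim = 8L, seed = seed)
}

tiny_images <- function(n = 4, size = 64, seed = 1) {
  set.seed(seed)
  array(stats::runif(size * size * 3 * n), dim = c(size, size, 3L, n))
}

# central finite differences on a few randomly chosen coordinates
fd_gradient_check <- function(fn, x, gx, eps = 1e-5, k = 15) {
  idx <- sample(length(x), min(k, length(x)))
  num <- vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (fn(xp) - fn(xm)) / (2 * eps)
  }, numeric(1))
  max(abs(num - gx[idx]))
}
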