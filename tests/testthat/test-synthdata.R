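# The OCT phantom generator: determinism, the null-lesion limit, the
# boundary-contrast effect of the lesion, and dataset output.

test_that("phantoms are bitwise deterministic given config and seed", {
  cfg <- phantom_config(size = 64, seed = 5)
  a <- generate_phantom(cfg, TRUE)
  b <- generate_phantom(cfg, TRUE)
  expect_identical(a$image, b$image)
  expect_identical(a$lesion_mask, b$lesion_mask)
  expect_equal(a$label, "DRIL")
  expect_equal(generate_phantom(cfg, FALSE)$label, "NO_DRIL")
  # different seeds give different speckle
  cfg2 <- phantom_config(size = 64, seed = 6)
  expect_false(identical(generate_phantom(cfg2, TRUE)$image, a$image))
})

test_that("zero blur strength is the null-lesion limit", {
  cfg <- phantom_config(size = 64, dril_blur_sigma = 0, seed = 7)
  pos <- generate_phantom(cfg, TRUE)
  neg <- generate_phantom(cfg, FALSE)
  expect_identical(pos$image, neg$image)
  expect_false(identical(pos$label, neg$label))
})

test_that("matched seeds differ only inside the lesion mask", {
  for (s in 1:5) {
    cfg <- phantom_config(size = 64, seed = 100 + s)
    pos <- generate_phantom(cfg, TRUE)
    neg <- generate_phantom(cfg, FALSE)
    expect_true(any(pos$lesion_mask))
    expect_identical(pos$image[!pos$lesion_mask], neg$image[!pos$lesion_mask])
    expect_false(identical(pos$image[pos$lesion_mask],
                           neg$image[pos$lesion_mask]))
  }
})

test_that("the lesion lowers vertical boundary contrast (100 matched pairs)", {
  lower <- 0
  for (s in 1:100) {
    cfg <- phantom_config(size = 64, seed = 1000 + s)
    pos <- generate_phantom(cfg, TRUE)
    neg <- generate_phantom(cfg, FALSE)
    g_pos <- sb$vertical_gradient_energy(pos$image, pos$lesion_mask)
    g_neg <- sb$vertical_gradient_energy(neg$image, pos$lesion_mask)
    if (g_pos < g_neg) lower <- lower + 1
  }
  expect_equal(lower, 100)
})

test_that("speckle is multiplicative with unit mean within a band", {
  # single mid-intensity layer filling most of the frame: the band mean
  # approaches the configured reflectivity at 10^4+ pixels
  cfg <- phantom_config(size = 160, n_layers = 1,
                        layer_intensities = 0.4, fovea_depth = 0,
                        dril_blur_sigma = 0, seed = 11)
  ph <- generate_phantom(cfg, FALSE)
  band <- ph$image[45:115, ]  # interior rows of the single band
  expect_gt(length(band), 1e4)
  mc_err <- 3 * stats::sd(band) / sqrt(length(band))
  # small downward allowance for clipping at intensity 1
  expect_lt(abs(mean(band) - 0.4), mc_err + 0.003)
})

test_that("phantom batches stack both classes with replicated channels", {
  ph <- phantom_batch(3, phantom_config(size = 32), seed = 8)
  expect_equal(dim(ph$images), c(32, 32, 3, 6))
  expect_equal(ph$labels, rep(c("DRIL", "NO_DRIL"), each = 3))
  expect_identical(ph$images[, , 1, ], ph$images[, , 2, ])
  expect_true(all(ph$images >= 0 & ph$images <= 1))
})

test_that("config validation rejects impossible geometry", {
  expect_error(phantom_config(size = 8), "at least 16")
  expect_error(phantom_config(size = 64, dril_extent = 64), "smaller than size")
  expect_error(phantom_config(size = 64, n_layers = 3,
                              layer_intensities = c(0.5, 0.2)),
               "n_layers entries")
})

test_that("dataset writer produces the folder-per-class layout and manifest", {
  out <- withr::local_tempdir()
  m <- generate_dataset(4, phantom_config(size = 32), out, seed = 9)
  expect_equal(nrow(m), 8)
  expect_setequal(list.dirs(out, recursive = FALSE, full.names = FALSE),
                  c("DRIL", "NO_DRIL"))
  expect_length(list.files(file.path(out, "DRIL"), pattern = "png$"), 4)
  man <- utils::read.csv(file.path(out, "manifest.csv"))
  expect_equal(names(man), c("path", "label"))
  expect_equal(nrow(man), 8)

  # byte-identical manifests (and images) across reruns with the same seed
  out2 <- withr::local_tempdir()
  generate_dataset(4, phantom_config(size = 32), out2, seed = 9)
  expect_identical(readBin(file.path(out, "manifest.csv"), "raw", 1e5),
                   readBin(file.path(out2, "manifest.csv"), "raw", 1e5))
  f <- list.files(file.path(out, "DRIL"), full.names = TRUE)[1]
  f2 <- list.files(file.path(out2, "DRIL"), full.names = TRUE)[1]
  expect_identical(readBin(f, "raw", 1e6), readBin(f2, "raw", 1e6))

  # pretrain mode mirrors the four-category public layout
  out3 <- withr::local_tempdir()
  m3 <- generate_dataset(2, phantom_config(size = 32), out3, seed = 10,
                         mode = "pretrain")
  expect_setequal(unique(m3$label), c("CNV", "DME", "DRUSEN", "NORMAL"))
  expect_equal(nrow(m3), 8)
})
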