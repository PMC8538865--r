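test_that("confusion counting handles perfect, constant and mixed predictors", {
  cfp <- mrslots:::confusion_from_preds
  perfect <- cfp(c(0L, 1L, 2L), c(0L, 1L, 2L), 3L)
  expect_equal(unname(diag(perfect)), c(1L, 1L, 1L))
  expect_equal(sum(perfect) - sum(diag(perfect)), 0L)
  constant <- cfp(c(0L, 1L, 2L), c(1L, 1L, 1L), 3L)
  expect_equal(unname(colSums(constant)), c(0L, 3L, 0L))
  mixed <- cfp(c(0L, 1L, 1L), c(0L, 1L, 0L), 2L)
  expect_equal(sum(diag(mixed)) / sum(mixed), 2 / 3)
})

test_that("attention confusion builds a K x K grid and flags missing classes", {
  ds <- generate_dataset(synthetic_spec(num_classes = 2L, image_size = 32L,
                                        seed = 31L), 3L)
  cfg <- desk_config(input_size = 32L, dim = 16L, epochs = 0L,
                     batch_size = 4L, augment = FALSE, seed = 5L)
  fit <- train(cfg, ds)
  ac <- attention_confusion(fit$model, ds)
  expect_equal(dim(ac$mean_mass), c(2L, 2L))
  expect_false(any(ac$empty))
  for (i in 1:2) for (j in 1:2) {
    expect_equal(dim(ac$maps[[i, j]]), c(32L, 32L))
    expect_true(all(ac$maps[[i, j]] >= 0))
  }
  # drop one class: its row is flagged empty
  only0 <- ds[vapply(ds, function(s) s$label == 0L, logical(1))]
  ac0 <- attention_confusion(fit$model, only0)
  expect_true(ac0$empty[2L])
  expect_false(ac0$empty[1L])
})

test_that("localization scores masks with the uniform-map null at 1", {
  K <- 2L
  mk_fused <- function(m) {
    maps <- array(0, c(K, nrow(m), ncol(m)))
    maps[1L, , ] <- m
    structure(list(maps = maps, weights_used = 1, K = K, size = nrow(m)),
              class = "fused_attention")
  }
  mask <- matrix(0L, 4L, 4L); mask[1:2, 1:4] <- 1L   # 8 of 16 pixels
  # map entirely inside the mask
  inside <- matrix(0, 4L, 4L); inside[1L, 1L] <- 3
  expect_equal(localization(mk_fused(inside), 0L, mask)$mass_in_mask, 1)
  # uniform map: mass fraction = area fraction, enrichment = 1
  u <- localization(mk_fused(matrix(0.3, 4L, 4L)), 0L, mask)
  expect_equal(u$mass_in_mask, 0.5, tolerance = 1e-12)
  expect_equal(u$enrichment, 1, tolerance = 1e-12)
  # 3/4 of the mass inside an 8-pixel mask
  m <- matrix(0, 4L, 4L); m[1L, 1L] <- 3; m[4L, 4L] <- 1
  got <- localization(mk_fused(m), 0L, mask)
  expect_equal(got$mass_in_mask, 0.75)
  expect_equal(got$enrichment, 1.5)
  expect_error(localization(mk_fused(m), 0L, mask * 0L), "data error")
})

test_that("overlay thresholding zeroes sub-threshold alpha", {
  img <- array(0.5, c(4L, 4L, 3L))
  maps <- array(0, c(1L, 4L, 4L))
  maps[1L, , ] <- matrix(c(0.8, 0.4, 0.07, 0.02,  rep(0.1, 12)), 4L, 4L)
  fused <- structure(list(maps = maps, weights_used = 1, K = 1L, size = 4L),
                     class = "fused_attention")
  rgba <- render_overlay(img, fused, 0L, threshold_frac = 0.1)
  expect_equal(dim(rgba), c(4L, 4L, 4L))
  a <- rgba[, , 4L]
  expect_equal(max(a), 1)                       # map max -> alpha 1
  expect_true(all(a[maps[1L, , ] < 0.08] == 0)) # below 0.1 * max(0.8)
  expect_true(all(a[maps[1L, , ] >= 0.08] > 0))
  # threshold 0 keeps the normalized map as alpha
  rgba0 <- render_overlay(img, fused, 0L, threshold_frac = 0)
  expect_equal(rgba0[, , 4L], maps[1L, , ] / 0.8, tolerance = 1e-12)
  # constant map -> uniform nonzero alpha
  cmaps <- maps; cmaps[1L, , ] <- 0.3
  cf <- structure(list(maps = cmaps, weights_used = 1, K = 1L, size = 4L),
                  class = "fused_attention")
  expect_equal(unique(as.vector(render_overlay(img, cf, 0L)[, , 4L])), 1)
  # all-zero map warns and is fully transparent
  zf <- cf; zf$maps[] <- 0
  expect_warning(z <- render_overlay(img, zf, 0L), "transparent")
  expect_equal(max(z[, , 4L]), 0)
})

test_that("the level gallery writes a deterministic montage per level", {
  set.seed(50)
  img <- generate_dataset(synthetic_spec(seed = 6L), 1L)[[1]]$image
  levels <- lapply(c(16L, 8L, 4L, 2L), function(s) {
    make_level(array(stats::runif(2 * s * s), c(2L, s, s)))
  })
  fused <- fuse(levels, 64L)
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  level_gallery(levels, fused, img, 0L, p1)
  level_gallery(levels, fused, img, 0L, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  arr <- level_gallery(levels, fused, img, 0L)
  # original + fused + one panel per level, 64px wide each, 6px scale bars,
  # 4px margins
  expect_equal(dim(arr)[2L], 64L + 5L * 70L + 5L * 4L)
  # single level: the fused panel equals that level's upsampled panel
  single <- levels[2L]
  fs <- fuse(single, 64L)
  arr1 <- level_gallery(single, fs, img, 0L)
  w0 <- 64L + 4L
  expect_equal(arr1[, (w0 + 1L):(w0 + 70L), ],
               arr1[, (w0 + 70L + 4L + 1L):(w0 + 2L * 70L + 4L), ],
               tolerance = 1e-12)
})
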