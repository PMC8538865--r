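test_that("fusion weights normalize level saliencies", {
  l1 <- make_level(array(0.5, c(2L, 2L, 2L)))
  expect_equal(fusion_weights(list(l1)), 1)
  l2 <- make_level(array(0.5, c(2L, 4L, 4L)))
  expect_equal(fusion_weights(list(l1, l2)), c(0.5, 0.5))
  la <- make_level(array(0.5, c(2L, 2L, 2L))); la$saliency <- 2
  lb <- make_level(array(0.5, c(2L, 2L, 2L))); lb$saliency <- 6
  expect_equal(fusion_weights(list(la, lb)), c(0.25, 0.75))
  # all-zero saliencies fall back to uniform
  lz <- make_level(array(0, c(2L, 2L, 2L)))
  expect_equal(fusion_weights(list(lz, lz, lz)), rep(1 / 3, 3L))
  expect_error(fusion_weights(list()), "data error")
})

test_that("fuse honors degenerate weights and constant maps", {
  set.seed(40)
  l1 <- make_level(array(stats::runif(2 * 4 * 4), c(2L, 4L, 4L)))
  l2 <- make_level(array(stats::runif(2 * 2 * 2), c(2L, 2L, 2L)))
  f <- fuse(list(l1, l2), 8L, weights = c(1, 0))
  for (k in 1:2) {
    expect_equal(f$maps[k, , ], bilinear_resize(l1$maps[k, , ], 8L, 8L),
                 tolerance = 1e-12)
  }
  # constant maps fuse to the same constant
  ca <- make_level(array(0.37, c(2L, 4L, 4L)))
  cb <- make_level(array(0.37, c(2L, 2L, 2L)))
  fc <- fuse(list(ca, cb), 8L)
  expect_equal(max(abs(fc$maps - 0.37)), 0, tolerance = 1e-12)
  # K mismatch is a data error
  l3 <- make_level(array(0.1, c(3L, 2L, 2L)))
  expect_error(fuse(list(l1, l3), 8L), "data error")
})

test_that("fused maps match a per-pixel loop oracle", {
  set.seed(41)
  m1 <- array(stats::runif(2 * 2 * 2), c(2L, 2L, 2L))
  m2 <- array(stats::runif(2 * 1 * 1), c(2L, 1L, 1L))
  l1 <- make_level(m1); l2 <- make_level(m2)
  w <- fusion_weights(list(l1, l2))
  f <- fuse(list(l1, l2), 4L)
  for (k in 1:2) {
    want <- w[1] * oracle_bilinear(m1[k, , ], 4L, 4L) +
      w[2] * oracle_bilinear(m2[k, , , drop = TRUE] + matrix(0, 1, 1), 4L, 4L)
    expect_equal(f$maps[k, , ], want, tolerance = 1e-6)
  }
})

test_that("fused pixels stay inside the envelope of upsampled level maps", {
  set.seed(42)
  for (rep in 1:5) {
    levels <- lapply(c(4L, 2L), function(s) {
      make_level(array(stats::runif(3 * s * s), c(3L, s, s)))
    })
    f <- fuse(levels, 8L)
    expect_equal(sum(f$weights_used), 1, tolerance = 1e-12)
    up <- lapply(levels, function(l) {
      vapply(1:3, function(k) bilinear_resize(l$maps[k, , ], 8L, 8L),
             matrix(0, 8L, 8L))
    })
    for (k in 1:3) {
      lo <- pmin(up[[1]][, , k], up[[2]][, , k])
      hi <- pmax(up[[1]][, , k], up[[2]][, , k])
      expect_true(all(f$maps[k, , ] >= lo - 1e-9))
      expect_true(all(f$maps[k, , ] <= hi + 1e-9))
    }
  }
})

test_that("class logits are the deepest level's slot masses", {
  maps <- array(0, c(2L, 2L, 2L))
  maps[1L, , ] <- matrix(c(1, 0.5, 1, 0.5), 2L)   # mass 3.0
  maps[2L, , ] <- matrix(c(0.25, 0.25, 0.25, 0.25), 2L)  # mass 1.0
  deep <- make_level(maps)
  expect_equal(class_logits(deep), c(3, 1))
  expect_equal(class_logits(deep, e = -1), c(-3, -1))
  # uniform maps -> equal logits -> probabilities 1/K
  u <- make_level(array(0.2, c(4L, 2L, 2L)))
  lg <- class_logits(u)
  expect_equal(stats::sd(lg), 0)
  # an all-zero slot map scores the minimum possible mass
  z <- maps; z[2L, , ] <- 0
  expect_equal(class_logits(make_level(z))[2L], 0)
})

test_that("the loss decomposes as ce + lambda * area", {
  # hand instance: uniform 2-class logits give ce = ln 2; area 1.5, lambda 2
  la <- make_level(array(1, c(2L, 1L, 1L))); la$saliency <- 0.5
  lb <- make_level(array(1, c(2L, 1L, 1L))); lb$saliency <- 1.0
  lb2 <- lb
  lo <- scouter_loss(c(0.7, 0.7), 0L, list(la, lb), lambda = 2)
  expect_equal(lo$ce, log(2), tolerance = 1e-9)
  expect_equal(lo$area, 1.5, tolerance = 1e-12)
  expect_equal(lo$total, log(2) + 3, tolerance = 1e-9)
  # lambda = 0 switches the regularizer off
  expect_equal(scouter_loss(c(2, 1), 1L, list(la), lambda = 0)$total,
               scouter_loss(c(2, 1), 1L, list(la), lambda = 0)$ce)
  # saturated one-hot logits: ce ~ 0, total ~ lambda * area
  sat <- scouter_loss(c(50, 0, 0), 0L, list(la), lambda = 2)
  expect_lt(sat$ce, 1e-12)
  expect_equal(sat$total, 2 * la$saliency, tolerance = 1e-9)
  # decomposition identity on random instances
  set.seed(43)
  for (rep in 1:10) {
    lv <- make_level(array(stats::runif(8), c(2L, 2L, 2L)))
    lg <- stats::rnorm(2)
    lam <- stats::runif(1, 0, 5)
    br <- scouter_loss(lg, 1L, list(lv), lambda = lam)
    expect_equal(br$total, br$ce + lam * br$area, tolerance = 1e-6)
    expect_gte(br$area, 0)
  }
  expect_error(scouter_loss(c(1, 2), 2L, list(la)), "data error")
})
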