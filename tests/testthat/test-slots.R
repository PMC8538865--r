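test_that("slot initialization follows the learned Gaussian", {
  p <- slot_module_params(dim = 8L, K = 3L, seed = 1L)
  st <- init_slots(p, 3L, seed = 5L)
  expect_equal(dim(st$slots), c(3L, 8L))
  expect_equal(st$iteration, 0L)
  expect_identical(init_slots(p, 3L, seed = 5L)$slots, st$slots)
  # degenerate Gaussian (std -> 0) collapses onto the means
  p0 <- p; p0$slot_init_logstd[] <- -Inf
  expect_equal(init_slots(p0, 3L, seed = 5L)$slots, p$slot_init_mean,
               tolerance = 1e-12)
  expect_error(init_slots(p, 4L), "configuration error")
})

test_that("attention_step matches the brute-force loop oracle", {
  set.seed(20)
  for (rep in 1:20) {
    K <- sample(2:3, 1); P <- sample(2:6, 1); D <- sample(2:4, 1)
    p <- slot_module_params(dim = D, K = K, seed = rep)
    st <- init_slots(p, K, seed = rep + 100L)
    feats <- rand_feats(P, D)
    got <- attention_step(st, feats, p)
    want <- oracle_attention_step(st$slots, feats$tokens, p$Wq, p$Wk, p$Wv)
    expect_equal(got$update, want$update, tolerance = 1e-6)
    expect_equal(got$attn, want$attn, tolerance = 1e-6)
    expect_equal(got$evidence, want$evidence, tolerance = 1e-6)
  }
})

test_that("identical slots and tokens give uniform competition", {
  D <- 6L; K <- 3L; P <- 4L
  p <- slot_module_params(dim = D, K = K, seed = 2L)
  p$slot_init_mean <- matrix(rep(stats::rnorm(D), each = K), K, D)
  st <- init_slots(p, K, sample = FALSE)
  tok <- matrix(rep(stats::rnorm(D), each = P), P, D)
  feats <- structure(list(tokens = tok, level = 1L, H = 1L, W = P),
                     class = "encoded_features")
  got <- attention_step(st, feats, p)
  expect_equal(got$attn, matrix(1 / K, K, P), tolerance = 1e-9)
  # every slot's update is the value projection of the (single) token
  vexp <- as.numeric(tok[1L, ] %*% p$Wv)
  for (k in seq_len(K)) expect_equal(got$update[k, ], vexp, tolerance = 1e-6)
})

test_that("zero queries give uniform attention everywhere", {
  p <- slot_module_params(dim = 4L, K = 3L, seed = 3L)
  p$Wq[] <- 0
  st <- init_slots(p, 3L, seed = 1L)
  got <- attention_step(st, rand_feats(5L, 4L), p)
  expect_equal(got$attn, matrix(1 / 3, 3L, 5L), tolerance = 1e-12)
})

test_that("update_slots honors the explanation sign contract", {
  p <- slot_module_params(dim = 5L, K = 2L, seed = 4L)
  st <- init_slots(p, 2L, seed = 2L)
  U <- matrix(stats::rnorm(10), 2L, 5L)
  pos <- update_slots(st, U, 1, p)
  neg <- update_slots(st, U, -1, p)
  expect_equal(pos$iteration, 1L)
  # e = +1 vs e = -1 feed exact negatives into the GRU: states differ
  expect_false(isTRUE(all.equal(pos$slots, neg$slots)))
  # zero update: both signs coincide (0 = -0)
  z0 <- update_slots(st, U * 0, 1, p)
  z1 <- update_slots(st, U * 0, -1, p)
  expect_equal(z0$slots, z1$slots, tolerance = 1e-12)
  # row-wise scalar oracle for the composed GRU + MLP refinement
  for (k in 1:2) {
    expect_equal(pos$slots[k, ],
                 oracle_refine_row(st$slots[k, ], U[k, ], 1, p$gru, p$mlp),
                 tolerance = 1e-9)
  }
})

test_that("T-iteration run equals the manual composition of its steps", {
  D <- 4L; K <- 2L; P <- 6L
  p <- slot_module_params(dim = D, K = K, T = 3L, seed = 6L)
  feats <- rand_feats(P, D, H = 2L, W = 3L)
  run <- run_slot_attention(feats, K, 1, p, seed = 9L, sample = TRUE)
  st <- init_slots(p, K, seed = 9L, sample = TRUE)
  for (t in 1:3) {
    stp <- attention_step(st, feats, p)
    last_attn <- stp$attn
    st <- update_slots(st, stp$update, 1, p)
  }
  expect_equal(run$state$slots, st$slots, tolerance = 1e-9)
  expect_equal(run$state$iteration, 3L)
  # returned maps are the FINAL iteration's attention
  expect_equal(matrix(aperm(run$level_attn$attn, c(1L, 3L, 2L)), K),
               last_attn, tolerance = 1e-9)
})

test_that("T = 0 leaves slots at initialization", {
  p <- slot_module_params(dim = 4L, K = 2L, T = 3L, seed = 7L)
  feats <- rand_feats(4L, 4L)
  run <- run_slot_attention(feats, 2L, 1, p, seed = 3L, sample = TRUE, T = 0L)
  expect_equal(run$state$slots, init_slots(p, 2L, seed = 3L)$slots,
               tolerance = 1e-12)
  expect_equal(run$state$iteration, 0L)
  expect_length(run$attn_history, 0L)
})

test_that("per-position slot weights sum to 1 after every iteration", {
  p <- slot_module_params(dim = 6L, K = 3L, T = 4L, seed = 8L)
  feats <- rand_feats(9L, 6L, H = 3L, W = 3L)
  run <- run_slot_attention(feats, 3L, -1, p, seed = 2L, sample = TRUE, T = 4L)
  expect_length(run$attn_history, 4L)
  for (A in run$attn_history) {
    expect_true(all(A >= 0))
    expect_equal(colSums(A), rep(1, 9L), tolerance = 1e-6)
  }
  # determinism of the full run
  run2 <- run_slot_attention(feats, 3L, -1, p, seed = 2L, sample = TRUE, T = 4L)
  expect_identical(run$level_attn$maps, run2$level_attn$maps)
})

test_that("the module is permutation-equivariant over tokens", {
  set.seed(30)
  D <- 5L; K <- 3L; P <- 7L
  p <- slot_module_params(dim = D, K = K, seed = 9L)
  st <- init_slots(p, K, seed = 4L)
  feats <- rand_feats(P, D)
  perm <- sample.int(P)
  featsP <- structure(list(tokens = feats$tokens[perm, , drop = FALSE],
                           level = 1L, H = 1L, W = P),
                      class = "encoded_features")
  a <- attention_step(st, feats, p)
  b <- attention_step(st, featsP, p)
  # permuting tokens permutes the attention columns and leaves updates fixed
  expect_equal(b$attn, a$attn[, perm], tolerance = 1e-9)
  expect_equal(b$update, a$update, tolerance = 1e-9)
})

test_that("empty token sets are data errors", {
  p <- slot_module_params(dim = 4L, K = 2L, seed = 10L)
  st <- init_slots(p, 2L, seed = 1L)
  feats <- structure(list(tokens = matrix(0, 0L, 4L), level = 1L,
                          H = 0L, W = 0L), class = "encoded_features")
  expect_error(attention_step(st, feats, p), "data error")
})
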