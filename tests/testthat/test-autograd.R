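# The gradient tape is validated against central finite differences on a
# composite graph that exercises every op the model forward uses.

fd_gradient <- function(build, params, nm, eps = 1e-6) {
  v <- params[[nm]]
  g <- array(0, dim = dim(as.matrix(v)))
  for (i in seq_along(v)) {
    p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
    f1 <- build(p2)$root$value
    p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
    f0 <- build(p2)$root$value
    g[i] <- (f1 - f0) / (2 * eps)
  }
  g
}

test_that("tape gradients match finite differences through the attention graph", {
  set.seed(11)
  B <- 2L; P <- 5L; K <- 3L; D <- 4L
  params <- list(
    X = matrix(rnorm(B * P * 3), B * P, 3),
    Wp = matrix(rnorm(3 * D) * 0.5, 3, D),
    pos = matrix(rnorm(P * D) * 0.3, P, D),
    Wq = matrix(rnorm(D * D) * 0.5, D, D),
    Wk = matrix(rnorm(D * D) * 0.5, D, D),
    Wv = matrix(rnorm(D * D) * 0.5, D, D),
    mu = matrix(rnorm(K * D) * 0.5, K, D),
    b = rnorm(D))
  build <- function(p) {
    tp <- mrslots:::ag_tape()
    pn <- lapply(p, function(v) mrslots:::ag_const(tp, v))
    tok <- mrslots:::ag_matmul(tp, pn$X, pn$Wp)
    tok <- mrslots:::ag_add(tp, tok,
             mrslots:::ag_gather_rows(tp, pn$pos, rep(seq_len(P), B)))
    tok <- mrslots:::ag_add_rowvec(tp, tok, pn$b)
    keys <- mrslots:::ag_matmul(tp, tok, pn$Wk)
    vals <- mrslots:::ag_matmul(tp, tok, pn$Wv)
    slots <- mrslots:::ag_gather_rows(tp, pn$mu, rep(seq_len(K), B))
    st <- mrslots:::fw_slot_step(tp, list(Wq = pn$Wq), slots, keys, vals,
                                 B, K, P, 1 / sqrt(D))
    M <- mrslots:::ag_sigmoid(tp, st$L)
    mass <- mrslots:::ag_rowsum_block(tp, M, P, B)
    ce <- mrslots:::ag_cross_entropy(tp, mass, c(1L, 2L))
    extra <- mrslots:::ag_mean(tp, mrslots:::ag_relu(tp, st$U))
    root <- mrslots:::ag_add(tp, ce, mrslots:::ag_scale(tp, extra, 0.3))
    list(tp = tp, root = root, pnodes = pn)
  }
  out <- build(params)
  grads <- mrslots:::ag_backward(out$tp, out$root)
  for (nm in names(params)) {
    expect_lt(max(abs(as.numeric(grads[[out$pnodes[[nm]]$id]]) -
                        as.numeric(fd_gradient(build, params, nm)))), 1e-5)
  }
})

test_that("im2col convolution gradients match finite differences", {
  set.seed(12)
  cfg <- backbone_config(kind = "tiny", n_levels = 1L, input_size = 32L,
                         dim = 8L)
  plan <- mrslots:::build_plan(cfg, 2L)
  params <- list(X = matrix(rnorm(2 * 32 * 32 * 3) * 0.3, 2 * 1024, 3),
                 W = matrix(rnorm(27 * 4) * 0.3, 27, 4),
                 b = rnorm(4))
  build <- function(p) {
    tp <- mrslots:::ag_tape()
    pn <- lapply(p, function(v) mrslots:::ag_const(tp, v))
    pat <- mrslots:::ag_im2col(tp, pn$X, plan$levels[[1]]$stages[[1]]$idx, 9L)
    y <- mrslots:::ag_relu(tp, mrslots:::ag_add_rowvec(tp,
           mrslots:::ag_matmul(tp, pat, pn$W), pn$b))
    root <- mrslots:::ag_mean(tp, mrslots:::ag_mul(tp, y, y))
    list(tp = tp, root = root, pnodes = pn)
  }
  out <- build(params)
  grads <- mrslots:::ag_backward(out$tp, out$root)
  for (nm in c("W", "b")) {
    expect_lt(max(abs(as.numeric(grads[[out$pnodes[[nm]]$id]]) -
                        as.numeric(fd_gradient(build, params, nm)))), 1e-5)
  }
  # spot-check a handful of input pixels (full loop would be slow)
  gX <- grads[[out$pnodes$X$id]]
  idx <- c(1L, 500L, 1025L, 2048L)
  p2 <- params
  for (i in idx) {
    eps <- 1e-6
    p2$X[i] <- params$X[i] + eps; f1 <- build(p2)$root$value
    p2$X[i] <- params$X[i] - eps; f0 <- build(p2)$root$value
    p2$X[i] <- params$X[i]
    expect_lt(abs(gX[i] - (f1 - f0) / (2 * eps)), 1e-5)
  }
})

test_that("block segment-sum and readout agree with their generic forms", {
  set.seed(13)
  B <- 3L; P <- 4L; K <- 2L; D <- 5L
  A <- matrix(rnorm(B * P * K), B * P, K)
  tp <- mrslots:::ag_tape()
  a <- mrslots:::ag_const(tp, A)
  blk <- mrslots:::ag_rowsum_block(tp, a, P, B)
  gen <- mrslots:::ag_rowsum_group(tp, a, rep(seq_len(B), each = P), B)
  expect_equal(blk$value, unname(gen$value), tolerance = 1e-12)
})
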