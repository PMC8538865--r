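# Independent oracles, written as plain nested loops so they share no code
# with the vectorized implementation they check.

# Brute-force slot-attention step: logits, softmax across slots per token,
# within-slot renormalization over tokens, weighted-mean readout, sigmoid
# evidence. All scalar loops.
oracle_attention_step <- function(slots, tokens, Wq, Wk, Wv) {
  K <- nrow(slots); D <- ncol(slots); P <- nrow(tokens)
  q <- matrix(0, K, D); kk <- matrix(0, P, D); v <- matrix(0, P, D)
  for (i in seq_len(K)) for (d in seq_len(D)) {
    q[i, d] <- sum(slots[i, ] * Wq[, d])
  }
  for (p in seq_len(P)) for (d in seq_len(D)) {
    kk[p, d] <- sum(tokens[p, ] * Wk[, d])
    v[p, d] <- sum(tokens[p, ] * Wv[, d])
  }
  logits <- matrix(0, K, P)
  for (i in seq_len(K)) for (p in seq_len(P)) {
    logits[i, p] <- sum(q[i, ] * kk[p, ]) / sqrt(D)
  }
  attn <- matrix(0, K, P)
  for (p in seq_len(P)) {
    e <- exp(logits[, p] - max(logits[, p]))
    attn[, p] <- e / sum(e)
  }
  update <- matrix(0, K, D)
  for (i in seq_len(K)) {
    w <- attn[i, ] / (sum(attn[i, ]) + 1e-8)
    for (d in seq_len(D)) update[i, d] <- sum(w * v[, d])
  }
  list(update = update, attn = attn,
       evidence = 1 / (1 + exp(-logits)), logits = logits)
}

# Scalar-loop GRU + residual-MLP refinement for one slot row.
oracle_refine_row <- function(s, u, e, gru, mlp) {
  x <- e * u
  sig <- function(z) 1 / (1 + exp(-z))
  z <- sig(as.numeric(x %*% gru$Wiz) + as.numeric(s %*% gru$Whz) + gru$bz)
  r <- sig(as.numeric(x %*% gru$Wir) + as.numeric(s %*% gru$Whr) + gru$br)
  n <- tanh(as.numeric(x %*% gru$Win) + r * as.numeric(s %*% gru$Whn) + gru$bn)
  h <- (1 - z) * n + z * s
  hid <- pmax(as.numeric(h %*% mlp$W1) + mlp$b1, 0)
  h + as.numeric(hid %*% mlp$W2) + mlp$b2
}

# Per-pixel loop bilinear resize with the package's center-aligned
# convention (clamped borders).
oracle_bilinear <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, out_h, out_w)
  for (r in seq_len(out_h)) for (cc in seq_len(out_w)) {
    sy <- (r - 0.5) * h / out_h - 0.5
    sx <- (cc - 0.5) * w / out_w - 0.5
    y0 <- min(max(floor(sy), 0), h - 1); y1 <- min(y0 + 1, h - 1)
    x0 <- min(max(floor(sx), 0), w - 1); x1 <- min(x0 + 1, w - 1)
    fy <- min(max(sy - y0, 0), 1); fx <- min(max(sx - x0, 0), 1)
    out[r, cc] <- (m[y0 + 1, x0 + 1] * (1 - fx) + m[y0 + 1, x1 + 1] * fx) * (1 - fy) +
      (m[y1 + 1, x0 + 1] * (1 - fx) + m[y1 + 1, x1 + 1] * fx) * fy
  }
  out
}

# Random encoded-features fixture.
rand_feats <- function(P, D, H = NULL, W = NULL, level = 1L) {
  if (is.null(H)) { H <- 1L; W <- P }
  structure(list(tokens = matrix(stats::rnorm(P * D), P, D),
                 level = level, H = H, W = W),
            class = "encoded_features")
}

make_level <- function(maps) {
  # maps: K x H x W array of nonnegative values
  K <- dim(maps)[1L]
  structure(list(maps = maps, attn = maps * 0, level = 1L,
                 saliency = mean(maps), K = K,
                 H = dim(maps)[2L], W = dim(maps)[3L],
                 saliency_mode = "mean"),
            class = "level_attention")
}
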