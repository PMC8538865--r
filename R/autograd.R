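# Minimal reverse-mode gradient tape over plain R matrices.
#
# Every differentiable quantity is a node on a tape; ops record a
# vector-Jacobian-product closure. The model forward pass is written once in
# terms of these ops and reused for training (with backward) and inference
# (values only). Ops are deliberately coarse (whole-batch matrices) so the
# interpreter overhead stays negligible next to the BLAS calls.

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ag_node <- function(tp, value, parents = list(), vjp = NULL) {
  # force args first: an argument expression may itself create nodes, and ids
  # must reflect creation order
  force(value); force(parents); force(vjp)
  nd <- new.env(parent = emptyenv())
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) {
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  }
  nd$id <- tp$n
  nd$value <- value
  nd$parents <- parents
  nd$vjp <- vjp
  tp$nodes[[tp$n]] <- nd
  nd
}

# Leaf holding a constant or a parameter; gradients are collected by node id.
ag_const <- function(tp, value) ag_node(tp, value)

#' @noRd
ag_backward <- function(tp, root, seed = 1) {
  grads <- vector("list", tp$n)
  grads[[root$id]] <- if (is.matrix(root$value)) {
    matrix(seed, nrow(root$value), ncol(root$value))
  } else {
    seed
  }
  for (i in seq.int(root$id, 1L)) {
    nd <- tp$nodes[[i]]
    g <- grads[[i]]
    if (is.null(g) || is.null(nd$vjp)) next
    pg <- nd$vjp(g)
    for (j in seq_along(nd$parents)) {
      if (is.null(pg[[j]])) next
      pid <- nd$parents[[j]]$id
      grads[[pid]] <- if (is.null(grads[[pid]])) pg[[j]] else grads[[pid]] + pg[[j]]
    }
    grads[i] <- list(NULL)   # free as we go (keep list length intact)
  }
  grads
}

ag_matmul <- function(tp, a, b) {
  A <- a$value; B <- b$value
  ag_node(tp, A %*% B, list(a, b), function(g) {
    list(g %*% t(B), crossprod(A, g))
  })
}

ag_add <- function(tp, a, b) {
  ag_node(tp, a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_sub <- function(tp, a, b) {
  ag_node(tp, a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(tp, a, b) {
  A <- a$value; B <- b$value
  ag_node(tp, A * B, list(a, b), function(g) list(g * B, g * A))
}

ag_div <- function(tp, a, b) {
  A <- a$value; B <- b$value
  ag_node(tp, A / B, list(a, b), function(g) list(g / B, -g * A / (B * B)))
}

# value + row vector broadcast over every row
ag_add_rowvec <- function(tp, a, b) {
  A <- a$value; bv <- as.numeric(b$value)
  ag_node(tp, A + matrix(bv, nrow(A), length(bv), byrow = TRUE), list(a, b),
          function(g) list(g, colSums(g)))
}

ag_scale <- function(tp, a, s) {
  ag_node(tp, a$value * s, list(a), function(g) list(g * s))
}

ag_add_const <- function(tp, a, c) {
  ag_node(tp, a$value + c, list(a), function(g) list(g))
}

# Multiply / shift by a learnable scalar (stored as a 1 x 1 matrix node).
ag_mul_scalar <- function(tp, a, s) {
  A <- a$value; sv <- as.numeric(s$value)
  ag_node(tp, A * sv, list(a, s), function(g) {
    list(g * sv, matrix(sum(g * A), 1L, 1L))
  })
}

ag_add_scalar <- function(tp, a, s) {
  A <- a$value; sv <- as.numeric(s$value)
  ag_node(tp, A + sv, list(a, s), function(g) {
    list(g, matrix(sum(g), 1L, 1L))
  })
}

ag_relu <- function(tp, a) {
  A <- a$value
  ag_node(tp, A * (A > 0), list(a), function(g) list(g * (A > 0)))
}

ag_sigmoid <- function(tp, a) {
  S <- 1 / (1 + exp(-a$value))
  ag_node(tp, S, list(a), function(g) list(g * S * (1 - S)))
}

ag_tanh <- function(tp, a) {
  S <- tanh(a$value)
  ag_node(tp, S, list(a), function(g) list(g * (1 - S * S)))
}

row_max <- function(A) {
  m <- A[, 1L]
  for (j in seq_len(ncol(A))[-1L]) m <- pmax(m, A[, j])
  m
}

# Row-wise softmax (each row sums to 1).
ag_softmax_rows <- function(tp, a) {
  A <- a$value
  m <- row_max(A)
  E <- exp(A - m)
  S <- E / rowSums(E)
  ag_node(tp, S, list(a), function(g) {
    list(S * (g - rowSums(g * S)))
  })
}

# Segment sum of rows: group must cover 1..ngroups (each at least once).
ag_rowsum_group <- function(tp, a, group, ngroups) {
  val <- rowsum(a$value, group, reorder = TRUE)
  stopifnot(nrow(val) == ngroups)
  ag_node(tp, val, list(a), function(g) list(g[group, , drop = FALSE]))
}

# Segment sum over B contiguous blocks of P rows each (batch layout):
# much cheaper than the generic grouped version.
ag_rowsum_block <- function(tp, a, P, B) {
  A <- a$value
  C <- ncol(A)
  val <- colSums(array(A, c(P, B, C)))          # B x C
  ag_node(tp, val, list(a), function(g) {
    list(g[rep(seq_len(B), each = P), , drop = FALSE])
  })
}

ag_gather_rows <- function(tp, a, idx) {
  A <- a$value
  ag_node(tp, A[idx, , drop = FALSE], list(a), function(g) {
    rs <- rowsum(g, idx, reorder = TRUE)
    if (nrow(rs) == nrow(A)) return(list(unname(rs)))   # every row gathered
    Z <- matrix(0, nrow(A), ncol(A))
    Z[as.integer(rownames(rs)), ] <- rs
    list(Z)
  })
}

# Multiply each row of a (N x D) by w (length-N vector node).
ag_scale_rows <- function(tp, a, w) {
  A <- a$value; wv <- as.numeric(w$value)
  ag_node(tp, A * wv, list(a, w), function(g) {
    list(g * wv, rowSums(g * A))
  })
}

ag_sum <- function(tp, a) {
  A <- a$value
  ag_node(tp, sum(A), list(a), function(g) {
    list(matrix(g, nrow(A), ncol(A)))
  })
}

ag_mean <- function(tp, a) {
  A <- a$value; n <- length(A)
  ag_node(tp, sum(A) / n, list(a), function(g) {
    list(matrix(g / n, nrow(A), ncol(A)))
  })
}

# Row sums as an N x 1 matrix.
ag_rowsums <- function(tp, a) {
  A <- a$value
  ag_node(tp, matrix(rowSums(A), ncol = 1L), list(a), function(g) {
    list(matrix(g, nrow(A), ncol(A)))
  })
}

# Mean cross-entropy of softmax(logits) against 1-based labels.
ag_cross_entropy <- function(tp, logits, labels1) {
  L <- logits$value
  B <- nrow(L)
  m <- row_max(L)
  E <- exp(L - m)
  P <- E / rowSums(E)
  picked <- P[cbind(seq_len(B), labels1)]
  val <- -mean(log(pmax(picked, 1e-12)))
  ag_node(tp, val, list(logits), function(g) {
    Y <- matrix(0, B, ncol(L))
    Y[cbind(seq_len(B), labels1)] <- 1
    list((P - Y) * (g / B))
  })
}

# im2col with implicit zero padding: x is (B*Pin) x C (positions row-major,
# image-major); idx has length (B*Pout*KK), kernel offset fastest, and points
# into x with value nrow(x)+1 meaning "padding" (zero). Returns
# (B*Pout) x (KK*C) patches, column index kk-fastest within each channel.
ag_im2col <- function(tp, x, idx, KK, uidx = NULL) {
  X <- x$value
  N <- nrow(X); C <- ncol(X)
  Xp <- rbind(X, 0)
  G <- Xp[idx, , drop = FALSE]               # (Nout*KK) x C, kk fastest
  Nout <- length(idx) %/% KK
  arr <- array(G, c(KK, Nout, C))
  M <- array(aperm(arr, c(2L, 1L, 3L)), c(Nout, KK * C))
  if (is.null(uidx)) uidx <- sort(unique(idx))
  ag_node(tp, M, list(x), function(g) {
    arr2 <- array(g, c(Nout, KK, C))
    dG <- array(aperm(arr2, c(2L, 1L, 3L)), c(KK * Nout, C))
    Z <- matrix(0, N + 1L, C)
    Z[uidx, ] <- rowsum(dG, idx, reorder = TRUE)
    list(Z[-(N + 1L), , drop = FALSE])
  })
}

# Slot-token similarity logits. q: (B*K) x D slot queries (slot-major within
# image), k: (B*P) x D token keys (position-major within image). Returns
# (B*P) x K with logits[(b,p), k] = scale * <q[(b,k),], k[(b,p),]>.
ag_attn_logits <- function(tp, q, k, B, K, P, scale) {
  Q <- q$value; Kv <- k$value
  D <- ncol(Q)
  L <- matrix(0, B * P, K)
  for (b in seq_len(B)) {
    tr <- ((b - 1L) * P + 1L):(b * P)
    sr <- ((b - 1L) * K + 1L):(b * K)
    L[tr, ] <- tcrossprod(Kv[tr, , drop = FALSE], Q[sr, , drop = FALSE]) * scale
  }
  ag_node(tp, L, list(q, k), function(g) {
    dQ <- matrix(0, B * K, D)
    dK <- matrix(0, B * P, D)
    for (b in seq_len(B)) {
      tr <- ((b - 1L) * P + 1L):(b * P)
      sr <- ((b - 1L) * K + 1L):(b * K)
      gb <- g[tr, , drop = FALSE] * scale
      dQ[sr, ] <- crossprod(gb, Kv[tr, , drop = FALSE])
      dK[tr, ] <- gb %*% Q[sr, , drop = FALSE]
    }
    list(dQ, dK)
  })
}

# Weighted-mean readout: ahat (B*P) x K attention (renormalized over tokens),
# v (B*P) x D values. Returns (B*K) x D updates, slot-major within image.
ag_attn_readout <- function(tp, ahat, v, B, K, P) {
  Ah <- ahat$value; V <- v$value
  D <- ncol(V)
  U <- matrix(0, B * K, D)
  for (b in seq_len(B)) {
    tr <- ((b - 1L) * P + 1L):(b * P)
    sr <- ((b - 1L) * K + 1L):(b * K)
    U[sr, ] <- crossprod(Ah[tr, , drop = FALSE], V[tr, , drop = FALSE])
  }
  ag_node(tp, U, list(ahat, v), function(g) {
    dAh <- matrix(0, B * P, K)
    dV <- matrix(0, B * P, D)
    for (b in seq_len(B)) {
      tr <- ((b - 1L) * P + 1L):(b * P)
      sr <- ((b - 1L) * K + 1L):(b * K)
      gb <- g[sr, , drop = FALSE]                        # K x D
      dAh[tr, ] <- tcrossprod(V[tr, , drop = FALSE], gb)
      dV[tr, ] <- Ah[tr, , drop = FALSE] %*% gb
    }
    list(dAh, dV)
  })
}
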