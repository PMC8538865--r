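# Model definition: multi-level convolutional backbone, per-level positional
# encoding, per-level slot-attention modules, and the batched forward pass on
# the gradient tape. The same forward code serves training (with backward),
# inference, and the exported single-image module operations.

#' Backbone configuration
#'
#' The backbone is a plain stack of 3 x 3 convolution + ReLU blocks, one per
#' pyramid level, each block halving the spatial resolution (the resnet50
#' kind's stem quarters it). In the `H_l = input / 2^(l+offset)` convention
#' the offset is fixed per backbone kind and documented here:
#' `kind = "tiny"` (16/32/64/128 channels) has offset 0 — stride plan
#' /2, /4, /8, /16 — so its deepest grid at 64 px input is 4 x 4, mirroring
#' the deep-grid-to-input ratio of the full-scale design point;
#' `kind = "resnet50"` mirrors ResNet-50's stage widths and its
#' offset-1 stride plan /4, /8, /16, /32 as plain blocks (no residual graph,
#' no pretrained weights). Channel widths can also be set explicitly.
#'
#' @param kind `"tiny"` or `"resnet50"`.
#' @param n_levels number of pyramid levels (1..4). `n_levels = 1` keeps only
#'   the deepest block's resolution path, i.e. the low-resolution attention
#'   pathway.
#' @param channels_per_level optional integer vector overriding the per-level
#'   channel widths.
#' @param input_size square input side in pixels; must be divisible by
#'   2^(n_levels+1).
#' @param dim common token/slot dimension D.
#' @return object of class `backbone_config`.
#' @export
backbone_config <- function(kind = c("tiny", "resnet50"),
                            n_levels = 4L,
                            channels_per_level = NULL,
                            input_size = 64L,
                            dim = 64L) {
  kind <- match.arg(kind)
  if (n_levels < 1L || n_levels > 4L) {
    stop("configuration error: n_levels must be in 1..4")
  }
  if (is.null(channels_per_level)) {
    channels_per_level <- if (kind == "tiny") c(16L, 32L, 64L, 128L)
                          else c(256L, 512L, 1024L, 2048L)
  }
  channels_per_level <- as.integer(channels_per_level[seq_len(n_levels)])
  strides <- if (kind == "tiny") rep(2L, 4L) else c(4L, 2L, 2L, 2L)
  strides <- strides[seq_len(n_levels)]
  # a /4 stem is realized as two stride-2 convolutions so no input pixel is
  # skipped (a single 3x3 stride-4 kernel would read only 9 of every 16
  # pixels and lose thin structures)
  stage_strides <- lapply(strides, function(s) {
    if (s == 4L) c(2L, 2L) else s
  })
  sz <- input_size
  for (s in strides) {
    if (sz %% s != 0L) {
      stop("configuration error: input_size ", input_size,
           " is not divisible through the stride plan")
    }
    sz <- sz %/% s
  }
  structure(list(kind = kind, n_levels = as.integer(n_levels),
                 channels = channels_per_level, strides = strides,
                 stage_strides = stage_strides,
                 input_size = as.integer(input_size), dim = as.integer(dim)),
            class = "backbone_config")
}

# Spatial sides per level for a config.
level_sizes <- function(cfg) {
  sz <- cfg$input_size
  out <- integer(cfg$n_levels)
  for (l in seq_len(cfg$n_levels)) {
    sz <- sz %/% cfg$strides[l]
    out[l] <- sz
  }
  out
}

# ---- parameters -------------------------------------------------------------

#' Initialize model parameters
#'
#' All parameters live in one flat named list of matrices/vectors:
#' `conv<l>.W` ((9*Cin) x Cout) and `conv<l>.b` for the backbone blocks, and
#' per level `L<l>.proj` (C x D), `L<l>.pos` (P x D positional grid),
#' `L<l>.Wq/Wk/Wv` (D x D), GRU gates `Wiz/Whz/bz, Wir/Whr/br, Win/Whn/bn`,
#' MLP `W1/b1/W2/b2`, per-slot initial means `mu` (K x D) and shared
#' `logstd` (D). Positional encodings are separate per level.
#'
#' @param cfg a [backbone_config()].
#' @param K number of classes / slots.
#' @param seed RNG seed (`NULL` = current stream).
#' @return flat named list of parameters.
#' @export
init_params <- function(cfg, K, seed = 1L) {
  with_seed(seed, {
    D <- cfg$dim
    p <- list()
    cin <- 3L
    sizes <- level_sizes(cfg)
    for (l in seq_len(cfg$n_levels)) {
      cout <- cfg$channels[l]
      for (j in seq_along(cfg$stage_strides[[l]])) {
        p[[sprintf("conv%d.%d.W", l, j)]] <-
          matrix(stats::rnorm(9L * cin * cout, 0, sqrt(2 / (9 * cin))),
                 9L * cin, cout)
        p[[sprintf("conv%d.%d.b", l, j)]] <- rep(0, cout)
        cin <- cout
      }
      P <- sizes[l]^2
      pre <- sprintf("L%d.", l)
      p[[paste0(pre, "proj")]] <-
        matrix(stats::rnorm(cout * D, 0, sqrt(1 / cout)), cout, D)
      p[[paste0(pre, "pos")]] <- matrix(stats::rnorm(P * D, 0, 0.02), P, D)
      for (nm in c("Wq", "Wk", "Wv")) {
        p[[paste0(pre, nm)]] <- matrix(stats::rnorm(D * D, 0, sqrt(1 / D)), D, D)
      }
      r <- 1 / sqrt(D)
      for (nm in c("Wiz", "Whz", "Wir", "Whr", "Win", "Whn")) {
        p[[paste0(pre, nm)]] <- matrix(stats::runif(D * D, -r, r), D, D)
      }
      # update gate biased open (z ~ 0.88) so slots retain their identity
      # across iterations at initialization
      p[[paste0(pre, "bz")]] <- rep(2, D)
      for (nm in c("br", "bn")) p[[paste0(pre, nm)]] <- rep(0, D)
      p[[paste0(pre, "W1")]] <- matrix(stats::rnorm(D * D, 0, sqrt(2 / D)), D, D)
      p[[paste0(pre, "b1")]] <- rep(0, D)
      p[[paste0(pre, "W2")]] <- matrix(stats::rnorm(D * D, 0, sqrt(1 / D)), D, D)
      p[[paste0(pre, "b2")]] <- rep(0, D)
      p[[paste0(pre, "mu")]] <- matrix(stats::rnorm(K * D, 0, 0.5), K, D)
      p[[paste0(pre, "logstd")]] <- rep(log(0.2), D)
      # evidence calibration: sigmoid(gain * logits + bias); identity at init
      p[[paste0(pre, "eg")]] <- matrix(1, 1L, 1L)
      p[[paste0(pre, "eb")]] <- matrix(0, 1L, 1L)
    }
    p
  })
}

#' Single-level view of the flat parameter list
#'
#' Repackages one level's entries in the shape the exported slot operations
#' take (q/k/v projections, GRU, MLP, slot initialization, T), plus the
#' level's `proj` and `pos` for [encode_positions()]-style use.
#'
#' @param params flat parameter list (see [init_params()]).
#' @param l level index.
#' @param T iteration count to attach.
#' @return list of slot-module parameters.
#' @export
level_params <- function(params, l, T = 3L) {
  pre <- sprintf("L%d.", l)
  g <- function(nm) params[[paste0(pre, nm)]]
  list(Wq = g("Wq"), Wk = g("Wk"), Wv = g("Wv"),
       gru = list(Wiz = g("Wiz"), Whz = g("Whz"), bz = g("bz"),
                  Wir = g("Wir"), Whr = g("Whr"), br = g("br"),
                  Win = g("Win"), Whn = g("Whn"), bn = g("bn")),
       mlp = list(W1 = g("W1"), b1 = g("b1"), W2 = g("W2"), b2 = g("b2")),
       slot_init_mean = g("mu"), slot_init_logstd = g("logstd"),
       evidence_gain = g("eg"), evidence_bias = g("eb"),
       proj = g("proj"), pos = g("pos"), T = T)
}

# ---- batch plan -------------------------------------------------------------

# Precomputed gather indices for an (cfg, B) pair: im2col indices per level
# (kernel-offset fastest, positions row-major, images outermost) and the
# token/image grouping vectors used by the slot modules.
build_plan <- function(cfg, B) {
  kkdi <- rep(0:2, each = 3L)
  kkdj <- rep(0:2, times = 3L)
  stage_idx <- function(Hin, s) {
    Hout <- Hin %/% s
    Pin <- Hin * Hin; Pout <- Hout * Hout
    I <- rep(0:(Hout - 1L), each = Hout)
    J <- rep(0:(Hout - 1L), times = Hout)
    SI <- outer(kkdi, I * s, "+") - 1L            # 9 x Pout
    SJ <- outer(kkdj, J * s, "+") - 1L
    pad <- SI < 0L | SI >= Hin | SJ < 0L | SJ >= Hin
    lin <- SI * Hin + SJ + 1L
    idx <- rep(as.vector(lin), times = B) +
      rep((0:(B - 1L)) * Pin, each = 9L * Pout)
    idx[rep(as.vector(pad), times = B)] <- B * Pin + 1L
    list(idx = idx, uidx = sort(unique(idx)), Hout = Hout)
  }
  levels <- vector("list", cfg$n_levels)
  H <- cfg$input_size
  for (l in seq_len(cfg$n_levels)) {
    stages <- vector("list", length(cfg$stage_strides[[l]]))
    for (j in seq_along(stages)) {
      stages[[j]] <- stage_idx(H, cfg$stage_strides[[l]][j])
      H <- stages[[j]]$Hout
    }
    Pout <- H * H
    levels[[l]] <- list(Hout = H, Pout = Pout, stages = stages,
                        imgid = rep(seq_len(B), each = Pout),
                        postile = rep(seq_len(Pout), times = B))
  }
  list(levels = levels, B = B, p0 = cfg$input_size^2)
}

# ---- forward pass -----------------------------------------------------------

# One slot-attention step: competition softmax across slots, within-slot
# renormalization over tokens, weighted-mean readout.
fw_slot_step <- function(tp, pn, slots, keys, vals, B, K, P, scale) {
  q <- ag_matmul(tp, slots, pn$Wq)
  L <- ag_attn_logits(tp, q, keys, B, K, P, scale)
  A <- ag_softmax_rows(tp, L)
  imgid <- rep(seq_len(B), each = P)
  ssum <- ag_rowsum_block(tp, A, P, B)
  denom <- ag_add_const(tp, ag_gather_rows(tp, ssum, imgid), 1e-8)
  Ahat <- ag_div(tp, A, denom)
  U <- ag_attn_readout(tp, Ahat, vals, B, K, P)
  list(L = L, A = A, Ahat = Ahat, U = U)
}

# GRU + residual-MLP slot refinement: S' = mlp(GRU(S, e * U)).
fw_slot_refine <- function(tp, pn, slots, U, e) {
  inp <- if (e == 1) U else ag_scale(tp, U, e)
  z <- ag_sigmoid(tp, ag_add_rowvec(tp, ag_add(tp,
         ag_matmul(tp, inp, pn$gru$Wiz), ag_matmul(tp, slots, pn$gru$Whz)),
         pn$gru$bz))
  r <- ag_sigmoid(tp, ag_add_rowvec(tp, ag_add(tp,
         ag_matmul(tp, inp, pn$gru$Wir), ag_matmul(tp, slots, pn$gru$Whr)),
         pn$gru$br))
  n <- ag_tanh(tp, ag_add_rowvec(tp, ag_add(tp,
         ag_matmul(tp, inp, pn$gru$Win),
         ag_mul(tp, r, ag_matmul(tp, slots, pn$gru$Whn))),
         pn$gru$bn))
  h <- ag_add(tp, n, ag_mul(tp, z, ag_sub(tp, slots, n)))   # (1-z)n + z*slots
  hid <- ag_relu(tp, ag_add_rowvec(tp, ag_matmul(tp, h, pn$mlp$W1), pn$mlp$b1))
  # residual MLP, as in the slot-attention lineage: keeps the slots' class
  # identities from contracting under the shared rowwise map
  ag_add(tp, h, ag_add_rowvec(tp, ag_matmul(tp, hid, pn$mlp$W2), pn$mlp$b2))
}

# Full T-iteration slot module on encoded tokens for one level.
# Returns the final-iteration competition attention A ((B*P) x K), the
# sigmoid evidence maps M, per-image slot masses (B x K) and mean saliency.
fw_slot_run <- function(tp, pn, enc, slots0, B, K, P, e, T, scale,
                        keep_history = FALSE) {
  keys <- ag_matmul(tp, enc, pn$Wk)
  vals <- ag_matmul(tp, enc, pn$Wv)
  slots <- slots0
  hist <- if (keep_history) list() else NULL
  if (T == 0L) {
    st <- fw_slot_step(tp, pn, slots, keys, vals, B, K, P, scale)
  } else {
    for (t in seq_len(T)) {
      st <- fw_slot_step(tp, pn, slots, keys, vals, B, K, P, scale)
      if (keep_history) hist[[t]] <- st$A$value
      slots <- fw_slot_refine(tp, pn, slots, st$U, e)
    }
  }
  Lcal <- if (!is.null(pn$eg)) {
    ag_add_scalar(tp, ag_mul_scalar(tp, st$L, pn$eg), pn$eb)
  } else st$L
  M <- ag_sigmoid(tp, Lcal)
  mass <- ag_rowsum_block(tp, M, P, B)                       # B x K
  sal <- ag_scale(tp, ag_rowsums(tp, mass), 1 / (K * P))     # B x 1 mean map value
  list(slots = slots, A = st$A, M = M, L = st$L, mass = mass, sal = sal,
       history = hist)
}

# Whole-model forward for a batch. X: (B*P0) x 3 token matrix of the input
# images (positions row-major, images outermost). Returns nodes for the
# per-level outputs, the class logits (e * deepest slot masses), and, when
# labels are given, the loss decomposition ce + lambda * area.
fw_model <- function(tp, params, X, plan, cfg, K, e, T,
                     labels1 = NULL, lambda = 2, keep_history = FALSE) {
  pn <- lapply(params, function(v) ag_const(tp, v))
  B <- plan$B
  scale <- 1 / sqrt(cfg$dim)
  cur <- X
  toks <- vector("list", cfg$n_levels)
  for (l in seq_len(cfg$n_levels)) {
    pl <- plan$levels[[l]]
    for (j in seq_along(pl$stages)) {
      pat <- ag_im2col(tp, cur, pl$stages[[j]]$idx, 9L, pl$stages[[j]]$uidx)
      cur <- ag_relu(tp, ag_add_rowvec(tp,
               ag_matmul(tp, pat, pn[[sprintf("conv%d.%d.W", l, j)]]),
               pn[[sprintf("conv%d.%d.b", l, j)]]))
    }
    toks[[l]] <- cur
  }
  lev <- vector("list", cfg$n_levels)
  for (l in seq_len(cfg$n_levels)) {
    pl <- plan$levels[[l]]
    pre <- sprintf("L%d.", l)
    lpn <- list(Wq = pn[[paste0(pre, "Wq")]], Wk = pn[[paste0(pre, "Wk")]],
                Wv = pn[[paste0(pre, "Wv")]],
                gru = list(Wiz = pn[[paste0(pre, "Wiz")]], Whz = pn[[paste0(pre, "Whz")]],
                           bz = pn[[paste0(pre, "bz")]],
                           Wir = pn[[paste0(pre, "Wir")]], Whr = pn[[paste0(pre, "Whr")]],
                           br = pn[[paste0(pre, "br")]],
                           Win = pn[[paste0(pre, "Win")]], Whn = pn[[paste0(pre, "Whn")]],
                           bn = pn[[paste0(pre, "bn")]]),
                mlp = list(W1 = pn[[paste0(pre, "W1")]], b1 = pn[[paste0(pre, "b1")]],
                           W2 = pn[[paste0(pre, "W2")]], b2 = pn[[paste0(pre, "b2")]]),
                eg = pn[[paste0(pre, "eg")]], eb = pn[[paste0(pre, "eb")]])
    enc <- ag_add(tp, ag_matmul(tp, toks[[l]], pn[[paste0(pre, "proj")]]),
                  ag_gather_rows(tp, pn[[paste0(pre, "pos")]], pl$postile))
    slots0 <- ag_gather_rows(tp, pn[[paste0(pre, "mu")]], rep(seq_len(K), B))
    lev[[l]] <- fw_slot_run(tp, lpn, enc, slots0, B, K, pl$Pout, e, T, scale,
                            keep_history = keep_history)
    lev[[l]]$H <- pl$Hout
  }
  deep <- lev[[cfg$n_levels]]
  logits <- if (e == 1) deep$mass else ag_scale(tp, deep$mass, e)
  out <- list(levels = lev, logits = logits, tokens = toks, pnodes = pn)
  if (!is.null(labels1)) {
    ce <- ag_cross_entropy(tp, logits, labels1)
    area <- lev[[1L]]$sal
    if (cfg$n_levels > 1L) {
      for (l in 2:cfg$n_levels) area <- ag_add(tp, area, lev[[l]]$sal)
    }
    area_mean <- ag_mean(tp, area)
    loss <- ag_add(tp, ce, ag_scale(tp, area_mean, lambda))
    out$ce <- ce; out$area <- area_mean; out$loss <- loss
  }
  out
}

# ---- layout helpers ---------------------------------------------------------

# H x W x 3 image array -> (P x 3) token matrix, positions row-major.
img_to_tokens <- function(img) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  out <- matrix(0, h * w, 3L)
  for (ch in 1:3) out[, ch] <- as.vector(t(img[, , ch]))
  out
}

# Length-P row-major token vector -> H x W matrix.
tokens_to_map <- function(v, H, W = H) matrix(v, H, W, byrow = TRUE)

# Stack images into the batched token matrix expected by fw_model.
stack_images <- function(images) {
  do.call(rbind, lapply(images, img_to_tokens))
}
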