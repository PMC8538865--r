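# Exported slot-attention operations (single-image views).
#
# One slot is learned per class. Each iteration computes scaled dot-product
# similarities between slot queries and token keys, normalizes them with a
# softmax ACROSS SLOTS (the competition that suppresses attention gained by
# the other classes), renormalizes within each slot over tokens for a
# weighted-mean readout, and refines all slots jointly with a shared
# GRU + MLP. The sign parameter e switches between positive (+1) and
# negative (-1) explanations by flipping the GRU input (and, downstream, the
# logit semantics). Alongside the competition weights, the module emits
# sigmoid class-evidence maps from the same final-iteration logits: their
# free total mass is what the fusion rule weighs, the classifier sums, and
# the area regularizer penalizes.

#' Standalone slot-module parameters
#'
#' Creates one level's slot-attention parameter set (query/key/value
#' projections, GRU, MLP, per-slot Gaussian initialization) without a
#' backbone; useful for unit-level experiments. Within [train()]ed models the
#' same structure is obtained with `level_params(model$params, l)`.
#'
#' @param dim slot dimension D.
#' @param K number of slots (= classes).
#' @param T iteration count (shared parameters across iterations).
#' @param seed RNG seed for the construction-time Gaussian initialization.
#' @export
slot_module_params <- function(dim, K, T = 3L, seed = 1L) {
  cfg <- list(n_levels = 1L, channels = 3L, strides = 4L,
              stage_strides = list(c(2L, 2L)),
              input_size = 32L, dim = as.integer(dim))
  # reuse the model initializer for one level, then strip the conv entries
  fake <- structure(c(cfg, list(kind = "tiny")), class = "backbone_config")
  p <- with_seed(seed, init_params(fake, K, seed = NULL))
  lp <- level_params(p, 1L, T = as.integer(T))
  lp$proj <- NULL; lp$pos <- NULL
  lp
}

#' Initialize slots from the learned Gaussian
#'
#' Each slot i is drawn from Normal(mean_i, exp(logstd)) i.i.d. across
#' dimensions; with `sample = FALSE` (the deterministic inference choice) the
#' per-slot means are returned as-is.
#'
#' @param params slot-module parameters (see [slot_module_params()]).
#' @param K number of slots; must match the parameter set.
#' @param seed RNG seed for the draw (`NULL` = current stream).
#' @param sample draw noise (TRUE) or return the means (FALSE).
#' @return `slot_state` with `$slots` (K x D) and `$iteration = 0`.
#' @export
init_slots <- function(params, K, seed = NULL, sample = TRUE) {
  mu <- params$slot_init_mean
  if (K < 2) stop("configuration error: K must be >= 2")
  if (nrow(mu) != K) stop("configuration error: parameter set has ", nrow(mu), " slots")
  D <- ncol(mu)
  slots <- if (sample) {
    with_seed(seed, mu + matrix(stats::rnorm(K * D), K, D) *
                matrix(exp(params$slot_init_logstd), K, D, byrow = TRUE))
  } else mu
  structure(list(slots = slots, iteration = 0L), class = "slot_state")
}

#' One attention step: competition and weighted-mean readout
#'
#' For slots S (K x D) and tokens X (P x D):
#' `logits[k, p] = <q(S_k), k(X_p)> / sqrt(D)`; `attn` is the softmax of the
#' logits over the slot axis (each token's weights sum to 1 across slots);
#' the update for slot k is the attention-weighted mean of `v(X_p)` with
#' weights renormalized over tokens within the slot. `evidence` is
#' `sigmoid(logits)`, the nonnegative class-evidence map whose spatial sum is
#' the slot's mass.
#'
#' @param state a `slot_state`.
#' @param feats `encoded_features` (see [encode_positions()]).
#' @param params slot-module parameters.
#' @return list with `update` (K x D), `attn` (K x P), `evidence` (K x P)
#'   and `logits` (K x P).
#' @export
attention_step <- function(state, feats, params) {
  P <- nrow(feats$tokens)
  if (P == 0L) stop("data error: no tokens")
  K <- nrow(state$slots)
  D <- ncol(state$slots)
  tp <- ag_tape()
  pn <- list(Wq = ag_const(tp, params$Wq), Wk = ag_const(tp, params$Wk),
             Wv = ag_const(tp, params$Wv))
  slots <- ag_const(tp, state$slots)
  enc <- ag_const(tp, feats$tokens)
  keys <- ag_matmul(tp, enc, pn$Wk)
  vals <- ag_matmul(tp, enc, pn$Wv)
  st <- fw_slot_step(tp, pn, slots, keys, vals, 1L, K, P, 1 / sqrt(D))
  list(update = st$U$value, attn = t(st$A$value),
       evidence = t(1 / (1 + exp(-st$L$value))), logits = t(st$L$value))
}

#' Refine slots with the GRU + MLP update
#'
#' `S^{t+1} = MLP(GRU(S^t, e * U^{t+1}))`, applied jointly to all K slots;
#' the explanation sign e = +1/-1 flips the GRU input between positive and
#' negative explanation modes.
#'
#' @param state a `slot_state` with `iteration < params$T`.
#' @param update K x D update matrix from [attention_step()].
#' @param e explanation sign, +1 or -1.
#' @param params slot-module parameters.
#' @return the refined `slot_state` (iteration incremented).
#' @export
update_slots <- function(state, update, e, params) {
  stopifnot(e %in% c(-1, 1))
  if (state$iteration >= (params$T %||% Inf)) {
    stop("configuration error: iteration budget T exhausted")
  }
  tp <- ag_tape()
  pn <- list(gru = list(), mlp = list())
  for (nm in names(params$gru)) pn$gru[[nm]] <- ag_const(tp, params$gru[[nm]])
  for (nm in names(params$mlp)) pn$mlp[[nm]] <- ag_const(tp, params$mlp[[nm]])
  slots <- ag_const(tp, state$slots)
  U <- ag_const(tp, update)
  nxt <- fw_slot_refine(tp, pn, slots, U, e)
  structure(list(slots = nxt$value, iteration = state$iteration + 1L),
            class = "slot_state")
}

# Shared constructor for per-level attention output.
make_level_attention <- function(M, A, H, W, level, saliency_mode = "mean") {
  K <- ncol(M)
  to_arr <- function(X) aperm(array(t(X), c(K, W, H)), c(1L, 3L, 2L))
  maps <- to_arr(M)
  sal <- if (identical(saliency_mode, "sum")) sum(maps) else mean(maps)
  structure(list(maps = maps, attn = to_arr(A), level = level,
                 saliency = sal, K = K, H = H, W = W,
                 saliency_mode = saliency_mode),
            class = "level_attention")
}

#' Run the full T-iteration slot attention on one level
#'
#' Iterates [attention_step()] / [update_slots()] T times; the returned
#' spatial maps come from the final iteration's logits. `T = 0` leaves the
#' slots at their initialization and reports the attention computed from
#' them. Deterministic given `seed` (or with `sample = FALSE`).
#'
#' @param feats `encoded_features` for the level.
#' @param K number of slots.
#' @param e explanation sign (+1 / -1).
#' @param params slot-module parameters (including `$T`).
#' @param seed RNG seed for the Gaussian slot draw.
#' @param sample draw initial slots (TRUE) or start from the means (FALSE).
#' @param T iteration count override.
#' @param saliency_mode `"mean"` (size-normalized, default) or `"sum"` for
#'   the level saliency W_l.
#' @return list with `state` (final `slot_state`), `level_attn`
#'   (`level_attention`: `$maps` = evidence, `$attn` = competition weights,
#'   `$saliency` = W_l), and `attn_history` (per-iteration K x P competition
#'   weights).
#' @export
run_slot_attention <- function(feats, K, e, params, seed = NULL,
                               sample = FALSE, T = NULL,
                               saliency_mode = "mean") {
  T <- T %||% params$T %||% 3L
  stopifnot(T >= 0L, e %in% c(-1, 1))
  st0 <- init_slots(params, K, seed = seed, sample = sample)
  P <- nrow(feats$tokens)
  D <- ncol(st0$slots)
  tp <- ag_tape()
  pn <- list(Wq = ag_const(tp, params$Wq), Wk = ag_const(tp, params$Wk),
             Wv = ag_const(tp, params$Wv), gru = list(), mlp = list())
  for (nm in names(params$gru)) pn$gru[[nm]] <- ag_const(tp, params$gru[[nm]])
  for (nm in names(params$mlp)) pn$mlp[[nm]] <- ag_const(tp, params$mlp[[nm]])
  if (!is.null(params$evidence_gain)) {
    pn$eg <- ag_const(tp, params$evidence_gain)
    pn$eb <- ag_const(tp, params$evidence_bias)
  }
  enc <- ag_const(tp, feats$tokens)
  slots0 <- ag_const(tp, st0$slots)
  run <- fw_slot_run(tp, pn, enc, slots0, 1L, K, P, e, T, 1 / sqrt(D),
                     keep_history = TRUE)
  state <- structure(list(slots = run$slots$value,
                          iteration = if (T == 0L) 0L else as.integer(T)),
                     class = "slot_state")
  la <- make_level_attention(run$M$value, run$A$value, feats$H, feats$W,
                             feats$level, saliency_mode)
  hist <- lapply(run$history %||% list(), t)
  list(state = state, level_attn = la, attn_history = hist)
}
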