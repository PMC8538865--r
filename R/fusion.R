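# Saliency-weighted fusion of per-level attention maps, class logits from
# slot masses, and the area-regularized loss.

#' Normalized fusion weights from level saliencies
#'
#' Each level contributes `w_l = W_l / sum_j W_j`, where W_l is that level's
#' saliency (the total class evidence of its slot maps, size-normalized by
#' default). Levels where the model is more certain therefore dominate the
#' fused map. If every saliency is zero the weights fall back to uniform.
#'
#' @param levels list of `level_attention` objects.
#' @return numeric vector of weights summing to 1.
#' @export
fusion_weights <- function(levels) {
  if (length(levels) == 0L) stop("data error: no attention levels")
  W <- vapply(levels, function(l) l$saliency, numeric(1))
  if (any(W < 0)) stop("data error: negative saliency")
  tot <- sum(W)
  if (tot <= 0) rep(1 / length(W), length(W)) else W / tot
}

#' Fuse per-level attention maps into one high-resolution map
#'
#' Every level's K maps are bilinearly upsampled to `out_size` and combined
#' as the saliency-weighted average `S_F = sum_l w_l * up(S_l)`. Being a
#' convex combination of interpolated nonnegative maps, each fused pixel lies
#' within the min/max envelope of the upsampled level maps at that pixel.
#'
#' @param levels list of `level_attention` objects sharing K.
#' @param out_size output side in pixels (typically the input resolution).
#' @param weights optional custom weights (length = number of levels); by
#'   default [fusion_weights()] of the levels.
#' @return `fused_attention` with `$maps` (K x out x out) and
#'   `$weights_used`.
#' @export
fuse <- function(levels, out_size, weights = NULL) {
  if (length(levels) == 0L) stop("data error: no attention levels")
  Ks <- vapply(levels, function(l) l$K, integer(1))
  if (length(unique(Ks)) != 1L) stop("data error: levels disagree on K")
  K <- Ks[1L]
  w <- weights %||% fusion_weights(levels)
  if (length(w) != length(levels)) stop("data error: one weight per level required")
  out <- array(0, c(K, out_size, out_size))
  for (li in seq_along(levels)) {
    if (w[li] == 0) next
    lv <- levels[[li]]
    for (k in seq_len(K)) {
      m <- matrix(lv$maps[k, , ], lv$H, lv$W)   # keep 1 x 1 maps as matrices
      out[k, , ] <- out[k, , ] + w[li] * bilinear_resize(m, out_size, out_size)
    }
  }
  structure(list(maps = out, weights_used = w, K = K, size = out_size),
            class = "fused_attention")
}

#' Class logits from the deepest level's slot masses
#'
#' The score of class k is the total evidence mass of its slot at the
#' deepest backbone level, `logit_k = e * sum_{h,w} maps[k, h, w]`. With the
#' negative explanation (e = -1) the class with the LEAST attention mass
#' scores highest, so the model is trained to withhold attention from the
#' true class.
#'
#' @param deepest `level_attention` of the deepest level.
#' @param e explanation sign (+1 default).
#' @return numeric length-K logits.
#' @export
class_logits <- function(deepest, e = 1) {
  stopifnot(inherits(deepest, "level_attention"), e %in% c(-1, 1))
  e * apply(deepest$maps, 1L, sum)
}

#' Area-regularized classification loss
#'
#' `total = ce + lambda * area`: cross-entropy of the softmax over the
#' mass logits against the true label, plus lambda times the total attention
#' area, where the area term sums the saliencies W_l of all levels' slot
#' maps. lambda controls how large the highlighted regions may grow.
#'
#' @param logits length-K class logits (see [class_logits()]).
#' @param label true class index in 0..K-1.
#' @param levels list of `level_attention` objects (all backbone levels).
#' @param lambda nonnegative area weight (reference default 2).
#' @return `loss_breakdown` list with `$total`, `$ce`, `$area`, `$lambda`.
#' @export
scouter_loss <- function(logits, label, levels, lambda = 2) {
  K <- length(logits)
  if (lambda < 0) stop("configuration error: lambda must be >= 0")
  if (label < 0 || label >= K) stop("data error: label out of range 0..", K - 1)
  z <- logits - max(logits)
  ce <- -(z[label + 1L] - log(sum(exp(z))))
  area <- sum(vapply(levels, function(l) l$saliency, numeric(1)))
  structure(list(total = ce + lambda * area, ce = ce, area = area,
                 lambda = lambda),
            class = "loss_breakdown")
}
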