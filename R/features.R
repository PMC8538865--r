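# Feature extraction: exported single-image views over the batched forward.

#' Extract multi-level feature grids from an image
#'
#' Runs the convolutional backbone and returns one feature grid per pyramid
#' level, shallowest (highest resolution) first, deepest last; spatial sizes
#' strictly decrease along the stride plan.
#'
#' @param image H x W x 3 array, already at `cfg$input_size` (anything else is
#'   a configuration error).
#' @param cfg a [backbone_config()].
#' @param params model parameters (e.g. `model$params` from [train()], or
#'   [init_params()] output).
#' @return list of `feature_level` objects with `$level` and `$grid`
#'   (C_l x H_l x W_l array).
#' @export
extract_features <- function(image, cfg, params) {
  if (!all(dim(image)[1:2] == cfg$input_size)) {
    stop("configuration error: image must be ", cfg$input_size, " x ",
         cfg$input_size)
  }
  tp <- ag_tape()
  plan <- build_plan(cfg, 1L)
  X <- ag_const(tp, img_to_tokens(image))
  cur <- X
  out <- vector("list", cfg$n_levels)
  sizes <- level_sizes(cfg)
  for (l in seq_len(cfg$n_levels)) {
    for (j in seq_along(plan$levels[[l]]$stages)) {
      pat <- ag_im2col(tp, cur, plan$levels[[l]]$stages[[j]]$idx, 9L)
      cur <- ag_relu(tp, ag_add_rowvec(tp,
               ag_matmul(tp, pat,
                         ag_const(tp, params[[sprintf("conv%d.%d.W", l, j)]])),
               ag_const(tp, params[[sprintf("conv%d.%d.b", l, j)]])))
    }
    H <- sizes[l]
    tok <- cur$value                                  # P x C, row-major
    arr <- aperm(array(t(tok), c(ncol(tok), H, H)), c(1L, 3L, 2L))
    out[[l]] <- structure(list(level = l, grid = arr), class = "feature_level")
  }
  out
}

#' Attach positional encoding and project features to the slot dimension
#'
#' Tokens are `proj(grid[, p]) + pos[, p]`, flattened row-major from the
#' top-left corner, so token p of a 2 x 2 grid covers positions
#' (0,0), (0,1), (1,0), (1,1).
#'
#' @param f a `feature_level` from [extract_features()].
#' @param proj C_l x D projection matrix.
#' @param pos learned positional grid, D x H_l x W_l.
#' @return `encoded_features` object with `$tokens` (P x D), `$level`,
#'   `$H`, `$W`.
#' @export
encode_positions <- function(f, proj, pos) {
  stopifnot(inherits(f, "feature_level"))
  C <- dim(f$grid)[1L]; H <- dim(f$grid)[2L]; W <- dim(f$grid)[3L]
  if (nrow(proj) != C) stop("configuration error: proj must map C=", C, " channels")
  if (!all(dim(pos) == c(ncol(proj), H, W))) {
    stop("configuration error: pos must be D x ", H, " x ", W)
  }
  # grid C x H x W -> tokens P x C (row-major positions)
  tokC <- t(array(aperm(f$grid, c(1L, 3L, 2L)), c(C, H * W)))
  posM <- t(array(aperm(pos, c(1L, 3L, 2L)), c(dim(pos)[1L], H * W)))
  structure(list(tokens = tokC %*% proj + posM, level = f$level, H = H, W = W),
            class = "encoded_features")
}

# Model-internal variant using the stored (P x D) positional grid.
encode_level <- function(params, l, f) {
  pre <- sprintf("L%d.", l)
  C <- dim(f$grid)[1L]; H <- dim(f$grid)[2L]; W <- dim(f$grid)[3L]
  tokC <- t(array(aperm(f$grid, c(1L, 3L, 2L)), c(C, H * W)))
  structure(list(tokens = tokC %*% params[[paste0(pre, "proj")]] +
                   params[[paste0(pre, "pos")]],
                 level = l, H = H, W = W),
            class = "encoded_features")
}
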