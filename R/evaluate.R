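# Evaluation and visualization: confusion matrices, attention confusion
# matrices, localization against ground-truth masks, alpha-channel overlays
# and per-level map galleries.

#' Confusion matrix and accuracy
#'
#' Rows are true classes, columns predictions; accuracy is the trace over the
#' total count.
#'
#' @param model an `mrslots_model`.
#' @param dataset labeled samples.
#' @return list with `$matrix` (K x K counts), `$accuracy`, `$pred`
#'   (0-based predictions).
#' @export
confusion_matrix <- function(model, dataset) {
  truth <- vapply(dataset, function(s) as.integer(s$label), integer(1))
  pred <- predict_dataset(model, dataset)$pred
  cm <- confusion_from_preds(truth, pred, model$K)
  list(matrix = cm, accuracy = sum(diag(cm)) / sum(cm), pred = pred)
}

# Pure counting core, exposed for direct testing.
confusion_from_preds <- function(truth, pred, K) {
  cm <- matrix(0L, K, K,
               dimnames = list(true = 0:(K - 1), pred = 0:(K - 1)))
  for (i in seq_along(truth)) {
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  cm
}

#' Attention confusion matrix
#'
#' A K x K grid indexed by (true class i, slot j): cell (i, j) holds the mean
#' total mass of slot j's fused evidence map over samples of true class i,
#' plus the slot-j map of a representative sample of class i (the
#' correctly-classified sample with the highest prediction confidence; if no
#' sample of the class was classified correctly the most confident one is
#' used and the cell is flagged). For a positive-explanation model the
#' diagonal carries the most mass; for a negative one the least.
#'
#' @param model an `mrslots_model`.
#' @param dataset labeled samples (>= 1 per class expected).
#' @param e explanation sign override.
#' @return `attention_confusion` with `$mean_mass` (K x K), `$maps`
#'   (K x K list matrix of representative maps), `$counts`, `$empty` flags.
#' @export
attention_confusion <- function(model, dataset, e = NULL) {
  K <- model$K
  truth <- vapply(dataset, function(s) as.integer(s$label), integer(1))
  old_e <- model$e
  if (!is.null(e)) model$e <- e
  pr <- predict_dataset(model, dataset, fused = TRUE)
  model$e <- old_e
  mean_mass <- matrix(0, K, K)
  counts <- integer(K)
  maps <- matrix(vector("list", K * K), K, K)
  empty <- logical(K)
  for (i in seq_len(K) - 1L) {
    sel <- which(truth == i)
    if (length(sel) == 0L) {
      empty[i + 1L] <- TRUE
      next
    }
    counts[i + 1L] <- length(sel)
    mm <- sapply(sel, function(s) apply(pr$fused[[s]]$maps, 1L, sum))
    mean_mass[i + 1L, ] <- rowMeans(matrix(mm, nrow = K))
    correct <- sel[pr$pred[sel] == i]
    pool <- if (length(correct)) correct else sel
    conf <- pr$prob[cbind(pool, pr$pred[pool] + 1L)]
    rep_idx <- pool[which.max(conf)]
    for (j in seq_len(K)) maps[[i + 1L, j]] <- pr$fused[[rep_idx]]$maps[j, , ]
  }
  structure(list(mean_mass = mean_mass, maps = maps, counts = counts,
                 empty = empty, e = e %||% old_e),
            class = "attention_confusion")
}

#' Attention-mass localization against a ground-truth mask
#'
#' `mass_in_mask` is the fraction of the predicted class's fused attention
#' mass that falls inside the object mask; `enrichment` divides it by the
#' mask's area fraction, so a uniform map scores exactly 1 and values above 1
#' mean the attention concentrates on the object.
#'
#' @param fused `fused_attention` for one image.
#' @param predicted_class 0-based class whose map is scored.
#' @param mask binary H x W matrix (resized nearest-neighbor if needed).
#' @return one-row data.frame: `mass_in_mask`, `mask_area_fraction`,
#'   `enrichment`.
#' @export
localization <- function(fused, predicted_class, mask) {
  m <- fused$maps[predicted_class + 1L, , ]
  if (!all(dim(mask) == dim(m))) {
    mask <- (bilinear_resize(mask + 0, dim(m)[1L], dim(m)[2L]) > 0.5) * 1L
  }
  if (sum(mask) == 0L) stop("data error: all-zero mask")
  tot <- sum(m)
  frac_in <- if (tot > 0) sum(m[mask == 1]) / tot else 0
  area <- mean(mask == 1)
  data.frame(mass_in_mask = frac_in, mask_area_fraction = area,
             enrichment = frac_in / area)
}

#' Dataset-level localization report
#'
#' Runs the model over masked samples and scores [localization()] per sample.
#'
#' @param model an `mrslots_model`.
#' @param dataset samples with `$mask`.
#' @return data.frame with one row per sample: true/predicted class,
#'   correctness, confidence, and the localization columns.
#' @export
localization_report <- function(model, dataset) {
  has_mask <- vapply(dataset, function(s) !is.null(s$mask), logical(1))
  dataset <- dataset[has_mask]
  if (length(dataset) == 0L) stop("data error: no samples with masks")
  truth <- vapply(dataset, function(s) as.integer(s$label), integer(1))
  pr <- predict_dataset(model, dataset, fused = TRUE)
  rows <- lapply(seq_along(dataset), function(i) {
    loc <- localization(pr$fused[[i]], pr$pred[i], dataset[[i]]$mask)
    cbind(data.frame(sample = i, true = truth[i], pred = pr$pred[i],
                     correct = truth[i] == pr$pred[i],
                     confidence = pr$prob[i, pr$pred[i] + 1L]), loc)
  })
  do.call(rbind, rows)
}

#' Alpha-channel attention overlay
#'
#' The fused map of one class, normalized by its maximum, becomes the alpha
#' channel of the image; values below `threshold_frac` of the map maximum
#' are set fully transparent so near-zero regions are neglected.
#'
#' @param image H x W x 3 array in \[0,1\].
#' @param fused `fused_attention` at the image resolution.
#' @param class_idx 0-based class whose map is rendered.
#' @param threshold_frac fraction of the map maximum below which alpha = 0.
#' @param path optional PNG output path.
#' @return H x W x 4 RGBA array (invisibly, when `path` is given).
#' @export
render_overlay <- function(image, fused, class_idx, threshold_frac = 0.1,
                           path = NULL) {
  stopifnot(threshold_frac >= 0, threshold_frac < 1)
  m <- fused$maps[class_idx + 1L, , ]
  if (!all(dim(m) == dim(image)[1:2])) {
    m <- bilinear_resize(m, dim(image)[1L], dim(image)[2L])
  }
  mx <- max(m)
  if (mx <= 0) {
    warning("all-zero attention map: overlay is fully transparent")
    alpha <- m * 0
  } else {
    alpha <- m / mx
    alpha[m < threshold_frac * mx] <- 0
  }
  out <- array(0, c(dim(image)[1:2], 4L))
  out[, , 1:3] <- image
  out[, , 4L] <- alpha
  if (!is.null(path)) {
    png::writePNG(out, path)
    return(invisible(out))
  }
  out
}

# Render one heatmap panel (own color scale) with a vertical scale bar.
.heat_panel <- function(m, side) {
  m <- bilinear_resize(m, side, side)
  rng <- range(m)
  v <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  cols <- heat_colors(as.vector(t(v)))
  panel <- array(0, c(side, side, 3L))
  for (ch in 1:3) panel[, , ch] <- matrix(cols[, ch], side, side, byrow = TRUE)
  bar_v <- seq(1, 0, length.out = side)
  bar <- array(0, c(side, 6L, 3L))
  bc <- heat_colors(bar_v)
  for (ch in 1:3) bar[, , ch] <- matrix(bc[, ch], side, 6L)
  abind3 <- function(a, b) {
    out <- array(0, c(dim(a)[1L], dim(a)[2L] + dim(b)[2L], 3L))
    out[, seq_len(dim(a)[2L]), ] <- a
    out[, dim(a)[2L] + seq_len(dim(b)[2L]), ] <- b
    out
  }
  abind3(panel, bar)
}

#' Per-level attention gallery
#'
#' Writes a single PNG montage: the original image, the fused map, then one
#' panel per backbone level, each heatmap normalized to its own color scale
#' with a vertical scale bar (the scales are therefore not comparable across
#' panels). Deterministic bytes for fixed inputs.
#'
#' @param levels list of `level_attention` objects.
#' @param fused `fused_attention`.
#' @param image original H x W x 3 array.
#' @param class_idx 0-based class whose maps are shown.
#' @param path output PNG path.
#' @return `path`, invisibly; the composed array as attribute is returned
#'   when `path` is NULL.
#' @export
level_gallery <- function(levels, fused, image, class_idx = 0L, path = NULL) {
  if (length(levels) == 0L) stop("data error: no levels")
  side <- dim(image)[1L]
  margin <- 4L
  panels <- list(array(image, c(side, dim(image)[2L], 3L)),
                 .heat_panel(fused$maps[class_idx + 1L, , ], side))
  for (lv in levels) {
    panels <- c(panels, list(.heat_panel(lv$maps[class_idx + 1L, , ], side)))
  }
  wtot <- sum(vapply(panels, function(p) dim(p)[2L], integer(1))) +
    margin * (length(panels) - 1L)
  out <- array(1, c(side, wtot, 3L))
  at <- 1L
  for (p in panels) {
    out[, at:(at + dim(p)[2L] - 1L), ] <- p
    at <- at + dim(p)[2L] + margin
  }
  if (!is.null(path)) {
    png::writePNG(out, path)
    return(invisible(path))
  }
  out
}
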