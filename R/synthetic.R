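# Synthetic single-plant image generator.
#
# Emulates the statistical structure of seedling classification datasets in
# which every image contains exactly one plant on a textured soil/stone
# background: the class is defined by the plant's shape family, apparent size
# varies like growth stage, and a ground-truth mask is produced alongside
# every image so localization can be scored exactly.

.shape_families <- c("blades", "rosette", "lobes", "rings")

#' Specification for a synthetic plant-image dataset
#'
#' Classes are shape families: `"blades"` (a cluster of thin crossing leaves,
#' the narrow-leaved/monocot analogue), `"rosette"` (broad petals around a
#' center, the dicot analogue), `"lobes"` (four large round lobes), and
#' `"rings"` (a ring of small discs). Objects are drawn at a random
#' orientation and position near the image center, over either a stone-speckle
#' background (bright blobs on dark soil) or a flat one, with additive
#' Gaussian pixel noise.
#'
#' @param num_classes number of classes K (>= 2).
#' @param image_size square image side in pixels (>= 32).
#' @param shapes_per_class character vector of shape families, one per class;
#'   defaults to cycling through the four built-in families.
#' @param size_range numeric length-2, fraction of the image side occupied by
#'   the object (its bounding diameter); within (0, 1].
#' @param background list with `kind` ("stones" or "flat") and `noise_sd`
#'   (standard deviation of additive Gaussian pixel noise).
#' @param palette list of foreground/background base colors and jitter.
#' @param pos_jitter maximal offset of the object center from the image
#'   center, as a fraction of the side.
#' @param seed integer RNG seed; the same spec and seed reproduce the dataset
#'   bitwise.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(num_classes = 4L,
                           image_size = 64L,
                           shapes_per_class = NULL,
                           size_range = c(0.32, 0.55),
                           background = list(kind = "stones", noise_sd = 0.03),
                           palette = NULL,
                           pos_jitter = 0.08,
                           seed = 1L) {
  if (num_classes < 2) stop("configuration error: num_classes must be >= 2")
  if (image_size < 32) stop("configuration error: image_size must be >= 32")
  if (length(size_range) != 2 || any(size_range <= 0) || any(size_range > 1) ||
      size_range[2] < size_range[1]) {
    stop("configuration error: size_range must be increasing and within (0, 1]")
  }
  if (is.null(shapes_per_class)) {
    shapes_per_class <- rep_len(.shape_families, num_classes)
  }
  shapes_per_class <- rep_len(shapes_per_class, num_classes)
  if (!all(shapes_per_class %in% .shape_families)) {
    stop("configuration error: unknown shape family")
  }
  if (is.null(palette)) {
    palette <- list(fg_base = c(0.12, 0.50, 0.12), fg_jitter = 0.06,
                    bg_soil = c(0.42, 0.35, 0.28), bg_stone = c(0.58, 0.56, 0.52))
  }
  structure(list(num_classes = as.integer(num_classes),
                 image_size = as.integer(image_size),
                 shapes_per_class = shapes_per_class,
                 size_range = size_range,
                 background = background,
                 palette = palette,
                 pos_jitter = pos_jitter,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Rotated-ellipse membership for pixel coordinate vectors px/py (in units of
# the image side), center (cx, cy), semi-axes (a, b), long axis at angle ang.
.in_ellipse <- function(px, py, cx, cy, a, b, ang) {
  dx <- px - cx; dy <- py - cy
  t <- dx * cos(ang) + dy * sin(ang)
  w <- -dx * sin(ang) + dy * cos(ang)
  (t / a)^2 + (w / b)^2 <= 1
}

# Draws one object mask for a shape family; coordinates in units of the side.
.render_mask <- function(family, S, cx, cy, s, phi) {
  p <- (seq_len(S) - 0.5) / S
  px <- matrix(p, S, S, byrow = TRUE)   # x = column coordinate
  py <- matrix(p, S, S)                 # y = row coordinate
  r2 <- s / 2
  mask <- matrix(FALSE, S, S)
  # families are kept close to rotation-symmetric (as overhead views of
  # grass stars, rosettes and compound whorls are), so the class signature
  # is a radial/width profile rather than an orientation-specific layout
  if (family == "blades") {
    nb <- sample(4:6, 1)
    for (b in seq_len(nb)) {
      ang <- phi + (b - 1) * pi / nb + stats::runif(1, -0.08, 0.08)
      L <- r2 * stats::runif(1, 0.85, 1)
      mask <- mask | .in_ellipse(px, py, cx, cy, L, 0.10 * r2, ang)
    }
  } else if (family == "rosette") {
    for (b in 1:6) {
      ang <- phi + (b - 1) * pi / 3 + stats::runif(1, -0.08, 0.08)
      ccx <- cx + 0.45 * r2 * cos(ang); ccy <- cy + 0.45 * r2 * sin(ang)
      mask <- mask | .in_ellipse(px, py, ccx, ccy, 0.52 * r2, 0.34 * r2, ang)
    }
    mask <- mask | ((px - cx)^2 + (py - cy)^2 <= (0.4 * r2)^2)
  } else if (family == "lobes") {
    # four broad arms in a cross: two perpendicular full-length ellipses
    for (b in 1:2) {
      ang <- phi + (b - 1) * pi / 2
      mask <- mask | .in_ellipse(px, py, cx, cy, 0.95 * r2, 0.26 * r2, ang)
    }
  } else if (family == "rings") {
    nd <- 8L
    for (b in seq_len(nd)) {
      ang <- phi + (b - 1) * 2 * pi / nd
      ccx <- cx + 0.78 * r2 * cos(ang); ccy <- cy + 0.78 * r2 * sin(ang)
      mask <- mask | ((px - ccx)^2 + (py - ccy)^2 <= (0.20 * r2)^2)
    }
  }
  mask
}

# One sample, consuming the current RNG stream.
.render_sample <- function(spec, label) {
  S <- spec$image_size
  jit <- spec$pos_jitter
  cx <- 0.5 + stats::runif(1, -jit, jit)
  cy <- 0.5 + stats::runif(1, -jit, jit)
  s <- stats::runif(1, spec$size_range[1], spec$size_range[2])
  phi <- stats::runif(1, 0, 2 * pi)
  family <- spec$shapes_per_class[label + 1L]
  mask <- .render_mask(family, S, cx, cy, s, phi)

  pal <- spec$palette
  img <- array(0, c(S, S, 3))
  if (identical(spec$background$kind, "stones")) {
    field <- bilinear_resize(matrix(stats::runif(64), 8, 8), S, S)
    stone <- field > 0.55
    shade <- 0.75 + 0.5 * field
    for (ch in 1:3) {
      plane <- matrix(pal$bg_soil[ch], S, S) * shade
      plane[stone] <- (pal$bg_stone[ch] * shade)[stone]
      img[, , ch] <- plane
    }
  } else {
    for (ch in 1:3) img[, , ch] <- pal$bg_soil[ch]
  }

  fg <- clamp01(pal$fg_base + stats::runif(3, -pal$fg_jitter, pal$fg_jitter))
  tex <- 0.8 + 0.4 * bilinear_resize(matrix(stats::runif(36), 6, 6), S, S)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- (fg[ch] * tex)[mask]
    img[, , ch] <- plane
  }
  noise_sd <- spec$background$noise_sd
  if (noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim(img))
  }
  img <- clamp01(img)
  structure(list(image = img, label = as.integer(label),
                 mask = mask * 1L,
                 class_name = sprintf("class_%02d_%s", label, family)),
            class = "synthetic_sample")
}

#' Generate a labeled synthetic dataset
#'
#' Produces `num_classes * n_per_class` samples, exactly `n_per_class` per
#' class (blocked by class, label order 0..K-1). Deterministic: the same spec
#' and seed give a bitwise-identical dataset, and the caller's RNG state is
#' left untouched.
#'
#' @param spec a [synthetic_spec()].
#' @param n_per_class samples per class (>= 1).
#' @return list of `synthetic_sample` objects, each with `$image`
#'   (H x W x 3 in \[0,1\]), `$label` (0-based class index), `$mask`
#'   (H x W, 1 = object) and `$class_name`.
#' @export
generate_dataset <- function(spec, n_per_class) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (n_per_class < 1) stop("configuration error: n_per_class must be >= 1")
  with_seed(spec$seed, {
    out <- vector("list", spec$num_classes * n_per_class)
    i <- 0L
    for (k in seq_len(spec$num_classes) - 1L) {
      for (j in seq_len(n_per_class)) {
        i <- i + 1L
        out[[i]] <- .render_sample(spec, k)
      }
    }
    out
  })
}

#' Class names of a synthetic dataset
#' @param samples list of samples from [generate_dataset()].
#' @return character vector ordered by class index.
#' @export
dataset_class_names <- function(samples) {
  labs <- vapply(samples, function(s) s$label, integer(1))
  nms <- vapply(samples, function(s) s$class_name %||% as.character(s$label),
                character(1))
  nms[match(sort(unique(labs)), labs)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
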