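# Shared numeric helpers: bilinear resampling, color mapping, RNG scoping.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Run code with a temporary RNG seed, restoring the caller's RNG state.
# With seed = NULL the current stream is used (and advanced).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Bilinear resize of a matrix or H x W x C array
#'
#' Output pixel centers are mapped into the source via
#' `src = (dst + 0.5) * size_in / size_out - 0.5` (center-aligned sampling,
#' clamped at the borders), so constant inputs stay exactly constant and a
#' 1 x 1 input broadcasts. Used for input resizing, attention-map upsampling
#' in the fusion rule, and mask resizing.
#'
#' @param x matrix or 3-d array (H x W x C).
#' @param out_h,out_w output size in pixels.
#' @return object of the same kind as `x` with the new spatial size.
#' @export
bilinear_resize <- function(x, out_h, out_w = out_h) {
  if (is.matrix(x)) {
    dim(x) <- c(dim(x), 1L)
    return(bilinear_resize(x, out_h, out_w)[, , 1L])
  }
  h <- dim(x)[1L]; w <- dim(x)[2L]; nc <- dim(x)[3L]
  sy <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  sx <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  y0 <- pmin(pmax(floor(sy), 0), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(pmax(floor(sx), 0), w - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- pmin(pmax(sy - y0, 0), 1); fx <- pmin(pmax(sx - x0, 0), 1)
  out <- array(0, c(out_h, out_w, nc))
  FY <- matrix(fy, out_h, out_w); FX <- matrix(fx, out_h, out_w, byrow = TRUE)
  for (ch in seq_len(nc)) {
    plane <- matrix(x[, , ch], h, w)   # keep dims even for 1 x 1 inputs
    a <- plane[cbind(rep(y0 + 1, out_w), rep(x0 + 1, each = out_h))]
    b <- plane[cbind(rep(y0 + 1, out_w), rep(x1 + 1, each = out_h))]
    cc <- plane[cbind(rep(y1 + 1, out_w), rep(x0 + 1, each = out_h))]
    d <- plane[cbind(rep(y1 + 1, out_w), rep(x1 + 1, each = out_h))]
    dim(a) <- dim(b) <- dim(cc) <- dim(d) <- c(out_h, out_w)
    out[, , ch] <- (a * (1 - FX) + b * FX) * (1 - FY) + (cc * (1 - FX) + d * FX) * FY
  }
  out
}

# Piecewise-linear heat colormap (dark blue -> green -> yellow -> red) for
# heatmap panels; input in [0,1], returns n x 3 RGB in [0,1].
heat_colors <- function(v) {
  stops <- rbind(c(0.05, 0.05, 0.35),
                 c(0.10, 0.55, 0.35),
                 c(0.95, 0.90, 0.20),
                 c(0.85, 0.15, 0.10))
  v <- clamp01(v)
  pos <- v * (nrow(stops) - 1)
  i0 <- pmin(floor(pos), nrow(stops) - 2)
  f <- pos - i0
  stops[i0 + 1, , drop = FALSE] * (1 - f) + stops[i0 + 2, , drop = FALSE] * f
}
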