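# Stochastic training-time augmentation.
#
# Mirrors the acquisition-level variation of seedling datasets: small
# translations, rotations, down-scaling, shear, occlusion (cut-out),
# photometric corruption, Gaussian pixel noise, and optional color jitter.
# Only a random subset of the enabled methods is applied per call, so most
# augmented images differ mildly from their source.

#' Augmentation configuration
#'
#' Defaults follow the reference training recipe: translation within
#' +/- 0.1 of the image side, rotation within +/- 10 degrees, scale in
#' \[0.8, 1\], shear within +/- 20 degrees; cut-out, photometric corruption
#' and Gaussian noise enabled; color jitter off. Each enabled method fires
#' independently with probability `p_apply` on every call.
#'
#' @param translation max |shift| as a fraction of the image side.
#' @param rotation max |angle| in degrees.
#' @param scale length-2 range of isotropic scale factors.
#' @param shear max |shear angle| in degrees.
#' @param cutout logical, occlude a random rectangle (10--30% of the side)
#'   with the image mean.
#' @param corruption logical, random brightness/contrast change.
#' @param noise_sd standard deviation of additive Gaussian noise (0 = off).
#' @param color_jitter logical, random per-channel gain.
#' @param p_apply per-method application probability.
#' @export
augment_config <- function(translation = 0.1, rotation = 10,
                           scale = c(0.8, 1), shear = 20,
                           cutout = TRUE, corruption = TRUE,
                           noise_sd = 0.05, color_jitter = FALSE,
                           p_apply = 0.25) {
  structure(list(translation = translation, rotation = rotation,
                 scale = scale, shear = shear, cutout = cutout,
                 corruption = corruption, noise_sd = noise_sd,
                 color_jitter = color_jitter, p_apply = p_apply),
            class = "augment_config")
}

# Inverse-mapped bilinear affine warp. The forward content transform moves a
# source pixel at offset (dx, dy) from the image center (dx along columns,
# dy along rows, rows increasing downward) to
#   (dx', dy') = s * R(theta) * Sh(shear) * (dx, dy) + (tx, ty),
# with R(theta) = [[cos, -sin], [sin, cos]] (counterclockwise in array
# coordinates) and Sh shearing x by y: (dx + tan(shear) * dy, dy).
# Out-of-range samples replicate the border.
.affine_warp <- function(img, theta = 0, sfac = 1, shear = 0, tx = 0, ty = 0) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  Sh <- matrix(c(1, 0, tan(shear), 1), 2, 2)
  M <- sfac * R %*% Sh
  Mi <- solve(M)
  cyc <- (h - 1) / 2; cxc <- (w - 1) / 2
  u <- matrix(seq_len(w) - 1 - cxc, h, w, byrow = TRUE)   # dx'
  v <- matrix(seq_len(h) - 1 - cyc, h, w)                 # dy'
  sx <- Mi[1, 1] * (u - tx) + Mi[1, 2] * (v - ty) + cxc
  sy <- Mi[2, 1] * (u - tx) + Mi[2, 2] * (v - ty) + cyc
  x0 <- pmin(pmax(floor(sx), 0), w - 1); x1 <- pmin(x0 + 1, w - 1)
  y0 <- pmin(pmax(floor(sy), 0), h - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- pmin(pmax(sx - x0, 0), 1); fy <- pmin(pmax(sy - y0, 0), 1)
  out <- img
  for (ch in seq_len(dim(img)[3L])) {
    plane <- img[, , ch]
    a <- plane[cbind(as.vector(y0 + 1), as.vector(x0 + 1))]
    b <- plane[cbind(as.vector(y0 + 1), as.vector(x1 + 1))]
    cc <- plane[cbind(as.vector(y1 + 1), as.vector(x0 + 1))]
    d <- plane[cbind(as.vector(y1 + 1), as.vector(x1 + 1))]
    val <- (a * (1 - fx) + b * fx) * (1 - fy) + (cc * (1 - fx) + d * fx) * fy
    out[, , ch] <- matrix(val, h, w)
  }
  out
}

#' Augment one image
#'
#' Applies a random subset of the configured methods (each enabled method
#' fires with probability `p_apply`); geometric methods are composed into a
#' single bilinear warp. Output has the same shape as the input and is
#' clipped to \[0,1\]. Deterministic given `seed`; with a degenerate
#' configuration (all ranges zero, no cut-out/corruption/noise) the input is
#' returned unchanged.
#'
#' @param image H x W x 3 array in \[0,1\].
#' @param config an [augment_config()].
#' @param seed optional integer seed; `NULL` uses (and advances) the current
#'   RNG stream.
#' @return H x W x 3 array in \[0,1\].
#' @export
augment <- function(image, config = augment_config(), seed = NULL) {
  stopifnot(length(dim(image)) == 3L)
  with_seed(seed, {
    cfg <- config
    p <- cfg$p_apply
    fire <- function() stats::runif(1) < p
    theta <- sfac <- shear <- tx <- ty <- NULL
    if (cfg$translation > 0 && fire()) {
      tx <- stats::runif(1, -cfg$translation, cfg$translation) * dim(image)[2L]
      ty <- stats::runif(1, -cfg$translation, cfg$translation) * dim(image)[1L]
    }
    if (cfg$rotation > 0 && fire()) {
      theta <- stats::runif(1, -cfg$rotation, cfg$rotation) * pi / 180
    }
    if ((cfg$scale[1] != 1 || cfg$scale[2] != 1) && fire()) {
      sfac <- stats::runif(1, cfg$scale[1], cfg$scale[2])
    }
    if (cfg$shear > 0 && fire()) {
      shear <- stats::runif(1, -cfg$shear, cfg$shear) * pi / 180
    }
    out <- image
    if (!is.null(theta) || !is.null(sfac) || !is.null(shear) ||
        !is.null(tx)) {
      out <- .affine_warp(out,
                          theta = theta %||% 0, sfac = sfac %||% 1,
                          shear = shear %||% 0,
                          tx = tx %||% 0, ty = ty %||% 0)
    }
    if (isTRUE(cfg$cutout) && fire()) {
      # kept small relative to the object scale so occlusion rarely removes
      # the whole plant
      h <- dim(out)[1L]; w <- dim(out)[2L]
      ch <- max(2L, round(stats::runif(1, 0.08, 0.2) * h))
      cw <- max(2L, round(stats::runif(1, 0.08, 0.2) * w))
      r0 <- sample.int(h - ch + 1L, 1); c0 <- sample.int(w - cw + 1L, 1)
      out[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), ] <- mean(out)
    }
    if (isTRUE(cfg$corruption) && fire()) {
      contr <- stats::runif(1, 0.8, 1.2)
      bright <- stats::runif(1, -0.15, 0.15)
      out <- (out - 0.5) * contr + 0.5 + bright
    }
    if (isTRUE(cfg$color_jitter) && fire()) {
      gain <- stats::runif(3, 0.85, 1.15)
      for (k in 1:3) out[, , k] <- out[, , k] * gain[k]
    }
    if (cfg$noise_sd > 0 && fire()) {
      out <- out + array(stats::rnorm(length(out), 0, cfg$noise_sd), dim(out))
    }
    clamp01(out)
  })
}

#' Rotate an image by an exact angle (no random subset)
#'
#' Convenience wrapper over the same warp used by [augment()]; mainly for
#' inspecting the geometric convention.
#' @param image H x W x 3 array.
#' @param degrees rotation angle, counterclockwise in array coordinates.
#' @export
rotate_image <- function(image, degrees) {
  .affine_warp(image, theta = degrees * pi / 180)
}
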