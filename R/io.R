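# Image-folder I/O: `root/<class_name>/*.png` with optional ground-truth
# masks in `root/<class_name>/masks/<same_stem>.png` (0/255).

.read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("TIFF support requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] >= 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3L] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  img
}

#' Load a class-labeled image folder
#'
#' Expects one subdirectory per class, each containing PNG (or TIFF) images;
#' class indices 0..K-1 are assigned by sorted subdirectory name. Every image
#' is resized to `image_size` x `image_size` with bilinear interpolation. If
#' a `masks/` subdirectory holds a same-stem PNG, it is loaded as the
#' ground-truth object mask (values > 0.5 after resizing are foreground).
#' Unreadable files are skipped with a warning; an empty class folder is an
#' error.
#'
#' @param root dataset directory.
#' @param image_size output side in pixels.
#' @return list of samples (`$image`, `$label`, `$class_name`, optional
#'   `$mask`) with attribute `class_names`.
#' @export
load_image_folder <- function(root, image_size = 64L) {
  if (!dir.exists(root)) stop("data error: no such directory: ", root)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  classes <- setdiff(classes, "masks")
  if (length(classes) == 0L) stop("data error: no class subdirectories in ", root)
  samples <- list()
  for (ci in seq_along(classes)) {
    cdir <- file.path(root, classes[ci])
    files <- sort(list.files(cdir, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    loaded <- 0L
    for (f in files) {
      img <- tryCatch(.read_image(f), error = function(e) {
        warning("skipping unreadable file ", f, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
      if (is.null(img)) next
      img <- clamp01(bilinear_resize(img, image_size, image_size))
      smp <- list(image = img, label = ci - 1L, class_name = classes[ci])
      mpath <- file.path(cdir, "masks",
                         paste0(tools::file_path_sans_ext(basename(f)), ".png"))
      if (file.exists(mpath)) {
        m <- .read_image(mpath)[, , 1L]
        smp$mask <- (bilinear_resize(m, image_size, image_size) > 0.5) * 1L
      }
      loaded <- loaded + 1L
      samples[[length(samples) + 1L]] <- smp
    }
    if (loaded == 0L) stop("data error: class folder has no readable image: ", cdir)
  }
  attr(samples, "class_names") <- classes
  samples
}

#' Write a dataset as an image folder
#'
#' Inverse of [load_image_folder()]; used by the `synth` command-line
#' subcommand. Masks, when present, are written under
#' `<class>/masks/<stem>.png`.
#'
#' @param samples list of samples with `$image`, `$label`, optional `$mask`
#'   and `$class_name`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(samples, dir) {
  counter <- new.env(parent = emptyenv())
  for (s in samples) {
    cname <- s$class_name %||% sprintf("class_%02d", s$label)
    cdir <- file.path(dir, cname)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    n <- (get0(cname, envir = counter, ifnotfound = 0L)) + 1L
    assign(cname, n, envir = counter)
    stem <- sprintf("sample_%04d", n)
    png::writePNG(s$image, file.path(cdir, paste0(stem, ".png")))
    if (!is.null(s$mask)) {
      mdir <- file.path(cdir, "masks")
      dir.create(mdir, showWarnings = FALSE)
      png::writePNG(s$mask + 0, file.path(mdir, paste0(stem, ".png")))
    }
  }
  invisible(dir)
}
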