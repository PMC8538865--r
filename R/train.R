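# End-to-end training: augmentation -> backbone -> per-level slot modules ->
# deepest-level mass logits, optimized with AdamW on the area-regularized
# cross-entropy. Single process, fully seed-deterministic.

#' Training configuration
#'
#' Defaults follow the reference recipe at full scale (360 x 360 inputs,
#' batch 32, AdamW with initial learning rate 1e-4, 80 epochs, lambda = 2,
#' T = 3 slot iterations, positive explanation). [desk_config()] provides the
#' small-scale preset used throughout the tests.
#'
#' @param input_size input side in pixels (images are bilinearly resized).
#' @param batch_size minibatch size.
#' @param lr initial AdamW learning rate.
#' @param weight_decay decoupled weight decay.
#' @param epochs training epochs.
#' @param lambda area-regularizer weight.
#' @param lambda_warmup epochs during which the area term is held at zero
#'   before ramping to its full weight over `lambda_ramp` further epochs.
#'   The area penalty acts along the uniform-logit direction that the
#'   (shift-invariant) cross-entropy cannot oppose, so with an adaptive
#'   optimizer any nonzero lambda drives an undiscriminating model into
#'   sigmoid saturation within a few steps; the hold gives the classifier
#'   time to separate the classes first, after which class-specific evidence
#'   is defended by the cross-entropy. Set to 0 to apply lambda immediately.
#' @param lambda_ramp epochs over which lambda then ramps linearly from 0 to
#'   its full value.
#' @param T slot-attention iterations.
#' @param e explanation sign: +1 (positive) or -1 (negative).
#' @param backbone backbone kind, see [backbone_config()].
#' @param n_levels pyramid levels.
#' @param channels optional channel widths per level.
#' @param dim slot/token dimension D.
#' @param augment apply training-time augmentation.
#' @param aug_config an [augment_config()].
#' @param seed RNG seed governing initialization, shuffling and augmentation.
#' @export
train_config <- function(input_size = 360L, batch_size = 32L, lr = 1e-4,
                         weight_decay = 1e-2, epochs = 80L, lambda = 2,
                         lambda_warmup = 10L, lambda_ramp = 5L, T = 3L,
                         e = 1L, backbone = "tiny", n_levels = 4L,
                         channels = NULL, dim = 64L, augment = TRUE,
                         aug_config = augment_config(), seed = 1L) {
  stopifnot(input_size > 0, batch_size > 0, lr > 0, epochs >= 0,
            lambda >= 0, lambda_warmup >= 0, lambda_ramp >= 0,
            T >= 0, e %in% c(-1, 1))
  structure(list(input_size = as.integer(input_size),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 lambda = lambda, lambda_warmup = as.integer(lambda_warmup),
                 lambda_ramp = as.integer(lambda_ramp),
                 T = as.integer(T), e = as.integer(e),
                 backbone = backbone, n_levels = as.integer(n_levels),
                 channels = channels, dim = as.integer(dim),
                 augment = augment, aug_config = aug_config,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Read a training configuration from a YAML file
#'
#' The file holds any subset of [train_config()]'s fields (augmentation
#' ranges under an `aug_config` block); unspecified fields take the
#' desk-preset defaults when `desk = TRUE` (the default) and the full-scale
#' defaults otherwise.
#'
#' @param path YAML file.
#' @param desk start from [desk_config()] defaults.
#' @export
train_config_from_yaml <- function(path, desk = TRUE) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("train_config_from_yaml requires the 'yaml' package")
  }
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$aug_config)) {
    vals$aug_config <- do.call(augment_config, vals$aug_config)
  }
  if (desk) do.call(desk_config, vals) else do.call(train_config, vals)
}

#' Desk-scale training preset
#'
#' 64 x 64 inputs, the tiny backbone, 30 epochs and learning rate 1e-3 --
#' sized for a small synthetic study on one CPU, with the area-term warm-up
#' covering the first 18 epochs (+6 ramp) since the backbone trains from
#' scratch. All other settings follow [train_config()].
#' @param ... overrides passed to [train_config()].
#' @export
desk_config <- function(...) {
  args <- list(input_size = 64L, epochs = 30L, lr = 1e-3, backbone = "tiny",
               dim = 32L, weight_decay = 1e-4,
               lambda_warmup = 18L, lambda_ramp = 6L,
               aug_config = augment_config(p_apply = 0.15))
  over <- list(...)
  args[names(over)] <- over
  do.call(train_config, args)
}

# AdamW step, in place on the flat parameter list.
adamw_step <- function(params, grads, state, lr, wd, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * (step + wd * params[[nm]])
  }
  params
}

#' Train a multi-resolution slot-attention classifier
#'
#' @param cfg a [train_config()] (or [desk_config()]).
#' @param dataset list of samples with `$image` (H x W x 3 in \[0,1\]) and
#'   `$label` (0-based); e.g. [generate_dataset()] or [load_image_folder()]
#'   output. Images not at `cfg$input_size` are resized.
#' @param eval_data optional held-out samples; accuracy on them is recorded
#'   per epoch.
#' @param verbose print a line per epoch.
#' @return list with `$model` (an `mrslots_model`) and `$history`
#'   (data.frame: epoch, loss, ce, area, train_acc, optional val_acc).
#'   `epochs = 0` returns the initialized, untrained model and an empty
#'   history.
#' @export
train <- function(cfg, dataset, eval_data = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  n <- length(dataset)
  if (n == 0L) stop("data error: empty dataset")
  labels <- vapply(dataset, function(s) as.integer(s$label), integer(1))
  K <- max(labels) + 1L
  if (K < 2L || length(unique(labels)) < 2L) {
    stop("data error: need >= 2 classes with samples")
  }
  bb <- backbone_config(kind = cfg$backbone, n_levels = cfg$n_levels,
                        channels_per_level = cfg$channels,
                        input_size = cfg$input_size, dim = cfg$dim)
  set.seed(cfg$seed)
  params <- init_params(bb, K, seed = NULL)
  imgs <- lapply(dataset, function(s) {
    if (all(dim(s$image)[1:2] == cfg$input_size)) s$image
    else clamp01(bilinear_resize(s$image, cfg$input_size, cfg$input_size))
  })

  opt <- new.env(parent = emptyenv())
  opt$t <- 0L; opt$m <- list(); opt$v <- list()
  plans <- new.env(parent = emptyenv())
  get_plan <- function(B) {
    key <- as.character(B)
    if (is.null(plans[[key]])) plans[[key]] <- build_plan(bb, B)
    plans[[key]]
  }

  hist <- list()
  cn <- dataset_class_names(dataset)
  for (ep in seq_len(cfg$epochs)) {
    lam_ep <- if (ep <= cfg$lambda_warmup) 0 else if (cfg$lambda_ramp > 0L) {
      cfg$lambda * min(1, (ep - cfg$lambda_warmup) / cfg$lambda_ramp)
    } else cfg$lambda
    ord <- sample.int(n)
    ep_loss <- ep_ce <- ep_area <- 0; ep_hits <- 0L; nb <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      take <- ord[start:min(start + cfg$batch_size - 1L, n)]
      B <- length(take)
      batch_imgs <- lapply(take, function(i) {
        if (isTRUE(cfg$augment)) augment(imgs[[i]], cfg$aug_config) else imgs[[i]]
      })
      X <- stack_images(batch_imgs)
      y1 <- labels[take] + 1L
      tp <- ag_tape()
      fw <- fw_model(tp, params, ag_const(tp, X), get_plan(B), bb, K,
                     cfg$e, cfg$T, labels1 = y1, lambda = lam_ep)
      loss <- fw$loss$value
      if (!is.finite(loss)) {
        stop("training diverged: non-finite loss at epoch ", ep,
             ", batch ", nb + 1L)
      }
      grads_by_id <- ag_backward(tp, fw$loss)
      grads <- lapply(fw$pnodes, function(nd) grads_by_id[[nd$id]])
      params <- adamw_step(params, grads, opt, cfg$lr, cfg$weight_decay)
      ep_loss <- ep_loss + loss
      ep_ce <- ep_ce + fw$ce$value
      ep_area <- ep_area + fw$area$value
      ep_hits <- ep_hits + sum(max.col(fw$logits$value) == y1)
      nb <- nb + 1L
    }
    row <- data.frame(epoch = ep, loss = ep_loss / nb, ce = ep_ce / nb,
                      area = ep_area / nb, train_acc = ep_hits / n)
    if (!is.null(eval_data)) {
      mdl <- new_model(params, bb, K, cfg, cn)
      row$val_acc <- mean(predict_dataset(mdl, eval_data)$pred ==
                            vapply(eval_data, function(s) s$label, integer(1)))
    }
    hist[[ep]] <- row
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  ce %.4f  area %.4f  acc %.3f",
                      ep, row$loss, row$ce, row$area, row$train_acc))
    }
  }
  history <- if (length(hist)) do.call(rbind, hist) else
    data.frame(epoch = integer(), loss = numeric(), ce = numeric(),
               area = numeric(), train_acc = numeric())
  list(model = new_model(params, bb, K, cfg, cn), history = history)
}

new_model <- function(params, bb, K, cfg, class_names = NULL) {
  structure(list(params = params, backbone = bb, K = K, e = cfg$e,
                 T = cfg$T, lambda = cfg$lambda, input_size = bb$input_size,
                 class_names = class_names, train_config = cfg),
            class = "mrslots_model")
}

#' @export
print.mrslots_model <- function(x, ...) {
  cat(sprintf("mrslots model: K=%d classes, %d levels, D=%d, T=%d, e=%+d, input %dpx\n",
              x$K, x$backbone$n_levels, x$backbone$dim, x$T, x$e,
              x$input_size))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Single-file archive (RDS) holding parameters, backbone configuration and
#' training settings.
#' @param model an `mrslots_model`.
#' @param path checkpoint file path.
#' @export
save_model <- function(model, path) {
  saveRDS(list(schema = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$schema) || obj$schema != 1L) stop("unknown checkpoint schema")
  obj$model
}

#' Batched inference over a dataset
#'
#' Returns 0-based predictions, softmax probabilities, per-image normalized
#' fusion weights, and (optionally) per-image fused attention maps and the
#' per-level evidence-map masses (n x K x n_levels).
#'
#' @param model an `mrslots_model`.
#' @param samples list of samples (or bare images).
#' @param batch_size inference batch size.
#' @param fused also compute each image's fused attention map.
#' @param masses also collect per-level slot masses.
#' @return list with `$pred`, `$prob`, `$weights`, `$fused`, `$mass`.
#' @export
predict_dataset <- function(model, samples, batch_size = 64L,
                            fused = FALSE, masses = FALSE) {
  bb <- model$backbone
  n <- length(samples)
  K <- model$K
  nl <- bb$n_levels
  preds <- integer(n)
  probs <- matrix(0, n, K)
  wts <- matrix(0, n, nl)
  fmaps <- if (fused) vector("list", n) else NULL
  mass_arr <- if (masses) array(0, c(n, K, nl)) else NULL
  sizes <- level_sizes(bb)
  plans <- new.env(parent = emptyenv())
  for (start in seq(1L, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1L, n)
    B <- length(take)
    key <- as.character(B)
    if (is.null(plans[[key]])) plans[[key]] <- build_plan(bb, B)
    imgs <- lapply(samples[take], function(s) {
      img <- if (is.list(s)) s$image else s
      if (!all(dim(img)[1:2] == bb$input_size)) {
        img <- clamp01(bilinear_resize(img, bb$input_size, bb$input_size))
      }
      img
    })
    tp <- ag_tape()
    fw <- fw_model(tp, model$params, ag_const(tp, stack_images(imgs)),
                   plans[[key]], bb, K, model$e, model$T)
    logit <- fw$logits$value
    z <- logit - apply(logit, 1L, max)
    pr <- exp(z) / rowSums(exp(z))
    preds[take] <- max.col(logit) - 1L
    probs[take, ] <- pr
    sal <- vapply(fw$levels, function(lv) as.numeric(lv$sal$value), numeric(B))
    sal <- matrix(sal, B, nl)
    wts[take, ] <- t(apply(sal, 1L, function(w) {
      if (sum(w) <= 0) rep(1 / nl, nl) else w / sum(w)
    }))
    if (masses) {
      for (l in seq_len(nl)) mass_arr[take, , l] <- fw$levels[[l]]$mass$value
    }
    if (fused) {
      for (bi in seq_len(B)) {
        levs <- lapply(seq_len(nl), function(l) {
          P <- sizes[l]^2
          rows <- ((bi - 1L) * P + 1L):(bi * P)
          make_level_attention(fw$levels[[l]]$M$value[rows, , drop = FALSE],
                               fw$levels[[l]]$A$value[rows, , drop = FALSE],
                               sizes[l], sizes[l], l)
        })
        fmaps[[take[bi]]] <- fuse(levs, bb$input_size)
      }
    }
  }
  list(pred = preds, prob = probs, weights = wts, fused = fmaps,
       mass = mass_arr)
}

#' Predict one image with full attention output
#'
#' Runs the backbone and all slot modules, fuses the per-level evidence maps
#' with the saliency weights, and classifies by the deepest level's mass
#' logits (argmax of `e * mass`). Inference is deterministic: slots start
#' from their learned means.
#'
#' @param model an `mrslots_model` from [train()].
#' @param image H x W x 3 array; resized (with a warning) if not at the
#'   model's input size.
#' @param e explanation sign override; defaults to the sign the model was
#'   trained with.
#' @return list with `class` (0-based), `class_name`, `probabilities`,
#'   `fused` (`fused_attention`), `levels` (list of `level_attention`) and
#'   `logits`.
#' @export
predict_sample <- function(model, image, e = NULL) {
  e <- e %||% model$e
  bb <- model$backbone
  if (!all(dim(image)[1:2] == bb$input_size)) {
    warning("resizing image to ", bb$input_size, " x ", bb$input_size)
    image <- clamp01(bilinear_resize(image, bb$input_size, bb$input_size))
  }
  K <- model$K
  tp <- ag_tape()
  fw <- fw_model(tp, model$params, ag_const(tp, img_to_tokens(image)),
                 build_plan(bb, 1L), bb, K, e, model$T)
  sizes <- level_sizes(bb)
  levels <- lapply(seq_len(bb$n_levels), function(l) {
    make_level_attention(fw$levels[[l]]$M$value, fw$levels[[l]]$A$value,
                         sizes[l], sizes[l], l)
  })
  fus <- fuse(levels, bb$input_size)
  logits <- as.numeric(fw$logits$value)
  z <- logits - max(logits)
  pr <- exp(z) / sum(exp(z))
  cls <- which.max(logits) - 1L
  list(class = cls,
       class_name = if (!is.null(model$class_names)) model$class_names[cls + 1L] else NULL,
       probabilities = pr, fused = fus, levels = levels, logits = logits)
}
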