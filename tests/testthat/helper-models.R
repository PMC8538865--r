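# Shared study fixtures for the acceptance suite. Models are trained once
# per session (memoised) and reused across test files.
#
# Study conditions: K = 4 shape classes at 64 x 64, tiny backbone, D = 64,
# T = 3, lambda = 2, 200 train + 100 test per class, 30 epochs (the desk
# preset). The negative twin and the lambda sweep use a reduced size
# (100 train / 50 test per class, 15 and 12 epochs) chosen for runtime;
# they are scored on directions, not magnitudes.

.acc_cache <- new.env(parent = emptyenv())

acc_train_spec <- function() synthetic_spec(seed = 2021L)
acc_test_spec <- function() synthetic_spec(seed = 6705L)

acc_dataset <- function(what = c("train", "test", "train_small", "test_small")) {
  what <- match.arg(what)
  key <- paste0("ds_", what)
  if (is.null(.acc_cache[[key]])) {
    .acc_cache[[key]] <- switch(what,
      train = generate_dataset(acc_train_spec(), 200L),
      test = generate_dataset(acc_test_spec(), 100L),
      train_small = generate_dataset(acc_train_spec(), 100L),
      test_small = generate_dataset(acc_test_spec(), 50L))
  }
  .acc_cache[[key]]
}

# The criterion-scale positive-explanation model.
acc_model_positive <- function() {
  if (is.null(.acc_cache$pos)) {
    cfg <- desk_config(epochs = 30L, lambda = 2, T = 3L, e = 1L, seed = 42L)
    .acc_cache$pos <- train(cfg, acc_dataset("train"))
  }
  .acc_cache$pos
}

# Reduced-size negative-explanation twin.
acc_model_negative <- function() {
  if (is.null(.acc_cache$neg)) {
    cfg <- desk_config(epochs = 15L, lambda = 2, T = 3L, e = -1L,
                       lambda_warmup = 6L, lambda_ramp = 3L, seed = 42L)
    .acc_cache$neg <- train(cfg, acc_dataset("train_small"))
  }
  .acc_cache$neg
}

# Reduced-size positive model matched to the negative twin (same data,
# epochs and seed; only the sign differs).
# Identical reduced runs differing only in lambda.
acc_lambda_run <- function(lambda) {
  key <- paste0("lam_", lambda)
  if (is.null(.acc_cache[[key]])) {
    cfg <- desk_config(epochs = 12L, lambda = lambda, T = 3L, e = 1L,
                       lambda_warmup = 6L, lambda_ramp = 3L, seed = 42L)
    .acc_cache[[key]] <- train(cfg, acc_dataset("train_small"))
  }
  .acc_cache[[key]]
}

acc_truth <- function(ds) vapply(ds, function(s) as.integer(s$label), integer(1))
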