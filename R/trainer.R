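# Model assembly, the training loop, and the evaluation / reconstruction /
# embedding workflows built on run_window().

#' Create an untrained CSDP model
#'
#' Bundles randomly initialized parameters, fresh adaptive thresholds and
#' Adam state with the configuration.
#'
#' @param config a [csdp_config()].
#' @param seed RNG seed for the parameter draw.
#' @param eta Adam step size (reference value 0.002).
#' @return A `csdp_model`.
#' @export
csdp_init <- function(config, seed = 1L, eta = 0.002) {
  params <- init_params(config, seed = derive_seed(seed, 0L))
  structure(list(
    config = config,
    params = params,
    thresholds = list(net = rep(config$v_thr_init, config$n_layers),
                      pred = rep(config$v_thr_init, config$n_layers),
                      cls = config$v_thr_init),
    opt = adam_init(params, eta = eta),
    metrics = NULL,
    seed = as.integer(seed)
  ), class = "csdp_model")
}

#' @export
print.csdp_model <- function(x, ...) {
  print(x$config)
  if (!is.null(x$metrics))
    cat("  trained ", nrow(x$metrics), " epoch(s); last pos/neg goodness ",
        signif(utils::tail(x$metrics$pos_goodness, 1), 3), "/",
        signif(utils::tail(x$metrics$neg_goodness, 1), 3), "\n", sep = "")
  invisible(x)
}

#' Train for one epoch
#'
#' Shuffles the dataset, and for every minibatch: synthesizes one negative
#' per positive sample (appended, doubling the batch), encodes the doubled
#' batch as Bernoulli spike trains, and runs the stimulus window with
#' plasticity on. Each batch draws its own RNG stream from
#' `(seed, epoch, batch)`, so results do not depend on batch-level
#' execution order. Thresholds persist across batches.
#'
#' @param model a `csdp_model`.
#' @param dataset a `csdp_dataset`.
#' @param batch_size minibatch width before negatives are appended
#'   (>= 2 in unsupervised mode).
#' @param epoch epoch index (seeds the shuffle and the per-batch streams).
#' @param seed global training seed.
#' @return List with the updated `model` and a one-row metrics data frame
#'   (mean positive/negative goodness probability and mean sequence loss).
#' @export
train_epoch <- function(model, dataset, batch_size, epoch, seed) {
  config <- model$config
  n <- ncol(dataset$pixels)
  if (n < 1L) stop("dataset is empty")
  if (!config$supervised && batch_size < 2L)
    stop("unsupervised training needs batch_size >= 2 (mixture negatives)")
  set.seed(derive_seed(seed, epoch, 0L))
  perm <- sample.int(n)
  starts <- seq(1L, n, by = batch_size)
  g_pos <- g_neg <- loss <- 0; n_pos <- n_neg <- 0L
  for (b in seq_along(starts)) {
    idx <- perm[starts[b]:min(starts[b] + batch_size - 1L, n)]
    if (!config$supervised && length(idx) < 2L) next  # no mixture partner
    aug <- append_negatives(dataset$pixels[, idx, drop = FALSE],
                            dataset$labels[idx], config,
                            side = dataset$side,
                            seed = derive_seed(seed, epoch, b, 1L))
    sb <- make_spike_batch(aug$pixels, aug$labels, config,
                           y_type = aug$y_type,
                           seed = derive_seed(seed, epoch, b, 2L))
    res <- run_window(model, sb, learn = TRUE,
                      clamp_class = config$supervised,
                      collect = "goodness")
    model <- res$model
    pos <- aug$y_type == 1
    g_pos <- g_pos + sum(res$goodness[pos]);  n_pos <- n_pos + sum(pos)
    g_neg <- g_neg + sum(res$goodness[!pos]); n_neg <- n_neg + sum(!pos)
    loss <- loss + sum(res$loss)
  }
  list(model = model,
       metrics = data.frame(epoch = epoch,
                            pos_goodness = g_pos / max(1L, n_pos),
                            neg_goodness = g_neg / max(1L, n_neg),
                            loss = loss / max(1L, n_pos + n_neg)))
}

#' Train a CSDP spiking network
#'
#' Full training loop: [csdp_init()] then [train_epoch()] for `epochs`
#' epochs. Deterministic given `seed` — two runs produce identical models.
#'
#' @param dataset a `csdp_dataset` ([read_idx_dataset()] or
#'   [make_synthetic_dataset()]).
#' @param config a [csdp_config()]; supervised mode requires labels.
#' @param epochs number of passes over the data (reference setting: 30).
#' @param batch_size minibatch width (reference setting: 500).
#' @param seed global seed for initialization, shuffling, encoding and
#'   negative synthesis.
#' @param eta Adam step size.
#' @param verbose print per-epoch goodness summaries?
#' @return A trained `csdp_model` with a `metrics` data frame (one row per
#'   epoch: mean positive/negative goodness probability, mean loss).
#' @examples
#' ds <- make_synthetic_dataset(2, 10, side = 8, noise = 0.05, seed = 1)
#' cfg <- calibrate_goodness(
#'   csdp_config(c(64, 16), 2, gamma = 1, R_I = 0.25, T_ms = 9, dt = 3))
#' m <- csdp_train(ds, cfg, epochs = 1, batch_size = 10, seed = 1)
#' m$metrics
#' @export
csdp_train <- function(dataset, config, epochs = 30, batch_size = 500,
                       seed = 1L, eta = 0.002, verbose = FALSE) {
  if (config$supervised && is.null(dataset$labels))
    stop("supervised training needs a labeled dataset")
  model <- csdp_init(config, seed = seed, eta = eta)
  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    res <- train_epoch(model, dataset, batch_size, epoch = ep, seed = seed)
    model <- res$model
    history[[ep]] <- res$metrics
    if (verbose)
      message(sprintf("epoch %d: pos %.4f neg %.4f loss %.3f",
                      ep, res$metrics$pos_goodness,
                      res$metrics$neg_goodness, res$metrics$loss))
  }
  model$metrics <- do.call(rbind, history)
  model
}

#' Fast-classifier predictions
#'
#' Runs the circuit with plasticity off and no class clamp (the network
#' sees only the sensory spikes) and reads the classifier head's
#' accumulated spike counts as a softmax distribution.
#'
#' @param model a trained `csdp_model`.
#' @param pixels `[J0 x N]` intensities in \[0, 1\].
#' @param seed seed for the Bernoulli encoding.
#' @param batch_size evaluation batch width (memory knob only).
#' @return `[C x N]` column-stochastic matrix of class probabilities.
#' @export
classify <- function(model, pixels, seed = 1L, batch_size = 100L) {
  eval_batches(model, pixels, seed, batch_size, collect = "counts",
               function(res) predict_distribution(res$counts))
}

#' Rate-code embeddings from the top layer
#'
#' @inheritParams classify
#' @return `[J_L x N]` matrix of time-averaged top-layer spike rates.
#' @export
rate_codes <- function(model, pixels, seed = 1L, batch_size = 100L) {
  gc <- model$config$gamma_c
  eval_batches(model, pixels, seed, batch_size, collect = "sL",
               function(res) rate_code(res$sL, gamma_c = gc))
}

#' Reconstruct patterns through the generative head
#'
#' Clamps each pattern as sensory spikes (no class input), simulates the
#' window with plasticity off, and averages the clipped trace of the
#' bottom predictor's spikes.
#'
#' @inheritParams classify
#' @return `[J0 x N]` matrix of reconstructions in \[0, 1\].
#' @export
reconstruct <- function(model, pixels, seed = 1L, batch_size = 100L) {
  cfg <- model$config
  eval_batches(model, pixels, seed, batch_size, collect = "smu0",
               function(res) reconstruction_trace(res$smu0, cfg))
}

# Shared evaluation plumbing: plasticity off, no class clamp, thresholds
# frozen (evaluation must not move the homeostats).
eval_batches <- function(model, pixels, seed, batch_size, collect, extract) {
  if (!is.matrix(pixels)) pixels <- matrix(pixels, ncol = 1L)
  n <- ncol(pixels)
  starts <- seq(1L, n, by = batch_size)
  out <- lapply(seq_along(starts), function(b) {
    idx <- starts[b]:min(starts[b] + batch_size - 1L, n)
    sb <- make_spike_batch(pixels[, idx, drop = FALSE], NULL, model$config,
                           seed = derive_seed(seed, 0L, b))
    extract(run_window(model, sb, learn = FALSE, clamp_class = FALSE,
                       collect = collect))
  })
  do.call(cbind, out)
}

#' Goodness-scan classification (supervised models)
#'
#' The slow classifier: for each candidate class, clamp its one-hot label,
#' simulate the window, and record the time-averaged summed squared traces
#' across layers; predict the class with the largest score.
#'
#' @inheritParams classify
#' @return Integer vector of 0-based predicted classes, with the
#'   `[C x N]` score matrix as attribute `"scores"`.
#' @export
goodness_scan_classify <- function(model, pixels, seed = 1L) {
  config <- model$config
  if (!config$supervised)
    stop("goodness-scan classification needs a supervised model (B bundles)")
  if (!is.matrix(pixels)) pixels <- matrix(pixels, ncol = 1L)
  n <- ncol(pixels)
  scores <- matrix(0, config$n_classes, n)
  for (c_idx in seq_len(config$n_classes)) {
    # identical encoding per candidate class: the scan varies only the clamp
    sb <- make_spike_batch(pixels, rep(c_idx - 1L, n), config,
                           seed = derive_seed(seed, 1L))
    res <- run_window(model, sb, learn = FALSE, clamp_class = TRUE,
                      collect = "goodness_sum")
    scores[c_idx, ] <- res$goodness_sum
  }
  structure(max.col(t(scores), ties.method = "first") - 1L, scores = scores)
}

#' Time-averaged goodness probability of given inputs
#'
#' Diagnostic used to measure the contrastive separation: runs the window
#' with plasticity off and returns each sample's goodness probability
#' averaged over time and layers. In supervised mode the provided labels
#' are clamped (pass true labels for positives, incorrect ones for
#' negatives); in unsupervised mode labels are ignored.
#'
#' @inheritParams classify
#' @param labels 0-based labels to clamp (supervised mode), or `NULL`.
#' @return Length-N vector of mean goodness probabilities.
#' @export
goodness_probabilities <- function(model, pixels, labels = NULL, seed = 1L) {
  if (!is.matrix(pixels)) pixels <- matrix(pixels, ncol = 1L)
  sb <- make_spike_batch(pixels, labels, model$config,
                         seed = derive_seed(seed, 2L))
  run_window(model, sb, learn = FALSE,
             clamp_class = model$config$supervised && !is.null(labels),
             collect = "goodness")$goodness
}

#' Accuracy and confusion counts on a labeled dataset
#'
#' @param model a trained `csdp_model`.
#' @param dataset a labeled `csdp_dataset`.
#' @param seed encoding seed.
#' @return List with `accuracy` and a `[C x C]` `confusion` matrix
#'   (rows = true class, columns = predicted).
#' @export
evaluate_accuracy <- function(model, dataset, seed = 1L) {
  if (is.null(dataset$labels)) stop("dataset has no labels")
  y_hat <- classify(model, dataset$pixels, seed = seed)
  pred <- max.col(t(y_hat), ties.method = "first") - 1L
  C <- model$config$n_classes
  conf <- table(factor(dataset$labels, levels = 0:(C - 1)),
                factor(pred, levels = 0:(C - 1)))
  list(accuracy = mean(pred == dataset$labels),
       confusion = unclass(conf))
}

#' Save / load a model checkpoint
#'
#' Single-file container (R serialization, version 3, uncompressed)
#' holding every parameter matrix, the configuration, the adaptive
#' thresholds and the optimizer state. Uncompressed serialization keeps
#' the file byte-stable for determinism checks.
#'
#' @param model a `csdp_model`.
#' @param path file path.
#' @return `save_model()`: `path`, invisibly. `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path, version = 3, compress = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "csdp_model")) stop("not a csdp model checkpoint")
  model
}

#' MD5 hash of a model's serialized form
#'
#' @param model a `csdp_model`.
#' @return Hex string; equal hashes imply bit-identical checkpoints.
#' @export
model_hash <- function(model) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  save_model(model, f)
  unname(tools::md5sum(f))
}

#' Write the per-epoch metrics log as CSV
#'
#' @param model a trained `csdp_model`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(model, path) {
  if (is.null(model$metrics)) stop("model has no training metrics")
  utils::write.csv(model$metrics, path, row.names = FALSE)
  invisible(path)
}
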