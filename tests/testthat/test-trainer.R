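# Optimizer, parameter initialization, the training loop's bookkeeping,
# checkpoints and determinism.

small_ds <- function(seed = 3) make_synthetic_dataset(2, 6, side = 6,
                                                      noise = 0.1, seed = seed)
small_cfg <- function(...) csdp_config(c(36, 10, 6), 2, gamma = 1,
                                       theta_z = 1, R_I = 0.25, T_ms = 9, ...)

test_that("the stimulus window divides into integration steps", {
  expect_equal(stimulus_steps(csdp_config(c(4, 2), 2, T_ms = 90, dt = 3)), 30L)
  expect_equal(stimulus_steps(csdp_config(c(4, 2), 2, T_ms = 150, dt = 3)), 50L)
  expect_error(csdp_config(c(4, 2), 2, T_ms = 100, dt = 3), "multiple")
})

test_that("initial parameters respect their declared ranges and the seed", {
  cfg <- small_cfg()
  p <- init_params(cfg, seed = 9)
  expect_true(params_in_range(p))
  expect_true(all(p[[1]]$M >= 0))
  expect_null(p[[2]]$V)  # no layer above the top
  expect_equal(dim(p[[1]]$G), c(36L, 10L))
  expect_equal(dim(p[[2]]$A), c(2L, 6L))
  expect_identical(p, init_params(cfg, seed = 9))
  expect_false(identical(p, init_params(cfg, seed = 10)))
})

test_that("Adam matches the textbook recurrence and honours the clip", {
  cfg <- csdp_config(c(1, 1), 2, T_ms = 9, supervised = FALSE)
  params <- structure(list(list(W = matrix(0.3, 1, 1), V = NULL,
                                M = matrix(0.5, 1, 1), B = NULL,
                                G = matrix(0, 1, 1), A = matrix(0, 2, 1))),
                      class = "csdp_params")
  opt <- adam_init(params, eta = 0.1)
  # zero gradients leave parameters untouched
  zg <- list(list(W = matrix(0, 1, 1)))
  expect_equal(apply_updates(params, zg, opt)$params[[1]]$W, params[[1]]$W)
  # three steps against a hand iteration on the single W entry
  w <- 0.3; m <- v <- 0
  st <- list(params = params, opt = opt)
  for (t in 1:3) {
    g <- c(0.2, -0.1, 0.05)[t]
    st <- apply_updates(st$params, list(list(W = matrix(g, 1, 1))), st$opt)
    m <- 0.9 * m + 0.1 * g
    v <- 0.999 * v + 0.001 * g^2
    w <- w - 0.1 * (m / (1 - 0.9^t)) / (sqrt(v / (1 - 0.999^t)) + 1e-8)
    expect_equal(st$params[[1]]$W[1, 1], w, tolerance = 1e-12)
  }
  # a parameter at the ceiling pushed upward stays at the ceiling
  params[[1]]$W[1, 1] <- 1
  st <- apply_updates(params, list(list(W = matrix(-5, 1, 1))), opt)
  expect_lte(st$params[[1]]$W[1, 1], 1)
  expect_error(apply_updates(params, list(list(W = matrix(NaN, 1, 1))), opt),
               "bundle W")
})

test_that("range invariants survive a burst of random optimizer steps", {
  cfg <- small_cfg()
  params <- init_params(cfg, seed = 1)
  opt <- adam_init(params, eta = 0.05)
  set.seed(2)
  for (k in 1:50) {
    grads <- lapply(params, function(lp)
      lapply(lp, function(x) if (is.null(x)) NULL
             else matrix(rnorm(length(x), sd = 3), nrow(x), ncol(x))))
    st <- apply_updates(params, grads, opt)
    params <- st$params; opt <- st$opt
  }
  expect_true(params_in_range(params))
})

test_that("a silent zero network stays exactly zero through an epoch", {
  cfg <- csdp_config(c(16, 6, 4), 2, lambda_d = 0, T_ms = 9, gamma = 1,
                     theta_z = 1)
  model <- csdp_init(cfg, seed = 1)
  model$params <- structure(lapply(model$params, function(lp)
    lapply(lp, function(x) if (is.null(x)) NULL else x * 0)),
    class = "csdp_params")
  ds <- new_ds <- list(pixels = matrix(0, 16, 4), labels = c(0L, 1L, 0L, 1L),
                       side = 4L, n_classes = 2L)
  class(ds) <- "csdp_dataset"
  res <- train_epoch(model, ds, batch_size = 4, epoch = 1, seed = 1)
  for (lp in res$model$params)
    for (x in lp) if (!is.null(x)) expect_equal(x, x * 0)
})

test_that("training is deterministic and metric history is well-formed", {
  ds <- small_ds()
  cfg <- small_cfg()
  m1 <- csdp_train(ds, cfg, epochs = 2, batch_size = 4, seed = 7)
  m2 <- csdp_train(ds, cfg, epochs = 2, batch_size = 4, seed = 7)
  expect_identical(model_hash(m1), model_hash(m2))
  expect_equal(nrow(m1$metrics), 2)
  expect_named(m1$metrics, c("epoch", "pos_goodness", "neg_goodness", "loss"))
  expect_true(all(is.finite(unlist(m1$metrics))))
  m3 <- csdp_train(ds, cfg, epochs = 2, batch_size = 4, seed = 8)
  expect_false(model_hash(m1) == model_hash(m3))
})

test_that("a single-hidden-layer network (no top-down bundle) trains and evaluates", {
  ds <- small_ds()
  cfg <- csdp_config(c(36, 12), 2, gamma = 1, theta_z = 1, R_I = 0.25,
                     T_ms = 9)
  m <- csdp_train(ds, cfg, epochs = 1, batch_size = 6, seed = 2)
  expect_null(m$params[[1]]$V)
  ev <- evaluate_accuracy(m, ds, seed = 3)
  expect_true(ev$accuracy >= 0 && ev$accuracy <= 1)
  expect_equal(sum(ev$confusion), 12)
})

test_that("unsupervised training refuses singleton batches and drops B", {
  ds <- small_ds()
  cfg <- csdp_config(c(36, 8), 2, supervised = FALSE, T_ms = 9,
                     gamma = 1, theta_z = 1)
  m <- csdp_init(cfg, 1)
  expect_null(m$params[[1]]$B)
  expect_error(train_epoch(m, ds, batch_size = 1, epoch = 1, seed = 1),
               "batch_size >= 2")
})

test_that("checkpoints round-trip bit-exactly", {
  ds <- small_ds()
  m <- csdp_train(ds, small_cfg(), epochs = 1, batch_size = 6, seed = 4)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  back <- load_model(f)
  expect_identical(back, m)
  expect_identical(model_hash(back), model_hash(m))
  # metrics CSV export
  csvf <- withr::local_tempfile(fileext = ".csv")
  write_metrics(m, csvf)
  expect_equal(read.csv(csvf)$epoch, m$metrics$epoch)
})

test_that("reconstruction and PGM export produce valid artifacts", {
  ds <- small_ds()
  m <- csdp_train(ds, small_cfg(), epochs = 1, batch_size = 6, seed = 4)
  xh <- reconstruct(m, ds$pixels[, 1:3], seed = 5)
  expect_equal(dim(xh), c(36L, 3L))
  expect_true(all(xh >= 0 & xh <= 1))
  f <- withr::local_tempfile(fileext = ".pgm")
  write_pgm_grid(cbind(ds$pixels[, 1], xh[, 1]), 6, f)
  lines <- readLines(f)
  expect_equal(lines[1], "P2")
  expect_equal(lines[2], "13 6")  # two 6-wide tiles plus a 1-px gap
})
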