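# The simulate -> (optionally) update loop over one stimulus window.
# Everything the trainer, the evaluators and the reconstruction path do
# goes through run_window(), so learning and inference share one set of
# dynamics.

#' Simulate one stimulus window, optionally with plasticity
#'
#' Steps the full circuit (hidden LIF layers, local generative predictors,
#' classifier head) through `T_steps` integration steps. With
#' `learn = TRUE`, the CSDP updates (all samples), the generative updates
#' and the classifier updates (positive samples only) are computed at every
#' step and applied immediately through Adam, implementing online
#' adaptation within the window. Adaptive thresholds carry over into the
#' returned model (slow homeostasis); fast state starts from rest.
#'
#' @param model a `csdp_model` (see [csdp_init()]).
#' @param batch a `csdp_spike_batch` from [make_spike_batch()].
#' @param learn logical; apply plasticity?
#' @param clamp_class logical; feed the clamped label spikes into the
#'   network's class-modulation bundles (supervised training and the
#'   goodness scan do; evaluation does not).
#' @param collect character subset of `c("goodness", "counts", "smu0",
#'   "sL", "goodness_sum")` naming extra outputs to record.
#' @return List with the updated `model` plus, depending on `collect`:
#'   `goodness` (per-sample time/layer-averaged goodness probability),
#'   `loss` (per-sample sequence loss), `counts` (classifier spike counts
#'   `[C x B]`), `smu0` (bottom-predictor spike train `[J0, B, T]`),
#'   `sL` (top-layer spike train), `goodness_sum` (per-sample time-averaged
#'   summed squared traces, the goodness-scan score).
#' @export
run_window <- function(model, batch, learn = FALSE, clamp_class = NULL,
                       collect = character()) {
  config <- model$config
  params <- model$params
  L <- config$n_layers
  d <- dim(batch$sensory)
  J0 <- d[1]; B <- d[2]; T_steps <- d[3]
  if (is.null(clamp_class)) clamp_class <- config$supervised
  y_type <- rep_len(batch$y_type, B)
  pos <- which(y_type == 1)

  state <- init_network_state(config, B)
  state$v_thr <- model$thresholds$net
  pred <- init_predictor_state(config, B)
  for (l in seq_len(L)) pred[[l]]$v_thr <- model$thresholds$pred[l]
  cls <- init_classifier_state(config, B)
  cls$v_thr <- model$thresholds$cls

  cls_in <- if (clamp_class && config$supervised) batch$class_spikes
  want <- function(x) x %in% collect
  g_acc <- numeric(B); loss_acc <- numeric(B); gsum_acc <- numeric(B)
  smu0 <- if (want("smu0")) array(0, c(J0, B, T_steps))
  sL <- if (want("sL")) array(0, c(config$layer_sizes[L + 1L], B, T_steps))

  prev_s0 <- matrix(0, J0, B)
  for (k in seq_len(T_steps)) {
    s0_k <- batch$sensory[, , k, drop = FALSE]; dim(s0_k) <- c(J0, B)
    old <- state
    state <- step_network(state, s0_k, params, config, class_spikes = cls_in)
    new_pred <- lapply(seq_len(L), function(l)
      predict_layer(old$layers[[l]]$s, params[[l]]$G, pred[[l]], config))
    cls <- classify_step(lapply(old$layers, `[[`, "s"),
                         lapply(params, `[[`, "A"), cls, config)
    if (!learn) {
      # evaluation must not move the homeostats: thresholds stay at the
      # model's trained values (adaptation is training-time plasticity)
      state$v_thr <- model$thresholds$net
      cls$v_thr <- model$thresholds$cls
    }

    if (learn) {
      grads <- vector("list", L)
      for (l in seq_len(L)) {
        delta <- modulator(state$layers[[l]]$z, y_type, config$theta_z[l])
        state$layers[[l]]$delta <- delta
        u <- csdp_updates(
          delta, state$layers[[l]]$s,
          s_pre_below = if (l == 1L) prev_s0 else old$layers[[l - 1L]]$s,
          s_pre_above = if (l < L) old$layers[[l + 1L]]$s,
          s_pre_same  = old$layers[[l]]$s,
          class_pre   = if (!is.null(cls_in)) {
            if (k == 1L) cls_in * 0 else cls_in   # no history at the first step
          },
          config = config)
        if (length(pos)) {
          target <- if (l == 1L) s0_k else state$layers[[l - 1L]]$s
          e <- mismatch(new_pred[[l]]$s, target)
          u$G <- generative_update(e[, pos, drop = FALSE],
                                   old$layers[[l]]$s[, pos, drop = FALSE],
                                   config$R_E)
          if (!is.null(batch$class_spikes))
            u$A <- classifier_update(
              cls$mu[, pos, drop = FALSE],
              batch$class_spikes[, pos, drop = FALSE],
              list(old$layers[[l]]$s[, pos, drop = FALSE]),
              config$R_E)[[1]]
        }
        grads[[l]] <- u
      }
      st <- apply_updates(params, grads, model$opt)
      params <- st$params
      model$opt <- st$opt
    }

    if (want("goodness") || want("goodness_sum")) {
      traces <- lapply(state$layers, `[[`, "z")
      if (want("goodness")) {
        p_mean <- Reduce(`+`, lapply(seq_len(L), function(l)
          goodness_probability(traces[[l]], config$theta_z[l]))) / L
        g_acc <- g_acc + p_mean
        loss_acc <- loss_acc + total_goodness(traces, y_type, config)
      }
      if (want("goodness_sum"))
        gsum_acc <- gsum_acc +
          Reduce(`+`, lapply(traces, function(z) colSums(z * z)))
    }
    if (want("smu0")) smu0[, , k] <- new_pred[[1L]]$s
    if (want("sL")) sL[, , k] <- state$layers[[L]]$s

    pred <- new_pred
    prev_s0 <- s0_k
  }

  model$params <- params
  model$thresholds <- list(net = state$v_thr,
                           pred = vapply(pred, `[[`, numeric(1), "v_thr"),
                           cls = cls$v_thr)
  out <- list(model = model)
  if (want("goodness")) {
    out$goodness <- g_acc / T_steps
    out$loss <- loss_acc
  }
  if (want("goodness_sum")) out$goodness_sum <- gsum_acc / T_steps
  if (want("counts")) out$counts <- cls$counts
  if (want("smu0")) out$smu0 <- smu0
  if (want("sL")) out$sL <- sL
  out
}
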