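# Fast spiking classifier head: a C-unit LIF group driven by the spikes of
# every hidden layer through bundles A^l, trained with an error-driven
# Hebbian rule; plus the slow goodness-scan classifier and metrics.

#' Initialize the classifier head's state
#'
#' @param config a [csdp_config()].
#' @param batch_size batch width.
#' @return List with voltage `v` `[C x B]`, prediction spikes `mu`,
#'   accumulated spike `counts` and the scalar threshold `v_thr`.
#' @export
init_classifier_state <- function(config, batch_size = 1L) {
  z <- matrix(0, config$n_classes, batch_size)
  list(v = z, mu = z, counts = z, v_thr = config$v_thr_init)
}

#' Step the classifier subcircuit once
#'
#' The class voltage integrates the summed drive from every hidden layer,
#' `v_y' = v_y + (dt/tau_m)(-v_y + R_E sum_l A^l s^l)`, spikes with the
#' usual strict threshold and gated reset, adapts its threshold with the
#' same homeostatic rule as the main layers, and accumulates spike counts
#' over the window.
#'
#' @param hidden_spikes list of per-layer spike matrices `[J_l x B]`
#'   (previous-step values).
#' @param A list of classifier bundles `[C x J_l]`.
#' @param cls classifier state (see [init_classifier_state()]).
#' @param config a [csdp_config()].
#' @return Updated classifier state.
#' @export
classify_step <- function(hidden_spikes, A, cls, config) {
  drive <- Reduce(`+`, Map(function(Al, sl) Al %*% as_colmat(sl),
                           A, hidden_spikes))
  v_hat <- step_voltage(cls$v, config$R_E * drive, config)
  em <- emit_spikes(v_hat, cls$v_thr)
  list(v = em$v, mu = em$s, counts = cls$counts + em$s,
       v_thr = update_threshold(cls$v_thr, em$s, config))
}

#' Error-driven Hebbian update of the classifier bundles
#'
#' `dA^l = R_E (mu_y - s_y) s^l^T`, batch-averaged, read as a gradient.
#' Zero exactly when the prediction spikes equal the label spikes wherever
#' hidden spikes occur.
#'
#' @param mu_y prediction spikes `[C x B]` at the current step.
#' @param s_y clamped label spikes `[C x B]`.
#' @param hidden_spikes list of the driving layers' spikes `[J_l x B]`.
#' @param R_E excitatory resistance.
#' @return List of gradient matrices, one per hidden layer.
#' @export
classifier_update <- function(mu_y, s_y, hidden_spikes, R_E = 1) {
  err <- as_colmat(mu_y) - as_colmat(s_y)
  B <- ncol(err)
  lapply(hidden_spikes, function(sl) R_E * (err %*% t(as_colmat(sl))) / B)
}

#' Class distribution from accumulated classifier spikes
#'
#' Softmax over the per-class spike counts collected across the stimulus
#' window: the circuit's approximate output distribution.
#'
#' @param counts `[C x B]` accumulated spike counts (or a length-C vector).
#' @return `[C x B]` column-stochastic matrix.
#' @export
predict_distribution <- function(counts) {
  counts <- as_colmat(counts)
  e <- exp(sweep(counts, 2, apply(counts, 2, max)))
  sweep(e, 2, colSums(e), `/`)
}

#' Classification accuracy
#'
#' Fraction of samples whose predicted distribution puts its argmax on the
#' true class; ties broken by the lowest class index.
#'
#' @param Y one-hot label matrix `[C x N]` (or `[N x C]`, auto-detected
#'   only when unambiguous — pass classes-in-rows to be safe).
#' @param Y_hat predicted distributions, same orientation.
#' @return Fraction in \[0, 1\].
#' @export
accuracy <- function(Y, Y_hat) {
  Y <- as_colmat(Y); Y_hat <- as_colmat(Y_hat)
  if (!all(dim(Y) == dim(Y_hat)))
    stop("label and prediction shapes differ")
  mean(apply(Y, 2, which.max) == apply(Y_hat, 2, which.max))
}

#' Rate-code embedding of a spike train
#'
#' Time-averaged spike counts, `c = (gamma_c / T_steps) sum_t s(t)`: the
#' real-valued code used for visualizing/embedding the top layer's
#' representation.
#'
#' @param spike_train binary array `[J, B, T_steps]`.
#' @param gamma_c rate-code scale.
#' @return `[J x B]` matrix; with `gamma_c = 1`, values in \[0, 1\].
#' @export
rate_code <- function(spike_train, gamma_c = 1) {
  d <- dim(spike_train)
  m <- matrix(0, d[1], d[2])
  for (t in seq_len(d[3])) {
    s <- spike_train[, , t, drop = FALSE]; dim(s) <- d[1:2]
    m <- m + s
  }
  gamma_c * m / d[3]
}
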