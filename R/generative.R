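# Local spiking generative head: each layer l owns a bundle G^l that
# predicts the spikes of the layer below from its own spikes, with the same
# LIF dynamics as the main layers and an error-driven Hebbian update.

#' Initialize a predictor's state
#'
#' One predictor per hidden layer `l`, predicting layer `l - 1` (the
#' bottom predictor targets the sensory layer). State mirrors a LIF layer:
#' voltage, spikes and a (fixed) threshold of its own.
#'
#' @param config a [csdp_config()].
#' @param batch_size batch width.
#' @return List of per-layer predictor states.
#' @export
init_predictor_state <- function(config, batch_size = 1L) {
  J <- config$layer_sizes
  lapply(seq_len(config$n_layers), function(l) {
    z <- matrix(0, J[l], batch_size)       # predicts layer l-1 (size J[l])
    list(v = z, s = z, v_thr = config$v_thr_init)
  })
}

#' Step one local spiking predictor
#'
#' The same leaky integrate-and-fire dynamics as the main layers: leaky
#' voltage driven by `R_E G s_driver`, strict-threshold spiking with gated
#' reset. The predictor's threshold is fixed (at `v_thr_init`): the
#' homeostatic rule is a sparsity constraint on the representational
#' layers, whereas a predictor must be free to match its target layer's
#' activity level — for the bottom predictor that target is the sensory
#' image itself, with tens of active pixels, and a spikes-minus-one
#' homeostat ratchets its threshold up until reconstruction dies.
#'
#' @param s_driver previous-step spikes of the predicting layer `[J_l x B]`.
#' @param G generative bundle `[J_below x J_l]`.
#' @param pred predictor state (element of [init_predictor_state()]).
#' @param config a [csdp_config()].
#' @return Updated predictor state with fields `v`, `s`, `v_thr`.
#' @export
predict_layer <- function(s_driver, G, pred, config) {
  s_driver <- as_colmat(s_driver)
  if (ncol(G) != nrow(s_driver))
    stop("bundle G expects ", ncol(G), " presynaptic units, got ",
         nrow(s_driver))
  v_hat <- step_voltage(pred$v, config$R_E * (G %*% s_driver), config)
  em <- emit_spikes(v_hat, pred$v_thr)
  list(v = em$v, s = em$s, v_thr = pred$v_thr)
}

#' Prediction mismatch
#'
#' `e = s_mu - s`, elementwise in `{-1, 0, 1}`: +1 where the predictor
#' spiked but the target layer did not, -1 for the reverse.
#'
#' @param s_mu prediction spikes.
#' @param s target-layer spikes (same shape).
#' @return Mismatch matrix.
#' @export
mismatch <- function(s_mu, s) {
  if (!all(dim(as_colmat(s_mu)) == dim(as_colmat(s))))
    stop("prediction and target spike shapes differ")
  s_mu - s
}

#' Error-driven Hebbian update of a generative bundle
#'
#' `dG = R_E e s_driver^T`, batch-averaged, read as a gradient (pass to a
#' minimizing optimizer). Zero exactly when predictions match the target
#' layer.
#'
#' @param e mismatch `[J_below x B]` at the current step.
#' @param s_driver the driving layer's spikes `[J_l x B]` (the ones that
#'   produced the prediction).
#' @param R_E excitatory resistance.
#' @return Gradient matrix `[J_below x J_l]`.
#' @export
generative_update <- function(e, s_driver, R_E = 1) {
  e <- as_colmat(e); s_driver <- as_colmat(s_driver)
  R_E * (e %*% t(s_driver)) / ncol(e)
}

#' Clipped-trace average of a prediction spike train
#'
#' Turns the bottom predictor's spike train into a graded image: the trace
#' follows `z' = z + (dt/tau_tr) * (-z * (1 - s_mu)) + s_mu`, hard-clipped
#' to \[0, 1\] at every step, and the reconstruction is the time average
#' of the trace over the window.
#'
#' @param s_mu_train binary array `[J0, B, T_steps]` of prediction spikes.
#' @param config a [csdp_config()].
#' @return `[J0 x B]` matrix with values in \[0, 1\].
#' @export
reconstruction_trace <- function(s_mu_train, config) {
  d <- dim(s_mu_train)
  z <- matrix(0, d[1], d[2])
  acc <- matrix(0, d[1], d[2])
  a <- config$dt / config$tau_tr
  for (t in seq_len(d[3])) {
    s <- s_mu_train[, , t, drop = FALSE]
    dim(s) <- d[1:2]
    z <- pmin(pmax(z + a * (-z * (1 - s)) + s, 0), 1)
    acc <- acc + z
  }
  acc / d[3]
}

#' Binary cross-entropy of a reconstruction (nats)
#'
#' `BCE = -sum_i [x_i log xhat_i + (1 - x_i) log(1 - xhat_i)]`, summed
#' over pixels and averaged over samples; the reconstruction is clipped to
#' `[eps, 1 - eps]` before taking logs.
#'
#' @param x_hat reconstruction `[J0 x B]` in \[0, 1\].
#' @param x target intensities, same shape.
#' @param eps log guard.
#' @return Mean per-sample BCE in nats.
#' @export
reconstruction_bce <- function(x_hat, x, eps = 1e-7) {
  x_hat <- as_colmat(x_hat); x <- as_colmat(x)
  if (!all(dim(x_hat) == dim(x)))
    stop("reconstruction and target shapes differ")
  x_hat <- pmin(pmax(x_hat, eps), 1 - eps)
  mean(colSums(-(x * log(x_hat) + (1 - x) * log(1 - x_hat))))
}
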