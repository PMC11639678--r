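# Core leaky integrate-and-fire dynamics. All per-layer quantities are
# matrices [J x B] (one column per batch sample); plain vectors are accepted
# and treated as single-column batches.

as_colmat <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 1L)

# M with its diagonal zeroed: lateral synapses give cross-inhibition only.
hollow <- function(M) { diag(M) <- 0; M }

#' Electrical current into one layer
#'
#' Sums bottom-up, top-down, lateral-inhibitory and (optionally)
#' class-modulating synaptic drive, all read from the previous step's spike
#' vectors of the neighbouring layers:
#' `j = R_E W s_below + R_E V s_above - R_I (M * (1-I)) s_same + R_E B s_y`.
#' The lateral matrix is applied hollow (zero diagonal), so a neuron never
#' inhibits itself.
#'
#' @param s_below spikes of the layer below (the sensory spike vector for
#'   the first hidden layer), `[J_below x B]`.
#' @param s_above spikes of the layer above, or `NULL` at the top layer.
#' @param s_same this layer's own previous spikes `[J x B]`.
#' @param params the layer's synaptic bundles (list with `W`, `V`, `M`,
#'   optionally `B`).
#' @param config a [csdp_config()].
#' @param class_spikes clamped one-hot label spikes `[C x B]`, or `NULL`.
#' @return Current matrix `[J x B]`.
#' @export
compute_current <- function(s_below, s_above, s_same, params, config,
                            class_spikes = NULL) {
  s_below <- as_colmat(s_below); s_same <- as_colmat(s_same)
  if (ncol(params$W) != nrow(s_below))
    stop("bundle W expects ", ncol(params$W), " presynaptic units, got ",
         nrow(s_below))
  if (nrow(params$M) != nrow(s_same))
    stop("bundle M expects ", nrow(params$M), " lateral units, got ",
         nrow(s_same))
  j <- config$R_E * (params$W %*% s_below) -
       config$R_I * (hollow(params$M) %*% s_same)
  if (!is.null(s_above)) {
    s_above <- as_colmat(s_above)
    if (is.null(params$V)) stop("bundle V absent but top-down spikes supplied")
    if (ncol(params$V) != nrow(s_above))
      stop("bundle V expects ", ncol(params$V), " presynaptic units, got ",
           nrow(s_above))
    j <- j + config$R_E * (params$V %*% s_above)
  }
  if (!is.null(class_spikes) && !is.null(params$B)) {
    class_spikes <- as_colmat(class_spikes)
    if (ncol(params$B) != nrow(class_spikes))
      stop("bundle B expects ", ncol(params$B), " class channels, got ",
           nrow(class_spikes))
    j <- j + config$R_E * (params$B %*% class_spikes)
  }
  j
}

#' Leaky membrane voltage update
#'
#' `v_hat = v + (dt/tau_m) * (-v + j)`: the membrane integrates current and
#' decays toward the resting potential 0.
#'
#' @param v current voltage, `j` injected current (same shape), `config` a
#'   [csdp_config()].
#' @param j injected current.
#' @param config a [csdp_config()].
#' @return Candidate voltage before spike emission.
#' @export
step_voltage <- function(v, j, config) {
  v + (config$dt / config$tau_m) * (-v + j)
}

#' Spike emission with depolarization reset
#'
#' A neuron spikes when its candidate voltage strictly exceeds the layer
#' threshold; spiking neurons are reset to the resting potential through
#' binary gating: `s = (v_hat > v_thr)`, `v = v_hat * (1 - s)`.
#'
#' @param v_hat candidate voltage.
#' @param v_thr nonnegative threshold (scalar).
#' @return List with binary `s` and reset voltage `v`.
#' @export
emit_spikes <- function(v_hat, v_thr) {
  s <- (v_hat > v_thr) * 1
  list(s = s, v = v_hat * (1 - s))
}

#' Homeostatic adaptive-threshold update
#'
#' The per-layer scalar threshold drifts up when the layer emits more than
#' one spike per step and down otherwise, clipped at zero:
#' `v_thr' = max(0, v_thr + lambda_v * (sum(s) - 1))`. For a batch the
#' increment uses the batch-mean spike count, so homeostasis is
#' batch-size independent.
#'
#' @param v_thr current threshold (scalar >= 0).
#' @param s the layer's spikes `[J x B]` at the new step.
#' @param config a [csdp_config()].
#' @return Updated threshold.
#' @export
update_threshold <- function(v_thr, s, config) {
  s <- as_colmat(s)
  max(0, v_thr + config$lambda_v * (mean(colSums(s)) - 1))
}

#' Activation trace update
#'
#' Low-pass filter of the spike train, a stand-in for intracellular calcium:
#' `z' = z + (dt/tau_tr) * (-z + gamma * s)`. With `dt = tau_tr` the trace
#' reduces to `gamma * s`; its fixed point under sustained spiking is
#' `gamma`.
#'
#' @param z current trace (nonnegative).
#' @param s spikes at the new step.
#' @param config a [csdp_config()].
#' @return Updated trace.
#' @export
update_trace <- function(z, s, config) {
  z + (config$dt / config$tau_tr) * (-z + config$gamma * s)
}

# Zeroed fast state for one layer and batch width B.
init_layer_state <- function(J, B) {
  z <- matrix(0, J, B)
  list(j = z, v = z, s = z, z = z, delta = z)
}

#' Initialize the network's fast state
#'
#' Fast variables (current, voltage, spikes, trace, modulator) start at
#' zero for every new stimulus window; the adaptive thresholds start at
#' `v_thr_init` and are meant to persist across patterns (slow
#' homeostasis).
#'
#' @param config a [csdp_config()].
#' @param batch_size number of samples simulated in parallel.
#' @return A `csdp_state`: list with `layers` (per-layer fast variables)
#'   and `v_thr` (one scalar per hidden layer).
#' @export
init_network_state <- function(config, batch_size = 1L) {
  J <- config$layer_sizes
  structure(list(
    layers = lapply(seq_len(config$n_layers),
                    function(l) init_layer_state(J[l + 1L], batch_size)),
    v_thr = rep(config$v_thr_init, config$n_layers)
  ), class = "csdp_state")
}

#' Advance every layer by one time step, fully in parallel
#'
#' Each layer's new state is computed from the time-`t` spikes of its
#' neighbours only (the layer-parallel contract), so the result is
#' bit-identical for any evaluation order of the layers. Within a layer the
#' order is current, voltage, spike/reset, threshold, trace.
#'
#' @param state a `csdp_state` at time t (see [init_network_state()]).
#' @param s0_t sensory spike slice `[J0 x B]` for this step.
#' @param params network parameters (see [init_params()]).
#' @param config a [csdp_config()].
#' @param class_spikes clamped one-hot label spikes `[C x B]`, or `NULL`;
#'   only used when the configuration is supervised.
#' @param layer_order permutation of `1..L` in which layers are evaluated;
#'   exposed to make the order-invariance contract testable.
#' @return The `csdp_state` at time t + dt.
#' @export
step_network <- function(state, s0_t, params, config, class_spikes = NULL,
                         layer_order = seq_len(config$n_layers)) {
  L <- config$n_layers
  old <- state$layers
  new <- old
  v_thr <- state$v_thr
  for (l in layer_order) {
    s_below <- if (l == 1L) s0_t else old[[l - 1L]]$s
    s_above <- if (l < L) old[[l + 1L]]$s else NULL
    j <- compute_current(s_below, s_above, old[[l]]$s, params[[l]], config,
                         class_spikes = if (config$supervised) class_spikes)
    v_hat <- step_voltage(old[[l]]$v, j, config)
    em <- emit_spikes(v_hat, v_thr[l])
    v_thr[l] <- update_threshold(state$v_thr[l], em$s, config)
    new[[l]] <- list(j = j, v = em$v, s = em$s,
                     z = update_trace(old[[l]]$z, em$s, config),
                     delta = old[[l]]$delta)
  }
  structure(list(layers = new, v_thr = v_thr), class = "csdp_state")
}
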