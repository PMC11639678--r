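#' Network configuration for a CSDP spiking circuit
#'
#' Collects every constant of the simulator: integration step, membrane and
#' trace time constants, the goodness threshold, homeostasis and decay rates,
#' resistances, the stimulus window, layer sizes and the class count.
#'
#' Defaults follow the reference operating point of the model: `dt = 3` ms,
#' `tau_tr = 3` ms, `gamma = 0.05`, `gamma_c = 1`, `theta_z = 10`,
#' `lambda_v = 0.001`, `lambda_d = 5e-5`, stimulus window `T_ms` in
#' \[90, 150\] ms. The membrane time constant, the resistances and the
#' initial threshold are not pinned by that operating point and default to
#' `tau_m = 30` ms (ten integration steps), `R_E = R_I = 1` and
#' `v_thr_init = 1`; all are configurable.
#'
#' `theta_z` may be a single number (shared by all hidden layers) or a vector
#' with one entry per hidden layer. The goodness sum of a layer of `J`
#' neurons is bounded by `J * gamma^2` (the trace saturates at `gamma`), so
#' for narrow layers the reference `theta_z = 10` leaves the goodness
#' probability pinned near zero; see [calibrate_goodness()] for a
#' width-aware setting.
#'
#' @param layer_sizes integer vector `c(J0, J1, ..., JL)`: input width
#'   followed by the hidden layer widths. At least one hidden layer.
#' @param n_classes number of classes `C` (>= 1).
#' @param supervised logical; if `TRUE` the circuit carries class-modulation
#'   synapses `B` and is driven by clamped label spikes during training.
#' @param dt integration step (ms).
#' @param tau_m membrane time constant (ms).
#' @param tau_tr trace time constant (ms).
#' @param gamma trace increment per spike (dimensionless).
#' @param gamma_c rate-code scale.
#' @param theta_z goodness threshold(s); scalar or one value per hidden layer.
#' @param lambda_v adaptive-threshold (homeostasis) rate.
#' @param lambda_d synaptic decay factor in the plasticity rule.
#' @param R_E,R_I excitatory and inhibitory resistance constants.
#' @param T_ms stimulus window (ms); must be a multiple of `dt`.
#' @param v_thr_init initial value of every adaptive threshold.
#'
#' @return An object of class `csdp_config` (a named list).
#' @examples
#' cfg <- csdp_config(c(144, 64, 32), n_classes = 2)
#' stimulus_steps(cfg)
#' @export
csdp_config <- function(layer_sizes, n_classes,
                        supervised = TRUE,
                        dt = 3, tau_m = 30, tau_tr = 3,
                        gamma = 0.05, gamma_c = 1, theta_z = 10,
                        lambda_v = 0.001, lambda_d = 5e-5,
                        R_E = 1, R_I = 1,
                        T_ms = 90, v_thr_init = 1) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L))
    stop("layer_sizes must give the input width and at least one hidden layer, all >= 1")
  if (dt <= 0 || tau_m <= 0 || tau_tr <= 0 || T_ms <= 0)
    stop("dt, tau_m, tau_tr and T_ms must be positive")
  if (any(theta_z <= 0)) stop("theta_z must be positive")
  n_hidden <- length(layer_sizes) - 1L
  if (!length(theta_z) %in% c(1L, n_hidden))
    stop("theta_z must be a scalar or have one value per hidden layer")
  cfg <- structure(list(
    layer_sizes = layer_sizes,
    n_layers    = n_hidden,
    n_classes   = as.integer(n_classes),
    supervised  = isTRUE(supervised),
    dt = dt, tau_m = tau_m, tau_tr = tau_tr,
    gamma = gamma, gamma_c = gamma_c,
    theta_z = rep_len(as.numeric(theta_z), n_hidden),
    lambda_v = lambda_v, lambda_d = lambda_d,
    R_E = R_E, R_I = R_I,
    T_ms = T_ms, v_thr_init = v_thr_init
  ), class = "csdp_config")
  stimulus_steps(cfg)  # validates divisibility early
  cfg
}

#' Number of simulation steps in the stimulus window
#'
#' @param config a [csdp_config()] object.
#' @return Integer `T_ms / dt`.
#' @examples
#' stimulus_steps(csdp_config(c(4, 2), 2, T_ms = 90, dt = 3))  # 30
#' @export
stimulus_steps <- function(config) {
  steps <- config$T_ms / config$dt
  if (abs(steps - round(steps)) > 1e-9)
    stop("stimulus window T_ms = ", config$T_ms,
         " is not a multiple of dt = ", config$dt)
  as.integer(round(steps))
}

#' Calibrate the goodness threshold to the spiking operating point
#'
#' Each spike contributes `gamma^2` to a layer's goodness sum (the
#' activation trace saturates at `gamma`), and the homeostatic threshold
#' rule drives every layer toward emitting on the order of one spike per
#' step. For the goodness probability `sigmoid(sum(z^2) - theta_z)` to be
#' responsive — rather than pinned at `sigmoid(-theta_z)` — the threshold
#' must sit near that operating point: this helper sets
#' `theta_z = target_spikes * gamma^2`, so the probability crosses 0.5
#' when `target_spikes` neurons of a layer are persistently active.
#'
#' For the contrastive gradient to be useful, the per-spike increment
#' `gamma^2` must also be of order 1 on the sigmoid's natural scale:
#' desk-scale networks (layers of tens of neurons, a handful of spikes per
#' step) should run with `gamma` near 1, whereas layers of thousands of
#' neurons sustaining thousands of spikes can afford a small `gamma` with
#' a correspondingly large `theta_z`.
#'
#' @param config a [csdp_config()] object.
#' @param target_spikes spikes per layer per step at which the goodness
#'   probability should cross 0.5 (default 1, the homeostatic set point).
#' @return The configuration with `theta_z` recalibrated.
#' @examples
#' cfg <- csdp_config(c(144, 64, 32), 2, gamma = 1)
#' calibrate_goodness(cfg)$theta_z  # 1
#' @export
calibrate_goodness <- function(config, target_spikes = 1) {
  stopifnot(inherits(config, "csdp_config"), target_spikes > 0)
  config$theta_z <- rep_len(target_spikes * config$gamma^2, config$n_layers)
  config
}

#' @export
print.csdp_config <- function(x, ...) {
  cat("<csdp_config> ", paste(x$layer_sizes, collapse = "-"),
      if (x$supervised) " (supervised)" else " (unsupervised)", "\n", sep = "")
  cat("  C = ", x$n_classes,
      ", T = ", x$T_ms, " ms in steps of ", x$dt,
      " ms (", stimulus_steps(x), " steps)\n", sep = "")
  cat("  tau_m = ", x$tau_m, ", tau_tr = ", x$tau_tr,
      ", gamma = ", x$gamma,
      ", theta_z = ", paste(signif(x$theta_z, 4), collapse = "/"), "\n", sep = "")
  cat("  lambda_v = ", x$lambda_v, ", lambda_d = ", x$lambda_d,
      ", R_E = ", x$R_E, ", R_I = ", x$R_I, "\n", sep = "")
  invisible(x)
}

# Derive a 31-bit child seed from a parent seed and stream indices, so each
# batch/epoch gets its own reproducible RNG stream.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  as.integer(s)
}
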