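# Contrastive signal-dependent plasticity: layer-local goodness, its
# logistic loss, the per-neuron modulator, and the four Hebbian-like
# synaptic updates it drives.

# log(1 + exp(x)) without overflow
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Goodness probability of a layer
#'
#' The probability a layer assigns to its input being in-distribution:
#' a logistic function of how far the layer's summed squared activation
#' traces sit above the goodness threshold,
#' `p = sigmoid(sum(z^2) - theta_z)`.
#'
#' @param z trace vector `[J]` or matrix `[J x B]` (one column per sample).
#' @param theta_z goodness threshold for this layer (scalar).
#' @return Probability per sample (length-B vector).
#' @examples
#' goodness_probability(rep(0, 4), theta_z = 10)  # sigmoid(-10)
#' @export
goodness_probability <- function(z, theta_z) {
  z <- as_colmat(z)
  p <- stats::plogis(colSums(z * z) - theta_z)
  # strictly inside (0, 1) even when the sigmoid saturates in floating point
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' Layer-local contrastive loss
#'
#' Binary cross-entropy of the goodness probability against the sample
#' type: `-[y log p + (1-y) log(1-p)]`, evaluated in overflow-safe
#' softplus form. Positive samples (`y_type = 1`) are pushed toward high
#' goodness, negative samples toward low goodness.
#'
#' @param z trace vector or `[J x B]` matrix.
#' @param y_type 1 for positive (in-distribution) samples, 0 for negative;
#'   scalar or length-B vector.
#' @param theta_z goodness threshold.
#' @return Loss per sample (nonnegative).
#' @export
contrastive_loss <- function(z, y_type, theta_z) {
  z <- as_colmat(z)
  a <- colSums(z * z) - theta_z
  y <- rep_len(y_type, ncol(z))
  # -log p = softplus(-a); -log(1-p) = softplus(a)
  softplus(ifelse(y == 1, -a, a))
}

#' CSDP modulator: gradient of the contrastive loss in the traces
#'
#' The per-neuron modulatory signal `delta_i = dC/dz_i`, which in closed
#' form is `2 z_i (p - y_type)`; the closed form is pinned against a
#' central-finite-difference oracle in the test suite. For positive samples
#' it points opposite the trace (raising goodness), for negative samples
#' along it.
#'
#' @inheritParams contrastive_loss
#' @return Matrix (or vector) shaped like `z`.
#' @export
modulator <- function(z, y_type, theta_z) {
  zc <- as_colmat(z)
  p <- goodness_probability(zc, theta_z)
  y <- rep_len(y_type, ncol(zc))
  d <- 2 * zc * rep(p - y, each = nrow(zc))
  if (is.matrix(z)) d else as.vector(d)
}

#' CSDP synaptic updates for one layer
#'
#' The four modulated Hebbian-like rules. For the bottom-up bundle:
#' `dW_ij = R_E delta_i s_j^below(t-dt) + lambda_d s_i(t) (1 - s_j^below(t-dt))`,
#' and analogously for the top-down bundle `V` (presynaptic = layer above),
#' the lateral bundle `M` (leading factor `R_I`, presynaptic = same layer)
#' and the class bundle `B` (presynaptic = clamped label spikes).
#' Presynaptic spikes are the previous step's values; the modulator and the
#' postsynaptic spikes are current-step values. Updates are averaged over
#' the batch and are to be read as gradients of the contrastive objective
#' (pass them to a minimizing optimizer; flipping the sign inverts
#' learning).
#'
#' @param delta modulator `[J x B]` at the current step.
#' @param s_post this layer's spikes `[J x B]` at the current step.
#' @param s_pre_below previous-step spikes of the layer below (zeros at the
#'   first step of a window, when no history exists).
#' @param s_pre_above previous-step spikes of the layer above, or `NULL`
#'   at the top layer.
#' @param s_pre_same previous-step spikes of this layer.
#' @param class_pre previous-step clamped label spikes `[C x B]`, or
#'   `NULL` in unsupervised mode.
#' @param config a [csdp_config()].
#' @return List with `W`, `V` (or `NULL`), `M`, `B` (or `NULL`) gradient
#'   matrices shaped like the bundles.
#' @export
csdp_updates <- function(delta, s_post, s_pre_below, s_pre_above,
                         s_pre_same, class_pre, config) {
  delta <- as_colmat(delta); s_post <- as_colmat(s_post)
  B <- ncol(delta)
  pair <- function(pre, lead) {
    pre <- as_colmat(pre)
    if (ncol(pre) != B) stop("presynaptic history has wrong batch width")
    (lead * (delta %*% t(pre)) +
       config$lambda_d * (s_post %*% t(1 - pre))) / B
  }
  list(
    W = pair(s_pre_below, config$R_E),
    V = if (!is.null(s_pre_above)) pair(s_pre_above, config$R_E),
    M = pair(s_pre_same, config$R_I),
    B = if (!is.null(class_pre)) pair(class_pre, config$R_E)
  )
}

#' Total goodness loss across layers, and over a window
#'
#' `total_goodness()` sums the per-layer contrastive losses at one step,
#' `F(t) = sum_l C(z_l(t), y_type)`; `sequence_loss()` sums `F(t)` over a
#' trajectory of trace snapshots. Both are monitoring quantities — the
#' plasticity itself is purely local.
#'
#' @param traces list of per-layer trace matrices `[J_l x B]`.
#' @param y_type sample types (scalar or length-B).
#' @param config a [csdp_config()].
#' @return Per-sample total loss (length-B vector).
#' @export
total_goodness <- function(traces, y_type, config) {
  Reduce(`+`, lapply(seq_along(traces), function(l)
    contrastive_loss(traces[[l]], y_type, config$theta_z[l])))
}

#' @rdname total_goodness
#' @param trajectory list over time steps, each a list of per-layer trace
#'   matrices.
#' @export
sequence_loss <- function(trajectory, y_type, config) {
  Reduce(`+`, lapply(trajectory, total_goodness, y_type = y_type,
                     config = config))
}
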