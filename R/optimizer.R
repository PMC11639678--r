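# Parameter initialization, the Adam optimizer and the hard range
# constraints enforced after every step: W/V/B/G/A in [-1, 1], lateral M
# in [0, 1].

#' Initialize all synaptic bundles
#'
#' Per hidden layer `l`: bottom-up `W` `[J_l x J_{l-1}]`, top-down `V`
#' `[J_l x J_{l+1}]` (absent at the top layer), lateral `M` `[J_l x J_l]`,
#' class-modulation `B` `[J_l x C]` (supervised only), generative `G`
#' `[J_{l-1} x J_l]` and classifier `A` `[C x J_l]`. `W`, `V`, `B`, `G`,
#' `A` are drawn from `U(-1, 1)`; the lateral `M` from `U(0, 1)`.
#'
#' @param config a [csdp_config()].
#' @param seed RNG seed; initialization is deterministic given the seed.
#' @return List of per-layer bundle lists, class `csdp_params`.
#' @export
init_params <- function(config, seed = 1L) {
  set.seed(as.integer(seed))
  J <- config$layer_sizes; L <- config$n_layers; C <- config$n_classes
  runi <- function(r, c, lo = -1) matrix(stats::runif(r * c, lo, 1), r, c)
  params <- lapply(seq_len(L), function(l) {
    list(
      W = runi(J[l + 1], J[l]),
      V = if (l < L) runi(J[l + 1], J[l + 2]),
      M = runi(J[l + 1], J[l + 1], lo = 0),
      B = if (config$supervised) runi(J[l + 1], C),
      G = runi(J[l], J[l + 1]),
      A = runi(C, J[l + 1])
    )
  })
  structure(params, class = "csdp_params")
}

# Range constraints: lateral synapses nonnegative, everything else in
# [-1, 1]. Enforced after every optimizer step.
clip_bundle <- function(x, name) {
  if (name == "M") pmin(pmax(x, 0), 1) else pmin(pmax(x, -1), 1)
}

#' Initialize Adam state for a parameter set
#'
#' @param params a `csdp_params` object.
#' @param eta step size (reference value 0.002).
#' @param beta1,beta2 moment decay constants.
#' @param eps numerical guard.
#' @return An opaque optimizer-state list.
#' @export
adam_init <- function(params, eta = 0.002, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  zeros <- lapply(params, function(lp)
    lapply(lp, function(m) if (is.null(m)) NULL else m * 0))
  list(m = zeros, v = zeros, t = 0L,
       eta = eta, beta1 = beta1, beta2 = beta2, eps = eps)
}

#' Apply one Adam step and re-clip the parameters
#'
#' Standard bias-corrected adaptive-moment descent, treating the supplied
#' update tensors as gradients to be minimized; afterwards every bundle is
#' clipped back to its declared range (`M` to \[0, 1\], the rest to
#' \[-1, 1\]) — the truncation is enforced throughout training.
#'
#' @param params a `csdp_params` object.
#' @param grads nested list mirroring `params` (missing/`NULL` entries are
#'   skipped; their moments decay).
#' @param opt optimizer state from [adam_init()].
#' @return List with updated `params` and `opt`.
#' @export
apply_updates <- function(params, grads, opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (l in seq_along(params)) {
    for (nm in names(params[[l]])) {
      p <- params[[l]][[nm]]
      if (is.null(p)) next
      g <- grads[[l]][[nm]]
      if (is.null(g)) g <- p * 0
      if (any(!is.finite(g)))
        stop("non-finite update for bundle ", nm, " of layer ", l)
      m <- opt$beta1 * opt$m[[l]][[nm]] + (1 - opt$beta1) * g
      v <- opt$beta2 * opt$v[[l]][[nm]] + (1 - opt$beta2) * g * g
      p <- p - opt$eta * (m / bc1) / (sqrt(v / bc2) + opt$eps)
      opt$m[[l]][[nm]] <- m
      opt$v[[l]][[nm]] <- v
      params[[l]][[nm]] <- clip_bundle(p, nm)
    }
  }
  list(params = params, opt = opt)
}

# TRUE iff every bundle satisfies its range constraint.
params_in_range <- function(params, tol = 0) {
  all(vapply(params, function(lp) {
    all(vapply(names(lp), function(nm) {
      x <- lp[[nm]]
      if (is.null(x)) return(TRUE)
      lo <- if (nm == "M") 0 else -1
      all(x >= lo - tol & x <= 1 + tol)
    }, logical(1)))
  }, logical(1)))
}
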