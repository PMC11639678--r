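# Independent scalar reference implementation of the circuit dynamics and
# the plasticity rules, written as explicit loops over neurons and
# presynaptic units. Used to pin the vectorized implementation.

oracle_init_state <- function(cfg, B) {
  lst <- lapply(seq_len(cfg$n_layers), function(l) {
    J <- cfg$layer_sizes[l + 1]
    z <- matrix(0, J, B)
    list(j = z, v = z, s = z, z = z)
  })
  list(layers = lst, v_thr = rep(cfg$v_thr_init, cfg$n_layers))
}

# One step of the layer-parallel dynamics: currents by scalar triple loops,
# then voltage, strict-threshold spike with gated reset, homeostatic
# threshold (batch-mean), trace.
oracle_step <- function(st, s0, params, cfg, s_y = NULL) {
  L <- cfg$n_layers
  B <- ncol(s0)
  new <- st
  for (l in seq_len(L)) {
    J <- cfg$layer_sizes[l + 1]
    jmat <- matrix(0, J, B)
    s_below <- if (l == 1) s0 else st$layers[[l - 1]]$s
    for (b in seq_len(B)) {
      for (i in seq_len(J)) {
        acc <- 0
        for (k in seq_len(nrow(s_below)))
          acc <- acc + cfg$R_E * params[[l]]$W[i, k] * s_below[k, b]
        if (l < L) {
          sa <- st$layers[[l + 1]]$s
          for (k in seq_len(nrow(sa)))
            acc <- acc + cfg$R_E * params[[l]]$V[i, k] * sa[k, b]
        }
        ss <- st$layers[[l]]$s
        for (k in seq_len(J))
          if (k != i) acc <- acc - cfg$R_I * params[[l]]$M[i, k] * ss[k, b]
        if (!is.null(s_y) && !is.null(params[[l]]$B))
          for (k in seq_len(nrow(s_y)))
            acc <- acc + cfg$R_E * params[[l]]$B[i, k] * s_y[k, b]
        jmat[i, b] <- acc
      }
    }
    v_hat <- matrix(0, J, B)
    smat <- matrix(0, J, B)
    v_res <- matrix(0, J, B)
    for (b in seq_len(B)) for (i in seq_len(J)) {
      v_hat[i, b] <- st$layers[[l]]$v[i, b] +
        (cfg$dt / cfg$tau_m) * (-st$layers[[l]]$v[i, b] + jmat[i, b])
      smat[i, b] <- if (v_hat[i, b] > st$v_thr[l]) 1 else 0
      v_res[i, b] <- v_hat[i, b] * (1 - smat[i, b])
    }
    new$v_thr[l] <- max(0, st$v_thr[l] +
                          cfg$lambda_v * (mean(colSums(smat)) - 1))
    znew <- matrix(0, J, B)
    for (b in seq_len(B)) for (i in seq_len(J))
      znew[i, b] <- st$layers[[l]]$z[i, b] +
        (cfg$dt / cfg$tau_tr) * (-st$layers[[l]]$z[i, b] +
                                   cfg$gamma * smat[i, b])
    new$layers[[l]] <- list(j = jmat, v = v_res, s = smat, z = znew)
  }
  new
}

# Scalar reference of one synaptic-change tensor:
# d_ij = mean_b [lead * delta_i * pre_j + lambda_d * s_post_i * (1 - pre_j)]
oracle_pair_update <- function(delta, s_post, pre, lead, lambda_d) {
  J <- nrow(delta); K <- nrow(pre); B <- ncol(delta)
  out <- matrix(0, J, K)
  for (i in seq_len(J)) for (k in seq_len(K)) {
    acc <- 0
    for (b in seq_len(B))
      acc <- acc + lead * delta[i, b] * pre[k, b] +
        lambda_d * s_post[i, b] * (1 - pre[k, b])
    out[i, k] <- acc / B
  }
  out
}

oracle_updates <- function(delta, s_post, pre_below, pre_above, pre_same,
                           class_pre, cfg) {
  list(
    W = oracle_pair_update(delta, s_post, pre_below, cfg$R_E, cfg$lambda_d),
    V = if (!is.null(pre_above))
      oracle_pair_update(delta, s_post, pre_above, cfg$R_E, cfg$lambda_d),
    M = oracle_pair_update(delta, s_post, pre_same, cfg$R_I, cfg$lambda_d),
    B = if (!is.null(class_pre))
      oracle_pair_update(delta, s_post, class_pre, cfg$R_E, cfg$lambda_d)
  )
}

# Random toy instance: layer sizes <= max_width, random params within their
# declared ranges, random binary spike states.
random_toy <- function(seed, max_width = 8, supervised = TRUE) {
  set.seed(seed)
  L <- sample(1:3, 1)
  sizes <- sample(2:max_width, L + 1, replace = TRUE)
  cfg <- csdp_config(sizes, n_classes = sample(2:4, 1),
                     supervised = supervised,
                     gamma = runif(1, 0.05, 1),
                     theta_z = runif(1, 0.5, 10),
                     R_E = runif(1, 0.5, 2), R_I = runif(1, 0.5, 2),
                     lambda_v = 0.001, v_thr_init = runif(1, 0.2, 1))
  params <- init_params(cfg, seed = seed + 1)
  list(cfg = cfg, params = params)
}

rand_spikes <- function(J, B, p = 0.4) matrix(rbinom(J * B, 1, p), J, B)
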