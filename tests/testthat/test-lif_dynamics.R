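# LIF circuit dynamics: current composition, voltage, spiking/reset,
# homeostatic threshold, trace, and the layer-parallel stepping contract.

toy_cfg <- function(...) csdp_config(c(3, 3, 2), 2, T_ms = 9, ...)

test_that("current sums bottom-up, top-down and hollow lateral drive", {
  cfg <- toy_cfg(R_E = 2, R_I = 3)
  p <- list(W = matrix(1:9 / 10, 3, 3), V = matrix(1:6 / 10, 3, 2),
            M = matrix(0.5, 3, 3), B = NULL)
  zero3 <- rep(0, 3)
  expect_equal(as.vector(compute_current(zero3, rep(0, 2), zero3, p, cfg)),
               rep(0, 3))
  # single presynaptic spike reads one column of W, scaled by R_E
  j <- compute_current(c(0, 1, 0), NULL, zero3,
                       list(W = p$W, V = NULL, M = p$M), cfg)
  expect_equal(as.vector(j), 2 * p$W[, 2])
  # a spiking neuron receives no lateral inhibition from itself
  diag(p$M) <- 100
  j <- compute_current(zero3, rep(0, 2), c(1, 0, 0), p, cfg)
  expect_equal(as.vector(j), -3 * c(0, 0.5, 0.5))
})

test_that("dimension mismatches name the offending bundle", {
  cfg <- toy_cfg()
  p <- list(W = matrix(0, 3, 3), V = matrix(0, 3, 2), M = matrix(0, 3, 3))
  expect_error(compute_current(rep(0, 4), NULL, rep(0, 3), p, cfg), "bundle W")
  expect_error(compute_current(rep(0, 3), rep(0, 5), rep(0, 3), p, cfg),
               "bundle V")
  expect_error(compute_current(rep(0, 3), NULL, rep(0, 2), p, cfg), "bundle M")
})

test_that("voltage follows the leaky-integrator recurrence", {
  cfg <- toy_cfg()
  expect_equal(step_voltage(0, 0, cfg), 0)
  cfg_eq <- csdp_config(c(3, 2), 2, tau_m = 3, dt = 3, T_ms = 9)
  expect_equal(step_voltage(c(0.4, -1), c(2, 5), cfg_eq), c(2, 5))  # dt = tau_m
  cfg_01 <- csdp_config(c(3, 2), 2, tau_m = 30, dt = 3, T_ms = 90)
  expect_equal(step_voltage(1, 0, cfg_01), 0.9)
})

test_that("spiking is strict and always resets the spiking neurons", {
  em <- emit_spikes(c(1, 2, 0), v_thr = 1)
  expect_equal(em$s, c(0, 1, 0))       # v_hat == v_thr does not spike
  expect_equal(em$v, c(1, 0, 0))
  set.seed(5)
  for (rep in 1:20) {
    v_hat <- matrix(rnorm(12), 3, 4)
    em <- emit_spikes(v_hat, v_thr = 0.3)
    expect_true(all(em$v * em$s == 0))  # reset invariant
    expect_true(all(em$s %in% c(0, 1)))
  }
})

test_that("the homeostatic threshold drifts with spike count and stays >= 0", {
  cfg <- csdp_config(c(3, 12), 2, lambda_v = 0.001, T_ms = 9)
  expect_equal(update_threshold(0.7, c(1, rep(0, 11)), cfg), 0.7)  # one spike
  expect_equal(update_threshold(0, rep(0, 12), cfg), 0)            # clipped
  expect_equal(update_threshold(1, c(rep(1, 11), 0), cfg), 1.01)   # 11 spikes
  # batch reduction: mean spike count across samples
  s <- cbind(rep(1, 12), rep(0, 12))  # 12 and 0 spikes -> mean 6
  expect_equal(update_threshold(1, s, cfg), 1 + 0.001 * 5)
})

test_that("the trace filter reduces to gamma * s when dt = tau_tr", {
  cfg <- csdp_config(c(3, 2), 2, dt = 3, tau_tr = 3, gamma = 0.05, T_ms = 9)
  expect_equal(update_trace(0, 0, cfg), 0)
  expect_equal(update_trace(c(0.9, 0.1), c(1, 0), cfg), c(0.05, 0))
  cfg_half <- csdp_config(c(3, 2), 2, dt = 3, tau_tr = 6, gamma = 0.05,
                          T_ms = 9)
  expect_equal(update_trace(0.05, 1, cfg_half), 0.05)  # fixed point z = gamma
})

test_that("layer evaluation order does not change the trajectory", {
  cfg <- csdp_config(c(5, 4, 4, 3), 2, T_ms = 150, gamma = 0.5,
                     theta_z = 1, v_thr_init = 0.5)
  params <- init_params(cfg, seed = 8)
  sens <- encode_bernoulli(matrix(runif(5), 5, 1), 50, seed = 9)
  run <- function(ord) {
    st <- init_network_state(cfg, 1)
    traj <- list()
    for (k in 1:50) {
      st <- step_network(st, matrix(sens[, 1, k], 5, 1), params, cfg,
                         layer_order = ord)
      traj[[k]] <- st
    }
    traj
  }
  set.seed(1); perm <- sample(1:3)
  expect_identical(run(1:3), run(3:1))
  expect_identical(run(1:3), run(perm))
})

test_that("a silent network stays silent and a driven one is oracle-exact", {
  cfg <- toy_cfg()
  params <- init_params(cfg, seed = 2)
  st <- init_network_state(cfg, 2)
  for (k in 1:4) st <- step_network(st, matrix(0, 3, 2), params, cfg)
  for (l in 1:2) {
    expect_equal(st$layers[[l]]$s, matrix(0, cfg$layer_sizes[l + 1], 2))
    expect_equal(st$layers[[l]]$v, matrix(0, cfg$layer_sizes[l + 1], 2))
  }
  expect_equal(st$v_thr, rep(1, 2) - 4 * 0.001)  # no spikes: drifts down

  # 3-layer toy, 5 steps, vs the scalar reference
  cfg3 <- csdp_config(c(4, 4, 3, 3), 2, gamma = 0.5, theta_z = 1,
                      v_thr_init = 0.4, T_ms = 15)
  params <- init_params(cfg3, seed = 31)
  set.seed(32)
  st <- init_network_state(cfg3, 1)
  ost <- oracle_init_state(cfg3, 1)
  sy <- encode_labels(1L, 2)
  for (k in 1:5) {
    s0 <- rand_spikes(4, 1, 0.6)
    st <- step_network(st, s0, params, cfg3, class_spikes = sy)
    ost <- oracle_step(ost, s0, params, cfg3, s_y = sy)
    for (l in 1:3) {
      expect_equal(st$layers[[l]]$s, ost$layers[[l]]$s)
      expect_equal(st$layers[[l]]$v, ost$layers[[l]]$v)
      expect_equal(st$layers[[l]]$z, ost$layers[[l]]$z)
    }
    expect_equal(st$v_thr, ost$v_thr)
  }
})

test_that("threshold increments have the homeostatic sign under constant drive", {
  # strong constant drive -> many spikes -> threshold must rise
  cfg <- csdp_config(c(4, 6), 2, v_thr_init = 0.1, T_ms = 9, R_E = 2)
  params <- init_params(cfg, seed = 12)
  params[[1]]$W <- abs(params[[1]]$W)   # purely excitatory drive
  params[[1]]$M <- params[[1]]$M * 0
  st <- init_network_state(cfg, 1)
  ones <- matrix(1, 4, 1)
  thr <- numeric(6)
  for (k in 1:6) { st <- step_network(st, ones, params, cfg); thr[k] <- st$v_thr }
  spikes_late <- sum(st$layers[[1]]$s)
  expect_gt(spikes_late, 1)
  expect_true(all(diff(thr[2:6]) > 0))
})
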