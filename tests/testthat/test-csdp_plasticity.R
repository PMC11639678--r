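# Goodness probability, contrastive loss, the modulator and the four
# synaptic update rules.

test_that("goodness probability is the sigmoid of the trace energy gap", {
  expect_equal(goodness_probability(c(sqrt(5), sqrt(5)), theta_z = 10), 0.5)
  expect_equal(goodness_probability(rep(0, 7), theta_z = 10),
               1 / (1 + exp(10)))
  # monotone in the trace energy
  p <- vapply(seq(0, 3, by = 0.2),
              function(a) goodness_probability(c(a, 0.3), 2), numeric(1))
  expect_true(all(diff(p) > 0))
  # strictly inside (0, 1) even far from the threshold
  expect_gt(goodness_probability(0, theta_z = 500), 0)
  expect_lt(goodness_probability(rep(30, 10), theta_z = 1e-3), 1)
})

test_that("contrastive loss pins to log 2 at the threshold and is safe at extremes", {
  z <- c(sqrt(3), sqrt(7))  # sum of squares = 10
  expect_equal(contrastive_loss(z, 1, 10), log(2))
  expect_equal(contrastive_loss(z, 0, 10), log(2))
  expect_equal(contrastive_loss(rep(0, 4), 1, 10),
               -log(1 / (1 + exp(10))), tolerance = 1e-12)  # ~ 10.0000454
  expect_equal(contrastive_loss(rep(0, 4), 1, 10), 10.0000454,
               tolerance = 1e-7)
  # no overflow/NaN far out on either branch
  expect_true(is.finite(contrastive_loss(rep(40, 10), 0, 1)))
  expect_true(all(contrastive_loss(matrix(runif(20), 4, 5),
                                   c(1, 0, 1, 0, 1), 3) >= 0))
})

test_that("the modulator equals the finite-difference gradient of the loss", {
  expect_equal(modulator(rep(0, 5), 1, 10), rep(0, 5))
  set.seed(77)
  worst <- 0
  for (rep in 1:100) {
    J <- sample(2:10, 1)
    z <- runif(J, 0, 1.5)
    y <- sample(0:1, 1)
    tz <- runif(1, 0.5, 12)
    d <- modulator(z, y, tz)
    h <- 1e-6
    fd <- vapply(seq_len(J), function(i) {
      zp <- z; zm <- z
      zp[i] <- z[i] + h; zm[i] <- z[i] - h
      (contrastive_loss(zp, y, tz) - contrastive_loss(zm, y, tz)) / (2 * h)
    }, numeric(1))
    rel <- abs(d - fd) / pmax(abs(fd), 1e-8)
    worst <- max(worst, max(rel[abs(fd) > 1e-10]))
    # closed form 2 z (p - y)
    expect_equal(d, 2 * z * (goodness_probability(z, tz) - y),
                 tolerance = 1e-12)
  }
  expect_lt(worst, 1e-5)
})

test_that("modulator signs follow the contrastive objective", {
  set.seed(3)
  z <- runif(6, 0.1, 1)
  # positive samples: p < 1 so delta and z have opposite signs
  expect_true(all(modulator(z, 1, 4) * z < 0))
  # negative samples: p > 0 so delta and z share signs
  expect_true(all(modulator(z, 0, 4) * z > 0))
  # one descent step on the traces raises p for positives, lowers it for negatives
  for (y in c(1, 0)) {
    d <- modulator(z, y, 4)
    z2 <- z - 0.05 * d
    dp <- goodness_probability(z2, 4) - goodness_probability(z, 4)
    if (y == 1) expect_gte(dp, 0) else expect_lte(dp, 0)
  }
})

test_that("synaptic updates match the scalar reference and the printed decay", {
  cfg <- csdp_config(c(3, 4, 2), 2, lambda_d = 5e-5, T_ms = 9,
                     R_E = 1.5, R_I = 0.7)
  # silence: no modulator, no postsynaptic spikes -> all-zero updates
  u0 <- csdp_updates(matrix(0, 4, 2), matrix(0, 4, 2),
                     s_pre_below = matrix(1, 3, 2),
                     s_pre_above = matrix(1, 2, 2),
                     s_pre_same = matrix(0, 4, 2),
                     class_pre = matrix(1, 2, 2), config = cfg)
  for (m in u0[!vapply(u0, is.null, logical(1))])
    expect_equal(m, m * 0)
  # pure decay term: delta = 0, post spike on, presynapse silent
  u <- csdp_updates(matrix(0, 4, 1), matrix(c(1, 0, 0, 0), 4, 1),
                    s_pre_below = matrix(0, 3, 1),
                    s_pre_above = NULL,
                    s_pre_same = matrix(0, 4, 1),
                    class_pre = NULL, config = cfg)
  expect_equal(u$W[1, ], rep(5e-5, 3))
  expect_equal(u$W[2:4, ], matrix(0, 3, 3))
  expect_null(u$V); expect_null(u$B)

  set.seed(41)
  for (rep in 1:10) {
    B <- sample(1:3, 1)
    delta <- matrix(rnorm(4 * B), 4, B)
    s_post <- rand_spikes(4, B)
    pb <- rand_spikes(3, B); pa <- rand_spikes(2, B)
    ps <- rand_spikes(4, B); pc <- rand_spikes(2, B)
    got <- csdp_updates(delta, s_post, pb, pa, ps, pc, cfg)
    want <- oracle_updates(delta, s_post, pb, pa, ps, pc, cfg)
    expect_equal(got$W, want$W, tolerance = 1e-13)
    expect_equal(got$V, want$V, tolerance = 1e-13)
    expect_equal(got$M, want$M, tolerance = 1e-13)
    expect_equal(got$B, want$B, tolerance = 1e-13)
  }
})

test_that("total goodness aggregates per-layer losses additively", {
  cfg <- csdp_config(c(3, 2), 2, theta_z = 4, T_ms = 9)
  z1 <- matrix(runif(4), 2, 2)
  expect_equal(total_goodness(list(z1), c(1, 0), cfg),
               contrastive_loss(z1, c(1, 0), 4))
  cfg2 <- csdp_config(c(3, 2, 2, 2), 2, theta_z = 6, T_ms = 9)
  at_thr <- matrix(sqrt(3), 2, 1)  # sum z^2 = 6 in every layer
  expect_equal(as.vector(total_goodness(list(at_thr, at_thr, at_thr), 1, cfg2)),
               3 * log(2))
  # sequence loss = sum over steps of independently computed totals
  traj <- lapply(1:4, function(k) list(matrix(runif(2), 2, 1) * k / 4,
                                       matrix(runif(2), 2, 1)))
  by_hand <- Reduce(`+`, lapply(traj, function(tr)
    contrastive_loss(tr[[1]], 1, 6) + contrastive_loss(tr[[2]], 1, 6)))
  cfg3 <- csdp_config(c(3, 2, 2), 2, theta_z = 6, T_ms = 9)
  expect_equal(sequence_loss(traj, 1, cfg3), by_hand)
})
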