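test_that("mask constraints hold for every seed", {
  cfg <- small_cfg(beta_ee_slow = 0.4)
  for (seed in 1:10) {
    topo <- build_recurrent_connectivity(cfg, seed = seed)
    expect_true(all(diag(topo$w_ee_fast) == 0))
    expect_true(all(diag(topo$w_ee_slow) == 0))
    expect_true(all(diag(topo$w_ii) == 0))
    prod_ei_ie <- (topo$masks$ei %*% topo$masks$ie) > 0
    prod_ie_ei <- (topo$masks$ie %*% topo$masks$ei) > 0
    expect_true(all(prod_ei_ie[topo$w_ee_fast != 0]))
    expect_true(all(prod_ei_ie[topo$w_ee_slow != 0]))
    expect_true(all(prod_ie_ei[topo$w_ii != 0]))
    # weight magnitudes within their uniform bounds
    expect_true(all(topo$w_pe >= 0 & topo$w_pe <= cfg$alpha))
    expect_true(all(topo$w_ee_fast <= cfg$beta_ee))
    expect_true(all(topo$w_ei <= cfg$beta_ei))
    expect_true(all(topo$w_ie <= cfg$beta_ie))
    expect_true(all(topo$w_ii <= cfg$beta_ii))
    # inhibitory neurons receive no input: w_pe only targets excitatory
    expect_equal(dim(topo$w_pe), c(40L, 120L))
  }
})

test_that("empirical connection counts match K and C within 3 binomial sd", {
  cfg <- small_cfg()
  n_seeds <- 100
  in_per_col <- ei_per_col <- ie_per_col <- numeric(0)
  for (seed in seq_len(n_seeds)) {
    topo <- build_recurrent_connectivity(cfg, seed = 1000 + seed)
    in_per_col <- c(in_per_col, colSums(topo$w_pe != 0))
    ei_per_col <- c(ei_per_col, colSums(topo$masks$ei))
    ie_per_col <- c(ie_per_col, colSums(topo$masks$ie))
  }
  check_binomial <- function(x, n, p) {
    se <- sqrt(n * p * (1 - p) / length(x))
    expect_lt(abs(mean(x) - n * p), 3 * se)
  }
  # each excitatory neuron: ~K of N_P inputs, ~C of N_I inhibitory afferents
  check_binomial(in_per_col, cfg$n_input, cfg$k_input / cfg$n_input)
  check_binomial(ie_per_col, cfg$n_inhibitory,
                 cfg$c_recurrent / cfg$n_inhibitory)
  # each inhibitory neuron: ~C of N_E excitatory afferents
  check_binomial(ei_per_col, cfg$n_excitatory,
                 cfg$c_recurrent / cfg$n_excitatory)
})

test_that("signed input initialization draws symmetric weights", {
  cfg <- init_config(n_input = 2, n_excitatory = 120, n_inhibitory = 30,
                     k_input = 2, c_recurrent = 4, alpha = 0.4,
                     input_weight_signed = TRUE)
  topo <- build_recurrent_connectivity(cfg, seed = 3)
  w <- topo$w_pe[topo$w_pe != 0]
  expect_true(all(abs(w) <= 0.4))
  expect_true(any(w < 0) && any(w > 0))
})

test_that("configuration preconditions are enforced", {
  expect_error(init_config(40, 120, 30, k_input = 0), "k_input")
  expect_error(init_config(40, 120, 30, k_input = 41), "k_input")
  expect_error(init_config(40, 120, 40), "4 \\* n_inhibitory")
  expect_error(init_config(40, 120, 30, c_recurrent = -1), "c_recurrent")
  expect_silent(init_config(40, 120, 40, allow_ratio_override = TRUE))
})

test_that("C = 0 yields an empty, feed-forward recurrent structure", {
  topo <- build_recurrent_connectivity(small_cfg(c_recurrent = 0), seed = 1)
  expect_true(all(topo$w_ee_fast == 0))
  expect_true(all(topo$w_ei == 0))
  expect_true(all(topo$w_ie == 0))
  expect_true(all(topo$w_ii == 0))
  expect_equal(spectral_radius(composite_matrix(topo)), 0)
})

test_that("composite matrix places and signs the blocks per the current sum", {
  # 2 excitatory + 1 inhibitory toy with hand-set weights
  w_ee <- matrix(c(0, 0.3, 0.2, 0), 2, 2, byrow = TRUE)  # 1->2: 0.2 etc.
  w_ei <- matrix(c(0.5, 0.6), 2, 1)
  w_ie <- matrix(c(0.7, 0.8), 1, 2)
  w_ii <- matrix(0, 1, 1)
  topo <- make_fake_topology(matrix(0, 1, 2), w_ee, w_ei, w_ie, w_ii)
  m <- composite_matrix(topo)
  # entry (i, j) = signed weight from neuron j to neuron i
  expected <- rbind(c(0,   0.2, -0.7),
                    c(0.3, 0,   -0.8),
                    c(0.5, 0.6,  0))
  expect_equal(unname(m), expected)
  # slow pathway weights add onto the fast E->E block
  topo2 <- make_fake_topology(matrix(0, 1, 2), w_ee, w_ei, w_ie, w_ii,
                              w_ee_slow = w_ee)
  expect_equal(unname(composite_matrix(topo2)[1:2, 1:2]),
               2 * unname(t(w_ee)))
})

test_that("spectral radius is the largest eigenvalue modulus", {
  expect_equal(spectral_radius(diag(3) * 0.5), 0.5)
  expect_error(spectral_radius(matrix(1, 2, 3)), "square")
  rot <- matrix(c(0, -2, 2, 0), 2, 2)  # eigenvalues +-2i
  expect_equal(spectral_radius(rot), 2)
})

test_that("scaling all recurrent weights up never decreases the radius", {
  for (seed in 1:5) {
    topo <- build_recurrent_connectivity(small_cfg(), seed = seed)
    r1 <- spectral_radius(composite_matrix(topo))
    scaled <- topo
    for (f in c("w_ee_fast", "w_ei", "w_ie", "w_ii"))
      scaled[[f]] <- 2 * scaled[[f]]
    r2 <- spectral_radius(composite_matrix(scaled))
    expect_gte(r2, r1)
  }
})

test_that("balanced initialization is linearly stable at liquid size 150", {
  for (seed in 1:5) {
    topo <- build_recurrent_connectivity(small_cfg(), seed = seed)
    expect_true(is_stable(topo))
  }
})

test_that("finite input pulses produce finite responses in stable liquids", {
  set.seed(7)
  # no recurrence: activity must stop almost immediately after input ends
  topo0 <- build_recurrent_connectivity(small_cfg(c_recurrent = 0), seed = 1)
  pr0 <- finite_response_probe(topo0, pulse_ms = 50, horizon_ms = 100)
  expect_true(pr0$decayed)
  expect_lte(pr0$last_spike_ms, 50 + 20)  # within one membrane time constant

  for (seed in 1:5) {
    topo <- build_recurrent_connectivity(small_cfg(), seed = seed)
    pr <- finite_response_probe(topo, pulse_ms = 100, horizon_ms = 500)
    expect_true(pr$decayed)
  }
})

test_that("membrane probe records bounded, fluctuating potentials", {
  topo <- build_recurrent_connectivity(small_cfg(), seed = 2)
  p <- neuron_params()
  set.seed(11)
  tr <- membrane_probe(topo, p, input_rates_hz = 100, n_neurons = 10,
                       duration_ms = 500)
  expect_equal(dim(tr), c(10L, 500L))
  expect_true(all(tr <= p$v_thres))
  # balanced fluctuation: both up- and down-swings on every recorded trace
  expect_true(all(apply(tr, 1, function(v) any(diff(v) > 0) &&
                                           any(diff(v) < 0))))
  # zero input: every trace sits exactly at rest
  set.seed(11)
  tr0 <- membrane_probe(topo, p, input_rates_hz = 0, duration_ms = 100)
  expect_true(all(tr0 == p$v_rest))
})

test_that("constant suprathreshold drive produces the oracle sawtooth", {
  # single excitatory neuron, no recurrence, driven through one input line
  w_pe <- matrix(0.1, 1, 1)
  zero1 <- matrix(0, 1, 1)
  topo <- make_fake_topology(w_pe, zero1, zero1, zero1, zero1)
  run <- liquid_run(topo, t_lsm_ms = 60)
  spk <- matrix(1L, 1, 60)
  act <- present(run, spk, record_neurons = 1L)
  oracle <- scalar_lif_trace(0, rep(0.1, 60))
  expect_equal(drop(attr(act, "vtrace")), oracle$v)
  expect_equal(act[1], mean(oracle$spikes))
})
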