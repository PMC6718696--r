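# Independent oracles used across the suite. These deliberately re-derive
# the dynamics step by step in plain scalar R, independent of the package's
# vectorized / compiled implementations.

# scalar forward-Euler LIF iteration for one neuron
scalar_lif_trace <- function(v0, currents, p = neuron_params()) {
  v <- v0
  refrac <- 0L
  out_v <- numeric(length(currents))
  out_s <- logical(length(currents))
  for (t in seq_along(currents)) {
    if (refrac > 0L) {
      refrac <- refrac - 1L
    } else {
      v <- v + (p$dt_ms / p$tau_ms) * (p$v_rest - v) + currents[t]
      if (v >= p$v_thres) {
        out_s[t] <- TRUE
        v <- p$v_reset
        refrac <- as.integer(ceiling(p$tau_refrac_ms / p$dt_ms))
      }
    }
    out_v[t] <- v
  }
  list(v = out_v, spikes = out_s)
}

# plain-R liquid simulator mirroring the delay structure: input spikes act
# in their own step, recurrent spikes with a 1-step delay, slow E->E
# spikes with the configured long delay
reference_liquid <- function(topology, input_spikes, p = neuron_params()) {
  cfg <- topology$config
  ne <- cfg$n_excitatory; ni <- cfg$n_inhibitory
  steps <- ncol(input_spikes)
  st <- liquid_state(ne + ni, p)
  prev_e <- numeric(ne); prev_i <- numeric(ni)
  slow <- !is.null(topology$w_ee_slow)
  if (slow) {
    d <- as.integer(round(cfg$ee_slow_delay_ms / p$dt_ms))
    hist_e <- matrix(0, ne, d)
  }
  counts <- numeric(ne)
  for (s in seq_len(steps)) {
    cur_e <- drop(t(topology$w_pe) %*% input_spikes[, s]) +
      drop(t(topology$w_ee_fast) %*% prev_e) -
      drop(t(topology$w_ie) %*% prev_i)
    if (slow) cur_e <- cur_e + drop(t(topology$w_ee_slow) %*% hist_e[, 1])
    cur_i <- drop(t(topology$w_ei) %*% prev_e) -
      drop(t(topology$w_ii) %*% prev_i)
    res <- lif_step(st, p, c(cur_e, cur_i))
    st <- res$state
    spk_e <- as.numeric(res$spikes[1:ne])
    spk_i <- as.numeric(res$spikes[(ne + 1):(ne + ni)])
    counts <- counts + spk_e
    if (slow) hist_e <- cbind(hist_e[, -1, drop = FALSE], spk_e)
    prev_e <- spk_e; prev_i <- spk_i
  }
  counts / steps
}

# independently coded cart-pole integrator (same physical constants)
reference_cartpole <- function(state, actions, force_mag = 10) {
  g <- 9.8; mc <- 1; mp <- 0.1; l <- 0.5; dt <- 0.02
  M <- mc + mp
  out <- matrix(NA_real_, length(actions), 4)
  for (k in seq_along(actions)) {
    f <- ifelse(actions[k] == 2, force_mag, -force_mag)
    x <- state[1]; xd <- state[2]; th <- state[3]; thd <- state[4]
    tmp <- (f + mp * l * thd^2 * sin(th)) / M
    thacc <- (g * sin(th) - cos(th) * tmp) /
      (l * (4 / 3 - mp * cos(th)^2 / M))
    xacc <- tmp - mp * l * thacc * cos(th) / M
    state <- c(x + dt * xd, xd + dt * xacc, th + dt * thd, thd + dt * thacc)
    out[k, ] <- state
  }
  out
}

# hand-tuned stabilizing controller; used to realize the maximum episode
# reward of the balancing task
pd_policy <- function(obs) {
  phi <- obs[3]; phid <- obs[4]
  if (phi + 0.5 * phid > 0) 2L else 1L
}

# small standard liquid configuration used throughout the suite
small_cfg <- function(c_recurrent = 4, ...) {
  init_config(n_input = 40, n_excitatory = 120, n_inhibitory = 30,
              k_input = 3, c_recurrent = c_recurrent, ...)
}

make_fake_topology <- function(w_pe, w_ee_fast, w_ei, w_ie, w_ii,
                               w_ee_slow = NULL, ee_slow_delay_ms = 20) {
  cfg <- list(n_input = nrow(w_pe), n_excitatory = ncol(w_pe),
              n_inhibitory = ncol(w_ei), k_input = 1, c_recurrent = 1,
              ee_slow_delay_ms = ee_slow_delay_ms,
              input_weight_signed = FALSE)
  class(cfg) <- "lsm_init_config"
  structure(list(w_pe = w_pe, w_ee_fast = w_ee_fast, w_ee_slow = w_ee_slow,
                 w_ei = w_ei, w_ie = w_ie, w_ii = w_ii, config = cfg),
            class = "lsm_topology")
}
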