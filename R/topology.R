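#' Connectivity initialization configuration
#'
#' Describes how the fixed input-to-liquid and recurrent-liquid connectivity
#' of a liquid state machine is drawn. The liquid holds `n_excitatory` (E)
#' and `n_inhibitory` (I) neurons, by default in the cortical 4:1 ratio.
#' Each excitatory neuron receives input connections from approximately
#' `k_input` of the `n_input` input channels, and approximately
#' `c_recurrent` inhibitory afferents (and each inhibitory neuron
#' approximately `c_recurrent` excitatory afferents). The E->E and I->I
#' connections are derived from the E->I / I->E supports; see
#' [build_recurrent_connectivity()]. Weight magnitudes are drawn uniformly
#' in `[0, bound]` with the per-pathway bounds `alpha` (input) and
#' `beta_*` (recurrent); the defaults are the balanced-initialization
#' values (alpha 0.6; beta EE 0.05, EI 0.25, IE 0.3, II 0.01) under which
#' the recurrent spectrum stays inside the unit circle.
#'
#' @param n_input number of input (Poisson) neurons, N_P.
#' @param n_excitatory,n_inhibitory liquid population sizes N_E, N_I. Unless
#'   `allow_ratio_override = TRUE`, `n_excitatory` must equal
#'   `4 * n_inhibitory`.
#' @param k_input expected number of input afferents per excitatory neuron, K.
#' @param c_recurrent expected number of recurrent afferents, C. `C = 0`
#'   yields a feed-forward (memoryless) liquid.
#' @param alpha maximum input weight; with `input_weight_signed` the input
#'   weights are uniform on `[-alpha, alpha]` (0.4 for the signed encoder).
#' @param beta_ee,beta_ei,beta_ie,beta_ii maximum recurrent weights per
#'   connection type.
#' @param beta_ee_slow maximum weight of the optional second E->E pathway
#'   with a long (20 ms) synaptic delay; `NULL` disables the pathway.
#' @param ee_slow_delay_ms synaptic delay of the slow E->E pathway in ms.
#' @param input_weight_signed draw input weights symmetrically around 0
#'   (used together with signed spike encoding).
#' @param allow_ratio_override permit E:I ratios other than 4:1.
#' @return An object of class `lsm_init_config`.
#' @examples
#' init_config(n_input = 40, n_excitatory = 120, n_inhibitory = 30,
#'             k_input = 3, c_recurrent = 4)
#' @export
init_config <- function(n_input, n_excitatory, n_inhibitory,
                        k_input = 3, c_recurrent = 4,
                        alpha = 0.6,
                        beta_ee = 0.05, beta_ei = 0.25,
                        beta_ie = 0.3, beta_ii = 0.01,
                        beta_ee_slow = NULL, ee_slow_delay_ms = 20,
                        input_weight_signed = FALSE,
                        allow_ratio_override = FALSE) {
  stopifnot(n_input >= 1, n_excitatory >= 1, n_inhibitory >= 1)
  if (!allow_ratio_override && n_excitatory != 4L * n_inhibitory)
    stop("n_excitatory must be 4 * n_inhibitory ",
         "(set allow_ratio_override = TRUE to deviate)")
  if (k_input <= 0 || k_input > n_input)
    stop("k_input must satisfy 0 < k_input <= n_input")
  if (c_recurrent < 0) stop("c_recurrent must be non-negative")
  bounds <- c(alpha = alpha, beta_ee = beta_ee, beta_ei = beta_ei,
              beta_ie = beta_ie, beta_ii = beta_ii)
  if (any(bounds < 0)) stop("weight bounds must be non-negative")
  if (!is.null(beta_ee_slow) && beta_ee_slow < 0)
    stop("beta_ee_slow must be non-negative")
  structure(list(n_input = as.integer(n_input),
                 n_excitatory = as.integer(n_excitatory),
                 n_inhibitory = as.integer(n_inhibitory),
                 k_input = k_input, c_recurrent = c_recurrent,
                 alpha = alpha, beta_ee = beta_ee, beta_ei = beta_ei,
                 beta_ie = beta_ie, beta_ii = beta_ii,
                 beta_ee_slow = beta_ee_slow,
                 ee_slow_delay_ms = ee_slow_delay_ms,
                 input_weight_signed = isTRUE(input_weight_signed)),
            class = "lsm_init_config")
}

bernoulli_mask <- function(nrow, ncol, p) {
  # uniform-draw-and-threshold construction: connect where U(0,1) < p
  matrix(stats::runif(nrow * ncol) < p, nrow, ncol)
}

#' Build the sparse input-to-liquid weight matrix
#'
#' Each excitatory neuron receives connections from approximately `k_input`
#' random input neurons: every (input, excitatory) pair is connected
#' independently with probability `k_input / n_input`. Weights are uniform
#' on `[0, alpha]`, or on `[-alpha, alpha]` when `input_weight_signed`.
#' Inhibitory neurons receive no input connections. Uses the current R RNG
#' state; seed the generator for reproducibility.
#'
#' @param config an `lsm_init_config`.
#' @return `n_input x n_excitatory` weight matrix (rows are presynaptic).
#' @export
build_input_connectivity <- function(config) {
  stopifnot(inherits(config, "lsm_init_config"))
  np <- config$n_input; ne <- config$n_excitatory
  mask <- bernoulli_mask(np, ne, config$k_input / np)
  w <- if (config$input_weight_signed)
    matrix(stats::runif(np * ne, -config$alpha, config$alpha), np, ne)
  else
    matrix(stats::runif(np * ne, 0, config$alpha), np, ne)
  w * mask
}

#' Build the recurrent liquid connectivity
#'
#' The E->I mask is drawn first (entrywise Bernoulli with probability
#' `C / n_excitatory`, so each inhibitory neuron receives ~C excitatory
#' afferents), then the I->E mask (probability `C / n_inhibitory`, so each
#' excitatory neuron receives ~C inhibitory afferents). The E->E mask is the
#' support of the product `W_EI %*% W_IE` with the diagonal forced to zero
#' (no self-excitation, and excitatory loops only where inhibition also
#' reaches); the I->I mask is the support of `W_IE %*% W_EI`, also with a
#' zero diagonal. Weights are uniform on `[0, beta_type]`. When
#' `beta_ee_slow` is set, a second independent E->E weight matrix is drawn
#' on the same mask; it is delivered with the long `ee_slow_delay_ms` delay.
#'
#' Draw order (fixed for bit-reproducibility per seed): input mask, input
#' weights, E->I mask, I->E mask, E->I weights, I->E weights, E->E weights,
#' slow E->E weights (if enabled), I->I weights.
#'
#' @param config an `lsm_init_config`.
#' @param seed optional integer; when supplied, `set.seed(seed)` is called
#'   first so the whole topology is a pure function of (config, seed).
#' @return An object of class `lsm_topology`: weight matrices `w_pe`
#'   (N_P x N_E), `w_ee_fast`, `w_ee_slow` (N_E x N_E or NULL), `w_ei`
#'   (N_E x N_I), `w_ie` (N_I x N_E), `w_ii` (N_I x N_I), all oriented
#'   presynaptic rows x postsynaptic columns, plus the binary masks and the
#'   originating config.
#' @examples
#' cfg <- init_config(40, 120, 30, k_input = 3, c_recurrent = 4)
#' topo <- build_recurrent_connectivity(cfg, seed = 1)
#' all(diag(topo$w_ee_fast) == 0)
#' @export
build_recurrent_connectivity <- function(config, seed = NULL) {
  stopifnot(inherits(config, "lsm_init_config"))
  if (!is.null(seed)) set.seed(seed)
  np <- config$n_input; ne <- config$n_excitatory; ni <- config$n_inhibitory

  w_pe <- build_input_connectivity(config)

  m_ei <- bernoulli_mask(ne, ni, config$c_recurrent / ne)
  m_ie <- bernoulli_mask(ni, ne, config$c_recurrent / ni)
  w_ei <- m_ei * matrix(stats::runif(ne * ni, 0, config$beta_ei), ne, ni)
  w_ie <- m_ie * matrix(stats::runif(ni * ne, 0, config$beta_ie), ni, ne)

  m_ee <- (m_ei %*% m_ie) > 0
  diag(m_ee) <- FALSE
  m_ii <- (m_ie %*% m_ei) > 0
  diag(m_ii) <- FALSE

  w_ee_fast <- m_ee * matrix(stats::runif(ne * ne, 0, config$beta_ee), ne, ne)
  w_ee_slow <- NULL
  if (!is.null(config$beta_ee_slow))
    w_ee_slow <- m_ee *
      matrix(stats::runif(ne * ne, 0, config$beta_ee_slow), ne, ne)
  w_ii <- m_ii * matrix(stats::runif(ni * ni, 0, config$beta_ii), ni, ni)

  structure(list(w_pe = w_pe,
                 w_ee_fast = w_ee_fast, w_ee_slow = w_ee_slow,
                 w_ei = w_ei, w_ie = w_ie, w_ii = w_ii,
                 masks = list(ee = m_ee, ei = m_ei, ie = m_ie, ii = m_ii),
                 config = config),
            class = "lsm_topology")
}

#' @export
print.lsm_topology <- function(x, ...) {
  cfg <- x$config
  cat("Liquid topology:", cfg$n_excitatory, "excitatory +", cfg$n_inhibitory,
      "inhibitory neurons,", cfg$n_input, "inputs\n")
  cat("  K =", cfg$k_input, " C =", cfg$c_recurrent,
      if (!is.null(x$w_ee_slow)) " (slow E->E pathway enabled)" else "", "\n")
  cat("  spectral radius:", format(spectral_radius(composite_matrix(x)),
                                   digits = 4), "\n")
  invisible(x)
}

#' Signed composite recurrent connectivity matrix
#'
#' Combines the four recurrent blocks into one signed
#' `(N_E + N_I) x (N_E + N_I)` matrix whose entry (i, j) is the current that
#' a spike of neuron j injects into neuron i: excitatory columns enter
#' positively, inhibitory columns negatively, mirroring the signed current
#' sum of the LIF dynamics. Both E->E pathways (fast and slow) contribute
#' their summed weight.
#'
#' @param topology an `lsm_topology`.
#' @return dense signed matrix, excitatory neurons first.
#' @export
composite_matrix <- function(topology) {
  stopifnot(inherits(topology, "lsm_topology"))
  w_ee <- topology$w_ee_fast
  if (!is.null(topology$w_ee_slow)) w_ee <- w_ee + topology$w_ee_slow
  rbind(cbind(t(w_ee), -t(topology$w_ie)),
        cbind(t(topology$w_ei), -t(topology$w_ii)))
}

#' Spectral radius of a square matrix
#'
#' @param m square numeric matrix.
#' @return the largest eigenvalue modulus.
#' @export
spectral_radius <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("m must be a square matrix")
  if (nrow(m) == 0) return(0)
  max(Mod(eigen(m, only.values = TRUE)$values))
}

#' Linear stability check of a liquid topology
#'
#' The liquid's spiking activity stays bounded in practice when all
#' eigenvalues of the signed composite recurrent matrix lie within the unit
#' circle; this checks `spectral_radius(composite_matrix(topology)) <= 1`.
#'
#' @param topology an `lsm_topology`.
#' @return logical flag.
#' @export
is_stable <- function(topology) {
  spectral_radius(composite_matrix(topology)) <= 1
}

#' Finite-response stability probe
#'
#' Drives the liquid with a finite pulse of Poisson input spikes, then with
#' silence, and reports whether the total excitatory spiking activity dies
#' out within a horizon. A stable liquid responds to any finite input
#' stream with a finite period of activity; sustained self-excited firing
#' marks an unstable initialization.
#'
#' @param topology an `lsm_topology`.
#' @param params an `lsm_neuron_params`.
#' @param pulse_ms pulse duration in ms (default 100).
#' @param pulse_rate_hz Poisson rate of every input channel during the pulse.
#' @param horizon_ms silence period after the pulse within which activity
#'   must reach zero (default 500 ms, several membrane time constants).
#' @return list with `decayed` (logical), `last_spike_ms` (last simulation
#'   step with any excitatory spike, NA if none) and `trace` (per-ms total
#'   excitatory spike count over pulse + horizon).
#' @export
finite_response_probe <- function(topology, params = neuron_params(),
                                  pulse_ms = 100, pulse_rate_hz = 100,
                                  horizon_ms = 500) {
  stopifnot(inherits(topology, "lsm_topology"))
  run <- liquid_run(topology, params, t_lsm_ms = pulse_ms + horizon_ms)
  rates <- rate_vector(rep(pulse_rate_hz, topology$config$n_input))
  pulse <- poisson_spikes(rates, pulse_ms, params$dt_ms)
  total_steps <- as.integer((pulse_ms + horizon_ms) / params$dt_ms)
  spk <- cbind(unclass(pulse),
               matrix(0L, topology$config$n_input,
                      total_steps - ncol(pulse)))
  out <- present(run, spk, record_counts = TRUE)
  trace <- attr(out, "counts")
  nz <- which(trace > 0)
  last <- if (length(nz)) nz[length(nz)] * params$dt_ms else NA_real_
  list(decayed = length(nz) == 0 || last < pulse_ms + horizon_ms,
       last_spike_ms = last, trace = trace)
}

#' Membrane-potential probe
#'
#' Records the membrane potential of randomly selected excitatory neurons
#' while the liquid is driven by Poisson input, for inspecting whether a
#' candidate initialization produces balanced sub-threshold fluctuation
#' (bounded between the reset and threshold potentials) rather than silence
#' or runaway drift.
#'
#' @param topology an `lsm_topology`.
#' @param params an `lsm_neuron_params`.
#' @param input_rates_hz per-input firing rates (recycled to `n_input`).
#' @param n_neurons number of excitatory neurons to record.
#' @param duration_ms recording duration.
#' @return matrix `n_neurons x duration_ms/dt` of membrane potentials, with
#'   the recorded neuron indices in attribute `"neurons"`.
#' @export
membrane_probe <- function(topology, params = neuron_params(),
                           input_rates_hz = 100, n_neurons = 10,
                           duration_ms = 1000) {
  stopifnot(inherits(topology, "lsm_topology"))
  ne <- topology$config$n_excitatory
  idx <- sample.int(ne, min(n_neurons, ne))
  run <- liquid_run(topology, params, t_lsm_ms = duration_ms)
  rates <- rate_vector(rep_len(input_rates_hz, topology$config$n_input))
  spk <- poisson_spikes(rates, duration_ms, params$dt_ms)
  out <- present(run, spk, record_neurons = idx)
  v <- attr(out, "vtrace")
  rownames(v) <- idx
  attr(v, "neurons") <- idx
  v
}
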