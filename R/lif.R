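#' Leaky integrate-and-fire neuron parameters
#'
#' Parameters of the discrete-time leaky integrate-and-fire (LIF) model used
#' for every neuron in the liquid, excitatory and inhibitory alike. The
#' membrane potential obeys \eqn{dV/dt = (V_{rest} - V)/\tau + I(t)},
#' integrated with forward Euler on a 1 ms grid. When the updated potential
#' reaches `v_thres` the neuron emits a spike, its potential is reset to
#' `v_reset`, and it is held constant (no update, no spike) for the
#' refractory period.
#'
#' @param v_rest resting potential the membrane leaks toward (dimensionless).
#' @param v_reset potential after a spike.
#' @param v_thres spiking threshold; must exceed `v_reset`.
#' @param tau_ms membrane time constant in ms.
#' @param tau_refrac_ms refractory period in ms; at the default 1 ms step a
#'   1 ms refractory period skips exactly one update.
#' @param dt_ms simulation step in ms.
#' @return An object of class `lsm_neuron_params`.
#' @examples
#' p <- neuron_params()
#' p$v_thres
#' @export
neuron_params <- function(v_rest = 0, v_reset = 0, v_thres = 0.5,
                          tau_ms = 20, tau_refrac_ms = 1, dt_ms = 1) {
  stopifnot(is.numeric(v_rest), is.numeric(v_reset), is.numeric(v_thres),
            length(v_rest) == 1, length(v_reset) == 1, length(v_thres) == 1)
  if (!(v_reset < v_thres)) stop("v_reset must be strictly below v_thres")
  if (!(tau_ms > 0)) stop("tau_ms must be positive")
  if (!(dt_ms > 0)) stop("dt_ms must be positive")
  if (tau_refrac_ms < 0) stop("tau_refrac_ms must be non-negative")
  structure(list(v_rest = v_rest, v_reset = v_reset, v_thres = v_thres,
                 tau_ms = tau_ms, tau_refrac_ms = tau_refrac_ms,
                 dt_ms = dt_ms),
            class = "lsm_neuron_params")
}

#' Number of update steps a neuron stays refractory after a spike
#' @param params an `lsm_neuron_params` object.
#' @return integer step count, `ceiling(tau_refrac_ms / dt_ms)`.
#' @export
refractory_steps <- function(params) {
  as.integer(ceiling(params$tau_refrac_ms / params$dt_ms))
}

#' Create a fresh liquid membrane state
#'
#' @param n number of neurons.
#' @param params an `lsm_neuron_params` object.
#' @return An `lsm_liquid_state` list with potentials at `v_rest`, zero
#'   refractory counters and step counter 0.
#' @export
liquid_state <- function(n, params = neuron_params()) {
  stopifnot(n >= 1)
  structure(list(v = rep(params$v_rest, n),
                 refrac_remaining = integer(n),
                 step_index = 0L),
            class = "lsm_liquid_state")
}

validate_liquid_state <- function(state, params) {
  if (!all(is.finite(state$v))) stop("non-finite membrane potential in state")
  if (any(state$refrac_remaining < 0L)) stop("negative refractory counter")
  if (any(state$refrac_remaining > refractory_steps(params)))
    stop("refractory counter exceeds ceiling(tau_refrac_ms/dt_ms)")
  invisible(state)
}

#' Advance the whole population one simulation step
#'
#' Vectorized forward-Euler LIF update. Non-refractory neurons integrate
#' `v <- v + (dt/tau) * (v_rest - v) + current`; those whose updated
#' potential reaches the threshold spike, are reset and enter the refractory
#' period. Refractory neurons hold their potential constant, never spike,
#' and their counters decrement by one step. A synaptic weight `w` on a
#' presynaptic spike contributes `w` to this step's current (delta synapse,
#' no kernel).
#'
#' This is the reference implementation; the liquid simulator uses an
#' equivalent compiled kernel (see [present()]), tested to agree exactly.
#'
#' @param state an `lsm_liquid_state`.
#' @param params an `lsm_neuron_params`.
#' @param current numeric vector of per-neuron input current for this step.
#' @return list with elements `state` (updated) and `spikes` (logical
#'   per-neuron spike indicator).
#' @examples
#' st <- liquid_state(1)
#' st$v <- 0.49
#' lif_step(st, neuron_params(), 0.02)$spikes
#' @export
lif_step <- function(state, params, current) {
  if (length(current) != length(state$v))
    stop("current must have one entry per neuron (expected ",
         length(state$v), ", got ", length(current), ")")
  if (!all(is.finite(current))) stop("non-finite entries in current")
  validate_liquid_state(state, params)

  v <- state$v
  refrac <- state$refrac_remaining
  active <- refrac == 0L

  leak <- params$dt_ms / params$tau_ms
  v[active] <- v[active] + leak * (params$v_rest - v[active]) + current[active]

  spikes <- active & (v >= params$v_thres)
  v[spikes] <- params$v_reset
  refrac[spikes] <- refractory_steps(params)
  refrac[!active] <- refrac[!active] - 1L

  state$v <- v
  state$refrac_remaining <- refrac
  state$step_index <- state$step_index + 1L
  list(state = state, spikes = spikes)
}
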