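#' Create a stateful liquid simulation run
#'
#' Wraps a fixed topology and neuron parameters into a mutable simulation
#' object that carries membrane potentials, refractory counters and
#' synaptic delay buffers across reinforcement-learning steps. Each call to
#' [present()] simulates one presentation window (`t_lsm_ms`) of input
#' spikes; potentials are deliberately *not* reset between calls so the
#' liquid retains fading memory of past inputs.
#'
#' Recurrent spikes are delivered with a one-simulation-step (1 ms) delay;
#' input spikes act within their own step. When the topology has a slow
#' E->E pathway, its spikes are delivered from a ring buffer
#' `ee_slow_delay_ms` steps deep.
#'
#' @param topology an `lsm_topology`.
#' @param params an `lsm_neuron_params`.
#' @param t_lsm_ms presentation window per RL step in ms (100 by default;
#'   20 for the partial-observation cartpole configuration).
#' @return An environment of class `lsm_liquid_run`.
#' @export
liquid_run <- function(topology, params = neuron_params(), t_lsm_ms = 100) {
  stopifnot(inherits(topology, "lsm_topology"),
            inherits(params, "lsm_neuron_params"))
  cfg <- topology$config
  ne <- cfg$n_excitatory; ni <- cfg$n_inhibitory
  st <- new.env(parent = emptyenv())
  st$topology <- topology
  st$params <- params
  st$t_lsm_ms <- t_lsm_ms
  st$n_e <- ne; st$n_i <- ni; st$n_p <- cfg$n_input
  # pre-transposed weights: column j = outgoing weights of presynaptic j
  st$wpe_t <- t(topology$w_pe)
  st$wee_fast_t <- t(topology$w_ee_fast)
  st$wei_t <- t(topology$w_ei)
  st$wie_t <- t(topology$w_ie)
  st$wii_t <- t(topology$w_ii)
  st$has_slow <- !is.null(topology$w_ee_slow)
  if (st$has_slow) {
    st$wee_slow_t <- t(topology$w_ee_slow)
    st$delay_slow <- as.integer(round(cfg$ee_slow_delay_ms / params$dt_ms))
  }
  st$v_rest <- params$v_rest; st$v_reset <- params$v_reset
  st$v_thres <- params$v_thres
  st$leak <- params$dt_ms / params$tau_ms
  st$refrac_steps <- refractory_steps(params)
  # compressed-column adjacency of each weight matrix for the kernel
  for (nm in c("wpe_t", "wee_fast_t", "wei_t", "wie_t", "wii_t",
               if (st$has_slow) "wee_slow_t")) {
    csc <- build_csc(st[[nm]])
    st[[paste0(nm, "_p")]] <- csc$p
    st[[paste0(nm, "_i")]] <- csc$i
    st[[paste0(nm, "_x")]] <- csc$x
  }
  class(st) <- "lsm_liquid_run"
  reset(st)
}

# compressed sparse column form (0-based) of a dense weight matrix
build_csc <- function(m) {
  idx <- which(m != 0)
  cols <- (idx - 1L) %/% nrow(m) + 1L
  list(p = c(0L, cumsum(tabulate(cols, ncol(m)))),
       i = as.integer((idx - 1L) %% nrow(m)),
       x = as.numeric(m[idx]))
}

#' Zero the liquid state of a run
#'
#' Sets every membrane potential to the resting potential, clears
#' refractory counters and empties all synaptic delay buffers. The fixed
#' topology is untouched. Used for controlled experiments; ordinary
#' training never resets the liquid between RL steps.
#'
#' @param run an `lsm_liquid_run`.
#' @return the run, invisibly (modified in place).
#' @export
reset <- function(run) {
  stopifnot(inherits(run, "lsm_liquid_run"))
  n <- run$n_e + run$n_i
  run$v <- rep(run$v_rest, n)
  run$refrac <- integer(n)
  run$prev_e <- numeric(run$n_e)
  run$prev_i <- numeric(run$n_i)
  run$step_index <- 0L
  if (run$has_slow) {
    run$ring <- matrix(0, run$n_e, run$delay_slow)
    run$ring_pos <- 0L
  }
  invisible(run)
}

#' Present one window of input spikes to the liquid
#'
#' Simulates the liquid for `t_lsm_ms / dt_ms` steps driven by the given
#' input spike raster, accumulating excitatory spikes, and returns the
#' normalized activation: each excitatory neuron's spike count divided by
#' the maximum possible count (the window length in steps). The liquid
#' state persists into the next call.
#'
#' @param run an `lsm_liquid_run`.
#' @param input_spikes spike raster (`lsm_spike_train` or plain integer
#'   matrix) of dimensions `n_input x (t_lsm_ms / dt_ms)`.
#' @param record_counts also record the per-step total excitatory spike
#'   count (returned in attribute `"counts"`).
#' @param record_neurons integer indices of liquid neurons whose membrane
#'   potentials to record (attribute `"vtrace"`, neurons x steps).
#' @return numeric vector of length `n_excitatory` with values in [0, 1].
#' @examples
#' cfg <- init_config(10, 20, 5, k_input = 3, c_recurrent = 2,
#'                    allow_ratio_override = TRUE)
#' run <- liquid_run(build_recurrent_connectivity(cfg, seed = 1),
#'                   t_lsm_ms = 50)
#' set.seed(2)
#' act <- present(run, poisson_spikes(rate_vector(rep(100, 10)), 50))
#' range(act)
#' @export
present <- function(run, input_spikes, record_counts = FALSE,
                    record_neurons = integer(0)) {
  stopifnot(inherits(run, "lsm_liquid_run"))
  expected <- as.integer(round(run$t_lsm_ms / run$params$dt_ms))
  if (!is.matrix(input_spikes) || nrow(input_spikes) != run$n_p ||
      ncol(input_spikes) != expected)
    stop("input_spikes must be an ", run$n_p, " x ", expected,
         " raster matching the run's input size and presentation window")
  storage.mode(input_spikes) <- "integer"
  out <- lsm_present_cpp(run, input_spikes, record_counts,
                         as.integer(record_neurons))
  act <- out$activation
  if (record_counts) attr(act, "counts") <- out$counts
  if (length(record_neurons)) attr(act, "vtrace") <- out$vtrace
  act
}

#' @export
print.lsm_liquid_run <- function(x, ...) {
  cat("Liquid run:", x$n_e, "E +", x$n_i, "I neurons,", x$n_p, "inputs, ",
      "T_LSM =", x$t_lsm_ms, "ms",
      if (x$has_slow) paste0("(slow E->E delay ", x$delay_slow, " steps)"),
      "\n  simulated steps so far:", x$step_index, "\n")
  invisible(x)
}
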