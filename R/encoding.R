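#' Per-input-neuron firing-rate vector
#'
#' The interface between an environment state and the spiking input layer:
#' each input neuron is assigned a Poisson firing rate (Hz) and a sign.
#' Ordinary rate coding uses all-positive signs; the signed encoding of
#' low-dimensional states lets a neuron emit unit negative spikes.
#'
#' @param rates non-negative rate magnitudes in Hz, one per input neuron.
#' @param signs per-neuron sign (+1 or -1); defaults to all +1.
#' @return An object of class `lsm_rate_vector`.
#' @export
rate_vector <- function(rates, signs = NULL) {
  if (!all(is.finite(rates))) stop("rates must be finite")
  if (any(rates < 0)) stop("rate magnitudes must be non-negative")
  if (is.null(signs)) signs <- rep(1, length(rates))
  if (length(signs) != length(rates)) stop("signs must match rates in length")
  if (!all(signs %in% c(-1, 1))) stop("signs must be +1 or -1")
  structure(list(rates = as.numeric(rates), signs = as.numeric(signs)),
            class = "lsm_rate_vector")
}

#' Generate a Poisson spike raster from firing rates
#'
#' Converts rates to spikes on the 1 ms simulation grid: at every step each
#' neuron spikes independently with probability `rate / 1000` (its rate in
#' Hz scaled by 1000), i.e. a uniform draw below the scaled rate produces a
#' spike. Spikes carry the neuron's sign. Uses the current R RNG state.
#'
#' @param rates an `lsm_rate_vector` (or bare numeric rate vector).
#' @param duration_ms raster duration in ms.
#' @param dt_ms simulation step; the rate-to-probability scaling assumes
#'   1 ms.
#' @return integer matrix (`lsm_spike_train`) of -1/0/+1, neurons x steps,
#'   with attributes `dt_ms` and `duration_ms`.
#' @examples
#' set.seed(1)
#' s <- poisson_spikes(rate_vector(c(100, 0)), duration_ms = 100)
#' rowMeans(s != 0)  # ~0.1 for the 100 Hz neuron, 0 for the silent one
#' @export
poisson_spikes <- function(rates, duration_ms, dt_ms = 1) {
  if (!inherits(rates, "lsm_rate_vector")) rates <- rate_vector(rates)
  if (dt_ms != 1) stop("rate-to-probability scaling is defined for dt_ms = 1")
  if (any(rates$rates > 1000))
    stop("rates above 1000 Hz give per-step spike probability > 1")
  n <- length(rates$rates)
  steps <- as.integer(round(duration_ms / dt_ms))
  p <- rates$rates / 1000
  hit <- matrix(stats::runif(n * steps), n, steps) < p  # p recycles by row
  spk <- matrix(as.integer(hit), n, steps) * as.integer(rates$signs)
  structure(spk, dt_ms = dt_ms, duration_ms = duration_ms,
            class = c("lsm_spike_train", class(spk)))
}

normalize_ranges <- function(ranges, d) {
  # accepts a vector of symmetric half-widths or a 2 x d / d x 2 matrix of
  # (lo, hi) bounds; returns a 2 x d matrix
  if (is.matrix(ranges)) {
    if (nrow(ranges) != 2 && ncol(ranges) == 2) ranges <- t(ranges)
    stopifnot(nrow(ranges) == 2, ncol(ranges) == d)
    if (any(ranges[1, ] >= ranges[2, ])) stop("range lower bound >= upper")
    return(ranges)
  }
  stopifnot(length(ranges) == d, all(ranges > 0))
  rbind(-abs(ranges), abs(ranges))
}

#' One-hot level encoding of a real state vector
#'
#' Each state dimension is clipped to its range and linearly discretized
#' into `bins` equal-width levels (left-closed bins, the last bin closed on
#' the right); the input neuron of the active level fires at `max_rate`
#' and the other neurons of that group are silent. The output has
#' `length(state) * bins` neurons, exactly one active per dimension.
#'
#' @param state finite numeric state vector.
#' @param ranges per-dimension clip bounds: either symmetric half-widths
#'   (e.g. `c(2.5, 0.5, 0.28, 0.88)` for cartpole) or a 2 x d matrix of
#'   (lo, hi).
#' @param bins number of levels per dimension.
#' @param max_rate firing rate (Hz) of the active neuron.
#' @return an `lsm_rate_vector` of length `length(state) * bins`.
#' @examples
#' enc <- one_hot_rate_encode(c(0, 0, 0, 0), c(2.5, 0.5, 0.28, 0.88))
#' which(enc$rates > 0)  # bin index 5 (0-based) of each group of 10
#' @export
one_hot_rate_encode <- function(state, ranges, bins = 10, max_rate = 100) {
  if (!all(is.finite(state))) stop("state must be finite")
  d <- length(state)
  r <- normalize_ranges(ranges, d)
  lo <- r[1, ]; hi <- r[2, ]
  x <- pmin(pmax(state, lo), hi)
  idx0 <- pmin(bins - 1, floor((x - lo) / (hi - lo) * bins))
  rates <- numeric(d * bins)
  rates[(seq_len(d) - 1L) * bins + idx0 + 1L] <- max_rate
  rate_vector(rates)
}

#' Signed proportional-rate encoding of a real state vector
#'
#' One input neuron per state dimension: the rate magnitude is
#' `max_rate * |clip(x)| / half_width` and the spike sign follows the sign
#' of the state value, so negative values produce unit negative spikes.
#'
#' @inheritParams one_hot_rate_encode
#' @return an `lsm_rate_vector` of length `length(state)`.
#' @examples
#' signed_rate_encode(c(-0.14), c(0.28))  # 50 Hz, negative spikes
#' @export
signed_rate_encode <- function(state, ranges, max_rate = 100) {
  if (!all(is.finite(state))) stop("state must be finite")
  d <- length(state)
  r <- normalize_ranges(ranges, d)
  if (any(r[1, ] != -r[2, ]))
    stop("signed encoding requires symmetric ranges")
  half <- r[2, ]
  x <- pmin(pmax(state, -half), half)
  rate_vector(max_rate * abs(x) / half, ifelse(x < 0, -1, 1))
}

#' Binary object-map encoding of a grid game state
#'
#' Encodes object locations (for grid-Pacman: Pacman, food, cherry, ghost,
#' scared ghost, in that fixed plane order) given as 2-D binary arrays of
#' the game-grid dimensions. The planes are flattened row-major and
#' concatenated; occupied cells fire at `max_rate`.
#'
#' @param object_grids list of H x W binary (0/1 or logical) matrices, all
#'   of identical dimensions.
#' @param max_rate firing rate (Hz) of active cells.
#' @return an `lsm_rate_vector` of length `length(object_grids) * H * W`.
#' @export
binary_map_encode <- function(object_grids, max_rate = 100) {
  stopifnot(is.list(object_grids), length(object_grids) >= 1)
  dims <- dim(object_grids[[1]])
  if (is.null(dims)) stop("object grids must be matrices")
  flat <- lapply(object_grids, function(g) {
    if (!identical(dim(g), dims)) stop("object grids differ in shape")
    as.numeric(t(g != 0))  # row-major flatten
  })
  rate_vector(max_rate * unlist(flat, use.names = FALSE))
}
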