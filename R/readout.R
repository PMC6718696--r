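#' Initialize readout parameters
#'
#' The readout maps the liquid activation (a vector of normalized
#' excitatory firing rates) to one Q-value per action. With `hidden > 0`
#' it is a two-layer network with a ReLU after the hidden layer and no
#' non-linearity after the output layer (Q-values are unbounded); with
#' `hidden = 0` it is a single linear layer (used for the tabular
#' equivalence checks). Weights are initialized uniformly on
#' `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`, biases at zero; uses the current
#' R RNG state.
#'
#' @param n_in input dimension (number of excitatory liquid neurons).
#' @param hidden hidden layer width (e.g. 32 for cartpole, 128-512 for
#'   Pacman); 0 for a linear readout.
#' @param n_actions number of actions / output units.
#' @return An environment of class `lsm_readout` with fields `w1`
#'   (`n_in x hidden`, absent if linear), `b1`, `w2`, `b2`, `hidden`.
#' @export
readout_init <- function(n_in, hidden, n_actions) {
  stopifnot(n_in >= 1, hidden >= 0, n_actions >= 1)
  par <- new.env(parent = emptyenv())
  par$hidden <- hidden > 0
  par$n_in <- as.integer(n_in)
  par$n_actions <- as.integer(n_actions)
  unif <- function(nr, nc, fan_in)
    matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan_in), nr, nc)
  if (hidden > 0) {
    par$w1 <- unif(n_in, hidden, n_in)
    par$b1 <- numeric(hidden)
    par$w2 <- unif(hidden, n_actions, hidden)
    par$b2 <- numeric(n_actions)
  } else {
    par$w2 <- unif(n_in, n_actions, n_in)
    par$b2 <- numeric(n_actions)
  }
  class(par) <- "lsm_readout"
  par
}

#' Q-values for one activation (or a batch)
#'
#' Computes `q = w2' * relu(w1' * x + b1) + b2` (or the linear variant).
#'
#' @param par an `lsm_readout`.
#' @param x numeric vector of length `n_in`, or an `n_in x batch` matrix.
#' @return numeric vector of `n_actions` Q-values (or a matrix
#'   `n_actions x batch`).
#' @export
readout_forward <- function(par, x) {
  stopifnot(inherits(par, "lsm_readout"))
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  if (nrow(xm) != par$n_in)
    stop("activation has length ", nrow(xm), "; readout expects ", par$n_in)
  feat <- if (par$hidden) pmax(crossprod(par$w1, xm) + par$b1, 0) else xm
  q <- crossprod(par$w2, feat) + par$b2
  if (is.matrix(x)) q else drop(q)
}

#' Gradient of the squared Q-error for chosen actions
#'
#' Analytic gradient of `0.5 * mean((Q(x, a) - target)^2)` over a batch,
#' with respect to every readout parameter. Only the chosen action's output
#' unit propagates error; the batch reduction is the mean.
#'
#' @param par an `lsm_readout`.
#' @param x activation vector or `n_in x batch` matrix.
#' @param action 1-based action index (vector for a batch).
#' @param target regression target Y (vector for a batch).
#' @return list with `w1`, `b1` (if hidden), `w2`, `b2` gradients and the
#'   scalar `loss`.
#' @export
readout_grad <- function(par, x, action, target) {
  stopifnot(inherits(par, "lsm_readout"))
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  B <- ncol(xm)
  stopifnot(length(action) == B, length(target) == B, all(is.finite(target)))
  if (any(action < 1 | action > par$n_actions)) stop("invalid action index")

  if (par$hidden) {
    hpre <- crossprod(par$w1, xm) + par$b1
    feat <- pmax(hpre, 0)
  } else feat <- xm
  q <- crossprod(par$w2, feat) + par$b2

  dq <- matrix(0, par$n_actions, B)
  resid <- q[cbind(action, seq_len(B))] - target
  dq[cbind(action, seq_len(B))] <- resid / B

  g <- list(w2 = feat %*% t(dq), b2 = rowSums(dq),
            loss = mean(0.5 * resid^2))
  if (par$hidden) {
    dh <- (par$w2 %*% dq) * (hpre > 0)
    g$w1 <- xm %*% t(dh)
    g$b1 <- rowSums(dh)
  }
  g
}

#' Initialize an RMSProp optimizer state
#'
#' Squared-gradient accumulators start at zero. Defaults: learning rate
#' 2e-4, smoothing constant 0.99, denominator term 1e-6, weight decay 0.
#'
#' @param par an `lsm_readout` whose parameters this optimizer will update.
#' @param lr learning rate.
#' @param smoothing exponential smoothing constant of the squared-gradient
#'   average.
#' @param eps_denom term added to the denominator for numerical stability.
#' @param weight_decay L2 coefficient (kept at 0).
#' @return An environment of class `lsm_rmsprop`.
#' @export
rmsprop_init <- function(par, lr = 2e-4, smoothing = 0.99,
                         eps_denom = 1e-6, weight_decay = 0) {
  stopifnot(inherits(par, "lsm_readout"))
  if (weight_decay != 0) stop("weight decay is fixed at 0")
  opt <- new.env(parent = emptyenv())
  opt$lr <- lr; opt$smoothing <- smoothing; opt$eps_denom <- eps_denom
  opt$weight_decay <- weight_decay
  opt$sq_w2 <- par$w2 * 0
  opt$sq_b2 <- par$b2 * 0
  if (par$hidden) {
    opt$sq_w1 <- par$w1 * 0
    opt$sq_b1 <- par$b1 * 0
  }
  class(opt) <- "lsm_rmsprop"
  opt
}

#' Apply one RMSProp update (reference implementation)
#'
#' For each parameter tensor:
#' `sq <- smoothing * sq + (1 - smoothing) * g^2`;
#' `theta <- theta - lr * g / (sqrt(sq) + eps_denom)`.
#' Modifies `par` and `opt` in place. The training loop uses a fused
#' compiled kernel ([readout_train_step()]) tested to agree with
#' [readout_grad()] followed by this update.
#'
#' @param par an `lsm_readout`.
#' @param grads gradient list from [readout_grad()].
#' @param opt an `lsm_rmsprop`.
#' @return `par`, invisibly.
#' @export
rmsprop_update <- function(par, grads, opt) {
  stopifnot(inherits(par, "lsm_readout"), inherits(opt, "lsm_rmsprop"))
  upd <- function(name) {
    g <- grads[[name]]
    sq_name <- paste0("sq_", name)
    opt[[sq_name]] <- opt$smoothing * opt[[sq_name]] +
      (1 - opt$smoothing) * g^2
    par[[name]] <- par[[name]] - opt$lr * g / (sqrt(opt[[sq_name]]) +
                                                 opt$eps_denom)
  }
  upd("w2"); upd("b2")
  if (par$hidden) { upd("w1"); upd("b1") }
  invisible(par)
}

#' Fused mini-batch training step
#'
#' Forward pass, squared Q-error semi-gradient and RMSProp update in one
#' compiled call, modifying `par` and `opt` in place.
#'
#' @param par an `lsm_readout`.
#' @param opt an `lsm_rmsprop`.
#' @param x `n_in x batch` activation matrix.
#' @param action 1-based action indices, length batch.
#' @param target regression targets, length batch.
#' @return the scalar batch loss, invisibly.
#' @export
readout_train_step <- function(par, opt, x, action, target) {
  stopifnot(inherits(par, "lsm_readout"), inherits(opt, "lsm_rmsprop"))
  invisible(readout_train_cpp(par, opt, x, as.integer(action),
                              as.numeric(target)))
}

#' Snapshot / restore readout parameters
#'
#' `readout_snapshot()` copies the trainable parameters into a plain list
#' (suitable for serialization); `readout_restore()` writes such a list
#' back into a readout environment.
#'
#' @param par an `lsm_readout`.
#' @return a named list of parameter matrices/vectors.
#' @export
readout_snapshot <- function(par) {
  # `+ 0` forces fresh allocations: the fused training kernel updates the
  # parameter matrices in place, so a plain reference would track them
  out <- list(w2 = par$w2 + 0, b2 = par$b2 + 0, hidden = par$hidden,
              n_in = par$n_in, n_actions = par$n_actions)
  if (par$hidden) { out$w1 <- par$w1 + 0; out$b1 <- par$b1 + 0 }
  out
}

#' @rdname readout_snapshot
#' @param snapshot a list produced by `readout_snapshot()`.
#' @export
readout_restore <- function(par, snapshot) {
  par$w2 <- snapshot$w2; par$b2 <- snapshot$b2
  if (par$hidden) { par$w1 <- snapshot$w1; par$b1 <- snapshot$b1 }
  invisible(par)
}
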