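#' Derive a sub-seed for an independent random concern
#'
#' Experiments split their base seed into separate streams (topology
#' construction, readout initialization, training) so that, e.g., the same
#' liquid can be rebuilt bit-for-bit regardless of how much training
#' randomness was consumed.
#'
#' @param seed base experiment seed.
#' @param k concern index.
#' @return a derived integer seed below 2^31.
#' @export
derive_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) * 1000003 + k * 7919) %% 2147483629)
}

#' Assemble the agent of an experiment for one seed
#'
#' Builds the topology (stream 1), initializes the readout and optimizer
#' (stream 2) and seeds the training stream (stream 3, shared by the
#' Poisson encoder, the epsilon-greedy policy, replay sampling and the
#' environment).
#'
#' @param config an `lsm_experiment_config`.
#' @param seed base experiment seed.
#' @return list with `agent`, `env`, `topology`.
#' @export
setup_experiment <- function(config, seed) {
  stopifnot(inherits(config, "lsm_experiment_config"))
  topology <- build_recurrent_connectivity(config$init,
                                           seed = derive_seed(seed, 1))
  env <- make_env(config)
  set.seed(derive_seed(seed, 2))
  par <- readout_init(config$init$n_excitatory, config$readout$hidden,
                      env$n_actions)
  opt <- rmsprop_init(par, lr = config$readout$lr,
                      smoothing = config$readout$smoothing,
                      eps_denom = config$readout$eps_denom)
  rep <- liquid_representation(topology, make_encoder(config),
                               config$neuron, config$t_lsm_ms)
  agent <- lsm_agent(rep, par, opt, config$train, config$schedule)
  set.seed(derive_seed(seed, 3))
  list(agent = agent, env = env, topology = topology)
}

#' Train and evaluate an experiment across seeds
#'
#' For every seed: build the agent, then alternate `epoch_length` training
#' steps with `eval_steps` evaluation steps at the schedule's evaluation
#' epsilon, recording the accumulated reward averaged over completed
#' evaluation gameplays. Aggregates the per-epoch median and 25th/75th
#' percentiles across seeds. Fully reproducible from (config, seeds): the
#' same inputs give byte-identical result tables.
#'
#' @param config an `lsm_experiment_config`.
#' @param seeds integer seeds (default: the config's seed list).
#' @param out_dir optional directory; when given, writes `per_seed.csv`
#'   and `aggregate.csv` there.
#' @param progress print a line per epoch.
#' @return list of class `lsm_experiment_result` with data frames
#'   `per_seed` (seed, epoch, step, eval_reward, gameplays) and
#'   `aggregate` (epoch, median, q25, q75).
#' @export
run_experiment <- function(config, seeds = config$seeds, out_dir = NULL,
                           progress = FALSE) {
  stopifnot(inherits(config, "lsm_experiment_config"))
  n_epochs <- config$train$total_steps %/% config$train$epoch_length
  rows <- vector("list", length(seeds) * n_epochs)
  ri <- 0L
  for (seed in seeds) {
    setup <- setup_experiment(config, seed)
    for (epoch in seq_len(n_epochs)) {
      train_agent(setup$agent, setup$env, config$train$epoch_length)
      ev <- evaluate_agent(setup$agent, setup$env, config$train$eval_steps)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(seed = seed, epoch = epoch,
                               step = setup$agent$step,
                               eval_reward = ev$mean_reward,
                               gameplays = ev$gameplays)
      if (progress)
        message(sprintf("[%s] seed %d epoch %d/%d: eval reward %.2f",
                        config$name, seed, epoch, n_epochs,
                        ev$mean_reward))
    }
  }
  per_seed <- do.call(rbind, rows[seq_len(ri)])
  res <- structure(list(per_seed = per_seed,
                        aggregate = aggregate_curves(per_seed),
                        config_name = config$name),
                   class = "lsm_experiment_result")
  if (!is.null(out_dir)) write_experiment(res, out_dir)
  res
}

#' Aggregate per-seed reward curves into median and quartiles
#'
#' @param per_seed data frame with columns `seed`, `epoch`, `eval_reward`.
#' @return data frame with one row per epoch: `epoch`, `median`, `q25`,
#'   `q75`, `n_seeds`.
#' @export
aggregate_curves <- function(per_seed) {
  stopifnot(all(c("seed", "epoch", "eval_reward") %in% names(per_seed)))
  epochs <- sort(unique(per_seed$epoch))
  out <- lapply(epochs, function(ep) {
    r <- per_seed$eval_reward[per_seed$epoch == ep]
    data.frame(epoch = ep, median = stats::median(r),
               q25 = unname(stats::quantile(r, 0.25)),
               q75 = unname(stats::quantile(r, 0.75)),
               n_seeds = length(r))
  })
  do.call(rbind, out)
}

write_experiment <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$per_seed, file.path(out_dir, "per_seed.csv"),
                   row.names = FALSE)
  utils::write.csv(res$aggregate, file.path(out_dir, "aggregate.csv"),
                   row.names = FALSE)
  invisible(res)
}

#' Rebuild summary tables from a completed run directory
#'
#' Reads `per_seed.csv` from a run directory, recomputes the aggregate
#' median/quartile curves and rewrites `aggregate.csv`. Idempotent.
#'
#' @param run_dir directory containing `per_seed.csv`.
#' @return list with `per_seed` and `aggregate` data frames.
#' @export
report <- function(run_dir) {
  f <- file.path(run_dir, "per_seed.csv")
  if (!file.exists(f)) stop("missing run file: ", f)
  per_seed <- utils::read.csv(f)
  agg <- aggregate_curves(per_seed)
  utils::write.csv(agg, file.path(run_dir, "aggregate.csv"),
                   row.names = FALSE)
  list(per_seed = per_seed, aggregate = agg)
}

#' Stability and dynamics diagnostics of a configuration
#'
#' Builds the topology for each seed and reports the spectral radius of
#' the signed composite recurrent matrix, the finite-response probe and
#' (for the first seed) a membrane-potential trace sample.
#'
#' @param config an `lsm_experiment_config`.
#' @param seeds seeds to diagnose.
#' @return list with `spectra` data frame (seed, spectral_radius, stable,
#'   response_decayed), the first seed's `eigenvalues` (complex vector)
#'   and `membrane` trace matrix.
#' @export
diagnose <- function(config, seeds = config$seeds) {
  stopifnot(inherits(config, "lsm_experiment_config"))
  rows <- list()
  eig1 <- NULL
  memb <- NULL
  for (i in seq_along(seeds)) {
    topo <- build_recurrent_connectivity(config$init,
                                         seed = derive_seed(seeds[i], 1))
    cm <- composite_matrix(topo)
    ev <- eigen(cm, only.values = TRUE)$values
    set.seed(derive_seed(seeds[i], 3))
    probe <- finite_response_probe(topo, config$neuron)
    rows[[i]] <- data.frame(seed = seeds[i],
                            spectral_radius = max(Mod(ev)),
                            stable = max(Mod(ev)) <= 1,
                            response_decayed = probe$decayed)
    if (i == 1) {
      eig1 <- ev
      memb <- membrane_probe(topo, config$neuron)
    }
  }
  list(spectra = do.call(rbind, rows), eigenvalues = eig1, membrane = memb)
}

#' Random-policy baseline of an experiment's environment
#'
#' @param config an `lsm_experiment_config`.
#' @param seed RNG seed for the baseline rollout.
#' @param n_steps rollout length (defaults to the config's `eval_steps`).
#' @return mean accumulated reward per completed gameplay.
#' @export
experiment_random_baseline <- function(config, seed,
                                       n_steps = config$train$eval_steps) {
  env <- make_env(config)
  set.seed(derive_seed(seed, 4))
  random_policy_reward(env, n_steps)
}
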