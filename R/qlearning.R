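#' Epsilon-greedy exploration schedule
#'
#' During training, epsilon decays linearly from `eps_start` (1) to
#' `eps_final` over the first `decay_fraction` (10%) of the total training
#' steps and stays at `eps_final` afterwards. Evaluation uses the fixed
#' `eps_eval`.
#'
#' @param eps_start initial exploration probability.
#' @param eps_final final training exploration probability (1e-3 for
#'   cartpole; 1e-1 for Pacman-class tasks).
#' @param decay_fraction fraction of total training steps over which the
#'   decay runs.
#' @param eps_eval exploration probability during evaluation (0.05 for
#'   cartpole; 0 for Pacman).
#' @return An object of class `lsm_epsilon_schedule`.
#' @export
epsilon_schedule <- function(eps_start = 1, eps_final = 1e-3,
                             decay_fraction = 0.1, eps_eval = 0.05) {
  stopifnot(eps_start >= 0, eps_start <= 1, eps_final >= 0,
            eps_final <= eps_start, decay_fraction > 0, decay_fraction <= 1,
            eps_eval >= 0, eps_eval <= 1)
  structure(list(eps_start = eps_start, eps_final = eps_final,
                 decay_fraction = decay_fraction, eps_eval = eps_eval),
            class = "lsm_epsilon_schedule")
}

#' Exploration probability at a given training step
#'
#' @param step 0-based training step.
#' @param schedule an `lsm_epsilon_schedule`.
#' @param total_steps total training steps of the experiment.
#' @return epsilon in [0, 1].
#' @examples
#' epsilon_at(0, epsilon_schedule(), 1e5)      # 1
#' epsilon_at(5e3, epsilon_schedule(), 1e5)    # 0.5005
#' @export
epsilon_at <- function(step, schedule, total_steps) {
  if (step < 0) stop("step must be non-negative")
  d <- schedule$decay_fraction * total_steps
  if (step >= d) return(schedule$eps_final)
  schedule$eps_start - (step / d) * (schedule$eps_start - schedule$eps_final)
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniformly random action; otherwise the
#' action with the highest Q-value, ties broken toward the lowest index.
#' Consumes the current R RNG stream.
#'
#' @param q_values numeric vector of Q-values, one per action.
#' @param epsilon exploration probability.
#' @return 1-based action index.
#' @export
select_action <- function(q_values, epsilon) {
  n <- length(q_values)
  if (n < 1) stop("empty action set")
  if (epsilon > 0 && stats::runif(1) < epsilon) sample.int(n, 1)
  else which.max(q_values)
}

#' Bellman targets for a batch of transitions
#'
#' `Y = r + gamma * max_a Q(x_next, a)` for non-terminal transitions and
#' `Y = r` for terminal ones, evaluated with the current readout weights.
#' The max term is treated as a constant (semi-gradient): no gradient flows
#' through it.
#'
#' @param par an `lsm_readout` (the current weights).
#' @param x_next `n_in x batch` matrix of next-state activations.
#' @param reward,terminal per-transition reward and terminal flag.
#' @param gamma discount factor.
#' @return numeric target vector.
#' @export
compute_targets <- function(par, x_next, reward, terminal, gamma) {
  qn <- readout_forward(par, x_next)
  if (!is.matrix(qn)) qn <- matrix(qn, ncol = 1)
  maxq <- apply(qn, 2, max)
  reward + gamma * maxq * as.numeric(!terminal)
}

#' Atari-style reward clipping
#'
#' Maps every positive immediate reward to +1 and every negative one to
#' -1; zero stays zero. Optional (off by default); applied to stored
#' training rewards only, never to evaluation scores.
#'
#' @param reward numeric reward(s).
#' @return clipped reward(s).
#' @export
clip_reward <- function(reward) sign(reward)

#' Experience replay buffer
#'
#' FIFO ring buffer of transitions `(x, action, reward, x_next, terminal)`
#' where `x` is the liquid activation of the state. Sampling is uniform
#' with replacement over the stored transitions (so mini-batches can be
#' drawn even from a nearly empty buffer). Storage grows geometrically up
#' to `capacity`.
#'
#' @param capacity maximum number of stored transitions (1e6).
#' @param n_features activation length.
#' @return An environment of class `lsm_replay_buffer`.
#' @export
replay_buffer <- function(capacity = 1e6, n_features) {
  stopifnot(capacity >= 1, n_features >= 1)
  buf <- new.env(parent = emptyenv())
  buf$capacity <- as.integer(capacity)
  buf$n_features <- as.integer(n_features)
  buf$alloc <- as.integer(min(capacity, 4096))
  buf$x <- matrix(0, n_features, buf$alloc)
  buf$xn <- matrix(0, n_features, buf$alloc)
  buf$action <- integer(buf$alloc)
  buf$reward <- numeric(buf$alloc)
  buf$terminal <- logical(buf$alloc)
  buf$size <- 0L
  buf$pos <- 0L  # last written slot
  class(buf) <- "lsm_replay_buffer"
  buf
}

grow_buffer <- function(buf, need) {
  new_alloc <- as.integer(min(buf$capacity, max(need, 2L * buf$alloc)))
  pad <- new_alloc - buf$alloc
  buf$x <- cbind(buf$x, matrix(0, buf$n_features, pad))
  buf$xn <- cbind(buf$xn, matrix(0, buf$n_features, pad))
  buf$action <- c(buf$action, integer(pad))
  buf$reward <- c(buf$reward, numeric(pad))
  buf$terminal <- c(buf$terminal, logical(pad))
  buf$alloc <- new_alloc
}

#' Store one transition
#'
#' Overwrites the oldest entry once the buffer is full (strict FIFO
#' eviction).
#'
#' @param buf an `lsm_replay_buffer`.
#' @param x,action,reward,x_next,terminal the transition record.
#' @return the buffer, invisibly.
#' @export
replay_add <- function(buf, x, action, reward, x_next, terminal) {
  pos <- if (buf$pos >= buf$capacity) 1L else buf$pos + 1L
  if (pos > buf$alloc) grow_buffer(buf, pos)
  replay_store_cpp(buf, pos, x, x_next, as.integer(action), reward,
                   terminal)
  buf$pos <- pos
  buf$size <- min(buf$size + 1L, buf$capacity)
  invisible(buf)
}

#' Sample transition indices uniformly with replacement
#'
#' @param buf an `lsm_replay_buffer`.
#' @param batch_size number of transitions to draw.
#' @return integer indices into the buffer's storage.
#' @export
replay_sample <- function(buf, batch_size) {
  if (buf$size < 1L) stop("cannot sample from an empty replay buffer")
  sample.int(buf$size, batch_size, replace = TRUE)
}

#' Bundle a representation, readout and training configuration into an agent
#'
#' The representation abstracts the liquid: `rep$fn(obs)` maps an
#' environment observation to a feature/activation vector of length
#' `rep$n_features` (possibly statefully, as the liquid does) and
#' `rep$reset()` (optional) zeroes that state. Use
#' [liquid_representation()] for the LSM agent or
#' [onehot_representation()] for the tabular checks.
#'
#' @param rep representation list (`fn`, `n_features`, optional `reset`).
#' @param par an `lsm_readout`.
#' @param opt an `lsm_rmsprop`.
#' @param train_cfg an `lsm_train_config` ([train_config()]).
#' @param schedule an `lsm_epsilon_schedule`.
#' @return An environment of class `lsm_agent` with a fresh replay buffer
#'   and step counter 0.
#' @export
lsm_agent <- function(rep, par, opt, train_cfg, schedule) {
  stopifnot(is.function(rep$fn), rep$n_features >= 1,
            inherits(par, "lsm_readout"), inherits(opt, "lsm_rmsprop"),
            inherits(train_cfg, "lsm_train_config"),
            inherits(schedule, "lsm_epsilon_schedule"))
  a <- new.env(parent = emptyenv())
  a$rep <- rep
  a$par <- par
  a$opt <- opt
  a$cfg <- train_cfg
  a$schedule <- schedule
  a$buffer <- replay_buffer(train_cfg$buffer_capacity, rep$n_features)
  a$step <- 0L
  class(a) <- "lsm_agent"
  a
}

#' Q-learning simulation parameters
#'
#' Defaults: discount 0.95, mini-batch 32, 100 warm-up steps before the
#' first weight update, one readout update per game-step, replay capacity
#' 1e6.
#'
#' @param total_steps total training steps of the experiment (drives the
#'   epsilon decay).
#' @param epoch_length training steps per epoch.
#' @param eval_steps evaluation steps after each epoch.
#' @param gamma discount factor.
#' @param batch_size replay mini-batch size.
#' @param warmup_steps steps collected before updates begin.
#' @param update_every game-steps between readout updates.
#' @param buffer_capacity replay buffer capacity.
#' @param clip_rewards apply [clip_reward()] to stored training rewards.
#' @param episodic_liquid_reset zero the liquid at episode boundaries
#'   (ablation; off by default — the liquid normally carries over).
#' @return An object of class `lsm_train_config`.
#' @export
train_config <- function(total_steps, epoch_length = 1000,
                         eval_steps = 1000, gamma = 0.95, batch_size = 32,
                         warmup_steps = 100, update_every = 1,
                         buffer_capacity = 1e6, clip_rewards = FALSE,
                         episodic_liquid_reset = FALSE) {
  stopifnot(total_steps >= 1, epoch_length >= 1, eval_steps >= 0,
            gamma >= 0, gamma <= 1, batch_size >= 1, warmup_steps >= 0,
            update_every >= 1, buffer_capacity >= 1)
  structure(list(total_steps = as.integer(total_steps),
                 epoch_length = as.integer(epoch_length),
                 eval_steps = as.integer(eval_steps),
                 gamma = gamma, batch_size = as.integer(batch_size),
                 warmup_steps = as.integer(warmup_steps),
                 update_every = as.integer(update_every),
                 buffer_capacity = buffer_capacity,
                 clip_rewards = isTRUE(clip_rewards),
                 episodic_liquid_reset = isTRUE(episodic_liquid_reset)),
            class = "lsm_train_config")
}

#' Liquid-based state representation
#'
#' Encodes each observation to input rates, draws a Poisson spike raster
#' for one presentation window and runs it through the (stateful) liquid,
#' returning the normalized excitatory activation.
#'
#' @param topology an `lsm_topology`.
#' @param encoder function mapping an observation to an
#'   `lsm_rate_vector` of length `n_input`.
#' @param params an `lsm_neuron_params`.
#' @param t_lsm_ms presentation window in ms.
#' @return representation list for [lsm_agent()]; the underlying
#'   `lsm_liquid_run` is exposed as `$run`.
#' @export
liquid_representation <- function(topology, encoder,
                                  params = neuron_params(),
                                  t_lsm_ms = 100) {
  run <- liquid_run(topology, params, t_lsm_ms)
  steps <- as.integer(round(t_lsm_ms / params$dt_ms))
  fast <- attr(encoder, "fast")
  # fused compiled path; bit-identical to poisson_spikes() |> present()
  fn <- if (is.null(fast)) function(obs) {
    rv <- encoder(obs)
    lsm_encode_present_cpp(run, rv$rates / 1000, rv$signs, steps)
  } else function(obs) {
    rv <- fast(obs)
    lsm_encode_present_cpp(run, rv$prob, rv$sign, steps)
  }
  list(fn = fn,
       reset = function() reset(run),
       n_features = topology$config$n_excitatory,
       run = run)
}

#' One-hot tabular state representation
#'
#' Replaces the liquid with an exact one-hot encoding of a discrete state
#' index; with a linear readout this reduces the architecture to tabular
#' Q-learning, whose fixed point is known from value iteration.
#'
#' @param n_states number of discrete states.
#' @return representation list for [lsm_agent()].
#' @export
onehot_representation <- function(n_states) {
  list(fn = function(obs) {
    v <- numeric(n_states); v[obs] <- 1; v
  }, n_features = n_states)
}

#' Run training steps
#'
#' Executes the per-game-step loop: represent the state, pick an
#' epsilon-greedy action, step the environment, store the transition
#' (activations, not raw states), and — once past the warm-up — sample a
#' mini-batch, compute Bellman targets with the current weights and apply
#' one RMSProp update. The epsilon schedule advances with the agent's
#' global step counter, so training may be split into epochs by calling
#' this repeatedly.
#'
#' @param agent an `lsm_agent`.
#' @param env an `lsm_env`.
#' @param n_steps game-steps to run.
#' @return invisibly, a list with `reward` (total training reward observed,
#'   unclipped) and `episodes` (episodes completed).
#' @export
train_agent <- function(agent, env, n_steps) {
  stopifnot(inherits(agent, "lsm_agent"), inherits(env, "lsm_env"))
  cfg <- agent$cfg
  buf <- agent$buffer
  par <- agent$par
  zero <- numeric(agent$rep$n_features)
  obs0 <- env$reset()   # forced before encoding (fn may ignore its arg)
  x <- agent$rep$fn(obs0)
  total_r <- 0
  episodes <- 0L
  for (i in seq_len(n_steps)) {
    eps <- epsilon_at(agent$step, agent$schedule, cfg$total_steps)
    q <- readout_q_cpp(par, x)
    act <- select_action(q, eps)
    res <- env$step(act)
    r <- if (cfg$clip_rewards) clip_reward(res$reward) else res$reward
    total_r <- total_r + res$reward
    xn <- if (res$terminal) zero else agent$rep$fn(res$obs)
    replay_add(buf, x, act, r, xn, res$terminal)
    agent$step <- agent$step + 1L
    if (agent$step > cfg$warmup_steps &&
        agent$step %% cfg$update_every == 0L) {
      idx <- replay_sample(buf, cfg$batch_size)
      qlearn_update_cpp(buf, par, agent$opt, idx, cfg$gamma)
    }
    if (res$terminal) {
      episodes <- episodes + 1L
      if (cfg$episodic_liquid_reset && !is.null(agent$rep$reset))
        agent$rep$reset()
      obs0 <- env$reset()
      x <- agent$rep$fn(obs0)
    } else x <- xn
  }
  invisible(list(reward = total_r, episodes = episodes))
}

#' Evaluate the agent for a fixed number of game-steps
#'
#' Runs the epsilon-greedy policy (no learning, no replay) for `n_steps`
#' and reports the accumulated reward averaged over completed gameplays;
#' the final gameplay, if truncated by the evaluation window, is excluded
#' (unless no gameplay completed, in which case its partial reward is
#' reported). Rewards are never clipped during evaluation.
#'
#' @param agent an `lsm_agent`.
#' @param env an `lsm_env`.
#' @param n_steps evaluation window in game-steps.
#' @param epsilon exploration probability; defaults to the schedule's
#'   `eps_eval`.
#' @return list with `mean_reward`, per-gameplay `rewards`, and the number
#'   of completed `gameplays`.
#' @export
evaluate_agent <- function(agent, env, n_steps,
                           epsilon = agent$schedule$eps_eval) {
  stopifnot(inherits(agent, "lsm_agent"), inherits(env, "lsm_env"))
  par <- agent$par
  obs0 <- env$reset()
  x <- agent$rep$fn(obs0)
  rewards <- numeric(0)
  cur <- 0
  for (i in seq_len(n_steps)) {
    act <- select_action(readout_q_cpp(par, x), epsilon)
    res <- env$step(act)
    cur <- cur + res$reward
    if (res$terminal) {
      rewards <- c(rewards, cur)
      cur <- 0
      obs0 <- env$reset()
      x <- agent$rep$fn(obs0)
    } else x <- agent$rep$fn(res$obs)
  }
  mean_r <- if (length(rewards)) mean(rewards) else cur
  list(mean_reward = mean_r, rewards = rewards,
       gameplays = length(rewards))
}

#' Mean gameplay reward of the uniform-random policy
#'
#' Baseline: plays `n_steps` with actions drawn uniformly, reporting the
#' mean accumulated reward per completed gameplay (same accounting as
#' [evaluate_agent()]).
#'
#' @param env an `lsm_env`.
#' @param n_steps number of game-steps.
#' @return mean reward per completed gameplay.
#' @export
random_policy_reward <- function(env, n_steps) {
  env$reset()
  rewards <- numeric(0)
  cur <- 0
  for (i in seq_len(n_steps)) {
    res <- env$step(sample.int(env$n_actions, 1))
    cur <- cur + res$reward
    if (res$terminal) {
      rewards <- c(rewards, cur)
      cur <- 0
      env$reset()
    }
  }
  if (length(rewards)) mean(rewards) else cur
}
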