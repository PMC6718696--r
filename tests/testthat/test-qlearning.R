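test_that("epsilon decays linearly over the first tenth of training", {
  sch <- epsilon_schedule(eps_final = 1e-3)
  total <- 1e5
  expect_equal(epsilon_at(0, sch, total), 1)
  expect_equal(epsilon_at(0.05 * total, sch, total), 1 - 0.5 * (1 - 1e-3))
  expect_equal(epsilon_at(0.1 * total, sch, total), 1e-3)
  expect_equal(epsilon_at(total, sch, total), 1e-3)
  # bounded and non-increasing at every step
  eps <- sapply(seq(0, total, by = 500), epsilon_at, schedule = sch,
                total_steps = total)
  expect_true(all(eps >= 0 & eps <= 1))
  expect_true(all(diff(eps) <= 0))
  expect_error(epsilon_schedule(eps_final = 2))
})

test_that("action selection exploits, breaks ties low, and explores uniformly", {
  expect_equal(select_action(c(1, 3), 0), 2L)
  expect_equal(select_action(c(2, 2), 0), 1L)   # documented tie-break
  expect_error(select_action(numeric(0), 0.5), "empty")
  set.seed(1)
  draws <- replicate(1e4, select_action(c(0, 1), 1))
  p1 <- mean(draws == 1)
  expect_lt(abs(p1 - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("Bellman targets bootstrap from the max next-state Q-value", {
  par <- readout_init(2, 0, 2)
  par$w2 <- matrix(c(1, 0, 0, 2), 2, 2)  # q = (x1, 2 * x2)
  par$b2 <- c(0, 0)
  x_next <- matrix(c(1, 1), 2, 1)        # q_next = (1, 2), max = 2
  expect_equal(compute_targets(par, x_next, 1, FALSE, 0.95), 2.9)
  expect_equal(compute_targets(par, x_next, 1, TRUE, 0.95), 1)
  expect_equal(compute_targets(par, x_next, 0.7, FALSE, 0), 0.7)
  # batch mixes terminal and non-terminal entries
  xb <- cbind(c(1, 1), c(3, 0))
  expect_equal(compute_targets(par, xb, c(1, 2), c(FALSE, FALSE), 0.5),
               c(1 + 0.5 * 2, 2 + 0.5 * 3))
})

test_that("reward clipping maps signs to unit rewards", {
  expect_equal(clip_reward(c(7.3, -0.2, 0)), c(1, -1, 0))
})

test_that("replay buffer evicts FIFO and samples uniformly", {
  buf <- replay_buffer(capacity = 5, n_features = 2)
  for (i in 1:7)
    replay_add(buf, c(i, i), 1L, i, c(0, 0), FALSE)
  expect_equal(buf$size, 5L)
  # slots now hold records 6, 7, 3, 4, 5 (ring overwrote the two oldest)
  expect_setequal(buf$reward[1:5], c(6, 7, 3, 4, 5))

  # uniform with replacement: chi-square over 1e4 draws on a 10-item buffer
  buf2 <- replay_buffer(capacity = 100, n_features = 1)
  for (i in 1:10) replay_add(buf2, 0, 1L, i, 0, FALSE)
  set.seed(2)
  idx <- replicate(1e4, replay_sample(buf2, 1))
  tab <- tabulate(idx, 10)
  pval <- stats::chisq.test(tab)$p.value
  expect_gt(pval, 1e-3)

  # a 1-transition buffer still yields full batches (with replacement)
  buf3 <- replay_buffer(capacity = 10, n_features = 1)
  replay_add(buf3, 1, 1L, 0, 0, FALSE)
  expect_length(replay_sample(buf3, 32), 32)
  expect_error(replay_sample(replay_buffer(5, 1), 4), "empty")
})

test_that("replay storage grows transparently past its initial allocation", {
  buf <- replay_buffer(capacity = 1e6, n_features = 3)
  n <- 5000  # beyond the 4096 initial allocation
  for (i in 1:n) replay_add(buf, c(i, 0, 0), 1L, i, c(0, 0, 0), FALSE)
  expect_equal(buf$size, n)
  expect_equal(buf$x[1, n], n)
  expect_equal(buf$reward[n], n)
})

make_toy_mdp_agent <- function(total_steps, hidden = 0,
                               eps_final = 0.1) {
  transitions <- matrix(c(1L, 1L,   # s1: a1 -> s1, s2: a1 -> s1
                          2L, 2L),  # s1: a2 -> s2, s2: a2 -> s2
                        2, 2)
  rewards <- matrix(c(0.02, 0.05,
                      0,    0), 2, 2)
  env <- mdp_env(transitions, rewards)
  par <- readout_init(2, hidden, 2)
  opt <- rmsprop_init(par)
  agent <- lsm_agent(onehot_representation(2), par, opt,
                     train_config(total_steps = total_steps,
                                  eval_steps = 0),
                     epsilon_schedule(eps_final = eps_final, eps_eval = 0))
  list(agent = agent, env = env, transitions = transitions,
       rewards = rewards)
}

test_that("no parameters change during the warm-up period", {
  set.seed(3)
  s <- make_toy_mdp_agent(1000)
  before <- readout_snapshot(s$agent$par)
  train_agent(s$agent, s$env, 100)   # exactly the warm-up length
  expect_identical(readout_snapshot(s$agent$par), before)
  expect_equal(s$agent$buffer$size, 100L)
  train_agent(s$agent, s$env, 10)    # first post-warm-up updates
  expect_false(identical(readout_snapshot(s$agent$par)$w2, before$w2))
})

test_that("training is bit-reproducible given the seed", {
  run_once <- function() {
    set.seed(99)
    s <- make_toy_mdp_agent(500)
    train_agent(s$agent, s$env, 500)
    readout_snapshot(s$agent$par)
  }
  expect_identical(run_once(), run_once())
})

test_that("tabular agent converges to the value-iteration fixed point", {
  set.seed(4)
  s <- make_toy_mdp_agent(20000)
  train_agent(s$agent, s$env, 20000)
  q_star <- value_iteration_q(s$transitions, s$rewards, 0.95)
  q_learned <- t(sapply(1:2, function(st) {
    readout_forward(s$agent$par, onehot_representation(2)$fn(st))
  }))
  expect_lt(max(abs(q_learned - q_star) / abs(q_star)), 0.05)
  # the greedy policy matches the optimal one
  expect_equal(apply(q_learned, 1, which.max),
               apply(q_star, 1, which.max))
})

test_that("evaluation averages completed gameplays only", {
  set.seed(5)
  # an environment that terminates every 3rd step with reward 1 per step
  env <- local({
    e <- new.env()
    e$n_actions <- 2L
    e$k <- 0L
    e$reset <- function() { e$k <- 0L; 0 }
    e$step <- function(a) {
      e$k <- e$k + 1L
      list(obs = 0, reward = 1, terminal = e$k >= 3L)
    }
    class(e) <- "lsm_env"
    e
  })
  par <- readout_init(1, 0, 2)
  agent <- lsm_agent(list(fn = function(obs) 1, n_features = 1),
                     par, rmsprop_init(par),
                     train_config(total_steps = 10),
                     epsilon_schedule())
  ev <- evaluate_agent(agent, env, 8)   # 2 full gameplays + 2 spare steps
  expect_equal(ev$gameplays, 2L)
  expect_equal(ev$mean_reward, 3)
})
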