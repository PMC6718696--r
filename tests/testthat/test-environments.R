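test_that("cartpole trajectory matches an independently coded integrator", {
  env <- cartpole_env()
  set.seed(1)
  obs0 <- env$reset()
  s0 <- env$s
  actions <- rep(c(1L, 2L, 2L, 1L), 10)
  traj <- matrix(NA_real_, length(actions), 4)
  for (k in seq_along(actions)) {
    r <- env$step(actions[k])
    traj[k, ] <- r$obs
    expect_equal(r$reward, 1)
    if (r$terminal) break
  }
  done <- which(!is.na(traj[, 1]))
  oracle <- reference_cartpole(s0, actions)
  expect_equal(traj[done, ], oracle[done, ], tolerance = 1e-12)
})

test_that("cartpole terminates on angle, position and the 200-step cap", {
  env <- cartpole_env()
  set.seed(2)
  env$reset()
  env$s <- c(0, 0, 0.279, 2)   # one step pushes the angle past 0.28
  r <- env$step(2L)
  expect_true(r$terminal)
  expect_error(env$step(1L), "terminal")

  env$reset()
  env$s <- c(2.49, 3, 0, 0)
  expect_true(env$step(2L)$terminal)   # cart leaves the rail
  expect_error(cartpole_env()$step(3L), "action")
})

test_that("a stabilizing controller collects the maximum reward of 200", {
  env <- cartpole_env()
  set.seed(3)
  obs <- env$reset()
  total <- 0
  repeat {
    r <- env$step(pd_policy(obs))
    total <- total + r$reward
    obs <- r$obs
    if (r$terminal) break
  }
  expect_equal(total, 200)
  expect_equal(env$steps, 200L)
})

test_that("partial observation exposes only position and angle", {
  env <- cartpole_env(partial = TRUE)
  set.seed(4)
  obs <- env$reset()
  expect_length(obs, 2)
  full <- env$s
  r <- env$step(1L)
  expect_equal(r$obs, env$s[c(1, 3)])
})

test_that("zero-force pole dynamics follow the linearized pendulum solution", {
  env <- cartpole_env(force_mag = 0)
  env$reset()
  phi0 <- 0.01
  env$s <- c(0, 0, phi0, 0)
  n <- 15
  phis <- numeric(n)
  for (k in 1:n) phis[k] <- env$step(1L)$obs[3]
  # inverted pendulum, small angle: phi'' = omega^2 phi with
  # omega^2 = g / (l (4/3 - m_p / M)); phi(t) = phi0 cosh(omega t)
  omega <- sqrt(9.8 / (0.5 * (4 / 3 - 0.1 / 1.1)))
  expected <- phi0 * cosh(omega * 0.02 * (1:n))
  # Euler at 20 ms accumulates a few percent against the exact solution
  expect_equal(phis, expected, tolerance = 0.03)
})

test_that("pacman corridor transcript matches the hand trace", {
  # P, cherry, food, ghost, food along a walled corridor
  lay <- ascii_to_layout(c("%%%%%%%",
                           "%Po.G.%",
                           "%%%%%%%"))
  expect_equal(lay$pacman, c(2L, 2L))
  expect_equal(max_achievable_reward(lay), 5L)  # 2 food + cherry + capture + bonus

  env <- pacman_env(lay, scared_duration = 10)
  env$reset()
  # step 1: eat the cherry; the ghost turns scared and flees to (2,6)
  r1 <- env$step(4L)
  expect_equal(r1$reward, 1)
  expect_false(r1$terminal)
  expect_equal(env$ghosts[[1]]$pos, c(2L, 6L))
  expect_equal(env$ghosts[[1]]$scared, 9L)
  # step 2: eat the food at (2,4); the cornered ghost's best flee is to stay
  r2 <- env$step(4L)
  expect_equal(r2$reward, 1)
  expect_equal(env$ghosts[[1]]$pos, c(2L, 6L))
  # step 3: advance; ghost still pinned in the corner
  r3 <- env$step(4L)
  expect_equal(r3$reward, 0)
  expect_equal(env$ghosts[[1]]$pos, c(2L, 6L))
  # step 4: eat the last food and the scared ghost on the same cell:
  # food + capture + completion bonus, ghost respawns at its start cell
  r4 <- env$step(4L)
  expect_equal(r4$reward, 3)
  expect_true(r4$terminal)
  expect_equal(sum(r4$obs$food), 0)
  expect_equal(env$ghosts[[1]]$pos, c(2L, 5L))
  # episode total equals the layout's accounting bound exactly
  expect_equal(r1$reward + r2$reward + r3$reward + r4$reward,
               max_achievable_reward(lay))
})

test_that("a chasing ghost that reaches Pacman ends the episode", {
  lay <- ascii_to_layout(c("%%%%%%",
                           "%P.oG%",
                           "%%%%%%"))
  env <- pacman_env(lay)
  env$reset()
  r1 <- env$step(5L)  # stay; ghost (2,5) -> (2,4)
  expect_equal(r1$reward, 0)
  r2 <- env$step(5L)  # ghost (2,4) -> (2,3)
  expect_false(r2$terminal)
  r3 <- env$step(5L)  # ghost moves onto Pacman
  expect_true(r3$terminal)
  expect_equal(r3$reward, 0)
  expect_error(env$step(5L), "terminal")
})

test_that("walls block movement and invalid actions are rejected", {
  lay <- ascii_to_layout(c("%%%%%%",
                           "%P. .%",
                           "%%%%%%"))
  env <- pacman_env(lay)
  env$reset()
  r <- env$step(1L)   # up into the wall: Pacman stays put
  expect_equal(which(r$obs$pacman == 1, arr.ind = TRUE)[1, ],
               c(row = 2L, col = 2L))
  expect_error(env$step(9L), "action")
})

test_that("accounting bound matches exhaustive search on a ghost-free grid", {
  lay <- layout_generator(c(2, 3), n_food = 2, n_ghost = 0, n_cherry = 0,
                          seed = 7)
  bound <- max_achievable_reward(lay)
  expect_equal(bound, 3L)
  # brute force over all action sequences of length 4
  best <- 0
  grid <- expand.grid(rep(list(1:5), 4))
  for (i in seq_len(nrow(grid))) {
    env <- pacman_env(lay)
    env$reset()
    tot <- 0
    for (a in unlist(grid[i, ])) {
      r <- env$step(a)
      tot <- tot + r$reward
      if (r$terminal) break
    }
    best <- max(best, tot)
  }
  expect_equal(best, bound)
})

test_that("episode rewards never exceed the accounting bound", {
  lay <- layout_generator(7, n_food = 3, n_ghost = 1, n_cherry = 1,
                          seed = 11)
  bound <- max_achievable_reward(lay)
  set.seed(12)
  for (rep in 1:10) {
    env <- pacman_env(lay, max_steps = 200)
    env$reset()
    tot <- 0
    repeat {
      r <- env$step(sample.int(5, 1))
      tot <- tot + r$reward
      # entity conservation: food/cherry counts never increase
      expect_lte(sum(r$obs$food), 3)
      expect_lte(sum(r$obs$cherry), 1)
      expect_equal(sum(r$obs$ghost) + sum(r$obs$scared_ghost), 1)
      if (r$terminal) break
    }
    expect_lte(tot, bound)
  }
})

test_that("layout generation is deterministic, capacity-checked and safe", {
  l1 <- layout_generator(7, 3, 1, 0, seed = 1)
  l2 <- layout_generator(7, 3, 1, 0, seed = 1)
  expect_identical(l1, l2)
  expect_equal(length(l1$foods), 3L)
  expect_equal(length(l1$ghosts), 1L)
  expect_error(layout_generator(2, 5, 0, 0, seed = 1), "capacity")
  # Pacman never starts adjacent to a ghost
  for (seed in 1:25) {
    l <- layout_generator(5, 2, 2, 0, seed = seed)
    for (g in l$ghosts)
      expect_gt(abs(g[1] - l$pacman[1]) + abs(g[2] - l$pacman[2]), 1)
  }
})

test_that("ascii layouts round-trip", {
  lay <- layout_generator(c(4, 6), 3, 1, 1, seed = 3)
  txt <- layout_to_ascii(lay)
  back <- ascii_to_layout(txt)
  expect_equal(back$h, lay$h)
  expect_equal(back$pacman, lay$pacman)
  expect_setequal(vapply(back$foods, paste, "", collapse = ","),
                  vapply(lay$foods, paste, "", collapse = ","))
})

test_that("pacman environments are deterministic given seed and actions", {
  lay <- layout_generator(7, 3, 2, 1, seed = 5)
  play <- function() {
    set.seed(42)
    env <- pacman_env(lay)
    env$reset()
    out <- numeric(0)
    for (i in 1:60) {
      r <- env$step(sample.int(5, 1))
      out <- c(out, r$reward)
      if (r$terminal) env$reset()
    }
    out
  }
  expect_identical(play(), play())
})
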