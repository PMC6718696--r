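#' Cartpole balancing environment
#'
#' Classic cart-pole dynamics (Sutton-Barto formulation: gravity 9.8 m/s^2,
#' cart mass 1 kg, pole mass 0.1 kg, half-pole length 0.5 m, force
#' magnitude 10 N, Euler integration at 0.02 s), with termination when the
#' cart leaves +-2.5 m or the pole exceeds +-0.28 rad, or after
#' `max_steps` steps. Every step returns unit reward, so a perfectly
#' balanced episode accumulates exactly `max_steps` (200) reward. In
#' partial mode the observation is only (position, angle); the full
#' observation is (position, velocity, angle, angular velocity). Episode
#' starts draw all four state variables uniformly from +-0.05 using the
#' current R RNG state.
#'
#' @param partial observe only cart position and pole angle.
#' @param max_steps episode length cap (200).
#' @param x_limit,phi_limit termination thresholds.
#' @param force_mag magnitude of the unit force action, in N.
#' @return An environment of class `lsm_env` with functions
#'   `reset()` and `step(action)`; actions are 1 (push left) and
#'   2 (push right). `step()` returns a list `(obs, reward, terminal)`.
#' @export
cartpole_env <- function(partial = FALSE, max_steps = 200,
                         x_limit = 2.5, phi_limit = 0.28, force_mag = 10) {
  e <- new.env(parent = emptyenv())
  e$n_actions <- 2L
  e$kind <- if (partial) "cartpole_partial" else "cartpole"
  gravity <- 9.8; masscart <- 1; masspole <- 0.1
  total_mass <- masscart + masspole
  length_half <- 0.5
  polemass_length <- masspole * length_half
  tau <- 0.02

  obs <- function() if (partial) e$s[c(1, 3)] else e$s

  e$reset <- function() {
    e$s <- stats::runif(4, -0.05, 0.05)
    e$steps <- 0L
    e$terminal <- FALSE
    obs()
  }
  e$step <- function(action) {
    if (!(action %in% c(1L, 2L))) stop("cartpole action must be 1 or 2")
    if (e$terminal) stop("step() called on a terminal cartpole episode")
    s <- e$s
    force <- if (action == 2L) force_mag else -force_mag
    costh <- cos(s[3]); sinth <- sin(s[3])
    temp <- (force + polemass_length * s[4]^2 * sinth) / total_mass
    phiacc <- (gravity * sinth - costh * temp) /
      (length_half * (4 / 3 - masspole * costh^2 / total_mass))
    xacc <- temp - polemass_length * phiacc * costh / total_mass
    s <- c(s[1] + tau * s[2], s[2] + tau * xacc,
           s[3] + tau * s[4], s[4] + tau * phiacc)
    e$s <- s
    e$steps <- e$steps + 1L
    e$terminal <- abs(s[1]) > x_limit || abs(s[3]) > phi_limit ||
      e$steps >= max_steps
    list(obs = obs(), reward = 1, terminal = e$terminal)
  }
  class(e) <- "lsm_env"
  e
}

manhattan <- function(a, b) abs(a[1] - b[1]) + abs(a[2] - b[2])

#' Generate a random grid-Pacman layout
#'
#' Places Pacman, ghosts, foods and cherries on distinct free cells of an
#' open `grid_size` grid (movement off the grid is blocked; no interior
#' walls), deterministically per seed, with the constraint that no ghost
#' starts on or orthogonally adjacent to Pacman.
#'
#' @param grid_size `c(height, width)` or a single integer for a square
#'   grid.
#' @param n_food,n_ghost,n_cherry entity counts.
#' @param seed integer seed.
#' @return An object of class `lsm_pacman_layout`.
#' @examples
#' layout_generator(7, n_food = 3, n_ghost = 1, n_cherry = 0, seed = 1)
#' @export
layout_generator <- function(grid_size, n_food, n_ghost = 0, n_cherry = 0,
                             seed = 1) {
  if (length(grid_size) == 1) grid_size <- c(grid_size, grid_size)
  h <- as.integer(grid_size[1]); w <- as.integer(grid_size[2])
  stopifnot(h >= 2, w >= 2, n_food >= 0, n_ghost >= 0, n_cherry >= 0)
  total <- 1 + n_food + n_ghost + n_cherry
  if (total > h * w)
    stop("layout over capacity: ", total, " entities on ", h * w, " cells")
  set.seed(seed)
  cell_rc <- function(idx) c((idx - 1L) %/% w + 1L, (idx - 1L) %% w + 1L)
  repeat {
    cells <- sample.int(h * w, total)
    pac <- cell_rc(cells[1])
    ghosts <- lapply(seq_len(n_ghost), function(i) cell_rc(cells[1 + i]))
    if (all(vapply(ghosts, function(g) manhattan(g, pac) > 1, logical(1))))
      break
  }
  foods <- lapply(seq_len(n_food),
                  function(i) cell_rc(cells[1 + n_ghost + i]))
  cherries <- lapply(seq_len(n_cherry),
                     function(i) cell_rc(cells[1 + n_ghost + n_food + i]))
  structure(list(h = h, w = w, walls = matrix(FALSE, h, w),
                 pacman = pac, ghosts = ghosts, foods = foods,
                 cherries = cherries),
            class = "lsm_pacman_layout")
}

#' Render / parse ASCII Pacman layouts
#'
#' Plain-text layout interchange: `%` wall, `P` Pacman, `G` ghost,
#' `.` food, `o` cherry, space free.
#'
#' @param layout an `lsm_pacman_layout`.
#' @return `layout_to_ascii()` returns a character vector of rows;
#'   `ascii_to_layout()` returns an `lsm_pacman_layout`.
#' @export
layout_to_ascii <- function(layout) {
  m <- matrix(" ", layout$h, layout$w)
  m[layout$walls] <- "%"
  for (f in layout$foods) m[f[1], f[2]] <- "."
  for (ch in layout$cherries) m[ch[1], ch[2]] <- "o"
  for (g in layout$ghosts) m[g[1], g[2]] <- "G"
  m[layout$pacman[1], layout$pacman[2]] <- "P"
  apply(m, 1, paste0, collapse = "")
}

#' @rdname layout_to_ascii
#' @param lines character vector of equal-length rows (or a file path to
#'   read them from).
#' @export
ascii_to_layout <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  stopifnot(length(lines) >= 2, length(unique(nchar(lines))) == 1)
  m <- do.call(rbind, strsplit(lines, ""))
  find <- function(chr) {
    idx <- which(m == chr, arr.ind = TRUE)
    lapply(seq_len(nrow(idx)), function(i) as.integer(idx[i, ]))
  }
  pac <- find("P")
  if (length(pac) != 1) stop("layout must contain exactly one P")
  structure(list(h = nrow(m), w = ncol(m), walls = m == "%",
                 pacman = pac[[1]], ghosts = find("G"), foods = find("."),
                 cherries = find("o")),
            class = "lsm_pacman_layout")
}

#' Grid-Pacman environment
#'
#' Pacman must eat all foods without being caught. Actions are 1 up, 2
#' down, 3 left, 4 right, 5 stay; moves into walls or off the grid leave
#' Pacman in place. Rewards are +1 for each food, cherry or scared ghost
#' consumed, and +1 extra when the last food is taken (the episode then
#' ends in success). Eating a cherry makes every ghost scared for
#' `scared_duration` ghost moves; a consumed scared ghost respawns at its
#' start cell. After Pacman moves, each ghost takes one step: chasing
#' ghosts minimize the Manhattan distance to Pacman, scared ghosts
#' maximize it, ties broken uniformly at random (consuming the R RNG
#' stream). Contact with a non-scared ghost ends the episode with no
#' reward that step (no death penalty by default). Episodes also truncate
#' after `max_steps` steps.
#'
#' The observation is the list of five binary object grids (pacman, food,
#' cherry, ghost, scared ghost) consumed by [binary_map_encode()].
#'
#' @param layout an `lsm_pacman_layout` from [layout_generator()] or
#'   [ascii_to_layout()].
#' @param scared_duration ghost moves a cherry keeps ghosts scared for.
#' @param max_steps episode truncation limit.
#' @param death_penalty reward added on death (0; configurable for
#'   ablations).
#' @return An environment of class `lsm_env` with `reset()`/`step(action)`.
#' @export
pacman_env <- function(layout, scared_duration = 40, max_steps = 1000,
                       death_penalty = 0) {
  stopifnot(inherits(layout, "lsm_pacman_layout"))
  e <- new.env(parent = emptyenv())
  e$n_actions <- 5L
  e$kind <- "pacman"
  e$layout <- layout
  h <- layout$h; w <- layout$w
  moves <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L), c(0L, 0L))

  free_cell <- function(rc)
    rc[1] >= 1 && rc[1] <= h && rc[2] >= 1 && rc[2] <= w &&
      !layout$walls[rc[1], rc[2]]

  grids <- function() {
    z <- matrix(0L, h, w)
    g_pac <- z; g_pac[e$pac[1], e$pac[2]] <- 1L
    g_food <- z; g_food[e$food] <- 1L
    g_cherry <- z; g_cherry[e$cherry] <- 1L
    g_ghost <- z; g_scared <- z
    for (gh in e$ghosts) {
      if (gh$scared > 0L) g_scared[gh$pos[1], gh$pos[2]] <- 1L
      else g_ghost[gh$pos[1], gh$pos[2]] <- 1L
    }
    list(pacman = g_pac, food = g_food, cherry = g_cherry,
         ghost = g_ghost, scared_ghost = g_scared)
  }

  e$reset <- function() {
    e$pac <- layout$pacman
    e$food <- matrix(FALSE, h, w)
    for (f in layout$foods) e$food[f[1], f[2]] <- TRUE
    e$cherry <- matrix(FALSE, h, w)
    for (ch in layout$cherries) e$cherry[ch[1], ch[2]] <- TRUE
    e$ghosts <- lapply(layout$ghosts, function(g)
      list(pos = g, start = g, scared = 0L))
    e$steps <- 0L
    e$terminal <- FALSE
    grids()
  }

  e$step <- function(action) {
    if (!(action %in% 1:5)) stop("pacman action must be in 1..5")
    if (e$terminal) stop("step() called on a terminal Pacman episode")
    reward <- 0
    mv <- moves[[action]]
    cand <- e$pac + mv
    if (free_cell(cand)) e$pac <- cand
    p <- e$pac

    if (e$food[p[1], p[2]]) {
      e$food[p[1], p[2]] <- FALSE
      reward <- reward + 1
    }
    if (e$cherry[p[1], p[2]]) {
      e$cherry[p[1], p[2]] <- FALSE
      reward <- reward + 1
      e$ghosts <- lapply(e$ghosts, function(g) {
        g$scared <- as.integer(scared_duration); g
      })
    }
    for (i in seq_along(e$ghosts)) {
      g <- e$ghosts[[i]]
      if (all(g$pos == p)) {
        if (g$scared > 0L) {              # Pacman eats the scared ghost
          reward <- reward + 1
          g$pos <- g$start; g$scared <- 0L
          e$ghosts[[i]] <- g
        } else {                          # caught
          e$terminal <- TRUE
          e$steps <- e$steps + 1L
          return(list(obs = grids(), reward = reward + death_penalty,
                      terminal = TRUE))
        }
      }
    }
    if (!any(e$food)) {                   # all foods captured: success
      reward <- reward + 1
      e$terminal <- TRUE
      e$steps <- e$steps + 1L
      return(list(obs = grids(), reward = reward, terminal = TRUE))
    }

    # ghosts move: chase (minimize distance) or flee (maximize) greedily
    for (i in seq_along(e$ghosts)) {
      g <- e$ghosts[[i]]
      cands <- Filter(free_cell, lapply(moves, function(m) g$pos + m))
      d <- vapply(cands, manhattan, numeric(1), b = p)
      best <- if (g$scared > 0L) which(d == max(d)) else which(d == min(d))
      pick <- if (length(best) == 1) best else
        best[sample.int(length(best), 1)]
      g$pos <- cands[[pick]]
      if (g$scared > 0L) g$scared <- g$scared - 1L
      if (all(g$pos == p)) {
        if (e$ghosts[[i]]$scared > 0L) {  # scared at the time of its move
          reward <- reward + 1            # scared ghost walked into Pacman
          g$pos <- g$start; g$scared <- 0L
        } else {
          e$ghosts[[i]] <- g
          e$terminal <- TRUE
          e$steps <- e$steps + 1L
          return(list(obs = grids(), reward = reward + death_penalty,
                      terminal = TRUE))
        }
      }
      e$ghosts[[i]] <- g
    }

    e$steps <- e$steps + 1L
    if (e$steps >= max_steps) e$terminal <- TRUE
    list(obs = grids(), reward = reward, terminal = e$terminal)
  }
  class(e) <- "lsm_env"
  e
}

#' Accounting bound on the accumulated reward of a Pacman layout
#'
#' Counts the unit rewards available in a layout: one per food, one per
#' cherry, one per (ghost, cherry) capture opportunity, plus the completion
#' bonus for taking the last food. Exact for ghost-free layouts (every food
#' and cherry is reachable on an open grid); an upper bound otherwise.
#'
#' @param layout an `lsm_pacman_layout`.
#' @return integer reward bound.
#' @examples
#' max_achievable_reward(layout_generator(7, 3, 1, 0, seed = 1))  # 4
#' @export
max_achievable_reward <- function(layout) {
  stopifnot(inherits(layout, "lsm_pacman_layout"))
  n_food <- length(layout$foods)
  n_cherry <- length(layout$cherries)
  n_ghost <- length(layout$ghosts)
  as.integer(n_food + n_cherry + n_cherry * n_ghost + 1L)
}

#' Toy deterministic MDP environment
#'
#' A small finite Markov decision process defined by transition and reward
#' tables, used for the tabular correctness checks of the Q-learning
#' update: with a one-hot state encoder in place of the liquid, the learned
#' Q-values must converge to the value-iteration fixed point.
#'
#' @param transitions `n_states x n_actions` integer matrix of successor
#'   states.
#' @param rewards `n_states x n_actions` reward matrix.
#' @param start_state state at episode start.
#' @return An `lsm_env`; observations are state indices, episodes never
#'   terminate.
#' @export
mdp_env <- function(transitions, rewards, start_state = 1L) {
  stopifnot(is.matrix(transitions), all(dim(transitions) == dim(rewards)))
  e <- new.env(parent = emptyenv())
  e$n_actions <- ncol(transitions)
  e$n_states <- nrow(transitions)
  e$kind <- "mdp"
  e$reset <- function() {
    e$s <- as.integer(start_state)
    e$terminal <- FALSE
    e$s
  }
  e$step <- function(action) {
    r <- rewards[e$s, action]
    e$s <- transitions[e$s, action]
    list(obs = e$s, reward = r, terminal = FALSE)
  }
  class(e) <- "lsm_env"
  e
}

#' Q-function of a finite MDP by value iteration
#'
#' Independent dynamic-programming oracle for the tabular tests.
#'
#' @inheritParams mdp_env
#' @param gamma discount factor.
#' @param tol convergence tolerance on the sup norm.
#' @return `n_states x n_actions` matrix of optimal Q-values.
#' @export
value_iteration_q <- function(transitions, rewards, gamma, tol = 1e-10) {
  q <- rewards * 0
  repeat {
    v <- apply(q, 1, max)
    q_new <- rewards + gamma * matrix(v[transitions], nrow(q), ncol(q))
    if (max(abs(q_new - q)) < tol) return(q_new)
    q <- q_new
  }
}
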