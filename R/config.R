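allowed_keys <- list(
  top = c("name", "environment", "encoder", "liquid", "neuron", "readout",
          "train", "epsilon", "seeds"),
  environment = c("type", "grid_size", "n_food", "n_ghost", "n_cherry",
                  "layout_seed", "layout_file", "scared_duration",
                  "max_steps", "death_penalty"),
  encoder = c("type", "ranges", "bins", "max_rate"),
  liquid = c("n_excitatory", "n_inhibitory", "k_input", "c_recurrent",
             "alpha", "beta_ee", "beta_ei", "beta_ie", "beta_ii",
             "beta_ee_slow", "ee_slow_delay_ms", "input_weight_signed",
             "allow_ratio_override", "t_lsm_ms"),
  neuron = c("v_rest", "v_reset", "v_thres", "tau_ms", "tau_refrac_ms",
             "dt_ms"),
  readout = c("hidden", "lr", "smoothing", "eps_denom"),
  train = c("total_steps", "epoch_length", "eval_steps", "gamma",
            "batch_size", "warmup_steps", "update_every", "buffer_capacity",
            "clip_rewards", "episodic_liquid_reset"),
  epsilon = c("eps_start", "eps_final", "decay_fraction", "eps_eval")
)

check_keys <- function(x, section) {
  bad <- setdiff(names(x), allowed_keys[[section]])
  if (length(bad))
    stop("unknown key(s) in '", section, "': ", paste(bad, collapse = ", "))
}

take <- function(x, defaults) {
  for (k in names(x)) defaults[[k]] <- x[[k]]
  defaults
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML experiment description covering the environment, the state
#' encoder, the liquid initialization, the neuron model, the readout and
#' the Q-learning schedule, fills every omitted field with its default
#' value, and cross-validates the shapes (the encoder determines the
#' number of input neurons; the environment determines the action count).
#' Unknown keys and inconsistent values are rejected with messages naming
#' the offending field. Ready-made configurations for the cartpole and
#' Pacman experiments ship under `system.file("extdata",
#' package = "liquidrl")`, each with a `_small` reduced-scale variant.
#'
#' @param path YAML file path, or a pre-parsed list.
#' @return An object of class `lsm_experiment_config`.
#' @examples
#' cfg <- load_config(system.file("extdata", "cartpole_full.yaml",
#'                                package = "liquidrl"))
#' cfg$init$n_input   # 40: 4 state dimensions x 10 one-hot levels
#' @export
load_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  check_keys(raw, "top")
  for (s in c("environment", "encoder", "liquid", "train"))
    if (is.null(raw[[s]])) stop("missing required section '", s, "'")
  for (s in intersect(names(raw), names(allowed_keys)))
    if (is.list(raw[[s]])) check_keys(raw[[s]], s)

  env_spec <- validate_env_spec(raw$environment)
  enc <- take(raw$encoder, list(type = NULL, ranges = NULL, bins = 10,
                                max_rate = 100))
  if (is.null(enc$type) ||
      !enc$type %in% c("one_hot", "signed", "binary_map"))
    stop("encoder$type must be one of one_hot, signed, binary_map")
  if (enc$type %in% c("one_hot", "signed")) {
    if (is.null(enc$ranges)) stop("encoder$ranges is required for ",
                                  enc$type, " encoding")
    enc$ranges <- as.numeric(unlist(enc$ranges))
  }
  n_input <- switch(enc$type,
    one_hot = length(enc$ranges) * enc$bins,
    signed = length(enc$ranges),
    binary_map = {
      if (env_spec$type != "pacman")
        stop("encoder$type binary_map requires a pacman environment")
      5L * env_spec$grid_size[1] * env_spec$grid_size[2]
    })
  obs_dim <- switch(env_spec$type, cartpole = 4L, cartpole_partial = 2L,
                    pacman = NA_integer_)
  if (enc$type %in% c("one_hot", "signed") && !is.na(obs_dim) &&
      length(enc$ranges) != obs_dim)
    stop("encoder$ranges has ", length(enc$ranges), " entries but the ",
         env_spec$type, " observation has ", obs_dim, " dimensions")

  liq <- raw$liquid
  t_lsm_ms <- if (is.null(liq$t_lsm_ms)) 100 else liq$t_lsm_ms
  liq$t_lsm_ms <- NULL
  init <- do.call(init_config, c(list(n_input = n_input), liq))

  neuron <- do.call(neuron_params, if (is.null(raw$neuron)) list()
                    else raw$neuron)
  ro <- take(raw$readout, list(hidden = 32, lr = 2e-4, smoothing = 0.99,
                               eps_denom = 1e-6))
  train <- do.call(train_config, raw$train)
  eps_defaults <- list(eps_start = 1,
                       eps_final = if (env_spec$type == "pacman") 0.1
                                   else 1e-3,
                       decay_fraction = 0.1,
                       eps_eval = if (env_spec$type == "pacman") 0 else 0.05)
  schedule <- do.call(epsilon_schedule,
                      take(if (is.null(raw$epsilon)) list() else raw$epsilon,
                           eps_defaults))
  seeds <- if (is.null(raw$seeds)) 1:5 else as.integer(unlist(raw$seeds))

  structure(list(name = if (is.null(raw$name)) "experiment" else raw$name,
                 env_spec = env_spec, encoder = enc, init = init,
                 neuron = neuron, t_lsm_ms = t_lsm_ms, readout = ro,
                 train = train, schedule = schedule, seeds = seeds),
            class = "lsm_experiment_config")
}

validate_env_spec <- function(spec) {
  check_keys(spec, "environment")
  if (is.null(spec$type) ||
      !spec$type %in% c("cartpole", "cartpole_partial", "pacman"))
    stop("environment$type must be cartpole, cartpole_partial or pacman")
  if (spec$type == "pacman") {
    if (!is.null(spec$layout_file)) {
      lay <- ascii_to_layout(spec$layout_file)
      spec$grid_size <- c(lay$h, lay$w)
    } else {
      for (k in c("grid_size", "n_food"))
        if (is.null(spec[[k]])) stop("environment$", k,
                                     " is required for pacman")
      spec$grid_size <- as.integer(rep_len(unlist(spec$grid_size), 2))
    }
    spec <- take(spec, list(type = "pacman", grid_size = spec$grid_size,
                            n_food = spec$n_food, n_ghost = 0, n_cherry = 0,
                            layout_seed = 1, layout_file = NULL,
                            scared_duration = 40, max_steps = 1000,
                            death_penalty = 0))
  }
  spec
}

#' Build the encoder function of a configuration
#'
#' @param config an `lsm_experiment_config`.
#' @return function mapping an environment observation to an
#'   `lsm_rate_vector` of length `config$init$n_input`.
#' @export
make_encoder <- function(config) {
  enc <- config$encoder
  f <- switch(enc$type,
    one_hot = function(obs) one_hot_rate_encode(obs, enc$ranges, enc$bins,
                                                enc$max_rate),
    signed = function(obs) signed_rate_encode(obs, enc$ranges,
                                              enc$max_rate),
    binary_map = function(obs) binary_map_encode(obs, enc$max_rate))
  # validation-free per-step closure used by liquid_representation();
  # tested to agree with the reference encoders above
  attr(f, "fast") <- switch(enc$type,
    one_hot = {
      d <- length(enc$ranges); bins <- enc$bins
      half <- abs(enc$ranges); p1 <- enc$max_rate / 1000
      offs <- (seq_len(d) - 1L) * bins + 1L
      sgn <- rep(1, d * bins)
      function(obs) {
        x <- pmin(pmax(obs, -half), half)
        prob <- numeric(d * bins)
        prob[offs + pmin(bins - 1, floor((x + half) / (2 * half) * bins))] <-
          p1
        list(prob = prob, sign = sgn)
      }
    },
    signed = {
      half <- abs(enc$ranges); p1 <- enc$max_rate / 1000
      function(obs) {
        x <- pmin(pmax(obs, -half), half)
        s <- rep(1, length(x)); s[x < 0] <- -1
        list(prob = p1 * abs(x) / half, sign = s)
      }
    },
    binary_map = {
      p1 <- enc$max_rate / 1000
      function(obs) {
        flat <- unlist(lapply(obs, function(g) as.numeric(t(g != 0))),
                       use.names = FALSE)
        list(prob = p1 * flat, sign = rep(1, length(flat)))
      }
    })
  f
}

#' Build the environment of a configuration
#'
#' @param config an `lsm_experiment_config`.
#' @return an `lsm_env`.
#' @export
make_env <- function(config) {
  spec <- config$env_spec
  switch(spec$type,
    cartpole = cartpole_env(partial = FALSE),
    cartpole_partial = cartpole_env(partial = TRUE),
    pacman = {
      layout <- if (!is.null(spec$layout_file))
        ascii_to_layout(spec$layout_file)
      else
        layout_generator(spec$grid_size, spec$n_food, spec$n_ghost,
                         spec$n_cherry, seed = spec$layout_seed)
      pacman_env(layout, spec$scared_duration, spec$max_steps,
                 spec$death_penalty)
    })
}
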