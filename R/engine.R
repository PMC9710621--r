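# The agent-based simulation loop: seed founders, then per fixed time step
# grow -> divide -> resolve overlaps, emitting snapshots to output hooks.

#' Simulation configuration
#'
#' @param seed integer seed; the entire trajectory is reproducible from it.
#' @param dt time step in h (default 1/60 h = 1 min, a typical time-lapse
#'   cadence).
#' @param duration simulated time span in h (>= 0).
#' @param n_founders number of founder cells (>= 1).
#' @param model a [homeostasis_model()].
#' @param placement a [placement_config()].
#' @param emit_every number of steps between snapshot emissions.
#' @param shape_kind catalogue shape of the cells.
#' @param width cell width in µm (constant through life and inherited).
#' @param bend centerline arc angle for bent rods (radians).
#' @param founder_length founder birth length in µm, or `NULL` for the
#'   model default (sizer: `trigger_mean / 2`, the steady-state birth length
#'   under symmetric fission; timer: 1.8 µm).
#' @param angle_sd std. dev. of the daughter angle perturbation (radians).
#' @param split_sd std. dev. of the division split-fraction perturbation.
#' @param fluorescence founder fluorescence level (arbitrary units).
#' @param max_cells stop stepping early once the colony exceeds this count
#'   (`Inf` to disable).
#' @param verbose emit a per-step log line (time, cell count, residual
#'   penetration) via [message()].
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, dt = 1 / 60, duration = 8,
                              n_founders = 1L,
                              model = homeostasis_model(),
                              placement = placement_config(),
                              emit_every = 30L,
                              shape_kind = "rod", width = 0.9, bend = 0,
                              founder_length = NULL,
                              angle_sd = 0.05, split_sd = 0,
                              fluorescence = 0,
                              max_cells = Inf, verbose = FALSE) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!is.finite(duration) || duration < 0) stop("duration must be >= 0", call. = FALSE)
  if (n_founders < 1) stop("n_founders must be >= 1", call. = FALSE)
  if (!inherits(model, "homeostasis_model")) stop("model must be a homeostasis_model", call. = FALSE)
  if (!inherits(placement, "placement_config")) stop("placement must be a placement_config", call. = FALSE)
  if (emit_every < 1) stop("emit_every must be >= 1", call. = FALSE)
  structure(list(seed = as.integer(seed), dt = dt, duration = duration,
                 n_founders = as.integer(n_founders), model = model,
                 placement = placement, emit_every = as.integer(emit_every),
                 shape_kind = shape_kind, width = width, bend = bend,
                 founder_length = founder_length,
                 angle_sd = angle_sd, split_sd = split_sd,
                 fluorescence = fluorescence,
                 max_cells = max_cells, verbose = isTRUE(verbose)),
            class = "simulation_config")
}

#' Initialize a simulation world
#'
#' Creates `n_founders` founder cells with per-cell elongation rates and
#' division triggers drawn from the model distributions, dispersed uniformly
#' in a disc of radius five mean cell lengths around the origin (then
#' separated by the placement solver). Fully reproducible from the seed.
#'
#' @param config a [simulation_config()].
#' @return A `colony_world`: list with `time` (h), `agents`, `next_id`,
#'   `seed`.
#' @export
init_world <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_founders
  model <- config$model
  len0 <- config$founder_length
  if (is.null(len0))
    len0 <- if (model$kind == "sizer") model$trigger_mean / 2 else 1.8
  ag <- with_seed(derive_seed(config$seed, 0L), {
    R <- 5 * len0
    rr <- R * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    cell_agent(
      id = seq_len(n), parent_id = NA_integer_, birth_time = 0,
      x = if (n == 1L) 0 else rr * cos(th),
      y = if (n == 1L) 0 else rr * sin(th),
      angle = stats::runif(n, 0, pi),
      kind = config$shape_kind, length = len0, width = config$width,
      bend = config$bend,
      growth_rate = sample_lognormal(n, model$rate_mean, model$rate_cv),
      division_trigger = sample_lognormal(n, model$trigger_mean,
                                          model$trigger_cv),
      birth_length = len0, fluorescence = config$fluorescence)
  })
  if (n > 1L) ag <- resolve_overlaps(ag, config$placement)
  structure(list(time = 0, agents = strip_placement_attrs(ag),
                 next_id = n + 1L, seed = config$seed),
            class = "colony_world")
}

strip_placement_attrs <- function(agents) {
  attr(agents, "iterations") <- NULL
  attr(agents, "converged") <- NULL
  attr(agents, "penetration_log") <- NULL
  agents
}

#' Advance the world by one time step
#'
#' Per step: (1) all agents elongate for `dt`; (2) the clock advances to
#' `time + dt` and every agent whose division rule holds at the new clock
#' divides (daughters are stamped with the new time and are not re-examined
#' within the same step); (3) the placement solver restores a feasible
#' monolayer packing. Cell count never decreases.
#'
#' @param world a `colony_world`.
#' @param config the [simulation_config()] driving the run.
#' @return The advanced `colony_world`.
#' @export
step_world <- function(world, config) {
  stopifnot(inherits(world, "colony_world"))
  ag <- grow(world$agents, config$dt)
  now <- world$time + config$dt
  div <- should_divide(ag, config$model, now)
  if (any(div)) {
    res <- divide_agents(ag, div, config$model, now, world$next_id,
                         seed = config$seed, angle_sd = config$angle_sd,
                         split_sd = config$split_sd)
    ag <- res$agents
    world$next_id <- res$next_id
  }
  ag <- resolve_overlaps(ag, config$placement)
  if (config$verbose) {
    pl <- attr(ag, "penetration_log")
    message(sprintf("t=%.3f h  cells=%d  residual penetration=%.3g",
                    now, nrow(ag), pl[length(pl)]))
  }
  world$agents <- strip_placement_attrs(ag)
  world$time <- now
  world
}

#' Run a colony simulation
#'
#' Executes `ceiling(duration / dt)` steps from a freshly initialized world.
#' Snapshots (the initial world, every `emit_every`-th step, and the final
#' step) are collected into the returned trajectory and also delivered to
#' each emitter hook as `emitter(world, frame_index)`.
#'
#' @param config a [simulation_config()].
#' @param emitters optional list of functions called at each emitted frame.
#' @return List of `colony_world` snapshots ordered by time.
#' @export
run_simulation <- function(config, emitters = list()) {
  world <- init_world(config)
  n_steps <- ceiling(config$duration / config$dt)
  trajectory <- list(world)
  frame <- 0L
  for (em in emitters) em(world, frame)
  if (n_steps >= 1L) for (s in seq_len(n_steps)) {
    world <- step_world(world, config)
    if (s %% config$emit_every == 0L || s == n_steps) {
      frame <- frame + 1L
      trajectory[[frame + 1L]] <- world
      for (em in emitters) em(world, frame)
    }
    if (nrow(world$agents) > config$max_cells) break
  }
  trajectory
}

#' Step a world until a target cell count is reached
#'
#' Advances an existing world until its population is at least
#' `target_count` or `max_steps` elapse. Used by the dataset generator to
#' snapshot colonies at prescribed densities.
#'
#' @param world a `colony_world` (e.g. from [init_world()]).
#' @param config the [simulation_config()].
#' @param target_count stop once `nrow(agents) >= target_count`.
#' @param max_steps step budget.
#' @return List with `world` (first state at or above the target), `previous`
#'   (last state below it) and `reached` (logical).
#' @export
step_until_count <- function(world, config, target_count, max_steps = 5000L) {
  previous <- world
  steps <- 0L
  while (nrow(world$agents) < target_count && steps < max_steps) {
    previous <- world
    world <- step_world(world, config)
    steps <- steps + 1L
  }
  list(world = world, previous = previous,
       reached = nrow(world$agents) >= target_count)
}
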