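# Simulation orchestration: declarative configs, the per-step update order
# (agents first, then populations in dependency order), history recording and
# long-format export.

.check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown))
    stop("unknown key(s) in ", where, ": ", paste(unknown, collapse = ", "))
}

.env_from_config <- function(cfg) {
  .check_keys(cfg, c("dimensionality", "boundary_conditions", "scale",
                     "aspect", "dx", "walls", "holes", "objects"),
              "environment config")
  walls <- cfg$walls
  if (!is.null(walls) && is.list(walls))
    walls <- lapply(walls, function(w) matrix(unlist(w), 2, 2, byrow = TRUE))
  holes <- cfg$holes
  if (!is.null(holes))
    holes <- lapply(holes, function(h) matrix(unlist(h), ncol = 2,
                                              byrow = TRUE))
  objects <- NULL
  if (!is.null(cfg$objects)) {
    objects <- do.call(rbind, lapply(cfg$objects, function(o) {
      pos <- as.numeric(unlist(o$pos))
      data.frame(x = pos[1], y = pos[2],
                 type = as.integer(o$type %||% 1L))
    }))
  }
  Arena(dimensionality = cfg$dimensionality %||% "2D",
        boundary_conditions = cfg$boundary_conditions %||% "solid",
        scale = cfg$scale %||% 1.0, aspect = cfg$aspect %||% 1.0,
        dx = cfg$dx %||% 0.01, walls = walls, holes = holes,
        objects = objects)
}

.agent_keys <- c("dt", "speed_mean", "speed_std", "speed_coherence_time",
                 "rotational_velocity_std",
                 "rotational_velocity_coherence_time", "thigmotaxis",
                 "wall_repel_distance", "walls_repel_strength",
                 "head_direction_smoothing", "drift_to_random_strength_ratio",
                 "position")

.pop_constructors <- list(
  PlaceCells = PlaceCells, GridCells = GridCells,
  BoundaryVectorCells = BoundaryVectorCells,
  ObjectVectorCells = ObjectVectorCells,
  AgentVectorCells = AgentVectorCells,
  FieldOfViewBVCs = FieldOfViewBVCs, FieldOfViewOVCs = FieldOfViewOVCs,
  FieldOfViewAVCs = FieldOfViewAVCs,
  HeadDirectionCells = HeadDirectionCells, VelocityCells = VelocityCells,
  SpeedCell = SpeedCell,
  PhasePrecessingPlaceCells = PhasePrecessingPlaceCells,
  RandomSpatialNeurons = RandomSpatialNeurons)

#' Load a simulation configuration from JSON
#'
#' The config mirrors the parameter tables of the simulator: an
#' `environment` block, a list of `agents` blocks, a list of `populations`
#' blocks (`type`, `name`, constructor arguments, optional `agent` index and
#' `inputs` for function-approximator layers) and a `run` block
#' (`duration`, `dt`, `seed`). Unknown keys are rejected.
#'
#' @param path Path to a JSON file.
#' @return The validated config list.
#' @export
load_simulation_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  .check_keys(cfg, c("environment", "agents", "populations", "run"),
              "config")
  cfg
}

#' Run a declarative simulation
#'
#' Builds the arena, agents and neuron populations from a config list and
#' steps them for `run$duration` seconds at `run$dt`: on each step every
#' agent updates its position and velocity, then every population updates
#' its firing rate (function-approximator layers after their inputs, see
#' [update_schedule]), and history is appended. Deterministic given
#' `run$seed`.
#'
#' @param config A config list (see [load_simulation_config]) or a path to a
#'   JSON config.
#' @return A list with `env`, `agents` (with `$history` data.frames),
#'   `rates` and `spikes` (per population: steps x cells matrices), `times`,
#'   and `populations` (final population objects).
#' @export
run_simulation <- function(config) {
  if (is.character(config)) config <- load_simulation_config(config)
  run <- config$run %||% list()
  .check_keys(run, c("duration", "dt", "seed"), "run config")
  duration <- run$duration %||% 60
  dt <- run$dt %||% 0.01
  if (!is.null(run$seed)) set.seed(run$seed)

  env <- .env_from_config(config$environment %||% list())
  agent_cfgs <- config$agents %||% list(list())
  agents <- lapply(agent_cfgs, function(a) {
    .check_keys(a, .agent_keys, "agent config")
    do.call(Agent, c(list(env = env, dt = dt), a))
  })

  pops <- list()
  for (pc in config$populations %||% list()) {
    type <- pc$type
    if (is.null(type) || !type %in% names(.pop_constructors))
      stop("unknown population type: ", type %||% "<missing>")
    ctor <- .pop_constructors[[type]]
    args <- pc[setdiff(names(pc), c("type", "agent", "inputs", "name"))]
    nm <- pc$name %||% type
    pop <- do.call(ctor, c(list(env = env), args))
    pop$name <- nm
    pop$agent_index <- pc$agent %||% 1L
    pop$input_names <- unlist(pc$inputs) %||% pop$input_names
    pops[[nm]] <- pop
  }
  order <- if (length(pops)) update_schedule(pops) else character(0)

  n <- round(duration / dt)
  d2 <- env$dimensionality == "2D"
  AH <- lapply(agents, function(a)
    matrix(NA_real_, n, if (d2) 9 else 4, dimnames = list(NULL,
      if (d2) c("t", "x", "y", "vx", "vy", "speed", "omega", "hx", "hy")
      else c("t", "x", "v", "h"))))
  PR <- lapply(pops, function(p) matrix(NA_real_, n, p$n))
  PS <- lapply(pops, function(p) matrix(NA_integer_, n, p$n))
  times <- numeric(n)

  walls <- .collision_walls(env)
  for (i in seq_len(n)) {
    for (k in seq_along(agents)) {
      agents[[k]] <- update_agent(agents[[k]], dt)
      st <- agents[[k]]$state
      AH[[k]][i, ] <- if (d2)
        c(st$t, st$position, st$velocity, sqrt(sum(st$velocity^2)),
          st$omega %||% 0, st$head_direction)
      else c(st$t, st$position, st$velocity, st$head_direction)
    }
    for (nm in order) {
      pop <- pops[[nm]]
      ag <- agents[[pop$agent_index %||% 1L]]
      if (length(pop$input_names %||% character(0)) &&
          inherits(pop, c("FeedForwardLayer", "NeuralNetworkNeurons"))) {
        ir <- lapply(pop$input_names, function(x) pops[[x]]$rates)
        pop <- update_neurons(pop, ag, dt, input_rates = ir)
      } else {
        pop <- update_neurons(pop, ag, dt)
      }
      pops[[nm]] <- pop
      PR[[nm]][i, ] <- pop$rates
      PS[[nm]][i, ] <- pop$spikes
    }
    times[i] <- i * dt
  }
  for (k in seq_along(agents)) agents[[k]]$history <- as.data.frame(AH[[k]])
  list(env = env, agents = agents, times = times, rates = PR, spikes = PS,
       populations = pops)
}

#' Export simulation history in long format
#'
#' One row per (time, population, cell): columns `t`, `agent_id`,
#' `population`, `cell_index`, `rate`, `spike`.
#'
#' @param result A [run_simulation] result.
#' @param path Optional CSV path; if given the table is also written there.
#' @return The long-format data.frame (invisibly if written).
#' @export
export_history <- function(result, path = NULL) {
  rows <- lapply(names(result$rates), function(nm) {
    R <- result$rates[[nm]]; S <- result$spikes[[nm]]
    pop <- result$populations[[nm]]
    data.frame(t = rep(result$times, ncol(R)),
               agent_id = pop$agent_index %||% 1L,
               population = nm,
               cell_index = rep(seq_len(ncol(R)), each = nrow(R)),
               rate = as.numeric(R), spike = as.integer(S))
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
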