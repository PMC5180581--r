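# Run configuration: a nested named list covering the genome anatomy,
# mutation rates, GRN dynamics constants, the ANN baseline, the world (grid,
# food, seasons), the energy schedule, population settings and the engine.
# A run is a pure function of (config, seed).

#' Default simulation configuration
#'
#' Returns the full nested configuration with the platform's default study
#' conditions: a 90 x 90 toroidal grid; genomes of 10 chromosomes x 10,000
#' characters; 800 robots with 130 energy each; three food types with access
#' thresholds 0/30/60 and energy contents 30/60/120, 200 sources initially;
#' density-dependent food regrowth (`r0`, `K`); four seasons of 100 steps
#' cycling extra survival/movement costs; extinction below 100 robots; at
#' most 3,000 steps with metrics sampled every 10. The energy and food
#' constants are the package's calibrated study conditions: under them the
#' regulatory-network arm runs the habitat down to roughly 60-90 food
#' sources before collapsing while the neural-network arm collapses with
#' roughly twice as much food left (see the methods vignette).
#'
#' @param ... named overrides merged into the defaults, e.g.
#'   `default_config(world = list(size = 30))` (partial lists are merged
#'   field-wise).
#' @return a nested list of class `sim_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    world = list(size = 90L, torus = TRUE),
    food = list(
      types = data.frame(threshold = c(0, 30, 60),
                         energy = c(30, 60, 120),
                         initial = c(80L, 60L, 60L)),
      r0 = 0.0015, K = 6,
      restore_schedule = list()
    ),
    seasons = list(length = 100L,
                   survival = c(0, 0.1, 0.2, 0.4),
                   movement = c(0, 0.1, 0.25, 0.5)),
    genome = list(n_chromosomes = 10L, chrom_length = 10000L,
                  alphabet = c("0", "1", "2", "3"), promoter = "0101",
                  type_len = 2L, binding_len = 4L, payload_len = 8L,
                  match_tolerance = 1L),
    mutation = list(point_rate = 0.001, duplication_rate = 0.01,
                    duplication_mean_len = 50),
    grn = list(decay = 0.02, feedback_gain = 0.3, feedback_scale = 5,
               c_min = 0.05, c_max = 50, c_init = 0.2),
    ann = list(hidden = 12L, eta = 3e-4, trace_decay = 0.9,
               zero_threshold = 1e-3, zero_window = 50L,
               mutation_sigma = 0.05),
    energy = list(basic = 0.3, move = 0.2, attack = 25, defend = 3,
                  replicate = 10, replicate_threshold = 100, endowment = 40,
                  aggregate = 2, aggregate_upkeep = 1, defence_bonus = 50,
                  prey_transfer = 0.5, satiety = 200),
    population = list(initial = 800L, initial_energy = 130,
                      extinction = 100L),
    sensors = list(radius = 1L, norm_robots = 8, norm_food = 9,
                   norm_energy = 300, trace_decay = 0.9),
    actions = list(threshold = 0.5),
    sim = list(controller = "grn", max_steps = 3000L,
               metrics_interval = 10L, log_events = FALSE, audit = FALSE)
  )
  overrides <- list(...)
  if (length(overrides) > 0L) cfg <- merge_config(cfg, overrides)
  structure(cfg, class = "sim_config")
}

merge_config <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]]) &&
        !is.data.frame(overrides[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' Validate a simulation configuration
#'
#' Checks types, ranges and cross-field invariants (positive dimensions,
#' probabilities in `[0, 1]`, non-decreasing food thresholds, payload long
#' enough for the gene anatomy, equal-length season tables). Errors before
#' any stepping on the first violation.
#'
#' @param config a configuration list.
#' @return the validated config, invisibly.
#' @export
validate_config <- function(config) {
  with(config, {
    if (world$size < 3L) stop_invalid("world.size must be >= 3")
    if (!is.data.frame(food$types) || nrow(food$types) < 1L)
      stop_invalid("food.types must be a non-empty data.frame")
    if (is.unsorted(food$types$threshold))
      stop_invalid("food access thresholds must be non-decreasing")
    if (any(food$types$energy <= 0))
      stop_invalid("food energy contents must be positive")
    if (food$r0 < 0 || food$r0 > 1)
      stop_invalid("food.r0 must lie in [0, 1]")
    if (food$K <= 0) stop_invalid("food.K must be positive")
    if (seasons$length < 1L) stop_invalid("seasons.length must be >= 1")
    if (length(seasons$survival) != length(seasons$movement))
      stop_invalid("season cost tables must have equal length")
    if (genome$n_chromosomes < 1L || genome$chrom_length < 1L)
      stop_invalid("genome dimensions must be positive")
    if (length(genome$alphabet) < 2L)
      stop_invalid("genome alphabet needs at least two letters")
    if (genome$payload_len < genome$binding_len + 4L)
      stop_invalid("genome.payload_len must be >= binding_len + 4")
    if (mutation$point_rate < 0 || mutation$point_rate > 1 ||
        mutation$duplication_rate < 0 || mutation$duplication_rate > 1)
      stop_invalid("mutation rates must lie in [0, 1]")
    if (grn$decay <= 0 || grn$decay >= 1)
      stop_invalid("grn.decay must lie in (0, 1)")
    if (grn$c_min <= 0 || grn$c_max <= grn$c_min)
      stop_invalid("need 0 < grn.c_min < grn.c_max")
    if (energy$prey_transfer < 0 || energy$prey_transfer > 1)
      stop_invalid("energy.prey_transfer must lie in [0, 1]")
    if (any(unlist(energy) < 0)) stop_invalid("energy costs must be >= 0")
    if (population$initial < 1L)
      stop_invalid("population.initial must be >= 1")
    if (!sim$controller %in% c("grn", "ann"))
      stop_invalid("sim.controller must be 'grn' or 'ann'")
    if (sim$max_steps < 0L) stop_invalid("sim.max_steps must be >= 0")
    if (sim$metrics_interval < 1L)
      stop_invalid("sim.metrics_interval must be >= 1")
  })
  invisible(config)
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @param config a configuration list.
#' @return `read_config` returns a validated `sim_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$food$types)) raw$food$types <- as.data.frame(raw$food$types)
  cfg <- merge_config(default_config(), raw)
  validate_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$food$types <- as.list(cfg$food$types)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
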