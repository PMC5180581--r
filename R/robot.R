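# Robot life cycle: energy accounting, the mapping from continuous actuator
# outputs to discrete actions, feeding, attack/prey resolution, replication
# with genome inheritance, aggregation, and upkeep/death. Selection is purely
# energetic: a robot that cannot cover its living costs dies the same step.

ACTION_PRIORITY <- c("eat", "attack", "defend", "replicate", "aggregate",
                     "move")

#' Create a robot
#'
#' @param id integer identifier.
#' @param x,y cell coordinates.
#' @param energy initial energy.
#' @param ctrl controller state (a `grn_state` or `ann_controller`).
#' @param controller `"grn"` or `"ann"`.
#' @return a list of class `swarm_robot`: position, energy, controller,
#'   non-decreasing action counters (attacks, defences, replications,
#'   feedings, aggregations), decaying event traces feeding the internal
#'   sensors, aggregate membership (`agg`, 0 = none) and last-step energy
#'   change (`last_delta`, the fitness feedback).
#' @export
new_robot <- function(id, x, y, energy, ctrl, controller = "grn") {
  structure(list(id = as.integer(id), x = as.integer(x), y = as.integer(y),
                 energy = as.numeric(energy), alive = TRUE,
                 controller = controller, ctrl = ctrl,
                 counters = c(attacks = 0L, defences = 0L, replications = 0L,
                              feedings = 0L, aggregations = 0L),
                 traces = c(attacks = 0, defences = 0, replications = 0,
                            feedings = 0),
                 agg = 0L, moved = FALSE, last_delta = 0),
            class = "swarm_robot")
}

#' Map an actuator vector to the discrete action of this step
#'
#' Gate channels (`move`, `eat`, `attack`, `defend`, `replicate`,
#' `aggregate`) fire when they exceed the threshold (default 0.5). Exactly
#' one action is taken per step, resolved by the fixed priority
#' eat > attack > defend > replicate > aggregate > move; when no gate fires
#' the robot idles (basic cost only). The movement direction is read from
#' the `direction` channel, whose fractional part selects one of the eight
#' Moore directions.
#'
#' @param actuators named numeric vector over [ACTUATORS].
#' @param threshold gate threshold.
#' @return list with `action` (string, `"idle"` when nothing fired) and
#'   `direction` (integer 1..8).
#' @export
decide_actions <- function(actuators, threshold = 0.5) {
  fired <- ACTION_PRIORITY[
    vapply(ACTION_PRIORITY, function(a) actuators[[a]] > threshold, TRUE)]
  v <- actuators[["direction"]]
  dir <- as.integer(floor((v %% 1) * 8)) + 1L
  if (dir > 8L) dir <- 8L
  list(action = if (length(fired) > 0L) fired[1L] else "idle",
       direction = dir)
}

#' Eat the best accessible food source in the robot's cell
#'
#' Consumes the highest-value food source in the cell whose access threshold
#' the robot's energy meets; the source is removed from the grid and its
#' energy content credited to the robot. With no accessible source the action
#' has no effect.
#'
#' @param robot a `swarm_robot`.
#' @param world a `world_grid` (mutated in place when food is consumed).
#' @return list with the updated `robot` and `gained` (energy, 0 if nothing
#'   was eaten).
#' @export
eat <- function(robot, world) {
  gained <- eat_cell(world, robot$x, robot$y, robot$energy)
  if (gained == 0) return(list(robot = robot, gained = 0))
  robot$energy <- robot$energy + gained
  robot$counters[["feedings"]] <- robot$counters[["feedings"]] + 1L
  robot$traces[["feedings"]] <- robot$traces[["feedings"]] + 1
  list(robot = robot, gained = gained)
}

# consume the best accessible source in a cell; returns the energy gained
# (0 if nothing accessible) and removes the source from the grid
eat_cell <- function(world, x, y, energy_available) {
  counts <- world$food[x, y, ]
  ok <- counts > 0L & world$types$threshold <= energy_available
  if (!any(ok)) return(0)
  ti <- which(ok)[which.max(world$types$energy[ok])]
  world$food[x, y, ti] <- counts[ti] - 1L
  world$types$energy[ti]
}

#' Resolve an attack between two co-located robots
#'
#' Strengths are energies; the defender gains the configured defence bonus
#' if its defend gate fired this step. The attacker preys only when strictly
#' stronger (ties favour the defender): it then gains the transfer fraction
#' of the defender's energy and the defender dies, the remainder dissipating.
#' Otherwise the attack is repelled and the defender pays the defence cost
#' and records a successful defence. The attack cost is paid in both cases.
#' Attacking a robot in another cell is a contract violation.
#'
#' @param attacker,defender `swarm_robot`s in the same cell.
#' @param config simulation configuration (energy schedule).
#' @param defender_defending did the defender's defend gate fire this step?
#' @return list with updated `attacker` and `defender`, `outcome`
#'   (`"prey"` or `"repelled"`), `transferred` (energy gained by the
#'   attacker) and `dissipated` (energy leaving the system).
#' @export
attack <- function(attacker, defender, config = default_config(),
                   defender_defending = FALSE) {
  if (attacker$x != defender$x || attacker$y != defender$y)
    stop_invalid("attack requires attacker and defender in the same cell")
  en <- config$energy
  s_att <- attacker$energy
  s_def <- defender$energy + if (defender_defending) en$defence_bonus else 0
  attacker$energy <- attacker$energy - en$attack
  dissipated <- en$attack
  if (s_att > s_def) {
    transferred <- en$prey_transfer * defender$energy
    attacker$energy <- attacker$energy + transferred
    dissipated <- dissipated + (1 - en$prey_transfer) * defender$energy
    defender$energy <- 0
    defender$alive <- FALSE
    attacker$counters[["attacks"]] <- attacker$counters[["attacks"]] + 1L
    attacker$traces[["attacks"]] <- attacker$traces[["attacks"]] + 1
    outcome <- "prey"
  } else {
    defender$energy <- defender$energy - en$defend
    dissipated <- dissipated + en$defend
    defender$counters[["defences"]] <- defender$counters[["defences"]] + 1L
    defender$traces[["defences"]] <- defender$traces[["defences"]] + 1
    transferred <- 0
    outcome <- "repelled"
  }
  list(attacker = attacker, defender = defender, outcome = outcome,
       transferred = transferred, dissipated = dissipated)
}

#' Replicate a robot
#'
#' A parent at or above the replication threshold pays the replication cost,
#' transfers the endowment to the offspring and increments its replication
#' counter. The offspring appears in the parent's cell with a freshly
#' initialised controller: GRN offspring inherit a mutated copy of the
#' parent's genome ([replicate_genome()]); ANN offspring inherit the weight
#' vector with Gaussian mutation ([replicate_ann()]).
#'
#' @param parent a `swarm_robot`.
#' @param config simulation configuration.
#' @param offspring_id id for the child.
#' @return list with updated `parent` and `offspring` (`NULL` when the
#'   parent is below the replication threshold).
#' @export
replicate_robot <- function(parent, config = default_config(),
                            offspring_id = parent$id + 1L) {
  en <- config$energy
  if (parent$energy < en$replicate_threshold)
    return(list(parent = parent, offspring = NULL))
  parent$energy <- parent$energy - en$replicate - en$endowment
  parent$counters[["replications"]] <- parent$counters[["replications"]] + 1L
  parent$traces[["replications"]] <- parent$traces[["replications"]] + 1
  offspring <- new_robot(offspring_id, parent$x, parent$y, en$endowment,
                         offspring_controller(parent, config),
                         parent$controller)
  list(parent = parent, offspring = offspring)
}

# inherited controller for a new offspring: mutated genome copy (GRN) or
# mutated weight vector (ANN)
offspring_controller <- function(parent, config) {
  if (parent$controller == "grn") {
    rates <- mutation_rates(config$mutation$point_rate,
                            config$mutation$duplication_rate,
                            config$mutation$duplication_mean_len)
    new_grn_state(replicate_genome(parent$ctrl$genome, rates), config)
  } else {
    replicate_ann(parent$ctrl, config)
  }
}

#' Joint actuator output of an aggregated organism
#'
#' All member controllers run on their own sensors; the organism is steered
#' by the unweighted per-channel mean of the members' actuator vectors.
#'
#' @param outputs list of named actuator vectors, one per member (>= 2).
#' @return the joint named actuator vector.
#' @export
aggregate_step <- function(outputs) {
  if (length(outputs) < 2L)
    stop_invalid("an aggregate needs at least two members")
  Reduce(`+`, outputs) / length(outputs)
}

#' Charge living costs and decide survival
#'
#' Debits the basic living cost, the seasonal survival extra and, if the
#' robot moved this step, the seasonal movement extra. A robot that cannot
#' cover the debit dies and is removed the same step (ending exactly at 0 is
#' survival); its remaining energy dissipates.
#'
#' @param robot a `swarm_robot`.
#' @param season list from [season_costs()].
#' @param config simulation configuration.
#' @return list with updated `robot`, `alive` flag and `dissipated` energy.
#' @export
upkeep <- function(robot, season, config = default_config()) {
  debit <- config$energy$basic + season$survival +
    if (robot$moved) season$movement else 0
  if (robot$energy < debit) {
    dissipated <- robot$energy
    robot$energy <- 0
    robot$alive <- FALSE
  } else {
    robot$energy <- robot$energy - debit
    dissipated <- debit
  }
  list(robot = robot, alive = robot$alive, dissipated = dissipated)
}
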