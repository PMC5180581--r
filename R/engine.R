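# The simulation engine: orchestrates timesteps over a frozen pipeline,
# enforces the extinction criterion, tallies per-window metrics and runs
# replicated two-arm experiments.
#
# Step pipeline (frozen; reordering is a breaking change):
#   1. sense on the frozen start-of-step world (occupancy + food rings)
#   2. controller update per robot (GRN kernel / ANN feedback + forward);
#      aggregates are steered by the mean of their members' outputs
#   3. decide actions (gate thresholds + fixed priority)
#   4. conflict-prone actions execute in seeded random order over acting
#      units; a unit's fired gates are attempted in priority order until one
#      succeeds against the world (food present, a co-located target, enough
#      energy to replicate, a consenting partner)
#   5. movements (the last resort) execute as one batch (conflict-free)
#   6. upkeep and deaths (aggregates share energy before paying upkeep)
#   7. food growth, then scheduled food restoration
#   8. metrics every `metrics_interval` steps; extinction check
#
# Population state is kept as parallel vectors/matrices (one slot per robot)
# for speed; the per-robot operations in R/robot.R define the same semantics
# on single robots and are what the unit tests exercise.

#' Run one simulation
#'
#' A run is a pure function of `(config, seed)`: identical arguments give
#' bit-identical logs. The run terminates when the population drops below
#' the extinction threshold (strictly fewer robots than
#' `config$population$extinction`) or after `config$sim$max_steps` steps.
#'
#' @param config simulation configuration, see [default_config()].
#' @param seed integer seed for the run's RNG stream.
#' @return an object of class `run_log`: `metrics` (data.frame sampled every
#'   `metrics_interval` steps: step, population, food, preys, aggregations,
#'   attacks, births, feedings, sum_neighbours, mean_energy, prey_freq,
#'   agg_freq, avg_neighbours), `extinct`, `extinction_step`,
#'   `food_at_extinction` (NA unless extinction occurred), `terminal_step`,
#'   `terminal_food`, `events` (data.frame when `sim$log_events`), `audit`
#'   (energy-conservation ledger), `config`, `seed`.
#' @export
run_simulation <- function(config = default_config(), seed = 1L) {
  validate_config(config)
  set.seed(as.integer(seed))
  ctype <- config$sim$controller
  world <- new_world(config)
  size <- world$size
  n0 <- as.integer(config$population$initial)
  en <- config$energy
  g <- config$grn
  rates <- mutation_rates(config$mutation$point_rate,
                          config$mutation$duplication_rate,
                          config$mutation$duplication_mean_len)
  nact <- length(ACTUATORS)

  # ---- population state: one slot per robot ---------------------------------
  ids <- seq_len(n0)
  xs <- sample.int(size, n0, replace = TRUE)
  ys <- sample.int(size, n0, replace = TRUE)
  energy <- rep(as.numeric(config$population$initial_energy), n0)
  alive <- rep(TRUE, n0)
  agg <- integer(n0)
  moved <- logical(n0)
  last_delta <- numeric(n0)
  counters <- matrix(0L, n0, 5L,
                     dimnames = list(NULL, c("attacks", "defences",
                                             "replications", "feedings",
                                             "aggregations")))
  traces <- matrix(0, n0, 4L,
                   dimnames = list(NULL, c("attacks", "defences",
                                           "replications", "feedings")))
  if (ctype == "grn") {
    genomes <- vector("list", n0)
    tabs <- vector("list", n0)
    agents <- vector("list", n0)
    for (i in seq_len(n0)) {
      genomes[[i]] <- init_genome(NULL, config$genome$n_chromosomes,
                                  config$genome$chrom_length,
                                  config$genome$alphabet)
      tabs[[i]] <- genome_tables(genomes[[i]], config)
      agents[[i]] <- list(loc = integer(0), conc = numeric(0),
                          age = integer(0))
    }
  } else {
    B <- ann_batch_new(lapply(seq_len(n0), function(i) new_ann(NULL, config)),
                       config)
  }
  next_id <- n0 + 1L
  aggs <- list()  # aggregate id (character) -> member robot ids

  # ledgers
  audit_on <- isTRUE(config$sim$audit)
  log_events <- isTRUE(config$sim$log_events)
  initial_total <- n0 * config$population$initial_energy + food_energy(world)
  dissipated <- 0
  events <- list()
  ev_n <- 0L
  note <- function(step, id, x, y, action, outcome, delta) {
    if (log_events) {
      ev_n <<- ev_n + 1L
      events[[ev_n]] <<- data.frame(step = step, id = id, x = x, y = y,
                                    action = action, outcome = outcome,
                                    delta = delta)
    }
  }

  interval <- as.integer(config$sim$metrics_interval)
  max_steps <- as.integer(config$sim$max_steps)
  thr <- config$actions$threshold
  ext_thr <- as.integer(config$population$extinction)
  win <- c(preys = 0L, aggregations = 0L, attacks = 0L, births = 0L,
           feedings = 0L, moves = 0L)
  metrics <- list()
  m_n <- 0L

  sample_metrics <- function(step) {
    n <- length(ids)
    occ <- occupancy(xs, ys, size)
    nbr <- conv_ring(occ, config$sensors$radius, world$torus)
    sum_nbr <- if (n > 0L) sum(nbr[cbind(xs, ys)]) else 0
    m_n <<- m_n + 1L
    metrics[[m_n]] <<- data.frame(
      step = step, population = n, food = food_count(world),
      preys = win[["preys"]], aggregations = win[["aggregations"]],
      attacks = win[["attacks"]], births = win[["births"]],
      feedings = win[["feedings"]], moves = win[["moves"]],
      sum_neighbours = sum_nbr,
      mean_energy = if (n > 0L) mean(energy) else NA_real_,
      prey_freq = if (n > 0L) win[["preys"]] / n * 100 else NA_real_,
      agg_freq = if (n > 0L) win[["aggregations"]] / n * 100 else NA_real_,
      avg_neighbours = if (n > 0L) sum_nbr / n * 100 else NA_real_)
    win <<- c(preys = 0L, aggregations = 0L, attacks = 0L, births = 0L,
              feedings = 0L, moves = 0L)
  }

  sample_metrics(0L)
  extinct <- length(ids) < ext_thr
  t <- 0L
  dirs <- moore_dirs()

  while (!extinct && t < max_steps && length(ids) > 0L) {
    n <- length(ids)
    # ---- 1. sense on the frozen world ---------------------------------------
    occ <- occupancy(xs, ys, size)
    world$occ <- occ
    nbrR <- conv_ring(occ, config$sensors$radius, world$torus)
    fm <- food_matrix(world)
    nbrF <- conv_ring(fm, config$sensors$radius, world$torus) + fm
    mag <- sensor_matrix(nbrR[cbind(xs, ys)] + occ[cbind(xs, ys)] - 1L,
                         nbrF[cbind(xs, ys)], energy, traces, config)
    e_start <- energy

    # ---- 2. controllers -------------------------------------------------------
    if (ctype == "grn") {
      res <- .grn_step_all_cpp(agents, tabs, mag, last_delta, nact,
                               g$decay, g$feedback_gain, g$feedback_scale,
                               g$c_min, g$c_max, g$c_init)
      agents <- res$agents
      outputs <- res$outputs
    } else {
      B <- ann_batch_feedback(B, last_delta, config)
      fw <- ann_batch_forward(B, mag)
      B <- fw$B
      outputs <- fw$outputs
    }
    colnames(outputs) <- ACTUATORS

    # ---- 3. units and decisions -----------------------------------------------
    id2idx <- structure(seq_len(n), names = ids)
    if (length(aggs) == 0L) {
      units <- as.list(seq_len(n))
      u_out <- outputs
    } else {
      units <- as.list(which(agg == 0L))
      for (anm in names(aggs)) {
        members <- unname(id2idx[as.character(aggs[[anm]])])
        members <- members[!is.na(members)]
        units[[length(units) + 1L]] <- members
      }
      u_out <- t(vapply(units, function(m) {
        if (length(m) == 1L) outputs[m, ] else
          colMeans(outputs[m, , drop = FALSE])
      }, numeric(nact)))
      colnames(u_out) <- ACTUATORS
    }
    u_dec <- decide_matrix(u_out, thr)
    defending <- logical(n)
    for (ui in which(u_dec$action == "defend")) defending[units[[ui]]] <- TRUE
    robot_action <- rep("idle", n)  # per-robot view of its unit's decision
    for (ui in seq_along(units)) robot_action[units[[ui]]] <- u_dec$action[ui]
    fired <- u_out[, ACTION_PRIORITY, drop = FALSE] > thr

    # ---- 4. conflict actions in seeded random order ---------------------------
    fallthrough <- logical(length(units))
    # only units with a fired non-move gate enter the sequential loop
    busy <- rowSums(fired[, 1:5, drop = FALSE]) > 0
    order_u <- sample.int(length(units))
    for (ui in order_u) {
      if (!busy[ui]) {
        fallthrough[ui] <- fired[ui, "move"]
        next
      }
      m <- units[[ui]]
      m <- m[alive[m]]
      if (length(m) == 0L) next
      gates <- ACTION_PRIORITY[fired[ui, ]]
      if (gates[1L] == "defend") next  # defensive stance this step
      done <- FALSE
      for (act in gates) {
        if (act == "defend") next
        if (act == "move") break
        if (act == "eat") {
          lead <- m[1L]
          # satiety: a robot (or organism, per capita) at full storage does
          # not consume; the attempt fails and the gate chain continues
          gained <- if (mean(energy[m]) >= en$satiety) 0 else
            eat_cell(world, xs[lead], ys[lead], sum(energy[m]))
          if (gained > 0) {
            energy[m] <- energy[m] + gained / length(m)
            counters[m, "feedings"] <- counters[m, "feedings"] + 1L
            traces[m, "feedings"] <- traces[m, "feedings"] + 1
            win[["feedings"]] <- win[["feedings"]] + 1L
            note(t + 1L, ids[lead], xs[lead], ys[lead], "eat", "fed", gained)
            done <- TRUE
          }
        } else if (act == "attack") {
          lead <- m[1L]
          # targets come from the frozen start-of-step population
          cand <- which(xs[seq_len(n)] == xs[lead] & ys[seq_len(n)] == ys[lead] &
                          alive[seq_len(n)])
          cand <- cand[!(cand %in% m)]
          if (length(cand) > 0L) {
            win[["attacks"]] <- win[["attacks"]] + 1L
            target <- cand[order(energy[cand], cand)][1L]  # weakest first
            d_members <- if (agg[target] > 0L) {
              dm <- unname(id2idx[as.character(aggs[[as.character(agg[target])]])])
              dm <- dm[!is.na(dm)]
              dm[alive[dm]]
            } else target
            s_att <- sum(energy[m])
            s_def <- sum(energy[d_members]) +
              if (defending[target]) en$defence_bonus else 0
            energy[m] <- energy[m] - en$attack / length(m)
            dissipated <- dissipated + en$attack
            if (s_att > s_def) {
              transferred <- en$prey_transfer * energy[target]
              dissipated <- dissipated +
                (1 - en$prey_transfer) * energy[target]
              energy[m] <- energy[m] + transferred / length(m)
              counters[m, "attacks"] <- counters[m, "attacks"] + 1L
              traces[m, "attacks"] <- traces[m, "attacks"] + 1
              energy[target] <- 0
              alive[target] <- FALSE
              win[["preys"]] <- win[["preys"]] + 1L
              note(t + 1L, ids[lead], xs[lead], ys[lead], "attack", "prey",
                   transferred)
            } else {
              energy[d_members] <- energy[d_members] -
                en$defend / length(d_members)
              counters[d_members, "defences"] <-
                counters[d_members, "defences"] + 1L
              traces[d_members, "defences"] <-
                traces[d_members, "defences"] + 1
              dissipated <- dissipated + en$defend
              note(t + 1L, ids[lead], xs[lead], ys[lead], "attack",
                   "repelled", -en$attack)
            }
            done <- TRUE
          }
        } else if (act == "replicate") {
          pooled <- sum(energy[m])
          if (pooled >= en$replicate_threshold) {
            parent_i <- if (length(m) == 1L) m else
              m[sample.int(length(m), 1L)]
            energy[m] <- energy[m] - (en$replicate + en$endowment) / length(m)
            counters[m, "replications"] <- counters[m, "replications"] + 1L
            traces[m, "replications"] <- traces[m, "replications"] + 1
            # ---- append the offspring (acts from the next step on) ----
            ids <- c(ids, next_id)
            xs <- c(xs, xs[parent_i]); ys <- c(ys, ys[parent_i])
            energy <- c(energy, en$endowment)
            alive <- c(alive, TRUE)
            agg <- c(agg, 0L)
            moved <- c(moved, FALSE)
            last_delta <- c(last_delta, 0)
            e_start <- c(e_start, en$endowment)
            counters <- rbind(counters, 0L)
            traces <- rbind(traces, 0)
            if (ctype == "grn") {
              child <- replicate_genome(genomes[[parent_i]], rates)
              genomes[[length(genomes) + 1L]] <- child
              tabs[[length(tabs) + 1L]] <- genome_tables(child, config)
              agents[[length(agents) + 1L]] <-
                list(loc = integer(0), conc = numeric(0), age = integer(0))
            } else {
              B <- ann_batch_add(B, parent_i, config)
            }
            dissipated <- dissipated + en$replicate
            win[["births"]] <- win[["births"]] + 1L
            note(t + 1L, ids[parent_i], xs[parent_i], ys[parent_i],
                 "replicate", "offspring", -en$replicate)
            next_id <- next_id + 1L
            done <- TRUE
          }
        } else if (act == "aggregate") {
          if (length(m) == 1L && agg[m] == 0L) {
            mates <- which(xs[seq_len(n)] == xs[m] & ys[seq_len(n)] == ys[m] &
                             alive[seq_len(n)] & agg[seq_len(n)] == 0L)
            mates <- mates[mates != m]
            # consenting: their own top fired gate this step is aggregate
            mates <- mates[robot_action[mates] == "aggregate"]
            if (length(mates) > 0L) {
              new_agg <- if (length(aggs) == 0L) 1L else
                max(as.integer(names(aggs))) + 1L
              members <- c(m, mates)
              agg[members] <- new_agg
              energy[members] <- energy[members] - en$aggregate
              counters[members, "aggregations"] <-
                counters[members, "aggregations"] + 1L
              dissipated <- dissipated + en$aggregate * length(members)
              aggs[[as.character(new_agg)]] <- ids[members]
              win[["aggregations"]] <- win[["aggregations"]] + 1L
              note(t + 1L, ids[m], xs[m], ys[m], "aggregate", "formed",
                   -en$aggregate)
              done <- TRUE
            }
          }
        }
        if (done) break
      }
      if (!done && fired[ui, "move"]) fallthrough[ui] <- TRUE
    }

    # ---- 5. movement (batch; conflict-free) -----------------------------------
    mv_units <- which(fallthrough)
    if (length(mv_units) > 0L) {
      is_single <- vapply(units[mv_units], length, 0L) == 1L
      mi <- unlist(units[mv_units][is_single], use.names = FALSE)
      dd <- u_dec$direction[mv_units][is_single]
      live <- alive[mi]
      mi <- mi[live]; dd <- dd[live]
      if (length(mi) > 0L) {
        xs[mi] <- wrap_coord(xs[mi] + dirs[dd, 1L], size, world$torus)
        ys[mi] <- wrap_coord(ys[mi] + dirs[dd, 2L], size, world$torus)
        energy[mi] <- energy[mi] - en$move
        moved[mi] <- TRUE
        dissipated <- dissipated + en$move * length(mi)
        win[["moves"]] <- win[["moves"]] + length(mi)
      }
      for (ui in mv_units[!is_single]) {  # aggregates move as one organism
        m <- units[[ui]]
        m <- m[alive[m]]
        if (length(m) == 0L) next
        d <- u_dec$direction[ui]
        xs[m] <- wrap_coord(xs[m] + dirs[d, 1L], size, world$torus)
        ys[m] <- wrap_coord(ys[m] + dirs[d, 2L], size, world$torus)
        energy[m] <- energy[m] - en$move
        moved[m] <- TRUE
        dissipated <- dissipated + en$move * length(m)
      }
    }

    # ---- 6. upkeep, energy sharing, deaths ------------------------------------
    sc <- season_costs(t, world)
    for (anm in names(aggs)) {  # aggregates share energy equally
      mm <- unname(id2idx[as.character(aggs[[anm]])])
      mm <- mm[!is.na(mm)]
      mm <- mm[alive[mm]]
      if (length(mm) >= 2L) energy[mm] <- sum(energy[mm]) / length(mm)
    }
    debit <- en$basic + sc$survival + en$aggregate_upkeep * (agg > 0L) +
      sc$movement * moved
    starved <- alive & (energy < debit)
    survivors <- alive & !starved
    dissipated <- dissipated + sum(energy[!survivors]) +
      sum(debit[survivors])
    energy[survivors] <- energy[survivors] - debit[survivors]
    energy[!survivors] <- 0
    if (log_events && any(starved)) {
      for (i in which(starved)) {
        note(t + 1L, ids[i], xs[i], ys[i], "upkeep", "death", 0)
      }
    }
    last_delta <- energy - e_start
    traces <- traces * config$sensors$trace_decay
    moved[] <- FALSE
    if (!all(survivors)) {
      keep <- which(survivors)
      ids <- ids[keep]; xs <- xs[keep]; ys <- ys[keep]
      energy <- energy[keep]; alive <- alive[keep]; agg <- agg[keep]
      moved <- moved[keep]; last_delta <- last_delta[keep]
      counters <- counters[keep, , drop = FALSE]
      traces <- traces[keep, , drop = FALSE]
      if (ctype == "grn") {
        genomes <- genomes[keep]; tabs <- tabs[keep]; agents <- agents[keep]
      } else {
        B <- ann_batch_subset(B, keep)
      }
      # prune aggregates: drop dead members, dissolve below two members
      if (length(aggs) > 0L) {
        for (anm in names(aggs)) {
          aggs[[anm]] <- aggs[[anm]][aggs[[anm]] %in% ids]
        }
        small <- names(aggs)[vapply(aggs, length, 0L) < 2L]
        for (anm in small) {
          agg[ids %in% aggs[[anm]]] <- 0L
          aggs[[anm]] <- NULL
        }
      }
    }

    # ---- 7. food growth and restoration ---------------------------------------
    grow_food(world)
    restore_food(world, t + 1L)

    # ---- 8. metrics, audit, extinction ----------------------------------------
    t <- t + 1L
    if (audit_on) {
      total <- sum(energy) + food_energy(world)
      if (abs(total + dissipated - world$created_energy - initial_total) >
          1e-6 * max(1, initial_total))
        stop("energy ledger violated at step ", t)
    }
    if (t %% interval == 0L) sample_metrics(t)
    extinct <- length(ids) < ext_thr
  }

  metrics <- do.call(rbind, metrics)
  structure(list(
    metrics = metrics,
    extinct = extinct,
    extinction_step = if (extinct) t else NA_integer_,
    food_at_extinction = if (extinct) food_count(world) else NA_integer_,
    terminal_step = t,
    terminal_food = food_count(world),
    final_population = length(ids),
    events = if (log_events && ev_n > 0L)
      do.call(rbind, events[seq_len(ev_n)]) else NULL,
    audit = list(initial = initial_total, created = world$created_energy,
                 dissipated = dissipated,
                 final = sum(energy) + food_energy(world)),
    config = config, seed = as.integer(seed)),
    class = "run_log")
}

#' @export
print.run_log <- function(x, ...) {
  cat("run_log: seed", x$seed, "-", x$terminal_step, "step(s),",
      if (x$extinct) paste0("extinct (food at extinction: ",
                            x$food_at_extinction, ")")
      else paste0("population ", x$final_population, " surviving"),
      "\n")
  invisible(x)
}

# robot-count matrix from coordinate vectors
occupancy <- function(xs, ys, size) {
  if (length(xs) == 0L) return(matrix(0L, size, size))
  matrix(tabulate(xs + size * (ys - 1L), size * size), size, size)
}

# vectorised sensor encoding across the population (one row per robot);
# row-equivalent to encode_sensors()
sensor_matrix <- function(nbr_robots, nbr_food, energies, traces, config) {
  ns <- config$sensors
  cbind(robots = pmin(nbr_robots / ns$norm_robots, 1),
        food = pmin(nbr_food / ns$norm_food, 1),
        energy = pmin(energies / ns$norm_energy, 1),
        attacks = pmin(traces[, 1L], 1),
        defences = pmin(traces[, 2L], 1),
        replications = pmin(traces[, 3L], 1),
        feedings = pmin(traces[, 4L], 1),
        constitutive = 1)
}

# vectorised decide_actions over unit output rows
decide_matrix <- function(out, threshold) {
  n <- nrow(out)
  action <- rep("idle", n)
  for (a in rev(ACTION_PRIORITY)) {
    action[out[, a] > threshold] <- a
  }
  dir <- as.integer(floor((out[, "direction"] %% 1) * 8)) + 1L
  dir[dir > 8L] <- 8L
  list(action = action, direction = dir)
}

#' Run a replicated two-arm experiment
#'
#' Runs `n_per_arm` simulations per controller arm over disjoint seed
#' streams derived from the master seed, collects the food remaining at each
#' extinction and compares the arms with [compare_extinction_food()].
#'
#' @param config shared configuration (the per-arm controller is set
#'   internally).
#' @param n_per_arm replicate runs per arm (>= 2 for the group statistics).
#' @param master_seed integer master seed; run seeds are derived with
#'   [derive_seed()] (GRN arm: counters 1..n, ANN arm: 1001..1000+n).
#' @param arms character vector of controller arms to run.
#' @param food_max food-count ceiling defining the food-scarce tail used for
#'   the per-run prey-food correlation (`NA` = full series).
#' @param quiet suppress the one-line progress message per run.
#' @return an object of class `swarm_experiment`: `runs` (data.frame with
#'   one row per run: arm, seed, extinct, extinction_step,
#'   food_at_extinction, terminal food/step, prey-food correlation over the
#'   food-scarce tail), `comparison` (Welch test on food-at-extinction,
#'   extinct runs only), `comparison_all` (same on terminal food of all
#'   runs), and `logs` (the individual `run_log`s).
#' @export
run_experiment <- function(config = default_config(), n_per_arm = 10L,
                           master_seed = 1L, arms = c("grn", "ann"),
                           food_max = 200, quiet = FALSE) {
  if (n_per_arm < 2L) stop_invalid("n_per_arm must be >= 2")
  rows <- list()
  logs <- list()
  for (arm in arms) {
    offset <- if (arm == "grn") 0L else 1000L
    cfg <- config
    cfg$sim$controller <- arm
    for (j in seq_len(n_per_arm)) {
      sd <- derive_seed(master_seed, offset + j)
      if (!quiet) message("run ", arm, " ", j, "/", n_per_arm,
                          " (seed ", sd, ")")
      log <- run_simulation(cfg, sd)
      pf <- tryCatch({
        r <- prey_food_correlation(log$metrics$prey_freq, log$metrics$food,
                                   food_max = food_max)
        c(r$r, r$p)
      }, error = function(e) c(NA_real_, NA_real_))
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm, seed = sd, extinct = log$extinct,
        extinction_step = log$extinction_step,
        food_at_extinction = log$food_at_extinction,
        terminal_step = log$terminal_step, terminal_food = log$terminal_food,
        prey_food_r = pf[1L], prey_food_p = pf[2L])
      logs[[paste0(arm, "_", j)]] <- log
    }
  }
  runs <- do.call(rbind, rows)
  cmp <- NULL
  cmp_all <- NULL
  if (all(c("grn", "ann") %in% arms)) {
    gx <- runs$food_at_extinction[runs$arm == "grn" & runs$extinct]
    ax <- runs$food_at_extinction[runs$arm == "ann" & runs$extinct]
    if (length(gx) >= 2L && length(ax) >= 2L)
      cmp <- compare_extinction_food(gx, ax)
    cmp_all <- compare_extinction_food(
      runs$terminal_food[runs$arm == "grn"],
      runs$terminal_food[runs$arm == "ann"])
  }
  structure(list(runs = runs, comparison = cmp, comparison_all = cmp_all,
                 logs = logs, n_per_arm = n_per_arm,
                 master_seed = master_seed),
            class = "swarm_experiment")
}

#' @export
print.swarm_experiment <- function(x, ...) {
  cat("swarm_experiment:", x$n_per_arm, "run(s) per arm, master seed",
      x$master_seed, "\n")
  for (arm in unique(x$runs$arm)) {
    sub <- x$runs[x$runs$arm == arm, ]
    cat(sprintf("  %s: %d/%d extinct, mean food at extinction %.2f\n",
                arm, sum(sub$extinct), nrow(sub),
                mean(sub$food_at_extinction[sub$extinct])))
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("  Welch t-test (extinct runs): t = %.3f, p = %.3g\n",
                x$comparison$t, x$comparison$p))
  }
  invisible(x)
}

#' Write a run log to a directory
#'
#' Emits `metrics.tsv` (one row per sampled window), `events.tsv` (when
#' event logging was on), `config.yaml` (configuration echo) and
#' `summary.yaml` (terminal record).
#'
#' @param log a `run_log`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_runlog <- function(log, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(log$metrics, file.path(dir, "metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(log$events))
    write.table(log$events, file.path(dir, "events.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  write_config(log$config, file.path(dir, "config.yaml"))
  yaml::write_yaml(list(seed = log$seed, extinct = log$extinct,
                        extinction_step = log$extinction_step,
                        food_at_extinction = log$food_at_extinction,
                        terminal_step = log$terminal_step,
                        terminal_food = log$terminal_food),
                   file.path(dir, "summary.yaml"))
  invisible(dir)
}
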