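# The simulated environment: a square (default 90x90, toroidal) grid holding
# robots and typed food sources, a season clock imposing extra survival and
# movement costs every 100 steps, and density-dependent food regrowth.
# The world is an environment (reference semantics): eating, growth and
# restoration mutate it in place, mirroring how the single shared habitat is
# consumed and replenished during a run.

#' Create a world grid
#'
#' Builds the grid and scatters the configured initial food sources uniformly
#' at random (several sources may share a cell). Food is kept as per-type
#' per-cell counts; robot occupancy (one count per cell) is maintained by the
#' engine and used by [neighbourhood()] and [neighbour_density_map()].
#'
#' @param config simulation configuration, see [default_config()].
#' @param scatter_food scatter the configured initial food (default `TRUE`;
#'   tests build empty worlds with `FALSE`).
#' @return an environment of class `world_grid` with fields `size`, `torus`,
#'   `types` (data.frame: threshold, energy, initial), `food` (size x size x
#'   n_types integer array), `occ` (robot-count matrix), season fields, the
#'   restoration schedule, and `created_energy` (cumulative energy injected
#'   by growth and restoration, for the conservation audit).
#' @export
new_world <- function(config = default_config(), scatter_food = TRUE) {
  w <- new.env(parent = emptyenv())
  w$size <- as.integer(config$world$size)
  w$torus <- isTRUE(config$world$torus)
  w$types <- config$food$types
  if (is.unsorted(w$types$threshold))
    stop_invalid("food access thresholds must be non-decreasing in type index")
  if (any(w$types$energy <= 0))
    stop_invalid("food energy_content must be positive")
  w$r0 <- config$food$r0
  w$K <- config$food$K
  w$restore <- config$food$restore_schedule
  w$season_length <- as.integer(config$seasons$length)
  w$season_survival <- config$seasons$survival
  w$season_movement <- config$seasons$movement
  nt <- nrow(w$types)
  w$food <- array(0L, dim = c(w$size, w$size, nt))
  w$occ <- matrix(0L, w$size, w$size)
  w$created_energy <- 0
  if (scatter_food) {
    for (ti in seq_len(nt)) {
      n <- as.integer(w$types$initial[ti])
      if (n > 0L) {
        cells <- sample.int(w$size^2, n, replace = TRUE)
        w$food[, , ti] <- w$food[, , ti] +
          matrix(tabulate(cells, w$size^2), w$size, w$size)
      }
    }
  }
  class(w) <- c("world_grid", "environment")
  w
}

#' @export
print.world_grid <- function(x, ...) {
  cat("world_grid:", x$size, "x", x$size, if (x$torus) "(torus)" else "(bounded)",
      "-", sum(x$food), "food source(s),", sum(x$occ), "robot(s)\n")
  invisible(x)
}

# total food count per cell, across types
food_matrix <- function(world) {
  nt <- dim(world$food)[3]
  m <- world$food[, , 1L]
  if (nt > 1L) for (ti in 2:nt) m <- m + world$food[, , ti]
  m
}

#' Total number of food sources on the grid
#' @param world a `world_grid`.
#' @return integer count.
#' @export
food_count <- function(world) sum(world$food)

# total energy stored in on-grid food (conservation audit)
food_energy <- function(world) {
  nt <- dim(world$food)[3]
  sum(vapply(seq_len(nt), function(ti) sum(world$food[, , ti]) *
               world$types$energy[ti], 0))
}

#' Count robots and food around a position
#'
#' Counts over the Moore neighbourhood of Chebyshev radius `radius` from the
#' viewpoint of a robot sitting at `pos`: all cells within the radius are
#' scanned, the focal robot itself is excluded from the robot count (so
#' co-located robots do count), and food in the focal cell counts (a robot
#' senses what it is standing on). Respects the boundary topology.
#'
#' @param world a `world_grid`.
#' @param pos integer vector `c(x, y)`.
#' @param radius sensing radius (>= 1).
#' @return named integer vector `c(robots = , food = )`.
#' @export
neighbourhood <- function(world, pos, radius = 1L) {
  n <- world$size
  if (length(pos) != 2L || any(pos < 1L) || any(pos > n))
    stop_invalid("position out of range")
  if (radius < 1L) stop_invalid("radius must be >= 1")
  fm <- food_matrix(world)
  robots <- 0L; food <- 0L
  for (dx in -radius:radius) for (dy in -radius:radius) {
    x <- pos[1L] + dx; y <- pos[2L] + dy
    if (world$torus) {
      x <- ((x - 1L) %% n) + 1L; y <- ((y - 1L) %% n) + 1L
    } else if (x < 1L || x > n || y < 1L || y > n) next
    robots <- robots + world$occ[x, y]
    food <- food + fm[x, y]
  }
  robots <- robots - min(world$occ[pos[1L], pos[2L]], 1L)  # not itself
  c(robots = robots, food = food)
}

#' Grow food by density-dependent replication
#'
#' Every food source independently spawns one offspring of its own type with
#' probability `r0 * max(0, 1 - k / K)`, where `k` is the number of other
#' food sources within its radius-1 neighbourhood (the eight surrounding
#' cells plus co-located sources). Offspring land in a uniformly chosen cell
#' among the eight neighbours of the parent (lost off-grid on bounded
#' worlds). Food count never decreases during this operation.
#'
#' @param world a `world_grid` (mutated in place).
#' @param seed optional integer seed (`NULL`: current RNG stream).
#' @return the number of new sources, invisibly.
#' @export
grow_food <- function(world, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- world$size
  total <- food_matrix(world)
  if (sum(total) == 0L) return(invisible(0L))
  k <- conv_ring(total, 1L, world$torus) + total - 1L
  p <- world$r0 * pmax(0, 1 - k / world$K)
  dirs <- moore_dirs()
  nt <- dim(world$food)[3]
  born <- 0L
  for (ti in seq_len(nt)) {
    slice <- world$food[, , ti]
    idx <- which(slice > 0L)
    if (length(idx) == 0L) next
    spawns <- rbinom(length(idx), slice[idx], p[idx])
    tot <- sum(spawns)
    if (tot == 0L) next
    src <- rep.int(idx, spawns)
    sx <- ((src - 1L) %% n) + 1L
    sy <- ((src - 1L) %/% n) + 1L
    d <- sample.int(8L, tot, replace = TRUE)
    x <- sx + dirs[d, 1L]; y <- sy + dirs[d, 2L]
    if (world$torus) {
      x <- wrap_coord(x, n); y <- wrap_coord(y, n)
    } else {
      ok <- x >= 1L & x <= n & y >= 1L & y <= n
      x <- x[ok]; y <- y[ok]
    }
    if (length(x) > 0L) {
      world$food[, , ti] <- world$food[, , ti] +
        matrix(tabulate(x + n * (y - 1L), n * n), n, n)
      world$created_energy <- world$created_energy +
        length(x) * world$types$energy[ti]
      born <- born + length(x)
    }
  }
  invisible(born)
}

#' Seasonal extra energy costs at a timestep
#'
#' Seasons are consecutive blocks of `season_length` steps (default 100)
#' cycling through the configured cost table; within a season the extra
#' survival and movement costs are constant.
#'
#' @param t timestep (>= 0).
#' @param world a `world_grid` (or anything with `season_length`,
#'   `season_survival`, `season_movement`).
#' @return list with `season` (0-based index), `survival` and `movement`
#'   extra costs.
#' @export
season_costs <- function(t, world) {
  if (t < 0) stop_invalid("t must be >= 0")
  ns <- length(world$season_survival)
  idx <- (as.integer(t) %/% world$season_length) %% ns + 1L
  list(season = idx - 1L, survival = world$season_survival[idx],
       movement = world$season_movement[idx])
}

#' Scheduled food restoration
#'
#' At every step listed in the restoration schedule, scatters the scheduled
#' number of new food sources uniformly over the grid, with the type mix
#' proportional to the configured initial counts. Robot state is untouched.
#'
#' @param world a `world_grid` (mutated in place).
#' @param t current timestep.
#' @param seed optional integer seed.
#' @return the number of restored sources, invisibly.
#' @export
restore_food <- function(world, t, seed = NULL) {
  sched <- world$restore
  key <- as.character(t)
  if (length(sched) == 0L || is.null(sched[[key]])) return(invisible(0L))
  if (!is.null(seed)) set.seed(as.integer(seed))
  count <- as.integer(sched[[key]])
  share <- world$types$initial / sum(world$types$initial)
  per_type <- floor(count * share)
  left <- count - sum(per_type)
  if (left > 0L) {
    extra <- order(count * share - per_type, decreasing = TRUE)[seq_len(left)]
    per_type[extra] <- per_type[extra] + 1L
  }
  n <- world$size
  for (ti in seq_along(per_type)) {
    m <- per_type[ti]
    if (m <= 0L) next
    cells <- sample.int(n * n, m, replace = TRUE)
    world$food[, , ti] <- world$food[, , ti] +
      matrix(tabulate(cells, n * n), n, n)
    world$created_energy <- world$created_energy + m * world$types$energy[ti]
  }
  invisible(count)
}
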