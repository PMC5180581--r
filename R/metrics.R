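# Behavioural statistics over run logs: windowed action frequencies, the
# average-neighbour statistic, the prey-food correlation, the
# food-at-extinction group comparison, and per-cell neighbour-density maps.

#' Windowed action frequency
#'
#' Frequency of an action over a sampling window:
#' `count / population * 100`, where `count` is the number of successful
#' actions accumulated over the window and `population` the population size
#' at the sample step.
#'
#' @param count successful actions in the window (>= 0).
#' @param population population size at the sample step (> 0).
#' @return the frequency (vectorised over its arguments).
#' @export
action_frequency <- function(count, population) {
  if (any(count < 0)) stop_invalid("count must be >= 0")
  if (any(population <= 0))
    stop_invalid("action frequency is undefined for an empty population")
  count / population * 100
}

#' Average-neighbour statistic
#'
#' `sum of all neighbouring robots / number of robots * 100`: the summed
#' per-robot neighbour counts, normalised by population size. Invariant
#' under robot relabelling.
#'
#' @param sum_neighbours sum over robots of their neighbour counts.
#' @param n_robots number of robots (> 0).
#' @return the statistic (vectorised).
#' @export
avg_neighbours <- function(sum_neighbours, n_robots) {
  if (any(sum_neighbours < 0)) stop_invalid("sum_neighbours must be >= 0")
  if (any(n_robots <= 0))
    stop_invalid("average neighbours is undefined for an empty population")
  sum_neighbours / n_robots * 100
}

#' Pearson correlation between prey activity and food availability
#'
#' Product-moment correlation (with two-sided p-value) between the per-window
#' successful-prey series and the food-count series of a run. With
#' `food_max` set, the correlation is restricted to the food-scarce tail
#' (windows with food count at most `food_max`), which is where preying is
#' expected to be a specific adaptation.
#'
#' @param preys,food equal-length numeric series sampled every metrics
#'   interval.
#' @param food_max optional food-count ceiling selecting the scarce tail
#'   (`NA` or `NULL`: use the full series).
#' @return list with `r`, `p` and `n` (windows used).
#' @export
prey_food_correlation <- function(preys, food, food_max = NULL) {
  if (length(preys) != length(food))
    stop_invalid("series must have equal length")
  if (!is.null(food_max) && !is.na(food_max)) {
    keep <- food <= food_max
    preys <- preys[keep]
    food <- food[keep]
  }
  if (length(preys) < 3L)
    stop_invalid("need at least 3 windows for a correlation")
  if (stats::var(preys) == 0 || stats::var(food) == 0)
    stop_invalid("correlation is undefined for a constant series")
  ct <- cor.test(preys, food, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(preys))
}

#' Compare food remaining at extinction between controller arms
#'
#' Two-sample t-test on the per-run food-at-extinction samples, Welch by
#' default (`var_equal = TRUE` gives the pooled-variance Student variant).
#'
#' @param grn,ann numeric samples (food sources remaining at extinction per
#'   run), each of size >= 2.
#' @param var_equal use the pooled-variance test instead of Welch.
#' @return list with `mean_grn`, `mean_ann`, `t`, `df`, `p`.
#' @export
compare_extinction_food <- function(grn, ann, var_equal = FALSE) {
  if (length(grn) < 2L || length(ann) < 2L)
    stop_invalid("each sample needs at least 2 runs")
  tt <- t.test(grn, ann, var.equal = var_equal)
  list(mean_grn = mean(grn), mean_ann = mean(ann),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Per-cell neighbour-density map
#'
#' For every cell of the grid, the number of robots in its radius-`radius`
#' neighbourhood (the surrounding ring, the cell itself excluded), binned
#' into the classes 0, 1, 2, 3 and 4+ used to colour spatial-distribution
#' maps.
#'
#' @param world a `world_grid` whose `occ` matrix holds the robot counts
#'   (maintained by the engine; tests can set it directly).
#' @param radius neighbourhood radius.
#' @return list of class `density_map` with `counts` (integer matrix) and
#'   `class` (character matrix over `"0".."3","4+"`).
#' @export
neighbour_density_map <- function(world, radius = 1L) {
  counts <- conv_ring(world$occ, radius, world$torus)
  storage.mode(counts) <- "integer"
  cls <- matrix(as.character(pmin(counts, 4L)), nrow(counts), ncol(counts))
  cls[counts >= 4L] <- "4+"
  structure(list(counts = counts, class = cls), class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat("density_map:", nrow(x$counts), "x", ncol(x$counts),
      "cells; class counts:\n")
  print(table(factor(x$class, levels = c("0", "1", "2", "3", "4+"))))
  invisible(x)
}
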