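# Robot life cycle: action decisions, feeding, attacks, replication,
# aggregation and upkeep.

cfg <- default_config()
neutral <- setNames(numeric(length(ACTUATORS)), ACTUATORS)

test_that("an all-neutral actuator vector means idling", {
  expect_identical(decide_actions(neutral)$action, "idle")
})

test_that("eat wins over a co-fired move gate", {
  v <- neutral
  v["eat"] <- 0.9
  v["move"] <- 0.9
  expect_identical(decide_actions(v)$action, "eat")
})

test_that("sweeping one gate across its threshold flips exactly that action", {
  for (a in grnswarm:::ACTION_PRIORITY) {
    v <- neutral
    v[a] <- 0.49
    expect_identical(decide_actions(v)$action, "idle")
    v[a] <- 0.51
    expect_identical(decide_actions(v)$action, a)
  }
})

test_that("the direction channel maps onto the eight headings", {
  dirs <- vapply(seq(0, 0.999, length.out = 64), function(v) {
    vv <- neutral
    vv["direction"] <- v
    decide_actions(vv)$direction
  }, 0L)
  expect_setequal(unique(dirs), 1:8)
  expect_true(all(diff(dirs) >= 0))
})

test_that("eating takes the best accessible source and respects thresholds", {
  w <- new_world(small_config(), scatter_food = FALSE)
  g <- genome_from_strings(strrep("2", 60))
  mk <- function(e) new_robot(1, 3, 3, e, new_grn_state(g, small_config()))
  # only an inaccessible type present: nothing is eaten
  w$food[3, 3, 2] <- 1L  # threshold 30
  r <- eat(mk(10), w)
  expect_identical(r$gained, 0)
  expect_identical(w$food[3, 3, 2], 1L)
  # both a 30- and a 120-energy source present: the best one goes first
  w$food[3, 3, 1] <- 1L
  w$food[3, 3, 3] <- 1L
  r <- eat(mk(100), w)
  expect_identical(r$gained, 120)
  expect_identical(w$food[3, 3, 3], 0L)
  expect_identical(r$robot$counters[["feedings"]], 1L)
  # an empty cell leaves the robot unchanged
  w2 <- new_world(small_config(), scatter_food = FALSE)
  expect_identical(eat(mk(100), w2)$gained, 0)
})

test_that("attack resolves prey, repelled and tie per the strength rule", {
  g <- genome_from_strings(strrep("2", 60))
  mk <- function(id, e, x = 3, y = 3) {
    new_robot(id, x, y, e, new_grn_state(g, small_config()))
  }
  acfg <- default_config(energy = list(attack = 5, defend = 3,
                                       prey_transfer = 0.8,
                                       defence_bonus = 30))
  # 100 vs 40 at transfer 0.8: prey, attacker gains 32, defender dies
  res <- attack(mk(1, 100), mk(2, 40), acfg)
  expect_identical(res$outcome, "prey")
  expect_equal(res$transferred, 32)
  expect_equal(res$attacker$energy, 100 - 5 + 32)
  expect_false(res$defender$alive)
  expect_identical(res$attacker$counters[["attacks"]], 1L)
  # the weaker attacker is repelled and both only pay costs
  res <- attack(mk(1, 40), mk(2, 100), acfg)
  expect_identical(res$outcome, "repelled")
  expect_equal(res$attacker$energy, 35)
  expect_equal(res$defender$energy, 97)
  expect_true(res$defender$alive)
  expect_identical(res$defender$counters[["defences"]], 1L)
  # equal strength favours the defender
  expect_identical(attack(mk(1, 80), mk(2, 80), acfg)$outcome, "repelled")
  # a firing defend gate adds the defence bonus
  expect_identical(attack(mk(1, 100), mk(2, 80), acfg,
                          defender_defending = TRUE)$outcome, "repelled")
  # attacking across cells violates the contract
  expect_error(attack(mk(1, 100), mk(2, 40, x = 4), acfg), "same cell")
})

test_that("replication transfers the endowment and spawns in place", {
  rcfg <- small_config(energy = list(replicate = 20,
                                     replicate_threshold = 150,
                                     endowment = 50))
  g <- init_genome(seed = 3, n_chromosomes = 2, chrom_length = 1200)
  parent <- new_robot(1, 7, 9, 200, new_grn_state(g, rcfg))
  set.seed(2)
  res <- replicate_robot(parent, rcfg, offspring_id = 99)
  expect_equal(res$parent$energy, 130)
  expect_equal(res$offspring$energy, 50)
  expect_identical(res$offspring$x, 7L)
  expect_identical(res$offspring$y, 9L)
  expect_identical(res$offspring$id, 99L)
  expect_identical(res$parent$counters[["replications"]], 1L)
  # the child's genome differs (mutation) but has the same chromosome count
  expect_length(res$offspring$ctrl$genome$chromosomes, 2L)
  expect_false(identical(res$offspring$ctrl$genome$chromosomes,
                         g$chromosomes))
  # below the threshold nothing happens
  poor <- new_robot(2, 1, 1, 100, new_grn_state(g, rcfg))
  expect_null(replicate_robot(poor, rcfg)$offspring)
})

test_that("aggregate output is the unweighted mean of member outputs", {
  a <- neutral; a["eat"] <- 0.2
  b <- neutral; b["eat"] <- 0.8
  expect_equal(unname(aggregate_step(list(a, b))["eat"]), 0.5)
  expect_identical(aggregate_step(list(a, a)), a)
  expect_error(aggregate_step(list(a)), "two members")
})

test_that("upkeep kills exactly when the debit cannot be covered", {
  g <- genome_from_strings(strrep("2", 60))
  ucfg <- small_config(energy = list(basic = 1))
  season <- list(season = 1L, survival = 5, movement = 2)
  r <- new_robot(1, 2, 2, 5, new_grn_state(g, ucfg))
  expect_false(upkeep(r, season, ucfg)$alive)   # 5 < 6
  r$energy <- 6
  res <- upkeep(r, season, ucfg)                # 6 - 6 = 0: survives at zero
  expect_true(res$alive)
  expect_equal(res$robot$energy, 0)
  r$energy <- 6
  r$moved <- TRUE
  expect_false(upkeep(r, season, ucfg)$alive)   # movement extra tips it over
  # a zero-extras season reproduces the baseline debit
  res <- upkeep(new_robot(1, 2, 2, 10, new_grn_state(g, ucfg)),
                list(season = 0L, survival = 0, movement = 0), ucfg)
  expect_equal(res$robot$energy, 9)
})
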