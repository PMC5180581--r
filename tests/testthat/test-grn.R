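# The agent-based controller layer: sensor encoding, signalling activation,
# transduction, actuator read-out and the concentration dynamics.

cfg <- default_config()

test_that("all-zero readings give all-zero sensory channels", {
  s <- encode_sensors(list(robots = 0, food = 0, energy = 0, attacks = 0,
                           defences = 0, replications = 0, feedings = 0), cfg)
  expect_true(all(s[setdiff(names(s), "constitutive")] == 0))
  expect_identical(unname(s[["constitutive"]]), 1)
})

test_that("sensor encoding is deterministic and bounded", {
  rd <- list(robots = 3, food = 120, energy = 1e6, attacks = 7, defences = 0.4,
             replications = 2, feedings = 0.1)
  a <- encode_sensors(rd, cfg)
  b <- encode_sensors(rd, cfg)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
})

test_that("the channel-to-signature map is injective", {
  ch <- sensor_channels(cfg)
  expect_identical(anyDuplicated(ch$signature), 0L)
  expect_identical(anyDuplicated(ch$code), 0L)
  expect_identical(nchar(ch$signature), rep(cfg$genome$binding_len,
                                            nrow(ch)))
})

test_that("a genome without signalling genes activates nothing", {
  g <- genome_from_strings(single_gene_chromosome(5, "structural"))
  st <- new_grn_state(g, cfg)
  sens <- encode_sensors(list(robots = 1, food = 5, energy = 50, attacks = 0,
                              defences = 0, replications = 0, feedings = 0),
                         cfg)
  ns <- activate_signalling(sens, st)
  expect_length(ns$loc, 0L)
})

test_that("a matching signalling gene is activated by its channel only", {
  # binding site complementary to the food channel's signature
  food_sig <- sensor_channels(cfg)$signature[
    sensor_channels(cfg)$channel == "food"]
  comp <- chartr("0123", "3210", food_sig)
  g <- genome_from_strings(single_gene_chromosome(5, "signalling",
                                                  site = comp))
  st <- new_grn_state(g, cfg)
  on <- encode_sensors(list(robots = 0, food = 5, energy = 0, attacks = 0,
                            defences = 0, replications = 0, feedings = 0), cfg)
  on["constitutive"] <- 0  # isolate the food channel
  ns <- activate_signalling(on, st)
  expect_identical(ns$loc, 1L)
  expect_gte(ns$conc, cfg$grn$c_init)
  off <- on
  off["food"] <- 0
  expect_length(activate_signalling(off, st)$loc, 0L)
})

test_that("transduction expresses bound targets and respects repression", {
  # activator regulatory gene whose product signature is complementary to a
  # structural gene's binding site
  act_gene <- single_gene_chromosome(5, "regulatory", site = "2222",
                                     payload = "01230000", total = 40)
  str_gene <- single_gene_chromosome(5, "structural", site = "3210",
                                     payload = "00000033", total = 40)
  g <- genome_from_strings(c(act_gene, str_gene))
  st <- new_grn_state(g, cfg)
  expect_identical(transduce(st)$agents, st$agents)  # no agents: unchanged
  # hand-inject the regulatory agent at concentration 2; perfect match (q=1)
  st$agents <- list(loc = 1L, conc = 2, age = 0L)
  st2 <- transduce(st)
  expect_true(2L %in% st2$agents$loc)
  expect_equal(st2$agents$conc[st2$agents$loc == 2L], 2)  # conc x quality 1
  # a co-bound repressor blocks the expression outright
  rep_gene <- single_gene_chromosome(5, "regulatory", site = "2222",
                                     payload = "01231000", total = 40)
  g2 <- genome_from_strings(c(act_gene, rep_gene, str_gene))
  st3 <- new_grn_state(g2, cfg)
  st3$agents <- list(loc = c(1L, 2L), conc = c(2, 0.1), age = c(0L, 0L))
  st4 <- transduce(st3)
  expect_false(3L %in% st4$agents$loc)
})

test_that("actuator outputs are concentration-weighted means", {
  g <- genome_from_strings(c(
    single_gene_chromosome(5, "structural", payload = "00000033", total = 40),
    single_gene_chromosome(5, "structural", payload = "00000033", total = 40),
    single_gene_chromosome(5, "structural", payload = "00000000", total = 40)))
  st <- new_grn_state(g, cfg)
  tab <- st$tab
  expect_true(all(tab$kind == 2L))
  expect_identical(tab$value, c(1, 1, 0))
  a <- tab$actuator[1]
  expect_identical(tab$actuator, rep(a, 3))
  # mean of one agent equals its value exactly
  st$agents <- list(loc = 1L, conc = 3.7, age = 0L)
  expect_equal(unname(actuator_outputs(st)[a]), 1)
  # equal concentrations, values 1 and 0 -> 0.5
  st$agents <- list(loc = c(1L, 3L), conc = c(2, 2), age = c(0L, 0L))
  expect_equal(unname(actuator_outputs(st)[a]), 0.5)
  # concentrations 1,1,2 with values 0,0,1 -> 0.5 (weighted-mean trace)
  st$agents <- list(loc = c(3L, 3L, 1L), conc = c(1, 1, 2), age = rep(0L, 3))
  st$agents <- list(loc = c(1L, 2L, 3L), conc = c(1, 1, 2), age = rep(0L, 3))
  expect_equal(unname(actuator_outputs(st)[a]),
               (1 * 1 + 1 * 1 + 2 * 0) / 4)
  # actuators with no contributor emit the neutral value 0
  expect_true(all(actuator_outputs(st)[-a] == 0))
})

test_that("concentrations decay, respond to feedback and delete at c_min", {
  g <- genome_from_strings(c(
    single_gene_chromosome(5, "structural", payload = "00000033", total = 40),
    single_gene_chromosome(5, "regulatory", payload = "01230000", total = 40)))
  st <- new_grn_state(g, cfg)
  st$cfg <- list(decay = 0.1, feedback_gain = 0.3, feedback_scale = 5,
                 c_min = 0.05, c_max = 50, c_init = 0.2)
  # pure decay at zero feedback: c = 1 -> 0.9
  st$agents <- list(loc = 2L, conc = 1, age = 0L)
  expect_equal(update_concentrations(st, 0)$agents$conc, 0.9)
  # an agent that lands below c_min does not survive the update
  st$agents <- list(loc = 2L, conc = 0.055, age = 0L)
  expect_length(update_concentrations(st, 0)$agents$loc, 0L)
  # positive feedback strictly raises a behaviour-supporting structural agent
  st$agents <- list(loc = 1L, conc = 1, age = 0L)  # sole contributor: o = v
  up <- update_concentrations(st, 100)$agents$conc
  zero <- {
    st$agents <- list(loc = 1L, conc = 1, age = 0L)
    update_concentrations(st, 0)$agents$conc
  }
  expect_gt(up, zero)
  # survivors age by one step
  st$agents <- list(loc = 1L, conc = 1, age = 3L)
  expect_identical(update_concentrations(st, 0)$agents$age, 4L)
})

test_that("the compiled controller step equals the R composition", {
  set.seed(21)
  for (rep in 1:5) {
    g <- init_genome(NULL, n_chromosomes = 2, chrom_length = 1500)
    st_c <- new_grn_state(g, cfg)
    st_r <- st_c
    for (i in 1:15) {
      sens <- runif(length(grnswarm:::SENSOR_CHANNELS))
      fb <- rnorm(1, 0, 10)
      a <- controller_step(sens, st_c, fb, cfg)
      b <- grnswarm:::controller_step_r(sens, st_r, fb, cfg)
      expect_identical(a$state$agents$loc, b$state$agents$loc)
      expect_identical(a$state$agents$age, b$state$agents$age)
      expect_lt(max(abs(a$state$agents$conc - b$state$agents$conc), 0), 1e-10)
      expect_lt(max(abs(a$actuators - b$actuators)), 1e-10)
      st_c <- a$state
      st_r <- b$state
    }
  }
})

test_that("the fast genome wiring equals the plain-R construction", {
  set.seed(33)
  for (rep in 1:5) {
    g <- init_genome(NULL, n_chromosomes = 2, chrom_length = 2000)
    a <- grnswarm:::genome_tables(g, cfg)
    b <- grnswarm:::genome_tables_r(g, cfg)
    for (f in c("n_loci", "kind", "mode", "actuator", "chan_ptr", "chan_tgt",
                "adj_ptr", "adj_tgt")) {
      expect_identical(as.integer(a[[f]]), as.integer(b[[f]]))
    }
    expect_equal(a$value, b$value)
    expect_equal(a$chan_q, b$chan_q)
    expect_equal(a$adj_q, b$adj_q)
  }
})

test_that("an empty genome yields neutral outputs every step", {
  g <- genome_from_strings(strrep("2", 100))
  st <- new_grn_state(g, cfg)
  for (i in 1:5) {
    res <- controller_step(rep(1, length(grnswarm:::SENSOR_CHANNELS)), st,
                           10, cfg)
    st <- res$state
    expect_true(all(res$actuators == 0))
  }
})

test_that("no agent below the deletion floor ever survives a step", {
  g <- init_genome(seed = 17, n_chromosomes = 2, chrom_length = 2000)
  st <- new_grn_state(g, cfg)
  sens <- encode_sensors(list(robots = 2, food = 3, energy = 80, attacks = 0,
                              defences = 0, replications = 0, feedings = 1),
                         cfg)
  for (i in 1:60) {
    res <- controller_step(sens, st, sin(i) * 5, cfg)
    st <- res$state
    if (length(st$agents$conc) > 0L) {
      expect_true(all(st$agents$conc >= cfg$grn$c_min))
    }
    expect_true(all(res$actuators >= 0 & res$actuators <= 1))
  }
})

test_that("under constant sensors the active gene set reaches a fixed point", {
  set.seed(55)
  g <- init_genome(NULL, n_chromosomes = 2, chrom_length = 2000)
  st <- new_grn_state(g, cfg)
  sens <- rep(0.4, length(grnswarm:::SENSOR_CHANNELS))
  locs <- list()
  for (i in 1:300) {
    st <- controller_step(sens, st, 0, cfg)$state
    if (i > 297) locs[[length(locs) + 1L]] <- sort(st$agents$loc)
  }
  expect_identical(locs[[1]], locs[[2]])
  expect_identical(locs[[2]], locs[[3]])
})

test_that("identical genome, sensors and state give identical outputs", {
  g <- init_genome(seed = 71, n_chromosomes = 1, chrom_length = 2000)
  s1 <- new_grn_state(g, cfg)
  s2 <- new_grn_state(g, cfg)
  sens <- rep(0.5, length(grnswarm:::SENSOR_CHANNELS))
  a <- controller_step(sens, s1, 1, cfg)
  b <- controller_step(sens, s2, 1, cfg)
  expect_identical(a$actuators, b$actuators)
  expect_identical(a$state$agents, b$state$agents)
})
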