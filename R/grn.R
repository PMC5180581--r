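# The runtime layer of the controller: sensor encoding, activation of
# signalling genes, transduction through the bound regulatory layer, actuator
# read-out, and concentration decay/feedback. The environment-activated part
# of the genome is instantiated as "agents" (gene products): each carries the
# signature encoded by its gene's payload and a non-negative concentration
# (dosage) that decays each step, is boosted or damped by the robot's energy
# feedback, and leads to deletion once it falls below a floor.

ACTUATORS <- c("direction", "move", "eat", "attack", "defend", "replicate",
               "aggregate")

SENSOR_CHANNELS <- c("robots", "food", "energy", "attacks", "defences",
                     "replications", "feedings", "constitutive")

# Hand-picked channel signatures: pairwise Hamming distance >= 3 over the
# default 4-digit code space, so different channels address well-separated
# sets of signalling genes. Codes in base 4:
# 0000 1111 2222 3333 0123 1032 2301 3210.
CHANNEL_CODES_4 <- c(0L, 85L, 170L, 255L, 27L, 78L, 177L, 228L)

#' Sensor channels and their genome-facing signatures
#'
#' Each sensor channel carries a bounded magnitude in `[0, 1]` and a fixed
#' character signature used to address signalling genes: a channel activates
#' the signalling genes whose binding site its signature matches (complement
#' match within the configured tolerance). The map from channel to signature
#' is injective.
#'
#' @param config a simulation configuration, see [default_config()].
#' @return data.frame with columns `channel`, `code` and `signature`.
#' @export
sensor_channels <- function(config = default_config()) {
  k <- length(config$genome$alphabet)
  len <- config$genome$binding_len
  n <- length(SENSOR_CHANNELS)
  if (k == 4L && len == 4L) {
    codes <- CHANNEL_CODES_4
  } else {
    codes <- as.integer(floor((seq_len(n) - 1L) * (k^len / n)))
  }
  sig <- vapply(codes, function(cd) {
    paste(config$genome$alphabet[code_to_digits(cd, k, len) + 1L],
          collapse = "")
  }, "")
  data.frame(channel = SENSOR_CHANNELS, code = codes, signature = sig)
}

#' Encode raw sensor readings into bounded channels
#'
#' External readings (robots and food sources within the sensing radius) and
#' internal readings (energy, plus decaying traces of recent successful
#' attacks, defences, replications and feedings) are each mapped to a channel
#' magnitude in `[0, 1]`. A constitutive channel of constant magnitude 1 —
#' the regulatory analogue of the neural network's bias input — keeps the
#' housekeeping part of the network expressed even under sensory silence.
#' The encoding is deterministic; a channel with magnitude 0 is inactive and
#' activates no genes.
#'
#' @param readings named list with elements `robots`, `food`, `energy`,
#'   `attacks`, `defences`, `replications`, `feedings` (all non-negative;
#'   the last four are recent-event traces).
#' @param config simulation configuration (normalisation constants live in
#'   `config$sensors`).
#' @return named numeric vector of channel magnitudes.
#' @export
encode_sensors <- function(readings, config = default_config()) {
  ns <- config$sensors
  out <- c(
    robots = min(readings$robots / ns$norm_robots, 1),
    food = min(readings$food / ns$norm_food, 1),
    energy = min(readings$energy / ns$norm_energy, 1),
    attacks = min(readings$attacks, 1),
    defences = min(readings$defences, 1),
    replications = min(readings$replications, 1),
    feedings = min(readings$feedings, 1),
    constitutive = 1
  )
  pmax(out, 0)
}

#' Create a fresh controller state for a genome
#'
#' Scans the genome, wires the binding graph (which gene products bind which
#' loci, with match qualities) and the channel-to-signalling-gene map, and
#' returns a state with no living agents. The wiring tables are cached inside
#' the state; [replicate_genome()] returns a new genome object, so a child's
#' state is always built from its own (freshly scanned) genome and the cache
#' can never go stale.
#'
#' @param genome an `artificial_genome`.
#' @param config simulation configuration.
#' @return an object of class `grn_state`: living agents (`loc`us index,
#'   `conc`entration, `age`), the wiring tables, and the last fitness
#'   feedback.
#' @export
new_grn_state <- function(genome, config = default_config()) {
  tab <- genome_tables(genome, config)
  structure(list(genome = genome, tab = tab,
                 agents = list(loc = integer(0), conc = numeric(0),
                               age = integer(0)),
                 feedback = 0),
            class = "grn_state")
}

#' @export
print.grn_state <- function(x, ...) {
  cat("grn_state:", x$tab$n_loci, "loci,", length(x$agents$loc),
      "living agent(s)\n")
  invisible(x)
}

# Precompute per-genome wiring: locus kinds/fields, channel->signalling-locus
# CSR and locus->target CSR (source agent signature binds target binding
# site). Runs in C++ for the default-size code spaces (the per-birth hot
# path); genome_tables_r() is the plain-R reference the tests hold it to.
genome_tables <- function(genome, config = default_config()) {
  anatomy <- anatomy_from_config(config)
  k <- length(genome$alphabet)
  if (k^anatomy$binding_len <= 4096) {
    mm <- mismatch_table(k, anatomy$binding_len)
    chans <- sensor_channels(config)
    return(.scan_tables_cpp(genome$chromosomes,
                            as.integer(string_to_raw(anatomy$promoter,
                                                     genome$alphabet)),
                            anatomy$type_len, anatomy$binding_len,
                            anatomy$payload_len, k, anatomy$match_tolerance,
                            mm, chans$code, length(ACTUATORS)))
  }
  genome_tables_r(genome, config)
}

genome_tables_r <- function(genome, config = default_config()) {
  anatomy <- anatomy_from_config(config)
  sc <- scan_codes(genome, anatomy)
  k <- length(genome$alphabet)
  len <- anatomy$binding_len
  h <- anatomy$match_tolerance
  n <- length(sc$start)
  kind <- sc$type_idx  # 0 sig / 1 reg / 2 struct
  chans <- sensor_channels(config)
  use_table <- k^len <= 4096
  site_of <- sc$site_code
  if (use_table) {
    mm <- mismatch_table(k, len)
    mc <- match_codes(k, len, h)
    # site codes grouped -> locus ids, for fast adjacency construction
    by_site <- split(seq_len(n), site_of)
    site_keys <- as.integer(names(by_site))
    lookup <- vector("list", k^len)
    lookup[site_keys + 1L] <- by_site
    edge <- function(code) {
      hits <- mc[[code + 1L]]
      tg <- unlist(lookup[hits + 1L], use.names = FALSE)
      if (is.null(tg)) tg <- integer(0)
      tg <- sort(tg)  # ascending locus order, as the compiled path emits
      list(tgt = tg, q = (len - mm[code + 1L, site_of[tg] + 1L]) / len)
    }
  } else {
    site_digits <- lapply(site_of, code_to_digits, base = k, n = len)
    edge <- function(code) {
      d <- code_to_digits(code, k, len)
      mmv <- vapply(site_digits, function(sd)
        complement_mismatches(d, sd, k), 0L)
      tg <- which(mmv <= h)
      list(tgt = tg, q = (len - mmv[tg]) / len)
    }
  }
  # channel -> matching signalling loci
  sig_loci <- which(kind == 0L)
  chan_tgt <- integer(0); chan_q <- numeric(0)
  chan_len <- integer(nrow(chans))
  for (ci in seq_len(nrow(chans))) {
    e <- edge(chans$code[ci])
    keep <- e$tgt %in% sig_loci
    chan_len[ci] <- sum(keep)
    chan_tgt <- c(chan_tgt, e$tgt[keep])
    chan_q <- c(chan_q, e$q[keep])
  }
  chan_ptr <- c(0L, cumsum(chan_len))
  # agent (source locus signature) -> target loci; structural products do not
  # bind, their rows stay empty
  adj_len <- integer(n)
  adj_list <- vector("list", n)
  adj_q_list <- vector("list", n)
  binder <- which(kind != 2L)
  for (i in binder) {
    e <- edge(sc$sig_code[i])
    adj_list[[i]] <- e$tgt
    adj_q_list[[i]] <- e$q
    adj_len[i] <- length(e$tgt)
  }
  list(n_loci = n, kind = as.integer(kind),
       mode = as.integer(sc$mode),
       actuator = as.integer(ifelse(kind == 2L, sc$actuator, 0L)),
       value = ifelse(kind == 2L, sc$value, 0),
       chan_ptr = as.integer(chan_ptr),
       chan_tgt = as.integer(chan_tgt), chan_q = as.numeric(chan_q),
       adj_ptr = as.integer(c(0L, cumsum(adj_len))),
       adj_tgt = as.integer(unlist(adj_list, use.names = FALSE)),
       adj_q = as.numeric(unlist(adj_q_list, use.names = FALSE)))
}

# merge freshly expressed dosage into the agent multiset: re-expression of a
# living agent refreshes (adds to) its concentration, capped at c_max; a locus
# never carries more than one agent
add_agents <- function(agents, loc, conc, c_max) {
  if (length(loc) == 0L) return(agents)
  idx <- match(loc, agents$loc)
  hit <- !is.na(idx)
  if (any(hit)) {
    agents$conc[idx[hit]] <- pmin(agents$conc[idx[hit]] + conc[hit], c_max)
  }
  if (any(!hit)) {
    agents$loc <- c(agents$loc, loc[!hit])
    agents$conc <- c(agents$conc, pmin(conc[!hit], c_max))
    agents$age <- c(agents$age, integer(sum(!hit)))
  }
  agents
}

#' Activate signalling genes from the current sensor channels
#'
#' Every active channel (magnitude > 0) expresses each signalling gene whose
#' binding site its signature matches; the expressed dosage is the channel
#' magnitude times the match quality, floored at `config$grn$c_init`.
#' Contributions from several channels to the same gene add up.
#'
#' @param sensors named channel magnitudes from [encode_sensors()].
#' @param state a `grn_state` (supplies the wiring tables).
#' @return list with `loc` (locus indices) and `conc` (expressed dosages) of
#'   the new signalling agents; empty when nothing matches.
#' @export
activate_signalling <- function(sensors, state) {
  tab <- state$tab
  c_init <- state_cfg(state)$c_init
  expr <- numeric(tab$n_loci)
  for (ci in seq_along(sensors)) {
    m <- sensors[[ci]]
    if (m <= 0) next
    jj <- seq_len(tab$chan_ptr[ci + 1L] - tab$chan_ptr[ci]) + tab$chan_ptr[ci]
    if (length(jj) == 0L) next
    tg <- tab$chan_tgt[jj]
    expr[tg] <- expr[tg] + pmax(m * tab$chan_q[jj], c_init)
  }
  loc <- which(expr > 0)
  list(loc = loc, conc = expr[loc])
}

# grn dynamics constants attached to the state (falls back to defaults so the
# sub-operations are usable standalone)
state_cfg <- function(state) {
  if (!is.null(state$cfg)) state$cfg else default_config()$grn
}

#' Transduce signals through the bound regulatory layer
#'
#' Living signalling and regulatory agents bind the loci whose binding sites
#' match their signatures. Activator binders contribute
#' `concentration x match quality` to a locus; a bound repressor blocks the
#' locus outright this step, regardless of co-binding activators. Every
#' unblocked regulatory or structural locus with positive bound activation is
#' expressed with that activation as dosage (added to the living agent for
#' that locus if one exists, capped at `c_max`). Signalling loci are expressed
#' only via sensor channels, never via binding. The genome itself is never
#' modified.
#'
#' @param state a `grn_state`.
#' @return the updated `grn_state`.
#' @export
transduce <- function(state) {
  tab <- state$tab
  ag <- state$agents
  if (length(ag$loc) == 0L) return(state)
  act <- numeric(tab$n_loci)
  rep_blocked <- logical(tab$n_loci)
  for (i in seq_along(ag$loc)) {
    g <- ag$loc[i]
    if (tab$kind[g] == 2L) next  # structural products are end products
    jj <- seq_len(tab$adj_ptr[g + 1L] - tab$adj_ptr[g]) + tab$adj_ptr[g]
    if (length(jj) == 0L) next
    tg <- tab$adj_tgt[jj]
    if (tab$kind[g] == 1L && tab$mode[g] == 1L) {
      rep_blocked[tg] <- TRUE
    } else {
      act[tg] <- act[tg] + ag$conc[i] * tab$adj_q[jj]
    }
  }
  expressible <- act > 0 & !rep_blocked & tab$kind != 0L
  loc <- which(expressible)
  state$agents <- add_agents(ag, loc, act[loc], state_cfg(state)$c_max)
  state
}

#' Read the actuator outputs of a controller state
#'
#' Each actuator's output is the concentration-weighted arithmetic mean of
#' the output values of the living structural agents that target it;
#' actuators with no contributor emit the neutral value 0.
#'
#' @param state a `grn_state`.
#' @return named numeric vector over [ACTUATORS] (values in `[0, 1]`).
#' @export
actuator_outputs <- function(state) {
  tab <- state$tab
  ag <- state$agents
  out <- numeric(length(ACTUATORS))
  names(out) <- ACTUATORS
  if (length(ag$loc) == 0L) return(out)
  st <- which(tab$kind[ag$loc] == 2L)
  if (length(st) == 0L) return(out)
  a <- tab$actuator[ag$loc[st]]
  w <- ag$conc[st]
  v <- tab$value[ag$loc[st]]
  num <- tapply(w * v, a, sum)
  den <- tapply(w, a, sum)
  out[as.integer(names(num))] <- num / den
  out
}

#' Decay agent concentrations and apply fitness feedback
#'
#' Each concentration is updated as
#' `c <- c * (1 - d) * (1 + beta * sign(f) * min(|f| / F, 1) * a)`
#' where `d` is the decay rate, `beta` the feedback gain, `F` the feedback
#' scale, `f` the robot's net energy change over the last step, and `a` the
#' agent's alignment with the behaviour that earned that feedback: for a
#' structural agent with output value `v` on an actuator currently emitting
#' `o`, `a = 2 * (1 - |v - o|) - 1` (in `[-1, 1]`), so agents supporting the
#' current behaviour are reinforced when energy rises and damped when it
#' falls, while dissenting agents move the other way — the concentration
#' change reflects each agent's own effect on fitness. Signalling and
#' regulatory agents have `a = 0` (pure decay). Agents whose concentration
#' falls below `c_min` are deleted at the end of the update and never
#' survive it; survivors age by one step.
#'
#' @param state a `grn_state`.
#' @param feedback net energy change of the robot over the last step.
#' @return the updated `grn_state` (with `feedback` recorded).
#' @export
update_concentrations <- function(state, feedback = 0) {
  cfg <- state_cfg(state)
  ag <- state$agents
  tab <- state$tab
  if (length(ag$loc) > 0L) {
    out <- actuator_outputs(state)
    align <- numeric(length(ag$loc))
    st <- tab$kind[ag$loc] == 2L
    if (any(st)) {
      v <- tab$value[ag$loc[st]]
      o <- out[tab$actuator[ag$loc[st]]]
      align[st] <- 2 * (1 - abs(v - o)) - 1
    }
    fterm <- 1 + cfg$feedback_gain * sign(feedback) *
      min(abs(feedback) / cfg$feedback_scale, 1) * align
    conc <- ag$conc * (1 - cfg$decay) * fterm
    keep <- conc >= cfg$c_min
    state$agents <- list(loc = ag$loc[keep], conc = conc[keep],
                         age = ag$age[keep] + 1L)
  }
  state$feedback <- feedback
  state
}

#' One full controller update
#'
#' Composition of [encode_sensors()] (done by the caller),
#' [activate_signalling()], [transduce()], [actuator_outputs()] and
#' [update_concentrations()], in that order: new signalling agents join the
#' state, signals propagate one layer, actuators are read out, then all
#' concentrations decay under the feedback law and dilute agents are removed.
#' Deterministic given (genome, sensors, state, feedback). Runs through the
#' compiled kernel; `controller_step_r()` is the plain-R composition used to
#' cross-check it.
#'
#' @param sensors named channel magnitudes from [encode_sensors()].
#' @param state a `grn_state`.
#' @param feedback net energy change of the robot over the last step.
#' @param config simulation configuration (GRN constants).
#' @return list with `actuators` (named numeric over [ACTUATORS]) and `state`.
#' @export
controller_step <- function(sensors, state, feedback = 0,
                            config = default_config()) {
  g <- config$grn
  tab <- state$tab
  res <- .grn_step_cpp(state$agents$loc, state$agents$conc, state$agents$age,
                       as.numeric(sensors),
                       tab$chan_ptr, tab$chan_tgt, tab$chan_q,
                       tab$adj_ptr, tab$adj_tgt, tab$adj_q,
                       tab$kind, tab$mode, tab$actuator, tab$value,
                       length(ACTUATORS), feedback,
                       g$decay, g$feedback_gain, g$feedback_scale,
                       g$c_min, g$c_max, g$c_init)
  state$agents <- list(loc = res$loc, conc = res$conc, age = res$age)
  state$feedback <- feedback
  out <- res$outputs
  names(out) <- ACTUATORS
  list(actuators = out, state = state)
}

# plain-R composition of the four sub-operations; semantically identical to
# the compiled kernel (asserted by tests)
controller_step_r <- function(sensors, state, feedback = 0,
                              config = default_config()) {
  state$cfg <- config$grn
  ns <- activate_signalling(sensors, state)
  state$agents <- add_agents(state$agents, ns$loc, ns$conc, config$grn$c_max)
  state <- transduce(state)
  out <- actuator_outputs(state)
  state <- update_concentrations(state, feedback)
  state$cfg <- NULL
  list(actuators = out, state = state)
}
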