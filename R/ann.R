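# Reference controller: a fixed-topology feed-forward network (sensors ->
# hidden -> actuators, tanh squashing) over the same sensor and actuator
# vectors as the GRN controller. Weights are heritable (a flat real-vector
# genome, Gaussian-mutated at replication). Within a lifetime the only
# learning is reward-modulated per-edge nudging plus performance-triggered
# edge zeroing: edges whose running contribution stays negligible for a
# window of consecutive steps are set to zero and stay zero until
# replication re-randomises them.

#' Create an ANN controller
#'
#' @param weights flat numeric weight vector (the ANN genome), length
#'   `hidden * (n_in + 1) + n_out * (hidden + 1)` (one bias per unit); when
#'   `NULL`, drawn uniformly from `[-1, 1]` using the current RNG stream.
#' @param config simulation configuration (`config$ann`).
#' @return an object of class `ann_controller` with weight matrices `W1`,
#'   `W2`, zeroing masks, eligibility traces, contribution traces and idle
#'   counters.
#' @export
new_ann <- function(weights = NULL, config = default_config()) {
  n_in <- length(SENSOR_CHANNELS)
  n_out <- length(ACTUATORS)
  h <- config$ann$hidden
  n_w <- h * (n_in + 1L) + n_out * (h + 1L)
  if (is.null(weights)) weights <- runif(n_w, -1, 1)
  if (length(weights) != n_w)
    stop_invalid("weight vector must have length ", n_w)
  W1 <- matrix(weights[seq_len(h * (n_in + 1L))], h, n_in + 1L)
  W2 <- matrix(weights[-seq_len(h * (n_in + 1L))], n_out, h + 1L)
  structure(list(W1 = W1, W2 = W2,
                 mask1 = matrix(FALSE, h, n_in + 1L),
                 mask2 = matrix(FALSE, n_out, h + 1L),
                 e1 = matrix(0, h, n_in + 1L),
                 e2 = matrix(0, n_out, h + 1L),
                 c1 = matrix(0, h, n_in + 1L),
                 c2 = matrix(0, n_out, h + 1L),
                 idle1 = matrix(0L, h, n_in + 1L),
                 idle2 = matrix(0L, n_out, h + 1L),
                 x = numeric(n_in + 1L), hact = numeric(h + 1L),
                 out = numeric(n_out)),
            class = "ann_controller")
}

#' @export
print.ann_controller <- function(x, ...) {
  cat("ann_controller:", ncol(x$W1) - 1L, "sensors ->", nrow(x$W1),
      "hidden ->", nrow(x$W2), "actuators;",
      sum(x$mask1) + sum(x$mask2), "edge(s) zeroed\n")
  invisible(x)
}

# flat weight vector (the heritable genome)
ann_weights <- function(ctrl) c(as.numeric(ctrl$W1), as.numeric(ctrl$W2))

#' Forward pass of the ANN controller
#'
#' Deterministic: identical inputs give identical outputs. All outputs lie
#' in the tanh range `(-1, 1)`; with all-zero weights every output is the
#' neutral value 0. The pre/post activities are stored in the controller for
#' the eligibility update of [ann_feedback()].
#'
#' @param ctrl an `ann_controller`.
#' @param sensors named channel magnitudes from [encode_sensors()].
#' @return list with `actuators` (named numeric over [ACTUATORS]) and the
#'   updated `ctrl`.
#' @export
ann_forward <- function(ctrl, sensors) {
  x <- c(as.numeric(sensors), 1)
  hact <- c(tanh(as.numeric(ctrl$W1 %*% x)), 1)
  out <- tanh(as.numeric(ctrl$W2 %*% hact))
  names(out) <- ACTUATORS
  ctrl$x <- x
  ctrl$hact <- hact
  ctrl$out <- out
  list(actuators = out, ctrl = ctrl)
}

#' Per-edge reinforcement update with edge zeroing
#'
#' Each edge accumulates an eligibility trace of its recent activity
#' (`pre x post`, decayed by `trace_decay`); weights are nudged by
#' `eta * reward * eligibility`. Rewiring is restricted to zeroing: an edge
#' whose running contribution `|w x pre|` stays below `zero_threshold` for
#' `zero_window` consecutive steps is set to zero, and zeroed edges stay
#' zero under all further feedback (only replication re-randomises them).
#'
#' @param ctrl an `ann_controller` (after at least one [ann_forward()]).
#' @param reward the robot's net energy change over the last step.
#' @param config simulation configuration (`config$ann`).
#' @return the updated `ann_controller`.
#' @export
ann_feedback <- function(ctrl, reward, config = default_config()) {
  a <- config$ann
  pre1 <- ctrl$x; post1 <- ctrl$hact[-length(ctrl$hact)]
  pre2 <- ctrl$hact; post2 <- ctrl$out
  ctrl$e1 <- a$trace_decay * ctrl$e1 + outer(post1, pre1)
  ctrl$e2 <- a$trace_decay * ctrl$e2 + outer(as.numeric(post2), pre2)
  ctrl$W1 <- ctrl$W1 + a$eta * reward * ctrl$e1
  ctrl$W2 <- ctrl$W2 + a$eta * reward * ctrl$e2
  # running contribution of each edge; persistently idle edges get zeroed
  ctrl$c1 <- a$trace_decay * ctrl$c1 +
    abs(ctrl$W1) * rep(abs(pre1), each = nrow(ctrl$W1))
  ctrl$c2 <- a$trace_decay * ctrl$c2 +
    abs(ctrl$W2) * rep(abs(pre2), each = nrow(ctrl$W2))
  ctrl$idle1 <- ifelse(ctrl$c1 < a$zero_threshold, ctrl$idle1 + 1L, 0L)
  ctrl$idle2 <- ifelse(ctrl$c2 < a$zero_threshold, ctrl$idle2 + 1L, 0L)
  ctrl$mask1 <- ctrl$mask1 | ctrl$idle1 >= a$zero_window
  ctrl$mask2 <- ctrl$mask2 | ctrl$idle2 >= a$zero_window
  ctrl$W1[ctrl$mask1] <- 0
  ctrl$W2[ctrl$mask2] <- 0
  ctrl
}

#' Replicate an ANN controller
#'
#' The offspring inherits the parent's flat weight vector (zeroed edges
#' included) with i.i.d. Gaussian mutation noise, and starts with fresh
#' eligibility traces and an empty zeroing mask.
#'
#' @param parent an `ann_controller`.
#' @param config simulation configuration.
#' @return the offspring `ann_controller`.
#' @export
replicate_ann <- function(parent, config = default_config()) {
  w <- ann_weights(parent)
  w <- w + rnorm(length(w), 0, config$ann$mutation_sigma)
  new_ann(w, config)
}

# ---- batched population implementation --------------------------------------
# The engine updates every ANN robot in one set of matrix operations per
# step. Per-robot weight matrices are stored column-major as columns of big
# matrices (one column per robot), so the batched update is elementwise
# algebra plus a grouped rowsum; semantics are identical to ann_forward() /
# ann_feedback(), which the tests assert.

ann_batch_new <- function(ctrls, config) {
  h <- config$ann$hidden
  ni1 <- length(SENSOR_CHANNELS) + 1L
  no <- length(ACTUATORS)
  n <- length(ctrls)
  grab <- function(field, len) {
    matrix(vapply(ctrls, function(ct) as.numeric(ct[[field]]), numeric(len)),
           nrow = len)
  }
  list(h = h, ni1 = ni1, no = no,
       W1 = grab("W1", h * ni1), W2 = grab("W2", no * (h + 1L)),
       m1 = matrix(FALSE, h * ni1, n), m2 = matrix(FALSE, no * (h + 1L), n),
       e1 = matrix(0, h * ni1, n), e2 = matrix(0, no * (h + 1L), n),
       c1 = matrix(0, h * ni1, n), c2 = matrix(0, no * (h + 1L), n),
       i1 = matrix(0L, h * ni1, n), i2 = matrix(0L, no * (h + 1L), n),
       X = matrix(0, ni1, n), Hb = matrix(0, h + 1L, n),
       OUT = matrix(0, no, n))
}

ann_batch_feedback <- function(B, reward, config) {
  a <- config$ann
  h <- B$h; ni1 <- B$ni1; no <- B$no
  post1 <- B$Hb[seq_len(h), , drop = FALSE]
  B$e1 <- a$trace_decay * B$e1 +
    post1[rep(seq_len(h), times = ni1), , drop = FALSE] *
    B$X[rep(seq_len(ni1), each = h), , drop = FALSE]
  B$e2 <- a$trace_decay * B$e2 +
    B$OUT[rep(seq_len(no), times = h + 1L), , drop = FALSE] *
    B$Hb[rep(seq_len(h + 1L), each = no), , drop = FALSE]
  B$W1 <- B$W1 + a$eta * B$e1 * rep(reward, each = nrow(B$W1))
  B$W2 <- B$W2 + a$eta * B$e2 * rep(reward, each = nrow(B$W2))
  B$c1 <- a$trace_decay * B$c1 +
    abs(B$W1) * abs(B$X)[rep(seq_len(ni1), each = h), , drop = FALSE]
  B$c2 <- a$trace_decay * B$c2 +
    abs(B$W2) * abs(B$Hb)[rep(seq_len(h + 1L), each = no), , drop = FALSE]
  B$i1 <- (B$i1 + 1L) * (B$c1 < a$zero_threshold)
  B$i2 <- (B$i2 + 1L) * (B$c2 < a$zero_threshold)
  B$m1 <- B$m1 | B$i1 >= a$zero_window
  B$m2 <- B$m2 | B$i2 >= a$zero_window
  B$W1[B$m1] <- 0
  B$W2[B$m2] <- 0
  B
}

ann_batch_forward <- function(B, mags) {
  X <- rbind(t(mags), 1)
  P1 <- B$W1 * X[rep(seq_len(B$ni1), each = B$h), , drop = FALSE]
  H <- tanh(rowsum(P1, rep(seq_len(B$h), times = B$ni1)))
  Hb <- rbind(H, 1)
  P2 <- B$W2 * Hb[rep(seq_len(B$h + 1L), each = B$no), , drop = FALSE]
  OUT <- tanh(rowsum(P2, rep(seq_len(B$no), times = B$h + 1L)))
  B$X <- X; B$Hb <- Hb; B$OUT <- OUT
  list(B = B, outputs = t(OUT))
}

# offspring column: parent weights + Gaussian mutation, fresh traces/mask
ann_batch_add <- function(B, parent_col, config) {
  w1 <- B$W1[, parent_col] + rnorm(nrow(B$W1), 0, config$ann$mutation_sigma)
  w2 <- B$W2[, parent_col] + rnorm(nrow(B$W2), 0, config$ann$mutation_sigma)
  B$W1 <- cbind(B$W1, w1); B$W2 <- cbind(B$W2, w2)
  B$m1 <- cbind(B$m1, FALSE); B$m2 <- cbind(B$m2, FALSE)
  B$e1 <- cbind(B$e1, 0); B$e2 <- cbind(B$e2, 0)
  B$c1 <- cbind(B$c1, 0); B$c2 <- cbind(B$c2, 0)
  B$i1 <- cbind(B$i1, 0L); B$i2 <- cbind(B$i2, 0L)
  B$X <- cbind(B$X, 0); B$Hb <- cbind(B$Hb, 0); B$OUT <- cbind(B$OUT, 0)
  B
}

ann_batch_subset <- function(B, keep) {
  for (f in c("W1", "W2", "m1", "m2", "e1", "e2", "c1", "c2", "i1", "i2",
              "X", "Hb", "OUT")) {
    B[[f]] <- B[[f]][, keep, drop = FALSE]
  }
  B
}
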