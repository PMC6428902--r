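#' Activity state of one representational node
#'
#' In SOP the representation of a stimulus (or of the experimental context)
#' is a large pool of elements, each of which is at any moment in one of
#' three states: inactive (I), primary activity (A1, the response-generating
#' state) or secondary activity (A2, a refractory/opponent state). Because
#' the model is simulated deterministically over mean proportions, the whole
#' momentary state of a node is the vector (pI, pA1, pA2) with
#' pI + pA1 + pA2 = 1.
#'
#' @param pI,pA1,pA2 Proportions of elements in the inactive, primary and
#'   secondary states. Each must lie in [0, 1] and the three must sum to 1
#'   (within 1e-9; the stored vector is exact).
#' @return A named numeric vector of class `sop_state` with components
#'   `pI`, `pA1`, `pA2`.
#' @examples
#' activity_state(1, 0, 0)          # all-inactive, the pre-stimulus state
#' activity_state(0.2, 0.8, 0)      # one moment into a p1 = 0.8 presentation
#' @export
activity_state <- function(pI, pA1, pA2) {
  s <- c(pI = as.numeric(pI), pA1 = as.numeric(pA1), pA2 = as.numeric(pA2))
  if (anyNA(s) || any(s < -1e-12) || any(s > 1 + 1e-12))
    stop("activity proportions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(s) - 1) > 1e-9)
    stop("pI + pA1 + pA2 must equal 1 (got ", format(sum(s), digits = 15), ")",
         call. = FALSE)
  s <- pmin(pmax(s, 0), 1)
  class(s) <- "sop_state"
  s
}

#' Per-node transition probabilities
#'
#' @param p1 Probability per moment that an inactive element is promoted to
#'   A1 while the node's stimulus is on. For an explicit stimulus `p1` is the
#'   model's proxy for stimulus intensity; for the context it is small
#'   because the context is a weak, tonically present cue.
#' @param pd1 Probability per moment of decay A1 -> A2.
#' @param pd2 Probability per moment of decay A2 -> I.
#' @param role `"explicit"` for a punctate stimulus (habituating stimulus,
#'   distractor, test stimulus) or `"context"` for the tonic background cue.
#' @return An object of class `sop_node` (a list with fields `p1`, `pd1`,
#'   `pd2`, `role`).
#' @examples
#' node_params(0.8, 0.1, 0.02)                    # the standard stimulus
#' node_params(0.05, 0.1, 0.02, role = "context") # the standard context
#' @export
node_params <- function(p1, pd1, pd2, role = c("explicit", "context")) {
  role <- match.arg(role)
  for (nm in c("p1", "pd1", "pd2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("'", nm, "' must be a single probability in [0, 1]", call. = FALSE)
  }
  structure(list(p1 = p1, pd1 = pd1, pd2 = pd2, role = role),
            class = "sop_node")
}

#' Effective per-moment transition rates of a node
#'
#' The rates actually applied at one moment, after context disruption or
#' distractor increments and after associative priming have been folded in:
#' `p1_eff` (I -> A1 while the stimulus is on), `pd1_eff` (A1 -> A2),
#' `pd2_eff` (A2 -> I) and `p2` (I -> A2, the retrieval-generated priming
#' channel driven by the context's association with the node). All rates are
#' clamped to [0, 1].
#'
#' @param p1_eff,pd1_eff,pd2_eff,p2 Probabilities per moment.
#' @return An object of class `sop_rates`.
#' @export
effective_rates <- function(p1_eff = 0, pd1_eff = 0, pd2_eff = 0, p2 = 0) {
  r <- c(p1_eff = p1_eff, pd1_eff = pd1_eff, pd2_eff = pd2_eff, p2 = p2)
  if (anyNA(r) || any(r < 0) || any(r > 1))
    stop("effective rates must lie in [0, 1]", call. = FALSE)
  class(r) <- "sop_rates"
  r
}

# Bare-vector state update used in the inner simulation loops; state and the
# return value are plain numeric c(pI, pA1, pA2). Promotion and decay are all
# computed from the previous moment's state (simultaneous update); p1 takes
# precedence over p2, which acts on the inactive fraction p1 leaves behind,
# so total outflow from I never exceeds pI.
.step <- function(state, p1, pd1, pd2, p2, on) {
  pI <- state[[1L]]; pA1 <- state[[2L]]; pA2 <- state[[3L]]
  promoted_a1 <- if (on) p1 * pI else 0
  promoted_a2 <- p2 * (pI - promoted_a1)
  new_a1 <- pA1 - pd1 * pA1 + promoted_a1
  new_a2 <- pA2 - pd2 * pA2 + pd1 * pA1 + promoted_a2
  c(1 - new_a1 - new_a2, new_a1, new_a2)
}

#' Advance one node by one moment
#'
#' Applies SOP's transition rules for a single discrete time step
#' ("moment"). All flows are evaluated on the previous moment's state and
#' applied simultaneously: while the stimulus is on, `p1_eff` of the inactive
#' elements are promoted to A1; `p2` of the inactive elements not claimed by
#' p1 are promoted directly to A2 (associative priming); `pd1_eff` of the A1
#' elements decay to A2 and `pd2_eff` of the A2 elements decay back to I.
#' Conservation (pI + pA1 + pA2 = 1) holds exactly because pI is recomputed
#' as the complement.
#'
#' Starting from all-inactive with the standard stimulus parameters
#' (p1 = 0.8, pd1 = 0.1, pd2 = 0.02), one stimulus-on moment gives
#' (0.2, 0.8, 0) and the following stimulus-off moment gives
#' (0.2, 0.72, 0.08).
#'
#' @param state An [activity_state()].
#' @param rates An [effective_rates()].
#' @param stimulus_on Logical; whether the node's stimulus is present this
#'   moment. When `FALSE` the `p1_eff` channel is inert.
#' @return The new `sop_state` one moment later.
#' @examples
#' s0 <- activity_state(1, 0, 0)
#' r  <- effective_rates(p1_eff = 0.8, pd1_eff = 0.1, pd2_eff = 0.02)
#' s1 <- step_node(s0, r, stimulus_on = TRUE)   # (0.2, 0.8, 0)
#' step_node(s1, r, stimulus_on = FALSE)        # (0.2, 0.72, 0.08)
#' @export
step_node <- function(state, rates, stimulus_on = FALSE) {
  if (!inherits(state, "sop_state"))
    state <- activity_state(state[[1L]], state[[2L]], state[[3L]])
  if (!inherits(rates, "sop_rates"))
    rates <- effective_rates(rates[[1L]], rates[[2L]], rates[[3L]],
                             if (length(rates) >= 4L) rates[[4L]] else 0)
  out <- .step(unclass(state), rates[["p1_eff"]], rates[["pd1_eff"]],
               rates[["pd2_eff"]], rates[["p2"]], isTRUE(stimulus_on))
  activity_state(out[1L], out[2L], out[3L])
}

#' Free decay of a node's activity
#'
#' Iterates [step_node()] with the stimulus off and no associative priming
#' (p2 = 0): elements drain from A1 to A2 at rate `pd1` and from A2 back to
#' inactivity at rate `pd2`. With the standard parameters the A2 trace is
#' long-lived - after a single 1-moment presentation it takes until about
#' moment 250 for 99% of the elements to return to inactivity, which is why
#' A2 behaves as a refractory state.
#'
#' @param initial The [activity_state()] at moment 0 of the decay.
#' @param params A [node_params()] supplying `pd1` and `pd2`.
#' @param n_moments Number of moments to simulate (>= 1).
#' @return A numeric matrix with `n_moments` rows and columns
#'   `pI`, `pA1`, `pA2`; row t is the state t moments after `initial`.
#' @examples
#' on <- step_node(activity_state(1, 0, 0),
#'                 effective_rates(0.8, 0.1, 0.02), stimulus_on = TRUE)
#' traj <- free_decay_trajectory(on, node_params(0.8, 0.1, 0.02), 250)
#' which(traj[, "pI"] >= 0.99)[1]  # trace fully dissipated well before 250
#' @export
free_decay_trajectory <- function(initial, params, n_moments) {
  if (!inherits(params, "sop_node"))
    stop("'params' must be a node_params() object", call. = FALSE)
  if (!is.numeric(n_moments) || length(n_moments) != 1L || n_moments < 1)
    stop("'n_moments' must be a positive integer", call. = FALSE)
  if (!inherits(initial, "sop_state"))
    initial <- activity_state(initial[[1L]], initial[[2L]], initial[[3L]])
  n <- as.integer(n_moments)
  out <- matrix(NA_real_, nrow = n, ncol = 3L,
                dimnames = list(NULL, c("pI", "pA1", "pA2")))
  s <- unclass(initial)
  for (t in seq_len(n)) {
    s <- .step(s, params$p1, params$pd1, params$pd2, 0, FALSE)
    out[t, ] <- s
  }
  out
}

#' @export
print.sop_state <- function(x, ...) {
  cat(sprintf("SOP activity state: pI = %.6g, pA1 = %.6g, pA2 = %.6g\n",
              x[["pI"]], x[["pA1"]], x[["pA2"]]))
  invisible(x)
}

#' @export
print.sop_node <- function(x, ...) {
  cat(sprintf("SOP node (%s): p1 = %g, pd1 = %g, pd2 = %g\n",
              x$role, x$p1, x$pd1, x$pd2))
  invisible(x)
}
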