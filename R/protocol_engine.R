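#' A single stimulus presentation within a session
#'
#' @param node Id of the explicit node being presented.
#' @param onset First moment (1-based within the session) the stimulus is on.
#' @param duration Number of consecutive moments it stays on (default 1, the
#'   standard brief stimulus).
#' @param intensity Optional override of the node's `p1` for this event only;
#'   `p1` is the model's proxy for stimulus intensity, so the same node can
#'   be trained at one intensity and tested at another.
#' @return An object of class `sop_event`.
#' @export
stimulus_event <- function(node, onset, duration = 1L, intensity = NULL) {
  if (onset < 1 || duration < 1)
    stop("'onset' and 'duration' must be >= 1", call. = FALSE)
  if (!is.null(intensity) && (is.na(intensity) || intensity < 0 || intensity > 1))
    stop("'intensity' must lie in [0, 1]", call. = FALSE)
  structure(list(node = as.character(node), onset = as.integer(onset),
                 duration = as.integer(duration),
                 intensity = intensity),
            class = "sop_event")
}

#' Response mapping rule
#'
#' SOP maps activity to behavior as R = f(w1 * pA1 + w2 * pA2). The default
#' (w1 = 1, w2 = 0, f identity) makes the response identical to the node's
#' primary activity, the reading appropriate for reflexive responses such as
#' startle or limb flexion, where the secondary state is behaviorally silent
#' and acts only through priming. A negative w2 models opponent secondary
#' responses; a positive w2 models summation.
#'
#' @param w1,w2 Finite linear weights on pA1 and pA2.
#' @param f Mapping identifier; currently `"identity"`.
#' @return An object of class `sop_response_rule`.
#' @export
response_rule <- function(w1 = 1, w2 = 0, f = "identity") {
  if (!is.finite(w1) || !is.finite(w2))
    stop("response weights must be finite", call. = FALSE)
  if (!identical(f, "identity"))
    stop("unknown response mapping '", f, "'; available: identity",
         call. = FALSE)
  structure(list(w1 = w1, w2 = w2, f = f), class = "sop_response_rule")
}

#' Map an activity state to a response value
#'
#' @param state An [activity_state()] (or anything with `pA1`/`pA2`
#'   components).
#' @param rule A [response_rule()].
#' @return The scalar response R = f(w1 * pA1 + w2 * pA2).
#' @examples
#' map_response(activity_state(0.2, 0.72, 0.08), response_rule())  # 0.72
#' map_response(activity_state(0, 0.6, 0.4), response_rule(w2 = -0.5)) # 0.4
#' @export
map_response <- function(state, rule = response_rule()) {
  if (!inherits(rule, "sop_response_rule"))
    stop("'rule' must be a response_rule()", call. = FALSE)
  rule$w1 * state[["pA1"]] + rule$w2 * state[["pA2"]]
}

#' A session within a protocol
#'
#' @param length Session length in moments.
#' @param events List of [stimulus_event()]s (may be empty).
#' @param context_on Whether the context is present throughout (default TRUE;
#'   the context is turned on at the first moment and stays on).
#' @return A list of class `sop_session`.
#' @export
protocol_session <- function(length = 300L, events = list(), context_on = TRUE) {
  if (length < 1) stop("session length must be >= 1", call. = FALSE)
  if (inherits(events, "sop_event")) events <- list(events)
  structure(list(length = as.integer(length), events = events,
                 context_on = isTRUE(context_on)),
            class = "sop_session")
}

#' Assemble a full experimental protocol
#'
#' A protocol is the complete description of one simulated experiment: the
#' nodes (exactly one context plus one or more explicit stimuli), the
#' ordered sessions with their stimulus events, the context-disruption
#' parameters, the learning rates, initial associative strengths, the
#' generalization coefficients between explicit nodes and the response rule.
#'
#' @param nodes Named list of [node_params()]; exactly one must have role
#'   `"context"`.
#' @param sessions List of [protocol_session()]s.
#' @param modulation A [modulation_params()].
#' @param L_plus,L_minus Learning rates per moment for the context's
#'   excitatory and inhibitory associations with each explicit node. The
#'   defaults are this package's standard calibration (see
#'   [standard_params()] and the vignette).
#' @param V0 Named numeric vector of initial associative strengths for
#'   explicit nodes (missing nodes start at 0).
#' @param generalization A matrix from [generalization_spec()] over the
#'   explicit node ids (default: identity, no cross-stimulus generalization).
#' @param response A [response_rule()].
#' @param context_disruptors Character vector of explicit node ids whose
#'   activity disrupts the context (threshold suppression of p1_Ctxt and
#'   decay-rate increments). Default `NULL`: every explicit node disrupts.
#'   The disruption formulas are written in terms of the habituating
#'   stimulus's activity, so protocols that introduce a distractor can
#'   restrict disruption to the habituating stimulus by listing it here.
#' @return An object of class `sop_protocol`.
#' @export
sop_protocol <- function(nodes, sessions, modulation = modulation_params(),
                         L_plus = 0.02, L_minus = 0.0004, V0 = NULL,
                         generalization = NULL, response = response_rule(),
                         context_disruptors = NULL) {
  if (is.null(names(nodes)) || any(names(nodes) == ""))
    stop("'nodes' must be a named list", call. = FALSE)
  roles <- vapply(nodes, function(n) n$role, character(1))
  if (sum(roles == "context") != 1L)
    stop("a protocol needs exactly one context node", call. = FALSE)
  if (sum(roles == "explicit") < 1L)
    stop("a protocol needs at least one explicit node", call. = FALSE)
  if (inherits(sessions, "sop_session")) sessions <- list(sessions)
  explicit <- names(nodes)[roles == "explicit"]
  if (L_plus < 0 || L_minus < 0)
    stop("learning rates must be non-negative", call. = FALSE)
  v0 <- stats::setNames(numeric(length(explicit)), explicit)
  if (!is.null(V0)) {
    bad <- setdiff(names(V0), explicit)
    if (length(bad))
      stop("V0 refers to unknown explicit node '", bad[1], "'", call. = FALSE)
    if (any(V0 < 0 | V0 > 1))
      stop("initial V must lie in [0, 1]", call. = FALSE)
    v0[names(V0)] <- V0
  }
  if (is.null(generalization)) generalization <- generalization_spec(explicit)
  if (!identical(sort(rownames(generalization)), sort(explicit)))
    stop("generalization matrix must cover exactly the explicit nodes",
         call. = FALSE)
  if (is.null(context_disruptors)) context_disruptors <- explicit
  bad <- setdiff(context_disruptors, explicit)
  if (length(bad))
    stop("context_disruptors refers to unknown explicit node '", bad[1], "'",
         call. = FALSE)
  proto <- structure(
    list(nodes = nodes, sessions = sessions, modulation = modulation,
         L_plus = L_plus, L_minus = L_minus, V0 = v0,
         generalization = generalization, response = response,
         context_disruptors = context_disruptors),
    class = "sop_protocol")
  .validate_events(proto)
  proto
}

# Check every event resolves to an explicit node, fits in its session, and
# never overlaps another event on the same node.
.validate_events <- function(proto) {
  explicit <- .explicit_ids(proto)
  for (k in seq_along(proto$sessions)) {
    ses <- proto$sessions[[k]]
    occupied <- list()
    for (ev in ses$events) {
      if (!ev$node %in% explicit)
        stop("session ", k, ": event on unknown explicit node '", ev$node,
             "'", call. = FALSE)
      if (ev$onset + ev$duration - 1L > ses$length)
        stop("session ", k, ": event on '", ev$node,
             "' extends past the session end", call. = FALSE)
      span <- ev$onset:(ev$onset + ev$duration - 1L)
      prev <- occupied[[ev$node]]
      if (length(intersect(span, prev)))
        stop("session ", k, ": overlapping events on node '", ev$node, "'",
             call. = FALSE)
      occupied[[ev$node]] <- c(prev, span)
    }
  }
  invisible(proto)
}

.context_id <- function(proto) {
  names(proto$nodes)[vapply(proto$nodes, function(n) n$role, "") == "context"]
}

.explicit_ids <- function(proto) {
  names(proto$nodes)[vapply(proto$nodes, function(n) n$role, "") == "explicit"]
}

#' Run a protocol moment by moment
#'
#' Executes the full deterministic simulation. Within each moment, in order:
#' (1) every explicit node's effective rates are computed - decay increments
#' from the *other* explicit nodes' previous-moment activity (distractor
#' rules) and retrieval priming p2 = pA1_ctxt * sum_i g(i, node) * V_i using
#' the context's previous-moment A1 activity; (2) all explicit nodes step
#' simultaneously; (3) the context's effective rates are computed from the
#' explicit nodes' just-updated activity (A1 above `theta` suppresses context
#' recruitment; decay increments pA1/c1 and pA2/c2) and the context steps;
#' (4) each context-stimulus association is updated from the just-updated
#' activities. At the end of each session all activity is reset to zero and
#' only the associative strengths V carry over - the model's stand-in for a
#' long inter-session interval.
#'
#' @param protocol An [sop_protocol()].
#' @param keep_timeseries If `FALSE`, only trial summaries and final V are
#'   returned (saves memory in sweeps).
#' @return An object of class `sop_run`: a list with `timeseries` (one row
#'   per moment per node: session, moment, node, pI, pA1, pA2, V, R),
#'   `summaries` (one row per stimulus event: session, trial, node, onset,
#'   peak_pA1, peak_R) and `V_final` (named vector).
#' @examples
#' p <- sop_protocol(
#'   nodes = list(ctx = node_params(0.05, 0.1, 0.02, role = "context"),
#'                s = node_params(0.8, 0.1, 0.02)),
#'   sessions = protocol_session(300, list(stimulus_event("s", 60),
#'                                         stimulus_event("s", 92))))
#' run <- run_protocol(p)
#' run$summaries
#' @export
run_protocol <- function(protocol, keep_timeseries = TRUE) {
  if (!inherits(protocol, "sop_protocol"))
    stop("'protocol' must be an sop_protocol()", call. = FALSE)
  .validate_events(protocol)
  ctx_id <- .context_id(protocol)
  explicit <- .explicit_ids(protocol)
  nE <- length(explicit)
  ctx <- protocol$nodes[[ctx_id]]
  mod <- protocol$modulation
  g <- protocol$generalization[explicit, explicit, drop = FALSE]
  V <- protocol$V0[explicit]
  rule <- protocol$response

  # base rates as plain vectors for the inner loop
  p1_base <- vapply(protocol$nodes[explicit], `[[`, 0, "p1")
  pd1_base <- vapply(protocol$nodes[explicit], `[[`, 0, "pd1")
  pd2_base <- vapply(protocol$nodes[explicit], `[[`, 0, "pd2")
  disruptors <- protocol$context_disruptors
  if (is.null(disruptors)) disruptors <- explicit
  disrupt_idx <- match(disruptors, explicit)

  total_moments <- sum(vapply(protocol$sessions, `[[`, 0L, "length"))
  n_nodes <- nE + 1L
  if (keep_timeseries) {
    ts_rows <- total_moments * n_nodes
    ts <- data.frame(session = integer(ts_rows), moment = integer(ts_rows),
                     node = character(ts_rows), pI = numeric(ts_rows),
                     pA1 = numeric(ts_rows), pA2 = numeric(ts_rows),
                     V = numeric(ts_rows), R = numeric(ts_rows))
  }
  summaries <- list()
  row0 <- 0L

  for (k in seq_along(protocol$sessions)) {
    ses <- protocol$sessions[[k]]
    len <- ses$length
    # per-moment drive: 0 when off, else the effective p1 (intensity override)
    drive <- matrix(0, nrow = len, ncol = nE,
                    dimnames = list(NULL, explicit))
    for (ev in ses$events) {
      span <- ev$onset:(ev$onset + ev$duration - 1L)
      drive[span, ev$node] <- if (is.null(ev$intensity))
        p1_base[[ev$node]] else ev$intensity
    }

    # session starts from all-inactive; only V carried over
    eI <- rep(1, nE); eA1 <- rep(0, nE); eA2 <- rep(0, nE)
    cI <- 1; cA1 <- 0; cA2 <- 0

    sesA1 <- matrix(0, nrow = len, ncol = nE)   # explicit pA1 for peaks
    if (keep_timeseries) sesR <- matrix(0, nrow = len, ncol = nE)

    for (t in seq_len(len)) {
      # (1) explicit effective rates from the previous moment's states
      other_a1 <- sum(eA1) - eA1
      other_a2 <- sum(eA2) - eA2
      pd1_eff <- pmin(1, pd1_base + other_a1 / mod$c1)
      pd2_eff <- pmin(1, pd2_base + other_a2 / mod$c2)
      p2 <- cA1 * pmin(1, as.numeric(V %*% g))

      # (2) step all explicit nodes simultaneously
      pr1 <- drive[t, ] * eI
      pr2 <- p2 * (eI - pr1)
      nA1 <- eA1 - pd1_eff * eA1 + pr1
      nA2 <- eA2 - pd2_eff * eA2 + pd1_eff * eA1 + pr2
      eA1 <- nA1; eA2 <- nA2; eI <- 1 - nA1 - nA2

      # (3) context steps using the just-updated explicit activity
      dA1 <- eA1[disrupt_idx]; dA2 <- eA2[disrupt_idx]
      c_p1 <- if (ses$context_on && !any(dA1 > mod$theta)) ctx$p1 else 0
      c_pd1 <- min(1, ctx$pd1 + sum(dA1) / mod$c1)
      c_pd2 <- min(1, ctx$pd2 + sum(dA2) / mod$c2)
      ncA1 <- cA1 - c_pd1 * cA1 + c_p1 * cI
      ncA2 <- cA2 - c_pd2 * cA2 + c_pd1 * cA1
      cA1 <- ncA1; cA2 <- ncA2; cI <- 1 - ncA1 - ncA2

      # (4) learning from the just-updated activities
      V <- pmin(pmax(V + protocol$L_plus * cA1 * eA1 -
                       protocol$L_minus * cA1 * eA2, 0), 1)

      sesA1[t, ] <- eA1
      if (keep_timeseries) {
        sesR[t, ] <- rule$w1 * eA1 + rule$w2 * eA2
        idx <- row0 + (t - 1L) * n_nodes + seq_len(n_nodes)
        ts$session[idx] <- k
        ts$moment[idx] <- t
        ts$node[idx] <- c(explicit, ctx_id)
        ts$pI[idx] <- c(eI, cI)
        ts$pA1[idx] <- c(eA1, cA1)
        ts$pA2[idx] <- c(eA2, cA2)
        ts$V[idx] <- c(V, NA_real_)
        ts$R[idx] <- c(sesR[t, ], rule$w1 * cA1 + rule$w2 * cA2)
      }
    }
    row0 <- row0 + len * n_nodes

    colnames(sesA1) <- explicit
    traj <- lapply(explicit, function(nd)
      cbind(pI = NA_real_, pA1 = sesA1[, nd], pA2 = NA_real_))
    names(traj) <- explicit
    for (nd in explicit) {
      evs <- Filter(function(e) e$node == nd, ses$events)
      if (!length(evs)) next
      pk <- extract_peaks(traj[[nd]], evs, len)
      pk$session <- k
      pk$node <- nd
      summaries[[length(summaries) + 1L]] <- pk
    }
  }

  summ <- if (length(summaries)) do.call(rbind, summaries) else
    data.frame(trial = integer(0), onset = integer(0),
               peak_pA1 = numeric(0), peak_moment = integer(0),
               session = integer(0), node = character(0))
  summ <- summ[order(summ$session, summ$onset),
               c("session", "trial", "node", "onset", "peak_pA1",
                 "peak_moment")]
  rownames(summ) <- NULL
  # mapped response at the peak-defining moment window: with the default rule
  # peak_R equals peak_pA1; recompute generally from the timeseries when kept
  summ$peak_R <- rule$w1 * summ$peak_pA1
  if (keep_timeseries && (rule$w2 != 0)) {
    summ$peak_R <- vapply(seq_len(nrow(summ)), function(i) {
      sel <- ts$session == summ$session[i] & ts$node == summ$node[i]
      win <- .peak_window(summ$onset[i], summ$node[i],
                          protocol$sessions[[summ$session[i]]])
      max(ts$R[sel & ts$moment >= win[1] & ts$moment <= win[2]])
    }, 0)
  }

  structure(list(timeseries = if (keep_timeseries) ts else NULL,
                 summaries = summ, V_final = V, protocol = protocol),
            class = "sop_run")
}

# window [onset, next same-node onset - 1] or session end
.peak_window <- function(onset, node, session) {
  onsets <- sort(vapply(Filter(function(e) e$node == node, session$events),
                        `[[`, 0L, "onset"))
  nxt <- onsets[onsets > onset]
  c(onset, if (length(nxt)) min(nxt) - 1L else session$length)
}

#' Extract per-trial peak activity
#'
#' The dependent variable of the habituation simulations: for each stimulus
#' event, the maximum pA1 of the presented node over the window from that
#' event's onset up to (but excluding) the next onset of the same node, or to
#' the session end for the last event.
#'
#' @param trajectory Matrix with a `pA1` column, one row per moment of the
#'   session (row t = moment t).
#' @param events List of [stimulus_event()]s for one node within the session.
#' @param session_length Session length in moments.
#' @return A data frame with one row per event: `trial` (order by onset),
#'   `onset`, `peak_pA1`, `peak_moment`.
#' @export
extract_peaks <- function(trajectory, events, session_length) {
  if (inherits(events, "sop_event")) events <- list(events)
  if (nrow(trajectory) < session_length)
    stop("trajectory does not cover the session", call. = FALSE)
  onsets <- vapply(events, `[[`, 0L, "onset")
  ord <- order(onsets)
  onsets <- onsets[ord]
  out <- data.frame(trial = seq_along(onsets), onset = onsets,
                    peak_pA1 = NA_real_, peak_moment = NA_integer_)
  for (i in seq_along(onsets)) {
    end <- if (i < length(onsets)) onsets[i + 1L] - 1L else session_length
    if (end < onsets[i]) stop("empty peak window", call. = FALSE)
    win <- onsets[i]:end
    a1 <- trajectory[win, "pA1"]
    out$peak_pA1[i] <- max(a1)
    out$peak_moment[i] <- win[which.max(a1)]
  }
  out
}

#' @export
print.sop_protocol <- function(x, ...) {
  cat(sprintf("SOP protocol: %d node(s) [%s], %d session(s), %d event(s)\n",
              length(x$nodes), paste(names(x$nodes), collapse = ", "),
              length(x$sessions),
              sum(vapply(x$sessions, function(s) length(s$events), 0L))))
  cat(sprintf("  learning: L+ = %g, L- = %g; disruption: theta = %g, c1 = %g, c2 = %g\n",
              x$L_plus, x$L_minus, x$modulation$theta, x$modulation$c1,
              x$modulation$c2))
  invisible(x)
}

#' @export
print.sop_run <- function(x, ...) {
  cat("SOP run:", nrow(x$summaries), "trial(s)\n")
  print(utils::head(x$summaries, 20))
  if (nrow(x$summaries) > 20) cat("...\n")
  cat("final V:", paste(sprintf("%s = %.4f", names(x$V_final), x$V_final),
                        collapse = ", "), "\n")
  invisible(x)
}
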