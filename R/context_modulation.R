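#' Context-disruption and distractor-rule parameters
#'
#' Explicit cues transiently disrupt the processing of the context: while any
#' explicit node's primary activity exceeds the threshold `theta`, the
#' context recruits no new A1 elements (p1_Ctxt = 0), and the context's decay
#' rates are incremented in proportion to the explicit nodes' activity
#' (pd1' = pd1 + pA1/c1, pd2' = pd2 + pA2/c2). The same proportionality
#' constants govern SOP's distractor rules, by which one explicit stimulus
#' accelerates the decay of another's trace. Defaults are theta = 0.07,
#' c1 = 2, c2 = 10.
#'
#' @param theta Threshold on an explicit node's pA1 above which context A1
#'   recruitment is suppressed; in [0, 1].
#' @param c1 Divisor converting A1 activity into a pd1 increment (> 0).
#' @param c2 Divisor converting A2 activity into a pd2 increment (> 0).
#' @return An object of class `sop_modulation`.
#' @export
modulation_params <- function(theta = 0.07, c1 = 2, c2 = 10) {
  if (is.na(theta) || theta < 0 || theta > 1)
    stop("'theta' must lie in [0, 1]", call. = FALSE)
  if (is.na(c1) || c1 <= 0 || is.na(c2) || c2 <= 0)
    stop("'c1' and 'c2' must be positive", call. = FALSE)
  structure(list(theta = theta, c1 = c1, c2 = c2), class = "sop_modulation")
}

# Pull pA1/pA2 vectors out of a list of states (each a numeric c(pI,pA1,pA2)).
.activity_cols <- function(states) {
  if (length(states) == 0L)
    return(list(pA1 = numeric(0), pA2 = numeric(0)))
  m <- do.call(rbind, lapply(states, function(s) unclass(s)[1:3]))
  list(pA1 = m[, 2L], pA2 = m[, 3L])
}

#' Effective rates of the context under disruption by explicit cues
#'
#' While any explicit node's pA1 exceeds `theta`, context A1 recruitment is
#' shut off entirely. Independently, every explicit node's activity
#' accelerates the context's decay: increments pA1/c1 on pd1 and pA2/c2 on
#' pd2 are summed across explicit nodes and the results clamped to [0, 1].
#' With the standard parameters and a stimulus at full activity this gives
#' pd1' = 0.1 + 0.8/2 = 0.5. The context itself is never associatively
#' primed, so its p2 is always 0.
#'
#' @param base The context's [node_params()].
#' @param explicit_states Named list of the explicit nodes' current
#'   [activity_state()]s.
#' @param params A [modulation_params()].
#' @return An [effective_rates()] for the context this moment.
#' @export
context_effective_rates <- function(base, explicit_states,
                                    params = modulation_params()) {
  act <- .activity_cols(explicit_states)
  p1 <- if (any(act$pA1 > params$theta)) 0 else base$p1
  effective_rates(
    p1_eff  = p1,
    pd1_eff = min(1, base$pd1 + sum(act$pA1) / params$c1),
    pd2_eff = min(1, base$pd2 + sum(act$pA2) / params$c2),
    p2      = 0
  )
}

#' Effective decay rates of an explicit node under distractor activity
#'
#' SOP's distractor rules: activity of any *other* explicit node increments
#' the target's decay rates, flushing its A1 and (crucially) its refractory
#' A2 trace faster. The increments use the same divisors as the context rule
#' and are additive across simultaneously active distractors. The target's
#' own p1 is untouched; its p2 (associative priming) is supplied by the
#' caller and defaults to 0 here.
#'
#' @param target The target node's [node_params()].
#' @param other_explicit_states Named list of the *other* explicit nodes'
#'   current states (the target itself must be excluded).
#' @param params A [modulation_params()].
#' @param p2 Retrieval-priming probability for the target this moment.
#' @return An [effective_rates()] for the target this moment.
#' @export
distractor_effective_rates <- function(target, other_explicit_states,
                                       params = modulation_params(), p2 = 0) {
  act <- .activity_cols(other_explicit_states)
  effective_rates(
    p1_eff  = target$p1,
    pd1_eff = min(1, target$pd1 + sum(act$pA1) / params$c1),
    pd2_eff = min(1, target$pd2 + sum(act$pA2) / params$c2),
    p2      = p2
  )
}
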