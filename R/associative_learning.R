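#' Update a context-stimulus associative strength
#'
#' SOP's concurrent-activity learning rule, applied once per moment. The
#' context plays the role of the conditioned stimulus and the habituating
#' stimulus that of the unconditioned stimulus. Excitatory growth is
#' proportional to the momentary product of the context's and the stimulus's
#' primary (A1) activity; inhibitory decrement is proportional to the product
#' of the context's primary activity and the stimulus's secondary (A2)
#' activity:
#'
#'   V' = V + L_plus * pA1_ctxt * pA1_s - L_minus * pA1_ctxt * pA2_s
#'
#' V is clamped to [0, 1] so that the retrieval-priming probability
#' p2 = pA1_ctxt * g * V is always a valid probability; a net-inhibitory
#' association is not represented (V floors at 0).
#'
#' @param V Current associative strength in [0, 1].
#' @param pA1_ctxt Context primary activity this moment.
#' @param pA1_s,pA2_s Stimulus primary and secondary activity this moment.
#' @param L_plus Excitatory learning rate per moment (>= 0).
#' @param L_minus Inhibitory learning rate per moment (>= 0).
#' @return The updated strength, clamped to [0, 1].
#' @examples
#' update_association(0.5, 0.2, 0.8, 0, L_plus = 0.1, L_minus = 0.02) # 0.516
#' update_association(0.5, 0.2, 0, 0.5, L_plus = 0.1, L_minus = 0.02) # 0.498
#' @export
update_association <- function(V, pA1_ctxt, pA1_s, pA2_s, L_plus, L_minus) {
  if (L_plus < 0 || L_minus < 0)
    stop("learning rates must be non-negative", call. = FALSE)
  p <- c(V, pA1_ctxt, pA1_s, pA2_s)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("V and activity proportions must lie in [0, 1]", call. = FALSE)
  v <- V + L_plus * pA1_ctxt * pA1_s - L_minus * pA1_ctxt * pA2_s
  min(max(v, 0), 1)
}

#' Retrieval-generated priming probability
#'
#' The probability per moment that the context promotes an inactive element
#' of a stimulus node directly into the secondary (A2) state:
#' p2 = pA1_ctxt * g * V. `g` is a static similarity coefficient that scales
#' how much of an association trained to one stimulus is retrieved when a
#' (possibly different) test stimulus is represented; g = 1 for the trained
#' stimulus itself and g = 0 for a completely dissimilar one.
#'
#' @param pA1_ctxt Context primary activity.
#' @param V Associative strength in [0, 1].
#' @param g Generalization coefficient in [0, 1] (default 1).
#' @return A probability in [0, 1].
#' @examples
#' compute_p2(0.5, 0.4)            # 0.2
#' compute_p2(0.5, 0.4, g = 0.25)  # 0.05
#' @export
compute_p2 <- function(pA1_ctxt, V, g = 1) {
  p <- c(pA1_ctxt, V, g)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("compute_p2 inputs must lie in [0, 1]", call. = FALSE)
  pA1_ctxt * g * V
}

#' Generalization coefficients between explicit nodes
#'
#' A square matrix g[from, to] giving, for each ordered pair of explicit
#' nodes, the fraction of the association trained to `from` that is retrieved
#' when `to` is the represented stimulus. The diagonal is fixed at 1 (a
#' stimulus fully retrieves its own association).
#'
#' @param nodes Character vector of explicit node ids.
#' @param coefficients Optional data frame with columns `from`, `to`, `g`
#'   giving off-diagonal entries; unspecified pairs default to 0.
#' @return A numeric matrix with `nodes` as row and column names.
#' @export
generalization_spec <- function(nodes, coefficients = NULL) {
  g <- diag(length(nodes))
  dimnames(g) <- list(nodes, nodes)
  if (!is.null(coefficients)) {
    if (!all(c("from", "to", "g") %in% names(coefficients)))
      stop("'coefficients' needs columns from, to, g", call. = FALSE)
    for (i in seq_len(nrow(coefficients))) {
      from <- as.character(coefficients$from[i])
      to <- as.character(coefficients$to[i])
      val <- coefficients$g[i]
      if (!from %in% nodes || !to %in% nodes)
        stop("generalization refers to unknown node '",
             if (from %in% nodes) to else from, "'", call. = FALSE)
      if (is.na(val) || val < 0 || val > 1)
        stop("generalization coefficients must lie in [0, 1]", call. = FALSE)
      if (from == to && val != 1)
        stop("g(x, x) is fixed at 1", call. = FALSE)
      g[from, to] <- val
    }
  }
  g
}
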