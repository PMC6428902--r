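# Shared fixtures and independent oracles for the test suite.

std_stimulus <- function() node_params(0.8, 0.1, 0.02)
std_context <- function() node_params(0.05, 0.1, 0.02, role = "context")

# a standard protocol: `trials` 1-moment presentations of "s" at the given
# onset-to-onset ISI, first onset at moment 60, repeated over `sessions`
std_protocol <- function(isi = 32, trials = 4, sessions = 1, len = 300,
                         intensity = NULL, ...) {
  onsets <- 60 + isi * (seq_len(trials) - 1)
  ses <- protocol_session(max(len, max(onsets) + 144),
                          lapply(onsets, function(o)
                            stimulus_event("s", o, intensity = intensity)))
  sop_protocol(nodes = list(ctx = std_context(), s = std_stimulus()),
               sessions = rep(list(ses), sessions), ...)
}

peak_of <- function(run, session, trial, node = "s") {
  s <- run$summaries
  s$peak_pA1[s$session == session & s$trial == trial & s$node == node]
}

# --- element-level Monte-Carlo oracle -------------------------------------
# Simulates n individual elements of one node through the three-state Markov
# chain (stimulus on at moment 1 only, p2 = 0) and returns the observed state
# proportions at the requested moments. Entirely independent of the package's
# deterministic mean-proportion engine; by the law of large numbers the two
# must agree at large n.
mc_element_oracle <- function(n, p1, pd1, pd2, moments, seed) {
  set.seed(seed)
  state <- integer(n)  # 0 = I, 1 = A1, 2 = A2
  out <- matrix(NA_real_, nrow = length(moments), ncol = 3,
                dimnames = list(paste0("m", moments), c("pI", "pA1", "pA2")))
  for (t in seq_len(max(moments))) {
    u <- stats::runif(n)
    nxt <- state
    nxt[state == 1L & u < pd1] <- 2L
    nxt[state == 2L & u < pd2] <- 0L
    if (t == 1L) nxt[state == 0L & u < p1] <- 1L
    state <- nxt
    hit <- match(t, moments)
    if (!is.na(hit))
      out[hit, ] <- c(mean(state == 0L), mean(state == 1L), mean(state == 2L))
  }
  out
}

# --- straight-line re-implementation oracle --------------------------------
# A from-scratch flat transcription of the update equations for the standard
# one-context/one-stimulus setting: no shared code with the engine. Returns
# the per-trial peak pA1 (windows onset..next onset - 1, last window to the
# session end) for every session.
straightline_peaks <- function(sessions, len, onsets, p1s = 0.8, pd1s = 0.1,
                               pd2s = 0.02, p1c = 0.05, pd1c = 0.1,
                               pd2c = 0.02, theta = 0.07, c1 = 2, c2 = 10,
                               Lp = 0.02, Lm = 4e-4) {
  V <- 0
  peaks <- matrix(NA_real_, nrow = sessions, ncol = length(onsets))
  for (k in seq_len(sessions)) {
    sI <- 1; sA1 <- 0; sA2 <- 0
    cI <- 1; cA1 <- 0; cA2 <- 0
    trace <- numeric(len)
    for (t in seq_len(len)) {
      p2 <- cA1 * V
      inA1 <- if (t %in% onsets) p1s * sI else 0
      inA2 <- p2 * (sI - inA1)
      nsA1 <- sA1 - pd1s * sA1 + inA1
      nsA2 <- sA2 - pd2s * sA2 + pd1s * sA1 + inA2
      sA1 <- nsA1; sA2 <- nsA2; sI <- 1 - nsA1 - nsA2
      cp1 <- if (sA1 > theta) 0 else p1c
      cpd1 <- min(1, pd1c + sA1 / c1)
      cpd2 <- min(1, pd2c + sA2 / c2)
      ncA1 <- cA1 - cpd1 * cA1 + cp1 * cI
      ncA2 <- cA2 - cpd2 * cA2 + cpd1 * cA1
      cA1 <- ncA1; cA2 <- ncA2; cI <- 1 - ncA1 - ncA2
      V <- min(1, max(0, V + Lp * cA1 * sA1 - Lm * cA1 * sA2))
      trace[t] <- sA1
    }
    for (i in seq_along(onsets)) {
      hi <- if (i < length(onsets)) onsets[i + 1] - 1 else len
      peaks[k, i] <- max(trace[onsets[i]:hi])
    }
  }
  peaks
}

# Same idea for the two-explicit-node (habituating stimulus + distractor)
# setting with the symmetric distractor rules; returns the target's per-trial
# peaks per session.
straightline_peaks_distractor <- function(sessions, len, onsets, d_onset,
                                          p1 = 0.8, pd1 = 0.1, pd2 = 0.02,
                                          p1c = 0.05, pd1c = 0.1, pd2c = 0.02,
                                          theta = 0.07, c1 = 2, c2 = 10,
                                          Lp = 0.02, Lm = 4e-4) {
  Vs <- 0; Vd <- 0
  peaks <- matrix(NA_real_, nrow = sessions, ncol = length(onsets))
  for (k in seq_len(sessions)) {
    sI <- 1; sA1 <- 0; sA2 <- 0
    dI <- 1; dA1 <- 0; dA2 <- 0
    cI <- 1; cA1 <- 0; cA2 <- 0
    trace <- numeric(len)
    for (t in seq_len(len)) {
      s_pd1 <- min(1, pd1 + dA1 / c1); s_pd2 <- min(1, pd2 + dA2 / c2)
      d_pd1 <- min(1, pd1 + sA1 / c1); d_pd2 <- min(1, pd2 + sA2 / c2)
      s_in1 <- if (t %in% onsets) p1 * sI else 0
      d_in1 <- if (!is.na(d_onset) && t == d_onset) p1 * dI else 0
      s_in2 <- cA1 * Vs * (sI - s_in1)
      d_in2 <- cA1 * Vd * (dI - d_in1)
      nsA1 <- sA1 - s_pd1 * sA1 + s_in1
      nsA2 <- sA2 - s_pd2 * sA2 + s_pd1 * sA1 + s_in2
      ndA1 <- dA1 - d_pd1 * dA1 + d_in1
      ndA2 <- dA2 - d_pd2 * dA2 + d_pd1 * dA1 + d_in2
      sA1 <- nsA1; sA2 <- nsA2; sI <- 1 - nsA1 - nsA2
      dA1 <- ndA1; dA2 <- ndA2; dI <- 1 - ndA1 - ndA2
      cp1 <- if (sA1 > theta || dA1 > theta) 0 else p1c
      cpd1 <- min(1, pd1c + (sA1 + dA1) / c1)
      cpd2 <- min(1, pd2c + (sA2 + dA2) / c2)
      ncA1 <- cA1 - cpd1 * cA1 + cp1 * cI
      ncA2 <- cA2 - cpd2 * cA2 + cpd1 * cA1
      cA1 <- ncA1; cA2 <- ncA2; cI <- 1 - ncA1 - ncA2
      Vs <- min(1, max(0, Vs + Lp * cA1 * sA1 - Lm * cA1 * sA2))
      Vd <- min(1, max(0, Vd + Lp * cA1 * dA1 - Lm * cA1 * dA2))
      trace[t] <- sA1
    }
    for (i in seq_along(onsets)) {
      hi <- if (i < length(onsets)) onsets[i + 1] - 1 else len
      peaks[k, i] <- max(trace[onsets[i]:hi])
    }
  }
  peaks
}
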