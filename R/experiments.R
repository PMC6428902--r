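#' Standard simulation parameters
#'
#' The parameter set used throughout the habituation simulations: the
#' habituating stimulus lasts 1 moment with p1 = 0.8 (unless intensity is
#' varied), pd1 = 0.1, pd2 = 0.02; the context has the same decay rates but
#' p1 = 0.05; context disruption uses theta = 0.07, c1 = 2, c2 = 10; sessions
#' are 300 moments long with the first stimulus onset at moment 60 and
#' successive onsets separated by the inter-stimulus interval (onset to
#' onset). Learning rates default to L+ = 0.02 and L- = 0.0004; the model's
#' source analyses state the learning rules but no rate values, so these are
#' this package's calibration (see the vignette) and are freely
#' configurable.
#'
#' @return A named list with elements `stimulus`, `context` (both
#'   [node_params()]), `modulation` ([modulation_params()]), `L_plus`,
#'   `L_minus`, `session_length`, `first_onset`, `intensities` (the
#'   high/medium/low p1 values 0.8, 0.5, 0.2) and `generalization_rates`
#'   (1, 0.75, 0.5, 0.25, 0).
#' @export
standard_params <- function() {
  list(stimulus = node_params(0.8, 0.1, 0.02),
       context = node_params(0.05, 0.1, 0.02, role = "context"),
       modulation = modulation_params(theta = 0.07, c1 = 2, c2 = 10),
       L_plus = 0.02, L_minus = 0.0004,
       session_length = 300L, first_onset = 60L,
       intensities = c(high = 0.8, medium = 0.5, low = 0.2),
       generalization_rates = c(1, 0.75, 0.5, 0.25, 0))
}

# a training session of `trials` 1-moment presentations at the given ISI
# (onset to onset); length grows past 300 only when the schedule needs it,
# keeping the post-training tail at 300 - (60 + 3*32) = 144 moments for the
# standard 4-trial schedules.
.train_session <- function(isi, trials, node = "s", intensity = NULL,
                           extra_events = list(), std = standard_params()) {
  onsets <- std$first_onset + isi * (seq_len(trials) - 1L)
  evs <- lapply(onsets, function(o) stimulus_event(node, o, intensity = intensity))
  protocol_session(max(std$session_length, max(onsets) + 144L),
                   c(evs, extra_events))
}

.std_protocol <- function(sessions, extra_nodes = list(), std = standard_params(),
                          ...) {
  args <- utils::modifyList(
    list(nodes = c(list(ctx = std$context, s = std$stimulus), extra_nodes),
         sessions = sessions, modulation = std$modulation,
         L_plus = std$L_plus, L_minus = std$L_minus),
    list(...))
  do.call(sop_protocol, args)
}

#' Build the packaged replication protocols
#'
#' Constructs, for a named figure of the habituation analysis, the full set
#' of condition protocols with the standard parameters:
#' \describe{
#'   \item{fig1c}{Two sessions of two presentations (ISI 32) with context
#'     learning disabled: pure self-generated priming and its between-session
#'     dissipation.}
#'   \item{fig2c}{The same schedule with context learning enabled:
#'     retrieval-generated priming appears in session 2.}
#'   \item{fig3}{One session of 4 presentations at ISI 2, 4, 8, 16 or 32
#'     (five conditions).}
#'   \item{fig4}{Ten sessions of 4 presentations at ISI 8 or 32 (two
#'     conditions).}
#'   \item{fig5}{4 or 10 training presentations at ISI 32 in session 1, a
#'     single recovery test presentation in session 2 (two conditions).}
#'   \item{fig6}{4 training presentations at ISI 32 with intensity p1 = 0.2
#'     or 0.8, tested in session 2 at the common intensity p1 = 0.5 (two
#'     conditions).}
#'   \item{fig7}{4 training presentations at ISI 32, then a session-2 test of
#'     a stimulus receiving a fraction g in 1, 0.75, 0.5, 0.25, 0 of the
#'     trained association (five conditions).}
#'   \item{fig8}{Three sessions of 4 presentations at ISI 32, with or without
#'     a 1-moment distractor (p1 = 0.8, pd1 = 0.1, pd2 = 0.02) at the
#'     temporal midpoint between trials 1 and 2 of every session (two
#'     conditions).}
#' }
#'
#' @param figure One of `"fig1c"`, `"fig2c"`, `"fig3"`, `"fig4"`, `"fig5"`,
#'   `"fig6"`, `"fig7"`, `"fig8"`.
#' @return A named list of [sop_protocol()] objects, one per condition, of
#'   class `sop_protocol_set` with attribute `figure`.
#' @export
build_figure_protocol <- function(figure = c("fig1c", "fig2c", "fig3", "fig4",
                                             "fig5", "fig6", "fig7", "fig8")) {
  figure <- match.arg(figure)
  std <- standard_params()
  set <- switch(figure,
    fig1c = list(
      no_learning = .std_protocol(rep(list(.train_session(32, 2)), 2),
                                  L_plus = 0, L_minus = 0)),
    fig2c = list(
      with_context = .std_protocol(rep(list(.train_session(32, 2)), 2))),
    fig3 = {
      isis <- c(2, 4, 8, 16, 32)
      stats::setNames(
        lapply(isis, function(isi) .std_protocol(list(.train_session(isi, 4)))),
        paste0("isi", isis))
    },
    fig4 = {
      isis <- c(8, 32)
      stats::setNames(
        lapply(isis, function(isi)
          .std_protocol(rep(list(.train_session(isi, 4)), 10))),
        paste0("isi", isis))
    },
    fig5 = {
      stats::setNames(
        lapply(c(4, 10), function(tr)
          .std_protocol(list(.train_session(32, tr), .train_session(32, 1)))),
        c("trials4", "trials10"))
    },
    fig6 = {
      stats::setNames(
        lapply(c(0.2, 0.8), function(p1)
          .std_protocol(list(.train_session(32, 4, intensity = p1),
                             .train_session(32, 1, intensity = 0.5)))),
        c("low", "high"))
    },
    fig7 = {
      rates <- std$generalization_rates
      stats::setNames(
        lapply(rates, function(g)
          .std_protocol(
            list(.train_session(32, 4),
                 .train_session(32, 1, node = "test")),
            extra_nodes = list(test = std$stimulus),
            generalization = generalization_spec(
              c("s", "test"), data.frame(from = "s", to = "test", g = g)))),
        paste0("g", rates * 100))
    },
    fig8 = {
      base <- function(with_distractor) {
        ses <- .train_session(32, 4, extra_events = if (with_distractor)
          list(stimulus_event("d", 76L)) else list())
        .std_protocol(rep(list(ses), 3),
                      extra_nodes = list(d = node_params(0.8, 0.1, 0.02)))
      }
      list(control = base(FALSE), distractor = base(TRUE))
    })
  structure(set, class = c("sop_protocol_set", "list"), figure = figure)
}

#' Run all conditions of a packaged figure protocol
#'
#' @param figure A figure name accepted by [build_figure_protocol()], or an
#'   `sop_protocol_set`.
#' @param keep_timeseries Passed to [run_protocol()].
#' @return A list with `figure`, `runs` (named list of `sop_run`s) and
#'   `summaries` (all trial summaries in one data frame with a leading
#'   `condition` column).
#' @export
run_figure <- function(figure, keep_timeseries = TRUE) {
  set <- if (inherits(figure, "sop_protocol_set")) figure
         else build_figure_protocol(figure)
  runs <- lapply(set, run_protocol, keep_timeseries = keep_timeseries)
  summaries <- do.call(rbind, lapply(names(runs), function(cond) {
    s <- runs[[cond]]$summaries
    if (nrow(s)) cbind(condition = cond, s) else NULL
  }))
  rownames(summaries) <- NULL
  list(figure = attr(set, "figure"), runs = runs, summaries = summaries)
}

# peak of node `node` on trial `trial` of session `session` in run `r`
.pk <- function(r, session, trial, node = "s") {
  s <- r$summaries
  s$peak_pA1[s$session == session & s$trial == trial & s$node == node]
}

#' Evaluate the ten behavioral characteristics of habituation
#'
#' Runs the packaged protocols and evaluates one ordered assertion per
#' classical characteristic of habituation (the Rankin et al. revision of the
#' Thompson & Spencer list), purely as functions of the per-trial peak pA1
#' summaries:
#'
#' 1. Within-session decrement: peaks strictly decrease over 4 trials for ISI
#'    8, 16 and 32 with shrinking successive decrements (approximately
#'    exponential), and ISI 2 shows transient facilitation (trial 2 > trial
#'    1) by A1 summation.
#' 2. Spontaneous recovery: the session-2 trial-1 peak lies strictly between
#'    the session-1 trial-4 and trial-1 peaks (partial recovery).
#' 3. Potentiation of habituation: the recovery ratio (session-k trial-1 peak
#'    over session-1 trial-1 peak) is smaller in session 10 than session 2.
#' 4. Frequency: ISI 8 gives more within-session decrement and a larger
#'    recovery ratio than ISI 32.
#' 5. Intensity: the p1 = 0.2 condition responds less throughout training
#'    (its response is decremented to a lower level - in this model a
#'    performance effect), and at a common test intensity p1 = 0.5 the
#'    p1 = 0.8-trained condition shows the lower peak (a learning effect).
#' 6. Below-zero habituation: 10-trial training yields a lower recovery-test
#'    peak than 4-trial training even though the final training peaks are
#'    nearly identical (within 10% relative).
#' 7. Generalization: test peaks are strictly ordered inversely to the
#'    generalization coefficient, and the coefficient-0 stimulus equals a
#'    never-trained control.
#' 8. Dishabituation: a distractor between trials 1 and 2 raises the trial-2
#'    peak above the no-distractor control in session 1.
#' 9. Habituation of dishabituation: the distractor-minus-control trial-2
#'    difference decreases from session 1 to session 3. With the standard
#'    parameters this model recreates dishabituation at near-full strength
#'    every session while the control keeps habituating, so this check
#'    currently fails; see the vignette's limitations section.
#' 10. Long-term habituation: the session-2 trial-1 peak is below the
#'    session-1 trial-1 peak.
#'
#' @param checks Integer vector selecting which characteristics to evaluate
#'   (default all ten).
#' @return A data frame with columns `characteristic`, `description`,
#'   `passed`, `detail` (the compared quantities, formatted).
#' @export
run_characteristic_suite <- function(checks = 1:10) {
  checks <- sort(unique(as.integer(checks)))
  if (any(checks < 1 | checks > 10))
    stop("'checks' must be within 1..10", call. = FALSE)
  need3 <- any(checks == 1)
  need4 <- any(checks %in% c(2, 3, 4, 10))
  fig3 <- if (need3) run_figure("fig3", keep_timeseries = FALSE)
  fig4 <- if (need4) run_figure("fig4", keep_timeseries = FALSE)
  fig5 <- if (any(checks == 6)) run_figure("fig5", keep_timeseries = FALSE)
  fig6 <- if (any(checks == 5)) run_figure("fig6", keep_timeseries = FALSE)
  fig7 <- if (any(checks == 7)) run_figure("fig7", keep_timeseries = FALSE)
  fig8 <- if (any(checks %in% c(8, 9))) run_figure("fig8", keep_timeseries = FALSE)

  res <- list()
  add <- function(id, description, passed, detail) {
    res[[length(res) + 1L]] <<- data.frame(
      characteristic = as.integer(id), description = description,
      passed = isTRUE(passed), detail = detail)
  }

  if (1 %in% checks) {
    ok <- TRUE; parts <- character()
    for (isi in c(8, 16, 32)) {
      pk <- sapply(1:4, function(tr) .pk(fig3$runs[[paste0("isi", isi)]], 1, tr))
      dec <- -diff(pk)
      ok <- ok && all(dec > 0) && all(diff(dec) < 0)
      parts <- c(parts, sprintf("ISI %d: %s", isi,
                                paste(sprintf("%.3f", pk), collapse = " > ")))
    }
    p2 <- sapply(1:2, function(tr) .pk(fig3$runs$isi2, 1, tr))
    ok <- ok && p2[2] > p2[1]
    parts <- c(parts, sprintf("ISI 2 facilitation: %.3f -> %.3f", p2[1], p2[2]))
    add(1, "within-session decrement, ~exponential; facilitation at ISI 2",
        ok, paste(parts, collapse = "; "))
  }
  if (2 %in% checks) {
    r <- fig4$runs$isi32
    q <- c(s1t1 = .pk(r, 1, 1), s1t4 = .pk(r, 1, 4), s2t1 = .pk(r, 2, 1))
    add(2, "partial spontaneous recovery between sessions",
        q["s2t1"] > q["s1t4"] && q["s2t1"] < q["s1t1"],
        sprintf("s1t4 = %.3f < s2t1 = %.3f < s1t1 = %.3f",
                q["s1t4"], q["s2t1"], q["s1t1"]))
  }
  if (3 %in% checks) {
    r <- fig4$runs$isi32
    rec <- function(k) .pk(r, k, 1) / .pk(r, 1, 1)
    add(3, "potentiation of habituation over sessions",
        rec(10) < rec(2),
        sprintf("recovery ratio session 2 = %.3f, session 10 = %.3f",
                rec(2), rec(10)))
  }
  if (4 %in% checks) {
    wdec <- sapply(c("isi8", "isi32"), function(cc) {
      r <- fig4$runs[[cc]]; 1 - .pk(r, 1, 4) / .pk(r, 1, 1)
    })
    rec2 <- sapply(c("isi8", "isi32"), function(cc) {
      r <- fig4$runs[[cc]]; .pk(r, 2, 1) / .pk(r, 1, 1)
    })
    add(4, "more frequent stimulation: more decrement, more recovery",
        wdec["isi8"] > wdec["isi32"] && rec2["isi8"] > rec2["isi32"],
        sprintf("decrement ISI8 = %.3f vs ISI32 = %.3f; recovery ratio ISI8 = %.3f vs ISI32 = %.3f",
                wdec["isi8"], wdec["isi32"], rec2["isi8"], rec2["isi32"]))
  }
  if (5 %in% checks) {
    lowpk <- sapply(1:4, function(tr) .pk(fig6$runs$low, 1, tr))
    highpk <- sapply(1:4, function(tr) .pk(fig6$runs$high, 1, tr))
    tlow <- .pk(fig6$runs$low, 2, 1); thigh <- .pk(fig6$runs$high, 2, 1)
    add(5, "intensity: weaker stimulus responds at lower level; stronger trains more",
        all(lowpk < highpk) && thigh < tlow,
        sprintf("final training peak low = %.3f vs high = %.3f; test (p1 = 0.5) high-trained = %.3f < low-trained = %.3f",
                lowpk[4], highpk[4], thigh, tlow))
  }
  if (6 %in% checks) {
    t4 <- .pk(fig5$runs$trials4, 1, 4)
    t10 <- .pk(fig5$runs$trials10, 1, 10)
    test4 <- .pk(fig5$runs$trials4, 2, 1)
    test10 <- .pk(fig5$runs$trials10, 2, 1)
    add(6, "below-zero habituation revealed at recovery test",
        abs(t4 - t10) / t4 < 0.1 && test10 < test4,
        sprintf("final training peaks %.3f vs %.3f (rel diff %.1f%%); test peaks %.3f vs %.3f",
                t4, t10, 100 * abs(t4 - t10) / t4, test4, test10))
  }
  if (7 %in% checks) {
    rates <- standard_params()$generalization_rates
    pk <- sapply(paste0("g", rates * 100), function(cc)
      .pk(fig7$runs[[cc]], 2, 1, node = "test"))
    naive <- run_protocol(.std_protocol(list(.train_session(32, 1))),
                          keep_timeseries = FALSE)
    npk <- .pk(naive, 1, 1)
    add(7, "generalization: test peak ordered inversely to similarity",
        all(diff(pk) > 0) && abs(pk[length(pk)] - npk) < 1e-9,
        sprintf("peaks at g = %s: %s; naive control %.6f",
                paste(rates, collapse = ", "),
                paste(sprintf("%.3f", pk), collapse = " < "), npk))
  }
  if (8 %in% checks || 9 %in% checks) {
    d2 <- function(k, cond) .pk(fig8$runs[[cond]], k, 2)
    diffs <- sapply(1:3, function(k) d2(k, "distractor") - d2(k, "control"))
    if (8 %in% checks)
      add(8, "dishabituation by a distractor in session 1",
          diffs[1] > 0,
          sprintf("trial-2 peak distractor = %.3f vs control = %.3f",
                  d2(1, "distractor"), d2(1, "control")))
    if (9 %in% checks)
      add(9, "habituation of dishabituation over sessions",
          diffs[3] < diffs[1],
          sprintf("distractor-minus-control difference: session 1 = %.3f, session 2 = %.3f, session 3 = %.3f",
                  diffs[1], diffs[2], diffs[3]))
  }
  if (10 %in% checks) {
    r <- fig4$runs$isi32
    add(10, "long-term habituation across sessions",
        .pk(r, 2, 1) < .pk(r, 1, 1),
        sprintf("trial-1 peak session 1 = %.3f, session 2 = %.3f",
                .pk(r, 1, 1), .pk(r, 2, 1)))
  }

  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
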