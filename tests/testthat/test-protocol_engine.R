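test_that("a protocol with no events leaves stimuli silent and V untouched", {
  p <- sop_protocol(nodes = list(ctx = std_context(), s = std_stimulus()),
                    sessions = protocol_session(100))
  run <- run_protocol(p)
  ts <- run$timeseries
  expect_true(all(ts$pA1[ts$node == "s"] == 0))
  expect_true(all(ts$V[ts$node == "s"] == 0))
  expect_identical(run$V_final[["s"]], 0)
  expect_identical(nrow(run$summaries), 0L)
  # the context itself still ramps up
  expect_gt(max(ts$pA1[ts$node == "ctx"]), 0.1)

  # with a pre-trained association but no presentations, the context primes
  # the stimulus into A2 without ever evoking A1, and the inhibitory rule
  # slowly extinguishes V (latent extinction)
  p2 <- sop_protocol(nodes = list(ctx = std_context(), s = std_stimulus()),
                     sessions = protocol_session(100), V0 = c(s = 0.3))
  run2 <- run_protocol(p2)
  ts2 <- run2$timeseries
  expect_true(all(ts2$pA1[ts2$node == "s"] == 0))
  expect_gt(max(ts2$pA2[ts2$node == "s"]), 0)
  expect_true(all(diff(ts2$V[ts2$node == "s"]) <= 0))
  expect_lt(run2$V_final[["s"]], 0.3)
})

test_that("self-generated priming halves the second peak at a 32-moment ISI", {
  p <- std_protocol(isi = 32, trials = 2, L_plus = 0, L_minus = 0)
  s <- run_protocol(p, keep_timeseries = FALSE)$summaries
  expect_equal(s$peak_pA1[1], 0.8)
  expect_lt(abs(s$peak_pA1[2] / s$peak_pA1[1] - 0.5), 0.1)
})

test_that("very short ISIs summate before habituating", {
  s <- run_protocol(std_protocol(isi = 2, trials = 4),
                    keep_timeseries = FALSE)$summaries
  expect_gt(s$peak_pA1[2], s$peak_pA1[1])   # transient facilitation
  expect_true(all(diff(s$peak_pA1[2:4]) < 0))  # then decline
})

test_that("the engine matches a straight-line re-implementation to 1e-9", {
  # two sessions of the standard schedule, full learning enabled
  onsets <- 60 + 32 * (0:3)
  run <- run_protocol(std_protocol(isi = 32, trials = 4, sessions = 2,
                                   L_plus = 0.02, L_minus = 4e-4),
                      keep_timeseries = FALSE)
  oracle <- straightline_peaks(2, 300, onsets, Lp = 0.02, Lm = 4e-4)
  got <- t(sapply(1:2, function(k) sapply(1:4, function(i) peak_of(run, k, i))))
  expect_equal(got, oracle, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("sessions communicate only through the associative strengths", {
  p <- std_protocol(isi = 32, trials = 4, sessions = 2)
  run <- run_protocol(p)
  # replay session 2 as a fresh single-session protocol seeded with V after
  # session 1
  v1 <- run$timeseries$V[run$timeseries$node == "s" &
                         run$timeseries$session == 1]
  p2 <- std_protocol(isi = 32, trials = 4, sessions = 1,
                     V0 = c(s = v1[length(v1)]))
  run2 <- run_protocol(p2)
  a <- subset(run$timeseries, session == 2 & node == "s")
  b <- subset(run2$timeseries, session == 1 & node == "s")
  expect_identical(a$pA1, b$pA1)
  expect_identical(a$pA2, b$pA2)
  expect_identical(a$V, b$V)
})

test_that("with learning disabled every session is identical and runs are deterministic", {
  p <- std_protocol(isi = 8, trials = 3, sessions = 3, L_plus = 0, L_minus = 0)
  run <- run_protocol(p)
  ts <- run$timeseries
  s1 <- subset(ts, session == 1, -session)
  s2 <- subset(ts, session == 2, -session)
  s3 <- subset(ts, session == 3, -session)
  rownames(s1) <- rownames(s2) <- rownames(s3) <- NULL
  expect_identical(s1, s2)
  expect_identical(s1, s3)
  # bit-identical repeat run
  expect_identical(run_protocol(p)$timeseries, ts)
})

test_that("malformed protocols are rejected with a diagnostic", {
  nodes <- list(ctx = std_context(), s = std_stimulus())
  expect_error(sop_protocol(nodes, protocol_session(100, list(
    stimulus_event("nope", 10)))), "unknown explicit node")
  expect_error(sop_protocol(nodes, protocol_session(100, list(
    stimulus_event("s", 10, duration = 5),
    stimulus_event("s", 12)))), "overlapping")
  expect_error(sop_protocol(nodes, protocol_session(100, list(
    stimulus_event("s", 99, duration = 5)))), "past the session end")
  expect_error(sop_protocol(list(s = std_stimulus()),
                            protocol_session(100)), "context")
  expect_error(stimulus_event("s", 10, intensity = 1.3), "\\[0, 1\\]")
})

test_that("peak extraction windows match a brute-force maximum", {
  run <- run_protocol(std_protocol(isi = 16, trials = 3))
  ts <- subset(run$timeseries, node == "s" & session == 1)
  onsets <- 60 + 16 * (0:2)
  ends <- c(onsets[-1] - 1, max(ts$moment))
  brute <- mapply(function(a, b) max(ts$pA1[ts$moment >= a & ts$moment <= b]),
                  onsets, ends)
  expect_equal(run$summaries$peak_pA1, unname(brute))
  # single event with monotone decay afterwards peaks at its onset
  one <- run_protocol(std_protocol(isi = 32, trials = 1))
  expect_identical(one$summaries$peak_moment, 60L)
  expect_equal(one$summaries$peak_pA1, 0.8)
  # direct call: rejects a trajectory shorter than the session
  expect_error(extract_peaks(matrix(0, 10, 3,
                                    dimnames = list(NULL, c("pI", "pA1", "pA2"))),
                             list(stimulus_event("s", 5)), 20),
               "cover the session")
})

test_that("response mapping applies the linear weights", {
  st <- activity_state(1 - 0.72 - 0.08, 0.72, 0.08)
  expect_identical(map_response(st, response_rule()), 0.72)
  st2 <- activity_state(0, 0.6, 0.4)
  expect_equal(map_response(st2, response_rule(w2 = -0.5)), 0.4)
  expect_equal(map_response(st2, response_rule(w2 = 0.5)), 0.8)
  expect_error(response_rule(f = "sigmoid"), "unknown response mapping")
  expect_error(response_rule(w1 = Inf), "finite")
})
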