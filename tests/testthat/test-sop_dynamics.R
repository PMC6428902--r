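test_that("a single presentation reproduces the canonical two-step walk-through", {
  r <- effective_rates(p1_eff = 0.8, pd1_eff = 0.1, pd2_eff = 0.02, p2 = 0)
  s1 <- step_node(activity_state(1, 0, 0), r, stimulus_on = TRUE)
  expect_equal(unname(unclass(s1)), c(0.2, 0.8, 0), tolerance = 1e-15)
  s2 <- step_node(s1, r, stimulus_on = FALSE)
  expect_equal(unname(unclass(s2)), c(0.2, 0.72, 0.08), tolerance = 1e-15)
})

test_that("degenerate states are fixed points or pure A2 drainage", {
  r <- effective_rates(p1_eff = 0.8, pd1_eff = 0.1, pd2_eff = 0.02, p2 = 0)
  # all-inactive is a fixed point with the stimulus off
  expect_identical(
    unname(unclass(step_node(activity_state(1, 0, 0), r, FALSE))),
    c(1, 0, 0))
  # with only A2 occupied, pd2 is the only flow: 0.5 * 0.02 returns to I
  s <- step_node(activity_state(0.5, 0, 0.5),
                 effective_rates(0, 0, 0.02, 0), FALSE)
  expect_equal(unname(unclass(s)), c(0.51, 0, 0.49), tolerance = 1e-15)
})

test_that("invalid states and rates are rejected", {
  expect_error(activity_state(0.5, 0.4, 0.3), "equal 1")
  expect_error(activity_state(-0.1, 0.6, 0.5), "\\[0, 1\\]")
  expect_error(effective_rates(1.2, 0, 0, 0), "\\[0, 1\\]")
  expect_error(node_params(0.8, -0.1, 0.02), "pd1")
  expect_error(free_decay_trajectory(activity_state(1, 0, 0),
                                     std_stimulus(), 0), "positive")
})

test_that("conservation holds to 1e-12 for randomized states and rates", {
  set.seed(42)
  for (i in 1:200) {
    x <- stats::rgamma(3, 1)
    x <- x / sum(x)
    st <- activity_state(x[1], x[2], x[3])
    rt <- effective_rates(stats::runif(1), stats::runif(1), stats::runif(1),
                          stats::runif(1))
    nxt <- step_node(st, rt, stimulus_on = i %% 2 == 0)
    expect_lt(abs(sum(nxt) - 1), 1e-12)
    expect_true(all(nxt >= 0 & nxt <= 1))
  }
})

test_that("free decay follows the closed-form geometric A1 decay", {
  on <- step_node(activity_state(1, 0, 0),
                  effective_rates(0.8, 0.1, 0.02), TRUE)
  traj <- free_decay_trajectory(on, std_stimulus(), 250)
  t_after <- 1:250
  expect_equal(traj[, "pA1"], 0.8 * 0.9^t_after, tolerance = 1e-12)
  # strictly decreasing while positive (stimulus off, pd1 > 0)
  expect_true(all(diff(traj[, "pA1"]) < 0))
})

test_that("almost all elements are inactive again by moment 250", {
  on <- step_node(activity_state(1, 0, 0),
                  effective_rates(0.8, 0.1, 0.02), TRUE)
  traj <- free_decay_trajectory(on, std_stimulus(), 400)
  first_inactive <- which(traj[, "pI"] >= 0.99)[1] + 1  # +1: onset is moment 1
  expect_false(is.na(first_inactive))
  expect_lte(first_inactive, 250)
})

test_that("deterministic proportions match an element-level Monte-Carlo chain", {
  # moderate n here; the full-scale comparison runs in the acceptance tests
  n <- 200000L
  moments <- c(5L, 50L, 250L)
  mc <- mc_element_oracle(n, 0.8, 0.1, 0.02, moments, seed = 7)
  on <- step_node(activity_state(1, 0, 0),
                  effective_rates(0.8, 0.1, 0.02), TRUE)
  traj <- free_decay_trajectory(on, std_stimulus(), 250)
  det <- rbind(unclass(on), traj)[moments, c("pA1", "pA2")]
  for (i in seq_along(moments)) for (j in 1:2) {
    p <- det[i, j]
    se <- sqrt(max(p * (1 - p), 1e-8) / n)
    expect_lt(abs(mc[i, c("pA1", "pA2")[j]] - p), 3 * se)
  }
})

test_that("A2 occupancy at the second onset controls priming vs summation", {
  # 32 moments apart: substantial A2 at the second onset -> smaller peak
  run_two <- function(isi) {
    p <- sop_protocol(
      nodes = list(ctx = std_context(), s = std_stimulus()),
      sessions = protocol_session(300, list(stimulus_event("s", 60),
                                            stimulus_event("s", 60 + isi))),
      L_plus = 0, L_minus = 0)
    run_protocol(p, keep_timeseries = FALSE)$summaries$peak_pA1
  }
  pk32 <- run_two(32)
  expect_lt(pk32[2], pk32[1])
  # 1 moment apart: residual A1 sums with the new recruitment -> larger peak
  pk1 <- run_two(1)
  expect_gt(pk1[2], pk1[1])
})
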