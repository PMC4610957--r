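test_that("rate constants are signed log-slopes", {
  # 0.1 -> 1.2 over 3.5 weeks (frozen hand evaluation of ln(12)/2116800)
  expect_rel(rate_constant(phase_d(0.1, 1.2, 24.5)), 1.17389769925737e-06, 1e-12)
  # doubling over t gives rate ln2/t
  p <- phase_d(0.2, 0.4, 10)
  expect_equal(rate_constant(p), log(2) / (10 * DAY))
  # shrink phase: negative rate, half-life from |rate|
  ps <- phase_d(0.15, 0.09, 6)
  expect_rel(rate_constant(ps), -9.85388934733778e-07, 1e-12)
  expect_rel(half_life(ps), 703424.968687326, 1e-12)
  expect_error(rate_constant(phase_d(1, 1, 1)), "static")
})

test_that("doubling time matches the exponential model", {
  expect_rel(doubling_time(phase_d(0.1, 1.2, 24.5)), 590466.427354312, 1e-12)
  expect_equal(doubling_time(phase_d(0.3, 0.6, 1)), DAY)
  # exact doubling over a 24.5-day window
  expect_equal(doubling_time(phase_d(0.1, 0.2, 24.5)), 2116800)
  expect_error(doubling_time(phase_d(0.15, 0.09, 6)), "virtualize")
})

test_that("doubling/half-life times satisfy t * |rate| == ln 2", {
  set.seed(42)
  for (i in 1:50) {
    v0 <- runif(1, 0.05, 2)
    fold <- exp(runif(1, -3, 3))
    if (abs(fold - 1) < 1e-3) next
    p <- phase_d(v0, v0 * fold, runif(1, 1, 60))
    r <- rate_constant(p)
    t_char <- if (fold > 1) doubling_time(p) else half_life(p)
    expect_rel(t_char * abs(r), log(2), 1e-12)
  }
})

test_that("virtualization strategies produce the documented virtual volumes", {
  p13 <- phase_d(0.4, 0.02, 85)
  vh <- virtualize(p13, "half_life_equivalence")
  expect_equal(vh$v_end, 8.0)
  expect_equal(vh$v_start, 0.4)
  expect_equal(vh$duration, p13$duration)
  expect_rel(doubling_time(vh) / DAY, 19.6671481185795, 1e-12)

  expect_equal(virtualize(p13, "reflection")$v_end, 0.78)
  # literal reading: v0 + v0^2 / (v0 - v1)
  expect_equal(virtualize(p13, "literal")$v_end, 0.4 + 0.16 / 0.38)

  grown <- phase_d(0.1, 0.2, 7)
  expect_message(same <- virtualize(grown), "unchanged")
  expect_identical(same, grown)
})

test_that("vanishing shrinkage limits match each strategy's algebra", {
  eps <- 1e-9
  p <- phase_d(0.4, 0.4 - eps, 10)
  # mirrored-change readings: virtual growth vanishes, tD -> infinity
  for (strat in c("half_life_equivalence", "reflection")) {
    v <- virtualize(p, strat)
    expect_lt(abs(v$v_end - 0.4), 1e-6)
    expect_gt(doubling_time(v), 1e10)
  }
  # the literal fraction instead diverges: an infinitesimal shrink fraction
  # demands an unbounded virtual gain, so tD -> 0
  vl <- virtualize(p, "literal")
  expect_gt(vl$v_end, 1e6)
  expect_lt(doubling_time(vl), p$duration / 10)
})

test_that("virtual doubling time equals the shrink half-life (default strategy)", {
  set.seed(7)
  for (i in 1:100) {
    v0 <- runif(1, 0.01, 5)
    v1 <- v0 * exp(-runif(1, 0.01, 4))
    p <- phase_d(v0, v1, runif(1, 0.5, 90))
    v <- virtualize(p, "half_life_equivalence")
    expect_rel(doubling_time(v), half_life(p), 1e-12)
    expect_rel(rate_constant(v), abs(rate_constant(p)), 1e-12)
  }
})

test_that("effective kinetics aggregates phases by time-weighted log change", {
  # single growing phase degenerates to doubling_time
  tr <- traj_d(phase_d(0.1, 1.2, 24.5))
  k <- effective_kinetics(tr)
  expect_equal(k$t_d, doubling_time(tr$phases[[1]]))
  expect_false(k$virtual)

  # shrink-then-grow arm: frozen hand evaluation of the virtualized sum
  tr3 <- parse_phase_string("0.15->0.09@6d;0.09->0.17@8d", arm = "treated")
  k3 <- effective_kinetics(tr3)
  expect_true(k3$virtual)
  expect_rel(k3$rate * DAY, 0.081915313606142, 1e-12)
  expect_rel(k3$t_d / DAY, 8.46175336509941, 1e-12)

  # two identical consecutive phases have the same rate as either alone
  two <- traj_d(phase_d(0.1, 0.2, 7), phase_d(0.2, 0.4, 7))
  expect_rel(effective_kinetics(two)$rate,
             rate_constant(phase_d(0.1, 0.2, 7)), 1e-12)

  expect_error(effective_kinetics(traj_d(phase_d(1, 1, 1))), "static")
})

test_that("effective kinetics recovers the generating rate from dense sampling", {
  # brute-force oracle: sample a noiseless exponential at many points, chop
  # into contiguous phases, and check the aggregated rate
  set.seed(11)
  for (i in 1:20) {
    r <- runif(1, -0.3, 0.3) / DAY
    if (abs(r) < 1e-3 / DAY) next
    v0 <- runif(1, 0.05, 1)
    times <- sort(c(0, runif(19, 0, 40), 40)) * DAY
    vols <- v0 * exp(r * times)
    phases <- lapply(seq_len(length(times) - 1L), function(k)
      volume_phase(vols[k], vols[k + 1L], times[k + 1L] - times[k]))
    k <- effective_kinetics(trajectory(phases))
    expect_rel(k$rate, abs(r), 1e-9)
  }
})

test_that("intraday doubling time is linear in elapsed time", {
  tr <- parse_phase_string("0.1->0.42@24.5d", arm = "treated")
  full <- t_d_intraday(tr, 24.5 * DAY)
  expect_rel(full, 1022416.39844418, 1e-12)
  expect_equal(t_d_intraday(tr, 12.25 * DAY), full / 2)
  for (a in c(0.1, 0.37, 0.5, 0.99, 1)) {
    expect_rel(t_d_intraday(tr, a * 24.5 * DAY), a * full, 1e-12)
  }
  # pure doubling: tD at the window end equals the window
  dbl <- parse_phase_string("0.1->0.2@24.5d")
  expect_equal(t_d_intraday(dbl, 24.5 * DAY), 24.5 * DAY)
  expect_error(t_d_intraday(tr, 0), "must lie")
  expect_error(t_d_intraday(tr, 25 * DAY), "must lie")
})

test_that("intraday doubling time virtualizes shrinking trajectories", {
  tr <- parse_phase_string("0.15->0.09@6d;0.09->0.17@8d", arm = "treated")
  k <- effective_kinetics(tr)
  expect_rel(t_d_intraday(tr, 14 * DAY), k$t_d, 1e-12)
})
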