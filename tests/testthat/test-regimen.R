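test_that("efficiency profile compares intraday doubling time to dosing intervals", {
  rec <- dtec_table1()[[11]]
  spec <- parse_regimen(rec$regimen_text)  # doses at day 0 and day 14
  prof <- efficiency_profile(rec, spec, mode = "to_next_dose")

  expect_equal(prof$per_dose$dose_time_s / DAY, c(0, 14))
  # day-0 dose is not evaluable (tD intraday is 0 by linearity)
  expect_true(is.na(prof$per_dose$efficient[1]))
  # frozen hand evaluation: tD(14 d) = 14 ln2 / ln 4.2 days, < 24.5-day interval
  expect_rel(prof$per_dose$t_d_intraday_s[2] / DAY, 6.76201321722345, 1e-12)
  expect_equal(prof$per_dose$comparison_interval_s[2] / DAY, 24.5)
  expect_false(prof$per_dose$efficient[2])
  expect_identical(prof$verdict, "inefficient")

  from_start <- efficiency_profile(rec, spec, mode = "from_start")
  expect_equal(from_start$per_dose$comparison_interval_s / DAY, c(0, 14))
})

test_that("boundary doses: single dose at span end, and exact doubling counts as efficient", {
  # single dose at the observation end compares to the whole span
  rec <- record_with(parse_phase_string("0.1->0.3@14d", arm = "treated"))
  spec <- regimen_spec(5, 14 * DAY)
  prof <- efficiency_profile(rec, spec, mode = "to_next_dose")
  expect_equal(nrow(prof$per_dose), 1L)
  expect_equal(prof$per_dose$comparison_interval_s, 14 * DAY)

  # exact doubling over the span: tD == span, >= makes it efficient
  rec2 <- record_with(parse_phase_string("0.1->0.2@14d", arm = "treated"))
  prof2 <- efficiency_profile(rec2, spec, mode = "to_next_dose")
  expect_true(prof2$per_dose$efficient[1])
  expect_identical(prof2$verdict, "efficient")
})

test_that("doses beyond the treated span are dropped with a warning", {
  rec <- record_with(parse_phase_string("0.1->0.3@14d", arm = "treated"))
  spec <- regimen_spec(5, c(7, 21) * DAY)
  expect_warning(prof <- efficiency_profile(rec, spec), "dropped")
  expect_equal(nrow(prof$per_dose), 1L)
})

test_that("from_start flags are monotone in dose order for single-phase arms", {
  # both sides of the inequality are linear in t with a fixed ratio, so once
  # a dose is efficient every later one is too
  for (rec in dtec_table1()) {
    spec <- suppressWarnings(parse_regimen(rec$regimen_text,
                                           total_duration(rec$treated)))
    prof <- suppressWarnings(efficiency_profile(rec, spec, mode = "from_start"))
    flags <- prof$per_dose$efficient
    flags <- flags[!is.na(flags)]
    if (length(flags) >= 2L) expect_true(all(diff(flags) >= 0))
  }
})

test_that("steadiness holds for single-phase arms but can fail per-phase", {
  # accelerating regrowth: 0.05/day then 0.20/day over 10 days each
  v1 <- 0.1 * exp(0.5)
  treated <- traj_d(phase_d(0.1, v1, 10), phase_d(v1, v1 * exp(2), 10),
                    arm = "treated")
  rec <- record_with(treated)
  spec <- regimen_spec(5, c(10, 20) * DAY)
  expect_true(steadiness_check(rec, spec, scope = "whole"))
  # frozen: per-phase tD is 13.86 d at day 10 but 6.93 d at day 20
  expect_false(steadiness_check(rec, spec, scope = "phase"))

  single <- record_with(parse_phase_string("0.1->0.42@24.5d", arm = "treated"))
  expect_true(steadiness_check(single, regimen_spec(5, c(7, 14) * DAY),
                               scope = "phase"))
  expect_error(regimen_spec(5, c(14, 7) * DAY), "increasing")
})

test_that("schedules are classified by dose size and dosing gap", {
  recs <- dtec_table1()
  s1 <- parse_regimen(recs[[1]]$regimen_text)   # 0.5 mg/kg thrice weekly
  s11 <- parse_regimen(recs[[11]]$regimen_text) # 15 mg/kg every 2 weeks
  expect_identical(classify_schedule(s1), "metronomic")
  expect_identical(classify_schedule(s11), "standard")
  expect_identical(classify_schedule(regimen_spec(0.5, 0)), "standard")
  # frequent but high-dose stays standard
  expect_identical(classify_schedule(regimen_spec(5, c(0, 3, 6, 9) * DAY)),
                   "standard")
})
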