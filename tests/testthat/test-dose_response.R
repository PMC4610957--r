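test_that("near-identical energies cluster by single linkage", {
  cl <- cluster_identical(c(a = 1.0, b = 1.04, c = 2.0), rel_tol = 0.05)
  expect_length(cl, 2L)
  expect_setequal(names(cl[[1]]), c("a", "b"))
  expect_setequal(names(cl[[2]]), "c")

  expect_length(cluster_identical(c(1, 1, 1)), 1L)
  # chaining: adjacent links merge into one component
  chain <- cluster_identical(c(1, 1.04, 1.08), rel_tol = 0.05)
  expect_length(chain, 1L)
  expect_error(cluster_identical(c(1, 2), rel_tol = 0.6), "rel_tol")
})

test_that("clustering agrees with the transitive closure of the pairwise relation", {
  skip_if_not_installed("igraph")
  set.seed(3)
  for (i in 1:40) {
    n <- sample(2:8, 1)
    x <- exp(runif(n, -1, 1)) * sample(c(1, 1, 1, -1), n, replace = TRUE)
    names(x) <- letters[seq_len(n)]
    tol <- runif(1, 0.02, 0.3)
    adj <- outer(x, x, function(a, b) {
      m <- pmax(abs(a), abs(b))
      ifelse(m == 0, TRUE, abs(a - b) / m <= tol)
    })
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
    oracle <- sort(as.integer(table(comp)), decreasing = TRUE)
    got <- vapply(cluster_identical(x, rel_tol = tol), length, integer(1))
    expect_identical(as.integer(got), oracle)
  }
})

test_that("dose-energy fits recover exact lines and flag two-point fits", {
  pts <- data.frame(dose = c(100, 500, 900, 1300), e_dose = 100 * c(100, 500, 900, 1300))
  m <- fit_dose_energy(pts)
  expect_equal(m$slope, 100)
  expect_equal(m$intercept, 0, tolerance = 1e-9)
  expect_equal(m$pearson_r, 1)
  expect_equal(m$r_squared, m$pearson_r^2)

  m2 <- fit_dose_energy(data.frame(dose = c(1, 2), e_dose = c(3, 1)))
  expect_true(m2$underdetermined)
  expect_equal(abs(m2$pearson_r), 1)
  expect_error(fit_dose_energy(data.frame(dose = c(1, 1), e_dose = c(1, 2))),
               "degenerate")
})

test_that("noiseless synthetic cohorts are recovered to numerical precision", {
  cfg <- cohort_config(n_records = 8, true_slope = 175, true_intercept = 2000,
                       noise_sigma = 0, seed = 1)
  cohort <- simulate_cohort(cfg)
  run <- run_pipeline(cohort$records)
  m <- run$model
  expect_rel(m$slope, 175, 1e-9)
  expect_rel(m$intercept, 2000, 1e-6)
  expect_lt(max(rel_err(run$results$e_dose_emad, cohort$truth$per_record$e_dose)),
            1e-9)
})

test_that("noisy cohorts still recover the slope within 10%", {
  cfg <- cohort_config(n_records = 20, true_slope = 175, noise_sigma = 0.05,
                       seed = 1)
  run <- run_pipeline(simulate_cohort(cfg)$records)
  expect_rel(run$model$slope, 175, 0.10)
})

test_that("response prediction inverts the energy bookkeeping", {
  m <- fit_dose_energy(data.frame(dose = c(400, 840), e_dose = c(70000, 147000)),
                       through_origin = TRUE)
  td <- 7 * DAY
  # dose 0 adds no energy
  expect_equal(predict_response(m, td, 1e6, 0)$predicted_t_d, td)
  # an energy increment equal to the gap between the control energy and the
  # energy of twice the doubling time predicts exactly twice the doubling time
  gap <- growth_energy(2 * td) - growth_energy(td)
  m1 <- structure(list(slope = gap * 1e6, intercept = 0,
                       through_origin = TRUE),
                  class = "dose_energy_model")
  expect_rel(predict_response(m1, td, 1e6, 1)$predicted_t_d, 2 * td, 1e-9)
  # fold change over one predicted doubling time is 2
  td_pred <- predict_response(m, td, 1e6, 840)$predicted_t_d
  expect_equal(predict_response(m, td, 1e6, 840, horizon = td_pred)$fold_change, 2)
})

test_that("a model fit on the 840-dose trio predicts the SKOV3ip1 response", {
  recs <- dtec_table1()
  trio <- recs[7:9]
  pts <- data.frame(dose = vapply(trio, `[[`, numeric(1), "dose_ug_per_ml"),
                    e_dose = vapply(trio, function(r) dose_energy(r)$e_dose_emad,
                                    numeric(1)))
  m <- fit_dose_energy(pts, through_origin = TRUE)
  k9 <- effective_kinetics(recs[[9]]$control)
  pred <- predict_response(m, k9$t_d, recs[[9]]$inoculum, 840)
  observed <- effective_kinetics(recs[[9]]$treated)$t_d
  expect_equal(observed, 2116800)
  expect_rel(pred$predicted_t_d, observed, 0.05)
})

test_that("prediction is the exact inverse of dose_energy on an interpolating model", {
  rec <- dtec_table1()[[8]]
  de <- dose_energy(rec)
  m <- structure(list(slope = de$e_dose_emad / rec$dose_ug_per_ml, intercept = 0,
                      through_origin = TRUE),
                 class = "dose_energy_model")
  pred <- predict_response(m, de$control_t_d, rec$inoculum, rec$dose_ug_per_ml)
  expect_rel(pred$predicted_t_d, de$treated_t_d, 1e-12)
})

test_that("the dose column tracks 28 x cumulative mg/kg except in one row", {
  recs <- dtec_table1()
  audit_one <- function(i) {
    spec <- suppressWarnings(parse_regimen(recs[[i]]$regimen_text,
                                           total_duration(recs[[i]]$treated)))
    audit_dose_column(recs[[i]], spec)
  }
  a2 <- audit_one(2)
  expect_equal(a2$cumulative_mg_kg, 14)
  expect_equal(a2$expected_ug_per_ml, 392)
  expect_true(a2$consistent)

  a6 <- audit_one(6)
  expect_equal(a6$expected_ug_per_ml, 649.6)
  expect_true(a6$consistent)

  a12 <- audit_one(12)
  expect_equal(a12$cumulative_mg_kg, 90)
  expect_equal(a12$expected_ug_per_ml, 2520)
  expect_false(a12$consistent)

  flags <- vapply(1:14, function(i) audit_one(i)$consistent, logical(1))
  expect_equal(sum(flags), 13L)
  expect_false(flags[12])
})
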