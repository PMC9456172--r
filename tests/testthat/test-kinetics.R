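test_that("kinetics recovery on the reference simulation", {
  params <- simulation_params(seed = 101, n_cells = 5000)
  est <- estimate_cycle_kinetics(labelled_timecourse(params))
  expect_gt(est$T_S_h, 4)
  expect_lt(est$T_S_h, 5)
  expect_gt(est$T_cycle_h, 13)
  expect_lt(est$T_cycle_h, 15)
  expect_gt(est$T_G2M_h, 2.5)
  expect_lt(est$T_G2M_h, 4.5)
})

test_that("recovery holds across seeds and for a slower cycle", {
  for (s in c(102, 103)) {
    est <- estimate_cycle_kinetics(
      labelled_timecourse(simulation_params(seed = s, n_cells = 5000)))
    expect_lt(abs(est$T_cycle_h - 14), 1)
    expect_lt(abs(est$T_S_h - 4.5), 0.5)
  }
  slow <- simulation_params(T_G1_h = 7, T_S_h = 5, T_G2M_h = 3,
                            chase_times_h = 0:22, seed = 104, n_cells = 5000)
  est <- estimate_cycle_kinetics(labelled_timecourse(slow))
  expect_lt(abs(est$T_cycle_h - 15), 1)
  expect_lt(abs(est$T_S_h - 5), 0.6)
})

test_that("a G2 block leaves the cycle duration undetermined, not wrong", {
  params <- simulation_params(seed = 105, n_cells = 2000,
                              arrest = list(g2_block = TRUE))
  est <- estimate_cycle_kinetics(labelled_timecourse(params))
  # no cell divides, so EdU+ cells never re-appear in 2N
  expect_true(is.na(est$T_cycle_h))
  expect_true(is.na(est$T_S_h))
})

test_that("a per-time list input is bound by its names", {
  params <- simulation_params(seed = 106, n_cells = 3000)
  lab <- labelled_timecourse(params)
  by_time <- split(lab[, setdiff(names(lab), "chase_time_h")], lab$chase_time_h)
  est_list <- estimate_cycle_kinetics(by_time)
  est_tbl <- estimate_cycle_kinetics(lab)
  expect_equal(est_list$T_cycle_h, est_tbl$T_cycle_h)
  expect_equal(est_list$T_S_h, est_tbl$T_S_h)

  names(by_time)[2] <- "0"  # duplicate time
  expect_error(estimate_cycle_kinetics(by_time), "unordered or duplicate",
               class = "focimetry_error")
})

test_that("input contracts are enforced", {
  params <- simulation_params(seed = 107, n_cells = 500,
                              chase_times_h = c(0, 5))
  lab <- labelled_timecourse(params)
  expect_error(estimate_cycle_kinetics(lab), "at least 3",
               class = "focimetry_error")
  sim2 <- simulate_pulse_chase(simulation_params(seed = 107, n_cells = 500,
                                                 chase_times_h = c(1, 2, 3)))
  lab2 <- classify_cell_cycle(sim2$cells, edu_threshold = 0.02)
  expect_error(estimate_cycle_kinetics(lab2), "t = 0",
               class = "focimetry_error")
  lab3 <- labelled_timecourse(simulation_params(seed = 107, n_cells = 500,
                                                chase_times_h = 0:3))
  expect_error(estimate_cycle_kinetics(lab3, q_lo = 0.3, q_s = c(0.2, 0.6)),
               class = "focimetry_error")
})
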