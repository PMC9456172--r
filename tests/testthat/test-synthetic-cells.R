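test_that("EdU content is exactly halved at each division with noise off", {
  params <- simulation_params(noise_cv = c(dna = 0, edu = 0),
                              n_cells = 3000, chase_times_h = c(0, 10, 20),
                              seed = 61)
  sim <- simulate_pulse_chase(params)
  tr <- sim$truth
  t0 <- tr[tr$chase_time_h == 0, ]
  for (t in c(10, 20)) {
    tt <- tr[tr$chase_time_h == t, ]
    expect_identical(tt$cell_id, t0$cell_id)
    expect_identical(tt$edu_true, t0$edu_true / 2^tt$n_divisions)
    # measured values equal true values when noise is off
    mt <- sim$cells[sim$cells$chase_time_h == t, ]
    expect_identical(mt$edu_total, tt$edu_true)
    expect_identical(mt$dna_total, tt$dna_true)
  }
  # cells that divided once carry exactly half their initial label
  tt10 <- tr[tr$chase_time_h == 10, ]
  once <- tt10$n_divisions == 1L & t0$edu_true > 0
  expect_gt(sum(once), 0)
  expect_identical(tt10$edu_true[once], t0$edu_true[once] / 2)
})

test_that("the simulation is bit-identical given a seed", {
  p <- simulation_params(seed = 62, n_cells = 500, chase_times_h = 0:3)
  a <- simulate_pulse_chase(p)
  b <- simulate_pulse_chase(p)
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth, b$truth)
  c <- simulate_pulse_chase(simulation_params(seed = 63, n_cells = 500,
                                              chase_times_h = 0:3))
  expect_false(identical(a$cells$dna_total, c$cells$dna_total))
})

test_that("DNA content follows the phase model", {
  p <- simulation_params(noise_cv = c(dna = 0, edu = 0), n_cells = 2000,
                         chase_times_h = 0, seed = 64)
  sim <- simulate_pulse_chase(p)
  tr <- sim$truth
  expect_true(all(tr$dna_true[tr$phase == "G1"] == 2))
  expect_true(all(tr$dna_true[tr$phase == "G2M"] == 4))
  s <- tr[tr$phase == "S", ]
  expect_true(all(s$dna_true >= 2 & s$dna_true <= 4))
  # DNA in S is linear in cycle position
  expect_equal(s$dna_true, 2 * (1 + (s$cycle_pos_h - p$T_G1_h) / p$T_S_h),
               tolerance = 1e-12)
})

test_that("only cells in S during the pulse are labelled", {
  p <- simulation_params(noise_cv = c(dna = 0, edu = 0), n_cells = 2000,
                         chase_times_h = 0, seed = 65)
  sim <- simulate_pulse_chase(p)
  tr <- sim$truth
  # the pulse is short: labelled cells were in S at t=0 or just exited
  lab <- tr$edu_true > 0
  in_window <- tr$cycle_pos_h > p$T_G1_h &
    tr$cycle_pos_h < p$T_G1_h + p$T_S_h + p$pulse_duration_h
  expect_true(all(in_window[lab]))
  # every cell strictly inside S at t=0 is labelled
  strict_s <- tr$phase == "S"
  expect_true(all(lab[strict_s]))
  # labelled fraction ~ (T_S + pulse) / T_cycle for a uniform cohort
  expect_equal(mean(lab), (p$T_S_h + p$pulse_duration_h) / 14, tolerance = 0.05)
})

test_that("a pulse longer than G2M is rejected", {
  expect_error(simulation_params(pulse_duration_h = 4, T_G2M_h = 3.5),
               "pulse", class = "focimetry_error")
  expect_error(simulation_params(chase_times_h = c(0, 2, 1)),
               class = "focimetry_error")
})

test_that("checkpoint arrest shapes the cohort as modelled", {
  pb <- simulation_params(noise_cv = c(dna = 0, edu = 0), n_cells = 2000,
                          chase_times_h = c(0, 20),
                          arrest = list(g1_block_fraction = 1), seed = 66)
  sim <- simulate_pulse_chase(pb)
  tr20 <- sim$truth[sim$truth$chase_time_h == 20, ]
  # blocked G1 cells never move or divide
  blocked <- tr20$g1_blocked
  expect_true(all(tr20$phase[blocked] == "G1"))
  expect_true(all(tr20$n_divisions[blocked] == 0L))
})
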