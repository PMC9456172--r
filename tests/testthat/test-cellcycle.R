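test_that("the six labels partition a full-coverage noise-free population", {
  # one cell at every DNA x EdU corner of each window, noise off
  p <- 100
  dna <- p * c(0.8, 1.0, 1.2, 1.3, 1.5, 1.6, 2.0, 2.4)
  tb <- tibble::tibble(dna_total = rep(dna, 2),
                       edu_total = rep(c(1, 0), each = length(dna)))
  out <- classify_cell_cycle(tb, edu_threshold = 0.5, dna_ref_2n = p)
  expect_true(all(out$cycle_label %in% cycle_labels()))
  # each of the six populations is hit
  expect_setequal(unique(out$cycle_label), cycle_labels())
  # windows: [0.8, 1.2] -> 2N, (1.2, 1.6) -> midN, [1.6, 2.4] -> 4N
  lab_pos <- out$cycle_label[seq_along(dna)]
  expect_identical(lab_pos,
                   c("2N+", "2N+", "2N+", "midN+", "midN+", "4N+", "4N+", "4N+"))
})

test_that("window edges are assigned exactly as documented", {
  p <- 50
  tb <- tibble::tibble(dna_total = p * c(0.8, 1.2, 1.6, 2.4, 0.799, 2.401),
                       edu_total = 0)
  out <- classify_cell_cycle(tb, edu_threshold = 0.5, dna_ref_2n = p)
  expect_identical(out$cycle_label,
                   c("2N-", "2N-", "4N-", "4N-", "unassigned", "unassigned"))
})

test_that("NA measurements are labelled unassigned, never dropped", {
  tb <- tibble::tibble(dna_total = c(100, NA, 120), edu_total = c(1, 1, NA))
  out <- classify_cell_cycle(tb, edu_threshold = 0.5, dna_ref_2n = 100)
  expect_identical(nrow(out), 3L)
  expect_identical(out$cycle_label[2:3], c("unassigned", "unassigned"))
})

test_that("the Otsu EdU split separates a clean positive mode", {
  set.seed(51)
  neg <- runif(200, 0, 0.01)
  pos <- runif(200, 1.5, 2.5)
  tb <- tibble::tibble(dna_total = rep(100, 400), edu_total = c(neg, pos))
  out <- classify_cell_cycle(tb, dna_ref_2n = 100)
  expect_identical(out$edu_positive, rep(c(FALSE, TRUE), each = 200))
  # the automatic threshold falls inside the gap between the two modes
  thr <- attr(out, "edu_threshold")
  expect_gt(thr, max(neg))
  expect_lt(thr, min(pos))
})

test_that("classification agrees with simulator truth when noise is off", {
  params <- simulation_params(noise_cv = c(dna = 0, edu = 0), n_cells = 2000,
                              chase_times_h = c(0, 5, 10), seed = 7)
  sim <- simulate_pulse_chase(params)
  out <- classify_cell_cycle(sim$cells, edu_threshold = 0, dna_ref_2n = 2)
  expect_identical(out$cycle_label, sim$truth$true_label)
})

test_that("population_fractions sums to one over assigned labels", {
  params <- simulation_params(n_cells = 1000, chase_times_h = c(0, 4, 8), seed = 8)
  lab <- labelled_timecourse(params)
  fr <- population_fractions(lab)
  sums <- fr |>
    dplyr::filter(.data$cycle_label != "unassigned") |>
    dplyr::group_by(.data$chase_time_h) |>
    dplyr::summarise(s = sum(.data$fraction), .groups = "drop")
  expect_equal(sums$s, rep(1, 3), tolerance = 1e-12)
  # uniform age structure: expected fractions proportional to durations
  t0 <- fr[fr$chase_time_h == 0, ]
  f2n_neg <- t0$fraction[t0$cycle_label == "2N-"]
  expect_gt(f2n_neg, 0.30)
})
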