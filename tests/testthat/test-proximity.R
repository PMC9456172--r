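test_that("association matches the brute-force oracle on random scenes", {
  for (s in 1:20) {
    sc <- synth_pla_scene(n_cells = 8, seed = s)
    res <- associate_spots_to_foci(sc$spots, sc$foci, threshold_um = 1)
    orc <- oracle_nearest(sc$spots, sc$foci)
    got <- res$spots[match(orc$spot_id, res$spots$spot_id), ]
    expect_identical(got$nearest_focus_id, orc$nearest)
    expect_equal(got$distance_um, orc$distance, tolerance = 1e-12)
    expect_identical(got$adjacent,
                     !is.na(orc$distance) & orc$distance <= 1)
  }
})

test_that("association matches the generator's planted truth", {
  sc <- synth_pla_scene(n_cells = 10, seed = 99)
  res <- associate_spots_to_foci(sc$spots, sc$foci, threshold_um = 1)
  got <- res$spots[match(sc$truth$spot_id, res$spots$spot_id), ]
  expect_identical(got$nearest_focus_id, sc$truth$nearest_focus_id)
  expect_equal(got$distance_um, sc$truth$distance_um, tolerance = 1e-12)
  expect_identical(got$adjacent, sc$truth$distance_um <= 1)
  # the true nearest focus can be closer than the planted anchor, never farther
  expect_true(all(sc$truth$distance_um <= sc$truth$planted_offset_um + 1e-12))
})

test_that("adjacency is monotone in the threshold", {
  sc <- synth_pla_scene(n_cells = 12, seed = 7)
  counts <- vapply(c(0.25, 0.5, 1, 2, 4), function(thr) {
    sum(associate_spots_to_foci(sc$spots, sc$foci, thr)$spots$adjacent)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  # large enough threshold captures every spot in a cell with foci
  all_in <- associate_spots_to_foci(sc$spots, sc$foci, 1e6)$spots
  expect_identical(all_in$adjacent, !is.na(all_in$distance_um))
})

test_that("the threshold is inclusive and defaults to 1 um", {
  foci <- tibble::tibble(focus_id = "f1", cell_id = "c1", x_um = 0, y_um = 0)
  spots <- tibble::tibble(spot_id = c("s1", "s2", "s3"), cell_id = "c1",
                          x_um = c(1, 1.0000001, 0.5), y_um = 0)
  res <- associate_spots_to_foci(spots, foci)
  expect_identical(res$threshold_um, 1)
  expect_identical(res$spots$adjacent[match(c("s1", "s2", "s3"),
                                            res$spots$spot_id)],
                   c(TRUE, FALSE, TRUE))
})

test_that("cells without foci give NA distances and appear in per_cell", {
  foci <- tibble::tibble(focus_id = "f1", cell_id = "c1", x_um = 0, y_um = 0)
  spots <- tibble::tibble(spot_id = c("s1", "s2"), cell_id = c("c1", "c2"),
                          x_um = 0.5, y_um = 0)
  res <- associate_spots_to_foci(spots, foci)
  s2 <- res$spots[res$spots$spot_id == "s2", ]
  expect_true(is.na(s2$distance_um))
  expect_false(s2$adjacent)
  pc <- res$per_cell
  expect_setequal(pc$cell_id, c("c1", "c2"))
  # a focus-only cell with no spots still appears, with NA fraction
  res2 <- associate_spots_to_foci(spots[1, ], foci)
  foci2 <- dplyr::bind_rows(foci, tibble::tibble(focus_id = "f2",
                                                 cell_id = "c9",
                                                 x_um = 5, y_um = 5))
  res3 <- associate_spots_to_foci(spots[1, ], foci2)
  c9 <- res3$per_cell[res3$per_cell$cell_id == "c9", ]
  expect_identical(c9$n_spots, 0L)
  expect_true(is.na(c9$frac_adjacent))
})

test_that("pearson_correlation matches stats::cor and enforces contracts", {
  set.seed(71)
  tb <- tibble::tibble(a = rnorm(100), b = rnorm(100))
  tb$b <- tb$a * 0.6 + tb$b
  r <- pearson_correlation(tb, "a", "b")
  expect_equal(r$r, stats::cor(tb$a, tb$b), tolerance = 1e-12)
  expect_identical(r$n, 100L)
  tb$a[5] <- NA
  r2 <- pearson_correlation(tb, "a", "b")
  expect_equal(r2$r, stats::cor(tb$a, tb$b, use = "complete.obs"),
               tolerance = 1e-12)
  expect_identical(r2$n, 99L)
  expect_error(pearson_correlation(tb, "a", "nope"), "unknown column",
               class = "focimetry_error")
  expect_error(pearson_correlation(tibble::tibble(a = 1:5, b = rep(2, 5)),
                                   "a", "b"), "zero variance",
               class = "focimetry_error")
  expect_error(pearson_correlation(tibble::tibble(a = 1:2, b = 2:3), "a", "b"),
               "at least 3", class = "focimetry_error")
})

test_that("median_split_compare sends ties below and summarises both groups", {
  tb <- tibble::tibble(s = c(1, 2, 2, 3, 4), v = c(10, 20, 30, 40, 50))
  res <- median_split_compare(tb, "s", "v")
  # median(s) = 2; ties (both 2s) go below
  expect_identical(nrow(res$below), 3L)
  expect_identical(nrow(res$above), 2L)
  expect_equal(res$summary$mean_below, 20)
  expect_equal(res$summary$mean_above, 45)
  expect_identical(tidy(res), res$summary)
  expect_error(median_split_compare(tibble::tibble(s = rep(1, 6), v = 1:6),
                                    "s", "v"), "constant",
               class = "focimetry_error")
  expect_error(median_split_compare(tb[1:3, ], "s", "v"), "at least 4",
               class = "focimetry_error")
})
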