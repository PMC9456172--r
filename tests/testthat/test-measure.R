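test_that("per-cell photometry matches the planted photon budget", {
  res <- analyse_scene(seed = 41, n_nuclei = 4, correct = FALSE)
  expect_false(anyNA(res$match))
  tr <- res$truth
  got <- res$cells[res$match, ]
  # area within the pixelation tolerance of the planted ellipse
  expect_equal(got$area_um2, tr$area_um2, tolerance = 0.08)
  # DNA integrated intensity = planted photons + background * area (Poisson noise)
  bg <- res$scene$spec$background
  expected <- tr$dna_photons + bg * tr$area_px
  expect_equal(got$dna_total, expected, tolerance = 0.05)
})

test_that("focus counts and centroids match ground truth", {
  for (s in c(42, 43)) {
    res <- analyse_scene(seed = s, n_nuclei = 4)
    expect_false(anyNA(res$match))
    got <- res$cells[res$match, ]
    expect_identical(as.integer(got$n_foci_gh2ax), res$truth$n_foci_gh2ax)
  }
})

test_that("foci_fraction tracks the planted photon fraction within 0.05", {
  errs <- unlist(lapply(c(44, 45, 46), function(s) {
    res <- analyse_scene(seed = s, n_nuclei = 4)
    got <- res$cells[res$match, ]
    foci_fraction(got, "gH2AX") - res$truth$photon_fraction_gh2ax
  }))
  expect_lt(max(abs(errs)), 0.05)
})

test_that("the measurement collar increases integrated focus intensity", {
  res <- analyse_scene(seed = 47, n_nuclei = 3)
  dna <- correct_illumination(res$scene$images$DNA)
  ch <- correct_illumination(res$scene$images$gH2AX)
  base_cells <- measure_cells(res$nuclei, list(dna, ch))
  bare <- measure_foci(res$foci, res$nuclei, ch, base_cells,
                       measure_dilate_px = 0L)
  expect_true(all(res$focus_table$integrated_intensity >=
                    bare$foci$integrated_intensity))
  expect_true(all(res$focus_table$measured_area_um2 >=
                    res$focus_table$area_um2))
  # undilated run reports measured area equal to the core area
  expect_equal(bare$foci$measured_area_um2, bare$foci$area_um2)
})

test_that("cells without foci get zero aggregates, not NA", {
  md <- acquisition_metadata(width_px = 64, height_px = 64, pixel_size_um = 0.2,
                             field_id = "f00")
  lab <- matrix(0L, 64, 64)
  lab[which(focimetry:::ellipse_mask(64, 64, 30, 30, 12, 12, 0))] <- 1L
  nuc <- label_mask(lab, "nucleus", 0.2)
  img <- channel_image(matrix(10, 64, 64), "gH2AX", md)
  cells <- measure_cells(nuc, list(img))
  empty_foci <- label_mask(matrix(0L, 64, 64), "focus", 0.2, "gH2AX",
                           parent_map = integer())
  mf <- measure_foci(empty_foci, nuc, img, cells)
  expect_identical(mf$cells$n_foci_gh2ax, 0L)
  expect_identical(mf$cells$foci_total_gh2ax, 0)
  expect_identical(mf$cells$foci_fraction_gh2ax, 0)
  expect_identical(nrow(mf$foci), 0L)
})

test_that("measurements are invariant to which other nuclei are present", {
  # measuring is per-label: removing one nucleus must not change the others
  res <- analyse_scene(seed = 48, n_nuclei = 3)
  lab <- res$nuclei$labels
  lab2 <- focimetry:::relabel_sequential(lab, drop = 1L)
  nuc2 <- label_mask(lab2, "nucleus", res$nuclei$pixel_size_um)
  dna <- correct_illumination(res$scene$images$DNA)
  ch <- correct_illumination(res$scene$images$gH2AX)
  c_all <- measure_cells(res$nuclei, list(dna, ch))
  c_sub <- measure_cells(nuc2, list(dna, ch))
  expect_equal(c_sub$area_um2, c_all$area_um2[-1])
  expect_equal(c_sub$dna_total, c_all$dna_total[-1])
  expect_equal(c_sub$x_px, c_all$x_px[-1])
})
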