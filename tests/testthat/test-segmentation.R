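test_that("segment_nuclei recovers the planted nucleus count", {
  for (s in c(21, 22, 23)) {
    sc <- synth_microscopy_scene(random_scene_spec(n_nuclei = 4, seed = s))
    nuc <- segment_nuclei(correct_illumination(sc$images$DNA),
                          min_area_um2 = 10, max_area_um2 = 100)
    expect_identical(max(nuc$labels), nrow(sc$truth$nuclei))
  }
})

test_that("blank (noise-only) images yield an empty mask, not noise objects", {
  md <- acquisition_metadata(width_px = 64, height_px = 64, pixel_size_um = 0.2)
  set.seed(31)
  blank <- channel_image(matrix(abs(rnorm(64 * 64, 10, 2)), 64, 64), "DNA", md)
  nuc <- segment_nuclei(blank)
  expect_identical(max(nuc$labels), 0L)
  flat <- channel_image(matrix(7, 64, 64), "DNA", md)
  expect_identical(max(segment_nuclei(flat)$labels), 0L)
})

test_that("border handling flags or drops edge-touching nuclei", {
  md <- acquisition_metadata(width_px = 96, height_px = 96, pixel_size_um = 0.2)
  px <- matrix(5, 96, 96)
  # one interior disc, one disc hanging off the left edge
  for (ij in which(focimetry:::ellipse_mask(96, 96, 60, 60, 12, 12, 0))) px[ij] <- px[ij] + 120
  for (ij in which(focimetry:::ellipse_mask(96, 96, 2, 40, 12, 12, 0))) px[ij] <- px[ij] + 120
  # a tiny ramp breaks the flat plateau so the saturation heuristic stays quiet
  px <- px + matrix(seq(0, 1, length.out = 96 * 96), 96)
  img <- channel_image(px, "DNA", md)
  keep <- segment_nuclei(img, min_area_um2 = 2, max_area_um2 = 100, border = "keep")
  expect_identical(max(keep$labels), 2L)
  expect_length(keep$border_labels, 1L)
  drop <- segment_nuclei(img, min_area_um2 = 2, max_area_um2 = 100, border = "drop")
  expect_identical(max(drop$labels), 1L)
  expect_length(drop$border_labels, 0L)
})

test_that("the area filter removes out-of-window objects", {
  md <- acquisition_metadata(width_px = 96, height_px = 96, pixel_size_um = 0.2)
  px <- matrix(5, 96, 96)
  for (ij in which(focimetry:::ellipse_mask(96, 96, 30, 30, 14, 14, 0))) px[ij] <- px[ij] + 120
  for (ij in which(focimetry:::ellipse_mask(96, 96, 70, 70, 4, 4, 0))) px[ij] <- px[ij] + 120
  px <- px + matrix(seq(0, 1, length.out = 96 * 96), 96)
  img <- channel_image(px, "DNA", md)
  both <- segment_nuclei(img, min_area_um2 = 0.5, max_area_um2 = 100)
  expect_identical(max(both$labels), 2L)
  big_only <- segment_nuclei(img, min_area_um2 = 10, max_area_um2 = 100)
  expect_identical(max(big_only$labels), 1L)
  small_only <- segment_nuclei(img, min_area_um2 = 0.5, max_area_um2 = 5)
  expect_identical(max(small_only$labels), 1L)
  none <- segment_nuclei(img, min_area_um2 = 0.1, max_area_um2 = 0.5)
  expect_identical(max(none$labels), 0L)
})

test_that("focus pixels are a subset of their parent nucleus", {
  sc <- synth_microscopy_scene(random_scene_spec(n_nuclei = 4, seed = 24))
  nuc <- segment_nuclei(correct_illumination(sc$images$DNA),
                        min_area_um2 = 10, max_area_um2 = 100)
  foci <- segment_foci(correct_illumination(sc$images$gH2AX), nuc,
                       focus_params(tophat_radius_um = 1.2, k_sigma = 3,
                                    min_area_um2 = 0.15, max_area_um2 = 20))
  expect_gt(max(foci$labels), 0L)
  idx <- which(foci$labels > 0L)
  expect_true(all(nuc$labels[idx] > 0L))
  # every focus pixel lies in the nucleus recorded as its parent
  expect_true(all(nuc$labels[idx] ==
                    unname(foci$parent_map[foci$labels[idx]])))
  # parent labels are valid nuclei
  expect_true(all(foci$parent_map %in% seq_len(max(nuc$labels))))
})

test_that("segment_foci with no nuclei returns an empty focus mask", {
  md <- acquisition_metadata(width_px = 32, height_px = 32, pixel_size_um = 0.2)
  img <- channel_image(matrix(5, 32, 32), "gH2AX", md)
  empty_nuc <- label_mask(matrix(0L, 32, 32), "nucleus", 0.2)
  foci <- segment_foci(img, empty_nuc)
  expect_identical(max(foci$labels), 0L)
  expect_length(foci$parent_map, 0L)
})

test_that("focus_params validates its window", {
  expect_error(focus_params(min_area_um2 = 2, max_area_um2 = 1),
               class = "focimetry_error")
  expect_error(focus_params(tophat_radius_um = 0), class = "focimetry_error")
})
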