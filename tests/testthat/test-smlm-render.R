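test_that("rendering conserves total mass", {
  pat <- synth_localization_patterns(200, 200, 0.5, seed = 81)
  img <- render_localizations(pat$red, pixel_size_nm = 20, sigma_mode = "fixed",
                              sigma_nm = 50)
  # default bounds pad by 3 sigma, so essentially all mass is captured
  expect_equal(sum(img$pixels), 200, tolerance = 1e-4)
  # precision mode conserves mass too
  img2 <- render_localizations(pat$red, 20, "precision")
  expect_equal(sum(img2$pixels), 200, tolerance = 1e-4)
  # mass is independent of the pixel size
  img3 <- render_localizations(pat$red, 7.5, "fixed", sigma_nm = 50)
  expect_equal(sum(img3$pixels), 200, tolerance = 1e-4)
})

test_that("rendering is linear in the localization table", {
  pat <- synth_localization_patterns(150, 150, 0, seed = 82)
  b <- c(0, pat$domain_nm, 0, pat$domain_nm)
  both <- dplyr::bind_rows(pat$red, pat$green)
  ra <- render_localizations(pat$red, 25, "fixed", sigma_nm = 60, bounds_nm = b)
  rb <- render_localizations(pat$green, 25, "fixed", sigma_nm = 60, bounds_nm = b)
  rab <- render_localizations(both, 25, "fixed", sigma_nm = 60, bounds_nm = b)
  expect_equal(rab$pixels, ra$pixels + rb$pixels, tolerance = 1e-12)
})

test_that("a single molecule renders at the right place with the right width", {
  loc <- tibble::tibble(x_nm = 500, y_nm = 300, precision_nm = 40)
  img <- render_localizations(loc, 10, "fixed", sigma_nm = 40,
                              bounds_nm = c(0, 1000, 0, 600))
  px <- img$pixels
  # the kernel is truncated at 5 sigma, so mass is exact to ~1e-6
  expect_equal(sum(px), 1, tolerance = 1e-5)
  peak <- which(px == max(px), arr.ind = TRUE)
  # x = 500 nm -> grid coordinate 50 -> brightest pixels straddle column 50
  expect_true(peak[1, "col"] %in% c(50, 51))
  expect_true(peak[1, "row"] %in% c(30, 31))
  # second moment of the rendered spot ~ sigma^2 + pixelation variance
  cc <- col(px); est_var <- sum(px * (cc - 0.5 - 50)^2) * 10^2
  expect_equal(sqrt(est_var), sqrt(40^2 + 10^2 / 12), tolerance = 0.02)
})

test_that("the sigma floor prevents sub-pixel spots from vanishing", {
  loc <- tibble::tibble(x_nm = 105, y_nm = 105, precision_nm = 1)
  img <- render_localizations(loc, 50, "precision",
                              bounds_nm = c(-200, 400, -200, 400))
  # sigma would be 0.02 px; floored at 1 px (50 nm) the mass spreads but is
  # conserved
  expect_equal(sum(img$pixels), 1, tolerance = 1e-5)
  expect_gt(sum(img$pixels > 1e-4), 4)
})

test_that("an empty table warns and renders a zero image", {
  empty <- tibble::tibble(x_nm = numeric(), y_nm = numeric(),
                          precision_nm = numeric())
  expect_warning(img <- render_localizations(empty, 20, "fixed", sigma_nm = 30),
                 "empty")
  expect_identical(sum(img$pixels), 0)
  expect_identical(img$n_locs, 0L)
})

test_that("rendering contracts are enforced", {
  loc <- tibble::tibble(x_nm = 1, y_nm = 1)
  expect_error(render_localizations(loc, 20, "precision"),
               "precision_nm", class = "focimetry_error")
  expect_error(render_localizations(loc, 20, "fixed"), "sigma_nm",
               class = "focimetry_error")
  expect_error(render_localizations(loc, -5, "fixed", sigma_nm = 10),
               class = "focimetry_error")
  expect_error(render_localizations(loc, 20, "fixed", sigma_nm = 10,
                                    bounds_nm = c(0, 0, 0, 1)),
               class = "focimetry_error")
})
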