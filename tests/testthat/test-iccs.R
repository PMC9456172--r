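test_that("self-colocalization is 1 within 0.02", {
  pat <- synth_localization_patterns(2000, 2000, 0, seed = 91)
  r <- render_pattern_pair(pat)$r
  res <- iccs_global(r, r)
  expect_equal(res$f, 1, tolerance = 0.02)
  expect_equal(unname(res$f_all["volume"]), 1, tolerance = 0.02)
})

test_that("the CSR null gives near-zero colocalization", {
  fs <- vapply(92:96, function(s) {
    pair <- render_pattern_pair(synth_localization_patterns(2000, 2000, 0,
                                                            seed = s))
    iccs_global(pair$r, pair$g)$f
  }, numeric(1))
  expect_lt(mean(fs), 0.05)
  expect_lt(max(fs), 0.10)
})

test_that("planted fractions are recovered across the range", {
  for (f in c(0.3, 0.7, 1.0)) {
    errs <- vapply(97:99, function(s) {
      pair <- render_pattern_pair(synth_localization_patterns(2000, 2000, f,
                                                              seed = s))
      iccs_global(pair$r, pair$g)$f - f
    }, numeric(1))
    expect_lt(mean(abs(errs)), 0.05)
  }
})

test_that("the estimate is invariant to intensity rescaling", {
  pair <- render_pattern_pair(synth_localization_patterns(2000, 2000, 0.5,
                                                          seed = 100))
  a <- iccs_global(pair$r$pixels, pair$g$pixels)
  b <- iccs_global(7.3 * pair$r$pixels, 0.2 * pair$g$pixels)
  expect_equal(a$f, b$f, tolerance = 1e-6)
})

test_that("the volume estimator tolerates channel jitter", {
  pat <- synth_localization_patterns(2000, 2000, 0.7, jitter_nm = 30,
                                     seed = 101)
  pair <- render_pattern_pair(pat, sigma_nm = 80)
  res <- iccs_global(pair$r, pair$g, estimator = "volume")
  expect_equal(res$f, 0.7, tolerance = 0.08)
})

test_that("tidy/glance expose the fits and the estimate", {
  pair <- render_pattern_pair(synth_localization_patterns(1000, 1000, 0.5,
                                                          seed = 102))
  res <- iccs_global(pair$r, pair$g)
  td <- tidy(res)
  expect_setequal(td$which, c("rr", "gg", "rg"))
  expect_true(all(c("amplitude", "width_px", "offset", "converged") %in% names(td)))
  gl <- glance(res)
  expect_identical(gl$f, res$f)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("input contracts are enforced", {
  m <- matrix(1, 64, 64)
  expect_error(iccs_global(m, matrix(1, 32, 32)), "identical dimensions",
               class = "focimetry_error")
  expect_error(iccs_global(m, matrix(0, 64, 64)), "zero mean",
               class = "focimetry_error")
  expect_error(iccs_global(m, m, fit_radius_px = 40),
               class = "focimetry_error")
})

test_that("the local map flags empty windows and finds hot regions", {
  set.seed(103)
  # left half: shared structure; right half: only red structure
  n <- 400
  x_sh <- runif(n, 0, 2400); y_sh <- runif(n, 0, 4800)
  red <- tibble::tibble(x_nm = c(x_sh, runif(n, 2600, 4800)),
                        y_nm = c(y_sh, runif(n, 0, 4800)))
  green <- tibble::tibble(x_nm = c(x_sh, runif(n, 2600, 4800)),
                          y_nm = c(y_sh, runif(n, 0, 4800)))
  b <- c(0, 4800, 0, 4800)
  r <- render_localizations(red, 40, "fixed", sigma_nm = 100, bounds_nm = b)
  g <- render_localizations(green, 40, "fixed", sigma_nm = 100, bounds_nm = b)
  map <- iccs_local_map(r, g, window_px = 60, fit_radius_px = 8)
  expect_identical(nrow(map), 4L)
  left <- map$f[map$x0_px == 0]
  right <- map$f[map$x0_px == 60]
  expect_gt(mean(left), 0.8)
  expect_lt(mean(right), 0.3)
  expect_error(iccs_local_map(r, g, window_px = 8), ">= 16",
               class = "focimetry_error")
})
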