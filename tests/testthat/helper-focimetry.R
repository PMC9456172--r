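# Shared helpers for the test suite. Oracles here are deliberately written
# independently of the package internals (plain loops, naive formulas).

# full analysis chain on one synthetic scene, returning measured cells
# matched to planted nuclei by centroid
analyse_scene <- function(seed, n_nuclei = 4, correct = TRUE, ...) {
  sc <- synth_microscopy_scene(random_scene_spec(n_nuclei = n_nuclei,
                                                 seed = seed, ...))
  dna <- if (correct) correct_illumination(sc$images$DNA) else sc$images$DNA
  ch <- if (correct) correct_illumination(sc$images$gH2AX) else sc$images$gH2AX
  nuc <- segment_nuclei(dna, min_area_um2 = 10, max_area_um2 = 100)
  fp <- focus_params(tophat_radius_um = 1.2, k_sigma = 3,
                     min_area_um2 = 0.15, max_area_um2 = 20)
  foci <- segment_foci(ch, nuc, fp)
  cells <- measure_cells(nuc, list(dna, ch))
  mf <- measure_foci(foci, nuc, ch, cells)
  tr <- sc$truth$nuclei
  match_idx <- vapply(seq_len(nrow(tr)), function(i) {
    d <- sqrt((mf$cells$x_px - tr$x_px[i])^2 + (mf$cells$y_px - tr$y_px[i])^2)
    j <- which.min(d)
    if (length(j) == 1L && d[j] < 3) j else NA_integer_
  }, integer(1))
  list(scene = sc, nuclei = nuc, foci = foci, cells = mf$cells,
       focus_table = mf$foci, truth = tr, match = match_idx)
}

# brute-force nearest-focus oracle: plain double loop, no vectorised tricks
oracle_nearest <- function(spots, foci) {
  out <- data.frame(spot_id = spots$spot_id, nearest = NA_character_,
                    distance = NA_real_)
  for (k in seq_len(nrow(spots))) {
    best <- Inf; who <- NA_character_
    for (j in seq_len(nrow(foci))) {
      if (foci$cell_id[j] != spots$cell_id[k]) next
      d <- sqrt((foci$x_um[j] - spots$x_um[k])^2 +
                  (foci$y_um[j] - spots$y_um[k])^2)
      if (d < best) { best <- d; who <- foci$focus_id[j] }
    }
    out$nearest[k] <- who
    out$distance[k] <- if (is.finite(best)) best else NA_real_
  }
  out
}

# render a two-channel pattern for ICCS with bounds equal to the domain
# (padding would add a shared dark frame and bias the null upward)
render_pattern_pair <- function(pat, sigma_nm = 50, pixel_nm = 20) {
  b <- c(0, pat$domain_nm, 0, pat$domain_nm)
  list(r = render_localizations(pat$red, pixel_nm, "fixed",
                                sigma_nm = sigma_nm, bounds_nm = b),
       g = render_localizations(pat$green, pixel_nm, "fixed",
                                sigma_nm = sigma_nm, bounds_nm = b))
}

# labelled pulse-chase time course under the reference conditions; a small
# explicit EdU threshold stands in for a negative-control percentile (the
# simulation has zero EdU background)
labelled_timecourse <- function(params) {
  sim <- simulate_pulse_chase(params)
  t0 <- sim$cells[sim$cells$chase_time_h == 0, ]
  ref <- dna_peak_mode(t0$dna_total)
  classify_cell_cycle(sim$cells, edu_threshold = 0.02, dna_ref_2n = ref)
}
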