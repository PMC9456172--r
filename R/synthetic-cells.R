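#' Parameters for the pulse-chase cell-cycle simulator
#'
#' Defaults are the reference conditions used throughout: a (6, 4.5, 3.5) h
#' G1/S/G2M cycle (14 h total, matching a fast-cycling epithelial line), a
#' 20-min (1/3 h) labelling pulse, hourly chase sampling over 0-20 h, 5000
#' cells per time point and 5% CV multiplicative log-normal measurement
#' noise on DNA and EdU.
#'
#' @param T_G1_h,T_S_h,T_G2M_h phase durations in hours (> 0).
#' @param pulse_duration_h labelling pulse length in hours; must be shorter
#'   than `T_G2M_h` so no cell can carry label from the previous cycle.
#' @param chase_times_h sorted unique chase times (h), usually including 0.
#' @param n_cells cells per time point (one cohort tracked across times).
#' @param noise_cv named vector `c(dna = , edu = )` of measurement CVs.
#' @param edu_background EdU measurement background added to the true content
#'   before noise (0 keeps the mitotic halving contract exact).
#' @param age_distribution `"uniform"` over cycle position (keeps population
#'   fractions proportional to phase durations) or `"exponential"` (the true
#'   age structure of exponential growth, weighted toward young cells).
#' @param arrest optional checkpoint model: `g1_block_fraction` (fraction of
#'   G1 cells permanently blocked), `s_slowdown` (S-phase stretch factor >= 1),
#'   `g2_block` (no cell passes mitosis).
#' @param seed RNG seed; the simulation is bit-identical given the seed.
#' @return a `simulation_params` list.
#' @export
simulation_params <- function(T_G1_h = 6, T_S_h = 4.5, T_G2M_h = 3.5,
                              pulse_duration_h = 1 / 3,
                              chase_times_h = 0:20,
                              n_cells = 5000,
                              noise_cv = c(dna = 0.05, edu = 0.05),
                              edu_background = 0,
                              age_distribution = c("uniform", "exponential"),
                              arrest = list(g1_block_fraction = 0,
                                            s_slowdown = 1,
                                            g2_block = FALSE),
                              seed = 1L) {
  age_distribution <- match.arg(age_distribution)
  fm_assert(T_G1_h > 0 && T_S_h > 0 && T_G2M_h > 0, "phase durations must be > 0")
  fm_assert(all(chase_times_h >= 0), "chase time < 0")
  fm_assert(!is.unsorted(chase_times_h, strictly = TRUE),
            "chase_times_h must be sorted unique")
  fm_assert(pulse_duration_h > 0 && pulse_duration_h < T_G2M_h,
            "pulse must be shorter than G2M (label cannot cross a division)")
  arrest <- utils::modifyList(list(g1_block_fraction = 0, s_slowdown = 1,
                                   g2_block = FALSE), arrest)
  fm_assert(arrest$s_slowdown >= 1, "s_slowdown must be >= 1")
  structure(list(T_G1_h = T_G1_h, T_S_h = T_S_h, T_G2M_h = T_G2M_h,
                 pulse_duration_h = pulse_duration_h,
                 chase_times_h = as.numeric(chase_times_h),
                 n_cells = as.integer(n_cells),
                 noise_cv = noise_cv, edu_background = edu_background,
                 age_distribution = age_distribution,
                 arrest = arrest, seed = as.integer(seed)),
            class = "simulation_params")
}

#' Simulate an EdU pulse-chase time course with ground truth
#'
#' An asynchronous cohort is placed on the cell cycle, labelled by the overlap
#' of its S phase with the pulse window, and propagated deterministically
#' through the chase: DNA content is 2N in G1, rises linearly from 2N to 4N
#' through S and is 4N in G2M; at each mitosis DNA resets to 2N and the EdU
#' content is exactly halved (one daughter is tracked, so the cohort size is
#' constant and population fractions stay interpretable). Optional checkpoint
#' arrest freezes G1 cells, stretches S, or blocks mitosis. Multiplicative
#' log-normal measurement noise is applied last.
#'
#' @param params a [simulation_params()].
#' @return object of class `pulse_chase_sim`: `cells` (long tibble of
#'   measured values: `cell_id`, `chase_time_h`, `dna_total`, `edu_total`),
#'   `truth` (planted values per cell and time: phase, true DNA/EdU, division
#'   count, true six-population label), and `params`.
#' @export
simulate_pulse_chase <- function(params = simulation_params()) {
  fm_assert(inherits(params, "simulation_params"), "params must be simulation_params")
  p <- params
  set.seed(p$seed)
  n <- p$n_cells
  T_tot <- p$T_G1_h + p$T_S_h + p$T_G2M_h

  u <- switch(p$age_distribution,
    uniform = stats::runif(n, 0, T_tot),
    # age density of exponential growth: f(a) = 2 ln2 / T * 2^(-a/T)
    exponential = -T_tot * log2(1 - stats::runif(n) / 2))

  # EdU: overlap of the pulse window [-pulse, 0] with the cell's S interval
  s_start <- p$T_G1_h - u
  s_end <- s_start + p$T_S_h
  edu0 <- pmax(0, pmin(s_end, 0) - pmax(s_start, -p$pulse_duration_h))

  phase0 <- ifelse(u < p$T_G1_h, "G1", ifelse(u < p$T_G1_h + p$T_S_h, "S", "G2M"))
  g1_blocked <- phase0 == "G1" &
    stats::runif(n) < p$arrest$g1_block_fraction

  # slowed coordinates: S is stretched by s_slowdown
  k <- p$arrest$s_slowdown
  T_slow <- p$T_G1_h + k * p$T_S_h + p$T_G2M_h
  u_slow <- ifelse(u <= p$T_G1_h, u,
                   ifelse(u <= p$T_G1_h + p$T_S_h,
                          p$T_G1_h + (u - p$T_G1_h) * k,
                          u + (k - 1) * p$T_S_h))

  noise <- function(nn, cv) lognormal_noise(nn, cv)
  cv_dna <- unname(p$noise_cv["dna"] %||% 0)
  cv_edu <- unname(p$noise_cv["edu"] %||% 0)
  if (is.na(cv_dna)) cv_dna <- 0
  if (is.na(cv_edu)) cv_edu <- 0

  per_time <- lapply(p$chase_times_h, function(t) {
    pos <- u_slow + t
    if (isTRUE(p$arrest$g2_block)) {
      n_div <- rep(0L, n)
      cyc <- pmin(pos, T_slow - 1e-9)
    } else {
      n_div <- as.integer(pos %/% T_slow)
      cyc <- pos %% T_slow
    }
    n_div[g1_blocked] <- 0L
    cyc[g1_blocked] <- u_slow[g1_blocked]

    in_g1 <- cyc < p$T_G1_h
    in_s <- !in_g1 & cyc < p$T_G1_h + k * p$T_S_h
    progress <- ifelse(in_s, (cyc - p$T_G1_h) / (k * p$T_S_h), 0)
    dna_true <- ifelse(in_g1, 2, ifelse(in_s, 2 * (1 + progress), 4))
    edu_true <- edu0 / 2^n_div
    phase <- ifelse(in_g1, "G1", ifelse(in_s, "S", "G2M"))

    dna_meas <- dna_true * noise(n, cv_dna)
    edu_meas <- (edu_true + p$edu_background) * noise(n, cv_edu)

    ratio <- dna_true / 2
    win <- ifelse(ratio <= 1.2, "2N", ifelse(ratio < 1.6, "midN", "4N"))
    true_label <- paste0(win, ifelse(edu_true > 0, "+", "-"))

    list(
      cells = tibble::tibble(
        cell_id = sprintf("cell%05d", seq_len(n)),
        chase_time_h = t,
        dna_total = dna_meas,
        edu_total = edu_meas),
      truth = tibble::tibble(
        cell_id = sprintf("cell%05d", seq_len(n)),
        chase_time_h = t,
        phase = phase,
        cycle_pos_h = cyc,
        n_divisions = n_div,
        dna_true = dna_true,
        edu_true = edu_true,
        edu_positive_true = edu_true > 0,
        true_label = true_label,
        g1_blocked = g1_blocked)
    )
  })

  structure(list(
    cells = dplyr::bind_rows(purrr::map(per_time, "cells")),
    truth = dplyr::bind_rows(purrr::map(per_time, "truth")),
    params = p
  ), class = "pulse_chase_sim")
}

#' @export
print.pulse_chase_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("<pulse_chase_sim> %d cells x %d chase times, ",
                     "(G1, S, G2M) = (%.3g, %.3g, %.3g) h\n"),
              p$n_cells, length(p$chase_times_h), p$T_G1_h, p$T_S_h, p$T_G2M_h))
  invisible(x)
}
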