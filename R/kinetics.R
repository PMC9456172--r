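#' Estimate cell-cycle phase durations from a pulse-chase time course
#'
#' Given a labelled time course (every cell classified into the six DNA x EdU
#' populations at each chase time), estimates phase durations from the
#' re-appearance of EdU-positive cells in the 2N window after their first
#' mitosis. Writing `R(t)` for the fraction of assigned EdU+ cells in the 2N
#' window at chase time `t`, and `t_up(q)` / `t_dn(q)` for its linearly
#' interpolated up/down crossings of level `q`:
#'
#' * the first labelled mitoses are cells that had just finished DNA synthesis
#'   at the pulse, so `t_up(q_lo)` estimates `T_G2M + q_lo * T_S`;
#' * the mitosis wave sweeps through the labelled cohort at rate `1/T_S`, so
#'   two crossings on the rising edge give
#'   `t_up(q_s[2]) - t_up(q_s[1]) = (q_s[2] - q_s[1]) * T_S`; the defaults
#'   (0.25, 0.60) sit away from the curve's kinks, where linear interpolation
#'   between sampled fractions is exact up to counting noise, and below the
#'   plateau, which stays under 1 when G1 is shorter than ~0.8 S;
#' * after a full cycle the labelled cohort has left the 2N window and is back
#'   in S (the DNA x EdU distribution resembles the first time point), so
#'   `t_dn(q_lo)` estimates `T_cycle + (w_hi2n - 1 - q_lo) * T_S`, where
#'   `w_hi2n` is the upper 2N window edge (default 1.2): after division a cell
#'   stays in the 2N window through G1 plus the first `(w_hi2n - 1)` of S.
#'
#' Inverting these gives unbiased estimates of `T_S`, `T_G2M` and the total
#' first-cycle duration under an asynchronous (uniform-age) cohort.
#' `T_G1_exit` is the first time the midN- fraction of EdU- cells exceeds
#' `g1_exit_level`: the onset of G1 to S progression (a checkpoint readout,
#' delayed by a G1 block), not the G1 duration. The alternative
#' `g2m_method = "4n_decay"` estimates G2M as the first time the 4N- fraction
#' falls below 10% of its initial value; that readout needs the G1 to S inflow
#' to be blocked (as after irradiation) and is generally undetermined in
#' unperturbed growth.
#'
#' Unassigned cells are excluded from all denominators. Crossing levels and
#' window edges are configuration, matching the qualitative logic of the
#' assay.
#'
#' @param cells labelled time course: a cell table with columns
#'   `chase_time_h`, `cycle_label`, `edu_positive` covering >= 3 time points
#'   including 0 (bind [classify_cell_cycle()] outputs over times).
#' @param q_lo crossing level anchoring the first labelled mitoses and the
#'   end-of-cycle descent of the 2N+ re-appearance curve.
#' @param q_s two rising-edge crossing levels whose spacing estimates `T_S`.
#' @param g1_exit_level midN- fraction of EdU- cells marking G1 exit.
#' @param g2m_method `"first_mitosis"` (default) or `"4n_decay"`.
#' @param decay_level for `"4n_decay"`: fraction of the initial 4N- level.
#' @param w_hi2n upper 2N window edge relative to the G1 peak (must match the
#'   classification windows).
#' @return object of class `kinetics_estimate` with elements `T_G2M_h`,
#'   `T_G1_exit_h`, `T_S_h`, `T_cycle_h` (each `NA` when the corresponding
#'   crossing never happens), `fractions` (per-time population fractions),
#'   `curves` and `crossings`.
#' @export
estimate_cycle_kinetics <- function(cells, q_lo = 0.05, q_s = c(0.25, 0.60),
                                    g1_exit_level = 0.05,
                                    g2m_method = c("first_mitosis", "4n_decay"),
                                    decay_level = 0.10,
                                    w_hi2n = 1.2) {
  g2m_method <- match.arg(g2m_method)
  if (!is.data.frame(cells) && is.list(cells)) {
    tt <- as.numeric(names(cells))
    fm_assert(!anyNA(tt) && !is.unsorted(tt, strictly = TRUE),
              "unordered or duplicate time-points")
    cells <- dplyr::bind_rows(purrr::map2(cells, tt, function(tb, ti) {
      tb$chase_time_h <- ti
      tb
    }))
  }
  fm_assert(all(c("chase_time_h", "cycle_label", "edu_positive") %in% names(cells)),
            "cells must carry chase_time_h, cycle_label and edu_positive")
  times <- sort(unique(cells$chase_time_h))
  fm_assert(length(times) >= 3L, "need at least 3 time-points")
  fm_assert(isTRUE(min(times) == 0), "time course must include t = 0")
  fm_assert(0 < q_lo && q_lo < q_s[1] && q_s[1] < q_s[2] && q_s[2] < 1,
            "need 0 < q_lo < q_s[1] < q_s[2] < 1")

  curves <- cells |>
    dplyr::filter(.data$cycle_label != "unassigned") |>
    dplyr::group_by(.data$chase_time_h) |>
    dplyr::summarise(
      r2n = sum(.data$edu_positive & .data$cycle_label == "2N+") /
        max(sum(.data$edu_positive), 1L),
      f4n_neg = sum(.data$cycle_label == "4N-") / dplyr::n(),
      fmidn_neg = sum(.data$cycle_label == "midN-") /
        max(sum(!.data$edu_positive), 1L),
      .groups = "drop") |>
    dplyr::arrange(.data$chase_time_h)

  t <- curves$chase_time_h
  r <- curves$r2n

  # the 2N window holds early-S EdU+ cells at t = 0; crossings are only
  # meaningful once that initial occupancy has cleared
  below <- which(r < q_lo)
  t_clear <- if (r[1] < q_lo) t[1] else if (length(below)) t[below[1]] else NA_real_
  t1 <- if (is.na(t_clear)) NA_real_ else
    first_crossing(t, r, q_lo, "up", after = t_clear - 1e-9)
  ta <- if (is.na(t1)) NA_real_ else
    first_crossing(t, r, q_s[1], "up", after = t1 - 1e-9)
  tb <- if (is.na(ta)) NA_real_ else
    first_crossing(t, r, q_s[2], "up", after = ta)
  t3 <- if (is.na(tb)) NA_real_ else first_crossing(t, r, q_lo, "down", after = tb)

  T_S <- if (is.na(tb)) NA_real_ else (tb - ta) / (q_s[2] - q_s[1])
  T_G2M <- switch(g2m_method,
    first_mitosis = if (is.na(t1) || is.na(T_S)) NA_real_ else t1 - q_lo * T_S,
    "4n_decay" = {
      lvl <- decay_level * curves$f4n_neg[1]
      first_crossing(t, curves$f4n_neg, lvl, "down")
    })
  T_cycle <- if (is.na(t3) || is.na(T_S)) NA_real_ else
    t3 - (w_hi2n - 1 - q_lo) * T_S
  T_G1_exit <- first_crossing(t, curves$fmidn_neg, g1_exit_level, "up")

  structure(
    list(T_G2M_h = T_G2M, T_G1_exit_h = T_G1_exit, T_S_h = T_S,
         T_cycle_h = T_cycle,
         fractions = population_fractions(cells),
         curves = curves,
         crossings = c(t_up_lo = t1, t_up_s1 = ta, t_up_s2 = tb, t_dn_lo = t3),
         params = list(q_lo = q_lo, q_s = q_s, g1_exit_level = g1_exit_level,
                       g2m_method = g2m_method, decay_level = decay_level,
                       w_hi2n = w_hi2n)),
    class = "kinetics_estimate")
}

#' @export
print.kinetics_estimate <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undetermined" else sprintf("%.2f h", v)
  cat("<kinetics_estimate>\n")
  cat("  G2M transit      :", fmt(x$T_G2M_h), "\n")
  cat("  G1 exit onset    :", fmt(x$T_G1_exit_h), "\n")
  cat("  S duration       :", fmt(x$T_S_h), "\n")
  cat("  first-cycle total:", fmt(x$T_cycle_h), "\n")
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.kinetics_estimate <- function(x, ...) x$fractions

#' @export
#' @importFrom generics glance
glance.kinetics_estimate <- function(x, ...) {
  tibble::tibble(T_G2M_h = x$T_G2M_h, T_G1_exit_h = x$T_G1_exit_h,
                 T_S_h = x$T_S_h, T_cycle_h = x$T_cycle_h)
}

#' @export
autoplot.kinetics_estimate <- function(object, ...) {
  fr <- dplyr::filter(object$fractions, .data$cycle_label != "unassigned")
  ggplot2::ggplot(fr, ggplot2::aes(x = .data$chase_time_h, y = .data$fraction,
                                   colour = .data$cycle_label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "chase time (h)", y = "fraction of assigned cells",
                  colour = "population") +
    ggplot2::theme_minimal()
}
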