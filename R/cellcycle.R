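#' Classify cells into the six pulse-chase DNA x EdU populations
#'
#' Splits cells into EdU-positive and -negative at a threshold (Otsu on
#' log-transformed EdU by default, or a supplied value, e.g. a
#' negative-control percentile) and into DNA-content windows anchored on the
#' G1 peak position `p` (kernel-density mode of the DNA column unless
#' supplied): 2N = `[0.8 p, 1.2 p]`, midN = `(1.2 p, 1.6 p)`,
#' 4N = `[1.6 p, 2.4 p]`. The six labels `2N+/midN+/4N+/2N-/midN-/4N-`
#' partition all assigned cells; cells outside `[0.8 p, 2.4 p]` are labelled
#' `"unassigned"` and kept, never dropped.
#'
#' @param table cell table.
#' @param edu_col,dna_col column names of EdU and DNA integrated intensities.
#' @param edu_threshold EdU positivity threshold; `NULL` for Otsu on
#'   `log1p(EdU)`.
#' @param dna_ref_2n G1 peak position `p`; `NULL` to estimate by kernel
#'   density mode. Estimate it once on the t = 0 table of a time course and
#'   pass it to later time points for stability.
#' @param windows DNA window edges relative to `p`:
#'   `c(lo_2n, hi_2n, lo_4n, hi_4n)`.
#' @return `table` with added columns `edu_positive` (logical) and
#'   `cycle_label` (character, one of the six labels or `"unassigned"`), plus
#'   attributes `edu_threshold` and `dna_ref_2n`.
#' @export
classify_cell_cycle <- function(table, edu_col = "edu_total", dna_col = "dna_total",
                                edu_threshold = NULL, dna_ref_2n = NULL,
                                windows = c(0.8, 1.2, 1.6, 2.4)) {
  fm_assert(all(c(edu_col, dna_col) %in% names(table)),
            "EdU/DNA columns not present in table")
  fm_assert(length(windows) == 4L && all(diff(windows) > 0),
            "windows must be increasing c(lo_2n, hi_2n, lo_4n, hi_4n)")
  edu <- table[[edu_col]]
  dna <- table[[dna_col]]

  if (is.null(edu_threshold)) {
    edu_threshold <- exp(otsu_threshold(log1p(edu[is.finite(edu)]))) - 1
  }
  if (is.null(dna_ref_2n)) {
    dna_ref_2n <- dna_peak_mode(dna)
  }
  p <- dna_ref_2n
  edu_pos <- edu > edu_threshold

  win <- cut(dna / p,
             breaks = c(-Inf, windows[1], windows[2], windows[3], windows[4], Inf),
             labels = c("low", "2N", "midN", "4N", "high"),
             right = TRUE)
  # cut() puts p*windows[2] in "2N" (right-closed): matches 2N = [0.8p, 1.2p],
  # midN = (1.2p, 1.6p) ... except the 1.6p edge, assigned to 4N per the
  # closed 4N window; shift it explicitly
  at_4n_lo <- !is.na(win) & win == "midN" & dna / p == windows[3]
  win[at_4n_lo] <- "4N"
  at_2n_lo <- !is.na(win) & win == "low" & dna / p == windows[1]
  win[at_2n_lo] <- "2N"

  lab <- ifelse(win %in% c("2N", "midN", "4N"),
                paste0(as.character(win), ifelse(edu_pos, "+", "-")),
                "unassigned")
  lab[!is.finite(dna) | !is.finite(edu)] <- "unassigned"

  table$edu_positive <- edu_pos
  table$cycle_label <- lab
  attr(table, "edu_threshold") <- edu_threshold
  attr(table, "dna_ref_2n") <- p
  table
}

#' Estimate the G1 (2N) peak position of a DNA-content distribution
#'
#' Mode of a Gaussian kernel density estimate, the usual anchor for drawing
#' DNA-content windows when no reference is supplied.
#'
#' @param dna numeric vector of DNA integrated intensities.
#' @return the estimated peak position.
#' @export
dna_peak_mode <- function(dna) {
  dna <- dna[is.finite(dna) & dna > 0]
  fm_assert(length(dna) >= 10L, "no detectable DNA peak: too few cells")
  d <- stats::density(dna, n = 1024)
  d$x[which.max(d$y)]
}

#' The six cell-cycle population labels
#' @return character vector of the six labels in canonical order.
#' @export
cycle_labels <- function() c("2N+", "midN+", "4N+", "2N-", "midN-", "4N-")

#' Population fractions per chase time
#'
#' Tabulates the six DNA x EdU populations (and `"unassigned"`) for every
#' chase time of a labelled time course, as counts and as fractions of
#' assigned cells. Unassigned cells (sub-2N debris, >4N) are excluded from
#' the denominators, mirroring standard cytometry practice.
#'
#' @param cells a labelled cell table with columns `chase_time_h` and
#'   `cycle_label` ([classify_cell_cycle()] output, possibly row-bound over
#'   times).
#' @return tibble with `chase_time_h`, `cycle_label`, `n`, `fraction` (of
#'   assigned), `n_assigned`.
#' @export
population_fractions <- function(cells) {
  fm_assert(all(c("chase_time_h", "cycle_label") %in% names(cells)),
            "cells must carry chase_time_h and cycle_label")
  all_labels <- c(cycle_labels(), "unassigned")
  cells |>
    dplyr::count(.data$chase_time_h,
                 cycle_label = factor(.data$cycle_label, levels = all_labels)) |>
    tidyr::complete(.data$chase_time_h, .data$cycle_label, fill = list(n = 0L)) |>
    dplyr::group_by(.data$chase_time_h) |>
    dplyr::mutate(n_assigned = sum(.data$n[.data$cycle_label != "unassigned"]),
                  fraction = ifelse(.data$cycle_label == "unassigned", NA_real_,
                                    .data$n / pmax(.data$n_assigned, 1L))) |>
    dplyr::ungroup() |>
    dplyr::mutate(cycle_label = as.character(.data$cycle_label))
}
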