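#' Cytometry-style DNA x EdU dot plot
#'
#' The standard pulse-chase readout: DNA content on x, EdU content on y
#' (log1p scale), one point per cell, coloured by population when the table
#' is classified. The DNA-window edges and the EdU threshold are drawn when
#' present as attributes (i.e. on [classify_cell_cycle()] output).
#'
#' @param cells a cell table, classified or not.
#' @param dna_col,edu_col column names.
#' @param windows window edges relative to the G1 peak (drawn only when the
#'   table carries a `dna_ref_2n` attribute).
#' @return a ggplot object.
#' @export
plot_dna_edu <- function(cells, dna_col = "dna_total", edu_col = "edu_total",
                         windows = c(0.8, 1.2, 1.6, 2.4)) {
  fm_assert(all(c(dna_col, edu_col) %in% names(cells)),
            "DNA/EdU columns not present in table")
  p <- ggplot2::ggplot(cells,
                       ggplot2::aes(x = .data[[dna_col]],
                                    y = log1p(.data[[edu_col]])))
  if ("cycle_label" %in% names(cells)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$cycle_label),
                                 size = 0.4, alpha = 0.6) +
      ggplot2::labs(colour = "population")
  } else {
    p <- p + ggplot2::geom_point(size = 0.4, alpha = 0.6)
  }
  ref <- attr(cells, "dna_ref_2n")
  if (!is.null(ref)) {
    p <- p + ggplot2::geom_vline(xintercept = ref * windows,
                                 linetype = "dotted", colour = "grey40")
  }
  thr <- attr(cells, "edu_threshold")
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = log1p(thr),
                                 linetype = "dashed", colour = "grey40")
  }
  p + ggplot2::labs(x = "DNA content (integrated intensity)",
                    y = "EdU content (log1p intensity)") +
    ggplot2::theme_minimal()
}

#' DNA-content histogram with window edges
#'
#' @param cells a cell table.
#' @param dna_col column name.
#' @param bins histogram bins.
#' @param windows window edges relative to the G1 peak (drawn when the table
#'   carries a `dna_ref_2n` attribute).
#' @return a ggplot object.
#' @export
plot_dna_histogram <- function(cells, dna_col = "dna_total", bins = 120,
                               windows = c(0.8, 1.2, 1.6, 2.4)) {
  fm_assert(dna_col %in% names(cells), "DNA column not present in table")
  p <- ggplot2::ggplot(cells, ggplot2::aes(x = .data[[dna_col]])) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35")
  ref <- attr(cells, "dna_ref_2n")
  if (!is.null(ref)) {
    p <- p + ggplot2::geom_vline(xintercept = ref * windows,
                                 linetype = "dotted", colour = "red")
  }
  p + ggplot2::labs(x = "DNA content (integrated intensity)", y = "cells") +
    ggplot2::theme_minimal()
}

#' Per-cell focus-count histogram
#'
#' @param cells an augmented cell table from [measure_foci()].
#' @param channel focus channel name.
#' @return a ggplot object.
#' @export
plot_foci_counts <- function(cells, channel) {
  col <- paste0("n_foci_", chan_key(channel))
  fm_assert(col %in% names(cells),
            sprintf("no foci measurements for channel '%s'", channel))
  ggplot2::ggplot(cells, ggplot2::aes(x = .data[[col]])) +
    ggplot2::geom_bar(fill = "grey35") +
    ggplot2::labs(x = sprintf("%s foci per cell", channel), y = "cells") +
    ggplot2::theme_minimal()
}
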