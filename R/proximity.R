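#' Associate proximity-assay spots to repair foci by nearest distance
#'
#' For every spot, finds the nearest reference focus *of the same cell* by
#' Euclidean distance between centroids (stage micrometres) and flags the
#' spot as adjacent when that distance is at most `threshold_um` (inclusive:
#' a spot exactly at the threshold counts). Spots in cells without any
#' reference focus get `NA` distance and are never adjacent.
#'
#' @param spots tibble of assay spots with columns `spot_id`, `cell_id`,
#'   `x_um`, `y_um`.
#' @param foci tibble of reference foci with columns `focus_id`, `cell_id`,
#'   `x_um`, `y_um`.
#' @param threshold_um adjacency radius (default 1 micrometre, the
#'   conventional optical-proximity criterion).
#' @return list of class `spot_association`: `spots` (input plus
#'   `nearest_focus_id`, `distance_um`, `adjacent`), `per_cell` (one row per
#'   cell appearing in either table: `n_spots`, `n_adjacent`,
#'   `frac_adjacent`), and `threshold_um`.
#' @export
associate_spots_to_foci <- function(spots, foci, threshold_um = 1) {
  fm_assert(all(c("spot_id", "cell_id", "x_um", "y_um") %in% names(spots)),
            "spots must carry spot_id, cell_id, x_um, y_um")
  fm_assert(all(c("focus_id", "cell_id", "x_um", "y_um") %in% names(foci)),
            "foci must carry focus_id, cell_id, x_um, y_um")
  fm_assert(is.numeric(threshold_um) && threshold_um >= 0,
            "threshold_um must be a non-negative number")

  foci_by_cell <- split(foci, foci$cell_id)
  annotated <- spots |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(sp, key) {
      fc <- foci_by_cell[[as.character(key$cell_id)]]
      if (is.null(fc) || nrow(fc) == 0L) {
        sp$nearest_focus_id <- rep(NA, nrow(sp))
        sp$distance_um <- NA_real_
        return(sp)
      }
      d2 <- outer(sp$x_um, fc$x_um, "-")^2 + outer(sp$y_um, fc$y_um, "-")^2
      nearest <- max.col(-d2, ties.method = "first")
      sp$nearest_focus_id <- fc$focus_id[nearest]
      sp$distance_um <- sqrt(d2[cbind(seq_len(nrow(sp)), nearest)])
      sp
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(adjacent = !is.na(.data$distance_um) &
                    .data$distance_um <= threshold_um)

  cell_ids <- union(unique(spots$cell_id), unique(foci$cell_id))
  per_cell <- annotated |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(n_spots = dplyr::n(),
                     n_adjacent = sum(.data$adjacent), .groups = "drop") |>
    dplyr::right_join(tibble::tibble(cell_id = cell_ids), by = "cell_id") |>
    dplyr::mutate(n_spots = dplyr::coalesce(.data$n_spots, 0L),
                  n_adjacent = dplyr::coalesce(.data$n_adjacent, 0L),
                  frac_adjacent = ifelse(.data$n_spots > 0,
                                         .data$n_adjacent / .data$n_spots,
                                         NA_real_)) |>
    dplyr::arrange(.data$cell_id)

  structure(list(spots = annotated, per_cell = per_cell,
                 threshold_um = threshold_um),
            class = "spot_association")
}

#' @export
print.spot_association <- function(x, ...) {
  cat(sprintf("<spot_association> %d spots, %d cells, threshold %.3g um: %d adjacent (%.1f%%)\n",
              nrow(x$spots), nrow(x$per_cell), x$threshold_um,
              sum(x$spots$adjacent), 100 * mean(x$spots$adjacent)))
  invisible(x)
}

#' @export
autoplot.spot_association <- function(object, ...) {
  d <- dplyr::filter(object$spots, is.finite(.data$distance_um))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$distance_um)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$threshold_um,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "distance to nearest focus (um)", y = "spots") +
    ggplot2::theme_minimal()
}

#' Pearson product-moment correlation between two cell-table columns
#'
#' Computed directly from the product-moment definition
#' `r = sum((x - mx)(y - my)) / sqrt(sum((x - mx)^2) sum((y - my)^2))`
#' over complete finite pairs. Errors (rather than returning `NA`) when fewer
#' than 3 finite pairs remain or when either column has zero variance, since
#' the correlation is undefined there.
#'
#' @param table a cell table.
#' @param x_col,y_col column names.
#' @return tibble with `r` and `n` (number of pairs used).
#' @export
pearson_correlation <- function(table, x_col, y_col) {
  fm_assert(all(c(x_col, y_col) %in% names(table)),
            paste("unknown column(s):",
                  paste(setdiff(c(x_col, y_col), names(table)), collapse = ", ")))
  x <- table[[x_col]]; y <- table[[y_col]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  fm_assert(n >= 3L, "need at least 3 finite pairs")
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  fm_assert(sxx > 0 && syy > 0, "zero variance: correlation undefined")
  tibble::tibble(r = sum(dx * dy) / sqrt(sxx * syy), n = n)
}

#' Split cells at the median of one column and compare others across the split
#'
#' Cells with `split_col` strictly greater than its median form the `"above"`
#' group; ties with the median go to `"below"` (so the split is unambiguous
#' for any data). For every comparison column, reports group means, medians,
#' SDs and a two-sided Wilcoxon rank-sum p-value.
#'
#' @param table a cell table.
#' @param split_col numeric column defining the split.
#' @param compare_cols columns to compare across the split.
#' @return list of class `median_split`: `summary` (one row per comparison
#'   column), `below`/`above` (the two subsets), `split_col`, `median`.
#' @export
median_split_compare <- function(table, split_col, compare_cols) {
  fm_assert(all(c(split_col, compare_cols) %in% names(table)),
            paste("unknown column(s):",
                  paste(setdiff(c(split_col, compare_cols), names(table)),
                        collapse = ", ")))
  s <- table[[split_col]]
  ok <- is.finite(s)
  table <- table[ok, , drop = FALSE]
  s <- s[ok]
  fm_assert(length(s) >= 4L, "need at least 4 cells with a finite split value")
  m <- stats::median(s)
  fm_assert(any(s > m), "split column is constant above its median: cannot split")
  above <- s > m
  below_tbl <- table[!above, , drop = FALSE]
  above_tbl <- table[above, , drop = FALSE]

  summary <- purrr::map_dfr(compare_cols, function(cl) {
    lo <- below_tbl[[cl]][is.finite(below_tbl[[cl]])]
    hi <- above_tbl[[cl]][is.finite(above_tbl[[cl]])]
    p <- if (length(lo) >= 1L && length(hi) >= 1L)
      suppressWarnings(stats::wilcox.test(lo, hi)$p.value) else NA_real_
    tibble::tibble(column = cl,
                   n_below = length(lo), mean_below = mean(lo),
                   median_below = stats::median(lo), sd_below = stats::sd(lo),
                   n_above = length(hi), mean_above = mean(hi),
                   median_above = stats::median(hi), sd_above = stats::sd(hi),
                   p_ranksum = p)
  })
  structure(list(summary = summary, below = below_tbl, above = above_tbl,
                 split_col = split_col, median = m),
            class = "median_split")
}

#' @export
print.median_split <- function(x, ...) {
  cat(sprintf("<median_split> by %s (median %.4g): %d below / %d above\n",
              x$split_col, x$median, nrow(x$below), nrow(x$above)))
  print(x$summary)
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.median_split <- function(x, ...) x$summary
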