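#' Read and write the per-cell feature database as tab-delimited text
#'
#' Cell tables are plain tab-delimited text with a header row; missing values
#' are written as empty fields and unknown extra columns are preserved
#' verbatim, so the database stays greppable and round trips losslessly.
#'
#' @param table a tibble/data frame of per-cell records.
#' @param path file path.
#' @return `read_cell_table()` returns a tibble; `write_cell_table()` returns
#'   `path` invisibly.
#' @export
write_cell_table <- function(table, path) {
  fm_assert(is.data.frame(table), "table must be a data frame")
  readr::write_tsv(table, path, na = "")
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  fm_assert(file.exists(path), paste("unreadable file:", path))
  header <- readLines(path, n = 1L)
  fm_assert(length(header) == 1L && nzchar(header), "malformed header")
  readr::read_tsv(path, na = "", show_col_types = FALSE, progress = FALSE)
}

#' Write and read a stage position list
#'
#' Exports selected cells as a position list for microscope re-acquisition.
#' The default dialect is a documented CSV with header `label,x_um,y_um`;
#' coordinates survive a round trip to better than 1e-6 um. Microscope vendors
#' consume different formats, so the writer is the adapter point: convert the
#' returned CSV downstream.
#'
#' @param cells tibble with columns `cell_id`, `centroid_stage_x_um`,
#'   `centroid_stage_y_um` (as produced by [measure_cells()] when metadata is
#'   available), or `label`, `x_um`, `y_um` directly.
#' @param path output file.
#' @param dialect only `"csv"` is built in.
#' @return the written tibble, invisibly (`read_position_list()` returns it).
#' @export
write_position_list <- function(cells, path, dialect = "csv") {
  fm_assert(identical(dialect, "csv"), "unknown position-list dialect")
  if (all(c("cell_id", "centroid_stage_x_um", "centroid_stage_y_um") %in% names(cells))) {
    pos <- tibble::tibble(label = as.character(cells$cell_id),
                          x_um = cells$centroid_stage_x_um,
                          y_um = cells$centroid_stage_y_um)
  } else {
    fm_assert(all(c("label", "x_um", "y_um") %in% names(cells)),
              "cells must carry stage centroids")
    pos <- tibble::as_tibble(cells[, c("label", "x_um", "y_um")])
    pos$label <- as.character(pos$label)
  }
  if (anyDuplicated(pos$label)) fm_abort("duplicate labels in position list")
  if (nrow(pos) == 0L) rlang::warn("empty selection: writing header-only position list")
  readr::write_csv(pos, path)
  invisible(pos)
}

#' @rdname write_position_list
#' @export
read_position_list <- function(path, dialect = "csv") {
  fm_assert(identical(dialect, "csv"), "unknown position-list dialect")
  pos <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(label = readr::col_character()))
  fm_assert(all(c("label", "x_um", "y_um") %in% names(pos)), "malformed position list")
  fm_assert(!anyDuplicated(pos$label), "duplicate labels in position list")
  pos
}

default_loc_dialect <- function() {
  list(x = "x [nm]", y = "y [nm]", precision = "uncertainty [nm]",
       photons = "intensity [photons]", frame = "frame", channel = "channel",
       unit = "nm", sep = ",")
}

#' Read and write single-molecule localization tables
#'
#' Localization tables are delimited text with header-named columns. The
#' default dialect matches common SMLM export conventions
#' (`x [nm], y [nm], uncertainty [nm], intensity [photons], frame, channel`);
#' any element can be remapped through `dialect`. Coordinates are normalised
#' to nanometres on read (`unit = "um"` multiplies by 1000); rows with
#' non-finite coordinates are dropped and counted in the `"dropped"`
#' attribute of the result.
#'
#' @param path delimited-text file.
#' @param dialect named list overriding any of `x`, `y`, `precision`,
#'   `photons`, `frame`, `channel` (column names), `unit` (`"nm"` or `"um"`),
#'   `sep`.
#' @return a tibble with columns `x_nm`, `y_nm`, `precision_nm`, `photons`,
#'   `frame`, `channel` (missing optional columns filled with defaults).
#' @export
read_localizations <- function(path, dialect = list()) {
  d <- utils::modifyList(default_loc_dialect(), dialect)
  fm_assert(d$unit %in% c("nm", "um"), paste("unknown unit declaration:", d$unit))
  raw <- readr::read_delim(path, delim = d$sep, show_col_types = FALSE, progress = FALSE)
  fm_assert(all(c(d$x, d$y) %in% names(raw)),
            sprintf("missing x/y columns ('%s', '%s') in %s", d$x, d$y, path))
  scale <- if (d$unit == "um") 1000 else 1
  n0 <- nrow(raw)
  out <- tibble::tibble(
    x_nm = as.numeric(raw[[d$x]]) * scale,
    y_nm = as.numeric(raw[[d$y]]) * scale,
    precision_nm = if (d$precision %in% names(raw))
      as.numeric(raw[[d$precision]]) * scale else 0,
    photons = if (d$photons %in% names(raw)) as.numeric(raw[[d$photons]]) else 1,
    frame = if (d$frame %in% names(raw)) as.integer(raw[[d$frame]]) else 0L,
    channel = if (d$channel %in% names(raw)) as.character(raw[[d$channel]]) else "1"
  )
  keep <- is.finite(out$x_nm) & is.finite(out$y_nm)
  out <- out[keep, ]
  fm_assert(all(out$precision_nm >= 0, na.rm = TRUE), "negative localization precision")
  attr(out, "dropped") <- n0 - sum(keep)
  out
}

#' @rdname read_localizations
#' @param locs a localization tibble as returned by [read_localizations()] or
#'   [synth_localization_patterns()].
#' @export
write_localizations <- function(locs, path, dialect = list()) {
  d <- utils::modifyList(default_loc_dialect(), dialect)
  fm_assert(identical(d$unit, "nm"), "localizations are written in nm")
  out <- stats::setNames(
    locs[, c("x_nm", "y_nm", "precision_nm", "photons", "frame", "channel")],
    c(d$x, d$y, d$precision, d$photons, d$frame, d$channel))
  readr::write_delim(out, path, delim = d$sep)
  invisible(path)
}
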