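#' Flow-cytometry-style logical gates over cell-table columns
#'
#' Gates are predicates over one or two numeric columns of a cell table, and
#' compose with `gate_and()`, `gate_or()` and `gate_not()` following ordinary
#' set algebra. Interval bounds are inclusive. Polygon gates select points
#' strictly inside or on the boundary of a closed polygon (even-odd rule).
#'
#' @param col,xcol,ycol column names.
#' @param min,max inclusive interval bounds (may be `-Inf`/`Inf`).
#' @param xmin,xmax,ymin,ymax rectangle bounds.
#' @param vertices two-column matrix of polygon vertices (closed implicitly).
#' @param name gate name used in summaries.
#' @param a,b gates to combine.
#' @return a `gate` object.
#' @export
gate_interval <- function(col, min = -Inf, max = Inf, name = NULL) {
  force(col); force(min); force(max)
  new_gate(name %||% sprintf("%s in [%g, %g]", col, min, max),
           cols = col,
           fn = function(tbl) tbl[[col]] >= min & tbl[[col]] <= max)
}

#' @rdname gate_interval
#' @export
gate_rectangle <- function(xcol, ycol, xmin = -Inf, xmax = Inf,
                           ymin = -Inf, ymax = Inf, name = NULL) {
  new_gate(name %||% sprintf("%s x %s rectangle", xcol, ycol),
           cols = c(xcol, ycol),
           fn = function(tbl) tbl[[xcol]] >= xmin & tbl[[xcol]] <= xmax &
             tbl[[ycol]] >= ymin & tbl[[ycol]] <= ymax)
}

#' @rdname gate_interval
#' @export
gate_polygon <- function(xcol, ycol, vertices, name = NULL) {
  vertices <- as.matrix(vertices)
  fm_assert(ncol(vertices) == 2L && nrow(vertices) >= 3L,
            "polygon needs >= 3 (x, y) vertices")
  new_gate(name %||% sprintf("%s x %s polygon", xcol, ycol),
           cols = c(xcol, ycol),
           fn = function(tbl) point_in_polygon(tbl[[xcol]], tbl[[ycol]], vertices))
}

#' @rdname gate_interval
#' @export
gate_and <- function(a, b, name = NULL) {
  new_gate(name %||% paste0("(", a$name, ") AND (", b$name, ")"),
           cols = union(a$cols, b$cols),
           fn = function(tbl) a$fn(tbl) & b$fn(tbl))
}

#' @rdname gate_interval
#' @export
gate_or <- function(a, b, name = NULL) {
  new_gate(name %||% paste0("(", a$name, ") OR (", b$name, ")"),
           cols = union(a$cols, b$cols),
           fn = function(tbl) a$fn(tbl) | b$fn(tbl))
}

#' @rdname gate_interval
#' @export
gate_not <- function(a, name = NULL) {
  new_gate(name %||% paste0("NOT (", a$name, ")"),
           cols = a$cols,
           fn = function(tbl) !a$fn(tbl))
}

new_gate <- function(name, cols, fn) {
  structure(list(name = name, cols = cols, fn = fn), class = "gate")
}

#' @export
print.gate <- function(x, ...) {
  cat("<gate>", x$name, "\n")
  invisible(x)
}

# even-odd ray casting; boundary points count as inside (tracked separately
# so a later edge crossing cannot toggle a boundary point back out)
point_in_polygon <- function(x, y, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(x))
  boundary <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    on_edge <- pmin(xi, xj) <= x & x <= pmax(xi, xj) &
      pmin(yi, yj) <= y & y <= pmax(yi, yj) &
      abs((xj - xi) * (y - yi) - (yj - yi) * (x - xi)) < 1e-12
    boundary <- boundary | (on_edge & !is.na(on_edge))
    j <- i
  }
  inside | boundary
}

#' Apply a gate to a cell table
#'
#' Returns the gated subset plus summary statistics, mirroring flow-cytometry
#' software: the number of events in and out of the gate and, for each
#' requested column, mean, median and SD inside the gate. Rows where a gated
#' column is `NA` never pass a gate.
#'
#' @param table a cell table.
#' @param gate a [gate_interval()] / combination.
#' @param summarise_cols columns to summarise inside the gate (default: the
#'   gate's own columns).
#' @return list of class `gated_cells`: `cells` (subset tibble), `summary`
#'   (per-column stats tibble), `n`, `n_total`, `gate`.
#' @export
apply_gate <- function(table, gate, summarise_cols = NULL) {
  fm_assert(inherits(gate, "gate"), "gate must be a gate object")
  missing_cols <- setdiff(gate$cols, names(table))
  fm_assert(length(missing_cols) == 0L,
            paste("unknown column(s):", paste(missing_cols, collapse = ", ")))
  sel <- gate$fn(table)
  sel[is.na(sel)] <- FALSE
  subset <- table[sel, , drop = FALSE]
  cols <- summarise_cols %||% intersect(gate$cols, names(table))
  summ <- purrr::map_dfr(cols, function(cl) {
    v <- subset[[cl]]
    tibble::tibble(column = cl, n = sum(is.finite(v)),
                   mean = mean(v, na.rm = TRUE), median = stats::median(v, na.rm = TRUE),
                   sd = stats::sd(v, na.rm = TRUE))
  })
  structure(list(cells = subset, summary = summ, n = nrow(subset),
                 n_total = nrow(table), gate = gate$name),
            class = "gated_cells")
}

#' @export
print.gated_cells <- function(x, ...) {
  cat(sprintf("<gated_cells> %s: %d / %d events (%.1f%%)\n",
              x$gate, x$n, x$n_total, 100 * x$n / max(x$n_total, 1L)))
  if (nrow(x$summary)) print(x$summary)
  invisible(x)
}
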