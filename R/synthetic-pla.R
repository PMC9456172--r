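#' Generate a synthetic proximity-assay scene with known nearest distances
#'
#' Places reference foci uniformly in each cell's field, then plants assay
#' spots at controlled offsets from randomly chosen anchor foci: each spot is
#' displaced from its anchor by a distance drawn from `offset_range_um` at a
#' uniform angle. The ground truth records, for every spot, the exact nearest
#' focus and distance, computed at generation time by an exhaustive scan over
#' the cell's foci (which can be closer than the planted anchor).
#'
#' @param n_cells number of cells.
#' @param foci_range integer range of reference foci per cell.
#' @param spots_range integer range of assay spots per cell (0 allowed).
#' @param field_um cells are abstract `field_um` x `field_um` regions; foci
#'   keep a margin of the maximum offset from the edge so spots stay
#'   in-field.
#' @param offset_range_um planted anchor-offset distances (uniform).
#' @param seed RNG seed.
#' @return list of class `pla_scene`: `foci` (`focus_id`, `cell_id`, `x_um`,
#'   `y_um`), `spots` (`spot_id`, `cell_id`, `x_um`, `y_um`), and `truth`
#'   (per spot: planted anchor and offset, exact `nearest_focus_id` and
#'   `distance_um`).
#' @export
synth_pla_scene <- function(n_cells = 20, foci_range = c(3, 10),
                            spots_range = c(2, 8), field_um = 20,
                            offset_range_um = c(0.1, 3), seed = 1L) {
  margin <- offset_range_um[2]
  fm_assert(field_um > 2 * margin + 1, "field_um too small for the offsets")
  set.seed(seed)
  foci <- purrr::map_dfr(seq_len(n_cells), function(i) {
    nf <- sample(seq(foci_range[1], foci_range[2]), 1)
    tibble::tibble(cell_id = sprintf("cell%03d", i),
                   x_um = stats::runif(nf, margin, field_um - margin),
                   y_um = stats::runif(nf, margin, field_um - margin))
  })
  foci$focus_id <- sprintf("f%04d", seq_len(nrow(foci)))
  foci <- foci[, c("focus_id", "cell_id", "x_um", "y_um")]

  spots <- purrr::map_dfr(seq_len(n_cells), function(i) {
    cid <- sprintf("cell%03d", i)
    ns <- sample(seq(spots_range[1], spots_range[2]), 1)
    if (ns == 0L) return(tibble::tibble())
    fc <- foci[foci$cell_id == cid, ]
    anchor <- sample(nrow(fc), ns, replace = TRUE)
    off <- stats::runif(ns, offset_range_um[1], offset_range_um[2])
    ang <- stats::runif(ns, 0, 2 * pi)
    tibble::tibble(cell_id = cid,
                   x_um = fc$x_um[anchor] + off * cos(ang),
                   y_um = fc$y_um[anchor] + off * sin(ang),
                   anchor_focus_id = fc$focus_id[anchor],
                   planted_offset_um = off)
  })
  spots$spot_id <- sprintf("s%04d", seq_len(nrow(spots)))

  # exhaustive ground-truth nearest focus, one spot at a time
  truth <- purrr::map_dfr(seq_len(nrow(spots)), function(k) {
    fc <- foci[foci$cell_id == spots$cell_id[k], ]
    d <- sqrt((fc$x_um - spots$x_um[k])^2 + (fc$y_um - spots$y_um[k])^2)
    j <- which.min(d)
    tibble::tibble(spot_id = spots$spot_id[k], cell_id = spots$cell_id[k],
                   anchor_focus_id = spots$anchor_focus_id[k],
                   planted_offset_um = spots$planted_offset_um[k],
                   nearest_focus_id = fc$focus_id[j], distance_um = d[j])
  })

  structure(list(foci = foci,
                 spots = spots[, c("spot_id", "cell_id", "x_um", "y_um")],
                 truth = truth, seed = seed),
            class = "pla_scene")
}
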