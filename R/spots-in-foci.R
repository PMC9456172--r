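#' Count query localizations inside reference-channel foci
#'
#' Bridges the localization and image-cytometry worlds: the reference channel
#' is rendered ([render_localizations()]) onto a pixel grid, its clusters are
#' segmented with the same adaptive focus segmentation used for widefield
#' images ([segment_foci()]), and each query localization is tested against
#' the resulting focus mask. Returns per-focus counts and, for every query
#' molecule, the distance to the nearest reference-focus centroid.
#'
#' @param ref_locs reference-channel localization tibble (`x_nm`, `y_nm`).
#' @param query_locs query-channel localization tibble (`x_nm`, `y_nm`).
#' @param pixel_size_nm rendering pixel size.
#' @param sigma_nm fixed rendering width (defaults to 2.5 pixels).
#' @param params [focus_params()] for the cluster segmentation; areas are in
#'   square micrometres of the *rendered* grid. The default is tuned for
#'   clusters a few rendering pixels across.
#' @param bounds_nm common extent; default spans both tables padded by
#'   `3 * sigma_nm`.
#' @return list of class `spots_in_foci`: `per_focus` (focus label, centroid
#'   in nm, area, `n_query` inside), `query` (per query molecule: containing
#'   `focus` or 0, `nearest_focus`, `distance_nm`), `n_inside`, `foci_mask`.
#' @export
count_spots_in_foci <- function(ref_locs, query_locs, pixel_size_nm = 20,
                                sigma_nm = 2.5 * pixel_size_nm,
                                params = focus_params(tophat_radius_um = 6 * pixel_size_nm / 1000,
                                                      k_sigma = 3,
                                                      min_area_um2 = 3 * (pixel_size_nm / 1000)^2,
                                                      max_area_um2 = 1e4 * (pixel_size_nm / 1000)^2,
                                                      min_threshold = 3 / (2 * pi * (sigma_nm / pixel_size_nm)^2)),
                                bounds_nm = NULL) {
  fm_assert(all(c("x_nm", "y_nm") %in% names(ref_locs)) &&
              all(c("x_nm", "y_nm") %in% names(query_locs)),
            "localization tables must carry x_nm and y_nm")
  fm_assert(nrow(ref_locs) > 0, "no reference localizations")

  if (is.null(bounds_nm)) {
    pad <- 3 * sigma_nm
    xs <- c(ref_locs$x_nm, query_locs$x_nm)
    ys <- c(ref_locs$y_nm, query_locs$y_nm)
    bounds_nm <- c(min(xs) - pad, max(xs) + pad, min(ys) - pad, max(ys) + pad)
  }
  rend <- render_localizations(ref_locs, pixel_size_nm, sigma_mode = "fixed",
                               sigma_nm = sigma_nm, bounds_nm = bounds_nm)
  px <- rend$pixels
  psz_um <- pixel_size_nm / 1000
  md <- acquisition_metadata(pixel_size_um = psz_um,
                             width_px = ncol(px), height_px = nrow(px),
                             field_id = "smlm")
  img <- channel_image(px, "render", md)
  # the whole field acts as one "nucleus" so the per-nucleus adaptive
  # threshold sees the full background statistics
  field <- label_mask(matrix(1L, nrow(px), ncol(px)), "nucleus", psz_um)
  foci <- segment_foci(img, field, params)
  lab <- foci$labels
  n_f <- max(lab)

  centroids <- if (n_f > 0) {
    idx <- which(lab > 0L)
    f <- lab[idx]
    rr <- (idx - 1L) %% nrow(px) + 1L
    cc <- (idx - 1L) %/% nrow(px) + 1L
    # pixel centre (r, c) sits at bounds + (index - 0.5) * pixel
    tibble::tibble(
      focus = seq_len(n_f),
      x_nm = bounds_nm[1] + (rowsum(cc, f)[, 1] / tabulate(f, n_f) - 0.5) * pixel_size_nm,
      y_nm = bounds_nm[3] + (rowsum(rr, f)[, 1] / tabulate(f, n_f) - 0.5) * pixel_size_nm,
      area_px = tabulate(f, n_f))
  } else tibble::tibble(focus = integer(), x_nm = numeric(),
                        y_nm = numeric(), area_px = integer())

  qc <- floor((query_locs$x_nm - bounds_nm[1]) / pixel_size_nm) + 1L
  qr <- floor((query_locs$y_nm - bounds_nm[3]) / pixel_size_nm) + 1L
  in_field <- qc >= 1L & qc <= ncol(px) & qr >= 1L & qr <= nrow(px)
  focus_of <- rep(0L, nrow(query_locs))
  focus_of[in_field] <- lab[cbind(qr[in_field], qc[in_field])]

  nearest <- rep(NA_integer_, nrow(query_locs))
  dist_nm <- rep(NA_real_, nrow(query_locs))
  if (n_f > 0 && nrow(query_locs) > 0) {
    d2 <- outer(query_locs$x_nm, centroids$x_nm, "-")^2 +
      outer(query_locs$y_nm, centroids$y_nm, "-")^2
    j <- max.col(-d2, ties.method = "first")
    nearest <- centroids$focus[j]
    dist_nm <- sqrt(d2[cbind(seq_len(nrow(query_locs)), j)])
  }

  per_focus <- centroids
  per_focus$n_query <- if (n_f > 0)
    tabulate(focus_of[focus_of > 0L], nbins = n_f) else integer()

  structure(list(per_focus = per_focus,
                 query = tibble::tibble(x_nm = query_locs$x_nm,
                                        y_nm = query_locs$y_nm,
                                        focus = focus_of,
                                        nearest_focus = nearest,
                                        distance_nm = dist_nm),
                 n_inside = sum(focus_of > 0L),
                 foci_mask = foci, rendered = rend),
            class = "spots_in_foci")
}

#' @export
print.spots_in_foci <- function(x, ...) {
  cat(sprintf("<spots_in_foci> %d foci, %d / %d query localizations inside\n",
              nrow(x$per_focus), x$n_inside, nrow(x$query)))
  invisible(x)
}
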