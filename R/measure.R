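chan_key <- function(channel) tolower(gsub("[^[:alnum:]]", "", channel))

#' Measure per-cell shape and fluorescence parameters
#'
#' For every nucleus label: area (um2), circularity (`4 * pi * area /
#' perimeter^2`, clamped to 1 for discretisation), centroid in pixel and --
#' when metadata carries a stage position -- stage coordinates, and, for
#' every supplied channel, the integrated intensity (sum of pixel values
#' inside the nucleus) and mean pixel intensity. Column names are derived
#' from channel names: `dna_total`, `dna_mean`, `edu_total`, ...
#'
#' @param nuclei a nucleus [label_mask()].
#' @param images list of [channel_image()] sharing the mask's geometry.
#' @return a tibble with one row per nucleus (`cell_id`, `label`, `field_id`,
#'   `x_px`, `y_px`, `centroid_stage_x_um`, `centroid_stage_y_um`,
#'   `area_um2`, `circularity`, `on_border`, per-channel intensities).
#' @export
measure_cells <- function(nuclei, images) {
  fm_assert(inherits(nuclei, "label_mask") && nuclei$kind == "nucleus",
            "nuclei must be a nucleus label_mask")
  if (inherits(images, "channel_image")) images <- list(images)
  lab <- nuclei$labels
  for (im in images) {
    fm_assert(inherits(im, "channel_image"), "images must be channel_images")
    fm_assert(all(dim(im$pixels) == dim(lab)), "image/mask geometry mismatch")
  }
  n <- max(lab)
  md <- images[[1]]$metadata
  psz <- nuclei$pixel_size_um
  if (n == 0L) {
    return(tibble::tibble(cell_id = character(), label = integer(),
                          field_id = character(), x_px = numeric(), y_px = numeric(),
                          area_um2 = numeric(), circularity = numeric(),
                          on_border = logical()))
  }

  idx <- which(lab > 0L)
  g <- lab[idx]
  counts <- tabulate(g, n)
  rr <- (idx - 1L) %% nrow(lab) + 1L
  cc <- (idx - 1L) %/% nrow(lab) + 1L
  x_px <- unname(rowsum(as.numeric(cc), g)[, 1]) / counts - 1
  y_px <- unname(rowsum(as.numeric(rr), g)[, 1]) / counts - 1

  shp <- EBImage::computeFeatures.shape(lab)
  circ <- pmin(4 * pi * counts / shp[, "s.perimeter"]^2, 1)

  out <- tibble::tibble(
    cell_id = sprintf("%s_c%04d", md$field_id, seq_len(n)),
    label = seq_len(n),
    field_id = md$field_id,
    x_px = x_px, y_px = y_px,
    area_um2 = counts * psz^2,
    circularity = as.numeric(circ),
    on_border = seq_len(n) %in% nuclei$border_labels
  )
  stage <- image_to_stage(cbind(x_px, y_px), md)
  out$centroid_stage_x_um <- stage$stage_x_um
  out$centroid_stage_y_um <- stage$stage_y_um

  for (im in images) {
    key <- chan_key(im$channel)
    tot <- unname(rowsum(im$pixels[idx], g)[, 1])
    out[[paste0(key, "_total")]] <- tot
    out[[paste0(key, "_mean")]] <- tot / counts
  }
  out
}

#' Measure foci per cell and as independent events
#'
#' Produces the flat focus table (each focus as an independent event: parent
#' cell, channel, area, mean/integrated intensity, centroid) and augments the
#' cell table with per-channel aggregates: focus count, summed focus
#' integrated intensity (raw and locally background-subtracted), mean focus
#' area, and the fraction of the nuclear signal localised in foci.
#'
#' Intensities are integrated over the segmented focus dilated by
#' `measure_dilate_px` pixels (clipped to the parent nucleus): the adaptive
#' threshold only captures the bright core of a diffraction-limited focus, so
#' the collar recovers the point-spread tails that carry a substantial share
#' of the focus photons. The background-subtracted focus intensity then
#' subtracts the nucleoplasm level (median of the channel inside the nucleus
#' but outside all dilated foci) times the measured area, so `foci_fraction`
#' estimates the share of signal generated by the protein concentrated in
#' foci rather than the diffuse pool under the focus footprint. Focus areas
#' and centroids are reported from the undilated segmentation.
#'
#' @param foci a focus [label_mask()] parented to `cells`' nuclei mask.
#' @param nuclei the nucleus [label_mask()] the foci were segmented in.
#' @param image the [channel_image()] the foci were segmented from.
#' @param cells cell table from [measure_cells()].
#' @param measure_dilate_px measurement collar width in pixels (0 integrates
#'   over the segmented core only).
#' @return list with `cells` (augmented tibble) and `foci` (flat tibble of
#'   focus records).
#' @export
measure_foci <- function(foci, nuclei, image, cells, measure_dilate_px = 2L) {
  fm_assert(inherits(foci, "label_mask") && foci$kind == "focus",
            "foci must be a focus label_mask")
  lab_f <- foci$labels
  lab_n <- nuclei$labels
  px <- image$pixels
  fm_assert(all(dim(lab_f) == dim(px)) && all(dim(lab_n) == dim(px)),
            "image/mask geometry mismatch")
  n_f <- max(lab_f)
  n_n <- max(lab_n)
  key <- chan_key(image$channel)
  psz <- foci$pixel_size_um

  # measurement mask: segmented foci dilated by the collar (max-label
  # grayscale dilation; rare collar collisions go to the higher label)
  lab_m <- lab_f
  if (n_f > 0L && measure_dilate_px > 0L) {
    brush <- EBImage::makeBrush(2L * as.integer(measure_dilate_px) + 1L,
                                shape = "disc")
    lab_m <- as.matrix(EBImage::dilate(lab_f, brush))
    storage.mode(lab_m) <- "integer"
    lab_m[lab_f > 0L] <- lab_f[lab_f > 0L]
  }

  # nucleoplasm level per nucleus: median outside the dilated foci
  nucleoplasm <- rep(0, max(n_n, 1L))
  if (n_n > 0L) {
    sel <- lab_n > 0L & lab_m == 0L
    nucleoplasm[] <- vapply(split(px[sel], lab_n[sel])[as.character(seq_len(n_n))],
                            function(v) if (length(v)) stats::median(v) else 0,
                            numeric(1))
  }

  if (n_f > 0L) {
    parent <- foci$parent_map
    fm_assert(length(parent) == n_f && all(parent >= 1L & parent <= n_n),
              "focus with unknown parent nucleus")
    # collar pixels outside the parent nucleus are dropped
    out_parent <- lab_m > 0L & lab_n != matrix(c(0L, parent)[lab_m + 1L], nrow(lab_m))
    lab_m[out_parent] <- 0L

    idx <- which(lab_f > 0L)
    g <- lab_f[idx]
    counts <- tabulate(g, n_f)
    rr <- (idx - 1L) %% nrow(px) + 1L
    cc <- (idx - 1L) %/% nrow(px) + 1L

    idx_m <- which(lab_m > 0L)
    g_m <- lab_m[idx_m]
    counts_m <- tabulate(g_m, n_f)
    integrated <- unname(rowsum(px[idx_m], g_m)[, 1])
    bgsub <- pmax(integrated - counts_m * unname(nucleoplasm[parent]), 0)
    focus_tbl <- tibble::tibble(
      focus_id = sprintf("%s_f%05d", key, seq_len(n_f)),
      cell_id = cells$cell_id[match(parent, cells$label)],
      channel = image$channel,
      area_um2 = counts * psz^2,
      measured_area_um2 = counts_m * psz^2,
      mean_intensity = unname(rowsum(px[idx], g)[, 1]) / counts,
      integrated_intensity = integrated,
      integrated_intensity_bgsub = bgsub,
      x_px = unname(rowsum(as.numeric(cc), g)[, 1]) / counts - 1,
      y_px = unname(rowsum(as.numeric(rr), g)[, 1]) / counts - 1
    )
  } else {
    focus_tbl <- tibble::tibble(
      focus_id = character(), cell_id = character(), channel = character(),
      area_um2 = numeric(), measured_area_um2 = numeric(),
      mean_intensity = numeric(),
      integrated_intensity = numeric(), integrated_intensity_bgsub = numeric(),
      x_px = numeric(), y_px = numeric())
  }

  agg <- focus_tbl |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      n_foci = dplyr::n(),
      foci_total = sum(.data$integrated_intensity_bgsub),
      foci_total_raw = sum(.data$integrated_intensity),
      mean_focus_area_um2 = mean(.data$area_um2),
      .groups = "drop")

  cells <- dplyr::left_join(cells, agg, by = "cell_id") |>
    dplyr::mutate(
      n_foci = dplyr::coalesce(.data$n_foci, 0L),
      foci_total = dplyr::coalesce(.data$foci_total, 0),
      foci_total_raw = dplyr::coalesce(.data$foci_total_raw, 0),
      mean_focus_area_um2 = dplyr::coalesce(.data$mean_focus_area_um2, 0))

  total_col <- paste0(key, "_total")
  fm_assert(total_col %in% names(cells),
            sprintf("channel '%s' not measured per cell; run measure_cells with it", image$channel))
  frac <- cells$foci_total / cells[[total_col]]
  frac[cells$n_foci == 0L] <- 0
  undef <- cells[[total_col]] <= 0 & cells$n_foci > 0L
  frac[undef] <- NA_real_
  cells[[paste0("foci_fraction_", key)]] <- pmin(pmax(frac, 0), 1)
  names(cells)[names(cells) == "n_foci"] <- paste0("n_foci_", key)
  names(cells)[names(cells) == "foci_total"] <- paste0("foci_total_", key)
  names(cells)[names(cells) == "foci_total_raw"] <- paste0("foci_total_raw_", key)
  names(cells)[names(cells) == "mean_focus_area_um2"] <- paste0("mean_focus_area_um2_", key)

  list(cells = cells, foci = focus_tbl)
}

#' Fraction of a channel's nuclear signal localised in foci
#'
#' Convenience accessor for the `foci_fraction_<channel>` column computed by
#' [measure_foci()]: focus-localised integrated intensity over the whole
#' nuclear integrated intensity, in `[0, 1]`; `NA` where the nuclear
#' intensity is zero (flagged, excluded from plots).
#'
#' @param cells augmented cell table.
#' @param channel channel name.
#' @return numeric vector of fractions.
#' @export
foci_fraction <- function(cells, channel) {
  col <- paste0("foci_fraction_", chan_key(channel))
  fm_assert(col %in% names(cells),
            sprintf("no foci measurements for channel '%s'", channel))
  cells[[col]]
}

#' Retrieve per-cell image crops for visual inspection
#'
#' Cuts a square crop around each selected cell's nucleus centroid, padded by
#' `pad_um`, from every supplied channel, without rescaling intensities.
#' Crops at the image edge are clipped and flagged.
#'
#' @param cells cell-table subset (e.g. after gating).
#' @param images list of [channel_image()].
#' @param pad_um padding beyond the nucleus radius, in micrometres.
#' @param nuclei optional nucleus [label_mask()]; when given, the crop is
#'   sized from the nucleus bounding box so the full mask is contained.
#' @return list of per-cell entries: `cell_id`, `clipped`, and one intensity
#'   matrix per channel.
#' @export
gallery_crops <- function(cells, images, pad_um = 2, nuclei = NULL) {
  if (inherits(images, "channel_image")) images <- list(images)
  if (nrow(cells) == 0L) return(list())
  md <- images[[1]]$metadata
  psz <- md$pixel_size_um
  pad_px <- ceiling(pad_um / psz)
  dims <- dim(images[[1]]$pixels)

  lapply(seq_len(nrow(cells)), function(i) {
    cy <- round(cells$y_px[i]) + 1L
    cx <- round(cells$x_px[i]) + 1L
    if (!is.null(nuclei)) {
      sel <- which(nuclei$labels == cells$label[i])
      rr <- (sel - 1L) %% dims[1] + 1L
      cc <- (sel - 1L) %/% dims[1] + 1L
      half <- max(cy - min(rr), max(rr) - cy, cx - min(cc), max(cc) - cx) + pad_px
    } else {
      half <- ceiling(sqrt(cells$area_um2[i] / pi) / psz) + pad_px
    }
    r0 <- cy - half; r1 <- cy + half; c0 <- cx - half; c1 <- cx + half
    clipped <- r0 < 1 || c0 < 1 || r1 > dims[1] || c1 > dims[2]
    rs <- max(r0, 1):min(r1, dims[1])
    cs <- max(c0, 1):min(c1, dims[2])
    crops <- lapply(images, function(im) im$pixels[rs, cs, drop = FALSE])
    names(crops) <- vapply(images, function(im) im$channel, character(1))
    c(list(cell_id = cells$cell_id[i], clipped = clipped), crops)
  })
}
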