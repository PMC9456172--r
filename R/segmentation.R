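#' Label masks for nuclei and sub-nuclear foci
#'
#' A label mask holds a 2-D integer matrix (`0` = background, `k > 0` =
#' object `k`) plus what kind of objects it labels. Focus masks also carry a
#' `parent_map` from focus label to nucleus label; focus pixels are always a
#' subset of their parent nucleus.
#'
#' @param labels integer matrix of object labels.
#' @param kind `"nucleus"` or `"focus"`.
#' @param pixel_size_um pixel size carried over from the source image.
#' @param channel source channel (focus masks).
#' @param parent_map named integer vector, focus label -> nucleus label.
#' @param border_labels labels of objects touching the image border.
#' @return object of class `label_mask`.
#' @export
label_mask <- function(labels, kind = c("nucleus", "focus"), pixel_size_um = 1,
                       channel = NA_character_, parent_map = NULL,
                       border_labels = integer()) {
  kind <- match.arg(kind)
  fm_assert(is.matrix(labels) && all(labels >= 0), "labels must be a nonnegative matrix")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, kind = kind, pixel_size_um = pixel_size_um,
                 channel = channel, parent_map = parent_map,
                 border_labels = as.integer(border_labels)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %s: %d object(s), %d x %d px\n",
              x$kind, max(x$labels), ncol(x$labels), nrow(x$labels)))
  invisible(x)
}

n_objects <- function(mask) max(mask$labels)

# drop the given labels and relabel 1..n preserving order
relabel_sequential <- function(labels, drop = integer()) {
  n <- max(labels)
  if (n == 0L) return(labels)
  keep <- setdiff(seq_len(n), drop)
  lut <- integer(n)
  lut[keep] <- seq_along(keep)
  out <- labels
  pos <- labels > 0L
  out[pos] <- lut[labels[pos]]
  out
}

labels_touching_border <- function(labels) {
  edge <- c(labels[1, ], labels[nrow(labels), ], labels[, 1], labels[, ncol(labels)])
  sort(unique(edge[edge > 0L]))
}

#' Segment nuclei on the DNA counterstain
#'
#' Standard high-content nucleus pipeline: Gaussian smoothing, Otsu global
#' threshold, hole filling, distance-transform watershed to split touching
#' nuclei, then an area filter. Objects touching the image border are flagged
#' and kept or dropped per `border`. A low-contrast guard returns an empty
#' mask on blank (noise-only) images instead of thresholding noise.
#'
#' @param dna a background/illumination-corrected DNA [channel_image()].
#' @param min_area_um2,max_area_um2 accepted nucleus area window.
#' @param border `"keep"` (flagged) or `"drop"`.
#' @param smooth_sigma_px Gaussian smoothing sigma before thresholding.
#' @param watershed_tolerance minimum distance-map depth (px) between object
#'   maxima for a split.
#' @param min_contrast minimum (foreground mean - background mean) / image SD
#'   for the threshold to be trusted; below it the image is declared blank.
#' @return a [label_mask()] of kind `"nucleus"`.
#' @export
segment_nuclei <- function(dna, min_area_um2 = 20, max_area_um2 = 1000,
                           border = c("keep", "drop"),
                           smooth_sigma_px = 1, watershed_tolerance = 2,
                           min_contrast = 2) {
  border <- match.arg(border)
  fm_assert(inherits(dna, "channel_image"), "dna must be a channel_image")
  px <- dna$pixels
  psz <- dna$metadata$pixel_size_um

  if (stats::sd(px) == 0) {
    return(label_mask(matrix(0L, nrow(px), ncol(px)), "nucleus", psz, dna$channel))
  }
  if (mean(px == max(px)) > 0.005) {
    rlang::warn("possible saturation: >0.5% of pixels at the maximum value")
  }

  sm <- as.matrix(EBImage::gblur(px, sigma = smooth_sigma_px))
  rng <- range(sm)
  norm <- (sm - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bw <- norm > thr

  # blank-image guard: foreground barely brighter than background means the
  # threshold only split noise
  contrast <- (mean(sm[bw]) - mean(sm[!bw])) / stats::sd(sm)
  if (!is.finite(contrast) || contrast < min_contrast) {
    return(label_mask(matrix(0L, nrow(px), ncol(px)), "nucleus", psz, dna$channel))
  }

  bw <- EBImage::fillHull(matrix(as.integer(bw), nrow(bw)))
  dm <- EBImage::distmap(bw)
  lab <- as.matrix(EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1))
  storage.mode(lab) <- "integer"

  n_raw <- max(lab)
  areas_px <- tabulate(lab[lab > 0L], nbins = n_raw)
  areas_um2 <- areas_px * psz^2
  bad <- which(areas_um2 < min_area_um2 | areas_um2 > max_area_um2)
  on_border <- labels_touching_border(lab)
  if (border == "drop") bad <- union(bad, on_border)
  keep <- setdiff(seq_len(n_raw), bad)
  lut <- integer(n_raw)
  lut[keep] <- seq_along(keep)
  lab <- relabel_sequential(lab, drop = bad)
  border_new <- sort(lut[on_border][lut[on_border] > 0L])

  label_mask(lab, "nucleus", psz, dna$channel, border_labels = border_new)
}

#' Foci segmentation parameters
#'
#' @param tophat_radius_um radius of the white top-hat structuring element;
#'   should exceed the focus radius so foci survive the filter.
#' @param k_sigma per-nucleus threshold multiplier: threshold =
#'   nucleoplasm mean + `k_sigma` * nucleoplasm SD on the top-hat image.
#' @param min_area_um2,max_area_um2 accepted focus area window.
#' @param split_touching split merged foci by an intensity watershed.
#' @param min_threshold absolute floor on the adaptive threshold (image
#'   intensity units, on the top-hat image). Useful for sparse images whose
#'   background statistics are near zero, e.g. rendered localization maps,
#'   where a focus must additionally exceed a known single-object amplitude.
#' @return a `focus_params` list.
#' @export
focus_params <- function(tophat_radius_um = 0.5, k_sigma = 3,
                         min_area_um2 = 0.04, max_area_um2 = 10,
                         split_touching = FALSE, min_threshold = 0) {
  fm_assert(tophat_radius_um > 0 && min_area_um2 > 0 && max_area_um2 > 0,
            "radii and areas must be > 0")
  fm_assert(min_area_um2 < max_area_um2, "min_area_um2 must be < max_area_um2")
  fm_assert(is.numeric(min_threshold) && min_threshold >= 0,
            "min_threshold must be >= 0")
  structure(list(tophat_radius_um = tophat_radius_um, k_sigma = k_sigma,
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 split_touching = isTRUE(split_touching),
                 min_threshold = min_threshold),
            class = "focus_params")
}

#' Segment sub-nuclear foci/spots inside nucleus masks
#'
#' White top-hat filtering flattens the nucleoplasm, then each nucleus gets
#' its own adaptive threshold (nucleoplasm mean + `k_sigma` SD of the top-hat
#' values inside that nucleus). The nucleoplasm statistics are refined by
#' iterated exclusion: pixels above the current threshold are removed and the
#' mean/SD recomputed until the threshold stabilises, so bright foci do not
#' inflate the background SD and mask dimmer foci in the same nucleus (the
#' usual fixed-point background estimator). Connected components above
#' threshold and
#' inside the area window become foci; each focus is assigned to the nucleus
#' containing its centroid and clipped to that nucleus, so focus pixels are
#' always a subset of their parent. Pixels outside all nuclei never belong to
#' a focus.
#'
#' @param channel a corrected [channel_image()] (e.g. gammaH2A.X, 53BP1, PLA).
#' @param nuclei a nucleus [label_mask()] from the same field.
#' @param params a [focus_params()].
#' @return a [label_mask()] of kind `"focus"` with a `parent_map`.
#' @export
segment_foci <- function(channel, nuclei, params = focus_params()) {
  fm_assert(inherits(channel, "channel_image"), "channel must be a channel_image")
  fm_assert(inherits(nuclei, "label_mask") && nuclei$kind == "nucleus",
            "nuclei must be a nucleus label_mask")
  psz <- channel$metadata$pixel_size_um
  fm_assert(is_scalar_num(psz) && psz > 0, "pixel size missing: areas cannot be converted to um2")
  px <- channel$pixels
  lab_n <- nuclei$labels
  fm_assert(all(dim(px) == dim(lab_n)), "image and nucleus mask geometry mismatch")

  r_px <- max(1L, round(params$tophat_radius_um / psz))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  th <- as.matrix(EBImage::whiteTopHat(px, brush))

  n_nuc <- max(lab_n)
  if (n_nuc == 0L) {
    return(label_mask(matrix(0L, nrow(px), ncol(px)), "focus", psz, channel$channel,
                      parent_map = integer()))
  }
  inside <- lab_n > 0L
  grp <- lab_n[inside]
  v <- th[inside]
  stats_for <- function(sel) {
    ns <- pmax(tabulate(grp[sel], n_nuc), 1L)
    acc <- function(x) {
      out <- rep(0, n_nuc)
      s <- rowsum(x, grp[sel])
      out[as.integer(rownames(s))] <- s[, 1]
      out
    }
    mu <- acc(v[sel]) / ns
    m2 <- acc(v[sel]^2) / ns
    list(mu = mu, sd = sqrt(pmax(m2 - mu^2, 0)))
  }
  st <- stats_for(rep(TRUE, length(v)))
  thr <- st$mu + params$k_sigma * st$sd
  sdv <- st$sd
  for (i in seq_len(20L)) {
    st <- stats_for(v <= thr[grp])
    thr_new <- st$mu + params$k_sigma * st$sd
    done <- max(abs(thr_new - thr)) < 1e-8 * max(abs(thr), 1e-12)
    thr <- thr_new
    sdv <- st$sd
    if (done) break
  }

  thr <- pmax(thr, params$min_threshold %||% 0)
  cand <- matrix(FALSE, nrow(px), ncol(px))
  cand[inside] <- v > thr[grp]

  lab_f <- as.matrix(EBImage::bwlabel(matrix(as.integer(cand), nrow(cand))))
  storage.mode(lab_f) <- "integer"
  if (params$split_touching && max(lab_f) > 0L) {
    rel <- th - min(th)
    lab_f <- as.matrix(EBImage::watershed(rel * (lab_f > 0L),
                                          tolerance = stats::median(params$k_sigma * sdv),
                                          ext = 1))
    storage.mode(lab_f) <- "integer"
  }

  n_f <- max(lab_f)
  if (n_f == 0L) {
    return(label_mask(lab_f, "focus", psz, channel$channel, parent_map = integer()))
  }

  # centroid-based parent assignment, then clip each focus to its parent
  idx <- which(lab_f > 0L)
  f <- lab_f[idx]
  rr <- (idx - 1L) %% nrow(px) + 1L
  cc <- (idx - 1L) %/% nrow(px) + 1L
  cr <- rowsum(rr, f)[, 1] / tabulate(f, n_f)
  ccol <- rowsum(cc, f)[, 1] / tabulate(f, n_f)
  parent <- lab_n[cbind(pmin(pmax(round(cr), 1L), nrow(px)),
                        pmin(pmax(round(ccol), 1L), ncol(px)))]
  # a centroid can fall on background for odd shapes: fall back to majority overlap
  for (k in which(parent == 0L)) {
    ov <- lab_n[idx[f == k]]
    ov <- ov[ov > 0L]
    parent[k] <- if (length(ov)) as.integer(names(which.max(table(ov)))) else 0L
  }
  # clip to parent and drop orphans / out-of-window areas
  keep_px <- parent[f] == lab_n[idx]
  lab_f[idx[!keep_px]] <- 0L
  areas_px <- tabulate(lab_f[lab_f > 0L], nbins = n_f)
  areas_um2 <- areas_px * psz^2
  drop <- which(parent == 0L | areas_um2 < params$min_area_um2 |
                  areas_um2 > params$max_area_um2)
  lab_f <- relabel_sequential(lab_f, drop = drop)
  parent_map <- parent[setdiff(seq_len(n_f), drop)]
  names(parent_map) <- seq_along(parent_map)

  label_mask(lab_f, "focus", psz, channel$channel, parent_map = parent_map)
}
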