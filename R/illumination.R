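#' Correct illumination inhomogeneity and background
#'
#' Standard shading correction: `corrected = (raw - background) / flatfield`,
#' clipped at zero, where the flatfield is normalised to mean 1 so corrected
#' intensities stay on the raw scale. The background is either a global
#' constant (a low percentile of the image) or a coarse rolling-median
#' surface for structured background.
#'
#' @param image a [channel_image()].
#' @param flatfield a numeric matrix of the same shape (strictly positive
#'   after normalisation), `1` for none, or `"estimate"` to estimate one from
#'   `reference_images` (pixelwise median over at least 10 images, smoothed).
#' @param background_mode `list(mode = "constant-percentile", percentile =
#'   0.05)` or `list(mode = "rolling-median", window_px = 65)` (odd window;
#'   separable row/column running median).
#' @param reference_images list of [channel_image()] used when
#'   `flatfield = "estimate"`.
#' @return a corrected [channel_image()].
#' @export
correct_illumination <- function(image,
                                 flatfield = 1,
                                 background_mode = list(mode = "constant-percentile",
                                                        percentile = 0.05),
                                 reference_images = NULL) {
  fm_assert(inherits(image, "channel_image"), "image must be a channel_image")
  px <- image$pixels

  if (identical(flatfield, "estimate")) {
    flatfield <- estimate_flatfield(reference_images)
  }
  if (identical(flatfield, 1) || is.null(flatfield)) {
    ff <- matrix(1, nrow(px), ncol(px))
  } else {
    fm_assert(is.matrix(flatfield) && all(dim(flatfield) == dim(px)),
              "flatfield must match the image shape")
    ff <- flatfield / mean(flatfield)
    fm_assert(all(ff > 0), "flatfield with non-positive values")
  }

  mode <- background_mode$mode %||% "constant-percentile"
  bg <- switch(mode,
    "constant-percentile" = {
      p <- background_mode$percentile %||% 0.05
      as.numeric(stats::quantile(px, p))
    },
    "rolling-median" = {
      w <- background_mode$window_px %||% 65L
      rolling_median_surface(px, w)
    },
    fm_abort(paste("unknown background_mode:", mode))
  )

  out <- pmax((px - bg) / ff, 0)
  dim(out) <- dim(px)
  channel_image(out, image$channel, image$metadata)
}

#' @rdname correct_illumination
#' @export
estimate_flatfield <- function(reference_images) {
  fm_assert(is.list(reference_images) && length(reference_images) >= 10L,
            "flatfield estimation needs at least 10 reference images")
  stacks <- lapply(reference_images, function(im) {
    fm_assert(inherits(im, "channel_image"), "reference_images must be channel_images")
    im$pixels
  })
  dims <- dim(stacks[[1]])
  fm_assert(all(vapply(stacks, function(m) all(dim(m) == dims), logical(1))),
            "reference images must share one shape")
  med <- apply(simplify2array(stacks), c(1, 2), stats::median)
  sm <- as.matrix(EBImage::gblur(med, sigma = max(dims) / 32))
  sm / mean(sm)
}

# coarse background surface: separable running median (rows then columns)
rolling_median_surface <- function(px, window_px) {
  w <- as.integer(window_px)
  if (w %% 2L == 0L) w <- w + 1L
  byrow <- t(apply(px, 1, function(r) stats::runmed(r, min(w, length(r) - (1 - length(r) %% 2)))))
  apply(byrow, 2, function(cc) stats::runmed(cc, min(w, length(cc) - (1 - length(cc) %% 2))))
}
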