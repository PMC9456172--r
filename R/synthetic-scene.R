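#' Specification for a synthetic microscopy scene
#'
#' Describes a field of elliptical nuclei with uniform DNA staining and, per
#' focus channel, a diffuse nucleoplasmic level plus Gaussian foci of known
#' photon mass, over a constant or linearly shaded background, with optional
#' Poisson shot noise and Gaussian read noise. [synth_microscopy_scene()]
#' turns it into images plus exact planted values.
#'
#' @param width_px,height_px field size in pixels.
#' @param pixel_size_um pixel size.
#' @param nuclei tibble with columns `x_px`, `y_px` (0-based centers),
#'   `a_px`, `b_px` (semi-axes), `theta` (radians), `dna_intensity`
#'   (photons/pixel).
#' @param foci_channels named list; each element is
#'   `list(nucleoplasm = <photons/px>, foci = tibble(nucleus, x_px, y_px,
#'   sigma_px, photons))`.
#' @param background constant background level (photons/pixel).
#' @param gradient `NULL` for flat illumination, or `c(lo, hi)`: a linear
#'   left-to-right multiplicative shading field.
#' @param poisson_noise,read_sd camera model.
#' @param seed RNG seed for the noise.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(width_px = 192, height_px = 192, pixel_size_um = 0.2,
                       nuclei, foci_channels = list(),
                       background = 5, gradient = NULL,
                       poisson_noise = TRUE, read_sd = 2, seed = 1L) {
  fm_assert(is.data.frame(nuclei) &&
              all(c("x_px", "y_px", "a_px", "b_px", "theta", "dna_intensity") %in% names(nuclei)),
            "nuclei must carry x_px, y_px, a_px, b_px, theta, dna_intensity")
  r <- pmax(nuclei$a_px, nuclei$b_px)
  inside <- nuclei$x_px - r >= 0 & nuclei$x_px + r <= width_px - 1 &
    nuclei$y_px - r >= 0 & nuclei$y_px + r <= height_px - 1
  fm_assert(all(inside), "nuclei outside the field")
  structure(list(width_px = width_px, height_px = height_px,
                 pixel_size_um = pixel_size_um, nuclei = nuclei,
                 foci_channels = foci_channels, background = background,
                 gradient = gradient, poisson_noise = poisson_noise,
                 read_sd = read_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Random scene specification under benchmark conditions
#'
#' Draws a seeded random scene respecting the standard test conditions:
#' nucleus centers at least `separation_factor` times the larger semi-axis
#' apart (default 2.5x, i.e. clearly separated), nuclei fully inside the
#' field, foci well inside their nucleus and at least `8 * sigma_px` apart so
#' planted counts are unambiguous (when a nucleus cannot geometrically hold
#' the drawn number of separated foci, fewer are placed and the ground truth
#' reflects the actual count).
#'
#' @param n_nuclei nuclei per scene.
#' @param foci_range integer range of foci per nucleus for the focus channel
#'   (`NULL` for a DNA-only scene).
#' @param seed RNG seed.
#' @param dna_intensity,nucleoplasm,focus_photons,focus_sigma_px,background,read_sd
#'   photometry (defaults give nucleus SNR > 10 and focus peak/nucleoplasm
#'   contrast ~6).
#' @param width_px,height_px,pixel_size_um geometry.
#' @param separation_factor minimum center distance in units of the larger
#'   semi-axis.
#' @param gradient,poisson_noise passed to [scene_spec()].
#' @return a `scene_spec`.
#' @export
random_scene_spec <- function(n_nuclei = 5, foci_range = c(2, 6), seed = 1L,
                              dna_intensity = 120, nucleoplasm = 80,
                              focus_photons = 8000, focus_sigma_px = 1.3,
                              background = 5, read_sd = 2,
                              width_px = 256, height_px = 256,
                              pixel_size_um = 0.2,
                              separation_factor = 2.5,
                              gradient = NULL, poisson_noise = TRUE) {
  set.seed(seed)
  a <- stats::runif(n_nuclei, 16, 21)
  b <- a * stats::runif(n_nuclei, 0.75, 1)
  r <- pmax(a, b)
  margin <- r + 4
  xs <- ys <- numeric(0)
  for (i in seq_len(n_nuclei)) {
    for (try in 1:2000) {
      x <- stats::runif(1, margin[i], width_px - 1 - margin[i])
      y <- stats::runif(1, margin[i], height_px - 1 - margin[i])
      if (!length(xs) ||
          all(sqrt((xs - x)^2 + (ys - y)^2) >=
                separation_factor * (r[seq_along(xs)] + r[i]) / 2)) break
      if (try == 2000) fm_abort("could not place nuclei at the requested separation")
    }
    xs <- c(xs, x); ys <- c(ys, y)
  }
  nuclei <- tibble::tibble(x_px = xs, y_px = ys, a_px = a, b_px = b,
                           theta = stats::runif(n_nuclei, 0, pi),
                           dna_intensity = dna_intensity)
  foci_channels <- list()
  if (!is.null(foci_range)) {
    foci <- purrr::map_dfr(seq_len(n_nuclei), function(i) {
      nf <- sample(seq(foci_range[1], foci_range[2]), 1)
      fx <- fy <- numeric(0)
      attempts <- 0L
      while (length(fx) < nf && attempts < 500L) {
        attempts <- attempts + 1L
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1)) * 0.7
        px <- xs[i] + rad * a[i] * cos(ang) * cos(nuclei$theta[i]) -
          rad * b[i] * sin(ang) * sin(nuclei$theta[i])
        py <- ys[i] + rad * a[i] * cos(ang) * sin(nuclei$theta[i]) +
          rad * b[i] * sin(ang) * cos(nuclei$theta[i])
        # 8 sigma separation keeps the above-threshold cores of neighbouring
        # foci disjoint for any sensible adaptive threshold, so the planted
        # count is unambiguous for a resolution-limited detector
        if (!length(fx) || all(sqrt((fx - px)^2 + (fy - py)^2) >= 8 * focus_sigma_px)) {
          fx <- c(fx, px); fy <- c(fy, py)
        }
      }
      tibble::tibble(nucleus = i, x_px = fx, y_px = fy,
                     sigma_px = focus_sigma_px, photons = focus_photons)
    })
    foci_channels <- list(gH2AX = list(nucleoplasm = nucleoplasm, foci = foci))
  }
  scene_spec(width_px, height_px, pixel_size_um, nuclei, foci_channels,
             background, gradient, poisson_noise, read_sd, seed)
}

ellipse_mask <- function(width, height, x0, y0, a, b, theta) {
  xg <- matrix(rep(0:(width - 1), each = height), height)
  yg <- matrix(rep(0:(height - 1), width), height)
  xr <- (xg - x0) * cos(theta) + (yg - y0) * sin(theta)
  yr <- -(xg - x0) * sin(theta) + (yg - y0) * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

# exact-mass Gaussian spot: separable pixel-integrated kernel added in place
add_gaussian_spot <- function(img, x0, y0, sigma, photons) {
  h <- nrow(img); w <- ncol(img)
  ext <- ceiling(5 * sigma)
  cols <- max(1, floor(x0) - ext + 1):min(w, ceiling(x0) + ext + 1)
  rows <- max(1, floor(y0) - ext + 1):min(h, ceiling(y0) + ext + 1)
  # pixel j covers [j - 1.5, j - 0.5) in 0-based center convention
  mx <- stats::pnorm((cols - 0.5 - x0) / sigma) - stats::pnorm((cols - 1.5 - x0) / sigma)
  my <- stats::pnorm((rows - 0.5 - y0) / sigma) - stats::pnorm((rows - 1.5 - y0) / sigma)
  img[rows, cols] <- img[rows, cols] + photons * (my %o% mx)
  img
}

#' Generate a synthetic multichannel microscopy scene with ground truth
#'
#' Renders the DNA channel (uniform intensity over each elliptical nucleus)
#' and any focus channels (diffuse nucleoplasm plus pixel-integrated Gaussian
#' foci of exact photon mass) over the background, applies the shading
#' gradient, then the camera noise. All planted values are returned exactly:
#' per-nucleus areas, photon sums per channel, per-focus positions and
#' masses, and the planted fraction of focus-channel photons localised in
#' foci.
#'
#' @param spec a [scene_spec()] / [random_scene_spec()].
#' @return list with `images` (named list of [channel_image()]), `truth`
#'   (list of `nuclei` and `foci` tibbles), and `spec`.
#' @export
synth_microscopy_scene <- function(spec) {
  fm_assert(inherits(spec, "scene_spec"), "spec must be a scene_spec")
  set.seed(spec$seed)
  h <- spec$height_px; w <- spec$width_px
  nuc <- spec$nuclei
  n <- nrow(nuc)

  masks <- lapply(seq_len(n), function(i)
    ellipse_mask(w, h, nuc$x_px[i], nuc$y_px[i], nuc$a_px[i], nuc$b_px[i], nuc$theta[i]))
  lab <- matrix(0L, h, w)
  for (i in seq_len(n)) lab[masks[[i]]] <- i

  grad <- if (is.null(spec$gradient)) matrix(1, h, w) else
    matrix(rep(seq(spec$gradient[1], spec$gradient[2], length.out = w), each = h), h)

  md <- acquisition_metadata(pixel_size_um = spec$pixel_size_um,
                             width_px = w, height_px = h,
                             field_id = sprintf("synth%04d", spec$seed))
  noisify <- function(img) {
    out <- img * grad
    if (isTRUE(spec$poisson_noise)) out <- matrix(stats::rpois(h * w, out), h)
    if (spec$read_sd > 0) out <- out + stats::rnorm(h * w, 0, spec$read_sd)
    pmax(out, 0)
  }

  dna_clean <- matrix(spec$background, h, w)
  for (i in seq_len(n)) dna_clean[masks[[i]]] <- dna_clean[masks[[i]]] + nuc$dna_intensity[i]
  images <- list(DNA = channel_image(noisify(dna_clean), "DNA", md))

  areas <- vapply(masks, sum, numeric(1))
  truth_nuclei <- tibble::tibble(
    nucleus = seq_len(n),
    x_px = nuc$x_px, y_px = nuc$y_px,
    area_px = areas,
    area_um2 = areas * spec$pixel_size_um^2,
    dna_photons = areas * nuc$dna_intensity)

  truth_foci <- tibble::tibble()
  for (ch in names(spec$foci_channels)) {
    cfg <- spec$foci_channels[[ch]]
    img <- matrix(spec$background, h, w)
    for (i in seq_len(n)) img[masks[[i]]] <- img[masks[[i]]] + cfg$nucleoplasm
    ff <- cfg$foci
    for (k in seq_len(nrow(ff))) {
      img <- add_gaussian_spot(img, ff$x_px[k], ff$y_px[k], ff$sigma_px[k], ff$photons[k])
    }
    images[[ch]] <- channel_image(noisify(img), ch, md)

    agg <- ff |>
      dplyr::group_by(.data$nucleus) |>
      dplyr::summarise(n_foci = dplyr::n(), foci_photons = sum(.data$photons),
                       .groups = "drop")
    truth_nuclei <- truth_nuclei |>
      dplyr::left_join(agg, by = "nucleus") |>
      dplyr::mutate(
        n_foci = dplyr::coalesce(.data$n_foci, 0L),
        foci_photons = dplyr::coalesce(.data$foci_photons, 0),
        nucleoplasm_photons = .data$area_px * cfg$nucleoplasm,
        photon_fraction = .data$foci_photons /
          (.data$foci_photons + .data$nucleoplasm_photons))
    names(truth_nuclei)[names(truth_nuclei) == "n_foci"] <- paste0("n_foci_", chan_key(ch))
    names(truth_nuclei)[names(truth_nuclei) == "foci_photons"] <- paste0("foci_photons_", chan_key(ch))
    names(truth_nuclei)[names(truth_nuclei) == "nucleoplasm_photons"] <- paste0("nucleoplasm_photons_", chan_key(ch))
    names(truth_nuclei)[names(truth_nuclei) == "photon_fraction"] <- paste0("photon_fraction_", chan_key(ch))
    truth_foci <- dplyr::bind_rows(truth_foci, dplyr::mutate(ff, channel = ch))
  }

  list(images = images,
       truth = list(nuclei = truth_nuclei, foci = truth_foci, labels = lab),
       spec = spec)
}
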