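#' Acquisition metadata for one microscope field
#'
#' Bundles the information needed to place an image on the microscope stage:
#' the stage position of the image origin, the pixel size, the image extent
#' and the axis orientation. This is what the relocalization math
#' ([image_to_stage()]) consumes when converting a segmented nucleus centroid
#' back into a stage position for re-acquisition.
#'
#' Pixel coordinates are 0-based `(x, y)` with `x` along image columns and
#' `y` along rows; the pixel center sits at integer coordinates, and pixel
#' `(0, 0)` is the image origin whose stage position is
#' `(stage_x_um, stage_y_um)`.
#'
#' @param stage_x_um,stage_y_um stage position of the image origin, in
#'   micrometres.
#' @param pixel_size_um pixel size in micrometres per pixel (> 0).
#' @param width_px,height_px image extent in pixels (>= 1).
#' @param axis_orientation length-2 vector of signs (+1/-1) mapping image x
#'   and y axes onto stage axes.
#' @param field_id identifier of the acquisition field.
#' @return an object of class `acquisition_metadata`.
#' @export
#' @examples
#' md <- acquisition_metadata(1000, 2000, 0.11, 512, 512)
#' image_to_stage(c(100, 50), md)
acquisition_metadata <- function(stage_x_um = 0, stage_y_um = 0,
                                 pixel_size_um = 1,
                                 width_px, height_px,
                                 axis_orientation = c(1, 1),
                                 field_id = "field_1") {
  fm_assert(is_scalar_num(pixel_size_um) && pixel_size_um > 0,
            "pixel_size_um must be a positive number")
  fm_assert(is_scalar_num(stage_x_um) && is_scalar_num(stage_y_um),
            "stage position must be finite")
  fm_assert(is_scalar_num(width_px) && width_px >= 1 &&
              is_scalar_num(height_px) && height_px >= 1,
            "width_px and height_px must be >= 1")
  fm_assert(length(axis_orientation) == 2L && all(abs(axis_orientation) == 1),
            "axis_orientation must be two signs (+1/-1)")
  structure(
    list(stage_x_um = stage_x_um, stage_y_um = stage_y_um,
         pixel_size_um = pixel_size_um,
         width_px = as.integer(width_px), height_px = as.integer(height_px),
         axis_orientation = as.numeric(axis_orientation),
         field_id = as.character(field_id)),
    class = "acquisition_metadata"
  )
}

#' A single fluorescence channel image
#'
#' One 2-D intensity plane plus its channel name and acquisition metadata.
#' Pixels are stored as a numeric matrix in `(row, col)` order, so
#' `dim(pixels) == c(height_px, width_px)`.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param channel channel name, e.g. `"DNA"`, `"EdU"`, `"gH2AX"`, `"53BP1"`,
#'   `"PLA"`.
#' @param metadata an [acquisition_metadata()] object; if missing, a default
#'   with pixel size 1 um is created from the matrix dimensions.
#' @return object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel, metadata = NULL) {
  fm_assert(is.matrix(pixels) && is.numeric(pixels), "pixels must be a numeric matrix")
  fm_assert(all(pixels >= 0, na.rm = TRUE), "intensities must be >= 0")
  if (is.null(metadata)) {
    metadata <- acquisition_metadata(width_px = ncol(pixels), height_px = nrow(pixels))
  }
  fm_assert(inherits(metadata, "acquisition_metadata"), "metadata must be acquisition_metadata")
  fm_assert(nrow(pixels) == metadata$height_px && ncol(pixels) == metadata$width_px,
            "pixels shape must equal (height_px, width_px)")
  structure(list(pixels = pixels, channel = as.character(channel), metadata = metadata),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s  %d x %d px, %.4g um/px, field %s\n",
              x$channel, x$metadata$width_px, x$metadata$height_px,
              x$metadata$pixel_size_um, x$metadata$field_id))
  invisible(x)
}

#' Convert image pixel coordinates to stage positions
#'
#' Relocalization: maps 0-based pixel `(x, y)` coordinates to absolute stage
#' positions in micrometres, so that cells selected by gating can be
#' re-acquired at higher resolution. `stage_to_image()` is the exact inverse.
#'
#' @param pixel_xy numeric vector `c(x, y)` or a two-column matrix/data frame
#'   of pixel coordinates (0-based, pixel centers at integers).
#' @param metadata an [acquisition_metadata()].
#' @return a tibble with columns `stage_x_um`, `stage_y_um` (or `x_px`,
#'   `y_px` for the inverse).
#' @export
image_to_stage <- function(pixel_xy, metadata) {
  xy <- as_xy_matrix(pixel_xy)
  fm_assert(all(is.finite(xy)), "pixel coordinates must be finite")
  oob <- xy[, 1] < 0 | xy[, 1] > metadata$width_px - 1 |
    xy[, 2] < 0 | xy[, 2] > metadata$height_px - 1
  if (any(oob)) {
    rlang::warn(sprintf("%d pixel coordinate(s) outside image bounds", sum(oob)))
  }
  s <- metadata$axis_orientation
  tibble::tibble(
    stage_x_um = metadata$stage_x_um + s[1] * xy[, 1] * metadata$pixel_size_um,
    stage_y_um = metadata$stage_y_um + s[2] * xy[, 2] * metadata$pixel_size_um
  )
}

#' @rdname image_to_stage
#' @param stage_xy stage coordinates `c(x_um, y_um)` or a two-column matrix.
#' @export
stage_to_image <- function(stage_xy, metadata) {
  xy <- as_xy_matrix(stage_xy)
  fm_assert(all(is.finite(xy)), "stage coordinates must be finite")
  s <- metadata$axis_orientation
  tibble::tibble(
    x_px = (xy[, 1] - metadata$stage_x_um) / (s[1] * metadata$pixel_size_um),
    y_px = (xy[, 2] - metadata$stage_y_um) / (s[2] * metadata$pixel_size_um)
  )
}

as_xy_matrix <- function(xy) {
  if (is.data.frame(xy)) xy <- as.matrix(xy)
  if (is.null(dim(xy))) {
    fm_assert(length(xy) == 2L, "coordinates must be c(x, y) or a two-column matrix")
    xy <- matrix(as.numeric(xy), ncol = 2L)
  }
  fm_assert(ncol(xy) == 2L, "coordinates must have two columns")
  storage.mode(xy) <- "double"
  xy
}
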