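#' Write and read channel images as TIFF with a JSON metadata sidecar
#'
#' Images are stored as single-plane TIFF. Integer-valued images in
#' `[0, 65535]` are written losslessly as 16-bit; anything else as 32-bit
#' float, scaled into `[0, 1]` with the scale factor recorded in the sidecar
#' (round trip accurate to ~1e-7 relative). Acquisition metadata and channel
#' name travel in `<path>.json`; vendor metadata formats are deliberately not
#' parsed -- adapters should populate [acquisition_metadata()] and call these
#' writers.
#'
#' @param img a [channel_image()].
#' @param path output TIFF path; the sidecar is written at `paste0(path, ".json")`.
#' @return `path`, invisibly (`read_channel_image()` returns a `channel_image`).
#' @export
write_channel_image <- function(img, path) {
  fm_assert(inherits(img, "channel_image"), "img must be a channel_image")
  px <- img$pixels
  integerish <- all(px == round(px)) && max(px) <= 65535
  if (integerish) {
    tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L)
    scale <- 65535
    kind <- "uint16"
  } else {
    scale <- max(px, 1e-300)
    tiff::writeTIFF(px / scale, path, bits.per.sample = 32L)
    kind <- "float32"
  }
  md <- img$metadata
  sidecar <- list(
    channel = img$channel, kind = kind, scale = scale,
    stage_x_um = md$stage_x_um, stage_y_um = md$stage_y_um,
    pixel_size_um = md$pixel_size_um,
    width_px = md$width_px, height_px = md$height_px,
    axis_orientation = md$axis_orientation, field_id = md$field_id
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_channel_image
#' @export
read_channel_image <- function(path) {
  fm_assert(file.exists(path), paste("unreadable file:", path))
  side_path <- paste0(path, ".json")
  fm_assert(file.exists(side_path), paste("missing metadata sidecar:", side_path))
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  fm_assert(!is.null(side$pixel_size_um), "missing pixel size in sidecar metadata")
  px <- tiff::readTIFF(path)
  if (identical(side$kind, "uint16")) {
    px <- round(px * 65535)
  } else {
    px <- px * side$scale
  }
  md <- acquisition_metadata(
    stage_x_um = side$stage_x_um, stage_y_um = side$stage_y_um,
    pixel_size_um = side$pixel_size_um,
    width_px = ncol(px), height_px = nrow(px),
    axis_orientation = side$axis_orientation, field_id = side$field_id
  )
  channel_image(px, side$channel, md)
}

#' Read a set of images grouped into acquisition fields
#'
#' Groups image files into fields and assigns channel names by parsing file
#' names with a layout configuration. The layout names a regular expression
#' with two capture groups and says which group is the field token and which
#' the channel token; a channel map translates file tokens into canonical
#' channel names.
#'
#' @param paths character vector of TIFF paths written by
#'   [write_channel_image()] (each with its JSON sidecar).
#' @param layout_config a list with elements `pattern` (regex with capture
#'   groups), `groups` (character vector naming the capture groups in order,
#'   containing `"field"` and `"channel"`), optional `channel_map` (named
#'   character vector token -> channel), and optional `required` (channels
#'   every field must contain, default `"DNA"`).
#' @return a named list of fields; each field is a named list of
#'   [channel_image()] objects keyed by channel. Fields missing required
#'   channels raise an error naming the field.
#' @export
read_image_set <- function(paths, layout_config) {
  fm_assert(all(file.exists(paths)), paste(
    "unreadable file(s):", paste(paths[!file.exists(paths)], collapse = ", ")))
  fm_assert(is.list(layout_config) && !is.null(layout_config$pattern) &&
              !is.null(layout_config$groups),
            "layout_config needs 'pattern' and 'groups'")
  groups <- layout_config$groups
  required <- layout_config$required %||% "DNA"
  tokens <- regmatches(basename(paths), regexec(layout_config$pattern, basename(paths)))
  bad <- vapply(tokens, function(m) length(m) != length(groups) + 1L, logical(1))
  fm_assert(!any(bad), paste("file name(s) not matching layout pattern:",
                             paste(basename(paths)[bad], collapse = ", ")))
  field_tok <- vapply(tokens, function(m) m[which(groups == "field") + 1L], character(1))
  chan_tok <- vapply(tokens, function(m) m[which(groups == "channel") + 1L], character(1))
  cmap <- layout_config$channel_map
  chan <- if (is.null(cmap)) chan_tok else unname(cmap[chan_tok])
  fm_assert(!anyNA(chan), "channel token(s) missing from channel_map")

  fields <- split(seq_along(paths), field_tok)
  out <- lapply(names(fields), function(f) {
    idx <- fields[[f]]
    ch <- chan[idx]
    if (anyDuplicated(ch)) {
      fm_abort(sprintf("channel '%s' named twice in field '%s'",
                       ch[duplicated(ch)][1], f))
    }
    imgs <- lapply(idx, function(i) read_channel_image(paths[i]))
    # the layout's canonical channel name wins over whatever the file says
    imgs <- Map(function(im, cc) { im$channel <- cc; im }, imgs, ch)
    names(imgs) <- ch
    missing <- setdiff(required, ch)
    if (length(missing)) {
      fm_abort(sprintf("field '%s' is missing required channel(s): %s",
                       f, paste(missing, collapse = ", ")))
    }
    imgs
  })
  names(out) <- names(fields)
  out
}
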