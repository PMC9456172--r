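#' The analysis-configuration schema
#'
#' The published schema that [validate_analysis_config()] enforces before a
#' pipeline run touches any data. Each entry names a config section, its
#' allowed keys and whether the section is required.
#'
#' @return nested list describing sections, keys and requiredness.
#' @export
analysis_config_schema <- function() {
  list(
    input = list(required = TRUE,
                 keys = c("dir", "pattern", "groups", "channel_map",
                          "required_channels")),
    illumination = list(required = FALSE,
                        keys = c("enabled", "background_mode")),
    segmentation = list(required = TRUE, keys = c("nuclei", "foci")),
    gates = list(required = FALSE, keys = c("name", "type", "col", "min", "max")),
    cellcycle = list(required = FALSE,
                     keys = c("enabled", "edu_col", "dna_col", "edu_threshold",
                              "dna_ref_2n", "windows")),
    proximity = list(required = FALSE,
                     keys = c("enabled", "spots_channel", "foci_channel",
                              "threshold_um")),
    output = list(required = TRUE, keys = "dir"),
    seed = list(required = FALSE, keys = character())
  )
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return the validated config list.
#' @export
read_analysis_config <- function(path) {
  fm_assert(file.exists(path), paste("unreadable config:", path))
  config <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    fm_abort("config must be a .yaml/.yml or .json file")
  }
  validate_analysis_config(config)
}

#' Validate an analysis configuration against the schema
#'
#' Checks structure (unknown sections or keys are errors), required sections,
#' types of the critical fields, and cross-references: every channel named in
#' the foci/proximity sections must be a canonical channel produced by the
#' input channel map. Runs before any computation, so a bad config never
#' starts a pipeline.
#'
#' @param config a config list (e.g. from [read_analysis_config()]).
#' @return the config, normalised (defaults filled), invisibly usable.
#' @export
validate_analysis_config <- function(config) {
  schema <- analysis_config_schema()
  fm_assert(is.list(config), "config must be a list")
  unknown <- setdiff(names(config), names(schema))
  fm_assert(length(unknown) == 0L,
            paste("unknown config section(s):", paste(unknown, collapse = ", ")))
  for (sec in names(schema)) {
    if (isTRUE(schema[[sec]]$required)) {
      fm_assert(sec %in% names(config), paste("missing config section:", sec))
    }
  }
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    fm_assert(length(bad) == 0L,
              sprintf("unknown key(s) in %s: %s", where, paste(bad, collapse = ", ")))
  }

  inp <- config$input
  check_keys(inp, schema$input$keys, "input")
  fm_assert(is.character(inp$dir %||% NA) && !is.na(inp$dir), "input$dir must be a string")
  fm_assert(is.character(inp$pattern %||% NA), "input$pattern must be a regex string")
  fm_assert(is.character(inp$groups) && all(c("field", "channel") %in% inp$groups),
            "input$groups must contain 'field' and 'channel'")
  fm_assert(!is.null(inp$channel_map) && length(names(inp$channel_map)) > 0,
            "input$channel_map is required (file token -> channel)")
  channel_map <- unlist(inp$channel_map)
  known <- unname(channel_map)
  config$input$required_channels <- inp$required_channels %||% "DNA"
  fm_assert(all(config$input$required_channels %in% known),
            "required channel(s) not produced by channel_map")

  seg <- config$segmentation
  check_keys(seg, schema$segmentation$keys, "segmentation")
  fm_assert(!is.null(seg$nuclei), "segmentation$nuclei is required")
  check_keys(seg$nuclei, c("min_area_um2", "max_area_um2", "border",
                           "smooth_sigma_px", "watershed_tolerance",
                           "min_contrast"), "segmentation$nuclei")
  for (ch in names(seg$foci)) {
    fm_assert(ch %in% known,
              sprintf("unknown channel in segmentation$foci: '%s'", ch))
    check_keys(seg$foci[[ch]], c("tophat_radius_um", "k_sigma", "min_area_um2",
                                 "max_area_um2", "split_touching",
                                 "measure_dilate_px"),
               sprintf("segmentation$foci$%s", ch))
  }

  if (!is.null(config$illumination)) {
    check_keys(config$illumination, schema$illumination$keys, "illumination")
  }
  if (!is.null(config$gates)) {
    for (i in seq_along(config$gates)) {
      g <- config$gates[[i]]
      check_keys(g, schema$gates$keys, sprintf("gates[[%d]]", i))
      fm_assert(identical(g$type %||% "interval", "interval"),
                "only interval gates are configurable; compose others in code")
      fm_assert(is.character(g$col %||% NA), "gate without a column")
    }
  }
  if (!is.null(config$cellcycle)) {
    check_keys(config$cellcycle, schema$cellcycle$keys, "cellcycle")
  }
  prox <- config$proximity
  if (!is.null(prox) && isTRUE(prox$enabled %||% TRUE)) {
    check_keys(prox, schema$proximity$keys, "proximity")
    for (k in c("spots_channel", "foci_channel")) {
      fm_assert(!is.null(prox[[k]]), sprintf("proximity$%s is required", k))
      fm_assert(prox[[k]] %in% known,
                sprintf("unknown channel in proximity$%s: '%s'", k, prox[[k]]))
      fm_assert(prox[[k]] %in% names(seg$foci),
                sprintf("proximity channel '%s' has no foci segmentation configured",
                        prox[[k]]))
    }
    config$proximity$threshold_um <- prox$threshold_um %||% 1
  }
  fm_assert(is.character(config$output$dir %||% NA), "output$dir must be a string")
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

#' Run the full configuration-driven analysis pipeline
#'
#' Stages run in fixed order: illumination/background correction, nucleus
#' segmentation on the DNA channel, focus segmentation per configured
#' channel, per-cell and per-focus measurement, gating and cell-cycle
#' classification, proximity association, export. Any stage failure aborts
#' with the stage name and the offending field id. Every tabular output is
#' written with a provenance record (configuration hash and package version)
#' and the log records per-stage object counts. Given identical config and
#' inputs, all tabular outputs are byte-identical across runs (no timestamps
#' are embedded).
#'
#' @param config a config list (validated) or a path to a YAML/JSON config.
#' @param quiet suppress progress messages.
#' @return object of class `pipeline_result`: `cells`, `foci`, `gates`,
#'   `proximity`, `provenance`, `log`, `paths` of written files.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_analysis_config(config)
  config <- validate_analysis_config(config)
  ver <- as.character(utils::packageVersion("focimetry"))
  hash <- config_hash(config)
  log <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log <<- c(log, line)
    if (!quiet) message(line)
  }
  stage <- function(name, field, expr) {
    tryCatch(expr, error = function(e) {
      fm_abort(sprintf("stage '%s' failed (field '%s'): %s",
                       name, field, conditionMessage(e)))
    })
  }
  set.seed(config$seed)
  say("pipeline start: config %s, version %s", hash, ver)

  files <- list.files(config$input$dir, full.names = TRUE)
  files <- files[grepl(config$input$pattern, basename(files)) &
                   !grepl("\\.json$", files)]
  fm_assert(length(files) > 0L, "no input images match the layout pattern")
  fields <- stage("input", "*", read_image_set(files, list(
    pattern = config$input$pattern, groups = config$input$groups,
    channel_map = unlist(config$input$channel_map),
    required = config$input$required_channels)))
  say("input: %d field(s), %d image(s)", length(fields), length(files))

  illum_on <- isTRUE((config$illumination$enabled) %||% TRUE)
  bg_mode <- config$illumination$background_mode %||%
    list(mode = "constant-percentile", percentile = 0.05)
  nuc_cfg <- config$segmentation$nuclei
  foci_cfg <- config$segmentation$foci

  all_cells <- list(); all_foci <- list(); masks <- list()
  for (f in names(fields)) {
    imgs <- fields[[f]]
    if (illum_on) {
      imgs <- stage("correct", f,
                    lapply(imgs, correct_illumination, background_mode = bg_mode))
    }
    nuclei <- stage("segment_nuclei", f, segment_nuclei(
      imgs$DNA,
      min_area_um2 = nuc_cfg$min_area_um2 %||% 20,
      max_area_um2 = nuc_cfg$max_area_um2 %||% 1000,
      border = nuc_cfg$border %||% "keep",
      smooth_sigma_px = nuc_cfg$smooth_sigma_px %||% 1,
      watershed_tolerance = nuc_cfg$watershed_tolerance %||% 2,
      min_contrast = nuc_cfg$min_contrast %||% 2))
    say("segment_nuclei [%s]: %d nuclei", f, max(nuclei$labels))

    cells <- stage("measure", f, measure_cells(nuclei, imgs))
    foci_tbls <- list()
    for (ch in names(foci_cfg)) {
      fc <- foci_cfg[[ch]]
      fp <- focus_params(
        tophat_radius_um = fc$tophat_radius_um %||% 0.5,
        k_sigma = fc$k_sigma %||% 3,
        min_area_um2 = fc$min_area_um2 %||% 0.04,
        max_area_um2 = fc$max_area_um2 %||% 10,
        split_touching = fc$split_touching %||% FALSE)
      fmask <- stage("segment_foci", f, segment_foci(imgs[[ch]], nuclei, fp))
      say("segment_foci [%s, %s]: %d foci", f, ch, max(fmask$labels))
      mf <- stage("measure", f,
                  measure_foci(fmask, nuclei, imgs[[ch]], cells,
                               measure_dilate_px = fc$measure_dilate_px %||% 2L))
      cells <- mf$cells
      md <- imgs[[ch]]$metadata
      if (nrow(mf$foci)) {
        st <- image_to_stage(cbind(mf$foci$x_px, mf$foci$y_px), md)
        mf$foci$x_um <- st$stage_x_um
        mf$foci$y_um <- st$stage_y_um
        mf$foci$field_id <- f
      }
      foci_tbls[[ch]] <- mf$foci
    }
    say("measure [%s]: %d cells, %d foci", f, nrow(cells),
        sum(vapply(foci_tbls, nrow, integer(1))))
    all_cells[[f]] <- cells
    all_foci[[f]] <- dplyr::bind_rows(foci_tbls)
    masks[[f]] <- nuclei
  }
  cells <- dplyr::bind_rows(all_cells)
  foci <- dplyr::bind_rows(all_foci)

  gate_summary <- tibble::tibble()
  for (g in config$gates %||% list()) {
    gt <- gate_interval(g$col, g$min %||% -Inf, g$max %||% Inf, name = g$name)
    res <- stage("gate", "*", apply_gate(cells, gt))
    say("gate '%s': %d / %d cells", res$gate, res$n, res$n_total)
    gate_summary <- dplyr::bind_rows(
      gate_summary, tibble::tibble(gate = res$gate, n = res$n, n_total = res$n_total))
  }

  cc <- config$cellcycle
  if (!is.null(cc) && isTRUE(cc$enabled %||% TRUE)) {
    cells <- stage("classify", "*", classify_cell_cycle(
      cells,
      edu_col = cc$edu_col %||% "edu_total",
      dna_col = cc$dna_col %||% "dna_total",
      edu_threshold = cc$edu_threshold,
      dna_ref_2n = cc$dna_ref_2n,
      windows = unlist(cc$windows %||% c(0.8, 1.2, 1.6, 2.4))))
    say("classify: %d assigned / %d cells",
        sum(cells$cycle_label != "unassigned"), nrow(cells))
  }

  proximity <- NULL
  prox <- config$proximity
  if (!is.null(prox) && isTRUE(prox$enabled %||% TRUE)) {
    mk <- function(ch, id_col) {
      d <- foci[foci$channel == ch, ]
      out <- tibble::tibble(id = d$focus_id, cell_id = d$cell_id,
                            x_um = d$x_um, y_um = d$y_um)
      names(out)[1] <- id_col
      out
    }
    proximity <- stage("proximity", "*", associate_spots_to_foci(
      mk(prox$spots_channel, "spot_id"), mk(prox$foci_channel, "focus_id"),
      threshold_um = prox$threshold_um))
    say("proximity: %d / %d spots adjacent at %.3g um",
        sum(proximity$spots$adjacent), nrow(proximity$spots),
        prox$threshold_um)
  }

  out_dir <- config$output$dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cells = file.path(out_dir, "cells.tsv"),
             foci = file.path(out_dir, "foci.tsv"))
  stage("export", "*", {
    write_cell_table(cells, paths[["cells"]])
    write_cell_table(foci, paths[["foci"]])
    if (nrow(gate_summary)) {
      paths[["gates"]] <- file.path(out_dir, "gates.tsv")
      write_cell_table(gate_summary, paths[["gates"]])
    }
    if (!is.null(proximity)) {
      paths[["proximity"]] <- file.path(out_dir, "proximity.tsv")
      write_cell_table(proximity$per_cell, paths[["proximity"]])
    }
  })
  provenance <- list(config_hash = hash, version = ver,
                     n_fields = length(fields), n_cells = nrow(cells),
                     n_foci = nrow(foci), log = log)
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  paths[["provenance"]] <- file.path(out_dir, "provenance.json")
  say("export: %d table(s) written to %s", length(paths) - 1L, out_dir)

  structure(list(cells = cells, foci = foci, gates = gate_summary,
                 proximity = proximity, nuclei_masks = masks,
                 provenance = provenance, log = log, paths = paths,
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d cells, %d foci, %d field(s); config %s (v%s)\n",
              nrow(x$cells), nrow(x$foci), x$provenance$n_fields,
              x$provenance$config_hash, x$provenance$version))
  invisible(x)
}
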