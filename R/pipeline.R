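# End-to-end orchestration: islet segmentation -> nuclear masking -> nucleus
# detection -> label painting -> guide construction -> seeded propagation ->
# per-cell features -> classification -> per-cell colocalization -> group
# summary, with deterministic seeding and standard-format outputs.

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate a cohort in memory) or `"files"`
#'   (read multi-channel and probability-map TIFFs from `inputs`).
#' @param n_nd,n_t2d Synthetic cohort sizes (defaults follow the six-ND /
#'   three-T2D study design).
#' @param geometry,model Synthetic generator parameters
#'   ([geometry_params()], [intensity_model()]).
#' @param islet,nuclei,propagation Stage parameters.
#' @param classification_ratio Insulin/glucagon classification ratio.
#' @param exclude_border_cells Drop cells whose territory touches the frame
#'   border (default FALSE).
#' @param per_image_rescale Summarise the per-image full-range-rescaled
#'   IGFBP7 medians instead of the raw ones (default FALSE; both are always
#'   recorded in the cell table).
#' @param seed Master seed; every stage derives its own stream from it.
#' @param inputs For `mode = "files"`: a list of field entries, each with
#'   `image` (multi-channel TIFF path), `prob_map` (TIFF path), `donor_id`,
#'   `group`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            n_nd = 6, n_t2d = 3,
                            geometry = geometry_params(),
                            model = intensity_model(),
                            islet = islet_params(),
                            nuclei = nuclei_params(),
                            propagation = propagation_params(),
                            classification_ratio = 1.5,
                            exclude_border_cells = FALSE,
                            per_image_rescale = FALSE,
                            seed = 1,
                            inputs = NULL) {
  mode <- match.arg(mode)
  if (is.list(geometry) && !inherits(geometry, "geometry_params")) {
    geometry <- do.call(geometry_params, geometry)
  }
  if (is.list(model) && !inherits(model, "intensity_model")) {
    model <- do.call(intensity_model, model)
  }
  if (is.list(islet) && !inherits(islet, "islet_params")) {
    islet <- do.call(islet_params, islet)
  }
  if (is.list(nuclei) && !inherits(nuclei, "nuclei_params")) {
    nuclei <- do.call(nuclei_params, nuclei)
  }
  if (is.list(propagation) && !inherits(propagation, "propagation_params")) {
    propagation <- do.call(propagation_params, propagation)
  }
  if (mode == "files") {
    if (is.null(inputs) || length(inputs) == 0) {
      stop("`inputs` required in files mode", call. = FALSE)
    }
    for (f in inputs) {
      if (!file.exists(f$image)) stop("missing image: ", f$image, call. = FALSE)
      if (!file.exists(f$prob_map)) stop("missing prob map: ", f$prob_map, call. = FALSE)
    }
  }
  structure(list(mode = mode, n_nd = n_nd, n_t2d = n_t2d, geometry = geometry,
                 model = model, islet = islet, nuclei = nuclei,
                 propagation = propagation,
                 classification_ratio = classification_ratio,
                 exclude_border_cells = exclude_border_cells,
                 per_image_rescale = per_image_rescale,
                 seed = seed, inputs = inputs),
            class = "pipeline_config")
}

#' Run the analysis on a single field
#'
#' Executes every stage on one multi-channel image plus its islet
#' probability map and returns all intermediate artefacts with the classified
#' cell table.
#'
#' @param image An `islet_image` (named list of channel matrices).
#' @param prob_map 8-bit islet probability map.
#' @param donor_id,group Labels for the cell table.
#' @param islet,nuclei,propagation Stage parameters.
#' @param classification_ratio Classification ratio (default 1.5).
#' @param exclude_border_cells Drop border-touching cells (default FALSE).
#' @param compute_moc Add the per-cell Manders overlap column (default TRUE).
#' @return A list of class `field_result` with `islet_mask`, `detections`,
#'   `seeds`, `cells` (label image) and `table` (classified cell tibble).
#' @export
run_field <- function(image, prob_map, donor_id = "D1", group = "ND",
                      islet = islet_params(), nuclei = nuclei_params(),
                      propagation = propagation_params(),
                      classification_ratio = 1.5,
                      exclude_border_cells = FALSE,
                      compute_moc = TRUE) {
  mask <- suppressWarnings(segment_islet(prob_map, islet))
  nuc_img <- mask_channel(image$nuclear, mask)
  dets <- detect_nuclei(nuc_img, nuclei)
  empty_tab <- classify_cells(
    cell_features(matrix(0L, nrow(prob_map), ncol(prob_map)), image,
                  donor_id, group)[0, ],
    classification_ratio)
  if (nrow(dets) == 0) {
    return(structure(list(islet_mask = mask, detections = dets,
                          seeds = matrix(0L, nrow(prob_map), ncol(prob_map)),
                          cells = matrix(0L, nrow(prob_map), ncol(prob_map)),
                          table = dplyr::mutate(empty_tab, moc = numeric(0))),
                     class = "field_result"))
  }
  seeds <- paint_labels(dets)
  guide <- suppressWarnings(make_guide(image))
  cells <- suppressWarnings(propagate_cells(seeds, guide, propagation))
  if (exclude_border_cells) {
    border <- unique(c(cells[1, ], cells[nrow(cells), ],
                       cells[, 1], cells[, ncol(cells)]))
    cells[cells %in% border[border > 0]] <- 0L
  }
  tab <- cell_features(cells, image, donor_id, group)
  tab <- classify_cells(tab, classification_ratio)
  if (compute_moc) tab <- cell_moc(tab, cells, image)
  structure(list(islet_mask = mask, detections = dets, seeds = seeds,
                 cells = cells, table = tab),
            class = "field_result")
}

#' Run the full pipeline over a cohort
#'
#' In synthetic mode, generates the cohort from the configuration's geometry
#' and intensity model; in files mode, reads the configured TIFFs. Every
#' field goes through [run_field()]; the pooled classified cell table is
#' summarised with [summarize_groups()]. With an output directory, masks and
#' label images (TIFF), the cell table (CSV), the summary (JSON) and a run
#' manifest (JSON) are written; outputs are byte-identical for identical
#' configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return A list of class `islet_run` with `cells` (pooled tibble),
#'   `summary` (an `islet_summary`), `fields` (per-field results) and
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  t0 <- Sys.time()
  timings <- list()
  if (config$mode == "synthetic") {
    tg <- system.time(
      cohort <- generate_cohort(config$n_nd, config$n_t2d, config$geometry,
                                config$model, config$seed)
    )
    timings$generate <- unname(tg["elapsed"])
  } else {
    cohort <- lapply(config$inputs, function(f) {
      list(donor_id = f$donor_id %||% basename(f$image),
           group = f$group %||% "ND",
           image = read_image_tiff(f$image),
           prob_map = read_prob_tiff(f$prob_map))
    })
  }
  fields <- list()
  tables <- list()
  for (k in seq_along(cohort)) {
    f <- cohort[[k]]
    ts <- system.time(
      res <- run_field(f$image, f$prob_map, f$donor_id, f$group,
                       config$islet, config$nuclei, config$propagation,
                       config$classification_ratio,
                       config$exclude_border_cells)
    )
    timings[[paste0("field_", f$donor_id)]] <- unname(ts["elapsed"])
    fields[[f$donor_id]] <- res
    tables[[k]] <- res$table
  }
  cells <- dplyr::bind_rows(tables)
  value <- if (config$per_image_rescale) "median_igfbp7_rescaled" else "median_igfbp7"
  summary <- summarize_groups(cells, value = value)
  manifest <- list(
    software = paste0("isletquant ", as.character(utils::packageVersion("isletquant"))),
    mode = config$mode,
    seed = config$seed,
    n_fields = length(cohort),
    groups = table_to_list(vapply(cohort, function(f) f$group, "")),
    n_cells = nrow(cells),
    n_unclassified = summary$n_unclassified,
    classification_ratio = config$classification_ratio,
    value_summarised = value,
    timings = timings,
    outputs = character(0)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    outs <- character(0)
    for (id in names(fields)) {
      p1 <- file.path(out_dir, paste0(id, "_islet_mask.tiff"))
      p2 <- file.path(out_dir, paste0(id, "_cells.tiff"))
      write_labels_tiff(fields[[id]]$islet_mask, p1)
      write_labels_tiff(fields[[id]]$cells, p2)
      outs <- c(outs, p1, p2)
    }
    pc <- file.path(out_dir, "cells.csv")
    readr::write_csv(cells, pc)
    ps <- file.path(out_dir, "summary.json")
    jsonlite::write_json(list(summary = summary$summary, tests = summary$tests,
                              n_unclassified = summary$n_unclassified,
                              n_total = summary$n_total),
                         ps, digits = NA, auto_unbox = TRUE)
    manifest$outputs <- c(outs, pc, ps)
    pm <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, pm, digits = NA, auto_unbox = TRUE)
    stopifnot(all(file.exists(manifest$outputs)))
  }
  manifest$total_elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  structure(list(cells = cells, summary = summary, fields = fields,
                 manifest = manifest),
            class = "islet_run")
}

table_to_list <- function(x) as.list(table(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.islet_run <- function(x, ...) {
  cat(sprintf("<islet_run> %d fields, %d cells\n",
              length(x$fields), nrow(x$cells)))
  print(x$summary)
  invisible(x)
}
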