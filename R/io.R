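# Standard-format I/O: multi-channel and label TIFFs, masks, nucleus sets as
# CSV, configuration as YAML, summaries and manifests as JSON.

#' Write a multi-channel image as a multi-page TIFF
#'
#' One page per channel in the canonical order nuclear / insulin / glucagon /
#' igfbp7; intensities on \[0, 1\] are stored as 16-bit.
#'
#' @param image An `islet_image` or named list of channel matrices.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  pages <- lapply(CHANNELS, function(ch) clip01(image[[ch]]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-channel TIFF written by [write_image_tiff()]
#'
#' @param path File path.
#' @param channels Channel names for the pages, in page order.
#' @return An `islet_image` (named list of matrices).
#' @export
read_image_tiff <- function(path, channels = CHANNELS) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < length(channels)) {
    stop("TIFF has fewer pages than channel names", call. = FALSE)
  }
  out <- stats::setNames(pages[seq_along(channels)], channels)
  structure(out, class = "islet_image")
}

#' Write a label image (or binary mask) as a single-plane 16-bit TIFF
#'
#' @param labels Integer label matrix (or logical mask).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_labels_tiff <- function(labels, path) {
  m <- labels * 1
  if (max(m) > 65535) stop("more than 65535 labels", call. = FALSE)
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a label image written by [write_labels_tiff()]
#'
#' @param path File path.
#' @return Integer label matrix.
#' @export
read_labels_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  out <- floor(m * 65535 + 0.5)
  storage.mode(out) <- "integer"
  out
}

#' Write an 8-bit probability map TIFF
#'
#' @param prob_map Integer matrix on \[0, 255\].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_prob_tiff <- function(prob_map, path) {
  tiff::writeTIFF(prob_map / 255, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Read an 8-bit probability map TIFF
#'
#' @param path File path.
#' @return Integer matrix on \[0, 255\].
#' @export
read_prob_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  out <- floor(m * 255 + 0.5)
  storage.mode(out) <- "integer"
  out
}

#' Write a nucleus set as CSV
#'
#' Columns `id, row, col, radius, score` (0-based pixel coordinates).
#'
#' @param nuclei A `nucleus_set`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_nuclei_csv <- function(nuclei, path) {
  readr::write_csv(tibble::as_tibble(nuclei), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}
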