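# Per-cell feature extraction, the alpha/beta/unclassified classification
# rule, Manders overlap colocalization and group-level statistics.

#' Extract per-cell features from a label image
#'
#' One record per positive label: pixel area, centroid (0-based row/col) and
#' the median intensity of every channel over the cell's pixels (the median
#' of an even count is the mean of the two middle values). A per-image
#' full-range-rescaled IGFBP7 median is recorded alongside the raw one.
#'
#' @param cells Integer label matrix of cell territories.
#' @param image An `islet_image` or named list of channel matrices.
#' @param donor_id,group Labels attached to every record.
#' @return A tibble (`CellTable`) with one row per cell.
#' @export
cell_features <- function(cells, image, donor_id = "D1", group = "ND") {
  assert_matrix(cells)
  for (ch in CHANNELS) {
    if (is.null(image[[ch]])) stop("missing channel: ", ch, call. = FALSE)
    assert_same_shape(cells, image[[ch]], "labels and channels")
  }
  pix <- which(cells > 0)
  if (length(pix) == 0) {
    return(tibble::tibble(donor_id = character(), group = character(),
                          cell_id = integer(), area_px = integer(),
                          centroid_row = numeric(), centroid_col = numeric(),
                          median_nuclear = numeric(), median_insulin = numeric(),
                          median_glucagon = numeric(), median_igfbp7 = numeric(),
                          median_igfbp7_rescaled = numeric()))
  }
  lab <- cells[pix]
  ids <- sort(unique(lab))
  f <- factor(lab, levels = ids)
  rows <- ((pix - 1) %% nrow(cells))        # 0-based
  cols <- ((pix - 1) %/% nrow(cells))
  med <- function(v) as.numeric(tapply(v, f, stats::median))
  igf_rescaled <- suppressWarnings(rescale_full_range(image$igfbp7))
  tibble::tibble(
    donor_id = donor_id,
    group = group,
    cell_id = as.integer(ids),
    area_px = as.integer(tabulate(f)),
    centroid_row = as.numeric(tapply(rows, f, mean)),
    centroid_col = as.numeric(tapply(cols, f, mean)),
    median_nuclear = med(image$nuclear[pix]),
    median_insulin = med(image$insulin[pix]),
    median_glucagon = med(image$glucagon[pix]),
    median_igfbp7 = med(image$igfbp7[pix]),
    median_igfbp7_rescaled = med(igf_rescaled[pix])
  )
}

#' Classify cells into alpha / beta / unclassified
#'
#' A cell is a beta-cell if its insulin median is at least `ratio` times its
#' glucagon median (inclusive boundary: "at least 50% more intense" with the
#' default ratio 1.5), an alpha-cell in the symmetric case, and unclassified
#' otherwise (including when both medians are zero). The rule is invariant
#' under multiplying all intensities by any positive constant.
#'
#' @param table A cell table with `median_insulin` and `median_glucagon`.
#' @param ratio Classification ratio (> 1), default 1.5.
#' @return The table with a `cell_class` column added (or replaced).
#' @export
classify_cells <- function(table, ratio = 1.5) {
  stopifnot(is.numeric(ratio), length(ratio) == 1, ratio > 1)
  ins <- table$median_insulin
  glu <- table$median_glucagon
  if (is.null(ins) || is.null(glu)) {
    stop("table must contain `median_insulin` and `median_glucagon`", call. = FALSE)
  }
  if (any(ins < 0) || any(glu < 0)) {
    stop("negative median intensities are not allowed", call. = FALSE)
  }
  cls <- dplyr::case_when(
    ins == 0 & glu == 0 ~ "unclassified",
    ins >= ratio * glu ~ "beta",
    glu >= ratio * ins ~ "alpha",
    TRUE ~ "unclassified"
  )
  dplyr::mutate(table, cell_class = cls)
}

#' Manders overlap coefficient over a region
#'
#' `r = sum(a * b) / sqrt(sum(a^2) * sum(b^2))` over the region's pixels;
#' bounded in \[0, 1\] for non-negative images, equal to 1 iff the two
#' channels are proportional on the region (Cauchy-Schwarz equality), and
#' invariant to separate positive rescaling of each channel.
#'
#' @param a,b Non-negative intensity matrices.
#' @param region Logical mask (non-empty) over which to evaluate.
#' @return The overlap coefficient (single number).
#' @export
manders_overlap <- function(a, b, region = NULL) {
  assert_matrix(a)
  assert_same_shape(a, b, "channels")
  if (is.null(region)) region <- matrix(TRUE, nrow(a), ncol(a))
  assert_same_shape(a, region, "channels and region")
  if (!any(region)) stop("`region` is empty", call. = FALSE)
  av <- a[region]; bv <- b[region]
  if (any(av < 0) || any(bv < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  sa <- sum(av^2); sb <- sum(bv^2)
  if (sa == 0 || sb == 0) {
    abort_degenerate("Manders overlap undefined: a channel is all zero on the region")
  }
  sum(av * bv) / sqrt(sa * sb)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison. The p-value is exact (enumeration of rank
#' assignments) when `n_x + n_y <= 12` and there are no ties; otherwise the
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`) mode;
#'   `NULL` (default) applies the size/tie rule above.
#' @return A tibble with `statistic` (U of `x`), `p_value` and `method`.
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- (length(x) + length(y) <= 12) && !ties
  if (exact && ties) exact <- FALSE
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  tibble::tibble(statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 method = if (exact) "exact" else "normal_approx")
}

#' Pooled-variance two-sample t test
#'
#' Classical Student t with `n_x + n_y - 2` degrees of freedom. Degenerate
#' samples with zero pooled variance yield `t = 0, p = 1` when the means are
#' equal and an error otherwise.
#'
#' @param x,y Numeric samples with at least two values each.
#' @return A tibble with `statistic`, `df` and `p_value`.
#' @export
t_test_two_sample <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("both samples need n >= 2", call. = FALSE)
  }
  df <- length(x) + length(y) - 2
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) / df
  if (sp2 == 0) {
    if (mean(x) == mean(y)) {
      return(tibble::tibble(statistic = 0, df = df, p_value = 1))
    }
    abort_degenerate("zero pooled variance with unequal means")
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Summarise per-cell IGFBP7 intensity by donor group and cell class
#'
#' For every (group, class in alpha/beta) cell population: the cell count
#' and the median of the per-cell median IGFBP7 intensities; plus a
#' Mann-Whitney ND-vs-T2D comparison within each class. Cells are the
#' statistical unit. Unclassified cells are excluded from the summaries but
#' counted in the diagnostics.
#'
#' @param table A classified cell table (see [classify_cells()]) with
#'   `group`, `cell_class` and `median_igfbp7` columns.
#' @param value Column to summarise (default `median_igfbp7`).
#' @return An object of class `islet_summary`: list with `summary` and
#'   `tests` tibbles plus diagnostic counts.
#' @export
summarize_groups <- function(table, value = "median_igfbp7") {
  if (nrow(table) == 0) {
    return(structure(list(
      summary = tibble::tibble(group = character(), cell_class = character(),
                               n_cells = integer(), median_igfbp7 = numeric()),
      tests = tibble::tibble(cell_class = character(), statistic = numeric(),
                             p_value = numeric(), method = character()),
      n_unclassified = 0L, n_total = 0L, value = value),
      class = "islet_summary"))
  }
  if (is.null(table$cell_class)) {
    stop("table must be classified first (see classify_cells)", call. = FALSE)
  }
  classified <- dplyr::filter(table, .data$cell_class %in% c("alpha", "beta"))
  summary <- classified |>
    dplyr::group_by(.data$group, .data$cell_class) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     median_igfbp7 = stats::median(.data[[value]]),
                     .groups = "drop") |>
    dplyr::arrange(.data$cell_class, .data$group)
  tests <- purrr::map_dfr(c("alpha", "beta"), function(cls) {
    nd <- classified[[value]][classified$cell_class == cls & classified$group == "ND"]
    t2d <- classified[[value]][classified$cell_class == cls & classified$group == "T2D"]
    if (length(nd) == 0 || length(t2d) == 0) return(NULL)
    dplyr::bind_cols(tibble::tibble(cell_class = cls), mann_whitney(nd, t2d))
  })
  structure(list(summary = summary, tests = tests,
                 n_unclassified = sum(table$cell_class == "unclassified"),
                 n_total = nrow(table), value = value),
            class = "islet_summary")
}

#' @export
print.islet_summary <- function(x, ...) {
  cat(sprintf("<islet_summary> %d cells (%d unclassified)\n",
              x$n_total, x$n_unclassified))
  print(x$summary)
  if (nrow(x$tests) > 0) {
    cat("ND vs T2D (Mann-Whitney):\n")
    print(x$tests)
  }
  invisible(x)
}

#' Per-cell Manders overlap with the class hormone
#'
#' For alpha-cells the IGFBP7 channel is compared with glucagon, for
#' beta-cells with insulin, each over the cell's own territory. Unclassified
#' cells get `NA`.
#'
#' @param table A classified cell table.
#' @param cells The label image the table was measured from.
#' @param image The multi-channel image.
#' @return The table with a `moc` column added.
#' @export
cell_moc <- function(table, cells, image) {
  moc <- rep(NA_real_, nrow(table))
  for (k in seq_len(nrow(table))) {
    cls <- table$cell_class[k]
    if (!cls %in% c("alpha", "beta")) next
    region <- cells == table$cell_id[k]
    other <- if (cls == "alpha") image$glucagon else image$insulin
    moc[k] <- tryCatch(manders_overlap(image$igfbp7, other, region),
                       isletquant_degenerate = function(e) NA_real_)
  }
  dplyr::mutate(table, moc = moc)
}
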