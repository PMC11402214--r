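# Synthetic islet fields with full ground truth. The generator emulates the
# statistical structure the analysis assumes: a roughly disk-shaped islet,
# dart-thrown nucleus centres with a hard minimum spacing, nearest-centroid
# cell territories clipped to the islet, hormone-specific channel levels for
# alpha/beta cells with per-cell lognormal variability, a T2D-vs-ND IGFBP7
# effect, pixel noise, and imperfect probability maps and "manual"
# annotations.

#' Geometry parameters for synthetic islet fields
#'
#' Defaults describe a desk-scale field: 512 x 512 pixels, one islet of
#' radius 180 px holding 120 cells with nuclei of radius 5 px. At roughly
#' 0.5 um per pixel this corresponds to cells ~11 um across, hence the
#' default minimum centre spacing of 22 px.
#'
#' @param field_shape Integer (rows, cols) of the field.
#' @param islet_radius_px Islet radius in pixels.
#' @param n_cells Number of cells (>= 1).
#' @param nucleus_radius_px Mean nucleus radius in pixels.
#' @param nucleus_radius_jitter Fractional jitter of nucleus radii (uniform
#'   in `1 +/- jitter`).
#' @param alpha_fraction Probability that a cell is an alpha-cell.
#' @param min_center_spacing_px Hard minimum distance between nucleus
#'   centres.
#' @return A list of class `geometry_params`.
#' @export
geometry_params <- function(field_shape = c(512, 512),
                            islet_radius_px = 180,
                            n_cells = 120,
                            nucleus_radius_px = 5,
                            nucleus_radius_jitter = 0.1,
                            alpha_fraction = 0.35,
                            min_center_spacing_px = 22) {
  stopifnot(length(field_shape) == 2, all(field_shape >= 16),
            islet_radius_px > 0, n_cells >= 1, nucleus_radius_px > 0,
            nucleus_radius_jitter >= 0, nucleus_radius_jitter < 1,
            alpha_fraction >= 0, alpha_fraction <= 1,
            min_center_spacing_px >= 2 * nucleus_radius_px * (1 - nucleus_radius_jitter))
  if (islet_radius_px > min(field_shape) / 2) {
    stop("islet does not fit inside the field", call. = FALSE)
  }
  structure(list(field_shape = as.integer(field_shape),
                 islet_radius_px = islet_radius_px,
                 n_cells = as.integer(n_cells),
                 nucleus_radius_px = nucleus_radius_px,
                 nucleus_radius_jitter = nucleus_radius_jitter,
                 alpha_fraction = alpha_fraction,
                 min_center_spacing_px = min_center_spacing_px),
            class = "geometry_params")
}

#' Intensity model for synthetic staining
#'
#' Per-class mean channel levels on the canonical \[0, 1\] intensity scale,
#' group multipliers for the IGFBP7 channel, per-cell lognormal variability,
#' pixel noise and a uniform background. The default IGFBP7 class levels and
#' T2D multipliers reproduce the published group medians for per-cell IGFBP7
#' intensity (alpha: ND 0.0863, T2D 0.102; beta: ND 0.102, T2D 0.1059), so
#' the configured T2D/ND effect is 0.102/0.0863 for alpha-cells and
#' 0.1059/0.102 for beta-cells.
#'
#' @param channel_levels Named list `alpha`/`beta`, each a named numeric
#'   vector of mean levels for `nuclear`, `insulin`, `glucagon`, `igfbp7`.
#' @param igfbp7_group_multiplier Named list mapping `"<group>.<class>"` to a
#'   positive multiplier applied to the IGFBP7 level.
#' @param cell_level_cv Coefficient of variation of the mean-preserving
#'   per-cell lognormal level multiplier.
#' @param gaussian_noise_sd Pixel noise standard deviation.
#' @param background_level Uniform background added to every channel.
#' @return A list of class `intensity_model`.
#' @export
intensity_model <- function(channel_levels = list(
                              alpha = c(nuclear = 0.85, insulin = 0.04,
                                        glucagon = 0.70, igfbp7 = 0.0863),
                              beta = c(nuclear = 0.85, insulin = 0.75,
                                       glucagon = 0.04, igfbp7 = 0.102)),
                            igfbp7_group_multiplier = list(
                              "ND.alpha" = 1, "ND.beta" = 1,
                              "T2D.alpha" = 0.102 / 0.0863,
                              "T2D.beta" = 0.1059 / 0.102),
                            cell_level_cv = 0.25,
                            gaussian_noise_sd = 0.02,
                            background_level = 0.005) {
  stopifnot(all(unlist(channel_levels) >= 0),
            all(unlist(igfbp7_group_multiplier) > 0),
            cell_level_cv >= 0, gaussian_noise_sd >= 0, background_level >= 0)
  for (cls in c("alpha", "beta")) {
    if (!all(CHANNELS %in% names(channel_levels[[cls]]))) {
      stop("channel_levels must name all four channels per class", call. = FALSE)
    }
  }
  structure(list(channel_levels = channel_levels,
                 igfbp7_group_multiplier = igfbp7_group_multiplier,
                 cell_level_cv = cell_level_cv,
                 gaussian_noise_sd = gaussian_noise_sd,
                 background_level = background_level),
            class = "intensity_model")
}

disk_mask <- function(shape, center, radius) {
  d2 <- outer((seq_len(shape[1]) - center[1])^2,
              (seq_len(shape[2]) - center[2])^2, `+`)
  d2 <= radius^2
}

#' Generate the ground truth for one synthetic islet field
#'
#' Nucleus centres are placed by dart throwing inside the islet disk (with a
#' margin keeping whole nuclei inside) respecting the minimum spacing; cell
#' territories are the nearest-centroid partition of the islet mask; cell
#' types are drawn i.i.d. with `P(alpha) = alpha_fraction`. Noiseless
#' per-cell channel levels (class means, with the group's IGFBP7 multiplier
#' applied) are recorded per cell.
#'
#' @param params A [geometry_params()] object.
#' @param alpha_fraction Optional override of the geometry's alpha fraction.
#' @param group Donor group label, `"ND"` or `"T2D"`.
#' @param seed Integer seed; the truth is a pure function of
#'   `(params, group, seed)`.
#' @param model An [intensity_model()] supplying class levels and group
#'   multipliers for the recorded noiseless levels.
#' @return A list of class `islet_truth` with elements `islet_mask`,
#'   `nucleus_centroids` (tibble, 0-based `row`/`col`), `nucleus_radii`,
#'   `cell_labels`, `cell_types`, `true_cell_levels` (tibble) and `group`.
#' @export
generate_truth <- function(params = geometry_params(), alpha_fraction = NULL,
                           group = c("ND", "T2D"), seed = 1,
                           model = intensity_model()) {
  group <- match.arg(group)
  af <- if (is.null(alpha_fraction)) params$alpha_fraction else alpha_fraction
  stopifnot(af >= 0, af <= 1)
  shape <- params$field_shape
  center <- (shape + 1) / 2
  R <- params$islet_radius_px
  margin <- params$nucleus_radius_px * (1 + params$nucleus_radius_jitter) + 4
  r_place <- R - margin
  if (r_place <= 0) abort_capacity("islet too small to hold any nucleus")
  n <- params$n_cells
  with_seed(seed, {
    pts <- matrix(NA_real_, n, 2)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 400L * n
    smin2 <- params$min_center_spacing_px^2
    while (placed < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      rad <- r_place * sqrt(stats::runif(1))
      th <- 2 * pi * stats::runif(1)
      p <- center + rad * c(cos(th), sin(th))
      if (placed == 0L ||
          min((pts[seq_len(placed), 1] - p[1])^2 +
              (pts[seq_len(placed), 2] - p[2])^2) >= smin2) {
        placed <- placed + 1L
        pts[placed, ] <- p
      }
    }
    if (placed < n) {
      abort_capacity(sprintf(
        "could not place %d nuclei with spacing %.1f px inside islet radius %.1f px",
        n, params$min_center_spacing_px, R))
    }
    radii <- params$nucleus_radius_px *
      stats::runif(n, 1 - params$nucleus_radius_jitter,
                   1 + params$nucleus_radius_jitter)
    types <- ifelse(stats::runif(n) < af, "alpha", "beta")

    mask <- disk_mask(shape, center, R)
    labels <- matrix(0L, shape[1], shape[2])
    in_islet <- which(mask)
    rows <- ((in_islet - 1) %% shape[1]) + 1
    cols <- ((in_islet - 1) %/% shape[1]) + 1
    best_d2 <- rep(Inf, length(in_islet))
    best_lab <- integer(length(in_islet))
    for (k in seq_len(n)) {
      d2 <- (rows - pts[k, 1])^2 + (cols - pts[k, 2])^2
      upd <- d2 < best_d2  # strict: ties keep the earlier (smaller) label
      best_d2[upd] <- d2[upd]
      best_lab[upd] <- k
    }
    labels[in_islet] <- best_lab

    mult <- unlist(model$igfbp7_group_multiplier[paste(group, types, sep = ".")])
    levels <- tibble::tibble(
      cell_id = seq_len(n),
      cell_class = types,
      nuclear = vapply(types, function(t) model$channel_levels[[t]]["nuclear"], 0),
      insulin = vapply(types, function(t) model$channel_levels[[t]]["insulin"], 0),
      glucagon = vapply(types, function(t) model$channel_levels[[t]]["glucagon"], 0),
      igfbp7 = vapply(types, function(t) model$channel_levels[[t]]["igfbp7"], 0) * mult
    )
    structure(list(
      islet_mask = mask,
      nucleus_centroids = tibble::tibble(cell_id = seq_len(n),
                                         row = pts[, 1] - 1,
                                         col = pts[, 2] - 1),
      nucleus_radii = radii,
      cell_labels = labels,
      cell_types = types,
      true_cell_levels = levels,
      group = group,
      params = params
    ), class = "islet_truth")
  })
}

#' Render a multi-channel image from a ground truth
#'
#' For every cell and cytoplasmic channel, the rendered level is the class
#' mean times a mean-preserving per-cell lognormal factor (the IGFBP7 level
#' additionally carries the group multiplier, already folded into the
#' truth's noiseless levels). Pixels receive level + background + Gaussian
#' noise, clipped to \[0, 1\]. The nuclear channel is bright disks at the
#' nucleus centroids.
#'
#' @param truth An `islet_truth`.
#' @param model An [intensity_model()].
#' @param seed Integer seed for the lognormal factors and pixel noise.
#' @return An object of class `islet_image`: a named list of matrices
#'   (`nuclear`, `insulin`, `glucagon`, `igfbp7`) with the realised per-cell
#'   levels attached as attribute `cell_levels`.
#' @export
render_image <- function(truth, model = intensity_model(), seed = 1) {
  shape <- dim(truth$islet_mask)
  n <- length(truth$cell_types)
  with_seed(seed, {
    sig <- sqrt(log(1 + model$cell_level_cv^2))
    cyto <- c("insulin", "glucagon", "igfbp7")
    factors <- matrix(exp(sig * stats::rnorm(n * 3) - sig^2 / 2), n, 3,
                      dimnames = list(NULL, cyto))
    if (model$cell_level_cv == 0) factors[] <- 1
    lab <- truth$cell_labels
    pix <- which(lab > 0)
    pl <- lab[pix]
    channels <- list()
    realized <- truth$true_cell_levels
    for (ch in cyto) {
      lev <- realized[[ch]] * factors[, ch]
      realized[[ch]] <- lev
      plane <- matrix(model$background_level, shape[1], shape[2])
      plane[pix] <- lev[pl] + model$background_level
      channels[[ch]] <- plane
    }
    nuc <- matrix(model$background_level, shape[1], shape[2])
    for (k in seq_len(n)) {
      i0 <- truth$nucleus_centroids$row[k] + 1
      j0 <- truth$nucleus_centroids$col[k] + 1
      rad <- truth$nucleus_radii[k]
      ri <- max(1, floor(i0 - rad)):min(shape[1], ceiling(i0 + rad))
      rj <- max(1, floor(j0 - rad)):min(shape[2], ceiling(j0 + rad))
      d2 <- outer((ri - i0)^2, (rj - j0)^2, `+`)
      blk <- nuc[ri, rj]
      blk[d2 <= rad^2] <- realized$nuclear[k] + model$background_level
      nuc[ri, rj] <- blk
    }
    channels <- c(list(nuclear = nuc), channels)
    if (model$gaussian_noise_sd > 0) {
      for (ch in names(channels)) {
        channels[[ch]] <- channels[[ch]] +
          matrix(stats::rnorm(prod(shape), 0, model$gaussian_noise_sd),
                 shape[1], shape[2])
      }
    }
    channels <- lapply(channels, clip01)
    structure(channels[CHANNELS], class = "islet_image",
              cell_levels = realized, group = truth$group)
  })
}

#' Render an 8-bit islet probability map
#'
#' Emulates pixel-classifier output: the true islet mask scaled to 255,
#' Gaussian-blurred, with additive Gaussian noise, clipped to \[0, 255\] and
#' rounded to integers.
#'
#' @param truth An `islet_truth`.
#' @param blur_sigma_px Blur sigma in pixels (>= 0).
#' @param noise_sd Noise standard deviation in gray levels.
#' @param seed Integer seed.
#' @return Integer matrix on \[0, 255\].
#' @export
render_probability_map <- function(truth, blur_sigma_px = 5, noise_sd = 8,
                                   seed = 1) {
  stopifnot(blur_sigma_px >= 0, noise_sd >= 0)
  plane <- truth$islet_mask * 255
  if (blur_sigma_px > 0) plane <- gaussian_blur(plane, blur_sigma_px)
  with_seed(seed, {
    if (noise_sd > 0) {
      plane <- plane + matrix(stats::rnorm(length(plane), 0, noise_sd),
                              nrow(plane), ncol(plane))
    }
    out <- floor(pmin(pmax(plane, 0), 255) + 0.5)
    storage.mode(out) <- "integer"
    out
  })
}

# Binary dilation (radius > 0) or erosion (radius < 0) by a disk, via
# shift-and-combine over the disk's offsets.
dilate_mask <- function(mask, radius) {
  if (radius == 0) return(mask)
  erode <- radius < 0
  r <- abs(radius)
  if (erode) mask <- !mask
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 <= r^2, ]
  for (k in seq_len(nrow(offs))) {
    di <- offs$di[k]; dj <- offs$dj[k]
    src_i <- max(1, 1 - di):min(nr, nr - di)
    src_j <- max(1, 1 - dj):min(nc, nc - dj)
    out[src_i + di, src_j + dj] <- out[src_i + di, src_j + dj] | mask[src_i, src_j]
  }
  if (erode) !out else out
}

#' Perturb a ground truth into an imperfect "manual" annotation
#'
#' Emulates hand annotation: centroids are jittered by an isotropic Gaussian
#' and dropped independently with probability `drop_rate`; the islet mask is
#' dilated (or eroded, for negative radius) by a disk.
#'
#' @param truth An `islet_truth`.
#' @param centroid_jitter_sd_px Gaussian jitter SD per coordinate (>= 0).
#' @param mask_dilate_px Dilation radius in pixels (negative erodes, 0 keeps
#'   the mask).
#' @param drop_rate Probability of dropping each centroid, in \[0, 1).
#' @param seed Integer seed.
#' @return A list of class `annotation_fixture` with `manual_islet_mask` and
#'   `manual_centroids` (tibble, 0-based `row`/`col`).
#' @export
perturb_truth <- function(truth, centroid_jitter_sd_px = 1,
                          mask_dilate_px = 0L, drop_rate = 0, seed = 1) {
  stopifnot(centroid_jitter_sd_px >= 0)
  if (!(drop_rate >= 0 && drop_rate < 1)) {
    stop("`drop_rate` must lie in [0, 1)", call. = FALSE)
  }
  with_seed(seed, {
    cen <- truth$nucleus_centroids
    n <- nrow(cen)
    keep <- stats::runif(n) >= drop_rate
    jit_r <- stats::rnorm(n, 0, centroid_jitter_sd_px)
    jit_c <- stats::rnorm(n, 0, centroid_jitter_sd_px)
    out <- tibble::tibble(row = cen$row + jit_r, col = cen$col + jit_c)[keep, ]
    structure(list(
      manual_islet_mask = dilate_mask(truth$islet_mask, as.integer(mask_dilate_px)),
      manual_centroids = out
    ), class = "annotation_fixture")
  })
}

#' Generate a synthetic donor cohort
#'
#' One field per donor; defaults follow the study design of six ND and three
#' T2D donors. Per-donor seeds are derived deterministically from the master
#' seed so one number reproduces the whole cohort.
#'
#' @param n_nd,n_t2d Number of ND and T2D donors (>= 0).
#' @param params A [geometry_params()].
#' @param model An [intensity_model()].
#' @param seed Master seed.
#' @param prob_blur_sigma_px,prob_noise_sd Probability-map imperfection
#'   parameters passed to [render_probability_map()].
#' @return A list of fields, each a list with `donor_id`, `group`, `truth`,
#'   `image` and `prob_map`.
#' @export
generate_cohort <- function(n_nd = 6, n_t2d = 3, params = geometry_params(),
                            model = intensity_model(), seed = 1,
                            prob_blur_sigma_px = 5, prob_noise_sd = 8) {
  stopifnot(n_nd >= 0, n_t2d >= 0)
  groups <- c(rep("ND", n_nd), rep("T2D", n_t2d))
  ids <- c(if (n_nd > 0) paste0("ND", seq_len(n_nd)),
           if (n_t2d > 0) paste0("T2D", seq_len(n_t2d)))
  purrr::map2(seq_along(groups), groups, function(k, grp) {
    truth <- generate_truth(params, group = grp,
                            seed = derive_seed(seed, 3L * k), model = model)
    image <- render_image(truth, model, seed = derive_seed(seed, 3L * k + 1L))
    pmap <- render_probability_map(truth, prob_blur_sigma_px, prob_noise_sd,
                                   seed = derive_seed(seed, 3L * k + 2L))
    list(donor_id = ids[k], group = grp, truth = truth, image = image,
         prob_map = pmap)
  })
}
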