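# The three segmentation stages: islet region from an 8-bit probability map,
# nucleus detection + label painting, and seeded propagation of cell
# boundaries over a guide image.

#' Islet segmentation parameters
#'
#' @param offset Gray-level offset subtracted from the 8-bit probability map
#'   before smoothing (default 40).
#' @param blur_sigma_px Gaussian blur sigma in pixels applied after the
#'   subtraction (default 20).
#' @return A list of class `islet_params`.
#' @export
islet_params <- function(offset = 40, blur_sigma_px = 20) {
  stopifnot(length(offset) == 1, offset >= 0, offset <= 255,
            length(blur_sigma_px) == 1, blur_sigma_px >= 0)
  structure(list(offset = offset, blur_sigma_px = blur_sigma_px),
            class = "islet_params")
}

#' Nucleus detection parameters
#'
#' @param blur_sigma_px Gaussian blur sigma (pixels) applied to the nuclear
#'   channel before locating candidate maxima (default 9).
#' @param peak_threshold Minimum detection score in (0, 1) (default 0.7). The
#'   score is the matched-filter correlation of the raw neighbourhood with a
#'   disk template of the estimated radius, so it behaves like a detection
#'   probability.
#' @param overlap_threshold Maximum allowed disk intersection-over-union
#'   between two retained detections (default 0.8); greedy non-maximum
#'   suppression removes lower-scoring overlaps.
#' @param min_radius_px,max_radius_px Bounds for the estimated nucleus radius
#'   in pixels.
#' @return A list of class `nuclei_params`.
#' @export
nuclei_params <- function(blur_sigma_px = 9, peak_threshold = 0.7,
                          overlap_threshold = 0.8,
                          min_radius_px = 3, max_radius_px = 9) {
  stopifnot(blur_sigma_px >= 0,
            peak_threshold > 0, peak_threshold < 1,
            overlap_threshold > 0, overlap_threshold < 1,
            min_radius_px > 0, min_radius_px < max_radius_px)
  structure(list(blur_sigma_px = blur_sigma_px,
                 peak_threshold = peak_threshold,
                 overlap_threshold = overlap_threshold,
                 min_radius_px = min_radius_px,
                 max_radius_px = max_radius_px),
            class = "nuclei_params")
}

#' Seeded propagation parameters
#'
#' @param regularization_lambda Weight of the spatial term in the step cost
#'   (default 0.25). Zero makes expansion follow intensity differences only.
#' @param smoothing_sigma_px Gaussian sigma applied to the guide image before
#'   thresholding and propagation (default 1).
#' @param threshold_correction Multiplier on the automatically selected
#'   growth-region threshold (default 1).
#' @param connectivity Pixel neighbourhood, 4 or 8 (default 8).
#' @return A list of class `propagation_params`.
#' @export
propagation_params <- function(regularization_lambda = 0.25,
                               smoothing_sigma_px = 1,
                               threshold_correction = 1,
                               connectivity = 8) {
  stopifnot(regularization_lambda >= 0, smoothing_sigma_px >= 0,
            threshold_correction > 0, connectivity %in% c(4, 8))
  structure(list(regularization_lambda = regularization_lambda,
                 smoothing_sigma_px = smoothing_sigma_px,
                 threshold_correction = threshold_correction,
                 connectivity = connectivity),
            class = "propagation_params")
}

#' Segment the islet region from a probability map
#'
#' Pipeline: clamp(map - offset, >= 0), Gaussian blur, Huang
#' minimum-fuzziness threshold; the foreground (strictly above threshold) is
#' the islet mask. Fields without islets are legitimate: a degenerate
#' post-blur histogram yields an empty mask with a warning rather than an
#' error.
#'
#' @param prob_map Integer-valued matrix on the \[0, 255\] scale (islet-class
#'   probability from a pixel classifier, or [render_probability_map()]).
#' @param params An [islet_params()] object.
#' @return Logical islet mask.
#' @export
segment_islet <- function(prob_map, params = islet_params()) {
  assert_matrix(prob_map)
  if (min(prob_map) < 0 || max(prob_map) > 255) {
    stop("`prob_map` must be on the [0, 255] scale", call. = FALSE)
  }
  x <- pmax(prob_map - params$offset, 0)
  x <- gaussian_blur(x, params$blur_sigma_px)
  tr <- tryCatch(huang_threshold(hist256(x)), isletquant_degenerate = function(e) NULL)
  if (is.null(tr)) {
    warning("degenerate probability map: returning empty islet mask", call. = FALSE)
    return(matrix(FALSE, nrow(prob_map), ncol(prob_map)))
  }
  mask <- apply_threshold(x, tr)
  if (!any(mask)) warning("empty islet mask", call. = FALSE)
  mask
}

#' Restrict a channel to the islet region
#'
#' Pixels inside the mask keep their value; pixels outside are set to zero,
#' leaving only signal within the islet region.
#'
#' @param img Numeric matrix.
#' @param islet_mask Logical mask of the same shape.
#' @return Masked matrix.
#' @export
mask_channel <- function(img, islet_mask) {
  assert_matrix(img)
  assert_same_shape(img, islet_mask, "image and mask")
  img * (islet_mask * 1)
}

# Intersection-over-union of two disks (analytic lens area).
disk_iou <- function(r1, c1, rad1, r2, c2, rad2) {
  d <- sqrt((r1 - r2)^2 + (c1 - c2)^2)
  a1 <- pi * rad1^2
  a2 <- pi * rad2^2
  if (d >= rad1 + rad2) return(0)
  if (d <= abs(rad1 - rad2)) {
    inter <- min(a1, a2)
  } else {
    x1 <- rad1^2 * acos((d^2 + rad1^2 - rad2^2) / (2 * d * rad1))
    x2 <- rad2^2 * acos((d^2 + rad2^2 - rad1^2) / (2 * d * rad2))
    x3 <- 0.5 * sqrt((-d + rad1 + rad2) * (d + rad1 - rad2) *
                     (d - rad1 + rad2) * (d + rad1 + rad2))
    inter <- x1 + x2 - x3
  }
  inter / (a1 + a2 - inter)
}

# Refine one candidate on the raw 8-bit plane: centre of mass and
# equivalent-disk radius of the pixels above the half-maximum level within a
# local window, plus the matched-filter score (Pearson correlation of the
# window with a binary disk template at the refined centre). The score is
# brightness- and size-invariant and behaves like a detection probability: a
# clean nucleus scores near 1, background fluctuations near 0, and a blob
# straddling two nuclei anticorrelates with a single-disk template.
refine_candidate <- function(img, i, j, min_radius, max_radius) {
  nr <- nrow(img); nc <- ncol(img)
  w <- as.integer(ceiling(max_radius)) + 3L
  ri <- max(1, i - w):min(nr, i + w)
  rj <- max(1, j - w):min(nc, j + w)
  win <- img[ri, rj]
  bg <- min(win)
  peak <- img[i, j]
  if (peak <= bg) return(NULL)
  half <- bg + 0.5 * (peak - bg)
  supra <- win >= half
  wts <- (win - bg) * supra
  sw <- sum(wts)
  if (sw == 0) return(NULL)
  ci <- sum(outer(ri, rep(1, length(rj))) * wts) / sw
  cj <- sum(outer(rep(1, length(ri)), rj) * wts) / sw
  radius <- min(max(sqrt(sum(supra) / pi), min_radius), max_radius)
  d2 <- outer((ri - ci)^2, (rj - cj)^2, `+`)
  tmpl <- (d2 <= radius^2) * 1
  if (stats::sd(as.vector(win)) == 0 || stats::sd(as.vector(tmpl)) == 0) {
    return(NULL)
  }
  list(row = ci, col = cj, radius = radius,
       score = max(0, stats::cor(as.vector(win), as.vector(tmpl))))
}

# Strict-ish local maxima of a plane: >= all 8 neighbours and > at least one
# (constant regions yield none; small plateaus yield duplicates that the
# later suppression collapses).
local_maxima <- function(b) {
  nr <- nrow(b); nc <- ncol(b)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- b
  ge_all <- matrix(TRUE, nr, nc)
  gt_any <- matrix(FALSE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nbr <- pad[(2:(nr + 1)) + di, (2:(nc + 1)) + dj]
    ge_all <- ge_all & (b >= nbr)
    gt_any <- gt_any | (b > nbr)
  }
  which(ge_all & gt_any, arr.ind = TRUE)
}

#' Detect nuclei in a (masked) nuclear channel
#'
#' Deterministic nucleus detector: the channel is converted to the 8-bit
#' scale and blurred at `blur_sigma_px`; local maxima of the blurred plane
#' (supplemented by maxima at a finer scale matched to the smallest expected
#' nucleus, so touching nuclei merged by the coarse blur are still proposed)
#' are candidate centres. Each candidate is refined on the raw plane: the
#' centre of mass and equivalent-disk radius of the pixels above the local
#' half-maximum level (radius clipped to the configured bounds), scored by
#' matched-filter correlation against a binary disk template of that radius
#' — a brightness- and size-invariant score in \[0, 1\] that plays the role
#' of a detection probability.
#' Candidates scoring below `peak_threshold` are dropped; greedy non-maximum
#' suppression in descending score order (ties toward the smaller (row, col))
#' removes any candidate whose disk IoU with a kept detection exceeds
#' `overlap_threshold`.
#'
#' @param nuclear_img Numeric matrix (nuclear channel, any scale).
#' @param params A [nuclei_params()] object.
#' @return A tibble of class `nucleus_set` with columns `id`, `row`, `col`
#'   (0-based pixel centres), `radius` and `score`, ordered by descending
#'   score; the frame shape is attached as attribute `shape`.
#' @export
detect_nuclei <- function(nuclear_img, params = nuclei_params()) {
  assert_matrix(nuclear_img)
  empty <- tibble::tibble(id = integer(), row = numeric(), col = numeric(),
                          radius = numeric(), score = numeric())
  attr(empty, "shape") <- dim(nuclear_img)
  class(empty) <- c("nucleus_set", class(empty))
  if (max(nuclear_img) <= 0) return(empty)

  img8 <- to_8bit(rescale_unit(nuclear_img))
  b <- gaussian_blur(img8, params$blur_sigma_px)

  # candidate centres: local maxima at the configured sigma, supplemented by
  # maxima at a finer sigma matched to the smallest expected nucleus so that
  # neighbouring nuclei merged by the coarse blur are still proposed; the
  # score filter and suppression remove duplicates and spurious candidates
  idx <- local_maxima(b)
  fine_sigma <- params$min_radius_px
  if (fine_sigma < params$blur_sigma_px) {
    idx <- unique(rbind(idx, local_maxima(gaussian_blur(img8, fine_sigma))))
  }
  if (nrow(idx) == 0) return(empty)

  refined <- vector("list", nrow(idx))
  for (k in seq_len(nrow(idx))) {
    refined[[k]] <- refine_candidate(img8, idx[k, 1], idx[k, 2],
                                     params$min_radius_px, params$max_radius_px)
  }
  refined <- refined[!vapply(refined, is.null, TRUE)]
  if (length(refined) == 0) return(empty)
  rows <- vapply(refined, `[[`, 0, "row")
  cols <- vapply(refined, `[[`, 0, "col")
  radius <- vapply(refined, `[[`, 0, "radius")
  score <- vapply(refined, `[[`, 0, "score")
  keep <- score >= params$peak_threshold
  if (!any(keep)) return(empty)
  rows <- rows[keep]; cols <- cols[keep]
  radius <- radius[keep]; score <- score[keep]

  # greedy NMS, descending score, ties toward smaller (row, col); a
  # candidate is suppressed when its disk IoU with a kept detection exceeds
  # the overlap threshold, or when its centre falls essentially on a kept
  # centre (duplicate proposals of the same object from the two scales)
  ord <- order(-score, rows, cols)
  kept <- integer(0)
  for (k in ord) {
    ok <- TRUE
    for (m in kept) {
      same_centre <- (rows[k] - rows[m])^2 + (cols[k] - cols[m])^2 <
        params$min_radius_px^2
      if (same_centre ||
          disk_iou(rows[k], cols[k], radius[k],
                   rows[m], cols[m], radius[m]) > params$overlap_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, k)
  }
  out <- tibble::tibble(id = seq_along(kept),
                        row = rows[kept] - 1,  # 0-based coordinates
                        col = cols[kept] - 1,
                        radius = radius[kept],
                        score = score[kept])
  attr(out, "shape") <- dim(nuclear_img)
  class(out) <- c("nucleus_set", class(out))
  out
}

# Rescale to [0, 1] without warning for already-unit images; constant maps to 0.
rescale_unit <- function(img) {
  lo <- min(img); hi <- max(img)
  if (hi == lo) return(matrix(0, nrow(img), ncol(img)))
  if (lo >= 0 && hi <= 1) return(img)
  (img - lo) / (hi - lo)
}

#' Paint detected nuclei onto a blank label image
#'
#' Disks are rasterised in descending score order; a pixel already labelled
#' is never overwritten, so painted nuclei never overlap. Label ids are
#' assigned 1..n in painting order.
#'
#' @param nuclei A `nucleus_set` (from [detect_nuclei()]) or a tibble with
#'   `row`, `col`, `radius` (and optionally `score`) in 0-based coordinates.
#' @param shape Integer vector `(rows, cols)`; defaults to the nucleus set's
#'   recorded frame shape.
#' @return Integer label matrix (`LabelImage`): 0 background, k > 0 nucleus k.
#' @export
paint_labels <- function(nuclei, shape = attr(nuclei, "shape")) {
  if (is.null(shape)) stop("`shape` must be supplied", call. = FALSE)
  out <- matrix(0L, shape[1], shape[2])
  if (nrow(nuclei) == 0) return(out)
  n <- nuclei
  if (!is.null(n$score)) {
    n <- n[order(-n$score, n$row, n$col), , drop = FALSE]
  }
  for (k in seq_len(nrow(n))) {
    i0 <- n$row[k] + 1; j0 <- n$col[k] + 1; rad <- n$radius[k]
    ri <- max(1, floor(i0 - rad)):min(shape[1], ceiling(i0 + rad))
    rj <- max(1, floor(j0 - rad)):min(shape[2], ceiling(j0 + rad))
    d2 <- outer((ri - i0)^2, (rj - j0)^2, `+`)
    sel <- d2 <= rad^2 & out[ri, rj] == 0L
    block <- out[ri, rj]
    block[sel] <- k
    out[ri, rj] <- block
  }
  out
}

#' Build the propagation guide image
#'
#' Rescales each non-nuclear channel (insulin, glucagon, IGFBP7) to fill the
#' full intensity range, then combines them in a maximum intensity
#' projection. Constant channels rescale to all zeros (with a warning) and
#' therefore do not influence the guide.
#'
#' @param channels An `islet_image` (see [render_image()]) or a named list of
#'   matrices containing at least `insulin`, `glucagon` and `igfbp7`.
#' @return Guide matrix on \[0, 1\].
#' @export
make_guide <- function(channels) {
  need <- c("insulin", "glucagon", "igfbp7")
  if (!all(need %in% names(channels))) {
    stop("`channels` must contain insulin, glucagon and igfbp7 planes",
         call. = FALSE)
  }
  planes <- lapply(channels[need], rescale_full_range)
  max_projection(planes)
}

#' Expand nuclear seeds into cell territories by seeded propagation
#'
#' The guide is smoothed at `smoothing_sigma_px`; the growth region is the
#' set of pixels whose smoothed guide value exceeds `threshold_correction`
#' times the global minimum cross-entropy threshold of the smoothed guide,
#' united with all seed pixels. Each growth-region pixel is assigned the
#' label of the seed reachable at minimum accumulated path cost, where a step
#' from p to q costs `sqrt((I(p) - I(q))^2 + lambda * |p - q|^2)` on the
#' smoothed guide `I`. Seed pixels have cost 0, keep their own label, and are
#' not traversed by other labels. Cost ties resolve to the smaller label id;
#' pixels outside the growth region stay 0.
#'
#' A constant smoothed guide has no threshold; the growth region then covers
#' the full frame (with a warning) and expansion is purely geometric.
#'
#' @param seeds Integer label matrix of seed objects (from [paint_labels()]).
#' @param guide Numeric guide matrix of the same shape.
#' @param params A [propagation_params()] object.
#' @return Integer label matrix of cell territories.
#' @export
propagate_cells <- function(seeds, guide, params = propagation_params()) {
  assert_matrix(seeds)
  assert_matrix(guide)
  assert_same_shape(seeds, guide, "seeds and guide")
  if (!any(seeds > 0)) stop("no seeds to propagate from", call. = FALSE)
  sm <- gaussian_blur(guide, params$smoothing_sigma_px)
  near_constant <- diff(range(sm)) <= 1e-10 * max(1, abs(max(sm)))
  tr <- if (near_constant) NULL else {
    tryCatch(min_cross_entropy_threshold(hist256(sm)),
             isletquant_degenerate = function(e) NULL)
  }
  if (is.null(tr)) {
    warning("constant guide: growth region covers the full frame", call. = FALSE)
    region <- matrix(TRUE, nrow(sm), ncol(sm))
  } else if (params$threshold_correction == 1) {
    region <- apply_threshold(sm, tr)
  } else {
    region <- sm > params$threshold_correction * tr$threshold_value
  }
  region <- region | seeds > 0
  storage.mode(seeds) <- "integer"
  propagate_cpp(seeds, sm, region, params$regularization_lambda,
                as.integer(params$connectivity))
}
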