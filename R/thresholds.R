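# Automatic threshold selection on 256-bin gray-level histograms: Huang's
# minimum-fuzziness criterion (islet masks) and Li's minimum cross-entropy
# criterion (cell-boundary growth region). Both scan every candidate
# threshold exhaustively and break ties toward the smallest threshold, the
# ascending-scan convention of the ImageJ family. Foreground is always the
# strictly-greater side of the threshold.

#' Build a 256-bin histogram of an image
#'
#' Integer images with values in \[0, 255\] are counted directly (bin = gray
#' level). Float images are binned linearly over their observed range into
#' 256 levels. The mapping back to intensity units is kept so thresholds can
#' be expressed on the original scale.
#'
#' @param img Numeric matrix.
#' @return An object of class `hist256`: a list with `counts` (256 integers),
#'   `lo`, `hi` (observed range) and `eight_bit` (logical).
#' @export
hist256 <- function(img) {
  assert_matrix(img)
  v <- as.vector(img)
  if (anyNA(v)) stop("image contains NA values", call. = FALSE)
  eight_bit <- all(v == floor(v)) && min(v) >= 0 && max(v) <= 255
  if (eight_bit) {
    counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
    lo <- 0; hi <- 255
  } else {
    lo <- min(v); hi <- max(v)
    if (hi == lo) {
      counts <- integer(256)
      counts[1] <- length(v)
    } else {
      bins <- pmin(floor((v - lo) / (hi - lo) * 256), 255)
      counts <- tabulate(as.integer(bins) + 1L, nbins = 256L)
    }
  }
  structure(list(counts = counts, lo = lo, hi = hi, eight_bit = eight_bit),
            class = "hist256")
}

as_hist256 <- function(x) {
  if (inherits(x, "hist256")) return(x)
  if (is.matrix(x)) return(hist256(x))
  if (is.numeric(x) && length(x) == 256) {
    if (any(x < 0) || sum(x) <= 0) stop("invalid histogram counts", call. = FALSE)
    return(structure(list(counts = as.numeric(x), lo = 0, hi = 255,
                          eight_bit = TRUE), class = "hist256"))
  }
  stop("expected a `hist256`, an image matrix, or 256 histogram counts",
       call. = FALSE)
}

# Bin index (0..255) of each pixel under the histogram's binning.
bin_index <- function(img, h) {
  if (h$eight_bit) return(matrix(as.integer(img), nrow(img), ncol(img)))
  if (h$hi == h$lo) return(matrix(0L, nrow(img), ncol(img)))
  b <- pmin(floor((img - h$lo) / (h$hi - h$lo) * 256), 255)
  matrix(as.integer(b), nrow(img), ncol(img))
}

# Intensity-scale value of a bin threshold: the infimum of foreground values.
bin_to_value <- function(t, h) {
  if (h$eight_bit) return(t)
  h$lo + (t + 1) * (h$hi - h$lo) / 256
}

threshold_result <- function(threshold, criterion_value, curve, candidates, h) {
  structure(list(threshold = threshold,
                 criterion_value = criterion_value,
                 criterion_curve = curve,
                 candidates = candidates,
                 threshold_value = bin_to_value(threshold, h),
                 lo = h$lo, hi = h$hi, eight_bit = h$eight_bit),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> t = %d (criterion %.6g)\n",
              x$threshold, x$criterion_value))
  invisible(x)
}

check_nondegenerate <- function(h) {
  occ <- which(h$counts > 0)
  if (length(occ) < 2) {
    abort_degenerate("degenerate histogram: fewer than two occupied gray levels")
  }
  range(occ) - 1L  # occupied gray-level range, 0-based
}

#' Huang minimum-fuzziness threshold
#'
#' Selects the threshold `t` minimising the Huang–Wang fuzziness
#' `E(t) = sum_g h(g) S(mu_t(g))` where `mu_t(g) = 1 / (1 + |g - m| / C)`,
#' `m` is the mean gray level of the class (`<= t` or `> t`) containing `g`,
#' `C` is the occupied gray-level range, and `S` is the binary Shannon
#' entropy. Candidate thresholds run over `[g_min, g_max)`; ties break toward
#' the smallest `t`. Foreground pixels are those with value `> t`.
#'
#' @param hist A `hist256`, an image matrix, or a vector of 256 counts.
#' @return A `threshold_result` with the selected threshold (bin units), the
#'   criterion value, and the full criterion curve.
#' @export
huang_threshold <- function(hist) {
  h <- as_hist256(hist)
  rng <- check_nondegenerate(h)
  gmin <- rng[1]; gmax <- rng[2]
  g <- 0:255
  cnt <- h$counts
  C <- gmax - gmin
  W <- cumsum(cnt)
  S <- cumsum(g * cnt)
  Wtot <- W[256]; Stot <- S[256]
  cand <- gmin:(gmax - 1)
  shannon <- function(u) {
    s <- numeric(length(u))
    inner <- u > 0 & u < 1
    ui <- u[inner]
    s[inner] <- -ui * log(ui) - (1 - ui) * log(1 - ui)
    s
  }
  curve <- vapply(cand, function(t) {
    w0 <- W[t + 1]; s0 <- S[t + 1]
    m0 <- s0 / w0
    m1 <- (Stot - s0) / (Wtot - w0)
    m <- ifelse(g <= t, m0, m1)
    u <- 1 / (1 + abs(g - m) / C)
    sum(cnt * shannon(u))
  }, numeric(1))
  i <- which.min(curve)  # first minimum = smallest t on ties
  threshold_result(cand[i], curve[i], curve, cand, h)
}

#' Minimum cross-entropy (Li) threshold
#'
#' Selects the threshold minimising the Li–Lee cross-entropy between the
#' image and its two-level reconstruction,
#' `CE(t) = -M0(t) log mu0(t) - M1(t) log mu1(t)` (up to a constant), where
#' `M0, M1` are the first moments and `mu0, mu1` the mean gray levels of the
#' two classes. Gray levels are shifted by +1 so level 0 contributes nothing
#' and no logarithm of zero arises. Exhaustive scan; ties toward smallest
#' `t`; foreground is `> t`.
#'
#' @inheritParams huang_threshold
#' @return A `threshold_result`.
#' @export
min_cross_entropy_threshold <- function(hist) {
  h <- as_hist256(hist)
  rng <- check_nondegenerate(h)
  gmin <- rng[1]; gmax <- rng[2]
  cnt <- h$counts
  G <- (0:255) + 1  # shifted gray levels
  W <- cumsum(cnt)
  M <- cumsum(G * cnt)
  Wtot <- W[256]; Mtot <- M[256]
  cand <- gmin:(gmax - 1)
  curve <- vapply(cand, function(t) {
    w0 <- W[t + 1]; m0 <- M[t + 1]
    w1 <- Wtot - w0; m1 <- Mtot - m0
    -m0 * log(m0 / w0) - m1 * log(m1 / w1)
  }, numeric(1))
  i <- which.min(curve)
  threshold_result(cand[i], curve[i], curve, cand, h)
}

#' Apply a threshold result to an image
#'
#' Foreground convention: strictly greater than the threshold, evaluated in
#' the bin space of the histogram the threshold was computed on.
#'
#' @param img Numeric matrix (the image the threshold was computed from, or
#'   one binned identically).
#' @param tr A `threshold_result`.
#' @return Logical mask of foreground pixels.
#' @export
apply_threshold <- function(img, tr) {
  assert_matrix(img)
  h <- structure(list(counts = NULL, lo = tr$lo, hi = tr$hi,
                      eight_bit = tr$eight_bit), class = "hist256")
  bin_index(img, h) > tr$threshold
}
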