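# Core deterministic image operators: Gaussian blur, range rescaling and
# maximum projection. All operate on plain numeric matrices (row, col),
# 0-based pixel-centred coordinates are used wherever positions are reported.

# One-dimensional blur operator as an n x n row-stochastic matrix with
# symmetric (edge-repeating) reflection at the boundary. Blurring a plane is
# then two dense matrix products, which keeps the operator exact and fast.
blur_matrix <- function(n, sigma) {
  radius <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k <- k / sum(k)
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- i + seq(-radius, radius)
    # reflect out-of-range indices back into 1..n (symmetric, edge repeated)
    while (any(bad <- (js < 1 | js > n))) {
      js[js < 1] <- 1 - js[js < 1]
      js[js > n] <- 2 * n + 1 - js[js > n]
    }
    for (t in seq_along(js)) B[i, js[t]] <- B[i, js[t]] + k[t]
  }
  B
}

#' Gaussian blur with reflecting boundary
#'
#' Separable Gaussian smoothing with a normalised kernel (truncated at four
#' standard deviations) and symmetric reflection at the image boundary.
#' `sigma_px = 0` returns the input unchanged.
#'
#' @param img Numeric matrix.
#' @param sigma_px Standard deviation of the kernel in pixels (>= 0).
#' @return Blurred matrix of the same shape.
#' @export
gaussian_blur <- function(img, sigma_px) {
  assert_matrix(img)
  if (!is.numeric(sigma_px) || length(sigma_px) != 1L || is.na(sigma_px) || sigma_px < 0) {
    stop("`sigma_px` must be a single non-negative number", call. = FALSE)
  }
  if (sigma_px == 0) return(img)
  out <- blur_matrix(nrow(img), sigma_px) %*% img
  out <- out %*% t(blur_matrix(ncol(img), sigma_px))
  out
}

#' Rescale an image to fill the full intensity range
#'
#' Affine map sending the observed minimum to 0 and the observed maximum to 1.
#' A constant image maps to all zeros, with a warning (degenerate convention).
#'
#' @param img Numeric matrix.
#' @return Rescaled matrix on \[0, 1\].
#' @export
rescale_full_range <- function(img) {
  assert_matrix(img)
  lo <- min(img)
  hi <- max(img)
  if (hi == lo) {
    warning("constant image: rescaled to all zeros", call. = FALSE)
    return(matrix(0, nrow(img), ncol(img)))
  }
  (img - lo) / (hi - lo)
}

#' Pixelwise maximum intensity projection
#'
#' @param planes A list of numeric matrices of identical shape (or a single
#'   matrix).
#' @return Matrix of pixelwise maxima.
#' @export
max_projection <- function(planes) {
  if (is.matrix(planes)) planes <- list(planes)
  if (!is.list(planes) || length(planes) == 0) {
    stop("`planes` must be a non-empty list of matrices", call. = FALSE)
  }
  for (p in planes) assert_matrix(p, "planes[[i]]")
  for (p in planes[-1]) assert_same_shape(planes[[1]], p, "projection planes")
  Reduce(pmax, planes)
}
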