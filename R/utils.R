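#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @useDynLib isletquant, .registration = TRUE
NULL

# Channel roles every multi-channel field must carry, in canonical page order.
CHANNELS <- c("nuclear", "insulin", "glucagon", "igfbp7")

abort_degenerate <- function(msg) {
  stop(structure(class = c("isletquant_degenerate", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_capacity <- function(msg) {
  stop(structure(class = c("isletquant_capacity", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  invisible(x)
}

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must have identical dimensions (%s vs %s)",
                 what, paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  }
  invisible(NULL)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic counter scheme used to give every stage, donor and replicate
#' its own reproducible stream while a single master seed reproduces the whole
#' analysis. Values stay below 2^31 - 1.
#'
#' @param master Master seed (single integer).
#' @param k Counter (single non-negative integer).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, k) {
  m <- 2147483647
  s <- (as.double(master) %% m) * 48271 + as.double(k) * 7919 + 1
  as.integer(s %% m)
}

#' Convert a unit-scale image to 8-bit integers
#'
#' Multiplies by 255 and rounds half-up, clipping to \[0, 255\].
#'
#' @param img Numeric matrix on the \[0, 1\] scale.
#' @return Integer-valued matrix on the \[0, 255\] scale.
#' @export
to_8bit <- function(img) {
  assert_matrix(img)
  out <- floor(pmin(pmax(img, 0), 1) * 255 + 0.5)
  storage.mode(out) <- "integer"
  out
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
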