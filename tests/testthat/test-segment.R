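test_that("segment_islet handles uniform probability maps", {
  full <- matrix(255, 32, 32)
  expect_error(m <- segment_islet(full), NA)
  # uniform map minus offset is constant: degenerate -> empty mask + warning
  expect_warning(m0 <- segment_islet(matrix(0, 32, 32)), "empty|degenerate")
  expect_false(any(m0))
})

test_that("segment_islet recovers a large disk islet accurately", {
  geom <- geometry_params(field_shape = c(1024, 1024), islet_radius_px = 360,
                          n_cells = 4, min_center_spacing_px = 22)
  truth <- generate_truth(geom, seed = 5)
  pm <- render_probability_map(truth, blur_sigma_px = 5, noise_sd = 8, seed = 6)
  mask <- segment_islet(pm)
  jaccard <- sum(mask & truth$islet_mask) / sum(mask | truth$islet_mask)
  expect_gte(jaccard, 0.95)
})

test_that("segment_islet is invariant to adding a constant below the offset", {
  geom <- small_geometry(n_cells = 4)
  truth <- generate_truth(geom, seed = 7)
  pm <- render_probability_map(truth, blur_sigma_px = 0, noise_sd = 0, seed = 1)
  m1 <- segment_islet(pm)
  m2 <- segment_islet(pmin(pm + 30L, 255L))  # background 0 -> 30, still <= offset 40
  expect_identical(m1, m2)
})

test_that("mask_channel keeps pixels inside the mask and zeroes the rest", {
  set.seed(21)
  img <- matrix(runif(100), 10, 10)
  expect_identical(mask_channel(img, matrix(TRUE, 10, 10)), img)
  expect_true(all(mask_channel(img, matrix(FALSE, 10, 10)) == 0))
  half <- matrix(FALSE, 10, 10); half[, 1:5] <- TRUE
  out <- mask_channel(img, half)
  expect_identical(out[, 1:5], img[, 1:5])
  expect_true(all(out[, 6:10] == 0))
})

gaussian_blob <- function(shape, center, sigma, amp = 0.8) {
  outer(seq_len(shape[1]), seq_len(shape[2]), function(i, j) {
    amp * exp(-((i - center[1])^2 + (j - center[2])^2) / (2 * sigma^2))
  })
}

test_that("detect_nuclei finds isolated blobs at their centres", {
  img <- gaussian_blob(c(64, 64), c(30.3, 33.6), 4)
  det <- detect_nuclei(img, nuclei_params(blur_sigma_px = 2))
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$row - 29.3), 1)  # 0-based
  expect_lt(abs(det$col - 32.6), 1)

  two <- gaussian_blob(c(100, 100), c(25, 50), 4) +
    gaussian_blob(c(100, 100), c(85, 50), 4)
  det2 <- detect_nuclei(two, nuclei_params(blur_sigma_px = 2))
  expect_equal(nrow(det2), 2)

  expect_equal(nrow(detect_nuclei(matrix(0, 32, 32))), 0)
})

test_that("non-maximum suppression keeps the higher-scoring of two overlapping detections", {
  # two disks close enough that their fitted disks overlap above threshold
  img <- matrix(0, 60, 60)
  d2a <- outer((1:60 - 30)^2, (1:60 - 28)^2, `+`)
  d2b <- outer((1:60 - 30)^2, (1:60 - 32)^2, `+`)
  img[d2a <= 36] <- 0.9
  img[d2b <= 36 & img == 0] <- 0.7
  p <- nuclei_params(blur_sigma_px = 1, overlap_threshold = 0.3,
                     min_radius_px = 3, max_radius_px = 9,
                     peak_threshold = 0.3)
  det <- detect_nuclei(img, p)
  expect_equal(nrow(det), 1)
  # analytic IoU used in suppression agrees with rasterised IoU
  expect_equal(isletquant:::disk_iou(30, 28, 6, 30, 32, 6),
               disk_iou_raster(30, 28, 6, 30, 32, 6), tolerance = 0.01)
})

test_that("paint_labels rasterises without overlap and in score order", {
  shape <- c(40, 40)
  empty <- tibble::tibble(row = numeric(), col = numeric(),
                          radius = numeric(), score = numeric())
  expect_true(all(paint_labels(empty, shape) == 0))

  two <- tibble::tibble(row = c(10, 30), col = c(10, 30),
                        radius = c(4, 5), score = c(0.9, 0.8))
  lab <- paint_labels(two, shape)
  a1 <- sum(outer((0:39 - 10)^2, (0:39 - 10)^2, `+`) <= 16)
  a2 <- sum(outer((0:39 - 30)^2, (0:39 - 30)^2, `+`) <= 25)
  expect_equal(sum(lab == 1), a1)
  expect_equal(sum(lab == 2), a2)

  overlapping <- tibble::tibble(row = c(20, 20), col = c(18, 24),
                                radius = c(5, 5), score = c(0.9, 0.8))
  lab2 <- paint_labels(overlapping, shape)
  in1 <- outer((0:39 - 20)^2, (0:39 - 18)^2, `+`) <= 25
  in2 <- outer((0:39 - 20)^2, (0:39 - 24)^2, `+`) <= 25
  expect_equal(sum(lab2 > 0), sum(in1 | in2))  # union covered, no overlap
  expect_equal(sum(lab2 == 1), sum(in1))       # higher score painted first
})

test_that("make_guide rescales channels and projects their maximum", {
  set.seed(22)
  a <- matrix(runif(64), 8, 8)
  img <- list(nuclear = a, insulin = a, glucagon = a, igfbp7 = a)
  expect_equal(make_guide(img), rescale_full_range(a))

  img2 <- list(insulin = a, glucagon = matrix(0, 8, 8), igfbp7 = a / 2)
  expect_warning(g2 <- make_guide(img2), "constant")
  expect_equal(g2, pmax(rescale_full_range(a), rescale_full_range(a / 2)))

  img3 <- list(insulin = matrix(0.2, 8, 8), glucagon = matrix(0.5, 8, 8),
               igfbp7 = matrix(0.9, 8, 8))
  w <- testthat::capture_warnings(g3 <- make_guide(img3))
  expect_length(w, 3)  # one per constant channel
  expect_true(all(grepl("constant", w)))
  expect_true(all(g3 == 0))
})

test_that("propagation: single seed floods a uniform guide; ties go to the smaller label", {
  seeds <- matrix(0L, 15, 15); seeds[8, 8] <- 1L
  expect_warning(lab <- propagate_cells(seeds, matrix(0.5, 15, 15)), "constant")
  expect_true(all(lab == 1))

  seeds2 <- matrix(0L, 11, 21)
  seeds2[6, 5] <- 1L; seeds2[6, 17] <- 2L
  expect_warning(lab2 <- propagate_cells(seeds2, matrix(0.5, 11, 21)), "constant")
  # geodesic split with the equidistant column taken by label 1
  expect_true(all(lab2[, 1:11] == 1))
  expect_true(all(lab2[, 12:21] == 2))
})

test_that("propagation matches the Dijkstra oracle on a ridge fixture", {
  guide <- matrix(0.1, 15, 15)
  guide[, 8] <- 0.9  # bright vertical ridge between the two seeds
  seeds <- matrix(0L, 15, 15)
  seeds[8, 3] <- 1L; seeds[8, 13] <- 2L
  p <- propagation_params(regularization_lambda = 0.25, smoothing_sigma_px = 0)
  lab <- propagate_cells(seeds, guide, p)
  sm <- guide
  tr <- min_cross_entropy_threshold(hist256(sm))
  region <- apply_threshold(sm, tr) | seeds > 0
  expect_identical(lab, dijkstra_oracle(seeds, sm, region, 0.25, 8))
})

test_that("propagation never re-assigns seed pixels and labels stay connected to their seed", {
  set.seed(23)
  for (rep in 1:5) {
    guide <- matrix(runif(18 * 18), 18, 18)
    seeds <- matrix(0L, 18, 18)
    pos <- sample(18 * 18, 3)
    seeds[pos] <- 1:3
    lab <- suppressWarnings(propagate_cells(seeds, guide,
      propagation_params(smoothing_sigma_px = 0)))
    expect_identical(lab[seeds > 0], seeds[seeds > 0])
    # each labelled pixel connects to its seed through same-labelled pixels
    for (L in 1:3) {
      comp <- matrix(FALSE, 18, 18)
      comp[seeds == L] <- TRUE
      repeat {
        grown <- comp
        idx <- which(comp, arr.ind = TRUE)
        for (k in seq_len(nrow(idx))) {
          for (di in -1:1) for (dj in -1:1) {
            i <- idx[k, 1] + di; j <- idx[k, 2] + dj
            if (i >= 1 && i <= 18 && j >= 1 && j <= 18 && lab[i, j] == L) {
              grown[i, j] <- TRUE
            }
          }
        }
        if (identical(grown, comp)) break
        comp <- grown
      }
      expect_true(all(comp[lab == L]), info = paste("label", L, "rep", rep))
    }
  }
})

test_that("increasing lambda never lets more pixels cross an intensity barrier", {
  guide <- matrix(0.05, 13, 13)
  guide[, 7] <- 0.85
  seeds <- matrix(0L, 13, 13)
  seeds[7, 2] <- 1L; seeds[7, 12] <- 2L
  crossings <- vapply(c(0, 0.1, 0.25, 1, 5), function(lam) {
    lab <- suppressWarnings(propagate_cells(seeds, guide,
      propagation_params(regularization_lambda = lam, smoothing_sigma_px = 0)))
    sum(lab[, 1:6] == 2)  # far-seed pixels on label 1's side of the ridge
  }, numeric(1))
  expect_true(all(diff(crossings) <= 0))
})

test_that("propagation requires at least one seed", {
  expect_error(propagate_cells(matrix(0L, 5, 5), matrix(0.5, 5, 5)), "seed")
})
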