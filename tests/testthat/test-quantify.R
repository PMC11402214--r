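make_image <- function(planes) {
  structure(planes, class = "islet_image")
}

test_that("cell_features computes medians with the even-count convention", {
  cells <- matrix(0L, 4, 4)
  cells[1, 1:3] <- 1L
  img <- list(nuclear = matrix(0, 4, 4), insulin = matrix(0, 4, 4),
              glucagon = matrix(0, 4, 4), igfbp7 = matrix(0, 4, 4))
  img$igfbp7[1, 1:3] <- c(1, 2, 3)
  img$igfbp7[4, 4] <- 9  # ensures a non-constant channel for rescaling
  tab <- cell_features(cells, img)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$median_igfbp7, 2)

  cells[2, 1:4] <- 2L
  img$igfbp7[2, 1:4] <- c(1, 2, 3, 4)
  tab2 <- cell_features(cells, img)
  expect_equal(tab2$median_igfbp7[tab2$cell_id == 2], 2.5)
  expect_equal(tab2$area_px, c(3L, 4L))

  expect_equal(nrow(cell_features(matrix(0L, 4, 4), img)), 0)
})

test_that("cell_features centroids are 0-based pixel means", {
  cells <- matrix(0L, 5, 5)
  cells[2:3, 4] <- 1L
  img <- lapply(list(1, 1, 1, 1), function(x) matrix(0.5, 5, 5))
  names(img) <- c("nuclear", "insulin", "glucagon", "igfbp7")
  img$igfbp7[1, 1] <- 1
  tab <- cell_features(cells, img)
  expect_equal(tab$centroid_row, 1.5)
  expect_equal(tab$centroid_col, 3)
})

test_that("classification rule: inclusive boundary, exclusivity, scale invariance", {
  tab <- tibble::tibble(median_insulin = c(150, 100, 100, 0, 1),
                        median_glucagon = c(100, 100, 160, 0, 1.49))
  out <- classify_cells(tab)
  expect_equal(out$cell_class,
               c("beta", "unclassified", "alpha", "unclassified", "unclassified"))

  out2 <- classify_cells(dplyr::mutate(tab,
    median_insulin = median_insulin * 7.3,
    median_glucagon = median_glucagon * 7.3))
  expect_equal(out2$cell_class, out$cell_class)

  expect_error(classify_cells(tibble::tibble(median_insulin = -1,
                                             median_glucagon = 2)), "negative")
  expect_error(classify_cells(tab, ratio = 1), "ratio")
})

test_that("classification partition is total and exclusive on a value lattice", {
  vals <- c(0, 0.01, 0.5, 1, 1.49, 1.5, 1.51, 2, 10, 100)
  grid <- expand.grid(ins = vals, glu = vals)
  out <- classify_cells(tibble::tibble(median_insulin = grid$ins,
                                       median_glucagon = grid$glu))
  expect_true(all(out$cell_class %in% c("alpha", "beta", "unclassified")))
  both <- grid$ins >= 1.5 * grid$glu & grid$glu >= 1.5 * grid$ins
  expect_true(all(out$cell_class[both] == "unclassified"))  # only at (0, 0)
  expect_true(all(grid$ins[both] == 0 & grid$glu[both] == 0))
  # exact boundary pairs classify as the hormone class
  b <- classify_cells(tibble::tibble(median_insulin = 1.5 * vals[vals > 0],
                                     median_glucagon = vals[vals > 0]))
  expect_true(all(b$cell_class == "beta"))
})

test_that("manders overlap: equality, disjoint support, direct formula", {
  set.seed(61)
  a <- matrix(runif(64), 8, 8)
  expect_equal(manders_overlap(a, a), 1)

  b <- matrix(0, 8, 8); c2 <- matrix(0, 8, 8)
  b[1:4, ] <- 1; c2[5:8, ] <- 1
  expect_equal(manders_overlap(b, c2), 0)

  x <- matrix(c(1, 2), 1, 2)
  y <- matrix(c(2, 1), 1, 2)
  expect_equal(manders_overlap(x, y), 0.8)

  expect_error(manders_overlap(matrix(0, 3, 3), matrix(0, 3, 3)),
               class = "isletquant_degenerate")
  expect_error(manders_overlap(a, a, matrix(FALSE, 8, 8)), "empty")
})

test_that("manders overlap is symmetric, bounded and scaling-invariant", {
  set.seed(62)
  for (i in 1:20) {
    a <- matrix(rexp(49), 7, 7)
    b <- matrix(rexp(49), 7, 7)
    region <- matrix(runif(49) < 0.7, 7, 7)
    if (!any(region)) region[1, 1] <- TRUE
    m <- manders_overlap(a, b, region)
    expect_equal(m, manders_overlap(b, a, region))
    expect_gte(m, 0); expect_lte(m, 1)
    expect_equal(manders_overlap(a * 3.7, b * 0.21, region), m)
  }
})

test_that("mann_whitney: exact enumeration examples and mode selection", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 2 / 6, tolerance = 1e-12)
  expect_equal(r$method, "exact")

  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))  # ties -> approximate
  expect_equal(same$method, "normal_approx")
  expect_equal(same$p_value, 1, tolerance = 0.05)

  # exact mode equals enumeration; the normal approximation at n = 5 vs 5 is
  # within its enumerated worst-case error bound (0.0172 over all U values)
  for (s in 1:5) {
    set.seed(63 + s)
    x <- rnorm(5); y <- rnorm(5)
    pe <- mann_whitney(x, y, exact = TRUE)$p_value
    pa <- mann_whitney(x, y, exact = FALSE)$p_value
    expect_equal(pe, mw_enum_oracle(x, y), tolerance = 1e-12)
    expect_lt(abs(pa - pe), 0.02)
  }

  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("pooled t test matches hand computation and handles degeneracy", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  r <- t_test_two_sample(x, y)
  expect_equal(r$statistic, -sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(r$df, 4)

  same <- t_test_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  const <- t_test_two_sample(c(2, 2), c(2, 2))
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)
  expect_error(t_test_two_sample(c(1, 1), c(2, 2)),
               class = "isletquant_degenerate")
})

test_that("summarize_groups reports per-group medians, counts and tests", {
  tab <- tibble::tibble(
    donor_id = c("a", "b", "c", "d", "e"),
    group = c("ND", "T2D", "ND", "T2D", "ND"),
    median_insulin = c(10, 10, 1, 1, 5),
    median_glucagon = c(1, 1, 10, 10, 5),
    median_igfbp7 = c(0.08, 0.1, 0.09, 0.11, 0.5)
  )
  tab <- classify_cells(tab)
  s <- summarize_groups(tab)
  expect_equal(s$n_unclassified, 1L)
  expect_equal(s$n_total, 5L)
  expect_equal(nrow(s$summary), 4)
  expect_equal(s$summary$n_cells, rep(1L, 4))
  # single cell per (group, class): medians are those cells' values, p = 1
  expect_equal(s$summary$median_igfbp7[s$summary$cell_class == "beta" &
                                       s$summary$group == "ND"], 0.08)
  expect_true(all(s$tests$p_value == 1))

  empty <- summarize_groups(classify_cells(tab[0, ]))
  expect_equal(empty$n_total, 0L)
  expect_equal(nrow(empty$summary), 0)
})

test_that("cell_moc pairs IGFBP7 with the class hormone over each territory", {
  cells <- matrix(0L, 6, 6)
  cells[1:2, 1:2] <- 1L  # alpha
  cells[4:5, 4:5] <- 2L  # beta
  img <- list(nuclear = matrix(0, 6, 6),
              insulin = matrix(0.5, 6, 6),
              glucagon = matrix(0.1, 6, 6),
              igfbp7 = matrix(0.2, 6, 6))
  img$glucagon[1:2, 1:2] <- 0.9
  img$insulin[1:2, 1:2] <- 0.01
  img$igfbp7[1, 1] <- 0.9
  tab <- classify_cells(cell_features(cells, img))
  out <- cell_moc(tab, cells, img)
  m1 <- manders_overlap(img$igfbp7, img$glucagon, cells == 1L)
  m2 <- manders_overlap(img$igfbp7, img$insulin, cells == 2L)
  expect_equal(out$moc, c(m1, m2))
})
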