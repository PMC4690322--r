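test_that("row/column slices tile the image and contain their spots", {
  p <- simulation_params(seed = 51, groups_nx = 1, groups_ny = 1)
  sim <- generate_pair(p)
  enh <- log_enhance(sim$cy3)
  g <- structure(list(x_lines = c(0, 100, 200, ncol(enh$pixels)),
                      y_lines = c(0, 150, nrow(enh$pixels)),
                      bounds = dim(enh$pixels)[2:1]), class = "grid_lines")
  sl <- slice_rows_cols(enh, g)
  expect_length(sl$rows, 2)
  expect_length(sl$cols, 3)
  expect_equal(do.call(rbind, sl$rows), enh$pixels)
  expect_equal(do.call(cbind, sl$cols), enh$pixels)
})

test_that("tight borders recover the edges of a clean spot", {
  # spot of half-width 7 centered at 30 inside cell (10, 50); edge scale
  # 0.45 px -> inflection points of the profile at 23 and 37
  x <- sigmoid_bump(60, 23, 37, 0.45, lo = 2, hi = 100)
  f <- shock_filter(x, 50)
  b <- spot_borders(f, 10, 50)
  expect_false(is.null(b))
  expect_lt(abs(b[1] - 23), 1.01)
  expect_lt(abs(b[2] - 37), 1.01)
})

test_that("blank cells report missing borders", {
  set.seed(52)
  flat <- 50 + rnorm(60, 0, 0.5)
  expect_null(spot_borders(shock_filter(flat, 50), 10, 50))
})

test_that("thr = 0 still yields ordered borders via leftmost/rightmost rule", {
  set.seed(53)
  x <- sigmoid_bump(60, 23, 37, 0.45, lo = 2, hi = 100) + rnorm(60, 0, 0.3)
  b <- spot_borders(shock_filter(x, 50), 10, 50, thr = 0)
  expect_false(is.null(b))
  expect_lt(b[1], b[2])
})

test_that("autocorrelation recovers cosine and lattice periods", {
  x <- cos(2 * pi * (0:199) / 20)
  expect_lte(abs(autocorrelation_period(x) - 20), 1)

  p <- simulation_params(seed = 54, groups_nx = 1, groups_ny = 1)
  sim <- generate_pair(p)
  enh <- log_enhance(sim$cy3)
  prof <- axis_profile(gaussian_smooth(enh$pixels), "h")
  expect_lte(abs(autocorrelation_period(prof) - 28), 1)
})

test_that("aperiodic profiles raise an error", {
  set.seed(55)
  expect_error(autocorrelation_period(rnorm(200)), "aperiodic")
  expect_error(autocorrelation_period(rep(1, 50)), "constant")
})

test_that("gap filling continues the lattice periodically", {
  borders <- list(c(10, 24), NULL, c(66, 80))
  out <- fill_border_gaps(borders, 28)
  expect_equal(out$borders[[2]], c(38, 52))
  expect_equal(out$filled, c(FALSE, TRUE, FALSE))

  # identity on complete lists
  full <- list(c(1, 5), c(29, 33))
  expect_identical(fill_border_gaps(full, 28)$borders, full)

  # edge gap extrapolated from nearest neighbour and clipped
  out2 <- fill_border_gaps(list(NULL, c(30, 44), c(58, 72)), 28,
                           bounds = c(0, 80))
  expect_equal(out2$borders[[1]], c(2, 16))
  out3 <- fill_border_gaps(list(c(10, 24), NULL), 20, bounds = c(0, 40))
  expect_equal(out3$borders[[2]], c(30, 40))  # clipped at bound

  expect_error(fill_border_gaps(list(NULL, NULL), 28), "all border")
})

test_that("geometry builds nested rectangles and ellipse triplet", {
  g <- build_geometry(c(13, 27), c(13, 27), cell = c(0, 40, 0, 40))
  expect_equal(g$center, c(20, 20))
  expect_equal(c(g$a_f, g$b_f), c(7, 7))
  expect_equal(c(g$a_e, g$b_e), c(10, 10))
  expect_equal(c(g$a_b, g$b_b), c(20, 20))
  expect_length(g$flags, 0)

  # cramped cell: exclusion ellipse clipped, flagged
  g2 <- build_geometry(c(2, 16), c(2, 16), cell = c(0, 18, 0, 18))
  expect_true("clipped_exclusion" %in% g2$flags)
  expect_lte(g2$a_e, g2$a_b)

  # degenerate tight box substituted by a 3x3 minimum
  g3 <- build_geometry(c(10, 11), c(10, 12), cell = c(0, 28, 0, 28))
  expect_true("degenerate_box" %in% g3$flags)
  expect_equal(g3$r_small[["x1"]] - g3$r_small[["x0"]], 3)
})

test_that("ellipse rasterization matches brute-force enumeration", {
  big <- c(0, 100, 0, 100)
  expect_equal(nrow(rasterize_ellipse(c(50, 50), c(0.5, 0.5), big)), 1)
  expect_equal(nrow(rasterize_ellipse(c(50, 50), c(7, 7), big)), 149)
  expect_equal(nrow(rasterize_ellipse(c(200, 200), c(5, 5), big)), 0)

  set.seed(56)
  for (i in 1:25) {
    center <- runif(2, 10, 90)
    semi <- runif(2, 0.5, 12)
    got <- nrow(rasterize_ellipse(center, semi, big))
    expect_equal(got, oracle_ellipse_count(center, semi))
  }
})

test_that("kmeans2 splits clean groups and flags degenerate input", {
  fit <- kmeans2(c(0, 0, 0, 10, 10, 10))
  expect_equal(fit$labels, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(unname(fit$centers), c(0, 10))

  dg <- kmeans2(rep(4, 5))
  expect_true(dg$degenerate)
  expect_false(any(dg$labels))
})

test_that("kmeans2 attains the exhaustive optimal contiguous split", {
  set.seed(57)
  for (i in 1:300) {
    n <- sample(2:12, 1)
    values <- switch(sample(3, 1),
                     runif(n, 0, 100),
                     rnorm(n, 50, 5),
                     sample(0:10, n, replace = TRUE) + 0)
    if (max(values) == min(values)) next
    fit <- kmeans2(values)
    expect_equal(kmeans2_wcss(values, fit),
                 oracle_best_split_wcss(values), tolerance = 1e-9)
  }
})

test_that("annular spots keep the ring and exclude the hole", {
  p <- simulation_params(seed = 58, groups_nx = 1, groups_ny = 1,
                         spots_nx = 3, spots_ny = 3, fraction_annular = 1)
  sim <- generate_pair(p)
  sp <- sim$truth$spots
  key <- function(m) m[, "u"] * 1e6 + m[, "v"]
  hole_total <- 0; hole_kept <- 0
  for (s in seq_len(nrow(sp))) {
    cell <- c(sp$cx[s] - 14, sp$cx[s] + 14, sp$cy[s] - 14, sp$cy[s] + 14)
    geom <- build_geometry(c(sp$cx[s] - 7, sp$cx[s] + 7),
                           c(sp$cy[s] - 7, sp$cy[s] + 7), cell)
    mask <- segment_spot(sim$cy3$pixels, sim$cy5$pixels, geom)
    truth <- sim$truth$masks[[s]]
    hole <- sim$truth$holes[[s]]
    covered <- length(intersect(key(truth), key(mask$foreground))) /
      nrow(truth)
    expect_gte(covered, 0.9)
    hole_total <- hole_total + nrow(hole)
    hole_kept <- hole_kept +
      length(intersect(key(hole), key(mask$foreground)))
  }
  expect_lte(hole_kept / hole_total, 0.1)
})

test_that("union semantics: pixel bright in one channel only is foreground", {
  n <- 41
  bg3 <- matrix(2000, n, n); bg5 <- matrix(2000, n, n)
  # disk bright in Cy3 only
  for (v in 0:(n - 1)) for (u in 0:(n - 1))
    if ((u - 20)^2 + (v - 20)^2 <= 49) bg3[v + 1, u + 1] <- 30000
  geom <- build_geometry(c(13, 27), c(13, 27), cell = c(0, n, 0, n))
  mask <- segment_spot(bg3, bg5, geom)
  expect_gt(nrow(mask$s_cy3), 100)
  expect_true(nrow(mask$foreground) >= nrow(mask$s_cy3))
  # blank in both channels (exactly constant) -> not found
  blank <- segment_spot(matrix(5, n, n), matrix(5, n, n), geom)
  expect_true("not_found" %in% blank$flags)
  expect_equal(nrow(blank$foreground), 0)
})

test_that("foreground, exclusion and background partition the E_B pixels", {
  p <- simulation_params(seed = 59, groups_nx = 1, groups_ny = 1,
                         spots_nx = 4, spots_ny = 4,
                         fraction_irregular = 0.3, fraction_annular = 0.3)
  sim <- generate_pair(p)
  sp <- sim$truth$spots
  for (s in seq_len(nrow(sp))) {
    cell <- c(sp$cx[s] - 14, sp$cx[s] + 14, sp$cy[s] - 14, sp$cy[s] + 14)
    geom <- build_geometry(c(sp$cx[s] - 7, sp$cx[s] + 7),
                           c(sp$cy[s] - 7, sp$cy[s] + 7), cell)
    mask <- segment_spot(sim$cy3$pixels, sim$cy5$pixels, geom)
    eb <- rasterize_ellipse(geom$big_center, c(geom$a_b, geom$b_b),
                            cell)
    key <- function(m) if (nrow(m)) m[, "u"] * 1e6 + m[, "v"] else numeric(0)
    parts <- c(key(mask$foreground), key(mask$exclusion),
               key(mask$background))
    expect_false(any(duplicated(parts)))         # no double counting
    expect_true(all(key(eb) %in% parts))         # E_B fully covered
  }
})
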