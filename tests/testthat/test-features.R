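make_mask <- function(fg, bg, flags = character(0)) {
  em <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("u", "v")))
  structure(list(s_cy3 = fg, s_cy5 = fg, foreground = fg, background = bg,
                 exclusion = em, ellipse_fg = fg, flags = flags),
            class = "spot_mask")
}

px_set <- function(us, vs) {
  m <- cbind(u = us, v = vs)
  storage.mode(m) <- "integer"
  m
}

test_that("medians of constant regions give exact features", {
  img3 <- matrix(40, 10, 10); img5 <- matrix(40, 10, 10)
  fg <- px_set(2:4, rep(2, 3)); bg <- px_set(6:8, rep(6, 3))
  img3[cbind(fg[, "v"] + 1, fg[, "u"] + 1)] <- 100
  img5[cbind(fg[, "v"] + 1, fg[, "u"] + 1)] <- 90
  f <- spot_features(img3, img5, make_mask(fg, bg))
  expect_equal(f$f_u_cy3, 100)
  expect_equal(f$b_cy3, 40)
  expect_equal(f$R, 60)
  expect_equal(f$G, 50)
  expect_equal(f$ratio, 1.2)
})

test_that("background above foreground floors F at zero with a flag", {
  img3 <- matrix(100, 10, 10)
  fg <- px_set(2:4, rep(2, 3)); bg <- px_set(6:8, rep(6, 3))
  img3[cbind(fg[, "v"] + 1, fg[, "u"] + 1)] <- 30
  f <- spot_features(img3, img3, make_mask(fg, bg))
  expect_equal(f$R, 0)
  expect_match(f$flags, "negative_R")
  expect_match(f$flags, "ratio_undefined")
  expect_true(is.na(f$ratio))
})

test_that("empty foreground is reported not-found", {
  em <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("u", "v")))
  f <- spot_features(matrix(1, 5, 5), matrix(1, 5, 5), make_mask(em, em))
  expect_match(f$flags, "not_found")
  expect_true(is.na(f$R))
})

test_that("features recover generator levels under Poisson-like noise", {
  # spec of the conditions: fg 30000, bg 2000 counts, counting noise
  set.seed(61)
  n <- 41
  errs <- numeric(16)
  for (k in seq_len(16)) {
    d <- outer((0:(n - 1)) - 20, (0:(n - 1)) - 20,
               function(v, u) sqrt(u^2 + v^2))   # [v+1, u+1]
    clean3 <- 2000 + 28000 / (1 + exp((d - 7) / 0.45))
    noisy <- matrix(rnorm(n * n, clean3, sqrt(clean3)), n, n)
    geom <- build_geometry(c(13, 27), c(13, 27), cell = c(0, n, 0, n))
    mask <- segment_spot(noisy, noisy, geom)
    f <- spot_features(noisy, noisy, mask)
    errs[k] <- (f$R - 28000) / 28000
  }
  expect_lt(abs(median(errs)), 0.02)
})

test_that("regression ratio is exact for proportional channels", {
  g <- c(10, 200, 4000, 9000, 30000)
  r <- regression_ratio(2 * g, g)
  expect_equal(r$rR, 2)
  expect_equal(r$r2, 1)

  set.seed(62)
  rr <- regression_ratio(rnorm(500), rnorm(500))
  expect_lt(rr$r2, 0.05)

  cg <- regression_ratio(c(1, 2, 3), c(5, 5, 5))
  expect_true(is.na(cg$rR))
  expect_equal(cg$flags, "constant_green")
})

test_that("noise-free homogeneous spots give r = rR = rho and R2 = 1", {
  for (rho in c(0.5, 1, 2, 4)) {
    p <- simulation_params(seed = 63, groups_nx = 1, groups_ny = 1,
                           spots_nx = 3, spots_ny = 3, ratio = rho,
                           noise_frac = 0, background_noise_sd = 0,
                           edge_width_px = 0, jitter_px = 0)
    sim <- generate_pair(p)
    run <- spot_pipeline(sim$cy3, sim$cy5, slide_layout(1, 1, 3, 3, 28),
                         pipeline_control(rotation_search_deg = 0))
    expect_true(all(abs(run$results$ratio - rho) < 1e-6))
    expect_true(all(abs(run$results$rR - rho) < 1e-6))
    expect_true(all(abs(run$results$R2 - 1) < 1e-9))
  }
})

test_that("lowess normalisation removes an imposed smooth M-A trend", {
  set.seed(64)
  n <- 400
  A <- runif(n, 8, 15)
  bias <- 0.5 * sin((A - 8) / 7 * pi) + 0.5   # smooth, amplitude 1.0
  M <- bias + rnorm(n, 0, 0.05)
  G <- 2^(A - M / 2); R <- 2^(A + M / 2)
  norm <- lowess_normalize(data.frame(R = R, G = G), window = 0.20)
  bins <- cut(A, 8)
  resid <- tapply(norm$M_norm, bins, mean)
  expect_lt(max(abs(resid), na.rm = TRUE), 0.05)
  expect_equal(nrow(norm), n)

  # identical M -> fitted constant -> normalised M identically 0
  cn <- lowess_normalize(data.frame(R = 2^seq(6, 14, length.out = 50),
                                    G = 2^seq(5, 13, length.out = 50)))
  expect_true(all(abs(cn$M_norm) < 1e-9))
})

test_that("normalisation preserves rank order within narrow A bins", {
  set.seed(65)
  n <- 200
  A <- runif(n, 8, 15)
  M <- 0.3 * A + rnorm(n, 0, 0.3)
  norm <- lowess_normalize(data.frame(R = 2^(A + M / 2), G = 2^(A - M / 2)))
  bins <- cut(A, 20)
  for (b in levels(bins)) {
    i <- which(bins == b)
    if (length(i) < 2) next
    fit_span <- diff(range(norm$M[i] - norm$M_norm[i]))
    for (k in seq_along(i)) for (l in seq_along(i)) {
      dM <- norm$M[i[k]] - norm$M[i[l]]
      if (dM > fit_span)   # separated beyond the local fit variation
        expect_gt(norm$M_norm[i[k]], norm$M_norm[i[l]])
    }
  }
})

test_that("fewer than 10 valid spots skips normalisation with warning", {
  expect_warning(
    norm <- lowess_normalize(data.frame(R = c(4, 8, 16), G = c(2, 2, 2))),
    "fewer than 10")
  expect_equal(norm$ratio_norm, c(2, 4, 8))
  expect_false(any(norm$normalized))
})

test_that("up-regulation uses a strict threshold", {
  ratios <- data.frame(ratio_norm = c(1.99, 2, 2.0000001, 4, NA))
  expect_equal(call_upregulated(ratios, 2), c(3L, 4L))
  expect_length(call_upregulated(data.frame(ratio_norm = numeric(0))), 0)
})

test_that("features are invariant under channel-wise affine re-scan", {
  p <- simulation_params(seed = 66, groups_nx = 1, groups_ny = 1,
                         spots_nx = 3, spots_ny = 3, ratio = 2,
                         fg_level_cy3 = 20000)
  sim <- generate_pair(p)
  run1 <- spot_pipeline(sim$cy3, sim$cy5, slide_layout(1, 1, 3, 3, 28),
                        pipeline_control(rotation_search_deg = 0))
  scaled3 <- raw_image(round(sim$cy3$pixels * 1.5), "Cy3")
  scaled5 <- raw_image(round(sim$cy5$pixels * 1.5), "Cy5")
  run2 <- spot_pipeline(scaled3, scaled5, slide_layout(1, 1, 3, 3, 28),
                        pipeline_control(rotation_search_deg = 0))
  expect_equal(run2$results$R / run1$results$R, rep(1.5, 9), tolerance = 0.02)
  expect_equal(run2$results$ratio, run1$results$ratio, tolerance = 0.02)
})
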