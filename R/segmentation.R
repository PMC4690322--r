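# Spot segmentation: slice profiles, tight borders (inflection points),
# autocorrelation gap filling, ellipse triplets and local 2-means.

#' Cut a sub-image into row and column slices along the grid
#'
#' Horizontal slice `i` spans the rows between adjacent y borderlines,
#' vertical slice `j` the columns between adjacent x borderlines. Together
#' the slices tile the sub-image and each contains one row (or column) of
#' spots.
#'
#' @param img An [enhanced_image()] or matrix (the group sub-image).
#' @param grid A `grid_lines` object from [grid_from_steps()].
#' @return List with `rows` and `cols`: lists of numeric matrices.
#' @export
slice_rows_cols <- function(img, grid) {
  px <- if (inherits(img, "enhanced_image")) img$pixels else img
  ys <- round(grid$y_lines); xs <- round(grid$x_lines)
  rows <- lapply(seq_len(length(ys) - 1), function(i)
    px[(ys[i] + 1):ys[i + 1], , drop = FALSE])
  cols <- lapply(seq_len(length(xs) - 1), function(j)
    px[, (xs[j] + 1):xs[j + 1], drop = FALSE])
  list(rows = rows, cols = cols)
}

#' Tight spot borders within a grid cell
#'
#' On the shock-filtered slice profile, the tight borders of the spot in
#' the cell `(x_l, x_r)` are the leftmost rising jump and the rightmost
#' falling jump whose magnitudes exceed `thr` (30% of the average profile
#' intensity by default). Spots of very low intensity produce no
#' qualifying jump; the border pair is then reported missing so that
#' [fill_border_gaps()] can reconstruct it from the lattice period.
#'
#' @param p Shock-filtered [intensity_profile()] (or vector) of the slice.
#' @param x_l,x_r Adjacent grid lines bounding the cell (0-based).
#' @param thr Minimum jump magnitude; default `0.30 * mean(p)`.
#' @return Numeric `c(h_l, h_r)` (0-based positions), or `NULL` when
#'   either border is undetected or they cross.
#' @export
spot_borders <- function(p, x_l, x_r, thr = NULL) {
  x <- if (inherits(p, "intensity_profile")) p$values else p
  if (is.null(thr)) thr <- 0.30 * mean(x)
  d <- diff(x)                      # d[i] = jump at 0-based position i
  pos <- seq_along(d)
  inside <- pos > x_l & pos < x_r
  rising <- inside & d > thr
  falling <- inside & d < -thr
  if (!any(rising) || !any(falling)) return(NULL)
  h_l <- min(pos[rising])
  h_r <- max(pos[falling])
  if (h_l >= h_r) return(NULL)
  c(h_l = h_l, h_r = h_r)
}

#' Lattice period from the autocorrelation of a profile
#'
#' The lag of the first local maximum (at lag >= 2 px) of the unbiased
#' autocorrelation of the mean-subtracted profile; for a periodic spot row
#' this is the typical center-to-center distance between spots. The
#' search is limited to lags up to `n / 3` (the profile must cover at
#' least about three pitches) and peaks must exceed a white-noise
#' significance bound (`3.5 * sqrt(n) / (n - k)`, i.e. 3.5 standard
#' errors of the unbiased lag-k autocorrelation, at least 0.15), so an
#' aperiodic profile raises an error instead of returning a noise lag.
#'
#' @param p An [intensity_profile()] or numeric vector covering at least
#'   about three spot pitches.
#' @return The period in pixels (integer lag).
#' @export
autocorrelation_period <- function(p) {
  x <- if (inherits(p, "intensity_profile")) p$values else p
  n <- length(x)
  stopifnot(n >= 8)
  xc <- x - mean(x)
  denom <- sum(xc^2) / n
  if (denom == 0) stop("profile is constant: no periodicity")
  max_lag <- max(3L, floor(n / 3))
  r <- vapply(seq_len(max_lag), function(k)
    sum(xc[seq_len(n - k)] * xc[seq_len(n - k) + k]) / (n - k) / denom,
    numeric(1))
  for (k in 2:(max_lag - 1)) {
    sig <- max(3.5 * sqrt(n) / (n - k), 0.15)
    if (r[k] > r[k - 1] && r[k] >= r[k + 1] && r[k] > sig)
      return(k)
  }
  stop("profile aperiodic: autocorrelation has no significant local maximum")
}

#' Fill missing border pairs by periodic continuation
#'
#' Missing entries (spots whose inflection points could not be detected)
#' are reconstructed from the nearest detected pair, translated by the
#' corresponding integer multiple of the lattice period and clipped to the
#' slice bounds. Filled entries are flagged.
#'
#' @param borders List of `c(h_l, h_r)` pairs or `NULL` for missing, one
#'   entry per grid cell of the slice.
#' @param period_px Lattice period from [autocorrelation_period()].
#' @param bounds Slice extent `c(0, dim)` used to clip extrapolations.
#' @return List with `borders` (complete list of pairs) and `filled`
#'   (logical vector marking reconstructed entries). Errors when every
#'   entry is missing.
#' @export
fill_border_gaps <- function(borders, period_px, bounds = NULL) {
  missing <- vapply(borders, is.null, logical(1))
  if (all(missing)) stop("all border pairs missing in slice")
  if (any(missing)) {
    found <- which(!missing)
    for (j in which(missing)) {
      j0 <- found[which.min(abs(found - j))]
      b <- borders[[j0]] + (j - j0) * period_px
      if (!is.null(bounds)) b <- pmin(pmax(b, bounds[1]), bounds[2])
      borders[[j]] <- b
    }
  }
  list(borders = borders, filled = missing)
}

#' Per-spot rectangles and ellipse triplet
#'
#' Combines the tight borders from the row slice (x axis) and the column
#' slice (y axis) with the grid cell to build, for one spot: the tight
#' rectangle `r_small = [h_l, h_r] x [v_l, v_r]`, the cell rectangle
#' `r_big`, the maximum-area inscribed foreground ellipse `E_F` of
#' `r_small`, the exclusion ellipse `E_E` (same center, semi-axes 3 px
#' larger, clipped so it cannot leave the cell) and the background ellipse
#' `E_B` inscribed in `r_big`.
#'
#' @param x_borders `c(h_l, h_r)` from the row slice.
#' @param y_borders `c(v_l, v_r)` from the column slice.
#' @param cell Grid cell `c(x0, x1, y0, y1)`, half-open.
#' @param margin_px Radius increment of the exclusion ellipse (default 3).
#' @return A `spot_geometry`: list with `r_small`, `r_big`, `center`,
#'   semi-axes `a_f, b_f, a_e, b_e, a_b, b_b` (E_B centered on `r_big`),
#'   and `flags` (subset of `"degenerate_box"`, `"clipped_exclusion"`).
#' @export
build_geometry <- function(x_borders, y_borders, cell, margin_px = 3) {
  flags <- character(0)
  h_l <- x_borders[1]; h_r <- x_borders[2]
  v_l <- y_borders[1]; v_r <- y_borders[2]
  if (h_r - h_l < 3 || v_r - v_l < 3) {
    flags <- c(flags, "degenerate_box")
    cx <- (h_l + h_r) / 2; cy <- (v_l + v_r) / 2
    h_l <- cx - 1.5; h_r <- cx + 1.5
    v_l <- cy - 1.5; v_r <- cy + 1.5
  }
  center <- c((h_l + h_r) / 2, (v_l + v_r) / 2)
  a_f <- (h_r - h_l) / 2
  b_f <- (v_r - v_l) / 2
  # exclusion ellipse: +margin on each semi-axis, clipped to the cell
  a_e <- a_f + margin_px
  b_e <- b_f + margin_px
  max_a <- min(center[1] - cell[1], cell[2] - center[1])
  max_b <- min(center[2] - cell[3], cell[4] - center[2])
  if (a_e > max_a || b_e > max_b) {
    flags <- c(flags, "clipped_exclusion")
    a_e <- min(a_e, max_a)
    b_e <- min(b_e, max_b)
  }
  bigc <- c((cell[1] + cell[2]) / 2, (cell[3] + cell[4]) / 2)
  structure(list(
    r_small = c(x0 = h_l, x1 = h_r, y0 = v_l, y1 = v_r),
    r_big = cell,
    center = center, big_center = bigc,
    a_f = a_f, b_f = b_f, a_e = a_e, b_e = b_e,
    a_b = (cell[2] - cell[1]) / 2, b_b = (cell[4] - cell[3]) / 2,
    flags = flags
  ), class = "spot_geometry")
}

#' Rasterize an ellipse by the pixel-center rule
#'
#' Pixels whose centers satisfy
#' `((u - cx)/a)^2 + ((v - cy)/b)^2 <= 1`, clipped to a half-open bounding
#' rectangle. Membership by pixel center makes the rasterization
#' bit-reproducible.
#'
#' @param center Ellipse center `c(cx, cy)` (0-based pixel coordinates).
#' @param semi_axes Semi-axes `c(a, b)` in pixels (> 0).
#' @param bounds Half-open clip rectangle `c(x0, x1, y0, y1)`.
#' @return Integer matrix with columns `u`, `v` (possibly 0 rows).
#' @export
rasterize_ellipse <- function(center, semi_axes, bounds) {
  a <- semi_axes[1]; b <- semi_axes[2]
  stopifnot(a > 0, b > 0)
  u0 <- max(ceiling(center[1] - a), bounds[1])
  u1 <- min(floor(center[1] + a), bounds[2] - 1)
  v0 <- max(ceiling(center[2] - b), bounds[3])
  v1 <- min(floor(center[2] + b), bounds[4] - 1)
  if (u0 > u1 || v0 > v1)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("u", "v"))))
  g <- expand.grid(u = u0:u1, v = v0:v1)
  inside <- ((g$u - center[1]) / a)^2 + ((g$v - center[2]) / b)^2 <= 1
  m <- as.matrix(g[inside, , drop = FALSE])
  dimnames(m) <- list(NULL, c("u", "v"))
  m
}

#' Deterministic two-class k-means of pixel intensities
#'
#' Exact 1-D 2-means: in one dimension the optimal 2-partition under the
#' within-cluster sum-of-squares objective is contiguous in sorted order,
#' so the global optimum is found by scanning all `n - 1` contiguous
#' splits with prefix sums. This is the fixed point Lloyd iteration aims
#' for, computed without any random initialisation, so the result is
#' bit-reproducible. Equal objective values are broken towards the larger
#' low (background) cluster. The high cluster is the foreground.
#'
#' @param values Numeric vector of pixel intensities.
#' @return List with `labels` (logical, `TRUE` = foreground/high),
#'   `centers` `c(low, high)` and `degenerate` (all values identical; all
#'   labels are then background).
#' @export
kmeans2 <- function(values) {
  n <- length(values)
  stopifnot(n >= 1, all(is.finite(values)))
  if (max(values) == min(values)) {
    return(list(labels = rep(FALSE, n),
                centers = c(low = values[1], high = values[1]),
                degenerate = TRUE))
  }
  o <- order(values)
  v <- values[o]
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  k <- seq_len(n - 1)
  wcss <- (cs2[k] - cs[k]^2 / k) +
    (cs2[n] - cs2[k] - (cs[n] - cs[k])^2 / (n - k))
  split <- max(which(wcss <= min(wcss) + 1e-12 * max(cs2[n], 1)))
  lab <- rep(FALSE, n)
  lab[o[(split + 1):n]] <- TRUE
  list(labels = lab,
       centers = c(low = cs[split] / split,
                   high = (cs[n] - cs[split]) / (n - split)),
       degenerate = FALSE)
}

#' Segment one spot by local 2-means over both channels
#'
#' Pixels inside the exclusion ellipse `E_E` are clustered with [kmeans2()]
#' independently in each channel; the high-intensity clusters `S_Cy3` and
#' `S_Cy5` are united into the spot foreground, so a pixel bright in either
#' dye is kept. Background pixels are those inside `E_B` but outside
#' `E_E`. Irregular contours and inner holes are captured because the
#' clustering is purely intensity-driven within the local window.
#'
#' @param img_cy3,img_cy5 Co-registered [enhanced_image()]s (or matrices)
#'   of the group sub-image.
#' @param geom A `spot_geometry` from [build_geometry()].
#' @return A `spot_mask`: list with pixel matrices `s_cy3`, `s_cy5`,
#'   `foreground`, `background`, `exclusion` (E_E minus foreground),
#'   `ellipse_fg` (pixels of E_F, for in-ellipse medians) and `flags`
#'   (may contain `"not_found"` when clustering is degenerate in both
#'   channels, plus any geometry flags).
#' @export
segment_spot <- function(img_cy3, img_cy5, geom) {
  p3 <- if (inherits(img_cy3, "enhanced_image")) img_cy3$pixels else img_cy3
  p5 <- if (inherits(img_cy5, "enhanced_image")) img_cy5$pixels else img_cy5
  bounds <- c(0, ncol(p3), 0, nrow(p3))
  ee <- rasterize_ellipse(geom$center, c(geom$a_e, geom$b_e),
                          clip_rect(geom$r_big, bounds))
  eb <- rasterize_ellipse(geom$big_center, c(geom$a_b, geom$b_b),
                          clip_rect(geom$r_big, bounds))
  ef <- rasterize_ellipse(geom$center, c(geom$a_f, geom$b_f),
                          clip_rect(geom$r_big, bounds))
  flags <- geom$flags
  if (nrow(ee) == 0) {
    return(spot_mask_empty(c(flags, "not_found"), ef))
  }
  i3 <- p3[cbind(ee[, "v"] + 1, ee[, "u"] + 1)]
  i5 <- p5[cbind(ee[, "v"] + 1, ee[, "u"] + 1)]
  k3 <- kmeans2(i3)
  k5 <- kmeans2(i5)
  if (k3$degenerate && k5$degenerate) {
    return(spot_mask_empty(c(flags, "not_found"), ef))
  }
  if (k3$degenerate || k5$degenerate)
    flags <- c(flags, "degenerate_clustering")
  s3 <- ee[k3$labels, , drop = FALSE]
  s5 <- ee[k5$labels, , drop = FALSE]
  fg <- unique(rbind(s3, s5))
  bg <- setdiff_pixels(eb, ee)
  excl <- setdiff_pixels(ee, fg)
  structure(list(s_cy3 = s3, s_cy5 = s5, foreground = fg,
                 background = bg, exclusion = excl, ellipse_fg = ef,
                 flags = flags),
            class = "spot_mask")
}

spot_mask_empty <- function(flags, ef = NULL) {
  em <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("u", "v")))
  structure(list(s_cy3 = em, s_cy5 = em, foreground = em,
                 background = em, exclusion = em,
                 ellipse_fg = ef %||% em, flags = flags),
            class = "spot_mask")
}

clip_rect <- function(rect, bounds) {
  c(max(rect[1], bounds[1]), min(rect[2], bounds[2]),
    max(rect[3], bounds[3]), min(rect[4], bounds[4]))
}

# set difference of (u,v) pixel matrices
setdiff_pixels <- function(a, b) {
  if (nrow(a) == 0) return(a)
  key_a <- a[, "u"] * 1e6 + a[, "v"]
  key_b <- if (nrow(b) > 0) b[, "u"] * 1e6 + b[, "v"] else numeric(0)
  a[!(key_a %in% key_b), , drop = FALSE]
}
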