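# Preprocessing: contrast enhancement, rotation correction, global addressing.

#' Logarithmic contrast enhancement
#'
#' Maps 16-bit counts `p` to `log2(p + 1)` and then applies a global shift
#' and uniform scaling so that the minimum maps to 0 and the maximum to
#' `2^16 - 1`. The transform is strictly monotone, so the rank order of
#' pixel values is preserved; only the reported intensities change scale,
#' which is why downstream feature extraction always returns to the raw
#' counts.
#'
#' @param img A [raw_image()].
#' @return An [enhanced_image()] of the same shape. A constant input image
#'   yields an all-zero output with a warning (the stretch is undefined).
#' @export
log_enhance <- function(img) {
  stopifnot(inherits(img, "raw_image"))
  r <- log2(img$pixels + 1)
  rng <- range(r)
  if (rng[2] - rng[1] <= 0) {
    warning("constant image: contrast stretch undefined, returning zeros")
    out <- array(0, dim = dim(r))
    dim(out) <- dim(r)
    return(enhanced_image(matrix(0, nrow(r), ncol(r)), img$channel))
  }
  enhanced_image((r - rng[1]) / (rng[2] - rng[1]) * 65535, img$channel)
}

#' Estimate the global rotation of a spot lattice
#'
#' Spotted slides are printed on a rectangular lattice but may be scanned
#' with a small in-plane rotation. The angle is recovered by a Radon-style
#' search: for each candidate angle the image is projected onto the x axis
#' along lines tilted by that angle, and the variance of the binned
#' projection profile is scored. The profile is sharpest — columns of spots
#' fall into common bins — exactly when the candidate matches the lattice
#' rotation. A coarse scan over `+/- search_range_deg` is refined to
#' `step_deg` resolution around the coarse optimum.
#'
#' @param img An [enhanced_image()] containing a roughly periodic lattice.
#' @param search_range_deg Half-width of the search interval (degrees).
#' @param step_deg Resolution of the fine search (degrees).
#' @return The estimated rotation in degrees: rotate the image by the
#'   negated estimate (see [rotate_image()]) to align the lattice with the
#'   axes. Featureless (constant) images return 0 with a warning.
#' @export
estimate_rotation <- function(img, search_range_deg = 5, step_deg = 0.05) {
  stopifnot(inherits(img, "enhanced_image"))
  px <- img$pixels
  if (max(px) - min(px) <= 0) {
    warning("featureless image: rotation estimate undefined, returning 0")
    return(0)
  }
  w <- as.vector(px - min(px))
  nr <- nrow(px); nc <- ncol(px)
  cx <- (nc - 1) / 2; cy <- (nr - 1) / 2
  du <- rep(seq_len(nc) - 1 - cx, each = nr)
  dv <- rep(seq_len(nr) - 1 - cy, times = nc)

  score <- function(theta) {
    a <- theta * pi / 180
    xp <- round(du * cos(a) + dv * sin(a))
    grp <- xp - min(xp) + 1
    acc <- rowsum(cbind(w, 1), grp)
    cnt <- acc[, 2]
    keep <- cnt >= max(cnt) / 2   # drop sparse corner bins
    stats::var(acc[keep, 1] / cnt[keep])
  }

  coarse_step <- max(step_deg, 0.25)
  coarse <- seq(-search_range_deg, search_range_deg, by = coarse_step)
  s1 <- vapply(coarse, score, numeric(1))
  best <- coarse[which.max(s1)]
  fine <- seq(best - coarse_step, best + coarse_step, by = step_deg)
  fine <- fine[abs(fine) <= search_range_deg + 1e-9]
  s2 <- vapply(fine, score, numeric(1))
  fine[which.max(s2)]
}

#' Rotate an image about its center
#'
#' Bilinear rotation of the pixel grid about the image center. Positive
#' angles rotate the content in the direction that [estimate_rotation()]
#' reports, so `rotate_image(img, -estimate_rotation(img))` aligns a tilted
#' lattice with the axes. Regions that fall outside the source are filled
#' with the image minimum.
#'
#' @param img An [enhanced_image()] or a bare numeric matrix.
#' @param angle_deg Rotation angle in degrees, `|angle| < 45`.
#' @return Same type as the input; for `enhanced_image` the cumulative
#'   `rotation_deg` is updated.
#' @export
rotate_image <- function(img, angle_deg) {
  is_enh <- inherits(img, "enhanced_image")
  px <- if (is_enh) img$pixels else img
  stopifnot(is.matrix(px), abs(angle_deg) < 45)
  out <- rotate_matrix_bilinear(px, angle_deg)
  if (is_enh)
    enhanced_image(out, img$channel, img$rotation_deg + angle_deg)
  else out
}

# inverse-mapping bilinear rotation; fill = min of source
rotate_matrix_bilinear <- function(px, angle_deg) {
  if (angle_deg == 0) return(px)
  nr <- nrow(px); nc <- ncol(px)
  cx <- (nc - 1) / 2; cy <- (nr - 1) / 2
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  u <- rep(seq_len(nc) - 1 - cx, each = nr)
  v <- rep(seq_len(nr) - 1 - cy, times = nc)
  # source coordinates: rotate output coords by -angle
  us <- ca * u + sa * v + cx
  vs <- -sa * u + ca * v + cy
  u0 <- floor(us); v0 <- floor(vs)
  fu <- us - u0; fv <- vs - v0
  fill <- min(px)
  at <- function(vv, uu) {
    ok <- uu >= 0 & uu <= nc - 1 & vv >= 0 & vv <= nr - 1
    val <- rep(fill, length(uu))
    val[ok] <- px[cbind(vv[ok] + 1, uu[ok] + 1)]
    val
  }
  val <- (1 - fu) * (1 - fv) * at(v0, u0) +
    fu * (1 - fv) * at(v0, u0 + 1) +
    (1 - fu) * fv * at(v0 + 1, u0) +
    fu * fv * at(v0 + 1, u0 + 1)
  matrix(val, nr, nc)
}

#' Split a slide into groups of co-localized spots (global addressing)
#'
#' Spots on printed slides accumulate in rectangular groups separated by
#' wide empty lanes. The image is binarized with Otsu's threshold and
#' dilated with a disk whose radius exceeds half the intra-group spot
#' spacing, so that spots within a group fuse into a single blob while
#' groups stay separate; the blob bounding boxes, ordered row-major, become
#' the group sub-images.
#'
#' @param img A rotation-corrected [enhanced_image()].
#' @param n_groups_expected Number of groups the slide layout prescribes.
#' @param pitch_px Spot pitch in pixels; when `NULL` it is estimated from
#'   the autocorrelation of the horizontal luminance profile.
#' @return A `group_layout`: list with `boxes` (list of half-open 0-based
#'   rectangles `c(x0, x1, y0, y1)` in row-major group order) and
#'   `n_groups_expected`. An error naming the detected boxes is raised when
#'   the detected count differs from the expectation; callers may then fall
#'   back to [geometric_group_layout()].
#' @export
split_into_groups <- function(img, n_groups_expected, pitch_px = NULL) {
  stopifnot(inherits(img, "enhanced_image"), n_groups_expected >= 1)
  px <- img$pixels
  if (is.null(pitch_px)) {
    prof <- axis_profile(gaussian_smooth(img), "h")
    pitch_px <- autocorrelation_period(prof)
  }
  ebi <- EBImage::Image(t(px) / 65535)
  thr <- EBImage::otsu(ebi, range = c(0, 1))
  bin <- ebi > thr
  rad <- ceiling(0.75 * pitch_px)
  brush <- EBImage::makeBrush(2L * rad + 1L, shape = "disc")
  fused <- EBImage::dilate(bin, brush)
  lab <- EBImage::bwlabel(fused)
  labm <- t(EBImage::imageData(lab))   # back to [row, col]
  nlab <- max(labm)
  if (nlab == 0)
    stop("no spot groups detected (image below threshold everywhere)")
  areas <- tabulate(labm[labm > 0], nbins = nlab)
  keep <- which(areas >= 0.1 * max(areas))  # discard small artifact blobs
  boxes <- lapply(keep, function(l) {
    idx <- which(labm == l, arr.ind = TRUE)
    c(x0 = min(idx[, 2]) - 1, x1 = max(idx[, 2]),
      y0 = min(idx[, 1]) - 1, y1 = max(idx[, 1]))
  })
  boxes <- order_boxes_rowmajor(boxes)
  if (length(boxes) != n_groups_expected) {
    msg <- paste(vapply(boxes, function(b)
      sprintf("[%d,%d)x[%d,%d)", b[1], b[2], b[3], b[4]), character(1)),
      collapse = ", ")
    stop(sprintf("detected %d spot groups but expected %d; boxes: %s",
                 length(boxes), n_groups_expected, msg))
  }
  structure(list(boxes = boxes, n_groups_expected = n_groups_expected),
            class = "group_layout")
}

# order group boxes row-major: cluster box centers into rows by y gaps
order_boxes_rowmajor <- function(boxes) {
  if (length(boxes) <= 1) return(boxes)
  cy <- vapply(boxes, function(b) (b[3] + b[4]) / 2, numeric(1))
  cx <- vapply(boxes, function(b) (b[1] + b[2]) / 2, numeric(1))
  h <- vapply(boxes, function(b) b[4] - b[3], numeric(1))
  o <- order(cy)
  row_id <- integer(length(boxes))
  row_id[o[1]] <- 1L
  for (k in seq_along(o)[-1]) {
    prev <- o[k - 1]; cur <- o[k]
    row_id[cur] <- row_id[prev] +
      (cy[cur] - cy[prev] > stats::median(h) / 2)
  }
  boxes[order(row_id, cx)]
}

#' Even geometric partition into groups
#'
#' Fallback addressing when blob detection fails: split the image into an
#' `groups_nx` by `groups_ny` grid of equal rectangles.
#'
#' @param dim_px Image dimensions `c(width, height)` in pixels.
#' @param groups_nx,groups_ny Number of group columns and rows.
#' @return A `group_layout` (see [split_into_groups()]).
#' @export
geometric_group_layout <- function(dim_px, groups_nx, groups_ny) {
  xs <- round(seq(0, dim_px[1], length.out = groups_nx + 1))
  ys <- round(seq(0, dim_px[2], length.out = groups_ny + 1))
  boxes <- list()
  for (gy in seq_len(groups_ny)) for (gx in seq_len(groups_nx))
    boxes[[length(boxes) + 1]] <-
      c(x0 = xs[gx], x1 = xs[gx + 1], y0 = ys[gy], y1 = ys[gy + 1])
  structure(list(boxes = boxes, n_groups_expected = groups_nx * groups_ny),
            class = "group_layout")
}
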