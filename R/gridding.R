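# Grid alignment: averaged luminance profiles, shock-filter PDE evolution,
# step detection and borderline placement.

#' Gaussian smoothing of a sub-image
#'
#' Separable convolution with a truncated Gaussian kernel (default width
#' `k = 3` pixels, standard deviation `sigma = 5` pixels — for ~15 px spots
#' this is close to a small box filter and only removes pixel noise before
#' profiles are averaged). Boundaries are handled by reflection.
#'
#' @param img An [enhanced_image()] or numeric matrix, at least `k x k`.
#' @param k Kernel width in pixels (odd).
#' @param sigma Kernel standard deviation in pixels.
#' @return Same type as the input, same shape.
#' @export
gaussian_smooth <- function(img, k = 3, sigma = 5) {
  is_enh <- inherits(img, "enhanced_image")
  px <- if (is_enh) img$pixels else img
  stopifnot(is.matrix(px), k %% 2 == 1, nrow(px) >= k, ncol(px) >= k)
  r <- (k - 1) / 2
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  out <- conv1_reflect(px, w, along = "rows")
  out <- conv1_reflect(out, w, along = "cols")
  if (is_enh) enhanced_image(out, img$channel, img$rotation_deg) else out
}

# 1-D convolution of each row/column with reflective padding
conv1_reflect <- function(px, w, along = c("rows", "cols")) {
  along <- match.arg(along)
  if (along == "rows") return(t(conv1_reflect(t(px), w, "cols")))
  # convolve down each column
  r <- (length(w) - 1) / 2
  n <- nrow(px)
  pad <- rbind(px[rev(seq_len(r) + 1), , drop = FALSE], px,
               px[n - seq_len(r), , drop = FALSE])
  out <- matrix(0, n, ncol(px))
  for (j in seq_along(w))
    out <- out + w[j] * pad[(j - 1) + seq_len(n), , drop = FALSE]
  out
}

#' Averaged luminance profile of a sub-image
#'
#' The horizontal profile `H(x)` is the mean over all rows of column `x`;
#' the vertical profile `V(y)` is the mean over all columns of row `y`.
#' These 1-D profiles are the objects the shock filter evolves.
#'
#' @param img An [enhanced_image()] or numeric matrix (already smoothed).
#' @param axis `"h"` for the horizontal (column-wise) profile, `"v"` for
#'   the vertical one.
#' @return An `intensity_profile`: list with `values` and `axis`.
#' @export
axis_profile <- function(img, axis = c("h", "v")) {
  axis <- match.arg(axis)
  px <- if (inherits(img, "enhanced_image")) img$pixels else img
  vals <- if (axis == "h") colMeans(px) else rowMeans(px)
  intensity_profile(unname(vals), axis)
}

#' @rdname axis_profile
#' @param values Numeric vector of luminances (length >= 3).
#' @export
intensity_profile <- function(values, axis = c("h", "v")) {
  axis <- match.arg(axis)
  stopifnot(length(values) >= 3, all(is.finite(values)))
  structure(list(values = as.numeric(values), axis = axis),
            class = "intensity_profile")
}

#' Shock-filter evolution of a luminance profile
#'
#' Iterates the hyperbolic scheme
#' \deqn{P^{t+1}(i) = P^t(i) - \mathrm{sign}(\Delta P^t(i))\,|\nabla P^t(i)|}
#' with the discrete Laplacian \eqn{\Delta P(i) = P(i+1) - 2P(i) + P(i-1)}
#' and the minmod gradient magnitude
#' \eqn{|\nabla P(i)| = \min(|P(i+1)-P(i)|, |P(i)-P(i-1)|)} applied only
#' where the two one-sided differences share their sign; at local extrema
#' (opposite signs) and at the two endpoints the identity is executed.
#' The iteration sharpens the profile towards a piecewise-constant function
#' whose ruptures sit at the inflection points of the initial profile;
#' piecewise-constant profiles are exact fixed points, and no value ever
#' leaves the initial range.
#'
#' @param p An [intensity_profile()] (or bare numeric vector).
#' @param t_f Number of iterations (default 50).
#' @return The evolved profile, same type as the input.
#' @export
shock_filter <- function(p, t_f = 50) {
  is_prof <- inherits(p, "intensity_profile")
  x <- if (is_prof) p$values else p
  stopifnot(length(x) >= 3, t_f >= 0)
  n <- length(x)
  i <- 2:(n - 1)
  for (t in seq_len(t_f)) {
    gl <- x[i + 1] - x[i]
    gr <- x[i] - x[i - 1]
    lap <- gl - gr
    mag <- pmin(abs(gl), abs(gr))
    upd <- ifelse(gl * gr > 0, -sign(lap) * mag, 0)
    if (all(upd == 0)) break
    x[i] <- x[i] + upd
  }
  if (is_prof) intensity_profile(x, p$axis) else x
}

#' Detect steps (ruptures) in a shock-filtered profile
#'
#' Positions `i` (0-based, so the jump is `P(i) - P(i-1)`) where the jump
#' magnitude exceeds `min_step`. Runs of adjacent detections with the same
#' sign — a step smeared over two pixels — are collapsed to the single
#' largest jump of the run.
#'
#' @param p An [intensity_profile()] (shock-filtered) or numeric vector.
#' @param min_step Minimum jump magnitude. Default: 30% of the profile
#'   mean, mirroring the threshold rule used for spot borders.
#' @return A `step_sequence`: list with integer `positions` (0-based,
#'   strictly increasing), `signs` (+1 rising / -1 falling) and
#'   `step_heights` (signed jumps). Empty when no jump qualifies.
#' @export
detect_steps <- function(p, min_step = NULL) {
  x <- if (inherits(p, "intensity_profile")) p$values else p
  if (is.null(min_step)) min_step <- 0.30 * mean(x)
  d <- diff(x)
  idx <- which(abs(d) > min_step)
  if (length(idx) == 0)
    return(step_sequence(integer(0), integer(0), numeric(0)))
  sg <- sign(d[idx])
  # collapse adjacent same-sign runs to the largest jump
  run <- cumsum(c(TRUE, diff(idx) > 1 | sg[-1] != sg[-length(sg)]))
  keep <- vapply(split(seq_along(idx), run), function(k)
    k[which.max(abs(d[idx[k]]))], integer(1))
  idx <- idx[keep]; sg <- sg[keep]
  step_sequence(idx, as.integer(sg), d[idx])
}

#' @rdname detect_steps
#' @param positions Strictly increasing 0-based step positions.
#' @param signs Integer vector of +1/-1 step directions.
#' @param step_heights Signed jump heights.
#' @export
step_sequence <- function(positions, signs, step_heights) {
  stopifnot(length(positions) == length(signs),
            length(positions) == length(step_heights),
            !is.unsorted(positions, strictly = TRUE))
  structure(list(positions = as.integer(positions), signs = as.integer(signs),
                 step_heights = as.numeric(step_heights)),
            class = "step_sequence")
}

#' Borderlines between rows/columns of spots from step sequences
#'
#' Each spot column produces a rising then a falling rupture in the
#' shock-filtered horizontal profile. The gap between two adjacent spot
#' columns is therefore bracketed by a falling step and the next rising
#' step; a borderline is placed at the midpoint of each such pair, and the
#' outer sub-image bounds are appended so every spot row/column is enclosed
#' by lines. Non-alternating sequences are repaired by dropping the weaker
#' of two same-sign neighbours (with a warning).
#'
#' @param h A `step_sequence` from the horizontal profile.
#' @param v A `step_sequence` from the vertical profile.
#' @param bounds Sub-image extent `c(dim_x, dim_y)` in pixels.
#' @return A `grid_lines` object: ordered `x_lines` and `y_lines` (each
#'   including the bounds 0 and the extent) plus `bounds`.
#' @export
grid_from_steps <- function(h, v, bounds) {
  stopifnot(length(bounds) == 2)
  gl <- list(
    x_lines = lines_one_axis(h, bounds[1]),
    y_lines = lines_one_axis(v, bounds[2]),
    bounds = bounds
  )
  structure(gl, class = "grid_lines")
}

lines_one_axis <- function(s, extent) {
  pos <- s$positions; sg <- s$signs; ht <- abs(s$step_heights)
  # repair: drop the weaker of adjacent same-sign steps
  repeat {
    same <- which(diff(sg) == 0)
    if (length(same) == 0) break
    warning("non-alternating step sequence; dropping weaker step")
    k <- same[1]
    drop <- if (ht[k] < ht[k + 1]) k else k + 1
    pos <- pos[-drop]; sg <- sg[-drop]; ht <- ht[-drop]
  }
  mids <- numeric(0)
  falls <- which(sg == -1)
  for (f in falls) {
    if (f < length(sg) && sg[f + 1] == 1)
      mids <- c(mids, (pos[f] + pos[f + 1]) / 2)
  }
  if (length(pos) == 0)
    warning("no steps detected; grid reduces to the outer bounds")
  sort(unique(c(0, mids, extent)))
}
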