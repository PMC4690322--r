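# Synthetic two-channel slide generator with per-pixel ground truth.
#
# The simulator emulates spotted cDNA slides: a periodic lattice of ~15 px
# diameter spots arranged in groups, with weak spots, missing spots,
# annular spots (inner holes), irregular (crescent) contours, bright
# streak artifacts, smooth dye bias, small global rotation and 16-bit
# quantization. Spot edges fall off as a radial sigmoid whose 10-90%
# transition spans ~2 px (scale 0.45 px), so the intensity profiles have
# well-defined analytic inflection points.

#' Simulation parameters for a synthetic slide
#'
#' Defaults mirror the geometry of real spotted slides at reduced scale:
#' 2 x 2 groups of 8 x 8 spots, 28 px pitch, 7 px spot radius (~15 px
#' diameter), 2000-count background under a 30000-count foreground, 5%
#' multiplicative noise.
#'
#' @param groups_nx,groups_ny Group columns and rows on the slide.
#' @param spots_nx,spots_ny Spot columns and rows per group.
#' @param spot_pitch_px Center-to-center spot distance (px).
#' @param spot_radius_px Spot radius (px); must be `< spot_pitch_px / 2`.
#' @param edge_width_px Scale of the sigmoid edge falloff (px); 0 renders
#'   hard-edged disks.
#' @param jitter_px Uniform random displacement of each spot center (px).
#' @param rotation_deg Global in-plane rotation applied to both channels.
#' @param background_level Background in counts.
#' @param background_noise_sd Additive Gaussian background noise (counts).
#' @param fg_level_cy3 Foreground plateau of a full-strength spot in the
#'   Cy3 channel (counts); scalar or per-spot vector (recycled row-major
#'   like `ratio`).
#' @param noise_frac Multiplicative noise: each pixel is scaled by
#'   `1 + N(0, noise_frac)`.
#' @param ratio Per-spot true R/G ratio (scalar or vector recycled over
#'   spots, row-major over groups then rows then columns).
#' @param fraction_weak,fraction_missing,fraction_annular,fraction_irregular
#'   Fractions of spots rendered weak (amplitude scaled by `weak_factor`),
#'   absent, with an inner hole, or with a crescent contour. Must sum to
#'   at most 1.
#' @param weak_factor Amplitude factor for weak spots.
#' @param hole_radius_frac Hole radius as a fraction of the spot radius.
#' @param dye_bias Coefficients `c(b0, b1)` of a smooth M-versus-A trend
#'   imposed on the Cy5 channel: the rendered Cy5 amplitude is divided by
#'   `2^(b0 + b1 * A)`.
#' @param artifact_count Number of bright streak artifacts.
#' @param margin_px Empty border around the lattice (px).
#' @param inter_group_gap_px Extra gap between groups beyond one pitch, so
#'   adjacent groups' nearest spot centers are
#'   `spot_pitch_px + inter_group_gap_px` apart.
#' @param seed Integer seed; a fixed seed gives bitwise-identical output.
#' @return A validated `simulation_params` list.
#' @export
simulation_params <- function(groups_nx = 2, groups_ny = 2,
                              spots_nx = 8, spots_ny = 8,
                              spot_pitch_px = 28, spot_radius_px = 7,
                              edge_width_px = 0.45, jitter_px = 0.5,
                              rotation_deg = 0,
                              background_level = 2000,
                              background_noise_sd = 100,
                              fg_level_cy3 = 30000, noise_frac = 0.05,
                              ratio = 1,
                              fraction_weak = 0, fraction_missing = 0,
                              fraction_annular = 0, fraction_irregular = 0,
                              weak_factor = 0.15, hole_radius_frac = 0.45,
                              dye_bias = c(0, 0), artifact_count = 0,
                              margin_px = 28, inter_group_gap_px = 56,
                              seed = 1) {
  p <- as.list(environment())
  fr <- c(fraction_weak, fraction_missing, fraction_annular,
          fraction_irregular)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("defect fractions must lie in [0, 1] and sum to at most 1")
  if (spot_radius_px >= spot_pitch_px / 2)
    stop("spot radius must be smaller than half the pitch (spots overlap)")
  stopifnot(groups_nx >= 1, groups_ny >= 1, spots_nx >= 1, spots_ny >= 1,
            background_level >= 0, all(fg_level_cy3 <= 65535))
  structure(p, class = "simulation_params")
}

#' Generate a synthetic two-channel slide with ground truth
#'
#' Renders the spot lattice described by `params` into co-registered Cy3
#' and Cy5 16-bit images and returns the full ground truth: per-spot
#' centers, noise-free masks (pixels where the rendered shape is at least
#' half the plateau), hole pixel sets for annular spots, true levels and
#' ratios, defect labels, group boxes and the applied rotation. Output is
#' deterministic for a fixed seed; the caller's RNG state is preserved.
#'
#' @param params A [simulation_params()] object.
#' @return List with `cy3`, `cy5` ([raw_image()]s) and `truth` (list with
#'   `spots` data.frame, `masks`, `holes`, `group_boxes`, `rotation_deg`,
#'   `dim`, `params`).
#' @export
generate_pair <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed",
                                               envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(params$seed)

  pt <- params$spot_pitch_px
  span_x <- (params$spots_nx - 1) * pt
  span_y <- (params$spots_ny - 1) * pt
  gap <- pt + params$inter_group_gap_px
  width <- 2 * params$margin_px + params$groups_nx * span_x +
    (params$groups_nx - 1) * gap
  height <- 2 * params$margin_px + params$groups_ny * span_y +
    (params$groups_ny - 1) * gap

  # spot table, row-major: groups (gy, gx), then spot rows, then columns
  spots <- expand.grid(col = seq_len(params$spots_nx),
                       row = seq_len(params$spots_ny),
                       gx = seq_len(params$groups_nx),
                       gy = seq_len(params$groups_ny))
  spots <- spots[order(spots$gy, spots$gx, spots$row, spots$col), ]
  n <- nrow(spots)
  spots$spot_id <- seq_len(n)
  spots$group <- (spots$gy - 1) * params$groups_nx + spots$gx
  spots$cx <- params$margin_px + (spots$gx - 1) * (span_x + gap) +
    (spots$col - 1) * pt + runif(n, -params$jitter_px, params$jitter_px)
  spots$cy <- params$margin_px + (spots$gy - 1) * (span_y + gap) +
    (spots$row - 1) * pt + runif(n, -params$jitter_px, params$jitter_px)

  # defect assignment
  defect <- rep("ok", n)
  n_def <- round(n * c(params$fraction_missing, params$fraction_weak,
                       params$fraction_annular, params$fraction_irregular))
  pool <- sample.int(n)
  labs <- c("missing", "weak", "annular", "irregular")
  off <- 0
  for (k in seq_along(labs)) {
    if (n_def[k] > 0) defect[pool[off + seq_len(n_def[k])]] <- labs[k]
    off <- off + n_def[k]
  }
  spots$defect <- defect

  ratio <- rep_len(params$ratio, n)
  amp3 <- rep_len(params$fg_level_cy3, n) - params$background_level
  amp3[defect == "weak"] <- amp3[defect == "weak"] * params$weak_factor
  amp3[defect == "missing"] <- 0
  amp5 <- amp3 / ratio
  # smooth dye bias in M-vs-A coordinates, applied to the Cy5 amplitude
  A <- ifelse(amp3 > 0 & amp5 > 0, 0.5 * log2(amp3 * amp5), 0)
  bias <- params$dye_bias[1] + params$dye_bias[2] * A
  amp5_rendered <- amp5 * 2^(-bias)

  spots$ratio_true <- ratio
  spots$amp_cy3 <- amp3
  spots$amp_cy5 <- amp5
  spots$amp_cy5_rendered <- amp5_rendered
  spots$fg_cy3 <- params$background_level + amp3
  spots$fg_cy5 <- params$background_level + amp5_rendered
  spots$bg <- params$background_level

  clean3 <- matrix(params$background_level, height, width)
  clean5 <- matrix(params$background_level, height, width)
  masks <- vector("list", n)
  holes <- vector("list", n)
  ew <- params$edge_width_px
  rad <- params$spot_radius_px
  hole_r <- params$hole_radius_frac * rad
  wr <- ceiling(rad + 4 * max(ew, 0.25) + 1)
  empty_px <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("u", "v")))

  for (s in seq_len(n)) {
    if (spots$defect[s] == "missing") { masks[[s]] <- empty_px; next }
    cx <- spots$cx[s]; cy <- spots$cy[s]
    us <- max(0, floor(cx) - wr):min(width - 1, ceiling(cx) + wr)
    vs <- max(0, floor(cy) - wr):min(height - 1, ceiling(cy) + wr)
    g <- expand.grid(u = us, v = vs)
    d <- sqrt((g$u - cx)^2 + (g$v - cy)^2)
    shape <- if (ew > 0) 1 / (1 + exp((d - rad) / ew)) else
      as.numeric(d <= rad)
    if (spots$defect[s] == "annular") {
      hole <- if (ew > 0) 1 / (1 + exp((d - hole_r) / ew)) else
        as.numeric(d <= hole_r)
      shape <- shape * (1 - hole)
      holes[[s]] <- as.matrix(g[hole >= 0.5, c("u", "v")])
    }
    if (spots$defect[s] == "irregular") {
      th <- runif(1, 0, 2 * pi)
      dot <- (g$u - cx) * cos(th) + (g$v - cy) * sin(th)
      cut <- if (ew > 0) 1 / (1 + exp(-(dot + 0.25 * rad) / ew)) else
        as.numeric(dot + 0.25 * rad >= 0)
      shape <- shape * cut
    }
    idx <- cbind(g$v + 1, g$u + 1)
    clean3[idx] <- clean3[idx] + spots$amp_cy3[s] * shape
    clean5[idx] <- clean5[idx] + spots$amp_cy5_rendered[s] * shape
    m <- as.matrix(g[shape >= 0.5, c("u", "v")])
    dimnames(m) <- list(NULL, c("u", "v"))
    masks[[s]] <- m
  }

  # bright streak artifacts (staining defects), channel-specific
  if (params$artifact_count > 0) {
    for (k in seq_len(params$artifact_count)) {
      x0 <- runif(1, 0, width - 1); y0 <- runif(1, 0, height - 1)
      th <- runif(1, 0, pi); len <- runif(1, 40, 120)
      tt <- seq(0, len, by = 0.5)
      au <- round(x0 + tt * cos(th)); av <- round(y0 + tt * sin(th))
      ok <- au >= 0 & au < width & av >= 0 & av < height
      idx <- cbind(av[ok] + 1, au[ok] + 1)
      tgt <- if (runif(1) < 0.5) "clean3" else "clean5"
      m <- get(tgt)
      m[idx] <- pmin(m[idx] + 45000, 65535)
      assign(tgt, m)
    }
  }

  noisy <- function(m) {
    m <- m * (1 + rnorm(length(m), 0, params$noise_frac)) +
      rnorm(length(m), 0, params$background_noise_sd)
    matrix(m, nrow(m), ncol(m))
  }
  img3 <- noisy(clean3)
  img5 <- noisy(clean5)
  if (params$rotation_deg != 0) {
    img3 <- rotate_matrix_bilinear(img3, params$rotation_deg)
    img5 <- rotate_matrix_bilinear(img5, params$rotation_deg)
  }
  quant <- function(m) matrix(as.integer(pmin(pmax(round(m), 0), 65535)),
                              nrow(m), ncol(m))

  group_boxes <- list()
  for (gy in seq_len(params$groups_ny)) for (gx in seq_len(params$groups_nx)) {
    x0 <- params$margin_px + (gx - 1) * (span_x + gap) - pt / 2
    y0 <- params$margin_px + (gy - 1) * (span_y + gap) - pt / 2
    group_boxes[[length(group_boxes) + 1]] <-
      c(x0 = x0, x1 = x0 + span_x + pt, y0 = y0, y1 = y0 + span_y + pt)
  }

  truth <- list(spots = spots, masks = masks, holes = holes,
                group_boxes = group_boxes,
                rotation_deg = params$rotation_deg,
                dim = c(width = width, height = height), params = params)
  list(cy3 = raw_image(quant(img3), "Cy3"),
       cy5 = raw_image(quant(img5), "Cy5"),
       truth = truth)
}

#' Score pipeline output against simulator ground truth
#'
#' Matches pipeline spots to ground-truth spots by `(group, row, col)` and
#' computes: per-spot Jaccard index of the foreground masks, the fraction
#' of true hole pixels excluded from foreground (annular spots), relative
#' errors of the background-corrected intensities and ratios, and the
#' confusion counts of the up-regulation calls against `ratio_true > 2`.
#'
#' @param run Output of [spot_pipeline()] (needs `results` and, for mask
#'   scoring, `masks` in slide coordinates).
#' @param truth The `truth` element of [generate_pair()].
#' @param upreg_threshold Ratio threshold used for the truth calls.
#' @return List with `per_spot` data.frame (`jaccard`, `rel_err_R`,
#'   `rel_err_G`, `rel_err_ratio`), `mean_jaccard`,
#'   `hole_exclusion_fraction`, `median_rel_err_R`, and `confusion`
#'   (tp, fp, fn, tn).
#' @export
score_against_truth <- function(run, truth, upreg_threshold = 2) {
  res <- run$results
  tsp <- truth$spots
  key_r <- paste(res$group, res$row, res$col)
  key_t <- paste(tsp$group, tsp$row, tsp$col)
  m <- match(key_t, key_r)
  if (anyNA(m))
    stop("unmatched spots between results and ground truth")
  res <- res[m, ]
  masks <- if (!is.null(run$masks)) run$masks[m] else NULL

  pix_key <- function(px) if (nrow(px) == 0) numeric(0) else
    px[, "u"] * 1e6 + px[, "v"]
  jac <- rep(NA_real_, nrow(tsp))
  hole_excl <- numeric(0)
  if (!is.null(masks)) {
    for (s in seq_len(nrow(tsp))) {
      tm <- truth$masks[[s]]
      if (tsp$defect[s] == "missing") next
      pm <- masks[[s]]
      if (is.null(pm)) pm <- truth$masks[[s]][0, , drop = FALSE]
      a <- pix_key(tm); b <- pix_key(pm)
      inter <- length(intersect(a, b))
      uni <- length(union(a, b))
      jac[s] <- if (uni == 0) NA_real_ else inter / uni
      if (tsp$defect[s] == "annular" && !is.null(truth$holes[[s]])) {
        h <- pix_key(truth$holes[[s]])
        if (length(h) > 0)
          hole_excl <- c(hole_excl, 1 - length(intersect(h, b)) / length(h))
      }
    }
  }
  rel <- function(est, tru) ifelse(tru > 0, abs(est - tru) / tru, NA_real_)
  per_spot <- data.frame(
    spot_id = tsp$spot_id, defect = tsp$defect, jaccard = jac,
    rel_err_R = rel(res$R, tsp$amp_cy3),
    rel_err_G = rel(res$G, tsp$amp_cy5_rendered),
    rel_err_ratio = rel(res$ratio, tsp$amp_cy3 / tsp$amp_cy5_rendered))
  called <- !is.na(res$ratio_norm) & res$ratio_norm > upreg_threshold
  truly <- tsp$ratio_true > upreg_threshold & tsp$defect != "missing"
  confusion <- c(tp = sum(called & truly), fp = sum(called & !truly),
                 fn = sum(!called & truly), tn = sum(!called & !truly))
  list(per_spot = per_spot,
       mean_jaccard = mean(jac, na.rm = TRUE),
       hole_exclusion_fraction =
         if (length(hole_excl)) mean(hole_excl) else NA_real_,
       median_rel_err_R = median(per_spot$rel_err_R, na.rm = TRUE),
       confusion = confusion)
}
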