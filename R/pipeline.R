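# Pipeline orchestration: preprocessing -> gridding -> segmentation ->
# feature extraction, plus result/mask writers and config handling.
# The whole pipeline is deterministic: it contains no random number draws.

#' Control parameters of the analysis pipeline
#'
#' @param t_f Shock-filter iterations.
#' @param gauss_k,gauss_sigma Gaussian smoothing kernel width and sd (px).
#' @param thr_frac Border threshold as a fraction of the mean slice
#'   profile intensity.
#' @param min_step_frac Step-detection threshold for gridding, as a
#'   fraction of the mean shock-filtered profile.
#' @param ellipse_margin_px Exclusion-ellipse radius increment (px).
#' @param lowess_span Lowess window as a fraction of the spots.
#' @param upreg_threshold Up-regulation ratio threshold (strict `>`).
#' @param rotation_search_deg Half-range of the rotation search; 0
#'   disables rotation correction.
#' @param rotation_step_deg Resolution of the rotation search.
#' @param geometry_channel Channel driving gridding and geometry:
#'   `"Cy3"` or `"mean"` of both enhanced channels.
#' @return A `pipeline_control` list.
#' @export
pipeline_control <- function(t_f = 50, gauss_k = 3, gauss_sigma = 5,
                             thr_frac = 0.30, min_step_frac = 0.30,
                             ellipse_margin_px = 3, lowess_span = 0.20,
                             upreg_threshold = 2,
                             rotation_search_deg = 5,
                             rotation_step_deg = 0.05,
                             geometry_channel = c("Cy3", "mean")) {
  geometry_channel <- match.arg(geometry_channel)
  p <- as.list(environment())
  stopifnot(t_f >= 1, gauss_k >= 1, gauss_sigma > 0,
            thr_frac > 0, thr_frac <= 1, lowess_span > 0, lowess_span <= 1,
            ellipse_margin_px >= 0, upreg_threshold > 0)
  structure(p, class = "pipeline_control")
}

#' Slide layout description
#'
#' @param groups_nx,groups_ny Group columns and rows on the slide.
#' @param spots_nx,spots_ny Spot columns and rows per group.
#' @param spot_pitch_px Optional spot pitch (px); estimated from the image
#'   autocorrelation when `NULL`.
#' @return A `slide_layout` list.
#' @export
slide_layout <- function(groups_nx, groups_ny, spots_nx, spots_ny,
                         spot_pitch_px = NULL) {
  stopifnot(groups_nx >= 1, groups_ny >= 1, spots_nx >= 1, spots_ny >= 1)
  structure(list(groups_nx = groups_nx, groups_ny = groups_ny,
                 spots_nx = spots_nx, spots_ny = spots_ny,
                 spot_pitch_px = spot_pitch_px),
            class = "slide_layout")
}

#' Run the full segmentation and quantification pipeline
#'
#' Executes the four stages on a co-registered image pair:
#' enhancement + rotation correction + global addressing, shock-filter
#' grid alignment per group, per-spot segmentation (tight borders,
#' autocorrelation gap filling, ellipse triplets, local 2-means over both
#' channels), and feature extraction with lowess normalisation and
#' up-regulation calls.
#'
#' @param raw_cy3,raw_cy5 [raw_image()]s of the two channels.
#' @param layout A [slide_layout()].
#' @param control A [pipeline_control()].
#' @return List with `results` (one row per expected spot), `masks`
#'   (foreground pixel sets in slide coordinates, after rotation
#'   correction), `grids` (per-group `grid_lines`), `groups`
#'   (`group_layout`), `rotation_deg` (estimated and corrected rotation)
#'   and `counts` (per-stage tallies).
#' @export
spot_pipeline <- function(raw_cy3, raw_cy5, layout,
                          control = pipeline_control()) {
  stopifnot(inherits(raw_cy3, "raw_image"), inherits(raw_cy5, "raw_image"),
            inherits(layout, "slide_layout"))
  if (!all(dim(raw_cy3$pixels) == dim(raw_cy5$pixels)))
    stop("channel images must have identical dimensions")

  enh3 <- log_enhance(raw_cy3)
  enh5 <- log_enhance(raw_cy5)
  ang <- 0
  if (control$rotation_search_deg > 0)
    ang <- estimate_rotation(enh3, control$rotation_search_deg,
                             control$rotation_step_deg)
  p3 <- enh3$pixels; p5 <- enh5$pixels
  r3 <- raw_cy3$pixels; r5 <- raw_cy5$pixels
  if (ang != 0) {
    p3 <- rotate_matrix_bilinear(p3, -ang)
    p5 <- rotate_matrix_bilinear(p5, -ang)
    r3 <- rotate_matrix_bilinear(r3, -ang)
    r5 <- rotate_matrix_bilinear(r5, -ang)
  }
  enh3 <- enhanced_image(p3, "Cy3", -ang)
  enh5 <- enhanced_image(p5, "Cy5", -ang)

  n_groups <- layout$groups_nx * layout$groups_ny
  groups <- tryCatch(
    split_into_groups(enh3, n_groups, layout$spot_pitch_px),
    error = function(e) {
      warning("group detection failed (", conditionMessage(e),
              "); falling back to an even geometric partition")
      geometric_group_layout(c(ncol(p3), nrow(p3)),
                             layout$groups_nx, layout$groups_ny)
    })

  all_rows <- list()
  all_masks <- list()
  grids <- list()
  counts <- c(groups_found = length(groups$boxes), spots_gridded = 0,
              borders_filled = 0, spots_not_found = 0, upregulated = 0)

  for (g in seq_along(groups$boxes)) {
    box <- groups$boxes[[g]]
    out <- analyze_group(p3, p5, r3, r5, box, g, layout, control)
    grids[[g]] <- out$grid
    counts["spots_gridded"] <- counts["spots_gridded"] + out$n_gridded
    counts["borders_filled"] <- counts["borders_filled"] + out$n_filled
    all_rows[[g]] <- out$rows
    all_masks <- c(all_masks, out$masks)
  }
  results <- do.call(rbind, all_rows)
  rownames(results) <- NULL
  results$spot_id <- seq_len(nrow(results))

  norm <- lowess_normalize(results, control$lowess_span)
  results$M <- norm$M
  results$A <- norm$A
  results$M_norm <- norm$M_norm
  results$ratio_norm <- norm$ratio_norm
  up <- call_upregulated(norm, control$upreg_threshold)
  results$upregulated <- FALSE
  results$upregulated[up] <- TRUE
  counts["upregulated"] <- length(up)
  counts["spots_not_found"] <- sum(grepl("not_found", results$flags))

  list(results = results, masks = all_masks, grids = grids,
       groups = groups, rotation_deg = ang, counts = counts,
       control = control, layout = layout)
}

# grid, segment and quantify one group sub-image
analyze_group <- function(p3, p5, r3, r5, box, g, layout, control) {
  sub3 <- crop_rect(p3, box); sub5 <- crop_rect(p5, box)
  sraw3 <- crop_rect(r3, box); sraw5 <- crop_rect(r5, box)
  geom_px <- if (control$geometry_channel == "mean")
    (sub3 + sub5) / 2 else sub3
  sm <- gaussian_smooth(geom_px, control$gauss_k, control$gauss_sigma)
  dims <- c(ncol(sm), nrow(sm))

  H <- axis_profile(sm, "h"); V <- axis_profile(sm, "v")
  fH <- shock_filter(H, control$t_f); fV <- shock_filter(V, control$t_f)
  sh <- detect_steps(fH, control$min_step_frac * mean(fH$values))
  sv <- detect_steps(fV, control$min_step_frac * mean(fV$values))
  grid <- suppressWarnings(grid_from_steps(sh, sv, dims))

  pitch <- layout$spot_pitch_px %||%
    tryCatch(autocorrelation_period(H), error = function(e) NULL)
  grid_flag <- character(0)
  if (length(grid$x_lines) - 1 != layout$spots_nx ||
      length(grid$y_lines) - 1 != layout$spots_ny) {
    warning(sprintf(
      "group %d: grid has %d x %d cells, expected %d x %d; using uniform grid",
      g, length(grid$x_lines) - 1, length(grid$y_lines) - 1,
      layout$spots_nx, layout$spots_ny))
    grid <- structure(list(
      x_lines = seq(0, dims[1], length.out = layout$spots_nx + 1),
      y_lines = seq(0, dims[2], length.out = layout$spots_ny + 1),
      bounds = dims), class = "grid_lines")
    grid_flag <- "uniform_grid_fallback"
  }
  xs <- grid$x_lines; ys <- grid$y_lines
  nx <- length(xs) - 1; ny <- length(ys) - 1

  # per-row-slice x borders and per-column-slice y borders
  xb <- vector("list", ny); x_filled <- matrix(FALSE, ny, nx)
  yb <- vector("list", nx); y_filled <- matrix(FALSE, ny, nx)
  n_filled <- 0
  for (i in seq_len(ny)) {
    sl <- sm[(round(ys[i]) + 1):round(ys[i + 1]), , drop = FALSE]
    prof <- colMeans(sl)
    fp <- shock_filter(prof, control$t_f)
    thr <- control$thr_frac * mean(fp)
    bs <- lapply(seq_len(nx), function(j)
      spot_borders(fp, xs[j], xs[j + 1], thr))
    per <- tryCatch(autocorrelation_period(prof),
                    error = function(e) pitch)
    filled <- tryCatch(
      fill_border_gaps(bs, per %||% mean(diff(xs)), c(0, dims[1])),
      error = function(e) NULL)
    if (is.null(filled)) {
      xb[[i]] <- rep(list(NULL), nx)
    } else {
      xb[[i]] <- filled$borders
      x_filled[i, ] <- filled$filled
      n_filled <- n_filled + sum(filled$filled)
    }
  }
  for (j in seq_len(nx)) {
    sl <- sm[, (round(xs[j]) + 1):round(xs[j + 1]), drop = FALSE]
    prof <- rowMeans(sl)
    fp <- shock_filter(prof, control$t_f)
    thr <- control$thr_frac * mean(fp)
    bs <- lapply(seq_len(ny), function(i)
      spot_borders(fp, ys[i], ys[i + 1], thr))
    per <- tryCatch(autocorrelation_period(prof),
                    error = function(e) pitch)
    filled <- tryCatch(
      fill_border_gaps(bs, per %||% mean(diff(ys)), c(0, dims[2])),
      error = function(e) NULL)
    if (is.null(filled)) {
      yb[[j]] <- rep(list(NULL), ny)
    } else {
      yb[[j]] <- filled$borders
      y_filled[, j] <- filled$filled
      n_filled <- n_filled + sum(filled$filled)
    }
  }

  rows <- list(); masks <- list(); n_gridded <- 0
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    cell <- c(xs[j], xs[j + 1], ys[i], ys[i + 1])
    bx <- xb[[i]][[j]]; by <- yb[[j]][[i]]
    flags <- grid_flag
    if (x_filled[i, j] || y_filled[i, j])
      flags <- c(flags, "filled_by_autocorrelation")
    if (is.null(bx) || is.null(by)) {
      feats <- spot_features(sraw3, sraw5,
                             spot_mask_empty(c(flags, "not_found")))
      row <- cbind(data.frame(group = g, row = i, col = j,
                              x_center = NA_real_, y_center = NA_real_,
                              a_F = NA_real_, b_F = NA_real_),
                   feats, data.frame(rR = NA_real_, R2 = NA_real_))
      rows[[length(rows) + 1]] <- row
      masks[[length(masks) + 1]] <- NULL
      next
    }
    n_gridded <- n_gridded + 1
    geom <- build_geometry(bx, by, cell, control$ellipse_margin_px)
    geom$flags <- c(geom$flags, flags)
    # cluster on raw counts: the log enhancement is monotone, but k-means
    # centroids on the compressed scale pull dim edge/hole pixels into the
    # foreground; raw counts separate inner holes cleanly
    mask <- segment_spot(sraw3, sraw5, geom)
    feats <- spot_features(sraw3, sraw5, mask)
    eb <- rasterize_ellipse(geom$big_center, c(geom$a_b, geom$b_b),
                            clip_rect(geom$r_big, c(0, dims[1], 0, dims[2])))
    reg <- if (nrow(eb) >= 3) {
      idx <- cbind(eb[, "v"] + 1, eb[, "u"] + 1)
      regression_ratio(sraw3[idx], sraw5[idx])
    } else list(rR = NA_real_, r2 = NA_real_)
    row <- cbind(data.frame(group = g, row = i, col = j,
                            x_center = box[1] + geom$center[1],
                            y_center = box[3] + geom$center[2],
                            a_F = geom$a_f, b_F = geom$b_f),
                 feats, data.frame(rR = reg$rR, R2 = reg$r2))
    rows[[length(rows) + 1]] <- row
    fg <- mask$foreground
    if (nrow(fg) > 0) {
      fg[, "u"] <- fg[, "u"] + box[1]
      fg[, "v"] <- fg[, "v"] + box[3]
    }
    masks[[length(masks) + 1]] <- fg
  }
  list(grid = grid, rows = do.call(rbind, rows), masks = masks,
       n_gridded = n_gridded, n_filled = n_filled)
}

#' Read a flat key/value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Numeric values
#' are converted automatically.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  vals <- lapply(kv, function(p) {
    v <- trimws(p[2])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, function(p) trimws(p[1]), character(1))
  vals
}

#' Run the pipeline on TIFF files and write outputs
#'
#' File-level wrapper around [spot_pipeline()]: reads both channels,
#' runs the analysis and writes `results.tsv` (with all parameters echoed
#' as comment lines), one labeled 16-bit mask TIFF per group
#' (`mask_group<g>.tif`, 0 = background, spot id = foreground) plus a
#' per-spot flag table, and `run.log` with per-stage counts.
#'
#' @param cy3_path,cy5_path Paths to the Cy3 and Cy5 TIFFs.
#' @param config Named list (or path to a flat key/value file) with layout
#'   keys `groups_nx, groups_ny, spots_per_group_nx, spots_per_group_ny`
#'   and optional `spot_pitch_px` and algorithm parameters (any argument
#'   of [pipeline_control()]).
#' @param out_dir Output directory (created if needed).
#' @param debug Also write per-group profile plots (before/after shock
#'   filtering, with detected grid lines).
#' @return The [spot_pipeline()] result, invisibly.
#' @export
run_pipeline <- function(cy3_path, cy5_path, config, out_dir,
                         debug = FALSE) {
  if (is.character(config)) config <- read_config(config)
  raw3 <- read_channel(cy3_path, "Cy3")
  raw5 <- read_channel(cy5_path, "Cy5")
  layout <- slide_layout(config$groups_nx, config$groups_ny,
                         config$spots_per_group_nx,
                         config$spots_per_group_ny,
                         config$spot_pitch_px)
  ctrl_args <- config[intersect(names(config),
                                names(formals(pipeline_control)))]
  control <- do.call(pipeline_control, ctrl_args)
  run <- spot_pipeline(raw3, raw5, layout, control)
  if (nrow(run$results) == 0) stop("pipeline produced no results")

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- c(list(cy3 = cy3_path, cy5 = cy5_path),
              config[order(names(config))],
              list(rotation_applied_deg = -run$rotation_deg))
  write_results(run$results, file.path(out_dir, "results.tsv"), params)
  write_group_masks(run, out_dir)
  log_lines <- c(sprintf("rotation estimate: %.3f deg", run$rotation_deg),
                 sprintf("%s: %d", names(run$counts), run$counts))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  message(paste(log_lines, collapse = "\n"))
  if (debug) write_debug_profiles(run, raw3, out_dir)
  invisible(run)
}

#' Write the per-spot results table
#'
#' Tab-delimited, one row per spot, `NA` for undefined values; parameters
#' are echoed as `# key = value` comment lines for provenance.
#'
#' @param results Results data.frame from [spot_pipeline()].
#' @param path Output path.
#' @param params Named list echoed into the header.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, params = list()) {
  out_cols <- c("spot_id", "group", "row", "col", "x_center", "y_center",
                "a_F", "b_F", "n_fg", "n_bg",
                "f_u_cy3", "b_cy3", "f_u_cy5", "b_cy5", "R", "G",
                "R_ellipse", "G_ellipse", "ratio", "ratio_norm",
                "rR", "R2", "upregulated", "flags")
  out_cols <- intersect(out_cols, names(results))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(params))
    writeLines(sprintf("# %s = %s", k, params[[k]]), con)
  write.table(format(results[, out_cols], digits = 8, trim = TRUE,
                     scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

write_group_masks <- function(run, out_dir) {
  flag_rows <- list()
  for (g in seq_along(run$groups$boxes)) {
    box <- run$groups$boxes[[g]]
    lab <- matrix(0, box[4] - box[3], box[2] - box[1])
    sel <- run$results$group == g
    for (s in which(sel)) {
      fg <- run$masks[[s]]
      if (is.null(fg) || nrow(fg) == 0) next
      u <- fg[, "u"] - box[1]; v <- fg[, "v"] - box[3]
      ok <- u >= 0 & u < ncol(lab) & v >= 0 & v < nrow(lab)
      lab[cbind(v[ok] + 1, u[ok] + 1)] <- run$results$spot_id[s]
    }
    tiff::writeTIFF(lab / 65535, file.path(out_dir,
                                           sprintf("mask_group%d.tif", g)),
                    bits.per.sample = 16L)
    flag_rows[[g]] <- run$results[sel, c("group", "row", "col", "flags")]
  }
  write.table(do.call(rbind, flag_rows),
              file.path(out_dir, "spot_flags.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

write_debug_profiles <- function(run, raw3, out_dir) {
  enh <- log_enhance(raw3)
  px <- if (run$rotation_deg != 0)
    rotate_matrix_bilinear(enh$pixels, -run$rotation_deg) else enh$pixels
  tab <- list()
  for (g in seq_along(run$groups$boxes)) {
    box <- run$groups$boxes[[g]]
    sm <- gaussian_smooth(crop_rect(px, box),
                          run$control$gauss_k, run$control$gauss_sigma)
    H <- axis_profile(sm, "h")
    fH <- shock_filter(H, run$control$t_f)
    grDevices::png(file.path(out_dir, sprintf("profiles_group%d.png", g)),
                   width = 900, height = 400)
    graphics::plot(H$values, type = "l", col = "grey50",
                   xlab = "x (px)", ylab = "luminance",
                   main = sprintf("group %d horizontal profile", g))
    graphics::lines(fH$values, col = "red")
    graphics::abline(v = run$grids[[g]]$x_lines, col = "blue", lty = 3)
    grDevices::dev.off()
    gl <- run$grids[[g]]
    tab[[g]] <- rbind(
      data.frame(group = g, axis = "x", position = gl$x_lines),
      data.frame(group = g, axis = "y", position = gl$y_lines))
  }
  write.table(do.call(rbind, tab), file.path(out_dir, "grid_lines.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Simulate a slide and write it to files
#'
#' Thin wrapper over [generate_pair()]: writes `cy3.tif`, `cy5.tif`, a
#' ground-truth manifest `truth.tsv` (spot id, center, defect, true
#' levels, true ratio) and a labeled truth-mask TIFF `truth_mask.tif`.
#'
#' @param params A [simulation_params()].
#' @param out_dir Output directory.
#' @return The [generate_pair()] result, invisibly.
#' @export
simulate_to_files <- function(params, out_dir) {
  sim <- generate_pair(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_channel(sim$cy3, file.path(out_dir, "cy3.tif"))
  write_channel(sim$cy5, file.path(out_dir, "cy5.tif"))
  sp <- sim$truth$spots
  write.table(sp[, c("spot_id", "group", "row", "col", "cx", "cy",
                     "defect", "fg_cy3", "fg_cy5", "bg", "ratio_true")],
              file.path(out_dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  dims <- sim$truth$dim
  lab <- matrix(0, dims["height"], dims["width"])
  for (s in seq_len(nrow(sp))) {
    m <- sim$truth$masks[[s]]
    if (nrow(m) > 0) lab[cbind(m[, "v"] + 1, m[, "u"] + 1)] <- sp$spot_id[s]
  }
  tiff::writeTIFF(lab / 65535, file.path(out_dir, "truth_mask.tif"),
                  bits.per.sample = 16L)
  invisible(sim)
}
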