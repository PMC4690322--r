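# Per-spot intensity features, regression ratio, lowess normalisation and
# up-regulation calls. All medians are taken on RAW scanner counts: the
# logarithmic enhancement is monotone (so classification is unaffected),
# but reported intensities must stay on the count scale.

#' Per-spot intensity features from raw counts
#'
#' Medians of the raw foreground and background pixel intensities per
#' channel; the background-corrected intensity is `F = F_u - B`, floored
#' at 0 (with a flag) when the background median exceeds the foreground
#' median. `R` is the corrected Cy3 intensity, `G` the corrected Cy5
#' intensity and `r = R/G` their ratio (defined only for `G > 0`). When
#' the spot geometry is supplied, the in-ellipse medians over `E_F` are
#' reported alongside the clustered ones.
#'
#' @param raw_cy3,raw_cy5 Raw count matrices (co-registered, same frame as
#'   the mask coordinates).
#' @param mask A `spot_mask` from [segment_spot()].
#' @return A one-row `data.frame` with columns `f_u_cy3, f_u_cy5, b_cy3,
#'   b_cy5, F_cy3, F_cy5, R, G, ratio, R_ellipse, G_ellipse, n_fg, n_bg,
#'   flags`. Undefined quantities are `NA`.
#' @export
spot_features <- function(raw_cy3, raw_cy5, mask) {
  p3 <- if (inherits(raw_cy3, "raw_image")) raw_cy3$pixels else raw_cy3
  p5 <- if (inherits(raw_cy5, "raw_image")) raw_cy5$pixels else raw_cy5
  flags <- mask$flags
  fg <- mask$foreground; bg <- mask$background
  n_fg <- nrow(fg); n_bg <- nrow(bg)
  if (n_fg == 0 || "not_found" %in% flags) {
    return(feature_row(NA, NA, NA, NA, n_fg, n_bg,
                       NA, NA, union_flags(flags, "not_found")))
  }
  med_at <- function(px, pix) {
    if (nrow(pix) == 0) return(NA_real_)
    median(px[cbind(pix[, "v"] + 1, pix[, "u"] + 1)])
  }
  f3 <- med_at(p3, fg); f5 <- med_at(p5, fg)
  b3 <- med_at(p3, bg); b5 <- med_at(p5, bg)
  re <- med_at(p3, mask$ellipse_fg)
  ge <- med_at(p5, mask$ellipse_fg)
  if (is.na(b3)) { b3 <- 0; flags <- union_flags(flags, "no_background") }
  if (is.na(b5)) { b5 <- 0; flags <- union_flags(flags, "no_background") }
  R <- f3 - b3; G <- f5 - b5
  if (R < 0) { R <- 0; flags <- union_flags(flags, "negative_R") }
  if (G < 0) { G <- 0; flags <- union_flags(flags, "negative_G") }
  feature_row(f3, f5, b3, b5, n_fg, n_bg,
              if (is.na(re)) NA else re - b3,
              if (is.na(ge)) NA else ge - b5,
              flags, R = R, G = G)
}

feature_row <- function(f3, f5, b3, b5, n_fg, n_bg, re, ge, flags,
                        R = NA_real_, G = NA_real_) {
  ratio <- if (!is.na(G) && G > 0 && !is.na(R)) R / G else NA_real_
  if (!is.na(G) && G <= 0) flags <- union_flags(flags, "ratio_undefined")
  data.frame(f_u_cy3 = f3, f_u_cy5 = f5, b_cy3 = b3, b_cy5 = b5,
             R = R, G = G, ratio = ratio,
             R_ellipse = re, G_ellipse = ge,
             n_fg = n_fg, n_bg = n_bg,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

union_flags <- function(flags, new) unique(c(flags, new))

#' Pixelwise regression ratio and coefficient of determination
#'
#' Ordinary least-squares fit of the red (Cy3) against the green (Cy5) raw
#' intensity over all pixels inside the background ellipse `E_B`
#' (foreground, exclusion zone and background together). The slope is the
#' regression ratio `rR` — for a homogeneous spot it equals the median
#' ratio `r` — and the coefficient of determination `R^2` of the fit
#' scores the regularity of the spot (1 best, 0 worst).
#'
#' @param red,green Numeric vectors of paired raw pixel intensities
#'   (length >= 3).
#' @return List with `rR`, `r2` and `flags`; both are `NA` (flagged) when
#'   the green channel has zero variance or fewer than 3 pixels are given.
#' @export
regression_ratio <- function(red, green) {
  stopifnot(length(red) == length(green))
  if (length(red) < 3)
    return(list(rR = NA_real_, r2 = NA_real_, flags = "too_few_pixels"))
  if (var(green) == 0)
    return(list(rR = NA_real_, r2 = NA_real_, flags = "constant_green"))
  slope <- stats::cov(red, green) / var(green)
  ss_res <- sum((red - (mean(red) + slope * (green - mean(green))))^2)
  ss_tot <- sum((red - mean(red))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(rR = slope, r2 = max(0, min(1, r2)), flags = character(0))
}

#' Lowess normalisation of two-channel ratios
#'
#' Intensity-dependent dye bias is removed in MA coordinates:
#' `M = log2(R/G)`, `A = 0.5 * log2(R * G)`. A locally weighted linear
#' smoother (Cleveland's lowess, span 20% of the spots, 3 robustness
#' iterations) is fitted to M as a function of A and subtracted;
#' `r' = 2^(M - fit(A))` is the normalised ratio. Spots with undefined or
#' non-positive `R` or `G` are passed through unnormalised (`NA` in the
#' normalised columns). With fewer than 10 valid spots no fit is attempted
#' and the raw ratios are returned with a warning.
#'
#' @param features `data.frame` with columns `R` and `G` (one row per
#'   spot), e.g. row-bound outputs of [spot_features()].
#' @param window Lowess span as a fraction of the points (default 0.20).
#' @return `data.frame` with one row per input spot: `M`, `A`, `M_norm`,
#'   `ratio_norm` and logical `normalized`.
#' @export
lowess_normalize <- function(features, window = 0.20) {
  stopifnot(is.data.frame(features), all(c("R", "G") %in% names(features)))
  n <- nrow(features)
  valid <- !is.na(features$R) & !is.na(features$G) &
    features$R > 0 & features$G > 0
  out <- data.frame(M = rep(NA_real_, n), A = rep(NA_real_, n),
                    M_norm = rep(NA_real_, n),
                    ratio_norm = rep(NA_real_, n),
                    normalized = rep(FALSE, n))
  if (!any(valid)) return(out)
  M <- log2(features$R[valid] / features$G[valid])
  A <- 0.5 * log2(features$R[valid] * features$G[valid])
  out$M[valid] <- M
  out$A[valid] <- A
  if (sum(valid) < 10) {
    warning("fewer than 10 valid spots: skipping lowess normalisation")
    out$M_norm[valid] <- M
    out$ratio_norm[valid] <- 2^M
    return(out)
  }
  fit <- stats::lowess(A, M, f = window, iter = 3)
  fitted <- stats::approx(fit$x, fit$y, xout = A, rule = 2,
                          ties = mean)$y
  out$M_norm[valid] <- M - fitted
  out$ratio_norm[valid] <- 2^(M - fitted)
  out$normalized[valid] <- TRUE
  out
}

#' Call up-regulated spots
#'
#' Spots whose normalised ratio strictly exceeds the threshold (default 2,
#' i.e. at least a two-fold increase of the Cy3 signal over the Cy5
#' reference) are called up-regulated.
#'
#' @param ratios Output of [lowess_normalize()] (needs `ratio_norm`).
#' @param threshold Ratio threshold; the comparison is strict (`>`).
#' @return Integer vector of row indices (spot ids) that are called.
#' @export
call_upregulated <- function(ratios, threshold = 2) {
  which(!is.na(ratios$ratio_norm) & ratios$ratio_norm > threshold)
}
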