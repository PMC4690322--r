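# Image containers and TIFF input/output.
#
# Pixel matrices are plain R matrices indexed [v + 1, u + 1] with v the
# 0-based row (y) and u the 0-based column (x) index.

#' Raw scanner image
#'
#' A single-channel 16-bit scanner image: an integer matrix of photon counts
#' in `[0, 65535]` plus the dye channel it was recorded from.
#'
#' @param pixels Integer (or whole-number numeric) matrix of intensities in
#'   `[0, 65535]`. 8-bit data are accepted and kept on their native scale.
#' @param channel Dye label, `"Cy3"` or `"Cy5"`.
#' @return An object of class `raw_image` with elements `pixels` and
#'   `channel`.
#' @seealso [read_channel()], [log_enhance()]
#' @export
raw_image <- function(pixels, channel = c("Cy3", "Cy5")) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("image must be non-empty")
  if (anyNA(pixels)) stop("image contains missing values")
  if (min(pixels) < 0 || max(pixels) > 65535)
    stop("intensities must lie in [0, 65535]")
  storage.mode(pixels) <- "double"
  structure(list(pixels = pixels, channel = channel), class = "raw_image")
}

#' Contrast-enhanced image
#'
#' Real-valued image produced by [log_enhance()]: log2-transformed and
#' affinely stretched to the full 16-bit dynamic range. Carries the rotation
#' (in degrees) that has been applied to it, if any.
#'
#' @param pixels Numeric matrix with values in `[0, 65535]`.
#' @param channel Dye label.
#' @param rotation_deg Rotation already applied to the pixel grid (degrees).
#' @return An object of class `enhanced_image`.
#' @export
enhanced_image <- function(pixels, channel = c("Cy3", "Cy5"),
                           rotation_deg = 0) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  structure(list(pixels = pixels, channel = channel,
                 rotation_deg = rotation_deg),
            class = "enhanced_image")
}

#' @export
print.raw_image <- function(x, ...) {
  cat(sprintf("<raw_image %s: %d x %d px, range [%g, %g]>\n",
              x$channel, ncol(x$pixels), nrow(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.enhanced_image <- function(x, ...) {
  cat(sprintf("<enhanced_image %s: %d x %d px, rotation %.3f deg>\n",
              x$channel, ncol(x$pixels), nrow(x$pixels), x$rotation_deg))
  invisible(x)
}

#' Read a single-channel TIFF scan
#'
#' Reads a grayscale TIFF as stored by microarray scanners. 16-bit images
#' are returned on their native count scale `[0, 65535]`; 8-bit images are
#' promoted by multiplying with 257 so that the full dynamic range maps to
#' the 16-bit range.
#'
#' @param path Path to the TIFF file.
#' @param channel Dye label to attach, `"Cy3"` or `"Cy5"`.
#' @return A [raw_image()].
#' @export
read_channel <- function(path, channel = c("Cy3", "Cy5")) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("cannot read image: ", path)
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] != 1L)
      stop("multi-sample TIFFs are not supported: ", path)
    px <- px[, , 1L]
  }
  if (max(px) <= 255) {
    # 8-bit scan (or a 16-bit scan so dim it is indistinguishable from
    # one): promote so full scale maps to the 16-bit range
    warning("image has 8-bit range; promoting counts by factor 257")
    px <- px * 257L
  }
  raw_image(px, channel)
}

#' Write a count matrix as a 16-bit TIFF
#'
#' @param pixels Numeric matrix of counts in `[0, 65535]` (rounded to
#'   integers on write).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_channel <- function(pixels, path) {
  if (inherits(pixels, "raw_image")) pixels <- pixels$pixels
  px <- pmin(pmax(round(pixels), 0), 65535)
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# crop a pixel matrix to a half-open rectangle c(x0, x1, y0, y1), 0-based
crop_rect <- function(pixels, rect) {
  pixels[(rect[3] + 1):rect[4], (rect[1] + 1):rect[2], drop = FALSE]
}
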