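# Oil-Red-O positive-area quantification by fixed HSB colour thresholding
# with per-specimen averaging. The HSB scale is the ImageJ convention: all
# three channels on 0..255, hue mapped from [0, 360) degrees.

#' Histology image container
#'
#' @param pixels h x w x 3 numeric array of RGB values; either 8-bit integers
#'   in 0..255 or unit-scaled floats (detected and rescaled).
#' @param scale_um_per_px Optional physical pixel size, microns per pixel.
#' @return An object of class \code{histology_image}.
#' @export
histology_image <- function(pixels, scale_um_per_px = NULL) {
  if (!is.numeric(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3L] < 3L)
    stop("pixels must be an h x w x 3 RGB array")
  pixels <- pixels[, , 1:3, drop = FALSE]
  if (max(pixels) <= 1 && min(pixels) >= 0) pixels <- round(pixels * 255)
  if (min(pixels) < 0 || max(pixels) > 255) stop("RGB channels must lie in [0, 255]")
  structure(list(pixels = pixels, scale_um_per_px = scale_um_per_px),
            class = "histology_image")
}

#' Read a histology image (PNG or TIFF)
#'
#' @param path Image file.
#' @param scale_um_per_px Optional physical pixel size tag.
#' @return A \code{\link{histology_image}}.
#' @export
read_histology_image <- function(path, scale_um_per_px = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               png = png::readPNG(path),
               tif = , tiff = tiff::readTIFF(path),
               stop("unsupported histology format: ", ext))
  if (length(dim(px)) == 2L) stop("expected an RGB image, got grayscale")
  histology_image(px, scale_um_per_px)
}

#' HSB threshold triple
#'
#' Closed intervals on the 0..255 ImageJ scale. Defaults are the published
#' ORO bands: hue 228..255, saturation 167..255, brightness 0..255 (i.e. no
#' brightness constraint). The hue interval is non-wrapping; set
#' \code{hue_wrap = TRUE} for stains whose hue band crosses 0.
#'
#' @param hue,saturation,brightness Length-2 numeric (lo, hi) on 0..255.
#' @param hue_wrap If TRUE the hue interval is interpreted modulo 256.
#' @return An object of class \code{hsb_threshold}.
#' @export
hsb_threshold <- function(hue = c(228, 255), saturation = c(167, 255),
                          brightness = c(0, 255), hue_wrap = FALSE) {
  for (b in list(hue, saturation, brightness)) {
    if (length(b) != 2L || any(b < 0) || any(b > 255))
      stop("each band must be (lo, hi) within 0..255")
  }
  if (!hue_wrap && hue[1] > hue[2]) stop("hue band inverted; set hue_wrap for wrap-around bands")
  if (saturation[1] > saturation[2] || brightness[1] > brightness[2])
    stop("band inverted: lo > hi")
  structure(list(hue = hue, saturation = saturation, brightness = brightness,
                 hue_wrap = hue_wrap),
            class = "hsb_threshold")
}

#' RGB to HSB conversion on the 0..255 scale
#'
#' Standard hexcone HSV conversion with hue rescaled from [0, 360) degrees to
#' 0..255 and saturation/brightness to 0..255, all rounded to integers
#' (ImageJ colour-threshold convention).
#'
#' @param img A \code{\link{histology_image}} or h x w x 3 RGB array.
#' @return h x w x 3 integer array with channels hue, saturation, brightness.
#' @export
rgb_to_hsb <- function(img) {
  if (inherits(img, "histology_image")) img <- img$pixels
  d <- dim(img)
  rgb <- rbind(as.vector(img[, , 1L]), as.vector(img[, , 2L]), as.vector(img[, , 3L]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  out <- array(0L, d)
  out[, , 1L] <- as.integer(round(hsv[1L, ] * 255))
  out[, , 2L] <- as.integer(round(hsv[2L, ] * 255))
  out[, , 3L] <- as.integer(round(hsv[3L, ] * 255))
  out
}

#' ORO-positive pixel mask
#'
#' A pixel is positive iff its hue, saturation and brightness all fall in
#' their closed threshold intervals and, when an ROI is given, the pixel is
#' inside the ROI.
#'
#' @param img A \code{\link{histology_image}}.
#' @param thr An \code{\link{hsb_threshold}}.
#' @param roi Optional logical matrix matching the image shape.
#' @return Logical matrix of positive pixels.
#' @export
oro_positive_mask <- function(img, thr = hsb_threshold(), roi = NULL) {
  stopifnot(inherits(thr, "hsb_threshold"))
  hsb <- rgb_to_hsb(img)
  d2 <- dim(hsb)[1:2]
  h <- array(hsb[, , 1L], d2); s <- array(hsb[, , 2L], d2)
  v <- array(hsb[, , 3L], d2)
  hue_in <- if (thr$hue_wrap && thr$hue[1] > thr$hue[2]) {
    h >= thr$hue[1] | h <= thr$hue[2]
  } else {
    h >= thr$hue[1] & h <= thr$hue[2]
  }
  pos <- hue_in &
    s >= thr$saturation[1] & s <= thr$saturation[2] &
    v >= thr$brightness[1] & v <= thr$brightness[2]
  if (!is.null(roi)) {
    if (!identical(dim(roi), dim(pos))) stop("ROI shape does not match image")
    pos <- pos & roi
  }
  pos
}

#' Positive area fraction of a mask
#'
#' @param mask Logical matrix of positive pixels.
#' @param roi Optional logical matrix; the denominator is the ROI pixel count
#'   (whole image when omitted). An empty ROI is an error.
#' @return Percentage in [0, 100].
#' @export
area_fraction <- function(mask, roi = NULL) {
  if (!is.logical(mask) || is.null(dim(mask))) stop("mask must be a logical matrix")
  if (is.null(roi)) return(100 * sum(mask) / length(mask))
  if (!identical(dim(roi), dim(mask))) stop("ROI shape does not match mask")
  n <- sum(roi)
  if (n == 0L) stop("empty ROI")
  100 * sum(mask & roi) / n
}

#' Per-specimen average of area fractions
#'
#' The protocol averages the percentage area fraction over four images per
#' specimen; other counts are allowed with a warning.
#'
#' @param per_image_pct Nonempty numeric vector of percentages.
#' @return A list with \code{per_image_pct} and \code{specimen_mean_pct},
#'   class \code{area_fraction_result}.
#' @export
specimen_average <- function(per_image_pct) {
  if (length(per_image_pct) == 0L) stop("no per-image values to average")
  if (any(per_image_pct < 0 | per_image_pct > 100))
    stop("area fractions must lie in [0, 100]")
  if (length(per_image_pct) != 4L)
    warning(sprintf("specimen averaged over %d image(s), protocol uses 4",
                    length(per_image_pct)))
  structure(list(per_image_pct = as.numeric(per_image_pct),
                 specimen_mean_pct = mean(per_image_pct)),
            class = "area_fraction_result")
}

#' @export
print.area_fraction_result <- function(x, ...) {
  cat(sprintf("ORO area fraction: %.3f%% (mean of %d image(s): %s)\n",
              x$specimen_mean_pct, length(x$per_image_pct),
              paste(sprintf("%.3f", x$per_image_pct), collapse = ", ")))
  invisible(x)
}
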