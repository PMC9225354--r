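# CT volume container, calibration, denoising, downscaling and file I/O.
# All attenuation values are carried in Hounsfield units (air ~ -1000,
# water ~ 0); voxels are isotropic.

#' CT volume container
#'
#' A calibrated 3-D attenuation volume with isotropic voxel geometry. This is
#' the input of every imaging stage: the animal micro-CT workflow uses an
#' 8.4 um preset and the human HR-pQCT workflow an 82 um preset.
#'
#' @param values 3-D numeric array of attenuation values in HU.
#' @param voxel_size_mm Positive scalar, isotropic voxel edge length in mm.
#' @param origin Numeric length-3, position of the first voxel in mm.
#' @param modality One of \code{"microCT"}, \code{"HRpQCT"}, \code{"synthetic"}.
#' @return An object of class \code{ct_volume}.
#' @export
ct_volume <- function(values, voxel_size_mm,
                      origin = c(0, 0, 0),
                      modality = c("synthetic", "microCT", "HRpQCT")) {
  modality <- match.arg(modality)
  if (!is.numeric(values) || length(dim(values)) != 3L)
    stop("expected 3-D volume")
  if (any(dim(values) < 1L)) stop("all dimensions must be >= 1")
  if (!all(is.finite(values))) stop("volume values must be finite")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 1L || !is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("voxel_size_mm must be a positive scalar")
  structure(list(values = values,
                 voxel_size_mm = voxel_size_mm,
                 origin = as.numeric(origin),
                 modality = modality),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("ct_volume: %d x %d x %d voxels, %.4g mm isotropic (%s)\n",
              d[1], d[2], d[3], x$voxel_size_mm, x$modality))
  cat(sprintf("  HU range [%.1f, %.1f], mean %.1f\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$values)

#' HU calibration map
#'
#' Linear map from raw scanner integers to Hounsfield units, with an optional
#' secondary linear map to hydroxyapatite-equivalent density (mgHA/cm^3);
#' the mgHA map is disabled by default because no universal constants exist
#' (they are scanner calibration data).
#'
#' @param slope,intercept HU = slope * raw + intercept; slope must be nonzero.
#' @param mgha_slope,mgha_intercept Optional mgHA/cm^3 = mgha_slope * HU + mgha_intercept.
#' @return An object of class \code{hu_calibration}.
#' @export
hu_calibration <- function(slope = 1, intercept = 0,
                           mgha_slope = NULL, mgha_intercept = NULL) {
  if (!is.finite(slope) || slope == 0) stop("calibration slope must be nonzero")
  structure(list(slope = slope, intercept = intercept,
                 mgha_slope = mgha_slope, mgha_intercept = mgha_intercept),
            class = "hu_calibration")
}

#' Apply an HU calibration to raw scanner data
#'
#' @param raw 3-D numeric/integer array of raw values.
#' @param cal An \code{\link{hu_calibration}}.
#' @param voxel_size_mm,origin,modality Passed to \code{\link{ct_volume}}.
#' @return A \code{ct_volume} in HU.
#' @export
apply_calibration <- function(raw, cal, voxel_size_mm,
                              origin = c(0, 0, 0), modality = "synthetic") {
  stopifnot(inherits(cal, "hu_calibration"))
  ct_volume(cal$slope * raw + cal$intercept, voxel_size_mm,
            origin = origin, modality = modality)
}

#' Gaussian filter specification
#'
#' Truncated separable Gaussian used for noise reduction before segmentation.
#' \code{support} is the truncation radius in voxels per side (Scanco
#' convention), giving axis kernels of 2*support+1 taps renormalised to unit
#' sum; the protocol default is sigma 2.5, support 5.
#'
#' @param sigma Kernel standard deviation in voxels (> 0).
#' @param support Truncation radius in voxels (integer >= 1).
#' @return An object of class \code{filter_spec}.
#' @export
filter_spec <- function(sigma = 2.5, support = 5L) {
  support <- as.integer(support)
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (support < 1L) stop("support must be >= 1")
  structure(list(sigma = sigma, support = support), class = "filter_spec")
}

.gauss_kernel <- function(spec) {
  k <- -spec$support:spec$support
  w <- exp(-(k^2) / (2 * spec$sigma^2))
  w / sum(w)
}

# Map out-of-range indices into [1, n] by mirror reflection with the edge
# sample repeated (scipy "reflect"): d c b a | a b c d | d c b a.
.reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  j <- ifelse(j >= n, 2L * n - 1L - j, j)
  as.integer(j + 1L)
}

.convolve_axis <- function(a, w, axis) {
  d <- dim(a)
  s <- (length(w) - 1L) %/% 2L
  n <- d[axis]
  pad_idx <- .reflect_index(seq.int(1L - s, n + s), n)
  sel <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  selp <- sel; selp[[axis]] <- pad_idx
  padded <- a[selp[[1]], selp[[2]], selp[[3]], drop = FALSE]
  out <- array(0, d)
  for (k in seq_along(w)) {
    s2 <- sel; s2[[axis]] <- seq.int(k, k + n - 1L)
    out <- out + w[k] * padded[s2[[1]], s2[[2]], s2[[3]], drop = FALSE]
  }
  out
}

#' Gaussian denoising of a CT volume
#'
#' Separable truncated-Gaussian convolution with mirror-reflected borders.
#' Each axis kernel has 2*support+1 taps and is renormalised to sum to one,
#' so constant volumes pass through unchanged.
#'
#' @param vol A \code{\link{ct_volume}}.
#' @param spec A \code{\link{filter_spec}}; default sigma 2.5, support 5.
#' @return A filtered \code{ct_volume} with identical geometry.
#' @export
gaussian_filter_volume <- function(vol, spec = filter_spec()) {
  stopifnot(inherits(vol, "ct_volume"), inherits(spec, "filter_spec"))
  w <- .gauss_kernel(spec)
  v <- vol$values
  for (ax in 1:3) v <- .convolve_axis(v, w, ax)
  out <- vol
  out$values <- v
  out
}

#' Downscale a volume by integer block averaging
#'
#' Non-overlapping factor^3 blocks are replaced by their arithmetic mean;
#' trailing voxels that do not fill a complete block are dropped. The human
#' workflow downscales 82 um data by a factor of 2 to 164 um.
#'
#' @param vol A \code{\link{ct_volume}}.
#' @param factor Integer >= 2.
#' @return A \code{ct_volume} with voxel_size_mm multiplied by \code{factor}.
#' @export
downscale_volume <- function(vol, factor = 2L) {
  stopifnot(inherits(vol, "ct_volume"))
  factor <- as.integer(factor)
  if (factor < 2L) stop("downscale factor must be an integer >= 2")
  d <- dim(vol$values)
  dn <- d %/% factor
  if (any(dn < 1L)) stop("volume too small for this downscale factor")
  dc <- dn * factor
  a <- vol$values[seq_len(dc[1]), seq_len(dc[2]), seq_len(dc[3]), drop = FALSE]
  out <- array(0, dn)
  for (i in seq_len(factor)) {
    for (j in seq_len(factor)) {
      for (k in seq_len(factor)) {
        out <- out + a[seq.int(i, dc[1], factor),
                       seq.int(j, dc[2], factor),
                       seq.int(k, dc[3], factor), drop = FALSE]
      }
    }
  }
  res <- vol
  res$values <- out / factor^3
  res$voxel_size_mm <- vol$voxel_size_mm * factor
  res
}

# ---------------------------------------------------------------------------
# File I/O: NIfTI (read/write), raw float64 + YAML sidecar (read/write),
# multi-page TIFF stack + sidecar (read only; TIFF storage is unit-scaled so
# writing HU volumes through it would be lossy).

.sidecar_path <- function(path) paste0(path, ".yaml")

.write_sidecar <- function(path, vol) {
  meta <- list(voxel_size_mm = vol$voxel_size_mm,
               modality_tag = vol$modality,
               origin = as.numeric(vol$origin),
               dim = as.integer(dim(vol$values)))
  yaml::write_yaml(meta, .sidecar_path(path))
}

.read_sidecar <- function(path) {
  sp <- .sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  yaml::read_yaml(sp)
}

.format_from_path <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  switch(ext,
         nii = "nifti",
         tif = , tiff = "tiff",
         raw = "raw",
         stop("cannot infer volume format from extension: ", path))
}

#' Write a CT volume to disk
#'
#' NIfTI (\code{.nii}/\code{.nii.gz}) stores geometry natively; \code{.raw}
#' stores little-endian float64 voxels with a YAML sidecar carrying geometry
#' and modality. A sidecar is also written next to NIfTI files so the
#' modality tag round-trips.
#'
#' @param vol A \code{\link{ct_volume}}.
#' @param path Output path; format inferred from the extension.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  fmt <- .format_from_path(path)
  if (fmt == "nifti") {
    img <- RNifti::asNifti(vol$values)
    RNifti::pixdim(img) <- rep(vol$voxel_size_mm, 3L)
    RNifti::writeNifti(img, path)
    .write_sidecar(path, vol)
  } else if (fmt == "raw") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(vol$values), con, size = 8L, endian = "little")
    .write_sidecar(path, vol)
  } else {
    stop("TIFF volume output is not supported (unit-scaled storage is lossy for HU); use NIfTI or raw")
  }
  invisible(path)
}

#' Read a CT volume from disk
#'
#' Accepts NIfTI, raw float64 + YAML sidecar, or a multi-page TIFF stack with
#' a YAML sidecar. The voxel size must be recoverable from the file or its
#' sidecar; a missing voxel size is a hard error.
#'
#' @param path Input file.
#' @param format_hint Optional \code{"nifti"}, \code{"raw"} or \code{"tiff"};
#'   inferred from the extension when omitted.
#' @return A \code{\link{ct_volume}}.
#' @export
read_volume <- function(path, format_hint = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- if (is.null(format_hint)) .format_from_path(path) else format_hint
  meta <- .read_sidecar(path)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    vals <- array(as.numeric(img), dim(img))
    if (length(dim(vals)) != 3L) stop("expected 3-D volume, got ", length(dim(vals)), "-D")
    # the sidecar stores the voxel size at full precision; the NIfTI header
    # keeps it as float32, so prefer the sidecar when present
    vs <- if (!is.null(meta$voxel_size_mm)) meta$voxel_size_mm else
      RNifti::pixdim(img)[1L]
    if (!is.finite(vs) || vs <= 0)
      stop("missing voxel size: voxel_size_mm not in NIfTI header or sidecar")
    modality <- if (!is.null(meta$modality_tag)) meta$modality_tag else "synthetic"
    return(ct_volume(vals, vs, modality = modality))
  }
  if (is.null(meta)) stop("missing sidecar for ", fmt, " volume: ", .sidecar_path(path))
  if (is.null(meta$voxel_size_mm)) stop("missing voxel size: sidecar lacks field voxel_size_mm")
  modality <- if (!is.null(meta$modality_tag)) meta$modality_tag else "synthetic"
  if (fmt == "raw") {
    if (is.null(meta$dim) || length(meta$dim) != 3L)
      stop("raw volume sidecar must carry a 3-element dim field")
    d <- as.integer(meta$dim)
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- readBin(con, "numeric", n = prod(d), size = 8L, endian = "little")
    return(ct_volume(array(vals, d), meta$voxel_size_mm, modality = modality))
  }
  if (fmt == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L && is.null(meta$force_3d))
      stop("expected 3-D volume: TIFF has a single page")
    if (length(dim(pages[[1L]])) != 2L) stop("expected grayscale TIFF pages")
    d <- c(dim(pages[[1L]]), length(pages))
    vals <- array(unlist(pages, use.names = FALSE), d)
    vol <- ct_volume(vals, meta$voxel_size_mm, modality = modality)
    if (!is.null(meta$calibration)) {
      cal <- hu_calibration(meta$calibration$slope, meta$calibration$intercept)
      vol <- apply_calibration(vol$values, cal, vol$voxel_size_mm, modality = modality)
    }
    return(vol)
  }
  stop("unsupported format: ", fmt)
}

#' Write a binary mask as uint8 NIfTI
#'
#' @param mask 3-D logical array.
#' @param path Output path (.nii or .nii.gz).
#' @param voxel_size_mm Isotropic voxel size recorded in the header.
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(mask, path, voxel_size_mm) {
  .check_mask(mask)
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
  RNifti::pixdim(img) <- rep(voxel_size_mm, 3L)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
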