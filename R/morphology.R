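# 3-D binary morphology on logical arrays. Masks are plain logical arrays;
# everything here is vectorised via axis shifts so results are independent of
# any voxel traversal order.

.check_mask <- function(mask) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3-D logical array")
  invisible(mask)
}

# Shift an array by `delta` (length-3 integer) voxels; vacated voxels get `fill`.
.shift3 <- function(a, delta, fill) {
  d <- dim(a)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    n <- d[ax]
    idx <- seq_len(n) - delta[ax]
    keep <- idx >= 1L & idx <= n
    if (!any(keep)) {
      return(array(fill, d))
    }
    src[[ax]] <- idx[keep]
    dst[[ax]] <- which(keep)
  }
  out <- array(fill, d)
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

# Neighbourhood offsets for face (6) or full (26) connectivity.
.neighbour_offsets <- function(connectivity = 6L, positive_only = FALSE) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), , drop = FALSE]
  if (connectivity == 6L) g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1L, , drop = FALSE]
  if (positive_only) {
    key <- g$dx + 3 * g$dy + 9 * g$dz
    g <- g[key > 0, , drop = FALSE]
  }
  lapply(seq_len(nrow(g)), function(i) c(g$dx[i], g$dy[i], g$dz[i]))
}

#' Dilate a binary mask
#'
#' One or more iterations of binary dilation with the 6- or 26-connected
#' structuring element. Voxels outside the array are treated as background.
#'
#' @param mask 3-D logical array.
#' @param iterations Number of dilation rounds (non-negative integer).
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return Logical array of the same dimensions.
#' @export
mask_dilate <- function(mask, iterations = 1L, connectivity = 6L) {
  .check_mask(mask)
  iterations <- as.integer(iterations)
  if (iterations < 0L) stop("iterations must be >= 0")
  offs <- .neighbour_offsets(connectivity)
  out <- mask
  for (i in seq_len(iterations)) {
    acc <- out
    for (o in offs) acc <- acc | .shift3(out, o, FALSE)
    out <- acc
  }
  out
}

#' Erode a binary mask
#'
#' Iterated binary erosion. With \code{border = "background"} (the default,
#' used for ROI peeling) the exterior of the array counts as background, so
#' voxels on the array border are always removed; \code{border =
#' "foreground"} treats the exterior as foreground, which is what a closing
#' needs so that structures running through the array faces are not eaten
#' from the ends.
#'
#' @inheritParams mask_dilate
#' @param border How voxels beyond the array are treated.
#' @return Logical array of the same dimensions.
#' @export
mask_erode <- function(mask, iterations = 1L, connectivity = 6L,
                       border = c("background", "foreground")) {
  .check_mask(mask)
  border <- match.arg(border)
  fill <- border == "foreground"
  iterations <- as.integer(iterations)
  if (iterations < 0L) stop("iterations must be >= 0")
  offs <- .neighbour_offsets(connectivity)
  out <- mask
  for (i in seq_len(iterations)) {
    acc <- out
    for (o in offs) acc <- acc & .shift3(out, o, fill)
    out <- acc
  }
  out
}

#' Label connected components of a binary mask
#'
#' 3-D connected-component labelling under 6- or 26-connectivity. Component
#' ids are assigned in order of the smallest linear voxel index they contain,
#' so the labelling is deterministic.
#'
#' @inheritParams mask_dilate
#' @return Integer array; 0 for background, 1..k for components.
#' @export
label_components <- function(mask, connectivity = 6L) {
  .check_mask(mask)
  idx <- which(mask)
  lab <- array(0L, dim(mask))
  if (length(idx) == 0L) return(lab)
  id <- array(0L, dim(mask))
  id[idx] <- seq_along(idx)
  offs <- .neighbour_offsets(connectivity, positive_only = TRUE)
  edges <- vector("list", length(offs))
  for (k in seq_along(offs)) {
    sh <- .shift3(id, offs[[k]], 0L)
    both <- id > 0L & sh > 0L
    edges[[k]] <- cbind(id[both], sh[both])
  }
  el <- do.call(rbind, edges)
  n <- length(idx)
  if (is.null(el) || nrow(el) == 0L) {
    membership <- seq_len(n)
  } else {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::add_edges(g, t(el))
    membership <- igraph::components(g)$membership
  }
  # renumber by first occurrence so ids are traversal-order independent
  membership <- match(membership, unique(membership))
  lab[idx] <- as.integer(membership)
  lab
}

#' Remove small connected components
#'
#' @inheritParams mask_dilate
#' @param min_size Minimum number of voxels a component must have to survive.
#' @return Logical array with undersized components cleared.
#' @export
filter_small_components <- function(mask, min_size, connectivity = 6L) {
  .check_mask(mask)
  if (min_size <= 1L) return(mask)
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask)
  sz <- tabulate(lab[lab > 0L])
  keep <- which(sz >= min_size)
  array(lab %in% keep, dim(mask))
}

#' Fill enclosed holes in a binary mask
#'
#' Background components that do not touch the designated outer faces of the
#' array are considered enclosed holes and are added to the mask. For a scan
#' stack whose tissue runs through the full z extent, pass
#' \code{border_faces = c("x", "y")} so that cavities open only to the top or
#' bottom slice still count as enclosed.
#'
#' @inheritParams mask_dilate
#' @param border_faces Axes whose two end faces count as "outside";
#'   subset of \code{c("x", "y", "z")}.
#' @return Logical array with holes filled.
#' @export
fill_holes <- function(mask, connectivity = 6L, border_faces = c("x", "y", "z")) {
  .check_mask(mask)
  lab <- label_components(!mask, connectivity)
  if (max(lab) == 0L) return(mask)
  d <- dim(mask)
  border <- integer(0)
  if ("x" %in% border_faces) border <- c(border, lab[c(1L, d[1L]), , ])
  if ("y" %in% border_faces) border <- c(border, lab[, c(1L, d[2L]), ])
  if ("z" %in% border_faces) border <- c(border, lab[, , c(1L, d[3L])])
  outside <- unique(border[border > 0L])
  holes <- lab > 0L & !(lab %in% outside)
  mask | holes
}

#' Dice similarity coefficient of two binary masks
#'
#' @param a,b 3-D logical arrays of identical dimensions.
#' @return Scalar in [0, 1]; defined as 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  .check_mask(a); .check_mask(b)
  if (!identical(dim(a), dim(b))) stop("mask dimensions differ")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) return(1)
  2 * sum(a & b) / (sa + sb)
}

# Slice-wise (2-D, 4-neighbour) morphological closing: dilate then erode by
# `radius` within each transverse slice. Used to smooth the muscle label into
# a contour-like ROI; working per slice keeps the z extent of a through-stack
# structure intact.
.close_slicewise <- function(mask, radius) {
  if (radius < 1L) return(mask)
  offs <- list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L), c(0L, -1L, 0L))
  out <- mask
  for (i in seq_len(radius)) {
    acc <- out
    for (o in offs) acc <- acc | .shift3(out, o, FALSE)
    out <- acc
  }
  for (i in seq_len(radius)) {
    acc <- out
    for (o in offs) acc <- acc & .shift3(out, o, FALSE)
    out <- acc
  }
  out
}

# Slice-wise convex hull of a mask: per transverse slice, rasterise the
# convex hull of the foreground pixels. Used to turn the grown muscle label
# into the muscle-envelope ROI; valid when the envelope is convex, as for a
# lower-leg cross-section.
.hull_slicewise <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (z in seq_len(d[3L])) {
    sl <- mask[, , z]
    pts <- which(sl, arr.ind = TRUE)
    if (nrow(pts) < 3L) next
    h <- grDevices::chull(pts[, 1L], pts[, 2L])
    vi <- pts[h, 1L]; vj <- pts[h, 2L]
    nv <- length(h)
    fill <- sl
    for (j in seq.int(min(vj), max(vj))) {
      xs <- numeric(0)
      for (e in seq_len(nv)) {
        j1 <- vj[e]; j2 <- vj[if (e == nv) 1L else e + 1L]
        i1 <- vi[e]; i2 <- vi[if (e == nv) 1L else e + 1L]
        if (j < min(j1, j2) || j > max(j1, j2)) next
        if (j1 == j2) {
          xs <- c(xs, i1, i2)
        } else {
          xs <- c(xs, i1 + (i2 - i1) * (j - j1) / (j2 - j1))
        }
      }
      if (length(xs) == 0L) next
      lo <- ceiling(min(xs) - 1e-9); hi <- floor(max(xs) + 1e-9)
      if (hi >= lo) fill[lo:hi, j] <- TRUE
    }
    out[, , z] <- fill
  }
  out
}
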