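#' Orthographic depth map of a surface cloud
#'
#' Projects the cloud along a signed body axis onto the plane spanned by the
#' two remaining axes and keeps, per cell, the depth of the surface point
#' nearest to the viewer. With `view_axis = "-y"` the viewer looks at the face
#' of a +y-facing head: depth is the point's coordinate along the view
#' direction, and the per-cell minimum is the nearest-to-viewer surface (the
#' nose tip is the global minimum).
#'
#' @param cloud n x 3 point matrix (mm).
#' @param view_axis one of `"+x"`, `"-x"`, `"+y"`, `"-y"`, `"+z"`, `"-z"` —
#'   the anterior-to-posterior viewing direction.
#' @param cell_size projection-plane cell edge, mm.
#' @return list of class `depth_map`: `grid` (depth, mm; `NA` where no surface
#'   projects), `u0`, `v0` (physical coordinates of the first cell centre),
#'   `cell_size`, `axes` (names of the in-plane axes), `view_axis`.
#' @export
project_depth <- function(cloud, view_axis = "-y", cell_size = 1) {
  cloud <- rbind(cloud)
  if (!nrow(cloud)) stop("empty point cloud")
  stopifnot(cell_size > 0)
  ax <- parse_view_axis(view_axis)
  u <- cloud[, ax$plane[1]]
  v <- cloud[, ax$plane[2]]
  depth <- cloud[, ax$axis] * ax$sign
  u0 <- min(u); v0 <- min(v)
  iu <- floor((u - u0) / cell_size + 0.5) + 1L
  iv <- floor((v - v0) / cell_size + 0.5) + 1L
  grid <- matrix(NA_real_, max(iu), max(iv))
  ord <- order(depth, decreasing = TRUE)     # nearest (min depth) written last
  grid[cbind(iu[ord], iv[ord])] <- depth[ord]
  structure(list(grid = grid, u0 = u0, v0 = v0, cell_size = cell_size,
                 axes = colnames(cloud)[ax$plane] %||% c("u", "v"),
                 plane = ax$plane, axis = ax$axis, sign = ax$sign,
                 view_axis = view_axis),
            class = "depth_map")
}

parse_view_axis <- function(view_axis) {
  if (!is.character(view_axis) || !grepl("^[+-][xyz]$", view_axis))
    stop('`view_axis` must be one of "+x", "-x", "+y", "-y", "+z", "-z"')
  axis <- match(substr(view_axis, 2, 2), c("x", "y", "z"))
  list(axis = axis, sign = if (substr(view_axis, 1, 1) == "-") -1 else 1,
       plane = setdiff(1:3, axis))
}

#' Feature-grid specification
#'
#' A rectangle on the projection plane sampled at `rows x cols` uniformly
#' spaced nodes (default 4 x 7 = 28 facial feature points over the eye-nose
#' region).
#'
#' @param rect `c(u0, v0, u1, v1)` rectangle on the projection plane, mm.
#' @param rows,cols grid sampling frequency; `rows * cols >= 3`.
#' @return list of class `feature_grid_spec`.
#' @export
feature_grid_spec <- function(rect, rows = 4, cols = 7) {
  rect <- as.numeric(rect)
  stopifnot(length(rect) == 4L, rect[3] > rect[1], rect[4] > rect[2],
            rows >= 1, cols >= 1, rows * cols >= 3)
  structure(list(rect = rect, rows = as.integer(rows), cols = as.integer(cols)),
            class = "feature_grid_spec")
}

#' Sample a feature-point grid from a depth map
#'
#' Places `rows x cols` nodes uniformly over the rectangle and lifts each node
#' to 3D at the depth of its nearest occupied cell within `capture_radius`
#' (node's own cell when `capture_radius = 0`). Nodes with no surface within
#' reach are dropped; with full coverage the result has exactly `rows * cols`
#' points (28 at the 4 x 7 default).
#'
#' @param depth a [project_depth()] result.
#' @param spec a [feature_grid_spec()].
#' @param capture_radius mm; default `2 * cell_size`.
#' @return k x 3 matrix of points `(x, y, z)`, `3 <= k <= rows * cols`.
#' @export
sample_feature_grid <- function(depth, spec, capture_radius = NULL) {
  stopifnot(inherits(depth, "depth_map"), inherits(spec, "feature_grid_spec"))
  capture_radius <- capture_radius %||% (2 * depth$cell_size)
  occ <- which(!is.na(depth$grid), arr.ind = TRUE)
  if (!nrow(occ)) stop("feature region off surface: depth map is empty")
  occ_u <- depth$u0 + (occ[, 1] - 1) * depth$cell_size
  occ_v <- depth$v0 + (occ[, 2] - 1) * depth$cell_size
  occ_d <- depth$grid[occ]
  us <- seq(spec$rect[1], spec$rect[3], length.out = spec$cols)
  vs <- seq(spec$rect[2], spec$rect[4], length.out = spec$rows)
  nodes <- cbind(u = rep(us, times = spec$rows), v = rep(vs, each = spec$cols))
  out <- matrix(NA_real_, nrow(nodes), 3)
  for (i in seq_len(nrow(nodes))) {
    d2 <- (occ_u - nodes[i, 1])^2 + (occ_v - nodes[i, 2])^2
    j <- which.min(d2)
    hit <- if (capture_radius > 0) sqrt(d2[j]) <= capture_radius
           else sqrt(d2[j]) <= depth$cell_size / 2 + 1e-9
    if (!hit) next
    p <- numeric(3)
    p[depth$plane[1]] <- nodes[i, 1]
    p[depth$plane[2]] <- nodes[i, 2]
    p[depth$axis] <- occ_d[j] * depth$sign
    out[i, ] <- p
  }
  keep <- stats::complete.cases(out)
  out <- out[keep, , drop = FALSE]
  if (!nrow(out)) stop("feature region off surface: no node captured a cell")
  colnames(out) <- c("x", "y", "z")
  attr(out, "node") <- which(keep)   # grid-node identity of each kept point
  out
}

#' Band (slab) specification along a body axis
#'
#' @param axis `"x"`, `"y"` or `"z"` (default `"z"`, the slice axis).
#' @param lo,hi physical range in mm, `lo < hi`.
#' @return list of class `band_spec`.
#' @export
band_spec <- function(lo, hi, axis = "z") {
  stopifnot(axis %in% c("x", "y", "z"), is.finite(lo), is.finite(hi), lo < hi)
  structure(list(axis = axis, lo = lo, hi = hi), class = "band_spec")
}

#' Select the circular-contour band of a surface cloud
#'
#' Subset of surface points whose coordinate along the band axis lies in
#' `[lo, hi]` — the axial slab of exterior contour rings used for the
#' scale-determining similarity registration. Provenance is preserved.
#'
#' @param cloud n x 3 point matrix with optional `provenance` attribute.
#' @param spec a [band_spec()].
#' @return subset point matrix.
#' @export
select_band <- function(cloud, spec) {
  stopifnot(inherits(spec, "band_spec"))
  prov <- attr(cloud, "provenance")
  cloud <- rbind(cloud)
  ax <- match(spec$axis, c("x", "y", "z"))
  keep <- cloud[, ax] >= spec$lo & cloud[, ax] <= spec$hi
  if (!any(keep)) stop("empty band selection [", spec$lo, ", ", spec$hi,
                       "] on axis ", spec$axis)
  out <- cloud[keep, , drop = FALSE]
  if (!is.null(prov)) attr(out, "provenance") <- prov[keep, , drop = FALSE]
  out
}
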