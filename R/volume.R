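#' Construct a volume
#'
#' A `volume` is a 3D scalar grid indexed `(slice, row, col)` — i.e. `(z, y, x)`
#' — with per-axis physical spacing in mm and a physical origin. Voxel centres
#' sit at `origin + (k*dx, j*dy, i*dz)` for 0-based indices `(i, j, k)` =
#' (slice, row, col); physical coordinates are always `(x, y, z)` in mm.
#'
#' @param data 3D numeric array indexed `(slice, row, col)`.
#' @param spacing numeric length-3 `(dz, dy, dx)` in mm, all strictly positive.
#' @param origin numeric length-3 physical position `(x, y, z)` in mm of voxel
#'   `(1, 1, 1)` (default `c(0, 0, 0)`).
#' @param intensity_kind one of `"ct_hu"`, `"mr_arbitrary"`, `"photo_grey"`;
#'   drives the default binarization threshold in contour extraction.
#' @return An object of class `volume`.
#' @export
new_volume <- function(data, spacing, origin = c(0, 0, 0),
                       intensity_kind = c("mr_arbitrary", "ct_hu", "photo_grey")) {
  intensity_kind <- match.arg(intensity_kind)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array (slice, row, col)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive finite values (dz, dy, dx)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be three finite values (x, y, z)")
  structure(list(data = data, spacing = spacing, origin = origin,
                 intensity_kind = intensity_kind),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume> %d x %d x %d (slice, row, col), spacing (dz,dy,dx) = %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = ", ")))
  cat(sprintf("  origin (x,y,z) = (%s) mm, intensity: %s, range [%.4g, %.4g]\n",
              paste(signif(x$origin, 4), collapse = ", "), x$intensity_kind,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a label volume
#'
#' Integer-labelled grid geometrically congruent with a [new_volume()] grid,
#' plus a table naming each label. Label 0 is background and every nonzero id
#' present in the grid must appear in the table.
#'
#' @param labels 3D integer array indexed `(slice, row, col)`.
#' @param table data.frame with columns `id` (integer, nonzero) and `name`.
#' @inheritParams new_volume
#' @return An object of class `label_volume`.
#' @export
new_label_volume <- function(labels, table, spacing, origin = c(0, 0, 0)) {
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  if (!is.data.frame(table) || !all(c("id", "name") %in% names(table)))
    stop("`table` must be a data.frame with columns `id` and `name`")
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, table$id)
  if (length(missing))
    stop("label ids present in grid but absent from table: ",
         paste(missing, collapse = ", "))
  v <- new_volume(labels, spacing, origin)
  structure(list(labels = labels, table = table,
                 spacing = v$spacing, origin = v$origin),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d, %d structures:\n", d[1], d[2], d[3],
              nrow(x$table)))
  for (i in seq_len(nrow(x$table)))
    cat(sprintf("  %d: %s (%d voxels)\n", x$table$id[i], x$table$name[i],
                sum(x$labels == x$table$id[i])))
  invisible(x)
}

#' Voxel indices to physical coordinates
#'
#' @param v a `volume` or `label_volume`.
#' @param idx n x 3 matrix of 1-based array indices `(slice, row, col)`.
#' @return n x 3 matrix of physical coordinates `(x, y, z)` in mm.
#' @export
voxel_to_world <- function(v, idx) {
  idx <- rbind(idx)
  # spacing is (dz,dy,dx); world axes are (x,y,z)
  cbind(v$origin[1] + (idx[, 3] - 1) * v$spacing[3],
        v$origin[2] + (idx[, 2] - 1) * v$spacing[2],
        v$origin[3] + (idx[, 1] - 1) * v$spacing[1])
}

#' Physical coordinates to (fractional) voxel indices
#'
#' @param v a `volume` or `label_volume`.
#' @param xyz n x 3 matrix of physical coordinates `(x, y, z)` in mm.
#' @return n x 3 matrix of 1-based fractional array indices `(slice, row, col)`.
#' @export
world_to_voxel <- function(v, xyz) {
  xyz <- rbind(xyz)
  cbind((xyz[, 3] - v$origin[3]) / v$spacing[1] + 1,
        (xyz[, 2] - v$origin[2]) / v$spacing[2] + 1,
        (xyz[, 1] - v$origin[1]) / v$spacing[3] + 1)
}

grid_of <- function(v) if (inherits(v, "label_volume")) v$labels else v$data

#' Sample a volume at arbitrary physical points
#'
#' Trilinear (`"linear"`) or nearest-neighbour (`"nearest"`) interpolation of
#' the grid at physical coordinates. Points outside the grid return `fill`.
#'
#' @param v a `volume` or `label_volume`.
#' @param xyz n x 3 matrix of physical coordinates (mm).
#' @param method `"linear"` or `"nearest"`; label volumes force `"nearest"`.
#' @param fill value returned for out-of-bounds points (default 0).
#' @return numeric vector of length n.
#' @export
interp_volume <- function(v, xyz, method = c("linear", "nearest"), fill = 0) {
  method <- match.arg(method)
  if (inherits(v, "label_volume")) method <- "nearest"
  g <- grid_of(v)
  d <- dim(g)
  ijk <- world_to_voxel(v, xyz)
  out <- rep(fill, nrow(ijk))
  if (method == "nearest") {
    ri <- round(ijk)
    ok <- ri[, 1] >= 1 & ri[, 1] <= d[1] & ri[, 2] >= 1 & ri[, 2] <= d[2] &
      ri[, 3] >= 1 & ri[, 3] <= d[3]
    if (any(ok)) out[ok] <- g[ri[ok, , drop = FALSE]]
    return(out)
  }
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] & ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  if (!any(ok)) return(out)
  p <- ijk[ok, , drop = FALSE]
  i0 <- pmin(floor(p[, 1]), d[1] - 1L); i0 <- pmax(i0, 1)
  j0 <- pmin(floor(p[, 2]), d[2] - 1L); j0 <- pmax(j0, 1)
  k0 <- pmin(floor(p[, 3]), d[3] - 1L); k0 <- pmax(k0, 1)
  # degenerate axes (single slice) interpolate along the remaining axes
  if (d[1] == 1L) i0 <- rep(1, nrow(p))
  if (d[2] == 1L) j0 <- rep(1, nrow(p))
  if (d[3] == 1L) k0 <- rep(1, nrow(p))
  fi <- pmin(pmax(p[, 1] - i0, 0), 1)
  fj <- pmin(pmax(p[, 2] - j0, 0), 1)
  fk <- pmin(pmax(p[, 3] - k0, 0), 1)
  i1 <- pmin(i0 + 1L, d[1]); j1 <- pmin(j0 + 1L, d[2]); k1 <- pmin(k0 + 1L, d[3])
  lin <- function(i, j, k) g[cbind(i, j, k)]
  val <-
    lin(i0, j0, k0) * (1 - fi) * (1 - fj) * (1 - fk) +
    lin(i1, j0, k0) * fi       * (1 - fj) * (1 - fk) +
    lin(i0, j1, k0) * (1 - fi) * fj       * (1 - fk) +
    lin(i0, j0, k1) * (1 - fi) * (1 - fj) * fk +
    lin(i1, j1, k0) * fi       * fj       * (1 - fk) +
    lin(i1, j0, k1) * fi       * (1 - fj) * fk +
    lin(i0, j1, k1) * (1 - fi) * fj       * fk +
    lin(i1, j1, k1) * fi       * fj       * fk
  out[ok] <- val
  out
}

#' Resample a volume to isotropic spacing
#'
#' The output grid spans from the first to the last input voxel centre on each
#' axis (closed extent, no extrapolation), with `floor(extent/spacing) + 1`
#' voxels per axis. Scalar volumes are interpolated linearly; label volumes
#' nearest-neighbour.
#'
#' @param v a `volume` or `label_volume`.
#' @param target_spacing positive scalar, mm.
#' @return resampled object of the same class.
#' @export
resample_isotropic <- function(v, target_spacing) {
  if (!is.numeric(target_spacing) || length(target_spacing) != 1L ||
      !is.finite(target_spacing) || target_spacing <= 0)
    stop("`target_spacing` must be a positive scalar (mm)")
  g <- grid_of(v)
  d <- dim(g)
  if (all(abs(v$spacing - target_spacing) < 1e-12)) return(v)
  extent <- (d - 1) * v$spacing            # (z, y, x) physical extents
  nd <- floor(extent / target_spacing + 1e-9) + 1
  zi <- seq(0, by = target_spacing, length.out = nd[1])
  yi <- seq(0, by = target_spacing, length.out = nd[2])
  xi <- seq(0, by = target_spacing, length.out = nd[3])
  pts <- cbind(rep(v$origin[1] + xi, each = nd[1] * nd[2]),
               rep(rep(v$origin[2] + yi, each = nd[1]), times = nd[3]),
               rep(v$origin[3] + zi, times = nd[2] * nd[3]))
  val <- interp_volume(v, pts,
                       method = if (inherits(v, "label_volume")) "nearest" else "linear")
  arr <- array(val, dim = nd)
  if (inherits(v, "label_volume")) {
    storage.mode(arr) <- "integer"
    new_label_volume(arr, v$table, rep(target_spacing, 3), v$origin)
  } else {
    out <- new_volume(arr, rep(target_spacing, 3), v$origin, v$intensity_kind)
    out
  }
}
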