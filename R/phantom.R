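#' Synthetic head-phantom specification
#'
#' Defines a deterministic head-like digital phantom: an ellipsoidal cranium
#' with a conical nose protruding along +y (anterior) and two spherical
#' eye-socket depressions, plus embedded region-of-interest labels (a midline
#' sphere playing the pituitary, a pair of tubes playing the optic nerves, and
#' a lateral slab playing the temporalis). Foreground intensity is 100 on a 0
#' background, with optional additive Gaussian noise. All randomness is fixed
#' by `seed`.
#'
#' @param shape grid dimensions `(slices, rows, cols)` = `(z, y, x)`.
#' @param spacing `(dz, dy, dx)` mm.
#' @param head_semiaxes ellipsoid semi-axes `(ax, ay, az)` mm.
#' @param nose_length,nose_radius nose cone length and base radius, mm.
#' @param eye_offset,eye_radius,eye_depth lateral eye separation from the
#'   midline, socket sphere radius, and how deep the socket centre sits
#'   relative to the anterior ellipsoid surface (mm).
#' @param noise_sigma additive Gaussian noise SD, intensity units.
#' @param seed integer seed fixing the noise.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 144, 128), spacing = c(1, 1, 1),
                         head_semiaxes = c(40, 50, 42),
                         nose_length = 25, nose_radius = 9,
                         eye_offset = 16, eye_radius = 8, eye_depth = 2,
                         noise_sigma = 0, seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 8),
            all(spacing > 0), all(head_semiaxes > 0),
            nose_length > 0, nose_radius > 0,
            eye_offset > 0, eye_radius > 0, noise_sigma >= 0)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 head_semiaxes = head_semiaxes, nose_length = nose_length,
                 nose_radius = nose_radius, eye_offset = eye_offset,
                 eye_radius = eye_radius, eye_depth = eye_depth,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# world-coordinate grids of a (z,y,x) array, as vectors in array fill order
world_grids <- function(shape, spacing, origin = c(0, 0, 0)) {
  z <- origin[3] + (seq_len(shape[1]) - 1) * spacing[1]
  y <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  x <- origin[1] + (seq_len(shape[3]) - 1) * spacing[3]
  list(x = rep(x, each = shape[1] * shape[2]),
       y = rep(rep(y, each = shape[1]), times = shape[3]),
       z = rep(z, times = shape[2] * shape[3]))
}

# membership of the analytic head solid at arbitrary world points
head_membership <- function(spec, x, y, z) {
  ctr <- c((spec$shape[3] - 1) * spec$spacing[3],
           (spec$shape[2] - 1) * spec$spacing[2],
           (spec$shape[1] - 1) * spec$spacing[1]) / 2
  a <- spec$head_semiaxes
  inside <- ((x - ctr[1]) / a[1])^2 + ((y - ctr[2]) / a[2])^2 +
    ((z - ctr[3]) / a[3])^2 <= 1
  # nose: cone along +y, base inside the ellipsoid, apex protruding
  nose_z <- ctr[3] + 0.05 * a[3]
  yb <- ctr[2] + 0.80 * a[2]
  frac <- (y - yb) / spec$nose_length
  nose <- frac >= 0 & frac <= 1 &
    sqrt((x - ctr[1])^2 + (z - nose_z)^2) <= spec$nose_radius * (1 - frac)
  solid <- inside | nose
  # eye sockets: spherical caps carved from the anterior surface
  eye_z <- ctr[3] + 0.30 * a[3]
  fr <- 1 - (spec$eye_offset / a[1])^2 - ((eye_z - ctr[3]) / a[3])^2
  ey <- ctr[2] + a[2] * sqrt(max(fr, 0)) + spec$eye_depth
  for (sx in c(-1, 1)) {
    ex <- ctr[1] + sx * spec$eye_offset
    socket <- (x - ex)^2 + (y - ey)^2 + (z - eye_z)^2 <= spec$eye_radius^2
    solid <- solid & !socket
  }
  solid
}

default_rois <- function(spec) {
  ctr <- c((spec$shape[3] - 1) * spec$spacing[3],
           (spec$shape[2] - 1) * spec$spacing[2],
           (spec$shape[1] - 1) * spec$spacing[1]) / 2
  a <- spec$head_semiaxes
  eye_z <- ctr[3] + 0.30 * a[3]
  list(
    list(id = 1L, name = "pituitary", shape = "sphere",
         center = ctr, radius = 5),
    list(id = 2L, name = "optic_nerve", shape = "tube",
         from = c(ctr[1] - 12, ctr[2] + 0.45 * a[2], eye_z - 4),
         to = c(ctr[1] - 2, ctr[2] + 4, ctr[3] + 6), radius = 2.5),
    list(id = 2L, name = "optic_nerve", shape = "tube",
         from = c(ctr[1] + 12, ctr[2] + 0.45 * a[2], eye_z - 4),
         to = c(ctr[1] + 2, ctr[2] + 4, ctr[3] + 6), radius = 2.5),
    list(id = 3L, name = "temporalis", shape = "tube",
         from = c(ctr[1] - 0.78 * a[1], ctr[2], ctr[3] - 8),
         to = c(ctr[1] - 0.70 * a[1], ctr[2] + 8, ctr[3] + 10), radius = 5)
  )
}

roi_membership <- function(roi, x, y, z) {
  if (roi$shape == "sphere") {
    (x - roi$center[1])^2 + (y - roi$center[2])^2 + (z - roi$center[3])^2 <=
      roi$radius^2
  } else if (roi$shape == "tube") {
    d <- roi$to - roi$from
    L2 <- sum(d^2)
    t <- ((x - roi$from[1]) * d[1] + (y - roi$from[2]) * d[2] +
            (z - roi$from[3]) * d[3]) / L2
    t <- pmin(pmax(t, 0), 1)
    (x - roi$from[1] - t * d[1])^2 + (y - roi$from[2] - t * d[2])^2 +
      (z - roi$from[3] - t * d[3])^2 <= roi$radius^2
  } else stop("unknown roi shape: ", roi$shape)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Generate the phantom atlas volume and its ROI labels
#'
#' Rasterizes the analytic head solid of a [phantom_spec()] (foreground 100,
#' background 0, optional Gaussian noise) together with an integer ROI label
#' grid and its name table. Deterministic for a fixed spec seed.
#'
#' @param spec a [phantom_spec()].
#' @param rois list of ROI descriptors (id, name, shape `"sphere"`/`"tube"`,
#'   geometry in mm); defaults to a pituitary-like sphere, paired optic-nerve
#'   tubes and a temporalis-like lateral tube.
#' @return list with `volume` (a [new_volume()]) and `labels`
#'   (a [new_label_volume()]).
#' @export
generate_atlas <- function(spec = phantom_spec(), rois = default_rois(spec)) {
  g <- world_grids(spec$shape, spec$spacing)
  solid <- head_membership(spec, g$x, g$y, g$z)
  vals <- ifelse(solid, 100, 0)
  if (spec$noise_sigma > 0)
    vals <- vals + with_seed(spec$seed, rnorm(length(vals), 0, spec$noise_sigma))
  vol <- new_volume(array(vals, spec$shape), spec$spacing,
                    intensity_kind = "mr_arbitrary")
  lab <- integer(length(g$x))
  for (roi in rois) {
    mem <- roi_membership(roi, g$x, g$y, g$z)
    if (any(mem & !solid))
      stop("roi '", roi$name, "' extends outside the head solid")
    lab[mem] <- roi$id
  }
  tab <- unique(data.frame(
    id = vapply(rois, `[[`, integer(1), "id"),
    name = vapply(rois, `[[`, character(1), "name")))
  labels <- new_label_volume(array(lab, spec$shape), tab, spec$spacing)
  list(volume = vol, labels = labels)
}

#' Derive a subject from the atlas by a known similarity transform
#'
#' Maps the atlas through a uniform-scale similarity transform (rotation about
#' the head centre, then translation), resamples onto the subject grid
#' (trilinear for intensities, nearest-neighbour for labels), applies optional
#' local defects in subject space and adds seeded Gaussian noise. The exact
#' atlas-to-subject transform and both label grids are returned as ground
#' truth.
#'
#' @param atlas a [new_volume()] (typically from [generate_atlas()]).
#' @param labels the matching [new_label_volume()].
#' @param scale uniform scale factor in `[0.5, 2]`.
#' @param rotation `c(yaw, pitch, roll)` degrees (see [euler_rotation()]),
#'   magnitudes <= 180.
#' @param translation `(x, y, z)` shift, mm.
#' @param defects list of defect descriptors: `list(type = "missing_region"
#'   , center =, radius =)` zeroes a sphere (e.g. missing teeth);
#'   `type = "bulge"` sets a sphere to foreground (e.g. a bone-defect bulge).
#'   Centres are in subject space, applied after the transform.
#' @param noise_sigma additive Gaussian noise SD.
#' @param seed integer seed for the noise.
#' @param out_shape,out_spacing subject grid. By default the grid is framed
#'   around the transformed head (bounding box of the mapped foreground plus a
#'   10 mm margin), the way a scanner's field of view frames the patient; pass
#'   `out_shape` explicitly to force a fixed grid (which may clip the head).
#' @return list with `volume`, `labels`, and `truth` (list: `transform`
#'   atlas-to-subject 4x4, `atlas_labels`, `subject_labels`).
#' @export
derive_subject <- function(atlas, labels, scale = 1, rotation = c(0, 0, 0),
                           translation = c(0, 0, 0), defects = list(),
                           noise_sigma = 0, seed = 1L,
                           out_shape = NULL, out_spacing = atlas$spacing) {
  stopifnot(inherits(atlas, "volume"), inherits(labels, "label_volume"))
  if (scale < 0.5 || scale > 2) stop("`scale` must lie in [0.5, 2]")
  if (any(abs(rotation) > 180)) stop("rotation magnitudes must be <= 180 deg")
  out_spacing <- rep(as.numeric(out_spacing), length.out = 3)
  d <- dim(atlas$data)
  ctr <- c(atlas$origin[1] + (d[3] - 1) * atlas$spacing[3] / 2,
           atlas$origin[2] + (d[2] - 1) * atlas$spacing[2] / 2,
           atlas$origin[3] + (d[1] - 1) * atlas$spacing[1] / 2)
  R <- euler_rotation(rotation[1], rotation[2], rotation[3])
  t <- ctr - scale * (R %*% ctr) + translation
  tr <- similarity_transform(scale, R, as.numeric(t))
  inv <- invert_transform(tr)
  origin <- atlas$origin
  if (is.null(out_shape)) {
    # frame the subject grid around the transformed head, 10 mm margin
    fg <- which(atlas$data > 50, arr.ind = TRUE)
    if (!nrow(fg)) stop("atlas has no foreground to frame")
    w <- voxel_to_world(atlas, fg[c(which.min(fg[, 1]), which.max(fg[, 1]),
                                    which.min(fg[, 2]), which.max(fg[, 2]),
                                    which.min(fg[, 3]), which.max(fg[, 3])),
                                  , drop = FALSE])
    lo <- apply(w, 2, min) - 1; hi <- apply(w, 2, max) + 1
    corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                     c(lo[3], hi[3])))
    mapped <- apply_transform(tr, corners)
    lo <- apply(mapped, 2, min) - 10; hi <- apply(mapped, 2, max) + 10
    origin <- lo
    out_shape <- as.integer(ceiling((hi - lo)[c(3, 2, 1)] /
                                      out_spacing) + 1)
  }
  g <- world_grids(out_shape, out_spacing, origin)
  src <- apply_transform(inv, cbind(g$x, g$y, g$z))
  vals <- interp_volume(atlas, src, method = "linear")
  labv <- interp_volume(labels, src)
  if (!any(vals > 50))
    stop("transform pushes the head fully outside the subject grid")
  for (df in defects) {
    mem <- (g$x - df$center[1])^2 + (g$y - df$center[2])^2 +
      (g$z - df$center[3])^2 <= df$radius^2
    if (df$type == "missing_region") vals[mem] <- 0
    else if (df$type == "bulge") vals[mem] <- 100
    else stop("unknown defect type: ", df$type)
  }
  if (noise_sigma > 0)
    vals <- vals + with_seed(seed, rnorm(length(vals), 0, noise_sigma))
  vol <- new_volume(array(vals, out_shape), out_spacing, origin,
                    atlas$intensity_kind)
  slab <- new_label_volume(array(as.integer(labv), out_shape), labels$table,
                           out_spacing, origin)
  list(volume = vol, labels = slab,
       truth = list(transform = tr, atlas_labels = labels,
                    subject_labels = slab))
}
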