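#' Two-step progressive registration of two surface clouds
#'
#' Step 1 (spatial orientation, performed once) produces a rigid transform
#' `m1` aligning the atlas face onto the subject face: 4 x 7 feature grids
#' are sampled from face-on depth maps of both surfaces over the eye-nose
#' region; their index-paired fit seeds a deterministic multi-start (spins
#' about the viewing axis) of a scale-tolerant ICP of the atlas face patch
#' against the subject surface, whose rigid part is `m1`. Step 2 (spatial
#' scale, `n_scale_steps` progressive repeats): the atlas circular-contour
#' band is pushed through the accumulated transform and aligned to the subject
#' band by similarity ICP, giving `m2_1 .. m2_n`. The final transform is the
#' composition (apply `m1`, then each `m2_x` in order).
#'
#' @param atlas_surface,subject_surface n x 3 surface clouds (mm), e.g. from
#'   [surface_from_volume()]; the atlas is always the moving set.
#' @param atlas_grid,subject_grid [feature_grid_spec()] rectangles on the
#'   respective face-on projection planes.
#' @param atlas_band,subject_band [band_spec()] slabs bracketing the eye-nose
#'   region on each surface; the two bands should hold approximately the same
#'   anatomy (a warning is issued when point counts differ by more than 3:1).
#' @param n_scale_steps number of progressive similarity passes (1..5; more
#'   risks over-registration and is refused).
#' @param control [icp_control()] for both steps.
#' @param atlas_view,subject_view viewing directions for [project_depth()].
#' @param cell_size depth-map cell edge, mm.
#' @return list of class `tspr_result`: `m1`, `m2_list`, `final` (4x4
#'   transforms with `final = compose_transforms(m1, m2_list)` exactly),
#'   `step1`, `step2` (per-step [icp()] results), `features` (the two sampled
#'   grids), `band_sizes`.
#' @export
tspr_register <- function(atlas_surface, subject_surface,
                          atlas_grid, subject_grid,
                          atlas_band, subject_band,
                          n_scale_steps = 1, control = icp_control(),
                          atlas_view = "-y", subject_view = "-y",
                          cell_size = 1) {
  if (n_scale_steps < 1) stop("`n_scale_steps` must be >= 1")
  if (n_scale_steps > 5)
    stop("`n_scale_steps` > 5 refused: repeating the scale registration ",
         "many times over-registers and wastes computation")
  ga <- sample_feature_grid(project_depth(atlas_surface, atlas_view, cell_size),
                            atlas_grid)
  gs <- sample_feature_grid(project_depth(subject_surface, subject_view, cell_size),
                            subject_grid)
  if (nrow(ga) < 3L || nrow(gs) < 3L)
    stop("feature grids must yield at least 3 points each")
  step1 <- orientation_step(ga, gs, atlas_surface, subject_surface,
                            atlas_grid, atlas_view, control)
  m1 <- step1$transform

  ab <- select_band(atlas_surface, atlas_band)
  sb <- select_band(subject_surface, subject_band)
  ratio <- max(nrow(ab), nrow(sb)) / min(nrow(ab), nrow(sb))
  if (ratio > 3)
    warning(sprintf(paste0("band point counts differ by %.1f:1; the two bands",
                           " should cover approximately the same anatomy"),
                    ratio))
  acc <- m1
  m2_list <- vector("list", n_scale_steps)
  step2 <- vector("list", n_scale_steps)
  for (x in seq_len(n_scale_steps)) {
    moved <- apply_transform(acc, ab)
    res <- icp(moved, sb, "similarity", control)
    m2_list[[x]] <- res$transform
    step2[[x]] <- res
    acc <- compose_transforms(acc, list(res$transform))
  }
  structure(list(m1 = m1, m2_list = m2_list,
                 final = compose_transforms(m1, m2_list),
                 step1 = step1, step2 = step2,
                 features = list(atlas = ga, subject = gs),
                 band_sizes = c(atlas = nrow(ab), subject = nrow(sb))),
            class = "tspr_result")
}

# Spatial-orientation step: a rigid transform aligning the atlas face onto
# the subject face.
#
# The index-paired fit of the 4 x 7 grid nodes recovers the out-of-plane tilt
# of the face but is blind to spin about the viewing axis (both rectangles
# are axis-aligned on their projection planes, so node pairing carries no
# in-plane rotation signal), and a purely rigid surface fit is biased when
# the two heads differ in size.  The step therefore (a) seeds from the paired
# node fit, (b) multi-starts over spins about the view axis in 15 degree
# increments, scoring each candidate by a short scale-tolerant (similarity)
# ICP of the dense atlas face patch against the full subject surface, (c)
# polishes the best candidate with a full similarity ICP, and (d) returns the
# rigid part only: the fitted rotation plus the translation that preserves
# the image of the face-patch centroid, leaving all scaling to the second
# step.  The multi-start is what escapes the nose-to-ear class of ICP local
# extrema; the scale-tolerant fit is what keeps the orientation unbiased for
# differently sized heads.
orientation_step <- function(ga, gs, atlas_surface, subject_surface,
                             atlas_grid, atlas_view, control) {
  na <- attr(ga, "node") %||% seq_len(nrow(ga))
  ns <- attr(gs, "node") %||% seq_len(nrow(gs))
  common <- intersect(na, ns)
  base <- if (length(common) >= 3L)
    tryCatch(fit_rigid(ga[match(common, na), , drop = FALSE],
                       gs[match(common, ns), , drop = FALSE]),
             error = function(e) transform_identity())
  else transform_identity()
  ax <- parse_view_axis(atlas_view)
  u <- atlas_surface[, ax$plane[1]]
  v <- atlas_surface[, ax$plane[2]]
  r <- atlas_grid$rect
  patch <- atlas_surface[u >= r[1] & u <= r[3] & v >= r[2] & v <= r[4], ,
                         drop = FALSE]
  if (nrow(patch) < nrow(ga)) patch <- ga
  axis <- numeric(3); axis[ax$axis] <- 1
  uaxis <- numeric(3); uaxis[ax$plane[1]] <- 1
  vaxis <- numeric(3); vaxis[ax$plane[2]] <- 1
  ctr <- colMeans(gs)
  short <- icp_control(max_iter = 8, tol = control$tol, max_points = 1200)
  # flips handle mirrored node pairing when the two faces look along opposite
  # axes (a projection cannot tell a face from its back-to-front double)
  flips <- list(transform_identity(),
                spin_transform(vaxis, 180, ctr),
                spin_transform(uaxis, 180, ctr))
  best <- base; best_rms <- Inf
  for (flip in flips) {
    seed <- compose_transforms(base, list(flip))
    for (ang in seq(-180, 150, by = 30)) {
      cand <- compose_transforms(seed, list(spin_transform(axis, ang, ctr)))
      # rigid scoring: a similarity fit at a wrong pose can shrink the patch
      # into the surface and fake a low rms
      res <- tryCatch(icp(patch, subject_surface, "rigid", short,
                          init = cand),
                      error = function(e) NULL)
      if (!is.null(res) && res$rms < best_rms) {
        best_rms <- res$rms
        best <- res$transform
      }
    }
  }
  fine <- icp(patch, subject_surface, "similarity",
              icp_control(max_iter = control$max_iter, tol = control$tol,
                          max_points = 1200),
              init = best)
  d <- decompose_similarity(fine$transform)
  c0 <- colMeans(patch)
  t_rigid <- as.numeric(d$scale * (d$rotation %*% c0) + d$translation -
                          d$rotation %*% c0)
  fine$transform <- rigid_transform(d$rotation, t_rigid)
  fine$mode <- "rigid"
  fine
}

#' @export
print.tspr_result <- function(x, ...) {
  cat(sprintf("<tspr_result> 1 rigid + %d similarity step(s)\n",
              length(x$m2_list)))
  cat(sprintf("  step 1 (orientation): rms %.4g mm, %d iterations\n",
              x$step1$rms, x$step1$iterations))
  for (i in seq_along(x$step2))
    cat(sprintf("  step 2.%d (scale):     rms %.4g mm, %d iterations\n",
                i, x$step2[[i]]$rms, x$step2[[i]]$iterations))
  dec <- decompose_similarity(x$final)
  cat(sprintf("  final: scale %.4f, rotation %.2f deg, |t| %.2f mm\n",
              dec$scale, rotation_angle(dec$rotation),
              sqrt(sum(dec$translation^2))))
  invisible(x)
}

#' Fit a two-step progressive registration between two head volumes
#'
#' The top-level fitting interface: extracts the exterior surface of both
#' volumes ([surface_from_volume()]), samples facial feature grids and
#' circular-contour bands, runs [tspr_register()], and measures the residual
#' surface misfit of the registered atlas against the subject surface.
#'
#' @param atlas,subject `volume` objects (the atlas is the moving image), or
#'   precomputed n x 3 surface clouds.
#' @param atlas_rect,subject_rect `c(u0, v0, u1, v1)` face-window rectangles
#'   on the projection plane (mm), or [feature_grid_spec()] objects.
#' @param atlas_band,subject_band `c(lo, hi)` axial ranges (mm), or
#'   [band_spec()] objects.
#' @param n_scale_steps progressive similarity passes (default 1).
#' @param contour [contour_params()] used for surface extraction.
#' @param control [icp_control()].
#' @param atlas_view,subject_view see [project_depth()].
#' @param cell_size depth-map cell edge, mm; default the larger in-plane
#'   spacing of the two inputs (1 mm for cloud inputs).
#' @return object of class `tspr` with components `transform` (final 4x4
#'   atlas-to-subject map), `registration` (the `tspr_result`), `rms`
#'   (residual surface RMS, mm), `surfaces`, and `call`. Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `residuals()` and `plot()`.
#' @export
tspr <- function(atlas, subject, atlas_rect, subject_rect,
                 atlas_band, subject_band, n_scale_steps = 1,
                 contour = contour_params(), control = icp_control(),
                 atlas_view = "-y", subject_view = "-y", cell_size = NULL) {
  cl <- match.call()
  spac <- function(v) if (inherits(v, "volume")) max(v$spacing[2:3]) else 1
  cell_size <- cell_size %||% max(spac(atlas), spac(subject))
  as_surface <- function(v) {
    if (inherits(v, "volume")) surface_from_volume(v, contour) else rbind(v)
  }
  sa <- as_surface(atlas)
  ss <- as_surface(subject)
  as_grid <- function(r) if (inherits(r, "feature_grid_spec")) r else feature_grid_spec(r)
  as_band <- function(b) if (inherits(b, "band_spec")) b else band_spec(b[1], b[2])
  reg <- tspr_register(sa, ss, as_grid(atlas_rect), as_grid(subject_rect),
                       as_band(atlas_band), as_band(subject_band),
                       n_scale_steps = n_scale_steps, control = control,
                       atlas_view = atlas_view, subject_view = subject_view,
                       cell_size = cell_size)
  mv <- thin_cloud(sa, 5000)
  nn <- nearest_correspondences(apply_transform(reg$final, mv), ss)
  structure(list(transform = reg$final, registration = reg,
                 rms = sqrt(mean(nn$distance^2)), resid = nn$distance,
                 surfaces = list(atlas = sa, subject = ss), call = cl),
            class = "tspr")
}

#' @export
print.tspr <- function(x, ...) {
  cat("Two-step progressive registration\n\nCall:\n  ")
  print(x$call)
  dec <- decompose_similarity(x$transform)
  cat(sprintf("\nFinal atlas-to-subject transform: scale %.4f, rotation %.2f deg, translation (%.2f, %.2f, %.2f) mm\n",
              dec$scale, rotation_angle(dec$rotation), dec$translation[1],
              dec$translation[2], dec$translation[3]))
  cat(sprintf("Residual surface rms: %.3f mm\n", x$rms))
  invisible(x)
}

#' @export
summary.tspr <- function(object, ...) {
  reg <- object$registration
  dec <- decompose_similarity(object$transform)
  steps <- data.frame(
    step = c("orientation (rigid)",
             sprintf("scale %d (similarity)", seq_along(reg$step2))),
    rms_mm = c(reg$step1$rms, vapply(reg$step2, `[[`, numeric(1), "rms")),
    iterations = c(reg$step1$iterations,
                   vapply(reg$step2, `[[`, numeric(1), "iterations")),
    converged = c(reg$step1$converged,
                  vapply(reg$step2, `[[`, logical(1), "converged")))
  structure(list(call = object$call, steps = steps, decomposition = dec,
                 transform = object$transform, rms = object$rms,
                 n_points = vapply(object$surfaces, nrow, integer(1)),
                 residual_quartiles = stats::quantile(object$resid)),
            class = "summary.tspr")
}

#' @export
print.summary.tspr <- function(x, ...) {
  cat("Two-step progressive registration\n\nCall:\n  ")
  print(x$call)
  cat(sprintf("\nSurfaces: atlas %d points, subject %d points\n",
              x$n_points[1], x$n_points[2]))
  cat("\nRegistration steps:\n")
  print(x$steps, row.names = FALSE)
  cat("\nFinal transform:\n")
  print(round(unclass(x$transform), 4))
  cat(sprintf("\nscale %.4f, rotation angle %.2f deg, translation (%.2f, %.2f, %.2f) mm\n",
              x$decomposition$scale, rotation_angle(x$decomposition$rotation),
              x$decomposition$translation[1], x$decomposition$translation[2],
              x$decomposition$translation[3]))
  cat(sprintf("Residual surface rms: %.3f mm; quartiles (mm):\n", x$rms))
  print(round(x$residual_quartiles, 3))
  invisible(x)
}

#' @export
coef.tspr <- function(object, ...) {
  dec <- decompose_similarity(object$transform)
  c(scale = dec$scale, rotation_deg = rotation_angle(dec$rotation),
    tx = dec$translation[1], ty = dec$translation[2], tz = dec$translation[3])
}

#' @export
#' @param newdata n x 3 matrix of atlas-space points (mm); defaults to the
#'   atlas surface cloud.
#' @rdname tspr
predict.tspr <- function(object, newdata = NULL, ...) {
  pts <- newdata %||% object$surfaces$atlas
  apply_transform(object$transform, pts)
}

#' @export
residuals.tspr <- function(object, ...) object$resid

#' @export
plot.tspr <- function(x, ...) {
  reg <- x$registration
  hists <- c(list(reg$step1$rms_history),
             lapply(reg$step2, `[[`, "rms_history"))
  cols <- c("black", rep("firebrick", length(hists) - 1))
  ylim <- range(unlist(hists))
  plot(NA, xlim = c(1, max(lengths(hists))), ylim = ylim,
       xlab = "ICP iteration", ylab = "rms nearest-neighbour distance (mm)",
       main = "TSPR convergence", log = "y", ...)
  for (i in seq_along(hists))
    lines(seq_along(hists[[i]]), hists[[i]], col = cols[i], lwd = 2,
          lty = if (i == 1) 1 else i)
  legend("topright", bty = "n", lwd = 2, col = cols,
         lty = c(1, seq_along(reg$step2) + 1),
         legend = c("step 1: rigid (orientation)",
                    sprintf("step 2.%d: similarity (scale)",
                            seq_along(reg$step2))))
  invisible(x)
}
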