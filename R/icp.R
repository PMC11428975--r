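#' Nearest-neighbour correspondences between point clouds
#'
#' For every moving point, the index of its Euclidean-nearest target point and
#' the distance. Ties break deterministically to the lowest target index.
#'
#' @param moving,target n x 3 and m x 3 matrices of points (mm).
#' @return list with integer `index` (length n, into `target`) and numeric
#'   `distance` (mm).
#' @export
nearest_correspondences <- function(moving, target) {
  moving <- rbind(moving); target <- rbind(target)
  if (!nrow(moving) || !nrow(target)) stop("point clouds must be nonempty")
  .nn_bruteforce(as.matrix(moving[, 1:3, drop = FALSE]),
                 as.matrix(target[, 1:3, drop = FALSE]))
}

#' ICP control parameters
#'
#' @param max_iter maximum iterations (>= 1).
#' @param tol convergence tolerance on the change in RMS distance, mm.
#' @param max_points moving clouds larger than this are thinned to a
#'   deterministic evenly-spaced subset before iterating (the fitted transform
#'   still applies to the full cloud).
#' @return list of class `icp_control`.
#' @export
icp_control <- function(max_iter = 300, tol = 1e-6, max_points = 3000) {
  stopifnot(max_iter >= 1, tol > 0, max_points >= 3)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 max_points = as.integer(max_points)), class = "icp_control")
}

thin_cloud <- function(pts, max_points) {
  n <- nrow(pts)
  if (n <= max_points) return(pts)
  pts[round(seq(1, n, length.out = max_points)), , drop = FALSE]
}

#' Iterative closest point registration
#'
#' Alternates nearest-neighbour correspondence search with a closed-form
#' rigid ([fit_rigid()]) or uniform-scale similarity ([fit_similarity()]) fit
#' on the matched pairs, accumulating the transform. The recorded
#' `rms_history` (root-mean-square nearest-neighbour distance after each
#' update) is non-increasing; iteration stops when it changes by less than
#' `tol` or `max_iter` is reached.
#'
#' @param moving,target n x 3 / m x 3 point matrices (mm); `moving` is mapped
#'   onto `target`.
#' @param mode `"rigid"` or `"similarity"`.
#' @param control see [icp_control()].
#' @param init optional 4x4 initial transform applied to `moving` before the
#'   first iteration (composed into the result).
#' @return list of class `registration_result`: `transform` (4x4), `rms` (mm),
#'   `iterations`, `converged`, `rms_history`, `mode`.
#' @export
icp <- function(moving, target, mode = c("rigid", "similarity"),
                control = icp_control(), init = NULL) {
  mode <- match.arg(mode)
  moving <- rbind(moving); target <- rbind(target)
  if (!nrow(moving) || !nrow(target)) stop("point clouds must be nonempty")
  mv <- thin_cloud(as.matrix(moving[, 1:3, drop = FALSE]), control$max_points)
  tg <- as.matrix(target[, 1:3, drop = FALSE])
  tr <- if (is.null(init)) transform_identity() else as_transform(init)
  history <- numeric(0)
  converged <- FALSE
  moved <- apply_transform(tr, mv)
  nn <- nearest_correspondences(moved, tg)
  for (k in seq_len(control$max_iter)) {
    delta <- if (mode == "rigid") {
      fit_rigid(moved, tg[nn$index, , drop = FALSE])
    } else {
      # a degenerate correspondence set (collapsed matches) can drive the
      # similarity scale non-positive; a rigid update keeps the iteration
      # monotone and lets the correspondences recover
      tryCatch(fit_similarity(moved, tg[nn$index, , drop = FALSE]),
               error = function(e) fit_rigid(moved, tg[nn$index, , drop = FALSE]))
    }
    tr <- compose_transforms(tr, list(delta))
    moved <- apply_transform(tr, mv)
    nn <- nearest_correspondences(moved, tg)
    rms <- sqrt(mean(nn$distance^2))
    history <- c(history, rms)
    if (rms < 1e-12 ||
        (k > 1L && abs(history[k - 1L] - rms) < control$tol)) {
      converged <- TRUE
      break
    }
  }
  structure(list(transform = tr, rms = history[length(history)],
                 iterations = length(history), converged = converged,
                 rms_history = history, mode = mode),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> %s ICP: rms %.4g mm after %d iterations (%s)\n",
              x$mode, x$rms, x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' RMS nearest-neighbour distance of one cloud to another
#'
#' Convenience metric: root-mean-square distance from each (optionally
#' transformed) moving point to its nearest target point.
#'
#' @inheritParams icp
#' @param transform optional 4x4 transform applied to `moving` first.
#' @param max_points thin the moving cloud to at most this many points.
#' @return scalar RMS distance, mm.
#' @export
surface_rms <- function(moving, target, transform = NULL, max_points = 5000) {
  mv <- thin_cloud(rbind(moving)[, 1:3, drop = FALSE], max_points)
  if (!is.null(transform)) mv <- apply_transform(transform, mv)
  nn <- nearest_correspondences(mv, rbind(target)[, 1:3, drop = FALSE])
  sqrt(mean(nn$distance^2))
}
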