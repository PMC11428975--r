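#' Homogeneous 4x4 transforms
#'
#' Points are column vectors augmented with 1: a transform `M` maps `p` to
#' `(M %*% c(p, 1))[1:3]`. The last row is always exactly `c(0, 0, 0, 1)`.
#' Rigid transforms hold an orthonormal rotation `R` (det +1) and a translation
#' `t`; similarity transforms hold `s * R` with a single positive scale `s`.
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param t length-3 translation (mm).
#' @param s positive uniform scale.
#' @return 4x4 matrix of class `homogeneous_transform`.
#' @name homogeneous_transform
NULL

#' Coerce a plain 4x4 matrix to a homogeneous transform
#'
#' Validates the shape and forces the last row to exactly `c(0, 0, 0, 1)`.
#'
#' @param m 4x4 numeric matrix.
#' @return `homogeneous_transform`.
#' @export
as_transform <- function(m) {
  m <- unclass(m)
  stopifnot(is.matrix(m), all(dim(m) == c(4L, 4L)))
  m[4, ] <- c(0, 0, 0, 1)
  class(m) <- c("homogeneous_transform", class(m))
  m
}

#' @rdname homogeneous_transform
#' @export
transform_identity <- function() as_transform(diag(4))

#' @rdname homogeneous_transform
#' @export
rigid_transform <- function(R, t = c(0, 0, 0)) {
  check_rotation(R)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- t
  as_transform(m)
}

#' @rdname homogeneous_transform
#' @export
similarity_transform <- function(s, R, t = c(0, 0, 0)) {
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
    stop("scale `s` must be a positive scalar")
  check_rotation(R)
  m <- diag(4)
  m[1:3, 1:3] <- s * R
  m[1:3, 4] <- t
  as_transform(m)
}

check_rotation <- function(R, tol = 1e-6) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  if (max(abs(crossprod(R) - diag(3))) > tol || det(R) < 0)
    stop("`R` must be orthonormal with determinant +1")
  invisible(R)
}

#' @export
print.homogeneous_transform <- function(x, digits = 4, ...) {
  cat("<homogeneous_transform>\n")
  print(round(unclass(x), digits))
  dec <- try(decompose_similarity(x), silent = TRUE)
  if (!inherits(dec, "try-error"))
    cat(sprintf("scale %.4f, rotation angle %.2f deg, |t| = %.2f mm\n",
                dec$scale, rotation_angle(dec$rotation),
                sqrt(sum(dec$translation^2))))
  invisible(x)
}

#' Apply a homogeneous transform to points
#'
#' @param t a 4x4 `homogeneous_transform` (or plain 4x4 matrix).
#' @param pts n x 3 matrix of points `(x, y, z)` in mm; point-cloud attributes
#'   (provenance) are preserved.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(t, pts) {
  prov <- attr(pts, "provenance")
  pts <- rbind(pts)
  out <- pts %*% t(t[1:3, 1:3, drop = FALSE])
  out <- sweep(out, 2, t[1:3, 4], "+")
  colnames(out) <- c("x", "y", "z")
  attr(out, "provenance") <- prov
  out
}

#' Compose transforms in order of application
#'
#' `compose_transforms(first, list(A, B))` returns the single matrix whose
#' action equals applying `first`, then `A`, then `B`: under the column-vector
#' convention this is `B %*% A %*% first`.
#'
#' @param first 4x4 transform applied first.
#' @param rest list of 4x4 transforms applied afterwards, in order.
#' @return 4x4 `homogeneous_transform`.
#' @export
compose_transforms <- function(first, rest = list()) {
  if (is.matrix(rest)) rest <- list(rest)
  m <- Reduce(function(acc, nxt) nxt %*% acc, rest, init = unclass(first))
  as_transform(m)
}

#' Invert a homogeneous transform
#' @param t 4x4 transform.
#' @return 4x4 `homogeneous_transform`.
#' @export
invert_transform <- function(t) as_transform(solve(unclass(t)))

#' Decompose a similarity transform into scale, rotation and translation
#'
#' The linear block of a similarity transform is `s * R`; the scale is
#' recovered as `det(A)^(1/3)` and the rotation is projected onto SO(3) by
#' polar decomposition (for exact similarity inputs the projection is the
#' identity operation).
#'
#' @param t 4x4 similarity (or rigid) transform.
#' @return list with `scale`, `rotation` (3x3), `translation` (length 3).
#' @export
decompose_similarity <- function(t) {
  A <- unclass(t)[1:3, 1:3]
  dt <- det(A)
  if (!is.finite(dt) || dt <= 0)
    stop("linear block has non-positive determinant; not a similarity transform")
  s <- dt^(1 / 3)
  sv <- svd(A / s)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) { sv$u[, 3] <- -sv$u[, 3]; R <- sv$u %*% t(sv$v) }
  list(scale = s, rotation = R, translation = unclass(t)[1:3, 4])
}

#' Rotation angle of a rotation matrix, in degrees
#' @param R 3x3 rotation matrix.
#' @return angle in `[0, 180]` degrees.
#' @export
rotation_angle <- function(R) {
  ca <- (sum(diag(R)) - 1) / 2
  acos(pmin(pmax(ca, -1), 1)) * 180 / pi
}

#' Rotation matrix about an arbitrary axis (degrees)
#'
#' Rodrigues rotation by `angle` degrees about the direction `axis`.
#'
#' @param axis length-3 direction (need not be unit).
#' @param angle degrees.
#' @return 3x3 rotation matrix.
#' @export
axis_angle_rotation <- function(axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# rigid spin about `axis` through `center`
spin_transform <- function(axis, angle, center) {
  R <- axis_angle_rotation(axis, angle)
  rigid_transform(R, as.numeric(center - R %*% center))
}

#' Rotation matrix from Euler angles (degrees)
#'
#' Intrinsic z-y-x convention: yaw about z (axial), then pitch about y, then
#' roll about x; `R = Rz(yaw) %*% Ry(pitch) %*% Rx(roll)`.
#'
#' @param yaw,pitch,roll angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_rotation <- function(yaw = 0, pitch = 0, roll = 0) {
  r <- pi / 180
  cz <- cos(yaw * r); sz <- sin(yaw * r)
  cy <- cos(pitch * r); sy <- sin(pitch * r)
  cx <- cos(roll * r); sx <- sin(roll * r)
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Rz %*% Ry %*% Rx
}
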