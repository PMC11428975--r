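#' Closed-form rigid fit between paired point sets
#'
#' Least-squares rigid transform (rotation + translation) mapping `moving`
#' onto `target`, with points paired by row index. The default solver is the
#' quaternion eigen-method (the largest eigenvector of the 4x4 profile matrix
#' gives the optimal rotation); `method = "svd"` uses orthogonal Procrustes
#' with a determinant guard. Both guarantee det(R) = +1 — a mirror pair is
#' fitted by the best proper rotation, never a reflection.
#'
#' @param moving,target n x 3 matrices, n >= 3, paired by index.
#' @param weights optional nonnegative per-pair weights.
#' @param method `"quaternion"` or `"svd"`.
#' @return 4x4 `homogeneous_transform` (rigid).
#' @export
fit_rigid <- function(moving, target, weights = NULL,
                      method = c("quaternion", "svd")) {
  method <- match.arg(method)
  pr <- prepare_pairs(moving, target, weights)
  S <- crossprod(pr$xc * pr$w, pr$yc)       # 3x3 profile, S[a,b] = sum w x_a y_b
  R <- if (method == "quaternion") rotation_from_profile_quat(S)
       else rotation_from_profile_svd(S)
  t <- pr$my - R %*% pr$mx
  rigid_transform(R, as.numeric(t))
}

#' Closed-form similarity fit between paired point sets
#'
#' Least-squares uniform-scale similarity transform (`s * R x + t`) mapping
#' `moving` onto `target`, points paired by row index (the Umeyama estimator,
#' with the determinant guard for degenerate/reflected configurations).
#'
#' @inheritParams fit_rigid
#' @return 4x4 `homogeneous_transform` (similarity), scale > 0.
#' @export
fit_similarity <- function(moving, target, weights = NULL) {
  pr <- prepare_pairs(moving, target, weights)
  var_x <- sum(pr$w * pr$xc^2)
  if (var_x < 1e-24) stop("moving set has zero variance; scale is undefined")
  S <- crossprod(pr$xc * pr$w, pr$yc)
  sv <- svd(S)
  d <- sign(det(sv$u) * det(sv$v))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)               # maps moving -> target
  s <- sum(sv$d * c(1, 1, d)) / var_x
  if (s <= 0) stop("fitted scale is non-positive; degenerate configuration")
  t <- pr$my - s * R %*% pr$mx
  similarity_transform(s, R, as.numeric(t))
}

prepare_pairs <- function(moving, target, weights = NULL) {
  moving <- rbind(moving); target <- rbind(target)
  if (nrow(moving) != nrow(target))
    stop("moving and target must have the same number of points")
  n <- nrow(moving)
  if (n < 3L) stop("at least 3 point pairs are required")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) <= 0)
    stop("`weights` must be nonnegative with positive sum")
  w <- w / sum(w)
  mx <- colSums(moving[, 1:3, drop = FALSE] * w)
  my <- colSums(target[, 1:3, drop = FALSE] * w)
  xc <- sweep(moving[, 1:3, drop = FALSE], 2, mx)
  yc <- sweep(target[, 1:3, drop = FALSE], 2, my)
  # collinear (rank < 2) moving sets leave the rotation unidentified
  if (svd(xc * sqrt(w))$d[2] < 1e-9 * max(1, svd(xc * sqrt(w))$d[1]))
    stop("degenerate (collinear) point configuration")
  list(xc = xc, yc = yc, mx = mx, my = my, w = w)
}

# Optimal rotation from the 3x3 profile matrix S[a,b] = sum_i w_i x_ia y_ib,
# via the largest eigenvector of Horn's symmetric 4x4 matrix.
rotation_from_profile_quat <- function(S) {
  tr <- S[1, 1] + S[2, 2] + S[3, 3]
  N <- matrix(0, 4, 4)
  N[1, 1] <- tr
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  quat_to_rotation(q)
}

rotation_from_profile_svd <- function(S) {
  sv <- svd(S)
  D <- diag(c(1, 1, sign(det(sv$u) * det(sv$v))))
  sv$v %*% D %*% t(sv$u)
}

quat_to_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2))
}
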