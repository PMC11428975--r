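#' Contour extraction parameters
#'
#' Parameters of the slice-wise exterior-contour pipeline: binarize, fill the
#' enclosed region, pad the canvas, remove impurities by morphological opening,
#' keep the largest connected component, crop back, and take the boundary as
#' (body mask) minus (eroded body mask). Structuring elements are Euclidean
#' discs; with `erosion_radius = 1` the disc is the 4-neighbour cross, so the
#' contour is exactly the set of body pixels with a non-body 4-neighbour.
#'
#' @param threshold binarization threshold; `NULL` picks a default by
#'   intensity kind (-300 for `ct_hu`, per-slice Otsu otherwise).
#' @param opening_radius disc radius (px) of the opening that removes
#'   impurities (e.g. headrest fragments) smaller than the element.
#' @param erosion_radius disc radius (px) of the final erosion; equals the
#'   contour thickness.
#' @param pad canvas padding (px) applied before filling/opening so border
#'   objects are handled; default `opening_radius + 1`.
#' @param min_area components smaller than this (px) are treated as empty
#'   slices rather than bodies.
#' @return list of class `contour_params`.
#' @export
contour_params <- function(threshold = NULL, opening_radius = 3,
                           erosion_radius = 1, pad = opening_radius + 1,
                           min_area = 64) {
  stopifnot(opening_radius >= 1, erosion_radius >= 1, pad >= 1, min_area >= 0)
  structure(list(threshold = threshold, opening_radius = opening_radius,
                 erosion_radius = erosion_radius, pad = pad,
                 min_area = min_area), class = "contour_params")
}

#' Binarize one slice at a threshold
#'
#' @param slice 2D numeric matrix.
#' @param threshold finite scalar; the mask is true where intensity >=
#'   threshold (boundary inclusive).
#' @return logical matrix of the same shape.
#' @export
binarize_slice <- function(slice, threshold) {
  if (!is.finite(threshold)) stop("`threshold` must be finite")
  slice >= threshold
}

disc_brush <- function(r) {
  d <- seq(-r, r)
  k <- outer(d^2, d^2, "+") <= r^2 + 1e-9
  storage.mode(k) <- "double"
  k
}

otsu_threshold <- function(x, levels = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1] + 1)     # constant slice: nothing above
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mu_t <- mu[levels]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  br[which.max(sb2) + 1L]
}

pad_canvas <- function(mask, pad) {
  d <- dim(mask)
  out <- matrix(FALSE, d[1] + 2 * pad, d[2] + 2 * pad)
  out[pad + seq_len(d[1]), pad + seq_len(d[2])] <- mask
  out
}

crop_canvas <- function(mask, pad, d) {
  mask[pad + seq_len(d[1]), pad + seq_len(d[2])]
}

fill_holes <- function(mask) {
  f <- EBImage::fillHull(matrix(as.numeric(mask), nrow(mask)))
  f > 0
}

morph_open <- function(mask, r) {
  m <- matrix(as.numeric(mask), nrow(mask))
  EBImage::opening(m, disc_brush(r)) > 0
}

morph_erode <- function(mask, r) {
  m <- matrix(as.numeric(mask), nrow(mask))
  EBImage::erode(m, disc_brush(r)) > 0
}

largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

#' Body mask of one slice
#'
#' Binarize, pad, fill enclosed holes, open with a disc to drop impurities,
#' keep the largest connected component and crop back. Returns an empty mask
#' (with attribute `empty = TRUE`) rather than an error when the slice holds
#' no body of at least `min_area` pixels.
#'
#' @param slice 2D numeric matrix.
#' @param params see [contour_params()]; a `NULL` threshold uses per-slice
#'   Otsu here (use [surface_from_volume()] for intensity-kind defaults).
#' @return logical body mask.
#' @export
extract_body_mask <- function(slice, params = contour_params()) {
  thr <- params$threshold %||% otsu_threshold(slice)
  mask <- binarize_slice(slice, thr)
  d <- dim(mask)
  m <- pad_canvas(mask, params$pad)
  m <- fill_holes(m)
  m <- morph_open(m, params$opening_radius)
  m <- largest_component(m)
  m <- crop_canvas(m, params$pad, d)
  if (sum(m) < params$min_area) {
    m <- matrix(FALSE, d[1], d[2])
    attr(m, "empty") <- TRUE
  }
  m
}

#' Exterior contour of one slice
#'
#' The body mask minus its erosion by a disc of `erosion_radius`: a closed
#' boundary ring whose thickness equals the erosion radius. Empty slices give
#' an empty mask flagged with attribute `empty = TRUE`, not an error.
#'
#' @inheritParams extract_body_mask
#' @return logical contour mask.
#' @export
extract_exterior_contour <- function(slice, params = contour_params()) {
  body <- extract_body_mask(slice, params)
  if (isTRUE(attr(body, "empty"))) return(body)
  out <- body & !morph_erode(body, params$erosion_radius)
  out
}

#' Exterior surface cloud of a volume
#'
#' Runs [extract_exterior_contour()] on every slice and assembles the contour
#' voxels into a 3D point cloud in physical coordinates (mm), with per-point
#' provenance `(slice, row, col)` kept as an attribute.
#'
#' @param v a `volume`.
#' @param params see [contour_params()]. A `NULL` threshold defaults to -300
#'   for `ct_hu` volumes (air/body boundary in Hounsfield units) and per-slice
#'   Otsu for `mr_arbitrary`/`photo_grey`.
#' @return n x 3 matrix of points `(x, y, z)` with attribute `provenance`
#'   (n x 3 integer matrix, 1-based `(slice, row, col)`).
#' @export
surface_from_volume <- function(v, params = contour_params()) {
  stopifnot(inherits(v, "volume"))
  if (is.null(params$threshold) && v$intensity_kind == "ct_hu")
    params$threshold <- -300
  nz <- dim(v$data)[1]
  pts <- vector("list", nz)
  prov <- vector("list", nz)
  for (i in seq_len(nz)) {
    cm <- extract_exterior_contour(v$data[i, , ], params)
    if (!any(cm)) next
    rc <- which(cm, arr.ind = TRUE)
    prov[[i]] <- cbind(slice = i, row = rc[, 1], col = rc[, 2])
    pts[[i]] <- voxel_to_world(v, prov[[i]])
  }
  prov <- do.call(rbind, prov)
  if (is.null(prov)) stop("no body surface found in any slice")
  cloud <- do.call(rbind, pts[!vapply(pts, is.null, logical(1))])
  colnames(cloud) <- c("x", "y", "z")
  attr(cloud, "provenance") <- prov
  cloud
}
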