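#' Map atlas ROI labels into subject space
#'
#' Pull-resampling label propagation: each subject voxel centre is sent through
#' the inverse of the atlas-to-subject transform and looked up in the atlas
#' label grid (nearest neighbour); the mask is true where the looked-up label
#' belongs to the requested ROI. Voxels mapping outside the atlas are false.
#'
#' @param labels atlas [new_label_volume()].
#' @param roi ROI ids (integer) or names (character) present in the label
#'   table.
#' @param transform 4x4 atlas-to-subject homogeneous transform.
#' @param subject subject `volume` (defines the output grid).
#' @return list of class `roi_mask`: `mask` (3D logical, subject grid),
#'   `roi_name`, `spacing`, `origin`.
#' @export
map_roi <- function(labels, roi, transform, subject) {
  stopifnot(inherits(labels, "label_volume"), inherits(subject, "volume"))
  if (is.character(roi)) {
    unknown <- setdiff(roi, labels$table$name)
    if (length(unknown))
      stop("unknown ROI name(s) ", paste(unknown, collapse = ", "),
           "; available: ", paste(labels$table$name, collapse = ", "))
    ids <- labels$table$id[labels$table$name %in% roi]
    roi_name <- paste(roi, collapse = "+")
  } else {
    ids <- as.integer(roi)
    unknown <- setdiff(ids, labels$table$id)
    if (length(unknown))
      stop("unknown ROI id(s) ", paste(unknown, collapse = ", "),
           "; available: ", paste(labels$table$id, collapse = ", "))
    roi_name <- paste(labels$table$name[match(ids, labels$table$id)],
                      collapse = "+")
  }
  d <- dim(subject$data)
  g <- world_grids(d, subject$spacing, subject$origin)
  src <- apply_transform(invert_transform(transform), cbind(g$x, g$y, g$z))
  lab <- interp_volume(labels, src, fill = 0)
  mask <- array(lab %in% ids, d)
  if (!any(mask))
    warning("mapped ROI '", roi_name, "' is empty on the subject grid")
  structure(list(mask = mask, roi_name = roi_name,
                 spacing = subject$spacing, origin = subject$origin),
            class = "roi_mask")
}

#' ROI mask directly from a label volume (no transform)
#'
#' @param labels a [new_label_volume()].
#' @param roi ids or names, as in [map_roi()].
#' @return `roi_mask` on the label grid.
#' @export
roi_mask_from_labels <- function(labels, roi) {
  subject <- new_volume(array(0, dim(labels$labels)), labels$spacing,
                        labels$origin)
  ids <- if (is.character(roi)) labels$table$id[labels$table$name %in% roi]
         else as.integer(roi)
  structure(list(mask = array(labels$labels %in% ids, dim(labels$labels)),
                 roi_name = paste(roi, collapse = "+"),
                 spacing = labels$spacing, origin = labels$origin),
            class = "roi_mask")
}

#' Per-slice recall of a mapped ROI against a reference ROI
#'
#' For every axial slice where the reference (expert-annotated) ROI has
#' positive area, recall = |mapped intersect reference| / |reference|, with
#' areas counted in voxels. Slices without reference area are skipped;
#' `slice_range` optionally restricts the evaluation.
#'
#' @param mapped,reference `roi_mask` objects (or 3D logical arrays) on the
#'   same grid.
#' @param slice_range optional `c(first, last)` 1-based slice indices.
#' @return data.frame of class `recall_series` with columns `slice`, `recall`.
#' @export
recall_per_slice <- function(mapped, reference, slice_range = NULL) {
  m <- if (inherits(mapped, "roi_mask")) mapped$mask else mapped
  r <- if (inherits(reference, "roi_mask")) reference$mask else reference
  if (!identical(dim(m), dim(r)))
    stop("mapped and reference grids are not congruent")
  slices <- seq_len(dim(r)[1])
  if (!is.null(slice_range))
    slices <- slices[slices >= slice_range[1] & slices <= slice_range[2]]
  area_ref <- vapply(slices, function(i) sum(r[i, , ]), numeric(1))
  keep <- area_ref > 0
  if (!any(keep)) stop("no slice with positive reference ROI area")
  slices <- slices[keep]
  rec <- vapply(seq_along(slices), function(k) {
    i <- slices[k]
    sum(m[i, , ] & r[i, , ]) / area_ref[keep][k]
  }, numeric(1))
  structure(data.frame(slice = slices, recall = rec),
            class = c("recall_series", "data.frame"))
}

#' Summary statistics of a recall series
#'
#' Maximum, minimum, median (middle order statistic; mean of the middle two
#' for even n) and mean of the per-slice recall values, plus the normal 95%
#' confidence interval `mean +/- 1.96 * s / sqrt(n)` with `s` the sample
#' (n - 1) standard deviation. The interval is omitted for n < 2.
#'
#' @param series a `recall_series` (from [recall_per_slice()]) or a numeric
#'   vector of recall values in `[0, 1]`.
#' @return list of class `recall_summary`: `max`, `min`, `median`, `mean`,
#'   `ci95` (`c(lo, hi)` or `NULL`), `n`.
#' @export
summarize_recall <- function(series) {
  x <- if (is.data.frame(series)) series$recall else as.numeric(series)
  if (!length(x)) stop("empty recall series")
  if (any(x < 0 | x > 1)) stop("recall values must lie in [0, 1]")
  n <- length(x)
  ci <- if (n >= 2) mean(x) + c(-1, 1) * 1.96 * sd(x) / sqrt(n) else NULL
  structure(list(max = max(x), min = min(x), median = median(x),
                 mean = mean(x), ci95 = ci, n = n),
            class = "recall_summary")
}

#' @export
print.recall_summary <- function(x, ...) {
  cat(sprintf("<recall_summary> n = %d slices\n", x$n))
  cat(sprintf("  max %.2f%%  min %.2f%%  median %.2f%%  mean %.2f%%\n",
              100 * x$max, 100 * x$min, 100 * x$median, 100 * x$mean))
  if (!is.null(x$ci95))
    cat(sprintf("  95%% CI [%.3f%%, %.3f%%]\n", 100 * x$ci95[1],
                100 * x$ci95[2]))
  invisible(x)
}
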