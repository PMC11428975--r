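#' Read a volume from NIfTI or a PNG slice stack
#'
#' NIfTI files (`.nii`, `.nii.gz`) carry their own spacing; a directory is read
#' as a stack of equally-sized greyscale PNG slices, ordered by ascending
#' lexicographic filename, with spacing taken from a JSON sidecar
#' (`spacing.json` with fields `dz`, `dy`, `dx`) in the same directory.
#' `spacing_override`, when given, wins over header and sidecar.
#'
#' NIfTI arrays are stored `(x, y, z)` on disk and are permuted to the package
#' convention `(slice, row, col)` = `(z, y, x)` on read.
#'
#' @param path a NIfTI file or a directory of PNG slices.
#' @param spacing_override optional `(dz, dy, dx)` in mm.
#' @param intensity_kind see [new_volume()]; defaults to `"photo_grey"` for PNG
#'   stacks and `"mr_arbitrary"` for NIfTI.
#' @return a [new_volume()] object.
#' @export
read_volume <- function(path, spacing_override = NULL, intensity_kind = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no PNG slices found in ", path)
    slices <- lapply(files, function(f) {
      m <- png::readPNG(f)
      if (length(dim(m)) == 3L) m <- m[, , 1]  # first channel of RGB(A) greys
      m
    })
    dims <- vapply(slices, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("inconsistent slice dimensions in PNG stack: ",
           paste(unique(apply(dims, 2, paste, collapse = "x")), collapse = ", "))
    spacing <- spacing_override
    sidecar <- file.path(path, "spacing.json")
    if (is.null(spacing)) {
      if (!file.exists(sidecar))
        stop("PNG stack has no spacing: provide ", sidecar,
             " (fields dz, dy, dx in mm) or `spacing_override`")
      sj <- jsonlite::read_json(sidecar)
      if (!all(c("dz", "dy", "dx") %in% names(sj)))
        stop("spacing sidecar must name dz, dy and dx")
      spacing <- c(sj$dz, sj$dy, sj$dx)
    }
    data <- array(0, c(length(slices), dims[1, 1], dims[2, 1]))
    for (i in seq_along(slices)) data[i, , ] <- slices[[i]]
    return(new_volume(data, spacing,
                      intensity_kind = intensity_kind %||% "photo_grey"))
  }
  if (!file.exists(path)) stop("no such file or directory: ", path)
  img <- RNifti::readNifti(path)
  arr <- aperm(array(as.numeric(img), dim(img)), c(3, 2, 1))
  pd <- RNifti::pixdim(img)                 # (dx, dy, dz)
  spacing <- spacing_override %||% rev(pd)
  orig <- tryCatch(unname(RNifti::xform(img)[1:3, 4]),
                   error = function(e) c(0, 0, 0))
  new_volume(arr, spacing, orig,
             intensity_kind = intensity_kind %||% "mr_arbitrary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a volume to NIfTI
#'
#' Integer grids round-trip bit-exactly (int32 on disk); floating grids are
#' stored as float64. Spacing is written to the NIfTI pixdim.
#'
#' @param v a `volume` or `label_volume`.
#' @param path output `.nii` or `.nii.gz` file.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  g <- grid_of(v)
  integral <- is.integer(g) || all(g == round(g))
  if (integral) storage.mode(g) <- "integer"
  img <- RNifti::asNifti(aperm(g, c(3, 2, 1)))
  RNifti::pixdim(img) <- rev(v$spacing)     # (dx, dy, dz)
  m <- diag(c(rev(v$spacing), 1))
  m[1:3, 4] <- v$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  ok <- tryCatch({
    RNifti::writeNifti(img, path, datatype = if (integral) "int32" else "double")
    TRUE
  }, error = function(e) stop("cannot write volume to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read a label volume (NIfTI labels + CSV name table)
#'
#' @param path integer NIfTI file of label ids.
#' @param table_path two-column CSV `id,name`.
#' @inheritParams read_volume
#' @return a [new_label_volume()] object.
#' @export
read_label_volume <- function(path, table_path, spacing_override = NULL) {
  v <- read_volume(path, spacing_override)
  tab <- utils::read.csv(table_path, stringsAsFactors = FALSE)
  arr <- v$data
  storage.mode(arr) <- "integer"
  new_label_volume(arr, tab, v$spacing, v$origin)
}

#' Write a label volume (NIfTI labels + CSV name table)
#'
#' @param lv a `label_volume`.
#' @param path output NIfTI file.
#' @param table_path output CSV; default replaces the NIfTI extension with
#'   `_labels.csv`.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(lv, path,
                               table_path = sub("\\.nii(\\.gz)?$", "_labels.csv", path)) {
  write_volume(lv, path)
  utils::write.csv(lv$table, table_path, row.names = FALSE)
  invisible(path)
}
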