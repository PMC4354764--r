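sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Read a dynamic series from NIfTI
#'
#' Reads a `.nii`/`.nii.gz` file holding a single-slice dynamic series. A 3-D
#' volume is interpreted as `H x W x T`; a 4-D volume as
#' `H x W x slices x T`, in which case `slice` (1-based) must be given.
#' Acquisition times are taken from a sidecar JSON file (same path with a
#' `.json` extension, field `"times"`, seconds), from the `times` argument,
#' or default to 80 s spacing starting at 0.
#'
#' @param path path to the NIfTI file.
#' @param times optional numeric vector of acquisition times (seconds).
#' @param slice optional 1-based slice index for 4-D volumes.
#' @param case_id case label; defaults to the file name.
#' @return A [dce_series()].
#' @export
read_dce_series <- function(path, times = NULL, slice = NULL, case_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vol <- as.array(RNifti::readNifti(path))
  nd <- length(dim(vol))
  if (nd == 4L) {
    if (is.null(slice))
      stop("4-D volume: a 1-based `slice` index is required", call. = FALSE)
    vol <- vol[, , slice, , drop = TRUE]
  } else if (nd != 3L) {
    stop("expected a 3-D (H x W x T) or 4-D NIfTI volume", call. = FALSE)
  }
  if (is.null(times)) {
    sj <- sidecar_path(path)
    if (file.exists(sj)) {
      times <- jsonlite::fromJSON(sj)$times
      if (is.null(times))
        stop("sidecar JSON lacks a `times` field: ", sj, call. = FALSE)
    }
  }
  if (is.null(case_id))
    case_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  dce_series(aperm(vol, c(3, 1, 2)), times = times, case_id = case_id)
}

#' Write a dynamic series to NIfTI (with a times sidecar)
#'
#' @param series a [dce_series()].
#' @param path output `.nii`/`.nii.gz` path; a sidecar JSON with the
#'   acquisition times is written next to it.
#' @return `path`, invisibly.
#' @export
write_dce_series <- function(series, path) {
  stopifnot(inherits(series, "dce_series"))
  RNifti::writeNifti(RNifti::asNifti(aperm(series$data, c(2, 3, 1))), path)
  jsonlite::write_json(list(times = series$times), sidecar_path(path),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read/write ROI polygons as JSON
#'
#' The on-disk format is `{"vertices": [[row, col], ...]}` with 0-based pixel
#' coordinates.
#'
#' @param path JSON file path.
#' @return `read_roi_json()` returns a [roi_polygon()].
#' @export
read_roi_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$vertices)) stop("ROI JSON lacks `vertices`", call. = FALSE)
  roi_polygon(obj$vertices)
}

#' @rdname read_roi_json
#' @param poly a [roi_polygon()].
#' @export
write_roi_json <- function(poly, path) {
  stopifnot(inherits(poly, "roi_polygon"))
  jsonlite::write_json(list(vertices = unname(poly$vertices)), path,
                       digits = NA)
  invisible(path)
}

#' Read/write binary masks as NIfTI
#'
#' Masks are stored as 0/1 integer images; the write/read round trip is
#' lossless.
#'
#' @param path NIfTI path.
#' @param kind mask kind to tag on read (`"roi"` or `"lesion"`).
#' @return `read_mask_nifti()` returns a [mask_image()].
#' @export
read_mask_nifti <- function(path, kind = "lesion") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- as.array(RNifti::readNifti(path))
  if (length(dim(m)) != 2L) stop("mask NIfTI must be 2-D", call. = FALSE)
  mask_image(m != 0, kind = kind)
}

#' @rdname read_mask_nifti
#' @param mask a [mask_image()].
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "mask_image"))
  img <- RNifti::asNifti(matrix(as.integer(mask$data), nrow = nrow(mask$data)),
                         datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read/write parameter maps as NIfTI
#'
#' Parameter maps are `H x W` float images; pixels where a parameter is
#' undefined hold NaN, which the round trip preserves.
#'
#' @param path NIfTI path.
#' @return `read_map_nifti()` returns a numeric matrix.
#' @export
read_map_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- as.array(RNifti::readNifti(path))
  if (length(dim(m)) != 2L) stop("map NIfTI must be 2-D", call. = FALSE)
  m
}

#' @rdname read_map_nifti
#' @param map numeric `H x W` matrix (NaN allowed).
#' @export
write_map_nifti <- function(map, path) {
  stopifnot(is.matrix(map))
  RNifti::writeNifti(RNifti::asNifti(map, datatype = "double"), path)
  invisible(path)
}

#' Write a cohort or result table to CSV
#'
#' Comma-separated, header row, UTF-8; missing values written as empty
#' fields.
#'
#' @param x data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = c("", "NA", "NaN"))
}
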