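#' Binary mask image
#'
#' A `H x W` logical matrix tagging pixels of interest, with a `kind`
#' attribute distinguishing user ROIs from segmented lesion footprints.
#' Lesion masks are always subsets of the ROI they were derived from.
#'
#' @param data logical (or 0/1 numeric) matrix.
#' @param kind `"roi"` or `"lesion"`.
#' @return An object of class `mask_image`.
#' @export
mask_image <- function(data, kind = c("roi", "lesion")) {
  kind <- match.arg(kind)
  if (!is.matrix(data)) stop("`data` must be a matrix", call. = FALSE)
  m <- matrix(as.logical(data), nrow = nrow(data))
  if (any(is.na(m))) stop("mask contains NA", call. = FALSE)
  structure(list(data = m, kind = kind), class = "mask_image")
}

#' @export
print.mask_image <- function(x, ...) {
  cat(sprintf("<mask_image kind=%s>  %d x %d, %d pixels set\n",
              x$kind, nrow(x$data), ncol(x$data), sum(x$data)))
  invisible(x)
}

#' Number of pixels set in a mask
#' @param mask a `mask_image`.
#' @return Integer count.
#' @export
mask_area <- function(mask) sum(mask$data)

#' Dice overlap coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)`; 1 for identical non-empty masks, NaN if both
#' masks are empty.
#'
#' @param a,b `mask_image` objects on the same grid.
#' @return Numeric in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(all(dim(a$data) == dim(b$data)))
  2 * sum(a$data & b$data) / (sum(a$data) + sum(b$data))
}
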