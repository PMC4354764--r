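#' Region-of-interest polygon
#'
#' An ordered list of (row, col) vertices in 0-based pixel coordinates
#' (row-major; pixel centers sit at integer coordinates). The polygon is
#' closed implicitly (last vertex connects back to the first).
#'
#' @param vertices numeric matrix or data frame with two columns (row, col),
#'   at least 3 vertices.
#' @return An object of class `roi_polygon`.
#' @examples
#' roi_polygon(rbind(c(1, 1), c(1, 6), c(6, 6), c(6, 1)))
#' @export
roi_polygon <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 3L)
    stop("polygon needs >= 3 (row, col) vertices", call. = FALSE)
  if (any(!is.finite(v))) stop("polygon vertices must be finite", call. = FALSE)
  storage.mode(v) <- "double"
  colnames(v) <- c("row", "col")
  structure(list(vertices = v), class = "roi_polygon")
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("<roi_polygon> %d vertices\n", nrow(x$vertices)))
  invisible(x)
}

# Even-odd point-in-polygon for pixel-center points; points lying exactly on
# a polygon edge count as inside.
pip_even_odd <- function(pr, pc, vr, vc) {
  n <- length(vr)
  inside <- rep(FALSE, length(pr))
  on_edge <- rep(FALSE, length(pr))
  eps <- 1e-12
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    r1 <- vr[j]; c1 <- vc[j]; r2 <- vr[i]; c2 <- vc[i]
    # boundary: zero cross-product and within the segment's bounding box
    cross <- (r2 - r1) * (pc - c1) - (c2 - c1) * (pr - r1)
    on_seg <- abs(cross) <= eps * (1 + abs(cross)) &
      pr >= pmin(r1, r2) - eps & pr <= pmax(r1, r2) + eps &
      pc >= pmin(c1, c2) - eps & pc <= pmax(c1, c2) + eps
    on_edge <- on_edge | on_seg
    # ray cast towards +col
    crosses <- ((r1 > pr) != (r2 > pr)) &
      (pc < (c2 - c1) * (pr - r1) / (r2 - r1) + c1)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' Rasterize a polygon onto a pixel grid
#'
#' A pixel is included iff its center (at integer (row, col) coordinates)
#' lies inside the polygon by the even-odd rule; centers exactly on the
#' boundary are counted as inside.
#'
#' @param poly a [roi_polygon()].
#' @param shape integer vector `c(H, W)`.
#' @return A [mask_image()] of kind `"roi"`.
#' @examples
#' m <- rasterize_roi(roi_polygon(rbind(c(1, 1), c(1, 6), c(6, 6), c(6, 1))),
#'                    c(8, 8))
#' mask_area(m) # 36
#' @export
rasterize_roi <- function(poly, shape) {
  stopifnot(inherits(poly, "roi_polygon"), length(shape) == 2L)
  h <- shape[1]; w <- shape[2]
  g <- expand.grid(row = 0:(h - 1), col = 0:(w - 1))
  inside <- pip_even_odd(g$row, g$col, poly$vertices[, 1], poly$vertices[, 2])
  if (!any(inside))
    stop("empty ROI: polygon covers no pixel centers", call. = FALSE)
  mask_image(matrix(inside, nrow = h), kind = "roi")
}
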