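#' Square structuring element for binary morphology
#'
#' An all-ones `size x size` element expressed as (drow, dcol) offsets. For
#' even sizes there is no central pixel; the origin is fixed at grid position
#' `(floor((size - 1) / 2), floor((size - 1) / 2))` (0-based), so the default
#' 4 x 4 element has offsets `{-1, 0, 1, 2}` in each axis. Erosion and
#' dilation both use these offsets directly (dilation is the Minkowski sum,
#' not the reflected sum), which makes `dilate(erode(x))` the algebraic
#' opening.
#'
#' @param size side length in pixels (default 4).
#' @return An object of class `structuring_element` with an `offsets` matrix.
#' @export
structuring_element <- function(size = 4L) {
  size <- as.integer(size)
  if (size < 1L) stop("structuring element size must be >= 1", call. = FALSE)
  origin <- (size - 1L) %/% 2L
  rng <- (0:(size - 1L)) - origin
  off <- as.matrix(expand.grid(drow = rng, dcol = rng))
  structure(list(offsets = off, size = size), class = "structuring_element")
}

#' Segmentation configuration
#'
#' @param post_phase_index 1-based post-contrast phase used for the
#'   subtraction image (default 3, the third post-contrast phase).
#' @param se_size structuring-element side length (default 4).
#' @param histogram_bins number of equal-width bins for Otsu (default 256).
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(post_phase_index = 3L, se_size = 4L,
                                histogram_bins = 256L) {
  if (post_phase_index < 1L)
    stop("post_phase_index must be >= 1 (post-contrast)", call. = FALSE)
  structure(list(post_phase_index = as.integer(post_phase_index),
                 se_size = as.integer(se_size),
                 histogram_bins = as.integer(histogram_bins)),
            class = "segmentation_config")
}

#' Post-contrast minus pre-contrast subtraction image
#'
#' Signed difference `data[post_phase_index] - data[pre]`; negative values
#' (pixels brighter before contrast) are preserved, no clamping.
#'
#' @param series a [dce_series()].
#' @param post_phase_index 1-based post-contrast phase (frame
#'   `post_phase_index + 1` of the stack).
#' @return Numeric `H x W` matrix.
#' @export
subtraction_image <- function(series, post_phase_index = 3L) {
  nt <- dim(series$data)[1]
  if (post_phase_index < 1L || post_phase_index > nt - 1L)
    stop("post_phase_index out of range: must be in 1..", nt - 1L, call. = FALSE)
  series$data[post_phase_index + 1L, , ] - series$data[1L, , ]
}

#' Otsu threshold over a sample of intensities
#'
#' Bins the values into `bins` equal-width bins over `[min, max]` and returns
#' the internal bin edge that maximizes the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` of the split `{<= t}` vs `{> t}` (class moments
#' computed from the raw values, which a bin-edge split partitions exactly).
#' Ties go to the smallest edge.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param bins number of histogram bins (default 256).
#' @return The threshold, a scalar; foreground is the `> t` class.
#' @export
otsu_threshold <- function(values, bins = 256L) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("non-finite values", call. = FALSE)
  lo <- min(values); hi <- max(values)
  if (lo == hi)
    stop("degenerate input: all values identical, no threshold exists",
         call. = FALSE)
  edges <- seq(lo, hi, length.out = bins + 1L)
  idx <- findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- tabulate(idx, nbins = bins)
  sums <- vapply(seq_len(bins), function(b) sum(values[idx == b]), numeric(1))
  n <- length(values); total <- sum(values)
  c_cnt <- cumsum(cnt)[-bins]   # counts in {<= edge b+1}
  c_sum <- cumsum(sums)[-bins]
  w0 <- c_cnt / n
  w1 <- 1 - w0
  valid <- c_cnt > 0 & c_cnt < n
  mu0 <- c_sum / c_cnt
  mu1 <- (total - c_sum) / (n - c_cnt)
  bcv <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  edges[which.max(bcv) + 1L]
}

shift_mask <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 - dr):min(h, h - dr)
  cs <- max(1, 1 - dc):min(w, w - dc)
  if (length(rs) > 0 && length(cs) > 0)
    out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

#' Binary erosion and dilation
#'
#' Erosion: a pixel `p` survives iff every offset `o` of the element lands
#' inside the image and on a set pixel (`mask[p + o]`); translates that exit
#' the image count as background, so the border erodes away. Dilation is the
#' Minkowski sum with the same offsets (`p` set iff `p = q + o` for some set
#' `q`), clipped to the image — together the pair is an algebraic opening.
#'
#' @param mask a [mask_image()].
#' @param se a [structuring_element()].
#' @return A [mask_image()] of the same kind.
#' @export
binary_erode <- function(mask, se = structuring_element(4L)) {
  m <- mask$data
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (k in seq_len(nrow(se$offsets)))
    out <- out & shift_mask(m, se$offsets[k, 1], se$offsets[k, 2], fill = FALSE)
  mask_image(out, kind = mask$kind)
}

#' @rdname binary_erode
#' @export
binary_dilate <- function(mask, se = structuring_element(4L)) {
  m <- mask$data
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (k in seq_len(nrow(se$offsets)))
    out <- out | shift_mask(m, -se$offsets[k, 1], -se$offsets[k, 2], fill = FALSE)
  mask_image(out, kind = mask$kind)
}

#' Largest eight-connected component
#'
#' Labels the set pixels by 8-connectivity (horizontal, vertical and diagonal
#' neighbours join) and keeps only the component with the most pixels. Equal
#' sizes are broken in favour of the component containing the
#' lexicographically smallest (row, col) pixel.
#'
#' @param mask a [mask_image()]; must be non-empty.
#' @return A [mask_image()] containing a single component.
#' @export
largest_component_8 <- function(mask) {
  m <- mask$data
  if (!any(m))
    stop("empty segmentation: mask has no pixels", call. = FALSE)
  h <- nrow(m); w <- ncol(m)
  # seed each set pixel with its row-major id (row * W + col, 0-based) so the
  # component minimum is its lexicographically smallest (row, col) pixel
  rows <- row(m) - 1; cols <- col(m) - 1
  lab <- matrix(Inf, h, w)
  lab[m] <- (rows * w + cols)[m]
  dirs <- expand.grid(dr = -1:1, dc = -1:1)
  dirs <- dirs[!(dirs$dr == 0 & dirs$dc == 0), ]
  repeat {
    new <- lab
    for (k in seq_len(nrow(dirs)))
      new <- pmin(new, shift_mask_num(lab, dirs$dr[k], dirs$dc[k], fill = Inf))
    new[!m] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- lab[m]
  sizes <- table(ids)
  best_size <- max(sizes)
  cand <- as.numeric(names(sizes)[sizes == best_size])
  keep <- min(cand)   # tie-break: smallest top-left id
  mask_image(is.finite(lab) & lab == keep, kind = mask$kind)
}

shift_mask_num <- function(m, dr, dc, fill = Inf) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 - dr):min(h, h - dr)
  cs <- max(1, 1 - dc):min(w, w - dc)
  if (length(rs) > 0 && length(cs) > 0)
    out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

#' Semi-automatic lesion segmentation
#'
#' The five-step extraction: (1) subtraction image (chosen post-contrast
#' phase minus pre-contrast); (2) Otsu threshold computed from the ROI pixels
#' only, foreground = above threshold; (3) binary erosion with the square
#' element; (4) largest eight-connected component; (5) dilation with the same
#' element, then intersection with the ROI so the lesion never leaks past the
#' user's boundary.
#'
#' @param series a [dce_series()].
#' @param roi a [mask_image()] (kind `"roi"`) on the same grid.
#' @param cfg a [segmentation_config()].
#' @return A [mask_image()] of kind `"lesion"` with attribute
#'   `"stage_counts"` giving the pixel count after each stage and
#'   `"threshold"` the Otsu threshold used.
#' @export
segment_lesion <- function(series, roi, cfg = segmentation_config()) {
  stopifnot(inherits(series, "dce_series"), inherits(roi, "mask_image"))
  d <- dim(series$data)
  if (!all(dim(roi$data) == d[2:3]))
    stop("ROI grid does not match the series", call. = FALSE)
  if (!any(roi$data)) stop("empty ROI", call. = FALSE)

  sub <- subtraction_image(series, cfg$post_phase_index)
  vals <- sub[roi$data]
  if (min(vals) == max(vals))
    stop("degenerate input: ROI intensities are constant; no lesion contrast",
         call. = FALSE)
  thr <- otsu_threshold(vals, bins = cfg$histogram_bins)
  fg <- mask_image(sub > thr & roi$data, kind = "lesion")

  se <- structuring_element(cfg$se_size)
  eroded <- binary_erode(fg, se)
  if (!any(eroded$data))
    stop("empty segmentation: nothing survives erosion; ",
         "enlarge ROI or reduce SE size", call. = FALSE)
  comp <- largest_component_8(eroded)
  dilated <- binary_dilate(comp, se)
  lesion <- mask_image(dilated$data & roi$data, kind = "lesion")

  attr(lesion, "threshold") <- thr
  attr(lesion, "stage_counts") <- c(
    roi = sum(roi$data), foreground = sum(fg$data), eroded = sum(eroded$data),
    largest_component = sum(comp$data), dilated = sum(dilated$data),
    final = sum(lesion$data)
  )
  lesion
}
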