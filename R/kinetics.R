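#' Time-intensity curve
#'
#' One signal-intensity trajectory (the mean over a mask or a single pixel).
#' `values[1]` is the pre-contrast intensity `SI_0`; `values[2..T]` are the
#' post-contrast phases `SI_1 .. SI_{T-1}`.
#'
#' @param values numeric vector, length >= 4, all finite.
#' @param times acquisition times in seconds (default 80 s spacing from 0).
#' @return An object of class `time_curve`.
#' @export
time_curve <- function(values, times = NULL) {
  values <- as.numeric(values)
  if (length(values) < 4L)
    stop("time curve needs >= 4 samples (1 pre + >= 3 post)", call. = FALSE)
  if (any(!is.finite(values)))
    stop("time curve values must be finite", call. = FALSE)
  if (is.null(times)) times <- (seq_along(values) - 1) * 80
  if (length(times) != length(values) || any(diff(times) <= 0))
    stop("times must match values and be strictly increasing", call. = FALSE)
  structure(list(values = values, times = as.numeric(times)),
            class = "time_curve")
}

#' @export
print.time_curve <- function(x, ...) {
  cat(sprintf("<time_curve> T=%d, SI_0=%g, peak=%g, tail=%g\n",
              length(x$values), x$values[1],
              max(x$values[-1]), x$values[length(x$values)]))
  invisible(x)
}

si0 <- function(curve) curve$values[1]
si_tail <- function(curve) curve$values[length(curve$values)]
si_post_mean <- function(curve) mean(curve$values[2:3])
si_peak <- function(curve) max(curve$values[-1])

#' Mean time-intensity curve over a mask
#'
#' @param series a [dce_series()].
#' @param mask a non-empty [mask_image()] on the same grid.
#' @return A [time_curve()] where each value is the arithmetic mean of the
#'   phase image over the mask pixels.
#' @export
extract_mean_curve <- function(series, mask) {
  stopifnot(inherits(series, "dce_series"), inherits(mask, "mask_image"))
  if (!any(mask$data)) stop("empty mask", call. = FALSE)
  vals <- apply(series$data, 1, function(img) mean(img[mask$data]))
  time_curve(vals, series$times)
}

#' Signal-intensity slope (late washout slope, %)
#'
#' `100 * (SI_tail - SI_mean) / SI_mean`, where `SI_mean` is the mean of the
#' first two post-contrast intensities and `SI_tail` the last. Positive for
#' persistent enhancement, negative for washout.
#'
#' @param curve a [time_curve()].
#' @return Percent; `NaN` if `SI_mean` is 0.
#' @export
si_slope <- function(curve) {
  m <- si_post_mean(curve)
  if (m == 0) return(NaN)
  100 * (si_tail(curve) - m) / m
}

#' Classify a curve as type I / II / III from its slope
#'
#' Type I (persistent) when the slope is +10% or larger, type III (washout)
#' when it is -10% or lower, type II (plateau) strictly in between. Both
#' bounds are inclusive at the named types.
#'
#' @param slope signal-intensity slope in percent (see [si_slope()]).
#' @param bounds half-width of the plateau band in percent points (default
#'   10).
#' @param upper optional override for the upper (type I) bound alone, e.g.
#'   9.7039, leaving the lower bound at `-bounds`.
#' @return `"I"`, `"II"` or `"III"`; `NA` if the slope is undefined.
#' @export
classify_tic <- function(slope, bounds = 10, upper = NULL) {
  up <- if (is.null(upper)) bounds else upper
  lo <- -bounds
  ifelse(is.na(slope), NA_character_,
         ifelse(slope >= up, "I", ifelse(slope <= lo, "III", "II")))
}

#' Maximum slope of increase (signal units)
#'
#' The largest consecutive-phase difference `SI_{i+1} - SI_i`, with `i`
#' running from the pre-contrast phase (the pre-to-first-post step counts).
#' Not clamped: a strictly decreasing curve yields a negative MSI.
#'
#' @param curve a [time_curve()].
#' @return Signal units (scales with the data).
#' @export
msi <- function(curve) max(diff(curve$values))

#' Initial percentage of enhancement
#'
#' `100 * (SI_1 - SI_0) / SI_0`.
#' @param curve a [time_curve()].
#' @return Percent points; `NaN` if `SI_0 <= 0`.
#' @export
e_initial <- function(curve) {
  s0 <- si0(curve)
  if (s0 <= 0) return(NaN)
  100 * (curve$values[2] - s0) / s0
}

#' Percentage of peak enhancement
#'
#' `100 * (SI_peak - SI_0) / SI_0` with the peak searched over the
#' post-contrast phases only (first occurrence on ties).
#' @param curve a [time_curve()].
#' @return Percent points; `NaN` if `SI_0 <= 0`.
#' @export
e_peak <- function(curve) {
  s0 <- si0(curve)
  if (s0 <= 0) return(NaN)
  100 * (si_peak(curve) - s0) / s0
}

#' Early signal enhancement ratio
#'
#' `100 * (SI_1 - SI_0) / (SI_2 - SI_0)`: how much of the second-phase
#' enhancement was already present at the first phase.
#' @param curve a [time_curve()].
#' @return Percent points; `NaN` if `SI_2 == SI_0`.
#' @export
eser <- function(curve) {
  s0 <- si0(curve)
  d2 <- curve$values[3] - s0
  if (d2 == 0) return(NaN)
  100 * (curve$values[2] - s0) / d2
}

#' Second enhancement percentage
#'
#' `100 * (SI_2 - SI_0) / SI_0`.
#' @param curve a [time_curve()].
#' @return Percent points; `NaN` if `SI_0 <= 0`.
#' @export
sep <- function(curve) {
  s0 <- si0(curve)
  if (s0 <= 0) return(NaN)
  100 * (curve$values[3] - s0) / s0
}

#' All six kinetic parameters plus the curve type
#'
#' NaN-tolerant: each parameter applies its own guard (zero baseline, zero
#' denominator) independently, and the curve type is `NA` only when the slope
#' itself is undefined.
#'
#' @param curve a [time_curve()].
#' @inheritParams classify_tic
#' @return A one-row tibble with columns `si_slope`, `msi`, `e_initial`,
#'   `e_peak`, `eser`, `sep`, `tic_type`.
#' @examples
#' compute_params(time_curve(c(100, 180, 200, 195, 190, 185, 180, 175, 170)))
#' @export
compute_params <- function(curve, bounds = 10, upper = NULL) {
  sl <- si_slope(curve)
  tibble::tibble(
    si_slope = sl,
    msi = msi(curve),
    e_initial = e_initial(curve),
    e_peak = e_peak(curve),
    eser = eser(curve),
    sep = sep(curve),
    tic_type = classify_tic(sl, bounds = bounds, upper = upper)
  )
}

#' Pixelwise kinetic parameter maps with region means
#'
#' Computes the six parameters for every pixel curve inside the lesion and
#' assembles one `H x W` map per parameter (NaN outside the lesion or where a
#' guard fires). Region means average the defined pixels only, per parameter
#' independently; the region-level curve type is classified from the mean
#' pixel slope.
#'
#' @param series a [dce_series()].
#' @param lesion a non-empty [mask_image()].
#' @inheritParams classify_tic
#' @return A list of class `parametric_maps` with elements `maps` (named list
#'   of matrices), `region_means` (one-row tibble in the [compute_params()]
#'   layout) and `pixels` (tibble of per-pixel parameters with row/col).
#' @export
pixelwise_maps <- function(series, lesion, bounds = 10, upper = NULL) {
  stopifnot(inherits(series, "dce_series"), inherits(lesion, "mask_image"))
  if (!any(lesion$data)) stop("empty mask", call. = FALSE)
  d <- dim(series$data)
  idx <- which(lesion$data, arr.ind = TRUE)
  # vectorized over pixels: V is T x n_pixels
  v <- apply(idx, 1, function(rc) series$data[, rc[1], rc[2]])
  v <- matrix(v, nrow = d[1])
  s0v <- v[1, ]
  post_mean <- (v[2, ] + v[3, ]) / 2
  tailv <- v[d[1], ]
  peakv <- apply(v[-1, , drop = FALSE], 2, max)
  slopev <- ifelse(post_mean == 0, NaN, 100 * (tailv - post_mean) / post_mean)
  px <- tibble::tibble(
    row = idx[, 1] - 1L, col = idx[, 2] - 1L,
    si_slope = slopev,
    msi = apply(diff(v), 2, max),
    e_initial = ifelse(s0v <= 0, NaN, 100 * (v[2, ] - s0v) / s0v),
    e_peak = ifelse(s0v <= 0, NaN, 100 * (peakv - s0v) / s0v),
    eser = ifelse(v[3, ] == s0v, NaN, 100 * (v[2, ] - s0v) / (v[3, ] - s0v)),
    sep = ifelse(s0v <= 0, NaN, 100 * (v[3, ] - s0v) / s0v),
    tic_type = classify_tic(slopev, bounds = bounds, upper = upper)
  )
  pars <- c("si_slope", "msi", "e_initial", "e_peak", "eser", "sep")
  maps <- lapply(pars, function(p) {
    m <- matrix(NaN, d[2], d[3])
    m[idx] <- px[[p]]
    m
  })
  names(maps) <- pars
  means <- vapply(pars, function(p) {
    v <- px[[p]]
    if (all(is.nan(v))) NaN else mean(v[!is.nan(v)])
  }, numeric(1))
  region_means <- tibble::as_tibble(as.list(means))
  region_means$tic_type <- classify_tic(region_means$si_slope,
                                        bounds = bounds, upper = upper)
  structure(list(maps = maps, region_means = region_means, pixels = px),
            class = "parametric_maps")
}

#' @export
print.parametric_maps <- function(x, ...) {
  cat(sprintf("<parametric_maps> %d lesion pixels; region means:\n",
              nrow(x$pixels)))
  print(x$region_means)
  invisible(x)
}
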