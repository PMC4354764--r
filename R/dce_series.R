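#' Dynamic contrast-enhanced series
#'
#' A single-slice dynamic series: `T` co-registered 2-D images where frame 0
#' is the pre-contrast acquisition and the remaining frames are post-contrast
#' phases. Stored time-first as a `T x H x W` array so `data[t, , ]` is one
#' phase image.
#'
#' @param data numeric array, `T x H x W`, signal intensity in scanner units.
#' @param times numeric vector of `T` acquisition times in seconds, strictly
#'   increasing, `times[1] == 0` (pre-contrast). Defaults to 80 s spacing.
#' @param case_id character label for the case.
#'
#' @return An object of class `dce_series`: a list with elements `data`,
#'   `times`, `case_id`.
#' @examples
#' arr <- array(100, dim = c(9, 16, 16))
#' s <- dce_series(arr)
#' dim(s$data)
#' s$times
#' @export
dce_series <- function(data, times = NULL, case_id = "case") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (time, row, col)", call. = FALSE)
  nt <- dim(data)[1]
  if (is.null(times)) times <- (seq_len(nt) - 1) * 80
  x <- structure(
    list(data = data, times = as.numeric(times), case_id = as.character(case_id)),
    class = "dce_series"
  )
  validate_dce_series(x)
}

validate_dce_series <- function(x) {
  d <- dim(x$data)
  if (d[1] < 4L)
    stop("invalid series: T < 4 (need 1 pre-contrast + >= 3 post-contrast phases)",
         call. = FALSE)
  if (d[2] < 8L || d[3] < 8L)
    stop("invalid series: image smaller than 8 x 8", call. = FALSE)
  if (length(x$times) != d[1])
    stop("invalid series: length(times) != T", call. = FALSE)
  if (any(!is.finite(x$data)))
    stop("invalid series: non-finite intensities", call. = FALSE)
  if (any(!is.finite(x$times)) || any(diff(x$times) <= 0))
    stop("invalid series: times must be strictly increasing", call. = FALSE)
  if (x$times[1] != 0)
    stop("invalid series: times[1] must be 0 (pre-contrast)", call. = FALSE)
  x
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dce_series '%s'>  T=%d phases, %d x %d pixels, t = %s s\n",
              x$case_id, d[1], d[2], d[3],
              paste(format(x$times, trim = TRUE), collapse = ", ")))
  invisible(x)
}

#' Number of phases, image height and width of a series
#' @param x a `dce_series`.
#' @return Integer vector `c(T, H, W)`.
#' @export
series_dim <- function(x) dim(x$data)
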