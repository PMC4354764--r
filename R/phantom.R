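#' Lesion kinetic archetype specification
#'
#' Describes a noise-free lesion enhancement curve: baseline `s0`, a linear
#' wash-in to `s0 * (1 + wash_in_fraction)` at `t_peak`, then a linear late
#' segment calibrated so that the signal-intensity slope of the *sampled*
#' curve equals `late_slope_target` exactly. The target must be consistent
#' with the archetype under the +/-10% rule (type I >= +10, type III <= -10,
#' type II strictly inside), so every generated curve classifies back to its
#' own archetype by construction.
#'
#' @param archetype `"I"`, `"II"` or `"III"`.
#' @param s0 pre-contrast baseline signal (> 0).
#' @param wash_in_fraction peak enhancement as a fraction of `s0` (default
#'   0.9, a strongly enhancing mass).
#' @param t_peak time of the wash-in peak in seconds (default 160 s, the
#'   second post-contrast phase of an 80 s protocol).
#' @param late_slope_target intended signal-intensity slope in percent;
#'   defaults to +25 / 0 / -25 for types I / II / III.
#' @return A list of class `lesion_kinetic_spec`.
#' @export
lesion_kinetic_spec <- function(archetype = c("I", "II", "III"), s0 = 500,
                                wash_in_fraction = 0.9, t_peak = 160,
                                late_slope_target = NULL) {
  archetype <- match.arg(archetype)
  if (is.null(late_slope_target))
    late_slope_target <- c(I = 25, II = 0, III = -25)[[archetype]]
  if (s0 <= 0) stop("s0 must be positive", call. = FALSE)
  if (wash_in_fraction <= 0) stop("wash_in_fraction must be > 0", call. = FALSE)
  if (t_peak <= 0) stop("t_peak must be > 0", call. = FALSE)
  implied <- classify_tic(late_slope_target)
  if (implied != archetype)
    stop(sprintf("late_slope_target %.2f classifies as type %s, not %s",
                 late_slope_target, implied, archetype), call. = FALSE)
  structure(list(archetype = archetype, s0 = s0,
                 wash_in_fraction = wash_in_fraction, t_peak = t_peak,
                 late_slope_target = late_slope_target),
            class = "lesion_kinetic_spec")
}

# Linear-coefficient representation of the piecewise curve: the value at time
# t is A(t) + B(t) * tail, where tail is the (unknown) last-sample value.
curve_coefs <- function(spec, t, t_last) {
  sp <- spec$s0 * (1 + spec$wash_in_fraction)
  rise <- t <= spec$t_peak
  beta <- (t - spec$t_peak) / (t_last - spec$t_peak)
  A <- ifelse(rise, spec$s0 * (1 + spec$wash_in_fraction * t / spec$t_peak),
              sp * (1 - beta))
  B <- ifelse(rise, 0, beta)
  cbind(A = A, B = B)
}

#' Noise-free archetype curve at the acquisition times
#'
#' Solves for the tail value that makes the sampled curve's
#' signal-intensity slope equal the spec's `late_slope_target`, then
#' evaluates the piecewise-linear curve at `times`.
#'
#' @param spec a [lesion_kinetic_spec()].
#' @param times acquisition times in seconds (default 9 phases at 80 s).
#' @return A [time_curve()].
#' @examples
#' cv <- kinetic_curve(lesion_kinetic_spec("III"))
#' si_slope(cv) # exactly -25
#' @export
kinetic_curve <- function(spec, times = (0:8) * 80) {
  stopifnot(inherits(spec, "lesion_kinetic_spec"))
  t_last <- times[length(times)]
  if (spec$t_peak >= t_last)
    stop("infeasible calibration: t_peak at or beyond the last sample",
         call. = FALSE)
  g <- spec$late_slope_target / 100
  cf <- curve_coefs(spec, times[2:3], t_last)
  a <- mean(cf[, "A"]); b <- mean(cf[, "B"])
  denom <- 1 - (1 + g) * b
  if (denom <= 0)
    stop("infeasible calibration: slope target unreachable for this t_peak",
         call. = FALSE)
  tail_val <- (1 + g) * a / denom
  cf_all <- curve_coefs(spec, times, t_last)
  time_curve(cf_all[, "A"] + cf_all[, "B"] * tail_val, times)
}

#' Digital phantom specification
#'
#' Geometry and noise for one simulated case: a mass-like elliptical lesion
#' on a mildly, slowly enhancing background. Geometry fields left `NULL` are
#' drawn at simulation time (the lesion always fits with a >= 4 px margin).
#'
#' @param size image side length in pixels (default 64).
#' @param center optional (row, col) lesion center.
#' @param semi_axes optional (a, b) semi-axes in pixels; drawn from
#'   \[3, 12\] if `NULL`.
#' @param theta optional orientation in radians.
#' @param background_fraction background enhancement at the last phase as a
#'   fraction of its baseline (default 0.2).
#' @param noise `"gaussian"` or `"rician"`.
#' @param sigma noise standard deviation as a fraction of the lesion baseline
#'   `s0` (default 0.05).
#' @param jitter half-width of the per-pixel multiplicative lesion
#'   heterogeneity (default 0.05, i.e. +/-5%).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 64L, center = NULL, semi_axes = NULL,
                         theta = NULL, background_fraction = 0.2,
                         noise = c("gaussian", "rician"), sigma = 0.05,
                         jitter = 0.05) {
  noise <- match.arg(noise)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(size = as.integer(size), center = center,
                 semi_axes = semi_axes, theta = theta,
                 background_fraction = background_fraction, noise = noise,
                 sigma = sigma, jitter = jitter),
            class = "phantom_spec")
}

ellipse_mask <- function(size, center, semi_axes, theta) {
  r <- row(matrix(0, size, size)) - 1 - center[1]
  c_ <- col(matrix(0, size, size)) - 1 - center[2]
  u <- c_ * cos(theta) + r * sin(theta)
  v <- -c_ * sin(theta) + r * cos(theta)
  mask_image((u / semi_axes[1])^2 + (v / semi_axes[2])^2 <= 1, kind = "lesion")
}

ellipse_polygon <- function(size, center, semi_axes, theta, pad = 4,
                            n_vertices = 64L) {
  phi <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  u <- (semi_axes[1] + pad) * cos(phi)
  v <- (semi_axes[2] + pad) * sin(phi)
  cc <- center[2] + u * cos(theta) - v * sin(theta)
  rr <- center[1] + u * sin(theta) + v * cos(theta)
  roi_polygon(cbind(pmin(pmax(rr, 0), size - 1), pmin(pmax(cc, 0), size - 1)))
}

#' Simulate one phantom case
#'
#' Background pixels follow a slow linear enhancement; lesion pixels follow
#' the archetype curve with per-pixel multiplicative jitter; noise is then
#' added to every pixel and phase. Deterministic for a fixed seed.
#'
#' @param pspec a [phantom_spec()].
#' @param kspec a [lesion_kinetic_spec()].
#' @param seed integer RNG seed for this case.
#' @param label truth label to record (`"benign"` or `"malignant"`).
#' @param times acquisition times (default 9 phases at 80 s).
#' @param case_id case label.
#' @return A list of class `simulated_case`: `series` ([dce_series()]),
#'   `truth_mask` ([mask_image()]), `roi` ([roi_polygon()], the truth ellipse
#'   padded by 4 px), `label`, `archetype`, and the generating specs.
#' @export
simulate_case <- function(pspec, kspec, seed, label = "benign",
                          times = (0:8) * 80, case_id = "case") {
  stopifnot(inherits(pspec, "phantom_spec"),
            inherits(kspec, "lesion_kinetic_spec"))
  set.seed(seed)
  size <- pspec$size
  axes <- pspec$semi_axes
  if (is.null(axes)) axes <- runif(2, 3, 12)
  margin <- max(axes) + 4
  if (2 * margin >= size - 1)
    stop("lesion does not fit inside the image with a 4 px margin",
         call. = FALSE)
  center <- pspec$center
  if (is.null(center)) center <- runif(2, margin, size - 1 - margin)
  theta <- pspec$theta
  if (is.null(theta)) theta <- runif(1, 0, pi)

  truth <- ellipse_mask(size, center, axes, theta)
  lesion_curve <- kinetic_curve(kspec, times)
  b0 <- 0.8 * kspec$s0
  bg_curve <- b0 * (1 + pspec$background_fraction * times / times[length(times)])

  nt <- length(times)
  data <- array(0, dim = c(nt, size, size))
  jit <- matrix(1, size, size)
  if (pspec$jitter > 0)
    jit[truth$data] <- 1 + runif(sum(truth$data), -pspec$jitter, pspec$jitter)
  for (t in seq_len(nt)) {
    frame <- matrix(bg_curve[t], size, size)
    frame[truth$data] <- lesion_curve$values[t] * jit[truth$data]
    data[t, , ] <- frame
  }
  if (pspec$sigma > 0) {
    sd_abs <- pspec$sigma * kspec$s0
    if (pspec$noise == "gaussian") {
      data <- data + array(rnorm(length(data), 0, sd_abs), dim = dim(data))
    } else {
      e1 <- array(rnorm(length(data), 0, sd_abs), dim = dim(data))
      e2 <- array(rnorm(length(data), 0, sd_abs), dim = dim(data))
      data <- sqrt((data + e1)^2 + e2^2)
    }
  }
  series <- dce_series(data, times = times, case_id = case_id)
  roi <- ellipse_polygon(size, center, axes, theta, pad = 4)
  structure(list(series = series, truth_mask = truth, roi = roi,
                 label = label, archetype = kspec$archetype,
                 kinetic_spec = kspec, phantom_spec = pspec,
                 geometry = list(center = center, semi_axes = axes,
                                 theta = theta),
                 case_id = case_id, seed = seed),
            class = "simulated_case")
}

#' @export
print.simulated_case <- function(x, ...) {
  cat(sprintf("<simulated_case '%s'> %s, type %s, %d lesion px, seed %d\n",
              x$case_id, x$label, x$archetype, mask_area(x$truth_mask),
              x$seed))
  invisible(x)
}

# Class-conditional slope-target ranges (percent). Within every curve type,
# carcinomas tend to wash out faster than benign lesions, so the malignant
# ranges sit lower; all ranges stay strictly inside their archetype's band so
# noise-free curves always classify back to their own type.
slope_target_ranges <- list(
  benign = list(I = c(15, 40), II = c(-5, 9), III = c(-25, -12)),
  malignant = list(I = c(10, 22), II = c(-9, 0), III = c(-50, -15))
)

default_archetype_mix <- list(
  benign = c(I = 0.75, II = 0.20, III = 0.05),
  malignant = c(I = 0.15, II = 0.35, III = 0.50)
)

#' Simulate a labelled cohort of phantom cases
#'
#' Draws an archetype per case from the class-specific mix, a slope target
#' from class- and archetype-specific ranges, a baseline and wash-in fraction
#' per case, and generates independent seeded cases. The entire cohort is
#' reproducible from the single `seed`; per-case seeds are drawn once from
#' the master stream.
#'
#' @param n_benign,n_malignant cases per class (default 30 each).
#' @param mix named list `benign` / `malignant` of I/II/III probabilities
#'   (each summing to 1); see `default_archetype_mix` in the package source.
#' @param seed master RNG seed.
#' @param sigma noise level, fraction of the lesion baseline (default 0.05).
#' @param size image side length (default 64).
#' @param noise `"gaussian"` (default) or `"rician"`.
#' @return A list with `cases` (list of [simulate_case()] results) and
#'   `cohort` (tibble: `case_id`, `truth_label`, `archetype`,
#'   `slope_target`, `s0`, `wash_in_fraction`, `seed`).
#' @export
simulate_cohort <- function(n_benign = 30L, n_malignant = 30L, mix = NULL,
                            seed = 1L, sigma = 0.05, size = 64L,
                            noise = "gaussian") {
  if (n_benign < 1L || n_malignant < 1L)
    stop("need at least one case per class", call. = FALSE)
  if (is.null(mix)) mix <- default_archetype_mix
  for (cls in c("benign", "malignant")) {
    p <- mix[[cls]]
    if (is.null(p) || length(p) != 3L || abs(sum(p) - 1) > 1e-8)
      stop("mix$", cls, " must be 3 archetype probabilities summing to 1",
           call. = FALSE)
  }
  set.seed(seed)
  labels <- rep(c("benign", "malignant"), c(n_benign, n_malignant))
  n <- length(labels)
  archetypes <- unname(vapply(labels, function(cls)
    sample(c("I", "II", "III"), 1L, prob = mix[[cls]]), character(1)))
  targets <- vapply(seq_len(n), function(i) {
    rg <- slope_target_ranges[[labels[i]]][[archetypes[i]]]
    runif(1, rg[1], rg[2])
  }, numeric(1))
  s0s <- runif(n, 400, 800)
  wash_ins <- runif(n, 0.6, 1.2)
  case_seeds <- sample.int(.Machine$integer.max - 1L, n)

  cases <- lapply(seq_len(n), function(i) {
    kspec <- lesion_kinetic_spec(archetypes[i], s0 = s0s[i],
                                 wash_in_fraction = wash_ins[i],
                                 late_slope_target = targets[i])
    pspec <- phantom_spec(size = size, sigma = sigma, noise = noise)
    simulate_case(pspec, kspec, seed = case_seeds[i], label = labels[i],
                  case_id = sprintf("case_%03d", i))
  })
  cohort <- tibble::tibble(
    case_id = vapply(cases, `[[`, character(1), "case_id"),
    truth_label = labels, archetype = archetypes, slope_target = targets,
    s0 = s0s, wash_in_fraction = wash_ins, seed = case_seeds
  )
  list(cases = cases, cohort = cohort)
}
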