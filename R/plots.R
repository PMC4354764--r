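#' Plot a time-intensity curve
#'
#' @param object a [time_curve()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot time_curve
#' @export
autoplot.time_curve <- function(object, ...) {
  df <- tibble::tibble(time = object$times, si = object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$si)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (s)", y = "signal intensity") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve with its optimal operating point
#'
#' @param object a `roc_result` from [optimal_cutoff()].
#' @param ... unused.
#' @return A ggplot of sensitivity vs 100 - specificity.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  crv <- object$curve[order(object$curve$specificity,
                            -object$curve$sensitivity), ]
  df <- tibble::tibble(fpr = 100 - crv$specificity, tpr = crv$sensitivity)
  df <- rbind(tibble::tibble(fpr = 100, tpr = 100), df,
              tibble::tibble(fpr = 0, tpr = 0))
  opt <- tibble::tibble(fpr = 100 - object$specificity,
                        tpr = object$sensitivity)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = opt, colour = "red", size = 2) +
    ggplot2::labs(x = "100 - specificity (%)", y = "sensitivity (%)",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot one kinetic parameter map
#'
#' @param maps a `parametric_maps` object from [pixelwise_maps()].
#' @param parameter which map to show (e.g. `"si_slope"`).
#' @return A ggplot raster; pixels where the parameter is undefined or
#'   outside the lesion are blank.
#' @export
plot_param_map <- function(maps, parameter = "si_slope") {
  stopifnot(inherits(maps, "parametric_maps"),
            parameter %in% names(maps$maps))
  m <- maps$maps[[parameter]]
  df <- tibble::tibble(
    row = as.vector(row(m)) - 1L,
    col = as.vector(col(m)) - 1L,
    value = as.vector(m)
  )
  df <- df[!is.nan(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = parameter) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
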