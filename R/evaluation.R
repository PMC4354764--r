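drop_nan_pairs <- function(scores, labels) {
  labels <- as.character(labels)
  keep <- is.finite(scores)
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " case(s) with undefined scores dropped from ROC analysis")
  scores <- scores[keep]; labels <- labels[keep]
  if (!all(labels %in% c("benign", "malignant")))
    stop("labels must be 'benign' or 'malignant'", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present after dropping undefined scores",
         call. = FALSE)
  list(scores = scores, labels = labels)
}

roc_obj <- function(scores, labels) {
  pROC::roc(response = labels, predictor = scores,
            levels = c("benign", "malignant"), direction = "<", quiet = TRUE)
}

#' Area under the ROC curve
#'
#' The Mann-Whitney concordance probability: the proportion of
#' (malignant, benign) score pairs ranked correctly, counting ties as half.
#'
#' @param scores numeric vector, one per case (NaN allowed; dropped).
#' @param labels `"benign"` / `"malignant"` per case.
#' @param positive_high if `TRUE` (default) higher scores indicate
#'   malignancy; if `FALSE` the scale is reversed.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, positive_high = TRUE) {
  d <- drop_nan_pairs(scores, labels)
  a <- as.numeric(pROC::auc(roc_obj(d$scores, d$labels)))
  if (positive_high) a else 1 - a
}

#' Standard error of the AUC (DeLong)
#'
#' The DeLong structural-components variance estimator; the 95% confidence
#' interval is `auc +/- 1.96 * SE`, clipped to \[0, 1\].
#'
#' @inheritParams roc_auc
#' @return A list with `auc`, `se`, `ci95` (length-2 numeric).
#' @export
auc_se <- function(scores, labels, positive_high = TRUE) {
  d <- drop_nan_pairs(scores, labels)
  if (min(table(d$labels)) < 3L)
    stop("need >= 3 cases per class for a standard error", call. = FALSE)
  r <- roc_obj(d$scores, d$labels)
  a <- as.numeric(pROC::auc(r))
  v <- withCallingHandlers(
    pROC::var(r, method = "delong"),
    warning = function(w) {
      # pROC warns that a separated sample has zero variance; that is the
      # documented behaviour here (SE = 0, degenerate CI), not a problem
      if (grepl("AUC == 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  se <- sqrt(as.numeric(v))
  if (!positive_high) a <- 1 - a
  ci <- pmin(pmax(a + c(-1, 1) * 1.96 * se, 0), 1)
  list(auc = a, se = se, ci95 = ci)
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Orients the score (if the raw AUC with "higher = malignant" is below 0.5
#' the direction flips to "lower = malignant", reported as direction `"le"`),
#' then scans every distinct observed score as a candidate criterion: for
#' direction `"gt"` a case is called malignant iff `score > c`, for `"le"`
#' iff `score <= c`. The criterion maximizing Youden's
#' J = sensitivity + specificity - 100 wins; ties are broken by higher
#' sensitivity, then by smaller `|c|`.
#'
#' @inheritParams roc_auc
#' @return An object of class `roc_result` with fields `auc`, `se`, `ci95`,
#'   `direction`, `cutoff`, `sensitivity`, `specificity`, `accuracy` (all
#'   percentages in \[0, 100\]), `n_benign`, `n_malignant`, `n_dropped`, and
#'   a `curve` tibble of all scanned operating points.
#' @examples
#' optimal_cutoff(c(1, 2, 3, 2.5, 4, 5),
#'                rep(c("benign", "malignant"), each = 3))
#' @export
optimal_cutoff <- function(scores, labels) {
  labels_chr <- as.character(labels)
  n_dropped <- sum(!is.finite(scores))
  d <- drop_nan_pairs(scores, labels_chr)
  s <- d$scores; lab <- d$labels
  n_pos <- sum(lab == "malignant"); n_neg <- sum(lab == "benign")

  have_se <- min(n_pos, n_neg) >= 3L
  est <- if (have_se) auc_se(s, lab, positive_high = TRUE)
         else list(auc = roc_auc(s, lab, TRUE), se = NA_real_,
                   ci95 = c(NA_real_, NA_real_))
  direction <- "gt"
  if (est$auc < 0.5) {
    direction <- "le"
    est <- if (have_se) auc_se(s, lab, positive_high = FALSE)
           else list(auc = roc_auc(s, lab, FALSE), se = NA_real_,
                     ci95 = c(NA_real_, NA_real_))
  }

  cand <- sort(unique(s))
  ops <- purrr::map_dfr(cand, function(cc) {
    called <- if (direction == "gt") s > cc else s <= cc
    tp <- sum(called & lab == "malignant")
    tn <- sum(!called & lab == "benign")
    tibble::tibble(cutoff = cc,
                   sensitivity = 100 * tp / n_pos,
                   specificity = 100 * tn / n_neg,
                   accuracy = 100 * (tp + tn) / (n_pos + n_neg))
  })
  ops$youden_j <- ops$sensitivity + ops$specificity - 100
  best <- ops[order(-ops$youden_j, -ops$sensitivity, abs(ops$cutoff)), ][1, ]

  structure(list(
    auc = est$auc, se = est$se, ci95 = est$ci95,
    direction = direction, cutoff = best$cutoff,
    sensitivity = best$sensitivity, specificity = best$specificity,
    accuracy = best$accuracy, youden_j = best$youden_j,
    n_benign = n_neg, n_malignant = n_pos, n_dropped = n_dropped,
    curve = ops
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result>  AUC %.3f (SE %.4f, 95%% CI %.3f-%.3f)\n",
              x$auc, x$se, x$ci95[1], x$ci95[2]))
  cat(sprintf("  optimal criterion: %s%.4f  (sens %.2f%%, spec %.2f%%, acc %.2f%%)\n",
              if (x$direction == "gt") ">" else "<=", x$cutoff,
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' @rdname optimal_cutoff
#' @param x a `roc_result`.
#' @param ... unused.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname optimal_cutoff
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, se = x$se,
                 ci_lo = x$ci95[1], ci_hi = x$ci95[2],
                 direction = x$direction, cutoff = x$cutoff,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 accuracy = x$accuracy,
                 n_benign = x$n_benign, n_malignant = x$n_malignant)
}

#' Rule-based malignancy call from the curve type
#'
#' Plateau and washout curves (types II and III) are called malignant;
#' persistent enhancement (type I) is called benign. Undefined types yield
#' `NA` and are excluded from downstream metrics.
#'
#' @param tic_type character vector of `"I"`, `"II"`, `"III"` (NA allowed).
#' @return `"benign"` / `"malignant"` / `NA`.
#' @export
malignancy_from_type <- function(tic_type) {
  out <- ifelse(is.na(tic_type), NA_character_,
                ifelse(tic_type %in% c("II", "III"), "malignant",
                       ifelse(tic_type == "I", "benign", NA_character_)))
  n_undef <- sum(is.na(out) & !is.na(tic_type))
  if (n_undef > 0) message(n_undef, " unknown curve type(s) left uncalled")
  out
}

#' Confusion-matrix metrics
#'
#' @param calls predicted `"benign"`/`"malignant"` per case (NA excluded,
#'   with a message).
#' @param truth true labels, same length.
#' @return A one-row tibble with counts `tp`, `fp`, `tn`, `fn`, `n` and
#'   percentages `sensitivity`, `specificity`, `accuracy` (unrounded).
#' @examples
#' confusion_metrics(rep(c("malignant", "benign"), c(70, 72)),
#'                   rep(c("malignant", "benign"), each = 71))
#' @export
confusion_metrics <- function(calls, truth) {
  if (length(calls) != length(truth))
    stop("calls and truth differ in length", call. = FALSE)
  calls <- as.character(calls); truth <- as.character(truth)
  keep <- !is.na(calls)
  if (any(!keep)) message(sum(!keep), " uncalled case(s) excluded from metrics")
  calls <- calls[keep]; truth <- truth[keep]
  if (length(unique(truth)) < 2L)
    stop("both truth classes must be present", call. = FALSE)
  tp <- sum(calls == "malignant" & truth == "malignant")
  fp <- sum(calls == "malignant" & truth == "benign")
  tn <- sum(calls == "benign" & truth == "benign")
  fn <- sum(calls == "benign" & truth == "malignant")
  n <- tp + fp + tn + fn
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn, n = n,
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 accuracy = 100 * (tp + tn) / n)
}

#' Cohort composition percentages
#'
#' Per-category percentages of a count table, e.g. the histopathological
#' composition of the benign arm of a cohort.
#'
#' @param counts data frame (or tibble) with columns `label` and `count`.
#' @return The input with a `percent` column, `100 * count / total`.
#' @examples
#' composition_summary(data.frame(label = c("fibroadenoma", "other"),
#'                                count = c(33, 38)))
#' @export
composition_summary <- function(counts) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("label", "count") %in% names(counts)))
  if (any(counts$count < 0)) stop("negative count", call. = FALSE)
  total <- sum(counts$count)
  if (total <= 0) stop("zero total count", call. = FALSE)
  dplyr::mutate(counts, percent = 100 * .data$count / total)
}
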