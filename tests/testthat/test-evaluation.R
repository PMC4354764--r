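mk_labels <- function(n_ben, n_mal) rep(c("benign", "malignant"), c(n_ben, n_mal))

test_that("AUC equals pair-counting concordance, including ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4, 5, 6), mk_labels(3, 3)), 1)
  expect_equal(roc_auc(rep(2, 8), mk_labels(4, 4)), 0.5)
  expect_equal(roc_auc(c(1, 2, 3, 2.5, 4, 5), mk_labels(3, 3)), 8 / 9)

  set.seed(909)
  for (i in 1:100) {
    nb <- sample(2:20, 1); nm <- sample(2:20, 1)
    sc <- sample(seq(0, 10, 0.5), nb + nm, replace = TRUE)  # forces ties
    lab <- mk_labels(nb, nm)
    expect_equal(roc_auc(sc, lab), oracle_auc(sc, lab), info = paste(i))
  }
})

test_that("AUC flips under reversed polarity and monotone transforms", {
  set.seed(910)
  sc <- rnorm(30); lab <- mk_labels(15, 15)
  expect_equal(roc_auc(sc, lab, TRUE) + roc_auc(sc, lab, FALSE), 1)
  expect_equal(roc_auc(exp(sc), lab), roc_auc(sc, lab))
  expect_equal(roc_auc(rank(sc), lab), roc_auc(sc, lab))
  expect_error(roc_auc(sc, rep("benign", 30)), "both classes")
})

test_that("DeLong SE matches the structural-components oracle", {
  # perfectly separated: zero variance
  r <- auc_se(c(1, 2, 3, 10, 11, 12), mk_labels(3, 3))
  expect_equal(r$auc, 1)
  expect_equal(r$se, 0)
  expect_equal(r$ci95, c(1, 1))

  # small mixed case against the placement-value computation
  sc <- c(1, 4, 6, 3, 5, 9)
  lab <- mk_labels(3, 3)
  r2 <- auc_se(sc, lab)
  expect_equal(r2$se, oracle_delong_se(sc, lab))
  expect_equal(r2$ci95, pmin(pmax(r2$auc + c(-1.96, 1.96) * r2$se, 0), 1))

  set.seed(911)
  for (i in 1:20) {
    sc <- rnorm(24); lab <- mk_labels(12, 12)
    expect_equal(auc_se(sc, lab)$se, oracle_delong_se(sc, lab),
                 info = paste(i))
  }
})

test_that("DeLong SE is consistent with a bootstrap under exchangeability", {
  set.seed(912)
  sc <- rnorm(40); lab <- mk_labels(20, 20)   # null: auc near 0.5
  r <- auc_se(sc, lab)
  boot <- replicate(2000, {
    idx_b <- sample(which(lab == "benign"), replace = TRUE)
    idx_m <- sample(which(lab == "malignant"), replace = TRUE)
    oracle_auc(c(sc[idx_b], sc[idx_m]), mk_labels(20, 20))
  })
  expect_equal(r$se, sd(boot), tolerance = 0.25)
})

test_that("optimal cutoff reproduces the worked tie-break example", {
  sc <- c(1, 2, 3, 2.5, 4, 5); lab <- mk_labels(3, 3)
  r <- optimal_cutoff(sc, lab)
  expect_equal(r$direction, "gt")
  expect_equal(r$cutoff, 2)          # J ties at c=2 and c=3; higher sens wins
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 200 / 3)
  expect_equal(r$youden_j, 200 / 3)

  perfect <- optimal_cutoff(c(1, 2, 3, 10, 11, 12), lab)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$youden_j, 100)

  # identical score distributions in both classes: J = 0 everywhere,
  # accuracy 50% on a balanced cohort
  same <- optimal_cutoff(c(1, 2, 3, 1, 2, 3), mk_labels(3, 3))
  expect_equal(same$youden_j, 0)
  expect_equal(same$accuracy, 50)
})

test_that("direction flips so reported AUC is always >= 0.5", {
  sc <- c(10, 11, 12, 1, 2, 3)   # malignant LOW
  r <- optimal_cutoff(sc, mk_labels(3, 3))
  expect_equal(r$direction, "le")
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
})

test_that("optimal J equals an exhaustive midpoint-and-value scan", {
  set.seed(913)
  for (i in 1:100) {
    nb <- sample(3:20, 1); nm <- sample(3:20, 1)
    sc <- round(rnorm(nb + nm, sd = 2), 1)
    lab <- mk_labels(nb, nm)
    r <- optimal_cutoff(sc, lab)
    expect_equal(r$youden_j, oracle_best_j(sc, lab, r$direction),
                 info = paste(i))
  }
})

test_that("NaN scores are dropped pairwise with a message", {
  sc <- c(1, 2, NaN, 4, 5, 6); lab <- mk_labels(3, 3)
  expect_message(r <- optimal_cutoff(sc, lab), "dropped")
  expect_equal(r$n_benign, 2)
  expect_equal(r$n_dropped, 1)
})

test_that("tidy and glance expose the curve and the summary", {
  r <- optimal_cutoff(c(1, 2, 3, 2.5, 4, 5), mk_labels(3, 3))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("cutoff", "sensitivity", "specificity", "youden_j")
                  %in% names(td)))
  gl <- glance(r)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$auc, r$auc)
  expect_equal(gl$cutoff, r$cutoff)
})

test_that("curve types map to malignancy calls", {
  expect_equal(malignancy_from_type(c("I", "II", "III")),
               c("benign", "malignant", "malignant"))
  expect_true(is.na(malignancy_from_type(NA_character_)))
})

test_that("confusion metrics reproduce the printed cohort arithmetic", {
  calls <- rep(c("malignant", "benign", "benign", "malignant"),
               c(58, 13, 50, 21))
  truth <- rep(c("malignant", "benign"), c(71, 71))
  cm <- confusion_metrics(calls, truth)
  expect_equal(cm$tp, 58); expect_equal(cm$fn, 13)
  expect_equal(cm$tn, 50); expect_equal(cm$fp, 21)
  expect_equal(round(cm$sensitivity, 2), 81.69)
  expect_equal(round(cm$specificity, 2), 70.42)
  expect_equal(round(cm$accuracy, 2), 76.06)
  expect_equal(cm$accuracy, 100 * (cm$tp + cm$tn) / cm$n)

  all_mal <- confusion_metrics(rep("malignant", 20), mk_labels(10, 10))
  expect_equal(all_mal$sensitivity, 100)
  expect_equal(all_mal$specificity, 0)
  expect_equal(all_mal$accuracy, 50)
  expect_error(confusion_metrics("benign", c("benign", "malignant")),
               "length")
})

test_that("composition percentages are count/total", {
  comp <- composition_summary(data.frame(
    label = c("high_risk", "fibroadenoma", "papilloma", "hyperplasia",
              "miscellaneous"),
    count = c(5, 33, 4, 16, 13)))
  expect_equal(round(comp$percent, 2), c(7.04, 46.48, 5.63, 22.54, 18.31))
  single <- composition_summary(data.frame(label = "only", count = 7))
  expect_equal(single$percent, 100)
  expect_error(composition_summary(data.frame(label = "x", count = 0)),
               "zero total")
})
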