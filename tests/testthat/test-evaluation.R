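make_scores <- function(fall, adl, fold = NULL) {
  n <- length(fall) + length(adl)
  df <- data.frame(id = seq_len(n),
                   label = c(rep("fall", length(fall)), rep("adl", length(adl))),
                   wavelet = c(fall, adl), upv_g = c(fall, adl),
                   lpv_g = -c(fall, adl))
  if (!is.null(fold)) df$fold <- fold
  df
}

test_that("stratified folds partition both classes evenly and reproducibly", {
  labels <- c(rep("fall", 30), rep("adl", 120))
  s1 <- stratified_kfold(labels, 10, seed = 5)
  s2 <- stratified_kfold(labels, 10, seed = 5)
  expect_identical(s1$fold, s2$fold)
  expect_false(identical(s1$fold, stratified_kfold(labels, 10, seed = 6)$fold))
  expect_identical(sort(unique(s1$fold)), 1:10)
  per_fold <- table(s1$fold, labels)
  expect_true(all(per_fold[, "fall"] == 3))
  expect_true(all(per_fold[, "adl"] == 12))
  expect_error(stratified_kfold(c(rep("fall", 5), rep("adl", 50)), 10),
               "at least")
  expect_error(stratified_kfold(labels, 1), "at least 2")
})

test_that("cross-validated scoring covers every recording exactly once", {
  ds <- tiny_dataset()
  split <- stratified_kfold(ds, 3, seed = 2)
  tab <- cross_validated_scores(ds, feature_config(), split)
  expect_identical(sort(tab$id), sort(ds$id))
  expect_identical(nrow(tab), length(ds$recordings))
  for (k in 1:3)
    expect_identical(sort(tab$id[tab$fold == k]), sort(ds$id[split$fold == k]))
})

test_that("fold-wise wavelets track the all-data wavelet", {
  ds <- tiny_dataset()
  split <- stratified_kfold(ds, 3, seed = 2)
  cv <- cross_validated_scores(ds, feature_config(), split)
  full <- build_feature_table(ds, fall_wavelet(ds))
  merged <- merge(cv, full, by = "id")
  expect_gt(cor(merged$wavelet.x, merged$wavelet.y), 0.9)
})

test_that("perfectly separated scores give a perfect averaged ROC", {
  sc <- make_scores(fall = c(9, 8, 7, 9), adl = c(1, 2, 3, 2, 1, 0),
                    fold = c(1, 1, 2, 2, 1, 1, 1, 2, 2, 2))
  r <- roc_vertical_average(sc, "wavelet")
  expect_equal(r$auc, 1, tolerance = 1e-9)
  expect_equal(r$max_yi, 1)
  expect_equal(r$best_point$sensitivity, 1)
  expect_equal(r$best_point$specificity, 1)
})

test_that("uninformative constant scores give the diagonal and AUC one half", {
  sc <- make_scores(fall = rep(2, 4), adl = rep(2, 6),
                    fold = rep(1:2, 5))
  r <- roc_vertical_average(sc, "wavelet")
  expect_equal(r$auc, 0.5, tolerance = 1e-3)
  expect_equal(r$sensitivity[r$specificity == 0.25], 0.75, tolerance = 1e-9)
  expect_equal(r$max_yi, 0, tolerance = 1e-9)
  # tie rule: the operating point sits at the high-specificity end
  expect_equal(r$best_point$specificity, 1)
})

test_that("single-fold ROC matches exhaustive threshold enumeration", {
  sc <- make_scores(fall = c(3, 2), adl = c(1, 2.5))
  r <- roc_vertical_average(sc, "wavelet")
  expect_equal(r$fold_auc, 0.75, tolerance = 1e-12)       # 3 of 4 pairs
  expect_equal(r$auc, 0.75, tolerance = 2e-3)
  expect_equal(r$max_yi, oracle_max_yi(sc$wavelet, sc$label == "fall"),
               tolerance = 1e-9)
  set.seed(51)
  for (i in 1:10) {
    fall <- runif(6); adl <- runif(9)
    sc <- make_scores(fall, adl)
    r <- roc_vertical_average(sc, "wavelet")
    expect_equal(r$fold_auc, oracle_auc(sc$wavelet, sc$label == "fall"),
                 tolerance = 1e-9)
    expect_equal(r$auc, r$fold_auc, tolerance = 2e-3)
    expect_equal(r$fold_yi, oracle_max_yi(sc$wavelet, sc$label == "fall"),
                 tolerance = 1e-9)
    expect_lt(abs(r$max_yi - oracle_max_yi(sc$wavelet, sc$label == "fall")),
              2e-3)
  }
})

test_that("ROC agrees with an established implementation on tie-free scores", {
  skip_if_not_installed("pROC")
  set.seed(52)
  sc <- make_scores(rnorm(20, 1), rnorm(30))
  r <- roc_vertical_average(sc, "wavelet")
  ref <- pROC::roc(sc$label, sc$wavelet, levels = c("adl", "fall"),
                   direction = "<", quiet = TRUE)
  expect_equal(r$fold_auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
})

test_that("averaged ROC is monotone and invariant to increasing transforms", {
  set.seed(53)
  sc <- make_scores(rexp(12) + 0.5, rexp(20), fold = rep(1:4, 8))
  r1 <- roc_vertical_average(sc, "wavelet")
  expect_true(all(diff(r1$sensitivity) <= 1e-12))
  sc2 <- sc; sc2$wavelet <- log(sc2$wavelet + 1) * 7
  r2 <- roc_vertical_average(sc2, "wavelet")
  expect_equal(r2$sensitivity, r1$sensitivity, tolerance = 1e-12)
  expect_equal(r2$auc, r1$auc, tolerance = 1e-12)
  expect_equal(r2$max_yi, r1$max_yi, tolerance = 1e-12)
})

test_that("LPV direction: lower pre-impact minima rank as more fall-like", {
  sc <- make_scores(fall = c(9, 8), adl = c(1, 2))  # lpv_g = negated scores
  r <- roc_vertical_average(sc, "lpv")
  expect_equal(r$fold_auc, 1)
})

test_that("single-class folds are rejected with a clear message", {
  sc <- make_scores(fall = c(1, 2), adl = c(0.5, 1.5),
                    fold = c(1, 1, 2, 2))
  expect_error(roc_vertical_average(sc, "wavelet"), "fold 1")
})

test_that("Youden index arithmetic and validation", {
  expect_equal(youden_index(0.90, 0.897), 0.797)
  expect_equal(youden_index(0.85, 0.863), 0.713)
  expect_equal(youden_index(1, 1), 1)
  expect_error(youden_index(1.2, 0.5), "\\[0, 1\\]")
})

test_that("false-alarm arithmetic scales with specificity and time", {
  fa <- false_alarm_rate(0.897, 1170, 168)
  expect_equal(round(fa$false_alarms, 1), 120.5)
  expect_equal(round(fa$per_hour, 2), 0.72)
  expect_equal(false_alarm_rate(1, 1170, 168)$per_hour, 0)
  expect_equal(round(false_alarm_rate(0.615, 1170, 168)$per_hour, 2), 2.68)
  expect_error(false_alarm_rate(0.9, 100, 0), "positive")
  expect_error(false_alarm_rate(1.2, 100, 1), "\\[0, 1\\]")
})

test_that("exact signed-rank p-values match full enumeration", {
  expect_equal(wilcoxon_signed_rank_paired(1:5, 1:5), 1)
  # all ten differences positive: smallest achievable two-sided p
  expect_equal(wilcoxon_signed_rank_paired(2:11, 1:10), 2 / 1024,
               tolerance = 1e-12)
  set.seed(61)
  for (n in c(5, 8, 10, 12)) {
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(wilcoxon_signed_rank_paired(x, y), oracle_signrank(x, y),
                 tolerance = 1e-12)
    # with ties and zeros
    x2 <- round(x, 1); y2 <- round(y, 1)
    expect_equal(wilcoxon_signed_rank_paired(x2, y2),
                 oracle_signrank(x2, y2), tolerance = 1e-12)
  }
})

test_that("exact signed-rank agrees with the reference implementation", {
  set.seed(62)
  for (i in 1:5) {
    x <- rnorm(10); y <- rnorm(10)   # continuous: no ties or zeros
    expect_equal(wilcoxon_signed_rank_paired(x, y),
                 stats::wilcox.test(x, y, paired = TRUE,
                                    exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Bonferroni decisions use the inclusive boundary", {
  out <- bonferroni(c(0.002, 0.152), m = 2)
  expect_identical(out$reject, c(TRUE, FALSE))
  expect_equal(out$p_adjusted, c(0.004, 0.304))
  expect_true(bonferroni(0.025, m = 2)$reject)     # exactly alpha/m
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "at least")
})

test_that("evaluate_features guards its inputs and reports all features", {
  ds <- tiny_dataset()
  expect_error(evaluate_features(ds, n_folds = 1), "at least 2")
  expect_error(evaluate_features(ds, n_folds = 13), "at least")
  ev <- evaluate_features(ds, n_folds = 3, seed = 4)
  expect_named(ev$roc, c("wavelet", "upv", "lpv"))
  expect_identical(nrow(ev$comparisons), 4L)
  ev2 <- evaluate_features(ds, n_folds = 3, seed = 4)
  expect_equal(ev2$roc$wavelet$auc, ev$roc$wavelet$auc)
})
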