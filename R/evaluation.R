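# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Stratified k-fold split
#'
#' Partitions a labeled dataset into `n_folds` folds so that each fold holds
#' approximately `1/n_folds` of the falls and of the ADLs. Reproducible from
#' `seed`; the caller's RNG state is untouched.
#'
#' @param dataset a [fall_dataset()], or a character vector of labels.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return An object of class `"cv_split"`: integer fold assignment per
#'   recording plus `n_folds` and `seed`.
#' @export
stratified_kfold <- function(dataset, n_folds = 10L, seed = 1L) {
  labels <- if (inherits(dataset, "fall_dataset")) dataset$label else
    as.character(dataset)
  if (n_folds < 2L) stop("`n_folds` must be at least 2", call. = FALSE)
  tab <- table(labels)
  if (any(tab[c("fall", "adl")] < n_folds) || anyNA(tab[c("fall", "adl")]))
    stop("need at least `n_folds` recordings of each class", call. = FALSE)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (lab in unique(labels)) {
      idx <- sample(which(labels == lab))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  structure(list(fold = fold, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "cv_split")
}

#' Cross-validated feature scores
#'
#' For each fold, fits the adapted wavelet on the *training* falls only
#' (the prototype must never see the recordings it scores), then computes
#' all three features for the held-out recordings. UPV and LPV need no
#' training but are computed on the same held-out sets for paired
#' comparisons. Every recording is scored exactly once.
#'
#' @param dataset a [fall_dataset()].
#' @param cfg a [feature_config()].
#' @param split a [stratified_kfold()] split of `dataset`.
#' @param ... passed to [fall_wavelet()] (e.g. `poly_degree`, `method`).
#' @return A feature-table data.frame with an extra `fold` column.
#' @export
cross_validated_scores <- function(dataset, cfg = feature_config(), split,
                                   ...) {
  stopifnot(inherits(dataset, "fall_dataset"), inherits(split, "cv_split"),
            length(split$fold) == length(dataset$recordings))
  out <- vector("list", split$n_folds)
  for (k in seq_len(split$n_folds)) {
    train_falls <- which(split$fold != k & dataset$label == "fall")
    if (length(train_falls) == 0L)
      stop(sprintf("training set of fold %d contains no falls", k),
           call. = FALSE)
    fw <- fall_wavelet(dataset$recordings[train_falls], ...)
    test <- which(split$fold == k)
    sub <- fall_dataset(dataset$recordings[test])
    tab <- build_feature_table(sub, fw, cfg)
    tab$fold <- k
    out[[k]] <- tab
  }
  do.call(rbind, out)
}

# Empirical ROC vertices of one score set under the "score > threshold =>
# fall" rule. Returns vertices ordered by increasing specificity, including
# (spec 0, sens 1) and (spec 1, sens 0), with the realizing threshold.
roc_vertices <- function(scores, is_fall) {
  stopifnot(any(is_fall), any(!is_fall))
  th <- c(-Inf, sort(unique(scores)))
  sens <- vapply(th, function(q) mean(scores[is_fall] > q), numeric(1))
  spec <- vapply(th, function(q) mean(scores[!is_fall] <= q), numeric(1))
  data.frame(threshold = th, specificity = spec, sensitivity = sens)
}

# Vertical sample of a fold ROC at fixed specificities. The curve is the
# threshold-ordered vertex path (specificity non-decreasing, sensitivity
# non-increasing): at a grid specificity strictly between two vertices the
# connecting segment is interpolated linearly — ties between classes thus
# trace the diagonal — and where several vertices share one specificity
# (a vertical run) the sample takes the achievable maximum, i.e. the
# earliest-threshold vertex.
interp_sens <- function(vertices, spec_grid) {
  s <- vertices$specificity; y <- vertices$sensitivity
  # j = first vertex with specificity >= grid value (vertices are in
  # threshold order, so the first one carries the highest sensitivity)
  j <- vapply(spec_grid, function(g) match(TRUE, s >= g - 1e-12), integer(1))
  out <- numeric(length(spec_grid))
  for (k in seq_along(spec_grid)) {
    i <- j[k]
    if (s[i] <= spec_grid[k] + 1e-12 || i == 1L) { out[k] <- y[i]; next }
    f <- (spec_grid[k] - s[i - 1L]) / (s[i] - s[i - 1L])
    out[k] <- y[i - 1L] + f * (y[i] - y[i - 1L])
  }
  out
}

# Exact area under one fold's ROC: trapezoid over the threshold-ordered
# vertex path; equals the Mann-Whitney statistic / (n_pos * n_neg) with
# half credit for cross-class ties.
vertex_auc <- function(vertices) {
  s <- vertices$specificity; y <- vertices$sensitivity
  sum(diff(s) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Vertically averaged cross-validated ROC
#'
#' Builds one ROC per fold from its held-out scores (sensitivity = fraction
#' of falls with score strictly above the threshold, specificity = fraction
#' of ADLs at or below it), samples each fold's curve at fixed specificities
#' from 0 to 1 in steps of 0.001 (linear interpolation between ROC
#' vertices), and averages the sensitivities across folds at each grid
#' point. The area under the averaged curve is computed by the trapezoid
#' rule on the grid; per-fold AUCs are computed exactly from the fold
#' vertices. The Youden index (sensitivity + specificity - 1) is maximized
#' over the grid to select the operating point; the reported threshold is
#' the median across folds of the smallest per-fold threshold reaching the
#' chosen specificity.
#'
#' @param scores a feature-table data.frame with a `fold` column, as from
#'   [cross_validated_scores()] (a table without `fold` is treated as one
#'   fold).
#' @param feature which feature to evaluate: `"wavelet"`, `"upv"` or
#'   `"lpv"`.
#' @param direction `">"` if larger scores are more fall-like (wavelet,
#'   UPV), `"<"` if smaller are (LPV: the deeper the free-fall dip, the more
#'   fall-like). `"auto"` picks by feature name.
#' @param spec_step specificity grid step (default 0.001).
#' @return An object of class `"roc_result"`: `specificity` (grid),
#'   `sensitivity` (grid-wise mean), `auc`, `max_yi`, `best_point`
#'   (sensitivity, specificity, threshold), `fold_auc`, `fold_yi`,
#'   `feature`, `n_folds`.
#' @export
roc_vertical_average <- function(scores, feature = c("wavelet", "upv", "lpv"),
                                 direction = c("auto", ">", "<"),
                                 spec_step = 0.001) {
  feature <- match.arg(feature)
  direction <- match.arg(direction)
  if (direction == "auto") direction <- if (feature == "lpv") "<" else ">"
  col <- switch(feature, wavelet = "wavelet", upv = "upv_g", lpv = "lpv_g")
  if (is.null(scores$fold)) scores$fold <- 1L
  x <- scores[[col]]
  if (direction == "<") x <- -x
  is_fall <- scores$label == "fall"
  grid <- seq(0, 1, by = spec_step)
  folds <- sort(unique(scores$fold))
  sens_mat <- matrix(NA_real_, nrow = length(grid), ncol = length(folds))
  fold_auc <- fold_yi <- numeric(length(folds))
  verts <- vector("list", length(folds))
  for (j in seq_along(folds)) {
    in_fold <- scores$fold == folds[j]
    if (!any(is_fall & in_fold) || !any(!is_fall & in_fold))
      stop(sprintf("fold %s has only one class in its test set", folds[j]),
           call. = FALSE)
    v <- roc_vertices(x[in_fold], is_fall[in_fold])
    verts[[j]] <- v
    sens_mat[, j] <- interp_sens(v, grid)
    fold_auc[j] <- vertex_auc(v)
    fold_yi[j] <- max(v$sensitivity + v$specificity - 1)
  }
  sens <- rowMeans(sens_mat)
  auc <- sum(diff(grid) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  yi <- sens + grid - 1
  best_yi <- max(yi)
  best_i <- max(which(yi == best_yi))  # ties: prefer higher specificity
  best_spec <- grid[best_i]
  # per-fold threshold: smallest threshold whose specificity reaches best_spec
  th <- vapply(verts, function(v) {
    ok <- v$specificity >= best_spec - 1e-12
    min(v$threshold[ok])
  }, numeric(1))
  th <- th[is.finite(th)]
  best_th <- if (length(th)) stats::median(th) else NA_real_
  if (direction == "<" && is.finite(best_th)) best_th <- -best_th
  structure(list(specificity = grid, sensitivity = sens, auc = auc,
                 max_yi = best_yi,
                 best_point = list(sensitivity = sens[best_i],
                                   specificity = best_spec,
                                   threshold = best_th),
                 fold_auc = fold_auc, fold_yi = fold_yi, feature = feature,
                 direction = direction, n_folds = length(folds)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %s feature, %d fold(s)\n", x$feature, x$n_folds))
  cat(sprintf("  AUC %.3f | max YI %.3f at sensitivity %.1f%%, specificity %.1f%% (threshold %.3g)\n",
              x$auc, x$max_yi, 100 * x$best_point$sensitivity,
              100 * x$best_point$specificity, x$best_point$threshold))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, add = FALSE, col = 1, ...) {
  if (!add)
    graphics::plot(1 - x$specificity, x$sensitivity, type = "l", col = col,
                   xlab = "1 - specificity", ylab = "sensitivity",
                   xlim = c(0, 1), ylim = c(0, 1), ...)
  else graphics::lines(1 - x$specificity, x$sensitivity, col = col, ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}

#' Youden's index
#'
#' `sensitivity + specificity - 1`: zero for a chance-level operating point,
#' one for a perfect one. Its maximum over an ROC curve selects the optimal
#' sensitivity/specificity combination.
#'
#' @param sensitivity,specificity numbers in \[0, 1\] (vectorized).
#' @return `sensitivity + specificity - 1`.
#' @export
youden_index <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1 | specificity < 0 | specificity > 1))
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  sensitivity + specificity - 1
}

#' Operating point maximizing Youden's index
#'
#' @param roc a `"roc_result"`.
#' @return A list with `sensitivity`, `specificity`, `threshold`, `yi`.
#' @export
best_operating_point <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  c(roc$best_point, list(yi = roc$max_yi))
}

#' False-alarm count and hourly rate
#'
#' At a given operating specificity, `(1 - specificity) * n_adl` of the ADL
#' recordings are misclassified as falls; dividing by the monitoring time
#' they were drawn from gives the expected false alarms per hour of wear.
#'
#' @param specificity operating specificity in \[0, 1\].
#' @param n_adl number of ADL recordings.
#' @param total_hours hours of monitoring the ADLs were extracted from.
#' @return A list with `false_alarms` and `per_hour`.
#' @export
false_alarm_rate <- function(specificity, n_adl, total_hours) {
  if (specificity < 0 || specificity > 1)
    stop("`specificity` must lie in [0, 1]", call. = FALSE)
  if (n_adl < 0) stop("`n_adl` must be non-negative", call. = FALSE)
  if (total_hours <= 0) stop("`total_hours` must be positive", call. = FALSE)
  fa <- (1 - specificity) * n_adl
  list(false_alarms = fa, per_hour = fa / total_hours)
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided p-value for paired samples. Zero differences are dropped and
#' ties among the absolute differences receive mid-ranks. For up to
#' `exact_max` nonzero differences the p-value is exact: the full null
#' distribution of the positive-rank sum over all 2^m equiprobable sign
#' assignments is computed (by the shift algorithm over doubled mid-ranks,
#' identical to direct enumeration), and the two-sided p is twice the
#' smaller tail, capped at 1. Above `exact_max` a normal approximation with
#' tie-corrected variance is used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_max largest number of nonzero differences for which the
#'   exact distribution is used (default 25).
#' @return The two-sided p-value.
#' @export
wilcoxon_signed_rank_paired <- function(x, y, exact_max = 25L) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (m <= exact_max) {
    r2 <- as.integer(round(2 * r))  # doubled mid-ranks are integers
    tot <- sum(r2)
    # f[k+1] = number of sign assignments with doubled rank-sum k
    f <- numeric(tot + 1L); f[1L] <- 1
    for (ri in r2) {
      g <- f
      g[(ri + 1L):(tot + 1L)] <- g[(ri + 1L):(tot + 1L)] + f[1L:(tot + 1L - ri)]
      f <- g
    }
    f <- f / 2^m
    w2 <- as.integer(round(2 * w))
    p_le <- sum(f[1L:(w2 + 1L)])
    p_ge <- sum(f[(w2 + 1L):(tot + 1L)])
    return(min(1, 2 * min(p_le, p_ge)))
  }
  mu <- m * (m + 1) / 4
  ties <- table(r)
  sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w - mu) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Bonferroni-corrected decisions
#'
#' @param p_values numeric vector of p-values.
#' @param m number of comparisons (default `length(p_values)`).
#' @param alpha family-wise error rate (default 0.05).
#' @return A data.frame with columns `p`, `p_adjusted` (`min(1, p * m)`) and
#'   `reject` (`p <= alpha / m`, boundary inclusive).
#' @export
bonferroni <- function(p_values, m = length(p_values), alpha = 0.05) {
  if (m < length(p_values))
    stop("`m` must be at least the number of tests", call. = FALSE)
  data.frame(p = p_values, p_adjusted = pmin(1, p_values * m),
             reject = p_values <= alpha / m)
}

#' Cross-validated evaluation of the three features
#'
#' End-to-end evaluation: stratified k-fold split, per-fold wavelet
#' refitting and held-out scoring, vertically averaged ROC per feature, and
#' paired exact Wilcoxon signed-rank comparisons of the per-fold AUCs and
#' Youden indices of the wavelet feature against UPV and LPV
#' (Bonferroni-corrected over the two comparisons per metric).
#'
#' @param dataset a [fall_dataset()].
#' @param n_folds number of CV folds (default 10).
#' @param seed integer seed for the fold split.
#' @param cfg a [feature_config()].
#' @param ... passed to [fall_wavelet()].
#' @return An object of class `"fall_eval"`: per-feature `"roc_result"`s
#'   (`$roc`), the cross-validated score table (`$scores`), the split, and
#'   the comparison table (`$comparisons`). 95% confidence intervals on AUC
#'   and max YI are mean +/- 1.96 * SD(fold values) / sqrt(n_folds).
#' @export
evaluate_features <- function(dataset, n_folds = 10L, seed = 1L,
                              cfg = feature_config(), ...) {
  split <- stratified_kfold(dataset, n_folds, seed)
  scores <- cross_validated_scores(dataset, cfg, split, ...)
  feats <- c("wavelet", "upv", "lpv")
  roc <- lapply(feats, function(f) roc_vertical_average(scores, f))
  names(roc) <- feats
  ci <- function(v) mean(v) + c(-1, 1) * 1.96 * stats::sd(v) / sqrt(length(v))
  cis <- lapply(roc, function(r) list(auc = ci(r$fold_auc), yi = ci(r$fold_yi)))
  cmp <- expand.grid(metric = c("auc", "yi"), baseline = c("upv", "lpv"),
                     stringsAsFactors = FALSE)
  cmp$p <- mapply(function(metric, baseline) {
    key <- if (metric == "auc") "fold_auc" else "fold_yi"
    wilcoxon_signed_rank_paired(roc$wavelet[[key]], roc[[baseline]][[key]])
  }, cmp$metric, cmp$baseline)
  adj <- do.call(rbind, lapply(split(cmp, cmp$metric), function(g)
    cbind(g, bonferroni(g$p, m = 2)[c("p_adjusted", "reject")])))
  rownames(adj) <- NULL
  structure(list(roc = roc, ci = cis, scores = scores, split = split,
                 comparisons = adj, n_folds = n_folds, seed = seed),
            class = "fall_eval")
}

#' @export
print.fall_eval <- function(x, ...) {
  cat(sprintf("Cross-validated fall-detection evaluation (%d folds, seed %d)\n",
              x$n_folds, x$seed))
  for (f in names(x$roc)) {
    r <- x$roc[[f]]
    ci <- x$ci[[f]]
    cat(sprintf("  %-7s AUC %.3f [%.3f, %.3f] | max YI %.3f [%.3f, %.3f] | sens %.1f%% spec %.1f%%\n",
                f, r$auc, ci$auc[1], ci$auc[2], r$max_yi, ci$yi[1], ci$yi[2],
                100 * r$best_point$sensitivity, 100 * r$best_point$specificity))
  }
  cat("  paired Wilcoxon (Bonferroni m = 2 per metric):\n")
  for (i in seq_len(nrow(x$comparisons)))
    cat(sprintf("    wavelet vs %s (%s): p = %.4g%s\n",
                x$comparisons$baseline[i], x$comparisons$metric[i],
                x$comparisons$p[i],
                if (x$comparisons$reject[i]) " *" else ""))
  invisible(x)
}

#' @export
plot.fall_eval <- function(x, ...) {
  cols <- c(wavelet = "blue", upv = "red", lpv = "darkgreen")
  plot(x$roc$wavelet, col = cols["wavelet"], ...)
  plot(x$roc$upv, add = TRUE, col = cols["upv"])
  plot(x$roc$lpv, add = TRUE, col = cols["lpv"])
  graphics::legend("bottomright", legend = sprintf("%s (AUC %.3f)",
                                                   names(x$roc),
                                                   vapply(x$roc, `[[`, numeric(1), "auc")),
                   col = cols, lty = 1, bty = "n")
  invisible(x)
}
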