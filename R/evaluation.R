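# Cross-validation over known associations and metrics for heavily
# imbalanced link prediction.

#' Partition the known associations into folds
#'
#' Only the positive entries of `Y` are partitioned; unknown pairs are
#' never masked. Fold sizes differ by at most one.
#'
#' @param Y Binary association matrix.
#' @param k_folds Number of folds (default 5).
#' @param seed Integer seed for the random partition.
#' @return A list of class `fold_plan`: `k_folds`, and `assignments`, a
#'   data frame with columns `i`, `j` (positions of positives) and
#'   `fold`.
#' @export
make_folds <- function(Y, k_folds = 5, seed = 1) {
  pos <- which(Y == 1, arr.ind = TRUE)
  n_pos <- nrow(pos)
  if (n_pos < k_folds)
    stop(sprintf("only %d known associations for %d folds", n_pos, k_folds),
         call. = FALSE)
  fold <- with_seed(seed, {
    sample(rep_len(seq_len(k_folds), n_pos))
  })
  structure(list(k_folds = as.integer(k_folds),
                 assignments = data.frame(i = pos[, 1], j = pos[, 2],
                                          fold = fold)),
            class = "fold_plan")
}

#' Mask one fold of positives out of the training matrix
#'
#' @param Y Binary association matrix.
#' @param plan A [make_folds()] plan for `Y`.
#' @param test_fold Fold id whose positives are hidden (set to 0).
#' @return A copy of `Y` with the test-fold positives zeroed.
#' @export
masked_training_matrix <- function(Y, plan, test_fold) {
  stopifnot(inherits(plan, "fold_plan"),
            test_fold %in% seq_len(plan$k_folds))
  a <- plan$assignments
  hide <- a[a$fold == test_fold, , drop = FALSE]
  Y[cbind(hide$i, hide$j)] <- 0
  Y
}

#' Confusion counts at a score threshold
#'
#' A pair is predicted positive iff its score is `>= threshold`.
#'
#' @param scores Numeric vector.
#' @param labels 0/1 vector of the same length.
#' @param threshold Decision threshold.
#' @return Named vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels), length(scores) > 0)
  pred <- scores >= threshold
  c(TP = sum(pred & labels == 1), FP = sum(pred & labels == 0),
    TN = sum(!pred & labels == 0), FN = sum(!pred & labels == 1))
}

#' Binary classification metrics from confusion counts
#'
#' Sensitivity (= recall = TPR), specificity, accuracy, precision, F1
#' and the Matthews correlation coefficient. Any metric whose
#' denominator vanishes is defined as 0.
#'
#' @param TP,FP,TN,FN Nonnegative counts (total > 0).
#' @return Named numeric vector.
#' @export
binary_metrics <- function(TP, FP, TN, FN) {
  TP <- unname(TP); FP <- unname(FP); TN <- unname(TN); FN <- unname(FN)
  safe_div <- function(num, den) if (den > 0) num / den else 0
  sens <- safe_div(TP, TP + FN)
  spec <- safe_div(TN, TN + FP)
  acc <- (TP + TN) / (TP + TN + FP + FN)
  prec <- safe_div(TP, TP + FP)
  f1 <- safe_div(2 * prec * sens, prec + sens)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mcc_den > 0) (TP * TN - FP * FN) / mcc_den else 0
  c(sensitivity = sens, specificity = spec, accuracy = acc,
    precision = prec, f1 = f1, mcc = mcc)
}

#' Area under the ROC curve
#'
#' Trapezoidal integral of the ROC curve over score thresholds, which
#' equals the Mann-Whitney probability that a random positive outscores
#' a random negative (ties counting one half).
#'
#' @param scores Numeric vector.
#' @param labels 0/1 vector; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  check_two_classes(labels)
  roc <- roc_points(scores, labels)
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Area under the precision-recall curve
#'
#' Non-interpolated average precision: thresholds step through the
#' distinct score values in descending order (tied scores form a single
#' step), and each step contributes its recall increment times the
#' precision at that threshold. With all scores tied this equals the
#' positive prevalence.
#'
#' @inheritParams auroc
#' @return AUPR in `(0, 1]`.
#' @export
aupr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("no positive labels: AUPR undefined", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- cumsum(rle(s)$lengths)  # end index of each tied score group
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

# ROC curve points over distinct thresholds (tie groups collapsed),
# anchored at (0,0) and (1,1).
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- cumsum(rle(s)$lengths)
  list(fpr = c(0, fp[last] / n_neg), tpr = c(0, tp[last] / n_pos))
}

check_two_classes <- function(labels) {
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0/1", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("both classes must be present", call. = FALSE)
  invisible(NULL)
}

#' Operating-point metrics at a fixed specificity
#'
#' Under heavy class imbalance a fixed high specificity (e.g. 0.95 or
#' 0.99) pins down a meaningful operating point. The threshold is the
#' smallest observed score value at which specificity reaches
#' `sp_level`; metrics are then computed via [binary_metrics()].
#'
#' @inheritParams auroc
#' @param sp_level Target specificity in (0, 1).
#' @return Named vector: the achieved `threshold`, `specificity`, and
#'   sensitivity/accuracy/precision/F1/Mcc at that threshold.
#' @export
metrics_at_specificity <- function(scores, labels, sp_level = 0.95) {
  check_two_classes(labels)
  stopifnot(sp_level > 0, sp_level < 1)
  neg <- scores[labels == 0]
  cand <- sort(unique(scores))
  for (t in cand) {
    if (sum(neg < t) / length(neg) >= sp_level) {
      cm <- confusion_counts(scores, labels, t)
      return(c(threshold = t,
               binary_metrics(cm["TP"], cm["FP"], cm["TN"], cm["FN"])))
    }
  }
  stop(sprintf("specificity %.3g unreachable at any observed threshold",
               sp_level), call. = FALSE)
}

#' True positives among the top-k predictions
#'
#' @inheritParams auroc
#' @param ks Integer cutoffs (each `<=` the number of scored pairs).
#' @return Named integer vector, one count per cutoff.
#' @export
topk_true_positives <- function(scores, labels, ks = c(20, 40, 60, 80, 100)) {
  stopifnot(length(scores) == length(labels), all(ks >= 1),
            all(ks <= length(scores)))
  ord <- order(scores, decreasing = TRUE)  # stable: ties keep input order
  ranked <- labels[ord]
  out <- vapply(ks, function(k) sum(ranked[seq_len(k)] == 1), integer(1))
  names(out) <- paste0("top", ks)
  out
}

#' Masked k-fold cross-validation of the full pipeline
#'
#' For each fold, the fold's positives are hidden from the training
#' matrix, the model is refit from scratch, and the fold's evaluation
#' set is its held-out positives (label 1) together with every pair that
#' is 0 in the full matrix (label 0); training positives are excluded.
#' Metrics are reported per fold and on the pooled scores of all folds.
#'
#' @inheritParams vemlda
#' @param k_folds Number of folds (default 5).
#' @param seed Seed for the fold partition (the model seed lives in
#'   `config`).
#' @param sp_levels Specificity levels for operating-point metrics.
#' @param ks Top-k cutoffs.
#' @return List of class `cv_report`: `per_fold` data frame (auroc/aupr
#'   per fold), `pooled` list (auroc, aupr, `at_specificity` matrix,
#'   `topk` counts), `mean_fold_auroc`, `mean_fold_aupr`, and the
#'   pooled `scores`/`labels`.
#' @export
cross_validate <- function(Y, X_l, X_d, config = train_config(), k_folds = 5,
                           seed = 1, sp_levels = c(0.95, 0.99),
                           ks = c(20, 40, 60, 80, 100)) {
  plan <- make_folds(Y, k_folds, seed)
  neg_idx <- which(Y == 0)
  per_fold <- vector("list", k_folds)
  pooled_scores <- numeric(0); pooled_labels <- integer(0)
  for (f in seq_len(k_folds)) {
    Y_train <- masked_training_matrix(Y, plan, f)
    fit <- vemlda(Y_train, X_l, X_d, config)
    a <- plan$assignments
    held <- a[a$fold == f, , drop = FALSE]
    pos_idx <- (held$j - 1L) * nrow(Y) + held$i
    sc <- c(fit$scores[pos_idx], fit$scores[neg_idx])
    lb <- c(rep(1L, length(pos_idx)), rep(0L, length(neg_idx)))
    per_fold[[f]] <- data.frame(fold = f, n_test_pos = length(pos_idx),
                                auroc = auroc(sc, lb), aupr = aupr(sc, lb))
    pooled_scores <- c(pooled_scores, sc)
    pooled_labels <- c(pooled_labels, lb)
  }
  per_fold <- do.call(rbind, per_fold)
  at_sp <- t(vapply(sp_levels,
                    function(sp) metrics_at_specificity(pooled_scores,
                                                        pooled_labels, sp),
                    numeric(7)))
  rownames(at_sp) <- paste0("sp", sp_levels)
  ks <- ks[ks <= length(pooled_scores)]
  structure(list(
    per_fold = per_fold,
    pooled = list(auroc = auroc(pooled_scores, pooled_labels),
                  aupr = aupr(pooled_scores, pooled_labels),
                  at_specificity = at_sp,
                  topk = topk_true_positives(pooled_scores, pooled_labels, ks)),
    mean_fold_auroc = mean(per_fold$auroc),
    mean_fold_aupr = mean(per_fold$aupr),
    scores = pooled_scores, labels = pooled_labels,
    k_folds = k_folds, seed = seed), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation over known associations\n", x$k_folds))
  print(x$per_fold, row.names = FALSE, digits = 4)
  cat(sprintf("pooled AUROC %.4f, pooled AUPR %.4f\n",
              x$pooled$auroc, x$pooled$aupr))
  cat("operating points at fixed specificity:\n")
  print(round(x$pooled$at_specificity, 4))
  cat("true positives in top-k predictions:\n")
  print(x$pooled$topk)
  invisible(x)
}
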