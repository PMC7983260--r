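test_that("fold plans partition the positives evenly and reproducibly", {
  Y <- matrix(0, 5, 4)
  Y[sample(20, 10)] <- 1
  plan <- make_folds(Y, 5, seed = 1)
  expect_equal(sort(table(plan$assignments$fold)), sort(rep(2L, 5)),
               ignore_attr = TRUE)
  # union of folds is exactly the positive set, each assigned once
  key <- paste(plan$assignments$i, plan$assignments$j)
  pos <- which(Y == 1, arr.ind = TRUE)
  expect_setequal(key, paste(pos[, 1], pos[, 2]))
  expect_equal(anyDuplicated(key), 0L)
  expect_identical(plan, make_folds(Y, 5, seed = 1))
  expect_false(identical(plan$assignments$fold,
                         make_folds(Y, 5, seed = 2)$assignments$fold))
  expect_error(make_folds(Y, 11), "11 folds")
})

test_that("masking hides exactly the test fold and is reversible", {
  set.seed(3)
  Y <- matrix(rbinom(60, 1, 0.3), 6, 10)
  plan <- make_folds(Y, 4, seed = 2)
  for (f in 1:4) {
    Ym <- masked_training_matrix(Y, plan, f)
    a <- plan$assignments
    held <- a[a$fold == f, ]
    expect_true(all(Ym[cbind(held$i, held$j)] == 0))
    expect_equal(sum(Y) - sum(Ym), nrow(held))
    # restoring the held positives reproduces Y
    Ym[cbind(held$i, held$j)] <- 1
    expect_equal(Ym, Y)
  }
})

test_that("confusion counts follow the score >= threshold convention", {
  expect_equal(confusion_counts(c(0.9, 0.1), c(1, 0), 0.5),
               c(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  expect_equal(sum(confusion_counts(runif(10), rbinom(10, 1, 0.5), 0)[c("TP", "FP")]),
               10L)
  cm <- confusion_counts(c(0.2, 0.4), c(1, 0), 0.41)
  expect_equal(unname(cm[c("TP", "FP")]), c(0L, 0L))
  # boundary: equality counts as positive
  expect_equal(confusion_counts(0.5, 1, 0.5)[["TP"]], 1L)
})

test_that("binary metrics evaluate the closed-form definitions", {
  perfect <- binary_metrics(1, 0, 1, 0)
  expect_equal(unname(perfect), c(1, 1, 1, 1, 1, 1))
  expect_equal(binary_metrics(0, 1, 0, 1)[["mcc"]], -1)
  m <- binary_metrics(2, 1, 3, 2)
  expect_equal(m[["sensitivity"]], 0.5)
  expect_equal(m[["specificity"]], 0.75)
  expect_equal(m[["precision"]], 2 / 3)
  expect_equal(m[["accuracy"]], 5 / 8)
  expect_equal(m[["f1"]], 4 / 7)
  expect_equal(m[["mcc"]], (2 * 3 - 1 * 2) / sqrt(4 * 3 * 5 * 4))
  # vanishing denominators resolve to zero
  expect_equal(binary_metrics(0, 0, 5, 5)[["precision"]], 0)
  expect_equal(binary_metrics(0, 0, 5, 5)[["mcc"]], 0)
})

test_that("mcc is symmetric under a joint class/prediction swap", {
  set.seed(4)
  for (i in 1:20) {
    cm <- rmultinom(1, 50, rep(0.25, 4))
    m1 <- binary_metrics(cm[1], cm[2], cm[3], cm[4])[["mcc"]]
    m2 <- binary_metrics(cm[3], cm[4], cm[1], cm[2])[["mcc"]]
    expect_equal(m1, m2, tolerance = 1e-12)
  }
})

test_that("auroc and aupr reproduce hand-enumerated values", {
  s <- c(0.9, 0.8, 0.3, 0.1); y <- c(1, 0, 1, 0)
  expect_equal(auroc(s, y), 0.75)
  expect_equal(aupr(s, y), 1 * (1 / 2) + (2 / 3) * (1 / 2))
  # perfect separation
  expect_equal(auroc(c(3, 2, 1), c(1, 1, 0)), 1)
  expect_equal(aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # all tied: chance AUROC, prevalence AUPR
  expect_equal(auroc(rep(0.5, 8), rep(c(1, 0), 4)), 0.5)
  expect_equal(aupr(rep(0.5, 8), c(1, 1, 1, 0, 0, 0, 0, 0)), 3 / 8)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
  expect_error(aupr(1:3, c(0, 0, 0)), "no positive")
})

test_that("ranking metrics agree with brute-force oracles under ties", {
  set.seed(5)
  for (i in 1:100) {
    n <- sample(20:120, 1)
    scores <- round(runif(n), sample(1:2, 1))  # coarse grid forces ties
    labels <- rbinom(n, 1, runif(1, 0.1, 0.6))
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels),
                 tolerance = 1e-9)
    expect_equal(aupr(scores, labels), oracle_aupr(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("auroc is invariant under strictly monotone score transforms", {
  set.seed(6)
  scores <- rnorm(60); labels <- rbinom(60, 1, 0.4)
  a <- auroc(scores, labels)
  expect_equal(auroc(exp(scores), labels), a, tolerance = 1e-12)
  expect_equal(auroc(qlogis(plogis(scores)), labels), a, tolerance = 1e-9)
})

test_that("random scores give chance-level auroc on large samples", {
  set.seed(7)
  n <- 20000
  a <- auroc(runif(n), rbinom(n, 1, 0.3))
  # 3 sigma of the Mann-Whitney null
  n1 <- 0.3 * n; n0 <- 0.7 * n
  sd0 <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(a - 0.5), 3 * sd0)
})

test_that("fixed-specificity thresholds exclude the right negatives", {
  # 100 negatives evenly spaced, plus separated positives
  neg <- seq(0.1, 0.9, length.out = 100)
  pos <- c(0.95, 0.97, 0.5)
  scores <- c(neg, pos); labels <- c(rep(0, 100), rep(1, 3))
  m <- metrics_at_specificity(scores, labels, 0.95)
  # threshold admits exactly the top 5 negatives as false positives
  expect_equal(sum(neg >= m[["threshold"]]), 5)
  expect_gte(m[["specificity"]], 0.95)
  # perfect separation keeps sensitivity 1 at any level
  m2 <- metrics_at_specificity(c(1:5 / 10, 0.9, 0.95), c(rep(0, 5), 1, 1), 0.99)
  expect_equal(m2[["sensitivity"]], 1)
  # specificity 1 is outside the open interval
  expect_error(metrics_at_specificity(scores, labels, 1), "sp_level")
  expect_error(metrics_at_specificity(rep(0.5, 4), c(0, 0, 1, 1), 0.95),
               "unreachable")
})

test_that("top-k counts follow the descending-score order", {
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.1)
  labels <- c(1, 1, 0, 1, 0)
  expect_equal(unname(topk_true_positives(scores, labels, c(1, 2, 3, 5))),
               c(1L, 2L, 2L, 3L))
  # perfect ranking saturates at the number of positives
  expect_equal(topk_true_positives(5:1, c(1, 1, 0, 0, 0), 4)[["top4"]], 2L)
  expect_equal(topk_true_positives(5:1, c(1, 1, 1, 0, 0), 2)[["top2"]], 2L)
  expect_error(topk_true_positives(scores, labels, 9), "ks <= length")
})

test_that("top-k counts track prevalence under random scoring", {
  set.seed(8)
  counts <- replicate(300, {
    topk_true_positives(runif(100), rbinom(100, 1, 0.2), 20)[["top20"]]
  })
  expect_equal(mean(counts), 20 * 0.2, tolerance = 0.3)
})

test_that("cross-validation evaluates held-out positives against unknowns", {
  dat <- tiny_problem()
  cfg <- tiny_config(epochs = 15)
  rep <- cross_validate(dat$Y, dat$X_l, dat$X_d, cfg, k_folds = 5, seed = 1,
                        ks = c(10, 20))
  expect_s3_class(rep, "cv_report")
  expect_equal(nrow(rep$per_fold), 5)
  expect_equal(sum(rep$per_fold$n_test_pos), sum(dat$Y))
  n_neg <- sum(dat$Y == 0)
  expect_equal(length(rep$scores), sum(dat$Y) + 5 * n_neg)
  expect_true(all(rep$per_fold$auroc >= 0 & rep$per_fold$auroc <= 1))
  expect_true(all(rep$pooled$topk <= c(10, 20)))
  # reproducible given both seeds
  rep2 <- cross_validate(dat$Y, dat$X_l, dat$X_d, cfg, k_folds = 5, seed = 1,
                         ks = c(10, 20))
  expect_identical(rep$pooled$auroc, rep2$pooled$auroc)
  expect_output(print(rep), "pooled AUROC")
})
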