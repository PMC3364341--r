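# SE/SP/CO, ROC/AUC, cross-validation, PCA and applicability domain.

test_that("confusion statistics reproduce direct arithmetic", {
  truth <- c(rep(1, 10), rep(-1, 10))
  pred <- c(rep(1, 9), -1, rep(-1, 8), 1, 1)
  cs <- confusion_stats(truth, pred)
  expect_equal(cs$counts, c(TP = 9, FP = 2, TN = 8, FN = 1))
  expect_equal(cs$SE, 90)
  expect_equal(cs$SP, 80)
  expect_equal(cs$CO, 85)
  perfect <- confusion_stats(truth, truth)
  expect_equal(c(perfect$SE, perfect$SP, perfect$CO), c(100, 100, 100))
  allpos <- confusion_stats(truth, rep(1, 20))
  expect_equal(c(allpos$SE, allpos$SP, allpos$CO), c(100, 0, 50))
})

test_that("metrics for an absent class are NA, not zero", {
  cs <- confusion_stats(c(1, 1), c(1, -1))
  expect_true(is.na(cs$SP))
  expect_equal(cs$SE, 50)
  expect_error(confusion_stats(integer(0), integer(0)), "empty")
  expect_error(confusion_stats(c(1, 0), c(1, 1)), "labels")
})

test_that("CO is the prevalence-weighted mean of SE and SP", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    truth <- sample(c(1L, -1L), n, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(truth)) < 2) next
    pred <- sample(c(1L, -1L), n, replace = TRUE)
    cs <- confusion_stats(truth, pred)
    npos <- sum(truth == 1)
    expect_equal(cs$CO, (npos * cs$SE + (n - npos) * cs$SP) / n,
                 tolerance = 1e-9)
  }
})

test_that("ROC endpoints behave as the normalization demands", {
  expect_equal(roc_curve_auc(c(1, -1), c(0.9, 0.1))$auc, 100)
  expect_equal(roc_curve_auc(c(1, -1), c(0.1, 0.9))$auc, 0)
  r <- roc_curve_auc(rep(c(1, -1), 50), rep(c(0.9, 0.1), 50))
  expect_equal(r$auc, 100)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(utils::tail(r$points$fpr, 1), 1)
  expect_equal(utils::tail(r$points$tpr, 1), 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  # one vertex per unique score, plus the origin
  s <- c(0.9, 0.9, 0.5, 0.1)
  expect_equal(nrow(roc_curve_auc(c(1, -1, 1, -1), s)$points), 4)
  expect_error(roc_curve_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("trapezoid AUC equals the Mann-Whitney oracle with ties", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(6:40, 1)
    truth <- c(rep(1L, ceiling(n / 2)), rep(-1L, floor(n / 2)))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force ties often
    expect_equal(roc_curve_auc(truth, scores)$auc,
                 oracle_auc(truth, scores), tolerance = 1e-9)
  }
})

test_that("stratified cross-validation partitions and pools correctly", {
  ds <- separable_dataset(10)
  cv <- cross_validate(ds, k = 5, learner = list(method = "rf",
                                                 ntree = 20), seed = 3)
  expect_equal(sum(cv$pooled$counts), 10)
  expect_equal(cv$pooled$CO, 100)
  expect_equal(unname(cv$mean["CO"]), 100)
  expect_error(cross_validate(separable_dataset(4), k = 10), "exceeds")
})

test_that("leave-one-out pooling equals sequential single holdout", {
  ds <- separable_dataset(12, p = 4)
  k <- n_pairs(ds)
  cv <- cross_validate(ds, k = k, learner = list(method = "rf", ntree = 20),
                       seed = 1)
  # sequential holdout with the same per-fold seeds and fold assignment
  folds <- dtiforge:::.stratified_folds(ds$y, k, seed = 1)
  counts <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  for (f in seq_len(k)) {
    tr <- pairs_subset(ds, which(folds != f))
    te <- pairs_subset(ds, which(folds == f))
    fit <- dti_fit(tr, "rf", ntree = 20,
                   seed = dtiforge:::derive_seed(1, paste0("fold", f)))
    cs <- confusion_stats(te$y, predict(fit, te, type = "label"))
    counts <- counts + cs$counts
  }
  expect_equal(cv$pooled$counts, counts)
})

test_that("PCA projects collinear data onto one component", {
  line <- cbind(1:10, 2 * (1:10), -0.5 * (1:10))
  colnames(line) <- paste0("f", 1:3)
  p <- pca_project(line, k = 1, standardize = FALSE)
  expect_equal(p$explained[1], 1, tolerance = 1e-9)
  set.seed(4)
  m <- matrix(rnorm(80), 16, 5, dimnames = list(NULL, paste0("f", 1:5)))
  p3 <- pca_project(m, k = 3)
  expect_true(all(diff(p3$explained) <= 1e-12))
  # the mean point projects to the origin
  centre <- predict(p3$fit, t(colMeans(scale(m) * 0) + colMeans(m)))
  expect_equal(unname(centre[1, 1:3]), rep(0, 3), tolerance = 1e-9)
  expect_error(pca_project(line, k = 3, standardize = FALSE), "rank")
})

test_that("applicability domain flags out-of-range features by name", {
  set.seed(5)
  train <- matrix(runif(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  q <- rbind(train[3, ], train[5, ])
  q[2, "f2"] <- max(train[, "f2"]) * 1.01 + 0.01
  rownames(q) <- c("a", "b")
  ad <- applicability_domain(train, q)
  expect_true(ad$in_domain[1])
  expect_false(ad$in_domain[2])
  expect_match(ad$offending[2], "f2")
  empty <- applicability_domain(train, train[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
  qq <- q
  colnames(qq)[2] <- "zz"
  expect_error(applicability_domain(train, qq), "match")
})
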