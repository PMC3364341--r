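# Model evaluation: confusion statistics (SE/SP/CO), ROC curves with AUC on
# the 0-100 scale, k-fold cross-validation, PCA projection and the
# min-max applicability domain.

#' Confusion counts and SE/SP/CO
#'
#' Sensitivity SE = TP/(TP+FN): the fraction of true interactions recovered.
#' Specificity SP = TN/(TN+FP): the fraction of non-interactions recovered.
#' Concordance CO = (TP+TN)/n: overall accuracy. All reported as
#' percentages; a metric whose defining class is absent is `NA`, never 0.
#'
#' @param truth Integer labels in \{+1, -1\}.
#' @param predicted Integer labels in \{+1, -1\}, same length.
#' @return List with `counts` (named TP, FP, TN, FN) and `SE`, `SP`, `CO`
#'   percentages.
#' @export
#' @examples
#' confusion_stats(c(1, 1, -1, -1), c(1, -1, -1, -1))
confusion_stats <- function(truth, predicted) {
  if (length(truth) == 0) stop("empty input")
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (!all(truth %in% c(-1, 1)) || !all(predicted %in% c(-1, 1)))
    stop("labels must be +1 or -1")
  tp <- sum(truth == 1 & predicted == 1)
  fn <- sum(truth == 1 & predicted == -1)
  tn <- sum(truth == -1 & predicted == -1)
  fp <- sum(truth == -1 & predicted == 1)
  se <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
  sp <- if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp)
  co <- 100 * (tp + tn) / length(truth)
  list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
       SE = se, SP = sp, CO = co)
}

#' ROC curve and normalized AUC
#'
#' Sweeps the classification threshold over the unique scores (tied scores
#' grouped, one ROC vertex per unique score), plotting the true-positive
#' rate against the false-positive rate. The area under the curve is
#' computed by the trapezoid rule — equivalent to the Mann-Whitney
#' U statistic with the midrank tie convention — and normalized to 100 for
#' a perfect inference (50 for a random one).
#'
#' @param truth Integer labels in \{+1, -1\}; both classes must be present.
#' @param scores Numeric scores, larger meaning more likely positive.
#' @return Object of class `dti_roc`: list with `points` (data.frame
#'   `threshold`, `fpr`, `tpr`, starting (0,0) and ending (1,1)) and `auc`
#'   on the 0-100 scale.
#' @export
#' @examples
#' roc_curve_auc(c(1, -1), c(0.9, 0.1))$auc  # 100
roc_curve_auc <- function(truth, scores) {
  if (length(truth) != length(scores))
    stop("truth and scores must have equal length")
  if (!all(truth %in% c(-1, 1))) stop("labels must be +1 or -1")
  npos <- sum(truth == 1)
  nneg <- sum(truth == -1)
  if (npos == 0 || nneg == 0)
    stop("both classes must be present to compute a ROC curve")
  if (any(!is.finite(scores))) stop("scores must be finite")
  thr <- sort(unique(scores), decreasing = TRUE)
  idx <- match(scores, thr)
  pos_at <- tabulate(idx[truth == 1], nbins = length(thr))
  neg_at <- tabulate(idx[truth == -1], nbins = length(thr))
  tpr <- c(0, cumsum(pos_at) / npos)
  fpr <- c(0, cumsum(neg_at) / nneg)
  auc <- 100 * sum(diff(fpr) * (utils::head(tpr, -1) +
                                  utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(threshold = c(Inf, thr), fpr = fpr,
                                     tpr = tpr),
                 auc = auc, n_pos = npos, n_neg = nneg),
            class = "dti_roc")
}

#' @export
print.dti_roc <- function(x, ...) {
  cat("ROC curve: ", nrow(x$points) - 1, " thresholds, ", x$n_pos,
      " positives / ", x$n_neg, " negatives\n", sep = "")
  cat("AUC =", format(x$auc, digits = 5), "(0-100 scale)\n")
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param x A `dti_roc` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @method plot dti_roc
#' @export
plot.dti_roc <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "False positive rate (1 - specificity)",
                 ylab = "True positive rate (sensitivity)",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", bty = "n",
                   legend = paste0("AUC = ", format(x$auc, digits = 4)))
  invisible(x)
}

#' Evaluate a fitted model on a test set
#'
#' @param model A `dti_model`.
#' @param test A `pair_dataset`.
#' @param threshold RF binding-score threshold.
#' @return List with `SE`, `SP`, `CO`, `AUC`, `counts` and `roc`.
#' @export
evaluate_model <- function(model, test, threshold = 0.5) {
  pred <- predict.dti_model(model, test, type = "both",
                            threshold = threshold)
  cs <- confusion_stats(test$y, pred$label)
  roc <- if (length(unique(test$y)) == 2)
    roc_curve_auc(test$y, pred$score) else NULL
  list(SE = cs$SE, SP = cs$SP, CO = cs$CO,
       AUC = if (is.null(roc)) NA_real_ else roc$auc,
       counts = cs$counts, roc = roc)
}

#' Internal k-fold cross-validation
#'
#' Splits the dataset into k label-stratified folds (so SE and SP remain
#' defined in every fold), trains on k-1 folds and evaluates on the held-out
#' fold, once per fold. Reports per-fold SE/SP/CO/AUC, their across-fold
#' means (`NA` folds skipped, with a count), and metrics pooled over the
#' per-fold confusion counts. Deterministic given `seed`.
#'
#' @param dataset A `pair_dataset` (unscaled; each fold is scaled on its own
#'   training part).
#' @param k Number of folds (default 5).
#' @param learner List of arguments for [dti_fit()] (at least `method`).
#' @param seed Integer seed.
#' @param threshold RF classification threshold.
#' @return Object of class `dti_cv`: list with `folds` (data.frame),
#'   `mean` (named vector), `pooled` (list) and `n_na` (NA fold counts).
#' @export
cross_validate <- function(dataset, k = 5, learner = list(method = "rf"),
                           seed = NULL, threshold = 0.5) {
  stopifnot(inherits(dataset, "pair_dataset"))
  n <- n_pairs(dataset)
  if (k > n) stop("k = ", k, " exceeds n = ", n)
  folds <- .stratified_folds(dataset$y, k, seed = seed)
  per <- data.frame(fold = seq_len(k), SE = NA_real_, SP = NA_real_,
                    CO = NA_real_, AUC = NA_real_)
  pooled <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  scores_all <- numeric(0)
  truth_all <- integer(0)
  for (f in seq_len(k)) {
    tr <- pairs_subset(dataset, which(folds != f), role = "train")
    te <- pairs_subset(dataset, which(folds == f), role = "test")
    args <- c(list(train = tr,
                   seed = derive_seed(seed %||% 0L, paste0("fold", f))),
              learner)
    model <- do.call(dti_fit, args)
    pred <- predict.dti_model(model, te, type = "both",
                              threshold = threshold)
    cs <- confusion_stats(te$y, pred$label)
    per$SE[f] <- cs$SE
    per$SP[f] <- cs$SP
    per$CO[f] <- cs$CO
    per$AUC[f] <- if (length(unique(te$y)) == 2)
      roc_curve_auc(te$y, pred$score)$auc else NA_real_
    pooled <- pooled + cs$counts
    scores_all <- c(scores_all, pred$score)
    truth_all <- c(truth_all, te$y)
  }
  n_na <- colSums(is.na(per[, c("SE", "SP", "CO", "AUC")]))
  means <- colMeans(per[, c("SE", "SP", "CO", "AUC")], na.rm = TRUE)
  pooled_stats <- list(
    counts = pooled,
    SE = if (pooled["TP"] + pooled["FN"] == 0) NA_real_ else
      unname(100 * pooled["TP"] / (pooled["TP"] + pooled["FN"])),
    SP = if (pooled["TN"] + pooled["FP"] == 0) NA_real_ else
      unname(100 * pooled["TN"] / (pooled["TN"] + pooled["FP"])),
    CO = unname(100 * (pooled["TP"] + pooled["TN"]) / sum(pooled)),
    AUC = if (length(unique(truth_all)) == 2)
      roc_curve_auc(truth_all, scores_all)$auc else NA_real_)
  structure(list(folds = per, mean = means, pooled = pooled_stats,
                 n_na = n_na, k = k, learner = learner),
            class = "dti_cv")
}

#' @export
print.dti_cv <- function(x, ...) {
  cat(x$k, "-fold cross-validation (", x$learner$method %||% "rf", ")\n",
      sep = "")
  print(round(x$folds, 2), row.names = FALSE)
  cat("mean:  ", paste(names(x$mean),
                       format(round(x$mean, 2)), sep = "=",
                       collapse = "  "), "\n")
  cat("pooled:", paste(c("SE", "SP", "CO", "AUC"),
                       format(round(unlist(x$pooled[c("SE", "SP", "CO",
                                                      "AUC")]), 2)),
                       sep = "=", collapse = "  "), "\n")
  if (any(x$n_na > 0))
    cat("folds with undefined metrics skipped in means:",
        paste(names(x$n_na)[x$n_na > 0], x$n_na[x$n_na > 0], sep = ":",
              collapse = ", "), "\n")
  invisible(x)
}

#' PCA projection of a descriptor matrix
#'
#' Centered principal component analysis, by default with features
#' standardized to unit variance first (descriptor scales are
#' incommensurable); zero-variance features are dropped before
#' standardization.
#'
#' @param m Descriptor matrix (rows = samples).
#' @param k Number of components (default 3); must not exceed the rank.
#' @param standardize Scale features to unit variance (default `TRUE`).
#' @return List with `scores` (n x k), `explained` (fraction of variance
#'   per component, non-increasing), and the `prcomp` fit.
#' @export
pca_project <- function(m, k = 3, standardize = TRUE) {
  if (nrow(m) < 2) stop("PCA needs at least 2 rows")
  if (standardize) {
    v <- apply(m, 2, stats::var)
    m <- m[, v > 0, drop = FALSE]
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = standardize)
  pos <- sum(fit$sdev > max(fit$sdev) * 1e-9)
  if (k > pos)
    stop("k = ", k, " exceeds the rank (", pos, ") of the centered matrix")
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)], fit = fit)
}

#' Min-max applicability domain check
#'
#' A query is in-domain iff every feature lies within the min-max range of
#' that feature over the training samples.
#'
#' @param train Training feature matrix.
#' @param queries Query feature matrix over the same (named) feature space.
#' @return Data frame with `id`, `in_domain`, and `offending` (comma-joined
#'   names of out-of-range features, `""` when in-domain).
#' @export
applicability_domain <- function(train, queries) {
  if (is.null(colnames(train)) || is.null(colnames(queries)) ||
      !identical(colnames(train), colnames(queries)))
    stop("train and query feature names must match exactly")
  lo <- apply(train, 2, min)
  hi <- apply(train, 2, max)
  if (nrow(queries) == 0)
    return(data.frame(id = character(0), in_domain = logical(0),
                      offending = character(0), stringsAsFactors = FALSE))
  out_lo <- sweep(queries, 2, lo, "<")
  out_hi <- sweep(queries, 2, hi, ">")
  off <- out_lo | out_hi
  data.frame(
    id = rownames(queries) %||% as.character(seq_len(nrow(queries))),
    in_domain = rowSums(off) == 0,
    offending = apply(off, 1, function(r)
      paste(colnames(queries)[r], collapse = ",")),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a metrics report as JSON and Markdown
#'
#' @param metrics Named list / nested list of metric values.
#' @param json_path,md_path Output paths (either may be `NULL`).
#' @return Invisibly, the metrics list.
#' @export
write_metrics_report <- function(metrics, json_path = NULL,
                                 md_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(metrics, json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (!is.null(md_path)) {
    flat <- unlist(metrics)
    lines <- c("| metric | value |", "| --- | --- |",
               paste0("| ", names(flat), " | ",
                      vapply(flat, function(v)
                        format(v, digits = 6), character(1)), " |"))
    writeLines(lines, md_path)
  }
  invisible(metrics)
}
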