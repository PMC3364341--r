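# Model fitting: Random Forest and RBF-SVM classifiers over drug-target
# pair vectors, exposed through one fitting front end (dti_fit) that returns
# a classed model object with predict/print/summary methods.

#' Fit a drug-target interaction classifier
#'
#' Trains a classifier on a labelled pair dataset and returns a
#' `dti_model` holding the fitted learner, its configuration, the feature
#' scaling ranges and the training entity-id sets (used later to annotate
#' predictions as known/new).
#'
#' For `method = "rf"` an ensemble of `ntree` unpruned classification trees
#' is grown, each on a bootstrap sample of the training set with `mtry`
#' candidate features per node (defaults: 500 trees,
#' `mtry = floor(sqrt(M))` for M pair-vector dimensions). The per-pair
#' binding score is the fraction of trees voting "interaction", so its
#' granularity is `1/ntree`.
#'
#' For `method = "svm"` a soft-margin SVM with RBF kernel
#' \eqn{K(x, x') = \exp(-\gamma ||x - x'||^2)} is fitted; the cost C and
#' kernel width gamma are selected by grid search maximizing 5-fold
#' cross-validated accuracy on the training set, with ties broken toward
#' the smallest C, then the smallest gamma, and the winner refitted on the
#' full training set.
#'
#' @param train A `pair_dataset` containing both classes.
#' @param method `"rf"` or `"svm"`.
#' @param scale Scale features to `[-1, 1]` with ranges fitted on `train`
#'   (default `TRUE`; stored ranges are re-applied by `predict`). Set to
#'   `FALSE` if `train` is already scaled.
#' @param ntree,mtry Random-forest parameters.
#' @param C_grid,gamma_grid,cv_folds SVM grid-search parameters (defaults:
#'   \eqn{C = 2^{-5}, 2^{-3}, ..., 2^{15}},
#'   \eqn{\gamma = 2^{-15}, ..., 2^{3}}, 5 folds).
#' @param seed Integer seed controlling bootstrap/fold randomness.
#' @return Object of class `dti_model`.
#' @export
#' @examples
#' cat <- synthetic_catalog(n_drugs = 12, n_targets = 12, seed = 1)
#' ds <- build_pair_dataset(cat$catalog, seed = 2)
#' fit <- dti_fit(ds, method = "rf", ntree = 50, seed = 3)
#' fit
dti_fit <- function(train, method = c("rf", "svm"), scale = TRUE,
                    ntree = 500, mtry = NULL,
                    C_grid = 2^seq(-5, 15, by = 2),
                    gamma_grid = 2^seq(-15, 3, by = 2),
                    cv_folds = 5, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(train, "pair_dataset"))
  if (length(unique(train$y)) < 2)
    stop("training set must contain both classes")
  scaling <- NULL
  x <- train$x
  if (scale) {
    scaling <- rbind(min = apply(x, 2, min), max = apply(x, 2, max))
    x <- scale_matrix(x, scaling)
  } else if (!is.null(train$scaling)) {
    scaling <- train$scaling
    # dataset already carries its scaling; predict must not rescale twice
    attr(scaling, "applied") <- TRUE
  }
  fitted <- if (method == "rf") {
    .train_rf(x, train$y, ntree = ntree, mtry = mtry, seed = seed)
  } else {
    .train_svm_grid(x, train$y, C_grid = C_grid, gamma_grid = gamma_grid,
                    cv_folds = cv_folds, seed = seed)
  }
  structure(list(
    method = method,
    fit = fitted$fit,
    config = fitted$config,
    grid = fitted$grid,
    scaling = scaling,
    rescale = scale,
    feature_names = colnames(train$x),
    train_drugs = unique(train$drug_id),
    train_targets = unique(train$target_id),
    n_train = n_pairs(train),
    seed = seed
  ), class = "dti_model")
}

.train_rf <- function(x, y, ntree = 500, mtry = NULL, seed = NULL) {
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  if (mtry < 1 || mtry > ncol(x))
    stop("mtry must lie in [1, ", ncol(x), "]")
  if (ntree < 1) stop("ntree must be >= 1")
  yf <- factor(y, levels = c(-1L, 1L))
  fit <- with_seed(seed,
    randomForest::randomForest(x, yf, ntree = ntree, mtry = mtry))
  list(fit = fit, config = list(ntree = ntree, mtry = mtry), grid = NULL)
}

# stratified fold assignment, both classes in every fold
.stratified_folds <- function(y, k, seed = NULL) {
  if (k < 2) stop("k must be >= 2")
  if (k > length(y)) stop("k = ", k, " exceeds n = ", length(y))
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    # k close to n can leave folds empty under stratification; refill each
    # empty fold from the currently largest one
    repeat {
      empty <- setdiff(seq_len(k), unique(folds))
      if (length(empty) == 0) break
      biggest <- as.integer(names(which.max(table(folds))))
      folds[which(folds == biggest)[1]] <- empty[1]
    }
  })
  folds
}

.train_svm_grid <- function(x, y, C_grid, gamma_grid, cv_folds = 5,
                            seed = NULL) {
  if (length(C_grid) == 0 || length(gamma_grid) == 0 ||
      any(C_grid <= 0) || any(gamma_grid <= 0))
    stop("C and gamma grids must be nonempty and positive")
  yf <- factor(y, levels = c(-1L, 1L))
  grid <- expand.grid(C = sort(unique(C_grid)),
                      gamma = sort(unique(gamma_grid)))
  grid$accuracy <- NA_real_
  if (nrow(grid) > 1) {
    folds <- .stratified_folds(y, cv_folds, seed = seed)
    for (i in seq_len(nrow(grid))) {
      correct <- 0L
      for (f in seq_len(cv_folds)) {
        tr <- folds != f
        fit <- with_seed(derive_seed(seed %||% 0L, paste0("svmcv", f)),
          e1071::svm(x[tr, , drop = FALSE], yf[tr], type = "C-classification",
                     kernel = "radial", cost = grid$C[i],
                     gamma = grid$gamma[i], scale = FALSE))
        pred <- stats::predict(fit, x[!tr, , drop = FALSE])
        correct <- correct + sum(pred == yf[!tr])
      }
      grid$accuracy[i] <- correct / length(y)
    }
    # ties: smallest C, then smallest gamma (grid is sorted C-fastest)
    ord <- order(grid$C, grid$gamma)
    grid <- grid[ord, ]
    best <- grid[which.max(grid$accuracy), ]
  } else {
    best <- grid[1, ]
  }
  fit <- with_seed(seed,
    e1071::svm(x, yf, type = "C-classification", kernel = "radial",
               cost = best$C, gamma = best$gamma, scale = FALSE))
  list(fit = fit,
       config = list(C = best$C, gamma = best$gamma, cv_folds = cv_folds),
       grid = grid)
}

# prepare a prediction matrix: accept pair_dataset or matrix, check dims,
# apply the stored scaling
.model_matrix <- function(object, newdata) {
  x <- if (inherits(newdata, "pair_dataset")) newdata$x else newdata
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(object$feature_names))
    stop("dimension mismatch: model expects ",
         length(object$feature_names), " features, got ", ncol(x))
  if (!is.null(object$scaling) && object$rescale)
    x <- scale_matrix(x, object$scaling)
  x
}

#' Predict binding scores and labels for drug-target pairs
#'
#' @param object A `dti_model`.
#' @param newdata A `pair_dataset` or numeric matrix of pair vectors on the
#'   original (unscaled) feature scale when the model was fitted with
#'   `scale = TRUE`.
#' @param type `"score"`, `"label"` or `"both"` (default). For RF the score
#'   is the binding score (fraction of trees voting interaction, in
#'   `[0, 1]`); for SVM it is the decision value, with labels by its sign.
#' @param threshold RF classification threshold on the binding score
#'   (default 0.5, i.e. majority vote); scores exactly at the threshold
#'   classify as positive.
#' @param ... Unused.
#' @return Numeric vector of scores, integer vector of labels, or a
#'   data.frame with both.
#' @export
predict.dti_model <- function(object, newdata, type = c("both", "score",
                                                        "label"),
                              threshold = 0.5, ...) {
  type <- match.arg(type)
  x <- .model_matrix(object, newdata)
  if (object$method == "rf") {
    score <- binding_score(object, x, .checked = TRUE)
    label <- ifelse(score >= threshold, 1L, -1L)
  } else {
    dvm <- attr(stats::predict(object$fit, x, decision.values = TRUE),
                "decision.values")
    dv <- dvm[, 1]
    # orient decision values so positive means "interaction"
    if (colnames(dvm)[1] == "-1/1") dv <- -dv
    score <- dv
    label <- ifelse(dv >= 0, 1L, -1L)
  }
  switch(type,
         score = score,
         label = label,
         both = data.frame(score = score, label = label))
}

#' Random-forest binding score
#'
#' The fraction of forest trees voting "+1" (interaction) for each pair, a
#' confidence in `[0, 1]` with granularity `1/ntree`. Thresholding at 0.5
#' reproduces the forest's majority vote. The literal vote odds
#' (votes for +1 divided by votes for -1) are available via
#' `ratio = TRUE`.
#'
#' @param model A `dti_model` with `method = "rf"`.
#' @param pairs A `pair_dataset` or numeric matrix of pair vectors.
#' @param ratio Return the +1/-1 vote odds instead of the fraction of total
#'   votes (infinite for unanimous positive votes).
#' @param .checked Internal: input already validated and scaled.
#' @return Numeric vector of scores.
#' @export
binding_score <- function(model, pairs, ratio = FALSE, .checked = FALSE) {
  stopifnot(inherits(model, "dti_model"))
  if (model$method != "rf")
    stop("binding scores are defined for random-forest models")
  x <- if (.checked) pairs else .model_matrix(model, pairs)
  votes <- stats::predict(model$fit, x, type = "vote")  # normalized
  frac <- votes[, "1"]
  out <- if (ratio) frac / votes[, "-1"] else frac
  unname(out)
}

#' Classify drug-target pairs
#'
#' @param model A `dti_model`.
#' @param pairs `pair_dataset` or matrix of pair vectors (possibly 0 rows).
#' @param threshold RF binding-score threshold (default 0.5; ties classify
#'   positive).
#' @return Data frame with `score` and `label` columns.
#' @export
classify_pairs <- function(model, pairs, threshold = 0.5) {
  x <- if (inherits(pairs, "pair_dataset")) pairs$x else pairs
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (nrow(x) == 0)
    return(data.frame(score = numeric(0), label = integer(0)))
  predict.dti_model(model, pairs, type = "both", threshold = threshold)
}

#' @export
print.dti_model <- function(x, ...) {
  cat("Drug-target interaction model (",
      if (x$method == "rf") "Random Forest" else "RBF-SVM", ")\n", sep = "")
  cat("  features: ", length(x$feature_names), "\n", sep = "")
  cat("  training: ", x$n_train, " pairs, ", length(x$train_drugs),
      " drugs, ", length(x$train_targets), " targets\n", sep = "")
  if (x$method == "rf") {
    cat("  ntree = ", x$config$ntree, ", mtry = ", x$config$mtry, "\n",
        sep = "")
  } else {
    cat("  C = ", format(x$config$C), ", gamma = ", format(x$config$gamma),
        " (5-fold CV grid search)\n", sep = "")
  }
  invisible(x)
}

#' @method summary dti_model
#' @export
summary.dti_model <- function(object, ...) {
  print(object)
  if (object$method == "rf") {
    conf <- object$fit$confusion
    cat("  OOB error rate:",
        format(100 * mean(object$fit$err.rate[object$config$ntree, "OOB"]),
               digits = 4), "%\n")
    print(conf)
  } else if (!is.null(object$grid)) {
    cat("  grid search (top 5 by CV accuracy):\n")
    g <- object$grid[order(-object$grid$accuracy), ]
    print(utils::head(g, 5), row.names = FALSE)
  }
  invisible(object)
}
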