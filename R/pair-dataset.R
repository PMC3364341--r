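# Labelled drug-target pair datasets: assembly by descriptor concatenation,
# negative sampling from the non-interaction space, [-1, 1] feature scaling,
# and the four general/cold-start train-test split scenarios.

#' Construct a pair dataset
#'
#' @param x Numeric matrix of pair vectors (drug block then target block).
#' @param y Integer labels, +1 (interaction) or -1 (non-interaction).
#' @param drug_id,target_id Character vectors identifying each row's pair.
#' @param role Optional role tag (`"train"`/`"test"`/`NA`).
#' @param scaling Optional per-feature scaling ranges (see
#'   [scale_features()]).
#' @return Object of class `pair_dataset`.
#' @export
pair_dataset <- function(x, y, drug_id, target_id, role = NA_character_,
                         scaling = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(y),
            length(drug_id) == nrow(x), length(target_id) == nrow(x))
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be +1 or -1")
  structure(list(x = x, y = y, drug_id = as.character(drug_id),
                 target_id = as.character(target_id), role = role,
                 scaling = scaling),
            class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat("Pair dataset: ", nrow(x$x), " samples x ", ncol(x$x),
      " features (", sum(x$y == 1), " positive / ", sum(x$y == -1),
      " negative)", sep = "")
  if (!is.na(x$role)) cat(" [", x$role, "]", sep = "")
  if (!is.null(x$scaling)) cat(" [scaled]")
  cat("\n")
  invisible(x)
}

#' Number of samples in a pair dataset
#' @param pd A `pair_dataset`.
#' @return Integer count.
#' @export
n_pairs <- function(pd) nrow(pd$x)

#' Subset a pair dataset by row index
#' @param pd A `pair_dataset`.
#' @param idx Integer or logical row index.
#' @param role Optional new role tag for the subset.
#' @return A `pair_dataset`.
#' @export
pairs_subset <- function(pd, idx, role = pd$role) {
  pair_dataset(pd$x[idx, , drop = FALSE], pd$y[idx], pd$drug_id[idx],
               pd$target_id[idx], role = role, scaling = pd$scaling)
}

# concatenated feature vector for one (drug, target): drug block ++ target
# block, in matrix column order, names prefixed to stay unique
.pair_matrix <- function(catalog, drug_id, target_id) {
  xd <- catalog$drugs[drug_id, , drop = FALSE]
  xt <- catalog$targets[target_id, , drop = FALSE]
  m <- cbind(xd, xt)
  colnames(m) <- c(paste0("drug.", colnames(catalog$drugs)),
                   paste0("target.", colnames(catalog$targets)))
  rownames(m) <- NULL
  m
}

#' Assemble labelled pair samples
#'
#' Builds the numeric pair vectors by concatenating each drug's descriptor
#' block with each target's descriptor block (in matrix column order).
#'
#' @param catalog An [interaction_catalog()].
#' @param pairs Data frame with `drug_id`, `target_id`.
#' @param label +1 or -1 applied to all pairs.
#' @return A `pair_dataset`.
#' @export
assemble_pairs <- function(catalog, pairs, label) {
  stopifnot(inherits(catalog, "interaction_catalog"))
  label <- as.integer(label)
  if (!label %in% c(-1L, 1L)) stop("label must be +1 or -1")
  d <- as.character(pairs$drug_id)
  t <- as.character(pairs$target_id)
  bad <- setdiff(d, rownames(catalog$drugs))
  if (length(bad) > 0) stop("unknown drug id '", bad[1], "'")
  bad <- setdiff(t, rownames(catalog$targets))
  if (length(bad) > 0) stop("unknown target id '", bad[1], "'")
  pair_dataset(.pair_matrix(catalog, d, t), rep(label, length(d)), d, t)
}

#' Sample negative pairs from the non-interaction space
#'
#' Conceptually enumerates the full drug x target cross product, removes the
#' known positives, and draws `n` of the remaining pairs uniformly without
#' replacement. The draw is implemented by rejection sampling against a
#' positives hash (with a dense-case fallback that materializes the
#' remainder), which is distributionally identical to explicit enumeration.
#' Deterministic given `seed`.
#'
#' @param catalog An [interaction_catalog()].
#' @param n Number of negatives; default `nrow(catalog$positives)` so the
#'   experimental dataset is class-balanced.
#' @param seed Integer seed.
#' @return Data frame with `drug_id`, `target_id` of the sampled negatives.
#' @export
sample_negatives <- function(catalog, n = nrow(catalog$positives),
                             seed = NULL) {
  stopifnot(inherits(catalog, "interaction_catalog"))
  nd <- nrow(catalog$drugs)
  nt <- nrow(catalog$targets)
  space <- as.numeric(nd) * nt - nrow(catalog$positives)
  if (n > space)
    stop("requested ", n, " negatives but the non-interaction space has ",
         "only ", space, " pairs")
  if (n == 0)
    return(data.frame(drug_id = character(0), target_id = character(0),
                      stringsAsFactors = FALSE))
  pos_key <- paste(match(catalog$positives$drug_id, rownames(catalog$drugs)),
                   match(catalog$positives$target_id,
                         rownames(catalog$targets)))
  with_seed(seed, {
    chosen <- character(0)
    if (n > 0.25 * space) {
      # dense request: materialize the non-interaction space and sample
      all_key <- paste(rep(seq_len(nd), each = nt), rep(seq_len(nt), nd))
      open <- setdiff(all_key, pos_key)
      chosen <- sample(open, n)
    } else {
      taken <- new.env(hash = TRUE, parent = emptyenv())
      for (k in pos_key) assign(k, TRUE, envir = taken)
      got <- 0L
      while (got < n) {
        m <- max(2L * (n - got), 100L)
        di <- sample.int(nd, m, replace = TRUE)
        ti <- sample.int(nt, m, replace = TRUE)
        key <- paste(di, ti)
        for (i in seq_len(m)) {
          if (got >= n) break
          if (!exists(key[i], envir = taken, inherits = FALSE)) {
            assign(key[i], TRUE, envir = taken)
            chosen <- c(chosen, key[i])
            got <- got + 1L
          }
        }
      }
    }
    idx <- do.call(rbind, strsplit(chosen, " ", fixed = TRUE))
    data.frame(drug_id = rownames(catalog$drugs)[as.integer(idx[, 1])],
               target_id = rownames(catalog$targets)[as.integer(idx[, 2])],
               stringsAsFactors = FALSE)
  })
}

#' Build the labelled experimental dataset
#'
#' Positives from the catalog plus an equal number (by default) of sampled
#' negatives, assembled into concatenated pair vectors.
#'
#' @param catalog An [interaction_catalog()].
#' @param n_negative Number of negatives (default: same as positives).
#' @param seed Seed for negative sampling.
#' @return A `pair_dataset` with +1 rows first, then -1 rows.
#' @export
build_pair_dataset <- function(catalog, n_negative = NULL, seed = NULL) {
  n_negative <- n_negative %||% nrow(catalog$positives)
  pos <- assemble_pairs(catalog, catalog$positives, 1L)
  neg_pairs <- sample_negatives(catalog, n_negative, seed = seed)
  if (nrow(neg_pairs) == 0) return(pos)
  neg <- assemble_pairs(catalog, neg_pairs, -1L)
  pair_dataset(rbind(pos$x, neg$x), c(pos$y, neg$y),
               c(pos$drug_id, neg$drug_id),
               c(pos$target_id, neg$target_id))
}

#' Scale pair features to [-1, 1]
#'
#' Fits a per-feature linear map of `[min, max]` to `[-1, 1]`. By default
#' ranges are fitted on the training set only and applied unchanged to the
#' other datasets (whose values may then fall outside `[-1, 1]`; no
#' clipping). `method = "joint"` fits the ranges on train and others pooled,
#' scaling every dataset into `[-1, 1]` at the price of using test-set
#' ranges during preprocessing. Constant features map to 0.
#'
#' @param train Training `pair_dataset`.
#' @param others List of further `pair_dataset`s to transform with the same
#'   ranges (e.g. test sets).
#' @param method `"train"` (default) or `"joint"`.
#' @return List with `train`, `others`, and `ranges` (2-row matrix `min`,
#'   `max`).
#' @export
scale_features <- function(train, others = list(), method = c("train",
                                                              "joint")) {
  method <- match.arg(method)
  stopifnot(inherits(train, "pair_dataset"), n_pairs(train) > 0)
  fit_x <- train$x
  if (method == "joint" && length(others) > 0)
    fit_x <- do.call(rbind, c(list(train$x), lapply(others, `[[`, "x")))
  rng <- rbind(min = apply(fit_x, 2, min), max = apply(fit_x, 2, max))
  apply_one <- function(pd) {
    pd$x <- scale_matrix(pd$x, rng)
    pd$scaling <- rng
    pd
  }
  list(train = apply_one(train), others = lapply(others, apply_one),
       ranges = rng)
}

#' Apply stored scaling ranges to a feature matrix
#'
#' @param x Numeric matrix.
#' @param ranges 2-row matrix (`min`, `max`) as produced by
#'   [scale_features()].
#' @return Scaled matrix; constant features (min == max) map to 0.
#' @export
scale_matrix <- function(x, ranges) {
  if (ncol(x) != ncol(ranges))
    stop("feature count mismatch: ", ncol(x), " vs ", ncol(ranges))
  lo <- ranges["min", ]
  hi <- ranges["max", ]
  span <- hi - lo
  const <- span == 0
  span[const] <- 1
  out <- sweep(sweep(x, 2, (lo + hi) / 2), 2, span / 2, "/")
  out[, const] <- 0
  out
}

#' Invert the [-1, 1] scaling
#'
#' @param x Scaled matrix.
#' @param ranges Ranges used to scale. Constant features are restored to
#'   their (single) training value.
#' @return Matrix on the original feature scale.
#' @export
unscale_matrix <- function(x, ranges) {
  lo <- ranges["min", ]
  hi <- ranges["max", ]
  span <- hi - lo
  const <- span == 0
  span[const] <- 0
  out <- sweep(sweep(x, 2, span / 2, "*"), 2, (lo + hi) / 2, "+")
  if (any(const)) out[, const] <- rep(lo[const], each = nrow(x))
  out
}

# entity sets of a pair-dataset subset
.entities <- function(pd, idx) {
  list(drugs = unique(pd$drug_id[idx]), targets = unique(pd$target_id[idx]))
}

#' Split the experimental dataset into train and test sets
#'
#' Four evaluation scenarios:
#' \describe{
#'   \item{I}{"general": a plain random split at `test_fraction`.}
#'   \item{II}{"new-drug vs known-target": after the random initial split,
#'     every initial-test sample whose drug is already in training (known
#'     drug) or whose target is not (new target) is moved into training,
#'     repeated to a fixed point; the remaining test samples pair a drug
#'     never seen in training with a target that is.}
#'   \item{III}{"new-target vs known-drug": the symmetric procedure; test
#'     samples pair a known drug with a never-seen target.}
#'   \item{IV}{"new-drug vs new-target": initial-test samples whose drug or
#'     target occurs in the initial training set are deleted; the training
#'     set is left unchanged.}
#' }
#' "Known" means the entity id occurs among the training samples.
#' Deterministic given `seed`.
#'
#' @param dataset A `pair_dataset`.
#' @param scenario `"I"`, `"II"`, `"III"` or `"IV"`.
#' @param test_fraction Fraction of samples in the initial test set
#'   (default 0.2).
#' @param seed Integer seed for the initial random split.
#' @return List with `train` and `test` `pair_dataset`s.
#' @export
make_split <- function(dataset, scenario = c("I", "II", "III", "IV"),
                       test_fraction = 0.2, seed = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(dataset, "pair_dataset"))
  n <- n_pairs(dataset)
  if (n < 2) stop("dataset must contain at least 2 samples")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  n_test <- max(1L, round(n * test_fraction))
  test_idx <- with_seed(seed, sort(sample.int(n, n_test)))
  in_test <- logical(n)
  in_test[test_idx] <- TRUE

  if (scenario %in% c("II", "III")) {
    repeat {
      tr <- .entities(dataset, !in_test)
      move <- if (scenario == "II") {
        in_test & (dataset$drug_id %in% tr$drugs |
                     !dataset$target_id %in% tr$targets)
      } else {
        in_test & (dataset$target_id %in% tr$targets |
                     !dataset$drug_id %in% tr$drugs)
      }
      if (!any(move)) break
      in_test[move] <- FALSE
    }
  } else if (scenario == "IV") {
    tr <- .entities(dataset, !in_test)
    drop <- in_test & (dataset$drug_id %in% tr$drugs |
                         dataset$target_id %in% tr$targets)
    keep_train <- !in_test
    in_test[drop] <- FALSE
    if (!any(in_test))
      stop("scenario IV produced an empty test set; ",
           "increase test_fraction")
    train <- pairs_subset(dataset, which(keep_train), role = "train")
    test <- pairs_subset(dataset, which(in_test), role = "test")
    return(list(train = train, test = test))
  }
  if (!any(in_test))
    stop("scenario ", scenario, " produced an empty test set; ",
         "increase test_fraction")
  list(train = pairs_subset(dataset, which(!in_test), role = "train"),
       test = pairs_subset(dataset, which(in_test), role = "test"))
}

#' Write a pair dataset description as TSV
#'
#' Records pair identity, label and role (not the feature values, which are
#' reproducible from the descriptor matrices).
#'
#' @param pd A `pair_dataset` or a named list of them (names become roles).
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_pair_tsv <- function(pd, path) {
  if (inherits(pd, "pair_dataset")) pd <- list(pd)
  rows <- lapply(pd, function(p)
    data.frame(drug_id = p$drug_id, target_id = p$target_id, label = p$y,
               role = p$role, stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
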