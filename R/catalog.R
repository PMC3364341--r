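# The interaction catalog: drug and target descriptor matrices plus the set
# of known (positive) drug-target pairs.

#' Construct an interaction catalog
#'
#' @param drugs Descriptor matrix for drugs (rows named by drug id).
#' @param targets Descriptor matrix for targets (rows named by target id).
#' @param positives Data frame with columns `drug_id`, `target_id` listing
#'   the known interactions. Every id must exist in the corresponding
#'   matrix; duplicate pairs are rejected.
#' @return An object of class `interaction_catalog`.
#' @export
interaction_catalog <- function(drugs, targets, positives) {
  check_descriptor_matrix(drugs, "drug matrix")
  check_descriptor_matrix(targets, "target matrix")
  if (!is.data.frame(positives) ||
      !all(c("drug_id", "target_id") %in% names(positives)))
    stop("positives must be a data.frame with drug_id and target_id")
  positives <- data.frame(drug_id = as.character(positives$drug_id),
                          target_id = as.character(positives$target_id),
                          stringsAsFactors = FALSE)
  bad_d <- setdiff(positives$drug_id, rownames(drugs))
  if (length(bad_d) > 0)
    stop("positive pair references unknown drug id(s): ",
         paste(utils::head(bad_d, 5), collapse = ", "))
  bad_t <- setdiff(positives$target_id, rownames(targets))
  if (length(bad_t) > 0)
    stop("positive pair references unknown target id(s): ",
         paste(utils::head(bad_t, 5), collapse = ", "))
  key <- paste(positives$drug_id, positives$target_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate positive pair(s), e.g. ",
         sub("\r", " / ", key[duplicated(key)][1]))
  structure(list(drugs = drugs, targets = targets, positives = positives),
            class = "interaction_catalog")
}

#' @export
print.interaction_catalog <- function(x, ...) {
  cat("Interaction catalog\n")
  cat("  drugs:    ", nrow(x$drugs), " (", ncol(x$drugs),
      " descriptors)\n", sep = "")
  cat("  targets:  ", nrow(x$targets), " (", ncol(x$targets),
      " descriptors)\n", sep = "")
  cat("  positives:", nrow(x$positives), "known pairs\n")
  cat("  non-interaction space:",
      format(as.numeric(nrow(x$drugs)) * nrow(x$targets) -
               nrow(x$positives), big.mark = ","), "pairs\n")
  invisible(x)
}

#' Read a known-interaction table
#'
#' @param path TSV with columns `drug_id`, `target_id` (header required).
#' @return Data frame of positives.
#' @export
read_interaction_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("drug_id", "target_id") %in% names(df)))
    stop("interaction TSV must have columns 'drug_id' and 'target_id'")
  df[, c("drug_id", "target_id")]
}

#' Write a known-interaction table
#'
#' @param positives Data frame with `drug_id`, `target_id`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_interaction_tsv <- function(positives, path) {
  utils::write.table(positives[, c("drug_id", "target_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
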