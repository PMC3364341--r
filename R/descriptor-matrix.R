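# Descriptor matrix I/O and curation. A descriptor matrix is a plain numeric
# matrix with entity ids as row names and descriptor names as column names;
# NA marks a descriptor that could not be computed for that entity.

#' Write a descriptor matrix as TSV
#'
#' Canonical on-disk form: a header row (`id` then descriptor names) and one
#' row per entity. Masked (incomputable) cells are written as `NA`.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_descriptor_matrix <- function(m, path) {
  check_descriptor_matrix(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a descriptor matrix from TSV
#'
#' @param path TSV file with an `id` column and numeric descriptor columns.
#' @return Numeric matrix with ids as row names.
#' @export
read_descriptor_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("descriptor TSV must have an 'id' column")
  m <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$id
  check_descriptor_matrix(m)
  m
}

#' Curate a descriptor matrix
#'
#' Applies the three descriptor-hygiene rules used before model building:
#' \enumerate{
#'   \item drop any descriptor that is not computable for all entities
#'     (any masked/NA or non-finite cell);
#'   \item drop constant descriptors;
#'   \item drop near-constant descriptors, i.e. those whose modal value
#'     accounts for at least `near_const_fraction` of the rows.
#' }
#' Column order of the retained descriptors and row order are preserved.
#' Curation is idempotent: curating a curated matrix drops nothing.
#'
#' @param m Descriptor matrix (may contain NA masks).
#' @param near_const_fraction Modal-value fraction at or above which a
#'   descriptor counts as near-constant (default 0.95).
#' @return A list with `matrix` (curated) and `dropped` (data.frame with
#'   columns `name`, `reason` in \{incomputable, constant, near_constant\}).
#' @export
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, NA, 1))
#' rownames(m) <- paste0("m", 1:3)
#' curate_descriptor_matrix(m)$dropped
curate_descriptor_matrix <- function(m, near_const_fraction = 0.95) {
  if (!is.matrix(m) || nrow(m) == 0 || ncol(m) == 0)
    stop("descriptor matrix must be nonempty")
  if (near_const_fraction <= 0 || near_const_fraction > 1)
    stop("near_const_fraction must be in (0, 1]")
  reasons <- character(0)
  names_dropped <- character(0)
  keep <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (any(!is.finite(col))) {
      names_dropped <- c(names_dropped, colnames(m)[j])
      reasons <- c(reasons, "incomputable")
    } else if (length(unique(col)) == 1) {
      names_dropped <- c(names_dropped, colnames(m)[j])
      reasons <- c(reasons, "constant")
    } else if (max(table(col)) / nrow(m) >= near_const_fraction) {
      names_dropped <- c(names_dropped, colnames(m)[j])
      reasons <- c(reasons, "near_constant")
    } else {
      keep[j] <- TRUE
    }
  }
  if (!any(keep))
    stop("empty descriptor space: all ", ncol(m), " descriptors dropped")
  list(matrix = m[, keep, drop = FALSE],
       dropped = data.frame(name = names_dropped, reason = reasons,
                            stringsAsFactors = FALSE))
}
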