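# Comprehensive screening of the drug x target space, top-N bipartite
# interaction networks with known/new annotation, degree-based topology
# statistics, and hierarchical clustering of predicted ligands.

#' Score every drug x target candidate pair
#'
#' Assembles and scores all pairs between the given drug and target
#' descriptor matrices with the model's binding score, annotates each pair
#' as known (in the catalog positives) or new, and returns the table sorted
#' by descending score (ties by drug then target id, so the order is fully
#' deterministic). Pairs are processed in blocks of drugs to bound memory;
#' the output is independent of `block_size`.
#'
#' @param model A `dti_model` (RF for binding scores; an SVM model scores by
#'   decision value).
#' @param drugs,targets Descriptor matrices (same descriptor spaces as the
#'   model's training catalog).
#' @param catalog Optional [interaction_catalog()] supplying the known
#'   positives for annotation (default: no pair is known).
#' @param block_size Number of drugs scored per block (default 100).
#' @return Data frame of class `score_table`: `drug_id`, `target_id`,
#'   `score`, `known`.
#' @export
comprehensive_screen <- function(model, drugs, targets, catalog = NULL,
                                 block_size = 100) {
  check_descriptor_matrix(drugs, "drug matrix")
  check_descriptor_matrix(targets, "target matrix")
  stopifnot(inherits(model, "dti_model"))
  nd <- nrow(drugs)
  nt <- nrow(targets)
  expected <- length(model$feature_names)
  if (ncol(drugs) + ncol(targets) != expected)
    stop("dimension mismatch: model expects ", expected,
         " pair features, drugs + targets give ",
         ncol(drugs) + ncol(targets))
  pair_names <- c(paste0("drug.", colnames(drugs)),
                  paste0("target.", colnames(targets)))
  if (!identical(pair_names, model$feature_names))
    stop("descriptor-space mismatch: the model was trained on different ",
         "pair feature names")
  pos_key <- if (!is.null(catalog))
    paste(catalog$positives$drug_id, catalog$positives$target_id,
          sep = "\r") else character(0)
  chunks <- split(seq_len(nd), ceiling(seq_len(nd) / max(1, block_size)))
  out <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    di <- chunks[[ci]]
    d_ids <- rep(rownames(drugs)[di], each = nt)
    t_ids <- rep(rownames(targets), length(di))
    x <- cbind(drugs[di, , drop = FALSE][rep(seq_along(di), each = nt), ,
                                         drop = FALSE],
               targets[rep(seq_len(nt), length(di)), , drop = FALSE])
    colnames(x) <- pair_names
    rownames(x) <- NULL
    score <- if (model$method == "rf") {
      binding_score(model, .model_matrix(model, x), .checked = TRUE)
    } else {
      predict.dti_model(model, x, type = "score")
    }
    out[[ci]] <- data.frame(drug_id = d_ids, target_id = t_ids,
                            score = score,
                            known = paste(d_ids, t_ids,
                                          sep = "\r") %in% pos_key,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(-tab$score, tab$drug_id, tab$target_id), ]
  rownames(tab) <- NULL
  class(tab) <- c("score_table", "data.frame")
  tab
}

#' Build the top-N bipartite interaction network
#'
#' Takes the `n` best-scoring pairs (ties at the cutoff resolved by the
#' table's deterministic score/drug/target order) and builds an undirected
#' bipartite graph. A node is `new` iff its entity occurs in no known
#' positive pair of the score table; an edge is `known` iff the pair itself
#' is a known positive.
#'
#' @param table A `score_table` from [comprehensive_screen()].
#' @param n Number of top edges (0 allowed; must not exceed `nrow(table)`).
#' @return An `igraph` graph with vertex attributes `kind`
#'   (`"drug"`/`"target"`), `status` (`"known"`/`"new"`) and `type` (logical
#'   bipartite mapping, `TRUE` for targets), and edge attributes `score`,
#'   `status`.
#' @export
top_n_network <- function(table, n) {
  stopifnot(is.data.frame(table))
  if (n > nrow(table))
    stop("n = ", n, " exceeds the ", nrow(table), " scored pairs")
  tab <- table[order(-table$score, table$drug_id, table$target_id), ,
               drop = FALSE]
  top <- tab[seq_len(n), , drop = FALSE]
  known_drugs <- unique(tab$drug_id[tab$known])
  known_targets <- unique(tab$target_id[tab$known])
  drugs <- unique(top$drug_id)
  targets <- unique(top$target_id)
  g <- igraph::make_empty_graph(0, directed = FALSE)
  if (n == 0) return(g)
  g <- igraph::add_vertices(g, length(drugs), name = drugs, kind = "drug",
                            type = FALSE,
                            status = ifelse(drugs %in% known_drugs,
                                            "known", "new"))
  g <- igraph::add_vertices(g, length(targets), name = targets,
                            kind = "target", type = TRUE,
                            status = ifelse(targets %in% known_targets,
                                            "known", "new"))
  edges <- rbind(match(top$drug_id, drugs),
                 match(top$target_id, targets) + length(drugs))
  g <- igraph::add_edges(g, as.vector(edges),
                         score = top$score,
                         status = ifelse(top$known, "known", "new"))
  g
}

#' Degree-based network topology statistics
#'
#' Degree centralization \eqn{(n/(n-2)) (k_{max}/(n-1) - density)} — 1 for
#' a star, 0 for a regular graph — and degree heterogeneity
#' \eqn{\sqrt{var(k)}/mean(k)} (population variance), plus the node degree
#' histogram. Degrees are taken over the bipartite graph as a whole; a
#' per-mode breakdown is included when the graph carries a `kind` vertex
#' attribute.
#'
#' @param net An `igraph` graph.
#' @return List of class `topology_report`: `centralization` (`NA` for
#'   fewer than 3 nodes), `heterogeneity`, `degree_histogram` (table),
#'   `n_nodes`, `n_edges`, and optionally `by_kind`.
#' @export
network_topology <- function(net) {
  k <- igraph::degree(net)
  n <- length(k)
  m <- igraph::ecount(net)
  centralization <- if (n < 3) NA_real_ else {
    dens <- 2 * m / (n * (n - 1))
    (n / (n - 2)) * (max(k) / (n - 1) - dens)
  }
  het <- if (n == 0 || mean(k) == 0) NA_real_ else
    sqrt(mean((k - mean(k))^2)) / mean(k)
  rep <- list(centralization = centralization, heterogeneity = het,
              degree_histogram = table(k), n_nodes = n, n_edges = m)
  kinds <- igraph::vertex_attr(net, "kind")
  if (!is.null(kinds)) {
    rep$by_kind <- lapply(split(k, kinds), function(kk)
      c(n = length(kk), mean_degree = mean(kk), max_degree = max(kk)))
  }
  class(rep) <- "topology_report"
  rep
}

#' @export
print.topology_report <- function(x, ...) {
  cat("Network topology: ", x$n_nodes, " nodes, ", x$n_edges, " edges\n",
      sep = "")
  cat("  centralization:", format(x$centralization, digits = 4), "\n")
  cat("  heterogeneity: ", format(x$heterogeneity, digits = 4), "\n")
  cat("  degree histogram:\n")
  print(x$degree_histogram)
  invisible(x)
}

#' Hierarchical clustering of ligand descriptor vectors
#'
#' Agglomerative clustering of molecules on standardized descriptors
#' (Euclidean distance, Ward linkage by default), cut into `k` clusters or
#' at a dendrogram `height`. The induced partition is invariant to row
#' order.
#'
#' @param chem Curated descriptor matrix (rows = molecules).
#' @param k Number of clusters (default 4); ignored when `height` given.
#' @param height Dendrogram cut height.
#' @param linkage Linkage method for [stats::hclust()] (default
#'   `"ward.D2"`).
#' @param standardize Standardize descriptors before distances.
#' @return List with `assignments` (named integer vector), `hclust`, and
#'   `k`.
#' @export
cluster_ligands <- function(chem, k = 4, height = NULL,
                            linkage = "ward.D2", standardize = TRUE) {
  if (nrow(chem) < 2) stop("clustering needs at least 2 molecules")
  if (is.null(height) && k > nrow(chem))
    stop("k = ", k, " exceeds the ", nrow(chem), " molecules")
  x <- chem
  if (standardize) {
    v <- apply(x, 2, stats::var)
    x <- scale(x[, v > 0, drop = FALSE])
  }
  # order rows by id so the dendrogram (and cutree labels) are independent
  # of input row order
  ord <- order(rownames(x))
  hc <- stats::hclust(stats::dist(x[ord, , drop = FALSE]), method = linkage)
  assignments <- if (is.null(height)) stats::cutree(hc, k = k)
    else stats::cutree(hc, h = height)
  list(assignments = assignments[rownames(chem)], hclust = hc,
       k = length(unique(assignments)))
}

#' Export a dendrogram as Newick
#'
#' @param hc An `hclust` object (e.g. from [cluster_ligands()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Export a network as GraphML and edge-list TSV
#'
#' @param net An `igraph` graph with the attributes set by
#'   [top_n_network()].
#' @param graphml_path,edges_path Output paths (either may be `NULL`).
#' @return Invisibly, `net`.
#' @export
write_network <- function(net, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(net, graphml_path, format = "graphml")
  if (!is.null(edges_path)) {
    el <- igraph::as_edgelist(net)
    df <- data.frame(drug_id = el[, 1], target_id = el[, 2],
                     score = igraph::edge_attr(net, "score") %||%
                       NA_real_,
                     status = igraph::edge_attr(net, "status") %||% NA,
                     stringsAsFactors = FALSE)
    utils::write.table(df, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(net)
}

#' Write a score table as TSV
#'
#' Scores are written in full precision; round only at presentation.
#'
#' @param table A `score_table`.
#' @param path Output TSV.
#' @param digits Optional rounding for presentation output (e.g. 3).
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path, digits = NULL) {
  tab <- as.data.frame(table)
  if (!is.null(digits)) tab$score <- round(tab$score, digits)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
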