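# Comprehensive screening, top-N bipartite networks, topology statistics
# and ligand clustering.

screen_fixture <- function() {
  syn <- synthetic_catalog(n_drugs = 10, n_targets = 8, density = 0.2,
                           label_noise = 0, seed = 4)
  ds <- build_pair_dataset(syn$catalog, seed = 5)
  fit <- dti_fit(ds, "rf", ntree = 50, seed = 6)
  list(syn = syn, fit = fit)
}

test_that("screening scores every pair, sorted, with known flags", {
  fx <- screen_fixture()
  cat_ <- fx$syn$catalog
  tab <- comprehensive_screen(fx$fit, cat_$drugs, cat_$targets, cat_)
  expect_equal(nrow(tab), nrow(cat_$drugs) * nrow(cat_$targets))
  expect_true(all(diff(tab$score) <= 0))
  expect_true(all(tab$score >= 0 & tab$score <= 1))
  key <- paste(tab$drug_id, tab$target_id)
  pos <- paste(cat_$positives$drug_id, cat_$positives$target_id)
  expect_setequal(key[tab$known], pos)
  # streaming contract: block size must not change the result
  tab1 <- comprehensive_screen(fx$fit, cat_$drugs, cat_$targets, cat_,
                               block_size = 1)
  expect_identical(tab, tab1)
  expect_error(
    comprehensive_screen(fx$fit, cat_$drugs[, 1:3], cat_$targets, cat_),
    "mismatch")
})

test_that("screening recovers the planted signal", {
  fx <- screen_fixture()
  cat_ <- fx$syn$catalog
  tab <- comprehensive_screen(fx$fit, cat_$drugs, cat_$targets, cat_)
  key <- paste(tab$drug_id, tab$target_id)
  truth <- paste(fx$syn$truth$drug_id, fx$syn$truth$target_id)
  expect_gt(mean(tab$score[key %in% truth]),
            mean(tab$score[!key %in% truth]))
})

test_that("top-N networks are bipartite with exact known/new annotation", {
  fx <- screen_fixture()
  cat_ <- fx$syn$catalog
  tab <- comprehensive_screen(fx$fit, cat_$drugs, cat_$targets, cat_)
  net <- top_n_network(tab, 12)
  expect_equal(igraph::ecount(net), 12)
  expect_lte(igraph::vcount(net), 24)
  kinds <- igraph::V(net)$kind
  el <- igraph::as_edgelist(net)
  # every edge joins a drug to a target
  k_by_name <- stats::setNames(kinds, igraph::V(net)$name)
  expect_true(all(k_by_name[el[, 1]] != k_by_name[el[, 2]]))
  # edge scores dominate every excluded score
  excluded <- tab$score[13:nrow(tab)]
  expect_true(min(igraph::E(net)$score) >= max(excluded))
  # new status iff the entity occurs in no known positive
  known_d <- unique(cat_$positives$drug_id)
  st <- stats::setNames(igraph::V(net)$status, igraph::V(net)$name)
  for (d in unique(el[, 1]))
    expect_equal(unname(st[d]) == "known", d %in% known_d)
  # empty and oversized requests
  expect_equal(igraph::vcount(top_n_network(tab, 0)), 0)
  expect_error(top_n_network(tab, nrow(tab) + 1), "exceeds")
  # determinism under score ties
  net2 <- top_n_network(tab, 12)
  expect_identical(igraph::as_edgelist(net), igraph::as_edgelist(net2))
})

test_that("topology formulas match the star and regular-graph cases", {
  star <- igraph::make_star(5, mode = "undirected")
  rep_ <- network_topology(star)
  expect_equal(rep_$centralization, 1.0)
  expect_equal(rep_$heterogeneity, 0.75)
  ring <- igraph::make_ring(6)
  expect_equal(network_topology(ring)$heterogeneity, 0)
  # fewer than 3 nodes: centralization undefined
  expect_true(is.na(network_topology(igraph::make_ring(2))$centralization))
})

test_that("topology agrees with the degree-sequence oracle", {
  set.seed(13)
  for (i in 1:50) {
    g <- igraph::sample_gnp(sample(4:25, 1), runif(1, 0.2, 0.8))
    if (igraph::ecount(g) == 0) next
    rep_ <- network_topology(g)
    orc <- oracle_topology(igraph::degree(g))
    expect_equal(rep_$centralization, orc$centralization,
                 tolerance = 1e-9)
    expect_equal(rep_$heterogeneity, orc$heterogeneity, tolerance = 1e-9)
    expect_equal(sum(rep_$degree_histogram), igraph::vcount(g))
  }
})

test_that("hierarchical clustering recovers planted blobs", {
  set.seed(9)
  blob <- function(center, n) sweep(matrix(rnorm(n * 4, sd = 0.3), n, 4),
                                    2, center, "+")
  m <- rbind(blob(c(5, 5, 5, 5), 20), blob(c(-5, -5, -5, -5), 20))
  dimnames(m) <- list(paste0("m", 1:40), paste0("f", 1:4))
  cl <- cluster_ligands(m, k = 2)
  expect_length(unique(cl$assignments[1:20]), 1)
  expect_length(unique(cl$assignments[21:40]), 1)
  expect_false(cl$assignments[1] == cl$assignments[40])
  # k = n gives singletons; duplicated rows always co-cluster
  expect_length(unique(cluster_ligands(m, k = 40)$assignments), 40)
  m2 <- rbind(m, m1dup = m[1, ])
  rownames(m2)[41] <- "dup"
  cl2 <- cluster_ligands(m2, k = 2)
  expect_equal(unname(cl2$assignments["dup"]),
               unname(cl2$assignments["m1"]))
  expect_error(cluster_ligands(m, k = 41), "exceeds")
})

test_that("cluster partitions are invariant to row permutation", {
  set.seed(10)
  m <- matrix(rnorm(120), 20, 6,
              dimnames = list(paste0("m", 1:20), paste0("f", 1:6)))
  cl <- cluster_ligands(m, k = 3)$assignments
  perm <- sample(20)
  clp <- cluster_ligands(m[perm, ], k = 3)$assignments[rownames(m)]
  # same partition up to label renaming
  expect_equal(length(unique(paste(cl, clp))), length(unique(cl)))
})

test_that("network and dendrogram exports round-trip", {
  fx <- screen_fixture()
  cat_ <- fx$syn$catalog
  tab <- comprehensive_screen(fx$fit, cat_$drugs, cat_$targets, cat_)
  net <- top_n_network(tab, 10)
  gml <- withr::local_tempfile(fileext = ".graphml")
  edges <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, gml, edges)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), 10)
  expect_equal(nrow(utils::read.table(edges, header = TRUE)), 10)
  hc <- cluster_ligands(cat_$drugs, k = 3)$hclust
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc, nwk)
  tree <- ape::read.tree(nwk)
  expect_equal(length(tree$tip.label), nrow(cat_$drugs))
})
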