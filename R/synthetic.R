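# Seeded synthetic interaction catalogs: drugs, targets and a planted
# bilinear interaction rule, so that every pipeline stage is testable
# without any external database. Two modes: "vectors" draws descriptor
# matrices directly (fast, no chemistry involved); "structures" emits
# SMILES and protein sequences and runs them through the real featurizers.

# small valid-fragment grammar for synthetic SMILES; fragments concatenate
# linearly into valid molecules (ring-closure digits are reusable after
# each closure)
.smiles_fragments <- c("C", "CC", "CO", "CN", "C(C)C", "c1ccccc1",
                       "C1CCCCC1", "C(=O)O", "C(=O)N", "CS", "C(F)",
                       "C(Cl)", "C(Br)", "C=C", "C(C#N)", "c1ccncc1",
                       "COC", "C(N)C")

#' Generate a synthetic drug-target world
#'
#' Creates `n_drugs` drugs and `n_targets` targets plus the latent weights
#' of a planted interaction rule. In `"vectors"` mode, drug and target
#' descriptor matrices are drawn as Gaussian blocks; in `"structures"` mode,
#' drugs are valid SMILES sampled from a small fragment grammar and targets
#' are random protein sequences of length 50-500 (uniform residue usage),
#' featurized with [featurize_molecules()] and [featurize_proteins()].
#' Fully reproducible from `seed`.
#'
#' @param n_drugs,n_targets Entity counts (>= 2).
#' @param mode `"vectors"` (default) or `"structures"`.
#' @param n_drug_features,n_target_features Descriptor dimensions in
#'   vectors mode (defaults 50 and 60).
#' @param coupling Strength of the bilinear drug x target term in the
#'   latent rule (default 0.5). The bilinear term is what makes cold-start
#'   prediction possible but harder than general prediction.
#' @param seed Integer seed.
#' @return Object of class `synthetic_world`: descriptor matrices `drugs`,
#'   `targets`, rule weights (`w_drug`, `w_target`, `A`, `coupling`), the
#'   `mode`, and in structures mode `smiles` and `sequences`.
#' @export
generate_world <- function(n_drugs = 60, n_targets = 60,
                           mode = c("vectors", "structures"),
                           n_drug_features = 50, n_target_features = 60,
                           coupling = 0.5, seed = 1) {
  mode <- match.arg(mode)
  if (n_drugs < 2 || n_targets < 2)
    stop("need at least 2 drugs and 2 targets")
  with_seed(seed, {
    drug_ids <- sprintf("D%04d", seq_len(n_drugs))
    target_ids <- sprintf("T%04d", seq_len(n_targets))
    smiles <- NULL
    sequences <- NULL
    if (mode == "vectors") {
      drugs <- matrix(stats::rnorm(n_drugs * n_drug_features),
                      nrow = n_drugs,
                      dimnames = list(drug_ids,
                                      sprintf("cd%03d",
                                              seq_len(n_drug_features))))
      targets <- matrix(stats::rnorm(n_targets * n_target_features),
                        nrow = n_targets,
                        dimnames = list(target_ids,
                                        sprintf("pd%03d",
                                                seq_len(n_target_features))))
    } else {
      smiles <- vapply(seq_len(n_drugs), function(i)
        paste(sample(.smiles_fragments, sample(2:6, 1), replace = TRUE),
              collapse = ""), character(1))
      names(smiles) <- drug_ids
      sequences <- vapply(seq_len(n_targets), function(i)
        paste(sample(amino_acids(), sample(50:500, 1), replace = TRUE),
              collapse = ""), character(1))
      names(sequences) <- target_ids
      drugs <- featurize_molecules(smiles)
      drugs <- curate_descriptor_matrix(drugs)$matrix
      targets <- featurize_proteins(sequences)
    }
    # latent rule weights on standardized features
    w_drug <- stats::rnorm(ncol(drugs)) / sqrt(ncol(drugs))
    w_target <- stats::rnorm(ncol(targets)) / sqrt(ncol(targets))
    A <- matrix(stats::rnorm(ncol(drugs) * ncol(targets)),
                nrow = ncol(drugs)) /
      sqrt(ncol(drugs) * ncol(targets))
    structure(list(drugs = drugs, targets = targets, mode = mode,
                   w_drug = w_drug, w_target = w_target, A = A,
                   coupling = coupling, seed = seed, smiles = smiles,
                   sequences = sequences),
              class = "synthetic_world")
  })
}

#' Plant interactions in a synthetic world
#'
#' The latent interaction score of a pair is
#' \eqn{s(d, t) = z_d w_d + z_t w_t + c \, z_d A z_t + b}
#' over column-standardized descriptors z; the threshold is the empirical
#' `1 - density` quantile of all scores, so the positive fraction is
#' approximately `density`. Labels are then perturbed by density-preserving
#' noise: each positive flips to negative with probability `label_noise`,
#' and each negative flips to positive with probability
#' `label_noise * p/(1-p)` (p the planted positive fraction), so the
#' expected positive count stays at `density` and the contamination of the
#' positive class is about `label_noise`. Both the noisy catalog and the
#' noise-free truth are returned so tests can measure recovery against the
#' planted rule.
#'
#' @param world A `synthetic_world`.
#' @param density Target fraction of positive pairs, in (0, 1).
#' @param label_noise Per-pair label flip probability, in `[0, 0.5)`.
#' @param seed Integer seed for the noise draws.
#' @return List with `positives` (noisy observed positives, data.frame),
#'   `truth` (noise-free positive pairs), `latent` (score matrix),
#'   `threshold`.
#' @export
plant_interactions <- function(world, density = 0.08, label_noise = 0.05,
                               seed = 1) {
  stopifnot(inherits(world, "synthetic_world"))
  if (density <= 0 || density >= 1) stop("density must be in (0, 1)")
  if (label_noise < 0 || label_noise >= 0.5)
    stop("label_noise must be in [0, 0.5): 0.5 would destroy the signal")
  if (all(world$w_drug == 0) && all(world$w_target == 0) &&
      (world$coupling == 0 || all(world$A == 0)))
    stop("degenerate rule: all weights are zero")
  zstand <- function(m) {
    mu <- colMeans(m)
    sd <- apply(m, 2, stats::sd)
    sd[sd == 0] <- 1
    scale(m, center = mu, scale = sd)
  }
  zd <- zstand(world$drugs)
  zt <- zstand(world$targets)
  s <- outer(as.numeric(zd %*% world$w_drug),
             as.numeric(zt %*% world$w_target), "+") +
    world$coupling * (zd %*% world$A %*% t(zt))
  dimnames(s) <- list(rownames(world$drugs), rownames(world$targets))
  threshold <- stats::quantile(s, 1 - density, names = FALSE)
  truth_mat <- s > threshold
  p <- mean(truth_mat)
  flip_neg <- label_noise * p / (1 - p)
  observed <- with_seed(seed, {
    u <- matrix(stats::runif(length(s)), nrow = nrow(s))
    flips <- ifelse(truth_mat, u < label_noise, u < flip_neg)
    xor(truth_mat, flips)
  })
  to_df <- function(mat) {
    idx <- which(mat, arr.ind = TRUE)
    data.frame(drug_id = rownames(s)[idx[, 1]],
               target_id = colnames(s)[idx[, 2]],
               stringsAsFactors = FALSE)
  }
  list(positives = to_df(observed), truth = to_df(truth_mat),
       latent = s, threshold = threshold)
}

#' One-call synthetic interaction catalog
#'
#' Convenience wrapper: [generate_world()] + [plant_interactions()] +
#' [interaction_catalog()]. The `"ci"` preset is the default desk-scale
#' fixture: 60 drugs x 60 targets, density 0.08, label noise 0.05,
#' seed 17.
#'
#' @param n_drugs,n_targets,mode,coupling,density,label_noise,seed As in
#'   the underlying generators.
#' @param preset `"ci"` overrides the size/rate arguments with the fixture
#'   defaults.
#' @param ... Passed to [generate_world()].
#' @return List with `catalog` (an [interaction_catalog()]), `world`,
#'   `truth`, `latent`.
#' @export
synthetic_catalog <- function(n_drugs = 60, n_targets = 60,
                              mode = "vectors", coupling = 0.5,
                              density = 0.08, label_noise = 0.05,
                              seed = 17, preset = NULL, ...) {
  if (!is.null(preset)) {
    if (preset != "ci") stop("unknown preset '", preset, "'")
    n_drugs <- 60; n_targets <- 60; density <- 0.08
    label_noise <- 0.05; mode <- "vectors"; coupling <- 0.5
  }
  world <- generate_world(n_drugs, n_targets, mode = mode,
                          coupling = coupling,
                          seed = derive_seed(seed, "world"), ...)
  planted <- plant_interactions(world, density = density,
                                label_noise = label_noise,
                                seed = derive_seed(seed, "labels"))
  if (nrow(planted$positives) == 0)
    stop("no positive pairs planted; increase density")
  list(catalog = interaction_catalog(world$drugs, world$targets,
                                     planted$positives),
       world = world, truth = planted$truth, latent = planted$latent)
}

#' Write a synthetic world to disk in the pipeline's input formats
#'
#' Emits the descriptor matrices (TSV), positives (TSV) and, in structures
#' mode, the SMILES table (TSV) and protein FASTA.
#'
#' @param syn Result of [synthetic_catalog()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_world <- function(syn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_descriptor_matrix(syn$world$drugs, file.path(dir, "drugs.tsv"))
  write_descriptor_matrix(syn$world$targets, file.path(dir, "targets.tsv"))
  write_interaction_tsv(syn$catalog$positives,
                        file.path(dir, "positives.tsv"))
  if (!is.null(syn$world$smiles)) {
    utils::write.table(
      data.frame(id = names(syn$world$smiles), smiles = syn$world$smiles),
      file.path(dir, "drugs_smiles.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  if (!is.null(syn$world$sequences)) {
    writeLines(paste0(">", names(syn$world$sequences), "\n",
                      syn$world$sequences),
               file.path(dir, "targets.fasta"))
  }
  invisible(dir)
}
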