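# Run configuration (YAML) and the one-shot pipeline chaining
# featurize -> build-dataset -> split -> train -> evaluate -> screen.

#' Read and validate a run configuration
#'
#' The configuration is schema-checked before any computation. Fields:
#' \preformatted{
#' seed: 17                      # root seed; every stage derives from it
#' output: runs/demo             # run directory
#' data:
#'   preset: ci                  # synthetic preset, OR explicit inputs:
#'   # drugs: drugs.tsv  targets: targets.tsv  positives: positives.tsv
#'   # fasta: targets.fasta  smiles: drugs_smiles.tsv
#' split: {scenario: I, test_fraction: 0.2}
#' learner: {method: rf, ntree: 500}      # or method: svm + grids
#' cv: {k: 5, enabled: true}
#' screen: {enabled: true, top_n: 50}
#' }
#'
#' @param path YAML file, or a list already in memory.
#' @return Validated config list of class `dti_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  fail <- function(...) stop("invalid run config: ", ..., call. = FALSE)
  if (is.null(cfg$seed)) fail("missing 'seed'")
  if (!is.numeric(cfg$seed)) fail("'seed' must be an integer")
  if (is.null(cfg$output)) fail("missing 'output' directory")
  if (is.null(cfg$data)) fail("missing 'data' block")
  d <- cfg$data
  has_preset <- !is.null(d$preset)
  has_matrices <- !is.null(d$drugs) && !is.null(d$targets)
  has_raw <- !is.null(d$fasta) && !is.null(d$smiles)
  if (!has_preset && !(has_matrices || has_raw) )
    fail("'data' needs a preset, drugs+targets matrices, or fasta+smiles")
  if (!has_preset) {
    if (is.null(d$positives)) fail("'data' needs a 'positives' TSV")
    for (f in c("drugs", "targets", "fasta", "smiles", "positives")) {
      if (!is.null(d[[f]]) && !file.exists(d[[f]]))
        fail("data file for '", f, "' not found: ", d[[f]])
    }
  }
  cfg$split <- cfg$split %||% list()
  cfg$split$scenario <- cfg$split$scenario %||% "I"
  if (!cfg$split$scenario %in% c("I", "II", "III", "IV"))
    fail("split scenario must be I, II, III or IV")
  cfg$split$test_fraction <- cfg$split$test_fraction %||% 0.2
  if (cfg$split$test_fraction <= 0 || cfg$split$test_fraction >= 1)
    fail("test_fraction must be in (0, 1)")
  cfg$learner <- cfg$learner %||% list(method = "rf")
  if (!cfg$learner$method %in% c("rf", "svm"))
    fail("learner method must be 'rf' or 'svm'")
  cfg$cv <- cfg$cv %||% list(enabled = FALSE)
  cfg$screen <- cfg$screen %||% list(enabled = TRUE, top_n = 50)
  class(cfg) <- c("dti_run_config", "list")
  cfg
}

.log_line <- function(con, level, stage, msg) {
  rec <- jsonlite::toJSON(list(time = format(Sys.time(),
                                             "%Y-%m-%dT%H:%M:%S"),
                               level = level, stage = stage,
                               message = msg), auto_unbox = TRUE)
  if (!is.null(con)) writeLines(rec, con)
  message("[", stage, "] ", msg)
}

#' Run the full modelling pipeline
#'
#' Executes the stages of the modelling flowchart in order — load or
#' simulate the catalog, assemble the labelled pair dataset with sampled
#' negatives, split by scenario, scale, train, evaluate (internal CV and
#' external test), and screen the full drug x target space into a top-N
#' network. Every artifact lands in the run directory together with a
#' resolved copy of the configuration; rerunning the same config reproduces
#' the metrics report exactly.
#'
#' @param config Path to a YAML run config, or a config list.
#' @param output Optional override of the configured output directory.
#' @return Invisibly, a list with the fitted `model`, the `metrics` list,
#'   the `split`, and the run directory.
#' @export
run_pipeline <- function(config, output = NULL) {
  cfg <- read_run_config(config)
  run_dir <- output %||% cfg$output
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(run_dir, "run.log.jsonl"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  stage <- function(name, expr) {
    .log_line(log_con, "info", name, "start")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seed <- as.integer(cfg$seed)
  yaml::write_yaml(unclass(cfg), file.path(run_dir, "resolved_config.yaml"))

  catalog <- stage("data", {
    d <- cfg$data
    if (!is.null(d$preset)) {
      synthetic_catalog(preset = d$preset, seed = seed)$catalog
    } else if (!is.null(d$drugs)) {
      interaction_catalog(read_descriptor_matrix(d$drugs),
                          read_descriptor_matrix(d$targets),
                          read_interaction_tsv(d$positives))
    } else {
      drugs <- featurize_molecules(read_smiles_tsv(d$smiles))
      drugs <- curate_descriptor_matrix(drugs)$matrix
      targets <- featurize_proteins(read_protein_fasta(d$fasta),
                                    sanitize = isTRUE(d$sanitize))
      interaction_catalog(drugs, targets, read_interaction_tsv(d$positives))
    }
  })

  dataset <- stage("build-dataset", {
    ds <- build_pair_dataset(catalog, seed = derive_seed(seed, "negatives"))
    write_pair_tsv(ds, file.path(run_dir, "dataset.tsv"))
    ds
  })

  split <- stage("split", {
    sp <- make_split(dataset, scenario = cfg$split$scenario,
                     test_fraction = cfg$split$test_fraction,
                     seed = derive_seed(seed, "split"))
    write_pair_tsv(list(sp$train, sp$test),
                   file.path(run_dir, "split.tsv"))
    sp
  })

  model <- stage("train", {
    args <- cfg$learner
    args$method <- NULL
    do.call(dti_fit, c(list(train = split$train,
                            method = cfg$learner$method,
                            seed = derive_seed(seed, "train")), args))
  })

  metrics <- stage("evaluate", {
    ext <- evaluate_model(model, split$test)
    m <- list(
      seed = seed,
      scenario = cfg$split$scenario,
      method = cfg$learner$method,
      n_train = n_pairs(split$train),
      n_test = n_pairs(split$test),
      test = ext[c("SE", "SP", "CO", "AUC")]
    )
    if (isTRUE(cfg$cv$enabled)) {
      cv <- cross_validate(split$train, k = cfg$cv$k %||% 5,
                           learner = cfg$learner,
                           seed = derive_seed(seed, "cv"))
      m$cv_mean <- as.list(cv$mean)
    }
    write_metrics_report(m, json_path = file.path(run_dir, "metrics.json"),
                         md_path = file.path(run_dir, "metrics.md"))
    if (!is.null(ext$roc))
      utils::write.table(ext$roc$points,
                         file.path(run_dir, "roc_points.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    m
  })

  if (isTRUE(cfg$screen$enabled)) {
    stage("screen", {
      tab <- comprehensive_screen(model, catalog$drugs, catalog$targets,
                                  catalog)
      write_score_table(tab, file.path(run_dir, "scores.tsv"))
      top_n <- min(cfg$screen$top_n %||% 50, nrow(tab))
      net <- top_n_network(tab, top_n)
      write_network(net,
                    graphml_path = file.path(run_dir, "network.graphml"),
                    edges_path = file.path(run_dir, "network_edges.tsv"))
      topo <- network_topology(net)
      write_metrics_report(
        list(centralization = topo$centralization,
             heterogeneity = topo$heterogeneity,
             n_nodes = topo$n_nodes, n_edges = topo$n_edges),
        json_path = file.path(run_dir, "network_topology.json"))
    })
  }
  .log_line(log_con, "info", "done", run_dir)
  invisible(list(model = model, metrics = metrics, split = split,
                 run_dir = run_dir, catalog = catalog))
}

#' Package and descriptor-profile version string
#'
#' Embeds the versions of the descriptor profile and chem battery so saved
#' models and run artifacts carry their provenance.
#'
#' @return Character scalar.
#' @export
dtiforge_version <- function() {
  paste0("dtiforge ", as.character(utils::packageVersion("dtiforge")),
         " (protein profile ", default_protein_profile()$version,
         ", chem battery ", default_chem_battery()$version, ")")
}
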