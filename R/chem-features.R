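# 2D molecular descriptor battery for drugs. Structures are parsed from
# SMILES with Open Babel (via ChemmineOB/ChemmineR); descriptor values that
# cannot be computed for a molecule are returned as NA masks, never silently
# zeroed, and are later removed by curate_descriptor_matrix().

# per-element properties for the 2D autocorrelation block
.element_props <- function() {
  el <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Se", "Br",
          "I")
  list(
    mass = stats::setNames(c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998,
                             28.085, 30.974, 32.06, 35.45, 78.971, 79.904,
                             126.904), el),
    electronegativity = stats::setNames(c(2.20, 2.04, 2.55, 3.04, 3.44,
                                          3.98, 1.90, 2.19, 2.58, 3.16,
                                          2.55, 2.96, 2.66), el),
    covalent_radius = stats::setNames(c(0.31, 0.84, 0.76, 0.71, 0.66, 0.57,
                                        1.11, 1.07, 1.05, 1.02, 1.20, 1.20,
                                        1.39), el),
    polarizability = stats::setNames(c(0.667, 3.03, 1.76, 1.10, 0.802,
                                       0.557, 5.38, 3.63, 2.90, 2.18, 3.77,
                                       3.05, 5.35), el)
  )
}

#' Default 2D descriptor battery
#'
#' Declares the descriptor layout computed by [featurize_molecule()]:
#' Open Babel physicochemical estimates (MW, logP, TPSA, molar refractivity,
#' H-bond donor/acceptor counts, fluorine count), constitutional counts
#' (heavy atoms, bonds by order, element and ring counts), classical
#' topological indices (Wiener, Zagreb, Randic, Platt, Balaban-type J,
#' diameter, mean topological distance) and Moreau-Broto 2D autocorrelations
#' of atomic mass, electronegativity, covalent radius and polarizability at
#' topological lags 1-5.
#'
#' @return A list of class `chem_battery` with `version` and `names` (the
#'   fixed descriptor order).
#' @export
default_chem_battery <- function() {
  ats <- as.vector(t(outer(c("mass", "electronegativity", "covalent_radius",
                             "polarizability"), 1:5,
                           function(p, d) paste0("ATS.", p, ".lag", d))))
  structure(list(
    version = "2d-v1",
    names = c(
      "MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF",
      "n_heavy", "n_bonds", "n_single", "n_double", "n_triple", "n_rings",
      "n_C", "n_N", "n_O", "n_S", "n_P", "n_halogen", "n_hetero", "frac_C",
      "wiener", "zagreb1", "zagreb2", "randic", "platt", "balaban_j",
      "diameter", "mean_distance",
      ats
    )
  ), class = "chem_battery")
}

# largest covalent fragment of a dotted SMILES, by count of letter characters
.largest_fragment <- function(smiles) {
  parts <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1) return(smiles)
  sizes <- vapply(parts, function(p)
    nchar(gsub("[^A-Za-z]", "", p)), integer(1))
  parts[which.max(sizes)]
}

# parse one SMILES into element symbols + bond table (heavy atoms only),
# via Open Babel SDF conversion; errors carry no id (caller adds it)
.parse_smiles_graph <- function(smiles) {
  txt <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, " mol\n"))
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) stop("unparsable SMILES '", smiles, "'")
  counts <- lines[4]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || n_atoms < 1)
    stop("unparsable SMILES '", smiles, "'")
  atom_lines <- lines[5:(4 + n_atoms)]
  elements <- trimws(substr(atom_lines, 32, 34))
  bonds <- if (n_bonds > 0) {
    bl <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    cbind(a1 = as.integer(substr(bl, 1, 3)),
          a2 = as.integer(substr(bl, 4, 6)),
          order = as.integer(substr(bl, 7, 9)))
  } else {
    matrix(integer(0), ncol = 3, dimnames = list(NULL, c("a1", "a2",
                                                         "order")))
  }
  keep <- which(elements != "H")
  if (length(keep) < length(elements)) {
    remap <- match(seq_along(elements), keep)
    bonds <- bonds[bonds[, 1] %in% keep & bonds[, 2] %in% keep, ,
                   drop = FALSE]
    bonds[, 1] <- remap[bonds[, 1]]
    bonds[, 2] <- remap[bonds[, 2]]
    elements <- elements[keep]
  }
  list(elements = elements, bonds = bonds)
}

#' Compute the 2D descriptor vector of one molecule
#'
#' @param smiles SMILES string. Dotted structures (salts/mixtures) are
#'   reduced to the largest covalent fragment first.
#' @param battery Battery declaration from [default_chem_battery()].
#' @return Named numeric vector in the fixed battery order. Descriptors that
#'   cannot be computed for this molecule (e.g. autocorrelations involving an
#'   element with no tabulated property) are `NA`.
#' @export
#' @examples
#' featurize_molecule("c1ccccc1")[c("n_heavy", "n_rings")]
featurize_molecule <- function(smiles, battery = default_chem_battery()) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  frag <- .largest_fragment(smiles)
  g <- .parse_smiles_graph(frag)
  props <- tryCatch(
    suppressWarnings(ChemmineOB::prop_OB(
      ChemmineOB::forEachMol("SMILES", frag, identity))),
    error = function(e) NULL)
  out <- stats::setNames(rep(NA_real_, length(battery$names)),
                         battery$names)
  if (!is.null(props) && nrow(props) == 1) {
    for (k in c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF")) {
      v <- suppressWarnings(as.numeric(props[[k]]))
      if (length(v) == 1 && is.finite(v)) out[k] <- v
    }
  }
  el <- g$elements
  n <- length(el)
  b <- g$bonds
  out["n_heavy"] <- n
  out["n_bonds"] <- nrow(b)
  out["n_single"] <- sum(b[, "order"] == 1)
  out["n_double"] <- sum(b[, "order"] == 2)
  out["n_triple"] <- sum(b[, "order"] == 3)
  out["n_C"] <- sum(el == "C")
  out["n_N"] <- sum(el == "N")
  out["n_O"] <- sum(el == "O")
  out["n_S"] <- sum(el == "S")
  out["n_P"] <- sum(el == "P")
  out["n_halogen"] <- sum(el %in% c("F", "Cl", "Br", "I"))
  out["n_hetero"] <- sum(el != "C")
  out["frac_C"] <- sum(el == "C") / n
  gr <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(b) > 0)
    gr <- igraph::add_edges(gr, as.vector(t(b[, 1:2, drop = FALSE])))
  comp <- igraph::components(gr)$no
  out["n_rings"] <- nrow(b) - n + comp
  deg <- igraph::degree(gr)
  D <- igraph::distances(gr)
  finD <- D[upper.tri(D)]
  finD <- finD[is.finite(finD)]
  out["wiener"] <- if (n > 1) sum(finD) else 0
  out["zagreb1"] <- sum(deg^2)
  out["zagreb2"] <- if (nrow(b) > 0)
    sum(deg[b[, 1]] * deg[b[, 2]]) else 0
  out["randic"] <- if (nrow(b) > 0)
    sum(1 / sqrt(deg[b[, 1]] * deg[b[, 2]])) else 0
  out["platt"] <- if (nrow(b) > 0) sum(deg[b[, 1]] + deg[b[, 2]] - 2) else 0
  out["diameter"] <- if (length(finD) > 0) max(finD) else 0
  out["mean_distance"] <- if (length(finD) > 0) mean(finD) else 0
  out["balaban_j"] <- {
    q <- nrow(b)
    mu <- q - n + comp
    if (q == 0) 0 else {
      sig <- rowSums(ifelse(is.finite(D), D, 0))
      q / (mu + 1) * sum(1 / sqrt(sig[b[, 1]] * sig[b[, 2]]))
    }
  }
  ep <- .element_props()
  for (pn in names(ep)) {
    pv <- ep[[pn]][el]
    for (d in 1:5) {
      nm <- paste0("ATS.", pn, ".lag", d)
      if (any(is.na(pv))) {
        out[nm] <- NA_real_
      } else {
        pairs <- which(D == d, arr.ind = TRUE)
        pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
        out[nm] <- if (nrow(pairs) > 0)
          sum(pv[pairs[, 1]] * pv[pairs[, 2]]) else 0
      }
    }
  }
  out
}

#' Featurize a set of molecules into a descriptor matrix
#'
#' @param smiles Named character vector of SMILES (names are molecule ids),
#'   or a data.frame with columns `id` and `smiles`.
#' @param battery Battery declaration.
#' @param on_error `"stop"` (default) fails on the first unparsable
#'   structure, naming it; `"omit"` drops unparsable molecules with a
#'   warning, mirroring the benchmark curation policy.
#' @return Numeric matrix (rows = molecules, columns = battery descriptors),
#'   possibly containing NA masks; pass through [curate_descriptor_matrix()]
#'   before modelling.
#' @export
featurize_molecules <- function(smiles, battery = default_chem_battery(),
                                on_error = c("stop", "omit")) {
  on_error <- match.arg(on_error)
  if (is.data.frame(smiles)) {
    if (!all(c("id", "smiles") %in% names(smiles)))
      stop("data.frame input needs columns 'id' and 'smiles'")
    smiles <- stats::setNames(smiles$smiles, smiles$id)
  }
  if (is.null(names(smiles)) || anyDuplicated(names(smiles)))
    stop("molecules must have unique names (ids)")
  rows <- list()
  for (id in names(smiles)) {
    v <- tryCatch(featurize_molecule(smiles[[id]], battery),
                  error = function(e) {
                    if (on_error == "omit") {
                      warning("dropping molecule '", id, "': ",
                              conditionMessage(e))
                      NULL
                    } else {
                      stop("molecule '", id, "': ", conditionMessage(e),
                           call. = FALSE)
                    }
                  })
    if (!is.null(v)) rows[[id]] <- v
  }
  if (length(rows) == 0) stop("no molecule could be featurized")
  do.call(rbind, rows)
}

#' Read a SMILES table
#'
#' @param path TSV file with columns `id` and `smiles`.
#' @return Named character vector of SMILES.
#' @export
read_smiles_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "")
  if (!all(c("id", "smiles") %in% names(df)))
    stop("SMILES TSV must have columns 'id' and 'smiles'")
  stats::setNames(df$smiles, df$id)
}
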