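# Protein sequence descriptor families and their assembly into the default
# 1080-dimensional feature vector.

#' Validate (and optionally sanitize) a protein sequence
#'
#' Ensures a sequence contains only the 20 standard residues. Nonstandard
#' letters (B, Z, X, U, O, J, `*`, gaps) are either reported as an error with
#' their position, or stripped with a warning when `sanitize = TRUE` —
#' mirroring the curation policy of dropping entries whose descriptors cannot
#' be computed.
#'
#' @param sequence Character scalar, amino-acid sequence.
#' @param sanitize Strip nonstandard residues instead of failing.
#' @param min_length Minimum accepted length after sanitization.
#' @return The validated upper-case sequence.
#' @export
check_protein_sequence <- function(sequence, sanitize = FALSE,
                                   min_length = 2) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  s <- toupper(gsub("[[:space:]]", "", sequence))
  letters <- strsplit(s, "")[[1]]
  bad <- which(!letters %in% amino_acids())
  if (length(bad) > 0) {
    if (sanitize) {
      warning("stripped ", length(bad), " nonstandard residue(s): ",
              paste0(letters[bad[seq_len(min(5, length(bad)))]],
                     "@", bad[seq_len(min(5, length(bad)))],
                     collapse = ", "),
              if (length(bad) > 5) ", ..." else "")
      letters <- letters[-bad]
      s <- paste(letters, collapse = "")
    } else {
      stop("nonstandard residue '", letters[bad[1]], "' at position ",
           bad[1], "; use sanitize = TRUE to strip")
    }
  }
  if (nchar(s) < min_length)
    stop("sequence too short: length ", nchar(s), " < required minimum ",
         min_length)
  s
}

.seq_letters <- function(sequence) strsplit(sequence, "")[[1]]

#' Amino-acid and dipeptide composition (420 values)
#'
#' First 20 values are residue frequencies (summing to 1); the following 400
#' are dipeptide frequencies over the L-1 adjacent residue pairs (summing to
#' 1), both in fixed alphabetical order.
#'
#' @param sequence Protein sequence (standard residues, length >= 2).
#' @return Named numeric vector of length 420 (`AAC.*` then `DPC.*`).
#' @export
#' @examples
#' composition_features("ACDA")[c("AAC.A", "AAC.C", "AAC.D")]
composition_features <- function(sequence) {
  s <- check_protein_sequence(sequence, min_length = 2)
  aa <- amino_acids()
  letters <- .seq_letters(s)
  n <- length(letters)
  aac <- table(factor(letters, levels = aa)) / n
  dip <- paste0(letters[-n], letters[-1])
  dipeptides <- as.vector(t(outer(aa, aa, paste0)))
  dpc <- table(factor(dip, levels = dipeptides)) / (n - 1)
  out <- c(as.numeric(aac), as.numeric(dpc))
  names(out) <- c(paste0("AAC.", aa), paste0("DPC.", dipeptides))
  out
}

#' Sequence autocorrelation descriptors
#'
#' Lagged autocorrelation of standardized residue property profiles along the
#' sequence, in one of three conventions:
#' \describe{
#'   \item{moreau_broto}{normalized Moreau-Broto,
#'     \eqn{AC(d) = \sum_i p_i p_{i+d} / (L-d)}}
#'   \item{moran}{Moran's I (centered, variance-scaled)}
#'   \item{geary}{Geary's C (squared-difference form)}
#' }
#' For a zero-variance profile the centered forms are 0/0; the convention
#' here is to return 0.
#'
#' @param sequence Protein sequence of length > `maxlag`.
#' @param properties Named list of standardized residue scales
#'   (default: the bundled set of 8 autocorrelation scales).
#' @param maxlag Maximum lag d (default 30).
#' @param kind One of `"moreau_broto"`, `"moran"`, `"geary"`.
#' @return Named numeric vector of length `length(properties) * maxlag`.
#' @export
autocorrelation_features <- function(sequence,
                                     properties = aa_scales(.autocorrelation_scale_names),
                                     maxlag = 30,
                                     kind = c("moreau_broto", "moran",
                                              "geary")) {
  kind <- match.arg(kind)
  if (length(properties) == 0) stop("at least one property scale required")
  s <- check_protein_sequence(sequence, min_length = maxlag + 1)
  letters <- .seq_letters(s)
  L <- length(letters)
  out <- numeric(0)
  for (pn in names(properties)) {
    p <- properties[[pn]][letters]
    pbar <- mean(p)
    varp <- mean((p - pbar)^2)
    vals <- vapply(seq_len(maxlag), function(d) {
      a <- p[1:(L - d)]
      b <- p[(1 + d):L]
      switch(kind,
        moreau_broto = sum(a * b) / (L - d),
        moran = {
          if (varp == 0) 0 else
            (sum((a - pbar) * (b - pbar)) / (L - d)) / varp
        },
        geary = {
          v1 <- sum((p - pbar)^2) / (L - 1)
          if (v1 == 0) 0 else
            (sum((a - b)^2) / (2 * (L - d))) / v1
        })
    }, numeric(1))
    names(vals) <- paste0(toupper(substr(kind, 1, 2)), ".", pn, ".lag",
                          seq_len(maxlag))
    out <- c(out, vals)
  }
  out
}

.ctd_group_of <- function(letters, groups) {
  g <- integer(length(letters))
  for (k in 1:3) g[letters %in% groups[[k]]] <- k
  g
}

#' Composition/transition/distribution descriptors (147 values)
#'
#' For each physicochemical attribute the residues fall into three groups;
#' the descriptor reports per attribute the group composition (3), the
#' normalized transition counts between distinct groups over adjacent pairs
#' (3), and for each group the positions of the first, 25\%, 50\%, 75\% and
#' last occurrence as a percentage of sequence length (15; 1-based residue
#' indexing, 0 when the group is absent).
#'
#' @param sequence Protein sequence, length >= 2.
#' @param groups Attribute groupings as returned by [ctd_groups()]; each
#'   attribute is a list of 3 residue groups partitioning the alphabet.
#' @return Named numeric vector of length `21 * length(groups)` (147 for the
#'   default 7 attributes).
#' @export
ctd_features <- function(sequence, groups = ctd_groups()) {
  s <- check_protein_sequence(sequence, min_length = 2)
  letters <- .seq_letters(s)
  L <- length(letters)
  out <- numeric(0)
  for (an in names(groups)) {
    gdef <- groups[[an]]
    covered <- unlist(gdef)
    if (any(!letters %in% covered))
      stop("attribute '", an, "' does not cover residue '",
           setdiff(letters, covered)[1], "'")
    g <- .ctd_group_of(letters, gdef)
    comp <- vapply(1:3, function(k) mean(g == k), numeric(1))
    names(comp) <- paste0("CTD.C.", an, ".g", 1:3)
    pairs <- cbind(g[-L], g[-1])
    trans <- c(
      sum((pairs[, 1] == 1 & pairs[, 2] == 2) |
            (pairs[, 1] == 2 & pairs[, 2] == 1)),
      sum((pairs[, 1] == 1 & pairs[, 2] == 3) |
            (pairs[, 1] == 3 & pairs[, 2] == 1)),
      sum((pairs[, 1] == 2 & pairs[, 2] == 3) |
            (pairs[, 1] == 3 & pairs[, 2] == 2))
    ) / (L - 1)
    names(trans) <- paste0("CTD.T.", an, c(".g1g2", ".g1g3", ".g2g3"))
    dist <- numeric(0)
    for (k in 1:3) {
      pos <- which(g == k)
      q <- if (length(pos) == 0) rep(0, 5) else {
        idx <- pmax(1, ceiling(c(0.25, 0.5, 0.75) * length(pos)))
        100 * c(pos[1], pos[idx], pos[length(pos)]) / L
      }
      names(q) <- paste0("CTD.D.", an, ".g", k,
                         c(".first", ".p25", ".p50", ".p75", ".p100"))
      dist <- c(dist, q)
    }
    out <- c(out, comp, trans, dist)
  }
  out
}

#' Sequence-order coupling numbers and quasi-sequence-order descriptors
#'
#' For each residue-distance matrix, the coupling number at lag d is
#' \eqn{\tau_d = \sum_{i=1}^{L-d} dist(r_i, r_{i+d})^2}. The quasi-sequence-
#' order block then contains 20 composition-type values
#' \eqn{f_u / (1 + w \sum_d \tau_d)} and `maxlag` order-type values
#' \eqn{w \tau_d / (1 + w \sum_d \tau_d)} (residue frequencies `f` summing
#' to 1). With the default two matrices the output is `2*maxlag` coupling
#' numbers plus `2*(20+maxlag)` quasi-sequence-order values (160 for
#' `maxlag = 30`).
#'
#' @param sequence Protein sequence of length > `maxlag`.
#' @param maxlag Maximum lag (default 30).
#' @param weight Weighting factor w (default 0.1).
#' @param dist_mats Named list of 20x20 residue-distance matrices (default
#'   [residue_distance_matrices()]).
#' @return Named numeric vector (`SOC.*` then `QSO.*`).
#' @export
order_features <- function(sequence, maxlag = 30, weight = 0.1,
                           dist_mats = residue_distance_matrices()) {
  s <- check_protein_sequence(sequence, min_length = maxlag + 1)
  letters <- .seq_letters(s)
  L <- length(letters)
  aa <- amino_acids()
  f <- as.numeric(table(factor(letters, levels = aa))) / L
  soc <- numeric(0)
  qso <- numeric(0)
  for (mn in names(dist_mats)) {
    dm <- dist_mats[[mn]]
    tau <- vapply(seq_len(maxlag), function(d) {
      i <- 1:(L - d)
      sum(dm[cbind(letters[i], letters[i + d])]^2)
    }, numeric(1))
    names(tau) <- paste0("SOC.", mn, ".lag", seq_len(maxlag))
    soc <- c(soc, tau)
    denom <- 1 + weight * sum(tau)
    q <- c(f / denom, weight * tau / denom)
    names(q) <- c(paste0("QSO.", mn, ".comp.", aa),
                  paste0("QSO.", mn, ".order.lag", seq_len(maxlag)))
    qso <- c(qso, q)
  }
  c(soc, qso)
}

#' Amphiphilic pseudo-amino-acid composition (20 + 2*lam values)
#'
#' Combines residue composition with sequence-correlation factors of the
#' standardized hydrophobicity and hydrophilicity profiles:
#' \eqn{\tau_{2k-1} = \sum_i H_1(i) H_1(i+k) / (L-k)} and
#' \eqn{\tau_{2k} = \sum_i H_2(i) H_2(i+k) / (L-k)} for lag k = 1..lam.
#' All components share the denominator \eqn{1 + w \sum_j \tau_j}: the first
#' 20 values are \eqn{f_u / denom}, the remaining 2*lam are
#' \eqn{w \tau_j / denom}.
#'
#' @param sequence Protein sequence of length > `lam`.
#' @param lam Number of correlation tiers (default 30).
#' @param weight Weight w of the correlation part (default 0.05).
#' @return Named numeric vector of length `20 + 2*lam`.
#' @export
apaac_features <- function(sequence, lam = 30, weight = 0.05) {
  s <- check_protein_sequence(sequence, min_length = lam + 1)
  letters <- .seq_letters(s)
  L <- length(letters)
  aa <- amino_acids()
  sc <- aa_scales(c("hydropathy", "hydrophilicity"))
  h1 <- sc$hydropathy[letters]
  h2 <- sc$hydrophilicity[letters]
  f <- as.numeric(table(factor(letters, levels = aa))) / L
  tau <- numeric(2 * lam)
  tn <- character(2 * lam)
  for (k in seq_len(lam)) {
    i <- 1:(L - k)
    tau[2 * k - 1] <- sum(h1[i] * h1[i + k]) / (L - k)
    tau[2 * k] <- sum(h2[i] * h2[i + k]) / (L - k)
    tn[2 * k - 1] <- paste0("APAAC.tau.H1.lag", k)
    tn[2 * k] <- paste0("APAAC.tau.H2.lag", k)
  }
  denom <- 1 + weight * sum(tau)
  out <- c(f / denom, weight * tau / denom)
  names(out) <- c(paste0("APAAC.comp.", aa), tn)
  out
}

#' Averaged amino-acid property descriptors
#'
#' One value per property scale: the mean of the standardized property over
#' the residues of the sequence.
#'
#' @param sequence Protein sequence, length >= 1.
#' @param properties Named list of standardized residue scales (default: all
#'   33 bundled scales).
#' @return Named numeric vector, one value per property (`AAP.*`).
#' @export
aaprop_features <- function(sequence, properties = aa_scales()) {
  if (length(properties) == 0) stop("property set must be nonempty")
  s <- check_protein_sequence(sequence, min_length = 1)
  letters <- .seq_letters(s)
  out <- vapply(properties, function(p) mean(p[letters]), numeric(1))
  names(out) <- paste0("AAP.", names(properties))
  out
}

#' Default protein descriptor profile (1080 dimensions)
#'
#' The family allocation behind the standard 1080-dimensional protein vector:
#' amino-acid composition 20 + dipeptide composition 400 + normalized
#' Moreau-Broto autocorrelation (8 scales x 30 lags = 240) + CTD 147 +
#' sequence-order coupling numbers 60 + quasi-sequence-order 100
#' (maxlag 30, two distance matrices, w = 0.1) + amphiphilic
#' pseudo-amino-acid composition 80 (lam = 30, w = 0.05) + 33 averaged
#' residue properties = 1080. The profile is versioned; any custom profile
#' must declare its expected total length.
#'
#' @return A list of class `protein_profile` with elements `version`,
#'   `total`, and `families` (ordered list of family specs).
#' @export
default_protein_profile <- function() {
  structure(list(
    version = "1080-v1",
    total = 1080L,
    families = list(
      list(family = "composition"),
      list(family = "autocorrelation", kind = "moreau_broto", maxlag = 30,
           properties = .autocorrelation_scale_names),
      list(family = "ctd"),
      list(family = "order", maxlag = 30, weight = 0.1),
      list(family = "apaac", lam = 30, weight = 0.05),
      list(family = "aaprop")
    )
  ), class = "protein_profile")
}

#' Minimum sequence length admitted by a profile
#'
#' The strictest family precondition: lag-based families require length
#' greater than their maximum lag (31 residues for the default profile).
#'
#' @param profile A `protein_profile`.
#' @return Integer minimum length.
#' @export
profile_min_length <- function(profile = default_protein_profile()) {
  m <- 2L
  for (fam in profile$families) {
    lag <- switch(fam$family,
                  autocorrelation = fam$maxlag %||% 30,
                  order = fam$maxlag %||% 30,
                  apaac = fam$lam %||% 30,
                  1)
    m <- max(m, as.integer(lag) + 1L)
  }
  m
}

#' Compute the full protein feature vector
#'
#' Concatenates the descriptor family blocks of a profile in their declared
#' order. With the default profile the result has exactly 1080 dimensions for
#' any admissible sequence, independent of its length.
#'
#' @param sequence Protein sequence (standard residues; length at least
#'   [profile_min_length()] of the profile).
#' @param profile Descriptor profile (default [default_protein_profile()]).
#' @param sanitize Strip nonstandard residues with a warning instead of
#'   failing.
#' @return Named numeric vector of length `profile$total`.
#' @export
#' @examples
#' v <- featurize_protein(paste(rep("ACDEFGHIKLMNPQRSTVWY", 3), collapse = ""))
#' length(v)  # 1080
featurize_protein <- function(sequence, profile = default_protein_profile(),
                              sanitize = FALSE) {
  if (!inherits(profile, "protein_profile"))
    stop("profile must be a protein_profile object")
  s <- check_protein_sequence(sequence, sanitize = sanitize,
                              min_length = profile_min_length(profile))
  out <- numeric(0)
  for (fam in profile$families) {
    block <- tryCatch(
      switch(fam$family,
        composition = composition_features(s),
        autocorrelation = autocorrelation_features(
          s, properties = aa_scales(fam$properties %||%
                                      .autocorrelation_scale_names),
          maxlag = fam$maxlag %||% 30,
          kind = fam$kind %||% "moreau_broto"),
        ctd = ctd_features(s),
        order = order_features(s, maxlag = fam$maxlag %||% 30,
                               weight = fam$weight %||% 0.1),
        apaac = apaac_features(s, lam = fam$lam %||% 30,
                               weight = fam$weight %||% 0.05),
        aaprop = aaprop_features(s),
        stop("unknown descriptor family '", fam$family, "'")),
      error = function(e)
        stop("descriptor family '", fam$family, "' failed: ",
             conditionMessage(e), call. = FALSE))
    out <- c(out, block)
  }
  if (!is.null(profile$total) && length(out) != profile$total)
    stop("profile declares ", profile$total, " dimensions but produced ",
         length(out))
  if (anyDuplicated(names(out)))
    stop("duplicate descriptor names in profile output")
  out
}

#' Featurize a set of protein sequences into a descriptor matrix
#'
#' @param sequences Named character vector of sequences, or an
#'   `AAStringSet`.
#' @param profile Descriptor profile.
#' @param sanitize Strip nonstandard residues (sequences that remain too
#'   short are dropped with a warning, mirroring the omission policy for
#'   entries whose descriptors cannot be computed).
#' @return Numeric matrix, rows = proteins (named), columns = descriptors.
#' @export
featurize_proteins <- function(sequences,
                               profile = default_protein_profile(),
                               sanitize = FALSE) {
  if (inherits(sequences, "XStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must have unique names (protein ids)")
  rows <- list()
  for (id in names(sequences)) {
    v <- tryCatch(featurize_protein(sequences[[id]], profile, sanitize),
                  error = function(e) {
                    if (sanitize) {
                      warning("dropping protein '", id, "': ",
                              conditionMessage(e))
                      NULL
                    } else {
                      stop("protein '", id, "': ", conditionMessage(e),
                           call. = FALSE)
                    }
                  })
    if (!is.null(v)) rows[[id]] <- v
  }
  if (length(rows) == 0) stop("no protein could be featurized")
  do.call(rbind, rows)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file (plain text).
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  stats::setNames(as.character(set), ids)
}
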