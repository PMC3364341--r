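# Amino-acid alphabet, bundled physicochemical scales, CTD groupings and
# residue-distance matrices used by the protein descriptor families.

#' The 20 standard amino acids
#'
#' One-letter codes in alphabetical order. This ordering fixes the layout of
#' every composition-type descriptor block.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# scales are written in the classic biochemistry order and reordered on access
.aa_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.scale <- function(x) {
  names(x) <- .aa_order
  x[amino_acids()]
}

# Bundled residue scales. Continuous scales follow common literature
# compilations (Kyte-Doolittle hydropathy, Hopp-Woods hydrophilicity,
# Grantham polarity/composition, Chou-Fasman propensities, ...); indicator
# and count scales are exact by construction. All are standardized to zero
# mean / unit variance over the 20 residues before use, so only the relative
# ordering of values matters downstream.
.aa_scale_data <- function() {
  list(
    hydropathy = .scale(c(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2,
                          4.5, 3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9,
                          -1.3, 4.2)),
    hydrophilicity = .scale(c(-0.5, 3.0, 0.2, 3.0, -1.0, 0.2, 3.0, 0.0, -0.5,
                              -1.8, -1.8, 3.0, -1.3, -2.5, 0.0, 0.3, -0.4,
                              -3.4, -2.3, -1.5)),
    sidechain_mass = .scale(c(15.02, 100.14, 58.06, 59.04, 47.10, 72.09,
                              73.07, 1.01, 81.10, 57.08, 57.08, 72.13, 75.15,
                              91.13, 42.08, 31.03, 45.06, 130.17, 107.13,
                              43.06)),
    flexibility = .scale(c(0.357, 0.529, 0.463, 0.511, 0.346, 0.493, 0.497,
                           0.544, 0.323, 0.462, 0.365, 0.466, 0.295, 0.314,
                           0.509, 0.507, 0.444, 0.305, 0.420, 0.386)),
    polarizability = .scale(c(0.046, 0.291, 0.134, 0.105, 0.128, 0.180,
                              0.151, 0.000, 0.230, 0.186, 0.186, 0.219,
                              0.221, 0.290, 0.131, 0.062, 0.108, 0.409,
                              0.298, 0.140)),
    free_energy = .scale(c(-0.368, -1.03, 0.0, 2.06, 4.53, 0.731, 1.77,
                           -0.525, 0.0, 0.791, 1.07, 0.0, 0.656, 1.06,
                           -2.24, -0.524, 0.0, 1.60, 4.91, 0.401)),
    surface_area = .scale(c(115, 225, 160, 150, 135, 180, 190, 75, 195, 175,
                            170, 200, 185, 210, 145, 115, 140, 255, 230,
                            155)),
    residue_volume = .scale(c(52.6, 109.1, 75.7, 68.4, 68.3, 89.7, 84.7,
                              36.3, 91.9, 102.0, 102.0, 105.1, 97.7, 113.9,
                              73.6, 54.9, 71.2, 135.4, 116.2, 85.1)),
    relative_mutability = .scale(c(100, 65, 134, 106, 20, 93, 102, 49, 66,
                                   96, 40, 56, 94, 41, 56, 120, 97, 18, 41,
                                   74)),
    polarity = .scale(c(8.1, 10.5, 11.6, 13.0, 5.5, 10.5, 12.3, 9.0, 10.4,
                        5.2, 4.9, 11.3, 5.7, 5.2, 8.0, 9.2, 8.6, 5.4, 6.2,
                        5.9)),
    composition = .scale(c(0.00, 0.65, 1.33, 1.38, 2.75, 0.89, 0.92, 0.74,
                           0.58, 0.00, 0.00, 0.33, 0.00, 0.00, 0.39, 1.42,
                           0.71, 0.13, 0.20, 0.00)),
    isoelectric_point = .scale(c(6.00, 10.76, 5.41, 2.77, 5.07, 5.65, 3.22,
                                 5.97, 7.59, 6.02, 5.98, 9.74, 5.74, 5.48,
                                 6.30, 5.68, 5.60, 5.89, 5.66, 5.96)),
    pk_carboxyl = .scale(c(2.34, 2.17, 2.02, 1.88, 1.96, 2.17, 2.19, 2.34,
                           1.82, 2.36, 2.36, 2.18, 2.28, 1.83, 1.99, 2.21,
                           2.09, 2.83, 2.20, 2.32)),
    pk_amino = .scale(c(9.69, 9.04, 8.80, 9.60, 10.28, 9.13, 9.67, 9.60,
                        9.17, 9.60, 9.60, 8.95, 9.21, 9.13, 10.60, 9.15,
                        9.10, 9.39, 9.11, 9.62)),
    molecular_weight = .scale(c(89.09, 174.20, 132.12, 133.10, 121.15,
                                146.15, 147.13, 75.07, 155.16, 131.17,
                                131.17, 146.19, 149.21, 165.19, 115.13,
                                105.09, 119.12, 204.23, 181.19, 117.15)),
    hydrophobicity_consensus = .scale(c(0.62, -2.53, -0.78, -0.90, 0.29,
                                        -0.85, -0.74, 0.48, -0.40, 1.38,
                                        1.06, -1.50, 0.64, 1.19, 0.12,
                                        -0.18, -0.05, 0.81, 0.26, 1.08)),
    helix_propensity = .scale(c(1.42, 0.98, 0.67, 1.01, 0.70, 1.11, 1.51,
                                0.57, 1.00, 1.08, 1.21, 1.16, 1.45, 1.13,
                                0.57, 0.77, 0.83, 1.08, 0.69, 1.06)),
    sheet_propensity = .scale(c(0.83, 0.93, 0.89, 0.54, 1.19, 1.10, 0.37,
                                0.75, 0.87, 1.60, 1.30, 0.74, 1.05, 1.38,
                                0.55, 0.75, 1.19, 1.37, 1.47, 1.70)),
    turn_propensity = .scale(c(0.66, 0.95, 1.56, 1.46, 1.19, 0.98, 0.74,
                               1.56, 0.95, 0.47, 0.59, 1.01, 0.60, 0.60,
                               1.52, 1.43, 0.96, 0.96, 1.14, 0.50)),
    bulkiness = .scale(c(11.50, 14.28, 12.82, 11.68, 13.46, 14.45, 13.57,
                         3.40, 13.69, 21.40, 21.40, 15.71, 16.25, 19.80,
                         17.43, 9.47, 15.77, 21.67, 18.03, 21.57)),
    refractivity = .scale(c(4.34, 26.66, 13.28, 12.00, 35.77, 17.56, 17.26,
                            0.00, 21.81, 19.06, 18.78, 21.29, 21.64, 29.40,
                            10.93, 6.35, 11.01, 42.53, 31.53, 13.92)),
    heavy_atoms_sidechain = .scale(c(1, 7, 4, 4, 2, 5, 5, 0, 6, 4, 4, 5, 4,
                                     7, 3, 2, 3, 10, 8, 3)),
    vdw_volume = .scale(c(1.00, 6.13, 2.95, 2.78, 2.43, 3.95, 3.78, 0.00,
                          4.66, 4.00, 4.00, 4.77, 4.43, 5.89, 2.72, 1.60,
                          2.60, 8.08, 6.47, 3.00)),
    net_charge = .scale(c(0, 1, 0, -1, 0, 0, -1, 0, 0.1, 0, 0, 1, 0, 0, 0,
                          0, 0, 0, 0, 0)),
    aromatic = .scale(c(0, 0, 0, 0, 0, 0, 1, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0,
                        1, 1, 0)),
    aliphatic = .scale(c(1, 0, 0, 0, 0, 0, 0, 1, 0, 1, 1, 0, 0, 0, 0, 0, 0,
                         0, 0, 1)),
    sulfur = .scale(c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0,
                      0, 0)),
    hydroxyl = .scale(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1,
                        0, 1, 0)),
    amide = .scale(c(0, 0, 1, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
                     0, 0)),
    small_residue = .scale(c(1, 0, 0, 1, 1, 0, 0, 1, 0, 0, 0, 0, 0, 0, 1, 1,
                             1, 0, 0, 0)),
    rotatable_bonds = .scale(c(0, 4, 2, 2, 1, 3, 3, 0, 1, 2, 2, 4, 3, 1, 0,
                               1, 1, 1, 1, 1)),
    hbond_donor = .scale(c(0, 5, 2, 1, 1, 2, 1, 0, 1, 0, 0, 2, 0, 0, 0, 1,
                           1, 1, 1, 0)),
    hbond_acceptor = .scale(c(0, 4, 2, 4, 0, 2, 4, 0, 1, 0, 0, 1, 0, 0, 0,
                              2, 2, 0, 2, 0))
  )
}

#' Bundled amino-acid property scales
#'
#' Thirty-three residue scales covering hydropathy, hydrophilicity, size,
#' flexibility, charge, secondary-structure propensity and simple structural
#' counts/indicators. They parameterize the autocorrelation, quasi-sequence-
#' order, amphiphilic pseudo-composition and averaged-property descriptor
#' families.
#'
#' @param names Optional character vector selecting a subset of scales.
#' @param standardize Standardize each scale to zero mean and unit variance
#'   over the 20 residues (population variance). Default `TRUE`; descriptor
#'   code always consumes standardized scales.
#' @return Named list of numeric vectors, each of length 20 and named by the
#'   residues of [amino_acids()].
#' @export
#' @examples
#' s <- aa_scales("hydropathy")
#' round(mean(s$hydropathy), 12)  # 0 after standardization
aa_scales <- function(names = NULL, standardize = TRUE) {
  sc <- .aa_scale_data()
  if (!is.null(names)) {
    missing <- setdiff(names, base::names(sc))
    if (length(missing) > 0)
      stop("unknown amino-acid scale(s): ", paste(missing, collapse = ", "))
    sc <- sc[names]
  }
  if (standardize) sc <- lapply(sc, standardize_scale)
  sc
}

#' Standardize a residue property scale
#'
#' Centers to zero mean and scales to unit variance over the 20 residues,
#' using the population variance (denominator 20).
#'
#' @param values Named numeric vector of length 20 (one value per residue).
#' @return Standardized named numeric vector.
#' @export
standardize_scale <- function(values) {
  if (length(values) != 20)
    stop("a property scale must have exactly 20 entries, got ",
         length(values))
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  if (sigma == 0) stop("cannot standardize a constant property scale")
  out <- (values - mu) / sigma
  out
}

# Scales used by the default autocorrelation family (the classic set of 8).
.autocorrelation_scale_names <- c(
  "hydropathy", "hydrophilicity", "flexibility", "polarizability",
  "free_energy", "surface_area", "residue_volume", "relative_mutability"
)

#' CTD residue groupings
#'
#' The seven physicochemical attributes used by the composition/transition/
#' distribution descriptors, each splitting the 20 residues into three
#' disjoint groups (the classic groupings by hydrophobicity, normalized van
#' der Waals volume, polarity, polarizability, charge, secondary structure
#' and solvent accessibility).
#'
#' @return Named list of 7 attributes; each element is a list of 3 character
#'   vectors partitioning [amino_acids()].
#' @export
ctd_groups <- function() {
  g <- function(a, b, c) list(g1 = strsplit(a, "")[[1]],
                              g2 = strsplit(b, "")[[1]],
                              g3 = strsplit(c, "")[[1]])
  list(
    hydrophobicity        = g("RKEDQN", "GASTPHY", "CLVIMFW"),
    vdw_volume            = g("GASCTPD", "NVEQIL", "MHKFRYW"),
    polarity              = g("LIFWCMVY", "PATGS", "HQRKNED"),
    polarizability        = g("GASDT", "CPNVEQIL", "KMHFRYW"),
    charge                = g("KR", "ANCQGHILMFPSTWYV", "DE"),
    secondary_structure   = g("EALMQKRH", "VIYCWFT", "GNPSD"),
    solvent_accessibility = g("ALFCGIVW", "RKQEND", "MSPTHY")
  )
}

#' Residue-distance matrices for quasi-sequence-order descriptors
#'
#' Two 20x20 symmetric distance matrices over the standard residues:
#' \describe{
#'   \item{physicochemical}{Euclidean distance over the standardized
#'     hydrophobicity, hydrophilicity and side-chain-mass scales (the
#'     construction popularized for sequence-order coupling numbers).}
#'   \item{chemical}{Grantham-style chemical distance from residue
#'     composition, polarity and volume with the canonical weighting
#'     coefficients.}
#' }
#' Both matrices are normalized to a maximum entry of 1 so that coupling
#' numbers from the two are on a common scale.
#'
#' @return Named list of two 20x20 numeric matrices with residue dimnames.
#' @export
residue_distance_matrices <- function() {
  aa <- amino_acids()
  sc <- aa_scales(c("hydropathy", "hydrophilicity", "sidechain_mass"))
  phys <- matrix(0, 20, 20, dimnames = list(aa, aa))
  for (p in sc) phys <- phys + outer(p, p, function(a, b) (a - b)^2)
  phys <- sqrt(phys / length(sc))
  phys <- phys / max(phys)

  raw <- .aa_scale_data()
  comp <- raw$composition
  pol <- raw$polarity
  # Grantham residue volumes (differ from the bundled partial-volume scale)
  vol <- .scale(c(31, 124, 56, 54, 55, 85, 83, 3, 96, 111, 111, 119, 105,
                  132, 32.5, 32, 61, 170, 136, 84))
  d2 <- 1.833 * outer(comp, comp, "-")^2 +
    0.1018 * outer(pol, pol, "-")^2 +
    0.000399 * outer(vol, vol, "-")^2
  chem <- sqrt(d2)
  chem <- chem / max(chem)
  list(physicochemical = phys, chemical = chem)
}
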