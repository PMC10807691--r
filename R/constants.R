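#' @title Descriptor constants
#' @description Fixed alphabets, physicochemical scales and group
#'   partitions used by the descriptor families.  Everything here is frozen:
#'   descriptor values are only comparable across runs if these tables never
#'   move.
#' @name bactipred-constants
#' @keywords internal
NULL

# Canonical amino-acid order used by every composition-type descriptor.
AA_ORDER <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Secondary-structure states (3-state).
SS_STATES <- c("H", "E", "C")

# Chou's three conventional property scales (hydrophobicity, hydrophilicity,
# side-chain mass), in AA_ORDER.  Standardized on the fly where needed.
AA_HYDROPHOBICITY <- c(
  A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
  E = -0.74, Q = -0.85, G = 0.48, H = -0.40, I = 1.38,
  L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
  S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08)

AA_HYDROPHILICITY <- c(
  A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0,
  E = 3.0, Q = 0.2, G = 0.0, H = -0.5, I = -1.8,
  L = -1.8, K = 3.0, M = -1.3, F = -2.5, P = 0.0,
  S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5)

AA_SIDECHAIN_MASS <- c(
  A = 15, R = 101, N = 58, D = 59, C = 47,
  E = 73, Q = 72, G = 1, H = 82, I = 57,
  L = 57, K = 73, M = 75, F = 91, P = 42,
  S = 31, T = 45, W = 130, Y = 107, V = 43)

# Seven physicochemical attributes, each partitioning the 20 letters into
# three groups (Dubchak's CTD grouping, as shipped by standard descriptor
# toolkits).  Order of attributes and groups is part of the feature schema.
CTD_GROUPS <- list(
  hydrophobicity = list(
    g1 = c("R", "K", "E", "D", "Q", "N"),
    g2 = c("G", "A", "S", "T", "P", "H", "Y"),
    g3 = c("C", "L", "V", "I", "M", "F", "W")),
  vdw_volume = list(
    g1 = c("G", "A", "S", "C", "T", "P", "D"),
    g2 = c("N", "V", "E", "Q", "I", "L"),
    g3 = c("M", "H", "K", "F", "R", "Y", "W")),
  polarity = list(
    g1 = c("L", "I", "F", "W", "C", "M", "V", "Y"),
    g2 = c("P", "A", "T", "G", "S"),
    g3 = c("H", "Q", "R", "K", "N", "E", "D")),
  polarizability = list(
    g1 = c("G", "A", "S", "D", "T"),
    g2 = c("C", "P", "N", "V", "E", "Q", "I", "L"),
    g3 = c("K", "M", "H", "F", "R", "Y", "W")),
  charge = list(
    g1 = c("K", "R"),
    g2 = c("A", "N", "C", "Q", "G", "H", "I", "L", "M",
           "F", "P", "S", "T", "W", "Y", "V"),
    g3 = c("D", "E")),
  secondary_structure = list(
    g1 = c("E", "A", "L", "M", "Q", "K", "R", "H"),
    g2 = c("V", "I", "Y", "C", "W", "F", "T"),
    g3 = c("G", "N", "P", "S", "D")),
  solvent_accessibility = list(
    g1 = c("A", "L", "F", "C", "G", "I", "V", "W"),
    g2 = c("R", "K", "Q", "E", "N", "D"),
    g3 = c("M", "S", "P", "T", "H", "Y")))

# Standardize a 20-value property scale: zero mean, unit population SD
# (divisor 20), the convention of Chou's pseudo amino acid composition.
standardize_scale <- function(p) {
  p <- p[AA_ORDER]
  (p - mean(p)) / sqrt(sum((p - mean(p))^2) / length(p))
}

#' Physicochemical distance matrix between amino acids
#'
#' Squared pairwise distance between residues computed as the mean squared
#' difference of the three standardized property scales (hydrophobicity,
#' hydrophilicity, side-chain mass).  Used by the sequence-order-coupling
#' and quasi-sequence-order descriptors.  Self-distance is zero.
#'
#' @return A 20 x 20 symmetric numeric matrix of squared distances, rows and
#'   columns in the canonical order `A,R,N,D,C,E,Q,G,H,I,L,K,M,F,P,S,T,W,Y,V`.
#' @export
#' @examples
#' d2 <- aa_distance_matrix()
#' all(diag(d2) == 0)
aa_distance_matrix <- function() {
  scales <- rbind(standardize_scale(AA_HYDROPHOBICITY),
                  standardize_scale(AA_HYDROPHILICITY),
                  standardize_scale(AA_SIDECHAIN_MASS))
  d2 <- matrix(0, 20, 20, dimnames = list(AA_ORDER, AA_ORDER))
  for (i in seq_len(20)) {
    for (j in seq_len(20)) {
      d2[i, j] <- mean((scales[, i] - scales[, j])^2)
    }
  }
  d2
}

#' Print the frozen descriptor schema constants
#'
#' Writes the amino-acid order, CTD attribute/group partitions and property
#' scales to the console so the exact feature schema can be audited.
#'
#' @return Invisibly, a list with the constants.
#' @export
describe_constants <- function() {
  cat("Amino-acid order:", paste(AA_ORDER, collapse = " "), "\n\n")
  cat("CTD attributes (3 groups each):\n")
  for (a in names(CTD_GROUPS)) {
    g <- CTD_GROUPS[[a]]
    cat(sprintf("  %-22s g1={%s} g2={%s} g3={%s}\n", a,
                paste(g$g1, collapse = ""), paste(g$g2, collapse = ""),
                paste(g$g3, collapse = "")))
  }
  cat("\nProperty scales (hydrophobicity / hydrophilicity / side-chain mass):\n")
  m <- rbind(AA_HYDROPHOBICITY, AA_HYDROPHILICITY, AA_SIDECHAIN_MASS)
  print(m)
  invisible(list(aa_order = AA_ORDER, ctd_groups = CTD_GROUPS,
                 scales = list(hydrophobicity = AA_HYDROPHOBICITY,
                               hydrophilicity = AA_HYDROPHILICITY,
                               mass = AA_SIDECHAIN_MASS)))
}
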