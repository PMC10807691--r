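#' Descriptor configuration
#'
#' Tunable parameters of the sequence-order descriptor families.  The
#' defaults are pinned to the candidate-set dimensions: lambda = 10 gives a
#' 30-dimensional pseudo amino acid composition (20 + lambda) and a
#' 40-dimensional amphiphilic variant (20 + 2*lambda); nlag = 20 gives 20
#' sequence-order-coupling numbers and 40 quasi-sequence-order descriptors.
#'
#' @param pseaac_lambda Correlation tier count for PseAAC (default 10).
#' @param pseaac_weight Weight factor for PseAAC correlation terms
#'   (default 0.05, Chou's conventional value).
#' @param apseaac_lambda Correlation tier count for APseAAC (default 10).
#' @param apseaac_weight Weight factor for APseAAC (default 0.5).
#' @param qso_nlag Maximum lag for quasi-sequence-order (default 20).
#' @param qso_weight Weight factor for QSO coupling terms (default 0.1).
#' @param socn_nlag Maximum lag for sequence-order-coupling numbers
#'   (default 20).
#' @param ehe_mode How the ss_6 feature treats the collapsed "EHE" motif:
#'   `"existence"` (default, 0/1) or `"count"` (number of occurrences,
#'   overlaps included).
#' @return A list of class `descriptor_config`.
#' @export
descriptor_config <- function(pseaac_lambda = 10L, pseaac_weight = 0.05,
                              apseaac_lambda = 10L, apseaac_weight = 0.5,
                              qso_nlag = 20L, qso_weight = 0.1,
                              socn_nlag = 20L,
                              ehe_mode = c("existence", "count")) {
  stopifnot(pseaac_lambda >= 1L, apseaac_lambda >= 1L,
            pseaac_weight > 0, apseaac_weight > 0, qso_weight > 0,
            qso_nlag >= 1L, socn_nlag >= 1L)
  structure(list(pseaac_lambda = as.integer(pseaac_lambda),
                 pseaac_weight = pseaac_weight,
                 apseaac_lambda = as.integer(apseaac_lambda),
                 apseaac_weight = apseaac_weight,
                 qso_nlag = as.integer(qso_nlag), qso_weight = qso_weight,
                 socn_nlag = as.integer(socn_nlag),
                 ehe_mode = match.arg(ehe_mode)),
            class = "descriptor_config")
}

seq_to_indices <- function(sequence) {
  idx <- match(strsplit(sequence, "")[[1]], AA_ORDER)
  if (anyNA(idx))
    stop("sequence contains non-canonical residues", call. = FALSE)
  idx
}

#' Amino acid composition (20 features)
#'
#' Per-residue frequencies in the canonical order
#' A,R,N,D,C,E,Q,G,H,I,L,K,M,F,P,S,T,W,Y,V; components sum to 1.
#'
#' @param sequence A validated amino-acid sequence string.
#' @return Named numeric vector `aac_1` .. `aac_20`.
#' @export
#' @examples
#' aac("ARNDCEQGHILKMFPSTWYV")  # uniform: every component 0.05
aac <- function(sequence) {
  idx <- seq_to_indices(sequence)
  v <- tabulate(idx, nbins = 20L) / length(idx)
  names(v) <- paste0("aac_", 1:20)
  v
}

#' Dipeptide composition (400 features)
#'
#' Frequencies of adjacent residue pairs; pair (i, j) in the canonical
#' amino-acid order maps to `dipep_{20(i-1)+j}`.  Components sum to 1.
#'
#' @inheritParams aac
#' @return Named numeric vector `dipep_1` .. `dipep_400`.
#' @export
dipeptide <- function(sequence) {
  idx <- seq_to_indices(sequence)
  L <- length(idx)
  if (L < 2L) stop("dipeptide composition needs length >= 2", call. = FALSE)
  pair <- 20L * (idx[-L] - 1L) + idx[-1L]
  v <- tabulate(pair, nbins = 400L) / (L - 1L)
  names(v) <- paste0("dipep_", 1:400)
  v
}

# Correlation function Theta(i, j): mean squared difference of the three
# standardized property scales; identical to the entries of
# aa_distance_matrix().
theta_matrix <- function() aa_distance_matrix()

#' Pseudo amino acid composition (30 features)
#'
#' Chou's type-1 PseAAC: 20 composition components plus `lambda`
#' sequence-order correlation factors computed from standardized
#' hydrophobicity, hydrophilicity and side-chain mass, weighted by
#' `pseaac_weight` and jointly normalized to sum to 1.
#'
#' @inheritParams aac
#' @param config A [descriptor_config()].
#' @return Named numeric vector `pseudo_1` .. `pseudo_{20+lambda}`.
#' @export
pseaac <- function(sequence, config = descriptor_config()) {
  idx <- seq_to_indices(sequence)
  L <- length(idx)
  lambda <- config$pseaac_lambda
  if (L <= lambda)
    stop("PseAAC with lambda = ", lambda, " needs sequence length > ",
         lambda, " (minimum ", lambda + 1L, ")", call. = FALSE)
  th <- theta_matrix()
  theta <- vapply(seq_len(lambda), function(d) {
    mean(th[cbind(idx[seq_len(L - d)], idx[seq_len(L - d) + d])])
  }, numeric(1))
  f <- tabulate(idx, nbins = 20L) / L
  denom <- sum(f) + config$pseaac_weight * sum(theta)
  v <- c(f, config$pseaac_weight * theta) / denom
  names(v) <- paste0("pseudo_", seq_along(v))
  v
}

#' Amphiphilic pseudo amino acid composition (40 features)
#'
#' Amphiphilic PseAAC: 20 composition components plus `2*lambda` correlation
#' factors built from hydrophobicity and hydrophilicity separately
#' (interleaved per lag: hydrophobicity then hydrophilicity).  Correlations
#' are mean squared differences of the standardized scale, so the vector is
#' nonnegative and sums to 1 (see the methods vignette for how this relates
#' to Chou's product-form original).
#'
#' @inheritParams pseaac
#' @return Named numeric vector `amphipseudo_1` .. `amphipseudo_{20+2*lambda}`.
#' @export
apseaac <- function(sequence, config = descriptor_config()) {
  idx <- seq_to_indices(sequence)
  L <- length(idx)
  lambda <- config$apseaac_lambda
  if (L <= lambda)
    stop("APseAAC with lambda = ", lambda, " needs sequence length > ",
         lambda, " (minimum ", lambda + 1L, ")", call. = FALSE)
  h1 <- standardize_scale(AA_HYDROPHOBICITY)
  h2 <- standardize_scale(AA_HYDROPHILICITY)
  tau <- numeric(2L * lambda)
  for (d in seq_len(lambda)) {
    i <- seq_len(L - d)
    tau[2L * d - 1L] <- mean((h1[idx[i]] - h1[idx[i + d]])^2)
    tau[2L * d] <- mean((h2[idx[i]] - h2[idx[i + d]])^2)
  }
  f <- tabulate(idx, nbins = 20L) / L
  denom <- sum(f) + config$apseaac_weight * sum(tau)
  v <- c(f, config$apseaac_weight * tau) / denom
  names(v) <- paste0("amphipseudo_", seq_along(v))
  v
}

#' Composition/transition/distribution descriptors (147 features)
#'
#' Seven physicochemical attributes (hydrophobicity, normalized van der
#' Waals volume, polarity, polarizability, charge, secondary-structure
#' propensity, solvent accessibility) each partition the alphabet into three
#' groups.  Composition: per-group residue fractions (`comp_1..comp_21`,
#' attribute-major).  Transition: frequencies of adjacent residues crossing
#' group pairs 1-2, 1-3, 2-3, divided by L-1 (`tran_1..tran_21`).
#' Distribution: for each attribute and group, the 1-based positions of the
#' first, 25%, 50%, 75% and 100% occurrence divided by L
#' (`dist_1..dist_105`); an absent group contributes five zeros.
#'
#' Sequences of length 1 have no adjacent pairs; their transition components
#' are 0 and a warning is emitted.
#'
#' @inheritParams aac
#' @return Named numeric vector of 147 values.
#' @export
ctd <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  if (anyNA(match(chars, AA_ORDER)))
    stop("sequence contains non-canonical residues", call. = FALSE)
  if (L < 2L)
    warning("length-1 sequence: CTD transition components set to 0")
  comp <- tran <- numeric(0)
  dist <- numeric(0)
  for (attr in names(CTD_GROUPS)) {
    groups <- CTD_GROUPS[[attr]]
    g <- integer(L)
    for (k in 1:3) g[chars %in% groups[[k]]] <- k
    comp <- c(comp, vapply(1:3, function(k) sum(g == k) / L, numeric(1)))
    if (L >= 2L) {
      a <- g[-L]; b <- g[-1L]
      tran <- c(tran,
                sum((a == 1 & b == 2) | (a == 2 & b == 1)) / (L - 1L),
                sum((a == 1 & b == 3) | (a == 3 & b == 1)) / (L - 1L),
                sum((a == 2 & b == 3) | (a == 3 & b == 2)) / (L - 1L))
    } else {
      tran <- c(tran, 0, 0, 0)
    }
    for (k in 1:3) {
      pos <- which(g == k)
      if (length(pos) == 0L) {
        dist <- c(dist, rep(0, 5))
      } else {
        n_k <- length(pos)
        take <- c(1L, ceiling(c(0.25, 0.5, 0.75, 1) * n_k))
        dist <- c(dist, pos[take] / L)
      }
    }
  }
  v <- c(comp, tran, dist)
  names(v) <- c(paste0("comp_", 1:21), paste0("tran_", 1:21),
                paste0("dist_", 1:105))
  v
}

map_ss8_to_ss3 <- function(states) {
  chars <- strsplit(states, "")[[1]]
  mapped <- ifelse(chars %in% c("G", "H", "I"), "H",
                   ifelse(chars %in% c("E", "B"), "E", "C"))
  paste(mapped, collapse = "")
}

#' Secondary-structure descriptors (6 features)
#'
#' From a three-state (H/E/C) secondary-structure string:
#' `ss_1`, `ss_2`, `ss_3` are the mean 1-based positions of H, E and C
#' divided by the length (0 when the state is absent); `ss_4` and `ss_5` are
#' the longest E run and longest H run divided by the length; `ss_6` flags
#' (or counts, see [descriptor_config()]) the motif "EHE" in the string
#' obtained by deleting all C and collapsing each maximal H or E run to a
#' single symbol.
#'
#' @param states A string over \{H, E, C\}.
#' @param config A [descriptor_config()] (controls the `ss_6` mode).
#' @return Named numeric vector `ss_1` .. `ss_6`.
#' @export
#' @examples
#' ss_features("CCHHHHECC")
ss_features <- function(states, config = descriptor_config()) {
  chars <- strsplit(states, "")[[1]]
  L <- length(chars)
  if (L < 1L) stop("empty secondary-structure string", call. = FALSE)
  bad <- setdiff(unique(chars), SS_STATES)
  if (length(bad))
    stop("invalid secondary-structure state(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  mean_pos <- function(state) {
    p <- which(chars == state)
    if (length(p) == 0L) 0 else mean(p) / L
  }
  runs <- rle(chars)
  longest <- function(state) {
    len <- runs$lengths[runs$values == state]
    if (length(len) == 0L) 0 else max(len) / L
  }
  collapsed <- paste(rle(chars[chars != "C"])$values, collapse = "")
  n_ehe <- length(unlist(regmatches(
    collapsed, gregexpr("(?=EHE)", collapsed, perl = TRUE))))
  ss6 <- if (config$ehe_mode == "existence") as.numeric(n_ehe > 0) else n_ehe
  v <- c(mean_pos("H"), mean_pos("E"), mean_pos("C"),
         longest("E"), longest("H"), ss6)
  names(v) <- paste0("ss_", 1:6)
  v
}

#' Sequence-order-coupling numbers (20 features)
#'
#' `socn_d = sum_{i=1}^{L-d} D2(r_i, r_{i+d})` for lags d = 1..nlag, where
#' D2 is the squared physicochemical distance of [aa_distance_matrix()].
#'
#' @inheritParams pseaac
#' @return Named numeric vector `socn_1` .. `socn_{nlag}`.
#' @export
socn <- function(sequence, config = descriptor_config()) {
  idx <- seq_to_indices(sequence)
  L <- length(idx)
  nlag <- config$socn_nlag
  if (L <= nlag)
    stop("SOCN with nlag = ", nlag, " needs sequence length > ", nlag,
         " (minimum ", nlag + 1L, ")", call. = FALSE)
  d2 <- aa_distance_matrix()
  tau <- vapply(seq_len(nlag), function(d) {
    i <- seq_len(L - d)
    sum(d2[cbind(idx[i], idx[i + d])])
  }, numeric(1))
  names(tau) <- paste0("socn_", seq_len(nlag))
  tau
}

#' Quasi-sequence-order descriptors (40 features)
#'
#' The first 20 components are `f_i / (sum(f) + w * sum(tau))` with `f_i`
#' the raw amino-acid counts; the last `nlag` components are
#' `w * tau_d / (sum(f) + w * sum(tau))` with `tau_d` the
#' sequence-order-coupling numbers of [socn()].  All components sum to 1.
#'
#' @inheritParams pseaac
#' @return Named numeric vector `qso_1` .. `qso_{20+nlag}`.
#' @export
qso <- function(sequence, config = descriptor_config()) {
  idx <- seq_to_indices(sequence)
  cfg_socn <- config
  cfg_socn$socn_nlag <- config$qso_nlag
  tau <- unname(socn(sequence, cfg_socn))
  f <- tabulate(idx, nbins = 20L)
  w <- config$qso_weight
  denom <- sum(f) + w * sum(tau)
  v <- c(f / denom, w * tau / denom)
  names(v) <- paste0("qso_", seq_along(v))
  v
}

#' Read a secondary-structure sidecar file
#'
#' Tab-separated file with two columns (id, secondary-structure string),
#' no header.  Eight-state strings are mapped to three states
#' (G,H,I -> H; E,B -> E; everything else -> C) when non-HEC letters are
#' detected.
#'
#' @param path Path to the TSV file.
#' @return Named character vector of H/E/C strings.
#' @export
read_ss_tsv <- function(path) {
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    col.names = c("id", "ss"),
                    colClasses = c("character", "character"))
  ss <- toupper(tab$ss)
  needs_map <- vapply(ss, function(s) {
    any(!strsplit(s, "")[[1]] %in% SS_STATES)
  }, logical(1))
  ss[needs_map] <- vapply(ss[needs_map], map_ss8_to_ss3, character(1))
  names(ss) <- tab$id
  ss
}

#' Write a secondary-structure sidecar file
#'
#' @param ss Named character vector of H/E/C strings.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ss_tsv <- function(ss, path) {
  write.table(data.frame(id = names(ss), ss = unname(ss)), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

feature_matrix <- function(x, labels = NULL) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    stopifnot(length(labels) == nrow(x))
    names(labels) <- rownames(x)
  }
  structure(list(x = x, labels = labels), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d features%s\n",
              nrow(x$x), ncol(x$x),
              if (is.null(x$labels)) "" else
                sprintf(" (%d positive, %d negative)",
                        sum(x$labels == 1L), sum(x$labels == 0L))))
  invisible(x)
}

full_feature_names <- function(config = descriptor_config()) {
  c(paste0("aac_", 1:20), paste0("dipep_", 1:400),
    paste0("pseudo_", seq_len(20L + config$pseaac_lambda)),
    paste0("amphipseudo_", seq_len(20L + 2L * config$apseaac_lambda)),
    paste0("comp_", 1:21), paste0("tran_", 1:21), paste0("dist_", 1:105),
    paste0("ss_", 1:6), paste0("socn_", seq_len(config$socn_nlag)),
    paste0("qso_", seq_len(20L + config$qso_nlag)),
    paste0("pssm_", 1:400))
}

#' Assemble the full candidate descriptor matrix
#'
#' Computes every descriptor family for each sequence and binds them into a
#' single matrix whose columns follow the fixed schema order: amino acid
#' composition (20), dipeptide composition (400), pseudo amino acid
#' composition (30), amphiphilic pseudo amino acid composition (40), CTD
#' composition (21), transition (21), distribution (105), secondary
#' structure (6), sequence-order-coupling numbers (20), quasi-sequence-order
#' (40) and PSSM bigrams (400) — 1,103 columns under the default
#' configuration.
#'
#' @param dataset A [labeled_dataset()] or a named character vector of
#'   sequences.
#' @param ss Named character vector of H/E/C strings (one per sequence).
#' @param pssm Named list of [pssm_profile()] objects (one per sequence).
#' @param config A [descriptor_config()].
#' @return A `feature_matrix` (samples x 1,103 named features, labels
#'   carried over when `dataset` is labeled).
#' @export
assemble_features <- function(dataset, ss, pssm,
                              config = descriptor_config()) {
  if (is(dataset, "labeled_dataset")) {
    sequences <- dataset$sequences
    labels <- dataset$labels
  } else {
    sequences <- dataset
    labels <- NULL
  }
  validate_sequences(sequences)
  ids <- names(sequences)
  too_short <- ids[nchar(sequences) < 22L]
  if (length(too_short))
    stop("sequences shorter than the 22-residue minimum for the full ",
         "descriptor set: ", paste(too_short, collapse = ", "),
         call. = FALSE)
  missing_ss <- setdiff(ids, names(ss))
  if (length(missing_ss))
    stop("missing secondary-structure string(s) for: ",
         paste(missing_ss, collapse = ", "), call. = FALSE)
  missing_pssm <- setdiff(ids, names(pssm))
  if (length(missing_pssm))
    stop("missing PSSM profile(s) for: ",
         paste(missing_pssm, collapse = ", "), call. = FALSE)
  bad_len <- ids[nchar(ss[ids]) != nchar(sequences)]
  if (length(bad_len))
    stop("secondary-structure length mismatch for: ",
         paste(bad_len, collapse = ", "), call. = FALSE)
  rows <- lapply(ids, function(id) {
    s <- sequences[[id]]
    c(aac(s), dipeptide(s), pseaac(s, config), apseaac(s, config),
      ctd(s), ss_features(ss[[id]], config), socn(s, config),
      qso(s, config), pssm_bigram(pssm[[id]]))
  })
  x <- do.call(rbind, rows)
  rownames(x) <- ids
  stopifnot(identical(colnames(x), full_feature_names(config)))
  if (any(!is.finite(x)))
    stop("non-finite descriptor values produced", call. = FALSE)
  feature_matrix(x, labels)
}

#' Write a feature matrix as TSV
#'
#' First column `sample_id`, then (if present) `label`, then the named
#' feature columns in schema order.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_tsv <- function(fm, path) {
  stopifnot(is(fm, "feature_matrix"))
  df <- data.frame(sample_id = rownames(fm$x), check.names = FALSE)
  if (!is.null(fm$labels)) df$label <- unname(fm$labels)
  df <- cbind(df, as.data.frame(fm$x, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix from TSV
#'
#' @param path Path to a TSV written by [write_feature_tsv()].
#' @return A `feature_matrix`.
#' @export
read_feature_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  labels <- NULL
  feat_cols <- setdiff(colnames(df), c("sample_id", "label"))
  if ("label" %in% colnames(df)) labels <- df$label
  x <- as.matrix(df[, feat_cols, drop = FALSE])
  rownames(x) <- df$sample_id
  feature_matrix(x, labels)
}
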