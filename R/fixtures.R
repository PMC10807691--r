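# UniProt-like background residue frequencies (approximate database-wide
# composition), in AA_ORDER; the default background is uniform.
UNIPROT_FREQS <- c(
  A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137,
  E = 0.0672, Q = 0.0393, G = 0.0708, H = 0.0227, I = 0.0593,
  L = 0.0965, K = 0.0580, M = 0.0241, F = 0.0386, P = 0.0472,
  S = 0.0661, T = 0.0535, W = 0.0110, Y = 0.0292, V = 0.0687)

# Dipeptides planted at elevated rates in positive sequences.
PLANTED_DIPEPTIDES <- c("KC", "RW", "GK")

#' Synthetic-data configuration
#'
#' Parameters of the synthetic bacteriocin-versus-background generator.
#' Positives mimic the cationic/amphiphilic character of bacteriocins:
#' elevated K/R frequencies, a few planted dipeptides and a bias toward
#' secondary-structure strings containing the collapsed "EHE" motif, each
#' scaled by `signal_strength`.  Fabricated PSSM files are dialect-correct
#' but not biologically meaningful; they exist to exercise parsing and the
#' bigram computation.
#'
#' @param n_pos,n_neg Number of positive / negative sequences.
#' @param length_range Inclusive sequence-length range; the minimum must be
#'   at least 22 (the shortest sequence the full descriptor set accepts).
#'   Default c(30, 80).
#' @param signal_strength Class-signal scale in [0, 1]; 0 makes the classes
#'   exchangeable.
#' @param signal_mode Which signals to plant: any subset of
#'   `"composition"`, `"dipeptide"`, `"ss_motif"` (default all).
#' @param background `"uniform"` (default) or `"uniprot"` residue
#'   frequencies.
#' @param seed Integer seed; all outputs are deterministic given the seed.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_pos, n_neg, length_range = c(30L, 80L),
                           signal_strength = 1,
                           signal_mode = c("composition", "dipeptide",
                                           "ss_motif"),
                           background = c("uniform", "uniprot"),
                           seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L,
            length_range[1] >= 22L, length_range[2] >= length_range[1],
            signal_strength >= 0, signal_strength <= 1)
  signal_mode <- match.arg(signal_mode, several.ok = TRUE)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 signal_strength = signal_strength,
                 signal_mode = signal_mode,
                 background = match.arg(background),
                 seed = as.integer(seed)),
            class = "fixture_config")
}

random_ss_string <- function(L, force_ehe) {
  if (force_ehe) {
    core_len <- c(E1 = sample(2:4, 1), H = sample(3:6, 1),
                  E2 = sample(2:4, 1))
    core <- c(rep("E", core_len[1]), rep("H", core_len[2]),
              rep("E", core_len[3]))
    pad <- L - length(core)
    left <- sample(0:pad, 1)
    states <- c(rep("C", left), core, rep("C", pad - left))
  } else {
    # most proteins are predominantly alpha, beta or mixed; only the mixed
    # architecture can produce the collapsed E-H-E arrangement
    pool <- switch(sample(c("alpha", "beta", "mixed"), 1,
                          prob = c(0.4, 0.4, 0.2)),
                   alpha = c("H", "C"), beta = c("E", "C"),
                   mixed = c("H", "E", "C"))
    states <- character(0)
    while (length(states) < L) {
      states <- c(states, rep(sample(pool, 1), sample(1:6, 1)))
    }
    states <- states[seq_len(L)]
  }
  paste(states, collapse = "")
}

fabricate_pssm <- function(id, sequence) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  scores <- matrix(round(rnorm(L * 20L, 0, 2)), L, 20L)
  colnames(scores) <- PSIBLAST_COLUMN_ORDER
  scores[cbind(seq_len(L), match(chars, PSIBLAST_COLUMN_ORDER))] <-
    scores[cbind(seq_len(L), match(chars, PSIBLAST_COLUMN_ORDER))] + 5
  pssm_profile(id, scores, PSIBLAST_COLUMN_ORDER, residues = chars)
}

#' Generate a labeled synthetic dataset with sidecar data
#'
#' Draws negative sequences i.i.d. from the background frequencies and
#' positive sequences from a shifted distribution (see [fixture_config()]),
#' together with secondary-structure strings and fabricated PSSM profiles,
#' all deterministic for a fixed seed.
#'
#' @param config A [fixture_config()].
#' @return A list with elements `dataset` (a [labeled_dataset()]), `ss`
#'   (named character vector of H/E/C strings) and `pssm` (named list of
#'   [pssm_profile()] objects).
#' @export
generate_fixtures <- function(config) {
  stopifnot(is(config, "fixture_config"))
  s <- config$signal_strength
  bg <- if (config$background == "uniform") rep(1 / 20, 20)
        else unname(UNIPROT_FREQS[AA_ORDER])
  names(bg) <- AA_ORDER
  pos_freq <- bg
  if ("composition" %in% config$signal_mode) {
    pos_freq[c("K", "R")] <- pos_freq[c("K", "R")] * (1 + 4 * s)
    pos_freq <- pos_freq / sum(pos_freq)
  }
  with_local_seed(config$seed, {
    n <- config$n_pos + config$n_neg
    labels <- c(rep(1L, config$n_pos), rep(0L, config$n_neg))
    ids <- sprintf("%s%03d", ifelse(labels == 1L, "pos", "neg"),
                   c(seq_len(config$n_pos), seq_len(config$n_neg)))
    lengths <- sample(seq(config$length_range[1], config$length_range[2]),
                      n, replace = TRUE)
    sequences <- character(n)
    ss <- character(n)
    pssm <- vector("list", n)
    for (i in seq_len(n)) {
      freq <- if (labels[i] == 1L) pos_freq else bg
      chars <- sample(AA_ORDER, lengths[i], replace = TRUE, prob = freq)
      if (labels[i] == 1L && "dipeptide" %in% config$signal_mode) {
        n_plant <- round(s * lengths[i] / 12)
        if (n_plant > 0) {
          starts <- sample(seq_len(lengths[i] - 1L), n_plant)
          for (st in starts) {
            dp <- strsplit(sample(PLANTED_DIPEPTIDES, 1), "")[[1]]
            chars[st:(st + 1L)] <- dp
          }
        }
      }
      sequences[i] <- paste(chars, collapse = "")
      force_ehe <- labels[i] == 1L &&
        "ss_motif" %in% config$signal_mode && runif(1) < s
      ss[i] <- random_ss_string(lengths[i], force_ehe)
      pssm[[i]] <- fabricate_pssm(ids[i], sequences[i])
    }
    names(sequences) <- ids
    names(ss) <- ids
    names(pssm) <- ids
    list(dataset = labeled_dataset(sequences, labels), ss = ss,
         pssm = pssm)
  })
}

#' Write generated fixtures to disk
#'
#' Emits `sequences.fasta`, `labels.tsv` (id, label), `ss.tsv` and one
#' `<id>.pssm` file per sequence under `dir/pssm/`.  Byte-identical across
#' runs for the same fixtures.
#'
#' @param fixtures Output of [generate_fixtures()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_fixtures <- function(fixtures, dir) {
  dir.create(file.path(dir, "pssm"), showWarnings = FALSE, recursive = TRUE)
  write_fasta(fixtures$dataset$sequences, file.path(dir, "sequences.fasta"))
  write.table(data.frame(id = names(fixtures$dataset$labels),
                         label = unname(fixtures$dataset$labels)),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_ss_tsv(fixtures$ss, file.path(dir, "ss.tsv"))
  for (id in names(fixtures$pssm)) {
    write_ascii_pssm(fixtures$pssm[[id]],
                     file.path(dir, "pssm", paste0(id, ".pssm")))
  }
  invisible(dir)
}
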