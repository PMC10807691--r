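#' @importFrom methods is
#' @importFrom stats qbeta cor predict rnorm runif rbinom sd var
#' @importFrom utils read.delim write.table head
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.  All randomized operations in the package go
# through this so that a seed argument fully determines the result.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

validate_sequences <- function(sequences) {
  ids <- names(sequences)
  if (is.null(ids) || any(ids == ""))
    stop("every sequence must have a non-empty id", call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    if (nchar(s) < 1L)
      stop("sequence '", ids[i], "' is empty", call. = FALSE)
    bad <- setdiff(unique(strsplit(s, "")[[1]]), AA_ORDER)
    if (length(bad))
      stop("sequence '", ids[i], "' contains non-canonical residue(s): ",
           paste(bad, collapse = ", "),
           " (only the 20 canonical amino-acid letters are accepted)",
           call. = FALSE)
  }
  invisible(sequences)
}

#' Read protein sequences from a FASTA file
#'
#' Parses a multi-record amino-acid FASTA file.  The header token up to the
#' first whitespace becomes the sequence id; sequences are uppercased and
#' validated against the 20 canonical amino-acid letters.  Ambiguous residues
#' (B, Z, X, U, O) are rejected rather than imputed, because the descriptor
#' formulas downstream are only defined for the canonical alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences (names are the record ids),
#'   in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "MKLV", ">p2", "ARNDC"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  first_content <- which(nzchar(trimws(lines)))[1]
  if (is.na(first_content))
    stop("malformed FASTA at line 1: file '", path, "' is empty",
         call. = FALSE)
  if (!startsWith(trimws(lines[first_content]), ">"))
    stop("malformed FASTA at line ", first_content,
         ": expected a '>' header", call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(names(set),
                        function(h) strsplit(trimws(h), "\\s+")[[1]][1],
                        character(1))
  validate_sequences(seqs)
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @param path Output file path.
#' @param width Line-wrap width (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  validate_sequences(sequences)
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a labeled dataset
#'
#' Bundles sequences with binary labels (1 = bacteriocin / positive,
#' 0 = non-bacteriocin / negative).
#'
#' @param sequences Named character vector of validated sequences.
#' @param labels Integer vector of 0/1 labels, one per sequence (recycled
#'   names are taken from `sequences`).
#' @return An object of class `labeled_dataset`: a list with elements
#'   `sequences` (named character) and `labels` (named integer).
#' @export
labeled_dataset <- function(sequences, labels) {
  validate_sequences(sequences)
  labels <- as.integer(labels)
  if (length(labels) != length(sequences))
    stop("labels must align one-to-one with sequences", call. = FALSE)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0 or 1", call. = FALSE)
  names(labels) <- names(sequences)
  structure(list(sequences = sequences, labels = labels),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d sequences (%d positive, %d negative)\n",
              length(x$sequences), sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' Read a labeled dataset from positive/negative FASTA files
#'
#' @param positive_fasta FASTA file of positive (bacteriocin) sequences.
#' @param negative_fasta FASTA file of negative sequences.
#' @return A [labeled_dataset()].
#' @export
read_labeled_fasta <- function(positive_fasta, negative_fasta) {
  pos <- read_fasta(positive_fasta)
  neg <- read_fasta(negative_fasta)
  labeled_dataset(c(pos, neg), c(rep(1L, length(pos)), rep(0L, length(neg))))
}

#' Read a labeled dataset from one FASTA plus a label TSV
#'
#' @param fasta FASTA file with all sequences.
#' @param labels_tsv Two-column tab-separated file (id, label in 0/1), no
#'   header.
#' @return A [labeled_dataset()].
#' @export
read_labeled_tsv <- function(fasta, labels_tsv) {
  seqs <- read_fasta(fasta)
  tab <- read.delim(labels_tsv, header = FALSE, sep = "\t",
                    col.names = c("id", "label"),
                    colClasses = c("character", "integer"))
  missing <- setdiff(names(seqs), tab$id)
  if (length(missing))
    stop("no label for sequence id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  labeled_dataset(seqs, tab$label[match(names(seqs), tab$id)])
}

# Global Needleman-Wunsch percent identity between two sequences:
# matches / alignment length (gap columns included), BLOSUM62 scoring.
pairwise_identity <- function(a, b) {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = data_env$BLOSUM62,
    gapOpening = 10, gapExtension = 0.5)
  aligned <- as.character(Biostrings::alignedPattern(aln))
  Biostrings::nmatch(aln) / nchar(aligned)
}

#' Remove redundant sequences by global-alignment identity
#'
#' Greedy representative selection: sequences are visited in order of
#' decreasing length and a sequence is kept only if its global-alignment
#' percent identity (Needleman-Wunsch, BLOSUM62; identity = matches /
#' alignment length) to every already-kept sequence is at most
#' `identity_threshold`.  Survivors are returned in their original input
#' order.  This is a deliberate simplification of CD-HIT-style clustering:
#' only the identity threshold contract is reproduced, not CD-HIT's word
#' heuristics.
#'
#' @param sequences Named character vector of sequences.
#' @param identity_threshold Maximum tolerated identity, in (0, 1];
#'   default 0.90 (sequences more than 90% identical to a kept one are
#'   dropped).
#' @return The surviving subset of `sequences`, in input order.
#' @export
reduce_redundancy <- function(sequences, identity_threshold = 0.90) {
  validate_sequences(sequences)
  if (!is.numeric(identity_threshold) || length(identity_threshold) != 1L ||
      identity_threshold <= 0 || identity_threshold > 1)
    stop("identity_threshold must lie in (0, 1]", call. = FALSE)
  ord <- order(-nchar(sequences))
  kept_idx <- integer(0)
  for (i in ord) {
    redundant <- FALSE
    for (j in kept_idx) {
      if (pairwise_identity(sequences[[i]], sequences[[j]]) >
          identity_threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept_idx <- c(kept_idx, i)
  }
  sequences[sort(kept_idx)]
}

#' Balance a dataset by random undersampling of the majority class
#'
#' The majority class is subsampled without replacement down to the minority
#' class count; the minority class is untouched.  Deterministic for a fixed
#' seed.
#'
#' @param data A [labeled_dataset()] containing both classes.
#' @param seed Integer seed; default 1.
#' @return A balanced [labeled_dataset()], sequences in original input order.
#' @export
balance_undersample <- function(data, seed = 1L) {
  stopifnot(is(data, "labeled_dataset"))
  n_pos <- sum(data$labels == 1L)
  n_neg <- sum(data$labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to balance", call. = FALSE)
  if (n_pos == n_neg) return(data)
  minority <- if (n_pos < n_neg) 1L else 0L
  maj_idx <- which(data$labels != minority)
  keep_maj <- with_local_seed(seed,
                              sample(maj_idx, min(n_pos, n_neg)))
  keep <- sort(c(which(data$labels == minority), keep_maj))
  labeled_dataset(data$sequences[keep], data$labels[keep])
}

#' Stratified train/test split
#'
#' Partitions a labeled dataset into disjoint, exhaustive train and test
#' sets.  When stratified (the default), the per-class train count is
#' `round(train_fraction * class size)` with the remainder going to test.
#'
#' @param data A [labeled_dataset()].
#' @param train_fraction Fraction of each class assigned to training, in
#'   (0, 1); default 0.8.
#' @param seed Integer seed; default 1.
#' @param stratified Stratify by class (default TRUE).  Requires at least
#'   two records per class.
#' @return A list with elements `train` and `test`, both [labeled_dataset()]s.
#' @export
split_dataset <- function(data, train_fraction = 0.8, seed = 1L,
                          stratified = TRUE) {
  stopifnot(is(data, "labeled_dataset"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  n <- length(data$sequences)
  if (stratified) {
    if (any(table(factor(data$labels, levels = 0:1)) < 2L))
      stop("stratified split needs at least 2 records per class",
           call. = FALSE)
    train_idx <- with_local_seed(seed, {
      unlist(lapply(c(0L, 1L), function(cl) {
        idx <- which(data$labels == cl)
        n_train <- round(train_fraction * length(idx))
        n_train <- max(1L, min(length(idx) - 1L, n_train))
        sample(idx, n_train)
      }))
    })
  } else {
    if (n < 2L) stop("need at least 2 records to split", call. = FALSE)
    n_train <- max(1L, min(n - 1L, round(train_fraction * n)))
    train_idx <- with_local_seed(seed, sample(seq_len(n), n_train))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = labeled_dataset(data$sequences[train_idx],
                               data$labels[train_idx]),
       test = labeled_dataset(data$sequences[test_idx],
                              data$labels[test_idx]))
}

#' Write a train/test split to disk
#'
#' Writes `train.fasta`, `test.fasta` and a `manifest.tsv` with columns
#' id, label, partition.
#'
#' @param split A list with `train` and `test` as from [split_dataset()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the manifest path.
#' @export
write_split <- function(split, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(split$train$sequences, file.path(outdir, "train.fasta"))
  write_fasta(split$test$sequences, file.path(outdir, "test.fasta"))
  manifest <- rbind(
    data.frame(id = names(split$train$sequences),
               label = unname(split$train$labels), partition = "train"),
    data.frame(id = names(split$test$sequences),
               label = unname(split$test$labels), partition = "test"))
  path <- file.path(outdir, "manifest.tsv")
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
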