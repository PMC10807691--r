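# PSI-BLAST writes its ASCII profile with this residue column order
# (note Q before E, unlike the canonical descriptor order).
PSIBLAST_COLUMN_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a PSSM profile
#'
#' @param id Sequence id the profile belongs to.
#' @param scores L x 20 numeric matrix of per-position log-odds scores.
#' @param column_order The 20 amino-acid letters naming the score columns,
#'   in column order (defaults to the PSI-BLAST file order).
#' @param residues Optional character vector of length L: the residue column
#'   of the profile, kept for cross-checking against the FASTA sequence.
#' @return An object of class `pssm_profile`.
#' @export
pssm_profile <- function(id, scores, column_order = PSIBLAST_COLUMN_ORDER,
                         residues = NULL) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L)
    stop("a PSSM profile must have exactly 20 score columns", call. = FALSE)
  if (!setequal(column_order, AA_ORDER))
    stop("column_order must be a permutation of the 20 amino-acid letters",
         call. = FALSE)
  if (!is.null(residues) && length(residues) != nrow(scores))
    stop("residues must have one entry per profile row", call. = FALSE)
  colnames(scores) <- column_order
  structure(list(id = id, scores = scores, column_order = column_order,
                 residues = residues), class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("pssm_profile '%s': %d positions x 20 residues\n",
              x$id, nrow(x$scores)))
  invisible(x)
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the `-out_ascii_pssm` dialect: header lines, a residue-letter
#' column header, then one row per position (index, residue, 20 log-odds
#' integers, optionally 20 weighted-percentage columns and two trailing
#' statistics).  Only the first 20 numeric columns are kept.
#'
#' @param path Path to the PSSM file.
#' @param id Profile id; defaults to the file name without the `.pssm`
#'   extension.
#' @return A [pssm_profile()].
#' @export
read_ascii_pssm <- function(path, id = sub("\\.pssm$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  header_at <- NA_integer_
  column_order <- NULL
  for (i in seq_along(lines)) {
    tokens <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tokens) >= 20L && all(tokens %in% AA_ORDER) &&
        setequal(tokens[1:20], AA_ORDER)) {
      header_at <- i
      column_order <- tokens[1:20]
      break
    }
  }
  if (is.na(header_at))
    stop("parse error in ", path,
         ": no residue column header line found", call. = FALSE)
  scores <- list()
  residues <- character(0)
  expected_index <- 1L
  for (i in seq(header_at + 1L, length(lines))) {
    line <- trimws(lines[i])
    if (!nzchar(line)) break  # blank line ends the matrix block
    tokens <- strsplit(line, "\\s+")[[1]]
    if (!grepl("^[0-9]+$", tokens[1])) break  # footer statistics
    if (as.integer(tokens[1]) != expected_index)
      stop("parse error at line ", i, " of ", path,
           ": expected row index ", expected_index, call. = FALSE)
    if (length(tokens) < 22L)
      stop("parse error at line ", i, " of ", path,
           ": row has ", length(tokens) - 2L,
           " score columns, need at least 20", call. = FALSE)
    vals <- suppressWarnings(as.numeric(tokens[3:22]))
    if (anyNA(vals))
      stop("parse error at line ", i, " of ", path,
           ": non-numeric score column", call. = FALSE)
    residues <- c(residues, tokens[2])
    scores[[expected_index]] <- vals
    expected_index <- expected_index + 1L
  }
  if (length(scores) == 0L)
    stop("parse error in ", path, ": no score rows found", call. = FALSE)
  pssm_profile(id, do.call(rbind, scores), column_order, residues)
}

#' Write a profile in the PSI-BLAST ASCII dialect
#'
#' Emits a file that [read_ascii_pssm()] parses back to the same scores:
#' two header lines, the residue column header (40 letters, as PSI-BLAST
#' prints the log-odds and percentage blocks), one row per position with the
#' 20 scores, 20 zero percentage columns and two trailing statistics, and a
#' footer.
#'
#' @param profile A [pssm_profile()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ascii_pssm <- function(profile, path) {
  stopifnot(is(profile, "pssm_profile"))
  res <- profile$residues
  if (is.null(res)) res <- rep("X", nrow(profile$scores))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted, and scaled"),
             con)
  writeLines(paste0("           ",
                    paste(sprintf("%3s", c(profile$column_order,
                                           profile$column_order)),
                          collapse = "")), con)
  for (i in seq_len(nrow(profile$scores))) {
    writeLines(paste0(sprintf("%5d %s ", i, res[i]),
                      paste(sprintf("%3d", as.integer(
                        round(profile$scores[i, ]))), collapse = ""),
                      paste(sprintf("%4d", rep(0L, 20L)), collapse = ""),
                      "  0.00 0.00"), con)
  }
  writeLines(c("", "                      K         Lambda",
               "Standard Ungapped    0.1337     0.3113"), con)
  invisible(path)
}

#' Read a directory of per-sequence PSSM files
#'
#' Expects one `<id>.pssm` file per requested id.
#'
#' @param dir Directory containing the files.
#' @param ids Character vector of sequence ids to load.
#' @param sequences Optional named character vector; when given, each
#'   profile's residue column is checked against the sequence.
#' @param strict With `sequences`: error on a residue mismatch (default)
#'   instead of warning.
#' @return Named list of [pssm_profile()] objects.
#' @export
read_pssm_dir <- function(dir, ids, sequences = NULL, strict = TRUE) {
  paths <- file.path(dir, paste0(ids, ".pssm"))
  missing <- ids[!file.exists(paths)]
  if (length(missing))
    stop("missing PSSM file(s) for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  profiles <- lapply(seq_along(ids), function(i) {
    p <- read_ascii_pssm(paths[i], id = ids[i])
    if (!is.null(sequences)) check_profile(p, sequences[[ids[i]]], strict)
    p
  })
  names(profiles) <- ids
  profiles
}

#' Cross-check a profile's residue column against a sequence
#'
#' @param profile A [pssm_profile()].
#' @param sequence The paired amino-acid sequence.
#' @param strict Error (TRUE, default) or warn on mismatch.
#' @return Invisibly TRUE if consistent.
#' @export
check_profile <- function(profile, sequence, strict = TRUE) {
  chars <- strsplit(sequence, "")[[1]]
  if (nrow(profile$scores) != length(chars)) {
    msg <- sprintf("profile '%s' has %d rows but sequence has %d residues",
                   profile$id, nrow(profile$scores), length(chars))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    return(invisible(FALSE))
  }
  if (!is.null(profile$residues) &&
      !all(profile$residues %in% c("X", "-")) &&
      !identical(profile$residues, chars)) {
    msg <- sprintf("profile '%s' residue column disagrees with the sequence",
                   profile$id)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    return(invisible(FALSE))
  }
  invisible(TRUE)
}

#' PSSM bigram descriptor (400 features)
#'
#' Scores are first squashed elementwise (default: logistic
#' `1 / (1 + exp(-x))`), giving a position-by-residue matrix P; the bigram
#' `B(m, n) = sum_t P(t, m) * P(t+1, n)` is computed for every ordered
#' residue pair (m, n) in the canonical amino-acid order, divided by L - 1,
#' and flattened row-major to `pssm_{20(m-1)+n}`.  With the logistic
#' default all values lie in [0, 1].
#'
#' @param profile A [pssm_profile()] with at least 2 rows.
#' @param normalization `"logistic"` (default), `"minmax"` (global min-max
#'   scaling of the scores to [0, 1]), or `"raw"` (no squashing).
#' @return Named numeric vector `pssm_1` .. `pssm_400`.
#' @export
pssm_bigram <- function(profile,
                        normalization = c("logistic", "minmax", "raw")) {
  stopifnot(is(profile, "pssm_profile"))
  normalization <- match.arg(normalization)
  L <- nrow(profile$scores)
  if (L < 2L)
    stop("PSSM bigram needs at least 2 profile rows", call. = FALSE)
  p <- profile$scores[, AA_ORDER, drop = FALSE]
  p <- switch(normalization,
              logistic = 1 / (1 + exp(-p)),
              minmax = if (diff(range(p)) == 0) {
                matrix(0.5, nrow(p), ncol(p))
              } else {
                (p - min(p)) / (max(p) - min(p))
              },
              raw = p)
  b <- crossprod(p[-L, , drop = FALSE], p[-1L, , drop = FALSE]) / (L - 1L)
  v <- as.vector(t(b))
  names(v) <- paste0("pssm_", 1:400)
  v
}
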