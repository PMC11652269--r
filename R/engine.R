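#' @useDynLib sgumbel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# The 20 standard amino acids; anything else in input sequences becomes X.
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read protein sequences from a FASTA file
#'
#' Parsing is delegated to [Biostrings::readAAStringSet()]; records are then
#' normalized for the alignment engine: ids are the header up to the first
#' whitespace, residues are uppercased, and any residue outside the 20
#' standard amino acids is mapped to `X`.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences (names are record ids),
#'   in file order.  An empty file yields an empty vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  set <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  bad <- sprintf("[^%s]", paste(AA_STANDARD, collapse = ""))
  stats::setNames(gsub(bad, "X", seqs), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Destination path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the standard NCBI matrix layout: `#` comment lines, a header row of
#' column letters, then one labeled row per residue.  The matrix must be
#' square, integer-valued and symmetric, with row labels matching the column
#' header.
#'
#' @param path Path to a matrix file (e.g. the shipped BLOSUM62 under
#'   `system.file("extdata", "BLOSUM62", package = "sgumbel")`).
#' @return An integer matrix with residue dimnames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) stop("not an NCBI matrix file: ", path)
  cols <- strsplit(lines[[1L]], "[ \t]+")[[1L]]
  nres <- length(cols)
  if (length(lines) != nres + 1L)
    stop(sprintf("expected %d matrix rows after the header, found %d",
                 nres, length(lines) - 1L))
  mat <- matrix(NA_integer_, nres, nres, dimnames = list(cols, cols))
  for (i in seq_len(nres)) {
    fields <- strsplit(lines[[i + 1L]], "[ \t]+")[[1L]]
    if (fields[[1L]] != cols[[i]])
      stop(sprintf("row label '%s' does not match column header '%s' (row %d)",
                   fields[[1L]], cols[[i]], i))
    vals <- suppressWarnings(as.integer(fields[-1L]))
    if (length(vals) != nres || anyNA(vals))
      stop(sprintf("malformed score row for residue '%s'", cols[[i]]))
    mat[i, ] <- vals
  }
  if (!identical(mat, t(mat))) stop("substitution matrix is not symmetric")
  mat
}

#' Scoring scheme for local alignment
#'
#' Bundles a symmetric substitution matrix with affine gap penalties under
#' the NCBI convention: a gap of length k costs `gap_open + k * gap_extend`,
#' so `(11, 1)` matches blastp's `-gapopen 11 -gapextend 1`.  (FASTA-family
#' tools fold the first extension into the open cost; that convention is not
#' used here.)
#'
#' @param matrix Integer substitution matrix with residue dimnames, or a path
#'   accepted by [read_matrix()].
#' @param gap_open,gap_extend Positive integer penalties.
#' @return An object of class `"scoring_scheme"`.
#' @export
scoring_scheme <- function(matrix, gap_open = 11L, gap_extend = 1L) {
  if (is.character(matrix) && length(matrix) == 1L) matrix <- read_matrix(matrix)
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            !is.null(rownames(matrix)),
            identical(rownames(matrix), colnames(matrix)))
  storage.mode(matrix) <- "integer"
  if (!identical(matrix, t(matrix))) stop("substitution matrix is not symmetric")
  stopifnot(gap_open > 0, gap_extend > 0,
            gap_open == as.integer(gap_open), gap_extend == as.integer(gap_extend))
  if (!"X" %in% rownames(matrix)) stop("matrix alphabet must include 'X'")
  structure(list(matrix = matrix,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring scheme: %dx%d matrix, gap open %d, gap extend %d\n",
              nrow(x$matrix), ncol(x$matrix), x$gap_open, x$gap_extend))
  invisible(x)
}

# Map a residue string to 0-based indices into the scheme's alphabet;
# residues absent from the alphabet score as X.
encode_residues <- function(seq, scheme) {
  alpha <- rownames(scheme$matrix)
  idx <- match(strsplit(toupper(seq), "")[[1L]], alpha)
  idx[is.na(idx)] <- match("X", alpha)
  as.integer(idx - 1L)
}

#' Optimal local alignment score (Smith-Waterman, affine gaps)
#'
#' Three-state dynamic program with score floor 0; returns the score only
#' (no traceback).  Symmetric in its arguments and deterministic.
#'
#' @param query,subject Residue strings (non-empty).
#' @param scheme A [scoring_scheme()].
#' @return Integer optimal local alignment score (>= 0).
#' @export
smith_waterman <- function(query, subject, scheme) {
  stopifnot(inherits(scheme, "scoring_scheme"),
            nchar(query) > 0, nchar(subject) > 0)
  sw_scores(encode_residues(query, scheme),
            list(encode_residues(subject, scheme)),
            scheme$matrix, scheme$gap_open, scheme$gap_extend)[[1L]]
}

#' Search a query against a sequence database
#'
#' Computes the per-subject optimal local alignment score for every database
#' sequence and the database-wide maximum S (the statistic the studentized
#' test is built on).  Ties in the maximum are broken by the first subject in
#' database order.
#'
#' @param query A residue string (optionally named with the query id).
#' @param database Named character vector of subject sequences.
#' @param scheme A [scoring_scheme()].
#' @return A list with `hits` (data.frame: query, subject, score, one row per
#'   subject in database order), `max_score`, and `max_subject`.
#' @export
search_database <- function(query, database, scheme) {
  stopifnot(length(database) >= 1L)
  qid <- if (!is.null(names(query)) && nzchar(names(query)[1])) names(query)[1] else "query"
  q <- encode_residues(query[[1L]], scheme)
  subj <- lapply(unname(database), encode_residues, scheme = scheme)
  scores <- sw_scores(q, subj, scheme$matrix, scheme$gap_open, scheme$gap_extend)
  imax <- which.max(scores)
  list(hits = data.frame(query = qid,
                         subject = if (is.null(names(database)))
                           paste0("subject_", seq_along(database)) else names(database),
                         score = as.integer(scores),
                         stringsAsFactors = FALSE),
       max_score = as.integer(scores[imax]),
       max_subject = if (is.null(names(database))) imax else names(database)[imax])
}

# Fastest path for the simulation harnesses: database pre-encoded once.
encode_database <- function(database, scheme) {
  lapply(unname(database), encode_residues, scheme = scheme)
}

max_score_encoded <- function(query_enc, db_enc, scheme) {
  max(sw_scores(query_enc, db_enc, scheme$matrix, scheme$gap_open, scheme$gap_extend))
}

# Pinned blastp tabular format; the adapter refuses any user override so the
# parser's column assumptions can never silently drift.
BLAST_OUTFMT <- "6 qseqid sseqid score evalue"

#' Parse blastp tabular output (format 6: qseqid sseqid score evalue)
#'
#' @param lines Character vector of tabular output lines.
#' @return data.frame with columns query, subject, score (integer raw score),
#'   evalue (numeric).  Zero lines give a zero-row data.frame.
#' @export
parse_blast_tabular <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(query = character(0), subject = character(0),
                      score = integer(0), evalue = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L))
    stop("unparsable blastp tabular line (expected 4 tab-separated fields): ",
         lines[which(nf != 4L)[1L]])
  score <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  evalue <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 4L)))
  if (anyNA(score) || anyNA(evalue))
    stop("non-numeric score/evalue field in blastp tabular line: ",
         lines[which(is.na(score) | is.na(evalue))[1L]])
  data.frame(query = vapply(fields, `[[`, character(1), 1L),
             subject = vapply(fields, `[[`, character(1), 2L),
             score = as.integer(round(score)),
             evalue = evalue,
             stringsAsFactors = FALSE)
}

#' Run an external blastp and parse its hits
#'
#' Invokes `blastp` with a pinned tabular output format
#' (`"6 qseqid sseqid score evalue"`) so raw scores and E-values are always
#' present and in known columns.  Any attempt to override the output format
#' through `extra_args` is rejected.  The identical invocation must be reused
#' for shuffled queries so that null scores are comparable.
#'
#' @param query_file Path to the query FASTA file.
#' @param db Path to a formatted BLAST database (makeblastdb).
#' @param matrix Matrix name blastp understands (e.g. `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (NCBI convention).
#' @param blastp Path to the blastp executable.
#' @param extra_args Additional command-line arguments (character vector).
#' @return data.frame as from [parse_blast_tabular()].
#' @export
run_blastp <- function(query_file, db, matrix = "BLOSUM62",
                       gap_open = 11L, gap_extend = 1L,
                       blastp = "blastp", extra_args = character()) {
  if (Sys.which(blastp) == "" && !file.exists(blastp))
    stop("blastp executable not found: ", blastp)
  if (any(grepl("outfmt", extra_args, fixed = TRUE)))
    stop("the blastp output format is pinned to '", BLAST_OUTFMT,
         "' and cannot be overridden")
  args <- c("-query", query_file, "-db", db,
            "-matrix", matrix,
            "-gapopen", gap_open, "-gapextend", gap_extend,
            "-outfmt", shQuote(BLAST_OUTFMT), extra_args)
  out <- suppressWarnings(system2(blastp, args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L)
    stop("blastp exited with status ", status, ": ",
         paste(utils::tail(out, 3L), collapse = " | "))
  parse_blast_tabular(out)
}
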