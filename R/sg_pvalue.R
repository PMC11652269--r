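#' Uniformly shuffle a residue sequence
#'
#' Fisher-Yates permutation of the residues (via [sample()]): the output has
#' the same length and residue multiset, and every arrangement is equally
#' likely.  This is the null model of the whole approach: the score of the
#' optimal alignment of a shuffled query against the database.
#'
#' @param sequence Non-empty residue string.
#' @param seed Optional integer seed (reproducible shuffle).
#' @return A shuffled residue string.
#' @export
shuffle_query <- function(sequence, seed = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("'sequence' must be a single non-empty string")
  res <- strsplit(sequence, "")[[1L]]
  perm <- with_seed(seed, sample.int(length(res)))
  paste(res[perm], collapse = "")
}

#' Null sample of database-wide optimal scores
#'
#' Wraps m maximal alignment scores Y_1..Y_m (one per query shuffle) together
#' with their sample mean and SD (m-1 denominator), the quantities used to
#' studentize observed scores.
#'
#' @param scores Numeric vector of m >= 2 maximal scores.
#' @param seed The master seed the shuffles were derived from (metadata).
#' @param engine Identifier of the engine that produced the scores.
#' @return An object of class `"null_sample"`.
#' @export
null_sample <- function(scores, seed = NA_integer_, engine = "builtin") {
  scores <- as.numeric(scores)
  if (length(scores) < 2L || any(!is.finite(scores)))
    stop("'scores' must hold at least 2 finite values")
  structure(list(scores = scores, ybar = mean(scores),
                 sy = stats::sd(scores), m = length(scores),
                 seed = seed, engine = engine),
            class = "null_sample")
}

#' @export
print.null_sample <- function(x, ...) {
  cat(sprintf("null sample: m = %d shuffled-query maxima (engine %s)\n",
              x$m, x$engine))
  cat(sprintf("  mean = %.4f, sd = %.4f, range = [%g, %g]\n",
              x$ybar, x$sy, min(x$scores), max(x$scores)))
  invisible(x)
}

#' Collect the null sample by searching shuffled queries
#'
#' Shuffles the query m times (per-shuffle seeds derived deterministically
#' from `seed`) and records, for each shuffle, the maximal alignment score
#' against the entire database, using exactly the same engine configuration
#' as the original search.
#'
#' @param query Residue string.
#' @param database Named character vector of subject sequences (used by the
#'   built-in engine).
#' @param engine A [scoring_scheme()] (built-in Smith-Waterman engine), or a
#'   function `function(query_string)` returning the database-wide maximal
#'   raw score (adapter for external tools); a failure inside the function is
#'   reported with the shuffle index.  An external engine reporting no
#'   alignment for a shuffle should return its floor score (0 for the
#'   built-in engine).
#' @param m Null-sample size (>= 2, canonically 50).
#' @param seed Integer master seed.
#' @return A [null_sample()].
#' @export
collect_null_sample <- function(query, database, engine, m = 50L, seed = NULL) {
  stopifnot(m >= 2)
  seeds <- if (is.null(seed)) rep(NA_integer_, m) else derive_seeds(seed, m)
  if (inherits(engine, "scoring_scheme")) {
    db_enc <- encode_database(database, engine)
    score_fun <- function(q) max_score_encoded(encode_residues(q, engine),
                                               db_enc, engine)
    engine_id <- "builtin"
  } else if (is.function(engine)) {
    score_fun <- engine
    engine_id <- "external"
  } else stop("'engine' must be a scoring_scheme or a function")
  y <- vapply(seq_len(m), function(j) {
    qj <- shuffle_query(query[[1L]], seed = if (is.na(seeds[j])) NULL else seeds[j])
    sj <- tryCatch(score_fun(qj),
                   error = function(e) stop(sprintf(
                     "engine failed on shuffle %d of %d: %s", j, m,
                     conditionMessage(e)), call. = FALSE))
    as.numeric(sj)
  }, numeric(1))
  null_sample(y, seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
              engine = engine_id)
}

#' Studentized-Gumbel P-value of observed alignment scores
#'
#' Studentizes each score against the null sample,
#' \eqn{T = (S - \bar Y)/\sigma_Y}, and looks up the tabulated SG_m right
#' tail.  T at or below 0 gives P = 1; T beyond the table's precision cutoff
#' gives the tail at the cutoff.  A degenerate null sample (zero SD, e.g. a
#' homopolymeric query whose shuffles are all identical) yields P = 1 for
#' scores at or below the null mean and the cutoff tail (with a warning)
#' above it, the limits of T as the SD vanishes.
#'
#' @param S Raw alignment score(s).
#' @param ns A [null_sample()]; its m must equal the table's m.
#' @param table An SG table (see [build_sg_table()] / [read_sg_table()]).
#' @return P-values in (0, 1], non-increasing in `S`.
#' @export
sg_p <- function(S, ns, table) {
  stopifnot(inherits(ns, "null_sample"), inherits(table, "sg_table"))
  if (ns$m != table$m)
    stop(sprintf("null sample has m = %d but the SG table was built for m = %d",
                 ns$m, table$m))
  if (ns$sy == 0) {
    p <- ifelse(S > ns$ybar, table$tail_at_cutoff, 1)
    if (any(S > ns$ybar))
      warning("degenerate null sample (zero SD); scores above the null mean ",
              "are assigned the precision-cutoff tail probability")
    return(p)
  }
  sg_tail_lookup(table, (S - ns$ybar) / ns$sy)
}

#' Flag significant alignments with FWER control
#'
#' Computes the SG P-value of every hit from the shared null sample of its
#' query and flags those with \eqn{p_i \le \alpha}.  Because all hits are
#' studentized against the same null sample and the database-wide maximum
#' dominates every hit, reporting \eqn{p_i \le \alpha} controls the
#' family-wise error rate at \eqn{\alpha} whenever the SG P-values are valid.
#'
#' @param hits data.frame with at least a `score` column (as produced by
#'   [search_database()] or [run_blastp()]); all rows must come from the same
#'   query/database/engine run as `ns`.
#' @param ns The query's [null_sample()].
#' @param table SG table with matching m.
#' @param alpha FWER level in (0, 1).
#' @return `hits` with `sg_pvalue` and `significant` columns appended.
#' @export
fwer_select <- function(hits, ns, table, alpha = 0.05) {
  stopifnot(is.data.frame(hits), "score" %in% names(hits))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  hits$sg_pvalue <- sg_p(hits$score, ns, table)
  hits$significant <- hits$sg_pvalue <= alpha
  hits
}

#' Benjamini-Yekutieli adjustment for dependent hypotheses
#'
#' Step-up FDR adjustment with the harmonic-sum inflation factor
#' \eqn{H(k) = \sum_{i=1}^k 1/i}, valid under arbitrary dependence among the
#' hypotheses (which alignment P-values certainly exhibit).  Delegates to
#' [stats::p.adjust()] with `method = "BY"`.
#'
#' @param pvalues P-values in (0, 1].
#' @return Adjusted P-values in (0, 1], same order as the input.
#' @export
by_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("'pvalues' must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BY")
}

#' Search a database and assign FWER-controlling SG P-values
#'
#' The end-to-end procedure: score the query against the database with the
#' built-in Smith-Waterman engine, collect the m-shuffle null sample with the
#' identical configuration, studentize, look up SG P-values, and flag
#' significance at level `alpha`.
#'
#' @param query Residue string (optionally named with the query id).
#' @param database Named character vector of subject sequences.
#' @param scheme A [scoring_scheme()].
#' @param table SG table whose m matches `m`.
#' @param m Null-sample size.
#' @param alpha FWER level.
#' @param seed Integer master seed for the shuffles.
#' @return An object of class `"sg_hits"`: the flagged hit table plus the
#'   null sample and run metadata.
#' @export
sg_search <- function(query, database, scheme, table, m = 50L,
                      alpha = 0.05, seed = NULL) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  res <- search_database(query, database, scheme)
  ns <- collect_null_sample(query[[1L]], database, scheme, m = m, seed = seed)
  hits <- fwer_select(res$hits, ns, table, alpha = alpha)
  structure(list(hits = hits, null_sample = ns, max_score = res$max_score,
                 max_subject = res$max_subject, alpha = alpha,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "sg_hits")
}

#' @export
print.sg_hits <- function(x, ...) {
  cat(sprintf("SG search: %d subjects, best score %d (%s)\n",
              nrow(x$hits), x$max_score, x$max_subject))
  cat(sprintf("  null sample: m = %d, mean %.2f, sd %.2f\n",
              x$null_sample$m, x$null_sample$ybar, x$null_sample$sy))
  sig <- x$hits[x$hits$significant, , drop = FALSE]
  cat(sprintf("  significant at FWER alpha = %g: %d alignment(s)\n",
              x$alpha, nrow(sig)))
  if (nrow(sig) > 0) print(sig, row.names = FALSE)
  invisible(x)
}

#' @export
summary.sg_hits <- function(object, ...) {
  h <- object$hits
  cat(sprintf("%d hits; min SG P-value %.3g; %d significant at alpha = %g\n",
              nrow(h), min(h$sg_pvalue), sum(h$significant), object$alpha))
  invisible(h[order(h$sg_pvalue), ])
}
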