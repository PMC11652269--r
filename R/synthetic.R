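#' Marginal amino-acid frequencies for iid sequence generation
#'
#' The default is the Robinson-Robinson frequency set (the classical marginal
#' amino-acid frequencies compiled from protein databases, and the set BLAST
#' carries in its statistics code).  Any user table can be supplied instead
#' via [read_freq_table()].
#'
#' @return Named numeric vector over the 20 standard amino acids, summing
#'   to 1.
#' @export
aa_frequencies <- function() {
  f <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
         Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
         L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
         S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
  f / sum(f)
}

#' Read an amino-acid frequency table
#'
#' Two-column TSV: residue, probability.  Must cover exactly the 20 standard
#' amino acids with non-negative values; probabilities are renormalized to
#' sum to 1 on load.
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector summing to 1.
#' @export
read_freq_table <- function(path) {
  dat <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("residue", "prob"),
                           colClasses = c("character", "numeric"))
  f <- stats::setNames(dat$prob, toupper(dat$residue))
  if (!setequal(names(f), AA_STANDARD) || length(f) != 20L)
    stop("frequency table must cover exactly the 20 standard amino acids")
  if (any(f < 0)) stop("frequencies must be non-negative")
  if (sum(f) <= 0) stop("frequencies sum to zero")
  f <- f[AA_STANDARD]
  f / sum(f)
}

#' Generate an iid protein sequence
#'
#' Residues drawn independently from the given frequency table; reproducible
#' for a fixed seed.
#'
#' @param length Sequence length (>= 1).
#' @param freq Named frequency vector (see [aa_frequencies()]).
#' @param seed Optional integer seed.
#' @return A residue string.
#' @export
generate_iid_sequence <- function(length, freq = aa_frequencies(), seed = NULL) {
  if (!is.numeric(length) || length < 1) stop("'length' must be >= 1")
  res <- with_seed(seed, sample(names(freq), size = length,
                                replace = TRUE, prob = freq))
  paste(res, collapse = "")
}

#' Generate a synthetic iid sequence database
#'
#' Independent iid sequences with ids `db_0001`, `db_0002`, ...  Lengths are
#' either given exactly (`lengths`, recycled to `n_sequences`) or drawn
#' uniformly from an integer range (`length_range = c(min, max)`).
#'
#' @param n_sequences Number of sequences (>= 1).
#' @param lengths Integer vector of lengths (recycled), or `NULL`.
#' @param length_range Integer `c(min, max)` to sample lengths from, or
#'   `NULL`.  Exactly one of `lengths`/`length_range` must be given.
#' @param freq Frequency table.
#' @param seed Optional integer master seed.
#' @return Named character vector of sequences.
#' @export
generate_database <- function(n_sequences, lengths = NULL, length_range = NULL,
                              freq = aa_frequencies(), seed = NULL) {
  if (n_sequences < 1) stop("'n_sequences' must be >= 1")
  if (is.null(lengths) == is.null(length_range))
    stop("give exactly one of 'lengths' or 'length_range'")
  with_seed(seed, {
    if (is.null(lengths)) {
      stopifnot(length(length_range) == 2L, length_range[1] >= 1,
                length_range[1] <= length_range[2])
      lengths <- sample(seq(length_range[1], length_range[2]),
                        n_sequences, replace = TRUE)
    } else {
      if (any(lengths < 1)) stop("all lengths must be >= 1")
      lengths <- rep_len(as.integer(lengths), n_sequences)
    }
    seqs <- vapply(lengths, function(len)
      paste(sample(names(freq), len, replace = TRUE, prob = freq),
            collapse = ""), character(1))
    stats::setNames(seqs, sprintf("db_%04d", seq_len(n_sequences)))
  })
}

#' Simulate scores directly from a null law
#'
#' Bypasses the alignment engine for distribution-level experiments: iid
#' draws from a Gumbel or normal law.  The Gumbel route is bit-identical to
#' [sample_gumbel()] under a shared seed.
#'
#' @param spec A list `list(dist = "gumbel", params = gumbel_params(...))` or
#'   `list(dist = "normal", mean = , sd = )`.
#' @param n Number of draws (0 gives an empty vector).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_score_null <- function(spec, n, seed = NULL) {
  stopifnot(is.list(spec), !is.null(spec$dist), n >= 0)
  if (n == 0) return(numeric(0))
  switch(spec$dist,
         gumbel = sample_gumbel(n, spec$params, seed = seed),
         normal = with_seed(seed, stats::rnorm(n, spec$mean, spec$sd)),
         stop("unknown score distribution spec: ", spec$dist))
}
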