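# Independent oracles used across the suite.  These deliberately take
# different algorithmic routes from the package implementation.

# Exhaustive local-alignment score: enumerate every ordered set of aligned
# residue pairs (i_1 < ... < i_k in x paired with j_1 < ... < j_k in y).
# Any local alignment under strictly positive gap penalties is optimal only
# if it starts and ends on an aligned column, and the cheapest realization
# of the gaps between consecutive aligned columns is one deletion run plus
# one insertion run, each costing open + len * extend.  The empty alignment
# contributes the score floor 0.
brute_force_local <- function(x, y, mat, gap_open, gap_extend) {
  xi <- match(strsplit(x, "")[[1L]], rownames(mat))
  yi <- match(strsplit(y, "")[[1L]], colnames(mat))
  n1 <- length(xi); n2 <- length(yi)
  gapcost <- function(idx) {
    if (nrow(idx) < 2L) return(numeric(ncol(idx)))
    d <- idx[-1L, , drop = FALSE] - idx[-nrow(idx), , drop = FALSE] - 1L
    colSums((d > 0) * gap_open + d * gap_extend)
  }
  best <- 0
  for (k in seq_len(min(n1, n2))) {
    A <- utils::combn(n1, k)
    B <- utils::combn(n2, k)
    match_mat <- matrix(0, ncol(A), ncol(B))
    for (t in seq_len(k))
      match_mat <- match_mat + mat[xi[A[t, ]], yi[B[t, ]], drop = FALSE]
    total <- match_mat - outer(gapcost(A), gapcost(B), "+")
    best <- max(best, max(total))
  }
  best
}

# Plain (no importance sampling) Monte-Carlo estimate of the SG_m right tail
# P(T >= t), drawing S and the null sample from the standard Gumbel (the law
# is pivotal, so any parameters would do).  Chunked to bound memory.
sg_tail_plain_mc <- function(t_values, m, n, seed, chunk = 1e5) {
  set.seed(seed)
  hits <- numeric(length(t_values))
  left <- n
  while (left > 0) {
    nc <- min(chunk, left)
    left <- left - nc
    Y <- matrix(-log(-log(stats::runif(nc * m))), nc, m)
    S <- -log(-log(stats::runif(nc)))
    ybar <- rowMeans(Y)
    sy <- sqrt(pmax(rowSums(Y * Y) - m * ybar^2, 0) / (m - 1))
    Tv <- (S - ybar) / sy
    hits <- hits + vapply(t_values, function(t) sum(Tv >= t), numeric(1))
  }
  hits / n
}

# Studentized statistics from simulated null draws of a given generator,
# one per replicate (used for the normal-analogue and validity checks).
studentized_sample <- function(n, m, rdraw, seed) {
  set.seed(seed)
  Y <- matrix(rdraw(n * m), n, m)
  S <- rdraw(n)
  ybar <- rowMeans(Y)
  sy <- sqrt(pmax(rowSums(Y * Y) - m * ybar^2, 0) / (m - 1))
  (S - ybar) / sy
}
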