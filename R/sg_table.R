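#' Configuration for tabulating the Studentized-Gumbel(m) tail
#'
#' The Studentized-Gumbel(m) (SG_m) law is the distribution of
#' \eqn{T = (S - \bar Y)/\sigma_Y} when S and the null sample Y_1..Y_m are
#' iid Gumbel; it depends only on m (it is pivotal), so it can be tabulated
#' once per m.  Tabulation draws the null samples from `y_params` and S from
#' a location-shifted, scale-inflated proposal (`proposal_params`),
#' reweighting each draw by the Gumbel likelihood ratio so that the far right
#' tail is populated (importance sampling).  The defaults mirror the
#' construction of the reference SG_50 table: Y ~ Gumbel(0, scale 3),
#' proposal Gumbel(33, scale 15), bins of width 0.001 on [0, 45), and a
#' coefficient-of-variation precision limit of 0.01.
#'
#' @param m Null-sample size (>= 2); 50 is the canonical choice.
#' @param n_draws Monte-Carlo replicates N (>= 1000).
#' @param bin_width Bin width in studentized-score units.
#' @param t_min,t_max Bin range; `(t_max - t_min)/bin_width` must be integral.
#' @param y_params [gumbel_params()] generating the null samples.
#' @param proposal_params [gumbel_params()] generating S.
#' @param cv_threshold Largest acceptable coefficient of variation of the
#'   tail-weight set; bins beyond the last compliant bin are not trusted.
#' @param seed Integer master seed (chunk seeds are derived from it).
#' @param chunk_size Replicates generated per chunk; part of the
#'   reproducibility contract (the draw stream depends on it), so it is
#'   recorded in the table metadata.
#' @param cv_method How the per-bin precision ratio is computed.
#'   `"standard_error"` (default) is the relative standard error of the
#'   importance-sampling estimator: the SD of the per-draw tail
#'   contributions (zeros included) divided by `sqrt(N) G(t)` — the
#'   coefficient of variation of the estimate G(t) itself, which grows into
#'   the tail and therefore yields a finite trust region.
#'   `"tail_weights"` is the alternative literal reading (sample SD of the
#'   nonzero tail weights divided by G(t)); because importance weights span
#'   many orders of magnitude this ratio stays far above any small threshold
#'   in every bin, so it is offered for sensitivity analysis only.
#' @return An object of class `"sg_table_config"`.
#' @export
sg_table_config <- function(m = 50L, n_draws, bin_width = 0.001,
                            t_min = 0, t_max = 45,
                            y_params = gumbel_params(0, 1 / 3),
                            proposal_params = gumbel_params(33, 1 / 15),
                            cv_threshold = 0.01, seed = NULL,
                            chunk_size = 2e5,
                            cv_method = c("standard_error", "tail_weights")) {
  stopifnot(m >= 2, m == as.integer(m), bin_width > 0, t_min < t_max,
            cv_threshold > 0, chunk_size >= 1)
  n_bins <- (t_max - t_min) / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-8)
    stop("(t_max - t_min)/bin_width must be an integer number of bins")
  if (n_draws < 1e3)
    stop("n_draws below 1000 cannot produce a meaningful table; refusing")
  structure(list(m = as.integer(m), n_draws = as.numeric(n_draws),
                 bin_width = bin_width, t_min = t_min, t_max = t_max,
                 n_bins = as.integer(round(n_bins)),
                 y_params = as_gumbel_params(y_params),
                 proposal_params = as_gumbel_params(proposal_params),
                 cv_threshold = cv_threshold,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 chunk_size = as.numeric(chunk_size),
                 cv_method = match.arg(cv_method)),
            class = "sg_table_config")
}

#' Importance-sampling weight (Gumbel likelihood ratio)
#'
#' The Radon-Nikodym derivative \eqn{w(s) = f_{target}(s) / f_{proposal}(s)}
#' attached to a draw `s` taken from the proposal; computed in log space.
#'
#' @param s Score(s) drawn from the proposal.
#' @param target,proposal [gumbel_params()] objects.
#' @return Positive weights, 1 wherever the two densities coincide.
#' @export
importance_weight <- function(s, target, proposal) {
  exp(gumbel_density(s, target, log = TRUE) -
        gumbel_density(s, proposal, log = TRUE))
}

#' Tabulate the Studentized-Gumbel(m) right tail
#'
#' For each of `n_draws` replicates, draws a null sample Y_1..Y_m from
#' `y_params` and one score S from `proposal_params`, studentizes
#' \eqn{t = (S - \bar Y)/\sigma_Y} (SD with the m-1 denominator), and adds
#' the importance weight of S to the half-open bin
#' `[edge, edge + bin_width)` containing t.  The right tail at a bin with
#' center t is \eqn{G(t) = \sum w_i / N} over that bin and all higher bins;
#' the precision cutoff is the largest bin center whose tail-weight
#' coefficient of variation is at or below `cv_threshold`.
#'
#' Replicates whose studentized value falls outside `[t_min, t_max)` carry no
#' weight (they still count in N); replicates with a zero null-sample SD are
#' dropped with a warning.  Draws are generated in fixed-size chunks with
#' chunk seeds derived from the master seed, so tables are reproducible at
#' bounded memory for any N.
#'
#' @param config An [sg_table_config()].
#' @return An object of class `"sg_table"`.
#' @export
build_sg_table <- function(config) {
  stopifnot(inherits(config, "sg_table_config"))
  m <- config$m
  nb <- config$n_bins
  wsum <- numeric(nb); w2sum <- numeric(nb); wcount <- numeric(nb)
  n_dropped <- 0
  n_left <- config$n_draws
  n_chunks <- ceiling(config$n_draws / config$chunk_size)
  seeds <- if (is.na(config$seed)) rep(NA, n_chunks) else
    derive_seeds(config$seed, n_chunks)
  yp <- config$y_params; pp <- config$proposal_params
  for (ci in seq_len(n_chunks)) {
    nc <- as.integer(min(config$chunk_size, n_left))
    n_left <- n_left - nc
    acc <- with_seed(if (is.na(seeds[ci])) NULL else seeds[ci], {
      u <- stats::runif(m * nc)
      Y <- matrix(yp$mu - log(-log(u)) / yp$lam, nrow = m, ncol = nc)
      s <- pp$mu - log(-log(stats::runif(nc))) / pp$lam
      ybar <- colMeans(Y)
      sy <- sqrt(pmax(colSums(Y * Y) - m * ybar^2, 0) / (m - 1))
      list(s = s, ybar = ybar, sy = sy)
    })
    degen <- acc$sy == 0
    n_dropped <- n_dropped + sum(degen)
    t <- (acc$s - acc$ybar) / acc$sy
    keep <- !degen & t >= config$t_min & t < config$t_max
    if (!any(keep)) next
    t <- t[keep]
    w <- importance_weight(acc$s[keep], yp, pp)
    bin <- as.integer(floor((t - config$t_min) / config$bin_width)) + 1L
    rs <- rowsum(cbind(w, w * w, 1), group = bin)
    idx <- as.integer(rownames(rs))
    wsum[idx] <- wsum[idx] + rs[, 1L]
    w2sum[idx] <- w2sum[idx] + rs[, 2L]
    wcount[idx] <- wcount[idx] + rs[, 3L]
  }
  if (n_dropped > 0)
    warning(sprintf("dropped %d replicate(s) with zero null-sample SD", n_dropped))
  N <- config$n_draws - n_dropped
  tw <- rev(cumsum(rev(wsum)))
  tw2 <- rev(cumsum(rev(w2sum)))
  tn <- rev(cumsum(rev(wcount)))
  G <- tw / N
  cv <- tail_cv(tw, tw2, tn, N, config$cv_method)
  centers <- config$t_min + (seq_len(nb) - 0.5) * config$bin_width
  ok <- is.finite(cv) & cv <= config$cv_threshold & G > 0
  if (!any(ok)) {
    if (all(tn < 2))
      warning("fewer than 2 tail weights in every bin; precision cutoff set to t_min")
    cutoff_idx <- NA_integer_
    cutoff <- config$t_min
    tail_at_cutoff <- 1
  } else {
    cutoff_idx <- max(which(ok))
    cutoff <- centers[cutoff_idx]
    tail_at_cutoff <- G[cutoff_idx]
  }
  structure(list(m = m,
                 bin_centers = centers,
                 log10_tail = ifelse(G > 0, log10(G), -Inf),
                 precision_cutoff = cutoff,
                 tail_at_cutoff = tail_at_cutoff,
                 t_min = config$t_min, t_max = config$t_max,
                 bin_width = config$bin_width,
                 n_draws = config$n_draws, n_dropped = as.integer(n_dropped),
                 seed = config$seed, chunk_size = config$chunk_size,
                 y_params = yp, proposal_params = pp,
                 cv_threshold = config$cv_threshold,
                 cv_method = config$cv_method,
                 format_version = 1L),
            class = "sg_table")
}

# CV of the tail-weight sets from cumulative sums (tw = sum of tail weights,
# tw2 = sum of squares, tn = count of nonzero tail weights, N = total draws).
tail_cv <- function(tw, tw2, tn, N, method) {
  G <- tw / N
  if (method == "tail_weights") {
    sd_tail <- ifelse(tn >= 2,
                      sqrt(pmax(tw2 - tw^2 / tn, 0) / (tn - 1)),
                      NA_real_)
    ifelse(G > 0, sd_tail / G, NA_real_)
  } else {
    sd_all <- sqrt(pmax(tw2 - tw^2 / N, 0) / (N - 1))
    ifelse(G > 0, sd_all / (sqrt(N) * G), NA_real_)
  }
}

#' Precision cutoff from explicit per-bin weight sets
#'
#' For each bin (ordered by increasing t), pools the weights in that bin and
#' every higher bin, computes the sample SD of the pooled weights divided by
#' the tail estimate G(t), and returns the largest bin center whose ratio is
#' at or below `cv_threshold`.  Exposed for desk-scale verification; the
#' table builder applies the same computation in cumulative form.
#'
#' @param bin_weights List of numeric vectors: the weights that fell in each
#'   bin, ordered by increasing t.
#' @param tail Per-bin tail estimates G(t), same length.
#' @param cv_threshold Positive CV limit.
#' @param bin_centers Bin centers; defaults to 1, 2, ...
#' @param t_min Value returned when no bin qualifies.
#' @param n_draws Total draw count N; needed for
#'   `cv_method = "standard_error"` (the draws whose studentized value missed
#'   every bin contribute zero weight).
#' @param cv_method As in [sg_table_config()]: `"tail_weights"` (default
#'   here, the hand-computable explicit-weights ratio) or
#'   `"standard_error"`.
#' @return The cutoff (a bin center, or `t_min`).
#' @export
precision_cutoff <- function(bin_weights, tail, cv_threshold,
                             bin_centers = seq_along(bin_weights),
                             t_min = min(bin_centers), n_draws = NULL,
                             cv_method = c("tail_weights", "standard_error")) {
  stopifnot(is.list(bin_weights), length(bin_weights) == length(tail),
            length(bin_centers) == length(tail), cv_threshold > 0)
  cv_method <- match.arg(cv_method)
  if (cv_method == "standard_error" && is.null(n_draws))
    stop("'n_draws' is required for cv_method = \"standard_error\"")
  nb <- length(bin_weights)
  tailsets <- vector("list", nb)
  acc <- numeric(0)
  for (b in rev(seq_len(nb))) {
    acc <- c(bin_weights[[b]], acc)
    tailsets[[b]] <- acc
  }
  if (all(lengths(tailsets) < 2)) {
    warning("fewer than 2 tail weights in every bin; returning t_min")
    return(t_min)
  }
  cv <- vapply(seq_len(nb), function(b) {
    ws <- tailsets[[b]]
    if (length(ws) < 2 || tail[b] <= 0) return(NA_real_)
    if (cv_method == "tail_weights") {
      stats::sd(ws) / tail[b]
    } else {
      all_w <- c(ws, numeric(n_draws - length(ws)))
      stats::sd(all_w) / (sqrt(n_draws) * tail[b])
    }
  }, numeric(1))
  ok <- which(is.finite(cv) & cv <= cv_threshold)
  if (length(ok) == 0L) return(t_min)
  bin_centers[max(ok)]
}

#' Look up the tabulated SG tail at studentized values
#'
#' Step-function lookup at bin resolution: a value t maps to the bin
#' containing it; t at or below 0 returns 1; t beyond the precision cutoff
#' returns the tail at the cutoff (values out there are real discoveries, and
#' the cutoff tail is an upper bound on their P-value).
#'
#' @param table An [sg_table()] object (see [build_sg_table()]).
#' @param t Studentized values.
#' @return Tail probabilities in (0, 1].
#' @export
sg_tail_lookup <- function(table, t) {
  stopifnot(inherits(table, "sg_table"))
  p <- rep(NA_real_, length(t))
  p[t <= 0] <- 1
  hi <- t > table$precision_cutoff & t > 0
  p[hi] <- table$tail_at_cutoff
  mid <- is.na(p)
  if (any(mid)) {
    below <- mid & t < table$t_min
    p[below] <- 1  # below the tabulated range: conservative
    mid <- is.na(p)
    bin <- pmin(as.integer(floor((t[mid] - table$t_min) / table$bin_width)) + 1L,
                length(table$log10_tail))
    p[mid] <- 10^table$log10_tail[bin]
  }
  p
}

#' @export
print.sg_table <- function(x, ...) {
  cat(sprintf("Studentized-Gumbel(m = %d) tail table\n", x$m))
  cat(sprintf("  bins: %d of width %g on [%g, %g)\n",
              length(x$bin_centers), x$bin_width, x$t_min, x$t_max))
  cat(sprintf("  draws: %s (%d dropped), seed %s, chunk %s\n",
              format(x$n_draws, big.mark = ","), x$n_dropped,
              ifelse(is.na(x$seed), "none", x$seed),
              format(x$chunk_size, big.mark = ",")))
  cat(sprintf("  precision cutoff: %g (CV <= %g, %s), G(cutoff) = %.4g\n",
              x$precision_cutoff, x$cv_threshold, x$cv_method, x$tail_at_cutoff))
  invisible(x)
}

SG_TABLE_HEADER_FIELDS <- c("format_version", "m", "n_draws", "n_dropped",
                            "seed", "chunk_size", "t_min", "t_max",
                            "bin_width", "y_mu", "y_lam", "proposal_mu",
                            "proposal_lam", "cv_threshold", "cv_method",
                            "precision_cutoff", "tail_at_cutoff")

#' Save an SG table to a plain-text TSV file
#'
#' The file starts with `# key\tvalue` metadata lines (format version, m, N,
#' seed, generator parameters, bin geometry, precision cutoff) followed by
#' two columns: `bin_center`, `log10_tail`.  Numbers are written with 17
#' significant digits so a save/load round trip is bit-identical.
#'
#' @param table An `sg_table`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_sg_table <- function(table, path) {
  stopifnot(inherits(table, "sg_table"))
  num <- function(v) sprintf("%.17g", v)
  hdr <- c(format_version = table$format_version, m = table$m,
           n_draws = num(table$n_draws), n_dropped = table$n_dropped,
           seed = table$seed, chunk_size = num(table$chunk_size),
           t_min = num(table$t_min), t_max = num(table$t_max),
           bin_width = num(table$bin_width),
           y_mu = num(table$y_params$mu), y_lam = num(table$y_params$lam),
           proposal_mu = num(table$proposal_params$mu),
           proposal_lam = num(table$proposal_params$lam),
           cv_threshold = num(table$cv_threshold), cv_method = table$cv_method,
           precision_cutoff = num(table$precision_cutoff),
           tail_at_cutoff = num(table$tail_at_cutoff))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s\t%s", names(hdr), hdr), con)
  writeLines("bin_center\tlog10_tail", con)
  writeLines(sprintf("%.17g\t%.17g", table$bin_centers, table$log10_tail), con)
  invisible(path)
}

#' Load an SG table written by [write_sg_table()]
#'
#' @param path Path to a table file.
#' @param m If given, the null-sample size the caller intends to use; a
#'   mismatch with the stored m is an error (an SG table is only valid for
#'   the m it was built with).
#' @return An `sg_table`.
#' @export
read_sg_table <- function(path, m = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "# ")
  hdr_lines <- lines[is_hdr]
  parts <- strsplit(sub("^# ", "", hdr_lines), "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L)
    stop("corrupted SG table header at line ", which(is_hdr)[bad[1L]],
         ": ", hdr_lines[bad[1L]])
  hdr <- stats::setNames(vapply(parts, `[[`, character(1), 2L),
                         vapply(parts, `[[`, character(1), 1L))
  missing_f <- setdiff(SG_TABLE_HEADER_FIELDS, names(hdr))
  if (length(missing_f) > 0L)
    stop("SG table header is missing field(s): ", paste(missing_f, collapse = ", "))
  if (hdr[["format_version"]] != "1")
    stop("unsupported SG table format version: ", hdr[["format_version"]])
  m_stored <- as.integer(hdr[["m"]])
  if (!is.null(m) && m != m_stored)
    stop(sprintf("SG table was built for m = %d but m = %d was requested",
                 m_stored, as.integer(m)))
  body <- lines[!is_hdr]
  if (length(body) < 2L || body[[1L]] != "bin_center\tlog10_tail")
    stop("corrupted SG table: expected 'bin_center\\tlog10_tail' column header")
  dat <- utils::read.table(text = body[-1L], sep = "\t",
                           col.names = c("bin_center", "log10_tail"))
  structure(list(m = m_stored,
                 bin_centers = dat$bin_center,
                 log10_tail = dat$log10_tail,
                 precision_cutoff = as.numeric(hdr[["precision_cutoff"]]),
                 tail_at_cutoff = as.numeric(hdr[["tail_at_cutoff"]]),
                 t_min = as.numeric(hdr[["t_min"]]),
                 t_max = as.numeric(hdr[["t_max"]]),
                 bin_width = as.numeric(hdr[["bin_width"]]),
                 n_draws = as.numeric(hdr[["n_draws"]]),
                 n_dropped = as.integer(hdr[["n_dropped"]]),
                 seed = suppressWarnings(as.integer(hdr[["seed"]])),
                 chunk_size = as.numeric(hdr[["chunk_size"]]),
                 y_params = gumbel_params(as.numeric(hdr[["y_mu"]]),
                                          as.numeric(hdr[["y_lam"]])),
                 proposal_params = gumbel_params(as.numeric(hdr[["proposal_mu"]]),
                                                 as.numeric(hdr[["proposal_lam"]])),
                 cv_threshold = as.numeric(hdr[["cv_threshold"]]),
                 cv_method = hdr[["cv_method"]],
                 format_version = 1L),
            class = "sg_table")
}
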