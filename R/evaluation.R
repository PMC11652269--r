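#' Simulate draws from the null distribution of the optimal alignment score
#'
#' Each replicate independently shuffles the query and records the maximal
#' alignment score against the entire database (and, for engines that report
#' one, the minimal E-value).  Per-replicate shuffle seeds are derived
#' deterministically from the master seed, so the sample is reproducible.
#'
#' @param query Residue string.
#' @param database Named character vector (built-in engine), or `NULL` when
#'   `engine` is a function.
#' @param engine A [scoring_scheme()] for the built-in Smith-Waterman engine,
#'   or a function `function(query_string)` returning either a single
#'   maximal score or `c(score = , evalue = )` for engines that report
#'   E-values.
#' @param n_replicates Number of null draws (>= 1).
#' @param seed Integer master seed.
#' @return data.frame with columns `replicate`, `score`, `evalue` (NA when
#'   the engine reports none).
#' @export
simulate_null_scores <- function(query, database, engine, n_replicates, seed = NULL) {
  stopifnot(n_replicates >= 1)
  seeds <- if (is.null(seed)) rep(NA_integer_, n_replicates)
           else derive_seeds(seed, n_replicates)
  if (inherits(engine, "scoring_scheme")) {
    db_enc <- encode_database(database, engine)
    score_fun <- function(q) max_score_encoded(encode_residues(q, engine),
                                               db_enc, engine)
  } else if (is.function(engine)) {
    score_fun <- engine
  } else stop("'engine' must be a scoring_scheme or a function")
  score <- numeric(n_replicates)
  evalue <- rep(NA_real_, n_replicates)
  for (j in seq_len(n_replicates)) {
    qj <- shuffle_query(query[[1L]], seed = if (is.na(seeds[j])) NULL else seeds[j])
    out <- tryCatch(score_fun(qj),
                    error = function(e) stop(sprintf(
                      "engine failed on replicate %d: %s", j,
                      conditionMessage(e)), call. = FALSE))
    score[j] <- as.numeric(out[[1L]])
    if (!is.null(names(out)) && "evalue" %in% names(out))
      evalue[j] <- as.numeric(out[["evalue"]])
  }
  data.frame(replicate = seq_len(n_replicates), score = score, evalue = evalue)
}

#' Probability-plot coordinates for a P-value (or E-value) sample
#'
#' For each replicate's value v the point is
#' (log10 of the fraction of replicates with value <= v, log10 v), sorted by
#' v (ties use the <= convention).  A valid, exactly uniform P-value sample
#' lies on the diagonal; points below the diagonal indicate liberal values,
#' points above indicate conservative ones.
#'
#' @param values Values in (0, 1]; non-empty.
#' @return data.frame with columns `log10_empirical`, `log10_value`.
#' @export
probability_plot_data <- function(values) {
  if (length(values) == 0L) stop("'values' must be non-empty")
  if (any(!is.finite(values)) || any(values <= 0 | values > 1))
    stop("'values' must lie in (0, 1]")
  v <- sort(values)
  frac <- findInterval(v, v) / length(v)   # count of values <= v, with ties
  data.frame(log10_empirical = log10(frac), log10_value = log10(v))
}

#' One-sided binomial exceedance test
#'
#' Tests whether observing `k` of `n` null values at or below level `alpha`
#' is compatible with valid values: returns \eqn{P(X \ge k)} for
#' \eqn{X \sim Binomial(n, \alpha)}.  Small values indicate a statistically
#' significant liberal bias.
#'
#' @param k Exceedance count, 0 <= k <= n.
#' @param n Number of replicates.
#' @param alpha Nominal level in (0, 1).
#' @return One-sided P-value.
#' @export
exceedance_binomial_test <- function(k, n, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  stopifnot(k >= 0, k <= n)
  stats::pbinom(k - 1, n, alpha, lower.tail = FALSE)
}

#' Plug-in Gumbel P-value from a fitted null sample (diagnostic)
#'
#' Fits a Gumbel to the null scores by maximum likelihood and returns the
#' fitted right tail at `S`.  This plug-in alternative to studentization is
#' provided as a diagnostic only: with small null samples the estimation
#' noise makes these P-values anti-conservative (liberal) in the far tail,
#' which is exactly the failure mode the studentized approach avoids.
#'
#' @param S Observed score(s).
#' @param null_scores Null sample with at least two distinct values.
#' @return P-value(s) under the fitted Gumbel.
#' @export
mle_pvalue <- function(S, null_scores) {
  fit <- fit_gumbel_mle(null_scores)
  gumbel_tail(S, fit)
}

#' Count discoveries at a significance cutoff
#'
#' @param values P-values or E-values, one per candidate alignment.
#' @param cutoff Report threshold; values <= cutoff are counted.
#' @param labels Optional labels (e.g. TRUE/FALSE for positives); when given,
#'   counts are split by label.
#' @return A named integer vector: `total`, plus one entry per label level
#'   when `labels` is given.
#' @export
count_discoveries <- function(values, cutoff, labels = NULL) {
  hit <- values <= cutoff
  out <- c(total = sum(hit))
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(values))
    out <- c(out, vapply(split(hit, labels), sum, integer(1)))
  }
  out
}

# Row-wise Gumbel MLE via vectorized Newton iteration on the profiled rate
# equation (same equations as fit_gumbel_mle, solved for many samples at
# once).  Rows with zero variance get NA.
fit_gumbel_rows <- function(X, max_iter = 60L, tol = 1e-12) {
  n <- ncol(X)
  xbar <- rowMeans(X)
  xmin <- do.call(pmin, as.data.frame(X))
  sdx <- sqrt(pmax(rowSums(X * X) - n * xbar^2, 0) / (n - 1))
  ok <- sdx > 0
  lam <- ifelse(ok, pi / (sdx * sqrt(6)), NA_real_)
  X0 <- X - xmin
  xbar0 <- xbar - xmin
  for (it in seq_len(max_iter)) {
    W <- exp(-lam * X0)
    sw <- rowSums(W)
    mw <- rowSums(X0 * W) / sw
    g <- 1 / lam - xbar0 + mw
    gp <- -1 / lam^2 - pmax(rowSums(X0 * X0 * W) / sw - mw^2, 0)
    step <- g / gp
    lam_new <- lam - step
    halve <- !is.na(lam_new) & lam_new <= 0
    lam_new[halve] <- lam[halve] / 2
    moved <- max(abs(step / lam), na.rm = TRUE)
    lam <- lam_new
    if (is.finite(moved) && moved < tol) break
  }
  mu <- xmin - log(rowMeans(exp(-lam * X0))) / lam
  list(mu = mu, lam = lam)
}

#' Null calibration of SG (and plug-in Gumbel) P-values
#'
#' The validity harness: given a sample of null optimal-alignment scores
#' (from [simulate_null_scores()] or any score-level simulator), each
#' replicate's score is assigned
#' \itemize{
#'   \item an SG P-value, studentized against an auxiliary null sample of
#'     size m drawn with replacement from the pooled null scores, and
#'   \item a plug-in "MLE" P-value from a Gumbel fitted to that same
#'     auxiliary sample (the diagnostic of [mle_pvalue()]),
#' }
#' and, per nominal level alpha, the empirical exceedance frequency
#' \eqn{\#\{p \le \alpha\}/N_s} is compared with alpha by the one-sided
#' binomial test (performed when the frequency exceeds alpha).  Minimal
#' E-values, when supplied, are summarized the same way.
#'
#' @param scores Numeric vector of null maximal scores (length >= m).
#' @param table SG table (defines m via its own m).
#' @param alphas Nominal levels; default the canonical grid 0.05, 0.01,
#'   1e-3, 1e-4, 1e-5, 1e-6.
#' @param evalues Optional minimal E-values, one per replicate.
#' @param seed Integer seed for the auxiliary resampling.
#' @return An object of class `"sg_calibration"`: `records` (per-replicate
#'   score, sg_pvalue, mle_pvalue, evalue), `summary` (per alpha and
#'   measure: count, frequency, binomial P), `n_replicates`, `m`.
#' @export
sg_calibration <- function(scores, table,
                           alphas = c(0.05, 0.01, 1e-3, 1e-4, 1e-5, 1e-6),
                           evalues = NULL, seed = NULL) {
  stopifnot(inherits(table, "sg_table"), length(scores) >= table$m)
  m <- table$m
  ns <- length(scores)
  X <- with_seed(seed, matrix(scores[sample.int(ns, ns * m, replace = TRUE)],
                              nrow = ns, ncol = m))
  ybar <- rowMeans(X)
  sy <- sqrt(pmax(rowSums(X * X) - m * ybar^2, 0) / (m - 1))
  sg_pv <- numeric(ns)
  degen <- sy == 0
  sg_pv[degen] <- ifelse(scores[degen] > ybar[degen], table$tail_at_cutoff, 1)
  sg_pv[!degen] <- sg_tail_lookup(table,
                                  (scores[!degen] - ybar[!degen]) / sy[!degen])
  fit <- fit_gumbel_rows(X)
  mle_pv <- gumbel_tail_vec(scores, fit$mu, fit$lam)
  records <- data.frame(replicate = seq_len(ns), score = scores,
                        sg_pvalue = sg_pv, mle_pvalue = mle_pv,
                        evalue = if (is.null(evalues)) NA_real_ else evalues)
  measures <- list(sg_pvalue = sg_pv, mle_pvalue = mle_pv)
  if (!is.null(evalues) && !all(is.na(evalues))) measures$evalue <- evalues
  summ <- do.call(rbind, lapply(names(measures), function(nm) {
    v <- measures[[nm]]
    nv <- sum(!is.na(v))
    k <- vapply(alphas, function(a) sum(v <= a, na.rm = TRUE), numeric(1))
    freq <- k / nv
    binp <- ifelse(freq > alphas,
                   mapply(exceedance_binomial_test, k, nv, alphas),
                   NA_real_)
    data.frame(measure = nm, alpha = alphas, count = k,
               frequency = freq, binomial_p = binp)
  }))
  structure(list(records = records, summary = summ,
                 n_replicates = ns, m = m, n_degenerate = sum(degen),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "sg_calibration")
}

# Vectorized Gumbel tail with per-element parameters.
gumbel_tail_vec <- function(x, mu, lam) {
  -expm1(-exp(-lam * (x - mu)))
}

#' @export
print.sg_calibration <- function(x, ...) {
  cat(sprintf("null calibration: %d replicates, auxiliary m = %d%s\n",
              x$n_replicates, x$m,
              if (x$n_degenerate > 0)
                sprintf(" (%d degenerate resamples)", x$n_degenerate) else ""))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Probability plot of calibration results
#'
#' Draws the empirical-vs-nominal log10 probability plot for each measure in
#' the calibration; the dashed diagonal marks exact uniformity, points below
#' it liberal values, points above conservative ones.
#'
#' @param x An `sg_calibration`.
#' @param measures Which record columns to draw.
#' @param ... Passed to [plot()].
#' @export
plot.sg_calibration <- function(x, measures = c("sg_pvalue", "mle_pvalue"), ...) {
  cols <- c(sg_pvalue = "#1b6ca8", mle_pvalue = "#c0392b", evalue = "#666666")
  measures <- intersect(measures, names(x$records))
  keep <- vapply(measures, function(nm) any(!is.na(x$records[[nm]])), logical(1))
  measures <- measures[keep]
  pd <- lapply(measures, function(nm) {
    v <- x$records[[nm]]
    probability_plot_data(pmin(v[!is.na(v)], 1))
  })
  rng <- range(unlist(lapply(pd, function(d) c(d$log10_empirical, d$log10_value))))
  plot(NA, xlim = rng, ylim = rng,
       xlab = "log10 empirical frequency", ylab = "log10 value", ...)
  abline(0, 1, lty = 2, col = "grey40")
  for (i in seq_along(measures))
    lines(pd[[i]]$log10_empirical, pd[[i]]$log10_value,
          col = cols[[measures[i]]], lwd = 1.5)
  legend("topleft", legend = measures, col = cols[measures],
         lwd = 1.5, bty = "n")
  invisible(x)
}

#' Write calibration records and summary to TSV files
#'
#' @param x An `sg_calibration`.
#' @param dir Output directory (created if needed); writes `records.tsv` and
#'   `summary.tsv`.
#' @return `dir`, invisibly.
#' @export
write_calibration <- function(x, dir) {
  stopifnot(inherits(x, "sg_calibration"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x$records, file.path(dir, "records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$summary, file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
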