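#' Gumbel distribution parameters
#'
#' Constructs the location/rate parameter pair used throughout the package.
#' The distribution function is \eqn{F(x) = \exp(-e^{-\lambda (x - \mu)})};
#' the scale is the reciprocal of the rate, \eqn{1/\lambda}.  Every function
#' in the package uses this (location, rate) parameterization to avoid the
#' scale/rate confusion common across libraries.
#'
#' @param mu Location, in score units.
#' @param lam Rate (1/scale), must be strictly positive.
#' @return An object of class `"gumbel_params"`.
#' @examples
#' gumbel_params(0, 1 / 3)
#' @export
gumbel_params <- function(mu, lam) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(lam), length(lam) == 1L, is.finite(lam))
  if (lam <= 0) stop("Gumbel rate 'lam' must be > 0")
  structure(list(mu = as.numeric(mu), lam = as.numeric(lam)),
            class = "gumbel_params")
}

#' @export
print.gumbel_params <- function(x, ...) {
  cat(sprintf("Gumbel(location = %g, rate = %g, scale = %g)\n",
              x$mu, x$lam, 1 / x$lam))
  invisible(x)
}

as_gumbel_params <- function(p) {
  if (inherits(p, "gumbel_params")) return(p)
  if (is.numeric(p) && length(p) == 2L) return(gumbel_params(p[[1L]], p[[2L]]))
  stop("expected a 'gumbel_params' object or a (mu, lam) numeric pair")
}

#' Gumbel density
#'
#' Density \eqn{f(x) = \lambda \exp[-\lambda(x-\mu) - e^{-\lambda(x-\mu)}]}.
#'
#' @param x Numeric vector of scores (finite).
#' @param p A [gumbel_params()] object.
#' @param log Return the log density?
#' @return Density values (or log densities), same length as `x`.
#' @export
gumbel_density <- function(x, p, log = FALSE) {
  p <- as_gumbel_params(p)
  if (any(!is.finite(x))) stop("'x' must be finite")
  z <- p$lam * (x - p$mu)
  ld <- log(p$lam) - z - exp(-z)
  if (log) ld else exp(ld)
}

#' Gumbel right-tail probability
#'
#' \eqn{P(X > x) = 1 - \exp(-e^{-\lambda(x-\mu)})}, computed via `expm1` so
#' that very small tails retain full relative precision.
#'
#' @inheritParams gumbel_density
#' @return Tail probabilities in (0, 1), strictly decreasing in `x`.
#' @export
gumbel_tail <- function(x, p) {
  p <- as_gumbel_params(p)
  if (any(!is.finite(x))) stop("'x' must be finite")
  -expm1(-exp(-p$lam * (x - p$mu)))
}

#' Gumbel quantile function
#'
#' Inverse of the CDF \eqn{F(x)=\exp(-e^{-\lambda(x-\mu)})}:
#' \eqn{Q(q) = \mu - \log(-\log q)/\lambda}.
#'
#' @param q Probabilities in (0, 1).
#' @param p A [gumbel_params()] object.
#' @export
gumbel_quantile <- function(q, p) {
  p <- as_gumbel_params(p)
  if (any(q <= 0 | q >= 1)) stop("'q' must lie in (0, 1)")
  p$mu - log(-log(q)) / p$lam
}

#' Sample from a Gumbel distribution
#'
#' Inverse-CDF sampling of iid Gumbel draws; reproducible for a fixed seed.
#' The caller's RNG state is left untouched when `seed` is supplied.
#'
#' @param n Number of draws (>= 1).
#' @param p A [gumbel_params()] object.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
sample_gumbel <- function(n, p, seed = NULL) {
  p <- as_gumbel_params(p)
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("'n' must be >= 1")
  with_seed(seed, p$mu - log(-log(stats::runif(n))) / p$lam)
}

#' Maximum-likelihood fit of a Gumbel distribution
#'
#' Profiles the likelihood down to a one-dimensional equation in the rate,
#' solved by bracketed root finding; the location then has a closed form.
#' For data \eqn{x_1..x_n} the rate solves
#' \deqn{1/\lambda = \bar x - \sum x_i e^{-\lambda x_i} / \sum e^{-\lambda x_i}}
#' and \eqn{\hat\mu = -\log(\frac1n\sum e^{-\hat\lambda x_i})/\hat\lambda}.
#' Exponentials are computed on shifted data for numerical stability, which
#' leaves both equations unchanged (the fit is affine-equivariant).
#'
#' @param scores Numeric vector with at least two distinct finite values.
#' @param tol Root-finding tolerance on the rate scale.
#' @return A [gumbel_params()] object with the fitted (mu, lam).
#' @export
fit_gumbel_mle <- function(scores, tol = 1e-10) {
  x <- as.numeric(scores)
  if (any(!is.finite(x))) stop("'scores' must be finite")
  if (length(x) < 2L || length(unique(x)) < 2L)
    stop("need at least 2 distinct values to fit a Gumbel (rate undefined for a constant sample)")
  xbar <- mean(x)
  x0 <- x - min(x)
  profile <- function(lam) {
    w <- exp(-lam * x0)
    1 / lam - xbar + sum(x * w) / sum(w)
  }
  # moment-based starting rate: sd = pi / (lam * sqrt(6))
  lam0 <- pi / (stats::sd(x) * sqrt(6))
  sol <- stats::uniroot(profile, lower = lam0 / 8, upper = lam0 * 8,
                        extendInt = "downX", tol = tol)
  lam <- sol$root
  mu <- min(x) - log(mean(exp(-lam * x0))) / lam
  gumbel_params(mu, lam)
}

#' Karlin-Altschul scoring model for HSP significance
#'
#' Holds the precomputed Gumbel parameters `K` (prefactor) and `lam` (rate)
#' together with the search geometry: query length `n`, single-subject length
#' `l`, total database length `L` and database sequence count `N`.  `K` and
#' `lam` are always caller-supplied; the package ships no parameter tables
#' (the studentized approach exists precisely to avoid them).
#'
#' @param K Dimensionless Gumbel prefactor, > 0.
#' @param lam Rate, > 0.
#' @param n Query length in residues.
#' @param l Length of a single subject sequence (optional).
#' @param L Total database length (optional; defaults to `l`).
#' @param N Number of database sequences (optional).
#' @return An object of class `"hsp_model"`.
#' @export
hsp_model <- function(K, lam, n, l = NULL, L = NULL, N = NULL) {
  stopifnot(K > 0, lam > 0, n >= 1, n == as.integer(n))
  if (is.null(L)) L <- l
  for (len in list(l, L, N)) {
    if (!is.null(len)) stopifnot(len >= 1, len == as.integer(len))
  }
  if (!is.null(l) && !is.null(L) && L < l) stop("total database length L must be >= l")
  structure(list(K = K, lam = lam, n = as.integer(n),
                 l = if (is.null(l)) NULL else as.integer(l),
                 L = if (is.null(L)) NULL else as.numeric(L),
                 N = if (is.null(N)) NULL else as.integer(N)),
            class = "hsp_model")
}

#' Classical Gumbel HSP P-value
#'
#' Probability that a random query of length `n` attains an optimal local
#' alignment of score at least `s` against a single random subject of length
#' `l`: \eqn{1 - \exp(-K n l e^{-\lambda s})}.  The uncorrected `n*l` form is
#' used; BLAST's finite-size edge-effect length adjustment is deliberately
#' not reproduced.
#'
#' @param s Raw alignment score(s).
#' @param model An [hsp_model()] with `n` and `l` set.
#' @return P-values in (0, 1), decreasing in `s`.
#' @export
hsp_pvalue <- function(s, model) {
  stopifnot(inherits(model, "hsp_model"))
  if (is.null(model$l)) stop("hsp_pvalue needs a single-subject length 'l'")
  -expm1(-model$K * model$n * model$l * exp(-model$lam * s))
}

#' Classical Gumbel HSP E-value
#'
#' Expected number of HSPs scoring at least `s`.  With `scope = "sequence"`
#' this is the per-subject Poisson mean \eqn{K n l e^{-\lambda s}}; with
#' `scope = "database"` the lengths add, giving \eqn{K n L e^{-\lambda s}}
#' with `L` the total database length.
#'
#' @inheritParams hsp_pvalue
#' @param scope `"database"` (default) or `"sequence"`.
#' @return Expected counts, >= the corresponding P-value.
#' @export
hsp_evalue <- function(s, model, scope = c("database", "sequence")) {
  stopifnot(inherits(model, "hsp_model"))
  scope <- match.arg(scope)
  len <- if (scope == "database") model$L else model$l
  if (is.null(len)) stop(sprintf("hsp_model lacks the length needed for scope '%s'", scope))
  model$K * model$n * len * exp(-model$lam * s)
}

#' Location of the maximum of independent Gumbel variables
#'
#' For independent Gumbel(\eqn{\mu_i}, \eqn{\lambda}) variables sharing a
#' rate, the maximum is again Gumbel with the same rate and location
#' \eqn{\nu = \log(\sum_i e^{\lambda \mu_i}) / \lambda} (max-stability).
#' Computed in log space so large \eqn{\lambda \mu_i} do not overflow.
#'
#' @param locations Numeric vector of locations (at least one).
#' @param lam Common rate, > 0.
#' @return The location `nu` of the maximum; always >= `max(locations)`.
#' @export
max_gumbel_location <- function(locations, lam) {
  if (length(locations) == 0L) stop("'locations' must be non-empty")
  stopifnot(all(is.finite(locations)), lam > 0)
  z <- lam * locations
  zmax <- max(z)
  (zmax + log(sum(exp(z - zmax)))) / lam
}

# Evaluate 'code' under a temporary RNG state seeded with 'seed', restoring
# the caller's state on exit; with seed = NULL the global stream is used.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic derivation of per-replicate seeds from a master seed, kept
# within 32-bit integer range.  Recorded in outputs so runs are replayable.
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  as.integer((as.numeric(master) + 48271 * as.numeric(seq_len(n))) %% 2147483647)
}
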