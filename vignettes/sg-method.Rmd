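---
title: "Studentized-Gumbel significance for local alignment search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Studentized-Gumbel significance for local alignment search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A protein database search reports optimal local alignments (high-scoring
segment pairs) between a query and each database sequence, and the user needs
to know which of those scores could plausibly have arisen by chance.  The
classical answer is the Karlin–Altschul E-value: under an iid-residue null the
score of the optimal local alignment between two random sequences is
approximately Gumbel,

$$F(x) = \exp\!\left(-e^{-\lambda (x - \mu)}\right),$$

so the per-subject P-value of a score $s$ is approximately
$1 - \exp(-K n l e^{-\lambda s})$ and the database-wide E-value is
$K n L e^{-\lambda s}$, with $n$ the query length, $l$ the subject length, $L$
the total database length, and $K, \lambda$ constants precomputed per
substitution matrix and gap-penalty pair.  This construction has two practical
weaknesses: it only works for the matrix/penalty combinations whose constants
have been precomputed, and the plug-in constants can make the reported
significance either conservative or — worse — liberal, depending on query
length, matrix and database.

`sgumbel` implements an alternative that drops the precomputed constants
entirely.  Let $S$ be the maximal alignment score of the query across the
whole database.  Shuffle the query $m$ times (we use the canonical $m = 50$),
search each shuffle identically, and record the $m$ maximal scores
$Y_1, \dots, Y_m$ — a small sample from the exact null of interest.
Studentize:

$$T = \frac{S - \bar Y}{\sigma_Y},$$

with $\sigma_Y$ the sample SD ($m-1$ denominator).  If $S$ and the $Y_j$ are
iid Gumbel — a reasonable approximation, because a maximum of independent
Gumbel variables with common rate is again Gumbel with the same rate — then
the distribution of $T$ does not depend on $(\mu, \lambda)$ at all.  It is a
pivotal law indexed only by $m$, the *Studentized-Gumbel(m)* distribution,
exactly analogous to the two-sample $t$ statistic: under a *normal* null the
same $T$ satisfies $T/\sqrt{1 + 1/m} \sim t_{m-1}$.  SG$_m$ has no closed
form, so the package tabulates its right tail once by Monte Carlo and then
assigns each observed score the tabulated tail probability of its studentized
value.  Reporting every alignment with $p \le \alpha$ controls the
family-wise error rate at $\alpha$: all of a query's hits are studentized
against the same null sample, so some hit is reported iff the database-wide
maximum is, and the maximum's P-value is valid by construction.

## Tabulating the SG$_m$ tail

`build_sg_table()` estimates $G(t) = P(T \ge t)$ on bins of width 0.001 over
$[0, 45)$.  Interesting observations always have $T > 0$ (a best score below
the null mean is not a discovery), and the upper limit is far beyond any
trustworthy estimate, so the range loses nothing.  Draws of $Y_1..Y_m$ come
from Gumbel(0, scale 3); $S$ is *not* drawn from the same law — that would
almost never produce large $T$ — but from the location-shifted,
scale-inflated proposal Gumbel(33, scale 15), and each draw contributes its
likelihood ratio $w(s) = f_{G(0,1/3)}(s) / f_{G(33,1/15)}(s)$ (importance
sampling) to the bin containing its studentized value.  The tail at a bin is
the summed weight of that bin and all higher bins over $N$.

Numerical conventions, chosen once and recorded in the table metadata:

* **Bins** are half-open `[edge, edge + width)`; a value maps to bin
  `floor((t - t_min)/width) + 1`, and bins are labelled by their centers.
* **SD** uses the $m-1$ denominator, matching the two-sample-$t$ analogy.
* **Lookup** is a step function at bin resolution (no interpolation); at
  width 0.001 the induced error is far below Monte-Carlo error and the
  behavior is exactly reproducible.  $T \le 0$ returns 1; $T$ beyond the
  precision cutoff returns the tail at the cutoff (an upper bound for such
  values, and those alignments are overwhelming discoveries anyway).
* **Chunked generation**: draws are produced in fixed-size chunks whose seeds
  derive deterministically from the master seed, so a table is reproducible
  at bounded memory for any $N$; the chunk size is part of the metadata.

### The precision cutoff

Far enough into the tail the estimate runs out of effective samples, so the
builder reports the largest bin at which the estimate is still trustworthy:
the largest $t$ whose precision ratio is at or below 0.01.  Two readings of
"coefficient of variation of the tail weights" are implemented:

* `standard_error` (default): the relative standard error of the
  importance-sampling estimator — the SD of the per-draw tail contributions,
  zeros included, divided by $\sqrt N \, G(t)$.  This is the coefficient of
  variation *of the estimate* $\hat G(t)$; it grows into the tail and crosses
  any small threshold at a finite $t$, which yields a meaningful trust
  region.
* `tail_weights`: the sample SD of the nonzero tail weights divided by
  $G(t)$.  Because importance weights span many orders of magnitude, this
  ratio exceeds 1 in every bin at any realistic $N$ and can never meet a
  threshold like 0.01; it is retained only for sensitivity analysis.

The reference construction of the SG$_{50}$ table at $N = 10^{10}$ places
this cutoff at 34.599, truncated in practice to 34, where
$G(34) = 8.716 \times 10^{-15}$; every studentized value beyond the cutoff is
assigned that tail.  A desk-scale table at $N = 10^{7}$ (the default used by
the acceptance script and tests, ~40 s on one core) reproduces $G(34)$ itself
to within Monte-Carlo error of roughly ±15–50%, but its *cutoff* sits near
$t \approx 18$, since the trust region scales with $N$; the $10^{10}$-draw
cutoff is therefore documented here rather than recomputed.  Users who need
the deep tail can run `inst/scripts/sg-table-build.R` with a larger
`--n-draws` (the builder's cost is linear in $N$).

One caveat at the *low* end: near $t = 0$ the proposal rarely produces small
scores, so the heavy-tailed weights make the IS estimate there noisier than a
plain Monte-Carlo of the same size (a few percent relative error at
$N = 10^{6}$, against <1% for $t \in [1, 4]$).  This is immaterial in
practice — P-values near 0.4 decide nothing — and the plain-MC cross-check in
the test suite bounds the discrepancy.

## From scores to P-values

`collect_null_sample()` shuffles the query with Fisher–Yates permutations
(per-shuffle seeds derived from a recorded master seed) and scores each
shuffle with *exactly* the engine configuration of the original search.  One
null sample per (query, database, engine settings) is shared by all of that
query's hits.  `sg_p()` studentizes raw integer alignment scores — not bit
scores; by the exact affine invariance of studentization the P-value would be
identical either way, and raw scores avoid rounding differences.  A
degenerate null sample ($\sigma_Y = 0$, e.g. a homopolymeric query whose
shuffles are all identical) is resolved by the limits of $T$ as
$\sigma_Y \to 0$: scores at or below $\bar Y$ get $p = 1$, scores above it
get the cutoff tail, with a warning.

For searches of many queries the per-query FWER guarantee can be relaxed to
FDR control with `by_adjust()`, the Benjamini–Yekutieli step-up procedure,
valid under the arbitrary dependence that alignment P-values exhibit.

## The validity harness

`simulate_null_scores()` + `sg_calibration()` reproduce the calibration
experiment design: search $N_s$ independent shuffles of a query, so that
every maximal score is a genuine null draw, then assign each replicate an SG
P-value.  The auxiliary null sample for each replicate is drawn with
replacement from the pooled $N_s$ maxima — the pool *is* the null
distribution, so resampling it is both faithful and ~$m$ times cheaper than
re-searching.  Valid P-values must satisfy
$P(p \le \alpha) \le \alpha$; the harness reports the empirical exceedance
frequency at $\alpha \in \{0.05, 0.01, 10^{-3}, 10^{-4}, 10^{-5}, 10^{-6}\}$
and, whenever a frequency lands above its $\alpha$ (the liberal direction), a
one-sided binomial P-value.  `probability_plot_data()` provides the log-log
empirical-vs-nominal coordinates (ties counted with the $\le$ convention);
the plotting layer is separated from the data computation so the statistics
are testable headlessly.

The same harness computes the plug-in alternative: fit a Gumbel to the
null sample by maximum likelihood (`fit_gumbel_mle()`: the profiled rate
equation solved by bracketed root finding to $10^{-10}$, then the location in
closed form) and read the tail of the fitted law.  These "MLE P-values" are
*not* valid — with $m = 50$ the estimation noise inflates the far tail — and
the package keeps them purely as a diagnostic; the test suite demonstrates
the ordering (MLE liberal at $\alpha = 10^{-3}$, SG not) on shared data.

## Study conditions used by the tests and acceptance script

All sizes were fixed in advance as desk-scale renditions of the reference
experiments, and are recorded here as the package's own choices:

* SG table: $m = 50$, $N = 10^{7}$ (tests and acceptance script), default
  generator/proposal parameters above.
* Calibration: 200 iid subjects with lengths uniform on 50–400, a length-90
  iid query, BLOSUM62 with gap open 11 / extend 1, $N_s = 10^{4}$ shuffles;
  validity asserted at $\alpha \in \{0.05, 0.01, 10^{-3}\}$ within
  $3\sqrt{\alpha(1-\alpha)/N_s}$.
* FWER: $10^{4}$ full-null replicates, each searching a freshly shuffled
  length-40 iid query against 30 iid subjects of length 60 with its own
  $m = 50$ null sample.
* Oracle checks: Smith–Waterman vs exhaustive enumeration on 500 random
  pairs of length ≤ 8 (an enumeration over ordered matched-pair subsets,
  valid because strictly positive gap penalties force optimal local
  alignments to start and end on aligned columns); importance sampling vs
  plain Monte Carlo on $t \in [0, 4]$ at matched $N = 10^{6}$;
  max-stability and MLE-recovery simulations at $10^{5}$.

Amino-acid composition for all synthetic sequences defaults to the
Robinson–Robinson marginal frequencies (the classical database-wide
composition, also used by BLAST's internal statistics); any 20-row
residue/probability TSV can be substituted via `read_freq_table()`.

## What the synthetic generators do and do not emulate

The generators produce iid residue sequences and iid Gumbel/normal score
samples.  They deliberately do not model compositional bias, low-complexity
regions, repeats, or homologous structure — the features that make real
databases deviate from the Karlin–Altschul null.  Passing the calibration
suite on synthetic data therefore shows that the SG machinery is valid *when
the Gumbel null approximately holds* and that its implementation is correct;
it does not by itself certify behavior on queries with strong compositional
bias, where the score of a shuffled query preserves composition but real
evolutionary signal does not.  (Composition-preserving k-let shuffles are out
of scope.)  For short queries the Gumbel approximation itself degrades; the
empirical effect is a *conservative* bias of the SG P-values — the direction
that preserves validity — which the calibration harness makes visible via
its probability plots.

## Known limitations

* The built-in engine is a rigorous-score Smith–Waterman without heuristic
  seeding; it exists so the statistical pipeline is self-contained and
  testable, not to compete with blastp on speed.  The `run_blastp()` adapter
  (pinned tabular format `qseqid sseqid score evalue`) plugs an external
  blastp in as the score engine.
* No edge-effect length correction and no compositional adjustment are
  applied in the classical E-value formulas implemented for comparison;
  `hsp_pvalue()`/`hsp_evalue()` are the uncorrected $n l$ forms and `K`,
  $\lambda$ are always caller-supplied.
* An SG table is valid only for the $m$ it was built with; the reader
  enforces this.
* The whole approach costs a factor of $m + 1$ searches per query.
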