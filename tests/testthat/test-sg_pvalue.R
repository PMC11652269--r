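test_that("shuffling preserves composition and is uniform over arrangements", {
  s <- "ACDEF"
  sh <- shuffle_query(s, seed = 3)
  expect_identical(sort(strsplit(sh, "")[[1]]), sort(strsplit(s, "")[[1]]))
  expect_identical(shuffle_query("W", seed = 1), "W")
  expect_identical(shuffle_query(s, seed = 5), shuffle_query(s, seed = 5))
  expect_error(shuffle_query(""), "non-empty")
  # all 12 distinct arrangements of AACD appear with frequency 1/12
  set.seed(17)
  draws <- replicate(12000, shuffle_query("AACD"))
  freq <- table(draws)
  expect_length(freq, 12)
  se <- sqrt((1 / 12) * (11 / 12) / 12000)
  expect_true(all(abs(freq / 12000 - 1 / 12) < 4 * se))
})

test_that("collect_null_sample is deterministic and records metadata", {
  sch <- blosum62_scheme()
  db <- generate_database(3, length_range = c(30, 60), seed = 2)
  q <- generate_iid_sequence(40, seed = 1)
  ns1 <- collect_null_sample(q, db, sch, m = 2, seed = 9)
  ns2 <- collect_null_sample(q, db, sch, m = 2, seed = 9)
  expect_identical(ns1$scores, ns2$scores)
  expect_identical(ns1$m, 2L)
  expect_equal(ns1$ybar, mean(ns1$scores))
  expect_equal(ns1$sy, stats::sd(ns1$scores))
  # homopolymer query: every shuffle identical, SD exactly 0
  ns_h <- collect_null_sample(strrep("A", 30), db, sch, m = 5, seed = 4)
  expect_identical(stats::sd(ns_h$scores), 0)
  # a database containing the query itself dominates its shuffles
  q2 <- generate_iid_sequence(60, seed = 12)
  res <- search_database(q2, c(db, self = q2), sch)
  ns_q <- collect_null_sample(q2, c(db, self = q2), sch, m = 10, seed = 13)
  expect_gte(res$max_score, max(ns_q$scores))
  # custom engine functions are supported and errors carry the shuffle index
  expect_error(collect_null_sample(q, NULL, function(qs) stop("boom"),
                                   m = 3, seed = 2),
               "shuffle 1 of 3")
})

test_that("sg_p studentizes, floors at 1, caps at the cutoff and is monotone", {
  tb <- sg_table_medium()
  # null sample with mean exactly 2 and SD exactly 1 (m = 50 to match the table)
  ns <- null_sample(2 + as.numeric(scale(1:50)))
  expect_equal(ns$ybar, 2)
  expect_equal(ns$sy, 1)
  # S at the null mean: T = 0 -> P = 1
  expect_equal(sg_p(2, ns, tb), 1)
  expect_equal(sg_p(-5, ns, tb), 1)
  # S = 5: T = 3 exactly; the P-value is the tabulated bin at t = 3
  bin3 <- floor((3 - tb$t_min) / tb$bin_width) + 1
  expect_equal(sg_p(5, ns, tb), 10^tb$log10_tail[bin3])
  # and that tabulated value matches the plain-MC oracle
  expect_equal(sg_p(5, ns, tb),
               sg_tail_plain_mc(3, m = 50, n = 2e5, seed = 83),
               tolerance = 0.06)
  # beyond the precision cutoff: capped at the cutoff tail
  s_huge <- ns$ybar + (tb$precision_cutoff + 2) * ns$sy
  expect_equal(sg_p(s_huge, ns, tb), tb$tail_at_cutoff)
  # monotone non-increasing in S
  svals <- seq(0, 40, by = 0.5)
  expect_true(all(diff(sg_p(svals, ns, tb)) <= 0))
})

test_that("sg_p is invariant under affine transforms of scores and null sample", {
  tb <- sg_table_medium()
  set.seed(41)
  y <- rnorm(50, 20, 4)
  s <- c(15, 25, 31.7, 40)
  a <- 3.7; b <- -12
  p1 <- sg_p(s, null_sample(y), tb)
  p2 <- sg_p(a * s + b, null_sample(a * y + b), tb)
  expect_equal(p1, p2)
})

test_that("sg_p handles degenerate null samples and m mismatches", {
  tb <- sg_table_medium()
  ns0 <- null_sample(rep(7, 50))
  expect_identical(ns0$sy, 0)
  expect_equal(sg_p(c(7, 3), ns0, tb), c(1, 1))
  expect_warning(p <- sg_p(8, ns0, tb), "degenerate")
  expect_equal(p, tb$tail_at_cutoff)
  ns20 <- null_sample(rnorm(20))
  expect_error(sg_p(1, ns20, tb), "m = 20.*m = 50")
})

test_that("fwer_select flags exactly the hits at or below alpha", {
  tb <- sg_table_medium()
  ns <- null_sample(c(10, 12, 14, 11, 13))
  expect_error(null_sample(5), "at least 2")
  hits <- data.frame(query = "q", subject = c("a", "b", "c"),
                     score = c(60, 13, 5))
  # m mismatch guard first: use a table-compatible null sample
  ns50 <- null_sample(10 + 2 * stats::qnorm(seq(0.02, 0.98, length.out = 50)))
  out <- fwer_select(hits, ns50, tb, alpha = 0.05)
  expect_identical(out$significant, out$sg_pvalue <= 0.05)
  expect_true(out$significant[1])   # huge score
  expect_false(out$significant[3])  # score below the null mean
  expect_error(fwer_select(hits, ns50, tb, alpha = 1.2), "alpha")
  # all P-values above alpha -> nothing flagged
  calm <- data.frame(score = c(5, 8))
  expect_false(any(fwer_select(calm, ns50, tb, alpha = 0.05)$significant))
})

test_that("Benjamini-Yekutieli adjustment matches hand computation", {
  expect_identical(by_adjust(numeric(0)), numeric(0))
  expect_equal(by_adjust(0.2), 0.2)
  p <- c(0.01, 0.02, 0.03)
  h3 <- 1 + 1 / 2 + 1 / 3
  # step-up: p_(i) * n * H(n) / i, then cumulative minimum from the top
  raw <- p * 3 * h3 / seq_len(3)
  expected <- rev(cummin(rev(pmin(raw, 1))))
  expect_equal(by_adjust(p), expected)
  expect_equal(by_adjust(rep(1, 4)), rep(1, 4))
  expect_error(by_adjust(c(0.1, 0)), "\\(0, 1\\]")
})

test_that("SG P-values are valid for Gumbel score nulls", {
  tb <- sg_table_medium()
  Tv <- studentized_sample(2e4, 50,
                           function(k) sample_gumbel(k, gumbel_params(4, 1 / 2)),
                           seed = 29)
  pv <- sg_tail_lookup(tb, Tv)
  for (alpha in c(0.05, 0.01)) {
    se <- sqrt(alpha * (1 - alpha) / length(pv))
    expect_lte(mean(pv <= alpha), alpha + 3 * se)
  }
})

test_that("sg_search ties the pipeline together deterministically", {
  sch <- blosum62_scheme()
  tb <- sg_table_medium()
  db <- generate_database(12, length_range = c(40, 120), seed = 6)
  q <- c(myquery = generate_iid_sequence(55, seed = 7))
  res <- sg_search(q, db, sch, tb, m = 50, alpha = 0.05, seed = 15)
  expect_s3_class(res, "sg_hits")
  expect_identical(nrow(res$hits), 12L)
  expect_true(all(res$hits$sg_pvalue > 0 & res$hits$sg_pvalue <= 1))
  res2 <- sg_search(q, db, sch, tb, m = 50, alpha = 0.05, seed = 15)
  expect_identical(res$hits$sg_pvalue, res2$hits$sg_pvalue)
  # a random query against unrelated random sequences should not be flagged
  expect_lte(sum(res$hits$significant), 1)
})
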