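test_that("importance weights are the Gumbel likelihood ratio", {
  tgt <- gumbel_params(0, 1 / 3)
  prop <- gumbel_params(33, 1 / 15)
  # identical target and proposal: weight 1 everywhere
  s <- seq(-10, 60, length.out = 25)
  expect_equal(importance_weight(s, tgt, tgt), rep(1, length(s)))
  # where the density curves cross, the ratio is 1
  cross <- stats::uniroot(function(x) gumbel_density(x, tgt, log = TRUE) -
                            gumbel_density(x, prop, log = TRUE),
                          c(5, 30), tol = 1e-12)$root
  expect_equal(importance_weight(cross, tgt, prop), 1, tolerance = 1e-6)
  # frozen 40-digit reference at s = 33 (denominator (1/15) e^-1)
  expect_equal(gumbel_density(33, prop), (1 / 15) * exp(-1))
  expect_equal(importance_weight(33, tgt, prop),
               2.269958575638705393371452088097e-4, tolerance = 1e-12)
})

test_that("config validation catches bad geometry and draw counts", {
  expect_error(sg_table_config(n_draws = 100), "refusing")
  expect_error(sg_table_config(n_draws = 1e4, bin_width = 0.3, t_min = 0, t_max = 1),
               "integer number of bins")
  expect_error(sg_table_config(m = 1, n_draws = 1e4), "m >= 2")
})

test_that("a built table is reproducible, monotone and internally consistent", {
  cfg <- sg_table_config(n_draws = 2e5, seed = 7, chunk_size = 5e4)
  tb <- build_sg_table(cfg)
  tb2 <- build_sg_table(cfg)
  expect_identical(tb$log10_tail, tb2$log10_tail)
  expect_identical(tb$precision_cutoff, tb2$precision_cutoff)
  # right tail is non-increasing across bins
  lt <- tb$log10_tail[is.finite(tb$log10_tail)]
  expect_true(all(diff(lt) <= 0))
  # 0 < G <= 1 up to the cutoff
  upto <- tb$bin_centers <= tb$precision_cutoff
  expect_true(all(tb$log10_tail[upto] <= 0))
  expect_true(all(is.finite(tb$log10_tail[upto])))
  expect_gte(tb$precision_cutoff, tb$t_min)
  expect_lte(tb$precision_cutoff, tb$t_max)
})

test_that("IS tabulation agrees with plain Monte-Carlo where both apply", {
  tb <- sg_table_medium()
  t_grid <- c(0.5, 1, 2, 3)
  plain <- sg_tail_plain_mc(t_grid, m = 50, n = 2e5, seed = 81)
  is_est <- sg_tail_lookup(tb, t_grid + tb$bin_width / 2)
  expect_equal(is_est, plain, tolerance = 0.06)
})

test_that("total tabulated mass matches the plain-MC bin-range probability", {
  tb <- sg_table_medium()
  mass_is <- 10^tb$log10_tail[1]   # G at the lowest bin = all weight / N
  p <- sg_tail_plain_mc(c(tb$t_min, tb$t_max), m = 50, n = 2e5, seed = 82)
  p_range <- p[1] - p[2]
  expect_equal(mass_is, p_range, tolerance = 0.06)
})

test_that("the SG law is pivotal: generator parameters do not move the table", {
  # affine map x -> a x + b with a = (1/2)/3, b = 7 sends Gumbel(0, scale 3)
  # to Gumbel(7, scale 1/2); the proposal transforms with the same map
  a <- (1 / 2) / 3; b <- 7
  cfg1 <- sg_table_config(n_draws = 4e5, seed = 19, chunk_size = 1e5)
  cfg2 <- sg_table_config(n_draws = 4e5, seed = 23, chunk_size = 1e5,
                          y_params = gumbel_params(7, 2),
                          proposal_params = gumbel_params(33 * a + b, (1 / 15) / a))
  t1 <- build_sg_table(cfg1)
  t2 <- build_sg_table(cfg2)
  t_grid <- c(0.5, 1, 1.5, 2, 2.5, 3)
  g1 <- sg_tail_lookup(t1, t_grid)
  g2 <- sg_tail_lookup(t2, t_grid)
  expect_equal(g1, g2, tolerance = 0.05)
})

test_that("precision cutoff reproduces hand-computed toy cases", {
  # three bins with weights {1,1}, {1,3}, {2}; choose G so that by hand:
  # bin 3 tail set {2} has a single weight (no SD) -> ineligible;
  # bin 2 tail set {1,3,2}: sd = 1;        CV = 1 / G2
  # bin 1 tail set {1,1,1,3,2}: sd = sqrt(0.8); CV = sqrt(0.8) / G1
  w <- list(c(1, 1), c(1, 3), 2)
  centers <- c(0.5, 1.5, 2.5)
  # G chosen so only bin 1 qualifies at threshold 0.5: CV1 = 0.894/2 = 0.447,
  # CV2 = 1/1.5 = 0.667
  expect_equal(precision_cutoff(w, tail = c(2, 1.5, 0.5), cv_threshold = 0.5,
                                bin_centers = centers), 0.5)
  # threshold 0.7 admits bin 2 as well; largest qualifying bin wins
  expect_equal(precision_cutoff(w, tail = c(2, 1.5, 0.5), cv_threshold = 0.7,
                                bin_centers = centers), 1.5)
  # nothing qualifies -> t_min
  expect_equal(precision_cutoff(w, tail = c(2, 1.5, 0.5), cv_threshold = 0.1,
                                bin_centers = centers), 0.5)
  # identical weights everywhere: SD = 0, every bin qualifies -> top bin
  w0 <- list(c(2, 2), c(2, 2), c(2, 2))
  expect_equal(precision_cutoff(w0, tail = c(3, 2, 1), cv_threshold = 0.01,
                                bin_centers = centers), 2.5)
  # fewer than 2 tail weights everywhere -> t_min with a warning
  expect_warning(
    out <- precision_cutoff(list(numeric(0), 5), tail = c(1, 1),
                            cv_threshold = 0.5, bin_centers = c(1, 2)),
    "fewer than 2")
  expect_equal(out, 1)
})

test_that("explicit-weights cutoff agrees with the builder's cumulative form", {
  set.seed(55)
  nb <- 40
  wsets <- lapply(seq_len(nb), function(b)
    stats::rexp(rpois(1, 30), rate = b))  # dispersion grows down the list
  N <- 5000
  tailw <- rev(cumsum(rev(vapply(wsets, sum, numeric(1))))) / N
  centers <- seq_len(nb)
  ref <- precision_cutoff(wsets, tailw, cv_threshold = 0.05,
                          bin_centers = centers, n_draws = N,
                          cv_method = "standard_error")
  # cumulative-form CV as used in build_sg_table
  tw <- rev(cumsum(rev(vapply(wsets, sum, numeric(1)))))
  tw2 <- rev(cumsum(rev(vapply(wsets, function(w) sum(w^2), numeric(1)))))
  tn <- rev(cumsum(rev(lengths(wsets))))
  cv <- sgumbel:::tail_cv(tw, tw2, tn, N, "standard_error")
  ok <- which(is.finite(cv) & cv <= 0.05 & tw > 0)
  expect_equal(ref, centers[max(ok)])
})

test_that("table save/load round trips bit-identically and validates input", {
  tb <- build_sg_table(sg_table_config(n_draws = 5e4, seed = 3, chunk_size = 2.5e4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sg_table(tb, path)
  tb2 <- read_sg_table(path)
  for (f in setdiff(names(tb), c("y_params", "proposal_params")))
    expect_identical(tb2[[f]], tb[[f]], label = f)
  expect_identical(unclass(tb2$y_params), unclass(tb$y_params))
  expect_identical(unclass(tb2$proposal_params), unclass(tb$proposal_params))
  # m mismatch is a distinct, explicit error
  expect_error(read_sg_table(path, m = 20), "m = 50.*m = 20")
  # corrupted header names the offending line
  lines <- readLines(path)
  lines[3] <- "# broken header line with no tab"
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, bad)
  expect_error(read_sg_table(bad), "header at line 3")
  # version mismatch
  lines2 <- readLines(path)
  lines2[1] <- "# format_version\t99"
  bad2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines2, bad2)
  expect_error(read_sg_table(bad2), "format version")
})

test_that("lookup maps studentized values to bins, floors and the cutoff cap", {
  tb <- sg_table_medium()
  expect_equal(sg_tail_lookup(tb, c(-3, 0)), c(1, 1))
  t_in <- 2.3456
  bin <- floor((t_in - tb$t_min) / tb$bin_width) + 1
  expect_equal(sg_tail_lookup(tb, t_in), 10^tb$log10_tail[bin])
  expect_equal(sg_tail_lookup(tb, tb$precision_cutoff + 5), tb$tail_at_cutoff)
  tt <- seq(-1, 12, by = 0.25)
  expect_true(all(diff(sg_tail_lookup(tb, tt)) <= 0))
})

test_that("studentization machinery under normal draws gives Student's t", {
  m <- 50
  Tv <- studentized_sample(2e4, m, function(k) stats::rnorm(k, 3, 2), seed = 61)
  ks <- stats::ks.test(Tv / sqrt(1 + 1 / m), stats::pt, df = m - 1)
  expect_gt(ks$p.value, 0.01)
})
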