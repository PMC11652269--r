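# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache, inherits = FALSE)
}

blosum62_scheme <- function(gap_open = 11L, gap_extend = 1L) {
  mat <- cached("blosum62", read_matrix(
    system.file("extdata", "BLOSUM62", package = "sgumbel")))
  scoring_scheme(mat, gap_open, gap_extend)
}

# Reference SG_50 tables.  The large one backs the tail-reproduction and
# calibration checks; the medium one backs distribution-level unit tests.
sg_table_large <- function() cached("table_1e7",
  build_sg_table(sg_table_config(n_draws = 1e7, seed = 101)))

sg_table_medium <- function() cached("table_1e6",
  build_sg_table(sg_table_config(n_draws = 1e6, seed = 11)))

# Synthetic iid study database and query for the calibration experiments:
# 200 sequences with lengths 50-400 and a length-90 query.
calibration_database <- function() cached("calib_db",
  generate_database(200, length_range = c(50, 400), seed = 42))

calibration_query <- function() cached("calib_query",
  generate_iid_sequence(90, seed = 43))
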