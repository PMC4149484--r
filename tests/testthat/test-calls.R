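test_that("call_state reproduces the allele-fraction truth table", {
  # spot checks straight from the calling rule
  expect_identical(call_state(0, 2), "1")    # 2 >= 2x and 2/2 >= 3/4
  expect_identical(call_state(5, 0), "0")
  expect_identical(call_state(0, 0), "-")
  expect_identical(call_state(1, 2), "?")    # 2/3 < 3/4 on both sides
  expect_identical(call_state(0, 1), "?")    # one alt read is never enough
  expect_identical(call_state(1, 3), "1")    # 3/4 inclusive
  expect_identical(call_state(3, 1), "0")    # 3/4 inclusive on reference side

  # brute-force re-derivation of the rule over a grid of counts
  pol <- site_filter_policy()
  for (ref in 0:6) {
    for (alt in 0:6) {
      tot <- ref + alt
      want <- if (tot == 0) "-"
      else if (alt >= pol$min_alt_reads && alt >= 3 / 4 * tot) "1"
      else if (ref >= 3 / 4 * tot) "0"
      else "?"
      expect_identical(call_state(ref, alt), want)
    }
  }
  expect_error(call_state(-1, 2), "negative")
  # total function: exactly one state per cell, vectorized
  out <- call_state(c(0, 1, 4, 0), c(3, 1, 0, 0))
  expect_identical(out, c("1", "?", "0", "-"))
})

test_that("private SNPs need four supporting reads; shared ones do not", {
  counts <- tibble::tibble(
    sample = rep(c("A", "B", "C"), times = 3),
    site = rep(sprintf("F%05d", 1:3), each = 3),
    ref_count = c(0L, 5L, 5L,  0L, 5L, 5L,  0L, 0L, 5L),
    alt_count = c(2L, 0L, 0L,  4L, 0L, 0L,  2L, 2L, 0L)
  )
  calls <- call_genotypes(counts)
  out <- calls_matrix(apply_private_filter(calls, counts))
  expect_identical(out["A", "F00001"], "?")  # singleton at 2x demoted
  expect_identical(out["A", "F00002"], "1")  # singleton at 4x retained
  expect_identical(out["A", "F00003"], "1")  # two carriers at 2x both kept
  expect_identical(out["B", "F00003"], "1")
})

test_that("the cohort coverage filter scales the >100/110 rule", {
  make_calls <- function(n_samples, n_informative, site = "F00001") {
    tibble::tibble(
      sample = sprintf("s%03d", seq_len(n_samples)),
      site = site,
      state = c(rep("1", 1), rep("0", n_informative - 1),
                rep("?", n_samples - n_informative))
    )
  }
  # 110 samples: 101 unambiguous kept, 100 dropped
  expect_equal(nrow(filter_sites(make_calls(110, 101))), 110)
  expect_equal(nrow(filter_sites(make_calls(110, 100))), 0)
  # all-ambiguous site dropped
  allq <- tibble::tibble(sample = sprintf("s%03d", 1:110), site = "F00001",
                         state = "?")
  expect_equal(nrow(filter_sites(allq)), 0)
  # 55 samples: threshold scales to >50
  expect_equal(nrow(filter_sites(make_calls(55, 51))), 55)
  expect_equal(nrow(filter_sites(make_calls(55, 50))), 0)
  # monomorphic sites are dropped for tree building unless asked otherwise
  mono <- tibble::tibble(sample = sprintf("s%03d", 1:110), site = "F00001",
                         state = "0")
  expect_equal(nrow(filter_sites(mono)), 0)
  expect_equal(nrow(filter_sites(mono, drop_monomorphic = FALSE)), 110)
})

test_that("sample quality tiers follow mean targeted coverage", {
  expect_identical(quality_tier(c(6.5, 6, 1.4, 1, 0.9, 0)),
                   c("good", "moderate", "moderate", "moderate", "low", "low"))
  counts <- tibble::tibble(
    sample = rep(c("A", "B"), each = 2),
    site = rep(sprintf("F%05d", 1:2), times = 2),
    ref_count = c(7L, 7L, 0L, 1L), alt_count = c(0L, 0L, 1L, 0L)
  )
  sq <- sample_quality(counts)
  expect_identical(sq$tier, c("good", "moderate"))
})

test_that("curation marks fold to analyzable states", {
  calls <- tibble::tibble(sample = c("A", "B", "C"), site = "F00001",
                          state = c("x", "@", "1"))
  expect_identical(normalize_curation_states(calls)$state, c("0", "1", "1"))
})

test_that("error-free calls are correct at any depth (monotonicity)", {
  sc <- star_scenario(6, 5400, 30000, n_background = 4)
  sim <- simulate_mutations(sc, seq_params(seed = 21))
  truth <- sim_call_matrix(sim)
  for (depth in c(2, 6, 12)) {
    p <- seq_params(depth_mean = depth, error_rate = 0, seed = 22)
    calls <- call_genotypes(simulate_reads(sim, p))
    m <- calls_matrix(calls)[rownames(truth), colnames(truth)]
    definite <- m %in% c("0", "1")
    expect_true(all(m[definite] == truth[definite]))
  }
})

test_that("at 6x coverage and 1e-3 error, under 1% of definite calls are wrong", {
  sc <- multi_star_scenario()
  sim <- simulate_mutations(sc, seq_params(seed = 31))
  truth <- sim_call_matrix(sim)
  p <- seq_params(depth_mean = 6, error_rate = 1e-3, seed = 32)
  calls <- call_genotypes(simulate_reads(sim, p))
  m <- calls_matrix(calls)[rownames(truth), colnames(truth)]
  definite <- m %in% c("0", "1")
  expect_gt(mean(definite), 0.9)
  expect_lt(mean(m[definite] != truth[definite]), 0.01)
})

test_that("call matrices round-trip through TSV and pseudo-FASTA encodes alleles", {
  m <- matrix(c("0", "1", "?", "-", "x", "@"), nrow = 2,
              dimnames = list(c("A", "B"), sprintf("F%05d", 1:3)))
  calls <- calls_from_matrix(m)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_call_matrix(calls, f, params = list(seed = 1))
  expect_equal(calls_matrix(read_call_matrix(f)), m)

  full <- calls_from_matrix(matrix(c("0", "1", "1", "0"), nrow = 2,
                                   dimnames = list(c("A", "B"),
                                                   c("F00001", "F00002"))))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_pseudo_fasta(full, fa)
  lines <- readLines(fa)
  expect_identical(lines, c(">A", "AG", ">B", "GA"))
  expect_error(write_pseudo_fasta(calls, fa), "impute")
})
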