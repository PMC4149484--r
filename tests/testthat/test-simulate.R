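test_that("scenario constructors validate ages and shapes", {
  sc <- star_scenario(10, 5400, 54100)
  expect_s3_class(sc, "ystar_scenario")
  expect_equal(sc$root_age, 54100)
  idx <- table(sc$tree$edge[, 1])
  expect_true(any(idx == 10))            # the star node is a true decafurcation

  # two lineages degenerate to a binary node
  sc2 <- star_scenario(2, 5400, 54100)
  expect_true(all(table(sc2$tree$edge[, 1]) <= 2))

  expect_error(star_scenario(10, 60000, 54100), "between")
  expect_error(star_scenario(1, 5400, 54100), "at least 2")

  sc3 <- multi_star_scenario()
  expect_length(sc3$tree$tip.label, 49)

  sc4 <- binary_scenario(20, 54100, seed = 1)
  expect_true(all(table(sc4$tree$edge[, 1]) == 2))
  expect_equal(scenario(sc4$tree)$root_age, 54100, tolerance = 1e-9)
})

test_that("mutation counts follow Poisson moments and branch durations", {
  # 10,000 branches of 2,560 years: mean and variance of per-branch counts
  # both ~10 (within 5% at this replication)
  sc <- star_scenario(1000, 2560, 100000, n_background = 4)
  term <- unlist(lapply(1:10, function(r) {
    sim <- simulate_mutations(sc, seq_params(seed = 11 + r))
    sim$edge_counts[sc$tree$edge.length == 2560]
  }))
  expect_length(term, 10000)
  expect_equal(mean(term), 10, tolerance = 0.05)
  expect_equal(var(term), 10, tolerance = 0.05)
})

test_that("a zero-duration branch never mutates and degenerate params error", {
  sc <- scenario(ape::read.tree(text = "((A:5400,B:5400):0,C:5400);"))
  zero_edge <- which(sc$tree$edge.length == 0)
  for (s in 1:5) {
    sim <- simulate_mutations(sc, seq_params(seed = s))
    expect_identical(sim$edge_counts[zero_edge], 0L)
  }
  # more expected mutations than positions
  expect_error(
    simulate_mutations(sc, seq_params(L = 5, mu = 1, seed = 1)),
    "positions"
  )
})

test_that("infinite sites holds: distinct positions, counts conserved", {
  sc <- multi_star_scenario()
  sim <- simulate_mutations(sc, seq_params(seed = 3))
  expect_false(any(duplicated(sim$sites$position)))
  expect_equal(sum(sim$edge_counts), nrow(sim$sites))
  expect_equal(sum(sim$edge_counts), ncol(sim$genotypes))
  # every site maps to exactly one branch
  expect_equal(anyDuplicated(sim$sites$site), 0L)
  # carriers of each site = tips below its branch
  g <- sim$genotypes
  expect_equal(unname(colSums(g)), vapply(sim$sites$node, function(v) {
    length(tips_under_node(sc$tree, v))
  }, 0L))
})

test_that("root-to-tip counts are clock-like across tips", {
  sc <- binary_scenario(49, 54100, seed = 5)
  sim <- simulate_mutations(sc, seq_params(seed = 6))
  counts <- branch_counts(true_genealogy(sim))
  lambda <- 1e-9 * 3.9e6 * 54100
  se <- sqrt(lambda / length(counts))
  expect_lt(abs(mean(counts) - lambda), 3 * se * sqrt(length(counts)))
  # individual tips are Poisson(lambda): variance on the right scale
  expect_gt(var(counts), 0)
})

test_that("simulation is fully deterministic under a fixed seed", {
  sc <- star_scenario(6, 5400, 30000, n_background = 4)
  p <- seq_params(depth_mean = 6, error_rate = 1e-3, seed = 99)
  s1 <- simulate_mutations(sc, p)
  s2 <- simulate_mutations(sc, p)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$genotypes, s2$genotypes)
  r1 <- simulate_reads(s1, p)
  r2 <- simulate_reads(s2, p)
  expect_identical(r1, r2)
})

test_that("read simulation matches its depth and error model", {
  g <- matrix(0L, 50, 40, dimnames = list(sprintf("s%02d", 1:50),
                                          sprintf("F%05d", 1:40)))
  # zero depth -> all cells (0,0)
  r0 <- simulate_reads(g, seq_params(depth_mean = 0, seed = 1))
  expect_true(all(r0$ref_count == 0 & r0$alt_count == 0))

  # error-free carrier: no reference reads, alt ~ Poisson(10)
  g1 <- g; g1[] <- 1L
  r1 <- simulate_reads(g1, seq_params(depth_mean = 10, error_rate = 0, seed = 2))
  expect_true(all(r1$ref_count == 0))
  expect_equal(mean(r1$alt_count), 10, tolerance = 0.05)

  # error 1e-3 on ~1e6 non-carrier reads: ~1000 spurious alternative reads
  g2 <- matrix(0L, 100, 1000, dimnames = list(sprintf("s%03d", 1:100),
                                              sprintf("F%05d", 1:1000)))
  r2 <- simulate_reads(g2, seq_params(depth_mean = 10, error_rate = 1e-3,
                                      seed = 3))
  n_reads <- sum(r2$ref_count + r2$alt_count)
  expect_equal(sum(r2$alt_count), n_reads * 1e-3, tolerance = 0.2)
})

test_that("scenario and count tables round-trip through their file formats", {
  sc <- star_scenario(5, 5400, 30000, n_background = 3)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_scenario(sc, f, params = list(seed = 1))
  sc2 <- read_scenario(f)
  expect_equal(sort(sc2$tree$tip.label), sort(sc$tree$tip.label))
  expect_equal(sc2$root_age, sc$root_age, tolerance = 1e-6)

  p <- seq_params(L = 1e5, depth_mean = 8, seed = 4)
  sim <- simulate_mutations(sc, p)
  counts <- simulate_reads(sim, p)
  g <- withr::local_tempfile(fileext = ".tsv")
  write_counts(counts, g, params = list(seed = 4))
  back <- read_counts(g)
  expect_equal(
    dplyr::arrange(back, sample, site),
    dplyr::arrange(counts, sample, site)
  )
})
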