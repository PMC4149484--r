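test_that("the rooted three-gamete check finds exactly the incompatible pairs", {
  m <- matrix("0", 3, 3, dimnames = list(c("A", "B", "C"),
                                         sprintf("F%05d", 1:3)))
  m[c("A", "B"), 1] <- "1"          # {A,B}
  m[c("A", "B", "C"), 2] <- "1"     # {A,B,C}: nested with site 1
  m[c("B", "C"), 3] <- "1"          # {B,C}: crosses {A,B}
  out <- check_compatibility(m)
  expect_identical(out$site_a, "F00001")
  expect_identical(out$site_b, "F00003")

  # one site alone is always compatible
  expect_equal(nrow(check_compatibility(m[, 1, drop = FALSE])), 0)
  # a perfect-phylogeny matrix certifies clean
  expect_equal(nrow(check_compatibility(m[, 1:2])), 0)
})

test_that("a compatible matrix yields the unique perfect phylogeny", {
  # carrier sets {A},{B},{A,B},{C},{A,B,C} on four samples -> caterpillar
  m <- matrix("0", 4, 5, dimnames = list(LETTERS[1:4], sprintf("F%05d", 1:5)))
  m["A", 1] <- "1"
  m["B", 2] <- "1"
  m[c("A", "B"), 3] <- "1"
  m["C", 4] <- "1"
  m[c("A", "B", "C"), 5] <- "1"
  gen <- build_tree(m)
  expect_identical(splits_of(gen$tree), c("A|B", "A|B|C"))
  expect_true(all(gen$tree$edge.length %in% c(0, 1)))
  expect_equal(sum(gen$tree$edge.length), 5)
  expect_equal(unname(branch_counts(gen)), c(3, 3, 2, 0))
  expect_equal(nrow(gen$conflicts), 0)
  # every site on exactly one branch
  expect_equal(sort(gen$site_map$site), sort(colnames(m)))
  expect_false(any(gen$site_map$recurrent))
})

test_that("an all-ancestral matrix gives a root polytomy with zero counts", {
  m <- matrix("0", 3, 2, dimnames = list(c("A", "B", "C"),
                                         sprintf("F%05d", 1:2)))
  gen <- build_tree(m)
  expect_equal(gen$tree$Nnode, 1)
  expect_true(all(gen$tree$edge.length == 0))
  expect_error(build_tree(m[1, , drop = FALSE]), "at least 2")
})

test_that("conflicting minority sites are demoted to recurrent and reported", {
  # {A,B} supported by two sites beats {B,C} supported by one
  m <- matrix("0", 3, 3, dimnames = list(c("A", "B", "C"),
                                         sprintf("F%05d", 1:3)))
  m[c("A", "B"), 1] <- "1"
  m[c("A", "B"), 2] <- "1"
  m[c("B", "C"), 3] <- "1"
  gen <- build_tree(m)
  expect_identical(splits_of(gen$tree), "A|B")
  expect_identical(gen$conflicts$site, "F00003")
  expect_equal(gen$conflicts$n_placements, 2L)
  rec <- gen$site_map[gen$site_map$recurrent, ]
  expect_identical(unique(rec$site), "F00003")
  expect_equal(nrow(rec), 2)          # placed on B and on C
  # recurrent counts land on the covering branches: path sums still additive
  expect_equal(unname(branch_counts(gen)), c(2, 3, 1))
})

test_that("reconstruction inverts the simulator exactly on clean data", {
  for (s in c(2, 9)) {
    scn <- multi_star_scenario()
    sim <- simulate_mutations(scn, seq_params(seed = s))
    gen <- build_tree(sim_call_matrix(sim))
    expect_equal(nrow(gen$conflicts), 0)
    # same topology once unsupported (zero-count) true branches collapse
    expect_identical(splits_of(gen$tree),
                     splits_of(true_genealogy(sim)$tree, positive_only = TRUE))
    # and identical root-to-tip counts, tip by tip
    want <- branch_counts(true_genealogy(sim))
    got <- branch_counts(gen)[names(want)]
    expect_equal(got, want)
  }
})

test_that("reconstructed parsimony length matches phangorn on the same data", {
  scn <- star_scenario(6, 5400, 30000, n_background = 4)
  sim <- simulate_mutations(scn, seq_params(seed = 13))
  m <- sim_call_matrix(sim)
  gen <- build_tree(m)
  pd <- phangorn::phyDat(m, type = "USER", levels = c("0", "1"))
  # the perfect phylogeny attains one change per segregating site
  expect_equal(
    phangorn::parsimony(ape::unroot(ape::multi2di(gen$tree)), pd,
                        method = "fitch"),
    ncol(m)
  )
  expect_equal(sum(gen$tree$edge.length), ncol(m))
})

test_that("genealogy Newick serialization re-parses identically", {
  m <- matrix("0", 4, 4, dimnames = list(LETTERS[1:4], sprintf("F%05d", 1:4)))
  m[c("A", "B"), 1] <- "1"
  m["A", 2] <- "1"
  m[c("A", "B", "C"), 3] <- "1"
  m["D", 4] <- "1"
  gen <- build_tree(m)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_genealogy(gen, f)
  back <- ape::read.tree(f)
  expect_identical(splits_of(back), splits_of(gen$tree))
  expect_equal(sum(back$edge.length), sum(gen$tree$edge.length))
  expect_true(file.exists(paste0(f, ".sites.tsv")))
  expect_true(file.exists(paste0(f, ".conflicts.tsv")))
})

test_that("root-to-tip counts are path sums and respect zero-branch collapse", {
  phy <- ape::read.tree(text = "((A:190,B:12):7,C:5);")
  gen <- genealogy(phy)
  expect_equal(unname(branch_counts(gen, c("A", "B", "C"))), c(197, 19, 5))
  expect_error(branch_counts(gen, "Z"), "unknown tip")
  # collapsing a zero-count internal branch leaves path sums unchanged
  phy2 <- ape::read.tree(text = "(((A:4,B:6):0,C:7):2,D:1);")
  gen2 <- genealogy(phy2)
  col <- collapse_short_branches(gen2, clock_model(), 1000)
  expect_equal(branch_counts(col)[names(branch_counts(gen2))],
               branch_counts(gen2))
})
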