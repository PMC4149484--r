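test_that("the default clock converts counts to years at 256.4 yr/substitution", {
  ck <- clock_model()
  expect_equal(ck$years_per_substitution, 256.4103, tolerance = 1e-4)
  expect_equal(time_point_estimate(1, ck), 256.4103, tolerance = 1e-4)
  expect_equal(time_point_estimate(0, ck), 0)
  # three substitutions separate two successive splits by under a millennium
  expect_equal(time_point_estimate(3, ck), 769.2308, tolerance = 1e-4)
  expect_lt(time_point_estimate(3, ck), 1000)
  expect_error(time_point_estimate(-1, ck), ">= 0")
  # linear in n
  n <- c(1, 10, 210)
  expect_equal(time_point_estimate(10 * n, ck), 10 * time_point_estimate(n, ck))
})

test_that("Poisson CI half-widths follow the inverse square-root law", {
  # frozen reference values: 1.96/sqrt(210) and the Garwood interval
  expect_equal(poisson_ci(210)$rel_halfwidth, 0.1352503, tolerance = 1e-5)
  expect_equal(poisson_ci(210, method = "exact")$rel_halfwidth, 0.1377358,
               tolerance = 1e-5)
  # 9 substitutions leave the interval wider than +/-60%
  expect_gt(poisson_ci(9)$rel_halfwidth, 0.60)
  expect_gt(poisson_ci(9, method = "exact")$rel_halfwidth, 0.60)
  # monotone decreasing, vanishing in the limit
  rel <- poisson_ci(c(10, 100, 1000, 1e6))$rel_halfwidth
  expect_true(all(diff(rel) < 0))
  expect_lt(rel[4], 0.002)
  # normal and exact agree within 3% relative for n >= 200
  for (n in c(200, 500, 2000)) {
    expect_equal(poisson_ci(n)$rel_halfwidth,
                 poisson_ci(n, method = "exact")$rel_halfwidth,
                 tolerance = 0.03)
  }
  expect_error(poisson_ci(210, conf = 1.2), "conf")
  expect_error(poisson_ci(0, method = "normal"), "n > 0")
  expect_equal(poisson_ci(0, method = "exact")$count_low, 0)
})

test_that("node ages divide mean descendant counts by the clock rate", {
  phy <- ape::read.tree(text = "(A:210,B:210,C:210);")
  gen <- genealogy(phy)
  a <- node_age(gen, 4)
  expect_equal(a$mean_count, 210)
  expect_equal(a$age_years, 53846.15, tolerance = 1e-4)
  # the point estimate sits inside the printed interval for that node
  expect_gt(a$age_years, 50600)
  expect_lt(a$age_years, 58200)
  expect_true(a$ci_low <= a$age_years && a$age_years <= a$ci_high)

  # zero counts date to the present
  gen0 <- genealogy(ape::read.tree(text = "(A:0,B:0);"))
  a0 <- node_age(gen0, 3)
  expect_equal(a0$age_years, 0)

  # the three interval methods bracket the same point estimate
  for (meth in c("normal", "exact", "gamma")) {
    ai <- node_age(gen, 4, method = meth)
    expect_true(ai$ci_low <= ai$age_years + 1e-9)
    expect_true(ai$ci_high >= ai$age_years - 1e-9)
  }
  expect_error(node_age(gen, 99), "unknown node")
})

test_that("date_nodes dates every internal node and carries the clock", {
  m <- matrix("0", 4, 3, dimnames = list(LETTERS[1:4], sprintf("F%05d", 1:3)))
  m[c("A", "B"), 1] <- "1"
  m[c("A", "B"), 2] <- "1"
  m[c("A", "B", "C"), 3] <- "1"
  gen <- build_tree(m)
  d <- date_nodes(gen)
  expect_s3_class(d, "clock_dating")
  expect_equal(nrow(d), gen$tree$Nnode)
  expect_true(all(d$ci_high >= d$ci_low))
  g <- glance(d)
  expect_equal(g$years_per_substitution, 256.4103, tolerance = 1e-4)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_dated_newick(gen, d, f)
  expect_match(readLines(f), "\\(", all = FALSE)
})

test_that("a planted star age is recovered without bias from true counts", {
  ests <- numeric(50)
  for (r in 1:50) {
    scn <- star_scenario(10, 5400, 54100)
    sim <- simulate_mutations(scn, seq_params(seed = 500 + r))
    gen <- true_genealogy(sim)
    deg <- table(gen$tree$edge[, 1])
    star_node <- as.integer(names(deg)[deg == 10][1])
    ests[r] <- node_age(gen, star_node)$age_years
  }
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 5400), 2 * se + 1e-9)
})

test_that("the dispersion test accepts clock-like counts and sees 2x violations", {
  # identical counts: no dispersion at all
  t0 <- clock_dispersion_test(c(210, 210, 210, 210))
  expect_equal(unname(t0$statistic), 0)
  expect_equal(t0$p.value, 1)
  expect_error(clock_dispersion_test(c(0, 0)), "zero")
  expect_error(clock_dispersion_test(210), "at least 2")

  # the observed 168-241 spread among 49 tips is what Poisson(210) produces
  set.seed(77)
  p_vals <- replicate(50, clock_dispersion_test(rpois(49, 210))$p.value)
  expect_gt(mean(p_vals > 0.05), 0.9)

  # a two-fold rate split between halves of the panel is caught
  set.seed(78)
  pow <- replicate(50, {
    clock_dispersion_test(c(rpois(24, 140), rpois(25, 280)))$p.value < 0.05
  })
  expect_gt(mean(pow), 0.8)
})

test_that("outgroup recalibration reproduces the interspecies arithmetic", {
  cal <- rate_from_outgroup(45800, 6e6, comparable_fraction = 0.75)
  expect_equal(cal$implied_rate, 3.8167e-3, tolerance = 1e-4)
  # the human-chimp rate re-dates a 210-count root to ~41 kyr, younger than
  # the within-species clock's ~54 kyr
  expect_equal(cal$redate(210), 41266.38, tolerance = 1e-4)
  expect_lt(cal$redate(210), time_point_estimate(210))

  # consistency: when the implied rate equals mu*L and everything is
  # comparable, re-dating changes nothing
  ck <- clock_model()
  n_match <- ck$mu * ck$L * 2 * 6e6
  cal2 <- rate_from_outgroup(n_match, 6e6, comparable_fraction = 1, clock = ck)
  expect_equal(cal2$age_scale, 1)
  expect_equal(cal2$redate(210), time_point_estimate(210, ck))

  expect_error(rate_from_outgroup(45800, 0), "> 0")
  td <- tidy(cal)
  expect_equal(td$age_scale, cal$age_scale)
})
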