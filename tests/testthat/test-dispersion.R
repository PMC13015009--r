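test_that("accumulated coverage is additive over multi-mapping segments", {
  expect_equal(accumulated_coverage(make_result("chrA", 1000)), 1.0)
  expect_equal(accumulated_coverage(make_result(c("chrA", "chrB"),
                                                c(1000, 1000))), 2.0)
  expect_equal(accumulated_coverage(make_result(character(0), numeric(0))), 0)
})

test_that("coverage of a simulated dispersal matches the truth ledger", {
  sim <- simulate_dispersal(dispersal_config(n_targets = 6,
                                             fragments_per_target = 5,
                                             seed = 30))
  res <- project_window(sim$chains, sim$window, sim$sizes)
  expect_true(accumulated_coverage(res) == sim$truth$accumulated_coverage)
})

test_that("burdens aggregate per qName, sorted by burden then name", {
  r <- make_result(c("chrA", "chrA", "chrB"), c(500, 300, 600))
  b <- qname_burdens(r)
  expect_equal(b$qName, c("chrA", "chrB"))
  expect_equal(b$alignedBases, c(800, 600))
  expect_equal(b$nSegments, c(2L, 1L))
  # lexicographic tie-break
  tie <- qname_burdens(make_result(c("chrZ", "chrM"), c(100, 100)))
  expect_equal(tie$qName, c("chrM", "chrZ"))
  expect_equal(nrow(qname_burdens(make_result(character(0), numeric(0)))), 0)
})

test_that("burdens equal a brute-force group-by on random dispersals", {
  sim <- simulate_dispersal(dispersal_config(n_targets = 8,
                                             fragments_per_target = 3,
                                             seed = 77))
  res <- project_window(sim$chains, sim$window, sim$sizes)
  b <- qname_burdens(res)
  seg <- res$segments
  for (i in seq_len(nrow(b))) {
    expect_equal(b$alignedBases[i],
                 sum(seg$alignedBases[seg$qName == b$qName[i]]))
  }
  expect_false(is.unsorted(rev(b$alignedBases)))
})

test_that("distinct qName counting", {
  expect_equal(distinct_qname_count(make_result(character(0), numeric(0))), 0)
  expect_equal(distinct_qname_count(
    make_result(c("chrA", "chrA", "chrB"), c(1, 2, 3))), 2)
  sim <- simulate_dispersal(dispersal_config(n_targets = 5, seed = 4))
  res <- project_window(sim$chains, sim$window, sim$sizes)
  expect_equal(distinct_qname_count(res), 5)
  expect_lte(distinct_qname_count(res), nrow(res$segments))
  expect_lte(distinct_qname_count(res), length(sim$sizes))
})

test_that("Top-K decomposition fractions are exact partition sums", {
  one <- topk_decomposition(qname_burdens(make_result("chrA", 100)))
  expect_equal(unname(one), c(1, 0, 0, 0))
  six <- topk_decomposition(qname_burdens(
    make_result(paste0("chr", 1:6), rep(100, 6))))
  expect_equal(unname(six), c(1, 2, 2, 1) / 6)
  expect_message(z <- topk_decomposition(
    qname_burdens(make_result(character(0), numeric(0)))), "empty")
  expect_equal(unname(z), c(0, 0, 0, 0))
})

test_that("Top-K fractions match brute-force sums and total 1 on random burdens", {
  withr::local_seed(19)
  for (i in 1:20) {
    n <- sample.int(12, 1)
    b <- qname_burdens(make_result(paste0("chr", seq_len(n)),
                                   sample.int(5000, n)))
    fr <- topk_decomposition(b)
    total <- sum(b$alignedBases)
    expect_equal(unname(fr[1]), sum(b$alignedBases[1]) / total)
    expect_equal(unname(fr[2]), sum(b$alignedBases[2:3], na.rm = TRUE) / total)
    expect_equal(unname(fr[3]), sum(b$alignedBases[4:5], na.rm = TRUE) / total)
    expect_equal(unname(fr[4]),
                 sum(b$alignedBases[-(1:5)][b$alignedBases[-(1:5)] > 0],
                     na.rm = TRUE) / total)
    expect_lt(abs(sum(fr) - 1), 1e-12)
  }
})

test_that("largest-block fraction agrees with a {1},{rest} decomposition", {
  b <- qname_burdens(make_result(paste0("chr", 1:3), c(600, 300, 100)))
  expect_equal(largest_block_fraction(b), 0.6)
  expect_equal(largest_block_fraction(qname_burdens(make_result("chrA", 5))), 1)
  two_group <- topk_decomposition(b, groups = list(top = 1, rest = NULL))
  expect_equal(largest_block_fraction(b), unname(two_group["top"]))
  expect_equal(largest_block_fraction(
    qname_burdens(make_result(character(0), numeric(0)))), 0)
})

test_that("top1 fraction never increases as extra positive burdens are added", {
  base <- c(1000, 400)
  for (extra in c(50, 200, 399)) {
    f1 <- largest_block_fraction(qname_burdens(
      make_result(paste0("chr", seq_along(base)), base)))
    f2 <- largest_block_fraction(qname_burdens(
      make_result(paste0("chr", seq_len(length(base) + 1)), c(base, extra))))
    expect_lte(f2, f1)
  }
})

test_that("alignment-length distributions summarize per-segment lengths", {
  d <- alignment_length_distribution(make_result(paste0("c", 1:3),
                                                 c(100, 200, 300)))
  expect_equal(d$count, 3)
  expect_equal(d$median, 200)
  e <- alignment_length_distribution(make_result(character(0), numeric(0)))
  expect_equal(e$count, 0)
  expect_length(e$lengths, 0)
})

test_that("coverage is invariant to permutation and segment splitting", {
  withr::local_seed(23)
  ab <- sample.int(500, 10)
  r <- make_result(paste0("chr", 1:10), ab)
  perm <- sample(10)
  r2 <- make_result(paste0("chr", 1:10)[perm], ab[perm])
  expect_equal(accumulated_coverage(r), accumulated_coverage(r2))
  # split the first segment into two that sum to it
  split <- c(ab[1] - 1, 1, ab[-1])
  r3 <- make_result(c("chr1", paste0("chr", 1:10)), split)
  expect_equal(accumulated_coverage(r3), accumulated_coverage(r))
})

test_that("dispersion summaries compose the statistics; empty stays zero-valued", {
  s0 <- summarize_dispersion(make_result(character(0), numeric(0)), "none")
  expect_equal(s0$accumulatedCoverage, 0)
  expect_equal(s0$nDistinctQNames, 0)
  expect_equal(unname(s0$topKFractions), c(0, 0, 0, 0))
  s1 <- summarize_dispersion(make_result("chrA", 1000), "one")
  expect_equal(s1$accumulatedCoverage, 1.0)
  expect_equal(s1$nDistinctQNames, 1)
  expect_equal(s1$top1Fraction, 1.0)
})

test_that("summaries across the six preset regimes reproduce each truth ledger", {
  presets <- dispersal_presets(seed = 12)
  summaries <- lapply(names(presets), function(nm) {
    sim <- simulate_dispersal(presets[[nm]])
    res <- project_window(sim$chains, sim$window, sim$sizes)
    s <- summarize_dispersion(res, species = nm)
    expect_true(s$accumulatedCoverage == sim$truth$accumulated_coverage)
    expect_equal(s$nDistinctQNames, sim$truth$n_distinct_qnames)
    expect_equal(s$burdens$qName, sim$truth$per_qname$qName)
    expect_equal(s$burdens$alignedBases, sim$truth$per_qname$alignedBases)
    s
  })
  tab <- dispersion_table(summaries)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$species, names(presets))
  # the regime contrast the presets encode: many-target high fragmentation
  # disperses more than few-target low fragmentation
  expect_gt(tab$nDistinctQNames[tab$species == "many_targets_high_frag"],
            tab$nDistinctQNames[tab$species == "few_targets_low_frag"])
})
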