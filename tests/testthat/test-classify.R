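test_that("pair recognition uses a strict >50% rule on either peak", {
  a <- peak_row("chr1", 100, 200, "H3K9me3")
  b <- peak_row("chr1", 140, 260, "H3K27me3")
  expect_true(pair_recognized(a, b)) # overlap 60 > 50

  b2 <- peak_row("chr1", 150, 250, "H3K27me3")
  expect_false(pair_recognized(a, b2)) # overlap 50 == 0.5*100: strict

  nested <- peak_row("chr1", 100, 110, "H3K9me2")
  big <- peak_row("chr1", 0, 1000, "H3K9me3")
  expect_true(pair_recognized(nested, big)) # 10 > 5

  expect_error(pair_recognized(a, peak_row("chr1", 0, 50, "H3K9me3")),
               "different marks")
})

test_that("triple recognition needs a non-empty three-way intersection", {
  a <- peak_row("chr1", 0, 100, "H3K9me3")
  b <- peak_row("chr1", 0, 100, "H3K9me2")
  c <- peak_row("chr1", 0, 100, "H3K27me3")
  expect_true(triple_recognized(a, b, c)) # identical intervals

  b2 <- peak_row("chr1", 80, 180, "H3K9me2")
  c2 <- peak_row("chr1", 160, 260, "H3K27me3")
  expect_false(triple_recognized(a, b2, c2)) # pairwise only, empty 3-way

  a3 <- peak_row("chr1", 0, 100, "H3K9me3")
  b3 <- peak_row("chr1", 40, 140, "H3K9me2")
  c3 <- peak_row("chr1", 60, 90, "H3K27me3")
  expect_true(triple_recognized(a3, b3, c3)) # I = [60,90): 30 > 15 = 0.5*len(C)

  expect_error(triple_recognized(a, b, peak_row("chr1", 0, 9, "H3K9me3")),
               "distinct marks")
})

test_that("recognition rules match direct evaluation on exhaustive grids", {
  # all placements of two/three intervals on a 60-bp toy chromosome
  grid2 <- expand.grid(s1 = seq(0, 57, by = 3), l1 = c(2, 5, 11, 17, 20),
                       s2 = seq(0, 57, by = 3), l2 = c(2, 5, 11, 17, 20))
  grid2 <- grid2[grid2$s1 + grid2$l1 <= 60 & grid2$s2 + grid2$l2 <= 60, ]
  a <- peak_row("t", grid2$s1, grid2$s1 + grid2$l1, "H3K9me3")
  b <- peak_row("t", grid2$s2, grid2$s2 + grid2$l2, "H3K9me2")
  got <- pair_recognized(a, b)
  want <- mapply(rule_pair_direct, grid2$s1, grid2$s1 + grid2$l1,
                 grid2$s2, grid2$s2 + grid2$l2)
  expect_identical(unname(got), unname(want))

  grid3 <- expand.grid(s1 = seq(0, 54, by = 6), l1 = c(4, 10, 20),
                       s2 = seq(0, 54, by = 6), l2 = c(4, 10, 20),
                       s3 = seq(0, 54, by = 6), l3 = c(4, 10, 20))
  grid3 <- grid3[grid3$s1 + grid3$l1 <= 60 & grid3$s2 + grid3$l2 <= 60 &
                   grid3$s3 + grid3$l3 <= 60, ]
  a <- peak_row("t", grid3$s1, grid3$s1 + grid3$l1, "H3K9me3")
  b <- peak_row("t", grid3$s2, grid3$s2 + grid3$l2, "H3K9me2")
  c <- peak_row("t", grid3$s3, grid3$s3 + grid3$l3, "H3K27me3")
  got3 <- triple_recognized(a, b, c)
  want3 <- mapply(rule_triple_direct, grid3$s1, grid3$s1 + grid3$l1,
                  grid3$s2, grid3$s2 + grid3$l2, grid3$s3, grid3$s3 + grid3$l3)
  expect_identical(unname(got3), unname(want3))
})

test_that("pair rule is equivalent to overlap > half the shorter peak", {
  withr::local_seed(21)
  for (rep in 1:200) {
    s1 <- sample(0:100, 1); l1 <- sample(1:50, 1)
    s2 <- sample(0:100, 1); l2 <- sample(1:50, 1)
    a <- peak_row("chr1", s1, s1 + l1, "H3K9me3")
    b <- peak_row("chr1", s2, s2 + l2, "H3K27me3")
    ov <- overlap_length("chr1", s1, s1 + l1, "chr1", s2, s2 + l2)
    expect_identical(pair_recognized(a, b), ov > 0.5 * min(l1, l2))
  }
})

test_that("classify_marks hand-traces: triple, disjoint singles, 50% boundary", {
  pk <- dplyr::bind_rows(
    peak_row("chr1", 0, 100, "H3K9me3", "a"),
    peak_row("chr1", 10, 90, "H3K9me2", "b"),
    peak_row("chr1", 20, 80, "H3K27me3", "c")
  )
  res <- classify_marks(pk)
  expect_equal(nrow(res), 1)
  expect_equal(res$n_marks, 3L)
  expect_equal(res$start, 20)
  expect_equal(res$end, 80)
  expect_equal(res$marks, "H3K27me3,H3K9me2,H3K9me3")

  disjoint <- dplyr::bind_rows(
    peak_row("chr1", 0, 100, "H3K9me3"),
    peak_row("chr1", 200, 300, "H3K9me2"),
    peak_row("chr1", 400, 500, "H3K27me3")
  )
  res2 <- classify_marks(disjoint)
  expect_equal(res2$n_marks, c(1L, 1L, 1L))

  boundary <- dplyr::bind_rows(
    peak_row("chr1", 0, 100, "H3K9me3"),
    peak_row("chr1", 50, 150, "H3K27me3")
  )
  res3 <- classify_marks(boundary) # overlap 50 == 0.5*100: two singles
  expect_equal(sort(res3$n_marks), c(1L, 1L))

  expect_error(classify_marks(pk[0, ]), "non-empty")
})

test_that("union extent reports the merged footprint for multi-mark regions", {
  pk <- dplyr::bind_rows(
    peak_row("chr1", 0, 100, "H3K9me3", "a"),
    peak_row("chr1", 40, 160, "H3K9me2", "b")
  )
  res_i <- classify_marks(pk)
  res_u <- classify_marks(pk, extent = "union")
  expect_equal(c(res_i$start, res_i$end), c(40, 100))
  expect_equal(c(res_u$start, res_u$end), c(0, 160))
})

test_that("every input peak contributes to exactly one region (partition)", {
  withr::local_seed(31)
  for (rep in 1:4) {
    cfg <- sim_config(n_peaks = 50, planted_pair_fraction = 0.3,
                      planted_triple_fraction = 0.2, seed = 100 + rep)
    sim <- simulate_peakset(cfg)
    res <- classify_marks(sim$peaks)
    n3 <- sum(res$n_marks == 3); n2 <- sum(res$n_marks == 2); n1 <- sum(res$n_marks == 1)
    expect_equal(3 * n3 + 2 * n2 + n1, nrow(sim$peaks))
    all_names <- unlist(strsplit(res$peaks, ",", fixed = TRUE))
    expect_setequal(all_names, sim$peaks$name)
    expect_equal(length(all_names), nrow(sim$peaks))
  }
})

test_that("classification is invariant to peak input order", {
  sim <- simulate_peakset(sim_config(n_peaks = 40, seed = 17))
  res1 <- classify_marks(sim$peaks)
  shuffled <- sim$peaks[withr::with_seed(2, sample.int(nrow(sim$peaks))), ]
  res2 <- classify_marks(shuffled)
  expect_equal(res1, res2)
})

test_that("planted groups are recovered exactly as constructed", {
  cfg60 <- sim_config(n_peaks = 60, planted_pair_fraction = 1,
                      planted_triple_fraction = 0,
                      planted_overlap_fraction = 0.6, seed = 42)
  sim <- simulate_peakset(cfg60)
  res <- classify_marks(sim$peaks)
  expect_equal(sum(res$n_marks == 2), nrow(sim$truth))

  cfg40 <- sim_config(n_peaks = 60, planted_pair_fraction = 1,
                      planted_triple_fraction = 0,
                      planted_overlap_fraction = 0.4, seed = 42)
  sim40 <- simulate_peakset(cfg40)
  res40 <- classify_marks(sim40$peaks)
  expect_equal(sum(res40$n_marks > 1), 0)
})

test_that("summaries count by class and aggregate additively with totals", {
  sim <- simulate_peakset(sim_config(n_peaks = 40, seed = 23))
  regions <- classify_marks(sim$peaks)
  s1 <- summarize_classification(regions, source = "simA")
  g <- glance(s1)
  expect_equal(g$n_regions, nrow(regions))
  expect_equal(g$n_two_mark, sum(regions$n_marks == 2))

  s_empty <- summarize_classification(regions[0, ], source = "empty")
  expect_equal(sum(tidy(s_empty)$n), 0)

  rep1 <- aggregate_report(s1)
  expect_equal(glance(rep1)$overall_total, nrow(regions))

  # two disjoint sources: totals are element-wise sums
  s2 <- summarize_classification(regions, source = "simB")
  rep2 <- aggregate_report(s1, s2)
  expect_equal(glance(rep2)$overall_total, 2 * nrow(regions))
  expect_equal(glance(rep2)$one_mark_total, 2 * glance(rep1)$one_mark_total)
})

test_that("aggregating the published per-source counts recovers the printed totals", {
  rep <- aggregate_report(published_region_counts())
  g <- glance(rep)
  expect_equal(g$one_mark_total, 41963845)
  expect_equal(g$two_mark_total, 872640)
  expect_equal(g$three_mark_total, 3258)
  expect_equal(g$overall_total, 42839743)
})

test_that("unknown marks are rejected", {
  expect_error(classify_marks(peak_row("chr1", 0, 10, "H3K4me3")), "unknown mark")
})
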