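test_that("uncovered regions are maximal sub-threshold runs", {
  g <- tiny_genome(c1 = "ACGTAC")
  un <- uncovered_regions(mk_tracks(c1 = c(0L, 1L, 2L, 3L, 3L, 2L)), g,
                          min_reads = 3)
  expect_equal(as.data.frame(un),
               data.frame(contig = "c1", start = c(0L, 5L), end = c(3L, 6L)))

  none <- uncovered_regions(mk_tracks(c1 = rep(5L, 6)), g, min_reads = 3)
  expect_equal(nrow(none), 0)

  zero <- uncovered_regions(mk_tracks(c1 = c(0L, 0L, 5L)),
                            tiny_genome(c1 = "ACG"), min_reads = 1)
  expect_equal(as.data.frame(zero),
               data.frame(contig = "c1", start = 0L, end = 2L))
})

test_that("N runs split uncovered regions and excluded contigs are skipped", {
  g <- genome_model(c(c1 = "ACNNGT", chrY = "ACGTAC"),
                    excluded_contigs = "chrY")
  un <- uncovered_regions(mk_tracks(c1 = rep(0L, 6), chrY = rep(0L, 6)), g)
  expect_equal(as.data.frame(un),
               data.frame(contig = "c1", start = c(0L, 4L), end = c(2L, 6L)))
})

test_that("uncovered regions match a per-base scan across thresholds", {
  for (s in 1:8) {
    g <- random_genome(c(c1 = 400), seed = 100 + s)
    tr <- with_seed_test(s, mk_tracks(c1 = rpois(400, 2)))
    for (mr in c(1, 3, 5)) {
      got <- uncovered_regions(tr, g, min_reads = mr)
      want <- naive_uncovered(tr$c1, g$informative$c1, mr)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
    # monotone: more stringent thresholds never shrink the uncovered mass
    w1 <- sum(uncovered_regions(tr, g, 1)$end -
                uncovered_regions(tr, g, 1)$start)
    w3 <- sum(uncovered_regions(tr, g, 3)$end -
                uncovered_regions(tr, g, 3)$start)
    w5 <- sum(uncovered_regions(tr, g, 5)$end -
                uncovered_regions(tr, g, 5)$start)
    expect_true(w1 <= w3 && w3 <= w5)
  }
})

test_that("size distributions bin region lengths exhaustively", {
  rs <- region_set(data.frame(contig = "c1", start = c(0, 10, 100),
                              end = c(1, 12, 250)))
  sd1 <- size_distribution(rs, c(1, 3, 150))
  expect_equal(sd1$count, c(2, 0, 1))
  expect_equal(sum(sd1$count), nrow(rs))

  empty <- region_set(data.frame(contig = character(0), start = integer(0),
                                 end = integer(0)))
  expect_true(all(size_distribution(empty, c(1, 10))$count == 0))

  with_seed_test(1, {
    n <- 50
    start <- sample.int(1000, n)
    rr <- region_set(data.frame(contig = "c1", start = start,
                                end = start + sample.int(200, n)))
    expect_equal(sum(size_distribution(rr, c(1, 5, 20, 100))$count), n)
  })
  expect_error(size_distribution(rs, c(3, 3)), "strictly increasing")
})

test_that("shores flank islands without overlapping them", {
  g <- random_genome(c(c1 = 20000), seed = 3)
  isl <- region_set(data.frame(contig = "c1", start = 5000, end = 5600),
                    "cpg_island")
  sh <- derive_shores(isl, g)
  expect_equal(as.data.frame(sh),
               data.frame(contig = "c1", start = c(3000L, 5600L),
                          end = c(5000L, 7600L)))

  edge <- derive_shores(region_set(data.frame(contig = "c1", start = 500,
                                              end = 900)), g)
  expect_equal(edge$start[1], 0L)
  expect_equal(edge$end[1], 500L)

  none <- derive_shores(region_set(data.frame(contig = character(0),
                                              start = integer(0),
                                              end = integer(0))), g)
  expect_equal(nrow(none), 0)

  # closure: each island's own shores never intersect it; with islands
  # spaced farther apart than the flank, shores overlap no island at all
  start <- seq(1000, 17000, by = 4000)
  isl2 <- region_set(data.frame(contig = "c1", start = start,
                                end = start + 300))
  sh2 <- derive_shores(isl2, g)
  expect_equal(fraction_uncovered(sh2, isl2), 0)
})

test_that("promoters are strand-aware and clipped", {
  g <- random_genome(c(c1 = 20000), seed = 5)
  pr <- derive_promoters(data.frame(contig = "c1", tss = 10000,
                                    strand = "+"), g)
  expect_equal(c(pr$start, pr$end), c(8000L, 10500L))
  pm <- derive_promoters(data.frame(contig = "c1", tss = 10000,
                                    strand = "-"), g)
  expect_equal(c(pm$start, pm$end), c(9500L, 12000L))
  pc <- derive_promoters(data.frame(contig = "c1", tss = 100, strand = "+"),
                         g)
  expect_equal(c(pc$start, pc$end), c(0L, 600L))
  expect_error(derive_promoters(data.frame(contig = "c1", tss = 1,
                                           strand = "*"), g), "strand")
  # unclipped promoters have length up + down
  with_seed_test(6, {
    tss <- data.frame(contig = "c1", tss = sample(3000:17000, 20),
                      strand = sample(c("+", "-"), 20, replace = TRUE))
    pw <- derive_promoters(tss, g)
    expect_true(all(pw$end - pw$start == 2500))
  })
})

test_that("introns are the gaps between exons", {
  tx <- list(contig = "c1",
             exons = data.frame(start = c(0, 800), end = c(200, 1000)))
  intr <- derive_introns(list(tx))
  expect_equal(as.data.frame(intr),
               data.frame(contig = "c1", start = 200L, end = 800L),
               ignore_attr = TRUE)

  single <- list(contig = "c1", exons = data.frame(start = 0, end = 500))
  expect_equal(nrow(derive_introns(list(single))), 0)

  abutting <- list(contig = "c1",
                   exons = data.frame(start = c(0, 200), end = c(200, 400)))
  expect_equal(nrow(derive_introns(list(abutting))), 0)

  overlapping <- list(contig = "c1",
                      exons = data.frame(start = c(0, 150),
                                         end = c(200, 400)))
  expect_error(derive_introns(list(overlapping)), "overlapping")
})

test_that("interval merging is minimal, exact and idempotent", {
  rs <- region_set(data.frame(contig = "c1", start = c(0, 5),
                              end = c(10, 20)))
  m <- merge_intervals(rs)
  expect_equal(as.data.frame(m),
               data.frame(contig = "c1", start = 0L, end = 20L),
               ignore_attr = TRUE)

  disj <- region_set(data.frame(contig = "c1", start = c(0, 30),
                                end = c(10, 40)))
  expect_equal(as.data.frame(merge_intervals(disj)), as.data.frame(disj))

  with_seed_test(7, {
    for (i in 1:5) {
      start <- sample.int(500, 40, replace = TRUE)
      rr <- region_set(data.frame(contig = sample(c("c1", "c2"), 40,
                                                  replace = TRUE),
                                  start = start,
                                  end = start + sample.int(60, 40,
                                                           replace = TRUE)))
      once <- merge_intervals(rr)
      twice <- merge_intervals(once)
      expect_equal(as.data.frame(twice), as.data.frame(once))
      # coverage-preserving: merged width equals union base count
      base_cov <- unique(unlist(mapply(seq, rr$start, rr$end - 1,
                                       SIMPLIFY = FALSE)
                                [order(rr$contig)]))
      by_ctg <- split(rr, rr$contig)
      total <- sum(vapply(names(by_ctg), function(nm) {
        length(unique(unlist(mapply(seq, by_ctg[[nm]]$start,
                                    by_ctg[[nm]]$end - 1,
                                    SIMPLIFY = FALSE))))
      }, numeric(1)))
      expect_equal(sum(once$end - once$start), total)
    }
  })
})

test_that("uncovered fractions are merge-invariant overlaps", {
  el <- region_set(data.frame(contig = "c1", start = 0, end = 100))
  un <- region_set(data.frame(contig = "c1", start = 42, end = 100))
  expect_equal(fraction_uncovered(un, el), 0.58)

  far <- region_set(data.frame(contig = "c1", start = 500, end = 600))
  expect_equal(fraction_uncovered(far, el), 0)

  dup_el <- region_set(data.frame(contig = "c1", start = c(0, 0),
                                  end = c(100, 100)))
  expect_equal(fraction_uncovered(un, dup_el), 0.58)

  expect_error(fraction_uncovered(un, el[0, ]), "zero bases")
})

test_that("fraction comparisons use the equal-variance t-test", {
  degenerate <- compare_fractions_ttest(c(0.1, 0.1), c(0.1, 0.1))
  expect_true(degenerate$noninformative)
  expect_true(is.na(degenerate$p_value))

  same <- compare_fractions_ttest(1:4, 1:4)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # frozen from the t-density integration oracle (df = 6)
  r <- compare_fractions_ttest(c(0.0, 0.1, 0.0, 0.1), c(0.5, 0.6, 0.5, 0.6))
  expect_equal(r$df, 6)
  expect_equal(r$p_value, 1.80424463198e-05, tolerance = 1e-6)

  expect_error(compare_fractions_ttest(0.5, c(0.1, 0.2)), "at least two")
})

test_that("high-GC elements lose coverage under a dropout profile", {
  g <- generate_reference(1, 400000,
                          data.frame(length = c(15000, 5000),
                                     gc = c(0.5, 0.75)),
                          seed = 91)
  cat <- plant_regions(g, list(
    cpg_island = list(rule = "gc_blocks", min_gc = 0.7),
    exon = list(rule = "random_intervals", n = 150, width = 200, seed = 1)))
  hits <- vapply(1:20, function(s) {
    rs <- filter_reads(simulate_reads(g, gc_dropout_profile(), 8, seed = s))
    un <- uncovered_regions(compute_depth(rs, g), g)
    fraction_uncovered(un, cat$cpg_island) > fraction_uncovered(un, cat$exon)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
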