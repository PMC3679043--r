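test_that("generated references hit their GC-block targets", {
  g <- generate_reference(1, 1000, data.frame(length = 1000, gc = 0.5),
                          seed = 1)
  gc <- sum(strsplit(g$contigs[[1]], "")[[1]] %in% c("G", "C")) / 1000
  expect_gte(gc, 0.45)
  expect_lte(gc, 0.55)

  g1 <- generate_reference(1, 100, data.frame(length = 100, gc = 1.0),
                           seed = 7)
  expect_match(g1$contigs[[1]], "^[GC]+$")

  # realized GC within +/-0.05 of target for every >=1 kb block
  blocks <- data.frame(length = c(2000, 1500, 3000), gc = c(0.2, 0.5, 0.8))
  g2 <- generate_reference(2, 13000, blocks, seed = 3)
  b <- g2$blocks
  for (i in seq_len(nrow(b))) {
    if (b$end[i] - b$start[i] < 1000) next
    chars <- strsplit(substring(g2$contigs[[b$contig[i]]], b$start[i] + 1,
                                b$end[i]), "")[[1]]
    realized <- mean(chars %in% c("G", "C"))
    expect_lt(abs(realized - b$target_gc[i]), 0.05)
  }
})

test_that("reference generation is deterministic and validates inputs", {
  a <- generate_reference(2, 5000, data.frame(length = 1000, gc = 0.4),
                          seed = 42)
  b <- generate_reference(2, 5000, data.frame(length = 1000, gc = 0.4),
                          seed = 42)
  expect_identical(a$contigs, b$contigs)
  c <- generate_reference(2, 5000, data.frame(length = 1000, gc = 0.4),
                          seed = 43)
  expect_false(identical(a$contigs, c$contigs))

  expect_error(generate_reference(1, 0, data.frame(length = 10, gc = 0.5),
                                  seed = 1), "positive")
  expect_error(generate_reference(1, 100, data.frame(length = 10, gc = 1.5),
                                  seed = 1), "\\[0, 1\\]")
})

test_that("N gaps are planted, masked, and terminate the informative mask", {
  g <- generate_reference(1, 2000, data.frame(length = 2000, gc = 0.5),
                          n_gap_spec = list(list(start = 500, length = 100)),
                          seed = 5)
  expect_identical(substring(g$contigs[[1]], 501, 600), strrep("N", 100))
  expect_false(any(g$informative[[1]][501:600]))
  expect_equal(informative_length(g), 1900)
})

test_that("annotation catalogues follow their rules", {
  g <- generate_reference(1, 5000,
                          data.frame(length = c(2000, 1000, 2000),
                                     gc = c(0.5, 0.8, 0.5)),
                          seed = 2)
  cat <- plant_regions(g, list(cpg_island = list(rule = "gc_blocks",
                                                 min_gc = 0.7)))
  expect_equal(as.data.frame(cat$cpg_island),
               data.frame(contig = "contig1", start = 2000L, end = 3000L),
               ignore_attr = TRUE)

  expect_identical(plant_regions(g, list()), list())

  # explicit intervals are retained verbatim, overlaps included
  reps <- data.frame(contig = "contig1", start = c(10, 50), end = c(100, 80))
  cat2 <- plant_regions(g, list(simple_repeat = reps))
  expect_equal(nrow(cat2$simple_repeat), 2)
  expect_equal(cat2$simple_repeat$start, c(10L, 50L))

  expect_error(plant_regions(g, list(x = data.frame(contig = "contig1",
                                                    start = 4900,
                                                    end = 5200))),
               "outside")
})

test_that("planted variants match density and het fraction in expectation", {
  g <- generate_reference(1, 50000, data.frame(length = 50000, gc = 0.5),
                          seed = 9)
  expect_equal(nrow(plant_variants(g, 0, 0.5, seed = 1,
                                   hom_ref_per_bp = 0)), 0)

  counts <- het_share <- numeric(20)
  for (s in 1:20) {
    tv <- plant_variants(g, 0.02, 0.6, seed = 100 + s, hom_ref_per_bp = 0)
    counts[s] <- nrow(tv)
    het_share[s] <- mean(zygosity(tv) == "het")
  }
  # 20-seed mean of a Binomial(5e4, 0.02) count: se ~ 7
  expect_lt(abs(mean(counts) - 1000), 100)
  expect_lt(abs(mean(het_share) - 0.6), 0.05)

  a <- plant_variants(g, 0.01, 0.5, seed = 11)
  b <- plant_variants(g, 0.01, 0.5, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # no site on an N base, alleles consistent with zygosity
  expect_true(all(a$ref %in% c("A", "C", "G", "T")))
  z <- zygosity(a)
  expect_true(all(a$a1[z == "het"] == a$ref[z == "het"]))
  expect_true(all(a$a2[z == "hom_alt"] != a$ref[z == "hom_alt"]))
})

test_that("simulated read sets hit target coverage and respect flags", {
  g <- generate_reference(1, 1000000, data.frame(length = 10000, gc = 0.5),
                          seed = 21)
  means <- vapply(1:5, function(s) {
    rs <- simulate_reads(g, flat_profile(), 10, seed = s)
    mean_coverage(compute_depth(filter_reads(rs), g), g)
  }, numeric(1))
  expect_true(all(means >= 9.5 & means <= 10.5))

  rs <- simulate_reads(g, flat_profile(duplicate_rate = 0.2), 5, seed = 3)
  # duplicate flags are per fragment and roughly at the configured rate
  dup_by_pair <- tapply(rs$is_duplicate, rs$pair_id, unique)
  expect_true(all(lengths(dup_by_pair) == 1))
  expect_lt(abs(mean(unlist(dup_by_pair)) - 0.2), 0.02)
  # post-filter coverage still on target
  expect_lt(abs(mean_coverage(compute_depth(filter_reads(rs), g), g) - 5),
            0.25)

  a <- simulate_reads(g, flat_profile(), 2, seed = 77)
  b <- simulate_reads(g, flat_profile(), 2, seed = 77)
  expect_identical(as.data.frame(a), as.data.frame(b))

  zero <- platform_profile("dead", data.frame(gc = c(0, 1), weight = c(0, 0)),
                           300, 30, 100, 0, 0, 1)
  expect_error(simulate_reads(g, zero, 1, seed = 1), "no sampleable")
})

test_that("fragment sampling avoids N runs and conserves coverage mass", {
  g <- generate_reference(1, 200000, data.frame(length = 20000, gc = 0.5),
                          n_gap_spec = list(list(start = 50000,
                                                 length = 1000)),
                          seed = 31)
  rs <- simulate_reads(g, flat_profile(), 6, seed = 4)
  # no read overlaps the N run
  expect_false(any(rs$start < 51000 & rs$end > 50000))
  # conservation: sum of depth equals total read bases (all informative)
  tracks <- compute_depth(rs, g)
  expect_equal(sum(as.numeric(tracks[[1]])), sum(rs$end - rs$start))
})

test_that("a GC-dropout profile starves high-GC windows", {
  g <- generate_reference(1, 1000000,
                          data.frame(length = 10000,
                                     gc = c(0.45, 0.7, 0.45, 0.5)),
                          seed = 41)
  rs <- simulate_reads(g, gc_dropout_profile(), 10, seed = 6)
  wt <- window_table(compute_depth(filter_reads(rs), g), g)
  high <- wt$coverage_sum[wt$gc_fraction >= 0.6]
  mid <- wt$coverage_sum[wt$gc_fraction >= 0.4 & wt$gc_fraction < 0.5]
  expect_gt(length(high), 10)
  expect_lt(mean(high), 0.2 * mean(mid))
})

test_that("a planted monotone GC response is recovered by the loess trend", {
  g <- generate_reference(1, 1000000,
                          data.frame(length = 5000,
                                     gc = c(0.3, 0.4, 0.5, 0.6, 0.7)),
                          seed = 51)
  declining <- platform_profile("declining",
                                data.frame(gc = c(0, 0.3, 0.7, 1),
                                           weight = c(1, 1, 0.25, 0.25)),
                                300, 30, 100, 0, 0, 1)
  rs <- simulate_reads(g, declining, 10, seed = 8)
  wt <- window_table(compute_depth(filter_reads(rs), g), g)
  curve <- fit_loess(wt)
  sel <- curve$gc >= 0.3 & curve$gc <= 0.7
  rho <- suppressWarnings(cor(curve$gc[sel], curve$fitted[sel],
                              method = "spearman"))
  expect_lte(rho, -0.9)
})

test_that("low-mappability dropout flags reads non-unique at the given rate", {
  g <- generate_reference(1, 500000, data.frame(length = 50000, gc = 0.5),
                          seed = 61)
  lowmap <- region_set(data.frame(contig = "contig1", start = 100000,
                                  end = 200000), "lowmap")
  p <- flat_profile(repeat_mappability = 0.4)
  rs <- simulate_reads(g, p, 5, low_mappability = lowmap, seed = 9)
  inside <- rs$start >= 100000 & rs$start < 200000
  expect_lt(abs(mean(!rs$is_unique[inside]) - 0.6), 0.05)
  expect_true(all(rs$is_unique[!inside]))
})
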