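test_that("read filtering keeps exactly unique non-duplicates, in order", {
  rs <- read_set(data.frame(contig = "c1", start = c(0, 10, 20),
                            end = c(5, 15, 25), pair_id = NA, mate = NA,
                            is_duplicate = c(FALSE, TRUE, FALSE),
                            is_unique = c(TRUE, TRUE, FALSE)))
  out <- filter_reads(rs)
  expect_equal(out$start, 0L)

  all_pass <- read_set(data.frame(contig = "c1", start = c(3, 1),
                                  end = c(8, 6), pair_id = NA, mate = NA,
                                  is_duplicate = FALSE, is_unique = TRUE))
  expect_equal(as.data.frame(filter_reads(all_pass)),
               as.data.frame(all_pass))
  expect_equal(nrow(filter_reads(all_pass[0, ])), 0)
})

test_that("depth is a per-base membership count", {
  g <- tiny_genome(c1 = "ACGTAC")
  rs <- mk_reads("c1", c(0, 2), c(4, 6))
  tr <- compute_depth(rs, g)
  expect_equal(tr$c1, c(1L, 1L, 2L, 2L, 1L, 1L))

  expect_equal(compute_depth(rs[0, ], g)$c1, integer(6))
  expect_error(compute_depth(mk_reads("cX", 0, 3), g), "unknown contig")
})

test_that("depth agrees with the naive oracle and conserves read mass", {
  g <- random_genome(c(c1 = 500, c2 = 300), seed = 5)
  for (s in 1:5) {
    rs <- with_seed_test(s, {
      n <- 200
      ctg <- sample(c("c1", "c2"), n, replace = TRUE)
      L <- ifelse(ctg == "c1", 500L, 300L)
      start <- floor(runif(n) * (L - 20))
      mk_reads(ctg, start, start + sample(5:20, n, replace = TRUE))
    })
    tr <- compute_depth(rs, g)
    expect_equal(tr$c1, naive_depth(rs, "c1", 500))
    expect_equal(tr$c2, naive_depth(rs, "c2", 300))
    expect_equal(sum(as.numeric(tr$c1)) + sum(as.numeric(tr$c2)),
                 sum(rs$end - rs$start))
  }
})

test_that("mean coverage averages over informative bases only", {
  g <- tiny_genome(c1 = "ACGT")
  expect_equal(mean_coverage(mk_tracks(c1 = c(0L, 0L, 3L, 5L)), g), 2.0)

  gn <- tiny_genome(c1 = "AN")
  expect_equal(mean_coverage(mk_tracks(c1 = c(4L, 4L)), gn), 4.0)

  expect_equal(mean_coverage(mk_tracks(c1 = c(0L, 0L, 0L, 0L)), g), 0.0)

  gx <- genome_model(c(c1 = "ACGT", chrY = "AAAA"),
                     excluded_contigs = "chrY")
  expect_equal(mean_coverage(mk_tracks(c1 = rep(2L, 4), chrY = rep(9L, 4)),
                             gx), 2.0)
  gall_n <- genome_model(c(c1 = "ACGT"))
  gall_n$informative$c1 <- rep(FALSE, 4)
  expect_error(mean_coverage(mk_tracks(c1 = rep(1L, 4)), gall_n),
               "zero informative")
})

test_that("downsampling thins pair-atomically at the expected rate", {
  pairs <- mk_reads("c1", start = rep(seq(0, 99990, by = 10), each = 2),
                    end = rep(seq(0, 99990, by = 10), each = 2) + 5,
                    pair_id = rep(1:10000, each = 2),
                    mate = rep(c(1L, 2L), 10000))
  expect_identical(downsample_reads(pairs, 30, 30, seed = 1), pairs)

  kept <- vapply(1:20, function(s) {
    out <- downsample_reads(pairs, 30, 15, seed = s)
    # atomicity: mates always survive together
    expect_true(all(table(out$pair_id) == 2))
    length(unique(out$pair_id))
  }, numeric(1))
  # Binomial(10000, 0.5): 3 sigma = 150
  expect_true(all(abs(kept - 5000) <= 150))

  exact <- downsample_reads(pairs, 30, 15, seed = 3, exact = TRUE)
  expect_equal(length(unique(exact$pair_id)), 5000)

  expect_error(downsample_reads(pairs, 15, 30, seed = 1), "target_mean")
})

test_that("merging read sets adds depth element-wise and keeps tags", {
  g <- random_genome(c(c1 = 400), seed = 2)
  a <- with_seed_test(7, {
    start <- sample.int(380, 150, replace = TRUE) - 1L
    mk_reads("c1", start, start + 20)
  })
  a$platform <- "alpha"
  empty <- a[0, ]
  expect_equal(as.data.frame(merge_readsets(list(a, empty))),
               as.data.frame(a))

  doubled <- merge_readsets(list(a, a))
  expect_equal(compute_depth(doubled, g)$c1, 2L * compute_depth(a, g)$c1)

  b <- with_seed_test(8, {
    start <- sample.int(380, 90, replace = TRUE) - 1L
    rs <- mk_reads("c1", start, start + 20)
    rs$platform <- "beta"
    rs
  })
  m <- merge_readsets(list(a, b), genome = g)
  expect_equal(compute_depth(m, g)$c1,
               compute_depth(a, g)$c1 + compute_depth(b, g)$c1)
  expect_equal(sort(unique(m$platform)), c("alpha", "beta"))

  bad <- mk_reads("cZ", 0, 10)
  expect_error(merge_readsets(list(a, bad), genome = g), "absent")
})

test_that("merged simulated platforms add their coverages", {
  g <- generate_reference(1, 300000, data.frame(length = 30000, gc = 0.5),
                          seed = 71)
  a <- filter_reads(simulate_reads(g, flat_profile(), 15, seed = 1))
  b <- filter_reads(simulate_reads(g, flat_profile(read_length = 50,
                                                   frag_mean = 200,
                                                   frag_sd = 20),
                                   50, seed = 2))
  m <- mean_coverage(compute_depth(merge_readsets(list(a, b), g), g), g)
  expect_lt(abs(m - 65) / 65, 0.05)
})

test_that("coverage histograms count informative bases and stay consistent", {
  g <- tiny_genome(c1 = "ACGT")
  h <- depth_histogram(mk_tracks(c1 = c(0L, 0L, 1L, 5L)), g)
  expect_equal(as.data.frame(h),
               data.frame(depth = c(0L, 1L, 5L), count = c(2, 1, 1)),
               ignore_attr = TRUE)
  expect_equal(attr(h, "total"), 4)
  expect_equal(bases_below(h, 5), 3)
  expect_equal(bases_below(h, 1), 2)

  hu <- depth_histogram(mk_tracks(c1 = rep(7L, 4)), g)
  expect_equal(as.data.frame(hu), data.frame(depth = 7L, count = 4),
               ignore_attr = TRUE)

  # random tracks: totals and mean recomputed from the histogram agree
  gr <- random_genome(c(c1 = 1000), seed = 3)
  tr <- with_seed_test(4, mk_tracks(c1 = rpois(1000, 8)))
  hr <- depth_histogram(tr, gr)
  expect_equal(sum(hr$count), 1000)
  expect_equal(sum(hr$depth * hr$count) / 1000, mean_coverage(tr, gr))
})

test_that("cumulative coverage starts at 1 and decreases", {
  h <- coverage_histogram(depth = c(0, 1, 5), count = c(2, 3, 5))
  cc <- cumulative_coverage(h)
  expect_equal(cc$fraction[cc$depth == 0], 1.0)
  expect_equal(cc$fraction[cc$depth == 1], 0.8)
  expect_equal(cc$fraction[cc$depth == 5], 0.5)
  expect_true(all(diff(cc$fraction) <= 0))

  expect_equal(bases_below(coverage_histogram(c(0, 3, 7), c(5, 10, 2)), 5),
               15)
  expect_equal(bases_below(coverage_histogram(integer(0), numeric(0)), 5), 0)
  expect_error(cumulative_coverage(coverage_histogram(integer(0),
                                                      numeric(0))),
               "empty")
})
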