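profile_from <- function(abund, group = "G") {
  structure(list(group = group, n_samples = 1L,
                 abundance = setNames(abund,
                                      sprintf("asv%03d", seq_along(abund)))),
            class = "group_profile")
}

test_that("group profiles are equal-weight means of per-sample proportions", {
  counts <- cbind(s1 = c(10, 30, 60))
  tab <- asv_table(counts, paste0("a", 1:3), "s1")
  meta <- sample_metadata(c(s1 = "G"))
  expect_equal(unname(group_profile(tab, meta, "G")$abundance),
               c(0.1, 0.3, 0.6))

  counts <- cbind(s1 = c(50, 50, 0), s2 = c(0, 0, 100))
  tab <- asv_table(counts, paste0("a", 1:3), c("s1", "s2"))
  meta <- sample_metadata(c(s1 = "G", s2 = "G"))
  expect_equal(unname(group_profile(tab, meta, "G")$abundance),
               c(0.25, 0.25, 0.5))
  # order invariance
  perm <- tab[, c("s2", "s1")]
  expect_equal(group_profile(perm, meta, "G")$abundance,
               group_profile(tab, meta, "G")$abundance)
  # pooled weighting lets the deeper sample dominate
  counts2 <- cbind(s1 = c(100, 0), s2 = c(0, 300))
  tab2 <- asv_table(counts2, c("a1", "a2"), c("s1", "s2"))
  expect_equal(unname(group_profile(tab2, meta, "G", "pooled")$abundance),
               c(0.25, 0.75))
  expect_error(group_profile(tab, meta, "missing"), "no samples")
})

test_that("partition matches hand-computed values and degenerate cases", {
  a <- profile_from(c(0.5, 0.5, 0), "A")
  b <- profile_from(c(0.25, 0.25, 0.5), "B")
  p <- partition_overlap(a, b)
  expect_equal(unname(p$unique_pct), c(0, 50))
  expect_equal(p$shared_pct, 50)
  expect_equal(unname(p$increased_pct), c(50, 0))

  same <- partition_overlap(profile_from(c(0.2, 0.3, 0.5), "A"),
                            profile_from(c(0.2, 0.3, 0.5), "B"))
  expect_equal(same$shared_pct, 100)
  expect_equal(unname(same$unique_pct), c(0, 0))
  expect_equal(unname(same$increased_pct), c(0, 0))

  disj <- partition_overlap(profile_from(c(0.4, 0.6, 0, 0), "A"),
                            profile_from(c(0, 0, 0.7, 0.3), "B"))
  expect_equal(disj$shared_pct, 0)
  expect_equal(unname(disj$unique_pct), c(100, 100))

  expect_error(partition_overlap(profile_from(c(0.5, 0.4)), b),
               "not normalized")
})

test_that("partition closes to 100 per group and shared is symmetric", {
  for (seed in 1:50) {
    a <- random_profile(40, "A", seed = seed)
    b <- random_profile(40, "B", seed = seed + 1000)
    p <- partition_overlap(a, b)
    expect_equal(p$unique_pct[["A"]] + p$shared_pct + p$increased_pct[["A"]],
                 100, tolerance = 1e-9)
    expect_equal(p$unique_pct[["B"]] + p$shared_pct + p$increased_pct[["B"]],
                 100, tolerance = 1e-9)
    expect_true(all(c(p$unique_pct, p$shared_pct, p$increased_pct) >= 0))
    q <- partition_overlap(b, a)
    expect_equal(q$shared_pct, p$shared_pct)
  }
})

test_that("raising the minority group's abundance on a co-occurring ASV raises shared", {
  a <- c(0.10, 0.50, 0.40)
  b <- c(0.30, 0.30, 0.40)
  base <- partition_overlap(profile_from(a, "A"), profile_from(b, "B"))
  # move abundance onto ASV 1 (where A is the smaller side) from ASV 2
  a2 <- c(0.15, 0.45, 0.40)
  bump <- partition_overlap(profile_from(a2, "A"), profile_from(b, "B"))
  expect_gt(bump$shared_pct, base$shared_pct)
  expect_lte(bump$increased_pct[["A"]], base$increased_pct[["A"]])
})

test_that("random-split null is deterministic and degenerate groups behave", {
  # ten identical samples: every split shares everything
  counts <- matrix(rep(c(100, 300, 600), 10), nrow = 3,
                   dimnames = list(paste0("a", 1:3), paste0("w", 1:10)))
  tab <- asv_table(counts)
  meta <- sample_metadata(setNames(rep("WD", 10), paste0("w", 1:10)))
  nul <- random_split_null(tab, meta, "WD", n_splits = 20, seed = 7)
  expect_equal(nul$shared_pct, rep(100, 20))

  sim <- simulate_community(community_spec(seed = 3))
  pre <- filter_taxa(filter_samples_by_depth(sim$table)$table,
                     sim$taxonomy)$table
  n1 <- random_split_null(pre, sim$metadata, "WD", n_splits = 25, seed = 9)
  n2 <- random_split_null(pre, sim$metadata, "WD", n_splits = 25, seed = 9)
  expect_identical(n1$shared_pct, n2$shared_pct)
  expect_equal(n1$mean, mean(n1$shared_pct))
  expect_length(n1$shared_pct, 25)
  expect_error(random_split_null(tab, meta, "WD", split_size = 6),
               "need at least 12")
})

test_that("two interleaved disjoint sub-populations depress the null shared", {
  # samples 1..5 carry only ASVs a1-a3, samples 6..10 only a4-a6; any split
  # mixing the two kinds shares nothing between pure pseudo-groups, and a
  # mixed split shares at most partially
  blockA <- matrix(rep(c(500, 300, 200, 0, 0, 0), 5), nrow = 6)
  blockB <- matrix(rep(c(0, 0, 0, 500, 300, 200), 5), nrow = 6)
  counts <- cbind(blockA, blockB)
  dimnames(counts) <- list(paste0("a", 1:6), paste0("w", 1:10))
  tab <- asv_table(counts)
  meta <- sample_metadata(setNames(rep("WD", 10), paste0("w", 1:10)))
  nul <- random_split_null(tab, meta, "WD", n_splits = 50, seed = 11,
                           refilter = FALSE)
  expect_true(all(nul$shared_pct < 100))
  expect_lt(nul$mean, 90)
})

test_that("unique_splits exhausts the 126 distinct 5+5 splits of 10 samples", {
  tab <- random_asv_table(6, 10, seed = 13)
  meta <- sample_metadata(setNames(rep("WD", 10), colnames(tab)))
  nul <- random_split_null(tab, meta, "WD", n_splits = 126, seed = 2,
                           unique_splits = TRUE, refilter = FALSE)
  expect_length(nul$shared_pct, 126)
  expect_error(random_split_null(tab, meta, "WD", n_splits = 127, seed = 2,
                                 unique_splits = TRUE, refilter = FALSE),
               "distinct splits")
})

test_that("compare_groups reproduces the documented toy-fixture partition", {
  fx <- make_toy_fixture()
  cmp <- compare_groups(fx$table, fx$taxonomy, fx$metadata, c("SD", "WD"))
  expect_equal(unname(cmp$partition$unique_pct), c(18.75, 35))
  expect_equal(cmp$partition$shared_pct, 65)
  expect_equal(unname(cmp$partition$increased_pct), c(16.25, 0))
  expect_setequal(cmp$partition$co_occurring_asvs, c("asv2", "asv5"))
  # the mitochondrial ASV was removed by the taxonomy stage
  expect_true("tox1" %in% cmp$filter_reports$taxa$removed$id)
  # and the shipped TSV fixture gives the identical result
  toy_dir <- system.file("extdata", "toy", package = "asvoverlap")
  cmp2 <- compare_groups(read_asv_table(file.path(toy_dir, "asv_counts.tsv")),
                         read_taxonomy(file.path(toy_dir, "taxonomy.tsv")),
                         read_metadata(file.path(toy_dir, "metadata.tsv")),
                         c("SD", "WD"))
  expect_equal(cmp2$partition$shared_pct, 65)
})

test_that("summary and plot methods run on a comparison with a null", {
  sim <- simulate_community(community_spec(seed = 8))
  cmp <- compare_groups(sim$table, sim$taxonomy, sim$metadata, c("SD", "WD"),
                        null = list(group = "WD", n_splits = 10,
                                    split_size = 5, seed = 8))
  s <- summary(cmp)
  expect_s3_class(s, "summary.overlap_comparison")
  expect_true(is.finite(s$shared_z))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(cmp))
})
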