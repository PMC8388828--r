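test_that("read mapping honors the identity cutoff boundary", {
  set.seed(6)
  contig <- seq_tbl("c1", random_dna(3000))
  clean <- substr(contig$seq, 1001, 1100)
  # evenly spaced interior substitutions so end-trimming cannot raise the
  # identity of the best-scoring alignment: 11/100 -> 89%, below the cutoff
  reads <- seq_tbl(c("ok", "low"),
                   c(mutate_seq(clean, 9, positions = seq(5, 85, by = 10)),
                     mutate_seq(clean, 11, positions = seq(4, 84, by = 8))))
  prof9 <- map_reads(reads[1, ], contig)
  expect_equal(prof9$mapped_reads, 1)
  prof11 <- map_reads(reads[2, ], contig)
  expect_equal(prof11$mapped_reads, 0)
})

test_that("presence flips exactly at the 75% coverage rule", {
  set.seed(7)
  contig <- seq_tbl("p1", random_dna(4000))
  # tiles covering exactly 75% and just below
  at <- map_reads(tiled_reads("p1", contig$seq, 0.75), contig)
  below <- map_reads(tiled_reads("p1", contig$seq, 0.725), contig)
  expect_equal(at$covered_fraction, 0.75)
  expect_true(at$present)
  expect_false(below$present)
  # adding reads never flips present -> absent
  more <- map_reads(dplyr::bind_rows(
    tiled_reads("p1", contig$seq, 0.75),
    seq_tbl("extra", substr(contig$seq, 3501, 3600),
            description = "p1")), contig)
  expect_true(more$present)
  expect_gte(more$covered_bases, at$covered_bases)
})

test_that("zero reads produce absent, zero-coverage profiles", {
  contig <- seq_tbl("c", random_dna(1000))
  prof <- map_reads(seq_tbl(character(), character()), contig)
  expect_equal(prof$covered_fraction, 0)
  expect_false(prof$present)
  expect_error(map_reads(seq_tbl("r", "ACGT"),
                         seq_tbl(character(), character())), "nonempty")
})

test_that("abundance normalization follows the RPKM-style formula", {
  prof <- tibble::tibble(contig_id = "c", contig_length = 2000L,
                         mapped_reads = 100L, covered_bases = 1600L,
                         covered_fraction = 0.8, present = TRUE)
  expect_equal(normalize_abundance(prof, 1e6)$abundance, 50)
  # doubling the library halves abundance
  expect_equal(normalize_abundance(prof, 2e6)$abundance, 25)
  # zero mapped reads and absent contigs give zero
  prof0 <- dplyr::mutate(prof, mapped_reads = 0L, present = FALSE)
  expect_equal(normalize_abundance(prof0, 1e6)$abundance, 0)
  expect_error(normalize_abundance(dplyr::mutate(prof, contig_length = 0L),
                                   1e6), "zero-length")
})

test_that("site partition recovers designed membership and sums to one", {
  d <- sim_design(seed = 31, n_hosts = 2, n_viruses = 2)
  cc <- simulate_community_counts(d)
  for (season in c("spring", "winter")) {
    p <- partition_by_site(cc$counts, cc$meta, season)
    sums <- tapply(p$fractions$fraction, p$fractions$sample_id, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    # categories equal generator truth for features whose seasons include
    # this season (others are undetected here)
    cmp <- dplyr::inner_join(p$categories, cc$truth, by = "feature_id")
    cmp <- cmp[grepl(season, cmp$seasons), ]
    expect_true(all(cmp$category == cmp$site_category))
    # partition is exhaustive and exclusive over detected features
    expect_equal(anyDuplicated(p$categories$feature_id), 0)
  }
})

test_that("season partition uses the all/swf/single/other categories", {
  d <- sim_design(seed = 32, n_hosts = 2, n_viruses = 2)
  cc <- simulate_community_counts(d)
  p <- partition_by_season(cc$counts, cc$meta, "head")
  expect_true(all(p$categories$category %in%
                    c("all", "spring/winter/fall", "single", "other")))
  cmp <- dplyr::inner_join(p$categories, cc$truth, by = "feature_id")
  cmp <- cmp[grepl("head", cmp$sites), ]
  expect_true(all(cmp$category == cmp$season_category))
  sums <- tapply(p$fractions$fraction, p$fractions$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("single-category synthetic designs land wholly in that category", {
  meta <- tidyr::expand_grid(site = c("head", "mixed", "river"),
                             season = "spring", replicate = 1:2)
  meta$sample_id <- sprintf("%s_%s_r%d", meta$site, meta$season,
                            meta$replicate)
  counts <- tibble::tibble(feature_id = paste0("f", 1:4))
  for (s in meta$sample_id) counts[[s]] <- runif(4, 1, 10)
  p <- partition_by_site(counts, meta, "spring")
  expect_true(all(p$categories$category == "all"))
  expect_true(all(p$fractions$fraction[p$fractions$category == "all"] == 1))
  # a feature detected only at head is categorized "head"
  counts2 <- counts
  for (s in meta$sample_id[meta$site != "head"]) counts2[[s]][1] <- 0
  p2 <- partition_by_site(counts2, meta, "spring")
  expect_equal(p2$categories$category[p2$categories$feature_id == "f1"],
               "head")
  # a summer+winter feature is "other"
  meta4 <- tidyr::expand_grid(site = "head",
                              season = c("spring", "summer", "fall",
                                         "winter"), replicate = 1)
  meta4$sample_id <- sprintf("%s_%s_r%d", meta4$site, meta4$season,
                             meta4$replicate)
  counts4 <- tibble::tibble(feature_id = "f1",
                            head_spring_r1 = 0, head_summer_r1 = 5,
                            head_fall_r1 = 0, head_winter_r1 = 3)
  p4 <- partition_by_season(counts4, meta4, "head")
  expect_equal(p4$categories$category, "other")
})

test_that("Bray-Curtis matches hand computations and vegan", {
  x <- tibble::tibble(feature_id = paste0("f", 1:3),
                      s1 = c(1, 2, 3), s2 = c(3, 2, 1), s3 = c(1, 2, 3))
  bc <- bray_curtis(x)
  expect_equal(unname(bc["s1", "s2"]), 1 / 3)
  expect_equal(unname(bc["s1", "s3"]), 0)
  disjoint <- tibble::tibble(feature_id = paste0("f", 1:2),
                             a = c(5, 0), b = c(0, 7))
  expect_equal(unname(bray_curtis(disjoint)["a", "b"]), 1)
  expect_error(bray_curtis(tibble::tibble(feature_id = "f", a = 0, b = 1)),
               "all-zero")
})

test_that("Mantel r is exact under identity and scaling", {
  set.seed(12)
  D <- as.matrix(stats::dist(matrix(stats::rnorm(30), 10)))
  rownames(D) <- colnames(D) <- paste0("s", 1:10)
  m1 <- mantel_test(D, D, 999, seed = 4)
  expect_equal(m1$statistic, 1)
  # identical matrices attain the minimum possible p
  expect_equal(m1$p_value, 1 / 1000)
  m2 <- mantel_test(D, 2 * D, 999, seed = 4)
  expect_equal(m2$statistic, 1)
  # seeded: same seed, same p
  expect_equal(mantel_test(D, D + stats::runif(1), 999, seed = 9)$p_value,
               mantel_test(D, D + stats::runif(1), 999, seed = 9)$p_value)
  D2 <- D
  rownames(D2) <- colnames(D2) <- paste0("x", 1:10)
  expect_error(mantel_test(D, D2), "label set")
})

test_that("virus-to-prokaryote ratios divide as printed", {
  expect_equal(virus_prokaryote_ratio(2e6, 1e6), 2)
  expect_equal(virus_prokaryote_ratio(5, 5), 1)
  expect_equal(virus_prokaryote_ratio(1.4e4, 5.5e3), 2.545455,
               tolerance = 1e-6)
  expect_error(virus_prokaryote_ratio(1e4, 0), "positive")
})

test_that("partition objects tidy, glance and plot", {
  d <- sim_design(seed = 33, n_hosts = 2, n_viruses = 2)
  cc <- simulate_community_counts(d)
  p <- partition_by_site(cc$counts, cc$meta, "fall")
  expect_s3_class(tidy(p), "tbl_df")
  expect_true("n_features" %in% names(glance(p)))
  expect_s3_class(autoplot(p), "ggplot")
  mt <- mantel_test(bray_curtis(relative_abundance(cc$counts)),
                    bray_curtis(relative_abundance(cc$counts)),
                    n_permutations = 99, seed = 1)
  expect_equal(tidy(mt)$statistic, 1)
})
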