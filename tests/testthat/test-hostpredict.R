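test_that("each evidence filter enforces exactly its stated cutoffs", {
  f <- default_filters()
  # CRISPR filter: identity >= 80, qcov >= 100, mismatches <= 1, E <= 1
  expect_equal(nrow(filter_hits(hit_row(pident = 100, qcovs = 100,
                                        mismatch = 0, evalue = 1e-5),
                                f$crispr)), 1)
  expect_equal(nrow(filter_hits(hit_row(mismatch = 2), f$crispr)), 0)
  expect_equal(nrow(filter_hits(hit_row(pident = 79.9), f$crispr)), 0)
  expect_equal(nrow(filter_hits(hit_row(qcovs = 99.9), f$crispr)), 0)
  expect_equal(nrow(filter_hits(hit_row(evalue = 1.01), f$crispr)), 0)
  expect_equal(nrow(filter_hits(hit_row(evalue = 1), f$crispr)), 1)
  # tRNA filter: length >= 60, identity >= 90, qcov >= 95, mm <= 10, E <= 1e-3
  expect_equal(nrow(filter_hits(hit_row(length = 59), f$trna)), 0)
  expect_equal(nrow(filter_hits(hit_row(length = 60), f$trna)), 1)
  expect_equal(nrow(filter_hits(hit_row(pident = 89.9), f$trna)), 0)
  expect_equal(nrow(filter_hits(hit_row(qcovs = 94.9), f$trna)), 0)
  expect_equal(nrow(filter_hits(hit_row(mismatch = 11), f$trna)), 0)
  expect_equal(nrow(filter_hits(hit_row(mismatch = 10), f$trna)), 1)
  expect_equal(nrow(filter_hits(hit_row(evalue = 0.002), f$trna)), 0)
  # homology filter: length >= 300, identity >= 50, E <= 1e-3
  expect_equal(nrow(filter_hits(hit_row(length = 299), f$homology)), 0)
  expect_equal(nrow(filter_hits(hit_row(length = 300), f$homology)), 1)
  expect_equal(nrow(filter_hits(hit_row(pident = 49.9, length = 400),
                                f$homology)), 0)
  expect_equal(nrow(filter_hits(hit_row(evalue = 0.0011), f$homology)), 0)
  # unset cutoffs are ignored: homology has no coverage or mismatch cap
  expect_equal(nrow(filter_hits(hit_row(qcovs = 10, mismatch = 50,
                                              length = 400),
                                f$homology)), 1)
})

test_that("filters error when hits lack an inspected field", {
  h <- hit_row()
  h$qcovs <- NULL
  expect_error(filter_hits(h, default_filters()$crispr), "qcovs")
})

test_that("relaxing any single cutoff never shrinks the retained set", {
  set.seed(3)
  hits <- dplyr::bind_rows(lapply(1:200, function(i) {
    hit_row(pident = runif(1, 40, 100), length = sample(30:500, 1),
            mismatch = sample(0:15, 1), qcovs = runif(1, 50, 100),
            evalue = 10^runif(1, -8, 1))
  }))
  base <- evidence_filter("trna", min_identity = 90, min_query_coverage = 95,
                          max_mismatches = 10, min_alignment_length = 60,
                          max_evalue = 0.001)
  n0 <- nrow(filter_hits(hits, base))
  relaxed <- list(
    evidence_filter("trna", 80, 95, 10, 60, 0.001),
    evidence_filter("trna", 90, 90, 10, 60, 0.001),
    evidence_filter("trna", 90, 95, 12, 60, 0.001),
    evidence_filter("trna", 90, 95, 10, 50, 0.001),
    evidence_filter("trna", 90, 95, 10, 60, 0.01)
  )
  for (f in relaxed) expect_gte(nrow(filter_hits(hits, f)), n0)
})

test_that("consensus scores add each evidence type once", {
  w <- scoring_weights()
  expect_equal(score_consensus(fake_evidence("v1", "tA", "crispr"), w)$score, 3)
  expect_equal(score_consensus(fake_evidence("v1", "tA", "homology"), w)$score, 2)
  expect_equal(score_consensus(fake_evidence("v1", "tA", "trna"), w)$score, 1)
  all3 <- dplyr::bind_rows(fake_evidence("v1", "tA", "crispr"),
                           fake_evidence("v1", "tA", "homology"),
                           fake_evidence("v1", "tA", "trna"))
  expect_equal(score_consensus(all3, w)$score, 6)
  # duplicating a record never changes any score (type idempotence)
  dup <- dplyr::bind_rows(all3, all3, fake_evidence("v1", "tA", "crispr"))
  expect_equal(score_consensus(dup, w)$score, 6)
  # per-hit accumulation is available but off by default
  expect_equal(score_consensus(dup, w, per_hit = TRUE)$score, 15)
})

test_that("the top-scoring taxon wins and exact ties are unresolved", {
  ev <- dplyr::bind_rows(fake_evidence("v1", "tA", "crispr"),
                         fake_evidence("v1", "tB", "homology"))
  pred <- predict_hosts(score_consensus(ev))
  expect_equal(pred$predicted_taxon, "tA")
  expect_equal(pred$score, 3)
  expect_false(pred$tie)
  # crispr (3) vs homology + trna (3): tie, unresolved, both listed
  ev2 <- dplyr::bind_rows(fake_evidence("v2", "tA", "crispr"),
                          fake_evidence("v2", "tB", "homology"),
                          fake_evidence("v2", "tB", "trna"))
  pred2 <- predict_hosts(score_consensus(ev2))
  expect_true(pred2$tie)
  expect_true(is.na(pred2$predicted_taxon))
  expect_setequal(pred2$tied_taxa[[1]], c("tA", "tB"))
  # single-taxon, single point still yields a call
  pred3 <- predict_hosts(score_consensus(fake_evidence("v3", "tC", "trna")))
  expect_equal(pred3$predicted_taxon, "tC")
  expect_equal(pred3$score, 1)
})

test_that("any taxon with CRISPR evidence outscores homology-only taxa", {
  w <- scoring_weights()
  for (v in paste0("v", 1:5)) {
    sc <- score_consensus(dplyr::bind_rows(
      fake_evidence(v, "tA", "crispr"),
      fake_evidence(v, "tB", "homology")), w)
    expect_gt(sc$score[sc$taxon_id == "tA"], sc$score[sc$taxon_id == "tB"])
  }
})

test_that("evidence collection tags hits with the host taxon per search direction", {
  d <- sim_design(seed = 21, n_hosts = 3, n_viruses = 3)
  h <- simulate_hosts(d)
  v <- simulate_viruses(d, h)
  spacers <- extract_spacers(find_arrays(h$genomes))
  taxa <- tibble::tibble(genome_id = h$genomes$id,
                         taxon_id = paste0("tax_", h$genomes$id))
  ev <- collect_evidence(spacers, v$genomes,
                         truth_sequences(v$truth, "trna"), h$genomes, taxa)
  expect_setequal(unique(ev$evidence_type), c("crispr", "trna", "homology"))
  # every virus gets all three types pointing at its planted true host
  for (i in 1:3) {
    vt <- ev[ev$virus_id == sprintf("virus%02d", i), ]
    expect_setequal(unique(vt$taxon_id),
                    paste0("tax_", sprintf("host%02d", i)))
    expect_setequal(unique(vt$evidence_type),
                    c("crispr", "trna", "homology"))
  }
})

test_that("an empty host set warns and returns no evidence", {
  expect_warning(
    ev <- collect_evidence(seq_tbl("s", "ACGTACGTACGT"),
                           seq_tbl("v", "ACGTACGTACGT"), NULL,
                           seq_tbl(character(), character()),
                           tibble::tibble(genome_id = character(),
                                          taxon_id = character())),
    "empty host set")
  expect_equal(nrow(ev), 0)
})

test_that("unmapped host genomes are rejected", {
  expect_error(
    collect_evidence(seq_tbl("s", "ACGT"), seq_tbl("v", "ACGT"), NULL,
                     seq_tbl("h", "ACGT"),
                     tibble::tibble(genome_id = "other", taxon_id = "t")),
    "map to a taxon")
})

test_that("tidy and glance summarize prediction objects", {
  ev <- dplyr::bind_rows(fake_evidence("v1", "tA", "crispr"),
                         fake_evidence("v1", "tA", "trna"),
                         fake_evidence("v2", "tB", "homology"))
  pred <- predict_hosts(score_consensus(ev), ev)
  td <- tidy(pred)
  expect_equal(td$score[td$virus_id == "v1"], 4)
  expect_equal(td$evidence_types[td$virus_id == "v1"], "crispr+trna")
  gl <- glance(pred)
  expect_equal(gl$n_viruses, 2)
  expect_equal(gl$n_resolved, 2)
})
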