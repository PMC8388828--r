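test_that("dereplication respects the identity cutoff boundary", {
  set.seed(4)
  base <- random_dna(3000)
  near <- mutate_seq(base, 120)   # 96% identity
  far <- mutate_seq(base, 400)    # ~86.7% identity
  cl <- dereplicate(seq_tbl(c("x", "y", "z"), c(base, near, far)))
  expect_equal(length(unique(cl$cluster_id)), 2)
  expect_true(all(cl$cluster_id[cl$contig_id %in% c("x", "y")] ==
                    cl$cluster_id[cl$contig_id == "x"]))
  # a 94%-identity pair stays separate
  below <- mutate_seq(base, 180)  # 94% identity
  cl2 <- dereplicate(seq_tbl(c("x", "w"), c(base, below)))
  expect_equal(length(unique(cl2$cluster_id)), 2)
  # single contig clusters with itself as representative
  cl3 <- dereplicate(seq_tbl("solo", base))
  expect_equal(cl3$representative, "solo")
  expect_true(cl3$is_representative)
})

test_that("dereplication cluster count is input-order invariant", {
  set.seed(14)
  base1 <- random_dna(2000)
  base2 <- random_dna(2500)
  contigs <- seq_tbl(paste0("c", 1:5),
                     c(base1, mutate_seq(base1, 40), base2,
                       mutate_seq(base2, 50), random_dna(1500)))
  n0 <- length(unique(dereplicate(contigs)$cluster_id))
  for (perm in list(c(5, 4, 3, 2, 1), c(3, 1, 5, 2, 4))) {
    n <- length(unique(dereplicate(contigs[perm, ])$cluster_id))
    expect_equal(n, n0)
  }
})

test_that("ORF calling finds planted frames and is strand symmetric", {
  set.seed(9)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*" &
                                             Biostrings::GENETIC_CODE != "M"]
  body <- paste(sample(sense, 90, replace = TRUE), collapse = "")
  contig <- paste0(strrep("C", 60), "ATG", body, "TAA", strrep("C", 60))
  orfs <- call_orfs(seq_tbl("ctg", contig), min_length_codons = 50)
  expect_equal(sum(nchar(orfs$seq) == 91), 1)
  expect_true(any(grepl("^ctg:\\+1:", orfs$id)))
  # reverse complement preserves the multiset of called proteins
  rc <- call_orfs(seq_tbl("rc", revcomp(contig)), min_length_codons = 50)
  expect_setequal(orfs$seq, rc$seq)
  # short stop-free sequences yield nothing at a high minimum
  expect_equal(nrow(call_orfs(seq_tbl("s", strrep("GCA", 66)),
                              min_length_codons = 100)), 0)
})

test_that("Dice distances hit their closed forms on constructed proteomes", {
  set.seed(3)
  p_shared <- replicate(4, random_protein(80))
  p_other <- replicate(4, random_protein(80))
  proteomes <- dplyr::bind_rows(
    seq_tbl(paste0("a", 1:4), p_shared, description = "A",
            alphabet = "protein"),
    seq_tbl(paste0("b", 1:4), p_shared, description = "B",
            alphabet = "protein"),
    seq_tbl(paste0("c", 1:4), p_other, description = "C",
            alphabet = "protein"),
    seq_tbl(paste0("d", 1:4), c(p_shared[1:2], p_other[1:2]),
            description = "D", alphabet = "protein"))
  D <- dice_distance_matrix(proteomes)
  expect_equal(unname(D["A", "B"]), 0)          # identical proteomes
  expect_equal(unname(D["A", "C"]), 1)          # fully disjoint
  expect_equal(unname(D["A", "D"]), 0.5)        # half shared, equal sizes
  # semimetric properties on the panel
  expect_true(all(diag(D) == 0))
  expect_true(isSymmetric(D))
  expect_true(all(D >= 0 & D <= 1))
})

test_that("a genome with no proteins is reported by name", {
  pp <- seq_tbl("a1", random_protein(50), description = "A",
                alphabet = "protein")
  expect_error(dice_distance_matrix(pp), "at least 2")
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(17)
  for (n in 4:8) {
    tru <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.5))
    dm <- stats::cophenetic(tru)
    tr <- build_nj_tree(dm)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(tru))), 0)
    # leaf-to-leaf path lengths are reproduced
    expect_equal(stats::cophenetic(tr)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-8)
  }
})

test_that("three taxa solve the closed-form branch lengths", {
  dm <- matrix(c(0, 0.4, 0.6,
                 0.4, 0, 0.8,
                 0.6, 0.8, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- build_nj_tree(dm)
  pd <- stats::cophenetic(tr)
  expect_equal(pd["a", "b"], 0.4, tolerance = 1e-8)
  expect_equal(pd["a", "c"], 0.6, tolerance = 1e-8)
  expect_equal(pd["b", "c"], 0.8, tolerance = 1e-8)
})

test_that("midpoint root of an ultrametric matrix is equidistant from leaves", {
  tru <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  tr <- build_nj_tree(stats::cophenetic(tru))
  depths <- ape::node.depth.edgelength(tr)
  leaf_depths <- depths[seq_along(tr$tip.label)]
  expect_true(max(leaf_depths) - min(leaf_depths) < 1e-8)
})

test_that("non-symmetric matrices are rejected", {
  m <- matrix(c(0, 1, 2, 0.5, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(build_nj_tree(m), "symmetric")
})

test_that("lineage cutting respects cutoffs and nests across levels", {
  tru <- ape::read.tree(text = "((a:0.1,b:0.1):0.4,(c:0.15,d:0.15):0.35);")
  la <- assign_lineages(tru, c(0, 0.3, 10))
  # cutoff 0: one lineage containing every leaf
  expect_equal(length(unique(la$lineage[la$cutoff == 0])), 1)
  # cutoff 0.3: the two clades
  l3 <- la[la$cutoff == 0.3, ]
  expect_equal(length(unique(l3$lineage)), 2)
  expect_equal(l3$lineage[l3$genome_id == "a"],
               l3$lineage[l3$genome_id == "b"])
  expect_false(l3$lineage[l3$genome_id == "a"] ==
                 l3$lineage[l3$genome_id == "c"])
  # cutoff above tree height: singletons
  expect_equal(length(unique(la$lineage[la$cutoff == 10])), 4)
  expect_error(assign_lineages(tru, c(-0.1, 0.5)), "non-negative")
})

test_that("lineage assignments at deeper cutoffs refine shallower ones", {
  set.seed(23)
  for (rep in 1:5) {
    tru <- ape::rtree(10, br = function(k) runif(k, 0.05, 0.5))
    la <- assign_lineages(tru, c(0.1, 0.3, 0.6))
    wide <- tidyr::pivot_wider(la, names_from = "cutoff",
                               values_from = "lineage")
    # every deep lineage maps into exactly one shallow lineage
    expect_true(all(tapply(wide[[2]], wide[[3]],
                           function(x) length(unique(x))) == 1))
    expect_true(all(tapply(wide[[3]], wide[[4]],
                           function(x) length(unique(x))) == 1))
  }
})

test_that("the completeness rule applies size range and hallmark genes", {
  rule <- completeness_rule(c("famA", "famB"), c(4000, 30000),
                            c(8000, 60000),
                            list(c("mcp", "terminase"), "rep"))
  ann <- tibble::tibble(
    contig_id = paste0("ctg", 1:5),
    length = c(5000L, 5000L, 3999L, 8001L, 5000L),
    family = c("famA", "famA", "famA", "famA", "famX"),
    hallmarks = list(c("mcp", "terminase"), "mcp", c("mcp", "terminase"),
                     c("mcp", "terminase"), "rep"))
  expect_warning(res <- filter_complete_genomes(ann, rule), "unevaluable")
  expect_equal(res$status,
               c("complete", "incomplete", "incomplete", "incomplete",
                 "unevaluable"))
  expect_equal(sum(res$complete), 1)
})
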