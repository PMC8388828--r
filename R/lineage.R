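#' Dereplicate viral contigs by identity and coverage
#'
#' Greedy incremental clustering, longest contig first: a contig joins the
#' first existing cluster whose representative it matches at
#' `>= min_identity` percent identity over `>= min_coverage` percent of the
#' shorter sequence, otherwise it founds a new cluster. The representative
#' of a cluster is its longest member. Defaults mirror the conventional
#' 95% identity / 50% coverage dereplication of viral contig sets.
#'
#' @param contigs DNA sequence tibble.
#' @param min_identity Minimum percent identity (default 95).
#' @param min_coverage Minimum percent of the shorter sequence covered by
#'   the alignment (default 50).
#' @param scheme,params Alignment scoring scheme and statistics.
#' @return A tibble `contig_id`, `cluster_id`, `representative`,
#'   `is_representative`.
#' @export
dereplicate <- function(contigs, min_identity = 95, min_coverage = 50,
                        scheme = scoring_scheme(), params = ka_params()) {
  stopifnot(min_identity > 0, min_identity <= 100, min_coverage > 0,
            min_coverage <= 100)
  ord <- order(-nchar(contigs$seq), contigs$id)
  reps <- integer(0)  # row indices of representatives, in founding order
  assign <- integer(nrow(contigs))
  for (i in ord) {
    placed <- FALSE
    for (ri in seq_along(reps)) {
      r <- reps[ri]
      shorter <- min(nchar(contigs$seq[i]), nchar(contigs$seq[r]))
      hits <- align_search(contigs[i, ], contigs[r, ], scheme, params,
                           max_evalue = 10, mode = "seeded")
      if (nrow(hits) == 0) next
      best <- hits[1, ]
      cov <- (best$qend - best$qstart + 1) / shorter * 100
      if (best$pident >= min_identity && cov >= min_coverage) {
        assign[i] <- ri
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[i] <- length(reps)
    }
  }
  tibble::tibble(
    contig_id = contigs$id,
    cluster_id = sprintf("cluster%03d", assign),
    representative = contigs$id[reps[assign]],
    is_representative = contigs$id == contigs$id[reps[assign]]
  )
}

#' Call open reading frames on all six frames
#'
#' Stop-to-stop segments with a required ATG start, standard genetic code,
#' reported as proteins of at least `min_length_codons` codons (excluding
#' the stop). Ids are `contig:frame:ordinal` with frames +1..+3/-1..-3.
#'
#' @param contig One-row DNA sequence tibble or character scalar.
#' @param min_length_codons Minimum protein length in codons (default 30).
#' @return A protein sequence tibble.
#' @export
call_orfs <- function(contig, min_length_codons = 30) {
  x <- as_single_seq(contig)
  frames <- c(1, 2, 3, -1, -2, -3)
  out <- purrr::map(frames, function(fr) {
    s <- if (fr > 0) x$seq else revcomp(x$seq)
    off <- abs(fr) - 1
    sub <- substr(s, off + 1, nchar(s))
    n_codon <- nchar(sub) %/% 3
    if (n_codon < min_length_codons) return(NULL)
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(sub, 1, n_codon * 3)),
      if.fuzzy.codon = "X"))
    # segments between stops; require leading M within each segment
    segs <- strsplit(aa, "*", fixed = TRUE)[[1]]
    pos <- 1L
    prots <- character(0)
    for (seg in segs) {
      m <- regexpr("M", seg, fixed = TRUE)
      if (m > 0) {
        prot <- substr(seg, m, nchar(seg))
        if (nchar(prot) >= min_length_codons) {
          prots <- c(prots, prot)
        }
      }
      pos <- pos + nchar(seg) + 1L
    }
    if (length(prots) == 0) return(NULL)
    tibble::tibble(frame = fr, prot = prots)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(seq_tbl(character(), character(), alphabet = "protein"))
  }
  out <- dplyr::group_by(out, .data$frame)
  out <- dplyr::mutate(out, ordinal = dplyr::row_number())
  out <- dplyr::ungroup(out)
  seq_tbl(sprintf("%s:%+d:%d", x$id, out$frame, out$ordinal), out$prot,
          description = x$id, alphabet = "protein")
}

#' Shared-protein Dice distance matrix between viral genomes
#'
#' For genomes A and B, `d(A,B) = 1 - 2 S(A,B) / (S(A,A) + S(B,B))` where
#' `S(X,Y)` sums the fractional identity of best reciprocal protein pairs
#' between the proteomes, i.e. an identity-weighted shared-gene count; by
#' construction `S(A,A)` equals the proteome size and `d(A,A) = 0`. The
#' result is a semimetric in `[0, 1]` (the triangle inequality is not
#' guaranteed).
#'
#' @param proteomes Protein sequence tibble with the owning genome id in
#'   `description` (as produced by [call_orfs()]).
#' @param scheme Protein scoring scheme (BLOSUM62 defaults).
#' @param params Karlin-Altschul parameters for the match significance
#'   threshold.
#' @param max_evalue A protein pair counts as matched only if its best
#'   local alignment reaches this E-value (pairwise search space).
#' @return A symmetric numeric matrix with genome labels, zero diagonal.
#' @export
dice_distance_matrix <- function(proteomes, scheme = protein_scoring(),
                                 params = ka_params_protein(),
                                 max_evalue = 1e-3) {
  genomes <- unique(proteomes$description)
  if (length(genomes) < 2) {
    rlang::abort("need proteomes for at least 2 genomes")
  }
  sets <- split(proteomes, proteomes$description)
  empty <- names(sets)[purrr::map_int(sets, nrow) == 0]
  if (length(empty)) {
    rlang::abort(paste("genomes with no proteins:", paste(empty, collapse = ", ")))
  }
  n <- length(genomes)
  S_self <- purrr::map_dbl(sets, nrow)[genomes]
  D <- matrix(0, n, n, dimnames = list(genomes, genomes))
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      s_ab <- proteome_similarity(sets[[genomes[a]]], sets[[genomes[b]]],
                                  scheme, params, max_evalue)
      d <- 1 - 2 * s_ab / (S_self[a] + S_self[b])
      D[a, b] <- D[b, a] <- min(1, max(0, d))
    }
  }
  D
}

# identity-weighted best-reciprocal-match similarity between two proteomes
proteome_similarity <- function(pa, pb, scheme, params, max_evalue) {
  na <- nrow(pa)
  nb <- nrow(pb)
  score <- matrix(-Inf, na, nb)
  ident <- matrix(0, na, nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      min_sc <- min_score_for_evalue(max_evalue, nchar(pa$seq[i]),
                                     nchar(pb$seq[j]), params)
      h <- sw_pair(pa$seq[i], pb$seq[j], scheme, min_score = min_sc,
                   max_hits = 1L)
      if (nrow(h) > 0 && h$raw_score[1] < min_sc) h <- h[0, ]
      if (nrow(h) > 0) {
        score[i, j] <- h$raw_score[1]
        ident[i, j] <- h$matches[1] / h$length[1]
      }
    }
  }
  s <- 0
  for (i in seq_len(na)) {
    j <- which.max(score[i, ])
    if (is.finite(score[i, j]) && which.max(score[, j]) == i) {
      s <- s + ident[i, j]
    }
  }
  s
}

#' Neighbor-joining tree from a distance matrix, midpoint rooted
#'
#' Standard Saitou-Nei neighbor joining followed by midpoint rooting.
#' Negative branch-length estimates are clamped to zero with the deficit
#' transferred to the adjacent edge.
#'
#' @param dm Symmetric distance matrix (labels as dimnames) or `dist`.
#' @return A rooted `phylo` tree.
#' @export
build_nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm), tol = 1e-8)) {
    rlang::abort("distance matrix must be symmetric")
  }
  if (nrow(dm) < 3) rlang::abort("need at least 3 labels")
  tr <- ape::nj(stats::as.dist(dm))
  # clamp negative edges, moving the deficit to the sibling edge so leaf
  # path lengths are preserved as far as possible
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent & seq_along(tr$edge.length) != e)
    if (length(sibs)) {
      tr$edge.length[sibs[1]] <- max(0, tr$edge.length[sibs[1]] + deficit)
    }
  }
  phangorn::midpoint(tr)
}

#' Assign genomes to lineages by node-depth cutoffs
#'
#' Node depth is the summed branch length from the (midpoint) root. For
#' each cutoff `c`, lineage roots are the shallowest nodes with depth
#' `>= c`; every leaf inherits the lineage of the first such node on its
#' root path, and leaves whose entire root path stays below `c` form
#' singleton lineages. Assignments at larger cutoffs refine those at
#' smaller ones.
#'
#' @param tree A rooted `phylo` with branch lengths (see
#'   [build_nj_tree()]).
#' @param depth_cutoffs Non-negative numeric cutoffs, sorted ascending.
#' @return A tibble `genome_id`, `cutoff`, `lineage`.
#' @export
assign_lineages <- function(tree, depth_cutoffs) {
  if (any(depth_cutoffs < 0)) rlang::abort("cutoffs must be non-negative")
  depth_cutoffs <- sort(depth_cutoffs)
  depths <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- rep(NA_integer_, ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  out <- purrr::map(depth_cutoffs, function(cut) {
    # walk from each leaf to the root, recording the shallowest ancestor
    # (incl. the leaf) whose depth >= cut
    lineage_node <- purrr::map_int(seq_len(ntip), function(leaf) {
      node <- leaf
      hit <- NA_integer_
      while (!is.na(node)) {
        if (depths[node] >= cut) hit <- node
        node <- parent[node]
      }
      if (is.na(hit)) leaf else hit  # whole path below cut -> singleton
    })
    labels <- match(lineage_node, sort(unique(lineage_node)))
    tibble::tibble(genome_id = tree$tip.label, cutoff = cut,
                   lineage = sprintf("L%g_%02d", cut, labels))
  })
  dplyr::bind_rows(out)
}

#' Completeness rule for assembled viral genomes
#'
#' @param family Viral family names.
#' @param min_length,max_length Genome size range (bp) per family.
#' @param hallmark_genes List of character vectors of required hallmark
#'   gene labels per family.
#' @return A tibble rule set for [filter_complete_genomes()].
#' @export
completeness_rule <- function(family, min_length, max_length,
                              hallmark_genes) {
  stopifnot(all(min_length < max_length))
  tibble::tibble(family = family, min_length = min_length,
                 max_length = max_length, hallmark_genes = hallmark_genes)
}

#' Filter contigs to complete genomes
#'
#' A contig is retained iff its length lies within the size range of its
#' assigned viral family and every required hallmark gene label is present.
#' Family assignments and hallmark flags are annotation inputs (produced
#' upstream); contigs whose family is absent from the rule set are recorded
#' as unevaluable and excluded with a warning.
#'
#' @param annotations Tibble with `contig_id`, `length`, `family` and
#'   `hallmarks` (list-column of character vectors of present hallmark
#'   labels).
#' @param rule A [completeness_rule()] tibble.
#' @return `annotations` with added columns `status`
#'   (`complete`/`incomplete`/`unevaluable`) and `complete` (logical).
#' @export
filter_complete_genomes <- function(annotations, rule) {
  idx <- match(annotations$family, rule$family)
  status <- character(nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    if (is.na(idx[i])) {
      status[i] <- "unevaluable"
      next
    }
    r <- rule[idx[i], ]
    size_ok <- annotations$length[i] >= r$min_length &&
      annotations$length[i] <= r$max_length
    hall_ok <- all(r$hallmark_genes[[1]] %in% annotations$hallmarks[[i]])
    status[i] <- if (size_ok && hall_ok) "complete" else "incomplete"
  }
  if (any(status == "unevaluable")) {
    rlang::warn(sprintf(
      "%d contig(s) with families absent from the rule set were excluded as unevaluable",
      sum(status == "unevaluable")))
  }
  dplyr::mutate(annotations, status = status,
                complete = status == "complete")
}
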