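#' Read-mapping configuration
#'
#' Reads map at a minimum percent identity, and a contig counts as present
#' in a sample only if a minimum fraction of its length is covered by
#' mapped reads (defaults 90% and 75%).
#'
#' @param min_read_identity Minimum percent identity for a read to map.
#' @param min_presence_coverage Minimum percent of the contig length that
#'   must be covered for the contig to be called present.
#' @return An object of class `vh_mapping_config`.
#' @export
mapping_config <- function(min_read_identity = 90,
                           min_presence_coverage = 75) {
  stopifnot(min_read_identity > 0, min_read_identity <= 100,
            min_presence_coverage > 0, min_presence_coverage <= 100)
  structure(list(min_read_identity = min_read_identity,
                 min_presence_coverage = min_presence_coverage),
            class = "vh_mapping_config")
}

#' Map reads to contigs and compute coverage profiles
#'
#' Each read is assigned to its best-scoring contig hit provided the hit
#' identity meets `min_read_identity`; reads tying across contigs are
#' discarded as ambiguous. Covered bases are the union of mapped subject
#' intervals, and the presence flag applies the coverage rule.
#'
#' @param reads,contigs DNA sequence tibbles.
#' @param config A [mapping_config()].
#' @param scheme,params Alignment scoring scheme and statistics.
#' @return A tibble of coverage profiles: `contig_id`, `contig_length`,
#'   `mapped_reads`, `covered_bases`, `covered_fraction`, `present`.
#' @export
map_reads <- function(reads, contigs, config = mapping_config(),
                      scheme = scoring_scheme(), params = ka_params()) {
  if (nrow(contigs) == 0) rlang::abort("contig set must be nonempty")
  hits <- align_search(reads, contigs, scheme, params, max_evalue = 10,
                       mode = "seeded")
  assigned <- empty_hits()
  n_ambig <- 0L
  if (nrow(hits) > 0) {
    # a read is judged by its best-scoring hit; the identity rule is then
    # applied to that hit, so a long low-identity alignment is not rescued
    # by a trimmed high-identity fragment of itself
    best <- hits |>
      dplyr::group_by(.data$qseqid) |>
      dplyr::filter(.data$raw_score == max(.data$raw_score)) |>
      dplyr::ungroup()
    per_read <- split(best, best$qseqid)
    amb <- purrr::map_lgl(per_read, ~ length(unique(.x$sseqid)) > 1)
    n_ambig <- sum(amb)
    assigned <- dplyr::bind_rows(purrr::map(per_read[!amb], ~ .x[1, ]))
    assigned <- assigned[assigned$pident >= config$min_read_identity, ,
                         drop = FALSE]
  }
  if (n_ambig > 0) {
    rlang::inform(sprintf("%d read(s) discarded as ambiguous (tied best hits)",
                          n_ambig))
  }
  n_mapped <- stats::setNames(integer(nrow(contigs)), contigs$id)
  if (nrow(assigned) > 0) {
    tab <- table(assigned$sseqid)
    n_mapped[names(tab)] <- as.integer(tab)
  }
  covered <- purrr::map_int(contigs$id, function(cid) {
    h <- assigned[assigned$sseqid == cid, , drop = FALSE]
    if (nrow(h) == 0) return(0L)
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(pmin(h$sstart, h$send), pmax(h$sstart, h$send)))))
  })
  len <- nchar(contigs$seq)
  tibble::tibble(
    contig_id = contigs$id,
    contig_length = len,
    mapped_reads = unname(n_mapped[contigs$id]),
    covered_bases = covered,
    covered_fraction = covered / len,
    present = covered / len >= config$min_presence_coverage / 100
  )
}

#' Normalize mapped-read counts by contig length and library size
#'
#' `abundance = mapped_reads / (contig_length / 1000) / (library_size /
#' 1e6)` — reads per kilobase of contig per million reads in the library.
#' Contigs not present get abundance 0.
#'
#' @param profiles Coverage tibble from [map_reads()].
#' @param library_size Total reads in the library, > 0.
#' @param respect_presence If `TRUE` (default) absent contigs get 0.
#' @return `profiles` with an `abundance` column.
#' @export
normalize_abundance <- function(profiles, library_size,
                                respect_presence = TRUE) {
  stopifnot(library_size > 0)
  if (any(profiles$contig_length <= 0)) {
    rlang::abort("zero-length contig in coverage profiles")
  }
  ab <- profiles$mapped_reads / (profiles$contig_length / 1000) /
    (library_size / 1e6)
  if (respect_presence) ab <- ifelse(profiles$present, ab, 0)
  dplyr::mutate(profiles, abundance = ab)
}

counts_matrix <- function(counts) {
  m <- as.matrix(counts[, -1, drop = FALSE])
  rownames(m) <- counts[[1]]
  m
}

#' Partition features by shared-site membership within one season
#'
#' A feature's site set is the set of sites where it is detected (count
#' > 0) in any replicate of the given season. Features fall into the seven
#' categories of the site power set (three single sites, three pairs,
#' `all`), and each sample's reads are fractionated over the categories.
#'
#' @param counts Count tibble (`feature_id` plus one column per sample).
#' @param meta Sample metadata (`sample_id`, `site`, `season`,
#'   `replicate`).
#' @param season Season label to partition within.
#' @return An object of class `vh_partition`: a list with `categories`
#'   (tibble `feature_id`, `category`) and `fractions` (tibble
#'   `sample_id`, `site`, `category`, `fraction`).
#' @export
partition_by_site <- function(counts, meta, season) {
  m <- meta[meta$season == season, ]
  sites <- sort(unique(meta$site))
  if (!setequal(unique(m$site), sites) || nrow(m) == 0) {
    rlang::abort("season must have samples from every site")
  }
  mat <- counts_matrix(counts)[, m$sample_id, drop = FALSE]
  site_of <- stats::setNames(m$site, m$sample_id)
  member <- purrr::map(rownames(mat), function(f) {
    s <- unique(site_of[colnames(mat)[mat[f, ] > 0]])
    sites[sites %in% s]
  })
  keep <- lengths(member) > 0
  site_order <- unique(meta$site)
  cats <- purrr::map_chr(member[keep], function(s) {
    if (length(s) == length(sites)) "all"
    else paste(site_order[site_order %in% s], collapse = "/")
  })
  categories <- tibble::tibble(feature_id = rownames(mat)[keep],
                               category = cats)
  fractions <- partition_fractions(mat[keep, , drop = FALSE], categories, m)
  structure(list(grouping = "site", season = season,
                 categories = categories, fractions = fractions),
            class = "vh_partition")
}

#' Partition features by shared-season membership within one site
#'
#' A feature's season set is the set of seasons where it is detected in
#' any replicate at the given site. Categories are `all` (all four
#' seasons), `spring/winter/fall` (exactly those three), `single` (one
#' season) and `other` (any other two- or three-season set).
#'
#' @inheritParams partition_by_site
#' @param site Site label to partition within.
#' @return A `vh_partition` object (see [partition_by_site()]).
#' @export
partition_by_season <- function(counts, meta, site) {
  m <- meta[meta$site == site, ]
  seasons <- sort(unique(meta$season))
  if (!setequal(unique(m$season), seasons) || nrow(m) == 0) {
    rlang::abort("site must have samples from every season")
  }
  mat <- counts_matrix(counts)[, m$sample_id, drop = FALSE]
  season_of <- stats::setNames(m$season, m$sample_id)
  member <- purrr::map(rownames(mat), function(f) {
    unique(season_of[colnames(mat)[mat[f, ] > 0]])
  })
  keep <- lengths(member) > 0
  cats <- purrr::map_chr(member[keep], function(s) {
    if (length(s) == length(seasons)) return("all")
    if (setequal(s, c("spring", "winter", "fall"))) {
      return("spring/winter/fall")
    }
    if (length(s) == 1) return("single")
    "other"
  })
  categories <- tibble::tibble(feature_id = rownames(mat)[keep],
                               category = cats)
  fractions <- partition_fractions(mat[keep, , drop = FALSE], categories, m)
  structure(list(grouping = "season", site = site,
                 categories = categories, fractions = fractions),
            class = "vh_partition")
}

partition_fractions <- function(mat, categories, m) {
  cat_of <- stats::setNames(categories$category, categories$feature_id)
  out <- purrr::map(m$sample_id, function(sid) {
    tot <- sum(mat[, sid])
    agg <- tapply(mat[, sid], cat_of[rownames(mat)], sum)
    tibble::tibble(sample_id = sid,
                   category = names(agg),
                   fraction = as.numeric(agg) / tot)
  })
  out <- dplyr::bind_rows(out)
  dplyr::left_join(out, m[, c("sample_id", "site", "season", "replicate")],
                   by = "sample_id")
}

#' Column-normalize a count table to relative abundance
#'
#' @param counts Count tibble (`feature_id` plus sample columns).
#' @return The tibble with each sample column divided by its sum.
#' @export
relative_abundance <- function(counts) {
  m <- counts_matrix(counts)
  cs <- colSums(m)
  if (any(cs == 0)) {
    rlang::abort(paste("all-zero sample(s):",
                       paste(colnames(m)[cs == 0], collapse = ", ")))
  }
  out <- sweep(m, 2, cs, `/`)
  dplyr::bind_cols(counts[, 1], tibble::as_tibble(out))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over features, computed
#' on relative abundances. Samples are the columns of the count table.
#'
#' @param counts Count tibble (`feature_id` plus sample columns), columns
#'   pre-normalized to relative abundance (see [relative_abundance()]).
#' @return A symmetric distance matrix with sample labels.
#' @export
bray_curtis <- function(counts) {
  m <- counts_matrix(counts)
  cs <- colSums(m)
  if (any(cs == 0)) {
    rlang::abort(paste("all-zero sample(s):",
                       paste(colnames(m)[cs == 0], collapse = ", ")))
  }
  as.matrix(vegan::vegdist(t(m), method = "bray"))
}

#' Mantel correlation between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries, with a seeded
#' label-permutation null: `p = (1 + #\{permuted r >= observed r\}) /
#' (1 + n_permutations)`.
#'
#' @param d1,d2 Distance matrices (or `dist`) over identical label sets.
#' @param n_permutations Number of permutations (>= 99).
#' @param seed Integer seed for the permutation null.
#' @return An object of class `vh_mantel`: list with `statistic`,
#'   `p_value`, `n_permutations`.
#' @export
mantel_test <- function(d1, d2, n_permutations = 999, seed = 1L) {
  if (inherits(d1, "dist")) d1 <- as.matrix(d1)
  if (inherits(d2, "dist")) d2 <- as.matrix(d2)
  stopifnot(n_permutations >= 99)
  if (is.null(rownames(d1)) || is.null(rownames(d2)) ||
      !identical(sort(rownames(d1)), sort(rownames(d2)))) {
    rlang::abort("distance matrices must share an identical label set")
  }
  d2 <- d2[rownames(d1), rownames(d1)]
  res <- with_seed(seed, {
    vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                  permutations = n_permutations)
  })
  structure(list(statistic = unname(res$statistic),
                 p_value = unname(res$signif),
                 n_permutations = n_permutations),
            class = "vh_mantel")
}

#' @export
print.vh_mantel <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

#' Virus-to-prokaryote ratio
#'
#' @param vlp_per_ml Virus-like particles per ml, > 0.
#' @param cells_per_ml Prokaryotic cells per ml, > 0.
#' @return `vlp_per_ml / cells_per_ml`, vectorized.
#' @export
virus_prokaryote_ratio <- function(vlp_per_ml, cells_per_ml) {
  if (any(cells_per_ml <= 0) || any(vlp_per_ml <= 0)) {
    rlang::abort("concentrations must be positive")
  }
  vlp_per_ml / cells_per_ml
}
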