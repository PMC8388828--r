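#' Simulation design for the synthetic study
#'
#' Bundles every knob of the synthetic-data generator: host genomes carrying
#' CRISPR arrays and tRNA genes, viral genomes carrying planted evidence
#' (protospacers, shared tRNAs, homologous segments), short-read libraries,
#' and site x season count matrices with designed shared-vs-unique
#' membership. Defaults emulate the sampling design of the study system:
#' three sites (head, mixed, river) by four seasons in triplicate.
#'
#' @param seed Integer master seed; all outputs are pure functions of
#'   `(design, seed)`.
#' @param n_hosts,n_viruses Numbers of host and virus genomes.
#' @param host_genome_length,virus_genome_length Genome lengths in bases.
#' @param array_spec List with `repeat_length`, `spacer_length`,
#'   `n_repeats`, `n_arrays_per_host` describing planted CRISPR arrays.
#' @param n_trnas_per_host,trna_length Planted tRNA genes per host genome
#'   and their length (literal marked sequences, 60-90 bp).
#' @param evidence_plan Tibble with one row per virus: `true_host` (host
#'   index), `plant_crispr`, `n_mismatches`, `plant_trna`,
#'   `plant_homology`, `segment_length`, `segment_identity`. `NULL` plants
#'   all three evidence types to a cycling true host with exact copies.
#' @param community_spec List with `sites`, `seasons`, `replicates`,
#'   `n_features`, `site_category_probs`, `season_category_probs`,
#'   `meanlog`, `sdlog` (log-normal abundance parameters), `library_size`.
#' @param read_spec List with `read_length`, `coverage` (target covered
#'   fraction per contig, in (0, 1)), `identity` (per-read, in (0, 1]).
#' @return A validated object of class `vh_sim_design`.
#' @export
sim_design <- function(seed = 1L,
                       n_hosts = 10L,
                       n_viruses = 50L,
                       host_genome_length = 20000L,
                       virus_genome_length = 5000L,
                       array_spec = list(repeat_length = 28L,
                                         spacer_length = 32L,
                                         n_repeats = 4L,
                                         n_arrays_per_host = 1L),
                       n_trnas_per_host = 2L,
                       trna_length = 72L,
                       evidence_plan = NULL,
                       community_spec = list(),
                       read_spec = list(read_length = 150L, coverage = 0.8,
                                        identity = 1)) {
  cs <- utils::modifyList(
    list(sites = c("head", "mixed", "river"),
         seasons = c("spring", "summer", "fall", "winter"),
         replicates = 3L, n_features = 100L,
         site_category_probs = NULL, season_category_probs = NULL,
         meanlog = 0, sdlog = 1, library_size = 1e5),
    community_spec
  )
  if (is.null(evidence_plan)) {
    evidence_plan <- tibble::tibble(
      virus = seq_len(n_viruses),
      true_host = rep_len(seq_len(n_hosts), n_viruses),
      plant_crispr = TRUE, n_mismatches = 0L,
      plant_trna = TRUE,
      plant_homology = TRUE, segment_length = 400L, segment_identity = 0.9
    )
  }
  d <- structure(
    list(seed = as.integer(seed), n_hosts = as.integer(n_hosts),
         n_viruses = as.integer(n_viruses),
         host_genome_length = as.integer(host_genome_length),
         virus_genome_length = as.integer(virus_genome_length),
         array_spec = array_spec, n_trnas_per_host = as.integer(n_trnas_per_host),
         trna_length = as.integer(trna_length),
         evidence_plan = evidence_plan, community_spec = cs,
         read_spec = read_spec),
    class = "vh_sim_design"
  )
  validate_design(d)
  d
}

validate_design <- function(d) {
  a <- d$array_spec
  stopifnot(d$n_hosts > 0, d$n_viruses > 0, d$host_genome_length > 0,
            d$virus_genome_length > 0, a$n_repeats >= 2,
            d$community_spec$replicates > 0, d$community_spec$n_features > 0)
  if (a$repeat_length < 21 || a$repeat_length > 48 ||
      a$spacer_length < 18 || a$spacer_length > 72) {
    rlang::abort(paste("repeat/spacer lengths must lie within the CRISPR",
                       "detector's default bounds (repeat 21-48, spacer 18-72)"))
  }
  array_len <- a$n_repeats * a$repeat_length +
    (a$n_repeats - 1) * a$spacer_length
  needed <- a$n_arrays_per_host * (array_len + 400) +
    d$n_trnas_per_host * (d$trna_length + 400)
  if (needed > d$host_genome_length) {
    rlang::abort("array/tRNA spec incompatible with host genome length")
  }
  ep <- d$evidence_plan
  stopifnot(nrow(ep) == d$n_viruses, all(ep$true_host >= 1),
            all(ep$true_host <= d$n_hosts),
            all(ep$segment_identity > 0 & ep$segment_identity <= 1))
  rs <- d$read_spec
  stopifnot(rs$read_length > 0, rs$identity > 0, rs$identity <= 1)
  invisible(d)
}

# deterministic per-stream seed derivation, kept below 2^31
derive_seed <- function(seed, stream, index = 0L) {
  as.integer((as.numeric(seed) * 48271 + stream * 99991 + index * 101) %%
               2147483629)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

new_truth <- function() {
  tibble::tibble(record_id = character(), kind = character(),
                 seq_id = character(), start = integer(), end = integer(),
                 source_id = character(), sequence = character(),
                 note = character())
}

truth_row <- function(record_id, kind, seq_id, start, end, source_id = NA,
                      sequence = NA, note = NA) {
  tibble::tibble(record_id = record_id, kind = kind, seq_id = seq_id,
                 start = as.integer(start), end = as.integer(end),
                 source_id = as.character(source_id),
                 sequence = as.character(sequence), note = as.character(note))
}

# sample non-overlapping insertion slots (with flanking buffer) on a genome
allocate_slots <- function(genome_length, widths, buffer = 200L) {
  taken <- IRanges::IRanges()
  starts <- integer(length(widths))
  for (i in seq_along(widths)) {
    w <- widths[i]
    for (try in 1:500) {
      s <- sample.int(genome_length - w + 1L, 1L)
      cand <- IRanges::IRanges(max(1L, s - buffer), min(genome_length,
                                                        s + w - 1L + buffer))
      if (length(IRanges::findOverlaps(cand, taken)) == 0) {
        taken <- c(taken, cand)
        starts[i] <- s
        break
      }
      if (try == 500) rlang::abort("could not place planted elements")
    }
  }
  starts
}

splice_in <- function(genome, start, insert) {
  paste0(substr(genome, 1, start - 1), insert,
         substr(genome, start + nchar(insert), nchar(genome)))
}

host_id_of <- function(i) sprintf("host%02d", i)
virus_id_of <- function(i) sprintf("virus%02d", i)

#' Simulate one host genome with planted CRISPR arrays and tRNA genes
#'
#' The genome background is i.i.d. uniform ACGT. Each planted array is
#' `n_repeats` identical copies of a random repeat separated by unique
#' random spacers; tRNA genes are literal marked random sequences. Identical
#' `(design$seed, host_index)` give byte-identical output.
#'
#' @param design A [sim_design()].
#' @param host_index Host number, 1-based, `<= design$n_hosts`.
#' @return A list with `genome` (one-row sequence tibble) and `truth`
#'   (tibble of planted-element records: one `crispr_array` row per array
#'   plus `crispr_repeat` and `spacer` rows, and `trna` rows).
#' @export
simulate_host_genome <- function(design, host_index) {
  stopifnot(inherits(design, "vh_sim_design"), host_index >= 1,
            host_index <= design$n_hosts)
  a <- design$array_spec
  gid <- host_id_of(host_index)
  with_seed(derive_seed(design$seed, 1L, host_index), {
    genome <- random_dna(design$host_genome_length)
    truth <- list()
    array_len <- a$n_repeats * a$repeat_length +
      (a$n_repeats - 1) * a$spacer_length
    n_arr <- a$n_arrays_per_host
    widths <- c(rep(array_len, n_arr),
                rep(design$trna_length, design$n_trnas_per_host))
    starts <- if (length(widths)) {
      allocate_slots(design$host_genome_length, widths)
    } else integer(0)
    if (n_arr > 0) {
      for (ai in seq_len(n_arr)) {
        rep_seq <- random_dna(a$repeat_length)
        spacers <- purrr::map_chr(seq_len(a$n_repeats - 1),
                                  ~ random_dna(a$spacer_length))
        s0 <- starts[ai]
        # recoverability: the columns flanking each repeat boundary must not
        # be unanimous across copies, or any consensus-based detector would
        # legitimately absorb them into the repeat
        right_flank <- substr(genome, s0 + a$n_repeats * a$repeat_length +
                                (a$n_repeats - 1) * a$spacer_length,
                              s0 + a$n_repeats * a$repeat_length +
                                (a$n_repeats - 1) * a$spacer_length)
        firsts <- c(substr(spacers, 1, 1), right_flank)
        if (length(unique(firsts)) == 1) {
          substr(spacers[1], 1, 1) <- setdiff(c("A", "C", "G", "T"),
                                              firsts[1])[1]
        }
        left_flank <- substr(genome, s0 - 1, s0 - 1)
        lasts <- c(left_flank,
                   substr(spacers, a$spacer_length, a$spacer_length))
        if (length(unique(lasts[nzchar(lasts)])) == 1) {
          substr(spacers[1], a$spacer_length,
                 a$spacer_length) <- setdiff(c("A", "C", "G", "T"),
                                             lasts[length(lasts)])[1]
        }
        unit <- paste0(rep_seq,
                       paste0(spacers, rep_seq, collapse = ""))
        genome <- splice_in(genome, s0, unit)
        truth[[length(truth) + 1]] <- truth_row(
          sprintf("%s:arr%d", gid, ai), "crispr_array", gid, s0,
          s0 + array_len - 1L, sequence = rep_seq)
        period <- a$repeat_length + a$spacer_length
        for (ri in seq_len(a$n_repeats)) {
          rs <- s0 + (ri - 1L) * period
          truth[[length(truth) + 1]] <- truth_row(
            sprintf("%s:arr%d:rep%d", gid, ai, ri), "crispr_repeat", gid,
            rs, rs + a$repeat_length - 1L, sequence = rep_seq)
        }
        for (si in seq_len(a$n_repeats - 1)) {
          ss <- s0 + (si - 1L) * period + a$repeat_length
          truth[[length(truth) + 1]] <- truth_row(
            sprintf("%s:arr%d:%d", gid, ai, si), "spacer", gid,
            ss, ss + a$spacer_length - 1L, sequence = spacers[si])
        }
      }
    }
    if (design$n_trnas_per_host > 0) {
      for (ti in seq_len(design$n_trnas_per_host)) {
        s0 <- starts[n_arr + ti]
        trna <- random_dna(design$trna_length)
        genome <- splice_in(genome, s0, trna)
        truth[[length(truth) + 1]] <- truth_row(
          sprintf("%s_trna%d", gid, ti), "trna", gid, s0,
          s0 + design$trna_length - 1L, sequence = trna)
      }
    }
    list(genome = seq_tbl(gid, genome, description = "synthetic host genome"),
         truth = if (length(truth)) dplyr::bind_rows(truth) else new_truth())
  })
}

#' Simulate all host genomes of a design
#'
#' @param design A [sim_design()].
#' @return A list with `genomes` (sequence tibble) and `truth` (combined
#'   planted-element records).
#' @export
simulate_hosts <- function(design) {
  out <- purrr::map(seq_len(design$n_hosts),
                    ~ simulate_host_genome(design, .x))
  list(genomes = dplyr::bind_rows(purrr::map(out, "genome")),
       truth = dplyr::bind_rows(purrr::map(out, "truth")))
}

#' Simulate one viral genome with planted host-linkage evidence
#'
#' Per the design's evidence plan the virus may carry: a protospacer copied
#' from one of its true host's CRISPR spacers with exactly `n_mismatches`
#' substitutions; a tRNA gene identical to one of the host's tRNAs; and a
#' homologous segment copied from the host genome at the stated length and
#' identity (substitutions only).
#'
#' @param design A [sim_design()].
#' @param virus_index Virus number, 1-based.
#' @param hosts Output of [simulate_hosts()] (genomes and truth records for
#'   the hosts referenced by the evidence plan).
#' @return A list with `genome` (one-row sequence tibble) and `truth`
#'   (records of kind `protospacer`, `trna`, `homology_segment` carrying
#'   coordinates on the virus and provenance in `source_id`).
#' @export
simulate_virus <- function(design, virus_index, hosts) {
  stopifnot(inherits(design, "vh_sim_design"), virus_index >= 1,
            virus_index <= design$n_viruses)
  plan <- design$evidence_plan[design$evidence_plan$virus == virus_index, ]
  stopifnot(nrow(plan) == 1)
  vid <- virus_id_of(virus_index)
  hid <- host_id_of(plan$true_host)
  host_truth <- hosts$truth[hosts$truth$seq_id == hid, ]
  with_seed(derive_seed(design$seed, 2L, virus_index), {
    genome <- random_dna(design$virus_genome_length)
    truth <- list()
    inserts <- list()
    if (isTRUE(plan$plant_crispr)) {
      sp <- host_truth[host_truth$kind == "spacer", ]
      if (nrow(sp) == 0) {
        rlang::abort(sprintf("plan for %s plants a protospacer but host %s has no spacers",
                             vid, hid))
      }
      sp <- sp[sample.int(nrow(sp), 1), ]
      proto <- mutate_dna(sp$sequence, plan$n_mismatches)$seq
      inserts[[length(inserts) + 1]] <- list(
        seq = proto, kind = "protospacer",
        record_id = paste0(vid, ":proto"), source_id = sp$record_id,
        note = sprintf("n_mismatches=%d", plan$n_mismatches))
    }
    if (isTRUE(plan$plant_trna)) {
      tr <- host_truth[host_truth$kind == "trna", ]
      if (nrow(tr) == 0) {
        rlang::abort(sprintf("plan for %s plants a tRNA but host %s has none",
                             vid, hid))
      }
      tr <- tr[sample.int(nrow(tr), 1), ]
      inserts[[length(inserts) + 1]] <- list(
        seq = tr$sequence, kind = "trna",
        record_id = paste0(vid, "_trna1"), source_id = tr$record_id,
        note = NA)
    }
    if (isTRUE(plan$plant_homology)) {
      hseq <- hosts$genomes$seq[hosts$genomes$id == hid]
      L <- plan$segment_length
      src <- sample.int(nchar(hseq) - L + 1L, 1)
      seg <- substr(hseq, src, src + L - 1L)
      n_subs <- round((1 - plan$segment_identity) * L)
      seg <- mutate_dna(seg, n_subs)$seq
      inserts[[length(inserts) + 1]] <- list(
        seq = seg, kind = "homology_segment",
        record_id = paste0(vid, ":hom"), source_id = hid,
        note = sprintf("source_start=%d;n_subs=%d", src, n_subs))
    }
    if (length(inserts)) {
      widths <- purrr::map_int(inserts, ~ nchar(.x$seq))
      starts <- allocate_slots(design$virus_genome_length, widths,
                               buffer = 100L)
      for (i in seq_along(inserts)) {
        ins <- inserts[[i]]
        genome <- splice_in(genome, starts[i], ins$seq)
        truth[[length(truth) + 1]] <- truth_row(
          ins$record_id, ins$kind, vid, starts[i],
          starts[i] + nchar(ins$seq) - 1L, source_id = ins$source_id,
          sequence = ins$seq, note = ins$note)
      }
    }
    list(genome = seq_tbl(vid, genome, description = "synthetic viral contig"),
         truth = if (length(truth)) dplyr::bind_rows(truth) else new_truth())
  })
}

#' Simulate all viral genomes of a design
#'
#' @inheritParams simulate_virus
#' @return A list with `genomes` and `truth` combined over viruses.
#' @export
simulate_viruses <- function(design, hosts) {
  out <- purrr::map(seq_len(design$n_viruses),
                    ~ simulate_virus(design, .x, hosts))
  list(genomes = dplyr::bind_rows(purrr::map(out, "genome")),
       truth = dplyr::bind_rows(purrr::map(out, "truth")))
}

#' Extract planted sequences of one kind as a sequence tibble
#'
#' Convenience accessor turning generator truth records (e.g. planted viral
#' tRNAs) into query sequences for the evidence searches.
#'
#' @param truth A truth-record tibble.
#' @param kind Record kind to extract.
#' @return A sequence tibble with the carrying sequence in `description`.
#' @export
truth_sequences <- function(truth, kind) {
  x <- truth[truth$kind == kind, ]
  seq_tbl(x$record_id, x$sequence, description = x$seq_id)
}

site_category_label <- function(sites, all_sites) {
  if (length(sites) == length(all_sites)) "all"
  else paste(all_sites[all_sites %in% sites], collapse = "/")
}

season_category_label <- function(seasons, all_seasons) {
  if (length(seasons) == length(all_seasons)) return("all")
  if (setequal(seasons, c("spring", "winter", "fall"))) {
    return("spring/winter/fall")
  }
  if (length(seasons) == 1) return("single")
  "other"
}

# deterministic largest-remainder allocation of n items to category probs
apportion <- function(n, probs) {
  raw <- n * probs / sum(probs)
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(probs))
}

#' Simulate a feature x sample count matrix with designed membership
#'
#' Each feature is assigned a site set and a season set from designed
#' category proportions; counts are log-normal within membership, zero
#' outside, and columns are rescaled so each sample sums to the designed
#' library size. Samples form the full site x season x replicate grid.
#'
#' @param design A [sim_design()].
#' @return A list with `counts` (tibble: `feature_id` plus one column per
#'   sample), `meta` (tibble: `sample_id`, `site`, `season`, `replicate`)
#'   and `truth` (per-feature membership with `site_category` and
#'   `season_category` labels).
#' @export
simulate_community_counts <- function(design) {
  cs <- design$community_spec
  sites <- cs$sites
  seasons <- cs$seasons
  site_cats <- c("all", sites,
                 utils::combn(sites, 2, paste, collapse = "/"))
  sp <- cs$site_category_probs
  if (is.null(sp)) {
    sp <- stats::setNames(c(0.25, rep(0.15, length(sites)),
                            rep(0.30 / choose(length(sites), 2),
                                choose(length(sites), 2))),
                          site_cats)
  }
  zp <- cs$season_category_probs
  if (is.null(zp)) {
    zp <- c(all = 0.4, `spring/winter/fall` = 0.15, single = 0.25,
            other = 0.2)
  }
  with_seed(derive_seed(design$seed, 3L), {
    n <- cs$n_features
    site_alloc <- apportion(n, sp)
    season_alloc <- apportion(n, zp)
    site_cat <- rep(names(site_alloc), site_alloc)
    season_cat <- rep(names(season_alloc), season_alloc)
    season_cat <- season_cat[sample.int(n)]
    fid <- sprintf("feat%04d", seq_len(n))
    feat_sites <- purrr::map(site_cat, function(cat) {
      if (cat == "all") sites else strsplit(cat, "/")[[1]]
    })
    feat_seasons <- purrr::map(season_cat, function(cat) {
      switch(cat,
             all = seasons,
             `spring/winter/fall` = c("spring", "winter", "fall"),
             single = sample(seasons, 1),
             other = {
               repeat {
                 k <- sample(2:3, 1)
                 ss <- sample(seasons, k)
                 if (!setequal(ss, c("spring", "winter", "fall"))) break
               }
               ss
             })
    })
    meta <- tidyr::expand_grid(site = sites, season = seasons,
                               replicate = seq_len(cs$replicates))
    meta <- dplyr::mutate(meta,
                          sample_id = sprintf("%s_%s_r%d", .data$site,
                                              .data$season, .data$replicate),
                          .before = 1)
    mat <- matrix(0, nrow = n, ncol = nrow(meta),
                  dimnames = list(fid, meta$sample_id))
    for (i in seq_len(n)) {
      in_member <- meta$site %in% feat_sites[[i]] &
        meta$season %in% feat_seasons[[i]]
      mat[i, in_member] <- stats::rlnorm(sum(in_member), cs$meanlog, cs$sdlog)
    }
    colsum <- colSums(mat)
    if (any(colsum == 0)) {
      rlang::abort("membership design leaves a sample with no features")
    }
    mat <- sweep(mat, 2, cs$library_size / colsum, `*`)
    counts <- tibble::as_tibble(mat, rownames = "feature_id")
    site_str <- purrr::map_chr(feat_sites,
                               ~ paste(sites[sites %in% .x], collapse = "/"))
    season_str <- purrr::map_chr(feat_seasons,
                                 ~ paste(seasons[seasons %in% .x],
                                         collapse = "/"))
    site_cat_lab <- purrr::map_chr(feat_sites, site_category_label, sites)
    season_cat_lab <- purrr::map_chr(feat_seasons, season_category_label,
                                     seasons)
    truth <- tibble::tibble(
      feature_id = fid,
      sites = site_str,
      seasons = season_str,
      site_category = site_cat_lab,
      season_category = season_cat_lab
    )
    list(counts = counts, meta = meta, truth = truth)
  })
}

#' Simulate short reads from contigs
#'
#' Reads are uniformly placed substrings (either strand) with per-read
#' substitutions to hit the target identity. The read count per contig is
#' chosen so the expected covered fraction under uniform placement,
#' `1 - exp(-n * read_length / contig_length)`, equals the target coverage.
#' Read ids encode the source contig, start and strand for truth checks.
#'
#' @param contigs Sequence tibble of source contigs.
#' @param read_spec List with `read_length`, `coverage` in (0, 1) and
#'   `identity` in (0, 1].
#' @param seed Integer seed.
#' @return A sequence tibble of reads.
#' @export
simulate_reads <- function(contigs, read_spec, seed = 1L) {
  rl <- read_spec$read_length
  cov <- read_spec$coverage
  ident <- read_spec$identity
  if (cov <= 0 || cov >= 1) {
    rlang::abort("read_spec$coverage must lie strictly between 0 and 1")
  }
  stopifnot(all(nchar(contigs$seq) >= rl))
  n_subs <- round((1 - ident) * rl)
  with_seed(derive_seed(seed, 4L), {
    out <- purrr::map(seq_len(nrow(contigs)), function(ci) {
      L <- nchar(contigs$seq[ci])
      n_reads <- ceiling(-L / rl * log(1 - cov))
      starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
      strands <- sample(c("+", "-"), n_reads, replace = TRUE)
      seqs <- substring(contigs$seq[ci], starts, starts + rl - 1L)
      seqs <- purrr::map_chr(seqs, ~ mutate_dna(.x, n_subs)$seq)
      seqs <- ifelse(strands == "-", revcomp(seqs), seqs)
      tibble::tibble(
        id = sprintf("%s|r%04d|%d|%s", contigs$id[ci], seq_len(n_reads),
                     starts, strands),
        description = contigs$id[ci], seq = seqs, alphabet = "dna")
    })
    dplyr::bind_rows(out)
  })
}
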