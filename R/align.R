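#' Alignment scoring scheme
#'
#' Defaults follow the classic blastn regime (match +2, mismatch -3, gap
#' open 5, gap extend 2) so that identity, mismatch and E-value semantics of
#' downstream evidence filters match BLAST tabular output. A gap of length L
#' costs `gap_open + L * gap_extend`.
#'
#' @param match Match reward (nucleotide mode), > 0.
#' @param mismatch Mismatch score (negative).
#' @param gap_open,gap_extend Gap penalties (non-negative).
#' @return An object of class `vh_scoring`.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = 5,
                           gap_extend = 2) {
  stopifnot(match > 0, gap_open >= 0, gap_extend >= 0)
  m <- matrix(mismatch, 5, 5)
  diag(m) <- match
  m[5, ] <- mismatch  # N never counts as a match
  m[, 5] <- mismatch
  structure(
    list(type = "dna", matrix = m, letters = NULL,
         gap_open = gap_open, gap_extend = gap_extend),
    class = "vh_scoring"
  )
}

#' Protein scoring scheme (BLOSUM62 by default)
#'
#' @param matrix_name Name of a substitution matrix shipped with Biostrings.
#' @param gap_open,gap_extend Gap penalties (blastp defaults 11/1).
#' @return An object of class `vh_scoring`.
#' @export
protein_scoring <- function(matrix_name = "BLOSUM62", gap_open = 11,
                            gap_extend = 1) {
  m <- get(utils::data(list = matrix_name, package = "Biostrings",
                       envir = environment()))
  structure(
    list(type = "protein", matrix = m, letters = rownames(m),
         gap_open = gap_open, gap_extend = gap_extend),
    class = "vh_scoring"
  )
}

#' Karlin-Altschul parameters for E-value computation
#'
#' Fixed published ungapped values: nucleotide lambda = 1.33, K = 0.621;
#' protein (BLOSUM62) lambda = 0.267, K = 0.041. The effective search space
#' is raw `m * n`. The E-value cutoffs used downstream (<= 1, <= 0.001) are
#' loose enough that any standard parameterization preserves filter outcomes
#' on genuine evidence hits.
#'
#' @param lambda Per-score rate, > 0.
#' @param K Constant, > 0.
#' @return An object of class `vh_ka_params`.
#' @export
ka_params <- function(lambda = 1.33, K = 0.621) {
  stopifnot(lambda > 0, K > 0)
  structure(list(lambda = lambda, K = K), class = "vh_ka_params")
}

#' @rdname ka_params
#' @export
ka_params_protein <- function(lambda = 0.267, K = 0.041) {
  ka_params(lambda, K)
}

#' Convert a raw alignment score to a bit score and E-value
#'
#' `bit = (lambda * raw - ln K) / ln 2`; `E = m * n * 2^(-bit)` with raw
#' query and database lengths as the search space. Vectorized over
#' `raw_score`.
#'
#' @param raw_score Raw alignment score(s).
#' @param query_length,database_length Search-space lengths, > 0.
#' @param params A [ka_params()] object.
#' @return A tibble with columns `bit_score` and `evalue`.
#' @export
#' @examples
#' compute_evalue(10, 100, 100, ka_params(lambda = log(2), K = 1))
compute_evalue <- function(raw_score, query_length, database_length,
                           params = ka_params()) {
  stopifnot(query_length > 0, database_length > 0)
  bit <- (params$lambda * raw_score - log(params$K)) / log(2)
  tibble::tibble(
    bit_score = bit,
    evalue = as.numeric(query_length) * as.numeric(database_length) * 2^(-bit)
  )
}

# raw score needed to reach an E-value of at most `evalue`
min_score_for_evalue <- function(evalue, query_length, database_length,
                                 params) {
  bit <- log2(as.numeric(query_length) * as.numeric(database_length) / evalue)
  (bit * log(2) + log(params$K)) / params$lambda
}

encode_seq <- function(seq, scheme) {
  if (scheme$type == "dna") encode_dna(seq) else encode_protein(seq, scheme$letters)
}

# raw HSPs for one (query, subject) pair; dna mode searches both strands.
# Coordinates are 1-based inclusive; minus-strand hits have sstart > send.
sw_pair <- function(qseq, sseq, scheme, min_score = 1e-9, max_hits = 25L) {
  qc <- encode_seq(qseq, scheme)
  run <- function(sc, strand, slen) {
    h <- .sw_hsps(qc, sc, scheme$matrix, scheme$gap_open, scheme$gap_extend,
                  min_score, as.integer(max_hits))
    h <- tibble::as_tibble(h)
    if (nrow(h) == 0) return(h)
    if (strand == "-") {
      s1 <- slen - h$sstart + 1L
      s2 <- slen - h$send + 1L
      h$sstart <- s1
      h$send <- s2
    }
    h
  }
  slen <- nchar(sseq)
  hits <- run(encode_seq(sseq, scheme), "+", slen)
  if (scheme$type == "dna") {
    hits <- dplyr::bind_rows(hits, run(encode_seq(revcomp(sseq), scheme),
                                       "-", slen))
  }
  hits
}

#' Exhaustive local alignment of one query against one subject
#'
#' Affine-gap Smith-Waterman returning all non-overlapping local alignments
#' with positive score, best first. Nucleotide mode searches both strands;
#' minus-strand hits are encoded BLAST-style with `sstart > send`.
#'
#' @param query,subject Single sequences: either character scalars or
#'   one-row sequence tibbles (see [seq_tbl()]).
#' @param scheme A [scoring_scheme()] or [protein_scoring()] object.
#' @param params [ka_params()] used for bit scores and E-values (database
#'   length = subject length).
#' @param min_score Minimum raw score to report.
#' @param max_hits Maximum number of alignments to extract.
#' @return A tibble of hits in BLAST tabular layout (`qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`, `qcovs`, plus `raw_score` and `matches`).
#' @export
smith_waterman <- function(query, subject, scheme = scoring_scheme(),
                           params = NULL, min_score = 1e-9, max_hits = 25L) {
  q <- as_single_seq(query)
  s <- as_single_seq(subject)
  if (is.null(params)) {
    params <- if (scheme$type == "dna") ka_params() else ka_params_protein()
  }
  hits <- sw_pair(q$seq, s$seq, scheme, min_score, max_hits)
  finish_hits(hits, q$id, s$id, nchar(q$seq), nchar(s$seq), params)
}

as_single_seq <- function(x) {
  if (is.character(x) && length(x) == 1) {
    return(list(id = "seq", seq = toupper(x)))
  }
  stopifnot(is.data.frame(x), nrow(x) == 1)
  list(id = x$id[[1]], seq = x$seq[[1]])
}

# attach ids, identity, coverage, E-values; order by the fixed tie-break
finish_hits <- function(hits, qid, sid, qlen, dblen, params) {
  if (nrow(hits) == 0) return(empty_hits())
  ev <- compute_evalue(hits$raw_score, qlen, dblen, params)
  out <- tibble::tibble(
    qseqid = qid,
    sseqid = sid,
    pident = hits$matches / hits$length * 100,
    length = hits$length,
    mismatch = hits$mismatches,
    gapopen = hits$gapopen,
    qstart = hits$qstart,
    qend = hits$qend,
    sstart = hits$sstart,
    send = hits$send,
    evalue = ev$evalue,
    bitscore = ev$bit_score,
    qcovs = (hits$qend - hits$qstart + 1) / qlen * 100,
    raw_score = hits$raw_score,
    matches = hits$matches
  )
  dplyr::arrange(out, dplyr::desc(.data$raw_score), .data$qstart,
                 pmin(.data$sstart, .data$send), .data$sseqid)
}

empty_hits <- function() {
  tibble::tibble(
    qseqid = character(), sseqid = character(), pident = numeric(),
    length = integer(), mismatch = integer(), gapopen = integer(),
    qstart = integer(), qend = integer(), sstart = integer(),
    send = integer(), evalue = numeric(), bitscore = numeric(),
    qcovs = numeric(), raw_score = numeric(), matches = integer()
  )
}

# cluster seed matches into diagonal bands, returning window bounds.
# Sparse clusters (<= 2 seeds) of long queries get reduced padding: any
# evidence-grade alignment produces dense seed clusters, so lone seeds are
# noise and need only a short extension margin.
seed_windows <- function(seeds, k, qlen, slen, pad, band = 24L,
                         max_gap = 300L, sparse_pad = 80L) {
  qpos <- seeds[, 1]
  spos <- seeds[, 2]
  dg <- spos - qpos
  o <- order(dg, spos)
  qpos <- qpos[o]; spos <- spos[o]; dg <- dg[o]
  grp <- cumsum(c(TRUE, diff(dg) > band | diff(spos) > max_gap |
                    diff(spos) < -max_gap))
  n <- rowsum(rep(1L, length(grp)), grp)[, 1]
  qmin <- tapply(qpos, grp, min)
  qmax <- tapply(qpos, grp, max)
  smin <- tapply(spos, grp, min)
  smax <- tapply(spos, grp, max)
  padv <- ifelse(n <= 2L & qlen > 150L, min(sparse_pad, pad), pad)
  data.frame(
    qlo = pmax(1L, as.integer(qmin) - padv),
    qhi = pmin(qlen, as.integer(qmax) + k - 1L + padv),
    slo = pmax(1L, as.integer(smin) - padv),
    shi = pmin(slen, as.integer(smax) + k - 1L + padv)
  )
}

seeded_pair_strand <- function(qc, sc, scheme, min_score, max_hits, k, pad,
                               seeds = NULL) {
  if (is.null(seeds)) seeds <- .kmer_seeds(qc, sc, as.integer(k))
  if (nrow(seeds) == 0) return(NULL)
  win <- seed_windows(seeds, k, length(qc), length(sc), pad)
  hits <- vector("list", nrow(win))
  for (wi in seq_len(nrow(win))) {
    qlo <- win$qlo[wi]; qhi <- win$qhi[wi]
    slo <- win$slo[wi]; shi <- win$shi[wi]
    h <- .sw_hsps(qc[qlo:qhi], sc[slo:shi], scheme$matrix, scheme$gap_open,
                  scheme$gap_extend, min_score, as.integer(max_hits))
    if (nrow(h) > 0) {
      h$qstart <- h$qstart + qlo - 1L
      h$qend <- h$qend + qlo - 1L
      h$sstart <- h$sstart + slo - 1L
      h$send <- h$send + slo - 1L
      hits[[wi]] <- tibble::as_tibble(h)
    }
  }
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0) return(NULL)
  # adjacent windows can rediscover the same alignment: keep the best hit of
  # any set overlapping on both query and subject
  hits <- dplyr::arrange(hits, dplyr::desc(.data$raw_score), .data$qstart,
                         .data$sstart)
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    if (i < nrow(hits)) {
      j <- seq(i + 1L, nrow(hits))
      ov <- keep[j] &
        hits$qstart[j] <= hits$qend[i] & hits$qend[j] >= hits$qstart[i] &
        hits$sstart[j] <= hits$send[i] & hits$send[j] >= hits$sstart[i]
      keep[j][ov] <- FALSE
    }
  }
  hits[keep, , drop = FALSE]
}

#' Search query sequences against a subject database
#'
#' Equivalent to [smith_waterman()] over all query-subject pairs, filtered
#' to `evalue <= max_evalue` against the whole-database search space. The
#' default `"seeded"` mode restricts the dynamic programming to windows
#' around exact k-mer seed clusters; `"exhaustive"` runs the full matrix and
#' is intended for small inputs and oracle tests. For queries shorter than
#' the window padding the two modes return identical hit sets.
#'
#' @param queries,subjects Sequence tibbles with a shared alphabet.
#' @param scheme Scoring scheme; defaults to nucleotide or protein defaults
#'   matching the query alphabet.
#' @param params [ka_params()]; defaults likewise.
#' @param max_evalue Report hits with E-value at most this.
#' @param mode `"seeded"` or `"exhaustive"`.
#' @param k Seed k-mer length (seeded mode, nucleotide only); 12 by
#'   default.
#' @param pad Window padding around a seed cluster; default
#'   `min(max(query length), 150) + 50`, which guarantees seeded and
#'   exhaustive hit sets agree for queries up to 150 residues.
#' @param max_hits_per_pair HSP cap per query-subject pair.
#' @return A hits tibble (see [smith_waterman()]).
#' @export
align_search <- function(queries, subjects, scheme = NULL, params = NULL,
                         max_evalue = 10, mode = c("seeded", "exhaustive"),
                         k = 12L, pad = NULL, max_hits_per_pair = 10L) {
  mode <- match.arg(mode)
  if (nrow(subjects) == 0) rlang::abort("subject set must be nonempty")
  if (nrow(queries) == 0) return(empty_hits())
  alphabet <- unique(c(queries$alphabet, subjects$alphabet))
  if (length(alphabet) != 1) {
    rlang::abort("queries and subjects mix alphabets")
  }
  if (is.null(scheme)) {
    scheme <- if (alphabet == "dna") scoring_scheme() else protein_scoring()
  }
  if (is.null(params)) {
    params <- if (alphabet == "dna") ka_params() else ka_params_protein()
  }
  if (alphabet == "protein") mode <- "exhaustive"
  dblen <- sum(nchar(subjects$seq))
  if (is.null(pad)) pad <- min(max(nchar(queries$seq)), 150L) + 50L
  qlens <- nchar(queries$seq)
  min_sc <- pmax(1e-9, min_score_for_evalue(max_evalue, qlens, dblen, params))
  if (mode == "exhaustive") {
    out <- purrr::map(seq_len(nrow(queries)), function(qi) {
      per_subject <- purrr::map(seq_len(nrow(subjects)), function(si) {
        hits <- sw_pair(queries$seq[[qi]], subjects$seq[[si]], scheme,
                        min_sc[qi], max_hits_per_pair)
        if (nrow(hits) == 0) return(NULL)
        finish_hits(hits, queries$id[[qi]], subjects$id[[si]], qlens[qi],
                    dblen, params)
      })
      dplyr::bind_rows(per_subject)
    })
    out <- dplyr::bind_rows(out)
  } else {
    # subject-indexed batch seeding: each subject strand is hashed once and
    # all queries are streamed against it
    qcodes <- purrr::map(queries$seq, encode_dna)
    out <- list()
    for (si in seq_len(nrow(subjects))) {
      slen <- nchar(subjects$seq[[si]])
      for (strand in c("+", "-")) {
        sc <- if (strand == "+") encode_dna(subjects$seq[[si]]) else {
          encode_dna(revcomp(subjects$seq[[si]]))
        }
        seed_list <- .kmer_seeds_batch(qcodes, sc, as.integer(k))
        for (qi in seq_len(nrow(queries))) {
          if (nrow(seed_list[[qi]]) == 0) next
          hits <- seeded_pair_strand(qcodes[[qi]], sc, scheme, min_sc[qi],
                                     max_hits_per_pair, k, pad,
                                     seeds = seed_list[[qi]])
          if (is.null(hits) || nrow(hits) == 0) next
          if (strand == "-") {
            s1 <- slen - hits$sstart + 1L
            hits$send <- slen - hits$send + 1L
            hits$sstart <- s1
          }
          out[[length(out) + 1]] <- finish_hits(
            hits, queries$id[[qi]], subjects$id[[si]], qlens[qi], dblen,
            params)
        }
      }
    }
    out <- dplyr::bind_rows(out)
  }
  if (nrow(out) == 0) return(empty_hits())
  out <- dplyr::filter(out, .data$evalue <= max_evalue)
  dplyr::arrange(out, .data$qseqid, dplyr::desc(.data$raw_score),
                 .data$qstart, pmin(.data$sstart, .data$send), .data$sseqid)
}

#' Write hits as BLAST tabular (outfmt 6 plus query coverage)
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore qcovs, tab-separated, no header.
#'
#' @param hits A hits tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore", "qcovs")
  readr::write_tsv(hits[, cols], path, col_names = FALSE)
  invisible(path)
}
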