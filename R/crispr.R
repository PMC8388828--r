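#' CRISPR detector configuration
#'
#' Conventional CRT-style bounds: admissible repeat and spacer lengths, the
#' minimum number of repeat copies, the minimum per-copy identity to the
#' repeat consensus, the exact seed k-mer length and the window within
#' which a seed pair may anchor an array.
#'
#' @param repeat_length Length-2 range of admissible repeat lengths (bp).
#' @param spacer_length Length-2 range of admissible spacer lengths (bp).
#' @param min_repeats Minimum repeat copies per array (>= 2).
#' @param min_repeat_consensus_identity Minimum fraction identity of each
#'   copy to the array consensus.
#' @param seed_kmer Exact seed length anchoring candidate repeat pairs.
#' @param window Maximum distance between seed matches of a candidate pair.
#' @return An object of class `vh_crispr_config`.
#' @export
crispr_config <- function(repeat_length = c(21L, 48L),
                          spacer_length = c(18L, 72L),
                          min_repeats = 3L,
                          min_repeat_consensus_identity = 0.85,
                          seed_kmer = 8L,
                          window = 500L) {
  stopifnot(length(repeat_length) == 2, length(spacer_length) == 2,
            repeat_length[1] <= repeat_length[2],
            spacer_length[1] <= spacer_length[2], min_repeats >= 2)
  structure(
    list(repeat_length = as.integer(repeat_length),
         spacer_length = as.integer(spacer_length),
         min_repeats = as.integer(min_repeats),
         min_repeat_consensus_identity = min_repeat_consensus_identity,
         seed_kmer = as.integer(seed_kmer), window = as.integer(window)),
    class = "vh_crispr_config"
  )
}

frac_ident <- function(a, b) mean(a == b)

# column-wise majority base and agreement over a matrix of characters
column_consensus <- function(mat) {
  apply(mat, 2, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    c(base = names(tb)[1], agree = as.numeric(tb[1]) / length(col))
  })
}

# extend a candidate repeat pair outwards, mismatch-tolerant; returns
# 0-based offsets (rel to p) of the repeat interval, or NULL
extend_pair <- function(chars, p, q, k, max_len) {
  L <- length(chars)
  right_stop <- function(start_off) {
    miss <- 0L
    j <- start_off
    last_match <- start_off - 1L
    while (p + j <= L && q + j <= L && j - 0 < max_len + 10L) {
      if (chars[p + j] == chars[q + j]) {
        miss <- 0L
        last_match <- j
      } else {
        miss <- miss + 1L
        if (miss >= 2L) break
      }
      j <- j + 1L
    }
    last_match
  }
  left_stop <- function() {
    miss <- 0L
    j <- -1L
    last_match <- 0L
    while (p + j >= 1 && q + j >= 1 && -j < max_len + 10L) {
      if (chars[p + j] == chars[q + j]) {
        miss <- 0L
        last_match <- j
      } else {
        miss <- miss + 1L
        if (miss >= 2L) break
      }
      j <- j - 1L
    }
    last_match
  }
  b <- right_stop(k)
  a <- left_stop()
  c(a, b)
}

#' Detect CRISPR arrays in prokaryote genomes
#'
#' Seeds on exact k-mers recurring at an admissible period within a window,
#' extends candidate repeats to maximal agreement across all copies, and
#' accepts arrays passing the configured repeat-count, length and
#' consensus-identity thresholds. Degenerate tandem repeats (spacer length
#' below the configured minimum) are rejected as non-CRISPR. Deterministic;
#' reported arrays never overlap.
#'
#' @param genomes A sequence tibble of one or more DNA genomes.
#' @param config A [crispr_config()].
#' @return A tibble with one row per array: `genome_id`, `array_id`,
#'   `repeat_consensus`, `n_repeats`, `start`, `end`, and list-columns
#'   `repeats` (tibble of repeat intervals) and `spacers` (tibble of
#'   `spacer_id`, `sequence`, `start`, `end`).
#' @export
find_arrays <- function(genomes, config = crispr_config()) {
  out <- purrr::map(seq_len(nrow(genomes)), function(i) {
    find_arrays_one(genomes$id[i], genomes$seq[i], config)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) empty_arrays() else out
}

empty_arrays <- function() {
  tibble::tibble(genome_id = character(), array_id = character(),
                 repeat_consensus = character(), n_repeats = integer(),
                 start = integer(), end = integer(), repeats = list(),
                 spacers = list())
}

find_arrays_one <- function(gid, seq, config) {
  L <- nchar(seq)
  k <- config$seed_kmer
  rep_rng <- config$repeat_length
  sp_rng <- config$spacer_length
  if (L < rep_rng[1]) return(empty_arrays())
  chars <- strsplit(seq, "")[[1]]
  min_period <- rep_rng[1] + sp_rng[1]
  max_period <- min(rep_rng[2] + sp_rng[2], config$window)
  starts <- seq_len(L - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  pos <- split(starts, kmers)
  pos <- pos[lengths(pos) >= 2]
  cand <- purrr::map(pos, function(p) {
    d <- diff(p)
    ok <- d >= min_period & d <= max_period
    if (!any(ok)) return(NULL)
    tibble::tibble(p = p[-length(p)][ok], d = d[ok])
  })
  cand <- dplyr::bind_rows(cand)
  if (nrow(cand) == 0) return(empty_arrays())
  cand <- dplyr::arrange(cand, .data$p, .data$d)
  covered <- rep(FALSE, L)
  arrays <- list()
  for (ci in seq_len(nrow(cand))) {
    p <- cand$p[ci]
    d <- cand$d[ci]
    if (covered[p]) next
    ab <- extend_pair(chars, p, p + d, k, rep_rng[2])
    rep_len <- ab[2] - ab[1] + 1L
    if (rep_len < rep_rng[1]) next
    if (rep_len > rep_rng[2]) rep_len <- rep_rng[2]
    if (d - rep_len < sp_rng[1] || d - rep_len > sp_rng[2]) next
    c0 <- p + ab[1]
    ref <- chars[c0:(c0 + rep_len - 1L)]
    # chain copies at period d in both directions
    chain_ids <- 0L
    i <- 1L
    repeat {
      s <- c0 + i * d
      if (s + rep_len - 1L > L) break
      if (frac_ident(chars[s:(s + rep_len - 1L)], ref) < 0.75) break
      chain_ids <- c(chain_ids, i)
      i <- i + 1L
    }
    i <- -1L
    repeat {
      s <- c0 + i * d
      if (s < 1L) break
      if (frac_ident(chars[s:(s + rep_len - 1L)], ref) < 0.75) break
      chain_ids <- c(i, chain_ids)
      i <- i - 1L
    }
    if (length(chain_ids) < config$min_repeats) next
    copy_starts <- c0 + sort(chain_ids) * d
    # refine boundaries using all copies: grow while a strict majority of
    # copies agrees on the column, then trim non-unanimous boundary columns
    lo <- 0L
    hi <- rep_len - 1L
    get_col <- function(j) {
      idx <- copy_starts + j
      if (any(idx < 1L | idx > L)) return(NULL)
      chars[idx]
    }
    unanim <- function(j) {
      col <- get_col(j)
      !is.null(col) && length(unique(col)) == 1L
    }
    while (hi - lo + 1L < rep_rng[2] && unanim(lo - 1L)) lo <- lo - 1L
    while (hi - lo + 1L < rep_rng[2] && unanim(hi + 1L)) hi <- hi + 1L
    # trim until the two outermost columns are both unanimous: a lone
    # coincidentally-unanimous spacer column cannot then freeze the boundary
    while (lo < hi - 1L && !(unanim(lo) && unanim(lo + 1L))) lo <- lo + 1L
    while (hi > lo + 1L && !(unanim(hi) && unanim(hi - 1L))) hi <- hi - 1L
    rep_len2 <- hi - lo + 1L
    if (rep_len2 < rep_rng[1] || rep_len2 > rep_rng[2]) next
    if (d - rep_len2 < sp_rng[1] || d - rep_len2 > sp_rng[2]) next
    copy_starts <- copy_starts + lo
    # consensus and per-copy identity; drop failing end copies
    mat <- t(vapply(copy_starts,
                    function(s) chars[s:(s + rep_len2 - 1L)],
                    character(rep_len2)))
    cons <- apply(mat, 2, function(col) {
      names(sort(table(col), decreasing = TRUE))[1]
    })
    idents <- apply(mat, 1, function(row) mean(row == cons))
    okc <- idents >= config$min_repeat_consensus_identity
    while (length(okc) && !okc[1]) {
      okc <- okc[-1]
      copy_starts <- copy_starts[-1]
    }
    while (length(okc) && !okc[length(okc)]) {
      okc <- okc[-length(okc)]
      copy_starts <- copy_starts[-length(copy_starts)]
    }
    if (length(copy_starts) < config$min_repeats || !all(okc)) next
    n_rep <- length(copy_starts)
    a_start <- copy_starts[1]
    a_end <- copy_starts[n_rep] + rep_len2 - 1L
    if (any(covered[a_start:a_end])) next
    ai <- length(arrays) + 1L
    repeats <- tibble::tibble(start = copy_starts,
                              end = copy_starts + rep_len2 - 1L)
    sp_start <- repeats$end[-n_rep] + 1L
    sp_end <- repeats$start[-1] - 1L
    spacers <- tibble::tibble(
      spacer_id = sprintf("%s:%d:%d", gid, ai, seq_len(n_rep - 1L)),
      sequence = substring(seq, sp_start, sp_end),
      start = sp_start, end = sp_end)
    arrays[[ai]] <- tibble::tibble(
      genome_id = gid, array_id = sprintf("%s:%d", gid, ai),
      repeat_consensus = paste(cons, collapse = ""),
      n_repeats = n_rep, start = a_start, end = a_end,
      repeats = list(repeats), spacers = list(spacers))
    covered[a_start:a_end] <- TRUE
  }
  if (length(arrays) == 0) return(empty_arrays())
  dplyr::bind_rows(arrays)
}

#' Extract spacers from detected arrays as query sequences
#'
#' @param arrays Output of [find_arrays()].
#' @return A sequence tibble, one record per spacer, with the source genome
#'   id in `description`.
#' @export
extract_spacers <- function(arrays) {
  if (nrow(arrays) == 0) {
    return(seq_tbl(character(), character()))
  }
  x <- tidyr::unnest(arrays[, c("genome_id", "spacers")], "spacers")
  seq_tbl(x$spacer_id, x$sequence, description = x$genome_id)
}
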