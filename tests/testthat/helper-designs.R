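# shared fixtures, built in code

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, replace = TRUE),
        collapse = "")
}

# substitute exactly n positions with a different base
mutate_seq <- function(seq, n_subs, positions = NULL) {
  if (n_subs == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  if (is.null(positions)) positions <- sample.int(length(chars), n_subs)
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# reads of fixed length tiling a known fraction of a contig, non-overlapping
tiled_reads <- function(contig_id, contig_seq, fraction, read_length = 100) {
  n <- floor(fraction * nchar(contig_seq) / read_length)
  starts <- seq(1, by = read_length, length.out = n)
  seq_tbl(sprintf("%s|t%03d", contig_id, seq_len(n)),
          substring(contig_seq, starts, starts + read_length - 1),
          description = contig_id)
}

# one-row evidence record with sensible hit fields, for scoring tests
fake_evidence <- function(virus_id, taxon_id, evidence_type) {
  tibble::tibble(virus_id = virus_id, taxon_id = taxon_id,
                 evidence_type = evidence_type,
                 qseqid = "q", sseqid = "s", pident = 100, length = 60L,
                 mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 60L,
                 sstart = 1L, send = 60L, evalue = 1e-10, bitscore = 100,
                 qcovs = 100, raw_score = 120, matches = 60L)
}

# a hit tibble row with every field a filter can inspect
hit_row <- function(pident = 100, length = 100L, mismatch = 0L,
                    qcovs = 100, evalue = 1e-10) {
  tibble::tibble(qseqid = "q", sseqid = "s", pident = pident,
                 length = as.integer(length), mismatch = as.integer(mismatch),
                 gapopen = 0L, qstart = 1L, qend = as.integer(length),
                 sstart = 1L, send = as.integer(length), evalue = evalue,
                 bitscore = 50, qcovs = qcovs, raw_score = 100,
                 matches = as.integer(length) - as.integer(mismatch))
}
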