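#' Write planted-element truth records as GFF3
#'
#' Feature kind goes in column 3, coordinates are 1-based inclusive, and
#' `record_id`/`source_id` are carried in the attributes column. Uses
#' rtracklayer when available, else writes the nine-column text directly.
#'
#' @param truth Truth-record tibble (from the simulators or
#'   [find_arrays()] converted via [arrays_as_truth()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(truth, path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- GenomicRanges::GRanges(
      seqnames = truth$seq_id,
      ranges = IRanges::IRanges(truth$start, truth$end),
      type = truth$kind, ID = truth$record_id,
      source_id = truth$source_id)
    rtracklayer::export(gr, path, format = "GFF3")
  } else {
    lines <- sprintf("%s\tvireco\t%s\t%d\t%d\t.\t+\t.\tID=%s%s",
                     truth$seq_id, truth$kind, truth$start, truth$end,
                     truth$record_id,
                     ifelse(is.na(truth$source_id), "",
                            paste0(";source_id=", truth$source_id)))
    writeLines(c("##gff-version 3", lines), path)
  }
  invisible(path)
}

#' Convert detected CRISPR arrays to truth-style interval records
#'
#' @param arrays Output of [find_arrays()].
#' @return A tibble in the truth-record layout (array, repeat and spacer
#'   intervals).
#' @export
arrays_as_truth <- function(arrays) {
  if (nrow(arrays) == 0) return(new_truth())
  rows <- purrr::map(seq_len(nrow(arrays)), function(i) {
    a <- arrays[i, ]
    reps <- a$repeats[[1]]
    sps <- a$spacers[[1]]
    dplyr::bind_rows(
      truth_row(a$array_id, "crispr_array", a$genome_id, a$start, a$end,
                sequence = a$repeat_consensus),
      truth_row(sprintf("%s:rep%d", a$array_id, seq_len(nrow(reps))),
                "crispr_repeat", a$genome_id, reps$start, reps$end),
      truth_row(sps$spacer_id, "spacer", a$genome_id, sps$start, sps$end,
                sequence = sps$sequence)
    )
  })
  dplyr::bind_rows(rows)
}

#' Write a count table and sample metadata as TSV
#'
#' @param counts Count tibble (`feature_id` plus sample columns).
#' @param meta Sample metadata tibble.
#' @param counts_path,meta_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_counts_tsv <- function(counts, meta, counts_path, meta_path) {
  readr::write_tsv(counts, counts_path)
  readr::write_tsv(meta, meta_path)
  invisible(c(counts_path, meta_path))
}

#' Read a count table and sample metadata written by [write_counts_tsv()]
#'
#' @param counts_path,meta_path Input paths.
#' @return A list with `counts` and `meta` tibbles.
#' @export
read_counts_tsv <- function(counts_path, meta_path) {
  list(counts = readr::read_tsv(counts_path, show_col_types = FALSE),
       meta = readr::read_tsv(meta_path, show_col_types = FALSE))
}

#' Write truth records as JSON
#'
#' @param truth Truth-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write host predictions as TSV
#'
#' @param predictions A `vh_host_predictions` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(predictions, path) {
  out <- dplyr::mutate(
    tibble::as_tibble(predictions),
    tied_taxa = purrr::map_chr(.data$tied_taxa, paste, collapse = ","))
  readr::write_tsv(out, path)
  invisible(path)
}
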