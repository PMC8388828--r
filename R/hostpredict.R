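#' Evidence filter for one virus-host association search
#'
#' Each of the three evidence searches applies a fixed set of cutoffs to
#' BLAST-tabular hits; a hit is retained only if it satisfies every
#' configured cutoff, and unset cutoffs (`NA`) are ignored.
#'
#' @param evidence_type `"crispr"`, `"trna"` or `"homology"`.
#' @param min_identity Minimum percent identity.
#' @param min_query_coverage Minimum percent query coverage, or `NA`.
#' @param max_mismatches Maximum mismatch count, or `NA`.
#' @param min_alignment_length Minimum alignment length (bp), or `NA`.
#' @param max_evalue Maximum E-value.
#' @return An object of class `vh_evidence_filter`.
#' @export
evidence_filter <- function(evidence_type, min_identity,
                            min_query_coverage = NA, max_mismatches = NA,
                            min_alignment_length = NA, max_evalue) {
  evidence_type <- match.arg(evidence_type, c("crispr", "trna", "homology"))
  structure(
    list(evidence_type = evidence_type, min_identity = min_identity,
         min_query_coverage = min_query_coverage,
         max_mismatches = max_mismatches,
         min_alignment_length = min_alignment_length,
         max_evalue = max_evalue),
    class = "vh_evidence_filter"
  )
}

#' The three default evidence filters
#'
#' CRISPR-spacer hits: identity >= 80%, query coverage >= 100%, at most 1
#' mismatch, E <= 1. Shared-tRNA hits: alignment length >= 60 bp, identity
#' >= 90%, query coverage >= 95%, at most 10 mismatches, E <= 0.001.
#' Homology hits: alignment length >= 300 bp, identity >= 50%, E <= 0.001.
#'
#' @return A named list of three [evidence_filter()] objects.
#' @export
default_filters <- function() {
  list(
    crispr = evidence_filter("crispr", min_identity = 80,
                             min_query_coverage = 100, max_mismatches = 1,
                             max_evalue = 1),
    trna = evidence_filter("trna", min_identity = 90,
                           min_query_coverage = 95, max_mismatches = 10,
                           min_alignment_length = 60, max_evalue = 0.001),
    homology = evidence_filter("homology", min_identity = 50,
                               min_alignment_length = 300,
                               max_evalue = 0.001)
  )
}

#' Consensus scoring weights
#'
#' Points added to a candidate taxon per evidence type present: CRISPR 3,
#' homology 2, shared tRNA 1.
#'
#' @param crispr,homology,trna Positive point weights.
#' @return A named numeric vector.
#' @export
scoring_weights <- function(crispr = 3, homology = 2, trna = 1) {
  stopifnot(crispr > 0, homology > 0, trna > 0)
  c(crispr = crispr, homology = homology, trna = trna)
}

#' Apply an evidence filter to alignment hits
#'
#' @param hits A hits tibble (see [smith_waterman()]).
#' @param filter An [evidence_filter()].
#' @return The retained subset of `hits`.
#' @export
filter_hits <- function(hits, filter) {
  needed <- c("pident", "evalue")
  if (!is.na(filter$min_query_coverage)) needed <- c(needed, "qcovs")
  if (!is.na(filter$max_mismatches)) needed <- c(needed, "mismatch")
  if (!is.na(filter$min_alignment_length)) needed <- c(needed, "length")
  missing <- setdiff(needed, names(hits))
  if (length(missing)) {
    rlang::abort(paste("hits lack fields the filter inspects:",
                       paste(missing, collapse = ", ")))
  }
  keep <- hits$pident >= filter$min_identity &
    hits$evalue <= filter$max_evalue
  if (!is.na(filter$min_query_coverage)) {
    keep <- keep & hits$qcovs >= filter$min_query_coverage
  }
  if (!is.na(filter$max_mismatches)) {
    keep <- keep & hits$mismatch <= filter$max_mismatches
  }
  if (!is.na(filter$min_alignment_length)) {
    keep <- keep & hits$length >= filter$min_alignment_length
  }
  hits[keep, , drop = FALSE]
}

#' Run the three evidence searches and collect filtered evidence
#'
#' Directionality follows the original searches: CRISPR spacers (query)
#' against viral contigs (subject); viral tRNAs (query) against host
#' genomes (subject); viral contigs (query) against host genomes (subject).
#' Each surviving hit is tagged with the candidate host taxon.
#'
#' @param spacers Spacer sequence tibble; the source genome id must be in
#'   `description` (as produced by [extract_spacers()]).
#' @param viruses Viral contig sequence tibble.
#' @param viral_trnas Viral tRNA sequence tibble; ids must be
#'   `<virus_id>_...` so the carrying virus can be recovered, or carry the
#'   virus id in `description`.
#' @param hosts Host genome sequence tibble.
#' @param taxon_of Tibble mapping `genome_id` to `taxon_id`; every host
#'   genome id must appear.
#' @param filters Named list of evidence filters (see [default_filters()]).
#' @param scheme,params Alignment scoring scheme and Karlin-Altschul
#'   parameters (nucleotide defaults).
#' @param mode Search mode passed to [align_search()].
#' @return A tibble of evidence records: `virus_id`, `taxon_id`,
#'   `evidence_type`, plus the hit columns.
#' @export
collect_evidence <- function(spacers, viruses, viral_trnas, hosts, taxon_of,
                             filters = default_filters(),
                             scheme = scoring_scheme(), params = ka_params(),
                             mode = "seeded") {
  if (nrow(hosts) == 0) {
    rlang::warn("empty host set; returning no evidence")
    return(empty_evidence())
  }
  if (!all(hosts$id %in% taxon_of$genome_id)) {
    rlang::abort("every host genome id must map to a taxon")
  }
  taxon <- stats::setNames(taxon_of$taxon_id, taxon_of$genome_id)
  ev <- list()
  if (nrow(spacers) > 0 && nrow(viruses) > 0) {
    hits <- align_search(spacers, viruses, scheme, params,
                         max_evalue = filters$crispr$max_evalue, mode = mode)
    hits <- filter_hits(hits, filters$crispr)
    if (nrow(hits) > 0) {
      ev[[length(ev) + 1]] <- dplyr::mutate(
        hits, virus_id = .data$sseqid,
        taxon_id = unname(taxon[spacers$description[
          match(.data$qseqid, spacers$id)]]),
        evidence_type = "crispr")
    }
  }
  if (!is.null(viral_trnas) && nrow(viral_trnas) > 0) {
    hits <- align_search(viral_trnas, hosts, scheme, params,
                         max_evalue = filters$trna$max_evalue, mode = mode)
    hits <- filter_hits(hits, filters$trna)
    if (nrow(hits) > 0) {
      vt_virus <- if (all(nzchar(viral_trnas$description))) {
        stats::setNames(viral_trnas$description, viral_trnas$id)
      } else {
        stats::setNames(sub("_.*$", "", viral_trnas$id), viral_trnas$id)
      }
      ev[[length(ev) + 1]] <- dplyr::mutate(
        hits, virus_id = unname(vt_virus[.data$qseqid]),
        taxon_id = unname(taxon[.data$sseqid]), evidence_type = "trna")
    }
  }
  if (nrow(viruses) > 0) {
    hits <- align_search(viruses, hosts, scheme, params,
                         max_evalue = filters$homology$max_evalue, mode = mode)
    hits <- filter_hits(hits, filters$homology)
    if (nrow(hits) > 0) {
      ev[[length(ev) + 1]] <- dplyr::mutate(
        hits, virus_id = .data$qseqid,
        taxon_id = unname(taxon[.data$sseqid]), evidence_type = "homology")
    }
  }
  if (length(ev) == 0) return(empty_evidence())
  out <- dplyr::bind_rows(ev)
  dplyr::relocate(out, "virus_id", "taxon_id", "evidence_type")
}

empty_evidence <- function() {
  dplyr::mutate(empty_hits(), virus_id = character(), taxon_id = character(),
                evidence_type = character()) |>
    dplyr::relocate("virus_id", "taxon_id", "evidence_type")
}

#' Consensus score per virus-taxon pair
#'
#' Each evidence TYPE present for a pair contributes its weight once,
#' regardless of hit multiplicity, so many weak homology HSPs can never
#' outvote a CRISPR match. Per-hit accumulation is available via
#' `per_hit = TRUE`.
#'
#' @param evidence Evidence tibble from [collect_evidence()].
#' @param weights A [scoring_weights()] vector.
#' @param per_hit If `TRUE`, every hit contributes its type weight.
#' @return A tibble `virus_id`, `taxon_id`, `score`.
#' @export
score_consensus <- function(evidence, weights = scoring_weights(),
                            per_hit = FALSE) {
  if (nrow(evidence) == 0) {
    return(tibble::tibble(virus_id = character(), taxon_id = character(),
                          score = numeric()))
  }
  x <- dplyr::select(evidence, "virus_id", "taxon_id", "evidence_type")
  if (!per_hit) x <- dplyr::distinct(x)
  x <- dplyr::mutate(x, points = unname(weights[.data$evidence_type]))
  x <- dplyr::group_by(x, .data$virus_id, .data$taxon_id)
  dplyr::summarise(x, score = sum(.data$points), .groups = "drop")
}

#' Call a putative host taxon per virus
#'
#' The top-scoring taxon is the putative host; ties are reported as
#' unresolved (`predicted_taxon = NA`, `tie = TRUE`) with all tied taxa
#' listed rather than broken arbitrarily.
#'
#' @param scores Score tibble from [score_consensus()].
#' @param evidence Optional evidence tibble, attached for inspection.
#' @return A tibble of class `vh_host_predictions`: `virus_id`,
#'   `predicted_taxon`, `score`, `tie`, `tied_taxa` (list-column), sorted
#'   by `virus_id`.
#' @export
predict_hosts <- function(scores, evidence = NULL) {
  if (nrow(scores) == 0) {
    out <- tibble::tibble(virus_id = character(),
                          predicted_taxon = character(), score = numeric(),
                          tie = logical(), tied_taxa = list())
  } else {
    out <- scores |>
      dplyr::group_by(.data$virus_id) |>
      dplyr::summarise(
        top_score = max(.data$score),
        tied_taxa = list(sort(.data$taxon_id[.data$score ==
                                               max(.data$score)])),
        .groups = "drop") |>
      dplyr::mutate(
        score = .data$top_score,
        tie = lengths(.data$tied_taxa) > 1,
        predicted_taxon = ifelse(.data$tie, NA_character_,
                                 purrr::map_chr(.data$tied_taxa, 1))) |>
      dplyr::select("virus_id", "predicted_taxon", "score", "tie",
                    "tied_taxa") |>
      dplyr::arrange(.data$virus_id)
  }
  structure(out, evidence = evidence,
            class = c("vh_host_predictions", class(out)))
}

#' End-to-end host prediction for a set of genomes
#'
#' Convenience wrapper: detects CRISPR arrays in the host genomes, extracts
#' spacers, runs the three evidence searches, scores the consensus and
#' calls hosts.
#'
#' @param viruses,hosts Sequence tibbles of viral contigs and host genomes.
#' @param viral_trnas Viral tRNA sequence tibble (annotations are inputs;
#'   no tRNA detector is run), or `NULL`.
#' @param taxon_of Genome-to-taxon map; defaults to one taxon per host
#'   genome named `tax_<genome id>`.
#' @param filters,weights,crispr_cfg,scheme,params,mode Stage parameters.
#' @return A [predict_hosts()] result.
#' @export
predict_virus_hosts <- function(viruses, hosts, viral_trnas = NULL,
                                taxon_of = NULL,
                                filters = default_filters(),
                                weights = scoring_weights(),
                                crispr_cfg = crispr_config(),
                                scheme = scoring_scheme(),
                                params = ka_params(), mode = "seeded") {
  if (is.null(taxon_of)) {
    taxon_of <- tibble::tibble(genome_id = hosts$id,
                               taxon_id = paste0("tax_", hosts$id))
  }
  spacers <- extract_spacers(find_arrays(hosts, crispr_cfg))
  ev <- collect_evidence(spacers, viruses, viral_trnas, hosts, taxon_of,
                         filters, scheme, params, mode)
  predict_hosts(score_consensus(ev, weights), ev)
}
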