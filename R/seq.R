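#' Build a tibble of sequence records
#'
#' Sequence collections throughout vireco are plain tibbles with columns
#' `id`, `description`, `seq` and `alphabet` (`"dna"` or `"protein"`), so
#' they compose with dplyr verbs like any other table.
#'
#' @param id Character vector of unique record ids.
#' @param seq Character vector of residues (upper case; `N`/`X` wildcards
#'   allowed).
#' @param description Optional character vector of free-text descriptions.
#' @param alphabet `"dna"` or `"protein"`.
#' @return A tibble with one row per record.
#' @export
#' @examples
#' seq_tbl(c("a", "b"), c("ACGT", "GGGT"))
seq_tbl <- function(id, seq, description = "", alphabet = "dna") {
  alphabet <- match.arg(alphabet, c("dna", "protein"))
  if (anyDuplicated(id)) {
    rlang::abort("sequence ids must be unique within a collection")
  }
  tibble::tibble(
    id = as.character(id),
    description = rep_len(as.character(description), length(id)),
    seq = toupper(as.character(seq)),
    alphabet = alphabet
  )
}

#' Read a FASTA file into a sequence tibble
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return A sequence tibble (see [seq_tbl()]).
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  x <- if (alphabet == "dna") {
    Biostrings::readDNAStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  full <- names(x)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  seq_tbl(id, as.character(x), desc, alphabet)
}

#' Write a sequence tibble to FASTA
#'
#' @param records A sequence tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  x <- if (identical(records$alphabet[1], "protein")) {
    Biostrings::AAStringSet(records$seq)
  } else {
    Biostrings::DNAStringSet(records$seq)
  }
  desc <- if ("description" %in% names(records)) records$description else ""
  names(x) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Reverse-complement DNA strings
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# integer codes for the aligner: DNA A/C/G/T -> 0:3, anything else -> 4
encode_dna <- function(seq) {
  code <- integer(256)
  code[] <- 5L
  code[utf8ToInt("A")] <- 1L
  code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L
  code[utf8ToInt("T")] <- 4L
  unname(code[utf8ToInt(seq)] - 1L)
}

encode_protein <- function(seq, letters) {
  code <- integer(256)
  code[] <- match("X", letters)
  code[utf8ToInt(paste(letters, collapse = ""))] <- seq_along(letters)
  unname(code[utf8ToInt(seq)] - 1L)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute k random positions with a different base; returns list(seq, pos)
mutate_dna <- function(seq, n_subs, positions = NULL) {
  if (n_subs == 0) return(list(seq = seq, pos = integer(0)))
  chars <- strsplit(seq, "")[[1]]
  if (is.null(positions)) {
    positions <- sort(sample.int(length(chars), n_subs))
  }
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  list(seq = paste(chars, collapse = ""), pos = positions)
}
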