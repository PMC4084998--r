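#' Read a protein multi-FASTA file
#'
#' Reads protein sequences from a FASTA file, uppercases them and returns
#' them in file order. Headers are kept as record ids; sequence content is
#' not filtered here — see [normalize_chains()] for handling of nonstandard
#' residues.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first word of the header) and
#'   `sequence` (uppercased residue string), one row per record.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKV", ">p2", "ac"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) {
      stop("malformed FASTA in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0L) stop("FASTA file has no records: ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  empty <- which(!nzchar(seqs))
  if (length(empty) > 0L) {
    stop("FASTA record with empty sequence: ", ids[empty[1L]], call. = FALSE)
  }
  tibble::tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write sequences to a multi-FASTA file
#'
#' @param seqs A character vector of sequences, or a data frame with
#'   `sequence` (and optionally `id`) columns.
#' @param path Output file path.
#' @param ids Record ids; defaults to the `id` column when present, else
#'   `seq1`, `seq2`, ...
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, ids = NULL) {
  if (is.data.frame(seqs)) {
    if (is.null(ids) && "id" %in% names(seqs)) ids <- seqs$id
    seqs <- seqs$sequence
  }
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  set <- Biostrings::BStringSet(as.character(seqs))
  names(set) <- ids
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta")
  invisible(path)
}

#' Normalize raw sequences into analyzable chains
#'
#' Restricts sequences to the 20-letter standard amino-acid alphabet.
#' Under `policy = "split"` each sequence is cut at every nonstandard
#' character (X, B, Z, U, `*`, gaps, ...), yielding sub-chains; empty
#' fragments are dropped. This way an ambiguous residue never anchors or
#' terminates a first passage and never contributes to a separation
#' distance. Under `policy = "drop_chain"` any sequence containing a
#' nonstandard character is discarded whole.
#'
#' @param raw A character vector of raw sequences, or a data frame with a
#'   `sequence` column (e.g. from [read_fasta()]).
#' @param policy `"split"` (default) or `"drop_chain"`.
#' @return A tibble with columns `protein` (index of the source sequence),
#'   `chain_id` and `sequence`; every character of every chain is in
#'   [aa_alphabet()].
#' @export
#' @examples
#' normalize_chains(c("MKXVA", "ACDE"))
#' normalize_chains(c("MKXVA", "ACDE"), policy = "drop_chain")
normalize_chains <- function(raw, policy = c("split", "drop_chain")) {
  policy <- match.arg(policy)
  if (is.data.frame(raw)) raw <- raw$sequence
  raw <- toupper(as.character(raw))
  bad_re <- paste0("[^", paste(AA20, collapse = ""), "]+")
  if (policy == "drop_chain") {
    keep <- !stringr::str_detect(raw, bad_re)
    pieces <- as.list(raw[keep])
    protein <- which(keep)
  } else {
    pieces <- stringr::str_split(raw, bad_re)
    protein <- rep(seq_along(raw), lengths(pieces))
    pieces <- unlist(pieces, use.names = FALSE)
    nz <- nzchar(pieces)
    pieces <- as.list(pieces[nz])
    protein <- protein[nz]
  }
  seqs <- unlist(pieces, use.names = FALSE)
  if (is.null(seqs)) seqs <- character(0)
  tibble::tibble(
    protein = protein,
    chain_id = if (length(seqs)) paste0("chain", seq_along(seqs)) else character(0),
    sequence = seqs
  )
}

#' Read an organism metadata table
#'
#' Reads the tab-separated study table describing one organism per row:
#' a unique id, a display name, the optimal growth temperature (OGT) in
#' degrees Celsius, and the path to the organism's proteome FASTA.
#'
#' @param path Path to a TSV file with header columns `organism_id`,
#'   `name`, `ogt_celsius`, `fasta_path`.
#' @return A tibble with those four columns, `ogt_celsius` numeric.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  meta <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("organism_id", "name", "ogt_celsius", "fasta_path")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0L) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ogt <- suppressWarnings(as.numeric(meta$ogt_celsius))
  bad <- which(is.na(ogt) | !is.finite(ogt))
  if (length(bad) > 0L) {
    stop("non-numeric OGT in metadata row ", bad[1L], ": \"",
         meta$ogt_celsius[bad[1L]], "\"", call. = FALSE)
  }
  if (anyDuplicated(meta$organism_id)) {
    stop("duplicate organism_id in metadata: ",
         meta$organism_id[duplicated(meta$organism_id)][1L], call. = FALSE)
  }
  tibble::tibble(
    organism_id = meta$organism_id,
    name = meta$name,
    ogt_celsius = ogt,
    fasta_path = meta$fasta_path
  )
}

#' Write an organism metadata table
#'
#' @param meta A data frame with columns `organism_id`, `name`,
#'   `ogt_celsius`, `fasta_path`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  required <- c("organism_id", "name", "ogt_celsius", "fasta_path")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0L) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_tsv(meta[required], path)
  invisible(path)
}
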