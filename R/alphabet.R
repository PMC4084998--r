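# 20-letter standard amino-acid alphabet, alphabetical by one-letter code.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V")

#' The 20-letter standard amino-acid alphabet
#'
#' One-letter codes for the twenty standard amino acids. All first-passage
#' statistics in this package are defined over this alphabet; nonstandard
#' residues (X, B, Z, U, gaps, stops) are handled by [normalize_chains()]
#' before any counting.
#'
#' @return A character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() AA20

# Integer-encode residues; error on characters outside the alphabet.
aa_encode <- function(chars) {
  code <- match(chars, AA20)
  if (anyNA(code)) {
    bad <- unique(chars[is.na(code)])
    stop("residue(s) outside the 20-letter amino-acid alphabet: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  code
}

check_aa <- function(x, arg = deparse(substitute(x))) {
  if (!is.character(x) || length(x) != 1L || !x %in% AA20) {
    stop("`", arg, "` must be a single one-letter amino-acid code (one of ",
         paste(AA20, collapse = ""), ")", call. = FALSE)
  }
  x
}

check_direction <- function(direction) {
  if (!is.character(direction) || length(direction) != 1L ||
      !direction %in% c("N", "C")) {
    stop('`direction` must be "N" or "C"', call. = FALSE)
  }
  direction
}

# Chains argument: accepts a character vector of sequences or a data frame
# with a `sequence` column (as returned by read_fasta()/normalize_chains()).
as_chains <- function(chains) {
  if (is.data.frame(chains)) {
    if (!"sequence" %in% names(chains)) {
      stop("data-frame input must have a `sequence` column", call. = FALSE)
    }
    chains <- chains$sequence
  }
  chains <- as.character(chains)
  chains <- chains[nchar(chains) > 0L]
  if (length(chains) == 0L) stop("no non-empty chains supplied", call. = FALSE)
  chains
}
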