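#' Read a FASTA file into a validated string set
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] /
#' [Biostrings::readDNAStringSet()] that enforces the package's record
#' contract: sequences are uppercased, must be non-empty, must use the
#' restricted alphabet (20 amino acids plus `X`, or `ACGTN`), and ids must be
#' unique.  Gap characters are rejected.
#'
#' @param path path to a FASTA file.
#' @param type `"protein"` or `"dna"`.
#' @return An [Biostrings::AAStringSet] or [Biostrings::DNAStringSet], in file
#'   order, named by the first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- if (type == "protein") {
    Biostrings::readBStringSet(path)
  } else {
    Biostrings::readBStringSet(path)
  }
  ids <- sub("\\s.*$", "", names(raw))
  seqs <- toupper(as.character(raw))
  validate_fasta_records(ids, seqs, type)
  names(seqs) <- ids
  if (type == "protein") Biostrings::AAStringSet(seqs) else Biostrings::DNAStringSet(seqs)
}

validate_fasta_records <- function(ids, seqs, type) {
  if (anyNA(ids) || any(ids == "")) stop("malformed FASTA header: empty record id")
  if (anyDuplicated(ids)) {
    stop("duplicate record id: ", ids[duplicated(ids)][1L])
  }
  empty <- !nzchar(seqs)
  if (any(empty)) stop("empty sequence for record: ", ids[empty][1L])
  allowed <- if (type == "protein") "ACDEFGHIKLMNPQRSTVWYX" else "ACGTN"
  bad <- grepl(sprintf("[^%s]", allowed), seqs)
  if (any(bad)) {
    id <- ids[bad][1L]
    ch <- sub(sprintf("^[%s]*", allowed), "", seqs[bad][1L])
    stop("invalid character '", substr(ch, 1L, 1L), "' in record: ", id)
  }
  invisible(TRUE)
}

#' Write sequences to FASTA
#'
#' @param x a named [Biostrings::XStringSet] or named character vector.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  if (is.null(names(x))) stop("sequences must be named")
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}
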