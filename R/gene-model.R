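#' Construct a gene model
#'
#' A gene model is an exon chain on one strand of a contig, with an optional
#' CDS annotation.  Intervals are 1-based inclusive genomic coordinates;
#' exons are stored in ascending genomic order and must not overlap; every
#' CDS interval must be contained in an exon.
#'
#' @param gene_id gene identifier.
#' @param contig contig/chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons an [IRanges::IRanges], or a two-column matrix/data.frame of
#'   start/end positions.
#' @param cds optional CDS intervals in the same form.
#' @return An object of class `GeneModel`.
#' @export
gene_model <- function(gene_id, contig, strand, exons, cds = NULL) {
  strand <- as.character(strand)
  if (!strand %in% c("+", "-")) stop("unknown strand for ", gene_id, ": ", strand)
  exons <- as_iranges(exons)
  if (length(exons) < 1L) stop("gene model needs at least one exon: ", gene_id)
  exons <- sort(exons)
  if (any(IRanges::start(exons) > IRanges::end(exons))) {
    stop("exon with start > end in ", gene_id)
  }
  if (length(exons) > 1L &&
      any(IRanges::start(exons)[-1L] <= IRanges::end(exons)[-length(exons)])) {
    stop("overlapping exons in ", gene_id)
  }
  if (!is.null(cds) && length(as_iranges(cds)) > 0L) {
    cds <- sort(as_iranges(cds))
    ov <- IRanges::findOverlaps(cds, exons, type = "within")
    if (length(unique(S4Vectors::queryHits(ov))) != length(cds)) {
      stop("CDS interval not contained in an exon: ", gene_id)
    }
  } else {
    cds <- NULL
  }
  structure(
    list(gene_id = gene_id, contig = contig, strand = strand,
         exons = exons, cds = cds),
    class = "GeneModel"
  )
}

#' Construct a transcript model
#'
#' Like [gene_model()] but identified by a transcript id with a parent gene
#' and a provenance tag; no CDS annotation is carried (the ORF is computed
#' from sequence).
#'
#' @param transcript_id transcript identifier.
#' @param gene_id parent gene identifier.
#' @param contig,strand,exons as in [gene_model()].
#' @param provenance `"reference"` or `"observed"`.
#' @return An object of class `TranscriptModel` (also a `GeneModel`).
#' @export
transcript_model <- function(transcript_id, gene_id, contig, strand, exons,
                             provenance = c("observed", "reference")) {
  provenance <- match.arg(provenance)
  m <- gene_model(gene_id, contig, strand, exons)
  m$transcript_id <- transcript_id
  m$provenance <- provenance
  class(m) <- c("TranscriptModel", "GeneModel")
  m
}

as_iranges <- function(x) {
  if (methods::is(x, "IRanges")) return(x)
  x <- as.matrix(as.data.frame(x))
  IRanges::IRanges(start = as.integer(x[, 1L]), end = as.integer(x[, 2L]))
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("<%s> %s %s(%s) %d exon(s), span %d-%d%s\n",
              class(x)[1L],
              if (!is.null(x$transcript_id)) x$transcript_id else x$gene_id,
              x$contig, x$strand, length(x$exons),
              min(IRanges::start(x$exons)), max(IRanges::end(x$exons)),
              if (is.null(x$cds)) "" else sprintf(", CDS %d bp", sum(IRanges::width(x$cds)))))
  invisible(x)
}

# exon chain in transcription order (5'->3')
exons_tx <- function(model) {
  ex <- model$exons
  if (model$strand == "-") rev(ex) else ex
}

# intron intervals in ascending genomic order; empty IRanges if single exon
introns_of <- function(model) {
  ex <- model$exons
  if (length(ex) < 2L) return(IRanges::IRanges())
  IRanges::IRanges(start = IRanges::end(ex)[-length(ex)] + 1L,
                   end = IRanges::start(ex)[-1L] - 1L)
}

# introns in transcription order
introns_tx <- function(model) {
  intr <- introns_of(model)
  if (model$strand == "-") rev(intr) else intr
}

# genomic coordinate of the first transcribed CDS base (the TIS)
cds_tss <- function(model) {
  if (is.null(model$cds)) stop("gene model has no CDS annotation: ", model$gene_id)
  if (model$strand == "+") min(IRanges::start(model$cds)) else max(IRanges::end(model$cds))
}

#' Spliced transcript sequence of a model
#'
#' Concatenates the exon sequences in transcription order (reverse complement
#' for minus-strand models).
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param model a `GeneModel` or `TranscriptModel`.
#' @return A [Biostrings::DNAString].
#' @export
transcript_sequence <- function(genome, model) {
  if (!model$contig %in% names(genome)) {
    stop("contig not found in genome: ", model$contig)
  }
  chr <- genome[[model$contig]]
  pieces <- Biostrings::extractAt(chr, model$exons)
  s <- Biostrings::DNAString(paste(vapply(pieces, as.character, ""), collapse = ""))
  if (model$strand == "-") Biostrings::reverseComplement(s) else s
}
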