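#' Number of introns of a gene
#'
#' For a gene model this is the number of exons minus one; the numeric
#' method applies the same arithmetic to exon counts (e.g. a column of the
#' packaged family table).
#'
#' @param x a `GeneModel`, or a vector of exon counts.
#' @param ... unused.
#' @return Integer intron count(s).
#' @export
intron_count <- function(x, ...) UseMethod("intron_count")

#' @export
intron_count.GeneModel <- function(x, ...) length(x$exons) - 1L

#' @export
intron_count.numeric <- function(x, ...) {
  if (any(x < 1L)) stop("exon counts must be >= 1")
  as.integer(x) - 1L
}

#' Is there an intron wholly upstream of the translation initiation site?
#'
#' TRUE iff at least one intron lies entirely 5' (in transcription
#' orientation) of the first CDS base.  An intron interrupting the start
#' codon does not count.
#'
#' @param model a `GeneModel` carrying a CDS annotation.
#' @return Logical scalar.
#' @export
utr_intron_before_tis <- function(model) {
  tis <- cds_tss(model)  # errors when CDS is missing
  intr <- introns_of(model)
  if (length(intr) == 0L) return(FALSE)
  if (model$strand == "+") {
    any(IRanges::end(intr) < tis)
  } else {
    any(IRanges::start(intr) > tis)
  }
}

#' Exon/intron architecture table
#'
#' One row per exon and intron of each model, in transcription order, with
#' genomic coordinates, lengths and intron phases.  The phase of an intron
#' is the cumulative number of CDS bases transcribed before it, modulo 3
#' (UTR bases excluded, matching GFF3 phase semantics).  Per gene, feature
#' lengths sum to the genomic span.
#'
#' @param models a list of `GeneModel` objects.
#' @return data.frame with `gene_id`, `feature`, `index` (1-based in
#'   transcription order), `start`, `end`, `length`, `phase` (introns only).
#' @export
exon_intron_table <- function(models) {
  if (inherits(models, "GeneModel")) models <- list(models)
  rows <- lapply(models, function(m) {
    ex <- exons_tx(m)
    intr <- introns_tx(m)
    exon_df <- data.frame(
      gene_id = m$gene_id, feature = "exon", index = seq_along(ex),
      start = IRanges::start(ex), end = IRanges::end(ex),
      width = IRanges::width(ex), phase = NA_integer_,
      stringsAsFactors = FALSE
    )
    if (length(intr) == 0L) return(exon_df)
    phase <- vapply(seq_along(intr), function(i) {
      if (is.null(m$cds)) return(NA_integer_)
      cds_before_intron(m, i)
    }, 0L)
    intron_df <- data.frame(
      gene_id = m$gene_id, feature = "intron", index = seq_along(intr),
      start = IRanges::start(intr), end = IRanges::end(intr),
      width = IRanges::width(intr), phase = phase %% 3L,
      stringsAsFactors = FALSE
    )
    out <- rbind(exon_df, intron_df)
    # interleave by transcription position
    key <- if (m$strand == "+") out$start else -out$end
    out[order(key), , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "width"] <- "length"
  rownames(out) <- NULL
  out
}

# CDS bases transcribed before intron i (transcription order), modulo nothing
cds_before_intron <- function(model, i) {
  intr <- introns_tx(model)[i]
  cds <- model$cds
  if (model$strand == "+") {
    upstream <- IRanges::restrict(cds, end = IRanges::start(intr) - 1L)
  } else {
    upstream <- IRanges::restrict(cds, start = IRanges::end(intr) + 1L)
  }
  as.integer(sum(IRanges::width(upstream)))
}
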