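#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features (via [rtracklayer::import()]) and
#' resolves ID/Parent links into one [gene_model()] per gene.  Multi-mRNA
#' genes take their first mRNA unless `transcript` names one.  Exon chains
#' are validated (non-overlapping; CDS contained in exons) and minus-strand
#' chains are returned in ascending genomic order with transcription order
#' derived from the strand.
#'
#' @param path path to a GFF3 file with 1-based inclusive coordinates.
#' @param transcript optional transcript (mRNA) ID to select for every gene
#'   that has it.
#' @return A named list of `GeneModel` objects, in file order of the gene
#'   features.
#' @export
read_gff3 <- function(path, transcript = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(S4Vectors::mcols(gr))) {
    vapply(gr$Parent, function(p) if (length(p)) as.character(p)[1L] else NA_character_, "")
  } else rep(NA_character_, length(gr))

  gene_idx <- which(type == "gene")
  models <- list()
  for (i in gene_idx) {
    gid <- ids[i]
    strand <- as.character(BiocGenerics::strand(gr[i]))
    if (!strand %in% c("+", "-")) stop("unknown strand for gene ", gid)
    mrna_idx <- which(type == "mRNA" & parents == gid)
    if (length(mrna_idx) > 0L) {
      pick <- mrna_idx[1L]
      if (!is.null(transcript) && transcript %in% ids[mrna_idx]) {
        pick <- mrna_idx[match(transcript, ids[mrna_idx])]
      }
      parent_id <- ids[pick]
    } else {
      parent_id <- gid
    }
    ex <- which(type == "exon" & parents == parent_id)
    cd <- which(type == "CDS" & parents == parent_id)
    if (length(ex) == 0L) stop("gene without exon features: ", gid)
    exons <- IRanges::ranges(gr[ex])
    cds <- if (length(cd)) IRanges::ranges(gr[cd]) else NULL
    models[[gid]] <- gene_model(gid, as.character(GenomicRanges::seqnames(gr[i])),
                                strand, exons, cds)
  }
  models
}

#' Write gene models to a GFF3 file
#'
#' Emits gene, mRNA, exon and CDS features with ID/Parent attributes, the
#' inverse of [read_gff3()].
#'
#' @param models a list of `GeneModel` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  contigs <- unique(vapply(models, function(m) m$contig, ""))
  rows <- lapply(models, function(m) {
    span <- range(m$exons)
    mrna_id <- paste0(m$gene_id, ".1")
    feat <- function(type, ranges, id = NA, parent = NA, phase = NA_integer_) {
      GenomicRanges::GRanges(
        seqnames = factor(m$contig, levels = contigs),
        ranges = ranges,
        strand = m$strand,
        type = type,
        ID = if (is.na(id)) NA_character_ else id,
        Parent = if (is.na(parent)) NA_character_ else parent,
        phase = phase
      )
    }
    parts <- list(
      feat("gene", span, id = m$gene_id),
      feat("mRNA", span, id = mrna_id, parent = m$gene_id),
      feat("exon", m$exons, parent = mrna_id)
    )
    if (!is.null(m$cds)) {
      # GFF3 phase: bases to skip at the feature 5' end to hit a codon start
      w_tx <- IRanges::width(if (m$strand == "-") rev(m$cds) else m$cds)
      before <- cumsum(c(0L, w_tx[-length(w_tx)]))
      phase_tx <- (3L - before %% 3L) %% 3L
      phase <- if (m$strand == "-") rev(phase_tx) else phase_tx
      parts <- c(parts, list(feat("CDS", m$cds, parent = mrna_id, phase = phase)))
    }
    do.call(c, parts)
  })
  gr <- do.call(c, unname(rows))
  gr$source <- "prxfam"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
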