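#' Extract the promoter of a gene
#'
#' The promoter is the `length` bases immediately 5' of the translation
#' initiation site (the first CDS base) in transcription orientation: on the
#' plus strand the bases upstream in genomic coordinates, on the minus
#' strand the reverse complement of the bases downstream.  Promoters
#' overhanging a contig edge are truncated with a warning.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param model a `GeneModel` with a CDS annotation.
#' @param length promoter length in bp (default 2500).
#' @return A [Biostrings::DNAString] reading 5' to 3' towards the gene.
#' @export
extract_promoter <- function(genome, model, length = 2500L) {
  if (!model$contig %in% names(genome)) {
    stop("contig not found in genome: ", model$contig)
  }
  chr <- genome[[model$contig]]
  tis <- cds_tss(model)
  if (model$strand == "+") {
    from <- tis - length
    if (from < 1L) {
      warning("promoter of ", model$gene_id, " truncated at contig start")
      from <- 1L
    }
    if (tis == 1L) return(Biostrings::DNAString(""))
    Biostrings::subseq(chr, from, tis - 1L)
  } else {
    to <- tis + length
    n <- length(chr)
    if (to > n) {
      warning("promoter of ", model$gene_id, " truncated at contig end")
      to <- n
    }
    if (tis == n) return(Biostrings::DNAString(""))
    Biostrings::reverseComplement(Biostrings::subseq(chr, tis + 1L, to))
  }
}

#' Scan a promoter against a cis-element catalogue
#'
#' Every occurrence of every consensus is reported, on both strands (or the
#' plus strand only), with IUPAC-aware exact matching: degenerate codes in
#' the consensus expand over A/C/G/T, promoter bases are taken literally
#' (an `N` in the promoter matches nothing).  Overlapping hits are allowed.
#' Output order is deterministic: offset, then element name.
#'
#' @param promoter a [Biostrings::DNAString] or character scalar
#'   (ACGTN alphabet), 5' to 3'.
#' @param catalogue data.frame with `name`, `consensus`, `class` (see
#'   [load_cis_catalogue()]).
#' @param strands `"both"` or `"plus"`.
#' @param gene_id optional id recorded in the output.
#' @return data.frame with `gene_id`, `name`, `class`, `offset` (1-based
#'   from the promoter 5' end), `strand`, `match` (promoter-forward
#'   substring).
#' @export
scan_elements <- function(promoter, catalogue, strands = c("both", "plus"),
                          gene_id = NA_character_) {
  strands <- match.arg(strands)
  subject <- Biostrings::DNAString(toupper(as.character(promoter)))
  hits <- list()
  for (i in seq_len(nrow(catalogue))) {
    pat <- Biostrings::DNAString(catalogue$consensus[i])
    one <- function(p, strand) {
      m <- Biostrings::matchPattern(p, subject,
                                    fixed = c(pattern = FALSE, subject = TRUE))
      if (length(m) == 0L) return(NULL)
      txt <- as.character(m)
      # an ambiguous promoter base (N) satisfies a degenerate pattern letter
      # under IUPAC matching; the record contract says it matches nothing
      keep <- !grepl("[^ACGT]", txt)
      if (!any(keep)) return(NULL)
      data.frame(gene_id = gene_id, name = catalogue$name[i],
                 class = catalogue$class[i],
                 offset = BiocGenerics::start(m)[keep], strand = strand,
                 match = txt[keep], stringsAsFactors = FALSE)
    }
    hits[[length(hits) + 1L]] <- one(pat, "+")
    if (strands == "both") {
      hits[[length(hits) + 1L]] <- one(Biostrings::reverseComplement(pat), "-")
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), name = character(),
                      class = character(), offset = integer(),
                      strand = character(), match = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$offset, out$name, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan many promoters
#'
#' @param promoters named [Biostrings::DNAStringSet] (or named character).
#' @param catalogue,strands as in [scan_elements()].
#' @return Row-bound hit table across genes.
#' @export
scan_promoters <- function(promoters, catalogue, strands = "both") {
  if (is.null(names(promoters))) stop("promoters must be named")
  seqs <- setNames(as.character(promoters), names(promoters))
  out <- lapply(names(seqs), function(id) {
    scan_elements(seqs[[id]], catalogue, strands, gene_id = id)
  })
  do.call(rbind, out)
}

#' Per-gene hit counts by element class
#'
#' Partitions hits by the catalogue's class labels and also reports how many
#' distinct element types of each class were hit.
#'
#' @param hits hit table from [scan_elements()]/[scan_promoters()].
#' @param catalogue the catalogue the hits were produced with.
#' @return data.frame with `gene_id`, `class`, `n_hits`, `n_types`.
#' @export
class_summary <- function(hits, catalogue) {
  unknown <- setdiff(hits$name, catalogue$name)
  if (length(unknown)) stop("unknown element name: ", unknown[1L])
  classes <- sort(unique(catalogue$class))
  genes <- unique(hits$gene_id)
  if (length(genes) == 0L) genes <- NA_character_
  grid <- expand.grid(gene_id = genes, class = classes,
                      stringsAsFactors = FALSE)
  grid$n_hits <- mapply(function(g, cl) {
    sum(hits$gene_id %in% g & hits$class == cl)
  }, grid$gene_id, grid$class)
  grid$n_types <- mapply(function(g, cl) {
    length(unique(hits$name[hits$gene_id %in% g & hits$class == cl]))
  }, grid$gene_id, grid$class)
  grid[order(grid$gene_id, grid$class), , drop = FALSE]
}
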