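# subclade label (as printed in the family table) -> active-site subfamily
SUBCLADE_TO_SUBFAMILY <- c(
  PRX1 = "2-CysPRX", PRX2 = "PRXIIE", TPX = "PRXIIB",
  PRXQ = "PRXQ", PRX5 = "PRXIIF", PRX6 = "1-CysPRX"
)

#' Load the packaged cotton PRX family table
#'
#' The packaged fixture transcribes the published characteristics of the 44
#' cotton PRX genes: ids, subclade, exon count, protein length, pI, MW and
#' chromosomal coordinates.  Known internal discrepancies of the published table
#' are recorded in the `notes` column rather than resolved.
#'
#' @return A data.frame with 44 rows and columns `gene_name`, `gene_id`,
#'   `subclade`, `exon_count`, `protein_length`, `pI`, `mw`, `chromosome`,
#'   `start`, `end`, `notes`, plus derived columns `species` (from the
#'   gene-name prefix: Gh, Gb, Gr or Ga) and `subfamily`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_prx_cotton.tsv", package = "prxfam",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  stopifnot(nrow(df) == 44L, all(df$exon_count >= 1L), all(df$start < df$end))
  df$species <- substr(df$gene_name, 1L, 2L)
  df$subfamily <- unname(SUBCLADE_TO_SUBFAMILY[df$subclade])
  df
}

#' Load a cis-element catalogue
#'
#' The packaged default carries 28 promoter element names in three classes
#' (9 abiotic, 10 hormone, 9 growth) with published
#' PlantCARE-style IUPAC consensus strings.  The catalogue is plain data and
#' can be replaced by any TSV with columns `name`, `consensus`, `class`.
#'
#' @param path optional path to a catalogue TSV; defaults to the packaged one.
#' @return A data.frame with columns `name`, `consensus`, `class`.
#' @export
load_cis_catalogue <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cis_element_catalogue.tsv",
                        package = "prxfam", mustWork = TRUE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("name", "consensus", "class")
  if (!all(need %in% names(df))) stop("catalogue needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$name)) stop("duplicate element name in catalogue")
  bad <- grepl("[^ACGTRYSWKMBDHVN]", toupper(df$consensus))
  if (any(bad)) stop("non-IUPAC consensus for element: ", df$name[bad][1L])
  df$consensus <- toupper(df$consensus)
  df
}
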