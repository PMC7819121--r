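#' Read a Ct measurement table
#'
#' @param path TSV with columns `gene`, `condition`, `timepoint`,
#'   `replicate`, `ct_target`, `ct_reference`.
#' @return A validated data.frame.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "condition", "timepoint", "replicate",
            "ct_target", "ct_reference")
  if (!all(need %in% names(df))) {
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  }
  ct <- c(df$ct_target, df$ct_reference)
  if (any(ct <= 0 | ct >= 45)) stop("Ct values must lie in (0, 45)")
  df
}

#' qPCR fold change by the three-step 2^-dCt procedure
#'
#' Per replicate, dCt1 = Ct(target) - Ct(reference housekeeping gene); the
#' stress dCt1 at each timepoint is compared against the mean control dCt1
#' at 0 h of the same gene (dCt2 = dCt1_stress - dCt1_control_0h); the fold
#' change is 2^(-dCt2).  The mean and standard deviation are taken over
#' replicate-level fold changes.
#'
#' @param stress,control data.frames in [read_ct_table()] layout.  `control`
#'   must contain a 0 h timepoint for every gene in `stress`.
#' @return data.frame with `gene`, `timepoint`, `fold_change` (replicate
#'   mean), `sd`, `n`.
#' @export
fold_change <- function(stress, control) {
  d1 <- function(df) df$ct_target - df$ct_reference
  out <- list()
  for (g in unique(stress$gene)) {
    ctrl0 <- control[control$gene == g & control$timepoint == 0, , drop = FALSE]
    if (nrow(ctrl0) == 0L) stop("missing control 0 h measurement for gene ", g)
    baseline <- mean(d1(ctrl0))
    sg <- stress[stress$gene == g, , drop = FALSE]
    for (tp in sort(unique(sg$timepoint))) {
      rep_rows <- sg[sg$timepoint == tp, , drop = FALSE]
      fc <- 2^(-(d1(rep_rows) - baseline))
      out[[length(out) + 1L]] <- data.frame(
        gene = g, timepoint = tp, fold_change = mean(fc),
        sd = if (length(fc) > 1L) stats::sd(fc) else 0,
        n = length(fc), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Log2-transform an expression (FPKM) matrix
#'
#' @param mat non-negative numeric matrix (genes x tissues).
#' @param pseudocount added before taking log2 so that zero FPKM maps to 0.
#' @param zscore if TRUE, per-gene (row) z-score normalization is applied
#'   after the transform.
#' @return Transformed matrix.
#' @export
log2_matrix <- function(mat, pseudocount = 1, zscore = FALSE) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("FPKM values must be non-negative")
  out <- log2(mat + pseudocount)
  if (zscore) {
    out <- t(apply(out, 1L, function(r) {
      s <- stats::sd(r)
      if (s == 0) r - mean(r) else (r - mean(r)) / s
    }))
  }
  out
}
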