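# ExPASy-style average residue masses (Da) and the Bjellqvist-style pKa set
# used by the classic Compute pI/Mw tool.  Both are plain data and can be
# swapped via the `pka_table()` / `mass_table()` arguments.

#' Average residue mass table
#'
#' @param x_mass average mass assigned to the ambiguous residue `X`.
#' @return Named numeric vector of average residue masses in daltons, plus
#'   attribute `water` (mass of one water molecule).
#' @export
mass_table <- function(x_mass = 110.0) {
  m <- c(
    A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326,
    X = x_mass
  )
  attr(m, "water") <- 18.01524
  m
}

#' Bjellqvist-style side-chain and terminal pKa values
#'
#' @return Named list with `nterm`, `cterm` and per-residue side-chain pKa
#'   for D, E, C, Y, H, K, R.
#' @export
pka_table <- function() {
  list(nterm = 7.5, cterm = 3.55,
       side = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0, H = 5.98,
                K = 10.0, R = 12.0))
}

#' Molecular weight of a protein
#'
#' Sum of average residue masses plus one water mass.
#'
#' @param sequence amino-acid sequence (character scalar or
#'   [Biostrings::AAString]).
#' @param masses see [mass_table()].
#' @return Mass in daltons.
#' @export
molecular_weight <- function(sequence, masses = mass_table()) {
  aa <- strsplit(as.character(sequence), "", fixed = TRUE)[[1L]]
  if (length(aa) == 0L) stop("empty sequence")
  idx <- match(aa, names(masses))
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1L]
    stop("unknown residue '", aa[p], "' at position ", p)
  }
  sum(masses[idx]) + attr(masses, "water")
}

#' Henderson--Hasselbalch net charge of a protein at a given pH
#'
#' Positive groups (N-terminus, H, K, R) contribute
#' \eqn{1/(1+10^{pH-pKa})}; negative groups (C-terminus, D, E, C, Y)
#' contribute \eqn{-1/(1+10^{pKa-pH})}.
#'
#' @param sequence amino-acid sequence.
#' @param pH pH value.
#' @param pka see [pka_table()].
#' @return Net charge (dimensionless).
#' @export
net_charge <- function(sequence, pH, pka = pka_table()) {
  aa <- strsplit(as.character(sequence), "", fixed = TRUE)[[1L]]
  counts <- table(factor(aa, levels = names(pka$side)))
  pos_pka <- c(pka$nterm, rep(pka$side[["H"]], counts[["H"]]),
               rep(pka$side[["K"]], counts[["K"]]), rep(pka$side[["R"]], counts[["R"]]))
  neg_pka <- c(pka$cterm, rep(pka$side[["D"]], counts[["D"]]),
               rep(pka$side[["E"]], counts[["E"]]), rep(pka$side[["C"]], counts[["C"]]),
               rep(pka$side[["Y"]], counts[["Y"]]))
  sum(1 / (1 + 10^(pH - pos_pka))) - sum(1 / (1 + 10^(neg_pka - pH)))
}

#' Theoretical isoelectric point
#'
#' The pH at which the Henderson--Hasselbalch net charge is zero, found by
#' bisection on \[0, 14\].  The net charge is strictly decreasing in pH, so a
#' unique root exists.
#'
#' @param sequence amino-acid sequence.
#' @param pka see [pka_table()].
#' @param tol bisection tolerance on pH.
#' @return The pI (dimensionless).
#' @export
isoelectric_point <- function(sequence, pka = pka_table(), tol = 1e-4) {
  seq <- as.character(sequence)
  if (!nzchar(seq)) stop("empty sequence")
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(seq, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Protein property table
#'
#' @param proteins named [Biostrings::AAStringSet] or named character vector.
#' @return data.frame with `id`, `length`, `mw`, `pI`.
#' @export
protein_properties <- function(proteins) {
  if (is.null(names(proteins))) stop("proteins must be named")
  seqs <- setNames(as.character(proteins), names(proteins))
  data.frame(
    id = names(seqs),
    length = nchar(seqs),
    mw = vapply(seqs, molecular_weight, 0),
    pI = vapply(seqs, isoelectric_point, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
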