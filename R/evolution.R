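STOP_CODONS <- c("TAA", "TAG", "TGA")

# validate a CDS, trim a terminal stop codon, split into codons
prepare_cds <- function(cds, id = "cds") {
  s <- toupper(as.character(cds))
  if (grepl("[^ACGT]", s)) stop("non-ACGT base in ", id)
  if (nchar(s) %% 3L != 0L) stop("CDS length not divisible by 3: ", id)
  codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  if (length(codons) && codons[length(codons)] %in% STOP_CODONS) {
    codons <- codons[-length(codons)]
  }
  if (any(codons %in% STOP_CODONS)) {
    stop("internal stop codon in ", id, " at codon ",
         which(codons %in% STOP_CODONS)[1L])
  }
  codons
}

codon_translate <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  unname(aa)
}

#' Codon-aware alignment of two coding sequences
#'
#' Terminal stop codons are trimmed; internal stops and lengths not
#' divisible by 3 are errors.  The two translated proteins are aligned
#' globally with [Biostrings::pairwiseAlignment()] (BLOSUM62, linear gap
#' penalty: opening 0, extension 8) and the alignment is back-threaded to
#' codons.  Codon columns containing a gap are excluded from downstream
#' counting.
#'
#' @param cds_a,cds_b nucleotide coding sequences (character or
#'   [Biostrings::DNAString]).
#' @param gap_extension per-residue linear gap penalty.
#' @return list with `codons_a`, `codons_b` (equal-length vectors of paired,
#'   ungapped codons), `n_gapped` (excluded columns) and `score`.
#' @export
codon_align <- function(cds_a, cds_b, gap_extension = 8) {
  ca <- prepare_cds(cds_a, "cds_a")
  cb <- prepare_cds(cds_b, "cds_b")
  pa <- paste(codon_translate(ca), collapse = "")
  pb <- paste(codon_translate(cb), collapse = "")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 0, gapExtension = gap_extension
  )
  sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  ia <- 0L; ib <- 0L
  keep_a <- integer(0); keep_b <- integer(0); n_gapped <- 0L
  for (k in seq_along(sa)) {
    if (sa[k] != "-") ia <- ia + 1L
    if (sb[k] != "-") ib <- ib + 1L
    if (sa[k] != "-" && sb[k] != "-") {
      keep_a <- c(keep_a, ia); keep_b <- c(keep_b, ib)
    } else {
      n_gapped <- n_gapped + 1L
    }
  }
  list(codons_a = ca[keep_a], codons_b = cb[keep_b],
       n_gapped = n_gapped, score = Biostrings::score(aln))
}

# fraction of synonymous one-step changes per codon position, nonsense
# changes excluded from the denominator; returns c(S, N) site counts
ng86_sites <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    alts <- vapply(setdiff(bases, substr(codon, pos, pos)), function(b) {
      alt <- codon
      substr(alt, pos, pos) <- b
      alt
    }, "")
    alt_aa <- Biostrings::GENETIC_CODE[alts]
    nonstop <- alt_aa != "*"
    if (any(nonstop)) s <- s + sum(alt_aa[nonstop] == aa) / sum(nonstop)
  }
  c(S = s, N = 3 - s)
}

# average synonymous/nonsynonymous differences between two codons over all
# orderings of single-base substitution pathways; pathways through stop
# codons are excluded (all-invalid falls back to all pathways)
ng86_diffs <- function(codon_a, codon_b) {
  pos <- which(strsplit(codon_a, "")[[1L]] != strsplit(codon_b, "")[[1L]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- permutations_of(pos)
  tally <- function(skip_stops) {
    acc <- c(0, 0); n_valid <- 0L
    for (p in perms) {
      cur <- codon_a
      sd <- 0; nd <- 0; ok <- TRUE
      for (j in p) {
        nxt <- cur
        substr(nxt, j, j) <- substr(codon_b, j, j)
        if (skip_stops && Biostrings::GENETIC_CODE[[nxt]] == "*") { ok <- FALSE; break }
        if (Biostrings::GENETIC_CODE[[cur]] == Biostrings::GENETIC_CODE[[nxt]]) {
          sd <- sd + 1
        } else {
          nd <- nd + 1
        }
        cur <- nxt
      }
      if (ok) { acc <- acc + c(sd, nd); n_valid <- n_valid + 1L }
    }
    if (n_valid == 0L) return(NULL)
    acc / n_valid
  }
  res <- tally(TRUE)
  if (is.null(res)) res <- tally(FALSE)
  c(sd = res[1L], nd = res[2L])
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

#' Nei--Gojobori (1986) Ka and Ks
#'
#' Counts synonymous and nonsynonymous sites per sequence (each codon
#' position contributes its fraction of synonymous one-step changes under
#' the standard genetic code, nonsense changes excluded) and averages the
#' two sequences' site counts.  Differences in multi-substitution codons are
#' averaged over all orderings of single-base pathways, excluding pathways
#' through stop codons.  Proportions are corrected with the Jukes--Cantor
#' formula \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3}p)}; a proportion at or
#' beyond the 3/4 saturation bound is an error naming the class.
#'
#' @param codons_a,codons_b equal-length vectors of paired codons, e.g. from
#'   [codon_align()]; alternatively pass a `codon_align()` result as
#'   `codons_a`.
#' @return list with `Ka`, `Ks`, `KaKs` (`NA` when `Ks == 0`), site counts
#'   `S`, `N` and raw difference counts `Sd`, `Nd`, `ps`, `pn`.
#' @export
ng86 <- function(codons_a, codons_b = NULL) {
  if (is.list(codons_a) && is.null(codons_b)) {
    codons_b <- codons_a$codons_b
    codons_a <- codons_a$codons_a
  }
  stopifnot(length(codons_a) == length(codons_b), length(codons_a) >= 1L)
  sites_a <- rowSums(vapply(codons_a, ng86_sites, c(S = 0, N = 0)))
  sites_b <- rowSums(vapply(codons_b, ng86_sites, c(S = 0, N = 0)))
  S <- (sites_a[["S"]] + sites_b[["S"]]) / 2
  N <- (sites_a[["N"]] + sites_b[["N"]]) / 2
  diffs <- rowSums(mapply(ng86_diffs, codons_a, codons_b))
  Sd <- diffs[[1L]]; Nd <- diffs[[2L]]
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p, class) {
    if (p >= 0.75) stop("Jukes-Cantor saturation (p >= 3/4) for ", class, " sites")
    -0.75 * log(1 - 4 * p / 3)
  }
  Ks <- jc(ps, "synonymous")
  Ka <- jc(pn, "nonsynonymous")
  list(Ka = Ka, Ks = Ks, KaKs = if (Ks == 0) NA_real_ else Ka / Ks,
       S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn)
}

#' Divergence time from a synonymous substitution rate
#'
#' \eqn{T = Ks / (2\lambda)} years, reported in millions of years (MYA);
#' \eqn{\lambda} is the per-site per-year synonymous substitution rate
#' (1.5e-8 for dicots).
#'
#' @param Ks synonymous substitutions per synonymous site.
#' @param lambda substitution rate per site per year.
#' @return Time in MYA.
#' @export
divergence_time <- function(Ks, lambda = 1.5e-8) {
  if (any(Ks < 0)) stop("Ks must be non-negative")
  Ks / (2 * lambda) / 1e6
}

#' Ka/Ks and divergence time for duplicate CDS pairs
#'
#' @param pairs data.frame with columns `id_a`, `id_b`.
#' @param cds named [Biostrings::DNAStringSet] (or named character) holding
#'   every id in `pairs`.
#' @param lambda substitution rate per site per year for dating.
#' @return data.frame with `id_a`, `id_b`, `Ka`, `Ks`, `KaKs`, `T_MYA`.
#' @export
kaks_table <- function(pairs, cds, lambda = 1.5e-8) {
  cds <- as.character(cds)
  missing <- setdiff(unique(c(pairs$id_a, pairs$id_b)), names(cds))
  if (length(missing)) stop("CDS missing for: ", paste(missing, collapse = ", "))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$id_a[i]; b <- pairs$id_b[i]
    res <- ng86(codon_align(cds[[a]], cds[[b]]))
    data.frame(id_a = a, id_b = b, Ka = res$Ka, Ks = res$Ks, KaKs = res$KaKs,
               T_MYA = divergence_time(res$Ks, lambda),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
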