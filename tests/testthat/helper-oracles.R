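# Independent oracles used by the unit and property tests.  These are
# deliberately written from first principles (different algorithms and data
# structures than the package code) so that agreement is evidence, not
# tautology.

GENCODE <- Biostrings::GENETIC_CODE
NT <- c("A", "C", "G", "T")

# ---- NG86 oracle: brute-force site and pathway enumeration ------------

# synonymous site count of one codon: over the 9 single-base neighbours,
# fraction per position of changes that keep the amino acid, counting only
# non-stop neighbours in the denominator
oracle_sites <- function(codon) {
  spl <- strsplit(codon, "")[[1L]]
  total <- 0
  for (p in 1:3) {
    syn <- 0L; valid <- 0L
    for (b in NT[NT != spl[p]]) {
      alt <- spl; alt[p] <- b
      aa <- GENCODE[[paste(alt, collapse = "")]]
      if (aa == "*") next
      valid <- valid + 1L
      if (aa == GENCODE[[codon]]) syn <- syn + 1L
    }
    if (valid > 0L) total <- total + syn / valid
  }
  total
}

# all orderings of a set, as a list of integer vectors
oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(oracle_perms(v[-i]), function(r) c(v[i], r))
  }))
}

# average (syn, nonsyn) differences between two codons over substitution
# pathways, stop-free pathways only (all pathways if none is stop-free)
oracle_diffs <- function(a, b) {
  sa <- strsplit(a, "")[[1L]]; sb <- strsplit(b, "")[[1L]]
  where <- which(sa != sb)
  if (length(where) == 0L) return(c(0, 0))
  walk <- function(order) {
    cur <- sa; syn <- 0; non <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- sb[p]
      aa1 <- GENCODE[[paste(cur, collapse = "")]]
      aa2 <- GENCODE[[paste(nxt, collapse = "")]]
      if (aa2 == "*") return(NULL)
      if (aa1 == aa2) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    c(syn, non)
  }
  res <- Filter(Negate(is.null), lapply(oracle_perms(where), walk))
  if (length(res) == 0L) {
    # no stop-free pathway: average over all, counting through stops
    walk_all <- function(order) {
      cur <- sa; syn <- 0; non <- 0
      for (p in order) {
        nxt <- cur; nxt[p] <- sb[p]
        if (GENCODE[[paste(cur, collapse = "")]] ==
            GENCODE[[paste(nxt, collapse = "")]]) syn <- syn + 1 else non <- non + 1
        cur <- nxt
      }
      c(syn, non)
    }
    res <- lapply(oracle_perms(where), walk_all)
  }
  Reduce(`+`, res) / length(res)
}

# full NG86 Ka/Ks on two equal-length codon vectors
oracle_ng86 <- function(codons_a, codons_b) {
  S <- (sum(vapply(codons_a, oracle_sites, 0)) +
        sum(vapply(codons_b, oracle_sites, 0))) / 2
  N <- 3 * length(codons_a) - S
  d <- Reduce(`+`, Map(oracle_diffs, codons_a, codons_b))
  ps <- d[1L] / S; pn <- d[2L] / N
  list(Ka = -0.75 * log(1 - 4 * pn / 3), Ks = -0.75 * log(1 - 4 * ps / 3),
       S = S, N = N, Sd = d[1L], Nd = d[2L])
}

# ---- IUPAC scan oracle: naive sliding window --------------------------

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B", N = "N")
  paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
}

# offsets (1-based) where `consensus` matches `subject`; a subject base
# outside ACGT matches nothing
oracle_scan_one <- function(subject, consensus) {
  s <- strsplit(subject, "")[[1L]]
  p <- strsplit(consensus, "")[[1L]]
  n <- length(s); k <- length(p)
  if (n < k) return(integer())
  out <- integer()
  for (i in seq_len(n - k + 1L)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!(s[i + j - 1L] %in% IUPAC_SETS[[p[j]]])) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, i)
  }
  out
}

# both-strand scan: data.frame(offset, strand), minus strand reported at the
# promoter-forward offset of the reverse-complemented consensus
oracle_scan <- function(subject, consensus) {
  plus <- oracle_scan_one(subject, consensus)
  minus <- oracle_scan_one(subject, oracle_revcomp(consensus))
  data.frame(
    offset = c(plus, minus),
    strand = c(rep("+", length(plus)), rep("-", length(minus))),
    stringsAsFactors = FALSE
  )
}

# ---- pI oracle: grid search -------------------------------------------

oracle_pi <- function(sequence, step = 1e-3) {
  aa <- strsplit(sequence, "")[[1L]]
  # count ionizable groups once, evaluate the charge curve on a pH grid
  nH <- sum(aa == "H"); nK <- sum(aa == "K"); nR <- sum(aa == "R")
  nD <- sum(aa == "D"); nE <- sum(aa == "E"); nC <- sum(aa == "C")
  nY <- sum(aa == "Y")
  ph <- seq(0, 14, by = step)
  pos <- 1 / (1 + 10^(ph - 7.5)) + nH / (1 + 10^(ph - 5.98)) +
    nK / (1 + 10^(ph - 10.0)) + nR / (1 + 10^(ph - 12.0))
  neg <- 1 / (1 + 10^(3.55 - ph)) + nD / (1 + 10^(4.05 - ph)) +
    nE / (1 + 10^(4.45 - ph)) + nC / (1 + 10^(9.0 - ph)) +
    nY / (1 + 10^(10.0 - ph))
  ph[which.min(abs(pos - neg))]
}

# ---- ORF oracle: exhaustive scan --------------------------------------

oracle_orf <- function(sequence) {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  best <- 0L; best_start <- NA_integer_
  for (a in seq_len(max(0L, n - 2L))) {
    if (substr(s, a, a + 2L) != "ATG") next
    i <- a + 3L
    while (i + 2L <= n) {
      if (substr(s, i, i + 2L) %in% c("TAA", "TAG", "TGA")) {
        len <- i - a
        if (len > best) { best <- len; best_start <- a }
        break
      }
      i <- i + 3L
    }
  }
  list(orf_bp = best, protein_aa = best %/% 3L, start = best_start)
}

# ---- qPCR oracle: literal three-step arithmetic -----------------------

oracle_fold_change <- function(stress, control, gene, timepoint) {
  c0 <- control[control$gene == gene & control$timepoint == 0, ]
  base <- mean(c0$ct_target - c0$ct_reference)
  sg <- stress[stress$gene == gene & stress$timepoint == timepoint, ]
  fcs <- vapply(seq_len(nrow(sg)), function(i) {
    d1 <- sg$ct_target[i] - sg$ct_reference[i]
    2^(-(d1 - base))
  }, 0)
  list(mean = mean(fcs), sd = stats::sd(fcs), n = length(fcs))
}

# random DNA / protein helpers
random_dna <- function(n) paste(sample(NT, n, replace = TRUE), collapse = "")
random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n, replace = TRUE),
        collapse = "")
}
random_cds <- function(n_codons) {
  nonstop <- names(GENCODE)[GENCODE != "*"]
  paste(sample(nonstop, n_codons, replace = TRUE), collapse = "")
}
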