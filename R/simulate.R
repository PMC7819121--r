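# Background alphabets for the generators.  Protein background excludes C
# and P on purpose: the classifier anchors on cysteines and on the
# P-x-x-x-T-x-x-C core, so a C/P-free background guarantees that the only
# matches are the planted ones, for any random draw.
BG_AA <- c("A", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "Q", "R",
           "S", "T", "V", "W", "Y")
BG_NT <- c("A", "C", "G", "T")

# canonical per-subfamily fixture layout: protein length, diagnostic motif,
# Cys_P position, and how the resolving cysteine is planted
SUBFAMILY_LAYOUT <- list(
  "2-CysPRX" = list(length = 250L, diag = "twocys_cysP", cysP = 118L,
                    resolving = "evcp_distal"),
  "1-CysPRX" = list(length = 220L, diag = "onecys", cysP = 50L,
                    resolving = "none"),
  "PRXQ"     = list(length = 217L, diag = "prxq", cysP = 60L,
                    resolving = "in_motif", spacing = 4L),
  "PRXIIB"   = list(length = 163L, diag = "prxiib", cysP = 50L,
                    resolving = "context", spacing = 24L),
  "PRXIIE"   = list(length = 228L, diag = "prxiie", cysP = 100L,
                    resolving = "bare_cys", spacing = 24L),
  "PRXIIF"   = list(length = 199L, diag = "prxiif", cysP = 80L,
                    resolving = "bare_cys", spacing = 24L)
)

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators.  The defaults
#' reproduce the canonical family layout: protein lengths and exon
#' counts per subfamily as in the family table, exact cysteine spacings
#' (4 / 24 / none), zero diagnostic-motif noise, three qPCR replicates.
#'
#' @param seed integer seed; fixes all generator output.
#' @param n_per_subfamily proteins generated per subfamily (the first of
#'   each is the canonical fixture).
#' @param motif_noise mismatches planted into each diagnostic motif
#'   (never at a catalytic cysteine).
#' @param include_reclassified also emit the PRXIIB-context fixture whose
#'   resolving cysteine is mutated to valine.
#' @param dup_n_codons,dup_n_syn,dup_n_nonsyn duplicate-pair generator:
#'   ancestral CDS length (codons) and the exact number of synonymous /
#'   nonsynonymous single-base substitutions applied.
#' @param promoter_length promoter length emitted around generated genes.
#' @param planted_elements data.frame (`name`, `offset`, `strand`) of
#'   catalogue elements planted into each generated promoter.
#' @param ct_genes,ct_timepoints,ct_replicates,ct_noise_sd Ct-table
#'   generator: gene names, sampling times (h), replicates, Gaussian
#'   replicate noise SD (cycles).
#' @param ct_fold_changes matrix (genes x timepoints) of planted fold
#'   changes; defaults to an induction and a repression profile recycled
#'   over genes.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_per_subfamily = 1L,
                       motif_noise = 0L,
                       include_reclassified = FALSE,
                       dup_n_codons = 200L, dup_n_syn = 6L, dup_n_nonsyn = 2L,
                       promoter_length = 2500L,
                       planted_elements = NULL,
                       ct_genes = c("PRXg1", "PRXg2"),
                       ct_timepoints = c(0, 1, 3, 6, 12),
                       ct_replicates = 3L,
                       ct_noise_sd = 0,
                       ct_fold_changes = NULL) {
  if (is.null(planted_elements)) {
    planted_elements <- data.frame(
      name = c("STRE", "ABRE", "MYB", "MBS"),
      offset = c(100L, 400L, 1200L, 2000L),
      strand = c("+", "-", "+", "+"),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(ct_fold_changes)) {
    ct_fold_changes <- rbind(c(1, 4, 2, 1.5, 1), c(1, 0.5, 0.25, 0.5, 1))
    ct_fold_changes <- ct_fold_changes[rep(1:2, length.out = length(ct_genes)), ,
                                       drop = FALSE]
    dimnames(ct_fold_changes) <- list(ct_genes, ct_timepoints)
  }
  structure(list(
    seed = as.integer(seed), n_per_subfamily = as.integer(n_per_subfamily),
    motif_noise = as.integer(motif_noise),
    include_reclassified = include_reclassified,
    dup_n_codons = dup_n_codons, dup_n_syn = dup_n_syn,
    dup_n_nonsyn = dup_n_nonsyn,
    promoter_length = as.integer(promoter_length),
    planted_elements = planted_elements,
    ct_genes = ct_genes, ct_timepoints = ct_timepoints,
    ct_replicates = as.integer(ct_replicates), ct_noise_sd = ct_noise_sd,
    ct_fold_changes = ct_fold_changes
  ), class = "sim_config")
}

plant <- function(chars, pos, text) {
  t <- strsplit(text, "", fixed = TRUE)[[1L]]
  chars[pos:(pos + length(t) - 1L)] <- t
  chars
}

# apply `noise` mismatches to a planted motif, never at the anchor offset
noise_motif <- function(motif, anchor, noise) {
  if (noise == 0L) return(motif)
  chars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  free <- setdiff(seq_along(chars), anchor)
  hit <- sample(free, min(noise, length(free)))
  for (i in hit) chars[i] <- sample(setdiff(BG_AA, chars[i]), 1L)
  paste(chars, collapse = "")
}

gen_one_protein <- function(subfamily, length, cysP, noise, reclassified = FALSE) {
  layout <- SUBFAMILY_LAYOUT[[subfamily]]
  diag <- PRX_DIAGNOSTICS[[layout$diag]]
  chars <- sample(BG_AA, length, replace = TRUE)
  motif <- noise_motif(diag$motif, diag$cys, noise)
  start <- cysP - diag$cys + 1L
  chars <- plant(chars, start, motif)
  cysR <- NA_integer_
  if (layout$resolving == "in_motif") {
    cysR <- cysP + layout$spacing + 1L  # the second cysteine of the motif
  } else if (layout$resolving == "bare_cys") {
    cysR <- cysP + layout$spacing + 1L
    chars <- plant(chars, cysR, "C")
  } else if (layout$resolving == "context") {
    res <- PRX_DIAGNOSTICS$prxiib_resolving
    cysR <- cysP + layout$spacing + 1L
    m <- res$motif
    if (reclassified) substr(m, res$cys, res$cys) <- "V"
    chars <- plant(chars, cysR - res$cys + 1L, noise_motif(m, res$cys, noise))
    if (reclassified) cysR <- NA_integer_
  } else if (layout$resolving == "evcp_distal") {
    res <- PRX_DIAGNOSTICS$twocys_cysR
    cysR <- length - 10L
    chars <- plant(chars, cysR - res$cys + 1L, res$motif)
  }
  list(sequence = paste(chars, collapse = ""), cysP = cysP, cysR = cysR,
       spacing = if (is.na(cysR)) NA_integer_ else cysR - cysP - 1L)
}

#' Generate synthetic PRX proteins with planted subfamily ground truth
#'
#' Each record embeds its subfamily's catalytic core (PxxxTxxC), the
#' subfamily-specific cysteine spacing (4 / 24 / distal / none) and
#' diagnostic submotifs in random background; the background alphabet
#' excludes C and P, so the planted sites are provably the only matches.
#' The first record per subfamily is the canonical fixture (fixed length
#' and Cys_P position); further records randomize both.
#'
#' @param config a [sim_config()].
#' @return list with `proteins` (named [Biostrings::AAStringSet]) and
#'   `truth` (data.frame `id`, `subfamily`, `cysP_pos`, `cysR_pos`,
#'   `spacing`, `reclassified_from`).
#' @export
gen_proteins <- function(config = sim_config()) {
  set.seed(config$seed)
  subfams <- names(SUBFAMILY_LAYOUT)
  rows <- list(); seqs <- character()
  emit <- function(subfamily, id, length, cysP, reclassified = FALSE) {
    p <- gen_one_protein(subfamily, length, cysP, config$motif_noise,
                         reclassified)
    seqs[[id]] <<- p$sequence
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id,
      subfamily = if (reclassified) "1-CysPRX" else subfamily,
      cysP_pos = p$cysP, cysR_pos = p$cysR, spacing = p$spacing,
      reclassified_from = if (reclassified) "PRXIIB" else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  for (sf in subfams) {
    layout <- SUBFAMILY_LAYOUT[[sf]]
    for (k in seq_len(config$n_per_subfamily)) {
      if (k == 1L) {
        len <- layout$length; cysP <- layout$cysP
      } else {
        len <- sample(seq(layout$length - 15L, layout$length + 15L), 1L)
        lo <- 30L
        hi <- len - 60L
        cysP <- sample(seq(lo, min(hi, layout$cysP + 20L)), 1L)
      }
      emit(sf, sprintf("%s_%02d", gsub("-", "", sf), k), len, cysP)
    }
  }
  if (config$include_reclassified) {
    layout <- SUBFAMILY_LAYOUT[["PRXIIB"]]
    emit("PRXIIB", "PRXIIB_CtoV", layout$length, layout$cysP,
         reclassified = TRUE)
  }
  list(proteins = Biostrings::AAStringSet(seqs), truth = do.call(rbind, rows))
}

# ---- loci -------------------------------------------------------------

# resample CDS codons / UTR bases until the transcript has no ATG after
# position 1 (so the designed reading frame provably holds the longest ORF)
strip_internal_atg <- function(codons, utr3, safe_codons, max_iter = 200L) {
  repeat {
    tx <- paste0(paste(codons, collapse = ""), utr3)
    hits <- gregexpr("ATG", tx)[[1L]]
    hits <- hits[hits > 1L]
    if (length(hits) == 0L || hits[1L] == -1L) return(list(codons = codons, utr3 = utr3))
    p <- hits[1L]
    cds_len <- 3L * length(codons)
    if (p <= cds_len) {
      idx <- (p - 1L) %/% 3L + 1L
      if (idx == 1L) idx <- 2L
      codons[idx] <- sample(safe_codons, 1L)
    } else {
      q <- p - cds_len
      u <- strsplit(utr3, "", fixed = TRUE)[[1L]]
      for (k in q:min(q + 2L, length(u))) u[k] <- sample(c("C", "T"), 1L)
      utr3 <- paste(u, collapse = "")
    }
    max_iter <- max_iter - 1L
    if (max_iter <= 0L) stop("could not build an ATG-free background")
  }
}

#' Generate the packaged five-exon splice-variant locus
#'
#' Builds a reference gene whose splice-variant arithmetic is pinned by
#' design: five exons, a 597-bp reference ORF (199 aa), internal exons
#' 2--4 summing to 284 bp, intron 1 carrying a 15-bp terminal segment and
#' intron 4 a 14-bp terminal segment whose retention produces the pinned
#' ORF arithmetic (612 bp / 204 aa and, with exons 2--4 skipped,
#' 327 bp / 109 aa).  The alternative acceptor contexts are planted so the
#' printed junction strings appear at the acceptor side and the alternative
#' junctions are noncanonical.  The construction is verified at build time
#' by running the package's own ORF detector on all three transcripts.
#'
#' @param seed integer seed for the background sequence.
#' @param strand `"+"` or `"-"`; the minus-strand locus is the exact mirror
#'   of the plus-strand one.
#' @return list with `genome`, `gene` (`GeneModel`, CDS annotated),
#'   `ref`, `as2`, `as3` (`TranscriptModel`s) and `truth` (planted event
#'   types, retained lengths and ORF lengths).
#' @export
gen_ghprx14_locus <- function(seed = 1L, strand = "+") {
  set.seed(seed)
  exon_len <- c(190L, 90L, 104L, 90L, 171L)   # CDS 600 bp incl. stop + 45 bp 3'UTR
  intron_len <- c(120L, 90L, 90L, 84L)
  ret15 <- "AACTCTCCTCTGCAG"   # retained 3' end of intron 1 (starts AA, ends AG)
  ret14 <- "ATCTCCTCTGCCAG"    # retained 3' end of intron 4 (starts AT, ends AG)

  safe_codons <- setdiff(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"], "ATG")
  codons <- c("ATG", sample(safe_codons, 198L, replace = TRUE), "TAA")
  # codon 64 spans the exon1/retention junction in the variants; keep its
  # first base != T so no stop can form against the retained segment
  while (substr(codons[64L], 1L, 1L) == "T") codons[64L] <- sample(safe_codons, 1L)
  utr3 <- paste(sample(c("C", "T", "A"), 45L, replace = TRUE), collapse = "")
  fixed <- strip_internal_atg(codons, utr3, safe_codons)
  while (substr(fixed$codons[64L], 1L, 1L) == "T") {
    fixed$codons[64L] <- sample(setdiff(safe_codons, "TTA"), 1L)
    fixed <- strip_internal_atg(fixed$codons, fixed$utr3, safe_codons)
  }
  tx <- paste0(paste(fixed$codons, collapse = ""), fixed$utr3)  # 645 bp

  intron_seq <- function(i) {
    if (i == 1L) {
      filler <- paste(sample(c("C", "T", "G"), intron_len[1L] - 4L - nchar(ret15),
                             replace = TRUE), collapse = "")
      paste0("AG", filler, "AG", ret15)   # AG donor: variant junctions are noncanonical
    } else if (i == 4L) {
      filler <- paste(sample(c("C", "T", "G"), intron_len[4L] - 4L - nchar(ret14),
                             replace = TRUE), collapse = "")
      paste0("GT", filler, "AG", ret14)
    } else {
      filler <- paste(sample(c("C", "T", "G"), intron_len[i] - 4L, replace = TRUE),
                      collapse = "")
      paste0("GT", filler, "AG")
    }
  }

  upstream <- 2600L
  lead <- paste(sample(BG_NT, upstream, replace = TRUE), collapse = "")
  tail_seq <- paste(sample(BG_NT, 100L, replace = TRUE), collapse = "")
  ex_seq <- substring(tx, cumsum(c(1L, exon_len[-5L])) + c(0L, cumsum(rep(0L, 4L))),
                      cumsum(exon_len))
  # exon genomic coordinates
  starts <- integer(5L); ends <- integer(5L)
  pos <- upstream + 1L
  gene_seq <- ""
  for (i in 1:5) {
    starts[i] <- pos
    ends[i] <- pos + exon_len[i] - 1L
    gene_seq <- paste0(gene_seq, ex_seq[i])
    pos <- ends[i] + 1L
    if (i < 5L) {
      iseq <- intron_seq(i)
      gene_seq <- paste0(gene_seq, iseq)
      pos <- pos + nchar(iseq)
    }
  }
  contig <- paste0(lead, gene_seq, tail_seq)
  exons <- IRanges::IRanges(starts, ends)
  # CDS: transcript bases 1..600 (ORF + stop); exon 5 contributes 126 bp
  cds <- IRanges::IRanges(starts, c(ends[1:4], starts[5L] + 126L - 1L))
  genome <- Biostrings::DNAStringSet(c(chrPRX14 = contig))
  gene <- gene_model("GhPRX14like", "chrPRX14", "+", exons, cds)
  intr <- introns_of(gene)
  as2_exons <- IRanges::IRanges(
    c(starts[1L], IRanges::end(intr)[1L] - 14L, starts[3:5]),
    c(ends[1L], ends[2L], ends[3:5])
  )
  as3_exons <- IRanges::IRanges(
    c(starts[1L], IRanges::end(intr)[4L] - 13L),
    c(ends[1L], ends[5L])
  )
  ref <- transcript_model("GhPRX14like-AS1", "GhPRX14like", "chrPRX14", "+",
                          exons, provenance = "reference")
  as2 <- transcript_model("GhPRX14like-AS2", "GhPRX14like", "chrPRX14", "+",
                          as2_exons)
  as3 <- transcript_model("GhPRX14like-AS3", "GhPRX14like", "chrPRX14", "+",
                          as3_exons)
  out <- list(genome = genome, gene = gene, ref = ref, as2 = as2, as3 = as3,
              truth = list(ref_orf = c(597L, 199L), as2_orf = c(612L, 204L),
                           as3_orf = c(327L, 109L),
                           as2_retained = 15L, as3_retained = 14L,
                           as3_skipped_exons = 2:4))
  if (strand == "-") out <- flip_locus(out)
  # build-time verification of the designed ORF arithmetic
  chk <- function(model, want) {
    o <- orf_and_translate(transcript_sequence(out$genome, model))
    stopifnot(o$orf_bp == want[1L], o$protein_aa == want[2L])
  }
  chk(out$ref, c(597L, 199L)); chk(out$as2, c(612L, 204L)); chk(out$as3, c(327L, 109L))
  out
}

#' Mirror a locus to the opposite strand
#'
#' Reverse-complements every contig and mirrors all model coordinates, so
#' the mirrored locus is the same gene on the other strand.  Used by the
#' strand-invariance checks.
#'
#' @param locus a list with a `genome` ([Biostrings::DNAStringSet]) and any
#'   number of `GeneModel`/`TranscriptModel` entries (or lists of them).
#' @return The mirrored locus in the same shape.
#' @export
flip_locus <- function(locus) {
  lens <- setNames(Biostrings::width(locus$genome), names(locus$genome))
  flip_model <- function(m) {
    L <- lens[[m$contig]]
    flip_ranges <- function(r) {
      IRanges::IRanges(L - IRanges::end(r) + 1L, L - IRanges::start(r) + 1L)
    }
    m$exons <- sort(flip_ranges(m$exons))
    if (!is.null(m$cds)) m$cds <- sort(flip_ranges(m$cds))
    m$strand <- if (m$strand == "+") "-" else "+"
    m
  }
  rec <- function(x) {
    if (inherits(x, "GeneModel")) return(flip_model(x))
    if (is.list(x)) return(lapply(x, rec))
    x
  }
  out <- rec(locus[setdiff(names(locus), "genome")])
  out$genome <- Biostrings::reverseComplement(locus$genome)
  out[c("genome", setdiff(names(locus), "genome"))]
}

# random multi-exon gene on a fresh contig; returns locus pieces
gen_random_gene <- function(gene_id, contig, n_exons, upstream = 300L) {
  exon_len <- sample(51:150, n_exons, replace = TRUE)
  # keep total CDS a codon multiple by padding the last exon
  total <- sum(exon_len)
  exon_len[n_exons] <- exon_len[n_exons] + (3L - total %% 3L) %% 3L
  intron_len <- if (n_exons > 1L) sample(60:120, n_exons - 1L, replace = TRUE) else integer()
  n_codons <- sum(exon_len) %/% 3L
  safe_codons <- setdiff(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"], "ATG")
  tx <- paste(c("ATG", sample(safe_codons, n_codons - 2L, replace = TRUE), "TAA"),
              collapse = "")
  pos <- upstream + 1L
  starts <- integer(n_exons); ends <- integer(n_exons)
  seqs <- character(); off <- 0L
  for (i in seq_len(n_exons)) {
    starts[i] <- pos; ends[i] <- pos + exon_len[i] - 1L
    seqs <- c(seqs, substr(tx, off + 1L, off + exon_len[i]))
    off <- off + exon_len[i]
    pos <- ends[i] + 1L
    if (i < n_exons) {
      filler <- paste(sample(BG_NT, intron_len[i] - 4L, replace = TRUE), collapse = "")
      seqs <- c(seqs, paste0("GT", filler, "AG"))
      pos <- pos + intron_len[i]
    }
  }
  lead <- paste(sample(BG_NT, upstream, replace = TRUE), collapse = "")
  tail_seq <- paste(sample(BG_NT, 150L, replace = TRUE), collapse = "")
  contig_seq <- paste0(lead, paste(seqs, collapse = ""), tail_seq)
  exons <- IRanges::IRanges(starts, ends)
  list(contig = contig, sequence = contig_seq,
       model = gene_model(gene_id, contig, "+", exons, exons))
}

#' Generate one alternative-splicing test case
#'
#' Builds a random multi-exon gene and an alternative transcript carrying
#' exactly one planted event of the requested type, with its ground truth.
#'
#' @param type one of `"IR"`, `"ES"`, `"A3SS"`, `"A5SS"`, `"AFE"`, `"ALE"`.
#' @param n_exons exons in the reference model (>= 4).
#' @param strand strand of the emitted locus.
#' @return list with `genome`, `ref` (`GeneModel`), `alt`
#'   (`TranscriptModel`) and `truth` (`type`, `index` in transcription
#'   order, `length` in bp).
#' @export
gen_as_case <- function(type = c("IR", "ES", "A3SS", "A5SS", "AFE", "ALE"),
                        n_exons = 5L, strand = "+") {
  type <- match.arg(type)
  stopifnot(n_exons >= 4L)
  g <- gen_random_gene("gene1", "chrAS", n_exons)
  ref <- g$model
  ex <- ref$exons
  intr <- introns_of(ref)
  st <- IRanges::start(ex); en <- IRanges::end(ex)
  truth <- NULL
  if (type == "IR") {
    i <- sample(seq_along(intr), 1L)
    alt_ex <- IRanges::IRanges(st[-(i + 1L)], en[-i])
    truth <- list(type = "IR", index = i, length = IRanges::width(intr)[i])
  } else if (type == "ES") {
    j <- sample(2:(n_exons - 1L), 1L)
    alt_ex <- ex[-j]
    truth <- list(type = "ES", index = j, length = IRanges::width(ex)[j])
  } else if (type == "A3SS") {
    i <- sample(seq_along(intr), 1L)
    d <- sample(5:20, 1L)
    st2 <- st; st2[i + 1L] <- st2[i + 1L] - d
    alt_ex <- IRanges::IRanges(st2, en)
    truth <- list(type = "A3SS", index = i, length = d)
  } else if (type == "A5SS") {
    i <- sample(seq_along(intr), 1L)
    d <- sample(5:20, 1L)
    en2 <- en; en2[i] <- en2[i] + d
    alt_ex <- IRanges::IRanges(st, en2)
    truth <- list(type = "A5SS", index = i, length = d)
  } else if (type == "AFE") {
    w <- sample(40:80, 1L)
    gap <- sample(30:60, 1L)
    new_end <- st[1L] - gap
    alt_ex <- IRanges::IRanges(c(new_end - w + 1L, st[-1L]), c(new_end, en[-1L]))
    truth <- list(type = "AFE", index = 1L,
                  length = w + IRanges::width(ex)[1L])
  } else {  # ALE
    w <- sample(40:80, 1L)
    gap <- sample(30:60, 1L)
    new_start <- en[n_exons] + gap
    alt_ex <- IRanges::IRanges(c(st[-n_exons], new_start),
                               c(en[-n_exons], new_start + w - 1L))
    truth <- list(type = "ALE", index = n_exons,
                  length = w + IRanges::width(ex)[n_exons])
  }
  alt <- transcript_model("alt1", "gene1", "chrAS", "+", alt_ex)
  out <- list(genome = Biostrings::DNAStringSet(c(chrAS = g$sequence)),
              ref = ref, alt = alt, truth = truth)
  # mirroring preserves transcription order, so truth indices are unchanged
  if (strand == "-") out <- flip_locus(out)
  out
}

#' Generate gene loci with planted promoter elements
#'
#' Emits one reference gene model per PRX subfamily with the subfamily's
#' exon count from the family table, each on its own contig with a promoter
#' region carrying the configured catalogue elements at recorded offsets,
#' plus a gene with an intron wholly inside the 5'UTR (upstream of the
#' translation initiation site) and the packaged five-exon splice-variant
#' locus of [gen_ghprx14_locus()].
#'
#' @param config a [sim_config()].
#' @param catalogue a cis-element catalogue ([load_cis_catalogue()]).
#' @return list with `genome`, `genes` (named `GeneModel` list),
#'   `splice_locus` (see [gen_ghprx14_locus()]), and truth tables
#'   `promoter_truth` (`gene_id`, `name`, `offset`, `strand`) and
#'   `exon_truth` (`gene_id`, `n_exons`).
#' @export
gen_locus <- function(config = sim_config(), catalogue = load_cis_catalogue()) {
  set.seed(config$seed)
  exon_counts <- c("2-CysPRX" = 7L, "PRXIIE" = 1L, "PRXIIB" = 3L,
                   "PRXQ" = 4L, "PRXIIF" = 5L, "1-CysPRX" = 4L)
  genomes <- character(); genes <- list(); prom_truth <- list()
  plen <- config$promoter_length
  for (sf in names(exon_counts)) {
    gid <- paste0("gene_", gsub("-", "", sf))
    contig <- paste0("chr_", gsub("-", "", sf))
    g <- gen_random_gene(gid, contig, exon_counts[[sf]], upstream = plen + 100L)
    chars <- strsplit(g$sequence, "", fixed = TRUE)[[1L]]
    tis <- IRanges::start(g$model$exons)[1L]
    pe <- config$planted_elements
    for (k in seq_len(nrow(pe))) {
      cons <- catalogue$consensus[match(pe$name[k], catalogue$name)]
      if (is.na(cons)) stop("planted element not in catalogue: ", pe$name[k])
      realized <- realize_iupac(cons)
      if (pe$strand[k] == "-") {
        realized <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(realized)))
      }
      gpos <- tis - plen + pe$offset[k] - 1L
      chars <- plant(chars, gpos, realized)
      prom_truth[[length(prom_truth) + 1L]] <- data.frame(
        gene_id = gid, name = pe$name[k], offset = pe$offset[k],
        strand = pe$strand[k], stringsAsFactors = FALSE
      )
    }
    genomes[[contig]] <- paste(chars, collapse = "")
    genes[[gid]] <- g$model
  }
  # gene with an intron wholly upstream of the TIS: exon 1 is pure 5'UTR
  u <- gen_random_gene("gene_utr5", "chr_utr5", 3L, upstream = plen + 100L)
  ex <- u$model$exons
  utr_exon <- IRanges::IRanges(IRanges::start(ex)[1L] - 140L,
                               IRanges::start(ex)[1L] - 81L)
  all_ex <- sort(c(utr_exon, ex))
  genes[["gene_utr5"]] <- gene_model("gene_utr5", "chr_utr5", "+", all_ex, ex)
  genomes[["chr_utr5"]] <- u$sequence

  splice <- gen_ghprx14_locus(seed = config$seed)
  genomes[["chrPRX14"]] <- as.character(splice$genome[["chrPRX14"]])
  genes[[splice$gene$gene_id]] <- splice$gene

  list(
    genome = Biostrings::DNAStringSet(genomes),
    genes = genes,
    splice_locus = splice,
    promoter_truth = do.call(rbind, prom_truth),
    exon_truth = data.frame(gene_id = paste0("gene_", gsub("-", "", names(exon_counts))),
                            n_exons = unname(exon_counts),
                            stringsAsFactors = FALSE)
  )
}

# one concrete realization of an IUPAC consensus
realize_iupac <- function(consensus) {
  sets <- Biostrings::IUPAC_CODE_MAP[strsplit(consensus, "", fixed = TRUE)[[1L]]]
  paste(vapply(strsplit(sets, "", fixed = TRUE),
               function(s) if (length(s) == 1L) s else sample(s, 1L), ""),
        collapse = "")
}

# ---- duplicate pairs --------------------------------------------------

# classify the single-base neighbours of a codon
codon_neighbours <- function(codon) {
  out <- list()
  aa <- Biostrings::GENETIC_CODE[[codon]]
  for (pos in 1:3) {
    for (b in setdiff(BG_NT, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      alt_aa <- Biostrings::GENETIC_CODE[[alt]]
      if (alt_aa == "*") next
      out[[length(out) + 1L]] <- list(codon = alt, synonymous = alt_aa == aa)
    }
  }
  out
}

#' Generate duplicate CDS pairs with planted substitution counts
#'
#' Starts from a random stop-free CDS and applies exactly the requested
#' number of synonymous and nonsynonymous single-base substitutions, each
#' in a distinct codon, verifying the class by translation.  The ancestral
#' sequence is reported as `id_a`, the derived one as `id_b`.
#'
#' @param config a [sim_config()]; uses `dup_n_codons`, `dup_n_syn`,
#'   `dup_n_nonsyn`.
#' @param n_pairs number of pairs to generate.
#' @return list with `cds` (named [Biostrings::DNAStringSet]), `pairs`
#'   (data.frame `id_a`, `id_b`, `n_syn`, `n_nonsyn`).
#' @export
gen_duplicate_pairs <- function(config = sim_config(), n_pairs = 1L) {
  set.seed(config$seed)
  nonstop <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  seqs <- character(); rows <- list()
  for (p in seq_len(n_pairs)) {
    anc <- sample(nonstop, config$dup_n_codons, replace = TRUE)
    der <- anc
    can_syn <- which(vapply(anc, function(cd) {
      any(vapply(codon_neighbours(cd), `[[`, TRUE, "synonymous"))
    }, TRUE))
    can_non <- which(vapply(anc, function(cd) {
      any(!vapply(codon_neighbours(cd), `[[`, TRUE, "synonymous"))
    }, TRUE))
    if (length(can_syn) < config$dup_n_syn) {
      stop("not enough codons admit a synonymous change")
    }
    syn_at <- sample(can_syn, config$dup_n_syn)
    non_at <- sample(setdiff(can_non, syn_at), config$dup_n_nonsyn)
    for (i in syn_at) {
      nb <- codon_neighbours(anc[i])
      nb <- nb[vapply(nb, `[[`, TRUE, "synonymous")]
      der[i] <- nb[[sample(length(nb), 1L)]]$codon
    }
    for (i in non_at) {
      nb <- codon_neighbours(anc[i])
      nb <- nb[!vapply(nb, `[[`, TRUE, "synonymous")]
      der[i] <- nb[[sample(length(nb), 1L)]]$codon
    }
    stopifnot(sum(codon_translate(anc) != codon_translate(der)) == config$dup_n_nonsyn)
    ida <- sprintf("pair%02d_a", p); idb <- sprintf("pair%02d_b", p)
    seqs[[ida]] <- paste(anc, collapse = "")
    seqs[[idb]] <- paste(der, collapse = "")
    rows[[p]] <- data.frame(id_a = ida, id_b = idb,
                            n_syn = config$dup_n_syn,
                            n_nonsyn = config$dup_n_nonsyn,
                            stringsAsFactors = FALSE)
  }
  list(cds = Biostrings::DNAStringSet(seqs), pairs = do.call(rbind, rows))
}

# ---- Ct tables --------------------------------------------------------

#' Generate a Ct table with planted fold changes
#'
#' Ct values are constructed so that the three-step 2^-dCt procedure
#' returns the planted fold change exactly at zero noise (reference gene Ct
#' fixed at 20 cycles, control dCt1 at 5 cycles); optional Gaussian
#' replicate noise is added to the target Ct.
#'
#' @param config a [sim_config()]; uses the `ct_*` fields.
#' @return list with `stress`, `control` (data.frames in [read_ct_table()]
#'   layout) and `truth` (`gene`, `timepoint`, `fold_change`).
#' @export
gen_ct_table <- function(config = sim_config()) {
  set.seed(config$seed)
  ref_ct <- 20; base_d1 <- 5
  fc <- config$ct_fold_changes
  mk <- function(gene, tp, d1) {
    data.frame(
      gene = gene, condition = NA_character_, timepoint = tp,
      replicate = seq_len(config$ct_replicates),
      ct_target = ref_ct + d1 + stats::rnorm(config$ct_replicates, 0,
                                             config$ct_noise_sd),
      ct_reference = ref_ct, stringsAsFactors = FALSE
    )
  }
  stress <- list(); control <- list(); truth <- list()
  for (g in config$ct_genes) {
    for (tp in config$ct_timepoints) {
      f <- fc[g, as.character(tp)]
      s <- mk(g, tp, base_d1 - log2(f)); s$condition <- "stress"
      c0 <- mk(g, tp, base_d1); c0$condition <- "control"
      stress[[length(stress) + 1L]] <- s
      control[[length(control) + 1L]] <- c0
      truth[[length(truth) + 1L]] <- data.frame(
        gene = g, timepoint = tp, fold_change = f, stringsAsFactors = FALSE
      )
    }
  }
  list(stress = do.call(rbind, stress), control = do.call(rbind, control),
       truth = do.call(rbind, truth))
}
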