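# transcription-orientation boundary coordinates of an intron interval
donor_pos <- function(intr, strand) {
  if (strand == "+") IRanges::start(intr) else IRanges::end(intr)
}
acceptor_pos <- function(intr, strand) {
  if (strand == "+") IRanges::end(intr) else IRanges::start(intr)
}

# genomic index -> transcription-order index
tx_index <- function(i, n, strand) if (strand == "+") i else n - i + 1L

as_event <- function(type, alias, feature, idx_first, idx_last, length,
                     used_start = NA_integer_, used_end = NA_integer_) {
  data.frame(type = type, alias = alias, feature = feature,
             index_first = idx_first, index_last = idx_last,
             length = as.integer(length),
             used_start = as.integer(used_start), used_end = as.integer(used_end),
             stringsAsFactors = FALSE)
}

empty_events <- function() {
  as_event(character(), character(), character(), integer(), integer(),
           integer(), integer(), integer())
}

#' Classify alternative-splicing events
#'
#' Compares an alternative transcript's exon chain against the reference
#' gene model (same contig and strand) and reports typed events in
#' transcription order:
#' \itemize{
#'   \item \strong{IR} -- a reference intron absent from the alternative
#'     intron chain and fully inside an alternative exon;
#'   \item \strong{A5SS}/\strong{A3SS} -- an alternative intron whose donor
#'     (5') or acceptor (3', in transcription orientation) boundary is
#'     shifted relative to the reference intron it replaces; a pure
#'     retention of one intron end additionally carries the alias
#'     `alias = "partial-IR"` (a common vocabulary for terminal
#'     intron-fragment retentions);
#'   \item \strong{ES} -- reference exons lying entirely inside one
#'     alternative intron (their flanking introns merged);
#'   \item \strong{AFE}/\strong{ALE} -- an alternative first/last exon
#'     disjoint from the reference one, with the rest of the chain identical.
#' }
#' Identical chains yield a zero-row table.
#'
#' @param ref a `GeneModel` (the reference transcript structure).
#' @param alt a `TranscriptModel`.
#' @return data.frame with columns `type`, `alias`, `feature`
#'   (`"exon"` or `"intron"`), `index_first`, `index_last` (1-based
#'   reference indices in transcription order), `length` (retained/shifted
#'   bp), `used_start`, `used_end` (genomic coordinates of the spliced
#'   intron the event derives from; for IR, of the retained intron).
#' @export
classify_events <- function(ref, alt) {
  if (ref$contig != alt$contig) stop("transcript on different contig than reference")
  if (ref$strand != alt$strand) stop("transcript on different strand than reference")
  strand <- ref$strand
  rex <- ref$exons; aex <- alt$exons
  rintr <- introns_of(ref); aintr <- introns_of(alt)
  n_rex <- length(rex); n_rintr <- length(rintr)

  if (length(rex) == length(aex) && all(rex == aex)) return(empty_events())

  events <- list()

  # AFE / ALE: a disjoint alternative terminal exon with the internal chain
  # identical; a terminal exon that merely shifts a splice boundary still
  # overlaps its reference counterpart and is handled as A5SS/A3SS below
  if (length(rex) == length(aex) && length(rex) >= 2L) {
    n <- length(rex)
    first_g <- if (strand == "+") 1L else n  # genomic index of tx-first exon
    rest <- setdiff(seq_len(n), first_g)
    if (all(rex[rest] == aex[rest]) &&
        !any(IRanges::overlapsAny(rex[first_g], aex[first_g]))) {
      diff_len <- sum(IRanges::width(
        IRanges::union(rex[first_g], aex[first_g]))) -
        sum(IRanges::width(IRanges::intersect(rex[first_g], aex[first_g])))
      return(as_event("AFE", "AFE", "exon", 1L, 1L, diff_len,
                      IRanges::start(aex[first_g]), IRanges::end(aex[first_g])))
    }
    last_g <- if (strand == "+") n else 1L
    rest <- setdiff(seq_len(n), last_g)
    if (all(rex[rest] == aex[rest]) &&
        !any(IRanges::overlapsAny(rex[last_g], aex[last_g]))) {
      diff_len <- sum(IRanges::width(
        IRanges::union(rex[last_g], aex[last_g]))) -
        sum(IRanges::width(IRanges::intersect(rex[last_g], aex[last_g])))
      return(as_event("ALE", "ALE", "exon", n, n, diff_len,
                      IRanges::start(aex[last_g]), IRanges::end(aex[last_g])))
    }
  }

  # intron retention: reference introns untouched by any alternative intron
  # and fully inside an alternative exon
  for (i in seq_len(n_rintr)) {
    ri <- rintr[i]
    if (length(aintr) && any(IRanges::overlapsAny(ri, aintr))) next
    if (any(IRanges::overlapsAny(ri, aex, type = "within"))) {
      ti <- tx_index(i, n_rintr, strand)
      events[[length(events) + 1L]] <-
        as_event("IR", "IR", "intron", ti, ti, IRanges::width(ri),
                 IRanges::start(ri), IRanges::end(ri))
    }
  }

  # alternative introns: exact matches are silent; otherwise compare the
  # donor/acceptor boundaries against the outermost overlapped reference
  # introns and report skipped exons in between
  for (j in seq_along(aintr)) {
    A <- aintr[j]
    if (n_rintr && any(rintr == A)) next
    ov <- which(IRanges::overlapsAny(rintr, A))
    if (length(ov) == 0L) next  # novel intron inside a reference exon: outside the event menu
    tx_first_i <- if (strand == "+") ov[1L] else ov[length(ov)]
    tx_last_i <- if (strand == "+") ov[length(ov)] else ov[1L]

    skipped <- which(IRanges::overlapsAny(rex, A, type = "within"))
    if (length(skipped)) {
      runs <- split(skipped, cumsum(c(1L, diff(skipped) != 1L)))
      for (r in runs) {
        t1 <- tx_index(r[1L], n_rex, strand)
        t2 <- tx_index(r[length(r)], n_rex, strand)
        events[[length(events) + 1L]] <-
          as_event("ES", "ES", "exon", min(t1, t2), max(t1, t2),
                   sum(IRanges::width(rex[r])),
                   IRanges::start(A), IRanges::end(A))
      }
    }

    pure_retention <- length(ov) == 1L && length(skipped) == 0L &&
      IRanges::start(A) >= IRanges::start(rintr[ov]) &&
      IRanges::end(A) <= IRanges::end(rintr[ov])

    d_shift <- abs(donor_pos(A, strand) - donor_pos(rintr[tx_first_i], strand))
    if (d_shift > 0L) {
      ti <- tx_index(tx_first_i, n_rintr, strand)
      events[[length(events) + 1L]] <-
        as_event("A5SS", if (pure_retention) "partial-IR" else "A5SS",
                 "intron", ti, ti, d_shift,
                 IRanges::start(A), IRanges::end(A))
    }
    a_shift <- abs(acceptor_pos(A, strand) - acceptor_pos(rintr[tx_last_i], strand))
    if (a_shift > 0L) {
      ti <- tx_index(tx_last_i, n_rintr, strand)
      events[[length(events) + 1L]] <-
        as_event("A3SS", if (pure_retention) "partial-IR" else "A3SS",
                 "intron", ti, ti, a_shift,
                 IRanges::start(A), IRanges::end(A))
    }
  }

  if (length(events) == 0L) return(empty_events())
  out <- do.call(rbind, events)
  key <- if (strand == "+") out$used_start else -out$used_end
  out <- out[order(key, out$index_first), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Donor and acceptor dinucleotides of an intron
#'
#' The first two and last two intron bases in transcription orientation;
#' canonical iff GT..AG.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param contig,strand location of the intron.
#' @param start,end 1-based inclusive genomic interval (vectors allowed).
#' @return data.frame with `donor`, `acceptor`, `canonical`.
#' @export
boundary_dinucleotides <- function(genome, contig, strand, start, end) {
  if (!contig %in% names(genome)) stop("contig not found in genome: ", contig)
  chr <- genome[[contig]]
  if (any(end - start + 1L < 4L)) stop("intron shorter than 4 bp")
  rows <- mapply(function(s, e) {
    intron <- Biostrings::subseq(chr, s, e)
    if (strand == "-") intron <- Biostrings::reverseComplement(intron)
    seq <- as.character(intron)
    c(donor = substr(seq, 1L, 2L),
      acceptor = substr(seq, nchar(seq) - 1L, nchar(seq)))
  }, start, end)
  out <- data.frame(donor = rows["donor", ], acceptor = rows["acceptor", ],
                    stringsAsFactors = FALSE)
  out$canonical <- out$donor == "GT" & out$acceptor == "AG"
  out
}

#' Boundary dinucleotides for classified events
#'
#' Applies [boundary_dinucleotides()] to the spliced (for IR: retained)
#' intron each event derives from.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param ref the reference `GeneModel` the events were called against.
#' @param events table from [classify_events()].
#' @return `events` with `donor`, `acceptor`, `canonical` columns appended.
#' @export
event_boundaries <- function(genome, ref, events) {
  if (nrow(events) == 0L) return(events)
  cbind(events, boundary_dinucleotides(genome, ref$contig, ref$strand,
                                       events$used_start, events$used_end))
}

#' Longest open reading frame and its translation length
#'
#' Scans all ATG positions and returns the longest ORF that runs from an
#' ATG to the first in-frame stop codon.  The reported ORF length excludes
#' the stop codon, so the protein length is `orf_bp / 3` amino acids.  Ties
#' go to the most 5' start.  `(0, 0)` if no ATG reaches an in-frame stop.
#'
#' @param sequence transcript nucleotide sequence (character or
#'   [Biostrings::DNAString]).
#' @return list with `orf_bp`, `protein_aa`, `start` (1-based ORF start, NA
#'   if none).
#' @export
orf_and_translate <- function(sequence) {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  codon_at <- function(i) substr(s, i, i + 2L)
  atg <- gregexpr("ATG", s)[[1L]]
  if (atg[1L] == -1L) return(list(orf_bp = 0L, protein_aa = 0L, start = NA_integer_))
  best_len <- 0L; best_start <- NA_integer_
  # first in-frame stop position per frame, precomputed
  stops_by_frame <- lapply(0:2, function(f) {
    starts <- seq.int(1L + f, n - 2L, by = 3L)
    if (length(starts) == 0L) return(integer())
    starts[substring(s, starts, starts + 2L) %in% STOP_CODONS]
  })
  for (a in as.integer(atg)) {
    f <- (a - 1L) %% 3L
    stops <- stops_by_frame[[f + 1L]]
    stops <- stops[stops >= a + 3L]
    if (length(stops) == 0L) next
    len <- stops[1L] - a
    if (len > best_len) { best_len <- len; best_start <- a }
  }
  list(orf_bp = best_len, protein_aa = best_len %/% 3L, start = best_start)
}
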