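# Diagnostic submotifs used by the subfamily rules.  The 2-Cys contexts and
# the type-II chloroplast (PRXIIE) context follow the conserved blocks of the
# family alignment; the PRXIIF context is the type-II context with the
# conserved serine after the catalytic cysteine replaced by alanine; the
# PRXIIB and 1-Cys contexts are composed from canonical plant PRX sequences.
# `cys` is the 1-based offset of the catalytic residue inside the motif; it
# must match exactly, mismatches elsewhere are tolerated up to the configured
# maximum.
PRX_DIAGNOSTICS <- list(
  twocys_cysP     = list(motif = "FFYPLDFTFVCPTEI", cys = 11L),
  twocys_cysR     = list(motif = "EVCP",            cys = 3L),
  prxiie          = list(motif = "FGLPGAYTGVCSQ",   cys = 11L),
  prxiif          = list(motif = "FGLPGAYTGVCAQ",   cys = 11L),
  prxiib          = list(motif = "FGVPGAFTPGCSK",   cys = 11L),
  prxiib_resolving = list(motif = "GLTCSLA",        cys = 4L),
  prxq            = list(motif = "PAAYTKACEFKSC",   cys = 8L),
  onecys          = list(motif = "SHPGDFTPVCTTE",   cys = 10L)
)

SUBFAMILY_LABELS <- c("2-CysPRX", "1-CysPRX", "PRXQ", "PRXIIB", "PRXIIE",
                      "PRXIIF", "UNCLASSIFIED")

#' Default classification parameters
#'
#' @param spacing_slack slack (residues, 0--2) around the exact
#'   peroxidatic/resolving cysteine spacings of 4 (PRXQ) and 24 (type II).
#' @param max_mismatch maximum mismatches tolerated in a diagnostic submotif
#'   match; the catalytic residue position must always match exactly.
#' @param s_window,wf_window windows (residues downstream) in which the
#'   conserved S and the aromatic W/F of the PxxxTxxC...S...W/F profile are
#'   looked up; their presence is recorded as evidence, never used as a
#'   filter.
#' @return A named list of parameters.
#' @export
classify_config <- function(spacing_slack = 0L, max_mismatch = 2L,
                            s_window = 100L, wf_window = 120L) {
  if (spacing_slack < 0L || spacing_slack > 2L) stop("spacing_slack must be in 0..2")
  list(spacing_slack = as.integer(spacing_slack),
       max_mismatch = as.integer(max_mismatch),
       s_window = as.integer(s_window), wf_window = as.integer(wf_window))
}

# best (fewest-mismatch, then leftmost) window match of a diagnostic motif;
# the residue at `cys` must match `anchor` (defaults to the motif's own
# residue there).  Returns list(pos, mismatches) or NULL.
match_diagnostic <- function(seq, diag, max_mismatch = 2L, anchor = NULL) {
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  m <- strsplit(diag$motif, "", fixed = TRUE)[[1L]]
  if (!is.null(anchor)) m[diag$cys] <- anchor
  k <- length(m)
  n <- length(s)
  if (n < k) return(NULL)
  best <- NULL
  for (i in seq_len(n - k + 1L)) {
    win <- s[i:(i + k - 1L)]
    if (win[diag$cys] != m[diag$cys]) next
    mm <- sum(win != m)
    if (mm <= max_mismatch && (is.null(best) || mm < best$mismatches)) {
      best <- list(pos = i, cys_pos = i + diag$cys - 1L, mismatches = mm)
      if (mm == 0L) break
    }
  }
  best
}

#' Locate the conserved active-site core of a PRX protein
#'
#' Finds the earliest (most N-terminal) match of the catalytic core pattern
#' P-x-x-x-T-x-x-C; the cysteine at pattern position 8 is taken as the
#' peroxidatic cysteine (Cys_P).  The downstream conserved S and aromatic
#' W/F of the full PxxxTxxC...S...W/F profile are located within configurable
#' windows and recorded as evidence.  Absence of the core is a `NULL` result
#' (the candidate screen), not an error.
#'
#' @param protein an amino-acid sequence (character scalar, or a single
#'   [Biostrings::AAString]).
#' @param config see [classify_config()].
#' @return An `ActiveSiteProfile` (list with 1-based `cysP_pos`,
#'   `core_start`, `core_end`, optional `resolving_S_pos`, `aromatic_pos`,
#'   `cysR_pos`, `spacing`, `diagnostic_hits`), or `NULL`.
#' @export
find_active_site <- function(protein, config = classify_config()) {
  seq <- as.character(protein)
  m <- regexpr("P.{3}T.{2}C", seq, perl = TRUE)
  if (m == -1L) return(NULL)
  core_start <- as.integer(m)
  cysP <- core_start + 7L
  tail_start <- cysP + 1L
  s_rel <- regexpr("S", substr(seq, tail_start, min(nchar(seq), cysP + config$s_window)))
  s_pos <- if (s_rel > 0L) tail_start + as.integer(s_rel) - 1L else NA_integer_
  wf_from <- if (is.na(s_pos)) tail_start else s_pos + 1L
  wf_rel <- regexpr("[WF]", substr(seq, wf_from, min(nchar(seq), cysP + config$wf_window)))
  wf_pos <- if (wf_rel > 0L) wf_from + as.integer(wf_rel) - 1L else NA_integer_
  structure(
    list(cysP_pos = cysP, core_start = core_start, core_end = cysP,
         resolving_S_pos = s_pos, aromatic_pos = wf_pos,
         cysR_pos = NA_integer_, spacing = NA_integer_,
         diagnostic_hits = list()),
    class = "ActiveSiteProfile"
  )
}

#' Locate the resolving cysteine
#'
#' Finds the nearest cysteine downstream of Cys_P whose spacing (residues
#' strictly between the two cysteines) falls in one of the allowed windows:
#' exactly 4 (PRXQ-type) or exactly 24 (type-II), each widened by
#' `spacing_slack`.  Updates `cysR_pos` and `spacing`; both stay `NA` if no
#' such cysteine exists.
#'
#' @param profile an `ActiveSiteProfile` from [find_active_site()].
#' @param protein the same sequence.
#' @param config see [classify_config()].
#' @return The updated profile.
#' @export
locate_resolving_cys <- function(profile, protein, config = classify_config()) {
  stopifnot(inherits(profile, "ActiveSiteProfile"))
  seq <- as.character(protein)
  cysP <- profile$cysP_pos
  downstream <- gregexpr("C", substr(seq, cysP + 1L, nchar(seq)))[[1L]]
  if (downstream[1L] == -1L) return(profile)
  cands <- cysP + as.integer(downstream)
  spacing <- cands - cysP - 1L
  ok <- abs(spacing - 4L) <= config$spacing_slack |
        abs(spacing - 24L) <= config$spacing_slack
  if (!any(ok)) return(profile)
  pick <- which(ok)[1L]
  profile$cysR_pos <- cands[pick]
  profile$spacing <- spacing[pick]
  profile
}

#' Assign a PRX subfamily from an active-site profile
#'
#' Applies the spacing and diagnostic-submotif decision rules in order:
#' \enumerate{
#'   \item spacing 4 between Cys_P and Cys_R: \strong{PRXQ};
#'   \item spacing 24: \strong{PRXIIE} if the chloroplast type-II diagnostic
#'     matches, \strong{PRXIIF} if the S-to-A variant matches (ties broken by
#'     lower mismatch count, then PRXIIE), else \strong{PRXIIB};
#'   \item Cys_P inside the 2-Cys diagnostic context and a distal resolving
#'     cysteine inside an EVCP context in the C-terminal third:
#'     \strong{2-CysPRX};
#'   \item no resolving cysteine: \strong{1-CysPRX}; when the sequence
#'     matches the PRXIIB context but carries V at the resolving position,
#'     the call is annotated `reclassified_from = "PRXIIB"`.
#' }
#'
#' @param profile an `ActiveSiteProfile` (after [locate_resolving_cys()]),
#'   or `NULL` for an unclassifiable protein.
#' @param protein the sequence.
#' @param config see [classify_config()].
#' @return A `SubfamilyCall`: list with `label`, `evidence` (rule names),
#'   `reclassified_from`.
#' @export
classify_subfamily <- function(profile, protein, config = classify_config()) {
  seq <- as.character(protein)
  call <- function(label, evidence, reclassified_from = NA_character_) {
    structure(list(label = label, evidence = evidence,
                   reclassified_from = reclassified_from),
              class = "SubfamilyCall")
  }
  if (is.null(profile)) return(call("UNCLASSIFIED", character()))
  sl <- config$spacing_slack
  tol <- config$max_mismatch

  if (!is.na(profile$spacing) && abs(profile$spacing - 4L) <= sl) {
    return(call("PRXQ", "spacing_4"))
  }
  if (!is.na(profile$spacing) && abs(profile$spacing - 24L) <= sl) {
    hit_e <- match_diagnostic(seq, PRX_DIAGNOSTICS$prxiie, tol)
    hit_f <- match_diagnostic(seq, PRX_DIAGNOSTICS$prxiif, tol)
    if (!is.null(hit_e) || !is.null(hit_f)) {
      mm_e <- if (is.null(hit_e)) Inf else hit_e$mismatches
      mm_f <- if (is.null(hit_f)) Inf else hit_f$mismatches
      # tie on equal mismatch counts goes to PRXIIE
      if (mm_e <= mm_f) {
        return(call("PRXIIE", c("spacing_24", "prxiie_context")))
      }
      return(call("PRXIIF", c("spacing_24", "prxiif_context")))
    }
    return(call("PRXIIB", c("spacing_24", "no_EF_context")))
  }
  hit_2p <- match_diagnostic(seq, PRX_DIAGNOSTICS$twocys_cysP, tol)
  if (!is.null(hit_2p) && hit_2p$cys_pos == profile$cysP_pos) {
    hit_2r <- match_diagnostic(substr(seq, profile$cysP_pos + 1L, nchar(seq)),
                               PRX_DIAGNOSTICS$twocys_cysR, min(tol, 1L))
    if (!is.null(hit_2r)) {
      cysR_abs <- profile$cysP_pos + hit_2r$cys_pos
      if (cysR_abs > ceiling(2 * nchar(seq) / 3)) {
        return(call("2-CysPRX", c("twocys_cysP_context", "EVCP_distal")))
      }
    }
  }
  if (is.na(profile$cysR_pos)) {
    hit_b <- match_diagnostic(seq, PRX_DIAGNOSTICS$prxiib, tol)
    hit_v <- match_diagnostic(seq, PRX_DIAGNOSTICS$prxiib_resolving, tol,
                              anchor = "V")
    if (!is.null(hit_b) && !is.null(hit_v) && hit_v$pos > hit_b$pos) {
      return(call("1-CysPRX", c("prxiib_context", "resolving_C_to_V"),
                  reclassified_from = "PRXIIB"))
    }
    return(call("1-CysPRX", "no_resolving_cys"))
  }
  call("UNCLASSIFIED", character())
}

#' Classify a set of proteins
#'
#' Runs [find_active_site()], [locate_resolving_cys()] and
#' [classify_subfamily()] over a protein set.
#'
#' @param proteins a named [Biostrings::AAStringSet] or named character
#'   vector.
#' @param config see [classify_config()].
#' @return A data.frame with columns `id`, `label`, `cysP_pos`, `cysR_pos`,
#'   `spacing`, `evidence` (rule names, `;`-joined), `reclassified_from`.
#' @export
classify_proteins <- function(proteins, config = classify_config()) {
  ids <- names(proteins)
  if (is.null(ids)) stop("proteins must be named")
  seqs <- setNames(as.character(proteins), ids)
  rows <- lapply(seq_along(seqs), function(i) {
    prof <- find_active_site(seqs[[i]], config)
    if (!is.null(prof)) prof <- locate_resolving_cys(prof, seqs[[i]], config)
    cl <- classify_subfamily(prof, seqs[[i]], config)
    data.frame(
      id = ids[[i]], label = cl$label,
      cysP_pos = if (is.null(prof)) NA_integer_ else prof$cysP_pos,
      cysR_pos = if (is.null(prof)) NA_integer_ else prof$cysR_pos,
      spacing = if (is.null(prof)) NA_integer_ else prof$spacing,
      evidence = paste(cl$evidence, collapse = ";"),
      reclassified_from = cl$reclassified_from,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
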