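test_that("generators are deterministic: same seed, identical output", {
  cfg <- sim_config(seed = 99, n_per_subfamily = 3, include_reclassified = TRUE)
  p1 <- gen_proteins(cfg); p2 <- gen_proteins(cfg)
  expect_identical(as.character(p1$proteins), as.character(p2$proteins))
  expect_identical(p1$truth, p2$truth)

  l1 <- gen_ghprx14_locus(seed = 99); l2 <- gen_ghprx14_locus(seed = 99)
  expect_identical(as.character(l1$genome), as.character(l2$genome))
  expect_identical(l1$truth, l2$truth)

  d1 <- gen_duplicate_pairs(cfg, n_pairs = 2)
  d2 <- gen_duplicate_pairs(cfg, n_pairs = 2)
  expect_identical(as.character(d1$cds), as.character(d2$cds))

  c1 <- gen_ct_table(cfg); c2 <- gen_ct_table(cfg)
  expect_identical(c1, c2)

  g1 <- gen_locus(cfg); g2 <- gen_locus(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$promoter_truth, g2$promoter_truth)
  # different seeds give different sequences
  expect_false(identical(as.character(p1$proteins),
                         as.character(gen_proteins(sim_config(seed = 100,
                           n_per_subfamily = 3, include_reclassified = TRUE))$proteins)))
})

test_that("generated proteins carry their planted active sites", {
  sim <- gen_proteins(sim_config(seed = 88, n_per_subfamily = 4))
  for (i in seq_len(nrow(sim$truth))) {
    s <- as.character(sim$proteins[[sim$truth$id[i]]])
    cysP <- sim$truth$cysP_pos[i]
    expect_identical(substr(s, cysP, cysP), "C")
    # the core pattern sits immediately upstream of Cys_P
    expect_match(substr(s, cysP - 7L, cysP), "^P.{3}T.{2}C$")
    if (!is.na(sim$truth$cysR_pos[i])) {
      expect_identical(substr(s, sim$truth$cysR_pos[i], sim$truth$cysR_pos[i]), "C")
    }
  }
})

test_that("the classifier round-trips generated proteins at zero noise", {
  for (seed in c(5, 6, 7)) {
    sim <- gen_proteins(sim_config(seed = seed, n_per_subfamily = 5,
                                   include_reclassified = TRUE))
    res <- classify_proteins(sim$proteins)
    m <- merge(res, sim$truth, by = "id", suffixes = c("", ".truth"))
    expect_identical(nrow(m), nrow(sim$truth))
    expect_identical(m$label, m$subfamily)
    expect_identical(m$cysP_pos, m$cysP_pos.truth)
    expect_identical(m$reclassified_from, m$reclassified_from.truth)
  }
})

test_that("every cysteine in a generated protein is a planted one", {
  sim <- gen_proteins(sim_config(seed = 89, n_per_subfamily = 2))
  for (i in seq_len(nrow(sim$truth))) {
    s <- as.character(sim$proteins[[sim$truth$id[i]]])
    n_c <- lengths(regmatches(s, gregexpr("C", s)))
    # every cysteine is a planted one: Cys_P, Cys_R, or a motif-internal C
    expect_lte(n_c, 4L)
  }
})

test_that("duplicate pairs carry exactly the planted substitution classes", {
  cfg <- sim_config(seed = 90, dup_n_codons = 150, dup_n_syn = 5, dup_n_nonsyn = 2)
  sim <- gen_duplicate_pairs(cfg, n_pairs = 5)
  for (i in seq_len(nrow(sim$pairs))) {
    a <- as.character(sim$cds[[sim$pairs$id_a[i]]])
    b <- as.character(sim$cds[[sim$pairs$id_b[i]]])
    ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
    cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
    diff <- which(ca != cb)
    expect_identical(length(diff), 7L)  # one base each in 7 distinct codons
    aa_diff <- sum(Biostrings::GENETIC_CODE[ca[diff]] !=
                     Biostrings::GENETIC_CODE[cb[diff]])
    expect_identical(aa_diff, 2L)
    # nucleotide-level: exactly one substitution per touched codon
    nt_diffs <- mapply(function(x, y) {
      sum(strsplit(x, "")[[1L]] != strsplit(y, "")[[1L]])
    }, ca[diff], cb[diff])
    expect_true(all(nt_diffs == 1L))
    expect_false(any(c(ca, cb) %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("synonymous-only pairs give Ka exactly zero downstream", {
  cfg <- sim_config(seed = 91, dup_n_codons = 120, dup_n_syn = 6, dup_n_nonsyn = 0)
  sim <- gen_duplicate_pairs(cfg, n_pairs = 3)
  tab <- kaks_table(sim$pairs, sim$cds)
  expect_equal(tab$Ka, rep(0, 3))
  expect_true(all(tab$Ks > 0))
})

test_that("identical pairs give Ka = Ks = 0 downstream", {
  cfg <- sim_config(seed = 92, dup_n_codons = 100, dup_n_syn = 0, dup_n_nonsyn = 0)
  sim <- gen_duplicate_pairs(cfg, n_pairs = 1)
  tab <- kaks_table(sim$pairs, sim$cds)
  expect_identical(tab$Ka, 0)
  expect_identical(tab$Ks, 0)
})

test_that("gen_locus emits the subfamily exon counts and the 5'UTR-intron gene", {
  loc <- gen_locus(sim_config(seed = 93))
  for (i in seq_len(nrow(loc$exon_truth))) {
    g <- loc$genes[[loc$exon_truth$gene_id[i]]]
    expect_identical(length(g$exons), loc$exon_truth$n_exons[i])
  }
  expect_true(utr_intron_before_tis(loc$genes$gene_utr5))
  expect_false(utr_intron_before_tis(loc$genes$gene_2CysPRX))
  # the splice locus rides along with its gene model registered
  expect_true("GhPRX14like" %in% names(loc$genes))
  expect_identical(names(loc$genome),
                   unique(vapply(loc$genes, function(g) g$contig, "")))
})

test_that("generated gene CDS translate end to end (ATG start, stop-free)", {
  loc <- gen_locus(sim_config(seed = 94))
  for (gid in loc$exon_truth$gene_id) {
    g <- loc$genes[[gid]]
    tx <- as.character(transcript_sequence(loc$genome, g))
    expect_identical(substr(tx, 1, 3), "ATG")
    orf <- orf_and_translate(tx)
    expect_identical(orf$start, 1L)
    expect_identical(orf$orf_bp, nchar(tx) - 3L)
  }
})

test_that("Ct tables invert the three-step procedure at zero noise", {
  ct <- gen_ct_table(sim_config(seed = 95, ct_noise_sd = 0))
  # reference gene Ct fixed; control dCt1 constant
  expect_true(all(ct$control$ct_reference == 20))
  expect_equal(unique(ct$control$ct_target - ct$control$ct_reference), 5)
  fc <- fold_change(ct$stress, ct$control)
  m <- merge(fc, ct$truth, by = c("gene", "timepoint"))
  expect_equal(m$fold_change.x, m$fold_change.y, tolerance = 1e-12)
})
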