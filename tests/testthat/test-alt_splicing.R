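test_that("identical exon chains yield no events; mismatches are errors", {
  sim <- gen_as_case("IR")
  same <- transcript_model("t", "gene1", sim$ref$contig, sim$ref$strand,
                           sim$ref$exons)
  expect_identical(nrow(classify_events(sim$ref, same)), 0L)
  other <- transcript_model("t", "gene1", "chrZ", sim$ref$strand, sim$ref$exons)
  expect_error(classify_events(sim$ref, other), "contig")
  flip <- transcript_model("t", "gene1", sim$ref$contig,
                           if (sim$ref$strand == "+") "-" else "+",
                           sim$ref$exons)
  expect_error(classify_events(sim$ref, flip), "strand")
})

test_that("planted events round-trip for all six types on both strands", {
  set.seed(71)
  for (type in c("IR", "ES", "A3SS", "A5SS", "AFE", "ALE")) {
    for (strand in c("+", "-")) {
      for (rep in 1:8) {
        sim <- gen_as_case(type, n_exons = sample(4:7, 1), strand = strand)
        ev <- classify_events(sim$ref, sim$alt)
        expect_identical(nrow(ev), 1L, label = paste(type, strand, rep))
        expect_identical(ev$type, sim$truth$type)
        expect_identical(ev$index_first, sim$truth$index)
        expect_identical(ev$length, sim$truth$length)
      }
    }
  }
})

test_that("a pure terminal-fragment retention carries the partial-IR alias", {
  set.seed(72)
  sim <- gen_as_case("A3SS")
  ev <- classify_events(sim$ref, sim$alt)
  expect_identical(ev$alias, "partial-IR")
  # a full intron retention is plain IR, not partial
  sim2 <- gen_as_case("IR")
  expect_identical(classify_events(sim2$ref, sim2$alt)$alias, "IR")
})

test_that("boundary dinucleotides are strand-aware and flag non-GT..AG", {
  #           123456789012345678
  chr <- paste0("AA", "GTCCCCAG", "TTTTTTTT")
  genome <- Biostrings::DNAStringSet(c(c1 = chr))
  b <- boundary_dinucleotides(genome, "c1", "+", 3L, 10L)
  expect_identical(b$donor, "GT")
  expect_identical(b$acceptor, "AG")
  expect_true(b$canonical)
  # the same interval read on the minus strand is CT..AC
  bm <- boundary_dinucleotides(genome, "c1", "-", 3L, 10L)
  expect_identical(bm$donor, "CT")
  expect_false(bm$canonical)
  expect_error(boundary_dinucleotides(genome, "c1", "+", 3L, 5L), "4 bp")
  expect_error(boundary_dinucleotides(genome, "nope", "+", 3L, 10L), "contig")
})

test_that("generated reference introns are canonical except the planted AG donor", {
  loc <- gen_ghprx14_locus(seed = 73)
  intr <- prxfam:::introns_of(loc$gene)
  b <- boundary_dinucleotides(loc$genome, "chrPRX14", "+",
                              BiocGenerics::start(intr), BiocGenerics::end(intr))
  expect_identical(b$canonical, c(FALSE, TRUE, TRUE, TRUE))
  expect_identical(b$donor[1], "AG")
  expect_identical(b$acceptor, rep("AG", 4))
})

test_that("event_boundaries annotates the derived junctions", {
  loc <- gen_ghprx14_locus(seed = 74)
  ev <- event_boundaries(loc$genome, loc$gene, classify_events(loc$gene, loc$as2))
  expect_identical(ev$type, "A3SS")
  expect_identical(ev$alias, "partial-IR")
  # the shortened intron 1 ends right before the retained AA...AG segment
  expect_identical(ev$donor, "AG")
  expect_identical(ev$acceptor, "AG")
  expect_false(ev$canonical)
  expect_identical(nrow(event_boundaries(loc$genome, loc$gene, classify_events(
    loc$gene, transcript_model("t", loc$gene$gene_id, loc$gene$contig,
                               loc$gene$strand, loc$gene$exons)))), 0L)
})

test_that("ORF detection matches the exhaustive oracle", {
  set.seed(75)
  for (i in 1:40) {
    s <- random_dna(sample(30:400, 1))
    got <- orf_and_translate(s)
    want <- oracle_orf(s)
    expect_identical(got$orf_bp, want$orf_bp)
    expect_identical(got$protein_aa, want$protein_aa)
    expect_identical(got$start, want$start)
  }
})

test_that("ORF arithmetic: stop excluded, ties to 5', no-ORF is zero", {
  # ATG AAA TAA: ORF 6 bp (stop excluded), 2 aa
  got <- orf_and_translate("ATGAAATAA")
  expect_identical(got$orf_bp, 6L)
  expect_identical(got$protein_aa, 2L)
  expect_identical(got$start, 1L)
  # two equal-length ORFs: most 5' start wins
  tie <- "ATGAAATAACCCATGAAATAA"
  expect_identical(orf_and_translate(tie)$start, 1L)
  # ATG without in-frame stop, and no ATG at all
  expect_identical(orf_and_translate("ATGAAAAAA")$orf_bp, 0L)
  expect_identical(orf_and_translate("CCCCCCCCC")$orf_bp, 0L)
})

test_that("the packaged splice-variant locus reproduces its ORF table", {
  loc <- gen_ghprx14_locus(seed = 1)
  orf <- function(m) orf_and_translate(transcript_sequence(loc$genome, m))
  r <- orf(loc$ref)
  expect_identical(c(r$orf_bp, r$protein_aa), c(597L, 199L))
  a2 <- orf(loc$as2)
  expect_identical(c(a2$orf_bp, a2$protein_aa), c(612L, 204L))
  a3 <- orf(loc$as3)
  expect_identical(c(a3$orf_bp, a3$protein_aa), c(327L, 109L))
  # event calls: AS2 retains 15 bp of intron 1; AS3 skips exons 2-4 and
  # retains 14 bp of intron 4
  ev2 <- classify_events(loc$gene, loc$as2)
  expect_identical(ev2$type, "A3SS")
  expect_identical(ev2$length, 15L)
  expect_identical(ev2$index_first, 1L)
  ev3 <- classify_events(loc$gene, loc$as3)
  expect_identical(ev3$type, c("ES", "A3SS"))
  expect_identical(ev3$length, c(284L, 14L))
  expect_identical(ev3$index_first, c(2L, 4L))
  expect_identical(ev3$index_last, c(4L, 4L))
})

test_that("the splice-variant locus behaves identically on the minus strand", {
  loc <- gen_ghprx14_locus(seed = 2, strand = "-")
  expect_identical(loc$gene$strand, "-")
  orf <- function(m) orf_and_translate(transcript_sequence(loc$genome, m))
  expect_identical(orf(loc$as2)$orf_bp, 612L)
  expect_identical(orf(loc$as3)$orf_bp, 327L)
  ev3 <- classify_events(loc$gene, loc$as3)
  expect_identical(ev3$type, c("ES", "A3SS"))
  expect_identical(ev3$index_first, c(2L, 4L))
})
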