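test_that("extract_promoter takes the bases 5' of the TIS, strand-aware", {
  chr <- paste0(strrep("A", 10), "CGTCA", strrep("T", 10), "ATGGCC",
                strrep("G", 10))
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))
  # plus strand: CDS starts at the ATG (position 26)
  mp <- gene_model("gp", "chr1", "+", IRanges::IRanges(26, 41),
                   IRanges::IRanges(26, 31))
  expect_identical(as.character(extract_promoter(genome, mp, length = 5)),
                   substr(chr, 21, 25))
  expect_identical(as.character(extract_promoter(genome, mp, length = 25)),
                   substr(chr, 1, 25))
  # minus strand: TIS at the CDS 3'-most coordinate, promoter is the
  # reverse complement of the downstream bases
  mm <- gene_model("gm", "chr1", "-", IRanges::IRanges(1, 15),
                   IRanges::IRanges(10, 15))
  got <- extract_promoter(genome, mm, length = 5)
  want <- Biostrings::reverseComplement(Biostrings::DNAString(substr(chr, 16, 20)))
  expect_identical(as.character(got), as.character(want))
})

test_that("promoters overhanging the contig are truncated with a warning", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 10)))
  mp <- gene_model("gp", "chr1", "+", IRanges::IRanges(11, 20),
                   IRanges::IRanges(11, 16))
  expect_warning(p <- extract_promoter(genome, mp, length = 50), "truncated")
  expect_identical(length(p), 10L)
  mm <- gene_model("gm", "chr1", "-", IRanges::IRanges(21, 30),
                   IRanges::IRanges(21, 26))
  expect_warning(p2 <- extract_promoter(genome, mm, length = 50), "truncated")
  expect_identical(length(p2), 14L)
})

test_that("scan_elements matches the naive sliding-window oracle", {
  set.seed(51)
  catalogue <- load_cis_catalogue()
  for (i in 1:30) {
    prom <- random_dna(300)
    hits <- scan_elements(prom, catalogue)
    for (k in sample(nrow(catalogue), 8)) {
      want <- oracle_scan(prom, catalogue$consensus[k])
      got <- hits[hits$name == catalogue$name[k], ]
      expect_equal(
        got[order(got$offset, got$strand), c("offset", "strand")],
        want[order(want$offset, want$strand), , drop = FALSE],
        ignore_attr = TRUE
      )
    }
  }
})

test_that("degenerate consensus codes expand, promoter N matches nothing", {
  catalogue <- data.frame(name = "el", consensus = "CANNTG", class = "x",
                          stringsAsFactors = FALSE)
  hits <- scan_elements("GGCAGGTGGG", catalogue, strands = "plus")
  expect_identical(hits$offset, 3L)
  # an N in the promoter must not satisfy the pattern
  hits_n <- scan_elements("GGCANGTGGG", catalogue, strands = "plus")
  expect_identical(nrow(hits_n), 0L)
})

test_that("minus-strand hits are reported at promoter-forward offsets", {
  catalogue <- data.frame(name = "tgacg", consensus = "TGACG", class = "x",
                          stringsAsFactors = FALSE)
  # plant the reverse complement CGTCA at offset 4
  prom <- paste0("AAA", "CGTCA", "TT")
  hits <- scan_elements(prom, catalogue)
  minus <- hits[hits$strand == "-", ]
  expect_identical(minus$offset, 4L)
  expect_identical(minus$match, "CGTCA")
  expect_identical(nrow(hits[hits$strand == "+", ]), 0L)
})

test_that("hit order is deterministic: offset then name", {
  catalogue <- data.frame(name = c("b_el", "a_el"), consensus = c("ACGT", "ACGT"),
                          class = "x", stringsAsFactors = FALSE)
  hits <- scan_elements("ACGTACGT", catalogue, strands = "plus")
  expect_identical(hits$offset, c(1L, 1L, 5L, 5L))
  expect_identical(hits$name, c("a_el", "b_el", "a_el", "b_el"))
})

test_that("planted elements in generated loci are recovered at truth offsets", {
  cfg <- sim_config(seed = 52)
  loc <- gen_locus(cfg)
  catalogue <- load_cis_catalogue()
  for (g in unique(loc$promoter_truth$gene_id)) {
    prom <- extract_promoter(loc$genome, loc$genes[[g]])
    hits <- scan_elements(prom, catalogue, gene_id = g)
    tr <- loc$promoter_truth[loc$promoter_truth$gene_id == g, ]
    for (k in seq_len(nrow(tr))) {
      expect_true(any(hits$name == tr$name[k] & hits$offset == tr$offset[k] &
                        hits$strand == tr$strand[k]),
                  label = paste("planted", tr$name[k], "for", g))
    }
  }
})

test_that("class_summary partitions hits and counts distinct types", {
  catalogue <- data.frame(
    name = c("e1", "e2", "e3"),
    consensus = c("AAAA", "CCCC", "GGGG"),
    class = c("abiotic", "abiotic", "hormone"),
    stringsAsFactors = FALSE
  )
  proms <- c(g1 = "AAAAACCCCGGGG", g2 = "TTTTTTTT")
  hits <- scan_promoters(proms, catalogue, strands = "plus")
  sm <- class_summary(hits, catalogue)
  g1a <- sm[sm$gene_id == "g1" & sm$class == "abiotic", ]
  expect_identical(g1a$n_hits, 3L)  # AAAA twice (overlap) + CCCC once
  expect_identical(g1a$n_types, 2L)
  g1h <- sm[sm$gene_id == "g1" & sm$class == "hormone", ]
  expect_identical(g1h$n_hits, 1L)
  bad <- hits; bad$name[1] <- "nope"
  expect_error(class_summary(bad, catalogue), "unknown element")
})
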