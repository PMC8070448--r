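# a small hand-built two-gene locus: identical gene on + and - strand
# (the minus gene is the reverse complement of the plus gene), so all
# sense-strand features must agree between the two
mirrorLocus <- function() {
  set.seed(99)
  exon <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  e1 <- exon(80); e2 <- exon(60); e3 <- exon(70)
  i1 <- paste0("GTAAGT", exon(108), "TTTCAG")  # 120-nt intron
  i2 <- paste0("GTAAGT", exon(238), "TTTCAG")  # 250-nt intron
  sense <- paste0(e1, i1, e2, i2, e3)
  pad <- exon(30)
  plusChrom <- paste0(pad, sense, pad)
  minusChrom <- paste0(pad, oracleRevcomp(sense), pad)
  genome <- Biostrings::DNAStringSet(c(plusChrom, minusChrom))
  names(genome) <- c("chrP", "chrM")
  L <- nchar(sense)
  # plus-strand exon coordinates
  s <- c(31, 31 + 80 + 120, 31 + 80 + 120 + 60 + 250)
  e <- s + c(80, 60, 70) - 1
  # minus-strand (mirrored) coordinates
  sM <- 60 + L - e + 1
  eM <- 60 + L - s + 1
  mk <- function(chr, strand, s, e) GenomicRanges::GRanges(
    chr, IRanges::IRanges(c(min(s), min(s), s), c(max(e), max(e), e)),
    strand = strand,
    type = c("gene", "transcript", rep("exon", 3)),
    gene_id = paste0("g", chr), transcript_id = paste0("t", chr),
    exon_number = c(NA, NA, 1:3), cassette = c(NA, NA, FALSE, TRUE, FALSE))
  ann <- suppressWarnings(c(mk("chrP", "+", s, e),
                            mk("chrM", "-", sM, eM)))  # disjoint seqlevels
  panel <- new("ProbePanel", events = {
    ev <- ann[ann$type == "exon" & ann$cassette %in% TRUE]
    S4Vectors::mcols(ev) <- S4Vectors::DataFrame(
      event_id = c("evP", "evM"), gene_id = c("gchrP", "gchrM"),
      event_type = "SE", inclusion_probe = c("pP_inc", "pM_inc"),
      skipping_probe = c("pP_skp", "pM_skp"))
    ev
  })
  list(genome = genome, ann = ann, panel = panel,
       exonSeqs = list(e1 = e1, e2 = e2, e3 = e3), i1 = i1, i2 = i2)
}

test_that("splice-site windows have the defined composition and strand symmetry", {
  loc <- mirrorLocus()
  ev <- cassetteExons(loc$panel)
  w <- extractSpliceWindows(loc$genome, ev)
  expect_identical(nchar(w$donor), c(9L, 9L))
  expect_identical(nchar(w$acceptor), c(23L, 23L))
  # mirrored genes give identical sense-strand windows
  expect_identical(w$donor[1], w$donor[2])
  expect_identical(w$acceptor[1], w$acceptor[2])
  # composition: last 3 exonic + first 6 intronic (donor); the cassette
  # exon's donor feeds intron 2, which starts with GTAAGT
  e2 <- loc$exonSeqs$e2
  expect_identical(w$donor[1],
                   paste0(substr(e2, nchar(e2) - 2, nchar(e2)), "GTAAGT"))
  # acceptor: last 20 intronic + first 3 exonic; intron 1 ends TTTCAG
  expect_identical(substr(w$acceptor[1], 15, 20), "TTTCAG")
  expect_identical(substr(w$acceptor[1], 21, 23), substr(e2, 1, 3))
  # exon at a contig edge errors with a named deficit
  edge <- GenomicRanges::GRanges("chrP", IRanges::IRanges(5, 40),
                                 strand = "+")
  expect_error(extractSpliceWindows(loc$genome, edge), "insufficient")
})

test_that("flank extraction truncates at short introns and respects strand", {
  loc <- mirrorLocus()
  fl <- extractFlanks(loc$panel, loc$ann, loc$genome, flankLen = 200)
  # upstream intron is 120 nt -> truncated; downstream 250 -> full
  expect_identical(nchar(fl$upstream), c(120L, 120L))
  expect_identical(nchar(fl$downstream), c(200L, 200L))
  expect_identical(fl$upstream_truncated, c(TRUE, TRUE))
  expect_identical(fl$downstream_truncated, c(FALSE, FALSE))
  # minus-strand flanks equal the plus-strand computation (mirror locus)
  expect_identical(fl$upstream[1], fl$upstream[2])
  expect_identical(fl$downstream[1], fl$downstream[2])
  expect_identical(fl$exon[1], fl$exon[2])
  # content: upstream window is the tail of intron 1, sense strand
  expect_identical(fl$upstream[1], loc$i1)
  expect_identical(fl$downstream[1], substr(loc$i2, 1, 200))
  expect_identical(fl$exon[1], loc$exonSeqs$e2)
})

test_that("window slices reassemble into the genomic sequence", {
  loc <- mirrorLocus()
  ev <- cassetteExons(loc$panel)[1]
  w <- extractSpliceWindows(loc$genome, ev)
  fl <- extractFlanks(loc$panel, loc$ann, loc$genome, flankLen = 200)
  # acceptor exonic 3 nt + exon interior + donor exonic 3 nt == exon
  inner <- substr(fl$exon[1], 4, nchar(fl$exon[1]) - 3)
  expect_identical(paste0(substr(w$acceptor[1], 21, 23), inner,
                          substr(w$donor[1], 1, 3)),
                   fl$exon[1])
})

test_that("architecture features carry exact lengths and GC", {
  loc <- mirrorLocus()
  feats <- computeArchitecture(loc$panel, loc$ann, loc$genome)
  expect_identical(feats$exon_length, c(60L, 60L))
  expect_identical(feats$upstream_intron_length, c(120L, 120L))
  expect_identical(feats$downstream_intron_length, c(250L, 250L))
  expect_identical(feats$median_tx_length, c(210L, 210L))
  manualGC <- sum(strsplit(loc$exonSeqs$e2, "")[[1]] %in% c("G", "C")) / 60
  expect_equal(feats$exon_gc, rep(manualGC, 2))
  expect_equal(gcFraction("ATGC"), 0.5)
})

test_that("group comparisons use the declared tests with direction signs", {
  set.seed(12)
  n <- 50
  base <- rnorm(n)
  feats <- data.frame(
    class = rep(c("up", "ndiff"), each = n),
    alt_donor_score = c(base, base),           # identical groups
    exon_length = rep(rpois(n, 150), 2))
  cmp <- compareGroups(feats, scoreFeatures = "alt_donor_score",
                       rankFeatures = "exon_length")
  tRow <- cmp[cmp$feature == "alt_donor_score" & cmp$test == "t", ]
  expect_gt(tRow$p_value, 0.5)
  expect_identical(tRow$direction, 0)
  mwRow <- cmp[cmp$test == "mann_whitney", ]
  expect_gt(mwRow$p_value, 0.5)

  # planted shift: positive direction, significant, label-symmetric
  feats2 <- data.frame(
    class = rep(c("up", "ndiff"), each = 200),
    alt_donor_score = c(rnorm(200, 1.5), rnorm(200, 0)))
  cmp2 <- compareGroups(feats2, scoreFeatures = "alt_donor_score",
                        rankFeatures = character())
  expect_lt(cmp2$p_value[1], 0.01)
  expect_identical(cmp2$direction[1], 1)
  feats3 <- feats2
  feats3$class <- ifelse(feats2$class == "up", "ndiff", "up")
  cmp3 <- compareGroups(feats3, scoreFeatures = "alt_donor_score",
                        rankFeatures = character())
  expect_equal(cmp3$p_value[1], cmp2$p_value[1])
  expect_identical(cmp3$direction[1], -1)

  # three groups add an ANOVA row for score features
  feats4 <- data.frame(class = rep(c("up", "down", "ndiff"), each = 20),
                       alt_donor_score = rnorm(60))
  cmp4 <- compareGroups(feats4, scoreFeatures = "alt_donor_score",
                        rankFeatures = character())
  expect_identical(sum(cmp4$test == "anova"), 1L)
  expect_identical(sum(cmp4$test == "t"), 3L)
  expect_error(compareGroups(data.frame(class = "up",
                                        alt_donor_score = 1)),
               "class")
})

test_that("k-mer enrichment matches the hypergeometric oracle and finds planted motifs", {
  # controlled contingency: motif in 30/100 targets vs 5/100 background
  tgt <- c(replicate(30, paste0(strrep("C", 40), "GTAAGA", strrep("C", 40))),
           replicate(70, strrep("C", 86)))
  bg <- c(replicate(5, paste0(strrep("C", 40), "GTAAGA", strrep("C", 40))),
          replicate(95, strrep("C", 86)))
  km <- kmerEnrichment(tgt, bg, k = 6)
  row <- km[km$kmer == "GUAAGA", ]
  expect_identical(row$n_target, 30L)
  expect_identical(row$n_background, 5L)
  oracle <- stats::fisher.test(matrix(c(30, 70, 5, 95), 2),
                               alternative = "greater")$p.value
  expect_equal(row$p_value, oracle)

  # identical sets: nothing significant
  same <- kmerEnrichment(tgt, tgt, k = c(4, 6))
  expect_false(any(same$significant))

  # BH never lowers a p-value and preserves its ranking
  expect_true(all(km$p_adj >= km$p_value))
  expect_false(is.unsorted(km$p_adj))

  # k larger than the shortest sequence is skipped with a warning
  expect_warning(kmerEnrichment(c("ACGT", "ACGTACGT"), c("ACGTAA"),
                                k = c(4, 6)), "skipped")
})
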