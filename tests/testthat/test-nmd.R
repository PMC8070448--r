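test_that("exon skipping removes the exon and its length from the mRNA", {
  set.seed(10)
  case <- randomTranscriptCase(nExons = 5)
  t <- case$model
  skp <- skipExon(t, 4L)
  expect_identical(exonCount(skp), 4L)
  exW <- IRanges::width(t@exons)
  txW <- if (t@strand == "+") exW else rev(exW)
  expect_identical(splicedLength(skp), splicedLength(t) - txW[4])
  expect_error(skipExon(t, 1L), "terminal")
  expect_error(skipExon(t, 5L), "terminal")
})

test_that("skipping the start-codon exon is rejected", {
  # ATG lives in exon 1 of randomTranscriptCase; build a case where it
  # sits in an internal exon by shifting cdsStart
  set.seed(11)
  case <- randomTranscriptCase(nExons = 4)
  t <- case$model
  ex <- if (t@strand == "+") t@exons else rev(t@exons)
  mid <- IRanges::start(ex)[2]   # transcript exon 2 on either strand
  t2 <- transcriptModel("t2", t@chrom, t@strand,
                        IRanges::start(t@exons), IRanges::end(t@exons),
                        cdsStart = mid)
  expect_error(skipExon(t2, 2L), "start codon")
})

test_that("ORF scanning finds the first in-frame stop", {
  expect_identical(scanORF("ATGTAA", 1), 4L)
  expect_identical(scanORF("ATGAAATAG", 1), 7L)
  expect_identical(scanORF("ATGAAAAAA", 1), NA_integer_)
  expect_warning(p <- scanORF("AAATAA", 1), "not an ATG")
  expect_identical(p, 4L)
  # random 3-kb sequence equals a codon-by-codon loop
  set.seed(13)
  s <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  s <- paste0("ATG", s)
  pos <- 4L
  expected <- NA_integer_
  while (pos + 2 <= nchar(s)) {
    if (substr(s, pos, pos + 2) %in% c("TAA", "TAG", "TGA")) {
      expected <- pos; break
    }
    pos <- pos + 3L
  }
  expect_identical(scanORF(s, 1), expected)
})

test_that("mRNA/genome coordinate maps are mutual inverses on both strands", {
  set.seed(14)
  for (i in 1:6) {
    case <- randomTranscriptCase()
    t <- case$model
    L <- splicedLength(t)
    for (p in unique(c(1L, L, sample.int(L, 10)))) {
      g <- txToGenome(t, p)
      expect_identical(genomeToTx(t, g), p)
    }
    # intronic position maps to NA
    ex <- t@exons
    if (length(ex) > 1)
      expect_true(is.na(genomeToTx(t, IRanges::end(ex)[1] + 1L)))
  }
})

test_that("frame-preserving skips leave the downstream protein unchanged", {
  # middle exon of length 30 with no stop codon in any frame
  body <- function(n) substr(strrep("GCA", ceiling(n / 3) + 1), 1, n)
  e1 <- body(60); e2 <- body(30); e3 <- body(90)
  substr(e1, 7, 9) <- "ATG"
  substr(e3, 61, 63) <- "TAA"
  intr <- paste0("GTAAGT", body(50), "TTTCAG")
  chrom <- paste0(body(12), e1, intr, e2, intr, e3, body(12))
  genome <- Biostrings::DNAStringSet(chrom); names(genome) <- "c"
  s1 <- 13L
  st <- c(s1, s1 + 60L + 62L, s1 + 60L + 62L + 30L + 62L)
  en <- st + c(60L, 30L, 90L) - 1L
  t <- transcriptModel("t", "c", "+", st, en, cdsStart = s1 + 6L)
  skp <- skipExon(t, 2L)
  pep <- function(m) {
    s <- splicedSequence(m, genome)
    cds <- substr(s, 7, 6 + 3 * ((nchar(s) - 6) %/% 3))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    sub("\\*.*$", "", aa)
  }
  pIncl <- pep(t); pSkip <- pep(skp)
  # skipped protein is the included protein minus 10 internal residues
  expect_identical(nchar(pIncl) - nchar(pSkip), 10L)
  expect_identical(substr(pIncl, nchar(pIncl) - 19, nchar(pIncl)),
                   substr(pSkip, nchar(pSkip) - 19, nchar(pSkip)))
})

test_that("NMD classification honours the junction rule at the boundary", {
  for (d in c(49L, 50L, 51L)) {
    case <- boundaryTranscriptCase(d)
    res <- classifyNMD(case$model, case$genome, threshold = 50)
    expect_identical(res$distance, d)
    expect_identical(res$nmd_flag, if (d >= 50) "NMD+" else "NMD-")
    expect_identical(oracleNMD(case$model, case$genome, 50),
                     res$nmd_flag)
  }
  # a stop in the last exon is NMD- regardless of distance
  case <- boundaryTranscriptCase(-30L)
  expect_identical(classifyNMD(case$model, case$genome)$nmd_flag, "NMD-")
  # raising the threshold never converts NMD- to NMD+
  case <- boundaryTranscriptCase(60L)
  lo <- classifyNMD(case$model, case$genome, threshold = 50)$nmd_flag
  hi <- classifyNMD(case$model, case$genome, threshold = 80)$nmd_flag
  expect_identical(lo, "NMD+")
  expect_identical(hi, "NMD-")
})

test_that("NMD classification agrees with brute force on random transcripts", {
  set.seed(15)
  mismatches <- 0L
  for (i in 1:150) {
    case <- randomTranscriptCase()
    res <- classifyNMD(case$model, case$genome, threshold = 50)
    bf <- oracleNMD(case$model, case$genome, 50)
    if (!identical(res$nmd_flag, bf)) mismatches <- mismatches + 1L
  }
  expect_identical(mismatches, 0L)
})

test_that("the packaged exon-skip fixture shows AS-coupled NMD", {
  genome <- readGenomeFasta(fixturePath("dcun1d5_like_synthetic.fa"))
  ann <- readAnnotationGTF(fixturePath("dcun1d5_like_synthetic.gtf"))
  t <- transcriptModels(ann)[[1]]
  expect_identical(exonCount(t), 6L)
  incl <- classifyNMD(t, genome)
  skp <- classifyNMD(skipExon(t, 4L), genome)
  expect_identical(incl$nmd_flag, "NMD-")
  expect_identical(skp$nmd_flag, "NMD+")
  # the PTC lands in the exon downstream of the skipped one (the gene's
  # exon 5 = the skipped isoform's exon 4), upstream of the final junction
  expect_identical(skp$stop_exon, 4L)
  expect_gte(skp$distance, 50L)
  # skipping shifts the frame: cassette length not divisible by 3
  ex <- ann[ann$type == "exon"]
  expect_false(IRanges::width(ex[ex$exon_number == 4]) %% 3 == 0)
})

test_that("PSI follows the spanning-transcript definition", {
  body <- function(n) substr(strrep("GCA", ceiling(n / 3) + 1), 1, n)
  chrom <- body(1000)
  genome <- Biostrings::DNAStringSet(chrom); names(genome) <- "c"
  mk <- function(id, st, en) transcriptModel(id, "c", "+", st, en)
  # cassette exon at [401, 460]
  ev <- GenomicRanges::GRanges("c", IRanges::IRanges(401, 460), "+")
  inc <- mk("inc", c(101L, 401L, 701L), c(160L, 460L, 760L))
  skp <- mk("skp", c(101L, 701L), c(160L, 760L))
  nonspan <- mk("non", c(501L, 701L), c(560L, 760L))  # nothing upstream
  models <- list(inc = inc, skp = skp, non = nonspan)
  expect_equal(psiFromTranscripts(ev, models,
                                  c(inc = 10, skp = 10, non = 99))$psi, 50)
  expect_equal(psiFromTranscripts(ev, models,
                                  c(inc = 30, skp = 10, non = 99))$psi, 75)
  # enumeration oracle on a multi-sample matrix
  ab <- matrix(c(3, 9, 50, 8, 2, 7), nrow = 3,
               dimnames = list(c("inc", "skp", "non"), c("s1", "s2")))
  res <- psiFromTranscripts(ev, models, ab)
  expect_equal(res$psi, 100 * ab["inc", ] / (ab["inc", ] + ab["skp", ]),
               ignore_attr = TRUE)
  # zero spanning abundance is undefined, not zero
  res0 <- psiFromTranscripts(ev, models, c(inc = 0, skp = 0, non = 5))
  expect_true(is.na(res0$psi))
  expect_false(res0$defined)
})

test_that("percent-NMD+ vs expression correlation behaves like Pearson", {
  x <- c(10, 20, 30, 40, 50)
  res <- nmdExpressionCorrelation(x, -x)
  expect_equal(res$r, -1)
  # no association: |r| small in nearly all seeds
  small <- vapply(1:20, function(s) {
    set.seed(s)
    abs(nmdExpressionCorrelation(rnorm(1000), rnorm(1000))$r)
  }, numeric(1))
  expect_gte(sum(small < 0.1), 19L)
  # planted negative coupling at a 46-sample panel
  hits <- vapply(1:20, function(s) {
    set.seed(100 + s)
    pct <- runif(46, 0, 50)
    expr <- 100 - 1.2 * pct + rnorm(46, sd = 15)
    r <- nmdExpressionCorrelation(pct, expr)
    r$r < 0 && r$p_value < 0.05
  }, logical(1))
  expect_gte(sum(hits), 18L)
  # degenerate input flagged
  res0 <- nmdExpressionCorrelation(rep(1, 5), 1:5)
  expect_false(res0$defined)
  expect_error(nmdExpressionCorrelation(1:2, 2:1), "3 paired")
})
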