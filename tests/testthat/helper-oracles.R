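# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: plain-string sequence handling, loop
# arithmetic, closed-form statistics.

COMP <- c(A = "T", C = "G", G = "C", T = "A")

oracleRevcomp <- function(x) {
  paste(rev(COMP[strsplit(x, "")[[1]]]), collapse = "")
}

# Welch t-test on log2 ratios from first principles
oracleWelchLog2 <- function(rB, rA) {
  x <- log2(rB); y <- log2(rA)
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Exhaustive reimplementation of filter + ratio-change calls on small
# count tables (matrices events x samples)
oracleCalls <- function(inc, skp, cond, minCount = 5, T = 2,
                        alpha = 0.05) {
  out <- character(nrow(inc))
  for (i in seq_len(nrow(inc))) {
    if (any(inc[i, ] < minCount) || any(skp[i, ] < minCount)) {
      out[i] <- "filtered"; next
    }
    r <- inc[i, ] / skp[i, ]
    rc <- mean(r[cond == "B"]) / mean(r[cond == "A"])
    p <- oracleWelchLog2(r[cond == "B"], r[cond == "A"])
    out[i] <- if (rc >= T && p < alpha) "up"
              else if (rc <= 1 / T && p < alpha) "down" else "ndiff"
  }
  out
}

# Brute-force NMD classification: naive spliced-sequence assembly,
# codon-by-codon translation loop, junction tabulation
oracleNMD <- function(t, genome, threshold = 50) {
  chromChr <- as.character(genome[[t@chrom]])
  st <- IRanges::start(t@exons); en <- IRanges::end(t@exons)
  parts <- character(length(st))
  for (i in seq_along(st)) parts[i] <- substr(chromChr, st[i], en[i])
  if (t@strand == "-") {
    parts <- rev(vapply(parts, oracleRevcomp, "", USE.NAMES = FALSE))
  }
  mrna <- paste(parts, collapse = "")
  widths <- nchar(parts)
  # mRNA offset of the start codon
  cdsTx <- NA
  cum <- 0
  ord <- seq_along(st)
  exOrd <- if (t@strand == "+") ord else rev(ord)
  for (i in exOrd) {
    if (t@cdsStart >= st[i] && t@cdsStart <= en[i]) {
      off <- if (t@strand == "+") t@cdsStart - st[i] else en[i] - t@cdsStart
      cdsTx <- cum + off + 1
      break
    }
    cum <- cum + en[i] - st[i] + 1
  }
  stopifnot(!is.na(cdsTx))
  # translate until a stop
  pos <- cdsTx + 3
  stopPos <- NA
  while (pos + 2 <= nchar(mrna)) {
    codon <- substr(mrna, pos, pos + 2)
    if (codon %in% c("TAA", "TAG", "TGA")) { stopPos <- pos; break }
    pos <- pos + 3
  }
  if (is.na(stopPos)) return("no-stop")
  junctions <- cumsum(widths)
  junctions <- junctions[-length(junctions)]   # exon-exon junctions
  if (!length(junctions)) return("NMD-")
  finalJ <- junctions[length(junctions)]
  stopLast <- stopPos + 2
  if (stopLast <= finalJ && finalJ - stopLast >= threshold) "NMD+"
  else "NMD-"
}

# Random single-transcript gene on a random genome; ATG planted at a
# random transcript offset in exon 1. Returns list(model, genome).
randomTranscriptCase <- function(nExons = sample(2:6, 1)) {
  exLens <- sample(30:200, nExons, replace = TRUE)
  inLens <- sample(60:300, nExons - 1, replace = TRUE)
  total <- sum(exLens) + sum(inLens) + 100
  chrom <- paste(sample(c("A", "C", "G", "T"), total, replace = TRUE),
                 collapse = "")
  strandv <- sample(c("+", "-"), 1)
  st <- integer(nExons); en <- integer(nExons)
  pos <- 51
  for (i in seq_len(nExons)) {
    st[i] <- pos; en[i] <- pos + exLens[i] - 1
    pos <- en[i] + 1 + if (i < nExons) inLens[i] else 0
  }
  atgTx <- sample(1:(min(exLens[1], exLens[nExons]) - 10), 1)
  # genomic coordinates of the three ATG bases, transcript orientation
  if (strandv == "+") {
    g <- st[1] + atgTx - 1 + 0:2
    for (k in 1:3)
      substr(chrom, g[k], g[k]) <- c("A", "T", "G")[k]
    cds <- g[1]
  } else {
    g <- en[nExons] - atgTx + 1 - 0:2
    for (k in 1:3)
      substr(chrom, g[k], g[k]) <- COMP[c("A", "T", "G")[k]]
    cds <- g[1]
  }
  genome <- Biostrings::DNAStringSet(chrom)
  names(genome) <- "chrR"
  model <- transcriptModel("tx", "chrR", strandv, st, en, cdsStart = cds)
  list(model = model, genome = genome)
}

# Two-exon transcript engineered so the stop codon's last nucleotide
# lies exactly `d` nt upstream of the single (final) junction
boundaryTranscriptCase <- function(d, exon1 = 200L, exon2 = 200L,
                                   intron = 100L) {
  body <- function(n) substr(strrep("GCA", ceiling(n / 3) + 1), 1, n)
  mrna <- body(exon1 + exon2)
  stopLast <- exon1 - d            # mRNA position of stop's last nt
  stopPos <- stopLast - 2
  a <- (stopPos - 1) %% 3 + 1      # ATG offset in the stop's frame
  substr(mrna, a, a + 2) <- "ATG"
  substr(mrna, stopPos, stopPos + 2) <- "TAA"
  e1 <- substr(mrna, 1, exon1)
  e2 <- substr(mrna, exon1 + 1, exon1 + exon2)
  chrom <- paste0(strrep("C", 10), e1, body(intron), e2,
                  strrep("C", 10))
  genome <- Biostrings::DNAStringSet(chrom)
  names(genome) <- "chrB"
  model <- transcriptModel("txB", "chrB", "+",
                           c(11L, 11L + exon1 + intron),
                           c(10L + exon1, 10L + exon1 + intron + exon2),
                           cdsStart = 10L + a)
  list(model = model, genome = genome)
}

# small deterministic count fixture builder
toyCounts <- function(inc, skp, cond = rep(c("A", "B"), each = 3)) {
  rn <- sprintf("ev%02d", seq_len(nrow(inc)))
  rownames(inc) <- rownames(skp) <- rn
  raslCounts(inc, skp, condition = cond,
             replicate = ave(seq_along(cond), cond, FUN = seq_along))
}

fixturePath <- function(f) {
  p <- system.file("extdata", f, package = "raslsplice")
  if (nzchar(p)) p else file.path("..", "..", "inst", "extdata", f)
}
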