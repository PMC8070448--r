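BASES <- c("A", "C", "G", "T")

# per-base sampling probabilities for a target GC fraction
.gcProbs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

.randSeq <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  paste(sample(BASES, n, replace = TRUE, prob = .gcProbs(gc)),
        collapse = "")
}

#' GC fraction of sequences
#'
#' @param x character vector, \code{DNAString} or \code{DNAStringSet}.
#' @return numeric vector of (G+C)/length.
#' @examples
#' gcFraction("ATGC")
#' @export
gcFraction <- function(x) {
  if (is.character(x)) x <- DNAStringSet(x)
  if (is(x, "DNAString")) x <- DNAStringSet(list(x))
  as.numeric(letterFrequency(x, "GC", as.prob = TRUE))
}

# extract [start, end] (1-based inclusive) from one chromosome of a
# DNAStringSet; reverse-complemented when strand == "-"
.extractRegion <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' not in genome")
  len <- length(genome[[chrom]])
  if (start < 1L || end > len)
    stop("region [", start, ", ", end, "] outside ", chrom,
         " (length ", len, "); insufficient flanking sequence")
  s <- subseq(genome[[chrom]], start, end)
  if (strand == "-") s <- reverseComplement(s)
  as.character(s)
}

# reverse-complement of a character string
.revcompChr <- function(x) as.character(reverseComplement(DNAString(x)))

.checkSeedArg <- function(seed) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be a finite integer")
  seed
}
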