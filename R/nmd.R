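## Exon skipping on transcript models, ORF scanning, the 50-nt
## premature-termination-codon junction rule, PSI from transcript
## abundances and the percent-NMD+ vs expression correlation.

# exons in transcript (5'->3') order
.txOrderedExons <- function(t) {
  ex <- t@exons
  if (t@strand == "+") ex else rev(ex)
}

#' Spliced mRNA sequence of a transcript model
#'
#' @param t a \code{\link{transcriptModel}}.
#' @param genome named \code{DNAStringSet}.
#' @return character scalar, sense-strand spliced sequence.
#' @export
splicedSequence <- function(t, genome) {
  ex <- .txOrderedExons(t)
  parts <- vapply(seq_along(ex), function(i)
    .extractRegion(genome, t@chrom, start(ex)[i], end(ex)[i], t@strand),
    character(1))
  paste(parts, collapse = "")
}

#' Map between genomic and mRNA coordinates
#'
#' Strand-aware, 1-based on both sides; the two maps are mutual
#' inverses on exonic positions.
#'
#' @param t a \code{\link{transcriptModel}}.
#' @param pos genomic (for \code{genomeToTx}) or mRNA (for
#'   \code{txToGenome}) position.
#' @return mapped position; \code{genomeToTx} returns NA for intronic
#'   or out-of-transcript positions.
#' @export
genomeToTx <- function(t, pos) {
  ex <- .txOrderedExons(t)
  cum <- 0L
  for (i in seq_along(ex)) {
    s <- start(ex)[i]; e <- end(ex)[i]
    if (pos >= s && pos <= e) {
      off <- if (t@strand == "+") pos - s else e - pos
      return(cum + off + 1L)
    }
    cum <- cum + e - s + 1L
  }
  NA_integer_
}

#' @rdname genomeToTx
#' @export
txToGenome <- function(t, pos) {
  ex <- .txOrderedExons(t)
  cum <- 0L
  for (i in seq_along(ex)) {
    w <- end(ex)[i] - start(ex)[i] + 1L
    if (pos <= cum + w) {
      off <- pos - cum - 1L
      return(if (t@strand == "+") start(ex)[i] + off else end(ex)[i] - off)
    }
    cum <- cum + w
  }
  NA_integer_
}

#' Delete one exon from a transcript model
#'
#' Builds the exon-skipped isoform. Terminal exons and the exon holding
#' the start codon cannot be skipped (the event would not be a cassette
#' exon in the coding sense).
#'
#' @param t a \code{\link{transcriptModel}}.
#' @param exonIndex index in transcript (5'->3') order.
#' @param suffix appended to the transcript id (default "_skip").
#' @return a new \code{TranscriptModel} with one exon fewer.
#' @export
skipExon <- function(t, exonIndex, suffix = "_skip") {
  nEx <- length(t@exons)
  if (exonIndex <= 1L || exonIndex >= nEx)
    stop("cannot skip a terminal exon (index ", exonIndex, " of ",
         nEx, ")")
  ex <- .txOrderedExons(t)
  if (!is.na(t@cdsStart) &&
      t@cdsStart >= start(ex)[exonIndex] &&
      t@cdsStart <= end(ex)[exonIndex])
    stop("exon ", exonIndex, " contains the start codon")
  keep <- ex[-exonIndex]
  keep <- keep[order(start(keep))]
  new("TranscriptModel",
      transcriptId = paste0(t@transcriptId, suffix), geneId = t@geneId,
      chrom = t@chrom, strand = t@strand, exons = keep,
      cdsStart = t@cdsStart)
}

#' Scan for the first in-frame stop codon
#'
#' First TAA/TAG/TGA at or after \code{start + 3} in the reading frame
#' anchored at \code{start} (the A of the initiator ATG, 1-based).
#'
#' @param mrna character scalar (spliced mRNA, sense strand).
#' @param start 1-based offset of the start codon; a non-ATG start
#'   triggers a warning, not an error.
#' @return 1-based position of the stop codon's first nucleotide, or
#'   \code{NA_integer_} when no in-frame stop exists.
#' @examples
#' scanORF("ATGTAA", 1)      # 4
#' scanORF("ATGAAATAG", 1)   # 7
#' @export
scanORF <- function(mrna, start) {
  start <- as.integer(start)
  n <- nchar(mrna)
  if (start < 1L || start + 2L > n) stop("start offset outside sequence")
  if (substr(mrna, start, start + 2L) != "ATG")
    warning("start offset is not an ATG; scanning anyway")
  from <- start + 3L
  if (from + 2L > n) return(NA_integer_)
  starts <- seq.int(from, n - 2L, by = 3L)
  cods <- substring(mrna, starts, starts + 2L)
  hit <- which(cods %in% c("TAA", "TAG", "TGA"))
  if (!length(hit)) return(NA_integer_)
  starts[hit[1L]]
}

#' Classify NMD sensitivity by the PTC junction rule
#'
#' Locates the first in-frame stop codon of the isoform's ORF and
#' measures d, the number of nucleotides between the stop codon's last
#' nucleotide and the final exon-exon junction in spliced (mRNA)
#' coordinates. The transcript is NMD+ when the stop lies upstream of
#' the final junction and d >= \code{threshold} (default 50 nt, the
#' lower bound of the canonical 50-55 nt rule); a stop in the last exon
#' or within the threshold of the final junction is NMD-; a missing
#' stop is flagged "no-stop". Single-exon transcripts are NMD-.
#'
#' @param t a \code{\link{transcriptModel}} with an annotated start
#'   codon (or \code{cdsStartTx} given).
#' @param genome named \code{DNAStringSet}.
#' @param threshold distance threshold in nt (> 0).
#' @param cdsStartTx optional 1-based mRNA offset of the start codon,
#'   overriding the genomic annotation.
#' @return data.frame (one row): isoform, stop_pos (mRNA, first nt),
#'   stop_exon, distance, nmd_flag.
#' @export
classifyNMD <- function(t, genome, threshold = 50L,
                        cdsStartTx = NULL) {
  stopifnot(threshold > 0L)
  mrna <- splicedSequence(t, genome)
  if (is.null(cdsStartTx)) {
    if (is.na(t@cdsStart)) stop("no start codon annotated")
    cdsStartTx <- genomeToTx(t, t@cdsStart)
  }
  stopPos <- scanORF(mrna, cdsStartTx)
  widths <- width(.txOrderedExons(t))
  cum <- cumsum(widths)
  finalJunction <- if (length(widths) > 1L)
    cum[length(widths) - 1L] else NA_integer_
  if (is.na(stopPos)) {
    return(data.frame(isoform = t@transcriptId, stop_pos = NA_integer_,
                      stop_exon = NA_integer_, distance = NA_integer_,
                      nmd_flag = "no-stop", stringsAsFactors = FALSE))
  }
  stopLast <- stopPos + 2L
  stopExon <- findInterval(stopPos - 1L, cum) + 1L
  d <- if (is.na(finalJunction)) NA_integer_ else finalJunction - stopLast
  flag <- if (!is.na(finalJunction) && stopLast <= finalJunction &&
              d >= threshold) "NMD+" else "NMD-"
  data.frame(isoform = t@transcriptId, stop_pos = stopPos,
             stop_exon = stopExon, distance = d, nmd_flag = flag,
             stringsAsFactors = FALSE)
}

#' Transcript models from an annotation GRanges
#'
#' @param annotation annotation \code{GRanges} with exon and (optional)
#'   start_codon features carrying \code{transcript_id}.
#' @return named list of \code{\link{transcriptModel}} objects.
#' @export
transcriptModels <- function(annotation) {
  exAll <- annotation[mcols(annotation)$type == "exon"]
  scAll <- annotation[mcols(annotation)$type == "start_codon"]
  ids <- unique(mcols(exAll)$transcript_id)
  out <- lapply(ids, function(tid) {
    ex <- exAll[mcols(exAll)$transcript_id == tid]
    sc <- scAll[mcols(scAll)$transcript_id == tid]
    strand <- as.character(strand(ex))[1L]
    cds <- if (length(sc) == 1L) {
      if (strand == "+") start(sc) else end(sc)
    } else NA_integer_
    transcriptModel(tid, as.character(seqnames(ex))[1L], strand,
                    start(ex), end(ex), cdsStart = cds,
                    geneId = mcols(ex)$gene_id[1L])
  })
  names(out) <- ids
  out
}

#' Percent spliced-in from transcript abundances
#'
#' PSI = 100 x (abundance of transcripts containing the cassette exon) /
#' (abundance of transcripts spanning the alternative region). A
#' transcript spans the region when it has at least one exon entirely
#' upstream and one entirely downstream of the cassette exon;
#' non-spanning transcripts are excluded from both sums. PSI is
#' undefined (NA, flagged) when the spanning abundance is zero.
#'
#' @param event length-1 \code{GRanges}: the cassette exon.
#' @param models list of \code{\link{transcriptModel}} objects for the
#'   locus.
#' @param abundance named numeric vector (one sample) or a matrix /
#'   data.frame of transcripts x samples; names/rownames must cover the
#'   models.
#' @return data.frame per sample: sample, psi, spanning_abundance,
#'   defined.
#' @export
psiFromTranscripts <- function(event, models, abundance) {
  stopifnot(is(event, "GRanges"), length(event) == 1L)
  if (is.vector(abundance))
    abundance <- matrix(abundance, ncol = 1L,
                        dimnames = list(names(abundance), "sample1"))
  abundance <- as.matrix(abundance)
  evS <- start(event); evE <- end(event)
  spans <- vapply(models, function(t) {
    ex <- t@exons
    any(end(ex) < evS) && any(start(ex) > evE)
  }, logical(1))
  contains <- vapply(models, function(t) {
    any(start(t@exons) == evS & end(t@exons) == evE)
  }, logical(1))
  if (!any(spans))
    stop("no transcript spans the alternative region")
  ids <- names(models)
  missing <- setdiff(ids[spans], rownames(abundance))
  if (length(missing))
    stop("abundance missing for: ", paste(missing, collapse = ", "))
  sp <- abundance[ids[spans], , drop = FALSE]
  inc <- abundance[ids[spans & contains], , drop = FALSE]
  spSum <- colSums(sp)
  incSum <- if (nrow(inc)) colSums(inc) else rep(0, ncol(sp))
  psi <- ifelse(spSum > 0, 100 * incSum / spSum, NA_real_)
  data.frame(sample = colnames(abundance), psi = psi,
             spanning_abundance = spSum, defined = spSum > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlation of percent-NMD+ with total expression
#'
#' Pearson product-moment correlation (two-sided) between the per-sample
#' percentage of NMD-sensitive transcript and total gene expression,
#' the readout used to link exon-skipping-induced NMD to steady-state
#' expression.
#'
#' @param pctNmd,expression paired numeric vectors (>= 3 samples).
#' @return data.frame: r, p_value, n, defined (FALSE when either vector
#'   has zero variance, with r = NA).
#' @export
nmdExpressionCorrelation <- function(pctNmd, expression) {
  stopifnot(length(pctNmd) == length(expression))
  if (length(pctNmd) < 3L) stop("need at least 3 paired samples")
  if (stats::sd(pctNmd) == 0 || stats::sd(expression) == 0)
    return(data.frame(r = NA_real_, p_value = NA_real_,
                      n = length(pctNmd), defined = FALSE))
  ct <- stats::cor.test(pctNmd, expression, method = "pearson")
  data.frame(r = unname(ct$estimate), p_value = ct$p.value,
             n = length(pctNmd), defined = TRUE)
}
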