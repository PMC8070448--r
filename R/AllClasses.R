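#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames strand start end width mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames
#'   rowData colData
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement letterFrequency subseq
#'   oligonucleotideFrequency consensusMatrix
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic RASL-style study: panel size, replicate
#' design, planted differential-inclusion effects, count noise, and the
#' sequence-architecture shifts planted between event classes.
#'
#' @slot nEvents number of alternative-splicing events in the panel.
#' @slot nReplicates biological replicates per condition.
#' @slot fracUp,fracDown fraction of events planted with increased /
#'   decreased inclusion in condition B.
#' @slot effectFold planted isoform-ratio fold change (>= 1; 1 disables
#'   planting).
#' @slot dispersion negative-binomial overdispersion (0 = Poisson).
#' @slot meanDepth expected reads for the skipping probe of each event.
#' @slot seed integer RNG seed; identical config => identical outputs.
#' @slot featureShifts named list of planted per-class architecture
#'   offsets: \code{donorMatch} (added consensus-match probability of the
#'   cassette donor site, up class), \code{exonLength} (nt added to the
#'   cassette-exon median length, up class), \code{upstreamIntron} (nt
#'   added to the upstream-intron median length, down class), \code{gc}
#'   (GC fraction subtracted for up / added for down on the cassette exon
#'   and flanking introns).
#' @slot exonLengthMedian,intronLengthMedian baseline median lengths (nt)
#'   of the log-normal exon/intron length distributions.
#' @slot gcContent baseline genomic GC fraction.
#' @slot donorMatch baseline per-position consensus-match probability of
#'   donor splice sites.
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nEvents = "integer",
    nReplicates = "integer",
    fracUp = "numeric",
    fracDown = "numeric",
    effectFold = "numeric",
    dispersion = "numeric",
    meanDepth = "numeric",
    seed = "integer",
    featureShifts = "list",
    exonLengthMedian = "numeric",
    intronLengthMedian = "numeric",
    gcContent = "numeric",
    donorMatch = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nEvents < 1L) msg <- c(msg, "nEvents must be >= 1")
  if (object@nReplicates < 2L) msg <- c(msg, "nReplicates must be >= 2")
  if (object@fracUp < 0 || object@fracDown < 0 ||
      object@fracUp + object@fracDown > 1)
    msg <- c(msg, "fracUp + fracDown must lie in [0, 1]")
  if (object@effectFold < 1) msg <- c(msg, "effectFold must be >= 1")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be > 0")
  if (object@gcContent <= 0 || object@gcContent >= 1)
    msg <- c(msg, "gcContent must lie in (0, 1)")
  if (object@donorMatch <= 0.25 || object@donorMatch > 1)
    msg <- c(msg, "donorMatch must lie in (0.25, 1]")
  fs <- object@featureShifts
  need <- c("donorMatch", "exonLength", "upstreamIntron", "gc")
  if (!all(need %in% names(fs)))
    msg <- c(msg, paste("featureShifts must contain:",
                        paste(need, collapse = ", ")))
  else {
    if (object@exonLengthMedian + min(0, fs$exonLength) <= 0)
      msg <- c(msg, "planted exon-length shift admits non-positive lengths")
    if (object@intronLengthMedian + min(0, fs$upstreamIntron) <= 0)
      msg <- c(msg, "planted intron-length shift admits non-positive lengths")
    if (object@gcContent - abs(fs$gc) <= 0 ||
        object@gcContent + abs(fs$gc) >= 1)
      msg <- c(msg, "planted GC shift leaves (0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulationConfig-class constructor with the study's default
#'   conditions: 5530-event panel, biological triplicates, 15\% up / 7.5\%
#'   down planted at fold 4, NB dispersion 0.05, depth 100.
#' @param nEvents,nReplicates,fracUp,fracDown,effectFold,dispersion,meanDepth,seed,featureShifts,exonLengthMedian,intronLengthMedian,gcContent,donorMatch see slots.
#' @return a \code{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nEvents = 20, seed = 7)
#' @export
simulationConfig <- function(nEvents = 5530L, nReplicates = 3L,
                             fracUp = 0.15, fracDown = 0.075,
                             effectFold = 4, dispersion = 0.05,
                             meanDepth = 100, seed = 1L,
                             featureShifts = list(donorMatch = 0.15,
                                                  exonLength = -30,
                                                  upstreamIntron = -90,
                                                  gc = 0.04),
                             exonLengthMedian = 120,
                             intronLengthMedian = 300,
                             gcContent = 0.5, donorMatch = 0.7) {
  new("SimulationConfig",
      nEvents = as.integer(nEvents), nReplicates = as.integer(nReplicates),
      fracUp = fracUp, fracDown = fracDown, effectFold = effectFold,
      dispersion = dispersion, meanDepth = meanDepth,
      seed = as.integer(seed), featureShifts = featureShifts,
      exonLengthMedian = exonLengthMedian,
      intronLengthMedian = intronLengthMedian,
      gcContent = gcContent, donorMatch = donorMatch)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nEvents, "events x",
      object@nReplicates, "replicates/condition\n")
  cat("  planted: up", object@fracUp, "/ down", object@fracDown,
      "at fold", object@effectFold, "\n")
  cat("  NB dispersion", object@dispersion, ", depth", object@meanDepth,
      ", seed", object@seed, "\n")
})

#' Probe panel of paired junction probes
#'
#' One row per alternative-splicing event; each event carries exactly one
#' inclusion-junction probe and one skipping-junction probe, plus the
#' genomic coordinates of its cassette exon.
#'
#' @slot events a \code{GRanges} of cassette exons with metadata columns
#'   \code{event_id}, \code{gene_id}, \code{event_type},
#'   \code{inclusion_probe}, \code{skipping_probe}.
#'
#' @exportClass ProbePanel
setClass("ProbePanel", representation(events = "GRanges"))

setValidity("ProbePanel", function(object) {
  m <- mcols(object@events)
  need <- c("event_id", "gene_id", "event_type",
            "inclusion_probe", "skipping_probe")
  if (!all(need %in% colnames(m)))
    return(paste("panel needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(m$event_id)) return("event_ids must be unique")
  ok <- m$event_type %in% c("SE", "A5SS", "A3SS", "MEE", "MES",
                            "AltS", "AltT", "IR")
  if (!all(ok)) return("unknown event_type")
  TRUE
})

setMethod("show", "ProbePanel", function(object) {
  tab <- table(mcols(object@events)$event_type)
  cat("ProbePanel with", length(object@events), "events (",
      paste(names(tab), tab, sep = ":", collapse = " "), ")\n")
})

setMethod("length", "ProbePanel", function(x) length(x@events))

#' @rdname ProbePanel-class
#' @param x a \code{ProbePanel}.
#' @return \code{eventIds}: character vector; \code{eventTypes}: character
#'   vector; \code{cassetteExons}: \code{GRanges}.
#' @export
eventIds <- function(x) mcols(x@events)$event_id

#' @rdname ProbePanel-class
#' @export
eventTypes <- function(x) mcols(x@events)$event_type

#' @rdname ProbePanel-class
#' @export
cassetteExons <- function(x) x@events

#' RASL junction-count container
#'
#' A \code{SummarizedExperiment} with two assays, \code{included} and
#' \code{skipped} (events x samples), and column metadata \code{condition}
#' and \code{replicate}.
#'
#' @exportClass RaslCounts
setClass("RaslCounts", contains = "SummarizedExperiment")

setValidity("RaslCounts", function(object) {
  if (!all(c("included", "skipped") %in% assayNames(object)))
    return("assays 'included' and 'skipped' are required")
  if (!all(c("condition", "replicate") %in% colnames(colData(object))))
    return("colData needs 'condition' and 'replicate'")
  inc <- assay(object, "included"); skp <- assay(object, "skipped")
  if (any(inc < 0, na.rm = TRUE) || any(skp < 0, na.rm = TRUE))
    return("counts must be non-negative")
  TRUE
})

#' Build a RaslCounts object
#'
#' @param included,skipped integer matrices (events x samples) of
#'   inclusion- and skipping-junction read counts, identical dimnames.
#' @param condition character/factor per sample (e.g. "A"/"B").
#' @param replicate replicate label per sample.
#' @param eventType optional per-event type annotation.
#' @return a \code{RaslCounts}.
#' @examples
#' inc <- matrix(10L, 2, 4, dimnames = list(c("e1", "e2"), NULL))
#' rc <- raslCounts(inc, inc, condition = rep(c("A", "B"), each = 2),
#'                  replicate = rep(1:2, 2))
#' @export
raslCounts <- function(included, skipped, condition, replicate,
                       eventType = NULL) {
  stopifnot(identical(dim(included), dim(skipped)))
  if (is.null(colnames(included)))
    colnames(included) <- colnames(skipped) <-
      paste0(condition, "_", replicate)
  rd <- if (is.null(eventType)) NULL else
    DataFrame(event_type = eventType, row.names = rownames(included))
  se <- SummarizedExperiment(
    assays = list(included = included, skipped = skipped),
    colData = DataFrame(condition = as.character(condition),
                        replicate = as.character(replicate),
                        row.names = colnames(included)),
    rowData = rd)
  new("RaslCounts", se)
}

#' @rdname raslCounts
#' @param x a \code{RaslCounts}.
#' @export
includedCounts <- function(x) assay(x, "included")

#' @rdname raslCounts
#' @export
skippedCounts <- function(x) assay(x, "skipped")

#' Position weight matrix splice-site scorer
#'
#' Per-position log2 odds of each nucleotide versus a background
#' distribution; scoring a window sums the per-position log-odds (bits).
#' The default scorer used in place of external maximum-entropy models;
#' externally computed score tables can be supplied wherever a score is
#' consumed.
#'
#' @slot logodds 4 x L matrix (rows A, C, G, T) of log2 odds.
#' @slot pseudocount additive pseudocount used in training.
#' @slot n number of training windows.
#' @slot siteKind "donor" or "acceptor".
#'
#' @exportClass PWMModel
setClass("PWMModel",
  representation(logodds = "matrix", pseudocount = "numeric",
                 n = "integer", siteKind = "character"))

setValidity("PWMModel", function(object) {
  if (!identical(rownames(object@logodds), c("A", "C", "G", "T")))
    return("logodds rows must be A, C, G, T")
  TRUE
})

setMethod("show", "PWMModel", function(object) {
  cat("PWMModel (", object@siteKind, "), width ",
      ncol(object@logodds), ", trained on ", object@n, " windows\n",
      sep = "")
})

#' Strand-aware transcript model
#'
#' Ordered exon structure of one transcript with its annotated start
#' codon, supporting exon deletion, spliced-sequence extraction and
#' mRNA/genome coordinate mapping.
#'
#' @slot transcriptId,geneId identifiers.
#' @slot chrom chromosome name.
#' @slot strand "+" or "-".
#' @slot exons \code{IRanges} of exons in genomic coordinates, ascending,
#'   non-overlapping.
#' @slot cdsStart genomic coordinate (1-based) of the first base of the
#'   start codon (the transcript-5'-most base, i.e. the largest coordinate
#'   of the codon on the minus strand is not stored; mapping is
#'   strand-aware).
#'
#' @exportClass TranscriptModel
setClass("TranscriptModel",
  representation(transcriptId = "character", geneId = "character",
                 chrom = "character", strand = "character",
                 exons = "IRanges", cdsStart = "integer"))

setValidity("TranscriptModel", function(object) {
  ex <- object@exons
  if (length(ex) < 1L) return("at least one exon required")
  if (is.unsorted(start(ex)) ||
      any(start(ex)[-1] <= end(ex)[-length(ex)]))
    return("exons must be ascending and non-overlapping")
  if (!object@strand %in% c("+", "-")) return("strand must be + or -")
  if (!is.na(object@cdsStart) &&
      !any(object@cdsStart >= start(ex) & object@cdsStart <= end(ex)))
    return("start codon must lie inside an exon")
  TRUE
})

#' @describeIn TranscriptModel-class constructor.
#' @param transcriptId,geneId,chrom,strand,cdsStart see slots.
#' @param exonStarts,exonEnds genomic exon boundaries (1-based inclusive).
#' @return a \code{TranscriptModel}.
#' @export
transcriptModel <- function(transcriptId, chrom, strand, exonStarts,
                            exonEnds, cdsStart = NA_integer_,
                            geneId = transcriptId) {
  o <- order(exonStarts)
  new("TranscriptModel", transcriptId = transcriptId, geneId = geneId,
      chrom = chrom, strand = strand,
      exons = IRanges(start = exonStarts[o], end = exonEnds[o]),
      cdsStart = as.integer(cdsStart))
}

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel ", object@transcriptId, " (", object@chrom,
      object@strand, "), ", length(object@exons), " exons, spliced length ",
      sum(width(object@exons)), " nt\n", sep = " ")
})

#' @rdname TranscriptModel-class
#' @param x a \code{TranscriptModel}.
#' @export
exonCount <- function(x) length(x@exons)

#' @rdname TranscriptModel-class
#' @export
splicedLength <- function(x) sum(width(x@exons))
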