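## Synthetic genomes, annotations, probe panels and replicate count
## tables with planted ground truth. Geometry is cassette-exon shaped:
## every simulated gene carries five exons (C1 and C2 constitutive
## flanks around one alternative exon, plus terminal exons), a
## translation start in exon 1 and a planted stop codon in the last
## exon so that the full-length isoform keeps an open reading frame.

DONOR_CONSENSUS <- c("C", "A", "G", "G", "T", "A", "A", "G", "T")

# sample a 9-nt donor window (3 exonic + 6 intronic) where each position
# matches the consensus with probability `match`
.donorSite <- function(match) {
  hit <- runif(9L) < match
  out <- DONOR_CONSENSUS
  miss <- which(!hit)
  for (i in miss) out[i] <- sample(setdiff(BASES, DONOR_CONSENSUS[i]), 1L)
  out
}

# 23-nt acceptor window: 17 pyrimidine-biased nt + "CAG" (intronic 20)
# followed by 3 exonic nt with a G-start consensus
.acceptorSite <- function(gc = 0.5) {
  py <- sample(BASES, 17L, replace = TRUE, prob = c(0.08, 0.32, 0.08, 0.52))
  tail3 <- c(if (runif(1) < 0.75) "C" else sample(BASES, 1L), "A", "G")
  ex <- c(if (runif(1) < 0.6) "G" else sample(BASES, 1L),
          sample(BASES, 2L, replace = TRUE, prob = .gcProbs(gc)))
  c(py, tail3, ex)
}

.rlen <- function(n, median, sdlog, min) {
  pmax(min, as.integer(round(stats::rlnorm(n, log(median), sdlog))))
}

# build one gene in sense orientation; returns list(seq, exons (sense
# IRanges-like matrix), cdsStartSense)
.buildGene <- function(cfg, class) {
  fs <- cfg@featureShifts
  exonMed <- rep(cfg@exonLengthMedian, 5L)
  intronMed <- rep(cfg@intronLengthMedian, 4L)
  gcExon <- rep(cfg@gcContent, 5L)
  gcIntron <- rep(cfg@gcContent, 4L)
  donorMatch <- rep(cfg@donorMatch, 4L)
  if (class == "up") {
    exonMed[3L] <- exonMed[3L] + fs$exonLength
    gcExon[3L] <- gcExon[3L] - fs$gc
    gcIntron[2:3] <- gcIntron[2:3] - fs$gc
    donorMatch[3L] <- min(0.99, donorMatch[3L] + fs$donorMatch)
  } else if (class == "down") {
    intronMed[2L] <- intronMed[2L] + fs$upstreamIntron
    gcExon[3L] <- gcExon[3L] + fs$gc
    gcIntron[2:3] <- gcIntron[2:3] + fs$gc
  }
  exLen <- integer(5L)
  for (j in 1:5) exLen[j] <- .rlen(1L, exonMed[j], 0.25, 30L)
  inLen <- integer(4L)
  for (j in 1:4) inLen[j] <- .rlen(1L, intronMed[j], 0.4, 60L)

  ex <- character(5L)
  for (j in 1:5) ex[j] <- .randSeq(exLen[j], gcExon[j])
  intr <- character(4L)
  for (j in 1:4) intr[j] <- .randSeq(inLen[j], gcIntron[j])

  # overwrite splice-site windows at each exon/intron boundary
  for (j in 1:4) {
    d <- .donorSite(donorMatch[j])
    substr(ex[j], exLen[j] - 2L, exLen[j]) <- paste(d[1:3], collapse = "")
    substr(intr[j], 1L, 6L) <- paste(d[4:9], collapse = "")
    a <- .acceptorSite(gcExon[j + 1L])
    substr(intr[j], inLen[j] - 19L, inLen[j]) <-
      paste(a[1:20], collapse = "")
    substr(ex[j + 1L], 1L, 3L) <- paste(a[21:23], collapse = "")
  }

  # translation start at transcript position 7 (6-nt 5' UTR)
  substr(ex[1L], 7L, 9L) <- "ATG"

  # keep the full-length reading frame open: scrub in-frame stops from
  # the spliced transcript, then plant one stop early in the last exon
  tx <- paste(ex, collapse = "")
  total <- nchar(tx)
  starts <- seq.int(7L, total - 2L, by = 3L)
  cods <- substring(tx, starts, starts + 2L)
  isStop <- cods %in% c("TAA", "TAG", "TGA")
  for (p in starts[isStop]) {
    third <- substr(tx, p + 2L, p + 2L)
    substr(tx, p + 2L, p + 2L) <- if (third == "A") "T" else "C"
  }
  lastOff <- sum(exLen[1:4])               # nt before the last exon
  pStop <- starts[starts >= lastOff + 4L][1L]
  if (is.na(pStop)) pStop <- starts[length(starts)]
  substr(tx, pStop, pStop + 2L) <- "TAA"

  cum <- c(0L, cumsum(exLen))
  for (j in 1:5) ex[j] <- substr(tx, cum[j] + 1L, cum[j + 1L])

  # sense coordinates of exons within the gene
  gLen <- sum(exLen) + sum(inLen)
  exStart <- integer(5L); exEnd <- integer(5L)
  pos <- 1L
  for (j in 1:5) {
    exStart[j] <- pos
    exEnd[j] <- pos + exLen[j] - 1L
    pos <- exEnd[j] + 1L
    if (j < 5L) pos <- pos + inLen[j]
  }
  list(seq = paste0(paste0(ex[1L], intr[1L], ex[2L], intr[2L], ex[3L],
                           intr[3L], ex[4L], intr[4L], ex[5L])),
       exStart = exStart, exEnd = exEnd, len = gLen,
       cdsStartSense = exStart[1L] + 6L)
}

# assemble genes into one chromosome + annotation GRanges
.buildGenome <- function(cfg, classes) {
  n <- cfg@nEvents
  spacer <- 100L
  seqs <- character(n)
  rows <- vector("list", n)
  offset <- spacer
  pieces <- character(2L * n + 1L)
  pieces[1L] <- .randSeq(spacer, cfg@gcContent)
  for (i in seq_len(n)) {
    g <- .buildGene(cfg, classes[i])
    strand <- if (runif(1) < 0.5) "+" else "-"
    gseq <- if (strand == "+") g$seq else .revcompChr(g$seq)
    gid <- sprintf("GENE%05d", i)
    tid <- sprintf("TX%05d", i)
    if (strand == "+") {
      s <- offset + g$exStart; e <- offset + g$exEnd
      cds <- offset + g$cdsStartSense
    } else {
      s <- offset + g$len - g$exEnd + 1L
      e <- offset + g$len - g$exStart + 1L
      cds <- offset + g$len - g$cdsStartSense + 1L
    }
    exNum <- 1:5  # transcript (5'->3') order on both strands
    rows[[i]] <- data.frame(
      start = c(offset + 1L, offset + 1L, s, cds - if (strand == "+") 0L else 2L),
      end = c(offset + g$len, offset + g$len, e,
              cds + if (strand == "+") 2L else 0L),
      type = c("gene", "transcript", rep("exon", 5L), "start_codon"),
      strand = strand, gene_id = gid, transcript_id = tid,
      exon_number = c(NA, NA, exNum, NA),
      cassette = c(FALSE, FALSE, exNum == 3L, FALSE))
    pieces[2L * i] <- gseq
    pieces[2L * i + 1L] <- .randSeq(spacer, cfg@gcContent)
    offset <- offset + g$len + spacer
  }
  chrom <- DNAStringSet(paste(pieces, collapse = ""))
  names(chrom) <- "chr1"
  ann <- do.call(rbind, rows)
  gr <- GRanges("chr1", IRanges(ann$start, ann$end), strand = ann$strand,
                type = ann$type, gene_id = ann$gene_id,
                transcript_id = ann$transcript_id,
                exon_number = ann$exon_number, cassette = ann$cassette)
  list(genome = chrom, annotation = gr)
}

#' Generate a synthetic genome and annotation
#'
#' Builds multi-exon gene models (five exons: two terminal, two
#' constitutive flanks C1/C2 and one internal cassette exon) with
#' consensus-bearing splice sites, a start codon in exon 1, an open
#' reading frame through the full-length isoform and a stop codon in
#' the last exon. Deterministic given \code{cfg@seed}.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @return list with \code{genome} (\code{DNAStringSet}) and
#'   \code{annotation} (\code{GRanges} of gene/transcript/exon/start_codon
#'   features; cassette exons flagged in \code{mcols()$cassette}).
#' @examples
#' gs <- generateGenome(simulationConfig(nEvents = 3, seed = 1))
#' @export
generateGenome <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  set.seed(cfg@seed)
  .buildGenome(cfg, rep("null", cfg@nEvents))
}

#' Regenerate event loci with planted architecture differences
#'
#' Rebuilds the genome so that event classes differ in the directions
#' the comparative analysis is designed to detect: up-class events get a
#' stronger cassette donor site, shorter cassette exons and lower flank
#' GC; down-class events get shorter upstream introns and higher flank
#' GC; the offsets come from \code{cfg@featureShifts}.
#'
#' @param truth truth table (data.frame with \code{event_id},
#'   \code{true_class}) as returned by \code{\link{simulateCounts}}; row
#'   order matches gene order.
#' @param cfg a \code{\link{simulationConfig}}.
#' @return as \code{\link{generateGenome}}.
#' @export
plantSequenceFeatures <- function(truth, cfg) {
  stopifnot(is(cfg, "SimulationConfig"),
            nrow(truth) == cfg@nEvents,
            all(truth$true_class %in% c("up", "down", "null")))
  set.seed(cfg@seed)
  .buildGenome(cfg, truth$true_class)
}

#' Design a paired-probe panel over annotated cassette exons
#'
#' Each event receives one inclusion-junction probe and one
#' skipping-junction probe. Event types are assigned 90\% SE with the
#' remainder spread over the other categories, matching the
#' skipped-exon dominance of RASL panels.
#'
#' @param annotation annotation \code{GRanges} (as from
#'   \code{\link{generateGenome}} or \code{\link{readAnnotationGTF}}).
#'   Cassette candidates are exons flagged \code{cassette}, or all
#'   internal exons when no flag is present.
#' @param cfg a \code{\link{simulationConfig}}; \code{cfg@nEvents} events
#'   are drawn (default 5530).
#' @return a \code{\link{ProbePanel-class}}.
#' @export
generatePanel <- function(annotation, cfg = simulationConfig()) {
  ex <- annotation[mcols(annotation)$type == "exon"]
  if ("cassette" %in% colnames(mcols(ex)) &&
      any(mcols(ex)$cassette %in% TRUE)) {
    cand <- ex[mcols(ex)$cassette %in% TRUE]
  } else {
    sp <- split(ex, mcols(ex)$transcript_id)
    cand <- unlist(GenomicRanges::GRangesList(lapply(sp, function(g) {
      n <- mcols(g)$exon_number
      g[n > min(n) & n < max(n)]
    })), use.names = FALSE)
  }
  n <- cfg@nEvents
  if (length(cand) < n)
    stop("annotation provides ", length(cand),
         " candidate cassette exons; ", n, " requested")
  cand <- cand[seq_len(n)]
  set.seed(cfg@seed + 11L)
  types <- c("A5SS", "A3SS", "MEE", "MES", "AltS", "AltT", "IR")
  etype <- sample(c(rep("SE", ceiling(0.9 * n)),
                    sample(types, n - ceiling(0.9 * n), replace = TRUE)))
  ids <- sprintf("EVT%05d", seq_len(n))
  mcols(cand) <- DataFrame(
    event_id = ids, gene_id = mcols(cand)$gene_id, event_type = etype,
    inclusion_probe = paste0(ids, "_inc"),
    skipping_probe = paste0(ids, "_skp"))
  new("ProbePanel", events = cand)
}

#' Coordinate-only probe panel
#'
#' A \code{\link{ProbePanel-class}} with placeholder coordinates, for
#' count-level simulation studies where no genome sequence is needed
#' (counts depend only on the panel's event list). Same event-id and
#' event-type layout as \code{\link{generatePanel}}.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @return a \code{ProbePanel}.
#' @export
panelSkeleton <- function(cfg) {
  n <- cfg@nEvents
  set.seed(cfg@seed + 11L)
  types <- c("A5SS", "A3SS", "MEE", "MES", "AltS", "AltT", "IR")
  etype <- sample(c(rep("SE", ceiling(0.9 * n)),
                    sample(types, n - ceiling(0.9 * n), replace = TRUE)))
  ids <- sprintf("EVT%05d", seq_len(n))
  gr <- GRanges("chr1", IRanges(seq_len(n) * 1000L, width = 100L),
                strand = "+",
                event_id = ids, gene_id = sprintf("GENE%05d", seq_len(n)),
                event_type = etype,
                inclusion_probe = paste0(ids, "_inc"),
                skipping_probe = paste0(ids, "_skp"))
  new("ProbePanel", events = gr)
}

#' Simulate replicate junction counts with planted ratio changes
#'
#' Draws negative-binomial counts per probe per sample. The skipping
#' probe's expected count is \code{meanDepth} in both conditions; the
#' inclusion probe's mean is \code{meanDepth * rho} in condition A, with
#' \code{rho} a per-event baseline inclusion/skipping ratio (log-normal,
#' unit mean). For planted-up events the condition-B inclusion mean is
#' multiplied by \code{effectFold}; for planted-down events divided by
#' it; null events share means across conditions.
#'
#' @param panel a \code{\link{ProbePanel-class}}.
#' @param cfg a \code{\link{simulationConfig}}.
#' @return list with \code{counts} (a \code{\link{raslCounts}} object)
#'   and \code{truth} (data.frame \code{event_id}, \code{true_class},
#'   \code{true_fold}).
#' @export
simulateCounts <- function(panel, cfg) {
  stopifnot(is(panel, "ProbePanel"), is(cfg, "SimulationConfig"))
  if (cfg@meanDepth <= 0) stop("meanDepth must be > 0")
  if (cfg@dispersion < 0) stop("dispersion must be >= 0")
  n <- length(panel)
  r <- cfg@nReplicates
  set.seed(cfg@seed + 101L)

  cls <- rep("null", n)
  if (cfg@effectFold > 1) {
    nUp <- round(cfg@fracUp * n)
    nDown <- round(cfg@fracDown * n)
    idx <- sample.int(n)
    cls[idx[seq_len(nUp)]] <- "up"
    if (nDown > 0) cls[idx[nUp + seq_len(nDown)]] <- "down"
  }
  fold <- ifelse(cls == "up", cfg@effectFold,
                 ifelse(cls == "down", 1 / cfg@effectFold, 1))

  sdlog <- 0.3
  rho <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  muSkp <- rep(cfg@meanDepth, n)
  muIncA <- cfg@meanDepth * rho
  muIncB <- muIncA * fold

  nSamp <- 2L * r
  cond <- rep(c("A", "B"), each = r)
  repl <- rep(seq_len(r), 2L)
  draw <- function(mu, cells) {
    mu <- rep(mu, times = cells)
    if (cfg@dispersion == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / cfg@dispersion)
  }
  inc <- matrix(0L, n, nSamp)
  skp <- matrix(0L, n, nSamp)
  for (j in seq_len(nSamp)) {
    muI <- if (cond[j] == "A") muIncA else muIncB
    inc[, j] <- as.integer(draw(muI, 1L))
    skp[, j] <- as.integer(draw(muSkp, 1L))
  }
  rownames(inc) <- rownames(skp) <- eventIds(panel)
  colnames(inc) <- colnames(skp) <- paste0(cond, repl)
  counts <- raslCounts(inc, skp, condition = cond, replicate = repl,
                       eventType = eventTypes(panel))
  truth <- data.frame(event_id = eventIds(panel), true_class = cls,
                      true_fold = fold, stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}
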