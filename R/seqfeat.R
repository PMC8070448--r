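## Splice-site windows, exon/intron architecture features, group
## comparisons and k-mer enrichment on flanking introns.

#' Extract donor and acceptor splice-site windows of an exon
#'
#' The donor (5' splice site) window is 9 nt: the last 3 exonic nt plus
#' the first 6 intronic nt downstream. The acceptor (3' splice site)
#' window is 23 nt: the last 20 intronic nt upstream plus the first 3
#' exonic nt. Both are reported in sense-strand (transcript)
#' orientation; minus-strand exons are reverse-complemented.
#'
#' @param genome a named \code{DNAStringSet}.
#' @param exon a length-1 \code{GRanges} (the exon, with strand), or a
#'   \code{GRanges} of several exons (vectorized).
#' @return data.frame with character columns \code{donor} (width 9) and
#'   \code{acceptor} (width 23), one row per exon.
#' @export
extractSpliceWindows <- function(genome, exon) {
  stopifnot(is(exon, "GRanges"))
  n <- length(exon)
  donor <- character(n); acceptor <- character(n)
  ch <- as.character(seqnames(exon))
  st <- start(exon); en <- end(exon)
  sd <- as.character(strand(exon))
  for (i in seq_len(n)) {
    if (sd[i] == "+") {
      donor[i] <- .extractRegion(genome, ch[i], en[i] - 2L, en[i] + 6L)
      acceptor[i] <- .extractRegion(genome, ch[i], st[i] - 20L, st[i] + 2L)
    } else {
      donor[i] <- .extractRegion(genome, ch[i], st[i] - 6L, st[i] + 2L, "-")
      acceptor[i] <- .extractRegion(genome, ch[i], en[i] - 2L, en[i] + 20L, "-")
    }
  }
  data.frame(donor = donor, acceptor = acceptor,
             stringsAsFactors = FALSE)
}

# one-time conversions that keep the per-event loops off GRanges
.exonTable <- function(annotation) {
  ex <- annotation[mcols(annotation)$type == "exon"]
  data.frame(chrom = as.character(seqnames(ex)), start = start(ex),
             end = end(ex), strand = as.character(strand(ex)),
             gene = as.character(mcols(ex)$gene_id),
             tx = as.character(mcols(ex)$transcript_id),
             n = as.integer(mcols(ex)$exon_number),
             stringsAsFactors = FALSE)
}

.seqCache <- function(genome) lapply(as.list(as.character(genome)), identity)

.substrBatch <- function(cache, chrom, start, end, strand) {
  out <- character(length(chrom))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    out[i] <- substring(cache[[ch]], start[i], end[i])
  }
  neg <- strand == "-"
  if (any(neg))
    out[neg] <- as.character(reverseComplement(DNAStringSet(out[neg])))
  out
}

# per-event context: cassette exon, constitutive neighbours, intron
# ranges (genomic) and median transcript length of the host gene
.eventContext <- function(panel, annotation) {
  ev <- cassetteExons(panel)
  et <- .exonTable(annotation)
  byGene <- split(et, et$gene)
  n <- length(ev)
  out <- data.frame(
    event_id = mcols(ev)$event_id, chrom = as.character(seqnames(ev)),
    strand = as.character(strand(ev)), evS = start(ev), evE = end(ev),
    c1S = NA_integer_, c1E = NA_integer_, c2S = NA_integer_,
    c2E = NA_integer_, upS = NA_integer_, upE = NA_integer_,
    dnS = NA_integer_, dnE = NA_integer_, medTx = NA_integer_,
    valid = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(mcols(ev)$gene_id)
  for (i in seq_len(n)) {
    g <- byGene[[genes[i]]]
    if (is.null(g)) next
    g <- g[order(g$n), ]
    hit <- which(g$start == out$evS[i] & g$end == out$evE[i])
    if (length(hit) != 1L || hit == 1L || hit == nrow(g)) next
    out$c1S[i] <- g$start[hit - 1L]; out$c1E[i] <- g$end[hit - 1L]
    out$c2S[i] <- g$start[hit + 1L]; out$c2E[i] <- g$end[hit + 1L]
    if (out$strand[i] == "+") {
      out$upS[i] <- out$c1E[i] + 1L; out$upE[i] <- out$evS[i] - 1L
      out$dnS[i] <- out$evE[i] + 1L; out$dnE[i] <- out$c2S[i] - 1L
    } else {
      out$upS[i] <- out$evE[i] + 1L; out$upE[i] <- out$c1S[i] - 1L
      out$dnS[i] <- out$c2E[i] + 1L; out$dnE[i] <- out$evS[i] - 1L
    }
    out$medTx[i] <- as.integer(stats::median(
      tapply(g$end - g$start + 1L, g$tx, sum)))
    out$valid[i] <- TRUE
  }
  out
}

#' Extract flanking intronic windows and exon body
#'
#' Returns the cassette-exon body plus up to \code{flankLen} nt of each
#' flanking intron (upstream = intron nt adjacent to the exon's
#' acceptor; downstream = adjacent to its donor), all in sense-strand
#' orientation. Windows never cross into the neighbouring exon: short
#' introns yield truncated windows with a flag.
#'
#' @param panel a \code{\link{ProbePanel-class}} (or \code{GRanges} of
#'   cassette exons with \code{gene_id} metadata).
#' @param annotation annotation \code{GRanges}.
#' @param genome named \code{DNAStringSet}.
#' @param flankLen flank width in nt (default 200).
#' @return data.frame: event_id, upstream, exon, downstream,
#'   upstream_truncated, downstream_truncated.
#' @export
extractFlanks <- function(panel, annotation, genome, flankLen = 200L) {
  ctx <- .eventContext(panel, annotation)
  cache <- .seqCache(genome)
  n <- nrow(ctx)
  out <- data.frame(event_id = ctx$event_id,
                    upstream = NA_character_, exon = NA_character_,
                    downstream = NA_character_,
                    upstream_truncated = NA, downstream_truncated = NA,
                    stringsAsFactors = FALSE)
  v <- ctx$valid
  upIntr <- ctx$upE - ctx$upS + 1L
  dnIntr <- ctx$dnE - ctx$dnS + 1L
  upLen <- pmin(flankLen, upIntr)
  dnLen <- pmin(flankLen, dnIntr)
  plus <- ctx$strand == "+"
  # flank windows hug the exon boundary on its transcript-upstream
  # (acceptor) and -downstream (donor) sides
  upS <- ifelse(plus, ctx$evS - upLen, ctx$evE + 1L)
  upE <- ifelse(plus, ctx$evS - 1L, ctx$evE + upLen)
  dnS <- ifelse(plus, ctx$evE + 1L, ctx$evS - dnLen)
  dnE <- ifelse(plus, ctx$evE + dnLen, ctx$evS - 1L)
  out$upstream[v] <- .substrBatch(cache, ctx$chrom[v], upS[v], upE[v],
                                  ctx$strand[v])
  out$downstream[v] <- .substrBatch(cache, ctx$chrom[v], dnS[v], dnE[v],
                                    ctx$strand[v])
  out$exon[v] <- .substrBatch(cache, ctx$chrom[v], ctx$evS[v],
                              ctx$evE[v], ctx$strand[v])
  out$upstream_truncated[v] <- upLen[v] < flankLen
  out$downstream_truncated[v] <- dnLen[v] < flankLen
  out
}

#' Compute architecture features of cassette exons
#'
#' Per event: cassette exon length, upstream/downstream intron lengths,
#' GC of the exon body and of each (possibly truncated) 200-nt flank,
#' median transcript length of the host gene, and PWM scores of the four
#' per-event splice sites: C1 donor, cassette (Alt) acceptor, cassette
#' donor, C2 acceptor. Events whose cassette exon is terminal (no C1 or
#' C2) are skipped with a warning.
#'
#' @param panel a \code{\link{ProbePanel-class}}.
#' @param annotation annotation \code{GRanges}.
#' @param genome named \code{DNAStringSet}.
#' @param calls optional data.frame from \code{\link{callDifferential}};
#'   merges a \code{class} column by event id.
#' @param donorPWM,acceptorPWM \code{\link{PWMModel-class}} scorers; when
#'   NULL they are trained on the panel's own donor/acceptor window
#'   populations.
#' @param flankLen flank width for GC (default 200).
#' @return data.frame of per-event features (one row per usable event).
#' @export
computeArchitecture <- function(panel, annotation, genome, calls = NULL,
                                donorPWM = NULL, acceptorPWM = NULL,
                                flankLen = 200L) {
  ctx <- .eventContext(panel, annotation)
  if (any(!ctx$valid))
    warning(sum(!ctx$valid), " event(s) with terminal or unmatched ",
            "cassette exons skipped")
  cache <- .seqCache(genome)
  idx <- which(ctx$valid)
  ct <- ctx[idx, , drop = FALSE]
  plus <- ct$strand == "+"
  # donor window: last 3 exonic + first 6 intronic nt (sense);
  # acceptor window: last 20 intronic + first 3 exonic nt (sense)
  winDonor <- function(s, e)  # exon boundaries -> window coords
    list(st = ifelse(plus, e - 2L, s - 6L),
         en = ifelse(plus, e + 6L, s + 2L))
  winAcc <- function(s, e)
    list(st = ifelse(plus, s - 20L, e - 2L),
         en = ifelse(plus, s + 2L, e + 20L))
  grab <- function(w) .substrBatch(cache, ct$chrom, w$st, w$en, ct$strand)
  c1d <- grab(winDonor(ct$c1S, ct$c1E))
  ad <- grab(winDonor(ct$evS, ct$evE))
  aa <- grab(winAcc(ct$evS, ct$evE))
  c2a <- grab(winAcc(ct$c2S, ct$c2E))
  fl <- extractFlanks(panel, annotation, genome, flankLen = flankLen)
  fl <- fl[idx, , drop = FALSE]
  if (is.null(donorPWM))
    donorPWM <- trainPWM(c(c1d, ad), siteKind = "donor")
  if (is.null(acceptorPWM))
    acceptorPWM <- trainPWM(c(aa, c2a), siteKind = "acceptor")
  out <- data.frame(
    event_id = ct$event_id,
    exon_length = ct$evE - ct$evS + 1L,
    upstream_intron_length = ct$upE - ct$upS + 1L,
    downstream_intron_length = ct$dnE - ct$dnS + 1L,
    exon_gc = gcFraction(fl$exon),
    upstream_gc = gcFraction(fl$upstream),
    downstream_gc = gcFraction(fl$downstream),
    median_tx_length = ct$medTx,
    c1_donor_score = scoreWindow(donorPWM, c1d),
    alt_acceptor_score = scoreWindow(acceptorPWM, aa),
    alt_donor_score = scoreWindow(donorPWM, ad),
    c2_acceptor_score = scoreWindow(acceptorPWM, c2a),
    stringsAsFactors = FALSE)
  if (!is.null(calls))
    out$class <- calls$class[match(out$event_id, calls$event_id)]
  out
}

#' Compare architecture features between event classes
#'
#' Splice-site strength (PWM scores) is compared by two-sided t-tests
#' for each pair of classes, plus an ordinary one-way ANOVA across all
#' classes when more than two are present. Lengths, GC and median
#' transcript length are compared by the two-sided Mann-Whitney U test.
#' Direction is the sign of (group1 central value - group2 central
#' value): means for t-tests, medians for rank tests.
#'
#' @param features data.frame from \code{\link{computeArchitecture}}
#'   with a \code{class} column (levels among up/down/ndiff).
#' @param scoreFeatures,rankFeatures feature columns routed to t-tests
#'   and Mann-Whitney tests respectively.
#' @return data.frame: feature, group1, group2, test, statistic,
#'   p_value, direction.
#' @export
compareGroups <- function(features,
                          scoreFeatures = c("c1_donor_score",
                                            "alt_acceptor_score",
                                            "alt_donor_score",
                                            "c2_acceptor_score"),
                          rankFeatures = c("exon_length",
                                           "upstream_intron_length",
                                           "downstream_intron_length",
                                           "exon_gc", "upstream_gc",
                                           "downstream_gc",
                                           "median_tx_length")) {
  stopifnot("class" %in% colnames(features))
  groups <- intersect(c("up", "down", "ndiff"),
                      unique(features$class))
  if (length(groups) < 2L) stop("need at least two classes to compare")
  sizes <- table(features$class)[groups]
  if (any(sizes < 3L))
    stop("every class needs >= 3 records (",
         paste(groups, sizes, sep = ":", collapse = ", "), ")")
  scoreFeatures <- intersect(scoreFeatures, colnames(features))
  rankFeatures <- intersect(rankFeatures, colnames(features))
  rows <- list()
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  for (f in c(scoreFeatures, rankFeatures)) {
    isScore <- f %in% scoreFeatures
    for (pr in pairs) {
      x1 <- features[[f]][features$class == pr[1L]]
      x2 <- features[[f]][features$class == pr[2L]]
      if (isScore) {
        tt <- stats::t.test(x1, x2)
        rows[[length(rows) + 1L]] <- data.frame(
          feature = f, group1 = pr[1L], group2 = pr[2L],
          test = "t", statistic = unname(tt$statistic),
          p_value = tt$p.value,
          direction = sign(mean(x1) - mean(x2)))
      } else {
        wt <- stats::wilcox.test(x1, x2, exact = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          feature = f, group1 = pr[1L], group2 = pr[2L],
          test = "mann_whitney", statistic = unname(wt$statistic),
          p_value = wt$p.value,
          direction = sign(stats::median(x1) - stats::median(x2)))
      }
    }
    if (isScore && length(groups) > 2L) {
      sub <- features[features$class %in% groups, ]
      fit <- stats::aov(sub[[f]] ~ factor(sub$class))
      sm <- summary(fit)[[1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, group1 = "all", group2 = "all",
        test = "anova", statistic = sm[["F value"]][1L],
        p_value = sm[["Pr(>F)"]][1L], direction = 0)
    }
  }
  do.call(rbind, rows)
}

#' k-mer enrichment between region sets
#'
#' For each k in \code{k}, counts how many target vs background
#' sequences contain each k-mer and tests enrichment with a one-sided
#' Fisher exact (hypergeometric) test, Benjamini-Hochberg corrected
#' across all tested k-mers. Only k-mers present in at least one
#' sequence are tested. Reported in the RNA alphabet (T -> U). A
#' documented exact-k-mer stand-in for degenerate-motif discovery.
#'
#' @param targets,background character vectors or \code{DNAStringSet}s.
#' @param k integer vector of k-mer sizes (default 4:8); values longer
#'   than the shortest sequence are skipped with a warning.
#' @param alpha reporting threshold on adjusted p (rows above it are
#'   kept in the table but flagged).
#' @return data.frame sorted by adjusted p: kmer (RNA), k, n_target,
#'   n_background, target_total, background_total, p_value, p_adj,
#'   significant.
#' @export
kmerEnrichment <- function(targets, background, k = 4:8, alpha = 0.05) {
  if (is.character(targets)) targets <- DNAStringSet(targets)
  if (is.character(background)) background <- DNAStringSet(background)
  if (length(targets) < 1L || length(background) < 1L)
    stop("both region sets must be non-empty")
  minLen <- min(min(width(targets)), min(width(background)))
  rows <- list()
  for (kk in sort(unique(as.integer(k)))) {
    if (kk > minLen) {
      warning("k = ", kk, " exceeds the shortest sequence (", minLen,
              " nt); skipped")
      next
    }
    ft <- oligonucleotideFrequency(targets, width = kk) > 0L
    fb <- oligonucleotideFrequency(background, width = kk) > 0L
    nt <- colSums(ft); nb <- colSums(fb)
    seen <- nt + nb > 0L
    nt <- nt[seen]; nb <- nb[seen]
    Nt <- length(targets); Nb <- length(background)
    # one-sided Fisher exact p via the hypergeometric tail
    p <- stats::phyper(nt - 1L, nt + nb, Nt + Nb - nt - nb, Nt,
                       lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      kmer = chartr("T", "U", names(nt)), k = kk,
      n_target = as.integer(nt), n_background = as.integer(nb),
      target_total = Nt, background_total = Nb, p_value = p,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (!length(rows)) stop("no k-mer size was applicable")
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adj < alpha
  out[order(out$p_adj, out$p_value, -out$n_target), , drop = FALSE]
}
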