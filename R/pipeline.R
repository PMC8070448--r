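#' Run the full synthetic analysis pipeline
#'
#' Simulates a study (genome + annotation with planted architecture
#' shifts, probe panel, replicate counts), then runs detection
#' filtering, differential calls and tallies, architecture features and
#' group comparisons, flank k-mer enrichment, and NMD classification of
#' every event's exon-skipped isoform. All outputs are written as
#' plain-text files under \code{outdir} together with a run manifest
#' (parameters, per-stage record counts, output checksums).
#' Deterministic given \code{cfg@seed}.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @param outdir output directory (created if missing).
#' @param minCount,ratioThreshold,alpha quantification parameters.
#' @param flankLen,kRange sequence-feature parameters.
#' @param nmdThreshold PTC-to-junction distance threshold (nt).
#' @return the manifest, invisibly (list).
#' @export
runPipeline <- function(cfg = simulationConfig(nEvents = 300),
                        outdir = tempfile("raslsplice_run"),
                        minCount = 5L, ratioThreshold = 2, alpha = 0.05,
                        flankLen = 200L, kRange = 4:6,
                        nmdThreshold = 50L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(outdir, f)
  stage <- function(name, expr) {
    message(format(Sys.time(), "%H:%M:%S"), " [", name, "] seed=",
            cfg@seed)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- simulate ---------------------------------------------------
  sim <- stage("simulate", {
    gs0 <- generateGenome(cfg)
    panel <- generatePanel(gs0$annotation, cfg)
    ct <- simulateCounts(panel, cfg)
    gs <- plantSequenceFeatures(ct$truth, cfg)
    panel <- generatePanel(gs$annotation, cfg)
    writeGenomeFasta(gs$genome, path("genome.fa"))
    writeAnnotationGTF(gs$annotation, path("annotation.gtf"))
    writeCountTable(ct$counts, path("counts.tsv"))
    utils::write.table(ct$truth, path("truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writePanelBED(panel, path("panel.bed"))
    list(genome = gs$genome, annotation = gs$annotation, panel = panel,
         counts = ct$counts, truth = ct$truth)
  })

  # --- quant ------------------------------------------------------
  calls <- stage("quant", {
    det <- detectEvents(sim$counts, minCount = minCount)
    calls <- callDifferential(det, ratioThreshold = ratioThreshold,
                              alpha = alpha)
    utils::write.table(calls, path("calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sm <- summarizeCalls(calls)
    utils::write.table(as.data.frame(sm$table), path("summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    calls
  })

  # --- seqfeat ----------------------------------------------------
  comparisons <- stage("seqfeat", {
    feats <- computeArchitecture(sim$panel, sim$annotation, sim$genome,
                                 calls = calls, flankLen = flankLen)
    utils::write.table(feats, path("features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cmp <- NULL
    if (sum(table(feats$class) >= 3L) >= 2L) {
      cmp <- compareGroups(feats)
      utils::write.table(cmp, path("comparisons.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    fl <- extractFlanks(sim$panel, sim$annotation, sim$genome,
                        flankLen = flankLen)
    upCls <- calls$class[match(fl$event_id, calls$event_id)]
    if (sum(upCls == "up", na.rm = TRUE) >= 5L &&
        sum(upCls == "ndiff", na.rm = TRUE) >= 5L) {
      km <- kmerEnrichment(fl$upstream[upCls %in% "up"],
                           fl$upstream[upCls %in% "ndiff"], k = kRange)
      utils::write.table(utils::head(km, 100L), path("kmers.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    cmp
  })

  # --- nmd --------------------------------------------------------
  nmdTab <- stage("nmd", {
    models <- transcriptModels(sim$annotation)
    ev <- cassetteExons(sim$panel)
    rows <- lapply(seq_along(ev), function(i) {
      tid <- paste0("TX", sub("^GENE", "", mcols(ev)$gene_id[i]))
      t <- models[[tid]]
      if (is.null(t)) return(NULL)
      exIdx <- which(start(.txOrderedExons(t)) == start(ev[i]) &
                     end(.txOrderedExons(t)) == end(ev[i]))
      if (length(exIdx) != 1L || exIdx == 1L ||
          exIdx == length(t@exons)) return(NULL)
      incl <- classifyNMD(t, sim$genome, threshold = nmdThreshold)
      skp <- classifyNMD(skipExon(t, exIdx), sim$genome,
                         threshold = nmdThreshold)
      cbind(event_id = mcols(ev)$event_id[i], rbind(incl, skp))
    })
    tab <- do.call(rbind, rows)
    utils::write.table(tab, path("nmd.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    tab
  })

  # --- manifest ---------------------------------------------------
  outs <- list.files(outdir, full.names = TRUE)
  manifest <- list(
    tool = paste0("raslsplice ",
                  as.character(utils::packageVersion("raslsplice"))),
    seed = cfg@seed,
    parameters = list(nEvents = cfg@nEvents,
                      nReplicates = cfg@nReplicates,
                      minCount = minCount,
                      ratioThreshold = ratioThreshold, alpha = alpha,
                      flankLen = flankLen, kRange = range(kRange),
                      nmdThreshold = nmdThreshold),
    records = list(events = length(sim$panel),
                   calls = nrow(calls),
                   comparisons = if (is.null(comparisons)) 0L
                                 else nrow(comparisons),
                   nmd_isoforms = if (is.null(nmdTab)) 0L
                                  else nrow(nmdTab)),
    checksums = as.list(stats::setNames(tools::md5sum(outs),
                                        basename(outs))))
  mf <- vapply(manifest$checksums, identity, character(1))
  writeLines(c(paste0("tool\t", manifest$tool),
               paste0("seed\t", manifest$seed),
               paste0(names(mf), "\t", mf)),
             path("manifest.tsv"))
  invisible(manifest)
}
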