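## Readers and writers for the plain-text formats the pipeline touches.
## Genomic intervals follow GRanges conventions (1-based inclusive)
## in memory; GTF is read/written through rtracklayer and BED6 export
## converts at the boundary.

#' Read / write a genome FASTA
#'
#' Sequences are uppercased on read; duplicate headers are an error.
#'
#' @param path file path.
#' @return \code{readGenomeFasta}: a named \code{DNAStringSet}.
#' @export
readGenomeFasta <- function(path) {
  x <- readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate FASTA headers: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  Biostrings::DNAStringSet(toupper(x))
}

#' @rdname readGenomeFasta
#' @param genome named \code{DNAStringSet}.
#' @export
writeGenomeFasta <- function(genome, path) {
  writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read / write annotation GTF
#'
#' Thin wrappers over \code{rtracklayer}; coordinates arrive 1-based
#' inclusive as per the format and are kept in that convention in the
#' returned \code{GRanges}. Exons lying outside their transcript's span
#' are rejected.
#'
#' @param path file path.
#' @return \code{readAnnotationGTF}: annotation \code{GRanges}.
#' @export
readAnnotationGTF <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  tx <- gr[gr$type == "transcript"]
  if (length(tx)) {
    m <- match(ex$transcript_id, tx$transcript_id)
    bad <- which(!is.na(m) &
                 (start(ex) < start(tx)[m] | end(ex) > end(tx)[m]))
    if (length(bad))
      stop("exon outside its transcript span (transcript ",
           ex$transcript_id[bad[1L]], ")")
  }
  if ("exon_number" %in% colnames(mcols(gr)))
    mcols(gr)$exon_number <- as.integer(mcols(gr)$exon_number)
  if ("cassette" %in% colnames(mcols(gr)))
    mcols(gr)$cassette <- as.logical(mcols(gr)$cassette)
  gr
}

#' @rdname readAnnotationGTF
#' @param annotation annotation \code{GRanges}.
#' @export
writeAnnotationGTF <- function(annotation, path) {
  rtracklayer::export(annotation, path, format = "gtf")
  invisible(path)
}

#' Read / write long-format count tables
#'
#' TSV with columns event_id, probe, sample, condition, replicate,
#' count; one row per probe per sample.
#'
#' @param path file path.
#' @return \code{readCountTable}: a \code{\link{raslCounts}} object.
#' @export
readCountTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("event_id", "probe", "sample", "condition", "replicate",
            "count")
  if (!all(need %in% colnames(d)))
    stop("count TSV needs columns: ", paste(need, collapse = ", "))
  events <- unique(d$event_id)
  samples <- unique(d$sample)
  iso <- ifelse(grepl("_inc$", d$probe), "included", "skipped")
  mk <- function(which) {
    sub <- d[iso == which, ]
    m <- matrix(NA_integer_, length(events), length(samples),
                dimnames = list(events, samples))
    m[cbind(match(sub$event_id, events), match(sub$sample, samples))] <-
      sub$count
    if (anyNA(m)) {
      bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop("incomplete count grid: event '", events[bad[1L]],
           "' lacks its ", which, " count in sample '",
           samples[bad[2L]], "'")
    }
    m
  }
  meta <- unique(d[, c("sample", "condition", "replicate")])
  meta <- meta[match(samples, meta$sample), ]
  raslCounts(mk("included"), mk("skipped"),
             condition = meta$condition, replicate = meta$replicate)
}

#' @rdname readCountTable
#' @param x a \code{RaslCounts}.
#' @export
writeCountTable <- function(x, path) {
  inc <- includedCounts(x); skp <- skippedCounts(x)
  cd <- colData(x)
  long <- function(m, tag) data.frame(
    event_id = rep(rownames(m), ncol(m)),
    probe = paste0(rep(rownames(m), ncol(m)), tag),
    sample = rep(colnames(m), each = nrow(m)),
    condition = rep(cd$condition, each = nrow(m)),
    replicate = rep(cd$replicate, each = nrow(m)),
    count = as.vector(m), stringsAsFactors = FALSE)
  d <- rbind(long(inc, "_inc"), long(skp, "_skp"))
  d <- d[order(d$event_id, d$sample, d$probe), ]
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export cassette exons and flanks as BED6
#'
#' Converts the panel's 1-based inclusive exon intervals to BED's
#' 0-based half-open convention via \code{rtracklayer}.
#'
#' @param panel a \code{\link{ProbePanel-class}}.
#' @param path file path.
#' @export
writePanelBED <- function(panel, path) {
  ev <- cassetteExons(panel)
  mcols(ev) <- DataFrame(name = mcols(ev)$event_id, score = 0L)
  rtracklayer::export(ev, path, format = "bed")
  invisible(path)
}
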