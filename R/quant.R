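## Detection filtering, per-replicate isoform ratios, ratio-change
## differential calls and per-type tallies for RASL junction counts.

#' Detection filter
#'
#' Retains events whose inclusion AND skipping counts reach
#' \code{minCount} in every sample of both conditions; all other events
#' are reported as filtered.
#'
#' @param x a \code{\link{raslCounts}} object (complete grid: both
#'   isoforms of every event counted in every sample).
#' @param minCount minimum read count per isoform per sample (default 5).
#' @return list with \code{counts} (the retained \code{RaslCounts}) and
#'   \code{filtered} (character vector of removed event ids).
#' @examples
#' inc <- matrix(c(10L, 4L), 1, 2, dimnames = list("e1", NULL))
#' rc <- raslCounts(inc, inc + 2L, condition = c("A", "B"),
#'                  replicate = c(1, 1))
#' detectEvents(rc, minCount = 5)$filtered
#' @export
detectEvents <- function(x, minCount = 5L) {
  stopifnot(is(x, "RaslCounts"))
  inc <- includedCounts(x); skp <- skippedCounts(x)
  if (anyNA(inc) || anyNA(skp)) {
    bad <- which(is.na(inc) | is.na(skp), arr.ind = TRUE)[1L, ]
    stop("incomplete count grid: event '", rownames(inc)[bad[1L]],
         "', sample '", colnames(inc)[bad[2L]], "' is missing")
  }
  keep <- rowSums(inc < minCount | skp < minCount) == 0L
  list(counts = x[keep, ], filtered = rownames(inc)[!keep])
}

#' Per-replicate isoform ratios
#'
#' Ratio of inclusion to skipping counts per event and sample,
#' element-wise. Intended for detection-filtered data; any zero
#' skipping count is an error rather than a clamped value.
#'
#' @param x a \code{\link{raslCounts}} object (after
#'   \code{\link{detectEvents}}).
#' @return numeric matrix (events x samples) of included/skipped ratios.
#' @export
eventRatios <- function(x) {
  stopifnot(is(x, "RaslCounts"))
  skp <- skippedCounts(x)
  if (any(skp == 0))
    stop("zero skipping counts present; apply detectEvents() with ",
         "minCount >= 1 before computing ratios")
  includedCounts(x) / skp
}

# degenerate-variance guard: constant, equal groups are a clean null
# (p = 1); constant but different groups are maximally inconsistent
# with the null (p = 0, the t statistic diverges)
.tGuard <- function(x, y, f) {
  if (stats::var(x) + stats::var(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  f(x, y)
}

.welchLog2 <- function(rB, rA)
  .tGuard(log2(rB), log2(rA),
          function(x, y) stats::t.test(x, y)$p.value)
.studentRaw <- function(rB, rA)
  .tGuard(rB, rA,
          function(x, y) stats::t.test(x, y, var.equal = TRUE)$p.value)

#' Call differential splicing events
#'
#' For each event the ratio change RC is the mean of per-replicate
#' inclusion/skipping ratios in condition B divided by the mean in
#' condition A. Events with RC >= \code{ratioThreshold} and p <
#' \code{alpha} are "up"; RC <= 1/\code{ratioThreshold} with p <
#' \code{alpha} are "down"; the rest are "ndiff". The default p-value is
#' a two-sided Welch t-test on log2 per-replicate ratios; a pooled-
#' variance t on raw ratios is available via \code{test}. A signed fold
#' (-1/RC for RC < 1) is reported for display. Raw p-values drive the
#' calls by default; set \code{adjust = "BH"} for a corrected variant.
#'
#' @param x a \code{RaslCounts} after filtering, or the list returned by
#'   \code{\link{detectEvents}} (filtered events are then carried through
#'   with class "filtered").
#' @param ratioThreshold ratio-change threshold T (default 2).
#' @param alpha significance level (default 0.05).
#' @param test "welch_log2" (default) or "student_raw".
#' @param adjust p-adjustment method passed to \code{p.adjust}
#'   (default "none").
#' @param conditions the two condition labels, numerator second:
#'   RC = mean ratio(conditions[2]) / mean ratio(conditions[1]).
#' @return data.frame: event_id, event_type, ratio_A, ratio_B, rc,
#'   signed_fold, p_value, class; attribute \code{"test"} records the
#'   test used.
#' @export
callDifferential <- function(x, ratioThreshold = 2, alpha = 0.05,
                             test = c("welch_log2", "student_raw"),
                             adjust = "none", conditions = c("A", "B")) {
  filtered <- character()
  if (is.list(x) && !is(x, "RaslCounts")) {
    filtered <- x$filtered
    x <- x$counts
  }
  stopifnot(is(x, "RaslCounts"))
  test <- match.arg(test)
  cond <- colData(x)$condition
  if (!all(conditions %in% cond))
    stop("conditions ", paste(conditions, collapse = "/"),
         " not both present")
  iA <- which(cond == conditions[1L]); iB <- which(cond == conditions[2L])
  if (length(iA) < 2L || length(iB) < 2L)
    stop("at least 2 replicates per condition are required")
  ratios <- eventRatios(x)
  rA <- ratios[, iA, drop = FALSE]
  rB <- ratios[, iB, drop = FALSE]
  rc <- rowMeans(rB) / rowMeans(rA)
  testFun <- if (test == "welch_log2") .welchLog2 else .studentRaw
  p <- vapply(seq_len(nrow(ratios)),
              function(i) testFun(rB[i, ], rA[i, ]), numeric(1))
  pUse <- stats::p.adjust(p, method = adjust)
  cls <- ifelse(rc >= ratioThreshold & pUse < alpha, "up",
                ifelse(rc <= 1 / ratioThreshold & pUse < alpha, "down",
                       "ndiff"))
  etype <- if ("event_type" %in% colnames(rowData(x)))
    as.character(rowData(x)$event_type) else NA_character_
  out <- data.frame(
    event_id = rownames(ratios), event_type = etype,
    ratio_A = rowMeans(rA), ratio_B = rowMeans(rB), rc = rc,
    signed_fold = ifelse(rc >= 1, rc, -1 / rc),
    p_value = p, class = cls,
    stringsAsFactors = FALSE, row.names = NULL)
  if (length(filtered))
    out <- rbind(out, data.frame(
      event_id = filtered, event_type = NA_character_, ratio_A = NA,
      ratio_B = NA, rc = NA, signed_fold = NA, p_value = NA,
      class = "filtered", stringsAsFactors = FALSE))
  attr(out, "test") <- test
  attr(out, "adjust") <- adjust
  out
}

#' Tally differential-splicing calls
#'
#' Counts events per event-type and class, the number detected
#' (non-filtered), the number significant (up + down) and the percent
#' significant (one decimal).
#'
#' @param calls data.frame from \code{\link{callDifferential}} (columns
#'   \code{event_type}, \code{class}).
#' @return object of class \code{"callSummary"}: list with \code{table}
#'   (type x class counts), \code{nDetected}, \code{nSignificant},
#'   \code{percentSignificant} (NA when nothing is detected).
#' @examples
#' calls <- data.frame(event_type = "SE",
#'                     class = c("up", "down", "ndiff"))
#' summarizeCalls(calls)
#' @export
summarizeCalls <- function(calls) {
  stopifnot(all(c("event_type", "class") %in% colnames(calls)))
  lv <- c("up", "down", "ndiff", "filtered")
  cls <- factor(calls$class, levels = lv)
  tab <- table(event_type = calls$event_type, class = cls)
  nDet <- sum(cls %in% c("up", "down", "ndiff"))
  nSig <- sum(cls %in% c("up", "down"))
  pct <- if (nDet > 0) round(100 * nSig / nDet, 1) else NA_real_
  structure(list(table = tab, nDetected = nDet, nSignificant = nSig,
                 percentSignificant = pct),
            class = "callSummary")
}

#' @export
print.callSummary <- function(x, ...) {
  cat("Differential-splicing call summary\n")
  print(x$table)
  cat(x$nSignificant, "significant of", x$nDetected, "detected")
  if (!is.na(x$percentSignificant))
    cat(" (", x$percentSignificant, "%)", sep = "")
  cat("\n")
  invisible(x)
}
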