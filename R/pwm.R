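#' Train a position weight matrix splice-site scorer
#'
#' Position-wise nucleotide frequencies with an additive pseudocount,
#' converted to log2 odds against a background distribution. With a
#' uniform training set and uniform background all log-odds are 0.
#'
#' @param windows character vector or \code{DNAStringSet} of equal-length
#'   splice-site windows (one site kind at a time).
#' @param pseudocount additive pseudocount per cell (default 1).
#' @param background length-4 background probabilities (A, C, G, T);
#'   default uniform.
#' @param siteKind label stored with the model ("donor"/"acceptor").
#' @return a \code{\link{PWMModel-class}}.
#' @examples
#' m <- trainPWM(c("CAGGTAAGT", "CAGGTAAGT"), pseudocount = 0)
#' scoreWindow(m, "CAGGTAAGT")  # 9 positions x 2 bits
#' @export
trainPWM <- function(windows, pseudocount = 1,
                     background = rep(0.25, 4), siteKind = "donor") {
  if (is.character(windows)) windows <- DNAStringSet(windows)
  if (length(windows) < 1L) stop("at least one training window required")
  if (length(unique(width(windows))) != 1L)
    stop("training windows have mixed lengths")
  counts <- consensusMatrix(windows)[c("A", "C", "G", "T"), , drop = FALSE]
  probs <- sweep(counts + pseudocount, 2,
                 colSums(counts + pseudocount), "/")
  lo <- log2(sweep(probs, 1, background, "/"))
  new("PWMModel", logodds = lo, pseudocount = pseudocount,
      n = length(windows), siteKind = siteKind)
}

#' Score splice-site windows against a PWM
#'
#' Sum of per-position log2 odds (bits); higher means a stronger match
#' to the training population.
#'
#' @param model a \code{\link{PWMModel-class}}.
#' @param windows character vector or \code{DNAStringSet}, each the
#'   model's width, alphabet ACGT.
#' @return numeric vector of scores in bits.
#' @export
scoreWindow <- function(model, windows) {
  stopifnot(is(model, "PWMModel"))
  if (is(windows, "XStringSet") || is(windows, "XString"))
    windows <- as.character(windows)
  L <- ncol(model@logodds)
  vapply(windows, function(w) {
    if (nchar(w) != L)
      stop("window length ", nchar(w), " does not match model width ", L)
    b <- match(strsplit(w, "")[[1L]], BASES)
    if (anyNA(b))
      stop("non-ACGT character in window: ", w)
    sum(model@logodds[cbind(b, seq_len(L))])
  }, numeric(1), USE.NAMES = FALSE)
}
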