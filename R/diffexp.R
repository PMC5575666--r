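#' @include AllClasses.R accessors.R
NULL

#' Log2 fold change between two group means
#'
#' \code{log2((meanA + pseudocount) / (meanB + pseudocount))}, with group A
#' the numerator (in the two-breed study, the lean-type group YY over the
#' fat-type group WH). The pseudocount guards the zero-FPKM case.
#'
#' @param meanA,meanB Non-negative mean FPKM values (vectorised).
#' @param pseudocount Positive stabiliser (default 0.25).
#' @return Numeric log2 fold change(s).
#' @examples
#' log2FoldChange(4, 1, pseudocount = 1e-9)  # ~2
#' @export
log2FoldChange <- function(meanA, meanB, pseudocount = 0.25) {
  if (any(meanA < 0) || any(meanB < 0)) stop("means must be non-negative")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  log2((meanA + pseudocount) / (meanB + pseudocount))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment, order-preserving with the
#' input and clipped to [0, 1].
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

.pooledT <- function(xa, xb) {
  # two-sided pooled-variance two-sample t; exact under equal-variance
  # normal noise. Returns p = 1 for degenerate (zero pooled variance) rows.
  na <- length(xa); nb <- length(xb)
  v <- ((na - 1) * stats::var(xa) + (nb - 1) * stats::var(xb)) / (na + nb - 2)
  if (!is.finite(v) || v <= 0) return(1)
  t <- (mean(xa) - mean(xb)) / sqrt(v * (1 / na + 1 / nb))
  2 * stats::pt(-abs(t), df = na + nb - 2)
}

#' Two-group differential expression on FPKM
#'
#' Per feature: group mean FPKM, log2 fold change (first group level over
#' second, see [log2FoldChange()]), a two-sided two-sample t-test on
#' \code{log2(FPKM + pseudocount)}, Benjamini-Hochberg q-values, and a call
#' at \code{q < alpha}. The default test pools variances, which is exactly
#' calibrated under the homoskedastic log-normal noise model; set
#' \code{varEqual = FALSE} for Welch's unequal-variance form. This is a
#' documented stand-in for assembler-native count-model tests; externally
#' computed p-values (e.g. from such a tool) can be supplied instead.
#'
#' @param expr An [FPKMSet-class]; each group needs >= 2 samples.
#' @param alpha FDR level for calls (default 0.05).
#' @param pseudocount Positive stabiliser (default 0.25).
#' @param features Optional subset of feature ids to test (default all).
#' @param externalP Optional data frame (\code{feature_id}, \code{p})
#'   replacing the computed p-values.
#' @param varEqual Pool variances (default \code{TRUE}).
#' @return Data frame: \code{feature_id}, \code{mean_a}, \code{mean_b},
#'   \code{log2fc}, \code{p}, \code{q}, \code{call} (\code{up}/\code{down}/
#'   \code{ns}; up = higher in the first group level).
#' @examples
#' sim <- simulateStudy(seed = 1)
#' head(deTest(sim$expr))
#' @export
deTest <- function(expr, alpha = 0.05, pseudocount = 0.25, features = NULL,
                   externalP = NULL, varEqual = TRUE) {
  g <- sampleGroups(expr)
  if (any(table(g) < 2L))
    stop("each group needs at least two samples")
  m <- fpkm(expr)
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(m))
    if (length(missing))
      stop("feature(s) absent from the expression matrix: ",
           paste(missing, collapse = ", "))
    m <- m[features, , drop = FALSE]
  }
  la <- levels(g)[1L]; lb <- levels(g)[2L]
  ma <- m[, g == la, drop = FALSE]
  mb <- m[, g == lb, drop = FALSE]
  meanA <- rowMeans(ma); meanB <- rowMeans(mb)
  lfc <- log2FoldChange(meanA, meanB, pseudocount)
  logm <- log2(m + pseudocount)
  if (is.null(externalP)) {
    p <- vapply(seq_len(nrow(m)), function(i) {
      xa <- logm[i, g == la]; xb <- logm[i, g == lb]
      if (varEqual) .pooledT(xa, xb)
      else if (stats::sd(xa) == 0 && stats::sd(xb) == 0) 1
      else stats::t.test(xa, xb)$p.value
    }, numeric(1))
  } else {
    hit <- match(rownames(m), externalP$feature_id)
    if (anyNA(hit))
      stop("external p-values missing for feature(s): ",
           paste(rownames(m)[is.na(hit)], collapse = ", "))
    p <- externalP$p[hit]
  }
  q <- bhAdjust(p)
  call <- ifelse(q < alpha & lfc != 0, ifelse(lfc > 0, "up", "down"), "ns")
  data.frame(feature_id = rownames(m), mean_a = meanA, mean_b = meanB,
             log2fc = lfc, p = p, q = q,
             call = factor(call, levels = c("up", "down", "ns")),
             row.names = NULL)
}
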