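#' @include AllClasses.R accessors.R
NULL

.geneSpans <- function(genes, biotype = "protein_coding") {
  sel <- biotypes(genes) == biotype
  if (!any(sel)) sel <- rep(TRUE, length(genes))
  sub <- genes[which(sel)]
  sp <- txSpans(sub)
  bygene <- S4Vectors::split(sp, unname(geneIds(sub)))
  g <- unlist(range(bygene, ignore.strand = TRUE), use.names = TRUE)
  GenomicRanges::strand(g) <- "*"
  g
}

#' Cis potential target genes within a genomic window
#'
#' Pairs every lincRNA with every protein-coding gene on the same
#' chromosome whose span lies strictly closer than \code{window} bp
#' (overlap counts as distance 0); strand is ignored and both sides of the
#' lincRNA are scanned.
#'
#' @param lincRNAs A [TranscriptSet-class].
#' @param genes A [TranscriptSet-class] annotation; transcripts with
#'   biotype \code{"protein_coding"} define the gene spans (all transcripts
#'   are used when that biotype is absent).
#' @param window Window size in bp, strict upper bound on the span gap
#'   (default 10000).
#' @return Data frame of edges: \code{lincRNA_id}, \code{gene_id},
#'   \code{mode = "cis"}, \code{distance} (bp gap, 0 for overlap).
#' @export
cisTargets <- function(lincRNAs, genes, window = 10000) {
  stopifnot(window > 0)
  lsp <- txSpans(lincRNAs)
  GenomicRanges::strand(lsp) <- "*"
  gsp <- .geneSpans(genes)
  hit <- GenomicRanges::findOverlaps(lsp, gsp, maxgap = window - 1L,
                                     ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hit); si <- S4Vectors::subjectHits(hit)
  d <- GenomicRanges::distance(lsp[qi], gsp[si], ignore.strand = TRUE)
  keep <- !is.na(d) & d < window
  data.frame(lincRNA_id = names(lsp)[qi][keep],
             gene_id = names(gsp)[si][keep],
             mode = "cis",
             distance = as.integer(d[keep]),
             row.names = NULL)
}

#' Pearson correlation with t-distribution p-value
#'
#' Sample Pearson correlation and the two-sided p-value from the
#' t-distribution with n - 2 degrees of freedom. A constant vector makes
#' the correlation undefined: the pair is flagged with \code{NA}s rather
#' than an error so callers can skip and count it.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Named numeric vector \code{c(r, p)}.
#' @examples
#' pearsonR(1:3, c(2, 4, 6))  # r = 1, p = 0
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 paired observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(r = NA_real_, p = NA_real_))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  c(r = unname(ct$estimate), p = ct$p.value)
}

#' Trans potential target genes by expression correlation
#'
#' Restricts lincRNAs and genes to features with detectable expression
#' (FPKM above \code{detect} in every sample), computes all lincRNA x gene
#' Pearson correlations with t-distribution p-values, adjusts p over the
#' full tested pair family (Benjamini-Hochberg), and returns edges passing
#' \code{|r| >= rMin} and \code{q <= alpha}. The sign of r is kept on the
#' edge; \code{positiveOnly = TRUE} restores the literal positive-threshold
#' reading (\code{r >= rMin}).
#'
#' @param expr An [FPKMSet-class] with >= 3 samples.
#' @param lincIds,geneIds Feature ids of the candidate regulators and
#'   targets; must be rows of \code{expr}.
#' @param rMin Minimum absolute correlation (default 0.95).
#' @param alpha Maximum BH-adjusted p (default 0.05).
#' @param detect Detectability floor: FPKM must exceed it in every sample
#'   (default 0).
#' @param positiveOnly Require r >= rMin instead of |r| >= rMin.
#' @return Data frame of edges (\code{lincRNA_id}, \code{gene_id},
#'   \code{mode = "trans"}, \code{r}, \code{p}, \code{q}) with attributes
#'   \code{nPairs} (pairs tested) and \code{nSkipped} (pairs dropped for a
#'   constant member).
#' @export
transTargets <- function(expr, lincIds, geneIds, rMin = 0.95, alpha = 0.05,
                         detect = 0, positiveOnly = FALSE) {
  stopifnot(rMin > 0, rMin <= 1)
  m <- fpkm(expr)
  if (ncol(m) < 3L) stop("at least 3 samples are required")
  missing <- setdiff(c(lincIds, geneIds), rownames(m))
  if (length(missing))
    stop("feature(s) absent from the expression matrix: ",
         paste(missing, collapse = ", "))
  detectable <- rownames(m)[rowSums(m > detect) == ncol(m)]
  lincIds <- intersect(lincIds, detectable)
  geneIds <- intersect(geneIds, detectable)
  empty <- data.frame(lincRNA_id = character(0), gene_id = character(0),
                      mode = character(0), r = numeric(0), p = numeric(0),
                      q = numeric(0))
  if (length(lincIds) == 0L || length(geneIds) == 0L) {
    attr(empty, "nPairs") <- 0L; attr(empty, "nSkipped") <- 0L
    return(empty)
  }
  lm <- m[lincIds, , drop = FALSE]
  gm <- m[geneIds, , drop = FALSE]
  sdl <- apply(lm, 1L, stats::sd); sdg <- apply(gm, 1L, stats::sd)
  nSkipped <- sum(sdl == 0) * length(geneIds) +
    sum(sdg == 0) * length(lincIds) - sum(sdl == 0) * sum(sdg == 0)
  lm <- lm[sdl > 0, , drop = FALSE]; gm <- gm[sdg > 0, , drop = FALSE]
  if (nrow(lm) == 0L || nrow(gm) == 0L) {
    attr(empty, "nPairs") <- 0L; attr(empty, "nSkipped") <- nSkipped
    return(empty)
  }
  n <- ncol(m)
  R <- stats::cor(t(lm), t(gm))
  R <- pmin(pmax(R, -1), 1)
  tt <- R * sqrt((n - 2) / pmax(1 - R^2, 0))
  P <- 2 * stats::pt(-abs(tt), df = n - 2)
  # drop self-pairs if an id sits on both sides
  self <- outer(rownames(lm), colnames(R), "==") & FALSE
  if (length(intersect(rownames(lm), rownames(gm))))
    self <- outer(rownames(lm), rownames(gm), "==")
  P[self] <- NA
  keepMask <- !self
  q <- matrix(NA_real_, nrow(P), ncol(P))
  q[keepMask] <- bhAdjust(P[keepMask])
  pass <- keepMask & (if (positiveOnly) R >= rMin else abs(R) >= rMin) &
    q <= alpha
  idx <- which(pass, arr.ind = TRUE)
  out <- data.frame(lincRNA_id = rownames(lm)[idx[, 1L]],
                    gene_id = rownames(gm)[idx[, 2L]],
                    mode = if (nrow(idx)) "trans" else character(0),
                    r = R[pass], p = P[pass], q = q[pass],
                    row.names = NULL)
  out <- out[order(out$lincRNA_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nPairs") <- sum(keepMask)
  attr(out, "nSkipped") <- nSkipped
  out
}

.deLookup <- function(de) {
  stats::setNames(seq_len(nrow(de)), de$feature_id)
}

#' Annotate edges with regulatory sign
#'
#' Sets \code{sign} to \code{"concordant"} (same fold-change direction at
#' both ends, the "upregulated by" relation) or \code{"discordant"} when
#' both endpoints are differentially expressed, else \code{NA}.
#'
#' @param edges Edge data frame (see [transTargets()], [cisTargets()]).
#' @param de [deTest()] result covering every edge endpoint.
#' @return \code{edges} with a \code{sign} column.
#' @export
edgeSigns <- function(edges, de) {
  look <- .deLookup(de)
  miss <- setdiff(unique(c(edges$lincRNA_id, edges$gene_id)), names(look))
  if (length(miss))
    stop("edge endpoint(s) missing from the differential-expression table: ",
         paste(miss, collapse = ", "))
  lrow <- look[edges$lincRNA_id]; grow <- look[edges$gene_id]
  bothDE <- de$call[lrow] != "ns" & de$call[grow] != "ns"
  conc <- sign(de$log2fc[lrow]) == sign(de$log2fc[grow])
  edges$sign <- ifelse(bothDE, ifelse(conc, "concordant", "discordant"),
                       NA_character_)
  edges
}

#' Direction tallies per differentially expressed lincRNA
#'
#' For every differentially expressed lincRNA (DEL) among the edges, counts
#' its differentially expressed targets (DEPTGs) whose fold-change
#' direction matches the lincRNA's (\code{n_up}, the targets it
#' "upregulates") and those changing oppositely (\code{n_down});
#' \code{n_deptg = n_up + n_down}.
#'
#' @param edges Edge data frame.
#' @param de [deTest()] result covering every edge endpoint (missing
#'   endpoints are an error).
#' @return Data frame: \code{lincRNA_id}, \code{n_deptg}, \code{n_up},
#'   \code{n_down}, one row per DEL (lincRNAs with no DE target get a zero
#'   row).
#' @seealso [majoritySummary()]
#' @export
directionTally <- function(edges, de) {
  edges <- edgeSigns(edges, de)
  look <- .deLookup(de)
  delIds <- unique(edges$lincRNA_id[de$call[look[edges$lincRNA_id]] != "ns"])
  out <- do.call(rbind, lapply(delIds, function(l) {
    s <- edges$sign[edges$lincRNA_id == l]
    s <- s[!is.na(s)]
    data.frame(lincRNA_id = l, n_deptg = length(s),
               n_up = sum(s == "concordant"), n_down = sum(s == "discordant"))
  }))
  if (is.null(out))
    out <- data.frame(lincRNA_id = character(0), n_deptg = integer(0),
                      n_up = integer(0), n_down = integer(0))
  out
}

#' Majority regulation direction across lincRNAs
#'
#' @param tallies Data frame from [directionTally()] (or any table with
#'   \code{n_up}, \code{n_down}); must be non-empty.
#' @return Named integer vector: \code{n_majority_up} (lincRNAs with more
#'   concordant than discordant DE targets), \code{n_majority_down},
#'   \code{ties}.
#' @export
majoritySummary <- function(tallies) {
  if (nrow(tallies) == 0L) stop("tallies must be non-empty")
  c(n_majority_up = sum(tallies$n_up > tallies$n_down),
    n_majority_down = sum(tallies$n_up < tallies$n_down),
    ties = sum(tallies$n_up == tallies$n_down))
}

#' Shared-target counts over a regulatory network
#'
#' @param edges Edge data frame.
#' @return Named integer vector: \code{n_unique_targets} (distinct target
#'   genes) and \code{n_multi_regulated} (targets linked to >= 2 distinct
#'   lincRNAs).
#' @export
sharedTargetCount <- function(edges) {
  if (nrow(edges) == 0L)
    return(c(n_unique_targets = 0L, n_multi_regulated = 0L))
  deg <- rowSums(table(edges$gene_id, edges$lincRNA_id) > 0)
  c(n_unique_targets = length(deg),
    n_multi_regulated = sum(deg >= 2L))
}

#' Validate edges on a second expression dataset
#'
#' Recomputes per-edge Pearson correlation and p-value on an independent
#' expression matrix and reports the fraction of edges whose correlation
#' sign agrees with the discovery edge.
#'
#' @param edges Edge data frame carrying a discovery \code{r} column.
#' @param expr2 An [FPKMSet-class] or a plain numeric matrix (features x
#'   samples) with >= 3 samples.
#' @return List: \code{results} (per-edge \code{r}, \code{p},
#'   \code{sign_agree}), \code{signAgreement} (fraction over evaluable
#'   edges), \code{skipped} (edges with an endpoint missing from
#'   \code{expr2}, logged and skipped).
#' @export
validatePairs <- function(edges, expr2) {
  m <- if (is(expr2, "FPKMSet")) fpkm(expr2) else as.matrix(expr2)
  if (ncol(m) < 3L) stop("the validation matrix needs at least 3 samples")
  present <- edges$lincRNA_id %in% rownames(m) & edges$gene_id %in% rownames(m)
  skipped <- edges[!present, c("lincRNA_id", "gene_id"), drop = FALSE]
  if (nrow(skipped))
    message(nrow(skipped), " edge(s) skipped: endpoint missing from the ",
            "validation matrix")
  ev <- edges[present, , drop = FALSE]
  rp <- t(vapply(seq_len(nrow(ev)), function(i)
    pearsonR(m[ev$lincRNA_id[i], ], m[ev$gene_id[i], ]), numeric(2)))
  results <- data.frame(lincRNA_id = ev$lincRNA_id, gene_id = ev$gene_id,
                        r_discovery = if ("r" %in% names(ev)) ev$r else NA,
                        r = if (nrow(ev)) rp[, 1L] else numeric(0),
                        p = if (nrow(ev)) rp[, 2L] else numeric(0),
                        row.names = NULL)
  results$sign_agree <- sign(results$r) == sign(results$r_discovery)
  list(results = results,
       signAgreement = mean(results$sign_agree, na.rm = TRUE),
       skipped = skipped)
}
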