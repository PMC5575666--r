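#' @include AllClasses.R accessors.R coding-potential.R
NULL

.CASCADE_STAGES <- c("intergenic_class", "size", "coding_potential",
                     "domain_hits", "homology_hits", "expression")

#' Default cascade thresholds
#'
#' @param classCode Class code retained at stage 1 (default \code{"u"},
#'   intergenic).
#' @param minLen Minimum transcript length in nt; transcripts strictly
#'   shorter are removed, exactly \code{minLen} is retained (default 200).
#' @param minExons Minimum exon count (default 2; single-exon models are
#'   removed).
#' @param cpcCut Coding-score cutoff; a score strictly above it on either
#'   strand removes the transcript (default 0, the CPC sign convention).
#' @param evalue Strict E-value cutoff for the domain and homology screens
#'   (default \code{1e-5}).
#' @param minFpkm Expression floor; a transcript below it in every sample is
#'   removed, at least one sample at or above keeps it (default 0.5).
#' @param theta ORF-fraction threshold of the heuristic coding score
#'   (default 0.3).
#' @return Named list of thresholds for [runCascade()].
#' @export
cascadeParams <- function(classCode = "u", minLen = 200, minExons = 2,
                          cpcCut = 0, evalue = 1e-5, minFpkm = 0.5,
                          theta = 0.3) {
  list(classCode = classCode, minLen = minLen, minExons = minExons,
       cpcCut = cpcCut, evalue = evalue, minFpkm = minFpkm, theta = theta)
}

#' Run the six-stage lincRNA identification cascade
#'
#' Applies, in order: (1) keep only transcripts with the intergenic class
#' code; (2) remove single-exon or short transcripts; (3) remove transcripts
#' whose coding score exceeds the cutoff on either strand; (4) remove
#' transcripts with a significant protein-domain hit; (5) remove transcripts
#' with a significant protein-homology hit; (6) remove transcripts below the
#' FPKM floor in every sample. Fate is attributed to the first failing
#' stage.
#'
#' @param x A [TranscriptSet-class] of candidate transcripts.
#' @param expr An [FPKMSet-class] covering every transcript that reaches
#'   stage 6 (missing ones are an error).
#' @param coding Optional external coding-score table
#'   (\code{transcript_id, score_forward, score_reverse}); when \code{NULL},
#'   heuristic scores are computed from the sequences of \code{x}, which
#'   must then be present for every transcript reaching stage 3.
#' @param domainHits,homologyHits Hit tables as from [readHitTable()]; may
#'   be \code{NULL} or empty.
#' @param params Thresholds, see [cascadeParams()].
#' @return List with elements \code{lincRNAs} (the retained
#'   [TranscriptSet-class]) and \code{report} (a [FilterReport-class]).
#' @examples
#' sim <- simulateStudy(seed = 1)
#' res <- runCascade(sim$candidates, sim$expr, domainHits = sim$domainHits,
#'                   homologyHits = sim$homologyHits)
#' res$report
#' @export
runCascade <- function(x, expr, coding = NULL, domainHits = NULL,
                       homologyHits = NULL, params = cascadeParams()) {
  ids <- transcriptIds(x)
  fate <- stats::setNames(rep("retained", length(ids)), ids)
  alive <- rep(TRUE, length(ids))
  survivors <- integer(length(.CASCADE_STAGES))
  drop <- function(bad, stage) {
    fate[alive & bad] <<- stage
    alive <<- alive & !bad
  }

  drop(classCodes(x) != params$classCode, "intergenic_class")
  survivors[1L] <- sum(alive)

  drop(exonCounts(x) < params$minExons | txLengths(x) < params$minLen, "size")
  survivors[2L] <- sum(alive)

  if (any(alive)) {
    sub <- x[alive]
    sc <- codingScores(sub,
                       mode = if (is.null(coding)) "heuristic" else "external",
                       external = coding, theta = params$theta)
    codingBad <- rep(FALSE, length(ids))
    codingBad[match(sc$transcript_id, ids)] <-
      sc$score_forward > params$cpcCut | sc$score_reverse > params$cpcCut
    drop(codingBad, "coding_potential")
  }
  survivors[3L] <- sum(alive)

  keep <- hitFilter(ids[alive], domainHits, params$evalue)
  drop(alive & !ids %in% keep, "domain_hits")
  survivors[4L] <- sum(alive)

  keep <- hitFilter(ids[alive], homologyHits, params$evalue)
  drop(alive & !ids %in% keep, "homology_hits")
  survivors[5L] <- sum(alive)

  if (any(alive)) {
    m <- fpkm(expr)
    missing <- setdiff(ids[alive], rownames(m))
    if (length(missing))
      stop("transcript(s) missing from the expression matrix at the ",
           "expression stage: ", paste(missing, collapse = ", "))
    expressed <- rownames(m)[rowSums(m >= params$minFpkm) > 0L]
    drop(alive & !ids %in% expressed, "expression")
  }
  survivors[6L] <- sum(alive)

  report <- new("FilterReport", nInput = length(ids),
                stageNames = .CASCADE_STAGES,
                survivors = survivors, fate = fate)
  list(lincRNAs = x[alive], report = report)
}

#' Classify lincRNAs as novel or overlapping known annotation
#'
#' A lincRNA is \code{novel} when its span (or exons, with
#' \code{mode = "exon"}) overlaps no annotated transcript; otherwise
#' \code{known_overlap}. One shared base pair counts as overlap.
#'
#' @param lincRNAs A [TranscriptSet-class].
#' @param known A [TranscriptSet-class] of annotated transcripts (coding and
#'   noncoding).
#' @param mode Compare transcript \code{"span"}s (default) or individual
#'   \code{"exon"}s.
#' @param ignoreStrand Ignore strand when testing overlap (default
#'   \code{TRUE}).
#' @return Factor (\code{novel}, \code{known_overlap}) named by transcript
#'   id.
#' @export
classifyNovelty <- function(lincRNAs, known, mode = c("span", "exon"),
                            ignoreStrand = TRUE) {
  mode <- match.arg(mode)
  q <- if (mode == "span") txSpans(lincRNAs)
       else unlist(exons(lincRNAs), use.names = TRUE)
  s <- if (mode == "span") txSpans(known)
       else unlist(exons(known), use.names = FALSE)
  hit <- GenomicRanges::findOverlaps(q, s, ignore.strand = ignoreStrand)
  hitIds <- unique(names(q)[S4Vectors::queryHits(hit)])
  ids <- transcriptIds(lincRNAs)
  out <- factor(ifelse(ids %in% hitIds, "known_overlap", "novel"),
                levels = c("novel", "known_overlap"))
  stats::setNames(out, ids)
}

.classStats <- function(x) {
  c(mean_tx_length = mean(txLengths(x)),
    mean_exon_length = mean(unlist(GenomicRanges::width(exons(x)),
                                   use.names = FALSE)),
    mean_exon_number = mean(exonCounts(x)))
}

#' Characterize lincRNAs against reference transcript classes
#'
#' Summarises transcript length, exon length (pooled over exons) and exon
#' number for novel lincRNAs, known lincRNAs and protein-coding transcripts,
#' plus group-wise mean FPKM for lincRNAs versus coding genes.
#'
#' @param lincRNAs,knownLincs,coding Non-empty [TranscriptSet-class]
#'   objects.
#' @param expr An [FPKMSet-class]; features absent from it are ignored in
#'   the expression summary.
#' @return List with \code{summary} (per-class structural means),
#'   \code{expression} (per class x group mean FPKM) and
#'   \code{perTranscript} (length/exon table for plotting).
#' @export
characterize <- function(lincRNAs, knownLincs, coding, expr) {
  sets <- list(novel_lincRNA = lincRNAs, known_lincRNA = knownLincs,
               protein_coding = coding)
  if (any(vapply(sets, length, integer(1)) == 0L))
    stop("all three transcript sets must be non-empty")
  summary <- data.frame(class = names(sets),
                        t(vapply(sets, .classStats, numeric(3))),
                        row.names = NULL)
  g <- sampleGroups(expr)
  m <- fpkm(expr)
  exprRows <- list(lincRNA = transcriptIds(lincRNAs),
                   protein_coding = unique(c(transcriptIds(coding),
                                             unname(geneIds(coding)))))
  expression <- do.call(rbind, lapply(names(exprRows), function(cl) {
    rows <- intersect(exprRows[[cl]], rownames(m))
    data.frame(class = cl, group = levels(g),
               mean_fpkm = vapply(levels(g), function(gr)
                 mean(m[rows, g == gr, drop = FALSE]), numeric(1)),
               row.names = NULL)
  }))
  perTranscript <- do.call(rbind, lapply(names(sets), function(cl) {
    s <- sets[[cl]]
    data.frame(class = cl, transcript_id = transcriptIds(s),
               tx_length = unname(txLengths(s)),
               n_exons = unname(exonCounts(s)), row.names = NULL)
  }))
  list(summary = summary, expression = expression,
       perTranscript = perTranscript)
}
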