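#' @include AllClasses.R
NULL

#' Accessors for TranscriptSet
#'
#' @param x A [TranscriptSet-class].
#' @return \code{transcriptIds}: character vector of transcript ids.
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))

#' @rdname TranscriptSet-accessors
#' @export
setMethod("transcriptIds", "TranscriptSet", function(x) names(x@exons))

#' @return \code{geneIds}: locus id per transcript.
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname TranscriptSet-accessors
#' @export
setMethod("geneIds", "TranscriptSet",
          function(x) stats::setNames(x@geneId, transcriptIds(x)))

#' @return \code{classCodes}: assembler class code per transcript.
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("classCodes", function(x) standardGeneric("classCodes"))

#' @rdname TranscriptSet-accessors
#' @export
setMethod("classCodes", "TranscriptSet",
          function(x) stats::setNames(x@classCode, transcriptIds(x)))

#' @return \code{biotypes}: biotype label per transcript.
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("biotypes", function(x) standardGeneric("biotypes"))

#' @rdname TranscriptSet-accessors
#' @export
setMethod("biotypes", "TranscriptSet",
          function(x) stats::setNames(x@biotype, transcriptIds(x)))

#' @return \code{exons}: the underlying \link[GenomicRanges]{GRangesList}.
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))

#' @rdname TranscriptSet-accessors
#' @export
setMethod("exons", "TranscriptSet", function(x) x@exons)

#' @return \code{sequences}: the transcript sequences
#'   (\link[Biostrings]{DNAStringSet}) or \code{NULL}.
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname TranscriptSet-accessors
#' @export
setMethod("sequences", "TranscriptSet", function(x) x@sequence)

#' @return \code{txLengths}: summed exon length (nt) per transcript.
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("txLengths", function(x) standardGeneric("txLengths"))

#' @rdname TranscriptSet-accessors
#' @export
setMethod("txLengths", "TranscriptSet", function(x) {
  stats::setNames(vapply(GenomicRanges::width(x@exons), sum, numeric(1)),
                  transcriptIds(x))
})

#' @return \code{exonCounts}: number of exons per transcript.
#' @rdname TranscriptSet-accessors
#' @export
setGeneric("exonCounts", function(x) standardGeneric("exonCounts"))

#' @rdname TranscriptSet-accessors
#' @export
setMethod("exonCounts", "TranscriptSet",
          function(x) stats::setNames(lengths(x@exons), transcriptIds(x)))

#' Transcript spans
#'
#' One genomic range per transcript covering its first to last exon
#' (introns included), used for locus grouping, novelty overlap and cis
#' window scans.
#'
#' @param x A [TranscriptSet-class].
#' @return A \link[GenomicRanges]{GRanges} named by transcript id.
#' @export
setGeneric("txSpans", function(x) standardGeneric("txSpans"))

#' @rdname txSpans
#' @export
setMethod("txSpans", "TranscriptSet", function(x) {
  sp <- unlist(range(x@exons), use.names = TRUE)
  sp
})

#' @param i Index, logical vector or transcript ids.
#' @param j,...,drop Ignored.
#' @rdname TranscriptSet-accessors
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, transcriptIds(x))
  if (anyNA(i)) stop("unknown transcript id(s) in subset")
  idx <- seq_along(x@exons)[i]
  new("TranscriptSet",
      exons = x@exons[idx],
      geneId = x@geneId[idx],
      classCode = x@classCode[idx],
      biotype = x@biotype[idx],
      sequence = if (is.null(x@sequence)) NULL else x@sequence[idx])
})

#' @rdname TranscriptSet-accessors
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@exons))

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet with", length(object), "transcripts\n")
  if (length(object)) {
    cat("  loci:", length(unique(object@geneId)),
        "| class codes:", paste(names(table(object@classCode)), collapse = " "),
        "\n")
    cat("  exons per transcript:",
        paste(range(exonCounts(object)), collapse = "-"),
        "| lengths:", paste(range(txLengths(object)), collapse = "-"), "nt\n")
    cat("  sequences:", if (is.null(object@sequence)) "absent" else "present",
        "\n")
  }
})

#' Group and FPKM accessors
#'
#' @param x An [FPKMSet-class].
#' @return \code{fpkm}: the FPKM matrix; \code{sampleGroups}: the two-level
#'   group factor named by sample id.
#' @rdname FPKMSet-accessors
#' @export
setGeneric("fpkm", function(x) standardGeneric("fpkm"))

#' @rdname FPKMSet-accessors
#' @export
setMethod("fpkm", "FPKMSet",
          function(x) SummarizedExperiment::assay(x, "fpkm"))

#' @rdname FPKMSet-accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname FPKMSet-accessors
#' @export
setMethod("sampleGroups", "FPKMSet", function(x) {
  stats::setNames(SummarizedExperiment::colData(x)$group, colnames(x))
})

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:", object@nInput, "transcripts in,",
      if (length(object@survivors)) object@survivors[length(object@survivors)]
      else object@nInput, "retained\n")
  for (i in seq_along(object@stageNames))
    cat(sprintf("  %d. %-18s -> %d survivors\n",
                i, object@stageNames[i], object@survivors[i]))
})

#' Accessors for FilterReport
#'
#' @param x A [FilterReport-class].
#' @return \code{stageSurvivors}: named integer vector of survivors after
#'   each stage; \code{transcriptFates}: named character vector mapping each
#'   input transcript to the first stage that removed it, or
#'   \code{"retained"}.
#' @rdname FilterReport-accessors
#' @export
setGeneric("stageSurvivors", function(x) standardGeneric("stageSurvivors"))

#' @rdname FilterReport-accessors
#' @export
setMethod("stageSurvivors", "FilterReport",
          function(x) stats::setNames(x@survivors, x@stageNames))

#' @rdname FilterReport-accessors
#' @export
setGeneric("transcriptFates", function(x) standardGeneric("transcriptFates"))

#' @rdname FilterReport-accessors
#' @export
setMethod("transcriptFates", "FilterReport", function(x) x@fate)
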