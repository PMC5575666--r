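#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRangesList
NULL

setClassUnion("DNAStringSet_OR_NULL", c("DNAStringSet", "NULL"))

#' TranscriptSet: assembled transcript models
#'
#' Container for a set of assembled transcript models, each a chain of exons
#' on one chromosome and strand, carrying the assembler's class code (e.g.
#' \code{"u"} for intergenic), a locus (gene) id, an optional biotype label
#' used when the set represents a reference annotation, and optional
#' nucleotide sequences.
#'
#' @slot exons A \link[GenomicRanges]{GRangesList}, one element per
#'   transcript, named by transcript id. Exons within a transcript are
#'   non-overlapping, sorted by start, and share chromosome and strand.
#' @slot geneId Character vector of locus ids, parallel to \code{exons}.
#' @slot classCode Single-character assembler class codes (\code{"."} when
#'   unknown), parallel to \code{exons}.
#' @slot biotype One of \code{"protein_coding"}, \code{"known_lincRNA"},
#'   \code{"other"} per transcript; meaningful for annotation sets.
#' @slot sequence Optional \link[Biostrings]{DNAStringSet} whose element
#'   widths equal the transcript lengths, or \code{NULL}.
#'
#' @seealso [readGTF()], [writeGTF()], [groupLoci()], [txSpans()]
#' @export
setClass("TranscriptSet",
  slots = c(
    exons = "GRangesList",
    geneId = "character",
    classCode = "character",
    biotype = "character",
    sequence = "DNAStringSet_OR_NULL"
  )
)

.validTranscriptSet <- function(object) {
  msg <- character()
  n <- length(object@exons)
  ids <- names(object@exons)
  if (n > 0 && (is.null(ids) || anyNA(ids) || any(ids == "")))
    msg <- c(msg, "every transcript must be named by a transcript id")
  else if (anyDuplicated(ids))
    msg <- c(msg, "transcript ids must be unique")
  if (length(object@geneId) != n || length(object@classCode) != n ||
      length(object@biotype) != n)
    msg <- c(msg, "geneId, classCode and biotype must parallel the transcripts")
  if (n > 0) {
    if (any(lengths(object@exons) < 1L))
      msg <- c(msg, "each transcript needs at least one exon")
    nchrom <- lengths(unique(GenomicRanges::seqnames(object@exons)))
    nstr <- lengths(unique(GenomicRanges::strand(object@exons)))
    if (any(nchrom != 1L) || any(nstr != 1L))
      msg <- c(msg, "all exons of a transcript must share one chromosome and strand")
    starts <- GenomicRanges::start(object@exons)
    ends <- GenomicRanges::end(object@exons)
    unsorted <- any(vapply(starts, is.unsorted, logical(1)))
    if (unsorted) msg <- c(msg, "exons must be sorted by start")
    overl <- vapply(seq_len(n), function(i) {
      s <- starts[[i]]; e <- ends[[i]]
      length(s) > 1L && any(s[-1L] <= e[-length(e)])
    }, logical(1))
    if (any(overl)) msg <- c(msg, "exons within a transcript must not overlap")
  }
  if (!is.null(object@sequence)) {
    if (length(object@sequence) != n)
      msg <- c(msg, "sequence must have one entry per transcript")
    else if (any(Biostrings::width(object@sequence) != txLengths(object)))
      msg <- c(msg, "sequence widths must equal the summed exon lengths")
  }
  if (length(msg)) msg else TRUE
}
setValidity("TranscriptSet", .validTranscriptSet)

#' Construct a TranscriptSet
#'
#' @param exons Named \link[GenomicRanges]{GRangesList} of exons per
#'   transcript (1-based, closed intervals, the GRanges convention).
#' @param geneId Locus id per transcript (recycled if length 1).
#' @param classCode Assembler class code per transcript (default \code{"."}).
#' @param biotype Biotype label per transcript (default \code{"other"}).
#' @param sequence Optional \link[Biostrings]{DNAStringSet} of transcript
#'   sequences, in transcript order.
#' @return A [TranscriptSet-class] object.
#' @examples
#' ex <- GenomicRanges::GRangesList(
#'   t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), "+"))
#' TranscriptSet(ex, geneId = "g1", classCode = "u")
#' @export
TranscriptSet <- function(exons, geneId, classCode = ".", biotype = "other",
                          sequence = NULL) {
  n <- length(exons)
  new("TranscriptSet",
      exons = exons,
      geneId = rep_len(as.character(geneId), n),
      classCode = rep_len(as.character(classCode), n),
      biotype = rep_len(as.character(biotype), n),
      sequence = sequence)
}

#' FPKMSet: a two-group FPKM expression matrix
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} holding one assay,
#' \code{"fpkm"}, of non-negative finite FPKM values, with a \code{group}
#' column in \code{colData} assigning every sample to exactly one of two
#' groups (e.g. the two breeds of a two-group design). The first factor
#' level is the numerator of all fold changes downstream.
#'
#' @seealso [FPKMSet()], [readExpression()], [deTest()]
#' @export
#' @import SummarizedExperiment
setClass("FPKMSet", contains = "SummarizedExperiment")

.validFPKMSet <- function(object) {
  msg <- character()
  if (!"fpkm" %in% SummarizedExperiment::assayNames(object))
    return("assay 'fpkm' is required")
  v <- SummarizedExperiment::assay(object, "fpkm")
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "FPKM values must be finite and non-missing")
  else if (any(v < 0))
    msg <- c(msg, "FPKM values must be non-negative")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'group' column")
  else {
    g <- cd$group
    if (!is.factor(g) || nlevels(g) != 2L || anyNA(g))
      msg <- c(msg, "'group' must be a factor with exactly two levels and no NAs")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "feature ids must be unique")
  if (length(msg)) msg else TRUE
}
setValidity("FPKMSet", .validFPKMSet)

#' Construct an FPKMSet
#'
#' @param values Numeric matrix of FPKM, features x samples, with row and
#'   column names.
#' @param group Group label per sample: a named vector (names = sample ids)
#'   or a vector parallel to the columns. Coerced to a two-level factor;
#'   the order of \code{levels} (or first appearance) fixes the fold-change
#'   numerator.
#' @return An [FPKMSet-class].
#' @examples
#' m <- matrix(1:16 / 2, 4, 4,
#'             dimnames = list(paste0("f", 1:4), paste0("s", 1:4)))
#' FPKMSet(m, group = c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
#' @export
FPKMSet <- function(values, group) {
  values <- as.matrix(values)
  if (!is.null(names(group))) {
    miss <- setdiff(colnames(values), names(group))
    if (length(miss))
      stop("samples missing from the group assignment: ",
           paste(miss, collapse = ", "))
    group <- group[colnames(values)]
  }
  if (!is.factor(group)) group <- factor(group, levels = unique(group))
  group <- droplevels(group)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = values),
    colData = S4Vectors::DataFrame(group = group, row.names = colnames(values)))
  new("FPKMSet", se)
}

#' FilterReport: per-stage accounting of the identification cascade
#'
#' Records, for a run of the six-stage lincRNA identification cascade, the
#' ordered stage names, the number of surviving transcripts after each
#' stage, and per-transcript fate (the first stage that removed it, or
#' \code{"retained"}).
#'
#' @slot nInput Number of transcripts entering the cascade.
#' @slot stageNames Ordered character vector of stage names.
#' @slot survivors Integer vector, survivors after each stage.
#' @slot fate Named character vector: transcript id to removing stage or
#'   \code{"retained"}.
#' @seealso [runCascade()]
#' @export
setClass("FilterReport",
  slots = c(nInput = "integer", stageNames = "character",
            survivors = "integer", fate = "character"))

.validFilterReport <- function(object) {
  msg <- character()
  if (length(object@survivors) != length(object@stageNames))
    msg <- c(msg, "one survivor count per stage is required")
  if (is.unsorted(rev(c(object@nInput, object@survivors))))
    msg <- c(msg, "survivor counts must be non-increasing")
  nret <- sum(object@fate == "retained")
  k <- length(object@survivors)
  if (k > 0 && nret != object@survivors[k])
    msg <- c(msg, "final survivor count must equal the number of retained fates")
  bad <- setdiff(unique(object@fate), c("retained", object@stageNames))
  if (length(bad))
    msg <- c(msg, paste0("unknown fate label(s): ", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
}
setValidity("FilterReport", .validFilterReport)
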