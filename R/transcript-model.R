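#' @include AllClasses.R accessors.R
NULL

# Cheap structural scan so malformed records are reported with their line
# number before the real parser runs.
.scanGTF <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop("malformed GTF record at line ", i, ": expected 9 tab-separated ",
           "fields, found ", length(f))
    st <- suppressWarnings(as.integer(f[4]))
    en <- suppressWarnings(as.integer(f[5]))
    if (is.na(st) || is.na(en))
      stop("malformed GTF record at line ", i, ": non-numeric coordinates")
    if (en < st)
      stop("malformed GTF record at line ", i, ": end (", en,
           ") < start (", st, ")")
  }
  invisible(TRUE)
}

#' Read transcript models from a GTF file
#'
#' Reads exon features from a GTF file (1-based, closed coordinates, the
#' GTF convention) and assembles one transcript model per distinct
#' \code{transcript_id}. The assembler class code is taken from the
#' attribute named by \code{classCodeAttr} when present, else \code{"."}.
#'
#' @param path Path to a GTF file.
#' @param classCodeAttr Attribute carrying the assembler class code
#'   (default \code{"class_code"}).
#' @param biotypeAttr Attribute carrying a biotype label for annotation
#'   files (default \code{"gene_biotype"}); \code{"other"} when absent.
#' @return A [TranscriptSet-class].
#' @details Malformed records (wrong field count, non-numeric coordinates,
#'   end < start) abort with the offending line number; a transcript whose
#'   exons span several chromosomes aborts with the transcript id.
#' @seealso [writeGTF()]
#' @export
readGTF <- function(path, classCodeAttr = "class_code",
                    biotypeAttr = "gene_biotype") {
  .scanGTF(path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L)
    return(TranscriptSet(GRangesList(), character(0), character(0)))
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
    stop("every exon record must carry a transcript_id attribute")
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stop("every exon record must carry a gene_id attribute")
  cc <- if (classCodeAttr %in% colnames(mcols(gr)))
    as.character(mcols(gr)[[classCodeAttr]]) else rep(".", length(gr))
  cc[is.na(cc)] <- "."
  bt <- if (biotypeAttr %in% colnames(mcols(gr)))
    as.character(mcols(gr)[[biotypeAttr]]) else rep("other", length(gr))
  bt[is.na(bt)] <- "other"
  txid <- gr$transcript_id
  ord <- order(txid, GenomicRanges::start(gr))
  gr <- gr[ord]; txid <- txid[ord]; cc <- cc[ord]; bt <- bt[ord]
  first <- !duplicated(txid)
  nchrom <- rowsum(as.integer(!duplicated(paste(txid,
            as.character(GenomicRanges::seqnames(gr))))), txid)
  if (any(nchrom > 1L))
    stop("transcript(s) with exons on multiple chromosomes: ",
         paste(rownames(nchrom)[nchrom > 1L], collapse = ", "))
  core <- GRanges(GenomicRanges::seqnames(gr), IRanges::ranges(gr),
                  strand = GenomicRanges::strand(gr))
  grl <- S4Vectors::split(core, factor(txid, levels = unique(txid)))
  TranscriptSet(grl,
                geneId = gr$gene_id[first],
                classCode = cc[first],
                biotype = bt[first])
}

#' Write transcript models to a GTF file
#'
#' Emits one exon record per exon, 1-based closed coordinates, with
#' \code{transcript_id}, \code{gene_id} and \code{class_code} attributes,
#' ordered by (chromosome, start, transcript id) so output is deterministic.
#'
#' @param x A [TranscriptSet-class].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @seealso [readGTF()]
#' @export
writeGTF <- function(x, path) {
  if (length(x) == 0L) {
    writeLines("##gff-version 2", path)
    return(invisible(path))
  }
  grl <- exons(x)
  flat <- unlist(grl, use.names = FALSE)
  n <- lengths(grl)
  nr <- length(flat)
  mcols(flat)$source <- rep("lincPipe", nr)
  mcols(flat)$type <- rep("exon", nr)
  mcols(flat)$transcript_id <- rep(transcriptIds(x), n)
  mcols(flat)$gene_id <- rep(unname(geneIds(x)), n)
  mcols(flat)$class_code <- rep(unname(classCodes(x)), n)
  mcols(flat)$gene_biotype <- rep(unname(biotypes(x)), n)
  ord <- order(as.character(GenomicRanges::seqnames(flat)),
               GenomicRanges::start(flat), mcols(flat)$transcript_id)
  rtracklayer::export(flat[ord], path, format = "gtf")
  invisible(path)
}

#' Group transcripts into loci
#'
#' Single-linkage grouping of transcripts whose spans (first to last exon)
#' overlap on the same chromosome and strand. Strand-aware: overlap on
#' opposite strands does not merge loci; \code{*} overlaps both strands.
#' Touching-but-not-overlapping spans stay separate.
#'
#' @param x A [TranscriptSet-class].
#' @return Named list, locus id (\code{"LOC000001"}, ...) to character
#'   vector of member transcript ids; every transcript appears in exactly
#'   one locus.
#' @export
groupLoci <- function(x) {
  if (length(x) == 0L) return(stats::setNames(list(), character(0)))
  sp <- txSpans(x)
  merged <- GenomicRanges::reduce(sp, min.gapwidth = 0L, ignore.strand = FALSE)
  hit <- GenomicRanges::findOverlaps(sp, merged, ignore.strand = FALSE)
  stopifnot(length(hit) == length(sp))
  grp <- S4Vectors::subjectHits(hit)
  ids <- split(names(sp), grp)
  names(ids) <- sprintf("LOC%06d", seq_along(ids))
  ids
}

#' Read a two-group FPKM matrix from TSV
#'
#' Expects a tab-separated file whose header row names the samples and whose
#' first column holds feature ids.
#'
#' @param path Path to the TSV.
#' @param group Group assignment: a named vector (sample id to group label)
#'   or a two-column TSV path (sample, group).
#' @return An [FPKMSet-class].
#' @details Duplicate feature ids, negative or non-numeric values, and
#'   samples absent from the group assignment are errors.
#' @seealso [writeExpression()], [FPKMSet()]
#' @export
readExpression <- function(path, group) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("expression values must be numeric")
  if (any(m < 0)) stop("negative FPKM value(s) found")
  rownames(m) <- ids
  if (is.character(group) && length(group) == 1L && file.exists(group)) {
    gt <- utils::read.delim(group, header = FALSE, stringsAsFactors = FALSE)
    group <- stats::setNames(gt[[2L]], gt[[1L]])
  }
  FPKMSet(m, group)
}

#' Write an FPKM matrix to TSV
#'
#' @param x An [FPKMSet-class].
#' @param path Output TSV path.
#' @param groupPath Optional path for a two-column (sample, group) TSV.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(x, path, groupPath = NULL) {
  m <- fpkm(x)
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groupPath)) {
    g <- sampleGroups(x)
    utils::write.table(data.frame(names(g), as.character(g)), groupPath,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
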