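#' @include AllClasses.R accessors.R
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement translate
#'   subseq width
NULL

.frameCodons <- function(seq, frame) {
  # codon strings of one forward frame (1, 2 or 3) of a character sequence
  L <- nchar(seq)
  usable <- L - frame + 1L
  ncod <- usable %/% 3L
  if (ncod <= 0L) return(character(0))
  starts <- frame + 3L * (seq_len(ncod) - 1L)
  substring(seq, starts, starts + 2L)
}

.translateFrame <- function(seq, frame) {
  codons <- .frameCodons(seq, frame)
  if (length(codons) == 0L) return("")
  pep <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(codons, collapse = "")),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
  aa <- strsplit(pep, "", fixed = TRUE)[[1L]]
  aa[grepl("N", codons, fixed = TRUE)] <- "X"
  paste(aa, collapse = "")
}

#' Translate a nucleotide sequence in all six frames
#'
#' Standard genetic code; stop codons become \code{"*"}; any codon
#' containing \code{N} becomes \code{"X"} (even when the ambiguity would
#' resolve); trailing 1-2 nt of a frame are ignored.
#'
#' @param seq Nucleotide string over \code{A,C,G,T,N} (case-insensitive),
#'   length >= 1.
#' @return Named character vector of six peptides: frames \code{F1,F2,F3}
#'   of the sequence and \code{R1,R2,R3} of its reverse complement.
#' @examples
#' sixFrameTranslate("ATGGCC")["F1"]  # "MA"
#' @export
sixFrameTranslate <- function(seq) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
    stop("a single non-empty nucleotide sequence is required")
  if (grepl("[^ACGTN]", seq)) stop("sequence contains letters outside ACGTN")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  out <- c(
    F1 = .translateFrame(seq, 1L), F2 = .translateFrame(seq, 2L),
    F3 = .translateFrame(seq, 3L),
    R1 = .translateFrame(rc, 1L), R2 = .translateFrame(rc, 2L),
    R3 = .translateFrame(rc, 3L))
  out
}

.STOPS <- c("TAA", "TAG", "TGA")

# longest ATG..stop ORF (nt, stop included) within one frame's codon vector;
# codons containing N break any open reading
.frameOrf <- function(codons) {
  best <- 0L
  open <- NA_integer_
  for (i in seq_along(codons)) {
    cod <- codons[i]
    if (grepl("N", cod, fixed = TRUE)) { open <- NA_integer_; next }
    if (cod %in% .STOPS) {
      if (!is.na(open)) best <- max(best, 3L * (i - open + 1L))
      open <- NA_integer_
    } else if (is.na(open) && cod == "ATG") {
      open <- i
    }
  }
  best
}

.strandOrf <- function(seq) {
  max(vapply(1:3, function(f) .frameOrf(.frameCodons(seq, f)), integer(1)))
}

#' Longest open reading frame over both strands
#'
#' Length in nucleotides (stop codon included) of the longest ATG-to-stop
#' open reading frame across all six frames; 0 when no complete ORF exists.
#' Codons containing \code{N} never extend an ORF.
#'
#' @param seq Nucleotide string over \code{A,C,G,T,N}.
#' @return Integer ORF length in nt; a multiple of 3 when positive.
#' @examples
#' longestOrfLength("ATGAAATAA")  # 9
#' @export
longestOrfLength <- function(seq) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
    stop("a single non-empty nucleotide sequence is required")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  max(.strandOrf(seq), .strandOrf(rc))
}

#' Per-strand coding-potential scores
#'
#' Assigns every transcript a forward- and reverse-strand coding score with
#' the sign convention of the Coding Potential Calculator: score > 0 flags
#' the transcript as coding. Two modes:
#' \describe{
#'   \item{\code{heuristic}}{score = (longest ATG-to-stop ORF on that
#'     strand, nt) / (transcript length, nt) - \code{theta}. A transcript
#'     devoting more than \code{theta} of its length to a single ORF is
#'     flagged coding.}
#'   \item{\code{external}}{scores are taken verbatim from a table computed
#'     by an external tool (e.g. CPC/CPAT), columns
#'     \code{transcript_id, score_forward, score_reverse}.}
#' }
#'
#' @param x A [TranscriptSet-class]; sequences are required in heuristic
#'   mode.
#' @param mode \code{"heuristic"} or \code{"external"}.
#' @param external Data frame of external scores (external mode).
#' @param theta Heuristic ORF-fraction threshold (default 0.3).
#' @return Data frame with columns \code{transcript_id},
#'   \code{score_forward}, \code{score_reverse}.
#' @seealso [longestOrfLength()], [runCascade()]
#' @export
codingScores <- function(x, mode = c("heuristic", "external"),
                         external = NULL, theta = 0.3) {
  mode <- match.arg(mode)
  ids <- transcriptIds(x)
  if (mode == "external") {
    if (is.null(external)) stop("external mode requires a score table")
    hit <- match(ids, external$transcript_id)
    if (anyNA(hit))
      stop("no external coding score for transcript(s): ",
           paste(ids[is.na(hit)], collapse = ", "))
    return(data.frame(transcript_id = ids,
                      score_forward = external$score_forward[hit],
                      score_reverse = external$score_reverse[hit]))
  }
  seqs <- sequences(x)
  if (is.null(seqs))
    stop("heuristic coding scores need sequences; missing for all transcripts")
  lens <- txLengths(x)
  sf <- sr <- numeric(length(ids))
  for (i in seq_along(ids)) {
    s <- toupper(as.character(seqs[[i]]))
    if (nchar(s) == 0L)
      stop("missing sequence for transcript ", ids[i])
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    sf[i] <- .strandOrf(s) / lens[i] - theta
    sr[i] <- .strandOrf(rc) / lens[i] - theta
  }
  data.frame(transcript_id = ids, score_forward = sf, score_reverse = sr)
}

#' Remove candidates with significant alignment hits
#'
#' Drops every candidate with at least one hit below the E-value threshold
#' (strict \code{<}); candidates absent from the table, or whose hits all
#' sit at or above the threshold, survive.
#'
#' @param candidates Character vector of transcript ids.
#' @param hits Data frame with columns \code{query_id}, \code{evalue}
#'   (see [readHitTable()]); may have zero rows.
#' @param evalue E-value cutoff (default \code{1e-5}).
#' @return Character vector of surviving candidates, input order preserved.
#' @export
hitFilter <- function(candidates, hits, evalue = 1e-5) {
  stopifnot(evalue > 0)
  if (is.null(hits) || nrow(hits) == 0L) return(candidates)
  if (any(hits$evalue < 0)) stop("E-values must be non-negative")
  flagged <- unique(hits$query_id[hits$evalue < evalue])
  candidates[!candidates %in% flagged]
}

#' Read a tabular alignment hit table
#'
#' Accepts either a two-column TSV (\code{query_id}, \code{evalue}) or the
#' standard 12-column tabular alignment format, from which columns 1 (query)
#' and 11 (E-value) are taken.
#'
#' @param path Path to the table; no header.
#' @param source Label recorded on the result (\code{"domain"} or
#'   \code{"homology"}).
#' @return Data frame with columns \code{query_id}, \code{evalue} and the
#'   \code{source} attribute set.
#' @export
readHitTable <- function(path, source = c("domain", "homology")) {
  source <- match.arg(source)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) >= 12L) {
    out <- data.frame(query_id = as.character(tab[[1L]]),
                      evalue = as.numeric(tab[[11L]]))
  } else if (ncol(tab) >= 2L) {
    out <- data.frame(query_id = as.character(tab[[1L]]),
                      evalue = as.numeric(tab[[2L]]))
  } else stop("hit table needs 2 or 12 columns, found ", ncol(tab))
  if (anyNA(out$evalue) || any(out$evalue < 0))
    stop("E-values must be non-negative numbers")
  attr(out, "source") <- source
  out
}

#' Read an external coding-score table
#'
#' @param path TSV with header columns \code{transcript_id},
#'   \code{score_forward}, \code{score_reverse}.
#' @return Data frame suitable for [codingScores()] external mode.
#' @export
readCodingScores <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "score_forward", "score_reverse")
  if (!all(need %in% colnames(tab)))
    stop("coding-score table must have columns: ", paste(need, collapse = ", "))
  tab[need]
}
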