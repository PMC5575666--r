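# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and, where the implementation delegates to a library
# routine, avoid that routine too).

# -- genetic code, written out by hand ----------------------------------------
.ORACLE_CODONS <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracleRevComp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]), collapse = "")
}

oracleTranslateFrame <- function(seq, frame) {
  L <- nchar(seq)
  out <- character(0)
  i <- frame
  while (i + 2 <= L) {
    cod <- substr(seq, i, i + 2)
    out <- c(out, if (grepl("N", cod)) "X" else unname(.ORACLE_CODONS[cod]))
    i <- i + 3
  }
  paste(out, collapse = "")
}

oracleSixFrame <- function(seq) {
  rc <- oracleRevComp(seq)
  c(F1 = oracleTranslateFrame(seq, 1), F2 = oracleTranslateFrame(seq, 2),
    F3 = oracleTranslateFrame(seq, 3),
    R1 = oracleTranslateFrame(rc, 1), R2 = oracleTranslateFrame(rc, 2),
    R3 = oracleTranslateFrame(rc, 3))
}

# exhaustive ORF scan: every frame, every ATG, walk to the first clean stop
oracleOrf <- function(seq) {
  scan1 <- function(s) {
    best <- 0
    L <- nchar(s)
    for (frame in 1:3) {
      starts <- seq(frame, L - 2, by = 3)
      if (length(starts) == 0) next
      codons <- substring(s, starts, starts + 2)
      for (a in which(codons == "ATG")) {
        for (b in a:length(codons)) {
          cod <- codons[b]
          if (grepl("N", cod)) break
          if (cod %in% c("TAA", "TAG", "TGA")) {
            best <- max(best, 3 * (b - a + 1))
            break
          }
        }
      }
    }
    best
  }
  max(scan1(seq), scan1(oracleRevComp(seq)))
}

# textbook BH step-up
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  pmin(q, 1)
}

# single-linkage components by union-find over pairwise span overlap
oracleLoci <- function(spans) {
  # spans: data.frame(id, chrom, strand, start, end), 1-based closed
  n <- nrow(spans)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (spans$chrom[i] != spans$chrom[j]) next
    si <- spans$strand[i]; sj <- spans$strand[j]
    if (si != "*" && sj != "*" && si != sj) next
    if (spans$start[i] <= spans$end[j] && spans$start[j] <= spans$end[i])
      parent[find(i)] <- find(j)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(lapply(split(spans$id, roots), function(x) sort(x)))
}

# all-pairs cis scan on plain coordinates
oracleCis <- function(lincs, genes, window) {
  # both: data.frame(id, chrom, start, end), 1-based closed
  out <- NULL
  for (i in seq_len(nrow(lincs))) for (j in seq_len(nrow(genes))) {
    if (lincs$chrom[i] != genes$chrom[j]) next
    gap <- max(lincs$start[i], genes$start[j]) -
      min(lincs$end[i], genes$end[j]) - 1
    gap <- max(0, gap)
    if (gap < window)
      out <- rbind(out, data.frame(lincRNA_id = lincs$id[i],
                                   gene_id = genes$id[j], distance = gap))
  }
  if (is.null(out))
    data.frame(lincRNA_id = character(0), gene_id = character(0),
               distance = numeric(0))
  else out
}

# from-scratch covariance formula + t CDF
oraclePearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  r <- sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# hypergeometric upper tail by explicit enumeration of the point masses
oracleHyperTail <- function(k, K, n, N) {
  js <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# -- random fixture builders --------------------------------------------------

randomTranscriptSet <- function(n, chroms = c("chr1", "chr2"),
                                classCodes = c("u", "o", "j", ".")) {
  tabs <- lapply(seq_len(n), function(i) {
    k <- sample(1:4, 1)
    chrom <- sample(chroms, 1)
    strand <- sample(c("+", "-"), 1)
    start <- sample(1:500000, 1)
    w <- sample(50:400, k, replace = TRUE)
    gaps <- if (k > 1) sample(100:2000, k - 1, replace = TRUE) else integer(0)
    starts <- start + cumsum(c(0, w[-k] + gaps))
    data.frame(tx = sprintf("T%03d", i), chrom = chrom, strand = strand,
               start = starts, width = w)
  })
  df <- do.call(rbind, tabs)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, width = df$width),
                               strand = df$strand)
  grl <- S4Vectors::split(gr, factor(df$tx, levels = unique(df$tx)))
  TranscriptSet(grl,
                geneId = sprintf("G%03d", sample(seq_len(max(1, n %/% 2)),
                                                 n, replace = TRUE)),
                classCode = sample(classCodes, n, replace = TRUE))
}

randomSeq <- function(L) paste(sample(c("A", "C", "G", "T", "N"), L,
                                      replace = TRUE,
                                      prob = c(.24, .24, .24, .24, .04)),
                               collapse = "")

# one single-exon transcript per row of df (id, chrom, strand, start, end)
.mkTs <- function(df, biotype = "other") {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  TranscriptSet(S4Vectors::split(gr, factor(df$id, unique(df$id))),
                geneId = if (!is.null(df$gene)) df$gene else df$id,
                biotype = biotype)
}

# span table of a TranscriptSet in plain columns, for the oracles
spanTable <- function(ts) {
  sp <- txSpans(ts)
  data.frame(id = names(sp),
             chrom = as.character(GenomeInfoDb::seqnames(sp)),
             strand = as.character(BiocGenerics::strand(sp)),
             start = BiocGenerics::start(sp),
             end = BiocGenerics::end(sp))
}

tallyFile <- function() {
  system.file("extdata", "del_deptg_tallies.tsv", package = "lincPipe")
}
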