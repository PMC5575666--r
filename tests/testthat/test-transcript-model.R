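test_that("GTF coordinates survive reading and exon grouping works", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsim\texon\t101\t200\t.\t+\t.\ttranscript_id "t1"; gene_id "g1"; class_code "u";',
    'chr1\tsim\texon\t501\t700\t.\t+\t.\ttranscript_id "t1"; gene_id "g1"; class_code "u";',
    'chr2\tsim\texon\t11\t40\t.\t-\t.\ttranscript_id "t2"; gene_id "g2";'),
    gtf)
  ts <- readGTF(gtf)
  expect_equal(length(ts), 2L)
  expect_equal(unname(exonCounts(ts)["t1"]), 2L)
  expect_equal(unname(txLengths(ts)["t1"]), 100 + 200)
  expect_equal(unname(classCodes(ts)), c("u", "."))
  ex <- exons(ts)[["t1"]]
  expect_equal(BiocGenerics::start(ex), c(101, 501))
  expect_equal(BiocGenerics::end(ex), c(200, 700))
})

test_that("malformed GTF records are rejected with their line number", {
  bad <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsim\texon\t101\t200\t.\t+\t.\ttranscript_id "t1"; gene_id "g1";',
    "chr1\tonly\tthree"), bad)
  expect_error(readGTF(bad), "line 2")

  rev <- tempfile(fileext = ".gtf")
  writeLines(
    'chr1\tsim\texon\t300\t200\t.\t+\t.\ttranscript_id "t1"; gene_id "g1";',
    rev)
  expect_error(readGTF(rev), "end.*start|line 1")

  split <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsim\texon\t101\t200\t.\t+\t.\ttranscript_id "t1"; gene_id "g1";',
    'chr2\tsim\texon\t101\t200\t.\t+\t.\ttranscript_id "t1"; gene_id "g1";'),
    split)
  expect_error(readGTF(split), "multiple chromosomes")
})

test_that("write -> read round trip preserves every transcript field", {
  set.seed(42)
  ts <- randomTranscriptSet(50)
  path <- tempfile(fileext = ".gtf")
  writeGTF(ts, path)
  back <- readGTF(path)
  expect_setequal(transcriptIds(back), transcriptIds(ts))
  idx <- match(transcriptIds(ts), transcriptIds(back))
  expect_equal(unname(geneIds(back))[idx], unname(geneIds(ts)))
  expect_equal(unname(classCodes(back))[idx], unname(classCodes(ts)))
  for (id in transcriptIds(ts)) {
    a <- exons(ts)[[id]]; b <- exons(back)[[id]]
    expect_equal(BiocGenerics::start(a), BiocGenerics::start(b))
    expect_equal(BiocGenerics::end(a), BiocGenerics::end(b))
    expect_equal(as.character(GenomeInfoDb::seqnames(a)),
                 as.character(GenomeInfoDb::seqnames(b)))
    expect_equal(as.character(BiocGenerics::strand(a)),
                 as.character(BiocGenerics::strand(b)))
  }
})

test_that("writing an empty transcript set yields a readable empty file", {
  ts <- TranscriptSet(GenomicRanges::GRangesList(), character(0),
                      character(0))
  path <- tempfile(fileext = ".gtf")
  expect_silent(writeGTF(ts, path))
  expect_equal(length(readGTF(path)), 0L)
})

test_that("locus grouping is single-linkage, strand-aware, and a partition", {
  mk <- function(id, chrom, strand, start, end) {
    data.frame(tx = id, chrom = chrom, strand = strand, start = start,
               width = end - start + 1)
  }
  df <- rbind(mk("a", "chr1", "+", 100, 500),
              mk("b", "chr1", "+", 400, 900),    # overlaps a
              mk("c", "chr1", "-", 400, 900),    # opposite strand
              mk("d", "chr2", "+", 100, 500),    # other chromosome
              mk("e", "chr1", "+", 901, 1000))   # touches b, no overlap
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, width = df$width),
                               strand = df$strand)
  ts <- TranscriptSet(S4Vectors::split(gr, factor(df$tx, unique(df$tx))),
                      geneId = "g")
  loci <- groupLoci(ts)
  part <- unname(lapply(loci, sort))
  expect_setequal(unlist(part), c("a", "b", "c", "d", "e"))
  expect_equal(sum(lengths(part)), 5L)  # partition, no duplicates
  expect_true(list(c("a", "b")) %in% part)
  expect_true(all(c(list("c"), list("d"), list("e")) %in% part))
})

test_that("locus partition equals brute-force union-find on random sets", {
  for (seed in 1:5) {
    set.seed(seed)
    ts <- randomTranscriptSet(20, chroms = c("chr1", "chr2"))
    got <- sort(vapply(groupLoci(ts), function(x) paste(sort(x),
                                                        collapse = ","),
                       character(1)))
    want <- sort(vapply(oracleLoci(spanTable(ts)),
                        paste, character(1), collapse = ","))
    expect_equal(unname(got), unname(want))
  }
})

test_that("expression TSV round trip is exact and errors are loud", {
  set.seed(7)
  m <- matrix(round(rlnorm(600, 2, 1), 4), 100, 6,
              dimnames = list(sprintf("f%03d", 1:100), sprintf("s%d", 1:6)))
  g <- setNames(rep(c("YY", "WH"), each = 3), colnames(m))
  x <- FPKMSet(m, g)
  path <- tempfile(fileext = ".tsv"); gpath <- tempfile(fileext = ".tsv")
  writeExpression(x, path, gpath)
  back <- readExpression(path, gpath)
  expect_identical(fpkm(back), m)
  expect_equal(as.character(sampleGroups(back)), as.character(g))

  neg <- tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2\ts3\ts4", "f1\t1\t-1\t2\t3"), neg)
  expect_error(readExpression(neg, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")),
               "negative")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2\ts3\ts4", "f1\t1\t1\t1\t1",
               "f1\t2\t2\t2\t2"), dup)
  expect_error(readExpression(dup, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")),
               "duplicate")

  expect_error(readExpression(path, c(s1 = "A", s2 = "B")), "missing")
})

test_that("transcript length sums exon lengths", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 100), c(10, 149)),
                               strand = "+")
  ts <- TranscriptSet(S4Vectors::split(gr, factor(c("t1", "t1"))), "g1")
  expect_equal(unname(txLengths(ts)), 10 + 50)
})
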