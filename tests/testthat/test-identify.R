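.miniCascadeFixture <- function() {
  # five hand-built 'u' candidates plus one overlapping-class transcript
  tabs <- list(
    data.frame(tx = "long1exon", chrom = "chr1", strand = "+",
               start = 1000, width = 1500),
    data.frame(tx = "ok200", chrom = "chr1", strand = "+",
               start = c(10000, 10400), width = c(100, 100)),
    data.frame(tx = "short", chrom = "chr1", strand = "+",
               start = c(20000, 20400), width = c(90, 90)),
    data.frame(tx = "kept", chrom = "chr1", strand = "+",
               start = c(30000, 30500), width = c(150, 150)),
    data.frame(tx = "overlapClass", chrom = "chr1", strand = "+",
               start = 40000, width = 900))
  df <- do.call(rbind, tabs)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, width = df$width),
                               strand = df$strand)
  grl <- S4Vectors::split(gr, factor(df$tx, unique(df$tx)))
  lens <- vapply(as.list(GenomicRanges::width(grl)), sum, numeric(1))
  # ORF-free filler so nothing trips the coding-potential stage
  big <- strrep("GGA", ceiling(max(lens) / 3))
  seqs <- Biostrings::DNAStringSet(setNames(
    vapply(lens, function(L) substr(big, 1, L), ""), names(grl)))
  ts <- TranscriptSet(grl, geneId = paste0(names(grl), ".loc"),
                      classCode = c("u", "u", "u", "u", "o"),
                      sequence = seqs)
  m <- matrix(5, length(grl), 4,
              dimnames = list(names(grl), c("a1", "a2", "b1", "b2")))
  expr <- FPKMSet(m, setNames(c("A", "A", "B", "B"), colnames(m)))
  list(ts = ts, expr = expr)
}

test_that("stage boundaries follow the printed wording", {
  fx <- .miniCascadeFixture()
  res <- runCascade(fx$ts, fx$expr)
  fate <- transcriptFates(res$report)
  # a 1500-bp single-exon intergenic transcript dies at the size stage
  expect_equal(unname(fate["long1exon"]), "size")
  # exactly 200 bp with 2 exons passes (only strictly shorter is removed)
  expect_equal(unname(fate["ok200"]), "retained")
  expect_equal(unname(fate["short"]), "size")
  expect_equal(unname(fate["overlapClass"]), "intergenic_class")
  expect_equal(unname(fate["kept"]), "retained")
})

test_that("expression floor keeps a transcript with one sample at 0.5", {
  fx <- .miniCascadeFixture()
  m <- fpkm(fx$expr)
  m["kept", ] <- c(0.5, 0.1, 0.2, 0.3)   # boundary: exactly 0.5 once
  m["ok200", ] <- c(0.49, 0.4, 0.3, 0.2) # below floor everywhere
  expr <- FPKMSet(m, sampleGroups(fx$expr))
  fate <- transcriptFates(runCascade(fx$ts, expr)$report)
  expect_equal(unname(fate["kept"]), "retained")
  expect_equal(unname(fate["ok200"]), "expression")
})

test_that("cascade recovers every planted fate and is internally consistent", {
  sim <- simulateStudy(seed = 5)
  res <- runCascade(sim$candidates, sim$expr, domainHits = sim$domainHits,
                    homologyHits = sim$homologyHits)
  fate <- transcriptFates(res$report)
  expect_identical(fate, sim$truth$fate[names(fate)])
  surv <- stageSurvivors(res$report)
  expect_true(all(diff(surv) <= 0))
  expect_equal(unname(surv[length(surv)]), length(res$lincRNAs))

  # every retained transcript satisfies all six predicates post hoc
  kept <- res$lincRNAs
  expect_true(all(classCodes(kept) == "u"))
  expect_true(all(exonCounts(kept) >= 2 & txLengths(kept) >= 200))
  sc <- codingScores(kept)
  expect_true(all(sc$score_forward <= 0 & sc$score_reverse <= 0))
  expect_true(all(hitFilter(transcriptIds(kept), sim$domainHits) ==
                    transcriptIds(kept)))
  expect_true(all(hitFilter(transcriptIds(kept), sim$homologyHits) ==
                    transcriptIds(kept)))
  expect_true(all(rowSums(fpkm(sim$expr)[transcriptIds(kept), ] >= 0.5) > 0))

  # external scores give the same outcome as the sequence heuristic here
  res2 <- runCascade(sim$candidates, sim$expr,
                     coding = sim$codingScoreTable,
                     domainHits = sim$domainHits,
                     homologyHits = sim$homologyHits)
  expect_identical(transcriptFates(res2$report), fate)
})

test_that("cascade fails loudly on missing expression rows", {
  fx <- .miniCascadeFixture()
  m <- fpkm(fx$expr)[-4, ]  # drop "kept"
  expr <- FPKMSet(m, sampleGroups(fx$expr))
  expect_error(runCascade(fx$ts, expr), "kept")
})

test_that("novelty is any-overlap based, with a 1-bp boundary", {
  lin <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(1000, 5000), width = 500),
                                strand = "+")
  lincs <- TranscriptSet(S4Vectors::split(lin, factor(c("L1", "L2"),
                                                      c("L1", "L2"))), "g")
  # annotation touches L1's last base only; far from L2
  ann <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1499, width = 300),
                                strand = "-")
  known <- TranscriptSet(S4Vectors::split(ann, "K1"), "kg",
                         biotype = "known_lincRNA")
  cls <- classifyNovelty(lincs, known)
  expect_equal(as.character(cls[["L1"]]), "known_overlap")
  expect_equal(as.character(cls[["L2"]]), "novel")
})

test_that("novelty classification matches the generator's planted flags", {
  sim <- simulateStudy(seed = 8)
  lincs <- sim$candidates[sim$truth$retained]
  cls <- classifyNovelty(lincs, sim$annotation)
  expect_identical(as.character(cls), unname(sim$truth$novelty[names(cls)]))
  expect_equal(sum(table(cls)), length(lincs))  # a partition
})

test_that("characterization arithmetic and determinism", {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(1, 500), width = c(100, 200)),
                               strand = "+")
  one <- TranscriptSet(S4Vectors::split(gr, factor(c("t", "t"))), "g")
  m <- matrix(2, 1, 4, dimnames = list("t", c("a1", "a2", "b1", "b2")))
  expr <- FPKMSet(m, setNames(c("A", "A", "B", "B"), colnames(m)))
  ch <- characterize(one, one, one, expr)
  expect_equal(ch$summary$mean_tx_length, rep(300, 3))
  expect_equal(ch$summary$mean_exon_length, rep(150, 3))
  expect_equal(ch$summary$mean_exon_number, rep(2, 3))
  ch2 <- characterize(one, one, one, expr)
  expect_identical(ch, ch2)
  expect_error(characterize(one[0], one, one, expr), "non-empty")
})

test_that("class means are recovered within three standard errors at n=500", {
  cfg <- simConfig(nRetained = 500, nPerFate = 2, nKnownLincs = 400)
  sim <- simulateStudy(cfg, seed = 17)
  lincs <- sim$candidates[sim$truth$retained]
  # exclude the copies planted onto candidates for the novelty truth: they
  # are positional artefacts, not draws from the known-lincRNA structure
  known <- sim$annotation[which(biotypes(sim$annotation) == "known_lincRNA" &
                                  !grepl("^KLOV", transcriptIds(sim$annotation)))]
  coding <- sim$annotation[which(biotypes(sim$annotation) == "protein_coding")]
  ch <- characterize(lincs, known, coding, sim$expr)
  sm <- ch$summary
  checkClass <- function(cls, set, meanLen, meanExons) {
    i <- match(cls, sm$class)
    L <- unname(txLengths(set)); k <- unname(exonCounts(set))
    n <- length(set)
    seLen <- sd(L) / sqrt(n)
    seEx <- sd(k) / sqrt(n)
    expect_lt(abs(sm$mean_tx_length[i] - meanLen), 3 * seLen + 1e-9)
    expect_lt(abs(sm$mean_exon_number[i] - meanExons), 3 * seEx + 1e-9)
    # pooled exon length is the ratio sum(L)/sum(k); ratio-estimator SE
    R <- meanLen / meanExons
    seR <- sd(L - R * k) / (sqrt(n) * mean(k))
    expect_lt(abs(sm$mean_exon_length[i] - R), 3 * seR + 1e-9)
  }
  checkClass("novel_lincRNA", lincs, 1226, 2.6)
  checkClass("known_lincRNA", known, 1362, 2.8)
  checkClass("protein_coding", coding, 1983, 8.7)
  # lincRNAs are expressed below coding genes in both groups
  ex <- ch$expression
  for (g in unique(ex$group))
    expect_lt(ex$mean_fpkm[ex$class == "lincRNA" & ex$group == g],
              ex$mean_fpkm[ex$class == "protein_coding" & ex$group == g])
})
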