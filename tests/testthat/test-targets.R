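test_that("cis window is strict and symmetric around the lincRNA", {
  lincs <- .mkTs(data.frame(id = "L1", chrom = "chr1", strand = "+",
                            start = 1001, end = 2000))
  genes <- .mkTs(data.frame(
    id = c("gA.t1", "gB.t1", "gC.t1", "gD.t1"),
    gene = c("gA", "gB", "gC", "gD"),
    chrom = "chr1", strand = c("+", "-", "+", "+"),
    start = c(5001, 12001, 200101, 1), # gA 3000 away, gB exactly 10000 away
    end = c(6000, 13000, 200200, 400)),
    biotype = "protein_coding")
  ed <- cisTargets(lincs, genes, window = 10000)
  expect_setequal(ed$gene_id, c("gA", "gD"))  # upstream gD counted too
  expect_equal(ed$distance[ed$gene_id == "gA"], 3000L)
  expect_equal(ed$distance[ed$gene_id == "gD"], 600L)
  # gap exactly 10,000 is excluded (strict <)
  expect_false("gB" %in% ed$gene_id)
})

test_that("cis edges equal an all-pairs brute-force scan", {
  set.seed(31)
  for (rep in 1:5) {
    nl <- 20; ng <- 20
    ldf <- data.frame(id = sprintf("L%02d", 1:nl),
                      chrom = sample(c("chr1", "chr2"), nl, TRUE),
                      strand = sample(c("+", "-"), nl, TRUE),
                      start = sample(1:200000, nl))
    ldf$end <- ldf$start + sample(500:3000, nl, TRUE)
    gdf <- data.frame(id = sprintf("G%02d.t1", 1:ng),
                      gene = sprintf("G%02d", 1:ng),
                      chrom = sample(c("chr1", "chr2"), ng, TRUE),
                      strand = sample(c("+", "-"), ng, TRUE),
                      start = sample(1:200000, ng))
    gdf$end <- gdf$start + sample(500:3000, ng, TRUE)
    got <- cisTargets(.mkTs(ldf), .mkTs(gdf, biotype = "protein_coding"),
                      window = 10000)
    want <- oracleCis(
      data.frame(id = ldf$id, chrom = ldf$chrom, start = ldf$start,
                 end = ldf$end),
      data.frame(id = gdf$gene, chrom = gdf$chrom, start = gdf$start,
                 end = gdf$end), 10000)
    key <- function(d) sort(paste(d$lincRNA_id, d$gene_id, d$distance))
    expect_equal(key(got), key(want))
  }
})

test_that("pearson correlation and p match a from-scratch evaluation", {
  expect_equal(unname(pearsonR(c(1, 2, 3), c(2, 4, 6))["r"]), 1)
  expect_equal(unname(pearsonR(c(1, 2, 3), c(3, 2, 1))["r"]), -1)
  expect_true(all(is.na(pearsonR(c(1, 1, 1), c(1, 2, 3)))))
  set.seed(32)
  for (i in 1:200) {
    x <- rnorm(6); y <- rnorm(6)
    expect_equal(pearsonR(x, y), oraclePearson(x, y), tolerance = 1e-12)
  }
})

test_that("trans screen keeps exact relationships and drops undetectable", {
  m <- rbind(L1 = c(1, 2, 3, 4, 5, 6),
             G1 = c(2, 4, 6, 8, 10, 12),     # y = 2x, r = 1
             G2 = c(5, 0, 5, 5, 5, 5),       # one zero sample
             G3 = c(9, 7, 5, 8, 6, 4))
  colnames(m) <- paste0("s", 1:6)
  x <- FPKMSet(m, setNames(rep(c("A", "B"), 3), colnames(m)))
  ed <- transTargets(x, "L1", c("G1", "G2", "G3"))
  expect_equal(ed$gene_id, "G1")
  expect_equal(ed$r, 1)
  # G2 must be excluded before correlation regardless of r
  expect_false("G2" %in% ed$gene_id)
})

test_that("signed edges reconcile concordant and discordant targets", {
  set.seed(33)
  n <- 6
  z <- rnorm(n)
  m <- rbind(L1 = 10 + z,
             Gp = 20 + 2 * z + rnorm(n, sd = 0.01),
             Gn = 20 - z + rnorm(n, sd = 0.01))
  colnames(m) <- paste0("s", 1:n)
  x <- FPKMSet(m, setNames(rep(c("A", "B"), 3), colnames(m)))
  ed <- transTargets(x, "L1", c("Gp", "Gn"))
  expect_setequal(ed$gene_id, c("Gp", "Gn"))
  expect_gt(ed$r[ed$gene_id == "Gp"], 0.95)
  expect_lt(ed$r[ed$gene_id == "Gn"], -0.95)
  # the literal positive-only reading drops the anti-correlated target
  edPos <- transTargets(x, "L1", c("Gp", "Gn"), positiveOnly = TRUE)
  expect_equal(edPos$gene_id, "Gp")
})

test_that("direction tallies count concordant targets and match recounts", {
  de <- data.frame(
    feature_id = c("L1", "L2", "g1", "g2", "g3", "g4", "g5"),
    mean_a = 1, mean_b = 1,
    log2fc = c(2, -1, 1, 2, -0.5, -2, 1),
    p = 0.001, q = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.9),
    call = factor(c("up", "down", "up", "up", "down", "down", "ns"),
                  levels = c("up", "down", "ns")))
  edges <- data.frame(
    lincRNA_id = c("L1", "L1", "L1", "L1", "L2", "L2"),
    gene_id = c("g1", "g2", "g3", "g5", "g3", "g4"),
    mode = "trans", r = 0.99, p = 1e-4, q = 1e-3)
  tal <- directionTally(edges, de)
  expect_equal(tal$n_deptg[tal$lincRNA_id == "L1"], 3)  # g5 not DE
  expect_equal(tal$n_up[tal$lincRNA_id == "L1"], 2)
  expect_equal(tal$n_down[tal$lincRNA_id == "L1"], 1)
  # L2 is down; g3 and g4 are both down -> concordant
  l2 <- tal[tal$lincRNA_id == "L2", ]
  expect_equal(c(l2$n_deptg, l2$n_up, l2$n_down), c(2, 2, 0))
  expect_true(all(tal$n_up + tal$n_down == tal$n_deptg))
  expect_error(directionTally(
    data.frame(lincRNA_id = "LX", gene_id = "g1"), de), "LX")

  # random fixtures against a brute-force recount
  set.seed(34)
  for (rep in 1:10) {
    ids <- c(sprintf("L%d", 1:4), sprintf("g%d", 1:12))
    lfc <- rnorm(16)
    call <- ifelse(runif(16) < 0.6, ifelse(lfc > 0, "up", "down"), "ns")
    de2 <- data.frame(feature_id = ids, mean_a = 1, mean_b = 1, log2fc = lfc,
                      p = 0.01, q = 0.01,
                      call = factor(call, levels = c("up", "down", "ns")))
    edges2 <- data.frame(lincRNA_id = sample(ids[1:4], 20, TRUE),
                         gene_id = sample(ids[5:16], 20, TRUE))
    edges2 <- unique(edges2)
    tal2 <- directionTally(edges2, de2)
    for (j in seq_len(nrow(tal2))) {
      l <- tal2$lincRNA_id[j]
      expect_true(call[match(l, ids)] != "ns")
      tg <- edges2$gene_id[edges2$lincRNA_id == l]
      tgDE <- tg[call[match(tg, ids)] != "ns"]
      conc <- sum(sign(lfc[match(tgDE, ids)]) == sign(lfc[match(l, ids)]))
      expect_equal(tal2$n_up[j], conc)
      expect_equal(tal2$n_deptg[j], length(tgDE))
    }
  }
})

test_that("majority summary counts directions with ties separated", {
  expect_equal(unname(majoritySummary(
    data.frame(n_up = 2, n_down = 1))), c(1, 0, 0))
  expect_equal(unname(majoritySummary(
    data.frame(n_up = c(3, 1, 2), n_down = c(1, 4, 2)))), c(1, 1, 1))
  expect_error(majoritySummary(data.frame(n_up = integer(0),
                                          n_down = integer(0))), "non-empty")
})

test_that("shared-target counting matches a bipartite degree oracle", {
  ed <- data.frame(lincRNA_id = c("L1", "L2", "L1"),
                   gene_id = c("G1", "G1", "G2"))
  expect_equal(unname(sharedTargetCount(ed)), c(2L, 1L))
  expect_equal(unname(sharedTargetCount(ed[0, ])), c(0L, 0L))
  set.seed(35)
  for (rep in 1:10) {
    ed <- unique(data.frame(lincRNA_id = sample(sprintf("L%d", 1:6), 30, TRUE),
                            gene_id = sample(sprintf("G%d", 1:15), 30, TRUE)))
    got <- sharedTargetCount(ed)
    deg <- tapply(ed$lincRNA_id, ed$gene_id, function(x) length(unique(x)))
    expect_equal(unname(got),
                 c(length(deg), sum(deg >= 2)))
  }
})

test_that("validation reproduces discovery on identical data and flags flips", {
  set.seed(36)
  sim <- simulateStudy(seed = 36)
  ed <- transTargets(sim$expr, sim$truth$delIds, sim$universe)
  # idempotence: validating on the discovery matrix returns identical r
  v <- validatePairs(ed, sim$expr)
  expect_equal(v$results$r, ed$r, tolerance = 1e-12)
  expect_equal(v$signAgreement, 1)

  # planted pairs keep their sign on the independent 18-sample dataset
  v2 <- validatePairs(ed, sim$expr2)
  pk <- paste(sim$truth$transEdges$lincRNA_id, sim$truth$transEdges$gene_id)
  planted <- paste(v2$results$lincRNA_id, v2$results$gene_id) %in% pk
  expect_true(mean(v2$results$sign_agree[planted]) > 0.99)

  # an artificially flipped pair is flagged negative
  flip <- ed[1, ]; flip$r <- -flip$r
  v3 <- validatePairs(flip, sim$expr)
  expect_false(v3$results$sign_agree[1])

  # missing endpoints are skipped and logged, not fatal
  m2 <- fpkm(sim$expr2)
  m2 <- m2[setdiff(rownames(m2), ed$gene_id[1]), ]
  expect_message(v4 <- validatePairs(ed, m2), "skipped")
  expect_equal(nrow(v4$skipped), sum(ed$gene_id == ed$gene_id[1]))
})
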