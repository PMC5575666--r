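#' @include AllClasses.R accessors.R transcript-model.R
NULL

#' Configuration of the synthetic study generator
#'
#' Defaults emulate the two-breed longissimus dorsi muscle study design
#' this pipeline targets: three biological replicates per group, candidate
#' transcripts of every filter fate, structural means of novel lincRNAs /
#' known lincRNAs / coding transcripts of 1226/1362/1983 nt transcript
#' length and 2.6/2.8/8.7 exons, multiplicative two-group differential
#' expression, trans regulation through shared latent factors tuned to a
#' target Pearson correlation, and cis neighbours planted on both sides of
#' the 10-kb window.
#'
#' @param nCodingGenes Protein-coding genes in the annotation (and
#'   expression matrix).
#' @param nKnownLincs Known lincRNA transcripts in the annotation (beyond
#'   those planted to overlap candidates).
#' @param nPerFate Candidates fated to fail at each of the six cascade
#'   stages.
#' @param nRetained Candidates fated to survive the whole cascade.
#' @param nSamplesPerGroup Biological replicates per group (default 3).
#' @param meanTxLength Named mean transcript lengths (nt) per class.
#' @param exonLambda Named Poisson rates: exon count is
#'   \code{minExons + rpois(lambda)} per class.
#' @param minExonsPerClass Named minimum exon counts per class.
#' @param sdLog Log-normal shape of transcript lengths (sdlog).
#' @param baselineLincFpkm,baselineCodingFpkm Class mean FPKM.
#' @param sigma Log2-scale sd of independent FPKM noise.
#' @param deEffect Planted log2 effect size of differential expression.
#' @param deFracCoding Fraction of non-target coding genes planted as
#'   differentially expressed.
#' @param nDELs Retained lincRNAs planted as differentially expressed with
#'   trans-target structure (must be <= nRetained).
#' @param transTargetsPerFactor Coding genes attached to each latent
#'   factor.
#' @param nMajorityDown Factors whose targets are mostly discordant
#'   ("downregulated") with their lincRNA.
#' @param nSharedDELPairs Pairs of DELs sharing one latent factor (and
#'   hence their targets).
#' @param fracConcordant Fraction of a majority-up factor's targets that are
#'   concordant (majority-down factors use its complement).
#' @param targetR Intended Pearson correlation between a lincRNA and its
#'   trans targets; the pair noise sd is derived from it.
#' @param latentSd Sd of the sample latent factor beyond the group shift.
#' @param nCisNear Retained lincRNAs planted strictly inside the 10-kb cis
#'   window of a coding gene.
#' @param nCisFar Retained lincRNAs planted 12-15 kb from a coding gene
#'   (outside the window).
#' @param fracKnownOverlap Fraction of retained lincRNAs planted to overlap
#'   a known lincRNA (the rest are novel).
#' @param nValidationSamples Samples in the second (validation) expression
#'   matrix (default 18).
#' @param nTermsBP,nTermsPathway Annotation terms per category.
#' @param nEnrichedTerms Terms planted to be enriched in the trans-target
#'   pool.
#' @param orfFrac ORF fraction planted in coding-fated candidate sequences;
#'   chosen well above the cascade's default ORF-fraction threshold.
#' @return Named list of generator settings.
#' @seealso [simulateStudy()]
#' @export
simConfig <- function(nCodingGenes = 250,
                      nKnownLincs = 30,
                      nPerFate = 20,
                      nRetained = 20,
                      nSamplesPerGroup = 3,
                      meanTxLength = c(novel_lincRNA = 1226,
                                       known_lincRNA = 1362,
                                       protein_coding = 1983),
                      exonLambda = c(novel_lincRNA = 0.6,
                                     known_lincRNA = 0.8,
                                     protein_coding = 7.7),
                      minExonsPerClass = c(novel_lincRNA = 2,
                                           known_lincRNA = 2,
                                           protein_coding = 1),
                      sdLog = 0.35,
                      baselineLincFpkm = 5,
                      baselineCodingFpkm = 16,
                      sigma = 0.25,
                      deEffect = 2,
                      deFracCoding = 0.15,
                      nDELs = 16,
                      transTargetsPerFactor = 12,
                      nMajorityDown = 2,
                      nSharedDELPairs = 2,
                      fracConcordant = 0.8,
                      targetR = 0.99,
                      latentSd = 0.35,
                      nCisNear = 8,
                      nCisFar = 4,
                      fracKnownOverlap = 0.5,
                      nValidationSamples = 18,
                      nTermsBP = 15,
                      nTermsPathway = 8,
                      nEnrichedTerms = 3,
                      orfFrac = 0.6) {
  stopifnot(nDELs <= nRetained, nCisNear + nCisFar <= nRetained,
            nSamplesPerGroup >= 2, targetR > 0, targetR < 1, sigma > 0,
            nSharedDELPairs * 2 + nMajorityDown <= nDELs)
  as.list(environment())
}

# --- sequence construction ---------------------------------------------------

.SENSE_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(c("A","C","G","T"), c("A","C","G","T"),
                                  paste0)), c("A","C","G","T"), paste0)),
  c("TAA", "TAG", "TGA"))

# sequence with no ATG on either strand (no ATG or CAT substring), hence no
# open reading frame at all
.orfFreeSeq <- function(L) {
  s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  str <- paste(s, collapse = "")
  for (iter in 1:20) {
    hits <- gregexpr("ATG|CAT", str)[[1L]]
    if (hits[1L] == -1L) break
    v <- strsplit(str, "", fixed = TRUE)[[1L]]
    mid <- hits + 1L
    v[mid] <- ifelse(v[mid] == "T", "C", "G")  # ATG -> ACG, CAT -> CGT
    str <- paste(v, collapse = "")
  }
  str
}

# plant an ATG..stop ORF covering `frac` of the transcript
.codingSeq <- function(L, frac = 0.6) {
  backbone <- .orfFreeSeq(L)
  ncod <- max(3L, ceiling(frac * L / 3))
  orfLen <- 3L * ncod
  if (orfLen > L - 3L) orfLen <- 3L * ((L - 3L) %/% 3L)
  inner <- paste(sample(.SENSE_CODONS, orfLen / 3L - 2L, replace = TRUE),
                 collapse = "")
  orf <- paste0("ATG", inner, "TAA")
  at <- sample.int(L - orfLen + 1L, 1L)
  paste0(substr(backbone, 1L, at - 1L), orf,
         substr(backbone, at + orfLen, L))
}

# --- transcript structure ----------------------------------------------------

.simStructure <- function(n, meanLen, lambda, minExons, sdLog, minLen = 210) {
  len <- round(stats::rlnorm(n, meanlog = log(meanLen) - sdLog^2 / 2,
                             sdlog = sdLog))
  len <- pmax(len, minLen)
  k <- minExons + stats::rpois(n, lambda)
  list(length = len, nExons = k)
}

# one row per exon; assembled into a single GRanges at the end (building
# many small GRanges objects is the dominant cost otherwise)
.exonTable <- function(id, chrom, strand, start, txLen, nExons) {
  w <- as.vector(stats::rgamma(nExons, shape = 5))
  w <- floor(w / sum(w) * txLen)
  w[w < 1L] <- 1L
  w[1L] <- w[1L] + (txLen - sum(w))
  if (w[1L] < 1L) { w[2L] <- w[2L] + w[1L] - 1L; w[1L] <- 1L }
  introns <- if (nExons > 1L) sample(200:1000, nExons - 1L, replace = TRUE)
             else integer(0)
  starts <- start + cumsum(c(0L, w[-nExons] + introns))
  data.frame(tx = id, chrom = chrom, strand = strand, start = starts,
             width = w)
}

.assembleGrl <- function(tabs) {
  df <- do.call(rbind, tabs)
  gr <- GRanges(df$chrom, IRanges(df$start, width = df$width),
                strand = df$strand)
  S4Vectors::split(gr, factor(df$tx, levels = unique(df$tx)))
}

# --- the generator -----------------------------------------------------------

#' Generate a complete synthetic two-group lincRNA study
#'
#' Builds, from a single seed, every input the pipeline consumes along with
#' full ground truth: a toy two-chromosome annotation (coding genes and
#' known lincRNAs), candidate transcripts fated to fail each cascade stage
#' or be retained (with sequences constructed so the coding-potential fate
#' is guaranteed), two-group FPKM matrices with planted differential
#' expression and latent-factor trans-regulation, a larger validation
#' expression matrix from the same latent structure, alignment hit tables,
#' an external coding-score table, and a term annotation with planted
#' enrichment.
#'
#' @param config Generator settings, see [simConfig()].
#' @param seed Integer seed; identical seed and config give identical
#'   output.
#' @return List: \code{candidates} ([TranscriptSet-class] with sequences),
#'   \code{annotation} (coding genes + known lincRNAs, biotyped),
#'   \code{expr} (discovery [FPKMSet-class]), \code{expr2} (validation
#'   [FPKMSet-class]), \code{domainHits}, \code{homologyHits},
#'   \code{codingScoreTable}, \code{termMap}, \code{universe},
#'   \code{truth} (ground-truth labels and planted edges), \code{config},
#'   \code{seed}.
#' @examples
#' sim <- simulateStudy(seed = 7)
#' sim$candidates
#' @export
simulateStudy <- function(config = simConfig(), seed = 1L) {
  set.seed(seed)
  cf <- config
  fates <- c("intergenic_class", "size", "coding_potential", "domain_hits",
             "homology_hits", "expression")

  # ---- genome layout: coding genes on two chromosomes -----------------------
  spacing <- 60000L
  geneIdsV <- sprintf("G%04d", seq_len(cf$nCodingGenes))
  gchrom <- rep(c("chr1", "chr2"), length.out = cf$nCodingGenes)
  gstrand <- sample(c("+", "-"), cf$nCodingGenes, replace = TRUE)
  gslot <- stats::ave(seq_len(cf$nCodingGenes), gchrom, FUN = seq_along)
  gstart <- 1L + (gslot - 1L) * spacing
  gstr <- .simStructure(cf$nCodingGenes, cf$meanTxLength["protein_coding"],
                        cf$exonLambda["protein_coding"],
                        cf$minExonsPerClass["protein_coding"], cf$sdLog)
  geneExons <- lapply(seq_len(cf$nCodingGenes), function(i)
    .exonTable(paste0(geneIdsV[i], ".t1"), gchrom[i], gstrand[i], gstart[i],
               gstr$length[i], gstr$nExons[i]))
  geneTx <- .assembleGrl(geneExons)

  # cursor past the gene block on each chromosome, plus clearance
  tailPos <- vapply(c("chr1", "chr2"), function(ch) {
    idx <- gchrom == ch
    if (!any(idx)) return(1L)
    max(gstart[idx]) + spacing
  }, integer(1))
  cursor <- tailPos + 40000L
  nextFar <- function(span) {
    ch <- names(which.min(cursor))
    st <- cursor[[ch]]
    cursor[[ch]] <<- st + span + 30000L
    list(chrom = ch, start = st)
  }

  # ---- known lincRNAs (independent of candidates) ---------------------------
  klIds <- sprintf("KL%04d", seq_len(cf$nKnownLincs))
  kstr <- .simStructure(cf$nKnownLincs, cf$meanTxLength["known_lincRNA"],
                        cf$exonLambda["known_lincRNA"],
                        cf$minExonsPerClass["known_lincRNA"], cf$sdLog)
  knownExons <- vector("list", cf$nKnownLincs)
  for (i in seq_len(cf$nKnownLincs)) {
    pos <- nextFar(kstr$length[i] + 2000L * kstr$nExons[i])
    knownExons[[i]] <- .exonTable(klIds[i], pos$chrom,
                                  sample(c("+", "-"), 1L), pos$start,
                                  kstr$length[i], kstr$nExons[i])
  }

  # ---- candidates -----------------------------------------------------------
  fate <- c(rep(fates, each = cf$nPerFate), rep("retained", cf$nRetained))
  nCand <- length(fate)
  candIds <- sprintf("TX%04d", seq_len(nCand))
  names(fate) <- candIds
  retainedIds <- candIds[fate == "retained"]

  cstr <- .simStructure(nCand, cf$meanTxLength["novel_lincRNA"],
                        cf$exonLambda["novel_lincRNA"],
                        cf$minExonsPerClass["novel_lincRNA"], cf$sdLog)
  # size-fated candidates: half single exon, half short multi-exon
  sizeIdx <- which(fate == "size")
  half <- seq_len(ceiling(length(sizeIdx) / 2))
  cstr$nExons[sizeIdx[half]] <- 1L
  short <- sizeIdx[-half]
  cstr$length[short] <- sample(60:199, length(short), replace = TRUE)
  cstr$nExons[short] <- pmax(cstr$nExons[short], 2L)

  classCode <- rep("u", nCand)
  classCode[fate == "intergenic_class"] <-
    sample(c("o", "j", "i", "x"), sum(fate == "intergenic_class"),
           replace = TRUE)

  # placement: cis-near / cis-far retained sit next to anchor genes, the
  # intergenic_class-fated overlap genes, everything else far from genes
  cisNearIds <- retainedIds[seq_len(cf$nCisNear)]
  cisFarIds <- retainedIds[cf$nCisNear + seq_len(cf$nCisFar)]
  nearGaps <- round(seq(500, 9400, length.out = max(cf$nCisNear, 1L)))
  farGaps <- round(seq(12000, 15000, length.out = max(cf$nCisFar, 1L)))
  anchorGene <- seq_len(cf$nCisNear + cf$nCisFar)
  geneEnd <- vapply(geneExons, function(g) max(g$start + g$width - 1L),
                    numeric(1))
  geneStart <- vapply(geneExons, function(g) min(g$start), numeric(1))

  candExons <- vector("list", nCand)
  overlapGeneIdx <- rep_len(seq_len(cf$nCodingGenes),
                            sum(fate == "intergenic_class"))
  oi <- 0L
  for (i in seq_len(nCand)) {
    id <- candIds[i]
    span <- cstr$length[i] + 2000L * cstr$nExons[i]
    if (fate[i] == "intergenic_class") {
      oi <- oi + 1L
      g <- overlapGeneIdx[oi]
      candExons[[i]] <- .exonTable(id, gchrom[g], gstrand[g],
                                   geneStart[g] + 50L,
                                   cstr$length[i], cstr$nExons[i])
    } else if (id %in% cisNearIds) {
      j <- match(id, cisNearIds)
      g <- anchorGene[j]
      st <- geneEnd[g] + nearGaps[j] + 1L
      candExons[[i]] <- .exonTable(id, gchrom[g], sample(c("+", "-"), 1L), st,
                                   cstr$length[i], cstr$nExons[i])
    } else if (id %in% cisFarIds) {
      j <- match(id, cisFarIds)
      g <- anchorGene[cf$nCisNear + j]
      st <- geneEnd[g] + farGaps[j] + 1L
      candExons[[i]] <- .exonTable(id, gchrom[g], sample(c("+", "-"), 1L), st,
                                   cstr$length[i], cstr$nExons[i])
    } else {
      pos <- nextFar(span)
      candExons[[i]] <- .exonTable(id, pos$chrom, sample(c("+", "-"), 1L),
                                   pos$start, cstr$length[i], cstr$nExons[i])
    }
  }
  candGrl <- .assembleGrl(candExons)

  # true lengths (exon splitting preserves the total by construction)
  candLen <- vapply(candExons, function(g) sum(g$width), numeric(1))

  # sequences: coding-fated get a planted ORF, everything else is ORF-free
  seqs <- character(nCand)
  for (i in seq_len(nCand)) {
    seqs[i] <- if (fate[i] == "coding_potential")
      .codingSeq(candLen[i], cf$orfFrac) else .orfFreeSeq(candLen[i])
  }
  candSeq <- Biostrings::DNAStringSet(stats::setNames(seqs, candIds))

  candidates <- TranscriptSet(candGrl,
                              geneId = sprintf("XLOC%04d", seq_len(nCand)),
                              classCode = classCode,
                              biotype = "other",
                              sequence = candSeq)

  # ---- novelty planting: known lincs copied over some retained lincs --------
  novelTruth <- stats::setNames(rep("novel", cf$nRetained), retainedIds)
  nOverlap <- round(cf$fracKnownOverlap * cf$nRetained)
  overlapIds <- retainedIds[cf$nRetained - seq_len(nOverlap) + 1L]
  novelTruth[overlapIds] <- "known_overlap"
  ovExons <- lapply(seq_along(overlapIds), function(j) {
    tab <- candExons[[match(overlapIds[j], candIds)]]
    spanStart <- min(tab$start)
    spanWidth <- max(tab$start + tab$width) - spanStart
    data.frame(tx = sprintf("KLOV%03d", j), chrom = tab$chrom[1L],
               strand = tab$strand[1L], start = spanStart,
               width = max(200L, spanWidth %/% 2L))
  })
  klAll <- c(klIds, sprintf("KLOV%03d", seq_along(overlapIds)))
  knownGrl <- .assembleGrl(c(knownExons, ovExons))
  annotation <- TranscriptSet(
    c(geneTx, knownGrl),
    geneId = c(geneIdsV, paste0(klAll, ".g")),
    classCode = "=",
    biotype = c(rep("protein_coding", cf$nCodingGenes),
                rep("known_lincRNA", length(klAll))))

  # ---- expression: latent-factor trans structure ----------------------------
  nPerG <- cf$nSamplesPerGroup
  samples <- c(sprintf("YY%02d", seq_len(nPerG)),
               sprintf("WH%02d", seq_len(nPerG)))
  group <- stats::setNames(rep(c("YY", "WH"), each = nPerG), samples)
  gInd <- ifelse(group == "YY", 0.5, -0.5)

  delIds <- sample(retainedIds, cf$nDELs)
  nFactors <- cf$nDELs - cf$nSharedDELPairs
  factorOfDel <- integer(cf$nDELs)
  factorOfDel[seq_len(nFactors)] <- seq_len(nFactors)
  # extra DELs of shared pairs re-use majority-up factors, so the
  # majority-down factors stay singleton DELs
  if (cf$nSharedDELPairs > 0)
    factorOfDel[nFactors + seq_len(cf$nSharedDELPairs)] <-
      cf$nMajorityDown + seq_len(cf$nSharedDELPairs)
  names(factorOfDel) <- delIds
  downFactors <- seq_len(cf$nMajorityDown)

  # disjoint target sets per factor
  needed <- nFactors * cf$transTargetsPerFactor
  if (needed > cf$nCodingGenes)
    stop("not enough coding genes for the requested trans-target structure")
  targetPool <- sample(geneIdsV, needed)
  targetsOfFactor <- split(targetPool,
                           rep(seq_len(nFactors),
                               each = cf$transTargetsPerFactor))
  nConc <- round(cf$fracConcordant * cf$transTargetsPerFactor)
  signsOfFactor <- lapply(seq_len(nFactors), function(f) {
    s <- c(rep(1, nConc), rep(-1, cf$transTargetsPerFactor - nConc))
    if (f %in% downFactors) s <- -s
    stats::setNames(s, targetsOfFactor[[f]])
  })
  # each factor responds to the group contrast in its own direction, so
  # lincRNAs are a mix of up- and down-regulated
  dirOfFactor <- sample(c(1, -1), nFactors, replace = TRUE)
  factorOfGene <- rep(seq_len(nFactors), each = cf$transTargetsPerFactor)
  names(factorOfGene) <- targetPool

  vu <- cf$deEffect^2 / 4 + cf$latentSd^2
  pairNoise <- sqrt(vu * (1 / cf$targetR - 1))

  # DE among non-target coding genes
  freeGenes <- setdiff(geneIdsV, targetPool)
  nDeg <- round(cf$deFracCoding * length(freeGenes))
  degFree <- sample(freeGenes, nDeg)
  degDir <- stats::setNames(sample(c(1, -1), nDeg, replace = TRUE), degFree)

  features <- c(candIds, geneIdsV)
  baseMu <- stats::setNames(
    c(ifelse(fate == "expression",
             stats::runif(nCand, 0.02, 0.45), cf$baselineLincFpkm),
      rep(cf$baselineCodingFpkm, cf$nCodingGenes)), features)

  makeMatrix <- function(sampleNames, gvec, zsd) {
    nS <- length(sampleNames)
    z <- matrix(stats::rnorm(nFactors * nS, sd = zsd), nFactors, nS)
    u <- sweep(z, 2L, cf$deEffect * gvec, "+")  # factor value per sample
    m <- matrix(0, length(features), nS,
                dimnames = list(features, sampleNames))
    for (f in features) {
      mu <- log2(baseMu[f])
      if (f %in% delIds) {
        fac <- factorOfDel[f]
        x <- mu + dirOfFactor[fac] * u[fac, ] +
          stats::rnorm(nS, sd = pairNoise)
      } else if (f %in% targetPool) {
        fac <- factorOfGene[f]
        s <- signsOfFactor[[fac]][f] * dirOfFactor[fac]
        x <- mu + s * u[fac, ] + stats::rnorm(nS, sd = pairNoise)
      } else if (f %in% degFree) {
        x <- mu + degDir[f] * cf$deEffect * gvec + stats::rnorm(nS, sd = cf$sigma)
      } else {
        x <- mu + stats::rnorm(nS, sd = cf$sigma)
      }
      m[f, ] <- 2^x
    }
    # expression-fated candidates must sit below the floor in every sample
    low <- candIds[fate == "expression"]
    m[low, ] <- pmin(m[low, , drop = FALSE], 0.45)
    m
  }

  exprM <- makeMatrix(samples, gInd, cf$latentSd)
  expr <- FPKMSet(exprM, factor(group, levels = c("YY", "WH")))

  nV <- cf$nValidationSamples
  vSamples <- sprintf("V%02d", seq_len(nV))
  vGroup <- stats::setNames(rep(c("A", "B"), length.out = nV), vSamples)
  # validation: no group design; the factor spread matches the discovery
  # variance so correlations carry over
  exprV <- makeMatrix(vSamples, rep(0, nV), sqrt(vu))
  expr2 <- FPKMSet(exprV, factor(vGroup, levels = c("A", "B")))

  # ---- hit tables, external coding scores -----------------------------------
  mkHits <- function(ids) {
    if (!length(ids))
      return(data.frame(query_id = character(0), evalue = numeric(0)))
    data.frame(query_id = ids,
               evalue = 10^stats::runif(length(ids), -20, -6))
  }
  domainHits <- mkHits(candIds[fate == "domain_hits"])
  homologyHits <- mkHits(candIds[fate == "homology_hits"])
  # weak decoy hits on a few retained candidates (must survive the strict <)
  decoys <- retainedIds[seq_len(min(3L, length(retainedIds)))]
  weak <- data.frame(query_id = decoys,
                     evalue = 10^stats::runif(length(decoys), -4, -1))
  domainHits <- rbind(domainHits, weak)

  codingScoreTable <- data.frame(
    transcript_id = candIds,
    score_forward = ifelse(fate == "coding_potential",
                           stats::runif(nCand, 0.1, 0.5),
                           -stats::runif(nCand, 0.1, 0.3)),
    score_reverse = -stats::runif(nCand, 0.1, 0.3))

  # ---- term annotation with planted enrichment ------------------------------
  nTerms <- cf$nTermsBP + cf$nTermsPathway
  termIds <- c(sprintf("BP%03d", seq_len(cf$nTermsBP)),
               sprintf("PW%03d", seq_len(cf$nTermsPathway)))
  category <- c(rep("biological_process", cf$nTermsBP),
                rep("pathway", cf$nTermsPathway))
  enriched <- seq_len(min(cf$nEnrichedTerms, cf$nTermsBP))
  # enriched terms are drawn wholly from the regulated pool; anything less
  # concentrated is indistinguishable from background when the pool spans
  # a large share of the universe
  termGenes <- lapply(seq_len(nTerms), function(i) {
    size <- sample(10:25, 1L)
    if (i %in% enriched && length(targetPool)) {
      sample(targetPool, min(size, length(targetPool)))
    } else sample(geneIdsV, size)
  })
  termMap <- data.frame(term_id = termIds,
                        term_name = paste0("synthetic term ", termIds),
                        category = category, stringsAsFactors = FALSE)
  termMap$genes <- termGenes

  # ---- ground truth ---------------------------------------------------------
  transEdges <- do.call(rbind, lapply(seq_len(cf$nDELs), function(d) {
    f <- factorOfDel[d]
    data.frame(lincRNA_id = delIds[d],
               gene_id = targetsOfFactor[[f]],
               sign = unname(signsOfFactor[[f]]),
               row.names = NULL)
  }))
  cisEdges <- data.frame(lincRNA_id = cisNearIds,
                         gene_id = geneIdsV[anchorGene[seq_len(cf$nCisNear)]],
                         distance = nearGaps)
  deTruth <- rbind(
    data.frame(feature_id = delIds,
               direction = ifelse(dirOfFactor[factorOfDel] > 0, "up", "down"),
               class = "lincRNA"),
    data.frame(feature_id = targetPool,
               direction = ifelse(unlist(signsOfFactor)[targetPool] *
                                    dirOfFactor[factorOfGene[targetPool]] > 0,
                                  "up", "down"),
               class = "coding"),
    data.frame(feature_id = degFree,
               direction = if (nDeg) ifelse(degDir > 0, "up", "down")
                           else character(0),
               class = rep("coding", nDeg)))
  truth <- list(fate = fate,
                retained = retainedIds,
                novelty = novelTruth,
                delIds = delIds,
                de = deTruth,
                transEdges = transEdges,
                cisEdges = cisEdges,
                cisFarIds = cisFarIds,
                enrichedTerms = termIds[enriched],
                factorOfDel = factorOfDel,
                downDelIds = delIds[factorOfDel %in% downFactors])

  list(candidates = candidates, annotation = annotation, expr = expr,
       expr2 = expr2, domainHits = domainHits, homologyHits = homologyHits,
       codingScoreTable = codingScoreTable, termMap = termMap,
       universe = geneIdsV, truth = truth, config = cf, seed = seed)
}

#' Write a simulated study to disk
#'
#' Emits the complete plain-text file bundle: candidate and annotation GTF,
#' candidate FASTA, discovery and validation expression TSVs with group
#' files, domain/homology hit TSVs, external coding-score TSV, term-map and
#' term-description TSVs, and the ground truth as JSON.
#'
#' @param sim Result of [simulateStudy()].
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeStudy <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeGTF(sim$candidates, p("candidates.gtf"))
  writeGTF(sim$annotation, p("annotation.gtf"))
  Biostrings::writeXStringSet(sequences(sim$candidates), p("candidates.fa"))
  writeExpression(sim$expr, p("expression.tsv"), p("groups.tsv"))
  writeExpression(sim$expr2, p("validation_expression.tsv"),
                  p("validation_groups.tsv"))
  utils::write.table(sim$domainHits, p("domain_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$homologyHits, p("homology_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$codingScoreTable, p("coding_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  map <- data.frame(
    gene_id = unlist(sim$termMap$genes, use.names = FALSE),
    term_id = rep(sim$termMap$term_id, lengths(sim$termMap$genes)))
  utils::write.table(map, p("term_map.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$termMap[c("term_id", "term_name", "category")],
                     p("term_desc.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(truth, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
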