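#' @include AllClasses.R accessors.R identify.R diffexp.R targets.R enrich.R simulate.R
NULL

#' Run the full analysis end to end
#'
#' Orchestrates identification, differential expression, cis/trans target
#' prediction, direction tallies, over-representation analysis and
#' cross-dataset validation, either on a simulated study or on inputs
#' supplied as package objects. Fails fast on any stage error and returns
#' all stage outputs plus a machine-readable run report.
#'
#' @param sim A simulated study from [simulateStudy()]; alternatively pass
#'   the inputs individually.
#' @param candidates,annotation,expr,expr2 Candidate [TranscriptSet-class],
#'   reference annotation, discovery and validation [FPKMSet-class]s,
#'   overriding the corresponding elements of \code{sim}.
#' @param domainHits,homologyHits,termMap,universe Hit tables, term map and
#'   gene universe, overriding the corresponding elements of \code{sim}.
#' @param params Cascade thresholds ([cascadeParams()]).
#' @param alpha FDR level for differential expression and the trans screen
#'   (default 0.05).
#' @param rMin Trans correlation threshold (default 0.95).
#' @param window Cis window in bp (default 10000).
#' @param useExternalScores Use \code{sim$codingScoreTable} instead of the
#'   sequence heuristic at the coding-potential stage (default
#'   \code{FALSE}).
#' @param outDir Optional directory for TSV/JSON stage outputs.
#' @return List with stage outputs (\code{cascade}, \code{novelty},
#'   \code{characterization}, \code{de}, \code{cisEdges}, \code{transEdges},
#'   \code{tallies}, \code{majority}, \code{shared}, \code{enrichment},
#'   \code{validation}) and \code{report}, the per-stage count summary.
#' @examples
#' res <- runPipeline(simulateStudy(seed = 3))
#' res$report
#' @export
runPipeline <- function(sim = NULL, candidates = sim$candidates,
                        annotation = sim$annotation, expr = sim$expr,
                        expr2 = sim$expr2, domainHits = sim$domainHits,
                        homologyHits = sim$homologyHits,
                        termMap = sim$termMap, universe = sim$universe,
                        params = cascadeParams(), alpha = 0.05, rMin = 0.95,
                        window = 10000, useExternalScores = FALSE,
                        outDir = NULL) {
  if (is.null(candidates) || is.null(expr))
    stop("candidates and expr are required")
  coding <- if (useExternalScores) sim$codingScoreTable else NULL

  cascade <- runCascade(candidates, expr, coding = coding,
                        domainHits = domainHits,
                        homologyHits = homologyHits, params = params)
  lincs <- cascade$lincRNAs

  novelty <- if (!is.null(annotation))
    classifyNovelty(lincs, annotation) else NULL

  characterization <- if (!is.null(annotation)) {
    known <- annotation[which(biotypes(annotation) == "known_lincRNA")]
    codingTx <- annotation[which(biotypes(annotation) == "protein_coding")]
    if (length(known) && length(codingTx) && length(lincs))
      characterize(lincs, known, codingTx, expr) else NULL
  } else NULL

  if (is.null(universe))
    universe <- setdiff(rownames(expr), transcriptIds(candidates))
  de <- deTest(expr, alpha = alpha,
               features = intersect(c(transcriptIds(lincs), universe),
                                    rownames(expr)))
  deLinc <- de[de$feature_id %in% transcriptIds(lincs), ]
  delIds <- deLinc$feature_id[deLinc$call != "ns"]
  degIds <- de$feature_id[de$feature_id %in% universe & de$call != "ns"]

  cisEdges <- if (!is.null(annotation))
    cisTargets(lincs, annotation, window = window)
  else data.frame(lincRNA_id = character(0), gene_id = character(0),
                  mode = character(0), distance = integer(0))

  transEdges <- transTargets(expr, lincIds = delIds, geneIds = universe,
                             rMin = rMin, alpha = alpha)
  deptgIds <- unique(transEdges$gene_id[transEdges$gene_id %in% degIds])

  tallies <- if (nrow(transEdges)) directionTally(transEdges, de) else
    data.frame(lincRNA_id = character(0), n_deptg = integer(0),
               n_up = integer(0), n_down = integer(0))
  majority <- if (nrow(tallies)) majoritySummary(tallies) else
    c(n_majority_up = 0L, n_majority_down = 0L, ties = 0L)
  shared <- sharedTargetCount(transEdges)

  enrichment <- if (!is.null(termMap) && length(deptgIds))
    hypergeomEnrich(deptgIds, termMap, universe) else NULL

  validation <- if (!is.null(expr2) && nrow(transEdges))
    validatePairs(transEdges, expr2) else NULL

  report <- list(
    seed = sim$seed,
    n_input_transcripts = length(candidates),
    survivors_per_stage = as.list(stageSurvivors(cascade$report)),
    n_lincRNAs = length(lincs),
    n_loci = length(groupLoci(lincs)),
    n_novel = if (!is.null(novelty)) sum(novelty == "novel") else NA,
    n_DELs = length(delIds),
    n_DEGs = length(degIds),
    n_cis_edges = nrow(cisEdges),
    n_trans_edges = nrow(transEdges),
    n_trans_PTGs = length(unique(transEdges$gene_id)),
    n_DEPTGs = length(deptgIds),
    n_majority_up = unname(majority["n_majority_up"]),
    n_majority_down = unname(majority["n_majority_down"]),
    n_multi_regulated = unname(shared["n_multi_regulated"]),
    n_enriched_terms = if (!is.null(enrichment))
      sum(enrichment$p < 0.05) else NA,
    validation_sign_agreement = if (!is.null(validation))
      validation$signAgreement else NA,
    parameters = list(alpha = alpha, rMin = rMin, window = window,
                      cascade = params))

  out <- list(cascade = cascade, novelty = novelty,
              characterization = characterization, de = de,
              delIds = delIds, degIds = degIds, deptgIds = deptgIds,
              cisEdges = cisEdges, transEdges = transEdges,
              tallies = tallies, majority = majority, shared = shared,
              enrichment = enrichment, validation = validation,
              report = report)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outDir, f)
    writeGTF(lincs, p("lincRNAs.gtf"))
    jsonlite::write_json(
      list(stages = as.list(stageSurvivors(cascade$report)),
           fate = as.list(transcriptFates(cascade$report))),
      p("filter_report.json"), auto_unbox = TRUE)
    utils::write.table(de, p("de.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(rbind(
      cbind(cisEdges[c("lincRNA_id", "gene_id", "mode")],
            distance = cisEdges$distance, r = NA, p = NA, q = NA),
      cbind(transEdges[c("lincRNA_id", "gene_id", "mode")], distance = NA,
            transEdges[c("r", "p", "q")])),
      p("edges.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tallies, p("tallies.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(enrichment))
      utils::write.table(
        enrichment[setdiff(names(enrichment), "genes")], p("enrichment.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(validation))
      utils::write.table(validation$results, p("validation.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  out
}
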