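#' @include AllClasses.R
NULL

#' Read a gene-to-term annotation map
#'
#' @param mapPath Two-column TSV, no header: gene_id, term_id.
#' @param descPath Optional TSV, no header: term_id, term_name, category
#'   (\code{biological_process} or \code{pathway}). Terms without a
#'   description default to their id and category
#'   \code{"biological_process"}.
#' @return Term map: data frame with columns \code{term_id},
#'   \code{term_name}, \code{category} and a list column \code{genes}.
#' @export
readTermMap <- function(mapPath, descPath = NULL) {
  map <- utils::read.delim(mapPath, header = FALSE, stringsAsFactors = FALSE)
  genes <- split(as.character(map[[1L]]), as.character(map[[2L]]))
  tm <- data.frame(term_id = names(genes), term_name = names(genes),
                   category = "biological_process", stringsAsFactors = FALSE)
  if (!is.null(descPath)) {
    d <- utils::read.delim(descPath, header = FALSE, stringsAsFactors = FALSE)
    hit <- match(tm$term_id, as.character(d[[1L]]))
    tm$term_name[!is.na(hit)] <- as.character(d[[2L]])[hit[!is.na(hit)]]
    tm$category[!is.na(hit)] <- as.character(d[[3L]])[hit[!is.na(hit)]]
  }
  tm$genes <- unname(genes)
  tm
}

#' Hypergeometric over-representation analysis
#'
#' For each term, the upper-tail hypergeometric probability of observing at
#' least the seen overlap between the query set and the term's genes within
#' the declared universe. With \code{ease = TRUE} the overlap is reduced by
#' one (floor 0) before the tail is computed, the conservative variant used
#' by common annotation servers. q-values are Benjamini-Hochberg within
#' each term category.
#'
#' @param query Gene set of interest; must be a subset of \code{universe}.
#' @param terms Term map, see [readTermMap()].
#' @param universe Background gene set.
#' @param ease Use the overlap-minus-one conservative score (default
#'   \code{FALSE}).
#' @return Data frame sorted by p: \code{term_id}, \code{term_name},
#'   \code{category}, \code{k} (overlap), \code{K} (term size), \code{n}
#'   (query size), \code{N} (universe size), \code{p}, \code{q}.
#' @export
hypergeomEnrich <- function(query, terms, universe, ease = FALSE) {
  query <- unique(query); universe <- unique(universe)
  if (length(query) == 0L || length(universe) == 0L)
    stop("query and universe must be non-empty")
  if (!all(query %in% universe))
    stop("query must be a subset of the universe")
  N <- length(universe); n <- length(query)
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    tg <- intersect(terms$genes[[i]], universe)
    K <- length(tg)
    if (K == 0L) return(NULL)
    k <- length(intersect(tg, query))
    keff <- if (ease) max(k - 1L, 0L) else k
    p <- stats::phyper(keff - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = terms$term_id[i], term_name = terms$term_name[i],
               category = terms$category[i], k = k, K = K, n = n, N = N,
               p = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(0), term_name = character(0),
                      category = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0)))
  out$q <- NA_real_
  for (cat in unique(out$category))
    out$q[out$category == cat] <- bhAdjust(out$p[out$category == cat])
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
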