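#' Read gene sets in GMT format
#'
#' Wrapper over \code{fgsea::gmtPathways} (tab-separated: name, description,
#' member genes).
#'
#' @param path GMT file path.
#' @return named list of gene symbol vectors.
#' @export
readGmt <- function(path) fgsea::gmtPathways(path)

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability of observing at least the realized overlap between
#' a query gene list and a gene set, drawing \code{|query|} genes without
#' replacement from the universe.  Query and set are intersected with the
#' universe first.  An empty query returns 1.
#'
#' @param query candidate genes.
#' @param geneSet gene-set members.
#' @param universe background gene universe.
#' @return p-value in (0, 1].
#' @examples
#' oraHypergeometric(c("A", "B", "C"), c("A", "B", "X"), LETTERS)
#' @export
oraHypergeometric <- function(query, geneSet, universe) {
  query <- unique(intersect(query, universe))
  geneSet <- unique(intersect(geneSet, universe))
  N <- length(unique(universe))
  m <- length(query)
  if (m == 0) return(1)
  K <- length(geneSet)
  k <- length(intersect(query, geneSet))
  phyper(k - 1, K, N - K, m, lower.tail = FALSE)
}

#' Over-representation filtering of candidate genes and variants
#'
#' Scores every gene set against the candidate genes, retains sets with ORA
#' p-value (optionally Benjamini-Hochberg adjusted) at or below
#' \code{threshold}, then keeps a candidate gene iff it belongs to at least
#' one retained set, and a candidate variant iff it maps to a kept gene.
#' The default universe is the set of genes carrying at least one tested
#' variant (i.e. the candidate-generation space), supplied by the caller.
#'
#' @param candidateGenes character vector of candidate genes.
#' @param geneSets named list of gene sets (see \code{\link{readGmt}}).
#' @param universe background universe; defaults to the union of all set
#'   members and candidates.
#' @param threshold ORA p-value threshold (the study searched windows
#'   0.005-0.2 and, with the literature panel added, 0.0025-0.13).
#' @param bhCorrect apply Benjamini-Hochberg across sets before
#'   thresholding (off by default; raw set p-values are the study's usage).
#' @param snvGeneMap optional data.frame \code{(variant_id, gene)} used to
#'   propagate the filter to variants.
#' @return list with \code{sets} (retained set names), \code{genes}
#'   (retained candidate genes), \code{snvs} (retained variant ids, or
#'   \code{NULL}), and \code{table} (per-set overlap, size, p, kept flag).
#' @export
enrichAndFilter <- function(candidateGenes, geneSets, universe = NULL,
                            threshold = 0.05, bhCorrect = FALSE,
                            snvGeneMap = NULL) {
  if (is.null(universe))
    universe <- unique(c(unlist(geneSets, use.names = FALSE), candidateGenes))
  candidateGenes <- unique(intersect(candidateGenes, universe))
  p <- vapply(geneSets, function(s)
    oraHypergeometric(candidateGenes, s, universe), 0)
  overlap <- vapply(geneSets, function(s)
    length(intersect(candidateGenes, intersect(s, universe))), 0L)
  padj <- if (bhCorrect) stats::p.adjust(p, "BH") else p
  kept <- padj <= threshold
  tab <- data.frame(set = names(geneSets),
                    overlap = overlap,
                    set_size = vapply(geneSets, function(s)
                      length(intersect(s, universe)), 0L),
                    p = p, p_used = padj, kept = kept)
  rownames(tab) <- NULL
  keptGenes <- unique(unlist(geneSets[kept], use.names = FALSE))
  genes <- intersect(candidateGenes, keptGenes)
  snvs <- NULL
  if (!is.null(snvGeneMap))
    snvs <- unique(snvGeneMap$variant_id[snvGeneMap$gene %in% genes])
  list(sets = names(geneSets)[kept], genes = genes, snvs = snvs, table = tab)
}
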