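# Interaction enrichment of selected expression genes against the
# inhibition-state protein set, with a resampling null.

#' Filter a network to high-confidence edges
#'
#' Keeps only edges whose confidence is strictly above the cutoff (the
#' "above 0.7" high-confidence convention) and drops any self-edges.
#'
#' @param network An [InteractionNetwork].
#' @param minConfidence Confidence cutoff; edges must exceed it strictly.
#' @return The filtered [InteractionNetwork] over the same node universe.
#' @export
filterNetwork <- function(network, minConfidence = 0.7) {
  stopifnot(is(network, "InteractionNetwork"))
  e <- networkEdges(network)
  keep <- e$confidence > minConfidence & e$node_a != e$node_b
  InteractionNetwork(edges = e[keep, , drop = FALSE],
                     nodes = networkNodes(network))
}

# Number of distinct target proteins adjacent to each node of `universe`.
.targetDegree <- function(universe, targetProteins, network) {
  e <- networkEdges(network)
  touchA <- e$node_b %in% targetProteins
  touchB <- e$node_a %in% targetProteins
  ends <- c(e$node_a[touchA], e$node_b[touchB])
  partners <- c(e$node_b[touchA], e$node_a[touchB])
  keyed <- unique(paste(ends, partners, sep = "\r"))
  ends <- sub("\r.*$", "", keyed)
  counts <- table(ends)
  out <- setNames(rep(0L, length(universe)), universe)
  hit <- intersect(names(counts), universe)
  out[hit] <- as.integer(counts[hit])
  out
}

#' Count target-set interactors of a query gene set
#'
#' For each query gene, counts the distinct target proteins adjacent to it
#' in the (filtered) network. Returns how many query genes interact with at
#' least one target and the mean interactor count over all query genes
#' (zeros included).
#'
#' @param queryGenes Non-empty character vector.
#' @param targetProteins Character vector of target-set proteins.
#' @param network A filtered [InteractionNetwork].
#' @return List with `nInteracting`, `meanInteractors` and `perGene` (named
#'   integer vector).
#' @export
countInteractors <- function(queryGenes, targetProteins, network) {
  if (length(queryGenes) == 0L) stop("empty query set", call. = FALSE)
  deg <- .targetDegree(queryGenes, targetProteins, network)
  list(nInteracting = sum(deg >= 1L),
       meanInteractors = mean(deg),
       perGene = deg)
}

#' Resampling null for interaction enrichment
#'
#' Compares a query gene set's interaction statistics against `nDraws`
#' uniform without-replacement samples of the same size from the gene
#' universe. Both statistics — the number of genes with at least one
#' target-set interactor and the mean interactor count — are computed per
#' draw. Percentiles use the mid-probability convention: the fraction of
#' draws strictly below the observed value plus half the ties, times 100,
#' which keeps the percentile calibrated on discrete statistics.
#'
#' @param queryGenes The observed gene set.
#' @param geneUniverse Universe to resample from; must contain >= the query
#'   size.
#' @param targetProteins Target-set proteins.
#' @param network A filtered [InteractionNetwork].
#' @param nDraws Number of null draws (default 10000; < 100 warns).
#' @param seed Resampling seed.
#' @return An `EnrichmentResult`.
#' @export
resampleNull <- function(queryGenes, geneUniverse, targetProteins, network,
                         nDraws = 10000L, seed = 1L) {
  stopifnot(length(queryGenes) >= 1L)
  if (length(queryGenes) > length(geneUniverse)) {
    stop("query set larger than the gene universe", call. = FALSE)
  }
  if (nDraws < 100L) warning("fewer than 100 draws gives an unstable percentile")
  obs <- countInteractors(queryGenes, targetProteins, network)
  deg <- .targetDegree(geneUniverse, targetProteins, network)
  m <- length(queryGenes)
  nullN <- numeric(nDraws)
  nullMean <- numeric(nDraws)
  .withSeed(seed, {
    for (i in seq_len(nDraws)) {
      idx <- sample.int(length(deg), m)
      d <- deg[idx]
      nullN[i] <- sum(d >= 1L)
      nullMean[i] <- mean(d)
    }
  })
  midp <- function(null, observed) {
    100 * (sum(null < observed) + 0.5 * sum(null == observed)) / length(null)
  }
  new("EnrichmentResult",
      observedNInteracting = as.integer(obs$nInteracting),
      observedMeanInteractors = obs$meanInteractors,
      nullNInteracting = nullN, nullMeanInteractors = nullMean,
      percentileN = midp(nullN, obs$nInteracting),
      percentileMean = midp(nullMean, obs$meanInteractors),
      nDraws = as.integer(nDraws), seed = as.integer(seed),
      querySize = as.integer(m))
}
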