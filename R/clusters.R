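#' Read an OrthoFinder-style orthogroups table
#'
#' Tab-separated with header \code{Orthogroup} plus one column per species;
#' each cell lists that species' member gene ids for the row's cluster,
#' comma(+space)-separated, possibly empty. Sequences absent from every row
#' are not represented in the file, so \code{unassigned} is left empty
#' unless \code{allSequenceIds} is supplied.
#'
#' @param path file path.
#' @param speciesNames character vector of known species; a header species
#'   outside this set is an error.
#' @param allSequenceIds optional character vector of all input sequence
#'   ids; ids not present in any cluster are recorded as unassigned.
#' @return a [ClusterSet-class].
#' @export
readOrthogroupsTsv <- function(path, speciesNames, allSequenceIds = NULL) {
  if (!file.exists(path)) stop(sprintf("orthogroups file '%s' not found", path))
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L || names(tab)[1L] != "Orthogroup")
    stop("header must be 'Orthogroup' followed by one column per species")
  sp <- names(tab)[-1L]
  extra <- setdiff(sp, speciesNames)
  if (length(extra))
    stop(sprintf("species in header but not in species list: %s",
                 paste(extra, collapse = ", ")))
  clusters <- list()
  for (i in seq_len(nrow(tab))) {
    members <- list()
    for (s in sp) {
      cell <- trimws(tab[i, s])
      if (nzchar(cell)) {
        ids <- trimws(strsplit(cell, ",", fixed = TRUE)[[1L]])
        members[[s]] <- ids[nzchar(ids)]
      }
    }
    if (length(members)) clusters[[tab$Orthogroup[i]]] <- members
  }
  ids <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(ids))
    stop(sprintf("gene id '%s' appears in more than one orthogroup",
                 ids[duplicated(ids)][1L]))
  un <- if (is.null(allSequenceIds)) character() else
    sort(setdiff(allSequenceIds, ids))
  new("ClusterSet", clusters = clusters, unassigned = un)
}

#' Write a ClusterSet in orthogroups table format
#'
#' @param cs a [ClusterSet-class].
#' @param path output file path.
#' @param speciesNames column order; defaults to the sorted species seen in
#'   the clusters.
#' @return \code{path}, invisibly.
#' @export
writeOrthogroupsTsv <- function(cs, path, speciesNames = NULL) {
  stopifnot(is(cs, "ClusterSet"))
  if (is.null(speciesNames))
    speciesNames <- sort(unique(unlist(lapply(cs@clusters, names))))
  rows <- lapply(names(cs@clusters), function(cid) {
    cl <- cs@clusters[[cid]]
    c(cid, vapply(speciesNames, function(s)
      if (s %in% names(cl)) paste(cl[[s]], collapse = ", ") else "",
      character(1)))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- matrix(character(), 0, length(speciesNames) + 1L)
  colnames(tab) <- c("Orthogroup", speciesNames)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cluster sequences by single linkage over reciprocal alignment scores
#'
#' A self-contained ortholog clusterer: every sequence pair whose local
#' alignments in both directions reach \code{minBit} bits contributes an
#' edge, and clusters are the connected components of the resulting graph
#' with at least two members; singletons go to \code{unassigned}. This is a
#' deliberately simple stand-in for graph-based orthogroup inference tools
#' (no score normalization, no MCL); pre-computed orthogroup tables can be
#' imported with [readOrthogroupsTsv()] instead.
#'
#' @param seqs named character vector or \link[Biostrings]{AAStringSet} of
#'   all protein sequences across species.
#' @param speciesOf named character vector mapping each sequence id to its
#'   species id.
#' @param scheme a [scoringScheme()].
#' @param minBit bit-score threshold for an edge (inclusive).
#' @return a [ClusterSet-class]; cluster ids are \code{OG0000000},
#'   \code{OG0000001}, ... assigned in order of each component's smallest
#'   member id, so the result is invariant under input order.
#' @export
internalCluster <- function(seqs, speciesOf, scheme = scoringScheme(),
                            minBit = 50) {
  if (length(seqs) == 0L) stop("no sequences to cluster")
  seqs <- .asNamedChar(seqs, "input")
  ids <- names(seqs)
  if (!all(ids %in% names(speciesOf)))
    stop(sprintf("no species recorded for sequence '%s'",
                 setdiff(ids, names(speciesOf))[1L]))
  ord <- order(ids)
  seqs <- seqs[ord]
  ids <- ids[ord]
  r <- .alignAllPairs(seqs, seqs, scheme)
  bits <- bitScore(r$score, scheme)
  adj <- (bits >= minBit) & (t(bits) >= minBit)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  clusters <- list()
  un <- character()
  memberSets <- split(ids, comp$membership)
  memberSets <- memberSets[order(vapply(memberSets, min, character(1)))]
  cidx <- 0L
  for (ms in memberSets) {
    if (length(ms) < 2L) { un <- c(un, ms); next }
    bySpecies <- split(ms, unname(speciesOf[ms]))
    bySpecies <- lapply(bySpecies[order(names(bySpecies))], sort)
    clusters[[sprintf("OG%07d", cidx)]] <- bySpecies
    cidx <- cidx + 1L
  }
  new("ClusterSet", clusters = clusters, unassigned = sort(un))
}

## Unordered co-membership pair counts used by the pairwise metrics.
.pairCounts <- function(cs, truth) {
  clustered <- unlist(cs@clusters, use.names = FALSE)
  missing <- setdiff(clustered, names(truth))
  if (length(missing))
    stop(sprintf("clustered sequence(s) without a truth label: %s",
                 paste(utils::head(missing, 3L), collapse = ", ")))
  correct <- 0L
  total <- 0L
  for (cl in cs@clusters) {
    ms <- unlist(cl, use.names = FALSE)
    n <- length(ms)
    total <- total + (n * (n - 1L)) %/% 2L
    labs <- table(truth[ms])
    correct <- correct + sum(labs * (labs - 1L)) %/% 2L
  }
  truthLabs <- table(truth)
  truePairs <- sum(truthLabs * (truthLabs - 1L)) %/% 2L
  list(correct = as.integer(correct), total = as.integer(total),
       truePairs = as.integer(truePairs))
}

.clusterEvaluation <- function(p) {
  structure(list(
    correctly_clustered_pairs = p$correct,
    total_clustered_pairs = p$total,
    total_true_pairs = p$truePairs,
    precision = if (p$total > 0) p$correct / p$total else NA_real_,
    recall = if (p$truePairs > 0) p$correct / p$truePairs else NA_real_),
    class = "ClusterEvaluation")
}

#' Pairwise clustering precision
#'
#' Of all unordered pairs of sequences placed together in one cluster, the
#' fraction sharing the same function label. Unassigned singletons take
#' part in no clustered pair and so are excluded; an all-singleton
#' clustering has no clustered pairs and precision is undefined (an error,
#' forcing explicit handling).
#'
#' @param cs a [ClusterSet-class].
#' @param truth named character vector mapping sequence id to its true
#'   function label; every clustered sequence must be labelled.
#' @return a \code{ClusterEvaluation} list: pair counts plus
#'   \code{precision} and \code{recall} in \eqn{[0, 1]} (the one whose
#'   denominator is zero is NA).
#' @export
clusteringPrecision <- function(cs, truth) {
  stopifnot(is(cs, "ClusterSet"))
  p <- .pairCounts(cs, truth)
  if (p$total == 0L)
    stop("no clustered pairs: precision is undefined")
  .clusterEvaluation(p)
}

#' Pairwise clustering recall
#'
#' Of all unordered pairs of sequences sharing the same function label in
#' the truth (including pairs involving unassigned sequences), the fraction
#' placed together in one cluster.
#'
#' @inheritParams clusteringPrecision
#' @return a \code{ClusterEvaluation} list (see [clusteringPrecision()]).
#' @export
clusteringRecall <- function(cs, truth) {
  stopifnot(is(cs, "ClusterSet"))
  p <- .pairCounts(cs, truth)
  if (p$truePairs == 0L)
    stop("no same-label pairs in truth: recall is undefined")
  .clusterEvaluation(p)
}

#' @export
print.ClusterEvaluation <- function(x, ...) {
  cat(sprintf("ClusterEvaluation: %d/%d clustered pairs correct; %d true pairs\n",
              x$correctly_clustered_pairs, x$total_clustered_pairs,
              x$total_true_pairs))
  cat(sprintf("  precision = %s, recall = %s\n",
              format(x$precision, digits = 4),
              format(x$recall, digits = 4)))
  invisible(x)
}
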