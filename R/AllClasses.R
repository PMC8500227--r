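#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
NULL

## Amino-acid alphabet accepted throughout: the 20 standard residues plus X
## (unknown). '*' is rejected; stop codons never reach protein containers.
AA_ALPHABET20X <- c("A","C","D","E","F","G","H","I","K","L",
                    "M","N","P","Q","R","S","T","V","W","Y","X")

KO_PATTERN <- "^K[0-9]{5}$"

.validKo <- function(x) grepl(KO_PATTERN, toupper(x))

.validGprAst <- function(ast) {
  if (!is.list(ast) || is.null(ast$op)) return("AST node is not a tagged list")
  if (ast$op == "KO") {
    if (!is.character(ast$ko) || length(ast$ko) != 1L || !.validKo(ast$ko))
      return(sprintf("invalid KO leaf '%s'", paste(ast$ko, collapse = ",")))
    return(TRUE)
  }
  if (!ast$op %in% c("AND", "OR"))
    return(sprintf("unknown operator '%s'", ast$op))
  if (length(ast$children) < 2L)
    return(sprintf("%s node with fewer than 2 children", ast$op))
  for (ch in ast$children) {
    v <- .validGprAst(ch)
    if (!isTRUE(v)) return(v)
  }
  TRUE
}

#' Gene-protein-reaction rule
#'
#' A boolean expression over KEGG Orthology (KO) identifiers stating which
#' gene sets enable one reaction: \code{AND} joins subunits of a protein
#' complex, \code{OR} joins isoenzymes or alternative complexes. The
#' expression is stored as an abstract syntax tree whose leaves are KO
#' identifiers; negation is not representable, so every rule is monotone.
#'
#' @slot reactionId single reaction identifier the rule belongs to.
#' @slot ast nested list representation of the expression: a leaf is
#'   \code{list(op = "KO", ko = "K00001")}; an internal node is
#'   \code{list(op = "AND"|"OR", children = list(...))} with at least two
#'   children.
#'
#' @seealso [parseGpr()], [evaluateGpr()], [gprToString()]
#' @export
setClass("GprRule", representation(reactionId = "character", ast = "list"))

setValidity("GprRule", function(object) {
  if (length(object@reactionId) != 1L || !nzchar(object@reactionId) ||
      grepl("[[:space:]]", object@reactionId))
    return("reactionId must be one non-empty token without whitespace")
  v <- .validGprAst(object@ast)
  if (!isTRUE(v)) return(v)
  TRUE
})

#' Ortholog-reaction association database (ORAdb)
#'
#' Reference protein sequence sets, one per KO, together with the mapping
#' from reactions to the KOs that can carry them and the gene-protein-
#' reaction rule of each reaction. This is the reference the two-stage
#' annotation searches against.
#'
#' @slot koSequences named list (one entry per KO) of
#'   \link[Biostrings]{AAStringSet} reference sequences; an entry may be
#'   empty, in which case the load report flags it.
#' @slot reactionKos named list mapping each reaction identifier to the
#'   character vector of KOs associated with it.
#' @slot gprRules named list of [GprRule-class] objects; reactions without an
#'   explicit rule default to OR over their KO set (a single protein
#'   suffices) and are flagged in the report.
#' @slot report data.frame with columns \code{item} and \code{issue}
#'   recording unresolved identifiers, empty KO sets and defaulted rules.
#'
#' @seealso [buildOradb()], [readOradb()], [writeOradb()],
#'   [reactionCapabilities()]
#' @export
setClass("ORAdb", representation(koSequences = "list", reactionKos = "list",
                                 gprRules = "list", report = "data.frame"))

setValidity("ORAdb", function(object) {
  kos <- names(object@koSequences)
  if (length(object@koSequences) && (is.null(kos) || anyDuplicated(kos)))
    return("koSequences must be uniquely named by KO")
  if (length(kos) && !all(.validKo(kos)))
    return(sprintf("malformed KO identifier(s): %s",
                   paste(kos[!.validKo(kos)], collapse = ", ")))
  for (ko in kos) {
    ss <- object@koSequences[[ko]]
    if (!is(ss, "AAStringSet"))
      return(sprintf("koSequences[['%s']] is not an AAStringSet", ko))
    if (length(ss)) {
      if (anyDuplicated(names(ss)))
        return(sprintf("duplicate sequence ids within KO '%s'", ko))
      bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET20X, collapse = "")),
                   as.character(ss))
      if (any(bad))
        return(sprintf("illegal residue in sequence '%s' of KO '%s'",
                       names(ss)[bad][1L], ko))
    }
  }
  rids <- names(object@reactionKos)
  if (length(object@reactionKos) && (is.null(rids) || anyDuplicated(rids)))
    return("reactionKos must be uniquely named by reaction")
  referenced <- unique(c(unlist(object@reactionKos, use.names = FALSE),
                         unlist(lapply(object@gprRules, function(r)
                           gprKos(r)), use.names = FALSE)))
  missing <- setdiff(referenced, kos)
  if (length(missing))
    return(sprintf("KO(s) referenced but absent from koSequences: %s",
                   paste(missing, collapse = ", ")))
  if (length(object@gprRules)) {
    if (is.null(names(object@gprRules)))
      return("gprRules must be named by reaction")
    if (!all(vapply(object@gprRules, is, logical(1), "GprRule")))
      return("gprRules entries must be GprRule objects")
  }
  TRUE
})

#' Set of ortholog clusters
#'
#' Clusters of protein sequences across species inferred to share ancestry
#' (orthogroups), plus the sequences left unassigned (singletons). Clusters
#' and unassigned sequences together partition the input sequence ids.
#'
#' @slot clusters named list, one entry per cluster; each cluster is itself a
#'   named list mapping species id to the character vector of member
#'   sequence ids from that species.
#' @slot unassigned character vector of sequence ids in no cluster.
#'
#' @seealso [readOrthogroupsTsv()], [internalCluster()],
#'   [clusteringPrecision()]
#' @export
setClass("ClusterSet",
         representation(clusters = "list", unassigned = "character"))

setValidity("ClusterSet", function(object) {
  if (length(object@clusters)) {
    if (is.null(names(object@clusters)) || anyDuplicated(names(object@clusters)))
      return("clusters must be uniquely named")
    sizes <- vapply(object@clusters, function(cl)
      length(unlist(cl, use.names = FALSE)), integer(1))
    if (any(sizes == 0L))
      return("every cluster must have at least one member sequence")
  }
  ids <- c(unlist(object@clusters, use.names = FALSE), object@unassigned)
  if (anyDuplicated(ids))
    return(sprintf("sequence id(s) present more than once: %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  TRUE
})

#' Two-stage annotation result
#'
#' Output of the relaxed (candidate KO discovery on a sample of each
#' cluster) and restrictive (full-cluster confirmation at strict thresholds)
#' annotation stages.
#'
#' @slot candidateKos named list mapping cluster id to the character vector
#'   of candidate KOs found by the relaxed stage; clusters with no candidate
#'   are absent.
#' @slot assignments data.frame with one row per confirmed (sequence, KO)
#'   annotation and the best supporting hit: columns \code{sequence_id},
#'   \code{ko}, \code{subject_id}, \code{evalue}, \code{bit_score},
#'   \code{pct_identity}, \code{aln_len}.
#'
#' @seealso [relaxedSearch()], [restrictiveSearch()], [speciesKoTable()]
#' @export
setClass("AnnotationResult",
         representation(candidateKos = "list", assignments = "data.frame"))

setValidity("AnnotationResult", function(object) {
  need <- c("sequence_id", "ko", "subject_id", "evalue", "bit_score",
            "pct_identity", "aln_len")
  if (!all(need %in% names(object@assignments)))
    return(sprintf("assignments must have columns: %s",
                   paste(need, collapse = ", ")))
  TRUE
})

#' Predicted species interactions for one pathway
#'
#' Species individually able to perform every reaction of the pathway
#' (complete species) and all enumerated multi-species combinations whose
#' joint capabilities cover it under the active constraints, with the
#' contributing species recorded per reaction.
#'
#' @slot pathwayName name of the pathway the result refers to.
#' @slot reactions the pathway's reaction identifiers, in pathway order.
#' @slot completeSpecies character vector of species whose own row covers
#'   every pathway reaction.
#' @slot combinations list of combinations ordered by size then
#'   lexicographically; each element is
#'   \code{list(members = <character>, contributors = <named list reaction ->
#'   character>)}.
#'
#' @seealso [enumerateCombinations()], [writeInteractions()]
#' @export
setClass("InteractionResult",
         representation(pathwayName = "character", reactions = "character",
                        completeSpecies = "character", combinations = "list"))

setValidity("InteractionResult", function(object) {
  for (cmb in object@combinations) {
    if (!is.list(cmb) || is.null(cmb$members) || length(cmb$members) < 2L)
      return("every combination must have at least 2 members")
  }
  TRUE
})

setMethod("show", "GprRule", function(object) {
  cat(sprintf("GprRule for %s: %s\n", object@reactionId, gprToString(object)))
})

setMethod("show", "ORAdb", function(object) {
  nseq <- sum(vapply(object@koSequences, length, integer(1)))
  cat(sprintf("ORAdb: %d KO(s), %d reference sequence(s), %d reaction(s)\n",
              length(object@koSequences), nseq, length(object@reactionKos)))
  if (nrow(object@report))
    cat(sprintf("  load report: %d flagged item(s)\n", nrow(object@report)))
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet: %d cluster(s), %d clustered sequence(s), %d unassigned\n",
              length(object@clusters),
              length(unlist(object@clusters, use.names = FALSE)),
              length(object@unassigned)))
})

setMethod("show", "AnnotationResult", function(object) {
  cat(sprintf("AnnotationResult: %d cluster(s) with candidates, %d (sequence, KO) assignment(s)\n",
              length(object@candidateKos), nrow(object@assignments)))
})

setMethod("show", "InteractionResult", function(object) {
  cat(sprintf("InteractionResult for pathway '%s' (%d reactions)\n",
              object@pathwayName, length(object@reactions)))
  cat(sprintf("  complete species: %s\n",
              if (length(object@completeSpecies))
                paste(object@completeSpecies, collapse = ", ") else "none"))
  cat(sprintf("  covering combinations: %d\n", length(object@combinations)))
})
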