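#' @rdname ORAdb-accessors
#' @export
setGeneric("koIds", function(x) standardGeneric("koIds"))

#' @rdname ORAdb-accessors
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname ORAdb-accessors
#' @export
setGeneric("koSequences", function(x, ko) standardGeneric("koSequences"))

#' @rdname ORAdb-accessors
#' @export
setGeneric("reactionKos", function(x, reaction) standardGeneric("reactionKos"))

#' @rdname ORAdb-accessors
#' @export
setGeneric("gprRule", function(x, reaction) standardGeneric("gprRule"))

#' @rdname ORAdb-accessors
#' @export
setGeneric("loadReport", function(x) standardGeneric("loadReport"))

#' @rdname ClusterSet-accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname ClusterSet-accessors
#' @export
setGeneric("unassigned", function(x) standardGeneric("unassigned"))

#' @rdname ClusterSet-accessors
#' @export
setGeneric("clusterMembers", function(x, cluster) standardGeneric("clusterMembers"))

#' @rdname AnnotationResult-accessors
#' @export
setGeneric("candidateKos", function(x) standardGeneric("candidateKos"))

#' @rdname AnnotationResult-accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' Species able to perform a whole pathway
#'
#' On a binary species-by-reaction capability matrix, returns the species
#' whose row is 1 for every reaction of the pathway. On an
#' [InteractionResult-class], returns the complete species recorded when the
#' result was computed.
#'
#' @param x a capability matrix from [reactionCapabilities()] or an
#'   [InteractionResult-class].
#' @param pathway a pathway definition from [pathwayDef()] (matrix method
#'   only).
#' @return character vector of species identifiers, lexicographically
#'   sorted.
#' @examples
#' tab <- matrix(c(1, 1, 1, 0), 2, 2,
#'               dimnames = list(c("spA", "spB"), c("R00001", "R00002")))
#' completeSpecies(tab, pathwayDef("p", c("R00001", "R00002")))
#' @export
setGeneric("completeSpecies", function(x, pathway) standardGeneric("completeSpecies"))

#' @rdname InteractionResult-accessors
#' @export
setGeneric("combinations", function(x) standardGeneric("combinations"))

#' Accessors for ORAdb objects
#'
#' \code{koIds} and \code{reactionIds} list the database's KO and reaction
#' identifiers; \code{koSequences} returns one KO's reference
#' \link[Biostrings]{AAStringSet} (or the full named list when \code{ko} is
#' missing); \code{reactionKos} returns a reaction's KO set (or the full
#' mapping); \code{gprRule} returns the reaction's [GprRule-class], falling
#' back to OR over the reaction's KO set when no explicit rule was loaded;
#' \code{loadReport} returns the data.frame of flagged load issues.
#'
#' @param x an [ORAdb-class] object.
#' @param ko,reaction optional single identifier to select one entry.
#' @name ORAdb-accessors
NULL

setMethod("koIds", "ORAdb", function(x) names(x@koSequences))
setMethod("reactionIds", "ORAdb", function(x) names(x@reactionKos))
setMethod("loadReport", "ORAdb", function(x) x@report)

setMethod("koSequences", "ORAdb", function(x, ko) {
  if (missing(ko)) return(x@koSequences)
  if (!ko %in% names(x@koSequences))
    stop(sprintf("KO '%s' not in database", ko))
  x@koSequences[[ko]]
})

setMethod("reactionKos", "ORAdb", function(x, reaction) {
  if (missing(reaction)) return(x@reactionKos)
  if (!reaction %in% names(x@reactionKos))
    stop(sprintf("reaction '%s' not in database", reaction))
  x@reactionKos[[reaction]]
})

setMethod("gprRule", "ORAdb", function(x, reaction) {
  if (!reaction %in% names(x@reactionKos))
    stop(sprintf("reaction '%s' not in database", reaction))
  if (reaction %in% names(x@gprRules)) return(x@gprRules[[reaction]])
  defaultGprRule(reaction, x@reactionKos[[reaction]])
})

#' Accessors for ClusterSet objects
#'
#' \code{clusters} returns the named list of clusters (each a named list
#' species -> member sequence ids); \code{unassigned} the singleton
#' sequence ids; \code{clusterMembers} one cluster's member ids flattened
#' across species.
#'
#' @param x a [ClusterSet-class] object.
#' @param cluster single cluster identifier.
#' @name ClusterSet-accessors
NULL

setMethod("clusters", "ClusterSet", function(x) x@clusters)
setMethod("unassigned", "ClusterSet", function(x) x@unassigned)
setMethod("clusterMembers", "ClusterSet", function(x, cluster) {
  if (!cluster %in% names(x@clusters))
    stop(sprintf("cluster '%s' not in ClusterSet", cluster))
  unlist(x@clusters[[cluster]], use.names = FALSE)
})

#' Accessors for AnnotationResult objects
#'
#' \code{candidateKos} returns the relaxed-stage candidate map (cluster ->
#' KOs); \code{assignments} the confirmed per-sequence annotation table.
#'
#' @param x an [AnnotationResult-class] object.
#' @name AnnotationResult-accessors
NULL

setMethod("candidateKos", "AnnotationResult", function(x) x@candidateKos)
setMethod("assignments", "AnnotationResult", function(x) x@assignments)

#' Accessors for InteractionResult objects
#'
#' \code{combinations} returns the list of covering species combinations;
#' \code{completeSpecies} the species individually covering the pathway.
#'
#' @param x an [InteractionResult-class] object.
#' @name InteractionResult-accessors
NULL

setMethod("combinations", "InteractionResult", function(x) x@combinations)
setMethod("completeSpecies", "InteractionResult",
          function(x, pathway) x@completeSpecies)
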