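#' Annotation thresholds and sampling configuration
#'
#' Parameters of the two-stage annotation. The relaxed stage aligns a
#' random sample of each cluster (default half of it) against the whole
#' reference database and keeps clusters with any hit at
#' \code{relaxedEvalue} or better; it is a permissive pre-filter meant to
#' capture candidates while avoiding a full all-vs-all. The restrictive
#' stage re-aligns every cluster sequence against the candidate KOs'
#' reference sets and confirms an annotation only at
#' \code{restrictiveEvalue} or better (inclusive) with a bit score strictly
#' greater than \code{minBitScore}.
#'
#' @param relaxedEvalue relaxed-stage E-value threshold (default 0.001).
#' @param restrictiveEvalue restrictive-stage E-value threshold (default
#'   1e-9); must not exceed \code{relaxedEvalue}.
#' @param minBitScore bit-score floor, applied strictly (default 50).
#' @param sampleFraction fraction of each cluster sampled in the relaxed
#'   stage, in (0, 1] (default 0.5).
#' @param seed integer sampling seed; the per-cluster stream is derived
#'   from it and the cluster id, so cluster order does not matter.
#' @return an \code{AnnotationConfig} (classed list).
#' @export
annotationConfig <- function(relaxedEvalue = 0.001, restrictiveEvalue = 1e-9,
                             minBitScore = 50, sampleFraction = 0.5,
                             seed = 42L) {
  if (relaxedEvalue < restrictiveEvalue)
    stop("relaxedEvalue must be >= restrictiveEvalue")
  if (sampleFraction <= 0 || sampleFraction > 1)
    stop("sampleFraction must be in (0, 1]")
  structure(list(relaxedEvalue = relaxedEvalue,
                 restrictiveEvalue = restrictiveEvalue,
                 minBitScore = minBitScore,
                 sampleFraction = sampleFraction,
                 seed = as.integer(seed)),
            class = "AnnotationConfig")
}

## 31-adic string hash mod 2^31-1; combined with the user seed it gives each
## cluster its own deterministic sampling stream.
.hashString <- function(x) {
  h <- 0
  for (v in utf8ToInt(x)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

.withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample sequences from a cluster for the relaxed stage
#'
#' Uniform sampling without replacement of \code{ceiling(fraction * size)}
#' members (at least 1, so one-member clusters are always represented).
#' Deterministic: the RNG stream is seeded from \code{seed} combined with a
#' hash of the cluster id, and members are sampled from their sorted order,
#' so neither cluster order nor member order changes the sample.
#'
#' @param memberIds character vector of the cluster's sequence ids.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer base seed.
#' @param clusterId cluster identifier combined into the seed.
#' @return character vector of sampled sequence ids.
#' @export
sampleCluster <- function(memberIds, fraction, seed = 42L,
                          clusterId = "cluster") {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  ids <- sort(memberIds)
  n <- max(1L, as.integer(ceiling(fraction * length(ids))))
  if (n >= length(ids)) return(ids)
  derived <- bitwXor(as.integer(seed), .hashString(clusterId)) %% 2147483647L
  .withLocalSeed(derived, sort(sample(ids, n)))
}

## Flatten a db's reference sequences with their KO of origin.
.referencePool <- function(db, kos = koIds(db)) {
  seqs <- character()
  koOf <- character()
  for (ko in kos) {
    ss <- db@koSequences[[ko]]
    if (length(ss)) {
      v <- as.character(ss)
      names(v) <- paste(ko, names(ss), sep = "|")
      seqs <- c(seqs, v)
      koOf <- c(koOf, stats::setNames(rep(ko, length(v)), names(v)))
    }
  }
  list(seqs = seqs, koOf = koOf)
}

#' Relaxed search: candidate KO discovery per cluster
#'
#' Aligns a random sample of each cluster (see [sampleCluster()]) against
#' every reference sequence in the database. A KO becomes a candidate for a
#' cluster when any sampled sequence hits any of that KO's references with
#' E-value at or below the relaxed threshold; only E-values count at this
#' stage. Clusters with no candidate KO are dropped from the result.
#'
#' @param cs a [ClusterSet-class].
#' @param seqs named character vector or \link[Biostrings]{AAStringSet}
#'   holding every clustered sequence.
#' @param db an [ORAdb-class].
#' @param config an [annotationConfig()].
#' @param scheme a [scoringScheme()].
#' @return named list mapping cluster id to its sorted candidate KO vector.
#' @export
relaxedSearch <- function(cs, seqs, db, config = annotationConfig(),
                          scheme = scoringScheme()) {
  stopifnot(is(cs, "ClusterSet"), is(db, "ORAdb"))
  seqs <- .asNamedChar(seqs, "cluster")
  pool <- .referencePool(db)
  if (length(pool$seqs) == 0L) stop("database has no reference sequences")
  nres <- sum(nchar(pool$seqs))
  out <- list()
  for (cid in names(cs@clusters)) {
    members <- unlist(cs@clusters[[cid]], use.names = FALSE)
    miss <- setdiff(members, names(seqs))
    if (length(miss))
      stop(sprintf("no sequence supplied for cluster member '%s'", miss[1L]))
    sampled <- sampleCluster(members, config$sampleFraction, config$seed, cid)
    r <- .alignAllPairs(seqs[sampled], pool$seqs, scheme)
    ev <- eValue(bitScore(r$score, scheme),
                 m = matrix(nchar(seqs[sampled]), nrow = length(sampled),
                            ncol = length(pool$seqs)), n = nres)
    hit <- which(ev <= config$relaxedEvalue, arr.ind = TRUE)
    if (nrow(hit)) {
      kos <- sort(unique(unname(pool$koOf[colnames(ev)[hit[, 2L]]])))
      out[[cid]] <- kos
    }
  }
  out
}

#' Restrictive search: full-cluster confirmation of candidate KOs
#'
#' For every cluster that survived the relaxed stage, aligns all of its
#' sequences against the full reference sets of its candidate KOs. A
#' sequence is annotated with a KO when its best hit against that KO's
#' references has E-value at or below the restrictive threshold and a bit
#' score strictly greater than the floor; a sequence may carry several KO
#' annotations. The E-value search space is the whole database's reference
#' residues, as in the relaxed stage: restricting the alignments computed
#' does not change the statistical reference, so the two stages use one
#' E-value scale.
#'
#' @param candidates output of [relaxedSearch()].
#' @inheritParams relaxedSearch
#' @return an [AnnotationResult-class].
#' @export
restrictiveSearch <- function(candidates, cs, seqs, db,
                              config = annotationConfig(),
                              scheme = scoringScheme()) {
  stopifnot(is(cs, "ClusterSet"), is(db, "ORAdb"))
  seqs <- .asNamedChar(seqs, "cluster")
  nres <- sum(nchar(.referencePool(db)$seqs))
  rows <- list()
  for (cid in names(candidates)) {
    kos <- candidates[[cid]]
    bad <- setdiff(kos, koIds(db))
    if (length(bad))
      stop(sprintf("candidate KO '%s' absent from database", bad[1L]))
    pool <- .referencePool(db, kos)
    if (length(pool$seqs) == 0L) next
    members <- unlist(cs@clusters[[cid]], use.names = FALSE)
    r <- .alignAllPairs(seqs[members], pool$seqs, scheme)
    bits <- bitScore(r$score, scheme)
    ev <- eValue(bits, m = matrix(nchar(seqs[members]),
                                  nrow = length(members),
                                  ncol = length(pool$seqs)), n = nres)
    for (qi in seq_along(members)) {
      for (ko in kos) {
        cols <- which(unname(pool$koOf) == ko)
        if (length(cols) == 0L) next
        bi <- cols[which.max(bits[qi, cols])]
        if (ev[qi, bi] <= config$restrictiveEvalue &&
            bits[qi, bi] > config$minBitScore) {
          rows[[length(rows) + 1L]] <- data.frame(
            sequence_id = members[qi], ko = ko,
            subject_id = sub("^[^|]*\\|", "", names(pool$seqs)[bi]),
            evalue = ev[qi, bi], bit_score = bits[qi, bi],
            pct_identity = if (r$aln_len[qi, bi] > 0)
              100 * r$n_ident[qi, bi] / r$aln_len[qi, bi] else 0,
            aln_len = r$aln_len[qi, bi], stringsAsFactors = FALSE)
        }
      }
    }
  }
  asn <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence_id = character(), ko = character(),
               subject_id = character(), evalue = numeric(),
               bit_score = numeric(), pct_identity = numeric(),
               aln_len = integer(), stringsAsFactors = FALSE)
  asn <- asn[order(asn$sequence_id, asn$ko), , drop = FALSE]
  rownames(asn) <- NULL
  new("AnnotationResult", candidateKos = candidates, assignments = asn)
}

#' Aggregate sequence annotations into a species-KO table
#'
#' @param result an [AnnotationResult-class].
#' @param seqSpecies named character vector mapping sequence id to species
#'   id; every annotated sequence must be mapped.
#' @return named list mapping species id to its sorted KO vector (set
#'   semantics: duplicate annotations within a species collapse).
#' @export
speciesKoTable <- function(result, seqSpecies) {
  stopifnot(is(result, "AnnotationResult"))
  asn <- result@assignments
  miss <- setdiff(unique(asn$sequence_id), names(seqSpecies))
  if (length(miss))
    stop(sprintf("annotated sequence '%s' has no species mapping", miss[1L]))
  if (nrow(asn) == 0L) return(list())
  sp <- unname(seqSpecies[asn$sequence_id])
  out <- lapply(split(asn$ko, sp), function(k) sort(unique(k)))
  out[order(names(out))]
}

#' Annotation performance against a reference annotation
#'
#' The fraction of reference (sequence, KO) annotations that the predicted
#' annotation also contains.
#'
#' @param predicted,reference data.frames with columns \code{sequence_id}
#'   and \code{ko} (extra columns ignored); \code{reference} must be
#'   non-empty.
#' @return list with \code{matching_annotated},
#'   \code{total_reference_annotations} and \code{performance} in
#'   \eqn{[0, 1]}.
#' @export
annotationPerformance <- function(predicted, reference) {
  keyOf <- function(df) {
    if (!all(c("sequence_id", "ko") %in% names(df)))
      stop("need columns sequence_id and ko")
    unique(paste(df$sequence_id, df$ko, sep = "\r"))
  }
  ref <- keyOf(reference)
  if (length(ref) == 0L) stop("reference annotation set is empty")
  pred <- keyOf(predicted)
  m <- length(intersect(pred, ref))
  list(matching_annotated = m, total_reference_annotations = length(ref),
       performance = m / length(ref))
}

#' Write the binary species-by-KO table as CSV
#'
#' @param speciesKos named list from [speciesKoTable()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSpeciesKoTable <- function(speciesKos, path) {
  sp <- sort(names(speciesKos))
  kos <- sort(unique(unlist(speciesKos, use.names = FALSE)))
  tab <- matrix(0L, length(sp), length(kos), dimnames = list(sp, kos))
  for (s in sp) tab[s, speciesKos[[s]]] <- 1L
  utils::write.csv(data.frame(species = sp, tab, check.names = FALSE,
                              row.names = NULL), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write the binary species-by-reaction capability table as CSV
#'
#' @param tab matrix from [reactionCapabilities()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeReactionTable <- function(tab, path) {
  utils::write.csv(data.frame(species = rownames(tab), tab,
                              check.names = FALSE, row.names = NULL),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a binary species-by-reaction capability table written by
#' [writeReactionTable()]
#'
#' @param path CSV path; first column \code{species}, remaining columns one
#'   per reaction, entries 0/1.
#' @return integer matrix with species rownames and reaction colnames.
#' @export
readReactionTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "species") stop("first column must be 'species'")
  tab <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(tab) <- "integer"
  rownames(tab) <- df$species
  tab
}

#' Per-cluster annotation report
#'
#' One row per input cluster stating how far it progressed through the two
#' stages and why it was dropped, for inspection alongside the main
#' outputs.
#'
#' @param cs the input [ClusterSet-class].
#' @param candidates relaxed-stage output.
#' @param result an [AnnotationResult-class].
#' @return data.frame with columns \code{cluster_id}, \code{stage_reached}
#'   (\code{"dropped_relaxed"}, \code{"relaxed"} or \code{"restrictive"}),
#'   \code{candidate_kos} (comma-separated), \code{n_assigned}.
#' @export
annotationReport <- function(cs, candidates, result) {
  asn <- result@assignments
  byCluster <- lapply(cs@clusters, function(cl) unlist(cl, use.names = FALSE))
  rows <- lapply(names(byCluster), function(cid) {
    cand <- candidates[[cid]]
    nAsn <- sum(asn$sequence_id %in% byCluster[[cid]])
    data.frame(
      cluster_id = cid,
      stage_reached = if (is.null(cand)) "dropped_relaxed"
                      else if (nAsn > 0L) "restrictive" else "relaxed",
      candidate_kos = paste(cand, collapse = ","),
      n_assigned = nAsn, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
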