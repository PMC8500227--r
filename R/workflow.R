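## Workflow commands mirror the three shell steps of the pipeline: build the
## reference database, cluster the proteomes, annotate and predict. Each
## returns an exit status (0 ok, 2 input/IO problem, 3 strict identifier
## resolution failure, 4 configuration problem) instead of raising, so the
## thin command-line dispatcher in inst/cli/ can forward it to the shell.

.statusMsg <- function(status, msg) {
  message(msg)
  invisible(as.integer(status))
}

#' Build an ORAdb directory from an identifier list (workflow step 1)
#'
#' Reads the identifier list, resolves it through the fetcher, writes the
#' database directory plus a \code{build_report.tsv} of flagged items.
#'
#' @param idsFile path to the identifier list (one per line, \code{#}
#'   comments).
#' @param outDir output database directory.
#' @param fetcher resolver from [offlineFetcher()].
#' @param strict if TRUE, any unresolved identifier yields exit status 3.
#' @return invisible exit status: 0 ok, 2 input failure, 3 unresolved under
#'   \code{strict}.
#' @export
cmdBuildDb <- function(idsFile, outDir, fetcher, strict = FALSE) {
  res <- tryCatch({
    ids <- readIdList(idsFile)
    if (length(ids) == 0L) stop("identifier list is empty")
    db <- buildOradb(ids, fetcher)
    writeOradb(db, outDir)
    utils::write.table(loadReport(db), file.path(outDir, "build_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    db
  }, error = function(e) e)
  if (inherits(res, "error"))
    return(.statusMsg(2L, sprintf("build-db failed: %s",
                                  conditionMessage(res))))
  rep <- loadReport(res)
  unresolved <- rep$item[rep$issue == "unresolved"]
  if (strict && length(unresolved))
    return(.statusMsg(3L, sprintf("unresolved identifier(s): %s",
                                  paste(unresolved, collapse = ", "))))
  invisible(0L)
}

#' Cluster per-species proteomes (workflow step 2)
#'
#' With the internal engine, clusters all proteome sequences by reciprocal
#' bit-score single linkage ([internalCluster()]); with \code{engine =
#' "import"}, validates a pre-computed orthogroups table against the
#' proteomes and passes it through. Writes \code{Orthogroups.tsv} and
#' \code{clustering_stats.tsv} (sequence, cluster and unassigned counts).
#'
#' @param proteomeDir directory of \code{<species>.fasta} files.
#' @param outDir output directory.
#' @param engine \code{"internal"} or \code{"import"}.
#' @param orthogroups orthogroups TSV path (import engine).
#' @param minBit internal-engine bit-score threshold.
#' @param scheme a [scoringScheme()].
#' @return invisible exit status (0 ok, 2 input failure).
#' @export
cmdCluster <- function(proteomeDir, outDir,
                       engine = c("internal", "import"), orthogroups = NULL,
                       minBit = 50, scheme = scoringScheme()) {
  engine <- match.arg(engine)
  res <- tryCatch({
    prot <- readProteomes(proteomeDir)
    cs <- if (engine == "internal") {
      internalCluster(prot$seqs, prot$speciesOf, scheme, minBit)
    } else {
      if (is.null(orthogroups)) stop("import engine needs an orthogroups file")
      readOrthogroupsTsv(orthogroups, unique(unname(prot$speciesOf)),
                         allSequenceIds = names(prot$seqs))
    }
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeOrthogroupsTsv(cs, file.path(outDir, "Orthogroups.tsv"),
                        sort(unique(unname(prot$speciesOf))))
    stats <- data.frame(
      n_sequences = length(prot$seqs),
      n_clusters = length(clusters(cs)),
      n_clustered = length(unlist(clusters(cs), use.names = FALSE)),
      n_unassigned = length(unassigned(cs)))
    utils::write.table(stats, file.path(outDir, "clustering_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cs
  }, error = function(e) e)
  if (inherits(res, "error"))
    return(.statusMsg(2L, sprintf("cluster failed: %s",
                                  conditionMessage(res))))
  invisible(0L)
}

## Two-stage annotation driven by an imported tabular hit file instead of
## the internal aligner. Subject ids are resolved to KOs through the
## database's reference sequence names.
.annotateFromHits <- function(hits, cs, db, config) {
  koOfSubject <- character()
  for (ko in koIds(db)) {
    nm <- names(db@koSequences[[ko]])
    if (length(nm)) koOfSubject[nm] <- ko
  }
  hits <- hits[hits$subject_id %in% names(koOfSubject), , drop = FALSE]
  hits$ko <- unname(koOfSubject[hits$subject_id])
  candidates <- list()
  for (cid in names(cs@clusters)) {
    members <- unlist(cs@clusters[[cid]], use.names = FALSE)
    sampled <- sampleCluster(members, config$sampleFraction, config$seed, cid)
    h <- hits[hits$query_id %in% sampled &
                hits$evalue <= config$relaxedEvalue, , drop = FALSE]
    if (nrow(h)) candidates[[cid]] <- sort(unique(h$ko))
  }
  rows <- list()
  for (cid in names(candidates)) {
    members <- unlist(cs@clusters[[cid]], use.names = FALSE)
    h <- hits[hits$query_id %in% members & hits$ko %in% candidates[[cid]], ,
              drop = FALSE]
    if (!nrow(h)) next
    for (key in split(seq_len(nrow(h)), paste(h$query_id, h$ko, sep = "\r"))) {
      best <- key[which.max(h$bit_score[key])]
      if (h$evalue[best] <= config$restrictiveEvalue &&
          h$bit_score[best] > config$minBitScore)
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_id = h$query_id[best], ko = h$ko[best],
          subject_id = h$subject_id[best], evalue = h$evalue[best],
          bit_score = h$bit_score[best],
          pct_identity = h$pct_identity[best],
          aln_len = h$aln_len[best], stringsAsFactors = FALSE)
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

#' Annotate clusters and predict interactions (workflow step 3)
#'
#' Runs the two-stage annotation of the clusters against the database,
#' evaluates GPR rules into the species-by-reaction capability table, and
#' enumerates covering species combinations for every pathway. Writes
#' \code{Species_KO_table.csv}, \code{Reactions_mapped_to_species.csv},
#' \code{annotation_report.tsv}, the \code{interactions} folder (per
#' pathway when several are defined), \code{network.json} /
#' \code{network.html}, and a \code{run_log.txt} capturing every threshold
#' and seed. All outputs are deterministic for a fixed seed.
#'
#' @param dbDir ORAdb directory.
#' @param clustersFile orthogroups TSV.
#' @param proteomeDir directory of per-species FASTA files.
#' @param pathwaysFile pathway TSV (see [readPathways()]).
#' @param constraintsFile optional constraint TSV (see [readConstraints()]).
#' @param outDir output directory.
#' @param relaxedEvalue,restrictiveEvalue,minBitScore,sampleFraction,seed
#'   see [annotationConfig()].
#' @param hitsFile optional BLAST 12-column tabular file; when given, the
#'   imported hits replace the internal aligner.
#' @param scheme a [scoringScheme()].
#' @return invisible exit status (0 ok, 2 missing input, 4 pathway
#'   referencing unknown reactions).
#' @export
cmdAnnotateAndPredict <- function(dbDir, clustersFile, proteomeDir,
                                  pathwaysFile, constraintsFile = NULL,
                                  outDir = "ortho_out",
                                  relaxedEvalue = 0.001,
                                  restrictiveEvalue = 1e-9,
                                  minBitScore = 50, sampleFraction = 0.5,
                                  seed = 42L, hitsFile = NULL,
                                  scheme = scoringScheme()) {
  inputs <- tryCatch({
    db <- readOradb(dbDir)
    prot <- readProteomes(proteomeDir)
    cs <- readOrthogroupsTsv(clustersFile, unique(unname(prot$speciesOf)),
                             allSequenceIds = names(prot$seqs))
    pathways <- readPathways(pathwaysFile)
    constraints <- if (!is.null(constraintsFile))
      readConstraints(constraintsFile) else list()
    hits <- if (!is.null(hitsFile)) readTabularHits(hitsFile) else NULL
    list(db = db, prot = prot, cs = cs, pathways = pathways,
         constraints = constraints, hits = hits)
  }, error = function(e) e)
  if (inherits(inputs, "error"))
    return(.statusMsg(2L, sprintf("annotate-and-predict failed: %s",
                                  conditionMessage(inputs))))
  db <- inputs$db
  unknown <- setdiff(unlist(lapply(inputs$pathways, `[[`, "reactions")),
                     reactionIds(db))
  if (length(unknown))
    return(.statusMsg(4L, sprintf("pathway references unknown reaction(s): %s",
                                  paste(unknown, collapse = ", "))))
  config <- annotationConfig(relaxedEvalue, restrictiveEvalue, minBitScore,
                             sampleFraction, seed)
  cs <- inputs$cs
  prot <- inputs$prot
  if (is.null(inputs$hits)) {
    candidates <- relaxedSearch(cs, prot$seqs, db, config, scheme)
    result <- restrictiveSearch(candidates, cs, prot$seqs, db, config, scheme)
  } else {
    result <- .annotateFromHits(inputs$hits, cs, db, config)
    candidates <- candidateKos(result)
  }
  spKos <- speciesKoTable(result, prot$speciesOf)
  for (s in setdiff(sort(unique(unname(prot$speciesOf))), names(spKos)))
    spKos[[s]] <- character()
  spKos <- spKos[order(names(spKos))]
  tab <- reactionCapabilities(spKos, db)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeSpeciesKoTable(spKos, file.path(outDir, "Species_KO_table.csv"))
  writeReactionTable(tab, file.path(outDir, "Reactions_mapped_to_species.csv"))
  utils::write.table(annotationReport(cs, candidates, result),
                     file.path(outDir, "annotation_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  multi <- length(inputs$pathways) > 1L
  for (pw in inputs$pathways) {
    con <- inputs$constraints[[pw$name]]
    if (is.null(con)) con <- constraintSet()
    res <- enumerateCombinations(tab, pw, con)
    writeInteractions(res, if (multi) file.path(outDir, pw$name) else outDir)
  }
  exportNetwork(tab, outDir)
  log <- c(
    sprintf("relaxed_evalue\t%g", config$relaxedEvalue),
    sprintf("restrictive_evalue\t%g", config$restrictiveEvalue),
    sprintf("min_bit_score\t%g", config$minBitScore),
    sprintf("sample_fraction\t%g", config$sampleFraction),
    sprintf("seed\t%d", config$seed),
    sprintf("aligner\t%s", if (is.null(inputs$hits)) "internal" else "import"),
    sprintf("n_species\t%d", length(spKos)),
    sprintf("n_clusters\t%d", length(clusters(cs))),
    sprintf("n_assignments\t%d", nrow(assignments(result))))
  writeLines(log, file.path(outDir, "run_log.txt"))
  invisible(0L)
}
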