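#' Classify a KEGG-style identifier token
#'
#' KO identifiers match \code{K#####}, reaction identifiers \code{R#####},
#' EC numbers \code{d.d.d.d}; anything else is unresolved.
#'
#' @param id character vector of tokens.
#' @return character vector with values \code{"ko"}, \code{"reaction"},
#'   \code{"ec"} or \code{"unresolved"}.
#' @export
classifyIdentifier <- function(id) {
  id <- toupper(trimws(id))
  out <- rep("unresolved", length(id))
  out[grepl("^K[0-9]{5}$", id)] <- "ko"
  out[grepl("^R[0-9]{5}$", id)] <- "reaction"
  out[grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$", id)] <- "ec"
  out
}

#' Read an identifier list file
#'
#' One identifier per line; blank lines and \code{#} comments ignored.
#'
#' @param path file path.
#' @return character vector of tokens.
#' @export
readIdList <- function(path) {
  if (!file.exists(path)) stop(sprintf("identifier file '%s' not found", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Offline identifier resolver backed by in-memory fixtures or a directory
#'
#' A fetcher is the pluggable boundary through which reference data enter
#' the database build: it resolves an identifier to KOs, supplies each KO's
#' reference sequences, and supplies GPR rule strings for reactions. This
#' constructor builds one from local data, so database construction is fully
#' reproducible offline; a live KEGG client would implement the same three
#' functions.
#'
#' @param koFastas named list (by KO) of \link[Biostrings]{AAStringSet}, or
#'   a directory containing \code{<ko>.fasta} files.
#' @param idToKos named list mapping reaction/EC identifiers to character
#'   vectors of KOs; KO identifiers resolve to themselves automatically.
#' @param gprRules named character vector (by reaction id) of rule strings.
#' @return a fetcher: list of functions \code{map_to_kos(id)},
#'   \code{ko_fasta(ko)}, \code{gpr_for(reactions)}.
#' @seealso [buildOradb()]
#' @export
offlineFetcher <- function(koFastas = list(), idToKos = list(),
                           gprRules = character()) {
  if (is.character(koFastas) && length(koFastas) == 1L) {
    dir <- koFastas
    files <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
    koFastas <- lapply(files, .readProteinFasta)
    names(koFastas) <- toupper(sub("\\.fasta$", "", basename(files)))
  }
  list(
    map_to_kos = function(id) {
      kind <- classifyIdentifier(id)
      if (kind == "ko") return(toupper(id))
      if (id %in% names(idToKos)) return(toupper(idToKos[[id]]))
      NULL
    },
    ko_fasta = function(ko) {
      if (ko %in% names(koFastas)) koFastas[[ko]] else AAStringSet()
    },
    gpr_for = function(reactions) {
      gprRules[intersect(reactions, names(gprRules))]
    }
  )
}

#' Build an ORAdb from an identifier list via a fetcher
#'
#' Classifies each input identifier (KO, reaction, EC), resolves it to KOs
#' through the fetcher, collects each KO's reference sequences and any GPR
#' rule strings the fetcher supplies, and assembles the database. Every
#' resolved input identifier becomes a reaction entry keyed by that
#' identifier (a bare KO input becomes a single-KO reaction named after
#' itself). Unresolved identifiers and empty KO sequence sets are flagged in
#' the build report rather than failing the build.
#'
#' @param ids character vector of identifier tokens (see
#'   [classifyIdentifier()]).
#' @param fetcher a resolver as returned by [offlineFetcher()].
#' @return an [ORAdb-class]; inspect [loadReport()] for unresolved ids,
#'   empty KO sets and defaulted rules.
#' @export
buildOradb <- function(ids, fetcher) {
  stopifnot(is.character(ids), length(ids) >= 1L)
  stopifnot(is.list(fetcher),
            all(c("map_to_kos", "ko_fasta", "gpr_for") %in% names(fetcher)))
  ids <- toupper(trimws(ids))
  report <- data.frame(item = character(), issue = character(),
                       stringsAsFactors = FALSE)
  reactionKos <- list()
  for (id in unique(ids)) {
    kos <- tryCatch(fetcher$map_to_kos(id), error = function(e)
      stop(sprintf("fetcher failed on identifier '%s': %s", id,
                   conditionMessage(e)), call. = FALSE))
    if (is.null(kos) || length(kos) == 0L) {
      report <- rbind(report, data.frame(item = id, issue = "unresolved"))
      next
    }
    reactionKos[[id]] <- sort(unique(toupper(kos)))
  }
  ruleStrings <- fetcher$gpr_for(names(reactionKos))
  gprRules <- list()
  for (r in names(ruleStrings))
    gprRules[[r]] <- parseGpr(ruleStrings[[r]], r)
  allKos <- sort(unique(c(unlist(reactionKos, use.names = FALSE),
                          unlist(lapply(gprRules, gprKos),
                                 use.names = FALSE))))
  koSequences <- list()
  for (ko in allKos) {
    ss <- tryCatch(fetcher$ko_fasta(ko), error = function(e)
      stop(sprintf("fetcher failed fetching sequences for KO '%s': %s", ko,
                   conditionMessage(e)), call. = FALSE))
    if (is.null(ss)) ss <- AAStringSet()
    if (length(ss) == 0L)
      report <- rbind(report,
                      data.frame(item = ko, issue = "empty KO sequence set"))
    koSequences[[ko]] <- ss
  }
  for (r in setdiff(names(reactionKos), names(gprRules)))
    report <- rbind(report,
                    data.frame(item = r, issue = "no GPR rule; defaulting to OR over KO set"))
  new("ORAdb", koSequences = koSequences, reactionKos = reactionKos,
      gprRules = gprRules, report = report)
}

.readProteinFasta <- function(path) {
  # validate the raw text first: the FASTA reader silently drops invalid
  # one-letter codes, which would hide corrupt records
  lines <- readLines(path, warn = FALSE)
  rec <- "(no record)"
  pat <- sprintf("[^%s[:space:]]", paste(AA_ALPHABET20X, collapse = ""))
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      rec <- strsplit(sub("^>", "", ln), "[[:space:]]+")[[1L]][1L]
      next
    }
    bad <- regexpr(pat, toupper(ln))
    if (bad > 0L)
      stop(sprintf("illegal character '%s' in record '%s' of '%s'",
                   substr(ln, bad, bad), rec, path), call. = FALSE)
  }
  ss <- tryCatch(readAAStringSet(path), error = function(e)
    stop(sprintf("FASTA parse failure in '%s': %s", path,
                 conditionMessage(e)), call. = FALSE))
  # keep only the id token of each header
  names(ss) <- vapply(strsplit(names(ss), "[[:space:]]+"), `[`, character(1), 1L)
  if (anyDuplicated(names(ss)))
    stop(sprintf("duplicate sequence id '%s' in '%s'",
                 names(ss)[duplicated(names(ss))][1L], path), call. = FALSE)
  AAStringSet(toupper(as.character(ss)))
}

#' Read / write the on-disk ORAdb directory layout
#'
#' The directory holds one \code{<ko>.fasta} amino-acid multi-FASTA per KO,
#' a \code{reaction_kos.tsv} (header \code{reaction_id<TAB>ko_id}, one pair
#' per line) and a \code{gpr_rules.tsv} (header
#' \code{reaction_id<TAB>rule}). \code{writeOradb} followed by
#' \code{readOradb} is the identity on database content, with sequence
#' order preserved.
#'
#' @param dir directory path.
#' @param db an [ORAdb-class].
#' @return \code{readOradb} returns an [ORAdb-class]; \code{writeOradb}
#'   returns \code{dir} invisibly.
#' @export
readOradb <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("ORAdb directory '%s' not found", dir))
  rkPath <- file.path(dir, "reaction_kos.tsv")
  gprPath <- file.path(dir, "gpr_rules.tsv")
  if (!file.exists(rkPath))
    stop(sprintf("missing mapping file '%s'", rkPath))
  if (!file.exists(gprPath))
    stop(sprintf("missing rules file '%s'", gprPath))
  rk <- utils::read.delim(rkPath, stringsAsFactors = FALSE)
  if (!all(c("reaction_id", "ko_id") %in% names(rk)))
    stop("reaction_kos.tsv must have columns reaction_id, ko_id")
  reactionKos <- lapply(split(toupper(rk$ko_id), rk$reaction_id),
                        function(k) sort(unique(k)))
  gpr <- utils::read.delim(gprPath, stringsAsFactors = FALSE)
  if (!all(c("reaction_id", "rule") %in% names(gpr)))
    stop("gpr_rules.tsv must have columns reaction_id, rule")
  gprRules <- list()
  if (nrow(gpr))
    for (i in seq_len(nrow(gpr)))
      gprRules[[gpr$reaction_id[i]]] <- parseGpr(gpr$rule[i], gpr$reaction_id[i])
  files <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
  kos <- toupper(sub("\\.fasta$", "", basename(files)))
  if (anyDuplicated(kos))
    stop(sprintf("duplicate KO file for '%s'", kos[duplicated(kos)][1L]))
  koSequences <- stats::setNames(lapply(files, .readProteinFasta), kos)
  report <- data.frame(item = character(), issue = character(),
                       stringsAsFactors = FALSE)
  # KOs referenced by the mapping or rules but lacking a FASTA get an empty
  # entry
  referenced <- unique(c(unlist(reactionKos, use.names = FALSE),
                         unlist(lapply(gprRules, gprKos), use.names = FALSE)))
  for (ko in setdiff(referenced, kos)) {
    koSequences[[ko]] <- AAStringSet()
    report <- rbind(report,
                    data.frame(item = ko, issue = "empty KO sequence set"))
  }
  new("ORAdb", koSequences = koSequences, reactionKos = reactionKos,
      gprRules = gprRules, report = report)
}

#' @rdname readOradb
#' @export
writeOradb <- function(db, dir) {
  stopifnot(is(db, "ORAdb"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ko in names(db@koSequences)) {
    ss <- db@koSequences[[ko]]
    if (length(ss))
      writeXStringSet(ss, file.path(dir, sprintf("%s.fasta", ko)))
  }
  rk <- data.frame(
    reaction_id = rep(names(db@reactionKos),
                      lengths(db@reactionKos)),
    ko_id = unlist(db@reactionKos, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(rk, file.path(dir, "reaction_kos.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gpr <- data.frame(
    reaction_id = names(db@gprRules),
    rule = vapply(db@gprRules, gprToString, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(gpr, file.path(dir, "gpr_rules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
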