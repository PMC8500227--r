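#' Define a pathway as an ordered set of reactions
#'
#' @param name pathway name (single token).
#' @param reactions character vector of reaction identifiers, non-empty,
#'   duplicates removed keeping first occurrence.
#' @return a \code{PathwayDef} (classed list).
#' @export
pathwayDef <- function(name, reactions) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("pathway name must be one non-empty token")
  reactions <- as.character(reactions)
  reactions <- reactions[!duplicated(reactions)]
  if (length(reactions) == 0L) stop("pathway must contain reactions")
  structure(list(name = name, reactions = reactions), class = "PathwayDef")
}

#' Constraints on species combinations
#'
#' Restricts which covering species combinations count as plausible
#' interactions: \code{singleSpeciesSubsets} lists reaction subsets that
#' must each be carried entirely by one member (e.g. consecutive steps whose
#' intermediate is not exchanged); \code{transporterMode} optionally
#' requires transporter-associated reactions in at least one member
#' (\code{"any_member"}) or in every member (\code{"every_member"});
#' \code{maxCombinationSize} caps combination size;
#' \code{completenessFraction} generalizes full pathway cover to a minimum
#' covered fraction; \code{includeComplete} decides whether species that
#' individually cover the pathway may also appear inside combinations (they
#' are always reported separately).
#'
#' @param singleSpeciesSubsets list of character vectors of reaction ids.
#' @param transporterReactions character vector of transporter reaction ids.
#' @param transporterMode one of \code{"off"}, \code{"any_member"},
#'   \code{"every_member"}.
#' @param maxCombinationSize integer >= 2, or \code{Inf} for unlimited.
#' @param completenessFraction minimum covered fraction of pathway
#'   reactions, in (0, 1]; default 1 (full cover).
#' @param includeComplete logical, default TRUE.
#' @return a \code{ConstraintSet} (classed list).
#' @export
constraintSet <- function(singleSpeciesSubsets = list(),
                          transporterReactions = character(),
                          transporterMode = c("off", "any_member",
                                              "every_member"),
                          maxCombinationSize = Inf,
                          completenessFraction = 1.0,
                          includeComplete = TRUE) {
  transporterMode <- match.arg(transporterMode)
  if (any(lengths(singleSpeciesSubsets) == 0L))
    stop("single-species subsets must be non-empty")
  if (!is.infinite(maxCombinationSize) && maxCombinationSize < 2)
    stop("maxCombinationSize must be >= 2 (or Inf)")
  if (completenessFraction <= 0 || completenessFraction > 1)
    stop("completenessFraction must be in (0, 1]")
  structure(list(singleSpeciesSubsets = singleSpeciesSubsets,
                 transporterReactions = as.character(transporterReactions),
                 transporterMode = transporterMode,
                 maxCombinationSize = maxCombinationSize,
                 completenessFraction = completenessFraction,
                 includeComplete = isTRUE(includeComplete)),
            class = "ConstraintSet")
}

.checkReactions <- function(tab, reactions, what) {
  bad <- setdiff(reactions, colnames(tab))
  if (length(bad))
    stop(sprintf("%s reaction(s) not in capability table: %s", what,
                 paste(bad, collapse = ", ")))
}

setMethod("completeSpecies", "matrix", function(x, pathway) {
  stopifnot(inherits(pathway, "PathwayDef"))
  .checkReactions(x, pathway$reactions, "pathway")
  sp <- rownames(x)[rowSums(x[, pathway$reactions, drop = FALSE] == 1L) ==
                      length(pathway$reactions)]
  sort(sp)
})

## Fraction of pathway reactions covered by the union of the members' rows.
.coverageFraction <- function(combo, tab, reactions) {
  sub <- tab[combo, reactions, drop = FALSE]
  sum(colSums(sub) > 0L) / length(reactions)
}

#' Does a species combination satisfy the constraint set?
#'
#' True iff every single-species subset is fully carried by at least one
#' member, the transporter requirement of the active mode holds, and the
#' combination does not exceed the size cap. The pathway-coverage
#' requirement is separate (see [enumerateCombinations()]).
#'
#' @param combo character vector of species ids (non-empty, rows of
#'   \code{tab}).
#' @param tab capability matrix from [reactionCapabilities()].
#' @param constraints a [constraintSet()].
#' @return logical scalar.
#' @export
satisfiesConstraints <- function(combo, tab, constraints = constraintSet()) {
  stopifnot(length(combo) >= 1L, all(combo %in% rownames(tab)))
  if (length(combo) > constraints$maxCombinationSize) return(FALSE)
  for (subset in constraints$singleSpeciesSubsets) {
    .checkReactions(tab, subset, "single-species-subset")
    ok <- any(rowSums(tab[combo, subset, drop = FALSE] == 1L) ==
                length(subset))
    if (!ok) return(FALSE)
  }
  if (constraints$transporterMode != "off") {
    tr <- constraints$transporterReactions
    .checkReactions(tab, tr, "transporter")
    hasTr <- rowSums(tab[combo, tr, drop = FALSE] == 1L) > 0L
    if (constraints$transporterMode == "any_member" && !any(hasTr))
      return(FALSE)
    if (constraints$transporterMode == "every_member" && !all(hasTr))
      return(FALSE)
  }
  TRUE
}

#' Enumerate species combinations covering a pathway
#'
#' Finds every subset of at least two species whose combined capabilities
#' cover at least the required fraction of the pathway's reactions and
#' satisfy the constraint set, by depth-first search over species in
#' lexicographic order with branch pruning (a branch is abandoned when even
#' the union of the current set with every remaining species cannot reach
#' the required coverage). Species individually covering the whole pathway
#' are always reported separately in \code{completeSpecies}; whether they
#' may also appear inside combinations is governed by
#' \code{constraints$includeComplete}. All covering subsets are emitted, not
#' only minimal ones, unless \code{minimalOnly}.
#'
#' @param tab capability matrix from [reactionCapabilities()]; at most 30
#'   species.
#' @param pathway a [pathwayDef()]; its reactions must be table columns.
#' @param constraints a [constraintSet()].
#' @param minimalOnly if TRUE, drop combinations containing a smaller
#'   emitted combination as a subset.
#' @return an [InteractionResult-class]; combinations ordered by size, then
#'   lexicographically by members.
#' @export
enumerateCombinations <- function(tab, pathway,
                                  constraints = constraintSet(),
                                  minimalOnly = FALSE) {
  stopifnot(inherits(pathway, "PathwayDef"))
  .checkReactions(tab, pathway$reactions, "pathway")
  if (nrow(tab) > 30L)
    stop("more than 30 species: tighten constraints or subset the table")
  complete <- completeSpecies(tab, pathway)
  pool <- sort(rownames(tab))
  if (!constraints$includeComplete) pool <- setdiff(pool, complete)
  rx <- pathway$reactions
  need <- constraints$completenessFraction
  maxSize <- min(constraints$maxCombinationSize, length(pool))
  found <- list()
  emit <- function(members) {
    frac <- .coverageFraction(members, tab, rx)
    if (frac + 1e-12 < need) return(invisible())
    if (!satisfiesConstraints(members, tab, constraints)) return(invisible())
    covered <- rx[colSums(tab[members, rx, drop = FALSE]) > 0L]
    contributors <- lapply(covered, function(r)
      members[tab[members, r] == 1L])
    names(contributors) <- covered
    found[[length(found) + 1L]] <<- list(members = members,
                                         contributors = contributors)
  }
  dfs <- function(members, startIdx) {
    if (length(members) >= 2L) emit(members)
    if (length(members) >= maxSize || startIdx > length(pool))
      return(invisible())
    rest <- pool[startIdx:length(pool)]
    if (.coverageFraction(c(members, rest), tab, rx) + 1e-12 < need)
      return(invisible())
    for (i in startIdx:length(pool))
      dfs(c(members, pool[i]), i + 1L)
  }
  if (length(pool) >= 2L) dfs(character(), 1L)
  if (minimalOnly && length(found)) {
    keys <- lapply(found, `[[`, "members")
    sizes <- lengths(keys)
    ord <- order(sizes)
    keep <- logical(length(found))
    kept <- list()
    for (i in ord) {
      if (!any(vapply(kept, function(k) all(k %in% keys[[i]]), logical(1)))) {
        keep[i] <- TRUE
        kept[[length(kept) + 1L]] <- keys[[i]]
      }
    }
    found <- found[keep]
  }
  if (length(found)) {
    key <- vapply(found, function(f)
      sprintf("%03d|%s", length(f$members), paste(f$members, collapse = ",")),
      character(1))
    found <- found[order(key)]
  }
  new("InteractionResult", pathwayName = pathway$name, reactions = rx,
      completeSpecies = complete, combinations = found)
}

#' Compare predicted coverage with observed growth of species sets
#'
#' For each observed species set that grew, checks whether its genomic
#' potential explains the growth: the set contains a complete species, or
#' its members' joint capabilities cover the pathway at the required
#' fraction and satisfy the constraints (the coverage predicate applied to
#' the observed set itself, whatever its size).
#'
#' @param tab capability matrix.
#' @param pathway a [pathwayDef()].
#' @param constraints a [constraintSet()].
#' @param observed list of \code{list(species = <character>, grew =
#'   <logical>)}; all species must be table rows.
#' @return list with \code{explained} and \code{total_grown} counts.
#' @export
compareToObservations <- function(tab, pathway, constraints = constraintSet(),
                                  observed = list()) {
  stopifnot(inherits(pathway, "PathwayDef"))
  complete <- completeSpecies(tab, pathway)
  explained <- 0L
  totalGrown <- 0L
  for (obs in observed) {
    bad <- setdiff(obs$species, rownames(tab))
    if (length(bad))
      stop(sprintf("unknown species id '%s' in observations", bad[1L]))
    if (!isTRUE(obs$grew)) next
    totalGrown <- totalGrown + 1L
    ok <- any(obs$species %in% complete) ||
      (.coverageFraction(obs$species, tab, pathway$reactions) + 1e-12 >=
         constraints$completenessFraction &&
         satisfiesConstraints(obs$species, tab, constraints))
    if (ok) explained <- explained + 1L
  }
  list(explained = explained, total_grown = totalGrown)
}

#' Read pathway definitions from TSV
#'
#' Columns \code{pathway_name} and \code{reactions} (comma-separated ids).
#'
#' @param path file path.
#' @return named list of [pathwayDef()] objects.
#' @export
readPathways <- function(path) {
  if (!file.exists(path)) stop(sprintf("pathway file '%s' not found", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pathway_name", "reactions") %in% names(df)))
    stop("pathway file needs columns pathway_name, reactions")
  out <- lapply(seq_len(nrow(df)), function(i)
    pathwayDef(df$pathway_name[i],
               trimws(strsplit(df$reactions[i], ",", fixed = TRUE)[[1L]])))
  stats::setNames(out, df$pathway_name)
}

#' Read per-pathway constraint sets from TSV
#'
#' Columns \code{pathway_name}, \code{single_species_subsets} (groups
#' separated by \code{;}, reactions within a group by \code{,}),
#' \code{transporters} (comma list), \code{transporter_mode},
#' \code{max_size} (integer or empty for unlimited), \code{completeness}.
#' Empty cells fall back to the defaults of [constraintSet()].
#'
#' @param path file path.
#' @return named list of [constraintSet()] objects.
#' @export
readConstraints <- function(path) {
  if (!file.exists(path)) stop(sprintf("constraint file '%s' not found", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!"pathway_name" %in% names(df))
    stop("constraint file needs a pathway_name column")
  get <- function(i, col) if (col %in% names(df)) trimws(df[i, col]) else ""
  out <- list()
  for (i in seq_len(nrow(df))) {
    subsets <- list()
    cell <- get(i, "single_species_subsets")
    if (nzchar(cell))
      subsets <- lapply(strsplit(cell, ";", fixed = TRUE)[[1L]], function(g)
        trimws(strsplit(g, ",", fixed = TRUE)[[1L]]))
    tr <- get(i, "transporters")
    trv <- if (nzchar(tr)) trimws(strsplit(tr, ",", fixed = TRUE)[[1L]])
           else character()
    mode <- get(i, "transporter_mode")
    ms <- get(i, "max_size")
    comp <- get(i, "completeness")
    out[[df$pathway_name[i]]] <- constraintSet(
      singleSpeciesSubsets = subsets,
      transporterReactions = trv,
      transporterMode = if (nzchar(mode)) mode else "off",
      maxCombinationSize = if (nzchar(ms)) as.numeric(ms) else Inf,
      completenessFraction = if (nzchar(comp)) as.numeric(comp) else 1.0)
  }
  out
}

#' Write an interaction result to the interactions folder
#'
#' Creates \code{<outDir>/interactions} with \code{complete_species.txt}
#' (one species per line) and \code{combinations.tsv} (columns
#' \code{members} comma-separated, \code{size}, \code{reaction_contributors}
#' as \code{reaction:speciesA|speciesB} groups separated by \code{;}).
#'
#' @param result an [InteractionResult-class].
#' @param outDir parent output directory.
#' @return the interactions directory path, invisibly.
#' @export
writeInteractions <- function(result, outDir) {
  stopifnot(is(result, "InteractionResult"))
  dir <- file.path(outDir, "interactions")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(result@completeSpecies, file.path(dir, "complete_species.txt"))
  rows <- vapply(result@combinations, function(cmb) {
    contrib <- paste(vapply(names(cmb$contributors), function(r)
      sprintf("%s:%s", r, paste(cmb$contributors[[r]], collapse = "|")),
      character(1)), collapse = ";")
    sprintf("%s\t%d\t%s", paste(cmb$members, collapse = ","),
            length(cmb$members), contrib)
  }, character(1))
  writeLines(c("members\tsize\treaction_contributors", rows),
             file.path(dir, "combinations.tsv"))
  invisible(dir)
}

#' Export the species-reaction capability network
#'
#' Writes a bipartite graph (species nodes and reaction nodes, one edge per
#' 1-cell of the capability matrix) as \code{network.json} plus a static
#' \code{network.html} page embedding the JSON and rendering the bipartite
#' layout; reaction nodes whose id matches the \code{R#####} pattern carry a
#' KEGG hyperlink.
#'
#' @param tab capability matrix from [reactionCapabilities()]; must be
#'   non-empty.
#' @param outDir output directory (created if needed).
#' @return invisible character vector of the two file paths
#'   (\code{network.json}, \code{network.html}).
#' @export
exportNetwork <- function(tab, outDir) {
  if (!is.matrix(tab) || nrow(tab) == 0L)
    stop("capability table must be a non-empty matrix")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  sp <- sort(rownames(tab))
  rx <- sort(colnames(tab))
  nodes <- rbind(
    data.frame(id = sp, type = "species", href = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(id = rx, type = "reaction",
               href = ifelse(grepl("^R[0-9]{5}$", rx),
                             sprintf("https://www.genome.jp/entry/%s", rx),
                             NA_character_),
               stringsAsFactors = FALSE))
  idx <- which(tab[sp, rx, drop = FALSE] == 1L, arr.ind = TRUE)
  edges <- data.frame(species = sp[idx[, 1L]], reaction = rx[idx[, 2L]],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$species, edges$reaction), , drop = FALSE]
  graph <- list(nodes = nodes, edges = edges)
  jsonPath <- file.path(outDir, "network.json")
  jsonlite::write_json(graph, jsonPath, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, pretty = TRUE)
  htmlPath <- file.path(outDir, "network.html")
  json <- paste(readLines(jsonPath, warn = FALSE), collapse = "\n")
  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">",
    "<title>Species-reaction network</title>\n<style>",
    "body{font-family:sans-serif} svg{border:1px solid #ccc}",
    "text{font-size:11px}</style></head>\n<body>\n",
    "<h2>Species-reaction capability network</h2>\n",
    "<svg id=\"net\" width=\"900\" height=\"600\"></svg>\n",
    "<script>\nvar graph = ", json, ";\n",
    "var svg=document.getElementById('net');",
    "var sp=graph.nodes.filter(function(n){return n.type==='species'});",
    "var rx=graph.nodes.filter(function(n){return n.type==='reaction'});",
    "function pos(list,x){var o={};list.forEach(function(n,i){",
    "o[n.id]={x:x,y:40+i*(520/Math.max(1,list.length-1||1))}});return o}",
    "var P=Object.assign(pos(sp,150),pos(rx,750));",
    "graph.edges.forEach(function(e){var a=P[e.species],b=P[e.reaction];",
    "var l=document.createElementNS('http://www.w3.org/2000/svg','line');",
    "l.setAttribute('x1',a.x);l.setAttribute('y1',a.y);",
    "l.setAttribute('x2',b.x);l.setAttribute('y2',b.y);",
    "l.setAttribute('stroke','#999');svg.appendChild(l)});",
    "graph.nodes.forEach(function(n){var p=P[n.id];",
    "var c=document.createElementNS('http://www.w3.org/2000/svg','circle');",
    "c.setAttribute('cx',p.x);c.setAttribute('cy',p.y);c.setAttribute('r',6);",
    "c.setAttribute('fill',n.type==='species'?'#4477aa':'#ee6677');",
    "svg.appendChild(c);",
    "var t=document.createElementNS('http://www.w3.org/2000/svg','text');",
    "t.setAttribute('x',p.x+(n.type==='species'?-10:10));",
    "t.setAttribute('y',p.y+4);",
    "t.setAttribute('text-anchor',n.type==='species'?'end':'start');",
    "if(n.href){var a=document.createElementNS('http://www.w3.org/2000/svg','a');",
    "a.setAttribute('href',n.href);a.appendChild(t);svg.appendChild(a)}",
    "else{svg.appendChild(t)}t.textContent=n.id});\n",
    "</script>\n</body></html>\n")
  writeLines(html, htmlPath)
  invisible(c(jsonPath, htmlPath))
}
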