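# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks: boolean rules are evaluated through R's own parser,
# local alignment by exhaustive path enumeration, clustering metrics by
# direct pair enumeration, and combination search by full subset scans.

# Evaluate a GPR rule string with R's parser: AND/OR become &&/|| and each
# KO becomes TRUE/FALSE by membership.
evalRuleStringOracle <- function(ruleText, kos) {
  expr <- gsub("\\bAND\\b", "&", ruleText, ignore.case = TRUE)
  expr <- gsub("\\bOR\\b", "|", expr, ignore.case = TRUE)
  expr <- gsub("(K[0-9]{5})", "`\\1`", expr)
  env <- new.env()
  for (ko in unique(regmatches(ruleText,
                               gregexpr("K[0-9]{5}", ruleText))[[1L]]))
    assign(ko, ko %in% kos, envir = env)
  isTRUE(eval(parse(text = expr), envir = env))
}

# Random GPR rule string over a KO pool (depth <= 3).
randomRuleString <- function(pool, depth = 2L) {
  if (depth == 0L || runif(1) < 0.35) return(sample(pool, 1L))
  op <- sample(c("AND", "OR"), 1L)
  k <- sample(2:3, 1L)
  parts <- replicate(k, randomRuleString(pool, depth - 1L))
  sprintf("(%s)", paste(parts, collapse = sprintf(" %s ", op)))
}

# Exhaustive local alignment score by enumerating every monotone alignment
# path from every start cell, with affine gap costs; exponential, for tiny
# sequences only.
bruteLocalScore <- function(q, s, scheme = scoringScheme()) {
  qc <- strsplit(q, "")[[1L]]
  sc <- strsplit(s, "")[[1L]]
  mat <- scheme$matrix
  open <- scheme$gapOpen + scheme$gapExt
  ext <- scheme$gapExt
  m <- length(qc); n <- length(sc)
  rec <- function(i, j, prev) {
    best <- 0
    if (i <= m && j <= n)
      best <- max(best, mat[qc[i], sc[j]] + rec(i + 1L, j + 1L, "M"))
    if (i <= m)
      best <- max(best, -(if (prev == "U") ext else open) + rec(i + 1L, j, "U"))
    if (j <= n)
      best <- max(best, -(if (prev == "L") ext else open) + rec(i, j + 1L, "L"))
    best
  }
  best <- 0
  for (i0 in seq_len(m))
    for (j0 in seq_len(n))
      best <- max(best, rec(i0, j0, "M"))
  best
}

# All set partitions of 1..n as lists of integer blocks.
allPartitions <- function(n) {
  if (n == 0L) return(list(list()))
  out <- list()
  for (p in allPartitions(n - 1L)) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# Pairwise precision/recall by direct enumeration over element pairs.
pairMetricsOracle <- function(blocks, labels) {
  ids <- names(labels)
  blockOf <- rep(NA_integer_, length(ids))
  names(blockOf) <- ids
  for (b in seq_along(blocks)) blockOf[blocks[[b]]] <- b
  correct <- 0L; clustered <- 0L; truePairs <- 0L
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq(i + 1L, length(ids))) {
        co <- !is.na(blockOf[i]) && !is.na(blockOf[j]) &&
          blockOf[i] == blockOf[j]
        same <- labels[i] == labels[j]
        if (co) clustered <- clustered + 1L
        if (co && same) correct <- correct + 1L
        if (same) truePairs <- truePairs + 1L
      }
    }
  }
  list(correct = correct, clustered = clustered, truePairs = truePairs)
}

# Transitive closure of a logical adjacency matrix by repeated expansion
# (independent of igraph); returns integer component labels.
closureComponents <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  labels <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == 0L) {
      cur <- cur + 1L
      labels[reach[i, ]] <- cur
    }
  }
  labels
}

# Direct re-implementation of the combination predicate: coverage fraction
# plus every constraint, written as plain loops.
constraintOracle <- function(combo, tab, cons) {
  if (length(combo) > cons$maxCombinationSize) return(FALSE)
  for (grp in cons$singleSpeciesSubsets) {
    found <- FALSE
    for (s in combo)
      if (all(tab[s, grp] == 1L)) { found <- TRUE; break }
    if (!found) return(FALSE)
  }
  if (cons$transporterMode == "any_member") {
    if (!any(sapply(combo, function(s)
      any(tab[s, cons$transporterReactions] == 1L)))) return(FALSE)
  } else if (cons$transporterMode == "every_member") {
    if (!all(sapply(combo, function(s)
      any(tab[s, cons$transporterReactions] == 1L)))) return(FALSE)
  }
  TRUE
}

coverageOracle <- function(combo, tab, reactions) {
  covered <- 0L
  for (r in reactions)
    if (any(tab[combo, r] == 1L)) covered <- covered + 1L
  covered / length(reactions)
}

# Exhaustive scan of all 2^n species subsets of size >= 2.
comboOracle <- function(tab, pathway, cons) {
  species <- sort(rownames(tab))
  pool <- species
  if (!cons$includeComplete)
    pool <- setdiff(pool, completeSpecies(tab, pathway))
  n <- length(pool)
  out <- character()
  if (n >= 2L) {
    for (mask in seq_len(2^n - 1L)) {
      combo <- pool[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
      if (length(combo) < 2L) next
      if (coverageOracle(combo, tab, pathway$reactions) + 1e-12 <
          cons$completenessFraction) next
      if (!constraintOracle(combo, tab, cons)) next
      out <- c(out, paste(sort(combo), collapse = ","))
    }
  }
  sort(out)
}

randomCapTable <- function(nSpecies, nReactions, p = 0.45) {
  matrix(rbinom(nSpecies * nReactions, 1L, p), nSpecies, nReactions,
         dimnames = list(sprintf("sp%02d", seq_len(nSpecies)),
                         sprintf("R%05d", seq_len(nReactions))))
}

randomConstraints <- function(reactions, nSpecies) {
  subsets <- list()
  if (runif(1) < 0.5)
    subsets <- list(sample(reactions, min(2L, length(reactions))))
  constraintSet(
    singleSpeciesSubsets = subsets,
    transporterReactions = sample(reactions, 1L),
    transporterMode = sample(c("off", "any_member", "every_member"), 1L),
    maxCombinationSize = sample(c(Inf, 2, 3, nSpecies), 1L),
    completenessFraction = sample(c(1, 0.75, 0.5), 1L),
    includeComplete = runif(1) < 0.5)
}

comboKeys <- function(result) {
  sort(vapply(combinations(result), function(x)
    paste(sort(x$members), collapse = ","), character(1)))
}

# Small two-reaction database with handwritten families, used by several
# suites. R00001 needs a two-subunit complex (K11111 AND K22222); R00002 a
# single protein with two isoenzymes (K33333 OR K44444).
tinyDb <- function() {
  fams <- list(
    K11111 = generateFamily(101, 60, 3, 0.05, "K11111")$members,
    K22222 = generateFamily(102, 60, 3, 0.05, "K22222")$members,
    K33333 = generateFamily(103, 60, 3, 0.05, "K33333")$members,
    K44444 = generateFamily(104, 60, 3, 0.05, "K44444")$members)
  buildOradb(c("R00001", "R00002"), offlineFetcher(
    koFastas = fams,
    idToKos = list(R00001 = c("K11111", "K22222"),
                   R00002 = c("K33333", "K44444")),
    gprRules = c(R00001 = "K11111 AND K22222",
                 R00002 = "K33333 OR K44444")))
}
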