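#' Parse a gene-protein-reaction rule string
#'
#' Parses a boolean expression over KO identifiers into a [GprRule-class].
#' The grammar is \code{expr := term (OR term)*}, \code{term := factor (AND
#' factor)*}, \code{factor := KO | '(' expr ')'}, so OR binds loosest and
#' parentheses group. \code{AND}/\code{OR} are accepted case-insensitively;
#' KEGG-module shorthand operators (\code{+}, \code{,}) are not part of the
#' grammar and must be normalized upstream.
#'
#' @param text rule string, e.g.
#'   \code{"(K04112 AND K04113 AND K04114 AND K04115) OR (K19515 AND K19516)"}
#'   for a reaction carried by either a four-subunit or a two-subunit
#'   complex.
#' @param reactionId reaction identifier to attach to the rule.
#' @return a [GprRule-class]; nested same-operator nodes are flattened,
#'   which preserves the truth table.
#' @examples
#' r <- parseGpr("(K19515 AND K19516) OR K04105", "Rx")
#' evaluateGpr(r, c("K04105"))
#' @export
parseGpr <- function(text, reactionId = "R_unnamed") {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("rule text must be one non-empty string")
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", text)[[1L]]
  toks <- regmatches(text, list(m))[[1L]]
  pos <- as.integer(m)
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[i] else NA_character_
  fail <- function(msg, at = i) {
    p <- if (at <= length(pos)) pos[at] else nchar(text) + 1L
    stop(sprintf("GPR parse error at position %d: %s", p, msg), call. = FALSE)
  }
  isKw <- function(tk, kw) !is.na(tk) && toupper(tk) == kw

  parseFactor <- function() {
    tk <- peek()
    if (is.na(tk)) fail("unexpected end of expression")
    if (tk == "(") {
      i <<- i + 1L
      node <- parseExpr()
      if (!identical(peek(), ")")) fail("expected ')'")
      i <<- i + 1L
      return(node)
    }
    if (tk == ")") fail("unexpected ')'")
    if (isKw(tk, "AND") || isKw(tk, "OR")) fail(sprintf("dangling operator '%s'", tk))
    if (!.validKo(tk)) fail(sprintf("malformed KO token '%s'", tk))
    i <<- i + 1L
    list(op = "KO", ko = toupper(tk))
  }
  joinNodes <- function(op, parts) {
    if (length(parts) == 1L) return(parts[[1L]])
    # flatten nested same-operator children (associativity)
    flat <- list()
    for (p in parts)
      flat <- c(flat, if (identical(p$op, op)) p$children else list(p))
    list(op = op, children = flat)
  }
  parseTerm <- function() {
    parts <- list(parseFactor())
    while (isKw(peek(), "AND")) {
      i <<- i + 1L
      parts <- c(parts, list(parseFactor()))
    }
    joinNodes("AND", parts)
  }
  parseExpr <- function() {
    parts <- list(parseTerm())
    while (isKw(peek(), "OR")) {
      i <<- i + 1L
      parts <- c(parts, list(parseTerm()))
    }
    joinNodes("OR", parts)
  }

  ast <- parseExpr()
  if (i <= length(toks)) fail(sprintf("unexpected token '%s'", toks[i]))
  new("GprRule", reactionId = as.character(reactionId), ast = ast)
}

#' Serialize a GPR rule back to its string form
#'
#' @param rule a [GprRule-class].
#' @return a string that [parseGpr()] parses to a truth-table-equivalent
#'   rule.
#' @export
gprToString <- function(rule) {
  stopifnot(is(rule, "GprRule"))
  ser <- function(node, parentOp) {
    if (node$op == "KO") return(node$ko)
    s <- paste(vapply(node$children, ser, character(1), node$op),
               collapse = sprintf(" %s ", node$op))
    # parenthesize AND under OR is unnecessary (AND binds tighter); OR under
    # AND must be grouped
    if (node$op == "OR" && identical(parentOp, "AND")) sprintf("(%s)", s) else s
  }
  ser(rule@ast, NA_character_)
}

#' Evaluate a GPR rule against a species' KO repertoire
#'
#' Standard boolean semantics: a leaf is true iff its KO is present, AND
#' requires all children, OR any child. Rules contain no negation, so the
#' result is monotone in the KO set and always false on the empty set.
#'
#' @param rule a [GprRule-class].
#' @param kos character vector of KO identifiers the species possesses (may
#'   be empty).
#' @return logical scalar.
#' @export
evaluateGpr <- function(rule, kos) {
  stopifnot(is(rule, "GprRule"))
  kos <- toupper(as.character(kos))
  ev <- function(node) {
    switch(node$op,
           KO  = node$ko %in% kos,
           AND = all(vapply(node$children, ev, logical(1))),
           OR  = any(vapply(node$children, ev, logical(1))))
  }
  ev(rule@ast)
}

#' KOs appearing in a GPR rule
#' @param rule a [GprRule-class].
#' @return character vector of distinct KO identifiers, sorted.
#' @export
gprKos <- function(rule) {
  stopifnot(is(rule, "GprRule"))
  walk <- function(node) {
    if (node$op == "KO") return(node$ko)
    unlist(lapply(node$children, walk), use.names = FALSE)
  }
  sort(unique(walk(rule@ast)))
}

## Default rule when none is supplied: any one of the reaction's KOs
## suffices (single-protein case).
defaultGprRule <- function(reactionId, kos) {
  kos <- toupper(kos)
  if (length(kos) == 0L)
    stop(sprintf("reaction '%s' has no KOs; cannot build a default rule",
                 reactionId))
  ast <- if (length(kos) == 1L) list(op = "KO", ko = kos) else
    list(op = "OR", children = lapply(kos, function(k) list(op = "KO", ko = k)))
  new("GprRule", reactionId = reactionId, ast = ast)
}

#' Binary species-by-reaction capability table
#'
#' Evaluates every reaction's GPR rule against every species' KO repertoire
#' and returns the binary capability matrix the interaction engine consumes
#' (the "reactions mapped to species" table). Reactions without an explicit
#' rule default to OR over their KO set.
#'
#' @param speciesKos named list mapping species id to its character vector
#'   of KOs (a species-KO table, e.g. from [speciesKoTable()]).
#' @param db an [ORAdb-class] supplying reactions and rules.
#' @return integer matrix with species as rows and reactions as columns,
#'   both lexicographically ordered; entry 1 iff the species' KO set
#'   satisfies the reaction's rule.
#' @examples
#' db <- generateOradbFixture(2, complexFraction = 0, seed = 1)
#' reactionCapabilities(list(sp1 = gprKos(gprRule(db, reactionIds(db)[1]))),
#'                      db)
#' @export
reactionCapabilities <- function(speciesKos, db) {
  stopifnot(is(db, "ORAdb"))
  if (!is.list(speciesKos) || length(speciesKos) == 0L)
    stop("speciesKos must be a non-empty named list")
  sp <- names(speciesKos)
  if (is.null(sp) || any(!nzchar(sp)) || anyDuplicated(sp))
    stop("species ids must be unique non-empty names")
  rx <- sort(names(db@reactionKos))
  sp <- sort(sp)
  tab <- matrix(0L, nrow = length(sp), ncol = length(rx),
                dimnames = list(sp, rx))
  for (r in rx) {
    rule <- gprRule(db, r)
    for (s in sp)
      tab[s, r] <- as.integer(evaluateGpr(rule, speciesKos[[s]]))
  }
  tab
}
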