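## Background amino-acid frequencies (approximate vertebrate/bacterial
## averages) used for decoy composition.
.AA_BACKGROUND <- c(A = 0.083, C = 0.017, D = 0.053, E = 0.062, F = 0.040,
                    G = 0.072, H = 0.022, I = 0.058, K = 0.058, L = 0.092,
                    M = 0.024, N = 0.044, P = 0.043, Q = 0.037, R = 0.051,
                    S = 0.069, T = 0.056, V = 0.066, W = 0.013, Y = 0.032)

.roundHalfUp <- function(x) floor(x + 0.5)

#' Generate a synthetic protein family
#'
#' Draws one random ancestor and derives each family member by substituting
#' a fixed number of positions, \code{round(divergence * length)}, chosen
#' without replacement and each replaced by a different residue — so every
#' member sits at exactly that Hamming distance from the ancestor. Families
#' stand in for KO reference sequence sets in fixtures with known truth.
#'
#' @param seed integer seed; the same seed reproduces the family exactly.
#' @param length ancestor length in residues, >= 30.
#' @param nMembers number of derived members.
#' @param divergence substitution fraction in \eqn{[0, 0.5]}; beyond 0.5 the
#'   family notion breaks down and an error is raised.
#' @param prefix name prefix for member ids (\code{<prefix>_m1}, ...).
#' @return list with \code{ancestor} (character) and \code{members}
#'   (named \link[Biostrings]{AAStringSet}).
#' @export
generateFamily <- function(seed, length = 80L, nMembers = 3L,
                           divergence = 0.05, prefix = "fam") {
  if (length < 30L) stop("family length must be >= 30")
  if (divergence < 0 || divergence > 0.5)
    stop("divergence must be in [0, 0.5]")
  aa <- names(.AA_BACKGROUND)
  .withLocalSeed(seed, {
    ancestor <- paste(sample(aa, length, replace = TRUE,
                             prob = .AA_BACKGROUND), collapse = "")
    nSub <- as.integer(.roundHalfUp(divergence * length))
    members <- vapply(seq_len(nMembers), function(i) {
      ch <- strsplit(ancestor, "")[[1L]]
      if (nSub > 0L) {
        posn <- sample(length, nSub)
        for (p in posn) ch[p] <- sample(setdiff(aa, ch[p]), 1L)
      }
      paste(ch, collapse = "")
    }, character(1))
    names(members) <- sprintf("%s_m%d", prefix, seq_len(nMembers))
    list(ancestor = ancestor, members = AAStringSet(members))
  })
}

#' Generate a synthetic ORAdb with known families and rules
#'
#' Builds a database of \code{nReactions} reactions over disjoint KO sets
#' (no KO is shared between reactions, so each reaction's capability
#' depends only on its own KOs). With probability \code{complexFraction} a
#' reaction's rule is a compound expression — an AND complex, or an OR of
#' isoenzymes, or an OR of two AND complexes, over 2-4 subunits (fixed to
#' \code{kosPerReaction} subunits of a pure AND when that is supplied) —
#' and otherwise a single-KO rule. Reference sets come from
#' [generateFamily()].
#'
#' @param nReactions number of reactions, >= 1.
#' @param complexFraction probability of a compound (multi-KO) rule.
#' @param kosPerReaction if non-NULL, every compound rule is an AND over
#'   exactly this many KOs.
#' @param seed integer seed.
#' @param familyLength,familySize,familyDivergence parameters passed to
#'   [generateFamily()] for each KO's reference set.
#' @return an [ORAdb-class].
#' @export
generateOradbFixture <- function(nReactions, complexFraction = 0.3,
                                 kosPerReaction = NULL, seed = 1L,
                                 familyLength = 80L, familySize = 3L,
                                 familyDivergence = 0.05) {
  if (nReactions < 1L) stop("need at least one reaction")
  .withLocalSeed(seed, {
    reactionKos <- list()
    ruleStrings <- character()
    nextKo <- 1L
    takeKos <- function(n) {
      kos <- sprintf("K%05d", seq(nextKo, nextKo + n - 1L))
      nextKo <<- nextKo + n
      kos
    }
    for (ri in seq_len(nReactions)) {
      rid <- sprintf("R%05d", ri)
      compound <- stats::runif(1) < complexFraction
      if (!compound) {
        kos <- takeKos(1L)
        ruleStrings[[rid]] <- kos
      } else if (!is.null(kosPerReaction)) {
        kos <- takeKos(as.integer(kosPerReaction))
        ruleStrings[[rid]] <- paste(kos, collapse = " AND ")
      } else {
        type <- sample(c("and", "or_iso", "or_and"), 1L)
        if (type == "and") {
          kos <- takeKos(sample(2:4, 1L))
          ruleStrings[[rid]] <- paste(kos, collapse = " AND ")
        } else if (type == "or_iso") {
          kos <- takeKos(2L)
          ruleStrings[[rid]] <- paste(kos, collapse = " OR ")
        } else {
          k1 <- takeKos(2L)
          k2 <- takeKos(2L)
          kos <- c(k1, k2)
          ruleStrings[[rid]] <- sprintf("(%s) OR (%s)",
                                        paste(k1, collapse = " AND "),
                                        paste(k2, collapse = " AND "))
        }
      }
      reactionKos[[rid]] <- kos
    }
    allKos <- sort(unique(unlist(reactionKos, use.names = FALSE)))
    famSeeds <- sample.int(2^30, length(allKos))
    koSequences <- list()
    for (i in seq_along(allKos)) {
      fam <- generateFamily(famSeeds[i], familyLength, familySize,
                            familyDivergence, prefix = allKos[i])
      koSequences[[allKos[i]]] <- fam$members
    }
    gprRules <- list()
    for (rid in names(ruleStrings))
      gprRules[[rid]] <- parseGpr(ruleStrings[[rid]], rid)
    new("ORAdb", koSequences = koSequences, reactionKos = reactionKos,
        gprRules = gprRules,
        report = data.frame(item = character(), issue = character(),
                            stringsAsFactors = FALSE))
  })
}

## Enumerate the irreducible KO sets satisfying a rule AST.
.satisfyingSets <- function(node) {
  if (node$op == "KO") return(list(node$ko))
  if (node$op == "OR")
    return(unlist(lapply(node$children, .satisfyingSets), recursive = FALSE))
  sets <- lapply(node$children, .satisfyingSets)
  out <- list(character())
  for (s in sets)
    out <- unlist(lapply(out, function(acc)
      lapply(s, function(x) unique(c(acc, x)))), recursive = FALSE)
  out
}

#' Generate a synthetic community with planted reaction capabilities
#'
#' Builds per-species proteomes realizing a planted binary species-by-
#' reaction table against a fixture database: for every reaction one
#' satisfying KO set of its GPR rule is chosen (a random OR branch, seeded,
#' shared by all species planted with that reaction) and each species
#' receives one diverged member of every KO family its reactions need;
#' decoy proteins unrelated to any KO are added to every species. The database must have reaction-private KO sets (as produced by
#' [generateOradbFixture()]) so the realized capabilities equal the planted
#' table exactly; this is validated and an inconsistency is an error.
#'
#' @param db an [ORAdb-class] fixture.
#' @param planted binary integer matrix, species rows x reaction columns;
#'   columns must be database reactions.
#' @param seed integer seed.
#' @param divergence substitution fraction applied when deriving each
#'   species' family member from the KO ancestor.
#' @param nDecoys decoy proteins per species; decoys are resampled until
#'   aligned identity to every KO ancestor stays below 30%.
#' @param decoyLength decoy length in residues.
#' @return list with \code{proteomes} (named list of
#'   \link[Biostrings]{AAStringSet} per species) and \code{truth}: the
#'   planted table, \code{sequenceLabels} (named KO per planted sequence),
#'   \code{speciesOf} (named species per sequence, decoys included),
#'   \code{speciesKos} (the KO sets actually planted per species).
#' @export
generateCommunity <- function(db, planted, seed = 1L, divergence = 0.05,
                              nDecoys = 4L, decoyLength = 60L) {
  stopifnot(is(db, "ORAdb"), is.matrix(planted))
  .checkPlanted <- setdiff(colnames(planted), names(db@reactionKos))
  if (length(.checkPlanted))
    stop(sprintf("planted reaction(s) not in database: %s",
                 paste(.checkPlanted, collapse = ", ")))
  ancestors <- vapply(koIds(db), function(ko) {
    ss <- db@koSequences[[ko]]
    if (length(ss) == 0L) NA_character_ else as.character(ss[[1L]])
  }, character(1))
  .withLocalSeed(seed, {
    proteomes <- list()
    labels <- character()
    speciesOf <- character()
    speciesKos <- list()
    # one satisfying KO set per reaction, shared by all species planted with
    # it, so a reaction carried by k species yields k-member KO families
    reactionChoice <- list()
    for (r in colnames(planted)) {
      sets <- .satisfyingSets(gprRule(db, r)@ast)
      pick <- sets[[sample.int(length(sets), 1L)]]
      if (any(is.na(ancestors[pick])))
        stop(sprintf("planted reaction '%s' needs KO(s) with no reference sequences",
                     r))
      reactionChoice[[r]] <- pick
    }
    for (s in rownames(planted)) {
      needed <- character()
      for (r in colnames(planted)) {
        if (planted[s, r] != 1L) next
        needed <- union(needed, reactionChoice[[r]])
      }
      needed <- sort(needed)
      speciesKos[[s]] <- needed
      seqs <- character()
      gi <- 1L
      for (ko in needed) {
        anc <- strsplit(ancestors[[ko]], "")[[1L]]
        nSub <- as.integer(.roundHalfUp(divergence * length(anc)))
        if (nSub > 0L) {
          posn <- sample(length(anc), nSub)
          for (p in posn)
            anc[p] <- sample(setdiff(names(.AA_BACKGROUND), anc[p]), 1L)
        }
        id <- sprintf("%s_g%03d", s, gi)
        gi <- gi + 1L
        seqs[[id]] <- paste(anc, collapse = "")
        labels[[id]] <- ko
        speciesOf[[id]] <- s
      }
      for (d in seq_len(nDecoys)) {
        repeat {
          dec <- paste(sample(names(.AA_BACKGROUND), decoyLength,
                              replace = TRUE, prob = .AA_BACKGROUND),
                       collapse = "")
          idents <- vapply(ancestors[!is.na(ancestors)], function(a) {
            r <- localAlign(dec, a)
            r$n_ident / min(nchar(dec), nchar(a))
          }, numeric(1))
          if (all(idents < 0.30)) break
        }
        id <- sprintf("%s_decoy%02d", s, d)
        seqs[[id]] <- dec
        speciesOf[[id]] <- s
      }
      proteomes[[s]] <- AAStringSet(seqs)
    }
    realized <- reactionCapabilities(speciesKos, db)
    plantedSorted <- planted[sort(rownames(planted)),
                             sort(colnames(planted)), drop = FALSE]
    realizedSub <- realized[rownames(plantedSorted), colnames(plantedSorted),
                            drop = FALSE]
    if (!identical(unname(realizedSub == 1L), unname(plantedSorted == 1L))) {
      bad <- which(realizedSub != plantedSorted, arr.ind = TRUE)[1L, ]
      stop(sprintf("planted table inconsistent with GPR rules at species '%s', reaction '%s'",
                   rownames(plantedSorted)[bad[1L]],
                   colnames(plantedSorted)[bad[2L]]))
    }
    list(proteomes = proteomes,
         truth = list(planted = plantedSorted, sequenceLabels = labels,
                      speciesOf = speciesOf, speciesKos = speciesKos))
  })
}

#' Translate a coding sequence, selecting the longest possible protein
#'
#' Enumerates candidate open reading frames within the original frame: the
#' translation from the first codon to the first in-frame stop (or the
#' end), plus from every in-frame ATG to the next in-frame stop (or the
#' end). Returns the longest candidate, ties broken by earliest start. Only
#' the original frame is considered: substitution-only mutation cannot
#' shift frames.
#'
#' @param dna DNA string over ACGT, length divisible by 3.
#' @return protein string (no stop character).
#' @export
translateLongest <- function(dna) {
  dna <- toupper(as.character(dna))
  if (nchar(dna) %% 3L != 0L) stop("length must be divisible by 3")
  if (grepl("[^ACGT]", dna)) stop("DNA must be over ACGT")
  codons <- substring(dna, seq(1L, nchar(dna), 3L), seq(3L, nchar(dna), 3L))
  gc <- Biostrings::GENETIC_CODE
  aas <- unname(gc[codons])
  starts <- unique(c(1L, which(codons == "ATG")))
  best <- ""
  bestStart <- Inf
  for (st in sort(starts)) {
    aa <- aas[st:length(aas)]
    stop_at <- which(aa == "*")
    prot <- if (length(stop_at)) aa[seq_len(stop_at[1L] - 1L)] else aa
    p <- paste(prot, collapse = "")
    if (nchar(p) > nchar(best)) {
      best <- p
      bestStart <- st
    }
  }
  if (!nzchar(best)) stop("no candidate protein of length >= 1")
  best
}

#' Mutate a coding sequence by random base substitutions
#'
#' Introduces \code{max(1, round(rate * length))} base substitutions (0 for
#' rate 0) at positions drawn uniformly without replacement from the bases
#' of the interior codons — the first and last codon are never touched.
#' Each substituted base becomes one of the three other bases uniformly, so
#' the substitution count is exact. The mutated protein is obtained with
#' [translateLongest()], which handles stop/start codons the mutation may
#' have introduced.
#'
#' @param dna DNA string over ACGT, length divisible by 3, at least 3
#'   codons.
#' @param rate substitution rate in \eqn{[0, 1]}.
#' @param seed integer seed.
#' @return list with \code{dna} (mutated sequence) and \code{protein}.
#' @export
mutateCds <- function(dna, rate, seed = 1L) {
  dna <- toupper(as.character(dna))
  if (nchar(dna) %% 3L != 0L) stop("length must be divisible by 3")
  if (nchar(dna) < 9L) stop("need at least 3 codons")
  if (grepl("[^ACGT]", dna)) stop("DNA must be over ACGT")
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  n <- nchar(dna)
  nSub <- if (rate == 0) 0L else max(1L, as.integer(.roundHalfUp(rate * n)))
  eligible <- seq(4L, n - 3L)
  if (nSub > length(eligible))
    stop(sprintf("cannot place %d substitutions in %d eligible positions",
                 nSub, length(eligible)))
  ch <- strsplit(dna, "")[[1L]]
  if (nSub > 0L) {
    .withLocalSeed(seed, {
      posn <- sample(eligible, nSub)
      for (p in posn)
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    })
  }
  mutated <- paste(ch, collapse = "")
  list(dna = mutated, protein = translateLongest(mutated))
}

#' Reverse-translate a protein to a coding sequence
#'
#' Picks one codon uniformly among the synonymous codons of each residue
#' (seeded), appends a stop codon, and prepends nothing: the first codon is
#' the first residue's codon. Useful for building coding sequences whose
#' mutated translations can be compared with the original protein.
#'
#' @param protein protein string over the 20 standard residues.
#' @param seed integer seed.
#' @return DNA string whose [translateLongest()] is \code{protein} (when no
#'   internal ATG yields a longer product).
#' @export
reverseTranslate <- function(protein, seed = 1L) {
  protein <- toupper(as.character(protein))
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", protein))
    stop("protein must use the 20 standard residues")
  gc <- Biostrings::GENETIC_CODE
  byAa <- split(names(gc), unname(gc))
  .withLocalSeed(seed, {
    codons <- vapply(strsplit(protein, "")[[1L]], function(a)
      sample(byAa[[a]], 1L), character(1))
    paste(c(codons, "TAA"), collapse = "")
  })
}

#' Write per-species proteome FASTA files
#'
#' @param proteomes named list of \link[Biostrings]{AAStringSet} (one per
#'   species), e.g. from [generateCommunity()].
#' @param dir output directory; one \code{<species>.fasta} per species.
#' @return \code{dir}, invisibly.
#' @export
writeProteomes <- function(proteomes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(proteomes))
    writeXStringSet(proteomes[[s]], file.path(dir, sprintf("%s.fasta", s)))
  invisible(dir)
}

#' Read per-species proteome FASTA files
#'
#' @param dir directory of \code{<species>.fasta} files; the species id is
#'   the file stem. Sequence ids must be unique across species.
#' @return list with \code{seqs} (named character vector of all sequences)
#'   and \code{speciesOf} (named species per sequence id).
#' @export
readProteomes <- function(dir) {
  files <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
  if (length(files) == 0L)
    stop(sprintf("no FASTA files in '%s'", dir))
  seqs <- character()
  speciesOf <- character()
  for (f in files) {
    sp <- sub("\\.fasta$", "", basename(f))
    ss <- .readProteinFasta(f)
    dup <- intersect(names(ss), names(seqs))
    if (length(dup))
      stop(sprintf("duplicate sequence id '%s' across species", dup[1L]))
    v <- as.character(ss)
    seqs <- c(seqs, v)
    speciesOf <- c(speciesOf, stats::setNames(rep(sp, length(v)), names(v)))
  }
  list(seqs = seqs, speciesOf = speciesOf)
}
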