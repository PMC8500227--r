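#' Scoring scheme for local protein alignment
#'
#' Bundles the substitution matrix, affine gap penalties and the
#' Karlin-Altschul statistical parameters used to turn raw Smith-Waterman
#' scores into bit scores and E-values. A gap of length L is penalized
#' \code{gapOpen + gapExt * L}. The default is BLOSUM62 with gap open 11 /
#' extend 1 and (lambda, K) = (0.267, 0.041), the standard parameters for
#' that matrix and gap setting; the unknown residue \code{X} scores 0
#' against everything.
#'
#' @param matrix square integer substitution matrix with residue dimnames
#'   covering the 20 amino acids plus \code{X}; must be symmetric.
#' @param gapOpen,gapExt positive gap penalties, \code{gapExt <= gapOpen}.
#' @param lambda,k positive Karlin-Altschul parameters.
#' @return a \code{ScoringScheme} (classed list).
#' @export
scoringScheme <- function(matrix = NULL, gapOpen = 11L, gapExt = 1L,
                          lambda = 0.267, k = 0.041) {
  if (is.null(matrix)) {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    matrix <- BLOSUM62[AA_ALPHABET20X, AA_ALPHABET20X]
    matrix["X", ] <- 0L
    matrix[, "X"] <- 0L
  }
  if (is.null(rownames(matrix)) || !identical(rownames(matrix), colnames(matrix)))
    stop("substitution matrix must have identical row and column names")
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  if (gapOpen <= 0 || gapExt <= 0 || gapExt > gapOpen)
    stop("require 0 < gapExt <= gapOpen")
  if (lambda <= 0 || k <= 0) stop("lambda and k must be positive")
  structure(list(matrix = matrix, gapOpen = as.integer(gapOpen),
                 gapExt = as.integer(gapExt), lambda = lambda, k = k),
            class = "ScoringScheme")
}

.encodeSeq <- function(seq, alphabet) {
  if (is(seq, "AAString") || is(seq, "AAStringSet")) seq <- as.character(seq)
  if (!is.character(seq) || length(seq) != 1L) stop("expected one sequence")
  if (!nzchar(seq)) stop("empty sequence")
  chars <- strsplit(toupper(seq), "")[[1L]]
  idx <- match(chars, alphabet)
  if (anyNA(idx))
    stop(sprintf("illegal character '%s' at position %d",
                 chars[which(is.na(idx))[1L]], which(is.na(idx))[1L]))
  idx - 1L
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gaps. The raw score is the maximum local
#' alignment score (0 when no positive-scoring alignment exists, i.e. the
#' empty alignment); identity and alignment length come from one optimal
#' traceback with ties resolved deterministically (diagonal preferred over a
#' gap in the subject over a gap in the query).
#'
#' @param query,subject protein sequences (character or
#'   \link[Biostrings]{AAString}), non-empty, alphabet restricted to the
#'   scheme's matrix.
#' @param scheme a [scoringScheme()].
#' @return list with \code{raw_score} (integer), \code{aln_len} (columns in
#'   the optimal alignment, gaps included), \code{n_ident}, and
#'   \code{pct_identity} in \eqn{[0, 100]} (0 for an empty alignment).
#' @examples
#' localAlign("ACDE", "ACDE")$raw_score  # 4 + 9 + 6 + 5 = 24
#' @export
localAlign <- function(query, subject, scheme = scoringScheme()) {
  alpha <- rownames(scheme$matrix)
  q <- .encodeSeq(query, alpha)
  s <- .encodeSeq(subject, alpha)
  r <- sw_align_cpp(q, s, scheme$matrix, scheme$gapOpen, scheme$gapExt)
  list(raw_score = r$score, aln_len = r$aln_len, n_ident = r$n_ident,
       pct_identity = if (r$aln_len > 0) 100 * r$n_ident / r$aln_len else 0)
}

#' Karlin-Altschul bit score of a raw alignment score
#'
#' \eqn{S' = (\lambda S - \ln K) / \ln 2}; strictly increasing in the raw
#' score.
#'
#' @param raw non-negative raw score(s).
#' @param scheme a [scoringScheme()] supplying lambda and K.
#' @return bit score(s), in bits.
#' @export
bitScore <- function(raw, scheme = scoringScheme()) {
  if (any(raw < 0)) stop("raw score must be >= 0")
  (scheme$lambda * raw - log(scheme$k)) / log(2)
}

#' E-value of a bit score in an m x n search space
#'
#' \eqn{E = m n \, 2^{-S'}}: the expected number of chance local alignments
#' scoring at least as well in a search of a length-m query against n
#' database residues. The search space is plain \eqn{m \times n}; no
#' effective-length correction is applied, so absolute values differ from
#' BLAST's while threshold behavior is preserved.
#'
#' @param bit bit score(s).
#' @param m query length in residues (>= 1).
#' @param n total database residues searched (>= 1).
#' @return E-value(s), >= 0, decreasing in \code{bit}.
#' @export
eValue <- function(bit, m, n) {
  if (any(m < 1) || any(n < 1)) stop("m and n must be >= 1")
  as.numeric(m) * as.numeric(n) * 2^(-bit)
}

## All query x subject alignments; returns score/aln_len/n_ident matrices
## with dimnames. Internal workhorse for search, clustering and annotation.
.alignAllPairs <- function(queries, subjects, scheme) {
  alpha <- rownames(scheme$matrix)
  qenc <- lapply(as.character(queries), .encodeSeq, alphabet = alpha)
  senc <- lapply(as.character(subjects), .encodeSeq, alphabet = alpha)
  r <- sw_all_pairs_cpp(qenc, senc, scheme$matrix, scheme$gapOpen,
                        scheme$gapExt)
  dn <- list(names(queries), names(subjects))
  dimnames(r$score) <- dimnames(r$aln_len) <- dimnames(r$n_ident) <- dn
  r
}

#' Search queries against a reference sequence set
#'
#' Aligns every query to every reference sequence and reports, per (query,
#' subject) pair, the maximal-scoring local alignment as one hit (no HSP
#' tiling), keeping hits with E-value at or below the threshold. The
#' E-value search space is the query length times the total residue count
#' of the reference set.
#'
#' @param queries named character vector or \link[Biostrings]{AAStringSet}.
#' @param reference named character vector or
#'   \link[Biostrings]{AAStringSet}; must be non-empty.
#' @param scheme a [scoringScheme()].
#' @param maxEvalue keep hits with \code{evalue <= maxEvalue} (inclusive).
#' @return data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{raw_score}, \code{bit_score}, \code{evalue}, \code{pct_identity},
#'   \code{aln_len}, ordered by query then subject.
#' @export
searchHits <- function(queries, reference, scheme = scoringScheme(),
                       maxEvalue = 10) {
  if (length(queries) == 0L) stop("no query sequences")
  if (length(reference) == 0L) stop("empty reference set")
  queries <- .asNamedChar(queries, "query")
  reference <- .asNamedChar(reference, "reference")
  nres <- sum(nchar(reference))
  r <- .alignAllPairs(queries, reference, scheme)
  bits <- bitScore(r$score, scheme)
  ev <- eValue(bits, m = matrix(nchar(queries), nrow = length(queries),
                                ncol = length(reference)), n = nres)
  keep <- which(ev <= maxEvalue, arr.ind = TRUE)
  keep <- keep[order(keep[, 1L], keep[, 2L]), , drop = FALSE]
  data.frame(
    query_id = names(queries)[keep[, 1L]],
    subject_id = names(reference)[keep[, 2L]],
    raw_score = r$score[keep],
    bit_score = bits[keep],
    evalue = ev[keep],
    pct_identity = ifelse(r$aln_len[keep] > 0,
                          100 * r$n_ident[keep] / r$aln_len[keep], 0),
    aln_len = r$aln_len[keep],
    stringsAsFactors = FALSE)
}

.asNamedChar <- function(x, what) {
  nm <- names(x)
  x <- stats::setNames(as.character(x), nm)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop(sprintf("%s sequences must have unique non-empty names", what))
  x
}

#' Import externally computed hits in BLAST 12-column tabular format
#'
#' Reads the tab-separated, headerless outfmt-6 dialect (qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore),
#' as written by BLAST+, DIAMOND or MMseqs2, so externally computed
#' alignments can replace the built-in aligner.
#'
#' @param path file path.
#' @return data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{raw_score} (NA; not recoverable from the format),
#'   \code{bit_score}, \code{evalue}, \code{pct_identity}, \code{aln_len}.
#' @export
readTabularHits <- function(path) {
  if (!file.exists(path)) stop(sprintf("hits file '%s' not found", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(query_id = character(), subject_id = character(),
                      raw_score = numeric(), bit_score = numeric(),
                      evalue = numeric(), pct_identity = numeric(),
                      aln_len = integer(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stop(sprintf("expected 12 tab-separated columns, found %d on line %d",
                 nf[nf != 12L][1L], which(nf != 12L)[1L]))
  m <- do.call(rbind, parts)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v))
      stop(sprintf("non-numeric %s on line %d", what, which(is.na(v))[1L]))
    v
  }
  data.frame(query_id = m[, 1L], subject_id = m[, 2L],
             raw_score = NA_real_,
             bit_score = num(12L, "bitscore"),
             evalue = num(11L, "evalue"),
             pct_identity = num(3L, "pident"),
             aln_len = as.integer(num(4L, "length")),
             stringsAsFactors = FALSE)
}
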