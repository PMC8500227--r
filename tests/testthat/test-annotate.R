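# Small annotation scenario shared by several tests: a database of four KO
# families and a community of clusters drawn from them plus unrelated decoys.
annotFixture <- function(divergence = 0.05, seed = 201) {
  db <- tinyDb()
  comm <- generateCommunity(
    db,
    matrix(c(1L, 1L, 0L,
             1L, 0L, 1L), nrow = 3L, ncol = 2L,
           dimnames = list(c("spA", "spB", "spC"), c("R00001", "R00002"))),
    seed = seed, divergence = divergence)
  seqs <- character()
  for (s in names(comm$proteomes)) {
    v <- as.character(comm$proteomes[[s]])
    seqs[names(v)] <- v
  }
  cs <- internalCluster(seqs, comm$truth$speciesOf)
  list(db = db, comm = comm, seqs = seqs, cs = cs)
}

test_that("sampleCluster sizes, floors and determinism", {
  expect_identical(sampleCluster("only1", 0.5), "only1")
  expect_length(sampleCluster(c("a", "b", "c"), 0.5), 2L)  # ceil(1.5)
  ids <- sprintf("s%03d", 1:100)
  s1 <- sampleCluster(ids, 0.5, seed = 7L, clusterId = "OG1")
  s2 <- sampleCluster(ids, 0.5, seed = 7L, clusterId = "OG1")
  expect_identical(s1, s2)
  expect_length(s1, 50L)
  # member order irrelevant; cluster id changes the stream
  expect_identical(sampleCluster(rev(ids), 0.5, 7L, "OG1"), s1)
  expect_false(identical(sampleCluster(ids, 0.5, 7L, "OG2"), s1))
  expect_identical(sampleCluster(ids, 1.0, 7L, "OG1"), ids)
  expect_error(sampleCluster(ids, 0), "fraction")
})

test_that("relaxedSearch finds planted candidates and honors the threshold", {
  fx <- annotFixture()
  cand <- relaxedSearch(fx$cs, fx$seqs, fx$db, annotationConfig())
  expect_gt(length(cand), 0L)
  # a cluster holding an exact copy of a reference has that KO as candidate
  ref <- as.character(koSequences(fx$db, "K33333"))[1L]
  seqs2 <- c(fx$seqs, copycat = unname(ref), copemate = unname(ref))
  cs2 <- internalCluster(seqs2, c(fx$comm$truth$speciesOf,
                                  copycat = "spZ", copemate = "spZ"))
  copyCluster <- names(Filter(function(cl)
    "copycat" %in% unlist(cl, use.names = FALSE), clusters(cs2)))
  cand2 <- relaxedSearch(cs2, seqs2, fx$db, annotationConfig())
  expect_true("K33333" %in% cand2[[copyCluster]])
  # E-value threshold of zero drops everything
  expect_length(relaxedSearch(fx$cs, fx$seqs, fx$db,
                              annotationConfig(relaxedEvalue = 0,
                                               restrictiveEvalue = 0)), 0L)
})

test_that("relaxed candidates equal brute-force filtering on the same sample", {
  fx <- annotFixture()
  config <- annotationConfig()
  cand <- relaxedSearch(fx$cs, fx$seqs, fx$db, config)
  scheme <- scoringScheme()
  refs <- list()
  for (ko in koIds(fx$db)) {
    ss <- as.character(koSequences(fx$db, ko))
    for (nm in names(ss)) refs[[paste(ko, nm)]] <- c(ko, ss[[nm]])
  }
  nres <- sum(vapply(refs, function(x) nchar(x[2L]), numeric(1)))
  for (cid in names(clusters(fx$cs))) {
    members <- unlist(clusters(fx$cs)[[cid]], use.names = FALSE)
    sampled <- sampleCluster(members, config$sampleFraction, config$seed,
                             cid)
    kos <- character()
    for (q in sampled) {
      for (r in refs) {
        raw <- localAlign(fx$seqs[[q]], r[2L], scheme)$raw_score
        ev <- eValue(bitScore(raw, scheme), nchar(fx$seqs[[q]]), nres)
        if (ev <= config$relaxedEvalue) kos <- c(kos, r[1L])
      }
    }
    expect_identical(cand[[cid]], if (length(kos)) sort(unique(kos)),
                     info = cid)
  }
})

test_that("restrictive assignments equal brute-force two-threshold filtering", {
  fx <- annotFixture()
  config <- annotationConfig()
  cand <- relaxedSearch(fx$cs, fx$seqs, fx$db, config)
  res <- restrictiveSearch(cand, fx$cs, fx$seqs, fx$db, config)
  scheme <- scoringScheme()
  nres <- sum(vapply(koIds(fx$db), function(ko)
    sum(nchar(as.character(koSequences(fx$db, ko)))), numeric(1)))
  expected <- character()
  for (cid in names(cand)) {
    members <- unlist(clusters(fx$cs)[[cid]], use.names = FALSE)
    for (q in members) {
      for (ko in cand[[cid]]) {
        best <- -Inf
        for (refseq in as.character(koSequences(fx$db, ko))) {
          raw <- localAlign(fx$seqs[[q]], refseq, scheme)$raw_score
          best <- max(best, bitScore(raw, scheme))
        }
        ev <- eValue(best, nchar(fx$seqs[[q]]), nres)
        if (ev <= config$restrictiveEvalue && best > config$minBitScore)
          expected <- c(expected, paste(q, ko))
      }
    }
  }
  asn <- assignments(res)
  expect_setequal(paste(asn$sequence_id, asn$ko), expected)
  # every assignment respects candidate sets and both thresholds
  for (i in seq_len(nrow(asn))) {
    cid <- names(Filter(function(cl)
      asn$sequence_id[i] %in% unlist(cl, use.names = FALSE),
      clusters(fx$cs)))
    expect_true(asn$ko[i] %in% cand[[cid]])
    expect_lte(asn$evalue[i], config$restrictiveEvalue)
    expect_gt(asn$bit_score[i], config$minBitScore)
  }
  expect_error(restrictiveSearch(list(OG0000000 = "K99999"), fx$cs, fx$seqs,
                                 fx$db, config), "K99999")
})

test_that("a best hit at bit score exactly 50 is rejected (strict filter)", {
  seqv <- paste(rep("W", 30), collapse = "")
  db <- buildOradb("K77777", offlineFetcher(
    koFastas = list(K77777 = Biostrings::AAStringSet(c(ref1 = seqv)))))
  cs <- new("ClusterSet", clusters = list(OG0 = list(sp = c("q1", "q2"))),
            unassigned = character())
  seqs <- c(q1 = seqv, q2 = seqv)
  raw <- localAlign(seqv, seqv)$raw_score
  # calibrate lambda so this alignment's bit score sits exactly at the floor
  kparam <- 0.041
  lambdaAt50 <- (50 * log(2) + log(kparam)) / raw
  schemeAt50 <- scoringScheme(lambda = lambdaAt50, k = kparam)
  bitAtFloor <- bitScore(raw, schemeAt50)
  expect_equal(bitAtFloor, 50)
  config <- annotationConfig(relaxedEvalue = 10, restrictiveEvalue = 10,
                             minBitScore = bitAtFloor, sampleFraction = 1)
  cand <- relaxedSearch(cs, seqs, db, config, schemeAt50)
  expect_identical(cand$OG0, "K77777")
  res <- restrictiveSearch(cand, cs, seqs, db, config, schemeAt50)
  expect_identical(nrow(assignments(res)), 0L)
  # a floor just below the hit's bit score lets it through
  configBelow <- annotationConfig(relaxedEvalue = 10, restrictiveEvalue = 10,
                                  minBitScore = bitAtFloor - 1e-6,
                                  sampleFraction = 1)
  res2 <- restrictiveSearch(cand, cs, seqs, db, configBelow, schemeAt50)
  expect_identical(nrow(assignments(res2)), 2L)
})

test_that("restrictive E-value threshold is inclusive", {
  seqv <- paste(rep("W", 30), collapse = "")
  db <- buildOradb("K77777", offlineFetcher(
    koFastas = list(K77777 = Biostrings::AAStringSet(c(ref1 = seqv)))))
  cs <- new("ClusterSet", clusters = list(OG0 = list(sp = "q1")),
            unassigned = character())
  seqs <- c(q1 = seqv)
  scheme <- scoringScheme()
  ev <- eValue(bitScore(localAlign(seqv, seqv, scheme)$raw_score, scheme),
               nchar(seqv), nchar(seqv))
  config <- annotationConfig(relaxedEvalue = ev, restrictiveEvalue = ev,
                             minBitScore = 0, sampleFraction = 1)
  res <- restrictiveSearch(relaxedSearch(cs, seqs, db, config, scheme),
                           cs, seqs, db, config, scheme)
  expect_identical(nrow(assignments(res)), 1L)
  configBelow <- annotationConfig(relaxedEvalue = ev * 0.999,
                                  restrictiveEvalue = ev * 0.999,
                                  minBitScore = 0, sampleFraction = 1)
  expect_length(relaxedSearch(cs, seqs, db, configBelow, scheme), 0L)
})

test_that("loosening any threshold never removes an annotation", {
  fx <- annotFixture(divergence = 0.12, seed = 333)
  base <- annotationConfig()
  resBase <- restrictiveSearch(relaxedSearch(fx$cs, fx$seqs, fx$db, base),
                               fx$cs, fx$seqs, fx$db, base)
  keysBase <- with(assignments(resBase), paste(sequence_id, ko))
  looser <- list(
    annotationConfig(relaxedEvalue = 0.01),
    annotationConfig(restrictiveEvalue = 1e-6),
    annotationConfig(minBitScore = 30))
  for (cfg in looser) {
    res <- restrictiveSearch(relaxedSearch(fx$cs, fx$seqs, fx$db, cfg),
                             fx$cs, fx$seqs, fx$db, cfg)
    keys <- with(assignments(res), paste(sequence_id, ko))
    expect_true(all(keysBase %in% keys))
  }
})

test_that("with full sampling the two stages are consistent", {
  fx <- annotFixture()
  cfg <- annotationConfig(sampleFraction = 1)
  cand <- relaxedSearch(fx$cs, fx$seqs, fx$db, cfg)
  # confirm at the relaxed threshold with no bit filter: the confirmed
  # cluster/KO pairs are exactly the relaxed candidates
  cfgRelaxedConfirm <- annotationConfig(relaxedEvalue = cfg$relaxedEvalue,
                                        restrictiveEvalue = cfg$relaxedEvalue,
                                        minBitScore = -Inf,
                                        sampleFraction = 1)
  res <- restrictiveSearch(cand, fx$cs, fx$seqs, fx$db, cfgRelaxedConfirm)
  asn <- assignments(res)
  confirmed <- list()
  for (cid in names(cand)) {
    members <- unlist(clusters(fx$cs)[[cid]], use.names = FALSE)
    kos <- sort(unique(asn$ko[asn$sequence_id %in% members]))
    if (length(kos)) confirmed[[cid]] <- kos
  }
  expect_identical(confirmed, cand)
})

test_that("speciesKoTable aggregates with set semantics", {
  res <- new("AnnotationResult",
             candidateKos = list(),
             assignments = data.frame(
               sequence_id = c("s1", "s2", "s3", "s3"),
               ko = c("K00001", "K00001", "K00002", "K00003"),
               subject_id = "r", evalue = 1e-20, bit_score = 100,
               pct_identity = 99, aln_len = 50,
               stringsAsFactors = FALSE))
  spOf <- c(s1 = "spA", s2 = "spA", s3 = "spB")
  tab <- speciesKoTable(res, spOf)
  expect_identical(tab, list(spA = "K00001", spB = c("K00002", "K00003")))
  expect_error(speciesKoTable(res, spOf[-3L]), "s3")

  # random instance equals an independent group-by
  set.seed(55)
  n <- 40L
  asn <- data.frame(sequence_id = sprintf("g%02d", sample(20, n, TRUE)),
                    ko = sprintf("K%05d", sample(5, n, TRUE)),
                    subject_id = "r", evalue = 0, bit_score = 100,
                    pct_identity = 1, aln_len = 1,
                    stringsAsFactors = FALSE)
  spOf2 <- stats::setNames(sprintf("sp%d", rep(1:4, each = 5L)),
                           sprintf("g%02d", 1:20))
  got <- speciesKoTable(new("AnnotationResult", candidateKos = list(),
                            assignments = asn), spOf2)
  expected <- lapply(split(asn$ko, unname(spOf2[asn$sequence_id])),
                     function(k) sort(unique(k)))
  expect_identical(got, expected[order(names(expected))])
})

test_that("annotationPerformance is the matched fraction of the reference", {
  ref <- data.frame(sequence_id = sprintf("s%02d", 1:50),
                    ko = "K00001", stringsAsFactors = FALSE)
  expect_equal(annotationPerformance(ref, ref)$performance, 1.0)
  pred <- ref[1:48, ]
  perf <- annotationPerformance(pred, ref)
  expect_identical(perf$matching_annotated, 48L)
  expect_identical(perf$total_reference_annotations, 50L)
  expect_equal(perf$performance, 0.96)
  disjoint <- data.frame(sequence_id = "x", ko = "K99999")
  expect_equal(annotationPerformance(disjoint, ref)$performance, 0.0)
  expect_error(annotationPerformance(pred, ref[0, ]), "empty")
})
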