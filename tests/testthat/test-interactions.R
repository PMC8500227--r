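abcTable <- function() {
  matrix(c(1L, 0L, 1L,
           0L, 1L, 1L), nrow = 3L, ncol = 2L,
         dimnames = list(c("A", "B", "C"), c("r1", "r2")))
}

test_that("completeSpecies lists exactly the all-ones rows", {
  tab <- abcTable()
  pw <- pathwayDef("p", c("r1", "r2"))
  expect_identical(completeSpecies(tab, pw), "C")
  expect_identical(completeSpecies(tab * 0L, pw), character(0))
  expect_error(completeSpecies(tab, pathwayDef("p", "r9")), "r9")

  set.seed(71)
  tab2 <- randomCapTable(8, 6)
  pw2 <- pathwayDef("p2", colnames(tab2)[1:4])
  expected <- sort(rownames(tab2)[apply(
    tab2[, pw2$reactions, drop = FALSE] == 1L, 1L, all)])
  expect_identical(completeSpecies(tab2, pw2), expected)
})

test_that("single-species subsets must be carried by one member", {
  tab <- abcTable()
  cons <- constraintSet(singleSpeciesSubsets = list(c("r1", "r2")))
  expect_false(satisfiesConstraints(c("A", "B"), tab, cons))  # split
  expect_true(satisfiesConstraints(c("A", "B", "C"), tab, cons))
  expect_true(satisfiesConstraints("C", tab, cons))
})

test_that("transporter modes and size caps behave as specified", {
  tab <- abcTable()
  anyTr <- constraintSet(transporterReactions = "r1",
                         transporterMode = "any_member")
  expect_true(satisfiesConstraints(c("A", "B"), tab, anyTr))
  expect_false(satisfiesConstraints("B", tab, anyTr))
  allTr <- constraintSet(transporterReactions = "r1",
                         transporterMode = "every_member")
  expect_false(satisfiesConstraints(c("A", "B"), tab, allTr))
  expect_true(satisfiesConstraints(c("A", "C"), tab, allTr))
  capped <- constraintSet(maxCombinationSize = 2)
  expect_false(satisfiesConstraints(c("A", "B", "C"), tab, capped))
})

test_that("satisfiesConstraints equals an independent predicate on random instances", {
  set.seed(73)
  for (i in 1:200) {
    tab <- randomCapTable(sample(3:7, 1L), sample(3:6, 1L))
    cons <- randomConstraints(colnames(tab), nrow(tab))
    combo <- sample(rownames(tab), sample(seq_len(nrow(tab)), 1L))
    expect_identical(satisfiesConstraints(combo, tab, cons),
                     constraintOracle(combo, tab, cons),
                     info = sprintf("instance %d", i))
  }
})

test_that("enumerateCombinations matches brute force on the worked example", {
  tab <- abcTable()
  pw <- pathwayDef("p", c("r1", "r2"))
  res <- enumerateCombinations(tab, pw,
                               constraintSet(includeComplete = FALSE))
  expect_identical(completeSpecies(res), "C")
  expect_identical(comboKeys(res), "A,B")
  # with complete species allowed inside combinations
  resIn <- enumerateCombinations(tab, pw, constraintSet())
  expect_setequal(comboKeys(resIn), c("A,B", "A,C", "B,C", "A,B,C"))
  # an uncoverable pathway yields no combinations
  tab0 <- cbind(tab, r3 = 0L)
  expect_length(combinations(enumerateCombinations(
    tab0, pathwayDef("p", c("r1", "r3")), constraintSet())), 0L)
})

test_that("per-reaction contributor attribution lists exactly the capable members", {
  tab <- abcTable()
  res <- enumerateCombinations(tab, pathwayDef("p", c("r1", "r2")),
                               constraintSet())
  cmb <- Filter(function(x) setequal(x$members, c("A", "B", "C")),
                combinations(res))[[1L]]
  expect_setequal(cmb$contributors$r1, c("A", "C"))
  expect_setequal(cmb$contributors$r2, c("B", "C"))
})

test_that("enumeration equals the exhaustive subset oracle on random instances", {
  set.seed(79)
  for (i in 1:25) {
    tab <- randomCapTable(sample(4:10, 1L), sample(3:6, 1L))
    pw <- pathwayDef("p", sample(colnames(tab),
                                 sample(2:ncol(tab), 1L)))
    cons <- randomConstraints(colnames(tab), nrow(tab))
    res <- enumerateCombinations(tab, pw, cons)
    expect_identical(comboKeys(res), comboOracle(tab, pw, cons),
                     info = sprintf("instance %d", i))
    # soundness re-check of everything emitted
    for (cmb in combinations(res)) {
      expect_true(satisfiesConstraints(cmb$members, tab, cons))
      expect_gte(coverageOracle(cmb$members, tab, pw$reactions) + 1e-12,
                 cons$completenessFraction)
    }
  }
})

test_that("combinations come out ordered by size then lexicographically", {
  set.seed(83)
  tab <- randomCapTable(6, 4)
  pw <- pathwayDef("p", colnames(tab)[1:3])
  res <- enumerateCombinations(tab, pw, constraintSet())
  keys <- vapply(combinations(res), function(x)
    sprintf("%03d|%s", length(x$members),
            paste(x$members, collapse = ",")), character(1))
  expect_identical(keys, sort(keys))
})

test_that("minimalOnly drops supersets of emitted combinations", {
  tab <- abcTable()
  res <- enumerateCombinations(tab, pathwayDef("p", c("r1", "r2")),
                               constraintSet(includeComplete = FALSE),
                               minimalOnly = TRUE)
  expect_identical(comboKeys(res), "A,B")
  set.seed(89)
  tab2 <- randomCapTable(7, 5)
  pw2 <- pathwayDef("p", colnames(tab2)[1:4])
  resMin <- enumerateCombinations(tab2, pw2, constraintSet(),
                                  minimalOnly = TRUE)
  keysMin <- lapply(combinations(resMin), `[[`, "members")
  for (i in seq_along(keysMin))
    for (j in seq_along(keysMin))
      if (i != j)
        expect_false(all(keysMin[[i]] %in% keysMin[[j]]))
})

test_that("coverage failure is anti-monotone and pathway shrinking is monotone", {
  set.seed(97)
  for (i in 1:20) {
    tab <- randomCapTable(6, 5)
    rx <- colnames(tab)
    combo <- sample(rownames(tab), sample(2:5, 1L))
    sub <- sample(combo, sample(seq_along(combo), 1L))
    if (coverageOracle(combo, tab, rx) < 1)
      expect_lt(coverageOracle(sub, tab, rx), 1)
    # removing a reaction never shrinks the combination list
    pwFull <- pathwayDef("p", rx)
    pwLess <- pathwayDef("p", rx[-1L])
    full <- comboKeys(enumerateCombinations(tab, pwFull, constraintSet()))
    less <- comboKeys(enumerateCombinations(tab, pwLess, constraintSet()))
    expect_true(all(full %in% less))
  }
})

test_that("species counts beyond the enumeration bound are refused", {
  tab <- matrix(1L, 31, 1, dimnames = list(sprintf("s%02d", 1:31), "r1"))
  expect_error(enumerateCombinations(tab, pathwayDef("p", "r1"),
                                     constraintSet()), "30")
})

test_that("compareToObservations explains growth via completeness or joint cover", {
  tab <- abcTable()
  pw <- pathwayDef("p", c("r1", "r2"))
  obs <- list(list(species = "C", grew = TRUE),            # complete
              list(species = c("A", "B"), grew = TRUE),    # joint cover
              list(species = "A", grew = TRUE),            # unexplained
              list(species = "B", grew = FALSE))           # not counted
  cmp <- compareToObservations(tab, pw, constraintSet(), obs)
  expect_identical(cmp$total_grown, 3L)
  expect_identical(cmp$explained, 2L)
  expect_error(compareToObservations(tab, pw, constraintSet(),
                                     list(list(species = "Z", grew = TRUE))),
               "Z")
})

test_that("interaction results and networks are written as specified", {
  tab <- abcTable()
  pw <- pathwayDef("p", c("r1", "r2"))
  res <- enumerateCombinations(tab, pw, constraintSet(includeComplete = FALSE))
  out <- withr::local_tempdir()
  dir <- writeInteractions(res, out)
  expect_identical(readLines(file.path(dir, "complete_species.txt")), "C")
  lines <- readLines(file.path(dir, "combinations.tsv"))
  expect_identical(lines[1L], "members\tsize\treaction_contributors")
  expect_match(lines[2L], "^A,B\t2\t")

  paths <- exportNetwork(tab, out)
  net <- jsonlite::read_json(paths[1L], simplifyVector = TRUE)
  expect_identical(nrow(net$nodes), 5L)  # 3 species + 2 reactions
  expect_identical(nrow(net$edges), sum(tab))
  # edge set equals the 1-cells
  expect_setequal(paste(net$edges$species, net$edges$reaction),
                  c("A r1", "B r2", "C r1", "C r2"))
  expect_true(file.exists(paths[2L]))
  # KEGG links only for R##### identifiers
  tabK <- tab
  colnames(tabK) <- c("R00001", "rx_custom")
  netK <- jsonlite::read_json(exportNetwork(tabK, out)[1L],
                              simplifyVector = TRUE)
  hrefs <- netK$nodes$href[netK$nodes$type == "reaction"]
  expect_identical(is.na(hrefs), c(FALSE, TRUE))
  # empty capability matrix: nodes only
  net0 <- jsonlite::read_json(exportNetwork(tab * 0L, out)[1L],
                              simplifyVector = TRUE)
  expect_identical(length(net0$edges), 0L)
  expect_identical(nrow(net0$nodes), 5L)
})

test_that("pathway and constraint files parse", {
  pf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pathway_name\treactions", "p1\tr1, r2", "p2\tr2"), pf)
  pws <- readPathways(pf)
  expect_identical(pws$p1$reactions, c("r1", "r2"))
  cf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "pathway_name\tsingle_species_subsets\ttransporters\ttransporter_mode\tmax_size\tcompleteness",
    "p1\tr1,r2;r2\tr1\tany_member\t3\t0.8",
    "p2\t\t\t\t\t"), cf)
  cons <- readConstraints(cf)
  expect_identical(cons$p1$singleSpeciesSubsets,
                   list(c("r1", "r2"), "r2"))
  expect_identical(cons$p1$transporterMode, "any_member")
  expect_identical(cons$p1$maxCombinationSize, 3)
  expect_equal(cons$p1$completenessFraction, 0.8)
  expect_identical(cons$p2$transporterMode, "off")
  expect_identical(cons$p2$maxCombinationSize, Inf)
})
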