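test_that("guide distances are pairwise-deletion p-distances", {
    d <- buildGuideDistances(c(a = "AAAA", b = "AAAT", c = "A-AT"))
    expect_equal(unname(d["a", "b"]), 0.25)
    expect_equal(unname(d["a", "c"]), 1 / 3)  # 3 shared columns, 1 mismatch
    expect_equal(unname(d["b", "c"]), 0)
    expect_true(isSymmetric(d))
    expect_true(all(diag(d) == 0))
    # zero mutually non-gap columns: maximal distance by convention
    d2 <- buildGuideDistances(c(x = "AA--", y = "--TT"))
    expect_equal(unname(d2["x", "y"]), 1)
})

test_that("guide ordering is by distance, then abundance, then id", {
    d <- buildGuideDistances(c(s = "AAAA", a = "AAAT", b = "AAAT",
                               c = "TTTT"))
    ab <- c(s = 5, a = 1, b = 9, c = 2)
    ord <- guideOrder(d, "s", c("s", "a", "b", "c"), ab)
    expect_identical(ord, c("b", "a", "c"))  # ties at 0.25 by abundance
    # equal abundance: lexicographic id
    ord2 <- guideOrder(d, "s", c("s", "a", "b", "c"),
                       c(s = 5, a = 1, b = 1, c = 2))
    expect_identical(ord2, c("a", "b", "c"))
})

test_that("seed selection is most-abundant-first with id tie-break", {
    expect_identical(selectSeed(c(a = 5, b = 2)), "a")
    expect_identical(selectSeed(c(b = 3, a = 3, c = 3)), "a")
    expect_identical(selectSeed(c(only = 0)), "only")
    expect_error(selectSeed(numeric()), "no sequences")
})

test_that("identical sequences agglomerate into one cluster with a plain pair", {
    coll <- identicalCollection(5L, geneLen = 150L)
    res <- growCluster(coll, seed = selectSeed(abundances(coll)))
    expect_setequal(res$members, targetIds(coll))
    expect_identical(res$rejected, character())
    expect_false(is.null(res$pair))
    expect_identical(res$pair$fwd_degeneracy, 1)
    expect_identical(res$pair$rev_degeneracy, 1)
})

test_that("incompatible clades are rejected from a growing cluster", {
    ic <- simulateIncompatibleClades(2L, membersPerClade = 3L, seed = 9L)
    coll <- ic$collection
    seed <- selectSeed(abundances(coll))
    res <- growCluster(coll, seed)
    seed_clade <- ic$truth[seed]
    expect_setequal(res$members, names(ic$truth)[ic$truth == seed_clade])
    expect_setequal(res$rejected, names(ic$truth)[ic$truth != seed_clade])
    expect_false(is.null(res$pair))
})

test_that("a sequence admitting no primer window is reported undesignable", {
    # CDS of N-codons only: consensus all N, no window passes the caps
    cds <- c(bad = strrep("AACAAT", 60))
    pal <- setNames(translateCds(cds[["bad"]]), "bad")
    coll <- TargetCollection(cds, pal)
    # make every slice fail via an impossible Tm band instead of Ns,
    # so the failure path (pair = NULL on the seed alone) is exercised
    cst <- primerConstraints(tmOpt = 5, tmMin = 4, tmMax = 6)
    panel <- designPanel(coll, cst)
    expect_identical(length(panel), 0L)
    expect_identical(undesignableTargets(panel), "bad")
    expect_identical(coveredTargets(panel), character(0))
})

test_that("panel design recovers exactly k clusters on incompatible clades", {
    for (k in c(2L, 5L)) {
        ic <- simulateIncompatibleClades(k, membersPerClade = 3L,
                                         seed = 20L + k)
        panel <- designPanel(ic$collection)
        expect_identical(length(panel), k)
        expect_identical(undesignableTargets(panel), character(0))
        cov <- panelCoverageMap(panel)
        # clusters are disjoint and ids dense, ordered by emission
        expect_identical(panelPairs(panel)$pair_id, paste0("PP", seq_len(k)))
        members <- strsplit(designLog(panel)$members, ",")
        expect_identical(anyDuplicated(unlist(members)), 0L)
        # every pair covers exactly one clade
        for (pid in names(cov)) {
            expect_identical(length(unique(ic$truth[cov[[pid]]])), 1L)
        }
    }
})

test_that("design is deterministic and invariant to input record order", {
    fam <- simulateFamily(nClades = 2L, nSequences = 10L, geneLen = 150L,
                          seed = 33L)
    coll <- fam$collection
    p1 <- designPanel(coll)
    p2 <- designPanel(coll)
    expect_identical(panelPairs(p1), panelPairs(p2))
    expect_identical(designLog(p1), designLog(p2))
    # permuted record order: same panel
    perm <- rev(targetIds(coll))
    coll_perm <- TargetCollection(targetCds(coll)[perm],
                                  targetProteins(coll)[perm],
                                  abundances(coll)[perm])
    p3 <- designPanel(coll_perm)
    expect_identical(panelPairs(p1), panelPairs(p3))
})

test_that("duplicating a target never changes the emitted primers", {
    fam <- simulateFamily(nClades = 2L, nSequences = 8L, geneLen = 150L,
                          seed = 44L)
    coll <- fam$collection
    p1 <- designPanel(coll)
    dup_of <- targetIds(coll)[1]
    cds <- c(as.character(targetCds(coll)),
             zz_dup = as.character(targetCds(coll))[[dup_of]])
    pal <- c(as.character(targetProteins(coll)),
             zz_dup = as.character(targetProteins(coll))[[dup_of]])
    ab <- c(abundances(coll), zz_dup = unname(abundances(coll)[dup_of]))
    p2 <- designPanel(TargetCollection(cds, pal, ab))
    expect_identical(panelPairs(p1)$fwd_seq, panelPairs(p2)$fwd_seq)
    expect_identical(panelPairs(p1)$rev_seq, panelPairs(p2)$rev_seq)
})

test_that("the strict coverage invariant holds: covered + undesignable partitions the collection", {
    fx <- designedFixture()
    panel <- fx$panel
    coll <- fx$fam$collection
    cov <- panelCoverage(panel, coll, 0)
    expect_setequal(c(cov$covered, undesignableTargets(panel)),
                    targetIds(coll))
    expect_length(intersect(cov$covered, undesignableTargets(panel)), 0)
    # stored coverage map equals a fresh recomputation
    expect_identical(panelCoverageMap(panel), cov$byPair)
})

test_that("outgroup-only pairs are pruned without renumbering", {
    ic <- simulateIncompatibleClades(3L, membersPerClade = 2L, seed = 6L)
    coll <- ic$collection
    og_ids <- names(ic$truth)[ic$truth == "clade03"]
    coll2 <- TargetCollection(targetCds(coll), targetProteins(coll),
                              abundances(coll), outgroup = og_ids)
    panel <- designPanel(coll2)
    expect_identical(length(panel), 3L)
    pruned <- pruneOutgroupOnlyPairs(panel, coll2)
    expect_identical(length(pruned), 2L)
    # surviving ids keep their original numbers
    expect_true(all(panelPairs(pruned)$pair_id %in%
                    panelPairs(panel)$pair_id))
    expect_setequal(outgroupOnlyTargets(pruned), og_ids)
    # a pair covering at least one ingroup target is kept: flag only
    # part of a clade as outgroup
    coll3 <- TargetCollection(targetCds(coll), targetProteins(coll),
                              abundances(coll), outgroup = og_ids[1])
    panel3 <- designPanel(coll3)
    expect_identical(length(pruneOutgroupOnlyPairs(panel3, coll3)), 3L)
    # no outgroup flags: panel unchanged
    panel0 <- designPanel(coll)
    expect_identical(pruneOutgroupOnlyPairs(panel0, coll), panel0)
})

test_that("abundance-weighted coverage is the covered abundance fraction", {
    ic <- simulateIncompatibleClades(2L, membersPerClade = 2L, seed = 3L)
    coll <- TargetCollection(targetCds(ic$collection),
                             targetProteins(ic$collection),
                             abundance = setNames(c(3, 3, 1, 1),
                                                  targetIds(ic$collection)))
    panel <- designPanel(coll)
    expect_equal(abundanceWeightedCoverage(panel, coll), 1.0)
    # drop the second clade's pair: weighted coverage 6/8
    cov <- panelCoverageMap(panel)
    kept <- names(cov)[vapply(cov, function(v)
        all(ic$truth[v] == "clade01"), logical(1))]
    part <- methods::new("PrimerPanel",
                         pairs = panelPairs(panel)[
                             panelPairs(panel)$pair_id %in% kept, ],
                         coverage = cov[kept],
                         undesignable = character(),
                         designLog = designLog(panel),
                         constraints = panel@constraints)
    expect_equal(abundanceWeightedCoverage(part, coll), 0.75)
    empty <- methods::new("PrimerPanel", pairs = panelPairs(panel)[0, ],
                          coverage = list(), undesignable = character(),
                          designLog = designLog(panel)[0, ],
                          constraints = panel@constraints)
    expect_equal(abundanceWeightedCoverage(empty, coll), 0)
})

test_that("degenerate inputs are rejected up front", {
    expect_error(designPanel(
        TargetCollection(character(), character())), "empty")
    cds <- c(a = "ATGGCA")
    expect_error(TargetCollection(cds, c(b = "MA")), "match")
})
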