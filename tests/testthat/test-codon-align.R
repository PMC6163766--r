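test_that("translation follows the standard code with solve-else-X fuzzy codons", {
    expect_identical(translateCds("ATGGCA"), "MA")
    expect_identical(translateCds("ATGTAA"), "M*")
    expect_identical(translateCds("ATGGC"), "M")  # partial codon dropped
    expect_identical(translateCds("AATGGCA", frame = 1L), "MA")
    expect_error(translateCds(""), "empty")
    # fuzzy codons: expected value from brute force over expansions
    for (cdn in c("GCN", "TCR", "CAY", "RAT", "NNN")) {
        aas <- unique(unname(Biostrings::GENETIC_CODE[oracleExpand(cdn)]))
        expect_identical(translateCds(cdn),
                         if (length(aas) == 1L) aas else "X")
    }
})

test_that("codon threading replaces residues by codons and validates hard", {
    na <- threadCodons(c(s1 = "MA-V"), c(s1 = "ATGGCAGTT"))
    expect_identical(as.character(na)[["s1"]], "ATGGCA---GTT")
    # terminal stop tolerated and dropped
    na2 <- threadCodons(c(s1 = "M"), c(s1 = "ATGTAA"))
    expect_identical(as.character(na2)[["s1"]], "ATG")
    expect_error(threadCodons(c(s1 = "MA"), c(s1 = "ATGTTT")),
                 "mismatch.*'A'.*'F'|mismatch")
    expect_error(threadCodons(c(s1 = "M", s2 = "M"), c(s1 = "ATG")),
                 "missing CDS.*s2")
})

test_that("threading round-trips: degapped rows reproduce the CDS", {
    set.seed(31)
    for (i in 1:40) {
        fam <- simulateFamily(nClades = 2L, nSequences = 4L,
                              geneLen = sample(20:40, 1),
                              conservedWindows = list(),
                              seed = sample.int(1e6, 1))
        coll <- fam$collection
        na <- threadCodons(targetProteins(coll), targetCds(coll))
        degapped <- gsub("-", "", as.character(na))
        expect_identical(degapped[targetIds(coll)],
                         setNames(as.character(targetCds(coll)),
                                  targetIds(coll)))
    }
})

test_that("column consensus is the minimal covering code, order independent", {
    expect_identical(columnConsensus(c("A", "A", "A")), "A")
    expect_identical(columnConsensus(c("A", "G")), "R")
    expect_identical(columnConsensus(c("A", "C", "G", "T")), "N")
    expect_identical(columnConsensus(c("-", "-")), "-")
    expect_identical(columnConsensus(c("A", "-", "G")), "R")
    expect_identical(columnConsensus(c("N", "A")), "N")  # member N forces N
    set.seed(5)
    for (i in 1:20) {
        col <- sample(c("A", "C", "G", "T", "R", "N", "-"),
                      sample(2:8, 1), replace = TRUE)
        expect_identical(columnConsensus(col),
                         columnConsensus(rev(col)))
        expect_identical(columnConsensus(col),
                         columnConsensus(sample(col)))
    }
})

test_that("alignment consensus drops all-gap columns and maps them", {
    expect_identical(alignmentConsensus(c(x = "ATG"))$consensus, "ATG")
    expect_identical(alignmentConsensus(c(x = "ATG", y = "ACG"))$consensus,
                     "AYG")
    res <- alignmentConsensus(c(x = "A-G", y = "A-G"))
    expect_identical(res$consensus, "AG")
    expect_identical(res$columnMap, c(1L, 3L))
    expect_error(alignmentConsensus(character()), "empty")
})

test_that("every member matches the consensus at zero mismatches over its span", {
    set.seed(99)
    for (i in 1:30) {
        n <- sample(2:6, 1)
        width <- sample(c(6L, 9L, 12L), 1)
        rows <- vapply(seq_len(n), function(j) {
            chars <- sample(c("A", "C", "G", "T", "R", "N", "-"), width,
                            replace = TRUE, prob = c(rep(0.2, 4), .05, .05, .1))
            paste(chars, collapse = "")
        }, character(1))
        names(rows) <- paste0("s", seq_len(n))
        res <- alignmentConsensus(rows)
        for (j in seq_len(n)) {
            chars <- strsplit(rows[[j]], "")[[1]][res$columnMap]
            ng <- chars != "-"
            if (!any(ng)) next
            cons <- strsplit(res$consensus, "")[[1]]
            expect_true(all(baseMatches(cons[ng], chars[ng])))
        }
    }
})

test_that("subsetting an alignment keeps rows and drops emptied columns", {
    aln <- c(x = "A-G", y = "ACG")
    expect_identical(as.character(subsetAlignment(aln, c("x", "y"))),
                     c(x = "A-G", y = "ACG"))
    expect_identical(as.character(subsetAlignment(aln, "x")), c(x = "AG"))
    expect_error(subsetAlignment(aln, character()), "zero rows")
    expect_error(subsetAlignment(aln, "zz"), "unknown")
})

test_that("subset consensus never widens a shared column's base set", {
    set.seed(17)
    fam <- simulateFamily(nClades = 2L, nSequences = 8L, geneLen = 30L,
                          seed = 23L)
    na <- threadCodons(targetProteins(fam$collection),
                       targetCds(fam$collection))
    full <- alignmentConsensus(as.character(na))
    ids <- targetIds(fam$collection)[1:3]
    sub <- alignmentConsensus(as.character(na)[ids])
    # no indels simulated: columns align one-to-one
    full_chars <- strsplit(full$consensus, "")[[1]]
    sub_chars <- strsplit(sub$consensus, "")[[1]]
    for (k in seq_along(sub_chars)) {
        expect_true(all(iupacCodeSet(sub_chars[k]) %in%
                        iupacCodeSet(full_chars[k])))
    }
})
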