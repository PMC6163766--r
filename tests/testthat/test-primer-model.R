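# Fixture: plain 20-mer flank F, a 60-N spacer, then revcomp(F), so the
# flank pair (fwd = F, rev = F) has identical Tms and zero penalty when
# the optimum is set to Tm(F) and length optimum to 20.
flankFixture <- function() {
    F <- "TGACCTGGAACGTACTGCAG"
    cons <- paste0(F, strrep("N", 60), reverseComplementIupac(F))
    list(F = F, cons = cons,
         constraints = primerConstraints(
             tmOpt = meltingTemperature(F), tmMin = 35, tmMax = 70,
             lenOpt = 20L, lenMin = 20L, lenMax = 20L,
             targetWindow = c(20L, 80L), productMin = 90L,
             productMax = 100L))
}

test_that("the zero-penalty flank pair tops the ranking on a constructed consensus", {
    fx <- flankFixture()
    res <- enumerateCandidates(fx$cons, fx$constraints)
    expect_gt(nrow(res), 0)
    expect_identical(res$fwd_seq[1], fx$F)
    expect_identical(res$rev_seq[1], fx$F)
    expect_identical(res$fwd_start[1], 0L)
    expect_identical(res$rev_start[1], 80L)
    expect_identical(res$product_len[1], 100L)
    expect_equal(res$penalty[1], 0, tolerance = 1e-9)
    # a penalty of zero requires optimal length and exactly optimal Tm
    expect_true(all(res$penalty[-1] > 0))
})

test_that("an all-N consensus admits no candidate", {
    c <- primerConstraints(targetWindow = c(30L, 60L), productMin = 60L,
                           productMax = 100L)
    expect_identical(nrow(enumerateCandidates(strrep("N", 120), c)), 0L)
})

test_that("enumeration is deterministic and errors on an out-of-range window", {
    fx <- flankFixture()
    r1 <- enumerateCandidates(fx$cons, fx$constraints)
    r2 <- enumerateCandidates(fx$cons, fx$constraints)
    expect_identical(r1, r2)
    expect_error(
        enumerateCandidates("ACGT", primerConstraints()),
        "outside consensus")
    expect_error(enumerateCandidates("AC-GT", primerConstraints(
        targetWindow = c(1L, 3L))), "gap")
})

test_that("optimized enumeration equals naive brute force on a small consensus", {
    fam <- simulateFamily(nClades = 2L, nSequences = 6L, geneLen = 40L,
                          conservedWindows = list(c(10L, 30L)),
                          pVarWithin = 0.05, seed = 77L)
    na <- threadCodons(targetProteins(fam$collection),
                       targetCds(fam$collection))
    cons <- alignmentConsensus(as.character(na))$consensus
    cst <- smallConstraints(window = c(40L, 80L), productMin = 70L,
                            productMax = 120L)
    got <- enumerateCandidates(cons, cst)
    want <- oracleCandidates(cons, cst)
    expect_gt(nrow(got), 0)
    cols <- c("fwd_seq", "fwd_start", "fwd_len", "rev_seq", "rev_start",
              "rev_len", "product_len")
    expect_identical(got[, cols], want[, cols])
    expect_equal(got$penalty, want$penalty, tolerance = 1e-9)
    # nMax = 1 returns exactly the top-ranked pair
    top <- enumerateCandidates(cons, cst, nMax = 1L)
    expect_identical(top[, cols], got[1, cols])
})

test_that("every emitted candidate independently satisfies all constraints", {
    fam <- simulateFamily(nClades = 1L, nSequences = 8L, geneLen = 40L,
                          pVarWithin = 0.04, seed = 31L)
    na <- threadCodons(targetProteins(fam$collection),
                       targetCds(fam$collection))
    cons <- alignmentConsensus(as.character(na))$consensus
    cst <- smallConstraints(window = c(40L, 80L), productMin = 70L,
                            productMax = 120L)
    res <- enumerateCandidates(cons, cst)
    expect_gt(nrow(res), 0)
    for (i in seq_len(min(nrow(res), 50L))) {
        for (side in c("fwd", "rev")) {
            s <- res[[paste0(side, "_seq")]][i]
            expect_gte(nchar(s), cst@lenMin)
            expect_lte(nchar(s), cst@lenMax)
            expect_lte(degeneracy(s), cst@maxDegeneracy)
            expect_lte(degeneratePositions(s), cst@maxDegeneratePositions)
            r <- tmRange(s)
            expect_true(r[2] >= cst@tmMin && r[1] <= cst@tmMax)
        }
        expect_gte(res$product_len[i], cst@productMin)
        expect_lte(res$product_len[i], cst@productMax)
        # product contains the target window; no primer overlap
        expect_lte(res$fwd_start[i], cst@targetWindow[1])
        expect_gte(res$rev_start[i] + res$rev_len[i], cst@targetWindow[2])
        expect_lte(res$fwd_start[i] + res$fwd_len[i], res$rev_start[i])
    }
})

test_that("a reverse primer is the reverse complement of its consensus slice", {
    fx <- flankFixture()
    res <- enumerateCandidates(fx$cons, fx$constraints)
    for (i in seq_len(min(nrow(res), 10L))) {
        slice <- substring(fx$cons, res$rev_start[i] + 1L,
                           res$rev_start[i] + res$rev_len[i])
        expect_identical(res$rev_seq[i], reverseComplementIupac(slice))
    }
})

test_that("the aa window mode scales coordinates by three", {
    fx <- flankFixture()
    cst_nt <- fx$constraints
    cst_aa <- primerConstraints(
        tmOpt = cst_nt@tmOpt, tmMin = 35, tmMax = 70, lenOpt = 20L,
        lenMin = 20L, lenMax = 20L, targetWindow = c(8L, 26L),
        windowUnits = "aa", productMin = 90L, productMax = 100L)
    # aa window [8, 26) is nt [24, 78) <= the nt window used above, so
    # the same flank pair must again rank first
    res <- enumerateCandidates(fx$cons, cst_aa)
    expect_identical(res$fwd_seq[1], fx$F)
    expect_identical(res$rev_seq[1], fx$F)
})

test_that("self-structure screening flags hairpin-prone primers only", {
    # palindromic 20-mer: perfectly self-complementary
    pal <- paste0("ACGTACGTAC", reverseComplementIupac("ACGTACGTAC"))
    expect_true(screenSelfStructure(pal))
    expect_false(screenSelfStructure("AAAAAAAACCCCAAAAAAAA"))
})
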