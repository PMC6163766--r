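test_that("site finding reproduces hand-scanned examples", {
    h <- findSites("ATGCAT", "GGGATGCATGG")
    plus <- h[h$strand == "+", ]
    expect_identical(plus$position, 3L)
    expect_identical(plus$mismatches, 0L)
    # degenerate primer base covers the template base
    h2 <- findSites("ATGCRT", "GGGATGCATGG")
    expect_true(any(h2$strand == "+" & h2$position == 3L &
                    h2$mismatches == 0L))
    # mismatch tolerance is floor(fraction * length)
    expect_identical(nrow(findSites("ATGCAT", "GGGATGGATGG", 0)), 0L)
    h3 <- findSites("ATGCAT", "GGGATGGATGG", 1 / 6)
    expect_true(any(h3$strand == "+" & h3$position == 3L &
                    h3$mismatches == 1L))
    expect_error(findSites("ATGCATGG", "ACGT"), "longer than template")
})

test_that("site finding equals brute-force expansion plus Hamming search", {
    set.seed(2024)
    for (i in 1:150) {
        primer <- randomIupac(sample(8:16, 1), sample(0:3, 1))
        template <- randomPlainDna(sample(60:150, 1))
        fraction <- sample(c(0, 0.1, 0.25), 1)
        expect_identical(findSites(primer, template, fraction),
                         oracleSites(primer, template, fraction))
    }
})

test_that("virtual amplification finds the constructed amplicon and only it", {
    fwd <- "TGACCTGGAACGTACTGCAG"
    rev <- "CTGAGGTTCACAGTCCATGC"
    set.seed(3)
    spacer <- randomPlainDna(100)
    tmpl <- paste0(fwd, spacer, reverseComplementIupac(rev))
    hits <- amplifyPair(fwd, rev, tmpl, productMin = 100L,
                        productMax = 200L)
    expect_identical(nrow(hits), 1L)
    expect_identical(hits$strand, "+")
    expect_identical(hits$product_len, nchar(fwd) + 100L + nchar(rev))
    expect_identical(hits$fwd_pos, 0L)
    expect_identical(hits$product_seq, tmpl)
    # a template lacking the reverse site yields nothing
    expect_identical(nrow(amplifyPair(fwd, rev, paste0(fwd, spacer),
                                      productMin = 100L,
                                      productMax = 200L)), 0L)
    # reverse-complemented template: the mirror hit on strand -
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tmpl)))
    hits_rc <- amplifyPair(fwd, rev, rc, productMin = 100L,
                           productMax = 200L)
    expect_identical(nrow(hits_rc), 1L)
    expect_identical(hits_rc$strand, "-")
    expect_identical(hits_rc$product_len, hits$product_len)
    expect_identical(hits_rc$product_seq, tmpl)
})

test_that("strand symmetry holds on randomized templates", {
    set.seed(41)
    for (i in 1:10) {
        fwd <- randomPlainDna(12)
        rev <- randomPlainDna(12)
        tmpl <- paste0(randomPlainDna(20), fwd, randomPlainDna(60),
                       reverseComplementIupac(rev), randomPlainDna(20))
        h <- amplifyPair(fwd, rev, tmpl, maxMismatchFraction = 0.1,
                         productMin = 50L, productMax = 150L)
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(tmpl)))
        h2 <- amplifyPair(fwd, rev, rc, maxMismatchFraction = 0.1,
                          productMin = 50L, productMax = 150L)
        expect_identical(nrow(h), nrow(h2))
        expect_setequal(h$product_seq, h2$product_seq)
        expect_setequal(h$product_len, h2$product_len)
    }
})

test_that("overlapping primer sites never produce a product", {
    # fwd and rev sites overlap: rev slice starts inside the fwd site
    fwd <- "ACGTACGTACGT"
    tmpl <- paste0("GGGG", fwd, "GGGG")
    hits <- amplifyPair(fwd, reverseComplementIupac(substring(fwd, 5)),
                        tmpl, productMin = 1L, productMax = 50L)
    expect_false(any(hits$strand == "+" & hits$fwd_pos == 4L &
                     hits$rev_pos < 4L + nchar(fwd)))
})

test_that("panel coverage is monotone in the mismatch tolerance", {
    fx <- designedFixture()
    cov0 <- panelCoverage(fx$panel, fx$fam$collection, 0)
    cov10 <- panelCoverage(fx$panel, fx$fam$collection, 0.10)
    expect_true(all(cov0$covered %in% cov10$covered))
    for (pid in names(cov0$byPair)) {
        expect_true(all(cov0$byPair[[pid]] %in% cov10$byPair[[pid]]))
    }
})

test_that("specificity screening inverts the coverage map on the panel's own targets", {
    fx <- designedFixture()
    rep <- screenSpecificity(fx$panel, targetCds(fx$fam$collection))
    cov <- panelCoverage(fx$panel, fx$fam$collection, 0)
    got <- split(rep$hits$template_id, rep$hits$pair_id)
    for (pid in names(cov$byPair)) {
        expect_setequal(unique(got[[pid]]), cov$byPair[[pid]])
    }
    expect_identical(rep$nTemplatesAmplified, length(cov$covered))
})
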