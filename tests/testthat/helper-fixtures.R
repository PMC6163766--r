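# Shared fixtures, all generated in code.

# n identical coding sequences (sense codons only) as a collection
identicalCollection <- function(n = 5L, geneLen = 120L, seed = 11L) {
    fam <- simulateFamily(nClades = 1L, nSequences = n, geneLen = geneLen,
                          pCons = 0, pVarBetween = 0, pVarWithin = 0,
                          seed = seed)
    fam$collection
}

# constraints scaled for short fixtures: window and product sized for
# an L-base consensus with 20-mer flanks
smallConstraints <- function(window = c(30L, 90L), productMin = 60L,
                             productMax = 160L, ...) {
    primerConstraints(targetWindow = window, productMin = productMin,
                      productMax = productMax, tmMin = 30, tmMax = 75,
                      ...)
}

# a tiny designed panel plus its collection, reused across tests
designedFixture <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            fam <- simulateFamily(nClades = 3L, nSequences = 18L,
                                  geneLen = 150L, seed = 5L)
            panel <- designPanel(fam$collection)
            cache <<- list(fam = fam, panel = panel)
        }
        cache
    }
})
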