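# Codon-aware synthetic gene-family generation: the test substrate for
# the panel designer.  Families have controllable clade structure,
# conserved cores, log-normal abundances and optional distant outgroup
# sequences; no indels are simulated, so the trivial columnwise protein
# alignment is exact.

.DNA_BASES <- c("A", "C", "G", "T")
.STOP_CODONS <- c("TAA", "TAG", "TGA")
.SENSE_CODONS <- local({
    all3 <- as.vector(outer(outer(.DNA_BASES, .DNA_BASES, paste0),
                            .DNA_BASES, paste0))
    setdiff(all3, .STOP_CODONS)
})

# run expr with a locally seeded RNG, restoring the caller's state
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

# per-site substitution of a base vector under probability vector p;
# draws creating stop codons are redrawn (bounded), then reverted
.mutateBases <- function(bases, p, maxTries = 10L) {
    stopifnot(length(p) == length(bases))
    hits <- which(runif(length(bases)) < p)
    for (i in hits) {
        c0 <- (i - 1L) %/% 3L
        cidx <- (3L * c0 + 1L):(3L * c0 + 3L)
        orig <- bases[i]
        for (try in seq_len(maxTries)) {
            bases[i] <- sample(setdiff(.DNA_BASES, orig), 1L)
            if (!paste(bases[cidx], collapse = "") %in% .STOP_CODONS) break
            bases[i] <- orig
        }
    }
    bases
}

#' Simulate a clade-structured gene family
#'
#' Generates a collection of homologous coding sequences with known
#' clade structure: one random ancestral CDS (sense codons only),
#' per-clade consensus sequences derived from it by substitution, and
#' members derived from their clade consensus.  Substitution
#' probabilities are position dependent: \code{pCons} inside the
#' conserved windows (both between and within clades),
#' \code{pVarBetween} outside them on the ancestor-to-clade step and
#' \code{pVarWithin} on the clade-to-member step.  Substitutions are
#' codon aware: draws that would create a stop codon are redrawn.
#' Abundance weights are log-normal.  Optional outgroup sequences are
#' distant mutants of the ancestor, flagged in the collection.
#'
#' No indels are simulated, so the columnwise protein alignment
#' returned inside the collection is exact by construction.
#'
#' @param nClades Number of clades.
#' @param nSequences Total number of ingroup sequences, distributed as
#'   evenly as possible across clades.
#' @param geneLen Gene length in codons.
#' @param conservedWindows List of 0-based half-open codon intervals
#'   held near-constant everywhere.  The default (NULL) places one
#'   40-codon window at codons 35-75 — covering the default design
#'   target window — or, for genes shorter than 75 codons, one window
#'   over the central 40% of the gene.  Use \code{list()} for no
#'   conserved window.
#' @param pCons Per-site substitution probability inside conserved
#'   windows (default 0.01).
#' @param pVarBetween Per-site probability outside windows, ancestor to
#'   clade consensus (default 0.15).
#' @param pVarWithin Per-site probability outside windows, clade
#'   consensus to member (default 0.02).
#' @param abundanceMeanlog,abundanceSdlog Log-normal abundance model
#'   (defaults 0 and 1.5).
#' @param nOutgroup Number of outgroup sequences (default 0).
#' @param pOutgroup Per-site substitution probability for outgroup
#'   sequences, applied everywhere (default 0.3).
#' @param seed Integer seed; all randomness flows from it and the
#'   caller's RNG state is left untouched.
#' @return List with \code{collection} (a [TargetCollection-class])
#'   and \code{truth} (named character vector: id -> clade label;
#'   outgroup sequences are labelled \code{"outgroup"}).
#' @examples
#' fam <- simulateFamily(nClades = 2, nSequences = 6, geneLen = 120,
#'                       seed = 7)
#' fam$collection
#' @export
simulateFamily <- function(nClades = 12L, nSequences = 200L,
                           geneLen = 400L,
                           conservedWindows = NULL,
                           pCons = 0.01, pVarBetween = 0.15,
                           pVarWithin = 0.02,
                           abundanceMeanlog = 0, abundanceSdlog = 1.5,
                           nOutgroup = 0L, pOutgroup = 0.3,
                           seed = 1L) {
    stopifnot(nClades >= 1L, nSequences >= nClades, geneLen >= 10L,
              pCons >= 0, pCons <= 1, pVarBetween >= 0, pVarBetween <= 1,
              pVarWithin >= 0, pVarWithin <= 1)
    if (is.null(conservedWindows)) {
        conservedWindows <- if (geneLen >= 75L) list(c(35L, 75L)) else
            list(c(as.integer(floor(geneLen * 0.3)),
                   as.integer(floor(geneLen * 0.7))))
    }
    L <- 3L * geneLen
    in_window <- logical(L)
    for (w in conservedWindows) {
        stopifnot(length(w) == 2L, w[1L] >= 0L, w[1L] < w[2L],
                  w[2L] <= geneLen)
        in_window[(3L * w[1L] + 1L):(3L * w[2L])] <- TRUE
    }
    p_between <- ifelse(in_window, pCons, pVarBetween)
    p_within <- ifelse(in_window, pCons, pVarWithin)

    sizes <- rep(nSequences %/% nClades, nClades)
    extra <- nSequences %% nClades
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L

    .withSeed(seed, {
        ancestor <- strsplit(paste(
            sample(.SENSE_CODONS, geneLen, replace = TRUE),
            collapse = ""), "")[[1L]]
        seqs <- character(0)
        truth <- character(0)
        for (cl in seq_len(nClades)) {
            clade_cons <- .mutateBases(ancestor, p_between)
            for (m in seq_len(sizes[cl])) {
                id <- sprintf("cl%02d_s%03d", cl, m)
                seqs[id] <- paste(.mutateBases(clade_cons, p_within),
                                  collapse = "")
                truth[id] <- sprintf("clade%02d", cl)
            }
        }
        for (o in seq_len(nOutgroup)) {
            id <- sprintf("og_s%03d", o)
            seqs[id] <- paste(.mutateBases(ancestor, rep(pOutgroup, L)),
                              collapse = "")
            truth[id] <- "outgroup"
        }
        abund <- setNames(rlnorm(length(seqs), abundanceMeanlog,
                                 abundanceSdlog), names(seqs))
        pal <- setNames(vapply(seqs, translateCds, character(1)),
                        names(seqs))
        coll <- TargetCollection(
            cds = seqs, proteinAlignment = pal, abundance = abund,
            outgroup = names(seqs)[truth == "outgroup"])
        list(collection = coll, truth = truth)
    })
}

#' Deterministic fixture: mutually primer-incompatible clades
#'
#' Builds a collection of \code{k} clades of identical members whose
#' clade consensi are pairwise incompatible by construction: each
#' clade is assigned a distinct base-4 digit pair (d0, d1); the first
#' half of the gene is built from per-position base patterns indexed
#' by d0 and the second half by d1, where at every position the four
#' patterns carry four distinct bases (a per-position permutation of
#' A/C/G/T, redrawn per codon so no pattern contains a stop).  Any two
#' distinct clades therefore differ at every position of at least one
#' half, so a merged consensus exceeds any usable degenerate-position
#' cap in every candidate primer window on that half, and a clade's
#' primers can never match another clade at zero mismatches.
#'
#' Under the default design constraints (target window [105, 214),
#' products of 200-600 nt) the designed panel recovers exactly one
#' pair per clade.
#'
#' @param k Number of clades (2 to 16; 1 is allowed for the trivial
#'   case).
#' @param membersPerClade Identical members per clade (default 3).
#' @param geneLen Gene length in codons, even split across halves
#'   (default 110, i.e. 330 nt).
#' @param seed Integer seed for the per-position patterns.
#' @return As [simulateFamily()]: list of \code{collection} and
#'   \code{truth}.
#' @export
simulateIncompatibleClades <- function(k, membersPerClade = 3L,
                                       geneLen = 110L, seed = 1L) {
    stopifnot(k >= 1L, k <= 16L, membersPerClade >= 1L, geneLen %% 2L == 0L)
    half <- geneLen %/% 2L
    .withSeed(seed, {
        # patterns[[d]] is a base vector; per position the 4 patterns
        # are a permutation of ACGT; redraw codons containing stops
        draw_half <- function(n_codons) {
            pat <- matrix("", nrow = 4L, ncol = 3L * n_codons)
            for (cdn in seq_len(n_codons)) {
                repeat {
                    cols <- (3L * cdn - 2L):(3L * cdn)
                    for (p in cols) pat[, p] <- sample(.DNA_BASES)
                    codons <- apply(pat[, cols, drop = FALSE], 1L,
                                    paste, collapse = "")
                    if (!any(codons %in% .STOP_CODONS)) break
                }
            }
            pat
        }
        pat1 <- draw_half(half)
        pat2 <- draw_half(geneLen - half)
        digits <- cbind(d0 = (seq_len(k) - 1L) %% 4L,
                        d1 = (seq_len(k) - 1L) %/% 4L)
        seqs <- character(0)
        truth <- character(0)
        for (cl in seq_len(k)) {
            s <- paste(c(pat1[digits[cl, 1L] + 1L, ],
                         pat2[digits[cl, 2L] + 1L, ]), collapse = "")
            for (m in seq_len(membersPerClade)) {
                id <- sprintf("cl%02d_s%03d", cl, m)
                seqs[id] <- s
                truth[id] <- sprintf("clade%02d", cl)
            }
        }
        pal <- setNames(vapply(seqs, translateCds, character(1)),
                        names(seqs))
        coll <- TargetCollection(cds = seqs, proteinAlignment = pal)
        list(collection = coll, truth = truth)
    })
}

#' Simulate decoy templates no panel pair amplifies
#'
#' Uniform-random sequences, rejection-sampled so that no pair of the
#' given panel amplifies them at zero mismatches; the natural negative
#' control for [screenSpecificity()].
#'
#' @param n Number of decoys.
#' @param len Decoy length in bases.
#' @param panel A [PrimerPanel-class] defining the forbidden pairs.
#' @param seed Integer seed.
#' @param maxRounds Rejection-sampling rounds before giving up.
#' @return A named [Biostrings::DNAStringSet] of length \code{n}.
#' @export
simulateDecoys <- function(n, len, panel, seed = 1L, maxRounds = 50L) {
    stopifnot(methods::is(panel, "PrimerPanel"), n >= 0L, len >= 1L)
    if (n == 0L) return(Biostrings::DNAStringSet())
    pairs <- panelPairs(panel)
    pmin <- panel@constraints@productMin
    pmax <- panel@constraints@productMax
    .withSeed(seed, {
        out <- character(0)
        for (round in seq_len(maxRounds)) {
            need <- n - length(out)
            if (need == 0L) break
            cand <- vapply(seq_len(need), function(i) {
                paste(sample(.DNA_BASES, len, replace = TRUE),
                      collapse = "")
            }, character(1))
            cand_set <- Biostrings::DNAStringSet(cand)
            bad <- logical(need)
            for (i in seq_len(nrow(pairs))) {
                bad <- bad | .pairCoversSet(
                    pairs$fwd_seq[i], pairs$rev_seq[i], cand_set,
                    maxMismatchFraction = 0, pmin, pmax)
            }
            out <- c(out, cand[!bad])
        }
        if (length(out) < n)
            stop("could not generate enough panel-free decoys",
                 call. = FALSE)
        Biostrings::DNAStringSet(setNames(out[seq_len(n)],
                                          sprintf("decoy_%03d", seq_len(n))))
    })
}
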