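# The agglomerative panel-design loop: abundance-seeded,
# similarity-ordered cluster growth with per-step degenerate primer
# design on the cluster consensus, and greedy set-cover removal of
# amplified sequences until the collection is exhausted.

#' Pairwise guide distances from a protein alignment
#'
#' p-distances (fraction of mismatched residues over mutually non-gap
#' columns) between every pair of aligned protein rows.  Pairs with no
#' mutually non-gap column get distance 1.  These distances drive the
#' order in which sequences are offered to a growing cluster.
#'
#' @param proteinAlignment Named [Biostrings::AAStringSet] or character
#'   vector of aligned rows (gap \code{-}), uniform width.
#' @return Symmetric numeric matrix with zero diagonal, dimnames the
#'   row ids.
#' @export
buildGuideDistances <- function(proteinAlignment) {
    rows <- .asAlignedCharacter(proteinAlignment)
    if (length(rows) < 2L)
        stop("need at least two aligned rows", call. = FALSE)
    ids <- names(rows)
    mat <- do.call(rbind, strsplit(unname(rows), ""))
    ng <- mat != "-"
    n <- length(ids)
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L)) {
        j <- (i + 1L):n
        both <- ng[j, , drop = FALSE] & rep(ng[i, ], each = length(j))
        neq <- mat[j, , drop = FALSE] != rep(mat[i, ], each = length(j))
        shared <- rowSums(both)
        mism <- rowSums(both & neq)
        dij <- ifelse(shared == 0L, 1, mism / shared)
        d[i, j] <- dij
        d[j, i] <- dij
    }
    d
}

#' Similarity order of candidates around a seed
#'
#' Candidates sorted by ascending guide distance to the seed, ties
#' broken by descending abundance and then by id (C-locale
#' lexicographic order, so the ordering is platform independent).
#'
#' @param distances Guide distance matrix from [buildGuideDistances()].
#' @param seed Seed id (excluded from the result).
#' @param candidates Character vector of candidate ids.
#' @param abundance Named numeric abundance weights.
#' @return Character vector: \code{candidates} in joining order.
#' @export
guideOrder <- function(distances, seed, candidates, abundance) {
    candidates <- setdiff(candidates, seed)
    if (!length(candidates)) return(character())
    d <- distances[seed, candidates]
    candidates[order(d, -abundance[candidates], candidates,
                     method = "radix")]
}

#' Pick the next cluster seed
#'
#' The most abundant remaining sequence; ties broken by id in
#' C-locale lexicographic order.
#'
#' @param abundance Named numeric abundances of the remaining
#'   sequences.
#' @return The seed id.
#' @export
selectSeed <- function(abundance) {
    if (!length(abundance)) stop("no sequences remaining", call. = FALSE)
    ids <- names(abundance)
    ids[order(-abundance, ids, method = "radix")][1L]
}

# Consensus masks of a member mask-OR with all-gap columns dropped;
# returns masks only (coordinates are consensus coordinates).
.clusterConsensusMasks <- function(or_masks) {
    or_masks[or_masks > 0L]
}

# Core cluster growth on the precomputed master mask matrix.
# M: integer mask matrix (rows = ids); candidates already in guide
# order.  Returns members, rejected, and the best pair row (or NULL).
.growClusterCore <- function(M, seed, candidates, constraints, memo) {
    cluster <- M[seed, ]
    members <- seed
    rejected <- character()
    best <- .enumerateCandidatesMasks(.clusterConsensusMasks(cluster),
                                      constraints, nMax = 1L, memo = memo)
    if (!nrow(best)) {
        return(list(members = seed, rejected = character(), pair = NULL))
    }
    for (cand in candidates) {
        trial <- bitwOr(cluster, M[cand, ])
        res <- .enumerateCandidatesMasks(.clusterConsensusMasks(trial),
                                         constraints, nMax = 1L, memo = memo)
        if (nrow(res)) {
            cluster <- trial
            members <- c(members, cand)
            best <- res
        } else {
            rejected <- c(rejected, cand)
        }
    }
    list(members = members, rejected = rejected, pair = best)
}

#' Grow one cluster around a seed
#'
#' Starts from the seed alone, designs on its consensus, then offers
#' every other remaining sequence in guide order: a sequence is kept
#' when the cluster consensus including it still yields at least one
#' primer-pair candidate under the constraints, and rejected
#' otherwise (rejected sequences stay in the collection and remain
#' eligible for later clusters).  Each remaining sequence is tested
#' once, in order.
#'
#' @param collection A [TargetCollection-class].
#' @param seed Seed id (must be among \code{remaining}).
#' @param remaining Character vector of ids still in the collection.
#' @param distances Guide distance matrix ([buildGuideDistances()]);
#'   computed from the collection when NULL.
#' @param constraints A [PrimerConstraints-class].
#' @return List with \code{members} (ids in joining order),
#'   \code{rejected} (ids tested and refused), and \code{pair} (the
#'   best candidate-pair row from the final successful design, or NULL
#'   when even the seed alone admits no pair).
#' @export
growCluster <- function(collection, seed, remaining = targetIds(collection),
                        distances = NULL, constraints = primerConstraints()) {
    stopifnot(methods::is(collection, "TargetCollection"))
    if (!seed %in% remaining)
        stop("seed must be among the remaining ids", call. = FALSE)
    na <- threadCodons(targetProteins(collection)[remaining],
                       targetCds(collection)[remaining])
    M <- .alignmentMaskMatrix(as.character(na))
    if (is.null(distances) && length(remaining) > 1L)
        distances <- buildGuideDistances(targetProteins(collection)[remaining])
    cand <- guideOrder(distances, seed, remaining, abundances(collection))
    res <- .growClusterCore(M, seed, cand, constraints,
                            memo = new.env(parent = emptyenv()))
    if (!is.null(res$pair) && !nrow(res$pair)) res$pair <- NULL
    res
}

#' Design a degenerate primer panel covering a target collection
#'
#' The greedy agglomerative design loop: pick the most abundant
#' remaining sequence as seed, grow a cluster around it in similarity
#' order under the primer constraints ([growCluster()]), store the
#' best pair of the final successful design as the next \code{PPn},
#' then remove the cluster members and every other remaining sequence
#' the pair amplifies at the sweep mismatch fraction, and repeat until
#' the collection is empty.  Seeds whose consensus admits no pair are
#' reported as undesignable and removed.  By construction, the
#' returned panel's strict coverage equals the collection minus the
#' undesignable set.
#'
#' The whole procedure is deterministic: ordering depends only on
#' abundances, guide distances and ids, never on input record order.
#'
#' @param collection A [TargetCollection-class]; its protein alignment
#'   is the master alignment that codon threading, consensus building
#'   and guide distances are derived from.
#' @param constraints A [PrimerConstraints-class].
#' @param sweepMismatchFraction Mismatch fraction for the removal
#'   sweep (default 0: exact degenerate matching).
#' @param sweepRequireProduct Whether the sweep requires a
#'   product-size-valid amplicon (default) or mere presence of both
#'   primer sites.
#' @param verbose Log each iteration to the console.
#' @return A [PrimerPanel-class].
#' @export
designPanel <- function(collection, constraints = primerConstraints(),
                        sweepMismatchFraction = 0,
                        sweepRequireProduct = TRUE, verbose = FALSE) {
    stopifnot(methods::is(collection, "TargetCollection"))
    if (length(collection) == 0L)
        stop("empty target collection", call. = FALSE)
    methods::validObject(collection)

    ids <- sort(targetIds(collection), method = "radix")
    cds <- targetCds(collection)
    abund <- abundances(collection)
    na <- threadCodons(targetProteins(collection)[ids], cds[ids])
    M <- .alignmentMaskMatrix(as.character(na))
    distances <- if (length(ids) > 1L)
        buildGuideDistances(targetProteins(collection)[ids]) else
        matrix(0, 1, 1, dimnames = list(ids, ids))
    memo <- new.env(parent = emptyenv())

    remaining <- ids
    pair_rows <- list()
    log_rows <- list()
    undesignable <- character()
    iter <- 0L
    n_pairs <- 0L
    while (length(remaining)) {
        iter <- iter + 1L
        seed <- selectSeed(abund[remaining])
        cand <- guideOrder(distances, seed, remaining, abund)
        res <- .growClusterCore(M, seed, cand, constraints, memo)
        if (is.null(res$pair) || !nrow(res$pair)) {
            undesignable <- c(undesignable, seed)
            remaining <- setdiff(remaining, seed)
            log_rows[[iter]] <- data.frame(
                iteration = iter, seed = seed, pair_id = NA_character_,
                members = "", rejected = paste(res$rejected, collapse = ","),
                swept = "", stringsAsFactors = FALSE)
            if (verbose)
                message(sprintf("iter %d: seed %s undesignable", iter, seed))
            next
        }
        n_pairs <- n_pairs + 1L
        pid <- paste0("PP", n_pairs)
        row <- res$pair
        row$pair_id <- pid
        pair_rows[[n_pairs]] <- row
        remaining2 <- setdiff(remaining, res$members)
        swept <- character()
        if (length(remaining2)) {
            hit <- .pairCoversSet(row$fwd_seq, row$rev_seq, cds[remaining2],
                                  sweepMismatchFraction,
                                  constraints@productMin,
                                  constraints@productMax,
                                  requireProduct = sweepRequireProduct)
            swept <- remaining2[hit]
        }
        remaining <- setdiff(remaining2, swept)
        log_rows[[iter]] <- data.frame(
            iteration = iter, seed = seed, pair_id = pid,
            members = paste(res$members, collapse = ","),
            rejected = paste(res$rejected, collapse = ","),
            swept = paste(swept, collapse = ","), stringsAsFactors = FALSE)
        if (verbose)
            message(sprintf(
                "iter %d: seed %s -> %s (%d members, %d swept, %d left)",
                iter, seed, pid, length(res$members), length(swept),
                length(remaining)))
    }

    pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
        .emptyPairTable()
    if (nrow(pairs)) {
        pairs <- pairs[, c("pair_id", setdiff(names(pairs), "pair_id"))]
        row.names(pairs) <- NULL
    } else {
        pairs$pair_id <- character()
        pairs <- pairs[, c("pair_id", setdiff(names(pairs), "pair_id"))]
    }
    cov <- if (nrow(pairs))
        panelCoverage(pairs, cds, maxMismatchFraction = 0,
                      productMin = constraints@productMin,
                      productMax = constraints@productMax)$byPair
    else list()
    methods::new("PrimerPanel", pairs = pairs, coverage = cov,
                 undesignable = undesignable,
                 designLog = do.call(rbind, log_rows),
                 constraints = constraints)
}

#' Drop pairs that only amplify outgroup sequences
#'
#' Removes from the panel every pair whose strict amplification set is
#' non-empty and consists solely of outgroup-flagged targets; a pair
#' touching at least one ingroup target is kept.  Remaining pair ids
#' are not renumbered.  Targets reachable only through dropped pairs
#' are reported in the \code{outgroupOnly} slot.
#'
#' @param panel A [PrimerPanel-class].
#' @param collection The [TargetCollection-class] the panel was
#'   designed on (supplies the outgroup flags).
#' @return The pruned [PrimerPanel-class].
#' @export
pruneOutgroupOnlyPairs <- function(panel, collection) {
    stopifnot(methods::is(panel, "PrimerPanel"),
              methods::is(collection, "TargetCollection"))
    og <- isOutgroup(collection)
    drop <- vapply(panel@coverage, function(covered) {
        length(covered) > 0L && all(og[covered])
    }, logical(1))
    if (!any(drop)) return(panel)
    dropped_ids <- names(drop)[drop]
    kept_cov <- panel@coverage[!drop]
    lost <- setdiff(unique(unlist(panel@coverage[drop], use.names = FALSE)),
                    unique(unlist(kept_cov, use.names = FALSE)))
    methods::new("PrimerPanel",
                 pairs = panel@pairs[!panel@pairs$pair_id %in% dropped_ids, ,
                                     drop = FALSE],
                 coverage = kept_cov,
                 undesignable = panel@undesignable,
                 designLog = panel@designLog,
                 constraints = panel@constraints,
                 outgroupOnly = sort(lost, method = "radix"))
}

#' Abundance-weighted coverage of a collection by a panel
#'
#' The sum of abundance weights of the targets amplified by at least
#' one pair (strict coverage map of the panel) divided by the total
#' abundance weight of the collection.
#'
#' @param panel A [PrimerPanel-class].
#' @param collection A [TargetCollection-class].
#' @return Fraction in [0, 1].
#' @export
abundanceWeightedCoverage <- function(panel, collection) {
    stopifnot(methods::is(panel, "PrimerPanel"),
              methods::is(collection, "TargetCollection"))
    ab <- abundances(collection)
    total <- sum(ab)
    if (total == 0) return(0)
    sum(ab[intersect(coveredTargets(panel), names(ab))]) / total
}
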