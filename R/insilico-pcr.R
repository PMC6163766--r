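# Degenerate-primer site finding and virtual amplification with a
# mismatch-percent tolerance.  Matching uses intersection semantics on
# IUPAC codes (a primer base matches a template base when their base
# sets share a member), with no indel tolerance: the engine behind both
# the strict removal sweep of the design loop and the relaxed screens.

.mismatchAllowance <- function(fraction, primer_len) {
    stopifnot(fraction >= 0, fraction <= 1)
    as.integer(floor(fraction * primer_len))
}

.asDNAString <- function(x) {
    if (methods::is(x, "DNAString")) x else
        Biostrings::DNAString(.normalizeIupac(as.character(x)))
}

# count mismatches of primer masks vs template masks at 0-based pos
.countMismatches <- function(pmasks, tmasks, pos0) {
    sl <- tmasks[(pos0 + 1L):(pos0 + length(pmasks))]
    sum(bitwAnd(pmasks, sl) == 0L)
}

#' Find degenerate-primer binding sites on a template
#'
#' Scans both strands of a template for ungapped sites where the
#' primer matches with at most \code{floor(fraction * length(primer))}
#' mismatching positions, a position mismatching when the primer and
#' template IUPAC base sets do not intersect.
#'
#' @param primer IUPAC primer string (5'->3').
#' @param template Template sequence (string or
#'   [Biostrings::DNAString]); IUPAC codes allowed.
#' @param maxMismatchFraction Mismatch tolerance as a fraction of
#'   primer length (default 0: exact degenerate matching).
#' @return data.frame with columns \code{position} (0-based leftmost
#'   template coordinate of the site), \code{strand} (\code{+} when the
#'   primer matches the template as given, \code{-} when it matches the
#'   reverse complement), and \code{mismatches}.
#' @examples
#' findSites("ATGCAT", "GGGATGCATGG")          # one + site at position 3
#' findSites("ATGCRT", "GGGATGCATGG")          # R covers A
#' @export
findSites <- function(primer, template, maxMismatchFraction = 0) {
    stopifnot(is.character(primer), length(primer) == 1L)
    p <- .normalizeIupac(primer)
    pmasks <- .iupacMasks(p)
    tmpl <- .asDNAString(template)
    L <- length(tmpl)
    if (nchar(p) > L)
        stop("primer longer than template", call. = FALSE)
    k <- .mismatchAllowance(maxMismatchFraction, nchar(p))
    tmasks <- .iupacMasks(as.character(tmpl), allow_gap = FALSE)

    scan <- function(pat, pm) {
        m <- Biostrings::matchPattern(Biostrings::DNAString(pat), tmpl,
                                      max.mismatch = k, fixed = FALSE)
        st <- BiocGenerics::start(m) - 1L
        st <- st[st >= 0L & st + nchar(pat) <= L]  # no overhanging sites
        if (!length(st)) return(NULL)
        mm <- vapply(st, function(s0) .countMismatches(pm, tmasks, s0),
                     integer(1))
        data.frame(position = st, mismatches = mm)
    }
    plus <- scan(p, pmasks)
    rc <- reverseComplementIupac(p)
    minus <- scan(rc, .iupacMasks(rc))
    out <- rbind(
        if (!is.null(plus)) cbind(plus, strand = "+"),
        if (!is.null(minus)) cbind(minus, strand = "-"))
    if (is.null(out))
        return(data.frame(position = integer(), strand = character(),
                          mismatches = integer()))
    out <- out[order(out$position, out$strand), c("position", "strand",
                                                  "mismatches")]
    row.names(out) <- NULL
    out
}

# All amplicons of one (fwd, rev) primer pair on one plus-strand
# template given precomputed site starts; 0-based coordinates.
.pairAmplicons <- function(fwd_starts, fwd_mm, rev_starts, rev_mm,
                           lf, lr, pmin, pmax) {
    if (!length(fwd_starts) || !length(rev_starts)) return(NULL)
    hits <- NULL
    for (i in seq_along(fwd_starts)) {
        f <- fwd_starts[i]
        re <- rev_starts + lr          # rev slice end (exclusive)
        ok <- rev_starts >= f + lf & (re - f) >= pmin & (re - f) <= pmax
        if (!any(ok)) next
        hits <- rbind(hits, data.frame(
            fwd_start = f, rev_slice_start = rev_starts[ok],
            product_len = re[ok] - f,
            fwd_mismatches = fwd_mm[i], rev_mismatches = rev_mm[ok]))
    }
    hits
}

#' Virtually amplify a template with one primer pair
#'
#' Finds every in silico amplification event: a forward-primer site and
#' a downstream reverse-primer site (the reverse primer binding the
#' opposite strand) whose product length lies within bounds, on either
#' strand of the template.  Primer sites may not overlap.
#'
#' @param fwdSeq,revSeq IUPAC primer strings, both 5'->3' in primer
#'   sense (the reverse primer is the reverse complement of the
#'   template slice it binds).
#' @param template Template sequence (string or
#'   [Biostrings::DNAString]).
#' @inheritParams findSites
#' @param productMin,productMax Product length bounds in bases
#'   (defaults 200 and 600).
#' @return data.frame with one row per amplicon: \code{fwd_pos} and
#'   \code{rev_pos} (0-based template coordinates of the two primers'
#'   5' ends), \code{strand} (template orientation amplified),
#'   \code{product_len}, \code{fwd_mismatches}, \code{rev_mismatches},
#'   \code{product_seq}; ordered by coordinate.
#' @export
amplifyPair <- function(fwdSeq, revSeq, template, maxMismatchFraction = 0,
                        productMin = 200L, productMax = 600L) {
    f <- .normalizeIupac(fwdSeq); r <- .normalizeIupac(revSeq)
    tmpl <- .asDNAString(template)
    tmpl_rc <- Biostrings::reverseComplement(tmpl)
    lf <- nchar(f); lr <- nchar(r)
    kf <- .mismatchAllowance(maxMismatchFraction, lf)
    kr <- .mismatchAllowance(maxMismatchFraction, lr)
    fm <- .iupacMasks(f)
    rrc <- reverseComplementIupac(r)
    rm <- .iupacMasks(rrc)
    L <- length(tmpl)

    one_strand <- function(t, strand) {
        if (max(lf, lr) > length(t)) return(NULL)
        tm <- .iupacMasks(as.character(t))
        fs <- BiocGenerics::start(Biostrings::matchPattern(
            Biostrings::DNAString(f), t, max.mismatch = kf,
            fixed = FALSE)) - 1L
        rs <- BiocGenerics::start(Biostrings::matchPattern(
            Biostrings::DNAString(rrc), t, max.mismatch = kr,
            fixed = FALSE)) - 1L
        fs <- fs[fs >= 0L & fs + lf <= length(t)]
        rs <- rs[rs >= 0L & rs + lr <= length(t)]
        if (!length(fs) || !length(rs)) return(NULL)
        fmm <- vapply(fs, function(s0) .countMismatches(fm, tm, s0),
                      integer(1))
        rmm <- vapply(rs, function(s0) .countMismatches(rm, tm, s0),
                      integer(1))
        h <- .pairAmplicons(fs, fmm, rs, rmm, lf, lr,
                            productMin, productMax)
        if (is.null(h)) return(NULL)
        h$product_seq <- substring(as.character(t), h$fwd_start + 1L,
                                   h$fwd_start + h$product_len)
        if (strand == "+") {
            data.frame(fwd_pos = h$fwd_start,
                       rev_pos = h$rev_slice_start + lr - 1L,
                       strand = "+", product_len = h$product_len,
                       fwd_mismatches = h$fwd_mismatches,
                       rev_mismatches = h$rev_mismatches,
                       product_seq = h$product_seq)
        } else {
            # map coordinates on the reverse complement back to the
            # template: position p on rc(T) is L - 1 - p on T
            data.frame(fwd_pos = L - 1L - h$fwd_start,
                       rev_pos = L - 1L - (h$rev_slice_start + lr - 1L),
                       strand = "-", product_len = h$product_len,
                       fwd_mismatches = h$fwd_mismatches,
                       rev_mismatches = h$rev_mismatches,
                       product_seq = h$product_seq)
        }
    }
    out <- rbind(one_strand(tmpl, "+"), one_strand(tmpl_rc, "-"))
    if (is.null(out))
        return(data.frame(fwd_pos = integer(), rev_pos = integer(),
                          strand = character(), product_len = integer(),
                          fwd_mismatches = integer(),
                          rev_mismatches = integer(),
                          product_seq = character()))
    out <- out[order(pmin(out$fwd_pos, out$rev_pos), out$strand), ]
    row.names(out) <- NULL
    out
}

# Fast boolean sweep: which templates does the pair amplify?
# Uses vmatchPattern over the whole set on both strands.
.pairCoversSet <- function(fwdSeq, revSeq, templates, maxMismatchFraction,
                           productMin, productMax, requireProduct = TRUE) {
    f <- .normalizeIupac(fwdSeq); r <- .normalizeIupac(revSeq)
    lf <- nchar(f); lr <- nchar(r)
    kf <- .mismatchAllowance(maxMismatchFraction, lf)
    kr <- .mismatchAllowance(maxMismatchFraction, lr)
    rrc <- reverseComplementIupac(r)
    covered <- logical(length(templates))
    for (orient in 1:2) {
        tset <- if (orient == 1L) templates else
            Biostrings::reverseComplement(templates)
        long_enough <- Biostrings::width(tset) >= max(lf, lr)
        if (!any(long_enough)) next
        sub <- tset[long_enough]
        fs <- Biostrings::vmatchPattern(Biostrings::DNAString(f), sub,
                                        max.mismatch = kf, fixed = FALSE)
        rs <- Biostrings::vmatchPattern(Biostrings::DNAString(rrc), sub,
                                        max.mismatch = kr, fixed = FALSE)
        fs <- BiocGenerics::start(fs); rs <- BiocGenerics::start(rs)
        wd <- Biostrings::width(sub)
        hit <- mapply(function(a, b, w) {
            a <- a[a >= 1L & a + lf - 1L <= w] - 1L
            b <- b[b >= 1L & b + lr - 1L <= w] - 1L
            if (!length(a) || !length(b)) return(FALSE)
            if (!requireProduct) return(TRUE)
            for (x in a) {
                pr <- b + lr - x
                if (any(b >= x + lf & pr >= productMin & pr <= productMax))
                    return(TRUE)
            }
            FALSE
        }, fs, rs, wd, USE.NAMES = FALSE)
        covered[long_enough] <- covered[long_enough] | hit
    }
    covered
}

#' Amplify a template collection with a whole panel
#'
#' Runs [amplifyPair()] for every pair of a panel over every template
#' and returns the combined hit table.
#'
#' @param panel A [PrimerPanel-class] (or a pair table data.frame with
#'   \code{pair_id}, \code{fwd_seq}, \code{rev_seq} columns).
#' @param templates Named [Biostrings::DNAStringSet] (or character
#'   vector) of templates.
#' @inheritParams findSites
#' @param productMin,productMax Product bounds; default from the
#'   panel's constraints when a panel is given.
#' @return data.frame with columns \code{template_id, pair_id,
#'   strand, fwd_pos, rev_pos, product_len, fwd_mismatches,
#'   rev_mismatches, product_seq}.
#' @export
amplifyPanel <- function(panel, templates, maxMismatchFraction = 0,
                         productMin = NULL, productMax = NULL) {
    pairs <- if (methods::is(panel, "PrimerPanel")) panelPairs(panel) else panel
    if (methods::is(panel, "PrimerPanel")) {
        if (is.null(productMin)) productMin <- panel@constraints@productMin
        if (is.null(productMax)) productMax <- panel@constraints@productMax
    } else {
        if (is.null(productMin)) productMin <- 200L
        if (is.null(productMax)) productMax <- 600L
    }
    if (!methods::is(templates, "DNAStringSet"))
        templates <- Biostrings::DNAStringSet(templates)
    if (is.null(names(templates)))
        stop("templates must be named", call. = FALSE)
    out <- NULL
    for (i in seq_len(nrow(pairs))) {
        for (j in seq_along(templates)) {
            h <- amplifyPair(pairs$fwd_seq[i], pairs$rev_seq[i],
                             templates[[j]], maxMismatchFraction,
                             productMin, productMax)
            if (nrow(h)) {
                out <- rbind(out, cbind(
                    data.frame(template_id = names(templates)[j],
                               pair_id = pairs$pair_id[i]), h))
            }
        }
    }
    if (is.null(out))
        out <- data.frame(template_id = character(), pair_id = character(),
                          fwd_pos = integer(), rev_pos = integer(),
                          strand = character(), product_len = integer(),
                          fwd_mismatches = integer(),
                          rev_mismatches = integer(),
                          product_seq = character())
    row.names(out) <- NULL
    out
}

#' Strict or relaxed coverage of a target collection by a panel
#'
#' For every pair of the panel, determines which targets it amplifies
#' at the given mismatch fraction (valid product required), and
#' summarizes per-target and overall coverage.
#'
#' @param panel A [PrimerPanel-class] or pair table (see
#'   [amplifyPanel()]).
#' @param targets A [TargetCollection-class], named
#'   [Biostrings::DNAStringSet], or named character vector.
#' @inheritParams amplifyPanel
#' @return List with \code{byPair} (named list: pair id -> character
#'   vector of amplified target ids), \code{byTarget} (target id ->
#'   pair ids), and \code{covered} (ids amplified by at least one
#'   pair).
#' @export
panelCoverage <- function(panel, targets, maxMismatchFraction = 0,
                          productMin = NULL, productMax = NULL) {
    if (methods::is(targets, "TargetCollection"))
        targets <- targetCds(targets)
    if (!methods::is(targets, "DNAStringSet"))
        targets <- Biostrings::DNAStringSet(targets)
    if (is.null(names(targets)))
        stop("targets must be named", call. = FALSE)
    pairs <- if (methods::is(panel, "PrimerPanel")) panelPairs(panel) else panel
    if (methods::is(panel, "PrimerPanel")) {
        if (is.null(productMin)) productMin <- panel@constraints@productMin
        if (is.null(productMax)) productMax <- panel@constraints@productMax
    } else {
        if (is.null(productMin)) productMin <- 200L
        if (is.null(productMax)) productMax <- 600L
    }
    by_pair <- setNames(vector("list", nrow(pairs)), pairs$pair_id)
    for (i in seq_len(nrow(pairs))) {
        cov <- .pairCoversSet(pairs$fwd_seq[i], pairs$rev_seq[i], targets,
                              maxMismatchFraction, productMin, productMax)
        by_pair[[i]] <- names(targets)[cov]
    }
    ids <- names(targets)
    by_target <- setNames(lapply(ids, function(id) {
        names(by_pair)[vapply(by_pair, function(v) id %in% v, logical(1))]
    }), ids)
    list(byPair = by_pair, byTarget = by_target,
         covered = ids[lengths(by_target) > 0L])
}
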