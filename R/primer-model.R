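# Enumeration and penalty ranking of degenerate primer-pair candidates
# on a consensus sequence under a PrimerConstraints object.

# Per-slice statistics for all (start, len) slices of a mask vector,
# restricted to 0-based starts in [start_lo, start_hi].  Returns a
# data.frame with 0-based start, len, ndeg, deg.
.sliceStats <- function(masks, lens, start_lo, start_hi) {
    L <- length(masks)
    sizes <- .maskSizes(masks)
    cum_ndeg <- c(0L, cumsum(sizes > 1L))
    cum_logd <- c(0, cumsum(log(sizes)))
    out <- vector("list", length(lens))
    for (k in seq_along(lens)) {
        l <- lens[k]
        s0 <- seq.int(max(0L, start_lo), min(start_hi, L - l))
        if (!length(s0) || s0[1L] > s0[length(s0)]) next
        ndeg <- cum_ndeg[s0 + l + 1L] - cum_ndeg[s0 + 1L]
        deg <- round(exp(cum_logd[s0 + l + 1L] - cum_logd[s0 + 1L]))
        out[[k]] <- data.frame(start = s0, len = l, ndeg = ndeg, deg = deg)
    }
    do.call(rbind, out)
}

# Tm ranges for the slices of `stats` (0-based starts) on `masks`
.sliceTms <- function(stats, masks, constraints, memo) {
    lo <- numeric(nrow(stats)); hi <- numeric(nrow(stats))
    plain <- stats$deg == 1L
    if (any(plain)) {
        # vectorized plain-slice Tm via cumulative NN sums
        base_idx <- integer(length(masks))
        pure <- c(1L, 2L, 4L, 8L)
        for (b in 1:4) base_idx[masks == pure[b]] <- b
        n <- length(base_idx)
        dh_step <- ds_step <- numeric(max(0L, n - 1L))
        ok <- base_idx[-n] > 0L & base_idx[-1L] > 0L
        flat <- (base_idx[-1L][ok] - 1L) * 4L + base_idx[-n][ok]
        dh_step[ok] <- .NN_TABLE$dh[flat]
        ds_step[ok] <- .NN_TABLE$ds[flat]
        cdh <- c(0, cumsum(dh_step)); cds <- c(0, cumsum(ds_step))
        s0 <- stats$start[plain]; l <- stats$len[plain]
        b_first <- base_idx[s0 + 1L]; b_last <- base_idx[s0 + l]
        dh <- cdh[s0 + l] - cdh[s0 + 1L] +
            .NN_TABLE$init_dh[b_first] + .NN_TABLE$init_dh[b_last]
        ds <- cds[s0 + l] - cds[s0 + 1L] +
            .NN_TABLE$init_ds[b_first] + .NN_TABLE$init_ds[b_last] +
            0.368 * (l - 1L) * log(constraints@saltMolar)
        tm <- dh * 1000 /
            (ds + .GAS_CONSTANT * log(constraints@oligoMolar / 4)) - 273.15
        lo[plain] <- tm; hi[plain] <- tm
    }
    for (i in which(!plain)) {
        r <- .tmRangeMasks(masks[(stats$start[i] + 1L):(stats$start[i] + stats$len[i])],
                           constraints@saltMolar, constraints@oligoMolar, memo)
        lo[i] <- r[1L]; hi[i] <- r[2L]
    }
    stats$tm_lo <- lo; stats$tm_hi <- hi
    stats$tm_mid <- (lo + hi) / 2
    stats
}

.emptyPairTable <- function() {
    data.frame(fwd_seq = character(), fwd_start = integer(),
               fwd_len = integer(), fwd_tm_lo = numeric(),
               fwd_tm_hi = numeric(), fwd_degeneracy = numeric(),
               fwd_degenerate_positions = integer(),
               rev_seq = character(), rev_start = integer(),
               rev_len = integer(), rev_tm_lo = numeric(),
               rev_tm_hi = numeric(), rev_degeneracy = numeric(),
               rev_degenerate_positions = integer(),
               product_len = integer(), penalty = numeric(),
               stringsAsFactors = FALSE)
}

#' Enumerate degenerate primer-pair candidates on a consensus
#'
#' Considers every (forward, reverse) pair of consensus slices such
#' that both primer lengths lie within the constraint band, the
#' amplified interval fully contains the target window and has a
#' product size within bounds, both primers respect the degeneracy and
#' degenerate-position caps, each primer's expansion Tm range
#' intersects the acceptance band, and the two midpoint Tms differ by
#' at most \code{pairTmMaxDiff}.  Surviving pairs are ranked by the
#' penalty \code{sum(|len - lenOpt|) + sum(|midTm - tmOpt|)}, ties
#' broken by ascending (fwd start, rev start, lengths); ranking is
#' deterministic.
#'
#' Reverse primers are reported 5'->3' in primer sense, i.e. as the
#' reverse complement of the consensus slice they bind;
#' \code{rev_start} is the 0-based consensus coordinate of the binding
#' slice.
#'
#' @param consensus IUPAC consensus string (no gaps), e.g. from
#'   [alignmentConsensus()].
#' @param constraints A [PrimerConstraints-class] object.
#' @param nMax Return at most this many top-ranked pairs (default all).
#' @return data.frame with one row per candidate pair (columns
#'   \code{fwd_seq, fwd_start, fwd_len, fwd_tm_lo, fwd_tm_hi,
#'   fwd_degeneracy, fwd_degenerate_positions}, the same for
#'   \code{rev_*}, \code{product_len}, \code{penalty}), possibly with
#'   zero rows.  Coordinates are 0-based.
#' @export
enumerateCandidates <- function(consensus, constraints = primerConstraints(),
                                nMax = Inf) {
    stopifnot(is.character(consensus), length(consensus) == 1L)
    masks <- .iupacMasks(consensus, allow_gap = TRUE)
    if (any(masks == 0L))
        stop("consensus must not contain gaps", call. = FALSE)
    .enumerateCandidatesMasks(masks, constraints, nMax, memo = NULL)
}

# Core enumeration on a mask vector; memo is an optional environment
# caching Tm ranges across calls within one design run.
.enumerateCandidatesMasks <- function(masks, constraints, nMax, memo = NULL) {
    L <- length(masks)
    w <- .ntWindow(constraints)
    if (w[2L] > L)
        stop(sprintf("target window [%d, %d) outside consensus of length %d",
                     w[1L], w[2L], L), call. = FALSE)
    lens <- seq.int(constraints@lenMin, constraints@lenMax)
    pmin <- constraints@productMin; pmax <- constraints@productMax

    # product contains [w1, w2) and len(product) <= pmax bounds the spans
    fst <- .sliceStats(masks, lens, start_lo = w[2L] - pmax, start_hi = w[1L])
    rst <- .sliceStats(masks, lens, start_lo = w[2L] - max(lens),
                       start_hi = min(L, w[1L] + pmax) - 1L)
    if (!is.null(rst)) rst <- rst[rst$start + rst$len >= w[2L], , drop = FALSE]
    keep_side <- function(st) {
        if (is.null(st) || !nrow(st)) return(st)
        st[st$deg <= constraints@maxDegeneracy &
           st$ndeg <= constraints@maxDegeneratePositions, , drop = FALSE]
    }
    fst <- keep_side(fst); rst <- keep_side(rst)
    if (is.null(fst) || is.null(rst) || !nrow(fst) || !nrow(rst))
        return(.emptyPairTable())
    if (!constraints@allowDegenerate3Prime) {
        sizes <- .maskSizes(masks)
        fst <- fst[sizes[fst$start + fst$len] == 1L, , drop = FALSE]
        rst <- rst[sizes[rst$start + 1L] == 1L, , drop = FALSE]
        if (!nrow(fst) || !nrow(rst)) return(.emptyPairTable())
    }
    fst <- .sliceTms(fst, masks, constraints, memo)
    rst <- .sliceTms(rst, masks, constraints, memo)
    band <- function(st) st[st$tm_hi >= constraints@tmMin &
                            st$tm_lo <= constraints@tmMax, , drop = FALSE]
    fst <- band(fst); rst <- band(rst)
    if (!nrow(fst) || !nrow(rst)) return(.emptyPairTable())

    fst <- fst[order(fst$start, fst$len), , drop = FALSE]
    rst <- rst[order(rst$start, rst$len), , drop = FALSE]
    fst$pen <- abs(fst$len - constraints@lenOpt) +
        abs(fst$tm_mid - constraints@tmOpt)
    rst$pen <- abs(rst$len - constraints@lenOpt) +
        abs(rst$tm_mid - constraints@tmOpt)
    rev_end <- rst$start + rst$len

    single_best <- is.finite(nMax) && nMax == 1L
    rows <- vector("list", nrow(fst))
    for (i in seq_len(nrow(fst))) {
        f_end <- fst$start[i] + fst$len[i]
        prod <- rev_end - fst$start[i]
        ok <- rst$start >= f_end & prod >= pmin & prod <= pmax &
            abs(rst$tm_mid - fst$tm_mid[i]) <= constraints@pairTmMaxDiff
        if (!any(ok)) next
        j <- which(ok)
        pen <- fst$pen[i] + rst$pen[j]
        if (single_best) {
            # rst already sorted by (start, len); which.min keeps first tie
            jb <- j[which.min(pen)]
            rows[[i]] <- data.frame(fi = i, ri = jb,
                                    penalty = fst$pen[i] + rst$pen[jb])
        } else {
            rows[[i]] <- data.frame(fi = i, ri = j, penalty = pen)
        }
    }
    rows <- do.call(rbind, rows)
    if (is.null(rows) || !nrow(rows)) return(.emptyPairTable())
    ord <- order(rows$penalty, fst$start[rows$fi], rst$start[rows$ri],
                 fst$len[rows$fi], rst$len[rows$ri])
    rows <- rows[ord, , drop = FALSE]
    if (is.finite(nMax) && nrow(rows) > nMax)
        rows <- rows[seq_len(nMax), , drop = FALSE]

    f <- fst[rows$fi, ]; r <- rst[rows$ri, ]
    fwd_seq <- vapply(seq_len(nrow(f)), function(k) {
        .masksToString(masks[(f$start[k] + 1L):(f$start[k] + f$len[k])])
    }, character(1))
    rev_seq <- vapply(seq_len(nrow(r)), function(k) {
        .masksToString(rev(.complementMasks(
            masks[(r$start[k] + 1L):(r$start[k] + r$len[k])])))
    }, character(1))
    data.frame(fwd_seq = fwd_seq, fwd_start = f$start, fwd_len = f$len,
               fwd_tm_lo = f$tm_lo, fwd_tm_hi = f$tm_hi,
               fwd_degeneracy = f$deg, fwd_degenerate_positions = f$ndeg,
               rev_seq = rev_seq, rev_start = r$start, rev_len = r$len,
               rev_tm_lo = r$tm_lo, rev_tm_hi = r$tm_hi,
               rev_degeneracy = r$deg, rev_degenerate_positions = r$ndeg,
               product_len = r$start + r$len - f$start,
               penalty = rows$penalty,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag primers with simple self-complementary structure
#'
#' Optional post-filter (off by default in the design loop): flags a
#' primer when it contains a perfect self-complementary stretch of at
#' least \code{minRun} bases at any ungapped offset against its own
#' reverse complement, a coarse proxy for hairpin/self-dimer risk.
#' Degenerate positions count as complementary when their base sets
#' allow a complementary pairing.
#'
#' @param primers Character vector of IUPAC primer sequences.
#' @param minRun Minimal self-complementary run to flag (default 8).
#' @return Logical vector, TRUE where structure is flagged.
#' @export
screenSelfStructure <- function(primers, minRun = 8L) {
    vapply(primers, function(p) {
        m <- .iupacMasks(p)
        rc <- rev(.complementMasks(m))
        n <- length(m)
        for (off in (-(n - minRun)):(n - minRun)) {
            i <- seq.int(max(1L, 1L + off), min(n, n + off))
            j <- i - off
            comp <- bitwAnd(m[i], rc[j]) > 0L
            r <- rle(comp)
            if (any(r$lengths[r$values] >= minRun)) return(TRUE)
        }
        FALSE
    }, logical(1), USE.NAMES = FALSE)
}
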