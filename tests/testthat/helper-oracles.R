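# Independent oracles used by the unit and acceptance tests.  These
# deliberately avoid the package's optimized code paths: the IUPAC
# table, expansion, Tm summation and site scans are re-implemented
# naively here.

.ORACLE_IUPAC <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# naive recursive Cartesian expansion of an IUPAC string
oracleExpand <- function(s) {
    chars <- strsplit(s, "")[[1L]]
    out <- ""
    for (ch in chars) out <- as.vector(outer(out, .ORACLE_IUPAC[[ch]], paste0))
    out
}

# independent nearest-neighbor Tm summation (published unified
# parameters typed as a flat dinucleotide table)
oracleTm <- function(seq, na_molar = 0.05, c_molar = 50e-9) {
    nn_dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
               CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
               CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
               CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
    nn_ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
               CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
               CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
               CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
    chars <- strsplit(seq, "")[[1L]]
    n <- length(chars)
    dh <- 0; ds <- 0
    for (i in seq_len(n - 1L)) {
        d <- paste0(chars[i], chars[i + 1L])
        dh <- dh + nn_dh[[d]]
        ds <- ds + nn_ds[[d]]
    }
    for (end in chars[c(1L, n)]) {
        if (end %in% c("A", "T")) { dh <- dh + 2.3; ds <- ds + 4.1 }
        else { dh <- dh + 0.1; ds <- ds - 2.8 }
    }
    ds <- ds + 0.368 * (n - 1L) * log(na_molar)
    dh * 1000 / (ds + 1.987 * log(c_molar / 4)) - 273.15
}

# brute-force degenerate site scan: expand the primer and Hamming-scan
# every offset of both template strands
oracleSites <- function(primer, template, fraction) {
    k <- floor(fraction * nchar(primer))
    variants <- oracleExpand(primer)
    revcomp <- function(s) chartr("ACGT", "TGCA",
                                  paste(rev(strsplit(s, "")[[1L]]),
                                        collapse = ""))
    scan_variants <- function(vars, tmpl) {
        tchars <- strsplit(tmpl, "")[[1L]]
        L <- length(tchars); l <- nchar(vars[1L])
        if (l > L) return(NULL)
        W <- matrix(tchars[outer(0:(L - l), seq_len(l), "+")], ncol = l)
        best <- rep(Inf, nrow(W))
        for (v in vars) {
            vm <- matrix(strsplit(v, "")[[1L]], nrow(W), l, byrow = TRUE)
            best <- pmin(best, rowSums(W != vm))
        }
        hit <- which(best <= k)
        if (!length(hit)) return(NULL)
        data.frame(position = hit - 1L, mismatches = as.integer(best[hit]))
    }
    plus <- scan_variants(variants, template)
    minus <- scan_variants(vapply(variants, revcomp, character(1)), template)
    out <- rbind(if (!is.null(plus)) cbind(plus, strand = "+"),
                 if (!is.null(minus)) cbind(minus, strand = "-"))
    if (is.null(out))
        return(data.frame(position = integer(), strand = character(),
                          mismatches = integer()))
    out <- out[order(out$position, out$strand),
               c("position", "strand", "mismatches")]
    row.names(out) <- NULL
    out
}

# naive enumeration of all candidate pairs on a small consensus, using
# direct per-slice predicate checks (package tmRange but none of the
# enumerator's vectorized machinery)
oracleCandidates <- function(consensus, constraints) {
    L <- nchar(consensus)
    w <- constraints@targetWindow
    if (constraints@windowUnits == "aa") w <- w * 3L
    lens <- seq.int(constraints@lenMin, constraints@lenMax)
    slice_ok <- function(s) {
        degeneracy(s) <= constraints@maxDegeneracy &&
            degeneratePositions(s) <= constraints@maxDegeneratePositions
    }
    rows <- list()
    for (lf in lens) for (f0 in 0:(L - lf)) {
        if (f0 > w[1L]) next
        fseq <- substring(consensus, f0 + 1L, f0 + lf)
        if (!slice_ok(fseq)) next
        ftm <- tmRange(fseq, constraints@saltMolar, constraints@oligoMolar,
                       maxDegeneracy = constraints@maxDegeneracy)
        if (ftm[2L] < constraints@tmMin || ftm[1L] > constraints@tmMax) next
        fmid <- mean(ftm)
        for (lr in lens) for (r0 in 0:(L - lr)) {
            re <- r0 + lr
            if (re < w[2L]) next
            if (r0 < f0 + lf) next
            prod <- re - f0
            if (prod < constraints@productMin ||
                prod > constraints@productMax) next
            rseq <- substring(consensus, r0 + 1L, re)
            if (!slice_ok(rseq)) next
            rtm <- tmRange(rseq, constraints@saltMolar,
                           constraints@oligoMolar,
                           maxDegeneracy = constraints@maxDegeneracy)
            if (rtm[2L] < constraints@tmMin ||
                rtm[1L] > constraints@tmMax) next
            rmid <- mean(rtm)
            if (abs(fmid - rmid) > constraints@pairTmMaxDiff) next
            pen <- abs(lf - constraints@lenOpt) +
                abs(lr - constraints@lenOpt) +
                abs(fmid - constraints@tmOpt) +
                abs(rmid - constraints@tmOpt)
            rows[[length(rows) + 1L]] <- data.frame(
                fwd_seq = fseq, fwd_start = f0, fwd_len = lf,
                rev_seq = reverseComplementIupac(rseq), rev_start = r0,
                rev_len = lr, product_len = prod, penalty = pen)
        }
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) return(out)
    out <- out[order(out$penalty, out$fwd_start, out$rev_start,
                     out$fwd_len, out$rev_len), ]
    row.names(out) <- NULL
    out
}

# random IUPAC string with a bounded number of degenerate positions
randomIupac <- function(len, n_degen) {
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    if (n_degen > 0L) {
        pos <- sample(len, n_degen)
        s[pos] <- sample(c("R", "Y", "S", "W", "K", "M", "N"), n_degen,
                         replace = TRUE)
    }
    paste(s, collapse = "")
}

randomPlainDna <- function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
}
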