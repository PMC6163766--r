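# Nearest-neighbor duplex melting temperatures (SantaLucia 1998
# unified parameters) for plain and degenerate oligonucleotides.

# dH in kcal/mol, dS in cal/(mol K); bases indexed A=1, C=2, G=3, T=4.
# Each dinucleotide shares parameters with its reverse complement.
.NN_TABLE <- local({
    vals <- rbind(
        AA = c(-7.9, -22.2), AT = c(-7.2, -20.4), TA = c(-7.2, -21.3),
        CA = c(-8.5, -22.7), GT = c(-8.4, -22.4), CT = c(-7.8, -21.0),
        GA = c(-8.2, -22.2), CG = c(-10.6, -27.2), GC = c(-9.8, -24.4),
        GG = c(-8.0, -19.9))
    bases <- c("A", "C", "G", "T")
    dh <- matrix(NA_real_, 4, 4, dimnames = list(bases, bases))
    ds <- dh
    rc <- function(d) chartr("ACGT", "TGCA", paste(rev(strsplit(d, "")[[1L]]),
                                                   collapse = ""))
    for (d in rownames(vals)) {
        b <- strsplit(d, "")[[1L]]
        dh[b[1L], b[2L]] <- vals[d, 1L]; ds[b[1L], b[2L]] <- vals[d, 2L]
        b2 <- strsplit(rc(d), "")[[1L]]
        dh[b2[1L], b2[2L]] <- vals[d, 1L]; ds[b2[1L], b2[2L]] <- vals[d, 2L]
    }
    # duplex initiation per terminal base pair
    init <- rbind(A = c(2.3, 4.1), C = c(0.1, -2.8),
                  G = c(0.1, -2.8), T = c(2.3, 4.1))
    list(dh = dh, ds = ds, init_dh = init[, 1L], init_ds = init[, 2L])
})

.GAS_CONSTANT <- 1.987  # cal/(mol K)

# Tm in degC for a matrix of plain-base index rows (variants x length)
.tmFromIndexMatrix <- function(idx, saltMolar, oligoMolar) {
    n <- ncol(idx)
    i1 <- idx[, -n, drop = FALSE]
    i2 <- idx[, -1L, drop = FALSE]
    flat <- (i2 - 1L) * 4L + i1  # column-major [i1, i2] lookup
    dh <- rowSums(matrix(.NN_TABLE$dh[flat], nrow = nrow(idx))) +
        .NN_TABLE$init_dh[idx[, 1L]] + .NN_TABLE$init_dh[idx[, n]]
    ds <- rowSums(matrix(.NN_TABLE$ds[flat], nrow = nrow(idx))) +
        .NN_TABLE$init_ds[idx[, 1L]] + .NN_TABLE$init_ds[idx[, n]]
    ds <- ds + 0.368 * (n - 1L) * log(saltMolar)
    unname(dh * 1000 / (ds + .GAS_CONSTANT * log(oligoMolar / 4)) - 273.15)
}

# base letter -> index A=1, C=2, G=3, T=4
.plainIndices <- function(s) {
    idx <- match(strsplit(s, "")[[1L]], c("A", "C", "G", "T"))
    if (anyNA(idx)) stop("plain A/C/G/T sequence required", call. = FALSE)
    idx
}

#' Nearest-neighbor melting temperature of a plain primer
#'
#' Duplex melting temperature from nearest-neighbor thermodynamics
#' (SantaLucia 1998 unified dH/dS parameters): Tm(K) = dH / (dS' +
#' R ln(C/4)), with the entropy salt correction dS' = dS +
#' 0.368 (N-1) ln[Na+], returned in degrees Celsius.
#'
#' @param primer Plain A/C/G/T string, length >= 8.  Degenerate primers
#'   must go through [tmRange()].
#' @param saltMolar Monovalent cation concentration in M (default 0.05).
#' @param oligoMolar Total oligo concentration in M (default 50e-9).
#' @return Melting temperature in degrees Celsius.
#' @examples
#' meltingTemperature("ACGTACGTACGTACGTACGT")
#' @export
meltingTemperature <- function(primer, saltMolar = 0.05, oligoMolar = 50e-9) {
    stopifnot(is.character(primer), length(primer) == 1L)
    s <- .normalizeIupac(primer)
    if (nchar(s) < 8L)
        stop("primer shorter than 8 bases", call. = FALSE)
    idx <- .plainIndices(s)
    .tmFromIndexMatrix(matrix(idx, nrow = 1L), saltMolar, oligoMolar)
}

# expand a mask vector into a variants x length index matrix
.maskIndexMatrix <- function(masks) {
    sets <- lapply(masks, function(m) which(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L))
    as.matrix(rev(expand.grid(rev(sets), KEEP.OUT.ATTRS = FALSE)))
}

#' Melting-temperature range of a degenerate primer
#'
#' Minimum and maximum nearest-neighbor Tm over the full plain-sequence
#' expansion of a degenerate primer.  For a degeneracy-1 primer both
#' bounds equal [meltingTemperature()].
#'
#' @param primer IUPAC string, length >= 8, degeneracy at most
#'   \code{maxDegeneracy}.
#' @inheritParams meltingTemperature
#' @param maxDegeneracy Refuse primers with more variants than this
#'   (default 256).
#' @return Named numeric vector \code{c(tm_lo = , tm_hi = )} in degC.
#' @examples
#' tmRange("ACGTACGTACGTACGTACGR")
#' @export
tmRange <- function(primer, saltMolar = 0.05, oligoMolar = 50e-9,
                    maxDegeneracy = 256L) {
    stopifnot(is.character(primer), length(primer) == 1L)
    s <- .normalizeIupac(primer)
    if (nchar(s) < 8L) stop("primer shorter than 8 bases", call. = FALSE)
    d <- degeneracy(s)
    if (d > maxDegeneracy)
        stop(sprintf("degeneracy %d exceeds cap %d", d, maxDegeneracy),
             call. = FALSE)
    tms <- .tmFromIndexMatrix(.maskIndexMatrix(.iupacMasks(s)),
                              saltMolar, oligoMolar)
    c(tm_lo = min(tms), tm_hi = max(tms))
}

# memoized Tm range on mask vectors; memo maps primer string -> c(lo, hi)
.tmRangeMasks <- function(masks, saltMolar, oligoMolar, memo = NULL) {
    key <- .masksToString(masks)
    if (!is.null(memo) && !is.null(memo[[key]])) return(memo[[key]])
    tms <- .tmFromIndexMatrix(.maskIndexMatrix(masks), saltMolar, oligoMolar)
    val <- c(min(tms), max(tms))
    if (!is.null(memo)) memo[[key]] <- val
    val
}
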