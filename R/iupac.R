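# IUPAC nucleotide ambiguity-code algebra: membership, degeneracy,
# expansion, complementation.  All other modules reduce base comparison
# to the bitmask encoding defined here (A=1, C=2, G=4, T=8).

.IUPAC_LETTERS <- names(Biostrings::IUPAC_CODE_MAP)

# letter -> bitmask, derived once from the Biostrings code map
.iupacMaskTable <- local({
    base_bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
    vapply(strsplit(Biostrings::IUPAC_CODE_MAP, ""), function(b) {
        sum(base_bit[b])
    }, integer(1))
})

# bitmask -> minimal letter (inverse table, positions 1..15)
.iupacLetterTable <- local({
    out <- character(15L)
    out[.iupacMaskTable] <- names(.iupacMaskTable)
    out
})

.validateIupacChars <- function(chars, allow_gap = FALSE, what = "sequence") {
    ok <- chars %in% .IUPAC_LETTERS
    if (allow_gap) ok <- ok | chars == "-"
    if (!all(ok)) {
        bad <- which(!ok)[1L]
        stop(sprintf("invalid IUPAC character '%s' at position %d in %s",
                     chars[bad], bad, what), call. = FALSE)
    }
    invisible(TRUE)
}

# Normalize tolerant FASTA input: uppercase, U -> T.
.normalizeIupac <- function(s) {
    chartr("u", "T", chartr("U", "T", toupper(s)))
}

.iupacMasks <- function(s, allow_gap = FALSE) {
    chars <- strsplit(.normalizeIupac(s), "")[[1L]]
    .validateIupacChars(chars, allow_gap = allow_gap)
    m <- integer(length(chars))
    idx <- chars != "-"
    m[idx] <- .iupacMaskTable[chars[idx]]
    m
}

.masksToString <- function(masks) {
    out <- character(length(masks))
    out[masks == 0L] <- "-"
    out[masks > 0L] <- .iupacLetterTable[masks[masks > 0L]]
    paste(out, collapse = "")
}

#' Base set of an IUPAC ambiguity code
#'
#' Returns the set of plain bases an IUPAC nucleotide code stands for,
#' e.g. \code{R} is \{A, G\} and \code{N} is \{A, C, G, T\}.
#'
#' @param base A single IUPAC character (case-insensitive; \code{U} is
#'   treated as \code{T}).
#' @return Character vector of plain bases, a non-empty subset of
#'   \code{c("A","C","G","T")}.
#' @examples
#' iupacCodeSet("R")
#' iupacCodeSet("N")
#' @export
iupacCodeSet <- function(base) {
    stopifnot(is.character(base), length(base) == 1L, nchar(base) == 1L)
    b <- .normalizeIupac(base)
    .validateIupacChars(b, what = "code")
    strsplit(Biostrings::IUPAC_CODE_MAP[[b]], "")[[1L]]
}

#' Degeneracy of a degenerate oligonucleotide
#'
#' The number of plain-sequence variants an IUPAC string stands for:
#' the product over positions of the size of each position's base set.
#'
#' @param s A character string over the IUPAC nucleotide alphabet
#'   (no gaps).
#' @return A positive number (1 for a plain sequence).
#' @examples
#' degeneracy("ACGT")   # 1
#' degeneracy("NNNN")   # 256
#' @export
degeneracy <- function(s) {
    stopifnot(is.character(s), length(s) == 1L)
    if (nchar(s) == 0L) stop("empty IUPAC string", call. = FALSE)
    masks <- .iupacMasks(s, allow_gap = TRUE)
    if (any(masks == 0L)) stop("gap character not allowed here", call. = FALSE)
    prod(.maskSizes(masks))
}

.maskSizes <- function(masks) {
    # popcount over 0..15
    c(0L, 1L, 1L, 2L, 1L, 2L, 2L, 3L,
      1L, 2L, 2L, 3L, 2L, 3L, 3L, 4L)[masks + 1L]
}

#' Number of degenerate positions
#'
#' Counts positions whose IUPAC code stands for more than one base.
#'
#' @inheritParams degeneracy
#' @return Non-negative integer.
#' @examples
#' degeneratePositions("ARGN")  # 2
#' @export
degeneratePositions <- function(s) {
    stopifnot(is.character(s), length(s) == 1L)
    if (nchar(s) == 0L) stop("empty IUPAC string", call. = FALSE)
    masks <- .iupacMasks(s, allow_gap = TRUE)
    if (any(masks == 0L)) stop("gap character not allowed here", call. = FALSE)
    sum(.maskSizes(masks) > 1L)
}

#' Expand a degenerate sequence into its plain variants
#'
#' Cartesian expansion of an IUPAC string into every plain A/C/G/T
#' sequence it stands for.  Refuses to expand beyond \code{limit}
#' variants to guard against combinatorial blow-up.
#'
#' @inheritParams degeneracy
#' @param limit Maximum number of variants to allow (default 4096).
#' @return Character vector of plain sequences, of length
#'   \code{degeneracy(s)}, in lexicographic-by-position order.
#' @examples
#' expandDegenerate("AR")
#' @export
expandDegenerate <- function(s, limit = 4096L) {
    d <- degeneracy(s)
    if (d > limit) {
        stop(sprintf("degeneracy %d exceeds expansion limit %d", d, limit),
             call. = FALSE)
    }
    sets <- lapply(strsplit(.normalizeIupac(s), "")[[1L]], function(ch) {
        strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1L]]
    })
    do.call(paste0, rev(expand.grid(rev(sets), stringsAsFactors = FALSE)))
}

#' Reverse complement of a degenerate sequence
#'
#' Per-code complementation (A/T, C/G, R/Y, K/M, B/V, D/H; S, W and N
#' are self-complementary) followed by reversal, so the result denotes
#' exactly the reverse complements of the variants of the input.
#'
#' @inheritParams degeneracy
#' @return IUPAC string of the same length and degeneracy.
#' @examples
#' reverseComplementIupac("ATGCR")  # "YGCAT"
#' @export
reverseComplementIupac <- function(s) {
    stopifnot(is.character(s), length(s) == 1L)
    if (nchar(s) == 0L) stop("empty IUPAC string", call. = FALSE)
    masks <- .iupacMasks(s, allow_gap = TRUE)
    if (any(masks == 0L)) stop("gap character not allowed here", call. = FALSE)
    .masksToString(rev(.complementMasks(masks)))
}

# complement of a bitmask: swap bit A<->T and C<->G
.complementMasks <- function(masks) {
    a <- bitwAnd(masks, 1L); c_ <- bitwAnd(masks, 2L)
    g <- bitwAnd(masks, 4L); t <- bitwAnd(masks, 8L)
    as.integer(a * 8L + c_ * 2L + g / 2L + t / 8L)
}

#' Do a primer base and a template base match?
#'
#' Intersection semantics: two IUPAC codes match when their base sets
#' share at least one plain base.  For a plain template base this
#' reduces to membership of the template base in the primer's set.
#' Vectorized over both arguments.
#'
#' @param primer_base,template_base IUPAC characters (recycled).
#' @return Logical vector.
#' @examples
#' baseMatches("R", "A")  # TRUE
#' baseMatches("R", "C")  # FALSE
#' @export
baseMatches <- function(primer_base, template_base) {
    p <- .normalizeIupac(primer_base)
    t <- .normalizeIupac(template_base)
    .validateIupacChars(p, what = "primer base")
    .validateIupacChars(t, what = "template base")
    bitwAnd(.iupacMaskTable[p], .iupacMaskTable[t]) > 0L
}

# minimal IUPAC letter covering a union of masks (internal)
.maskToChar <- function(mask) {
    if (mask == 0L) "-" else .iupacLetterTable[mask]
}
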