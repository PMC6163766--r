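# Codon-aware threading of CDS into protein alignments and IUPAC
# consensus construction from nucleotide alignments.

#' Translate a coding sequence
#'
#' Standard genetic code translation with solve-else-X handling of
#' IUPAC-ambiguous codons: a codon containing ambiguity codes
#' translates to the amino acid all of its plain expansions agree on,
#' and to \code{X} otherwise.  Stop codons translate to \code{*}.
#' A trailing partial codon is ignored.
#'
#' @param cds Nucleotide string (IUPAC codes allowed, no gaps).
#' @param frame Reading frame offset, 0, 1 or 2.
#' @return Protein string.
#' @examples
#' translateCds("ATGGCA")        # "MA"
#' translateCds("GCN")           # "A": all four GCx codons encode Ala
#' @export
translateCds <- function(cds, frame = 0L) {
    stopifnot(is.character(cds), length(cds) == 1L, frame %in% 0:2)
    if (nchar(cds) == 0L) stop("empty CDS", call. = FALSE)
    s <- .normalizeIupac(cds)
    .validateIupacChars(strsplit(s, "")[[1L]], what = "CDS")
    s <- substring(s, frame + 1L)
    n_codon <- nchar(s) %/% 3L
    if (n_codon == 0L) return("")
    codons <- substring(s, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
    aa <- unname(Biostrings::GENETIC_CODE[codons])
    fuzzy <- which(is.na(aa))
    for (i in fuzzy) {
        aas <- unique(unname(
            Biostrings::GENETIC_CODE[expandDegenerate(codons[i], limit = 64L)]))
        aa[i] <- if (length(aas) == 1L) aas else "X"
    }
    paste(aa, collapse = "")
}

.asAlignedCharacter <- function(x, class = "AAStringSet") {
    if (methods::is(x, "XStringSet")) x <- as.character(x)
    if (is.null(names(x)) || anyDuplicated(names(x)))
        stop("alignment rows must have unique names", call. = FALSE)
    if (length(unique(nchar(x))) > 1L)
        stop("alignment rows must have uniform length", call. = FALSE)
    x
}

#' Thread coding sequences into a protein alignment
#'
#' Back-translates a protein multiple alignment into a codon-aware
#' nucleotide alignment: every residue is replaced by the codon that
#' encodes it in the corresponding CDS and every gap by \code{---}.
#' One terminal stop codon on a CDS is tolerated and dropped.  The
#' translation of each CDS must match its ungapped protein row
#' residue-for-residue (\code{X} on either side is treated as a
#' wildcard); any disagreement is an error naming the row, the
#' position, and the two residues.
#'
#' @param proteinAlignment Named [Biostrings::AAStringSet] (or character
#'   vector) of aligned protein rows, gap \code{-}.
#' @param cds Named [Biostrings::DNAStringSet] (or character vector) of
#'   unaligned coding sequences covering every alignment id.
#' @return A [Biostrings::DNAStringSet] nucleotide alignment of width
#'   3x the protein alignment width.
#' @examples
#' threadCodons(c(s1 = "MA-V"), c(s1 = "ATGGCAGTT"))
#' @export
threadCodons <- function(proteinAlignment, cds) {
    pal <- .asAlignedCharacter(proteinAlignment)
    if (methods::is(cds, "XStringSet")) cds <- as.character(cds)
    missing_ids <- setdiff(names(pal), names(cds))
    if (length(missing_ids))
        stop("missing CDS for alignment id(s): ",
             paste(missing_ids, collapse = ", "), call. = FALSE)
    out <- vapply(names(pal), function(id) {
        .threadOneRow(id, pal[[id]], .normalizeIupac(cds[[id]]))
    }, character(1))
    Biostrings::DNAStringSet(out)
}

.threadOneRow <- function(id, row, cds) {
    res <- strsplit(row, "")[[1L]]
    ungapped <- res[res != "-"]
    n_res <- length(ungapped)
    n_codon <- nchar(cds) %/% 3L
    if (nchar(cds) %% 3L != 0L)
        stop(sprintf("CDS length of '%s' is not a multiple of 3", id),
             call. = FALSE)
    trans <- strsplit(translateCds(cds), "")[[1L]]
    # tolerate exactly one terminal stop codon
    if (n_codon == n_res + 1L && trans[n_codon] == "*") {
        trans <- trans[-n_codon]
        n_codon <- n_codon - 1L
    }
    if (n_codon != n_res)
        stop(sprintf(
            "CDS of '%s' has %d codons but its protein row has %d residues",
            id, n_codon, n_res), call. = FALSE)
    bad <- which(trans != ungapped & trans != "X" & ungapped != "X")
    if (length(bad)) {
        b <- bad[1L]
        stop(sprintf(
            "translation mismatch for '%s' at residue %d: row has '%s', CDS encodes '%s'",
            id, b, ungapped[b], trans[b]), call. = FALSE)
    }
    codons <- substring(cds, 3L * seq_len(n_res) - 2L, 3L * seq_len(n_res))
    cells <- character(length(res))
    cells[res == "-"] <- "---"
    cells[res != "-"] <- codons
    paste(cells, collapse = "")
}

#' Consensus IUPAC code of one alignment column
#'
#' The minimal IUPAC code whose base set equals the union of the base
#' sets observed among non-gap entries of the column; \code{-} when the
#' column is all gaps.  Order-independent (multiset semantics); an
#' ambiguity code in a member (for instance a rare \code{N}) contributes
#' its full base set, so the consensus always covers every member.
#'
#' @param column Character vector of IUPAC characters and/or \code{-}.
#' @return A single IUPAC character, or \code{-}.
#' @examples
#' columnConsensus(c("A", "G"))        # "R"
#' columnConsensus(c("A", "-", "A"))   # "A"
#' @export
columnConsensus <- function(column) {
    stopifnot(length(column) >= 1L)
    chars <- .normalizeIupac(column)
    .validateIupacChars(chars, allow_gap = TRUE, what = "column")
    masks <- .iupacMaskTable[chars[chars != "-"]]
    if (!length(masks)) return("-")
    .maskToChar(Reduce(bitwOr, masks))
}

# --- internal mask-matrix representation of a nucleotide alignment ---
# rows = sequences, columns = alignment columns, values 0 (gap) .. 15

.alignmentMaskMatrix <- function(rows) {
    rows <- .asAlignedCharacter(rows)
    m <- matrix(0L, nrow = length(rows), ncol = nchar(rows[[1L]]),
                dimnames = list(names(rows), NULL))
    for (i in seq_along(rows)) m[i, ] <- .iupacMasks(rows[[i]], allow_gap = TRUE)
    m
}

.maskMatrixConsensus <- function(m) {
    # bitwise OR down each column
    cons <- m[1L, ]
    if (nrow(m) > 1L) for (i in 2:nrow(m)) cons <- bitwOr(cons, m[i, ])
    cons
}

#' Consensus of a nucleotide alignment
#'
#' Per-column IUPAC consensus ([columnConsensus()]) with all-gap columns
#' removed, plus a column map relating consensus positions back to
#' original alignment columns (needed to interpret window coordinates
#' after column removal).
#'
#' @param alignment Named [Biostrings::DNAStringSet] or character vector
#'   of aligned nucleotide rows (gap \code{-}), uniform width.
#' @return List with \code{consensus} (IUPAC string, no gaps) and
#'   \code{columnMap} (integer vector: consensus position i came from
#'   alignment column \code{columnMap[i]}, 1-based).
#' @examples
#' alignmentConsensus(c(a = "A-G", b = "A-G"))
#' @export
alignmentConsensus <- function(alignment) {
    if (length(alignment) == 0L) stop("empty alignment", call. = FALSE)
    m <- .alignmentMaskMatrix(alignment)
    cons <- .maskMatrixConsensus(m)
    keep <- which(cons > 0L)
    list(consensus = .masksToString(cons[keep]), columnMap = keep)
}

#' Subset a nucleotide alignment by id
#'
#' Keeps the selected rows and drops columns that became all-gap, so
#' the result is the alignment the selected sequences induce.
#'
#' @param alignment Named aligned [Biostrings::DNAStringSet] or
#'   character vector.
#' @param ids Non-empty character vector of row ids to keep.
#' @return A [Biostrings::DNAStringSet] with the surviving columns.
#' @export
subsetAlignment <- function(alignment, ids) {
    rows <- .asAlignedCharacter(alignment)
    if (length(ids) == 0L) stop("cannot subset to zero rows", call. = FALSE)
    missing_ids <- setdiff(ids, names(rows))
    if (length(missing_ids))
        stop("unknown alignment id(s): ",
             paste(missing_ids, collapse = ", "), call. = FALSE)
    m <- .alignmentMaskMatrix(rows[ids])
    keep <- .maskMatrixConsensus(m) > 0L
    out <- apply(m[, keep, drop = FALSE], 1L, .masksToString)
    Biostrings::DNAStringSet(setNames(out, ids))
}
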