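#' @import methods
#' @importFrom stats setNames rlnorm runif
#' @importFrom utils read.delim write.table
NULL

#' Primer design constraints
#'
#' Container for the constraint set under which degenerate primer-pair
#' candidates are enumerated on a consensus sequence: melting-temperature
#' optimum and acceptance band, primer length band, caps on degeneracy
#' and on the number of degenerate positions, the target window the
#' amplified product must contain, and product-size bounds.
#'
#' Defaults encode a panel-design protocol for a highly diverse
#' protein-coding marker: Tm optimum 52 degC (band 47-57), optimal
#' 20-mers (18-27 allowed), at most 8 degenerate positions and total
#' degeneracy at most 256 per primer, products of 200-600 bases that
#' fully contain the target window.
#'
#' @slot tmOpt,tmMin,tmMax Melting temperature optimum and acceptance
#'   band, degrees Celsius.
#' @slot lenOpt,lenMin,lenMax Primer length optimum and band, bases.
#' @slot maxDegeneratePositions Cap on positions with ambiguity codes.
#' @slot maxDegeneracy Cap on the number of plain variants per primer.
#' @slot targetWindow Integer pair, 0-based half-open coordinates of the
#'   region every amplified product must contain.
#' @slot windowUnits Either \code{"nt"} (consensus nucleotide columns,
#'   the default) or \code{"aa"} (amino-acid columns, multiplied by 3
#'   when applied).
#' @slot productMin,productMax Product-size bounds, bases.
#' @slot pairTmMaxDiff Maximal difference between the two primers'
#'   midpoint Tm, degrees Celsius.
#' @slot saltMolar Monovalent cation concentration for the Tm model, M.
#' @slot oligoMolar Oligo concentration for the Tm model, M.
#'
#' @seealso [primerConstraints()] for the user constructor,
#'   [enumerateCandidates()] for where the constraints act.
#' @export
setClass("PrimerConstraints", representation(
    tmOpt = "numeric", tmMin = "numeric", tmMax = "numeric",
    lenOpt = "integer", lenMin = "integer", lenMax = "integer",
    maxDegeneratePositions = "integer",
    maxDegeneracy = "integer",
    targetWindow = "integer",
    windowUnits = "character",
    productMin = "integer", productMax = "integer",
    pairTmMaxDiff = "numeric",
    saltMolar = "numeric", oligoMolar = "numeric",
    allowDegenerate3Prime = "logical"
))

setValidity("PrimerConstraints", function(object) {
    msgs <- character()
    if (!(object@lenMin <= object@lenOpt && object@lenOpt <= object@lenMax))
        msgs <- c(msgs, "need lenMin <= lenOpt <= lenMax")
    if (!(object@tmMin <= object@tmOpt && object@tmOpt <= object@tmMax))
        msgs <- c(msgs, "need tmMin <= tmOpt <= tmMax")
    if (length(object@targetWindow) != 2L ||
        object@targetWindow[1L] >= object@targetWindow[2L])
        msgs <- c(msgs, "targetWindow must be (start, end) with start < end")
    if (object@targetWindow[1L] < 0L)
        msgs <- c(msgs, "targetWindow start must be >= 0")
    if (!(object@productMin < object@productMax))
        msgs <- c(msgs, "need productMin < productMax")
    if (!object@windowUnits %in% c("nt", "aa"))
        msgs <- c(msgs, "windowUnits must be 'nt' or 'aa'")
    if (object@maxDegeneracy < 1L || object@maxDegeneratePositions < 0L)
        msgs <- c(msgs, "degeneracy caps must be positive")
    if (object@saltMolar <= 0 || object@oligoMolar <= 0)
        msgs <- c(msgs, "Tm model concentrations must be positive")
    if (length(msgs)) msgs else TRUE
})

#' Construct a PrimerConstraints object
#'
#' @param tmOpt,tmMin,tmMax Tm optimum and acceptance band (degC).
#' @param lenOpt,lenMin,lenMax Primer length optimum and band (bases).
#' @param maxDegeneratePositions Cap on ambiguous positions per primer.
#' @param maxDegeneracy Cap on variants per primer.
#' @param targetWindow Length-2 vector, 0-based half-open window that
#'   every product must contain.
#' @param windowUnits \code{"nt"} or \code{"aa"} (see class docs).
#' @param productMin,productMax Product-size bounds (bases).
#' @param pairTmMaxDiff Max midpoint-Tm difference within a pair (degC).
#' @param saltMolar,oligoMolar Conditions for the nearest-neighbor Tm
#'   model (default 50 mM Na+, 50 nM oligo).
#' @param allowDegenerate3Prime Whether a primer may end (3') on an
#'   ambiguity code (default TRUE).
#' @return A validated [PrimerConstraints-class] object.
#' @examples
#' primerConstraints()
#' primerConstraints(targetWindow = c(50, 150), productMin = 150)
#' @export
primerConstraints <- function(tmOpt = 52, tmMin = 47, tmMax = 57,
                              lenOpt = 20L, lenMin = 18L, lenMax = 27L,
                              maxDegeneratePositions = 8L,
                              maxDegeneracy = 256L,
                              targetWindow = c(105L, 214L),
                              windowUnits = c("nt", "aa"),
                              productMin = 200L, productMax = 600L,
                              pairTmMaxDiff = 5,
                              saltMolar = 0.05, oligoMolar = 50e-9,
                              allowDegenerate3Prime = TRUE) {
    new("PrimerConstraints",
        tmOpt = as.numeric(tmOpt), tmMin = as.numeric(tmMin),
        tmMax = as.numeric(tmMax),
        lenOpt = as.integer(lenOpt), lenMin = as.integer(lenMin),
        lenMax = as.integer(lenMax),
        maxDegeneratePositions = as.integer(maxDegeneratePositions),
        maxDegeneracy = as.integer(maxDegeneracy),
        targetWindow = as.integer(targetWindow),
        windowUnits = match.arg(windowUnits),
        productMin = as.integer(productMin),
        productMax = as.integer(productMax),
        pairTmMaxDiff = as.numeric(pairTmMaxDiff),
        saltMolar = as.numeric(saltMolar),
        oligoMolar = as.numeric(oligoMolar),
        allowDegenerate3Prime = isTRUE(allowDegenerate3Prime))
}

# target window in nucleotide consensus coordinates
.ntWindow <- function(constraints) {
    w <- constraints@targetWindow
    if (constraints@windowUnits == "aa") w <- w * 3L
    w
}

setMethod("show", "PrimerConstraints", function(object) {
    w <- object@targetWindow
    cat("PrimerConstraints\n",
        sprintf("  Tm: opt %.1f degC, band [%.1f, %.1f], pair diff <= %.1f\n",
                object@tmOpt, object@tmMin, object@tmMax,
                object@pairTmMaxDiff),
        sprintf("  length: opt %d, band [%d, %d]\n",
                object@lenOpt, object@lenMin, object@lenMax),
        sprintf("  degeneracy <= %d, degenerate positions <= %d\n",
                object@maxDegeneracy, object@maxDegeneratePositions),
        sprintf("  target window: [%d, %d) %s; product: [%d, %d] nt\n",
                w[1L], w[2L], object@windowUnits,
                object@productMin, object@productMax), sep = "")
})

#' A collection of homologous protein-coding target genes
#'
#' Bundles the unaligned CDS sequences, the protein multiple alignment
#' covering them (the master alignment that codon threading and the
#' similarity guide are derived from), per-sequence abundance weights
#' (mapped reads per gene length, or 1 when unknown), and outgroup
#' flags.
#'
#' @slot cds A [Biostrings::DNAStringSet] of unaligned coding sequences,
#'   uniquely named.
#' @slot proteinAlignment An [Biostrings::AAStringSet] of aligned
#'   protein rows (gap \code{-}), same names, uniform width.
#' @slot abundance Named numeric weights, non-negative.
#' @slot outgroup Named logical outgroup flags.
#' @export
setClass("TargetCollection", representation(
    cds = "DNAStringSet",
    proteinAlignment = "AAStringSet",
    abundance = "numeric",
    outgroup = "logical"
))

setValidity("TargetCollection", function(object) {
    ids <- names(object@cds)
    msgs <- character()
    if (length(object@cds) == 0L) {
        # empty collection: a valid degenerate object
    } else if (is.null(ids) || anyDuplicated(ids))
        msgs <- c(msgs, "cds must have unique names")
    else {
        if (!identical(sort(ids), sort(names(object@proteinAlignment))))
            msgs <- c(msgs, "protein alignment ids must match cds ids")
        if (!identical(sort(ids), sort(names(object@abundance))))
            msgs <- c(msgs, "abundance names must match cds ids")
        if (!identical(sort(ids), sort(names(object@outgroup))))
            msgs <- c(msgs, "outgroup names must match cds ids")
    }
    if (length(object@proteinAlignment) &&
        length(unique(Biostrings::width(object@proteinAlignment))) != 1L)
        msgs <- c(msgs, "protein alignment rows must have uniform width")
    if (any(object@abundance < 0))
        msgs <- c(msgs, "abundances must be non-negative")
    if (length(msgs)) msgs else TRUE
})

#' Construct a TargetCollection
#'
#' @param cds [Biostrings::DNAStringSet] (or named character vector) of
#'   unaligned coding sequences.
#' @param proteinAlignment [Biostrings::AAStringSet] (or named character
#'   vector) of aligned protein rows covering the same ids.
#' @param abundance Optional named numeric weights; default 1 for every
#'   sequence (the semantics used throughout are mapped reads divided by
#'   gene length).
#' @param outgroup Optional character vector of outgroup ids, or a named
#'   logical vector.
#' @return A validated [TargetCollection-class].
#' @export
TargetCollection <- function(cds, proteinAlignment, abundance = NULL,
                             outgroup = character()) {
    if (!methods::is(cds, "DNAStringSet"))
        cds <- Biostrings::DNAStringSet(cds)
    if (!methods::is(proteinAlignment, "AAStringSet"))
        proteinAlignment <- Biostrings::AAStringSet(proteinAlignment)
    ids <- names(cds)
    if (length(ids)) {
        missing_ids <- setdiff(ids, names(proteinAlignment))
        if (length(missing_ids))
            stop("protein alignment ids must match cds ids; missing: ",
                 paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    if (is.null(abundance)) abundance <- setNames(rep(1, length(ids)), ids)
    if (is.logical(outgroup) && !is.null(names(outgroup))) {
        og <- outgroup[ids]
        og[is.na(og)] <- FALSE
        names(og) <- ids
    } else {
        og <- setNames(ids %in% as.character(outgroup), ids)
    }
    new("TargetCollection", cds = cds,
        proteinAlignment = proteinAlignment[ids],
        abundance = abundance[ids], outgroup = og)
}

#' @describeIn TargetCollection-class Number of target sequences.
#' @param x A \code{TargetCollection}.
#' @export
setMethod("length", "TargetCollection", function(x) length(x@cds))

#' Accessors for TargetCollection
#'
#' @param x A [TargetCollection-class].
#' @return \code{targetCds}: the CDS [Biostrings::DNAStringSet];
#'   \code{targetProteins}: the aligned [Biostrings::AAStringSet];
#'   \code{abundances}: named numeric; \code{isOutgroup}: named logical;
#'   \code{targetIds}: character vector of sequence ids.
#' @name TargetCollection-accessors
NULL

#' @rdname TargetCollection-accessors
#' @export
targetCds <- function(x) x@cds

#' @rdname TargetCollection-accessors
#' @export
targetProteins <- function(x) x@proteinAlignment

#' @rdname TargetCollection-accessors
#' @export
abundances <- function(x) x@abundance

#' @rdname TargetCollection-accessors
#' @export
isOutgroup <- function(x) x@outgroup

#' @rdname TargetCollection-accessors
#' @export
targetIds <- function(x) names(x@cds)

#' Subset a TargetCollection by id
#'
#' @param x A [TargetCollection-class].
#' @param i Character vector of ids (or logical/integer index).
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "TargetCollection", function(x, i, j, ..., drop = FALSE) {
    ids <- names(x@cds)[seq_along(x@cds)]
    if (is.character(i)) {
        missing_ids <- setdiff(i, ids)
        if (length(missing_ids))
            stop("unknown target id(s): ",
                 paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    new("TargetCollection", cds = x@cds[i],
        proteinAlignment = x@proteinAlignment[i],
        abundance = x@abundance[i], outgroup = x@outgroup[i])
})

setMethod("show", "TargetCollection", function(object) {
    cat(sprintf("TargetCollection with %d sequences (%d outgroup)\n",
                length(object), sum(object@outgroup)))
    if (length(object)) {
        cat(sprintf("  CDS length: %d-%d nt; alignment width: %d aa\n",
                    min(Biostrings::width(object@cds)),
                    max(Biostrings::width(object@cds)),
                    Biostrings::width(object@proteinAlignment)[1L]))
        cat(sprintf("  total abundance weight: %.3g\n",
                    sum(object@abundance)))
    }
})

#' A designed panel of degenerate primer pairs
#'
#' The result of [designPanel()]: an ordered table of primer pairs
#' (ids \code{PP1}, \code{PP2}, ...), the strict (0-mismatch) coverage
#' map from pair id to amplified target ids, the set of targets for
#' which no pair could be designed, the per-iteration design log, and
#' the constraints used.
#'
#' By construction every target outside \code{undesignable} is amplified
#' by at least one pair at mismatch fraction 0 with a product within
#' bounds.
#'
#' @slot pairs data.frame, one row per pair with columns
#'   \code{pair_id, fwd_seq, fwd_start, fwd_tm_lo, fwd_tm_hi,
#'   fwd_degeneracy, fwd_degenerate_positions, rev_seq, rev_start,
#'   rev_tm_lo, rev_tm_hi, rev_degeneracy, rev_degenerate_positions,
#'   product_len, penalty}.
#' @slot coverage Named list, pair id to character vector of target ids
#'   amplified at mismatch fraction 0.
#' @slot undesignable Character vector of target ids no pair amplifies.
#' @slot designLog data.frame with one row per design iteration:
#'   \code{iteration, seed, pair_id, members, rejected, swept}
#'   (id lists comma-separated).
#' @slot constraints The [PrimerConstraints-class] used.
#' @slot outgroupOnly Character vector of target ids that were only
#'   reachable through pairs pruned as outgroup-only (empty until
#'   [pruneOutgroupOnlyPairs()] is applied).
#' @export
setClass("PrimerPanel", representation(
    pairs = "data.frame",
    coverage = "list",
    undesignable = "character",
    designLog = "data.frame",
    constraints = "PrimerConstraints",
    outgroupOnly = "character"
), prototype(outgroupOnly = character()))

setValidity("PrimerPanel", function(object) {
    msgs <- character()
    need <- c("pair_id", "fwd_seq", "rev_seq", "product_len", "penalty")
    if (nrow(object@pairs) && !all(need %in% names(object@pairs)))
        msgs <- c(msgs, "pairs table is missing required columns")
    if (nrow(object@pairs) && anyDuplicated(object@pairs$pair_id))
        msgs <- c(msgs, "pair ids must be unique")
    if (!all(names(object@coverage) %in% object@pairs$pair_id))
        msgs <- c(msgs, "coverage keys must be pair ids")
    if (length(msgs)) msgs else TRUE
})

#' @describeIn PrimerPanel-class Number of primer pairs in the panel.
#' @param x A \code{PrimerPanel}.
#' @export
setMethod("length", "PrimerPanel", function(x) nrow(x@pairs))

#' Accessors for PrimerPanel
#'
#' @param x A [PrimerPanel-class].
#' @return \code{panelPairs}: the pair table (data.frame);
#'   \code{panelCoverageMap}: named list pair id -> covered target ids;
#'   \code{undesignableTargets}: character vector;
#'   \code{designLog}: the per-iteration log (data.frame);
#'   \code{coveredTargets}: unique ids amplified by at least one pair.
#' @name PrimerPanel-accessors
NULL

#' @rdname PrimerPanel-accessors
#' @export
panelPairs <- function(x) x@pairs

#' @rdname PrimerPanel-accessors
#' @export
panelCoverageMap <- function(x) x@coverage

#' @rdname PrimerPanel-accessors
#' @export
undesignableTargets <- function(x) x@undesignable

#' @rdname PrimerPanel-accessors
#' @export
designLog <- function(x) x@designLog

#' @rdname PrimerPanel-accessors
#' @export
outgroupOnlyTargets <- function(x) x@outgroupOnly

#' @rdname PrimerPanel-accessors
#' @export
coveredTargets <- function(x) {
    as.character(unique(unlist(x@coverage, use.names = FALSE)))
}

setMethod("show", "PrimerPanel", function(object) {
    n_cov <- length(coveredTargets(object))
    cat(sprintf("PrimerPanel with %d primer pairs\n", length(object)))
    cat(sprintf("  covered targets (0-mismatch): %d; undesignable: %d\n",
                n_cov, length(object@undesignable)))
    if (length(object)) {
        d <- object@pairs
        cat(sprintf("  degeneracy: fwd %d-%d, rev %d-%d; product %d-%d nt\n",
                    min(d$fwd_degeneracy), max(d$fwd_degeneracy),
                    min(d$rev_degeneracy), max(d$rev_degeneracy),
                    min(d$product_len), max(d$product_len)))
    }
})
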