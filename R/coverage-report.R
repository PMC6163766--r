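# Specificity screening against decoy collections and per-sample
# genotype censuses for shotgun-assembly comparisons.

#' Screen a panel for off-target amplification
#'
#' Runs strict (or relaxed) in silico PCR of every panel pair against a
#' decoy collection and reports every virtual amplicon; an empty hit
#' table means the panel is specific against the decoys at that
#' tolerance.
#'
#' @param panel A [PrimerPanel-class].
#' @param decoys Named [Biostrings::DNAStringSet] (or character
#'   vector) of off-target templates.
#' @param maxMismatchFraction Mismatch tolerance (default 0).
#' @return List with \code{hits} (the [amplifyPanel()] hit table),
#'   \code{nTemplatesAmplified} (number of distinct decoys amplified)
#'   and \code{nAmplicons} (total amplification events).
#' @export
screenSpecificity <- function(panel, decoys, maxMismatchFraction = 0) {
    stopifnot(methods::is(panel, "PrimerPanel"))
    if (length(panel) == 0L)
        stop("empty panel", call. = FALSE)
    hits <- amplifyPanel(panel, decoys, maxMismatchFraction)
    list(hits = hits,
         nTemplatesAmplified = length(unique(hits$template_id)),
         nAmplicons = nrow(hits))
}

#' Count distinct amplifiable genotypes per assembly
#'
#' For each assembly (a collection of contig/gene sequences), counts
#' the distinct amplicon product sequences recoverable by any pair of
#' the panel, deduplicated at 100% identity: product sequence, not
#' coordinates, defines a genotype, so duplicated records and record
#' order cannot change the count.
#'
#' @param panel A [PrimerPanel-class].
#' @param assemblies List of named [Biostrings::DNAStringSet] (or
#'   character vectors), one per sample.
#' @param maxMismatchFraction Mismatch tolerance (default 0).
#' @return List with \code{perSample} (integer vector of genotype
#'   counts, named when the assembly list is) and \code{summary}
#'   (mean, min, max).
#' @export
genotypeCensus <- function(panel, assemblies, maxMismatchFraction = 0) {
    stopifnot(methods::is(panel, "PrimerPanel"), length(assemblies) >= 1L)
    counts <- vapply(assemblies, function(a) {
        if (length(a) == 0L) return(0L)
        hits <- amplifyPanel(panel, a, maxMismatchFraction)
        length(unique(hits$product_seq))
    }, integer(1))
    list(perSample = counts,
         summary = c(mean = mean(counts), min = min(counts),
                     max = max(counts)))
}
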