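# Flat-file plumbing: primer tables, abundance tables, coverage
# reports, run configuration, and synthesis-ready primer FASTA.

#' Write / read a primer-pair table
#'
#' Tab-separated serialization of a panel's pair table.  A header
#' comment line embeds the resolved constraints as JSON for
#' provenance.  Coordinates are written 1-based inclusive
#' (\code{fwd_start}, \code{rev_start} columns) and converted back on
#' read.
#'
#' @param panel A [PrimerPanel-class] (or bare pair table).
#' @param path Output TSV path.
#' @return \code{writePrimerTable} returns \code{path} invisibly;
#'   \code{readPrimerTable} returns the pair table as a data.frame
#'   with 0-based coordinates.
#' @export
writePrimerTable <- function(panel, path) {
    pairs <- if (methods::is(panel, "PrimerPanel")) panelPairs(panel) else panel
    header <- if (methods::is(panel, "PrimerPanel"))
        paste0("# constraints: ",
               jsonlite::toJSON(constraintsAsList(panel@constraints),
                                auto_unbox = TRUE)) else
        "# constraints: unknown"
    out <- pairs
    if (nrow(out)) {
        out$fwd_start <- out$fwd_start + 1L
        out$rev_start <- out$rev_start + 1L
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    suppressWarnings(write.table(out, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE, col.names = TRUE))
    invisible(path)
}

#' @rdname writePrimerTable
#' @export
readPrimerTable <- function(path) {
    out <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    if (nrow(out)) {
        out$fwd_start <- out$fwd_start - 1L
        out$rev_start <- out$rev_start - 1L
    }
    out
}

#' Export panel primers as FASTA
#'
#' One record per primer, ids \code{PPn_F} / \code{PPn_R}.
#'
#' @param panel A [PrimerPanel-class] or pair table.
#' @param path Output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writePrimerFasta <- function(panel, path) {
    pairs <- if (methods::is(panel, "PrimerPanel")) panelPairs(panel) else panel
    seqs <- c(setNames(pairs$fwd_seq, paste0(pairs$pair_id, "_F")),
              setNames(pairs$rev_seq, paste0(pairs$pair_id, "_R")))
    ord <- as.vector(rbind(paste0(pairs$pair_id, "_F"),
                           paste0(pairs$pair_id, "_R")))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs[ord]), path)
    invisible(path)
}

#' Append 5' overhang adapters to panel primers
#'
#' Prepends constant overhang adapters (for instance the Illumina
#' two-step amplicon library overhangs) to the 5' end of every primer
#' and returns synthesis-ready sequences.  Overhangs are never used in
#' melting-temperature or matching computations; this is a pure export
#' step.
#'
#' @param pairs A pair table ([panelPairs()]) or [PrimerPanel-class].
#' @param fwdOverhang,revOverhang Constant 5' adapter strings (plain
#'   or IUPAC; empty string for none).
#' @return A named character vector of synthesis sequences, ids
#'   \code{PPn_F} / \code{PPn_R}.
#' @export
attachOverhangs <- function(pairs,
                            fwdOverhang = "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG",
                            revOverhang = "GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG") {
    if (methods::is(pairs, "PrimerPanel")) pairs <- panelPairs(pairs)
    for (ov in c(fwdOverhang, revOverhang)) {
        if (nchar(ov))
            .validateIupacChars(strsplit(.normalizeIupac(ov), "")[[1L]],
                                what = "overhang")
    }
    c(setNames(paste0(fwdOverhang, pairs$fwd_seq),
               paste0(pairs$pair_id, "_F")),
      setNames(paste0(revOverhang, pairs$rev_seq),
               paste0(pairs$pair_id, "_R")))
}

#' Serialize constraints to a plain list
#'
#' @param constraints A [PrimerConstraints-class].
#' @return Named list of all constraint fields (suitable for JSON or
#'   YAML round-tripping via [constraintsFromList()]).
#' @export
constraintsAsList <- function(constraints) {
    list(tmOpt = constraints@tmOpt, tmMin = constraints@tmMin,
         tmMax = constraints@tmMax, lenOpt = constraints@lenOpt,
         lenMin = constraints@lenMin, lenMax = constraints@lenMax,
         maxDegeneratePositions = constraints@maxDegeneratePositions,
         maxDegeneracy = constraints@maxDegeneracy,
         targetWindow = constraints@targetWindow,
         windowUnits = constraints@windowUnits,
         productMin = constraints@productMin,
         productMax = constraints@productMax,
         pairTmMaxDiff = constraints@pairTmMaxDiff,
         saltMolar = constraints@saltMolar,
         oligoMolar = constraints@oligoMolar,
         allowDegenerate3Prime = constraints@allowDegenerate3Prime)
}

#' @rdname constraintsAsList
#' @param fields Named list (e.g. parsed from YAML/JSON config); any
#'   missing field keeps its default.
#' @export
constraintsFromList <- function(fields) {
    do.call(primerConstraints,
            fields[intersect(names(fields),
                             names(formals(primerConstraints)))])
}

#' Read a run configuration file
#'
#' YAML or JSON file whose fields are [primerConstraints()] arguments
#' plus optional \code{strictFraction} / \code{relaxedFraction}
#' mismatch fractions (defaults 0 and 0.10).
#'
#' @param path Config path (\code{.yaml}/\code{.yml} or \code{.json}).
#' @return List with \code{constraints} (a
#'   [PrimerConstraints-class]), \code{strictFraction} and
#'   \code{relaxedFraction}.
#' @export
readRunConfig <- function(path) {
    fields <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::fromJSON(path) else yaml::read_yaml(path)
    list(constraints = constraintsFromList(fields),
         strictFraction = fields$strictFraction %||% 0,
         relaxedFraction = fields$relaxedFraction %||% 0.10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a coverage report as JSON
#'
#' @param panel A [PrimerPanel-class].
#' @param collection The [TargetCollection-class] it covers.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeCoverageJson <- function(panel, collection, path) {
    cov <- panelCoverageMap(panel)
    report <- list(
        constraints = constraintsAsList(panel@constraints),
        nPairs = length(panel),
        nTargets = length(collection),
        covered = sort(coveredTargets(panel), method = "radix"),
        undesignable = undesignableTargets(panel),
        outgroupOnly = outgroupOnlyTargets(panel),
        coverageFraction =
            length(coveredTargets(panel)) / length(collection),
        abundanceWeightedCoverage =
            abundanceWeightedCoverage(panel, collection),
        byPair = cov)
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' Read / write an abundance table
#'
#' Two-column TSV \code{id <tab> weight} (header optional on read).
#'
#' @param path TSV path.
#' @return Named numeric vector of weights.
#' @export
readAbundanceTable <- function(path) {
    first <- readLines(path, n = 1L)
    has_header <- !grepl("\t[0-9.eE+-]+$", first)
    tab <- read.delim(path, header = has_header,
                      stringsAsFactors = FALSE)
    setNames(as.numeric(tab[[2L]]), as.character(tab[[1L]]))
}

#' @rdname readAbundanceTable
#' @param abundance Named numeric vector.
#' @export
writeAbundanceTable <- function(abundance, path) {
    write.table(data.frame(id = names(abundance), weight = abundance),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a target collection from FASTA files
#'
#' @param cdsFasta Unaligned CDS FASTA.
#' @param alignmentFasta Aligned protein FASTA over the same ids.
#' @param abundanceTsv Optional abundance TSV
#'   ([readAbundanceTable()]); default weight 1.
#' @param outgroupIds Optional file with one outgroup id per line, or
#'   a character vector.
#' @return A [TargetCollection-class].
#' @export
readTargetCollection <- function(cdsFasta, alignmentFasta,
                                 abundanceTsv = NULL,
                                 outgroupIds = character()) {
    cds <- Biostrings::readDNAStringSet(cdsFasta)
    pal <- Biostrings::readAAStringSet(alignmentFasta)
    names(cds) <- sub("\\s.*$", "", names(cds))
    names(pal) <- sub("\\s.*$", "", names(pal))
    abund <- if (!is.null(abundanceTsv)) readAbundanceTable(abundanceTsv)
             else NULL
    og <- if (length(outgroupIds) == 1L && file.exists(outgroupIds))
        readLines(outgroupIds) else as.character(outgroupIds)
    TargetCollection(cds, pal, abundance = abund, outgroup = og)
}
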