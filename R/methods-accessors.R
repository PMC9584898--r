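#' @describeIn PhosphoProteome-class Number of entries.
#' @export
setMethod("length", "PhosphoProteome", function(x) length(x@sequences))

#' @describeIn PhosphoProteome-class The sequences as an [Biostrings::AAStringSet],
#'   named by primary accession.
#' @export
setMethod("sequences", "PhosphoProteome", function(x) x@sequences)

#' @describeIn PhosphoProteome-class Per-entry metadata as a
#'   [S4Vectors::DataFrame].
#' @export
setMethod("entryData", "PhosphoProteome", function(x) x@entryData)

#' @describeIn PhosphoProteome-class Annotated phosphosites as a
#'   [S4Vectors::DataFrame] (`accession`, `position`, `residue`, `kind`).
#' @export
setMethod("phosphoSites", "PhosphoProteome", function(x) x@sites)

#' @describeIn PhosphoProteome-class Subcellular-location phrases per entry.
#' @export
setMethod("subcellularLocations", "PhosphoProteome", function(x) x@locations)

#' @describeIn PhosphoProteome-class Parse diagnostics: a `data.frame` with
#'   columns `record` (1-based index of the `//`-separated record in the
#'   input), `id`, `type` (`"rejected"` or `"site_dropped"`) and `reason`.
#' @export
setMethod("parseReport", "PhosphoProteome", function(x) x@report)

#' @describeIn PhosphoProteome-class Subset entries by index, accession or
#'   logical mask; sites and locations follow their entries.
#' @param i Index vector.
#' @param j,drop,... Ignored (matrix-style subsetting is not supported).
#' @export
setMethod("[", "PhosphoProteome", function(x, i, j, ..., drop = TRUE) {
    acc <- as.character(x@entryData$accession)
    if (is.character(i)) i <- match(i, acc)
    ed <- x@entryData[i, , drop = FALSE]
    keep <- as.character(ed$accession)
    st <- x@sites[x@sites$accession %in% keep, , drop = FALSE]
    new("PhosphoProteome",
        sequences = x@sequences[i],
        entryData = ed,
        sites     = st,
        locations = x@locations[i],
        report    = x@report)
})

setMethod("show", "PhosphoProteome", function(object) {
    tx <- table(object@entryData$organismTaxon, useNA = "ifany")
    cat("PhosphoProteome with", length(object), "entries and",
        nrow(object@sites), "annotated phosphosites\n")
    if (length(tx))
        cat("  organisms (taxon: entries):",
            paste(sprintf("%s: %d", names(tx), as.integer(tx)), collapse = ", "),
            "\n")
    if (nrow(object@report))
        cat("  parse diagnostics:", nrow(object@report),
            "record(s); see parseReport()\n")
})

#' @describeIn PeptideWindow-class In-sequence residue text.
#' @export
setMethod("windowResidues", "PeptideWindow", function(x) x@residues)

#' @describeIn PeptideWindow-class 1-based source position of the phosphosite.
#' @export
setMethod("centerPos", "PeptideWindow", function(x) x@centerPos)

#' @describeIn PeptideWindow-class The residue at the window center.
#' @export
setMethod("centerResidue", "PeptideWindow", function(x) {
    total <- x@leftMissing + nchar(x@residues) + x@rightMissing
    idx <- (total - 1L) %/% 2L + 1L - x@leftMissing
    substring(x@residues, idx, idx)
})

#' @describeIn PeptideWindow-class Window positions before residue 1.
#' @export
setMethod("leftMissing", "PeptideWindow", function(x) x@leftMissing)

#' @describeIn PeptideWindow-class Window positions beyond the C-terminus.
#' @export
setMethod("rightMissing", "PeptideWindow", function(x) x@rightMissing)

#' @describeIn PeptideWindow-class Whether the window reaches the final residue.
#' @export
setMethod("isCTerminal", "PeptideWindow", function(x) x@cTerminal)

setMethod("show", "PeptideWindow", function(object) {
    cat("PeptideWindow ", formatWindow(object),
        " (center ", object@centerPos,
        if (object@cTerminal) ", C-terminal" else "", ")\n", sep = "")
})

#' @describeIn SeedFragment-class The seed label, e.g. `"S129"`.
#' @export
setMethod("seedId", "SeedFragment", function(x) x@seedId)

#' @describeIn SeedFragment-class The underlying [PeptideWindow-class].
#' @export
setMethod("seedWindow", "SeedFragment", function(x) x@window)

#' @describeIn SeedFragment-class Windows of seeds delegate to the fragment's
#'   window.
#' @export
setMethod("windowResidues", "SeedFragment", function(x) x@window@residues)

#' @describeIn SeedFragment-class Center position of the seed window.
#' @export
setMethod("centerPos", "SeedFragment", function(x) x@window@centerPos)

#' @describeIn SeedFragment-class Center residue of the seed window.
#' @export
setMethod("centerResidue", "SeedFragment", function(x) centerResidue(x@window))

setMethod("show", "SeedFragment", function(object) {
    cat("SeedFragment ", object@seedId, " [", object@sourceName, "] ",
        formatWindow(object@window), "\n", sep = "")
})

setMethod("show", "SimilarityRule", function(object) {
    cat("SimilarityRule:", nrow(object@matrix), "x", ncol(object@matrix),
        "substitution matrix, similar iff score >", object@threshold, "\n")
})
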