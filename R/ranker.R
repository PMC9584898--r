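#' Rank candidate hits by the five-key comparator
#'
#' Orders hits by: longest continuous exact-match stretch (descending), then
#' longest exact+similar stretch (descending), then number of exact matches
#' (descending), then number of similar matches (descending), then molecular
#' weight. The weight direction is configurable (ascending by default); a
#' final tie-break on accession and site position makes the order total and
#' byte-reproducible. Ranks are assigned 1..n within each
#' (seed, organism) group.
#'
#' @param hits Hit `data.frame` from [scanProteome()].
#' @param mwDirection `"ascending"` (default) or `"descending"`.
#' @return The hits reordered (seed, then organism, then rank), with a
#'   `rank` column added.
#' @export
rankHits <- function(hits, mwDirection = c("ascending", "descending")) {
    mwDirection <- match.arg(mwDirection)
    if (nrow(hits) == 0L) {
        hits$rank <- integer(0)
        return(hits)
    }
    mwKey <- if (mwDirection == "ascending") hits$mwDa else -hits$mwDa
    o <- order(hits$seedId, hits$organismTaxon,
               -hits$exactStretch, -hits$exactOrSimilarStretch,
               -hits$nExact, -hits$nSimilar, mwKey,
               hits$accession, hits$position, method = "radix")
    out <- hits[o, , drop = FALSE]
    grp <- paste(out$seedId, out$organismTaxon, sep = "\r")
    out$rank <- stats::ave(seq_len(nrow(out)), grp,
                           FUN = seq_along)
    rownames(out) <- NULL
    out
}

## Internal: matching key of a hit for cross-organism comparison — the gene
## name, case-folded, falling back to the entry-name stem (text before the
## "_" organism suffix) when no gene name is recorded.
.proteinKey <- function(hits) {
    key <- toupper(hits$geneName)
    stem <- toupper(sub("_.*$", "", hits$entryName))
    ifelse(is.na(key) | !nzchar(key), stem, key)
}

#' Cross-organism commonality of candidate proteins
#'
#' A protein is "common" to both organisms for a seed when a case-insensitive
#' gene-name match exists between a human hit and a mouse hit of that seed
#' (proteins without gene names are matched on the entry-name stem before
#' the `_` organism suffix). Reported both per seed and over the union of
#' all seeds.
#'
#' @param humanHits,mouseHits Hit `data.frame`s from [scanProteome()] for
#'   the two organism groups.
#' @return A list with `perSeed` (named list of common key sets),
#'   `sizes` (named integer vector), `union` (common keys over all seeds)
#'   and `unionSize`.
#' @export
commonAcrossOrganisms <- function(humanHits, mouseHits) {
    seedsSeen <- sort(unique(c(humanHits$seedId, mouseHits$seedId)))
    perSeed <- lapply(seedsSeen, function(s) {
        h <- .proteinKey(humanHits[humanHits$seedId == s, , drop = FALSE])
        m <- .proteinKey(mouseHits[mouseHits$seedId == s, , drop = FALSE])
        sort(intersect(h, m))
    })
    names(perSeed) <- seedsSeen
    uni <- sort(intersect(.proteinKey(humanHits), .proteinKey(mouseHits)))
    list(perSeed = perSeed,
         sizes = vapply(perSeed, length, integer(1)),
         union = uni,
         unionSize = length(uni))
}

#' Read a presence list (plasma / CSF)
#'
#' One identifier (accession or gene symbol) per line; blank lines and `#`
#' comments are ignored. Matching downstream is case-insensitive.
#'
#' @param path Text file path.
#' @return Character vector of identifiers.
#' @export
readPresenceList <- function(path) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines[nzchar(lines)]
}

#' Biofluid overlap of candidate proteins
#'
#' Counts how many distinct candidate proteins (deduplicated by accession
#' across all seeds) appear in a user-supplied presence list, matching
#' case-insensitively against the primary accession, secondary accessions
#' (when a proteome is supplied) and then the gene name.
#'
#' @param hits Hit `data.frame` from [scanProteome()] (any subset).
#' @param presence Character vector of identifiers, e.g. from
#'   [readPresenceList()].
#' @param label Group label for the summary row, e.g. `"plasma"`.
#' @param proteome Optional [PhosphoProteome-class] used to also match
#'   secondary accessions.
#' @return A one-row `data.frame`: `label`, `total`, `present`,
#'   `percentage` (present/total x 100, two decimals; 0 with a warning when
#'   there are no candidate proteins).
#' @export
annotateBiofluids <- function(hits, presence, label = "biofluid",
                              proteome = NULL) {
    accs <- unique(hits$accession)
    total <- length(accs)
    if (total == 0L) {
        warning("no candidate proteins; overlap percentage undefined, ",
                "reported as 0", call. = FALSE)
        return(data.frame(label = label, total = 0L, present = 0L,
                          percentage = 0, stringsAsFactors = FALSE))
    }
    pres <- toupper(presence)
    gene <- toupper(hits$geneName[match(accs, hits$accession)])
    hit <- toupper(accs) %in% pres | (nzchar(gene) & gene %in% pres)
    if (!is.null(proteome)) {
        ed <- entryData(proteome)
        sec <- ed$secondaryAccessions[match(accs, ed$accession)]
        hit <- hit | vapply(seq_along(accs), function(i) {
            s <- unlist(sec[i])
            length(s) > 0L && any(toupper(s) %in% pres)
        }, logical(1))
    }
    present <- sum(hit)
    data.frame(label = label, total = total, present = present,
               percentage = round(100 * present / total, 2),
               stringsAsFactors = FALSE)
}
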