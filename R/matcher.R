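## Internal: residues of a window as a character vector over offsets
## -h..+h, with NA at positions outside the source sequence.
.windowChars <- function(x) {
    if (is(x, "SeedFragment")) x <- x@window
    total <- x@leftMissing + nchar(x@residues) + x@rightMissing
    out <- rep(NA_character_, total)
    idx <- seq(x@leftMissing + 1L, total - x@rightMissing)
    out[idx] <- strsplit(x@residues, "")[[1]]
    out
}

#' Anchor filter: perfect flank matches around the phosphosite
#'
#' The screen's only hard constraint: the residues immediately preceding and
#' following the phosphosite must match the seed exactly. A candidate whose
#' window is missing either flank (a site at the first or last residue of
#' its protein) fails automatically. The center residue itself is not
#' required to match.
#'
#' @param seed A [SeedFragment-class] (or [PeptideWindow-class]).
#' @param candidate A [PeptideWindow-class].
#' @return `TRUE` iff both the -1 and +1 offsets are identical residues.
#' @examples
#' s129 <- aSynSeeds()[["S129"]]
#' anchorsMatch(s129, extractWindow(aSynSequence("mouse"), 129))  # TRUE
#' @export
anchorsMatch <- function(seed, candidate) {
    a <- .windowChars(seed)
    b <- .windowChars(candidate)
    stopifnot(length(a) == length(b))
    c0 <- (length(a) + 1L) %/% 2L
    at <- c(c0 - 1L, c0 + 1L)
    all(!is.na(a[at]) & !is.na(b[at]) & a[at] == b[at])
}

#' Compare two phosphosite-centered windows
#'
#' Aligns the candidate to the seed center-to-center (offsets -h..+h, no
#' gaps) and computes the four match statistics:
#' \describe{
#'   \item{nExact}{aligned positions with identical residues.}
#'   \item{nSimilar}{aligned, non-identical positions whose substitution
#'     score is strictly greater than the rule threshold. Identical pairs
#'     are counted once, as exact, never as similar.}
#'   \item{exactStretch}{length of the longest run of consecutive
#'     exactly-matching positions that contains the center; 0 when the
#'     center residues differ.}
#'   \item{exactOrSimilarStretch}{the same under the exact-or-similar
#'     predicate.}
#' }
#' A position where either window is missing (terminus truncation) is
#' neither exact nor similar and breaks both stretches.
#'
#' @param seed A [SeedFragment-class] or [PeptideWindow-class].
#' @param candidate A [PeptideWindow-class] (or [SeedFragment-class]).
#' @param rule A [SimilarityRule-class]; default PAM120 with threshold 1.
#' @return Named integer vector
#'   `c(nExact, nSimilar, exactStretch, exactOrSimilarStretch)`.
#' @examples
#' s129 <- aSynSeeds()[["S129"]]
#' compareWindows(s129, seedWindow(s129))  # identity: 13, 0, 13, 13
#' @export
compareWindows <- function(seed, candidate, rule = similarityRule()) {
    a <- .windowChars(seed)
    b <- .windowChars(candidate)
    if (length(a) != length(b))
        stop("windows have different widths (", length(a), " vs ", length(b),
             ")", call. = FALSE)
    n <- length(a)
    c0 <- (n + 1L) %/% 2L
    aligned <- !is.na(a) & !is.na(b)
    exact <- aligned & a == b
    similar <- rep(FALSE, n)
    cand <- aligned & !exact
    if (any(cand))
        similar[cand] <- .ruleScore(rule, a[cand], b[cand]) > rule@threshold
    stretchAround <- function(ok) {
        if (!ok[c0]) return(0L)
        lo <- c0
        while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
        hi <- c0
        while (hi < n && ok[hi + 1L]) hi <- hi + 1L
        hi - lo + 1L
    }
    c(nExact = sum(exact), nSimilar = sum(similar),
      exactStretch = stretchAround(exact),
      exactOrSimilarStretch = stretchAround(exact | similar))
}

#' Scan a proteome's phosphosites against a set of seeds
#'
#' For every (seed, entry, annotated phosphosite) triple, extracts the
#' candidate window centered on the site and emits one hit iff the anchor
#' filter passes. Every annotated site is tested against every seed
#' regardless of site kind (the anchor filter and the metrics decide), and a
#' seed's own source protein is not excluded. Duplicate annotations at one
#' position were already collapsed on ingest; one protein may still appear
#' multiple times per seed via distinct sites.
#'
#' @param seeds List of [SeedFragment-class] (e.g. [aSynSeeds()]).
#' @param proteome A [PhosphoProteome-class], already filtered to the
#'   organisms of interest.
#' @param rule A [SimilarityRule-class]; default PAM120, threshold 1.
#' @param strictCenter When `TRUE`, additionally require the candidate's
#'   central residue to be the same amino acid as the seed's (off by
#'   default: the screen constrains only the flanking residues).
#' @return A `data.frame` with one row per hit: `seedId`, `accession`,
#'   `entryName`, `geneName`, `organismTaxon`, `position`, `residue`,
#'   `kind`, `window` (display string, `-`/`*` padding), `nExact`,
#'   `nSimilar`, `exactStretch`, `exactOrSimilarStretch`, `mwDa`.
#'   Use `split(hits, hits$seedId)` for a per-seed view.
#' @examples
#' prot <- proteinEntry("SYUA_HUMAN", "P37840", aSynSequence("human"), 9606,
#'                      geneName = "SNCA",
#'                      sites = data.frame(position = c(87, 125, 129),
#'                                         kind = c("phosphoserine",
#'                                                  "phosphotyrosine",
#'                                                  "phosphoserine")))
#' hits <- scanProteome(aSynSeeds(), prot)
#' hits$seedId   # "S87" "Y125" "S129"
#' @export
scanProteome <- function(seeds, proteome, rule = similarityRule(),
                         strictCenter = FALSE) {
    stopifnot(is(proteome, "PhosphoProteome"))
    if (is(seeds, "SeedFragment")) seeds <- list(seeds)
    ed <- proteome@entryData
    st <- proteome@sites
    rows <- list()
    seedChars <- lapply(seeds, .windowChars)
    widths <- unique(vapply(seedChars, length, integer(1)))
    if (length(widths) > 1L)
        stop("all seeds must share one window width", call. = FALSE)
    halfWidth <- (widths - 1L) %/% 2L
    seqs <- as.character(proteome@sequences)
    for (k in seq_len(nrow(st))) {
        acc <- st$accession[k]
        ei <- match(acc, ed$accession)
        w <- extractWindow(seqs[[ei]], st$position[k], halfWidth = halfWidth,
                           name = ed$entryName[ei])
        for (s in seeds) {
            if (!anchorsMatch(s, w)) next
            if (strictCenter && centerResidue(s) != centerResidue(w)) next
            m <- compareWindows(s, w, rule)
            rows[[length(rows) + 1L]] <- data.frame(
                seedId = s@seedId, accession = acc,
                entryName = ed$entryName[ei], geneName = ed$geneName[ei],
                organismTaxon = ed$organismTaxon[ei],
                position = st$position[k], residue = st$residue[k],
                kind = st$kind[k], window = formatWindow(w),
                nExact = m[["nExact"]], nSimilar = m[["nSimilar"]],
                exactStretch = m[["exactStretch"]],
                exactOrSimilarStretch = m[["exactOrSimilarStretch"]],
                mwDa = ed$mwDa[ei], stringsAsFactors = FALSE)
        }
    }
    if (!length(rows)) return(.emptyHits())
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

.emptyHits <- function() {
    data.frame(seedId = character(0), accession = character(0),
               entryName = character(0), geneName = character(0),
               organismTaxon = integer(0), position = integer(0),
               residue = character(0), kind = character(0),
               window = character(0), nExact = integer(0),
               nSimilar = integer(0), exactStretch = integer(0),
               exactOrSimilarStretch = integer(0), mwDa = integer(0),
               stringsAsFactors = FALSE)
}
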