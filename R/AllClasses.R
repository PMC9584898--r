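#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges CharacterList
#' @importFrom Biostrings AAStringSet width
NULL

## Residue alphabet admitted on ingest: the 20 standard one-letter codes plus
## the ambiguity/rare codes the flat-file format permits. Codes outside the
## scoring table (X, U, O) are never counted as similar.
.AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
.AA_ALLOWED <- c(.AA_STANDARD, "B", "Z", "X", "U", "O")

## Characters used only for display/padding of terminus-truncated windows;
## they never participate in scoring.
.PAD_CHARS <- c("-", "*", ".", " ")

#' Container for a set of reviewed proteome entries with phosphosites
#'
#' A `PhosphoProteome` holds the parsed content of one or more UniProtKB-style
#' flat-text records: the amino-acid sequences, per-entry metadata (entry name,
#' accession, gene, organism, molecular weight), the annotated phosphoserine /
#' phosphotyrosine sites, and any subcellular-location phrases. Entries are
#' indexed by primary accession throughout.
#'
#' @slot sequences [Biostrings::AAStringSet] named by primary accession.
#' @slot entryData [S4Vectors::DataFrame] with one row per entry and columns
#'   `entryName`, `accession`, `geneName` (may be `""`), `organismTaxon`
#'   (integer NCBI taxon id; `NA` when the record states none), `mwDa`
#'   (integer Daltons from the SQ header) and `secondaryAccessions`
#'   (a [IRanges::CharacterList]).
#' @slot sites [S4Vectors::DataFrame] with columns `accession`, `position`
#'   (1-based), `residue` (`"S"` or `"Y"`) and `kind` (`"phosphoserine"` or
#'   `"phosphotyrosine"`).
#' @slot locations [IRanges::CharacterList] of subcellular-location phrases,
#'   named by primary accession.
#' @slot report `data.frame` of per-record parse diagnostics (rejected records
#'   and dropped sites); see [parseReport()].
#'
#' @seealso [parseFlatFile()], [proteinEntry()], [scanProteome()]
#' @export
setClass("PhosphoProteome",
    slots = c(
        sequences = "AAStringSet",
        entryData = "DataFrame",
        sites     = "DataFrame",
        locations = "CharacterList",
        report    = "data.frame"
    )
)

setValidity("PhosphoProteome", function(object) {
    ed <- object@entryData
    need <- c("entryName", "accession", "geneName", "organismTaxon", "mwDa",
              "secondaryAccessions")
    if (!all(need %in% colnames(ed)))
        return(paste("entryData must have columns:", paste(need, collapse = ", ")))
    acc <- ed$accession
    if (length(object@sequences) != nrow(ed))
        return("sequences and entryData disagree on entry count")
    if (nrow(ed) > 0L) {
        if (anyDuplicated(acc))
            return("duplicated primary accessions")
        if (!identical(names(object@sequences), as.character(acc)))
            return("sequences must be named by primary accession, in entry order")
        if (!identical(names(object@locations), as.character(acc)))
            return("locations must be named by primary accession, in entry order")
        if (any(width(object@sequences) == 0L))
            return("empty sequence")
        letters <- unique(unlist(strsplit(as.character(object@sequences), "")))
        bad <- setdiff(letters, .AA_ALLOWED)
        if (length(bad))
            return(paste("sequence letters outside the permitted alphabet:",
                         paste(bad, collapse = "")))
    }
    st <- object@sites
    needS <- c("accession", "position", "residue", "kind")
    if (!all(needS %in% colnames(st)))
        return(paste("sites must have columns:", paste(needS, collapse = ", ")))
    if (nrow(st) > 0L) {
        if (!all(st$accession %in% acc))
            return("site accession not present among entries")
        w <- width(object@sequences)[match(st$accession, acc)]
        if (any(st$position < 1L | st$position > w))
            return("phosphosite position outside [1, length(sequence)]")
        obs <- substring(as.character(object@sequences[match(st$accession, acc)]),
                         st$position, st$position)
        if (!all(obs == st$residue))
            return("recorded phosphosite residue disagrees with the sequence")
        okKind <- (st$kind == "phosphoserine" & st$residue == "S") |
                  (st$kind == "phosphotyrosine" & st$residue == "Y")
        if (!all(okKind))
            return("phosphosite kind inconsistent with residue (S/phosphoserine, Y/phosphotyrosine)")
    }
    TRUE
})

#' A phosphosite-centered peptide window
#'
#' The elementary object of the screen: a window of `2 * halfWidth + 1`
#' positions centered on a phosphosite. Positions that fall before residue 1
#' or beyond the C-terminus of the source sequence are recorded as missing
#' counts rather than padded into the residue text, so the stored residues are
#' always genuine sequence.
#'
#' @slot residues Amino-acid text of the in-sequence part of the window.
#' @slot centerPos 1-based position of the phosphosite in the source sequence.
#' @slot leftMissing Number of window positions before residue 1.
#' @slot rightMissing Number of window positions beyond the C-terminus.
#' @slot cTerminal `TRUE` when the window reaches the final residue of the
#'   source sequence.
#'
#' @seealso [extractWindow()], [formatWindow()]
#' @export
setClass("PeptideWindow",
    slots = c(
        residues     = "character",
        centerPos    = "integer",
        leftMissing  = "integer",
        rightMissing = "integer",
        cTerminal    = "logical"
    )
)

setValidity("PeptideWindow", function(object) {
    if (length(object@residues) != 1L || is.na(object@residues) ||
        nchar(object@residues) == 0L)
        return("residues must be a single non-empty string")
    if (object@leftMissing < 0L || object@rightMissing < 0L)
        return("missing counts must be non-negative")
    total <- object@leftMissing + nchar(object@residues) + object@rightMissing
    if (total %% 2L != 1L)
        return("total window width must be odd (a center flanked symmetrically)")
    h <- (total - 1L) %/% 2L
    centerIdx <- h + 1L - object@leftMissing
    if (centerIdx < 1L || centerIdx > nchar(object@residues))
        return("center falls outside the in-sequence residues")
    TRUE
})

#' A query fragment: one seed window with its label
#'
#' A `SeedFragment` pairs a [PeptideWindow-class] with a seed label of the
#' form `<residue><position>` (for example `"S129"`), as used for the six
#' default alpha-synuclein fragments.
#'
#' @slot seedId Label `<residue><position>`; its residue letter must equal the
#'   window's center residue.
#' @slot window The [PeptideWindow-class].
#' @slot sourceName Name of the source entry (for example `"SYUA_HUMAN"`).
#'
#' @seealso [buildSeedSet()], [aSynSeeds()]
#' @export
setClass("SeedFragment",
    slots = c(
        seedId     = "character",
        window     = "PeptideWindow",
        sourceName = "character"
    )
)

setValidity("SeedFragment", function(object) {
    if (length(object@seedId) != 1L || !grepl("^[A-Z][0-9]+$", object@seedId))
        return("seedId must look like <residue><position>, e.g. 'S129'")
    if (substring(object@seedId, 1L, 1L) != centerResidue(object@window))
        return("seedId residue letter must equal the window's center residue")
    TRUE
})

#' Similarity rule: substitution matrix plus strict threshold
#'
#' Defines "high similarity" between two aligned, non-identical residues: a
#' substitution-matrix score strictly greater than `threshold`. The default
#' rule uses the standard PAM120 matrix with threshold 1, under which for
#' example Glu/Gln (score 2) and Tyr/Phe (score 4) are similar while Ile/Leu
#' (score 1) and Ile/Phe (score 0) are not.
#'
#' @slot matrix Symmetric integer score matrix over residue one-letter codes.
#' @slot threshold Integer; a pair is similar iff its score is `> threshold`.
#'
#' @seealso [similarityRule()], [pam120Score()]
#' @export
setClass("SimilarityRule",
    slots = c(matrix = "matrix", threshold = "integer")
)

setValidity("SimilarityRule", function(object) {
    m <- object@matrix
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
        return("matrix must have identical row and column residue names")
    if (!isSymmetric(unname(m)))
        return("substitution matrix must be symmetric")
    if (length(object@threshold) != 1L || is.na(object@threshold))
        return("threshold must be a single integer")
    TRUE
})
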