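#' Extract a phosphosite-centered peptide window
#'
#' Cuts the window of `2 * halfWidth + 1` positions centered on `position`
#' out of `sequence`. Positions before residue 1 or beyond the C-terminus are
#' counted in `leftMissing` / `rightMissing`; the stored residue text is only
#' genuine sequence. The `cTerminal` flag is set when the window reaches the
#' final residue of the sequence.
#'
#' @param sequence Amino-acid text (single string) or an [Biostrings::AAString].
#' @param position 1-based center position; must lie within the sequence.
#' @param halfWidth Residues on each side of the center; default 6 (13-mer).
#' @param name Optional entry name used in error messages.
#' @return A [PeptideWindow-class].
#' @examples
#' w <- extractWindow(aSynSequence("human"), 129)
#' windowResidues(w)   # "EAYEMPSEEGYQD"
#' @export
extractWindow <- function(sequence, position, halfWidth = 6L, name = NULL) {
    sequence <- as.character(sequence)
    stopifnot(length(sequence) == 1L)
    n <- nchar(sequence)
    position <- as.integer(position)
    if (is.na(position) || position < 1L || position > n)
        stop("position ", position, " out of range [1, ", n, "]",
             if (!is.null(name)) paste0(" for entry ", name), call. = FALSE)
    halfWidth <- as.integer(halfWidth)
    lo <- position - halfWidth
    hi <- position + halfWidth
    new("PeptideWindow",
        residues     = toupper(substring(sequence, max(1L, lo), min(n, hi))),
        centerPos    = position,
        leftMissing  = max(0L, 1L - lo),
        rightMissing = max(0L, hi - n),
        cTerminal    = hi >= n)
}

#' Render a window for display
#'
#' Terminus-truncated windows are padded to full width: `"-"` for positions
#' outside the sequence, with a `"*"` marking the C-terminal boundary when the
#' window runs past the last residue (the convention used to display the
#' C-terminal alpha-synuclein seed). Padding characters never participate in
#' scoring.
#'
#' @param x A [PeptideWindow-class] or [SeedFragment-class].
#' @return A single string of the full window width.
#' @examples
#' formatWindow(extractWindow(aSynSequence("human"), 136))  # "EEGYQDYEPEA*-"
#' @export
formatWindow <- function(x) {
    if (is(x, "SeedFragment")) x <- x@window
    stopifnot(is(x, "PeptideWindow"))
    right <- if (x@cTerminal && x@rightMissing > 0L)
        paste0("*", strrep("-", x@rightMissing - 1L))
    else strrep("-", x@rightMissing)
    paste0(strrep("-", x@leftMissing), x@residues, right)
}

#' Build a set of seed fragments
#'
#' Constructs one [SeedFragment-class] per position, labeled
#' `<residue><position>`. A seed must be centered on a phosphorylatable
#' residue (serine or tyrosine).
#'
#' @param sequence Source amino-acid sequence (single string).
#' @param positions Integer vector of 1-based phosphosite positions.
#' @param sourceName Label of the source entry, e.g. `"SYUA_HUMAN"`.
#' @param halfWidth Window half-width; default 6.
#' @return A list of [SeedFragment-class] objects, named by seed id.
#' @examples
#' seeds <- buildSeedSet(aSynSequence("human"), c(125, 129))
#' names(seeds)  # "Y125" "S129"
#' @export
buildSeedSet <- function(sequence, positions, sourceName = "SEED",
                         halfWidth = 6L) {
    sequence <- as.character(sequence)
    positions <- as.integer(positions)
    out <- lapply(positions, function(p) {
        res <- substring(sequence, p, p)
        if (!res %in% c("S", "Y"))
            stop("seed center at position ", p, " is '", res,
                 "', not a phosphorylatable S or Y", call. = FALSE)
        w <- extractWindow(sequence, p, halfWidth = halfWidth, name = sourceName)
        new("SeedFragment", seedId = paste0(res, p), window = w,
            sourceName = sourceName)
    })
    names(out) <- vapply(out, seedId, character(1))
    out
}

#' The six default alpha-synuclein seed fragments
#'
#' The 13-mer windows centered on Y39, S87, Y125, S129, Y133 and Y136 of
#' canonical human alpha-synuclein — the epitope regions of antibodies raised
#' against the corresponding phosphosite peptides. The Y136 window runs two
#' positions past the C-terminus and is truncated accordingly.
#'
#' @param positions Seed positions; default `c(39, 87, 125, 129, 133, 136)`.
#' @param halfWidth Window half-width; default 6.
#' @return A named list of six [SeedFragment-class] objects.
#' @examples
#' vapply(aSynSeeds(), formatWindow, character(1))
#' @export
aSynSeeds <- function(positions = .ASYN_SEED_POSITIONS, halfWidth = 6L) {
    buildSeedSet(aSynSequence("human"), positions,
                 sourceName = "SYUA_HUMAN", halfWidth = halfWidth)
}

#' Export and import seeds as FASTA
#'
#' Seed FASTA headers carry the seed id and the window geometry
#' (`center_pos`, `left_missing`, `right_missing`, `c_terminal`, `source`)
#' so a truncated seed round-trips exactly; the sequence line holds only the
#' in-sequence residues.
#'
#' @param seeds A list of [SeedFragment-class] objects.
#' @param path Output (or input) file path.
#' @return `writeSeedsFasta` returns `path` invisibly; `readSeedsFasta`
#'   returns a named list of [SeedFragment-class] objects.
#' @export
writeSeedsFasta <- function(seeds, path) {
    lines <- unlist(lapply(seeds, function(s) {
        w <- s@window
        c(sprintf(">%s center_pos=%d left_missing=%d right_missing=%d c_terminal=%s source=%s",
                  s@seedId, w@centerPos, w@leftMissing, w@rightMissing,
                  tolower(as.character(w@cTerminal)), s@sourceName),
          w@residues)
    }))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeSeedsFasta
#' @export
readSeedsFasta <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    out <- lapply(seq_along(hdr), function(k) {
        h <- sub("^>", "", lines[hdr[k]])
        to <- if (k < length(hdr)) hdr[k + 1L] - 1L else length(lines)
        seqtxt <- toupper(gsub("\\s", "", paste(lines[(hdr[k] + 1L):to],
                                                collapse = "")))
        fields <- strsplit(h, "\\s+")[[1]]
        id <- fields[1]
        kv <- strsplit(fields[-1], "=")
        vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                                vapply(kv, `[`, character(1), 1L))
        w <- new("PeptideWindow",
                 residues     = seqtxt,
                 centerPos    = as.integer(vals[["center_pos"]]),
                 leftMissing  = as.integer(vals[["left_missing"]]),
                 rightMissing = as.integer(vals[["right_missing"]]),
                 cTerminal    = identical(vals[["c_terminal"]], "true"))
        new("SeedFragment", seedId = id, window = w,
            sourceName = if ("source" %in% names(vals)) vals[["source"]] else "SEED")
    })
    names(out) <- vapply(out, seedId, character(1))
    out
}
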