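## Average residue masses (Da) for molecular-weight computation, plus water.
## Ambiguity codes use the mean of their members; X uses an average residue.
.AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326,
              U = 150.0388, O = 237.3018,
              B = 114.5962, Z = 128.6231, X = 110.0000)
.WATER_MASS <- 18.01524

#' Average molecular weight of a protein sequence
#'
#' @param sequence Amino-acid text (vectorised).
#' @return Integer Daltons (rounded), as printed in flat-file SQ headers.
#' @examples
#' molecularWeight(aSynSequence("human"))  # 14460
#' @export
molecularWeight <- function(sequence) {
    vapply(as.character(sequence), function(s) {
        chars <- strsplit(toupper(s), "")[[1]]
        as.integer(round(sum(.AA_MASS[chars]) + .WATER_MASS))
    }, integer(1), USE.NAMES = FALSE)
}

.TAXON_OS <- c(`9606` = "Homo sapiens (Human)",
               `10090` = "Mus musculus (Mouse)")

.emptyEntryData <- function() {
    DataFrame(entryName = character(0), accession = character(0),
              geneName = character(0), organismTaxon = integer(0),
              mwDa = integer(0),
              secondaryAccessions = CharacterList())
}

.emptySites <- function() {
    DataFrame(accession = character(0), position = integer(0),
              residue = character(0), kind = character(0))
}

.emptyReport <- function() {
    data.frame(record = integer(0), id = character(0), type = character(0),
               reason = character(0), stringsAsFactors = FALSE)
}

#' Construct a single-entry proteome
#'
#' Convenience constructor for fixtures and tests: builds a
#' [PhosphoProteome-class] holding one entry. Multiple entries are combined
#' with [bindProteomes()].
#'
#' @param entryName Entry name, e.g. `"SYUA_HUMAN"`.
#' @param accession Primary accession.
#' @param sequence Amino-acid text; upper-cased on ingest.
#' @param organismTaxon Integer NCBI taxon id (9606 human, 10090 mouse).
#' @param geneName Gene symbol or `""`.
#' @param mwDa Integer molecular weight; computed from the sequence when `NULL`.
#' @param sites `data.frame` with columns `position` and `kind`
#'   (`"phosphoserine"` / `"phosphotyrosine"`), or `NULL` for none.
#' @param locations Character vector of subcellular-location phrases.
#' @param secondaryAccessions Character vector of secondary accessions.
#' @return A [PhosphoProteome-class] of length 1.
#' @examples
#' e <- proteinEntry("SYUA_HUMAN", "P37840", aSynSequence("human"), 9606,
#'                   geneName = "SNCA",
#'                   sites = data.frame(position = c(87, 125, 129),
#'                                      kind = c("phosphoserine",
#'                                               "phosphotyrosine",
#'                                               "phosphoserine")))
#' @export
proteinEntry <- function(entryName, accession, sequence, organismTaxon = NA,
                         geneName = "", mwDa = NULL, sites = NULL,
                         locations = character(0),
                         secondaryAccessions = character(0)) {
    sequence <- toupper(gsub("[\\s0-9]", "", as.character(sequence), perl = TRUE))
    if (is.null(mwDa)) mwDa <- molecularWeight(sequence)
    if (is.null(sites) || nrow(sites) == 0L) {
        st <- .emptySites()
    } else {
        pos <- as.integer(sites$position)
        st <- DataFrame(accession = rep(accession, length(pos)),
                        position = pos,
                        residue = substring(sequence, pos, pos),
                        kind = as.character(sites$kind))
        st <- st[order(st$position), , drop = FALSE]
    }
    ed <- DataFrame(entryName = entryName, accession = accession,
                    geneName = geneName,
                    organismTaxon = as.integer(organismTaxon),
                    mwDa = as.integer(mwDa),
                    secondaryAccessions = CharacterList(as.character(secondaryAccessions)))
    seqs <- AAStringSet(stats::setNames(sequence, accession))
    loc <- CharacterList(stats::setNames(list(as.character(locations)), accession))
    new("PhosphoProteome", sequences = seqs, entryData = ed, sites = st,
        locations = loc, report = .emptyReport())
}

#' Combine proteomes
#'
#' @param ... [PhosphoProteome-class] objects (or a single list of them).
#' @return One [PhosphoProteome-class]; parse reports are concatenated.
#' @export
bindProteomes <- function(...) {
    xs <- list(...)
    if (length(xs) == 1L && is.list(xs[[1]]) && !is(xs[[1]], "PhosphoProteome"))
        xs <- xs[[1]]
    new("PhosphoProteome",
        sequences = do.call(c, lapply(xs, slot, "sequences")),
        entryData = do.call(rbind, lapply(xs, slot, "entryData")),
        sites     = do.call(rbind, lapply(xs, slot, "sites")),
        locations = do.call(c, lapply(xs, slot, "locations")),
        report    = do.call(rbind, lapply(xs, slot, "report")))
}

## ---------------------------------------------------------------------------
## Parsing
## ---------------------------------------------------------------------------

.splitRecords <- function(lines) {
    ends <- grep("^//", lines)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    recs <- mapply(function(s, e) lines[s:(e - 1L)],
                   starts, ends, SIMPLIFY = FALSE)
    recs[vapply(recs, function(r) any(nzchar(trimws(r))), logical(1))]
}

## Parse the FT block of one record into a data.frame of features.
## Handles both the current layout (location on the key line, description in
## /note continuation lines) and the legacy fixed-column layout with the
## description trailing on the same line.
.parseFeatures <- function(lines) {
    ft <- lines[startsWith(lines, "FT")]
    feats <- list()
    cur <- NULL
    for (ln in ft) {
        keyField <- substr(ln, 6L, 20L)
        body <- trimws(substring(ln, 6L))
        if (nzchar(trimws(keyField))) {
            if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
            toks <- strsplit(body, "\\s+")[[1]]
            cur <- list(key = toks[1],
                        loc = if (length(toks) >= 2L) toks[2] else NA_character_,
                        loc2 = if (length(toks) >= 3L && grepl("^[0-9]+$", toks[3]))
                            toks[3] else NA_character_,
                        note = if (length(toks) >= 3L)
                            paste(toks[if (grepl("^[0-9]+$", toks[3])) -(1:3) else -(1:2)],
                                  collapse = " ") else "")
        } else if (!is.null(cur)) {
            cur$note <- paste0(cur$note, if (nzchar(cur$note)) " " else "", body)
        }
    }
    if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
    feats
}

.featureNote <- function(note) {
    m <- regmatches(note, regexpr('/note="[^"]*"', note))
    if (length(m)) sub('^/note="', "", sub('"$', "", m)) else sub("\\.$", "", note)
}

#' Extract subcellular-location phrases from one flat-text entry
#'
#' Parses the `CC   -!- SUBCELLULAR LOCATION:` paragraph(s) of a single
#' record. Each semicolon- or period-delimited phrase is returned with
#' evidence tags (text in braces or square brackets) stripped; `Note=` free
#' text is dropped. Absence of the paragraph is not an error.
#'
#' @param entryText Character vector of lines (or one string) of one record.
#' @return Character vector of location phrases (possibly empty).
#' @examples
#' parseSubcellularLocations(
#'   "CC   -!- SUBCELLULAR LOCATION: Cytoplasm. Nucleus.")
#' @export
parseSubcellularLocations <- function(entryText) {
    lines <- unlist(strsplit(as.character(entryText), "\n"))
    cc <- startsWith(lines, "CC")
    out <- character(0)
    inPar <- FALSE
    buf <- character(0)
    flush <- function(buf) {
        if (!length(buf)) return(character(0))
        txt <- paste(buf, collapse = " ")
        txt <- gsub("\\{[^}]*\\}", "", txt)   # evidence tags
        txt <- gsub("\\[[^]]*\\]", "", txt)   # isoform/topology brackets
        parts <- trimws(unlist(strsplit(txt, "[.;]")))
        parts <- parts[nzchar(parts)]
        parts[!startsWith(parts, "Note=")]
    }
    for (ln in lines) {
        if (!startsWith(ln, "CC")) {
            if (inPar) { out <- c(out, flush(buf)); inPar <- FALSE; buf <- character(0) }
            next
        }
        body <- substring(ln, 6L)
        if (startsWith(trimws(body), "-!-")) {
            if (inPar) { out <- c(out, flush(buf)); inPar <- FALSE; buf <- character(0) }
            head <- trimws(sub("^\\s*-!-\\s*", "", body))
            if (startsWith(head, "SUBCELLULAR LOCATION:")) {
                inPar <- TRUE
                buf <- sub("^SUBCELLULAR LOCATION:\\s*", "", head)
            }
        } else if (inPar) {
            buf <- c(buf, trimws(body))
        }
    }
    if (inPar) out <- c(out, flush(buf))
    out
}

.parseRecord <- function(rec, idx) {
    fail <- function(id, reason)
        list(entry = NULL,
             report = data.frame(record = idx, id = id, type = "rejected",
                                 reason = reason, stringsAsFactors = FALSE))
    idLine <- rec[startsWith(rec, "ID   ")]
    if (!length(idLine)) return(fail(NA_character_, "missing ID line"))
    entryName <- strsplit(trimws(substring(idLine[1], 6L)), "\\s+")[[1]][1]

    sqAt <- grep("^SQ   ", rec)
    if (!length(sqAt)) return(fail(entryName, "missing SQ line"))
    sqLine <- rec[sqAt[1]]
    sqLen <- as.integer(sub("^SQ\\s+SEQUENCE\\s+(\\d+)\\s+AA.*$", "\\1", sqLine))
    mwDa <- as.integer(sub("^.*?(\\d+)\\s+MW.*$", "\\1", sqLine))
    seqLines <- rec[seq(sqAt[1] + 1L, length(rec))]
    seqLines <- seqLines[startsWith(seqLines, " ")]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
    if (!nzchar(sequence)) return(fail(entryName, "empty sequence block"))
    if (!is.na(sqLen) && nchar(sequence) != sqLen)
        return(fail(entryName, sprintf(
            "sequence length %d disagrees with SQ header (%d AA)",
            nchar(sequence), sqLen)))

    acLines <- rec[startsWith(rec, "AC   ")]
    accs <- unlist(strsplit(gsub(";", "", trimws(substring(acLines, 6L))), "\\s+"))
    accs <- accs[nzchar(accs)]
    if (!length(accs)) return(fail(entryName, "missing AC line"))

    oxLine <- rec[startsWith(rec, "OX   ")]
    taxon <- NA_integer_
    if (length(oxLine)) {
        m <- regmatches(oxLine[1], regexpr("NCBI_TaxID=\\d+", oxLine[1]))
        if (length(m)) taxon <- as.integer(sub("NCBI_TaxID=", "", m))
    }
    if (is.na(taxon)) {
        osLine <- rec[startsWith(rec, "OS   ")]
        if (length(osLine)) {
            os <- paste(trimws(substring(osLine, 6L)), collapse = " ")
            if (grepl("Homo sapiens", os)) taxon <- 9606L
            else if (grepl("Mus musculus", os)) taxon <- 10090L
        }
    }

    gnLine <- rec[startsWith(rec, "GN   ")]
    geneName <- ""
    if (length(gnLine)) {
        m <- regmatches(gnLine[1], regexpr("Name=[^;,]+", gnLine[1]))
        if (length(m))
            geneName <- trimws(gsub("\\{[^}]*\\}", "", sub("Name=", "", m)))
    }

    dropped <- .emptyReport()
    pos <- integer(0); kind <- character(0)
    for (f in .parseFeatures(rec)) {
        if (!identical(f$key, "MOD_RES")) next
        loc <- f$loc
        if (is.na(loc)) next
        if (grepl(":", loc, fixed = TRUE)) next      # isoform-scoped feature
        loc <- sub("\\.\\.\\d+$", "", loc)
        if (!grepl("^[0-9]+$", loc)) next
        p <- as.integer(loc)
        note <- .featureNote(f$note)
        k <- if (startsWith(note, "Phosphoserine")) "phosphoserine"
             else if (startsWith(note, "Phosphotyrosine")) "phosphotyrosine"
             else NA_character_
        if (is.na(k)) next
        if (p > nchar(sequence))
            return(fail(entryName, sprintf(
                "MOD_RES position %d beyond sequence length %d", p, nchar(sequence))))
        expected <- if (k == "phosphoserine") "S" else "Y"
        if (substring(sequence, p, p) != expected) {
            dropped <- rbind(dropped, data.frame(
                record = idx, id = entryName, type = "site_dropped",
                reason = sprintf("%s at %d but sequence has '%s'",
                                 k, p, substring(sequence, p, p)),
                stringsAsFactors = FALSE))
            next
        }
        pos <- c(pos, p); kind <- c(kind, k)
    }
    ## collapse duplicate annotations at one position
    if (length(pos)) {
        keep <- !duplicated(pos)
        o <- order(pos[keep])
        pos <- pos[keep][o]; kind <- kind[keep][o]
    }

    entry <- proteinEntry(entryName = entryName, accession = accs[1],
                          sequence = sequence, organismTaxon = taxon,
                          geneName = geneName, mwDa = mwDa,
                          sites = if (length(pos))
                              data.frame(position = pos, kind = kind) else NULL,
                          locations = parseSubcellularLocations(rec),
                          secondaryAccessions = accs[-1])
    list(entry = entry, report = dropped)
}

#' Parse UniProtKB-style flat text
#'
#' Reads zero or more `//`-terminated flat-text records into a
#' [PhosphoProteome-class]. `MOD_RES` features whose description begins with
#' `Phosphoserine` or `Phosphotyrosine` (kinase attributions after a
#' semicolon are tolerated) become phosphosites; all other features are
#' ignored, and isoform-scoped features are skipped. Entries from any
#' organism are parsed — organism filtering is the caller's job.
#'
#' Malformed records (missing ID or SQ, sequence length disagreeing with the
#' SQ header, feature position beyond the sequence) are rejected per entry
#' and recorded in [parseReport()], never silently truncated. A phosphosite
#' whose sequence residue is not the expected S/Y is dropped with a warning
#' and logged in the report.
#'
#' @param text Character vector of lines, or a single string with embedded
#'   newlines.
#' @return A [PhosphoProteome-class]; diagnostics in [parseReport()].
#' @seealso [readPhosphoProteome()] to read from a file,
#'   [writeFlatFile()] for the inverse.
#' @export
parseFlatFile <- function(text) {
    lines <- unlist(strsplit(as.character(text), "\n"))
    recs <- .splitRecords(lines)
    parts <- lapply(seq_along(recs), function(i) .parseRecord(recs[[i]], i))
    entries <- Filter(Negate(is.null), lapply(parts, `[[`, "entry"))
    report <- do.call(rbind, c(list(.emptyReport()),
                               lapply(parts, `[[`, "report")))
    ndrop <- sum(report$type == "site_dropped")
    if (ndrop)
        warning(ndrop, " phosphosite(s) dropped: annotated residue does not ",
                "match the sequence (see parseReport())", call. = FALSE)
    if (!length(entries)) {
        out <- new("PhosphoProteome", sequences = AAStringSet(),
                   entryData = .emptyEntryData(), sites = .emptySites(),
                   locations = CharacterList(), report = report)
        return(out)
    }
    out <- bindProteomes(entries)
    out@report <- report
    out
}

#' @rdname parseFlatFile
#' @param path Path to a flat-text file.
#' @export
readPhosphoProteome <- function(path) parseFlatFile(readLines(path))

## ---------------------------------------------------------------------------
## Writing
## ---------------------------------------------------------------------------

.wrapContinuation <- function(prefix, text, width = 75L) {
    words <- strsplit(text, " ")[[1]]
    lines <- character(0)
    cur <- prefix
    for (w in words) {
        cand <- if (identical(cur, prefix)) paste0(cur, w) else paste(cur, w)
        if (nchar(cand) > width && !identical(cur, prefix)) {
            lines <- c(lines, cur)
            cur <- paste0(prefix, w)
        } else cur <- cand
    }
    c(lines, cur)
}

.writeRecord <- function(p, i) {
    ed <- p@entryData[i, , drop = FALSE]
    acc <- as.character(ed$accession)
    seqtxt <- as.character(p@sequences[[i]])
    n <- nchar(seqtxt)
    taxon <- ed$organismTaxon
    osName <- if (!is.na(taxon) && as.character(taxon) %in% names(.TAXON_OS))
        .TAXON_OS[[as.character(taxon)]] else "Synthetic organism"
    lines <- c(
        sprintf("ID   %-24sReviewed;%10d AA.", ed$entryName, n),
        sprintf("AC   %s;", paste(c(acc, unlist(ed$secondaryAccessions)),
                                  collapse = "; ")),
        sprintf("OS   %s.", osName))
    if (!is.na(taxon))
        lines <- c(lines, sprintf("OX   NCBI_TaxID=%d;", taxon))
    if (nzchar(ed$geneName))
        lines <- c(lines, sprintf("GN   Name=%s;", ed$geneName))
    st <- p@sites[p@sites$accession == acc, , drop = FALSE]
    if (nrow(st)) {
        kindLabel <- c(phosphoserine = "Phosphoserine",
                       phosphotyrosine = "Phosphotyrosine")
        for (k in seq_len(nrow(st)))
            lines <- c(lines,
                       sprintf("FT   MOD_RES         %d", st$position[k]),
                       sprintf("FT                   /note=\"%s\"",
                               kindLabel[[st$kind[k]]]))
    }
    loc <- unlist(p@locations[[i]])
    if (length(loc)) {
        par <- paste0(paste(loc, collapse = ". "), ".")
        wrapped <- .wrapContinuation("CC       ", par)
        wrapped[1] <- sub("^CC       ", "CC   -!- SUBCELLULAR LOCATION: ",
                          wrapped[1])
        lines <- c(lines, wrapped)
    }
    lines <- c(lines,
               sprintf("SQ   SEQUENCE   %d AA;  %d MW;  0000000000000000 CRC64;",
                       n, ed$mwDa))
    starts <- seq(1L, n, by = 60L)
    for (s in starts) {
        chunk <- substring(seqtxt, s, min(n, s + 59L))
        groups <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                            pmin(nchar(chunk), seq(10L, nchar(chunk) + 9L, by = 10L)))
        lines <- c(lines, paste0("     ", paste(groups, collapse = " ")))
    }
    c(lines, "//")
}

#' Write a proteome (or single entry) as flat text
#'
#' Emits minimal, standard-conformant records (ID, AC, OS/OX, GN, FT MOD_RES,
#' CC SUBCELLULAR LOCATION, SQ header with length and molecular weight,
#' 60-column sequence block, `//` terminator). [parseFlatFile()] applied to
#' the output reproduces the input exactly.
#'
#' @param proteome A [PhosphoProteome-class].
#' @param path Optional output file; when `NULL` the text is only returned.
#' @return Character vector of lines, invisibly when `path` is given.
#' @export
writeFlatFile <- function(proteome, path = NULL) {
    stopifnot(is(proteome, "PhosphoProteome"))
    validObject(proteome)
    lines <- unlist(lapply(seq_len(length(proteome)),
                           function(i) .writeRecord(proteome, i)))
    if (is.null(lines)) lines <- character(0)
    if (!is.null(path)) {
        writeLines(lines, path)
        return(invisible(lines))
    }
    lines
}

#' @rdname writeFlatFile
#' @param entry A single-entry [PhosphoProteome-class] (see [proteinEntry()]);
#'   refused with a diagnostic if the object violates its invariants.
#' @export
writeFixtureEntry <- function(entry) {
    stopifnot(is(entry, "PhosphoProteome"))
    if (length(entry) != 1L)
        stop("writeFixtureEntry() expects exactly one entry; got ",
             length(entry), call. = FALSE)
    writeFlatFile(entry)
}

## ---------------------------------------------------------------------------
## FASTA + site-table alternative input
## ---------------------------------------------------------------------------

#' Read a proteome from FASTA plus a phosphosite table
#'
#' Alternative input route for users without flat files: sequences from a
#' FASTA file and sites from a TSV with columns `accession`, `position`,
#' `kind` (`phosphoserine` / `phosphotyrosine`). FASTA headers may be plain
#' accessions or UniProt-style `sp|ACC|ENTRY_NAME`; an `_HUMAN` / `_MOUSE`
#' entry-name suffix sets the organism. Molecular weights are computed from
#' the sequences. Sites whose residue does not match their kind are dropped
#' with a warning, as in [parseFlatFile()].
#'
#' @param fastaPath FASTA file of amino-acid sequences.
#' @param sitesPath Tab-separated site table with a header row.
#' @return A [PhosphoProteome-class].
#' @export
readFastaSites <- function(fastaPath, sitesPath) {
    seqs <- Biostrings::readAAStringSet(fastaPath)
    hdr <- names(seqs)
    first <- vapply(strsplit(hdr, "\\s+"), `[`, character(1), 1L)
    piped <- strsplit(first, "|", fixed = TRUE)
    acc <- vapply(piped, function(x) if (length(x) >= 2L) x[2] else x[1],
                  character(1))
    entryName <- vapply(piped, function(x) if (length(x) >= 3L) x[3] else x[1],
                        character(1))
    taxon <- ifelse(grepl("_HUMAN$", entryName), 9606L,
                    ifelse(grepl("_MOUSE$", entryName), 10090L, NA_integer_))
    sites <- utils::read.delim(sitesPath, stringsAsFactors = FALSE,
                               comment.char = "#")
    entries <- lapply(seq_along(seqs), function(i) {
        st <- sites[sites$accession == acc[i], , drop = FALSE]
        sq <- toupper(as.character(seqs[[i]]))
        if (nrow(st)) {
            expected <- ifelse(st$kind == "phosphoserine", "S", "Y")
            obs <- substring(sq, st$position, st$position)
            bad <- obs != expected
            if (any(bad))
                warning(sum(bad), " site(s) for ", acc[i],
                        " dropped: residue does not match kind", call. = FALSE)
            st <- st[!bad, , drop = FALSE]
        }
        proteinEntry(entryName = entryName[i], accession = acc[i],
                     sequence = sq, organismTaxon = taxon[i],
                     sites = if (nrow(st)) st else NULL)
    })
    bindProteomes(entries)
}
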