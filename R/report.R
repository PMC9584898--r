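.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "",
                       fileEncoding = "UTF-8")
}

#' Write the screen's report files
#'
#' Emits one hit TSV per seed (in rank order; empty but with a header when a
#' seed has no hits), a `summary.tsv` of hit counts per seed and organism
#' (plus common-to-both counts when commonality is supplied), an
#' `overlap.tsv` of biofluid overlap summaries when supplied, and a
#' `manifest.txt` of key-value pairs that makes the run reproducible.
#' Outputs are deterministic: re-running on identical inputs yields
#' byte-identical files. An unwritable destination raises an error before
#' any partial output.
#'
#' @param ranked Ranked hit `data.frame` from [rankHits()] (must carry a
#'   `rank` column).
#' @param destination Output directory; created if needed.
#' @param seeds Optional list of [SeedFragment-class]; guarantees a hit file
#'   for seeds with zero hits. Defaults to the seeds present in `ranked`.
#' @param common Optional result of [commonAcrossOrganisms()].
#' @param overlaps Optional `data.frame` of rows from [annotateBiofluids()].
#' @param proteome Optional [PhosphoProteome-class]; adds a `locations`
#'   column (phrases joined by `;`) to the hit tables.
#' @param manifest Named list of extra manifest fields (seed set, threshold,
#'   organism filter, input digest, ...).
#' @return Invisibly, the character vector of files written.
#' @export
writeReport <- function(ranked, destination, seeds = NULL, common = NULL,
                        overlaps = NULL, proteome = NULL, manifest = list()) {
    if (!("rank" %in% colnames(ranked)))
        stop("'ranked' must come from rankHits() (missing rank column)",
             call. = FALSE)
    if (!dir.exists(destination) &&
        !dir.create(destination, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create destination directory: ", destination,
             call. = FALSE)
    if (file.access(destination, mode = 2L) != 0L)
        stop("destination not writable: ", destination, call. = FALSE)

    seedIds <- if (!is.null(seeds)) names(seeds) else sort(unique(ranked$seedId))
    if (!is.null(proteome)) {
        locs <- vapply(seq_len(length(proteome)), function(i)
            paste(unlist(subcellularLocations(proteome)[[i]]), collapse = ";"),
            character(1))
        names(locs) <- as.character(entryData(proteome)$accession)
        ranked$locations <- unname(locs[ranked$accession])
        ranked$locations[is.na(ranked$locations)] <- ""
    }
    files <- character(0)
    for (s in seedIds) {
        sub <- ranked[ranked$seedId == s, , drop = FALSE]
        o <- order(sub$organismTaxon, sub$rank, method = "radix")
        f <- file.path(destination, paste0("hits_", s, ".tsv"))
        .writeTsv(sub[o, , drop = FALSE], f)
        files <- c(files, f)
    }
    counts <- if (nrow(ranked)) {
        agg <- stats::aggregate(list(nHits = ranked$rank),
                                by = list(seedId = ranked$seedId,
                                          organismTaxon = ranked$organismTaxon),
                                FUN = length)
        agg
    } else data.frame(seedId = character(0), organismTaxon = integer(0),
                      nHits = integer(0))
    missing <- setdiff(seedIds, counts$seedId)
    if (length(missing))
        counts <- rbind(counts, data.frame(seedId = missing,
                                           organismTaxon = NA_integer_,
                                           nHits = 0L))
    counts$organismTaxon <- as.character(counts$organismTaxon)
    if (!is.null(common)) {
        cm <- data.frame(seedId = names(common$sizes),
                         organismTaxon = "common",
                         nHits = as.integer(common$sizes))
        counts <- rbind(counts, cm,
                        data.frame(seedId = "ALL", organismTaxon = "common",
                                   nHits = common$unionSize))
    }
    counts <- counts[order(counts$seedId, counts$organismTaxon,
                           method = "radix"), , drop = FALSE]
    f <- file.path(destination, "summary.tsv")
    .writeTsv(counts, f)
    files <- c(files, f)
    if (!is.null(overlaps)) {
        f <- file.path(destination, "overlap.tsv")
        .writeTsv(overlaps, f)
        files <- c(files, f)
    }
    man <- c(list(package = "CrossPhos",
                  version = as.character(utils::packageVersion("CrossPhos")),
                  seeds = paste(seedIds, collapse = ",")),
             manifest)
    f <- file.path(destination, "manifest.txt")
    writeLines(sprintf("%s: %s", names(man),
                       vapply(man, function(v) paste(as.character(v),
                                                     collapse = ","),
                              character(1))), f)
    files <- c(files, f)
    invisible(files)
}
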