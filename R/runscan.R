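#' Configuration for a full screening run
#'
#' The defaults reproduce the screen's stated procedure exactly: 13-mer
#' windows, perfect-match flank anchors, PAM120 similarity strictly greater
#' than 1, five-key sort with ascending molecular weight, organisms human
#' (9606) and mouse (10090), and the six alpha-synuclein seeds.
#'
#' @param input Path to a UniProtKB-style flat-text file (or `NULL` when
#'   using `fasta` + `sitesTsv`).
#' @param fasta,sitesTsv Alternative input: FASTA plus a site table (see
#'   [readFastaSites()]).
#' @param organisms Integer taxon filter; default `c(9606, 10090)`.
#' @param seedPositions Seed phosphosite positions on human alpha-synuclein;
#'   default `c(39, 87, 125, 129, 133, 136)`. Ignored when `seedFasta` is
#'   given.
#' @param seedFasta Optional seed FASTA (see [readSeedsFasta()]).
#' @param halfWidth Window half-width; default 6.
#' @param threshold Similarity threshold (strictly-greater-than); default 1.
#' @param strictCenter Require the candidate center residue to equal the
#'   seed's; default `FALSE`.
#' @param mwDirection Molecular-weight sort direction; default
#'   `"ascending"`.
#' @param plasmaList,csfList Optional presence-list files (see
#'   [readPresenceList()]).
#' @param outDir Output directory for [writeReport()].
#' @return A validated config (class `RunConfig`).
#' @export
runConfig <- function(input = NULL, fasta = NULL, sitesTsv = NULL,
                      organisms = c(9606L, 10090L),
                      seedPositions = c(39L, 87L, 125L, 129L, 133L, 136L),
                      seedFasta = NULL, halfWidth = 6L, threshold = 1L,
                      strictCenter = FALSE,
                      mwDirection = c("ascending", "descending"),
                      plasmaList = NULL, csfList = NULL,
                      outDir = "crossphos-out") {
    mwDirection <- match.arg(mwDirection)
    if (is.null(input) && (is.null(fasta) || is.null(sitesTsv)))
        stop("either 'input' (flat file) or both 'fasta' and 'sitesTsv' ",
             "must be given", call. = FALSE)
    structure(list(input = input, fasta = fasta, sitesTsv = sitesTsv,
                   organisms = as.integer(organisms),
                   seedPositions = as.integer(seedPositions),
                   seedFasta = seedFasta, halfWidth = as.integer(halfWidth),
                   threshold = as.integer(threshold),
                   strictCenter = isTRUE(strictCenter),
                   mwDirection = mwDirection,
                   plasmaList = plasmaList, csfList = csfList,
                   outDir = outDir),
              class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Fields mirror the arguments of [runConfig()]; values given in `...`
#' (typically command-line flags) override the file.
#'
#' @param path YAML file path.
#' @param ... Overrides, as named [runConfig()] arguments.
#' @return A `RunConfig`.
#' @export
runConfigFromYaml <- function(path, ...) {
    vals <- yaml::read_yaml(path)
    overrides <- list(...)
    vals[names(overrides)] <- overrides
    do.call(runConfig, vals)
}

#' Execute the full screen: parse, scan, rank, summarise, report
#'
#' Runs the pipeline stages in order — input parsing, organism filtering,
#' seed construction, proteome scan, five-key ranking, cross-organism
#' commonality (when both human and mouse entries are present), biofluid
#' overlap (when presence lists are configured) and report writing — with
#' progress logged via `message()`.
#'
#' @param config A [runConfig()] (or [runConfigFromYaml()]).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `status` (0 = success, 2 = parse failure,
#'   3 = empty result set), `proteome`, `hits`, `ranked`, `common`,
#'   `overlaps`, and `files` (the report paths written).
#' @export
runScan <- function(config, quiet = FALSE) {
    stopifnot(inherits(config, "RunConfig"))
    note <- function(...) if (!quiet) message(...)

    proteome <- tryCatch({
        if (!is.null(config$input)) readPhosphoProteome(config$input)
        else readFastaSites(config$fasta, config$sitesTsv)
    }, error = function(e) e)
    if (inherits(proteome, "error")) {
        note("parse failure: ", conditionMessage(proteome))
        return(invisible(list(status = 2L, error = proteome)))
    }
    rep <- parseReport(proteome)
    note("parsed ", length(proteome), " entries (",
         sum(rep$type == "rejected"), " rejected, ",
         sum(rep$type == "site_dropped"), " sites dropped)")

    keep <- entryData(proteome)$organismTaxon %in% config$organisms
    proteome <- proteome[which(keep)]
    note("organism filter [", paste(config$organisms, collapse = ", "),
         "]: ", length(proteome), " entries, ",
         nrow(phosphoSites(proteome)), " phosphosites")

    seeds <- if (!is.null(config$seedFasta)) readSeedsFasta(config$seedFasta)
             else aSynSeeds(config$seedPositions, halfWidth = config$halfWidth)
    rule <- similarityRule(threshold = config$threshold)

    hits <- scanProteome(seeds, proteome, rule = rule,
                         strictCenter = config$strictCenter)
    for (s in names(seeds))
        note("seed ", s, ": ", sum(hits$seedId == s), " hits")
    ranked <- rankHits(hits, mwDirection = config$mwDirection)

    common <- NULL
    humanHits <- hits[hits$organismTaxon %in% 9606L, , drop = FALSE]
    mouseHits <- hits[hits$organismTaxon %in% 10090L, , drop = FALSE]
    if (nrow(humanHits) && nrow(mouseHits))
        common <- commonAcrossOrganisms(humanHits, mouseHits)

    overlaps <- NULL
    fluidLists <- Filter(Negate(is.null),
                         list(plasma = config$plasmaList, csf = config$csfList))
    if (length(fluidLists) && nrow(hits)) {
        overlaps <- do.call(rbind, lapply(names(fluidLists), function(lb)
            annotateBiofluids(hits, readPresenceList(fluidLists[[lb]]),
                              label = lb, proteome = proteome)))
    }

    inputFiles <- Filter(Negate(is.null),
                         c(config$input, config$fasta, config$sitesTsv))
    manifest <- list(
        inputDigest = paste(unname(tools::md5sum(unlist(inputFiles))),
                            collapse = ","),
        organisms = config$organisms,
        seedPositions = config$seedPositions,
        halfWidth = config$halfWidth,
        threshold = config$threshold,
        strictCenter = config$strictCenter,
        mwDirection = config$mwDirection)
    files <- writeReport(ranked, config$outDir, seeds = seeds,
                         common = common, overlaps = overlaps,
                         proteome = proteome, manifest = manifest)
    note("wrote ", length(files), " report files to ", config$outDir)

    status <- if (nrow(hits) == 0L) 3L else 0L
    invisible(list(status = status, proteome = proteome, hits = hits,
                   ranked = ranked, common = common, overlaps = overlaps,
                   files = files))
}
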