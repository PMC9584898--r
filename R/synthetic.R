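#' Independent brute-force window comparison oracle
#'
#' Reference implementation of the window metrics, sharing no code with
#' [compareWindows()]: stretch lengths are found by exhaustively enumerating
#' every contiguous offset interval that contains the center and checking
#' the predicate at each position. Inputs are display-format window strings
#' of the full window width, with explicit padding marks (`-`, `*`, `.` or
#' space) at positions outside the sequence.
#'
#' @param seedText,candText Window strings of equal odd length (e.g. 13
#'   characters), padding marks included.
#' @param rule A [SimilarityRule-class]; default PAM120, threshold 1.
#' @return Named integer vector
#'   `c(nExact, nSimilar, exactStretch, exactOrSimilarStretch)`.
#' @examples
#' oracleCompare("EAYEMPSEEGYQD", "EAYEMPSEEGYQD")  # 13, 0, 13, 13
#' @export
oracleCompare <- function(seedText, candText, rule = similarityRule()) {
    a <- strsplit(seedText, "")[[1]]
    b <- strsplit(candText, "")[[1]]
    if (length(a) != length(b) || length(a) %% 2L != 1L)
        stop("windows must be equal odd-length strings", call. = FALSE)
    n <- length(a)
    c0 <- (n + 1L) %/% 2L
    isPad <- function(ch) ch %in% .PAD_CHARS
    nExact <- 0L
    nSimilar <- 0L
    for (i in seq_len(n)) {
        if (isPad(a[i]) || isPad(b[i])) next
        if (a[i] == b[i]) nExact <- nExact + 1L
        else if (.ruleScore(rule, a[i], b[i]) > rule@threshold)
            nSimilar <- nSimilar + 1L
    }
    predicate <- function(i, allowSimilar) {
        if (isPad(a[i]) || isPad(b[i])) return(FALSE)
        if (a[i] == b[i]) return(TRUE)
        allowSimilar && .ruleScore(rule, a[i], b[i]) > rule@threshold
    }
    longest <- function(allowSimilar) {
        best <- 0L
        for (lo in seq_len(c0)) {
            for (hi in seq(c0, n)) {
                ok <- TRUE
                for (i in lo:hi) if (!predicate(i, allowSimilar)) { ok <- FALSE; break }
                if (ok) best <- max(best, hi - lo + 1L)
            }
        }
        best
    }
    c(nExact = nExact, nSimilar = nSimilar,
      exactStretch = longest(FALSE),
      exactOrSimilarStretch = longest(TRUE))
}

## Minimal number of stretch-breaking positions for a centered run of
## length k in a window of width 13: a run containing offsets -1..+1 can
## touch a window edge only when k >= halfWidth + 2.
.minBreaks <- function(k, width = 13L) {
    if (k >= width) return(0L)
    h <- (width - 1L) %/% 2L
    if (k >= h + 2L) 1L else 2L
}

#' Validate a generator configuration
#'
#' Describes a synthetic proteome: entry count, sequence length bounds,
#' residue model, organism mix, planted candidate sites with requested match
#' metrics, anchor-failing decoy sites, and the RNG seed. Infeasible metric
#' targets are rejected here, naming the violated inequality.
#'
#' Planted windows always match the seed at the anchors and center, so a
#' requested `exactStretch` below 3 is infeasible; other constraints are
#' `exactStretch <= nExact`, `nExact + nSimilar <= 13` and room for the
#' stretch-breaking positions flanking the central run.
#'
#' @param nEntries Number of entries; default 50.
#' @param lengthRange Uniform min/max sequence length; default c(120, 400).
#' @param residueFreqs Optional named numeric vector of residue frequencies
#'   over the 20 standard codes; default uniform.
#' @param plantedTargets `data.frame` with columns `seedId`, `exactStretch`,
#'   `nExact`, `nSimilar` and optionally `taxon` (default 9606) and `gene`
#'   (default auto-assigned, unique per entry): one planted candidate site
#'   per row.
#' @param decoysPerEntry Decoy (anchor-failing) annotated sites per
#'   unplanted entry; default 1.
#' @param organismMix Named proportions for taxa, default
#'   `c("9606" = 0.5, "10090" = 0.5)`.
#' @param seed Integer RNG seed; generation is a pure function of the
#'   config including this seed.
#' @return A validated config (class `GeneratorConfig`).
#' @export
generatorConfig <- function(nEntries = 50L, lengthRange = c(120L, 400L),
                            residueFreqs = NULL,
                            plantedTargets = NULL,
                            decoysPerEntry = 1L,
                            organismMix = c("9606" = 0.5, "10090" = 0.5),
                            seed = 1L) {
    nEntries <- as.integer(nEntries)
    stopifnot(nEntries >= 0L, length(lengthRange) == 2L,
              lengthRange[1] >= 30L, lengthRange[2] >= lengthRange[1])
    if (is.null(residueFreqs)) {
        residueFreqs <- stats::setNames(rep(1 / 20, 20), .AA_STANDARD)
    } else {
        stopifnot(all(names(residueFreqs) %in% .AA_STANDARD),
                  all(residueFreqs >= 0), sum(residueFreqs) > 0)
        residueFreqs <- residueFreqs / sum(residueFreqs)
    }
    if (is.null(plantedTargets))
        plantedTargets <- data.frame(seedId = character(0),
                                     exactStretch = integer(0),
                                     nExact = integer(0),
                                     nSimilar = integer(0))
    if (!("taxon" %in% colnames(plantedTargets)))
        plantedTargets$taxon <- rep(9606L, nrow(plantedTargets))
    if (!("gene" %in% colnames(plantedTargets)))
        plantedTargets$gene <- rep(NA_character_, nrow(plantedTargets))
    for (i in seq_len(nrow(plantedTargets))) {
        k <- plantedTargets$exactStretch[i]
        e <- plantedTargets$nExact[i]
        s <- plantedTargets$nSimilar[i]
        if (k < 3L)
            stop("infeasible target ", i, ": exactStretch >= 3 is required ",
                 "(anchors and center are planted as exact)", call. = FALSE)
        if (e < k)
            stop("infeasible target ", i, ": exactStretch <= nExact violated",
                 call. = FALSE)
        if (e + s > 13L)
            stop("infeasible target ", i, ": nExact + nSimilar <= 13 violated",
                 call. = FALSE)
        if (e > 13L - .minBreaks(k))
            stop("infeasible target ", i, ": nExact <= 13 - ",
                 .minBreaks(k), " breaks required around a stretch of ", k,
                 call. = FALSE)
        if (k == 13L && s > 0L)
            stop("infeasible target ", i,
                 ": a full-width exact stretch leaves no similar positions",
                 call. = FALSE)
    }
    perTaxon <- table(plantedTargets$taxon)
    mixN <- round(nEntries * organismMix / sum(organismMix))
    for (tx in names(perTaxon)) {
        have <- if (tx %in% names(mixN)) mixN[[tx]] else 0
        if (perTaxon[[tx]] > have)
            stop("not enough ", tx, " entries (", have, ") for ",
                 perTaxon[[tx]], " planted targets", call. = FALSE)
    }
    structure(list(nEntries = nEntries,
                   lengthRange = as.integer(lengthRange),
                   residueFreqs = residueFreqs,
                   plantedTargets = plantedTargets,
                   decoysPerEntry = as.integer(decoysPerEntry),
                   organismMix = organismMix,
                   seed = as.integer(seed)),
              class = "GeneratorConfig")
}

## Residues similar (score > threshold, non-identical) / dissimilar to `res`
## under `rule`, drawn from the 20 standard codes.
.similarSet <- function(res, rule) {
    sc <- .ruleScore(rule, rep(res, 20L), .AA_STANDARD)
    .AA_STANDARD[sc > rule@threshold & .AA_STANDARD != res]
}

.dissimilarSet <- function(res, rule) {
    sc <- .ruleScore(rule, rep(res, 20L), .AA_STANDARD)
    .AA_STANDARD[sc <= rule@threshold & .AA_STANDARD != res]
}

#' Plant a metric-controlled candidate window into a sequence
#'
#' Rewrites the 13-residue window centered at `position` so that, compared
#' against `seed`, the realized window has anchors and center identical to
#' the seed, a central run of exactly `target["exactStretch"]` exact
#' matches, isolated exact matches to reach `target["nExact"]`, exactly
#' `target["nSimilar"]` positions carrying residues similar (but not
#' identical) to the seed residue, and all remaining positions drawn from
#' residues scoring at or below the threshold. Uses the current RNG state;
#' call `set.seed()` for reproducibility.
#'
#' @param sequence Amino-acid text.
#' @param position Center position; must admit a full 13-mer
#'   (`7 <= position <= nchar(sequence) - 6`).
#' @param seed A [SeedFragment-class].
#' @param target Named integer vector or list with `exactStretch`, `nExact`,
#'   `nSimilar` (validated as in [generatorConfig()]).
#' @param rule A [SimilarityRule-class].
#' @return The modified sequence (character string).
#' @export
plantCandidate <- function(sequence, position, seed, target,
                           rule = similarityRule()) {
    k <- as.integer(target[["exactStretch"]])
    e <- as.integer(target[["nExact"]])
    s <- as.integer(target[["nSimilar"]])
    sequence <- as.character(sequence)
    n <- nchar(sequence)
    position <- as.integer(position)
    sChars <- .windowChars(seed)
    width <- length(sChars)
    h <- (width - 1L) %/% 2L
    if (position < h + 1L || position > n - h)
        stop("position must admit a full window of width ", width,
             call. = FALSE)
    c0 <- h + 1L
    avail <- which(!is.na(sChars))
    ## candidate run intervals [lo, hi] within the seed's in-sequence part,
    ## containing the center and both anchors
    runs <- list()
    for (lo in avail) {
        hi <- lo + k - 1L
        if (hi > max(avail)) next
        if (lo > c0 - 1L || hi < c0 + 1L) next
        if (!all(seq(lo, hi) %in% avail)) next
        runs[[length(runs) + 1L]] <- c(lo, hi)
    }
    if (!length(runs))
        stop("no placement for an exact stretch of ", k,
             " within this seed's window", call. = FALSE)
    ## try run placements in random order until one admits the requested
    ## similar and extra-exact slots; several residues (e.g. Ala, Gly) have
    ## no PAM120 partner above the threshold, so similarity slots are the
    ## scarce resource and are assigned before the isolated exact matches.
    ## Break positions may host similars — a similar residue is
    ## non-identical, so the run stays broken.
    placement <- NULL
    for (run in runs[sample.int(length(runs))]) {
        runIdx <- seq(run[1], run[2])
        breaks <- intersect(c(run[1] - 1L, run[2] + 1L), avail)
        simPool <- setdiff(avail, runIdx)
        simPool <- simPool[vapply(simPool, function(i)
            length(.similarSet(sChars[i], rule)) > 0L, logical(1))]
        if (s > length(simPool)) next
        simIdx <- if (s > 0L) {
            pref <- intersect(breaks, simPool)
            rest <- setdiff(simPool, pref)
            nPref <- min(length(pref), s)
            c(if (nPref > 0L) pref[sample.int(length(pref), nPref)]
              else integer(0),
              if (s > nPref) rest[sample.int(length(rest), s - nPref)]
              else integer(0))
        } else integer(0)
        free <- setdiff(avail, c(runIdx, breaks, simIdx))
        if (e - k > length(free)) next
        extra <- if (e - k > 0L) free[sample.int(length(free), e - k)]
                 else integer(0)
        placement <- list(runIdx = runIdx, simIdx = simIdx, extra = extra)
        break
    }
    if (is.null(placement))
        stop("no residue satisfies a similarity slot for ", s,
             " similar positions (with ", e - k, " extra exact matches) ",
             "against this seed in any run placement", call. = FALSE)
    runIdx <- placement$runIdx
    simIdx <- placement$simIdx
    extra <- placement$extra

    win <- character(width)
    for (i in seq_len(width)) {
        if (is.na(sChars[i])) {
            ## beyond the seed's terminus: any residue, cannot score
            win[i] <- sample(.AA_STANDARD, 1L)
        } else if (i %in% c(runIdx, extra)) {
            win[i] <- sChars[i]
        } else if (i %in% simIdx) {
            pool <- .similarSet(sChars[i], rule)
            win[i] <- pool[sample.int(length(pool), 1L)]
        } else {
            pool <- .dissimilarSet(sChars[i], rule)
            win[i] <- pool[sample.int(length(pool), 1L)]
        }
    }
    paste0(substring(sequence, 1L, position - h - 1L),
           paste(win, collapse = ""),
           substring(sequence, position + h + 1L, n))
}

.randomSequence <- function(len, freqs) {
    paste(sample(names(freqs), len, replace = TRUE, prob = freqs),
          collapse = "")
}

#' Generate a synthetic flat-file proteome with planted ground truth
#'
#' Emits a parseable flat-text proteome in which every planted candidate
#' site is embedded by [plantCandidate()] and every decoy site differs from
#' every seed at the -1 flank (a tryptophan, which no seed carries there),
#' so the expected scan outcome is known by construction: precision and
#' recall of [scanProteome()] against the truth table are exactly 1. The
#' truth table's expected metrics are computed with [oracleCompare()] on the
#' realized windows. Identical config (including its seed) gives
#' byte-identical output.
#'
#' @param config A [generatorConfig()].
#' @param seeds Seed set the targets refer to; default [aSynSeeds()].
#' @param rule A [SimilarityRule-class].
#' @return A list: `text` (flat-file lines), `proteome`
#'   ([PhosphoProteome-class]), `truth` (list with `planted` and `decoys`
#'   data frames), `config`.
#' @export
generateSyntheticProteome <- function(config, seeds = aSynSeeds(),
                                      rule = similarityRule()) {
    stopifnot(inherits(config, "GeneratorConfig"))
    tg <- config$plantedTargets
    if (nrow(tg) && !all(tg$seedId %in% names(seeds)))
        stop("plantedTargets refer to unknown seeds: ",
             paste(setdiff(tg$seedId, names(seeds)), collapse = ", "),
             call. = FALSE)
    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
    })
    set.seed(config$seed)

    nE <- config$nEntries
    mix <- config$organismMix / sum(config$organismMix)
    taxa <- as.integer(names(mix))
    nPer <- round(nE * mix)
    nPer[1] <- nE - sum(nPer[-1])
    entryTaxon <- rep(taxa, times = nPer)
    lens <- sample(seq(config$lengthRange[1], config$lengthRange[2]),
                   nE, replace = TRUE)
    seqsTxt <- vapply(lens, .randomSequence, character(1),
                      freqs = config$residueFreqs)
    suffix <- ifelse(entryTaxon == 9606L, "HUMAN",
                     ifelse(entryTaxon == 10090L, "MOUSE", "SYNTH"))
    entryName <- sprintf("SYN%03d_%s", seq_len(nE), suffix)
    accession <- sprintf("P%05d", seq_len(nE))
    gene <- sprintf("GN%03d", seq_len(nE))

    h <- 6L
    width <- 2L * h + 1L
    planted <- data.frame(accession = character(0), position = integer(0),
                          seedId = character(0), nExact = integer(0),
                          nSimilar = integer(0), exactStretch = integer(0),
                          exactOrSimilarStretch = integer(0),
                          stringsAsFactors = FALSE)
    siteTab <- list()
    ## assign each target its own entry of the right taxon
    used <- integer(0)
    for (i in seq_len(nrow(tg))) {
        cand <- setdiff(which(entryTaxon == tg$taxon[i]), used)
        ei <- cand[1]
        used <- c(used, ei)
        if (!is.na(tg$gene[i])) gene[ei] <- tg$gene[i]
        sd <- seeds[[tg$seedId[i]]]
        pos <- sample(seq(h + 1L, lens[ei] - h), 1L)
        seqsTxt[ei] <- plantCandidate(seqsTxt[ei], pos, sd,
                                      c(exactStretch = tg$exactStretch[i],
                                        nExact = tg$nExact[i],
                                        nSimilar = tg$nSimilar[i]),
                                      rule = rule)
        res <- centerResidue(sd)
        siteTab[[length(siteTab) + 1L]] <- data.frame(
            entry = ei, position = pos,
            kind = if (res == "S") "phosphoserine" else "phosphotyrosine",
            stringsAsFactors = FALSE)
        win <- extractWindow(seqsTxt[ei], pos, halfWidth = h)
        m <- oracleCompare(formatWindow(sd), formatWindow(win), rule)
        planted <- rbind(planted, data.frame(
            accession = accession[ei], position = pos, seedId = tg$seedId[i],
            nExact = m[["nExact"]], nSimilar = m[["nSimilar"]],
            exactStretch = m[["exactStretch"]],
            exactOrSimilarStretch = m[["exactOrSimilarStretch"]],
            stringsAsFactors = FALSE))
    }
    ## decoys in the remaining entries: center S or Y, tryptophan at -1
    decoys <- data.frame(accession = character(0), position = integer(0),
                         stringsAsFactors = FALSE)
    if (config$decoysPerEntry > 0L) {
        for (ei in setdiff(seq_len(nE), used)) {
            posUsed <- integer(0)
            for (d in seq_len(config$decoysPerEntry)) {
                ## keep decoys in one entry >2 apart so a later decoy cannot
                ## overwrite an earlier decoy's center or flank
                pool <- setdiff(seq(h + 1L, lens[ei] - h),
                                unlist(lapply(posUsed, function(p) (p - 2L):(p + 2L))))
                if (!length(pool)) break
                pos <- pool[sample.int(length(pool), 1L)]
                posUsed <- c(posUsed, pos)
                res <- sample(c("S", "Y"), 1L)
                ch <- strsplit(seqsTxt[ei], "")[[1]]
                ch[pos] <- res
                ch[pos - 1L] <- "W"
                seqsTxt[ei] <- paste(ch, collapse = "")
                siteTab[[length(siteTab) + 1L]] <- data.frame(
                    entry = ei, position = pos,
                    kind = if (res == "S") "phosphoserine" else "phosphotyrosine",
                    stringsAsFactors = FALSE)
                decoys <- rbind(decoys, data.frame(
                    accession = accession[ei], position = pos,
                    stringsAsFactors = FALSE))
            }
        }
    }
    sitesAll <- do.call(rbind, c(list(data.frame(entry = integer(0),
                                                 position = integer(0),
                                                 kind = character(0))),
                                 siteTab))
    entries <- lapply(seq_len(nE), function(ei) {
        st <- sitesAll[sitesAll$entry == ei, c("position", "kind"),
                       drop = FALSE]
        proteinEntry(entryName = entryName[ei], accession = accession[ei],
                     sequence = seqsTxt[ei], organismTaxon = entryTaxon[ei],
                     geneName = gene[ei],
                     sites = if (nrow(st)) st else NULL)
    })
    proteome <- bindProteomes(entries)
    list(text = writeFlatFile(proteome), proteome = proteome,
         truth = list(planted = planted, decoys = decoys),
         config = config)
}
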