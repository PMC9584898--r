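# Fixtures are built in code: the two alpha-synuclein entries with the
# annotation state the screen's worked examples assume, plus randomized
# entries and window texts for property tests.

humanASynEntry <- function() {
    proteinEntry("SYUA_HUMAN", "P37840", aSynSequence("human"), 9606,
                 geneName = "SNCA",
                 sites = data.frame(position = c(87, 125, 129),
                                    kind = c("phosphoserine",
                                             "phosphotyrosine",
                                             "phosphoserine")),
                 locations = c("Cytoplasm", "Membrane", "Nucleus"),
                 secondaryAccessions = c("Q4JHI3", "Q6IAU6"))
}

mouseASynEntry <- function() {
    proteinEntry("SYUA_MOUSE", "O55042", aSynSequence("mouse"), 10090,
                 geneName = "Snca",
                 sites = data.frame(position = c(125, 129),
                                    kind = c("phosphotyrosine",
                                             "phosphoserine")))
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

randomSeq <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

# A random valid entry with S/Y phosphosites guaranteed to sit on the right
# residue, a random gene/taxon mix, and brace-free location phrases.
randomEntry <- function(i) {
    len <- sample(40:200, 1)
    sq <- strsplit(randomSeq(len), "")[[1]]
    nSites <- sample(0:4, 1)
    pos <- if (nSites > 0) sort(sample(seq_len(len), nSites)) else integer(0)
    kind <- sample(c("phosphoserine", "phosphotyrosine"), nSites, TRUE)
    sq[pos] <- ifelse(kind == "phosphoserine", "S", "Y")
    taxon <- sample(c(9606L, 10090L, NA_integer_), 1)
    locVocab <- c("Cytoplasm", "Nucleus", "Membrane", "Secreted",
                  "Cell projection, axon", "Mitochondrion matrix")
    proteinEntry(
        entryName = sprintf("RND%03d_%s", i,
                            if (is.na(taxon)) "SYNTH"
                            else if (taxon == 9606L) "HUMAN" else "MOUSE"),
        accession = sprintf("R%05d", i),
        sequence = paste(sq, collapse = ""),
        organismTaxon = taxon,
        geneName = if (runif(1) < 0.3) "" else sprintf("Gene%d", i),
        sites = if (nSites > 0) data.frame(position = pos, kind = kind)
                else NULL,
        locations = sample(locVocab, sample(0:3, 1)),
        secondaryAccessions = if (runif(1) < 0.5)
            sprintf("S%05d", i + c(1000, 2000)) else character(0))
}

expect_proteome_equal <- function(a, b) {
    expect_equal(length(a), length(b))
    ea <- entryData(a); eb <- entryData(b)
    for (col in c("entryName", "accession", "geneName", "organismTaxon",
                  "mwDa"))
        expect_equal(as.vector(ea[[col]]), as.vector(eb[[col]]))
    expect_equal(lapply(ea$secondaryAccessions, as.character),
                 lapply(eb$secondaryAccessions, as.character))
    expect_equal(as.character(sequences(a)), as.character(sequences(b)))
    expect_equal(as.data.frame(phosphoSites(a)),
                 as.data.frame(phosphoSites(b)))
    expect_equal(lapply(subcellularLocations(a), as.character),
                 lapply(subcellularLocations(b), as.character))
}

# A random padded 13-character window text (padding only at the ends, the
# center always in sequence), for oracle-equivalence sweeps.
randomWindowText <- function(pPad = 0.25) {
    left <- if (runif(1) < pPad) sample(0:6, 1) else 0L
    right <- if (runif(1) < pPad) sample(0:6, 1) else 0L
    body <- randomSeq(13L - left - right)
    rightPad <- if (right > 0)
        paste0("*", strrep("-", right - 1L)) else ""
    paste0(strrep("-", left), body, rightPad)
}

# Rebuild a PeptideWindow from a padded window text.
windowFromText <- function(txt, centerPos = 100L) {
    chars <- strsplit(txt, "")[[1]]
    pad <- chars %in% c("-", "*", ".", " ")
    left <- match(FALSE, pad) - 1L
    right <- length(chars) - max(which(!pad))
    new("PeptideWindow",
        residues = paste(chars[!pad], collapse = ""),
        centerPos = as.integer(centerPos),
        leftMissing = left, rightMissing = right,
        cTerminal = right > 0L)
}

# Random hit table (already shaped like scanProteome output) for ranking
# property tests.
randomHits <- function(n, seedIds = c("S129", "Y125")) {
    data.frame(
        seedId = sample(seedIds, n, TRUE),
        accession = sprintf("H%05d", sample(1:(2 * n), n)),
        entryName = sprintf("H%d_HUMAN", seq_len(n)),
        geneName = sprintf("G%d", seq_len(n)),
        organismTaxon = sample(c(9606L, 10090L), n, TRUE),
        position = sample(10:500, n, TRUE),
        residue = sample(c("S", "Y"), n, TRUE),
        kind = "phosphoserine",
        window = replicate(n, randomSeq(13)),
        nExact = sample(3:13, n, TRUE),
        nSimilar = sample(0:5, n, TRUE),
        exactStretch = sample(0:8, n, TRUE),
        exactOrSimilarStretch = sample(0:13, n, TRUE),
        mwDa = sample(8000:250000, n, TRUE),
        stringsAsFactors = FALSE)
}
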