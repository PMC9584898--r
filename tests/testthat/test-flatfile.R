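test_that("flat-text round trip reproduces entries exactly", {
    two <- bindProteomes(humanASynEntry(), mouseASynEntry())
    txt <- writeFlatFile(two)
    back <- parseFlatFile(txt)
    expect_proteome_equal(two, back)

    set.seed(11)
    for (rep in 1:15) {
        e <- randomEntry(rep)
        back <- parseFlatFile(writeFixtureEntry(e))
        expect_proteome_equal(e, back)
    }
})

test_that("the alpha-synuclein fixture carries its three annotated sites", {
    p <- parseFlatFile(writeFixtureEntry(humanASynEntry()))
    st <- as.data.frame(phosphoSites(p))
    expect_equal(st$position, c(87L, 125L, 129L))
    expect_equal(st$residue, c("S", "Y", "S"))
    expect_equal(st$kind,
                 c("phosphoserine", "phosphotyrosine", "phosphoserine"))
    expect_equal(entryData(p)$mwDa, 14460L)
})

test_that("only phosphoserine/phosphotyrosine MOD_RES become sites", {
    txt <- c(
        "ID   TEST1_HUMAN             Reviewed;        30 AA.",
        "AC   T00001;",
        "OX   NCBI_TaxID=9606;",
        "FT   MOD_RES         5",
        "FT                   /note=\"Phosphothreonine\"",
        "FT   MOD_RES         7",
        "FT                   /note=\"N6-acetyllysine\"",
        "SQ   SEQUENCE   30 AA;  3000 MW;  0000000000000000 CRC64;",
        "     MAAATKASYA AAAAAAAAAA AAAAAAAAAA",
        "//")
    p <- parseFlatFile(txt)
    expect_equal(length(p), 1L)
    expect_equal(nrow(phosphoSites(p)), 0L)
})

test_that("kinase attributions, legacy FT layout and duplicates are handled", {
    txt <- c(
        "ID   TEST2_HUMAN             Reviewed;        20 AA.",
        "AC   T00002;",
        "OX   NCBI_TaxID=9606;",
        "FT   MOD_RES         3",
        "FT                   /note=\"Phosphoserine; by PLK3\"",
        "FT   MOD_RES     3    3       Phosphoserine; by CK2.",
        "FT   MOD_RES     9    9       Phosphotyrosine.",
        "SQ   SEQUENCE   20 AA;  2000 MW;  0000000000000000 CRC64;",
        "     MASAAAAAYA AAAAAAAAAA",
        "//")
    p <- parseFlatFile(txt)
    st <- as.data.frame(phosphoSites(p))
    # duplicate annotations at one position collapse to a single site
    expect_equal(st$position, c(3L, 9L))
    expect_equal(st$kind, c("phosphoserine", "phosphotyrosine"))
})

test_that("isoform-scoped features are skipped", {
    txt <- c(
        "ID   TEST3_HUMAN             Reviewed;        20 AA.",
        "AC   T00003;",
        "OX   NCBI_TaxID=9606;",
        "FT   MOD_RES         T00003-2:5",
        "FT                   /note=\"Phosphoserine\"",
        "FT   MOD_RES         3",
        "FT                   /note=\"Phosphoserine\"",
        "SQ   SEQUENCE   20 AA;  2000 MW;  0000000000000000 CRC64;",
        "     MASAAAAAAA AAAAAAAAAA",
        "//")
    p <- parseFlatFile(txt)
    expect_equal(as.data.frame(phosphoSites(p))$position, 3L)
})

test_that("malformed records are rejected into the report, not truncated", {
    good <- writeFixtureEntry(humanASynEntry())
    noId <- c("AC   X00001;",
              "SQ   SEQUENCE   5 AA;  500 MW;  0000000000000000 CRC64;",
              "     MAAAA", "//")
    badLen <- c("ID   BADLEN_HUMAN            Reviewed;        99 AA.",
                "AC   X00002;",
                "SQ   SEQUENCE   99 AA;  500 MW;  0000000000000000 CRC64;",
                "     MAAAA", "//")
    badPos <- c("ID   BADPOS_HUMAN            Reviewed;         5 AA.",
                "AC   X00003;",
                "FT   MOD_RES         12",
                "FT                   /note=\"Phosphoserine\"",
                "SQ   SEQUENCE   5 AA;  500 MW;  0000000000000000 CRC64;",
                "     MASAA", "//")
    p <- parseFlatFile(c(good, noId, badLen, badPos))
    expect_equal(length(p), 1L)
    rep <- parseReport(p)
    rejected <- rep[rep$type == "rejected", ]
    expect_equal(nrow(rejected), 3L)
    # count conservation: records in == parsed + rejected
    expect_equal(length(p) + nrow(rejected), 4L)
    expect_match(rejected$reason[1], "missing ID")
    expect_match(rejected$reason[2], "disagrees")
    expect_match(rejected$reason[3], "beyond sequence")
})

test_that("a site on the wrong residue is dropped with a warning", {
    txt <- c("ID   WRONG_HUMAN             Reviewed;         5 AA.",
             "AC   X00004;",
             "FT   MOD_RES         2",
             "FT                   /note=\"Phosphotyrosine\"",
             "FT   MOD_RES         3",
             "FT                   /note=\"Phosphoserine\"",
             "SQ   SEQUENCE   5 AA;  500 MW;  0000000000000000 CRC64;",
             "     MASAA", "//")
    expect_warning(p <- parseFlatFile(txt), "dropped")
    expect_equal(as.data.frame(phosphoSites(p))$position, 3L)
    expect_equal(sum(parseReport(p)$type == "site_dropped"), 1L)
})

test_that("subcellular-location phrases split and lose evidence tags", {
    expect_equal(parseSubcellularLocations(
        "CC   -!- SUBCELLULAR LOCATION: Cytoplasm. Nucleus."),
        c("Cytoplasm", "Nucleus"))
    expect_equal(parseSubcellularLocations(
        "ID   X\nAC   Y;"), character(0))
    expect_equal(parseSubcellularLocations(
        "CC   -!- SUBCELLULAR LOCATION: Cytoplasm {ECO:0000269|PubMed:1}."),
        "Cytoplasm")
    # multi-line paragraph with a Note and a second comment block
    txt <- c("CC   -!- SUBCELLULAR LOCATION: Cytoplasm; Cell membrane",
             "CC       {ECO:0000250}. Note=Binds membranes.",
             "CC   -!- FUNCTION: Something else.")
    expect_equal(parseSubcellularLocations(txt),
                 c("Cytoplasm", "Cell membrane"))
})

test_that("secondary accessions survive and the first accession is primary", {
    p <- parseFlatFile(writeFixtureEntry(humanASynEntry()))
    expect_equal(as.vector(entryData(p)$accession), "P37840")
    expect_equal(as.character(entryData(p)$secondaryAccessions[[1]]),
                 c("Q4JHI3", "Q6IAU6"))
})

test_that("an entry without sites writes no FT lines", {
    e <- proteinEntry("BARE_HUMAN", "B00001", "MAAAAKKA", 9606)
    txt <- writeFixtureEntry(e)
    expect_false(any(grepl("^FT", txt)))
    expect_true(any(grepl("8 AA", txt)))
})

test_that("FASTA plus site-table input builds the same model", {
    fa <- tempfile(fileext = ".fasta")
    tsv <- tempfile(fileext = ".tsv")
    writeLines(c(">sp|P37840|SYUA_HUMAN Alpha-synuclein",
                 aSynSequence("human")), fa)
    writeLines(c("accession\tposition\tkind",
                 "P37840\t129\tphosphoserine",
                 "P37840\t125\tphosphotyrosine",
                 "P37840\t87\tphosphotyrosine"), tsv)  # 87 is S: dropped
    expect_warning(p <- readFastaSites(fa, tsv), "dropped")
    expect_equal(entryData(p)$organismTaxon, 9606L)
    expect_equal(entryData(p)$mwDa, 14460L)
    expect_equal(as.data.frame(phosphoSites(p))$position, c(125L, 129L))
})
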