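test_that("PAM120 lookups are symmetric and unknown codes score low", {
    expect_equal(pam120Score("E", "Q"), 2L)
    expect_equal(pam120Score("Q", "E"), 2L)
    expect_equal(pam120Score("Y", "F"), 4L)
    expect_equal(pam120Score("I", "L"), 1L)
    expect_equal(pam120Score("I", "F"), 0L)
    m <- pam120Matrix()
    expect_true(isSymmetric(unname(m)))
    # codes outside the table never reach the similarity threshold
    expect_true(all(pam120Score(c("U", "O", "-", "*"), "S") < 1L))
})

test_that("the anchor filter requires perfect -1/+1 flank matches", {
    seeds <- aSynSeeds()
    s129 <- seeds[["S129"]]
    # human S129 flanks are P/E; mouse window shares them
    expect_true(anchorsMatch(s129, extractWindow(aSynSequence("mouse"), 129)))
    # single-flank mismatch: A at -1
    cand <- windowFromText("AAAAAAASEAAAA")
    expect_false(anchorsMatch(s129, cand))
    # matching P/E flanks around a different center residue still pass
    expect_true(anchorsMatch(s129, windowFromText("AAAAAPYEAAAAA")))
    # a candidate missing a flank fails automatically
    expect_false(anchorsMatch(s129, extractWindow("SEAAAAAA", 1)))
})

test_that("self-comparison is maximal and padding breaks stretches", {
    seeds <- aSynSeeds()
    for (s in seeds) {
        m <- compareWindows(s, seedWindow(s))
        full <- 13L - leftMissing(seedWindow(s)) - rightMissing(seedWindow(s))
        expect_equal(unname(m),
                     c(full, 0L, full, full))
    }
    # Y136 seed against a full 13-mer bearing the same residues: the two
    # positions beyond the terminus cannot match anything
    y136 <- seeds[["Y136"]]
    cand <- windowFromText("EEGYQDYEPEAGG")
    m <- compareWindows(y136, cand)
    expect_equal(m[["nExact"]], 11L)
    expect_equal(m[["exactStretch"]], 11L)
})

test_that("similar counts only non-identical pairs above the threshold", {
    # seed center S; candidate differs at +2 with E->Q (score 2, similar)
    # and at +4 with I->F (score 0, not similar)
    a <- windowFromText("AAAAAPSEAEAIA")
    b <- windowFromText("AAAAAPSEAQAFA")
    m <- compareWindows(a, b)
    expect_equal(m[["nExact"]], 11L)
    expect_equal(m[["nSimilar"]], 1L)
    expect_equal(m[["exactStretch"]], 9L)
    expect_equal(m[["exactOrSimilarStretch"]], 11L)
})

test_that("stretches are zero when the center fails the predicate", {
    a <- windowFromText("AAAAAPSEAAAAA")
    b <- windowFromText("AAAAAPWEAAAAA")  # S vs W: not similar
    m <- compareWindows(a, b)
    expect_equal(m[["exactStretch"]], 0L)
    expect_equal(m[["exactOrSimilarStretch"]], 0L)
    expect_equal(m[["nExact"]], 12L)
    # S vs T scores 2: similar center rescues only the similar stretch
    b2 <- windowFromText("AAAAAPTEAAAAA")
    m2 <- compareWindows(a, b2)
    expect_equal(m2[["exactStretch"]], 0L)
    expect_equal(m2[["exactOrSimilarStretch"]], 13L)
})

test_that("comparison is symmetric for full windows", {
    set.seed(31)
    for (rep in 1:50) {
        a <- windowFromText(randomWindowText(pPad = 0))
        b <- windowFromText(randomWindowText(pPad = 0))
        expect_identical(compareWindows(a, b), compareWindows(b, a))
    }
})

test_that("raising the threshold never increases similarity metrics", {
    set.seed(32)
    for (rep in 1:40) {
        a <- windowFromText(randomWindowText())
        b <- windowFromText(randomWindowText())
        prev <- compareWindows(a, b, similarityRule(threshold = 0L))
        for (th in 1:4) {
            cur <- compareWindows(a, b, similarityRule(threshold = th))
            expect_lte(cur[["nSimilar"]], prev[["nSimilar"]])
            expect_lte(cur[["exactOrSimilarStretch"]],
                       prev[["exactOrSimilarStretch"]])
            expect_identical(cur[["nExact"]], prev[["nExact"]])
            prev <- cur
        }
    }
})

test_that("metric invariants hold on random pairs", {
    set.seed(33)
    for (rep in 1:200) {
        m <- compareWindows(windowFromText(randomWindowText()),
                            windowFromText(randomWindowText()))
        expect_lte(m[["nExact"]] + m[["nSimilar"]], 13L)
        expect_lte(m[["exactStretch"]], m[["exactOrSimilarStretch"]])
        expect_lte(m[["exactOrSimilarStretch"]], 13L)
        expect_lte(m[["exactStretch"]], m[["nExact"]])
        expect_lte(m[["exactOrSimilarStretch"]],
                   m[["nExact"]] + m[["nSimilar"]])
    }
})

test_that("the six seeds recover alpha-synuclein through its own sites", {
    seeds <- aSynSeeds()
    hsHits <- scanProteome(seeds, humanASynEntry())
    expect_equal(sort(unique(hsHits$seedId)), c("S129", "S87", "Y125"))
    expect_equal(nrow(hsHits), 3L)
    # the self-hits are identities
    expect_true(all(hsHits$nExact == 13L & hsHits$exactStretch == 13L))

    mmHits <- scanProteome(seeds, mouseASynEntry())
    expect_equal(sort(unique(mmHits$seedId)), c("S129", "Y125"))
    expect_equal(nrow(mmHits), 2L)
})

test_that("anchored hits with a matching center have a stretch of >= 3", {
    set.seed(34)
    cfg <- generatorConfig(nEntries = 40,
        plantedTargets = data.frame(
            seedId = sample(c("S129", "Y125", "S87", "Y133"), 12, TRUE),
            exactStretch = sample(3:6, 12, TRUE),
            nExact = sample(6:9, 12, TRUE),
            nSimilar = sample(0:3, 12, TRUE)),
        seed = 99)
    g <- generateSyntheticProteome(cfg)
    hits <- scanProteome(aSynSeeds(), g$proteome)
    expect_true(all(hits$exactStretch >= 3L))
})

test_that("scanning an empty proteome returns an empty, typed hit table", {
    empty <- parseFlatFile(character(0))
    hits <- scanProteome(aSynSeeds(), empty)
    expect_equal(nrow(hits), 0L)
    expect_true(all(c("seedId", "accession", "exactStretch", "mwDa") %in%
                    colnames(hits)))
})

test_that("strict-center mode drops hits whose center residue differs", {
    # phosphotyrosine site with S129's P/E flanks: passes the default scan,
    # dropped when the center is required to match
    sq <- paste0(strrep("A", 20), "PYE", strrep("A", 20))
    e <- proteinEntry("CENT_HUMAN", "C00001", sq, 9606,
                      sites = data.frame(position = 22,
                                         kind = "phosphotyrosine"))
    s129 <- aSynSeeds()[["S129"]]
    expect_equal(nrow(scanProteome(list(S129 = s129), e)), 1L)
    expect_equal(nrow(scanProteome(list(S129 = s129), e,
                                   strictCenter = TRUE)), 0L)
})
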