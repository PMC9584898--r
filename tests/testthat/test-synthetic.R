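test_that("the oracle agrees with itself on degenerate inputs", {
    w <- "EAYEMPSEEGYQD"
    expect_equal(unname(oracleCompare(w, w)), c(13L, 0L, 13L, 13L))
    # windows differing everywhere, all pairs dissimilar
    a <- "WWWWWWWWWWWWW"
    b <- "DDDDDDDDDDDDD"  # W/D scores -8
    expect_equal(unname(oracleCompare(a, b)), c(0L, 0L, 0L, 0L))
    expect_equal(unname(oracleCompare("------S------", "AAAAAASAAAAAA")),
                 c(1L, 0L, 1L, 1L))
})

test_that("oracle and matcher agree field-by-field on random pairs", {
    set.seed(51)
    for (rep in 1:1000) {
        ta <- randomWindowText()
        tb <- randomWindowText()
        expect_identical(
            compareWindows(windowFromText(ta), windowFromText(tb)),
            oracleCompare(ta, tb))
    }
})

test_that("planting realizes requested metric targets exactly", {
    seeds <- aSynSeeds()
    set.seed(52)
    sq <- randomSeq(60)
    cases <- list(
        list(seed = "S129", t = c(exactStretch = 3, nExact = 4, nSimilar = 2)),
        list(seed = "Y133", t = c(exactStretch = 5, nExact = 7, nSimilar = 0)),
        list(seed = "S129", t = c(exactStretch = 13, nExact = 13, nSimilar = 0)),
        list(seed = "S87",  t = c(exactStretch = 4, nExact = 8, nSimilar = 3)),
        list(seed = "Y136", t = c(exactStretch = 5, nExact = 7, nSimilar = 2)))
    for (cs in cases) {
        for (rep in 1:5) {
            planted <- plantCandidate(sq, 30, seeds[[cs$seed]], cs$t)
            w <- extractWindow(planted, 30)
            m <- oracleCompare(formatWindow(seeds[[cs$seed]]), formatWindow(w))
            expect_equal(m[["exactStretch"]], unname(cs$t["exactStretch"]))
            expect_equal(m[["nExact"]], unname(cs$t["nExact"]))
            expect_equal(m[["nSimilar"]], unname(cs$t["nSimilar"]))
            # planting only rewrites the window
            expect_equal(substring(planted, 1, 23), substring(sq, 1, 23))
            expect_equal(substring(planted, 37), substring(sq, 37))
        }
    }
    # the maximal target forces identity with the seed
    planted <- plantCandidate(sq, 30, seeds[["S129"]],
                              c(exactStretch = 13, nExact = 13, nSimilar = 0))
    expect_equal(windowResidues(extractWindow(planted, 30)), "EAYEMPSEEGYQD")
})

test_that("infeasible metric targets are rejected with the violated rule", {
    expect_error(generatorConfig(plantedTargets = data.frame(
        seedId = "S129", exactStretch = 5, nExact = 4, nSimilar = 0)),
        "exactStretch <= nExact")
    expect_error(generatorConfig(plantedTargets = data.frame(
        seedId = "S129", exactStretch = 3, nExact = 8, nSimilar = 6)),
        "nExact \\+ nSimilar")
    expect_error(generatorConfig(plantedTargets = data.frame(
        seedId = "S129", exactStretch = 2, nExact = 4, nSimilar = 0)),
        "exactStretch >= 3")
    expect_error(generatorConfig(plantedTargets = data.frame(
        seedId = "S129", exactStretch = 4, nExact = 12, nSimilar = 0)),
        "breaks")
})

test_that("generation is deterministic and leaves the global RNG intact", {
    cfg <- generatorConfig(nEntries = 20, seed = 77,
        plantedTargets = data.frame(seedId = "S129", exactStretch = 3,
                                    nExact = 4, nSimilar = 2))
    set.seed(1); before <- runif(1)
    g1 <- generateSyntheticProteome(cfg)
    g2 <- generateSyntheticProteome(cfg)
    expect_identical(g1$text, g2$text)
    expect_identical(g1$truth, g2$truth)
    set.seed(1)
    expect_equal(runif(1), before)
})

test_that("scan recovers exactly the planted hits, decoys never pass", {
    cfg <- generatorConfig(nEntries = 50, decoysPerEntry = 2, seed = 42,
        plantedTargets = data.frame(
            seedId = rep("S129", 5),
            exactStretch = c(3, 4, 5, 6, 13),
            nExact = c(4, 6, 8, 9, 13),
            nSimilar = c(2, 3, 1, 0, 0)))
    g <- generateSyntheticProteome(cfg)
    hits <- scanProteome(aSynSeeds(), g$proteome)
    expect_equal(nrow(hits), 5L)
    expect_true(all(hits$seedId == "S129"))
    key <- function(df) paste(df$accession, df$position)
    expect_setequal(key(hits), key(g$truth$planted))
    expect_length(intersect(key(hits), key(g$truth$decoys)), 0L)
    # truth and decoy site sets are disjoint by construction
    expect_length(intersect(key(g$truth$planted), key(g$truth$decoys)), 0L)
    # realized metrics equal the oracle-computed truth
    m <- merge(hits, g$truth$planted, by = c("accession", "position"))
    expect_equal(m$nExact.x, m$nExact.y)
    expect_equal(m$nSimilar.x, m$nSimilar.y)
    expect_equal(m$exactStretch.x, m$exactStretch.y)
    expect_equal(m$exactOrSimilarStretch.x, m$exactOrSimilarStretch.y)
})

test_that("paired gene names make cross-organism commonality testable", {
    cfg <- generatorConfig(nEntries = 10, seed = 5,
        plantedTargets = data.frame(
            seedId = c("S129", "S129"),
            exactStretch = c(4, 4), nExact = c(6, 6), nSimilar = c(1, 1),
            taxon = c(9606, 10090), gene = c("PAIR1", "Pair1")))
    g <- generateSyntheticProteome(cfg)
    hits <- scanProteome(aSynSeeds(), g$proteome)
    cm <- commonAcrossOrganisms(hits[hits$organismTaxon == 9606, ],
                                hits[hits$organismTaxon == 10090, ])
    expect_equal(cm$perSeed[["S129"]], "PAIR1")
})

test_that("generated flat text is parseable and faithful", {
    cfg <- generatorConfig(nEntries = 15, seed = 8,
        plantedTargets = data.frame(seedId = "Y125", exactStretch = 5,
                                    nExact = 6, nSimilar = 2))
    g <- generateSyntheticProteome(cfg)
    p <- parseFlatFile(g$text)
    expect_proteome_equal(p, g$proteome)
})
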