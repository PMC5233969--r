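region <- function(start, end, chrom = "chr1", id = "r1") {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
    names(gr) <- id
    gr
}

test_that("weighted level is the pooled count ratio", {
    s <- gridSites(pos = c(10, 20), m = c(3, 1), u = c(1, 3))
    wl <- weightedLevels(s, region(1, 100), contexts = "CG",
                         counts = "raw")
    expect_equal(wl$level, 0.5)
    expect_equal(wl$numerator, 4)
    expect_equal(wl$denominator, 8)

    full <- gridSites(pos = c(10, 20), m = c(5, 7), u = c(0, 0))
    expect_equal(weightedLevels(full, region(1, 100), contexts = "CG",
                                counts = "raw")$level, 1)

    ## no covered sites: undefined, not zero
    wl <- weightedLevels(s, region(50, 60), contexts = "CG",
                         counts = "raw")
    expect_true(is.na(wl$level))
    expect_error(weightedLevels(s, region(1, 10, chrom = "chrX"),
                                counts = "raw"), "absent")
})

test_that("corrected counts feed the level after calling", {
    ## site 2 gets zeroed by the correction (1/10 not significant)
    calls <- callSites(gridSites(pos = c(10, 20), m = c(10, 1),
                                 u = c(0, 9)), pErr = 0.001114)
    wl <- weightedLevels(calls, region(1, 100), contexts = "CG")
    expect_equal(wl$level, 10 / 20)
    raw <- weightedLevels(calls, region(1, 100), contexts = "CG",
                          counts = "raw")
    expect_equal(raw$level, 11 / 20)
})

test_that("weighted level equals mean site level at equal depth", {
    set.seed(31)
    m <- rbinom(50, 20, 0.4)
    s <- gridSites(pos = 1:50 * 3, m = m, u = 20 - m)
    wl <- weightedLevels(s, region(1, 200), contexts = "CG",
                         counts = "raw")
    expect_equal(wl$level, mean(m / 20))
})

test_that("metagene profile is flat on a uniform methylome", {
    s <- gridSites(pos = seq(5, 995, by = 7), m = 30, u = 0)
    calls <- quickCalls(s)
    gene <- region(1, 1000, id = "g1")
    prof <- metageneProfile(calls, gene, flankBp = 0, flankBins = 0,
                            bodyBins = 10, context = "CG")
    expect_equal(prof$level, rep(1, 10))
    expect_identical(nrow(prof), 10L)
})

test_that("flank-only methylation shows up in flank bins only", {
    ## methylated sites in the upstream/downstream 500 bp, none in body
    body <- seq(1000, 1999, by = 10)
    flank <- c(seq(500, 999, by = 10), seq(2000, 2499, by = 10))
    s <- gridSites(pos = c(body, flank),
                   m = c(rep(0L, length(body)), rep(30L, length(flank))),
                   u = c(rep(30L, length(body)), rep(0L, length(flank))))
    calls <- quickCalls(s)
    gene <- region(1000, 1999, id = "g1")
    prof <- metageneProfile(calls, gene, flankBp = 500, flankBins = 5,
                            bodyBins = 10, context = "CG")
    expect_true(all(prof$level[prof$zone == "body"] < 0.01))
    expect_true(all(prof$level[prof$zone != "body"] > 0.99))
})

test_that("minus-strand features are reversed to 5'->3' bin order", {
    ## plus gene methylated near its 5' (left) end
    sPlus <- gridSites(pos = seq(3000, 3999, by = 5),
                       m = rep(c(30L, 0L), c(40, 160)),
                       u = rep(c(0L, 30L), c(40, 160)))
    ## minus gene methylated near its 5' (right) end
    sMinus <- gridSites(pos = seq(6000, 6999, by = 5),
                        m = rep(c(0L, 30L), c(160, 40)),
                        u = rep(c(30L, 0L), c(160, 40)))
    calls <- quickCalls(c(sPlus, sMinus))
    gPlus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3000, 3999),
                                    "+")
    gMinus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(6000, 6999),
                                     "-")
    pP <- metageneProfile(calls, gPlus, flankBp = 0, flankBins = 0,
                          bodyBins = 10)
    pM <- metageneProfile(calls, gMinus, flankBp = 0, flankBins = 0,
                          bodyBins = 10)
    expect_equal(pP$level, pM$level)
    expect_gt(pP$level[1], 0.9)
    expect_lt(pP$level[10], 0.1)
})

test_that("short features are skipped and counted", {
    calls <- quickCalls(gridSites(pos = c(10, 50), m = 30, u = 0))
    feats <- c(region(1, 5, id = "tiny"), region(1, 100, id = "ok"))
    prof <- metageneProfile(calls, feats, flankBp = 0, flankBins = 0,
                            bodyBins = 10)
    expect_identical(attr(prof, "nSkipped"), 1L)
})

test_that("window counts tile chromosomes and conserve totals", {
    set.seed(13)
    pos <- sort(sample(120000, 400))
    m <- rep(c(30L, 0L), 200)
    calls <- quickCalls(gridSites(pos = pos, m = m, u = 30L - m,
                                  seqlen = 120000))
    wc <- windowCounts(calls, windowBp = 50000)
    expect_identical(BiocGenerics::start(wc), c(1L, 50001L, 100001L))
    expect_identical(BiocGenerics::end(wc), c(50000L, 100000L, 120000L))
    expect_identical(sum(wc$total),
                     sum(methStatus(calls) == "methylated"))
    none <- quickCalls(gridSites(pos = pos, m = 0L, u = 30L,
                                 seqlen = 120000))
    expect_true(all(windowCounts(none, windowBp = 50000)$total == 0L))
})

test_that("site categories follow the precedence and partition the calls", {
    feats <- c(
        featureRow("chr1", 2001, 2400, "+", "gene", "g1"),
        featureRow("chr1", 2001, 2100, "+", "exon", "g1.e1", "g1"),
        featureRow("chr1", 2001, 2050, "+", "five_prime_UTR", "g1.u5",
                   "g1"),
        featureRow("chr1", 2101, 2200, "+", "intron", "g1.i1", "g1"),
        featureRow("chr1", 2201, 2400, "+", "exon", "g1.e2", "g1"))
    ## UTR, CDS, intron, upstream (strand-aware), intergenic
    calls <- quickCalls(gridSites(pos = c(2010, 2080, 2150, 1500, 9000),
                                  m = 30, u = 0))
    tab <- categorizeSites(calls, feats, upstreamBp = 1000)
    expect_identical(unname(tab["CG", ]), c(1L, 1L, 1L, 1L, 1L))
    expect_identical(sum(tab), 5L)

    ## a minus-strand gene's upstream window sits to its right
    featsM <- featureRow("chr1", 2001, 2400, "-", "gene", "g2")
    callsM <- quickCalls(gridSites(pos = c(2500, 1900), m = 30, u = 0))
    tabM <- categorizeSites(callsM, featsM, upstreamBp = 1000)
    expect_identical(unname(tabM["CG", "upstream"]), 1L)
    expect_identical(unname(tabM["CG", "intergenic"]), 1L)
})
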