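test_that("two-sided Fisher p matches enumeration and closed forms", {
    expect_equal(fisherTwoSided(10, 0, 0, 10), 2 / choose(20, 10),
                 tolerance = 1e-12)
    expect_equal(fisherTwoSided(5, 5, 5, 5), 1)
    expect_equal(fisherTwoSided(1, 0, 0, 1), 1)
    ## degenerate margins admit a single table
    expect_equal(fisherTwoSided(0, 5, 0, 7), 1)
    expect_equal(fisherTwoSided(3, 0, 4, 0), 1)
    expect_error(fisherTwoSided(0, 0, 0, 0), "all-zero")
    expect_error(fisherTwoSided(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
    set.seed(88)
    for (i in 1:200) {
        m1 <- rpois(1, 6); u1 <- rpois(1, 6)
        m2 <- rpois(1, 6); u2 <- rpois(1, 6)
        if (m1 + u1 == 0 || m2 + u2 == 0 || m1 + m2 == 0 || u1 + u2 == 0)
            next
        want <- stats::fisher.test(matrix(c(m1, m2, u1, u2), 2))$p.value
        expect_equal(fisherTwoSided(m1, u1, m2, u2), want,
                     tolerance = 1e-9)
    }
})

test_that("per-site tests use the common covered sites", {
    a <- callSites(gridSites(pos = c(10, 20, 30), m = c(25, 0, 25),
                             u = c(5, 30, 5)), pErr = 0.001114)
    b <- callSites(gridSites(pos = c(10, 20, 40), m = c(25, 0, 9),
                             u = c(5, 30, 21)), pErr = 0.001114)
    res <- perSiteTests(a, b)
    ## sites 30 and 40 are not shared; 10 and 20 are
    expect_identical(BiocGenerics::start(res), c(10L, 20L))
    expect_identical(attr(res, "nCommon"), 2L)
    expect_identical(attr(res, "nDifferential"), 0L)

    ## identical samples: nothing differential
    res2 <- perSiteTests(a, a)
    expect_identical(attr(res2, "nDifferential"), 0L)
    expect_equal(res2$p, rep(1, length(res2)), tolerance = 1e-9)
})

test_that("per-site tests detect planted level flips at depth 30", {
    set.seed(303)
    n <- 100
    mA <- rbinom(n, 30, 0.95)
    mB <- rbinom(n, 30, 0.05)
    a <- callSites(gridSites(pos = 1:n * 5, m = mA, u = 30L - mA),
                   pErr = 0.001114)
    b <- callSites(gridSites(pos = 1:n * 5, m = mB, u = 30L - mB),
                   pErr = 0.001114)
    res <- perSiteTests(a, b)
    expect_gte(mean(res$differential), 0.90)
    ## swapping samples preserves p and flips the table
    swp <- perSiteTests(b, a)
    expect_equal(swp$p, res$p)
    expect_identical(swp$mA, res$mB)
    ## the optional BH mode is at least as conservative as raw p
    adj <- perSiteTests(a, b, adjust = "BH")
    expect_lte(attr(adj, "nDifferential"), attr(res, "nDifferential"))
    expect_equal(adj$p, res$p)
})

test_that("window start arithmetic yields fully contained windows", {
    calls <- callSites(gridSites(pos = c(10, 100, 390), m = 20, u = 10,
                                 seqlen = 400), pErr = 0.001114)
    d <- dmrScan(calls, calls, windowBp = 200, stepBp = 50)
    expect_identical(attr(d, "nWindows"), 5L)   # starts 1,51,101,151,201
    ## identical samples: candidates exist but none significant
    expect_true(all(!d$significant))
    expect_equal(d$p, rep(1, length(d)), tolerance = 1e-9)

    short <- callSites(gridSites(pos = 5, m = 20, u = 10, seqlen = 150),
                       pErr = 0.001114)
    expect_message(d0 <- dmrScan(short, short), "shorter than window")
    expect_identical(attr(d0, "nWindows"), 0L)
})

test_that("candidate rule requires more than minMethReads in a sample", {
    ## window 1..200 holds 5 corrected methylated reads in each sample:
    ## not a candidate; 6 reads qualifies
    five <- callSites(gridSites(pos = 50, m = 5, u = 25, seqlen = 260),
                      pErr = 1e-6)
    six <- callSites(gridSites(pos = 50, m = 6, u = 24, seqlen = 260),
                     pErr = 1e-6)
    expect_length(dmrScan(five, five, windowBp = 200, stepBp = 50), 0L)
    expect_gt(length(dmrScan(six, five, windowBp = 200, stepBp = 50)), 0L)
})

test_that("window scan is invariant to input record order", {
    set.seed(17)
    pos <- sample(1000, 60)
    m <- rbinom(60, 30, 0.5)
    shuf <- sample(60)
    a1 <- callSites(gridSites(pos = pos, m = m, u = 30L - m,
                              seqlen = 1000), pErr = 0.001114)
    a2 <- callSites(gridSites(pos = pos[shuf], m = m[shuf],
                              u = 30L - m[shuf], seqlen = 1000),
                    pErr = 0.001114)
    b <- callSites(gridSites(pos = pos, m = 30L - m, u = m,
                             seqlen = 1000), pErr = 0.001114)
    expect_identical(as.data.frame(dmrScan(a1, b)),
                     as.data.frame(dmrScan(a2, b)))
})

test_that("sample swap preserves window p-values and flips direction", {
    a <- defaultCallsA()
    b <- defaultCallsB()
    d <- defaultDmrScan()
    sub <- head(order(d$p), 50)
    dSwap <- dmrScan(b, a)
    expect_equal(dSwap$p, d$p)
    expect_identical(dSwap$direction[sub] == "hyperA",
                     d$direction[sub] == "hyperB")
})

test_that("gene-level test flags planted hypermethylation only", {
    set.seed(71)
    n <- 60
    posG1 <- seq(1001, 1999, length.out = n)
    posG2 <- seq(3001, 3999, length.out = n)
    mkCalls <- function(p1, p2) {
        m <- c(rbinom(n, 30, p1), rbinom(n, 30, p2))
        callSites(gridSites(pos = c(posG1, posG2), m = m, u = 30L - m),
                  pErr = 0.001114)
    }
    a <- mkCalls(0.8, 0.5)
    b <- mkCalls(0.1, 0.5)
    genes <- c(featureRow("chr1", 1001, 1999, "+", "gene", "gHyper"),
               featureRow("chr1", 3001, 3999, "+", "gene", "gSame"),
               featureRow("chr1", 5001, 5999, "+", "gene", "gEmpty"))
    res <- geneDifferential(a, b, genes, context = "CG")
    expect_true(res$significant[res$gene == "gHyper"])
    expect_false(res$significant[res$gene == "gSame"])
    expect_identical(attr(res, "nExcluded"), 1L)
    expect_identical(attr(res, "nTested") + attr(res, "nExcluded"), 3L)
})
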