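## Construct a gene-summary table directly (it is a plain data.frame);
## the summarizeGenes path itself is covered by the first test.
mkSummary <- function(level, expr, exonMeth = NULL, intronMeth = NULL,
                      exonLevel = NULL, intronLevel = NULL) {
    n <- length(level)
    data.frame(gene = paste0("g", seq_len(n)),
               levelCG = level, levelCHG = level, levelCHH = level,
               exonMeth = if (is.null(exonMeth)) level * 100 else exonMeth,
               exonTotal = 100,
               exonLevel = if (is.null(exonLevel)) level else exonLevel,
               intronMeth = if (is.null(intronMeth)) 0 else intronMeth,
               intronTotal = 100,
               intronLevel = if (is.null(intronLevel)) 0 else intronLevel,
               meanExpr = expr, stringsAsFactors = FALSE)
}

test_that("gene summaries pool levels, compartments and expression", {
    feats <- c(
        featureRow("chr1", 1001, 1400, "+", "gene", "g1"),
        featureRow("chr1", 1001, 1200, "+", "exon", "g1.e1", "g1"),
        featureRow("chr1", 1201, 1300, "+", "intron", "g1.i1", "g1"),
        featureRow("chr1", 1301, 1400, "+", "exon", "g1.e2", "g1"))
    ## exon sites methylated, intron sites not
    calls <- quickCalls(gridSites(pos = c(1100, 1350, 1250),
                                  m = c(30, 30, 0), u = c(0, 0, 30)))
    expr <- data.frame(gene_id = "g1", sample = "A", replicate = 1:3,
                       abundance = c(10, 20, 30))
    gs <- summarizeGenes(calls, feats, expr, sample = "A")
    expect_equal(gs$levelCG, 60 / 90)
    expect_equal(gs$exonLevel, 1)
    expect_equal(gs$intronLevel, 0)
    expect_equal(gs$exonMeth, 60)
    expect_equal(gs$intronMeth, 0)
    expect_equal(gs$meanExpr, 20)
})

test_that("association is rank-based and sign-correct", {
    lv <- seq(0.01, 0.99, length.out = 50)
    res <- methylationExpressionAssociation(
        mkSummary(lv, 100 - 99 * lv))
    expect_equal(res$rho, -1)
    ## invariant under monotone transforms of expression
    res2 <- methylationExpressionAssociation(
        mkSummary(lv, exp(100 - 99 * lv)))
    expect_equal(res2$rho, -1)
    ## permuted expression: no association at n = 500
    set.seed(505)
    lv <- runif(500)
    res3 <- methylationExpressionAssociation(
        mkSummary(lv, sample(exp(5 - 3 * lv))))
    expect_lt(abs(res3$rho), 0.1)
    expect_error(methylationExpressionAssociation(
        mkSummary(runif(5), runif(5))), "fewer than 10")
})

test_that("binned medians expose the silenced high-methylation tail", {
    set.seed(42)
    lv <- c(runif(200, 0, 0.15), runif(200, 0.75, 0.95))
    ex <- exp(5 - 6 * lv + rnorm(400, 0, 0.3))
    res <- methylationExpressionAssociation(mkSummary(lv, ex))
    b <- res$bins[res$bins$nGenes > 0, ]
    expect_gt(b$medianExpr[1], b$medianExpr[nrow(b)])
})

test_that("compartment sets are exclusive and sized-checked", {
    ## 15 exon-only genes with coupling, 15 intron-only without
    set.seed(99)
    lvE <- runif(15); lvI <- runif(15)
    gs <- rbind(
        mkSummary(lvE, exp(5 - 6 * lvE), exonMeth = lvE * 100 + 1,
                  intronMeth = 0, exonLevel = lvE, intronLevel = 0),
        mkSummary(lvI, exp(5 + rnorm(15, 0, 0.5)), exonMeth = 0,
                  intronMeth = lvI * 100 + 1, exonLevel = 0,
                  intronLevel = lvI))
    gs$gene <- paste0("g", seq_len(nrow(gs)))
    res <- compartmentEffect(gs)
    expect_identical(res$nE, 15L)
    expect_identical(res$nI, 15L)
    expect_true(res$evaluableE && res$evaluableI)
    expect_lt(res$rhoE, -0.8)
    expect_gt(abs(res$rhoE), abs(res$rhoI))

    ## a gene methylated in both compartments belongs to neither set
    both <- mkSummary(0.5, 10, exonMeth = 10, intronMeth = 10)
    resB <- compartmentEffect(both)
    expect_identical(resB$nE, 0L)
    expect_identical(resB$nI, 0L)
    expect_false(resB$evaluableE)
})

test_that("paralog fold changes are antisymmetric and sign-correct", {
    gs <- mkSummary(c(0.8, 0.2, 0.5, 0.5), c(2, 40, 10, 10))
    pairs <- data.frame(gene_a = c("g1", "g3"), gene_b = c("g2", "g4"))
    fc <- paralogFoldChanges(pairs, gs, pseudocount = 0.01)
    expect_equal(fc$methFC[1], log2(0.81 / 0.21), tolerance = 1e-12)
    ## identical paralogs: both fold changes zero
    expect_equal(fc$methFC[2], 0)
    expect_equal(fc$exprFC[2], 0)
    ## swapping pair members negates both fold changes
    swp <- paralogFoldChanges(
        data.frame(gene_a = pairs$gene_b, gene_b = pairs$gene_a), gs,
        pseudocount = 0.01)
    expect_equal(swp$methFC, -fc$methFC)
    expect_equal(swp$exprFC, -fc$exprFC)
    ## missing genes are skipped and counted
    miss <- paralogFoldChanges(
        data.frame(gene_a = "g1", gene_b = "nope"), gs)
    expect_identical(nrow(miss), 0L)
    expect_identical(attr(miss, "nSkipped"), 1L)
})

test_that("silencing flags follow the exon/downstream-DMR rule", {
    gsA <- mkSummary(c(0.05, 0.3), c(100, 10), exonLevel = c(0.05, 0.3))
    gsB <- mkSummary(c(0.9, 0.3), c(0.1, 10), exonLevel = c(0.9, 0.3))
    degs <- data.frame(gene_id = c("g1", "g2"),
                       lower_sample = c("B", "B"))
    res <- flagSilencingCases(gsA, gsB, degs)
    expect_true(res$flagged[1])    # silenced in B, exon-methylated in B
    expect_false(res$flagged[2])   # no methylation difference
    empty <- flagSilencingCases(gsA, gsB, degs[0, ])
    expect_identical(nrow(empty), 0L)
})

test_that("a downstream hyper-DMR in the lower sample flags the gene", {
    gsA <- mkSummary(0.2, 100)
    gsB <- mkSummary(0.2, 1)
    feats <- featureRow("chr1", 1000, 2000, "+", "gene", "g1")
    dmr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2500, 2699))
    dmr$p <- 1e-5; dmr$direction <- "hyperB"; dmr$significant <- TRUE
    res <- flagSilencingCases(gsA, gsB,
                              data.frame(gene_id = "g1",
                                         lower_sample = "B"),
                              features = feats, dmrs = dmr)
    expect_true(res$downstreamDMR)
    expect_identical(res$dmrHyperIn, "B")
    expect_true(res$flagged)
})

test_that("planted silenced genes are flagged end-to-end", {
    sim <- defaultSim()
    gsA <- summarizeGenes(defaultCallsA(), sim$features, sim$expression,
                          sample = "A")
    gsB <- summarizeGenes(defaultCallsB(), sim$features, sim$expression,
                          sample = "B")
    res <- flagSilencingCases(gsA, gsB, sim$degs,
                              features = sim$features,
                              dmrs = defaultDmrScan())
    expect_true(all(res$flagged))
    expect_gt(nrow(res), 0L)
})
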