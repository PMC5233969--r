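smallParams <- function(...) {
    simulationParams(seed = 414, nChroms = 1L, chromLength = 20000L,
                     nGenes = 5L, nTEs = 2L, nPlantedDMRs = 2L,
                     nSNPs = 25L, chloroplastLength = 4000L,
                     nSilenced = 1L, nParalogPairs = 2L, ...)
}

test_that("identical parameters give byte-identical output", {
    s1 <- simulateDataset(smallParams())
    s2 <- simulateDataset(smallParams())
    expect_identical(as.character(s1$genome), as.character(s2$genome))
    expect_identical(as.data.frame(s1$sampleA), as.data.frame(s2$sampleA))
    expect_identical(s1$expression, s2$expression)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    writeSimulation(s1, d1)
    writeSimulation(s2, d2)
    f1 <- list.files(d1, recursive = TRUE)
    expect_setequal(f1, list.files(d2, recursive = TRUE))
    h1 <- tools::md5sum(file.path(d1, f1))
    h2 <- tools::md5sum(file.path(d2, f1))
    expect_identical(unname(h1), unname(h2))
})

test_that("written files round-trip through the package readers", {
    sim <- simulateDataset(smallParams())
    d <- withr::local_tempdir()
    writeSimulation(sim, d)
    g <- readGenomeFasta(file.path(d, "genome.fa"))
    expect_identical(as.character(g), as.character(sim$genome))
    sa <- readCXReport(file.path(d, "sampleA.CX.txt"))
    expect_identical(nMeth(sa), nMeth(sim$sampleA))
    expect_identical(trinucleotide(sa), trinucleotide(sim$sampleA))
    snps <- readSNPTable(file.path(d, "snps.vcf"), genome = g)
    expect_identical(BiocGenerics::start(snps),
                     BiocGenerics::start(sim$snps))
    expect_identical(snps$alt, sim$snps$alt)
    feats <- readGFFFeatures(file.path(d, "features.gff3"))
    expect_setequal(unique(feats$type), unique(sim$features$type))
    expect_identical(sum(feats$type == "gene"),
                     sum(sim$features$type == "gene"))
    expr <- readExpressionTable(file.path(d, "expression.tsv"))
    expect_equal(nrow(expr), nrow(sim$expression))
})

test_that("boundary parameter settings behave as specified", {
    set.seed(1)
    gcOnly <- simulateGenome(simulationParams(gcFraction = 1,
                                              nChroms = 1L,
                                              chromLength = 2000L,
                                              nGenes = 0L, nTEs = 0L,
                                              nSNPs = 0L, nSilenced = 0L,
                                              nParalogPairs = 0L))
    freq <- Biostrings::alphabetFrequency(gcOnly$genome, collapse = TRUE)
    expect_identical(unname(freq["A"] + freq["T"]), 0L)
    expect_length(gcOnly$snps, 0L)

    ## zero depth: all sites uncovered in both samples
    zd <- simulateDataset(smallParams(meanDepth = 0))
    expect_true(all(siteDepth(zd$sampleA) == 0L))
    expect_true(all(siteDepth(zd$sampleB) == 0L))
})

test_that("oversubscribed feature placement is a configuration error", {
    expect_error(simulateDataset(simulationParams(
        seed = 1, nChroms = 1L, chromLength = 5000L, nGenes = 10L,
        geneLengthMin = 1000L, geneLengthMax = 1000L, nTEs = 0L,
        nSilenced = 0L, nParalogPairs = 0L)),
        "configuration error")
})

test_that("emitted sites match the genome's cytosine enumeration", {
    sim <- simulateDataset(smallParams())
    want <- enumerateCytosines(sim$genome)
    expect_identical(BiocGenerics::start(sim$sampleA),
                     BiocGenerics::start(want))
    expect_identical(methContext(sim$sampleA),
                     S4Vectors::mcols(want)$context)
    wantB <- enumerateCytosines(sim$altGenome)
    expect_identical(BiocGenerics::start(sim$sampleB),
                     BiocGenerics::start(wantB))
})

test_that("an all-unmethylated genome reads out at the error rate", {
    sim <- nullSim()
    nm <- sum(as.numeric(nMeth(sim$sampleA)))
    nt <- sum(as.numeric(siteDepth(sim$sampleA)))
    se <- sqrt(0.001114 * (1 - 0.001114) / nt)
    expect_lt(abs(nm / nt - 0.001114), 3 * se)
})

test_that("expression has the replicate schema and silenced genes", {
    sim <- simulateDataset(smallParams())
    ex <- sim$expression
    expect_true(all(ex$abundance >= 0))
    expect_identical(anyDuplicated(ex[, c("gene_id", "sample",
                                          "replicate")]), 0L)
    tab <- table(ex$gene_id, ex$sample)
    expect_true(all(tab == 3L))
    sil <- sim$degs$gene_id
    expect_true(all(ex$abundance[ex$gene_id %in% sil &
                                 ex$sample == "B"] == 0))
    expect_true(all(ex$abundance[ex$gene_id %in% sil &
                                 ex$sample == "A"] > 0))
})

test_that("expression coupling strength controls the correlation", {
    cfg <- function(beta, sigma, seed)
        simulationParams(seed = seed, nChroms = 1L, chromLength = 250000L,
                         nGenes = 100L, nTEs = 0L, nPlantedDMRs = 0L,
                         nSNPs = 0L, chloroplastLength = 4000L,
                         nSilenced = 0L, nParalogPairs = 10L,
                         exprBeta = beta, exprSigma = sigma)
    strong <- simulateDataset(cfg(5, 0.1, 881))$truth$geneTruth
    rhoS <- cor(strong$exonLevelA, strong$meanExprA, method = "spearman")
    expect_lt(rhoS, -0.8)
    null <- simulateDataset(cfg(0, 0.5, 882))$truth$geneTruth
    rhoN <- cor(null$exonLevelA, null$meanExprA, method = "spearman")
    expect_lt(abs(rhoN), 0.3)
})
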