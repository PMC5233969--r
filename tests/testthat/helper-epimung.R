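## Shared fixtures and independent oracles. The default dataset and its
## calls are memoised: several test files use the same study-condition
## simulation, and it is generated exactly once per test run.

.cache <- new.env(parent = emptyenv())

defaultSim <- function() {
    if (is.null(.cache$sim))
        .cache$sim <- simulateDataset(simulationParams(seed = 20240901))
    .cache$sim
}

defaultCallsA <- function() {
    if (is.null(.cache$callsA)) {
        sim <- defaultSim()
        est <- estimateNonConversion(sim$controlA)
        .cache$pErrA <- est$pErr
        .cache$callsA <- callSites(sim$sampleA, est$pErr)
    }
    .cache$callsA
}

defaultCallsB <- function() {
    if (is.null(.cache$callsB)) {
        sim <- defaultSim()
        est <- estimateNonConversion(sim$controlB)
        .cache$callsB <- callSites(sim$sampleB, est$pErr)
    }
    .cache$callsB
}

defaultDmrScan <- function() {
    if (is.null(.cache$dmrs))
        .cache$dmrs <- dmrScan(defaultCallsA(), defaultCallsB())
    .cache$dmrs
}

## A fully unmethylated dataset (every cytosine at the non-conversion
## floor): used for FDR sanity and the p_err law-of-large-numbers check.
nullSim <- function() {
    if (is.null(.cache$nullSim))
        .cache$nullSim <- simulateDataset(simulationParams(
            seed = 20240902, nChroms = 1L, chromLength = 100000L,
            piCG = 0, piCHG = 0, piCHH = 0, nGenes = 0L, nTEs = 0L,
            nPlantedDMRs = 0L, nSNPs = 0L, nSilenced = 0L,
            nParalogPairs = 0L, chloroplastLength = 10000L))
    .cache$nullSim
}

## --- fixture builders -----------------------------------------------

randomSeqStr <- function(n, letters = c("A", "C", "G", "T")) {
    paste(sample(letters, n, replace = TRUE), collapse = "")
}

## Fabricated width-1 site grid (context consistent by construction).
gridSites <- function(pos, m, u, chrom = "chr1", strand = "+",
                      context = "CG", tri = "CGA", seqlen = NULL) {
    si <- NULL
    if (!is.null(seqlen))
        si <- GenomeInfoDb::Seqinfo(seqnames = chrom, seqlengths = seqlen)
    MethylSiteCounts(rep(chrom, length(pos)), pos,
                     rep(strand, length.out = length(pos)),
                     rep(context, length.out = length(pos)),
                     rep(tri, length.out = length(pos)),
                     rep(m, length.out = length(pos)),
                     rep(u, length.out = length(pos)), seqinfo = si)
}

quickCalls <- function(sites) callSites(sites, pErr = 1e-4)

featureRow <- function(chrom, start, end, strand, type, id, parent = "") {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                 strand = strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(type = type, ID = id,
                                                 Parent = parent)
    gr
}

## --- independent oracles --------------------------------------------

## Upper-tail binomial probability by direct mass summation.
bruteBinomP <- function(k, n, p) {
    j <- k:n
    sum(choose(n, j) * p^j * (1 - p)^(n - j))
}

## Two-sided Fisher p by explicit hypergeometric enumeration (lchoose
## route, independent of dhyper); same conventional tie band.
bruteFisherP <- function(m1, u1, m2, u2, relErr = 1 + 1e-7) {
    r1 <- m1 + u1; r2 <- m2 + u2; c1 <- m1 + m2; N <- r1 + r2
    ks <- max(0, c1 - r2):min(c1, r1)
    lp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(N, c1)
    pr <- exp(lp)
    pObs <- pr[ks == m1]
    min(1, sum(pr[pr <= pObs * relErr]))
}

## Per-position brute-force cytosine/context enumeration of one sequence
## string; tests every position on both strands directly.
bruteContexts <- function(seqStr) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    h <- c("A", "T", "C")
    chars <- strsplit(seqStr, "", fixed = TRUE)[[1L]]
    n <- length(chars)
    classify1 <- function(tri) {
        if (length(tri) < 1L || tri[1L] != "C") return(NA_character_)
        b2 <- if (length(tri) >= 2L) tri[2L] else ""
        if (b2 == "G") return("CG")
        if (!b2 %in% h) return(NA_character_)
        b3 <- if (length(tri) >= 3L) tri[3L] else ""
        if (b3 == "G") return("CHG")
        if (b3 %in% h) return("CHH")
        NA_character_
    }
    ctxP <- vapply(seq_len(n), function(i)
        if (chars[i] == "C") classify1(chars[i:min(n, i + 2L)])
        else NA_character_, character(1L))
    ctxM <- vapply(seq_len(n), function(i)
        if (chars[i] == "G")
            classify1(unname(comp[chars[i:max(1L, i - 2L)]]))
        else NA_character_, character(1L))
    triOf <- function(i, strand) {
        if (strand == "+")
            paste(chars[i:min(n, i + 2L)], collapse = "")
        else paste(comp[chars[i:max(1L, i - 2L)]], collapse = "")
    }
    pp <- which(!is.na(ctxP)); mp <- which(!is.na(ctxM))
    df <- rbind(
        data.frame(pos = pp, strand = rep("+", length(pp)),
                   context = ctxP[pp],
                   trinucleotide = vapply(pp, triOf, "", strand = "+"),
                   stringsAsFactors = FALSE),
        data.frame(pos = mp, strand = rep("-", length(mp)),
                   context = ctxM[mp],
                   trinucleotide = vapply(mp, triOf, "", strand = "-"),
                   stringsAsFactors = FALSE))
    ## trinucleotide truncation: decidable terminal CG keeps 2 bases; trim
    ## any trailing bases beyond what the string holds (already exact)
    df <- df[order(df$pos, df$strand), , drop = FALSE]
    rownames(df) <- NULL
    df
}

## GRanges -> plain data.frame for comparison with bruteContexts.
sitesAsDf <- function(gr) {
    df <- data.frame(pos = BiocGenerics::start(gr),
                     strand = as.character(BiocGenerics::strand(gr)),
                     context = S4Vectors::mcols(gr)$context,
                     trinucleotide = S4Vectors::mcols(gr)$trinucleotide,
                     stringsAsFactors = FALSE)
    df <- df[order(df$pos, df$strand), , drop = FALSE]
    rownames(df) <- NULL
    df
}

## Whole-genome re-enumeration transition oracle: outer join of the two
## genomes' brute-force site sets.
bruteTransitions <- function(refStr, altStr) {
    a <- bruteContexts(refStr)
    b <- bruteContexts(altStr)
    keyA <- paste(a$pos, a$strand)
    keyB <- paste(b$pos, b$strand)
    onlyA <- !(keyA %in% keyB)
    onlyB <- !(keyB %in% keyA)
    shared <- match(keyB, keyA)
    changed <- which(!is.na(shared) & b$context != a$context[shared])
    rbind(
        data.frame(pos = a$pos[onlyA], strand = a$strand[onlyA],
                   contextRef = a$context[onlyA], contextAlt = "none",
                   stringsAsFactors = FALSE),
        data.frame(pos = b$pos[changed], strand = b$strand[changed],
                   contextRef = a$context[shared[changed]],
                   contextAlt = b$context[changed],
                   stringsAsFactors = FALSE),
        data.frame(pos = b$pos[onlyB], strand = b$strand[onlyB],
                   contextRef = "none", contextAlt = b$context[onlyB],
                   stringsAsFactors = FALSE))
}
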