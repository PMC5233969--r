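## Synthetic two-cultivar WGBS generator with ground truth. The generative
## model mirrors the measured structure of a plant methylome rather than
## any mechanistic model: per-context methylated-site probabilities pi,
## Beta-distributed levels at methylated sites (bimodal weighted-level
## landscape via per-gene high/low methylation classes), a non-conversion
## floor p_err at unmethylated sites, site-independent Poisson depth, an
## unmethylated chloroplast control, planted DMRs, SNP-induced context
## changes, and expression negatively coupled to exon methylation.

#' Create simulation parameters
#'
#' Builds a [MethylSimParams-class] object; any slot can be overridden by
#' name. See the class documentation for the meaning and defaults of each
#' parameter.
#'
#' @param ... named parameter overrides (e.g. `seed = 7`,
#'   `chromLength = 1e5`).
#' @return a validated `MethylSimParams` object.
#' @examples
#' simulationParams(seed = 7, nChroms = 1, chromLength = 50000)
#' @export
simulationParams <- function(...) {
    args <- list(...)
    proto <- methods::new("MethylSimParams")
    unknown <- setdiff(names(args), methods::slotNames("MethylSimParams"))
    if (length(unknown))
        stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    for (nm in names(args)) {
        v <- args[[nm]]
        if (is(methods::slot(proto, nm), "integer")) v <- as.integer(v)
        methods::slot(proto, nm) <- v
    }
    methods::validObject(proto)
    proto
}

.randomSeq <- function(n, gc) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

## Lay out one gene: exons/introns/UTRs as a data.frame of sub-features
## with coordinates relative to the gene start (1-based).
.geneStructure <- function(w) {
    nExons <- sample.int(3L, 1L)
    intronW <- max(80L, w %/% 10L)
    while (nExons > 1L && w - (nExons - 1L) * intronW < 150L * nExons)
        nExons <- nExons - 1L
    if (nExons == 1L) {
        ex <- data.frame(start = 1L, end = w)
    } else {
        exTotal <- w - (nExons - 1L) * intronW
        base <- exTotal %/% nExons
        exW <- c(rep(base, nExons - 1L), exTotal - base * (nExons - 1L))
        s <- integer(nExons); e <- integer(nExons)
        cur <- 1L
        for (i in seq_len(nExons)) {
            s[i] <- cur
            e[i] <- cur + exW[i] - 1L
            cur <- e[i] + intronW + 1L
        }
        ex <- data.frame(start = s, end = e)
    }
    ex
}

#' Simulate a genome, annotation and SNP set
#'
#' Generates i.i.d. bases at the configured GC fraction, places
#' non-overlapping genes (1-3 exons, synthesized introns, 100 bp terminal
#' UTRs on genes long enough) and transposable elements with random gaps,
#' a separate chloroplast sequence of the same composition, and uniform
#' SNP positions (avoiding the two terminal bases of each chromosome so
#' context windows stay decidable) with the alternate allele drawn
#' uniformly from the three non-reference bases.
#'
#' The caller controls the RNG state (seed once, e.g. via
#' [simulateDataset()], for a single reproducible stream).
#'
#' @param params a [MethylSimParams-class] object.
#' @return a list with `genome`, `chloroplast` (DNAStringSets),
#'   `features` (GRanges: gene/exon/intron/UTR/TE), `snps` (GRanges with
#'   ref/alt), `altGenome` (SNP-substituted genome).
#' @export
simulateGenome <- function(params) {
    p <- params
    chromNames <- paste0("chr", seq_len(p@nChroms))
    seqs <- vapply(chromNames, function(x)
        .randomSeq(p@chromLength, p@gcFraction), character(1L))
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- chromNames
    chloroplast <- Biostrings::DNAStringSet(
        stats::setNames(.randomSeq(p@chloroplastLength, p@gcFraction),
                        "chloroplast"))
    ## feature placement: genes and TEs round-robin across chromosomes
    featLen <- c(if (p@nGenes) sample(p@geneLengthMin:p@geneLengthMax,
                                      p@nGenes, replace = TRUE),
                 if (p@nTEs) sample(p@teLengthMin:p@teLengthMax, p@nTEs,
                                    replace = TRUE))
    featType <- c(rep("gene", p@nGenes), rep("TE", p@nTEs))
    ord <- sample(length(featLen))
    featLen <- featLen[ord]; featType <- featType[ord]
    chromOf <- rep_len(seq_len(p@nChroms), length(featLen))
    rows <- list()
    geneCounter <- 0L; teCounter <- 0L
    for (ci in seq_len(p@nChroms)) {
        idx <- which(chromOf == ci)
        lens <- featLen[idx]
        minGap <- 100L
        need <- sum(lens) + minGap * (length(idx) + 1L)
        if (need > p@chromLength)
            stop("configuration error: requested features exceed placeable ",
                 "capacity on ", chromNames[ci], " (need ", need, " bp of ",
                 p@chromLength, ")")
        slack <- p@chromLength - sum(lens) - minGap * (length(idx) + 1L)
        u <- stats::runif(length(idx) + 1L)
        extra <- floor(slack * u / sum(u))
        gaps <- minGap + extra
        cur <- 1L
        for (k in seq_along(idx)) {
            cur <- cur + gaps[k]
            fStart <- cur
            fEnd <- cur + lens[k] - 1L
            cur <- fEnd + 1L
            if (featType[idx[k]] == "TE") {
                teCounter <- teCounter + 1L
                rows[[length(rows) + 1L]] <- data.frame(
                    chrom = chromNames[ci], start = fStart, end = fEnd,
                    strand = "+", type = "TE",
                    ID = sprintf("TE%04d", teCounter), Parent = "",
                    stringsAsFactors = FALSE)
            } else {
                geneCounter <- geneCounter + 1L
                gid <- sprintf("gene%04d", geneCounter)
                strand <- sample(c("+", "-"), 1L)
                ex <- .geneStructure(lens[k])
                sub <- list(data.frame(
                    chrom = chromNames[ci], start = fStart, end = fEnd,
                    strand = strand, type = "gene", ID = gid, Parent = "",
                    stringsAsFactors = FALSE))
                for (j in seq_len(nrow(ex))) {
                    sub[[length(sub) + 1L]] <- data.frame(
                        chrom = chromNames[ci],
                        start = fStart + ex$start[j] - 1L,
                        end = fStart + ex$end[j] - 1L,
                        strand = strand, type = "exon",
                        ID = paste0(gid, ".exon", j), Parent = gid,
                        stringsAsFactors = FALSE)
                    if (j < nrow(ex))
                        sub[[length(sub) + 1L]] <- data.frame(
                            chrom = chromNames[ci],
                            start = fStart + ex$end[j],
                            end = fStart + ex$start[j + 1L] - 2L,
                            strand = strand, type = "intron",
                            ID = paste0(gid, ".intron", j), Parent = gid,
                            stringsAsFactors = FALSE)
                }
                if (lens[k] >= 500L && ex$end[1L] >= 150L) {
                    utr5 <- c(fStart, fStart + 99L)
                    utr3 <- c(fEnd - 99L, fEnd)
                    if (strand == "-") { tmp <- utr5; utr5 <- utr3
                                         utr3 <- tmp }
                    sub[[length(sub) + 1L]] <- data.frame(
                        chrom = chromNames[ci], start = utr5[1L],
                        end = utr5[2L], strand = strand,
                        type = "five_prime_UTR",
                        ID = paste0(gid, ".utr5"), Parent = gid,
                        stringsAsFactors = FALSE)
                    sub[[length(sub) + 1L]] <- data.frame(
                        chrom = chromNames[ci], start = utr3[1L],
                        end = utr3[2L], strand = strand,
                        type = "three_prime_UTR",
                        ID = paste0(gid, ".utr3"), Parent = gid,
                        stringsAsFactors = FALSE)
                }
                rows <- c(rows, sub)
            }
        }
    }
    fdf <- do.call(rbind, rows)
    si <- GenomeInfoDb::Seqinfo(seqnames = chromNames,
                                seqlengths = rep(p@chromLength, p@nChroms))
    features <- GenomicRanges::GRanges(
        factor(fdf$chrom, levels = chromNames),
        IRanges::IRanges(fdf$start, fdf$end), strand = fdf$strand,
        seqinfo = si)
    S4Vectors::mcols(features) <- S4Vectors::DataFrame(
        type = fdf$type, ID = fdf$ID, Parent = fdf$Parent)
    features <- sort(features, ignore.strand = TRUE)
    ## SNPs: uniform over positions 3 .. L-2 of each chromosome
    validPer <- p@chromLength - 4L
    if (p@nSNPs > validPer * p@nChroms)
        stop("configuration error: more SNPs requested than placeable ",
             "positions")
    flat <- sample.int(validPer * p@nChroms, p@nSNPs)
    snpChrom <- chromNames[(flat - 1L) %/% validPer + 1L]
    snpPos <- (flat - 1L) %% validPer + 3L
    refBase <- .refBaseAt(genome, snpChrom, snpPos)
    altBase <- vapply(refBase, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L),
        USE.NAMES = FALSE)
    snps <- GenomicRanges::GRanges(factor(snpChrom, levels = chromNames),
                                   IRanges::IRanges(snpPos, width = 1L),
                                   seqinfo = si)
    S4Vectors::mcols(snps) <- S4Vectors::DataFrame(ref = refBase,
                                                   alt = altBase)
    snps <- sort(snps, ignore.strand = TRUE)
    list(genome = genome, chloroplast = chloroplast, features = features,
         snps = snps, altGenome = applySNPs(genome, snps))
}

## Per-gene class assignment with exact counts: nHigh genes get the high
## site rate so the expected genome-wide methylated fraction stays pinned
## at pi without binomial class-count noise.
.assignClasses <- function(nGenes, pi, high, low) {
    rho <- (pi - low) / (high - low)
    rho <- min(1, max(0, rho))
    nHigh <- round(rho * nGenes)
    sample(rep(c(TRUE, FALSE), c(nHigh, nGenes - nHigh)))
}

#' Simulate two-sample methylomes with ground truth
#'
#' For every context-decidable cytosine (both strands) of the reference
#' genome: a true methylation state (Bernoulli with context-specific
#' probability; within gene bodies CG and CHG states follow per-gene
#' high/low classes so gene-body weighted levels are bimodal), a true
#' level (Beta at methylated sites, the non-conversion rate p_err at
#' unmethylated ones), Poisson depth and Binomial methylated counts.
#' Sample B shares sample A's truth except: inside planted DMRs the level
#' is shifted by `dmrDelta` (random direction per DMR, clamped to [0,1]);
#' at SNP-changed contexts states are redrawn from the new context's
#' probability over the substituted genome's cytosines; silenced genes
#' have their exon sites forced to high methylation. Chloroplast sites
#' are unmethylated-truth (level p_err) in both samples.
#'
#' The caller controls the RNG state (see [simulateDataset()]).
#'
#' @param genome,chloroplast,features,snps,altGenome as produced by
#'   [simulateGenome()].
#' @param params a [MethylSimParams-class] object.
#' @return a list: `sampleA`, `sampleB`, `controlA`, `controlB`
#'   ([MethylSiteCounts]); `truth` (list with `siteA`, `siteB`
#'   data.frames, `dmrs` GRanges with `shift`, `transitions` data.frame,
#'   `geneClasses` data.frame).
#' @export
simulateMethylomes <- function(genome, chloroplast, features, snps, params,
                               altGenome = NULL) {
    p <- params
    if (is.null(altGenome)) altGenome <- applySNPs(genome, snps)
    sitesRef <- enumerateCytosines(genome)
    sitesAlt <- enumerateCytosines(altGenome)
    ctxRef <- S4Vectors::mcols(sitesRef)$context
    nRef <- length(sitesRef)
    piOf <- c(CG = p@piCG, CHG = p@piCHG, CHH = p@piCHH)
    rate <- unname(piOf[ctxRef])
    type <- S4Vectors::mcols(features)$type
    genes <- features[type == "gene"]
    nGenes <- length(genes)
    geneClasses <- NULL
    if (nGenes) {
        classCG <- .assignClasses(nGenes, p@piCG, p@highSiteRate,
                                  p@lowSiteRate)
        classCHG <- .assignClasses(nGenes, p@piCHG, p@highSiteRate,
                                   p@lowSiteRate)
        nEx <- round(p@fracExonOnly * nGenes)
        nIn <- round(p@fracIntronOnly * nGenes)
        ## compartment patterns only make sense for genes that have both
        ## compartments, i.e. multi-exon genes
        multiExon <- genes$ID %in%
            S4Vectors::mcols(features)$Parent[type == "intron"]
        patIdx <- sample(which(multiExon))
        if (nEx + nIn > length(patIdx))
            stop("configuration error: not enough multi-exon genes for ",
                 "the requested compartment patterns")
        pattern <- rep("uniform", nGenes)
        pattern[patIdx[seq_len(nEx)]] <- "exonOnly"
        if (nIn) pattern[patIdx[nEx + seq_len(nIn)]] <- "intronOnly"
        silenced <- rep(FALSE, nGenes)
        if (p@nSilenced)
            silenced[sample(which(pattern == "uniform"), p@nSilenced)] <- TRUE
        ov <- GenomicRanges::findOverlaps(sitesRef, genes,
                                          ignore.strand = TRUE,
                                          select = "first")
        inExon <- IRanges::overlapsAny(sitesRef,
                                             features[type == "exon"],
                                             ignore.strand = TRUE)
        inIntron <- IRanges::overlapsAny(sitesRef,
                                               features[type == "intron"],
                                               ignore.strand = TRUE)
        genic <- !is.na(ov)
        for (cx in c("CG", "CHG")) {
            cls <- if (cx == "CG") classCG else classCHG
            sel <- genic & ctxRef == cx
            g <- ov[sel]
            rate[sel] <- ifelse(cls[g], p@highSiteRate, p@lowSiteRate)
        }
        ## compartment patterns: zero out the silent compartment (CG+CHG)
        zeroSel <- (genic & ctxRef %in% c("CG", "CHG")) &
            ((pattern[ifelse(is.na(ov), 1L, ov)] == "exonOnly" & inIntron) |
             (pattern[ifelse(is.na(ov), 1L, ov)] == "intronOnly" & inExon))
        rate[zeroSel] <- 0
        geneClasses <- data.frame(gene = genes$ID, classCG = classCG,
                                  classCHG = classCHG, pattern = pattern,
                                  silenced = silenced,
                                  stringsAsFactors = FALSE)
    }
    ## TEs: heavily methylated in every context
    inTE <- rep(FALSE, nRef)
    if (any(type == "TE")) {
        inTE <- IRanges::overlapsAny(sitesRef, features[type == "TE"],
                                     ignore.strand = TRUE)
        rate[inTE] <- pmax(rate[inTE], p@highSiteRate)
    }
    ## recalibrate background (non-gene, non-TE) rates so the expected
    ## genome-wide methylated fraction stays pinned at pi per context
    inFeature <- inTE
    if (nGenes)
        inFeature <- inFeature | IRanges::overlapsAny(sitesRef, genes,
                                                      ignore.strand = TRUE)
    for (cx in .CONTEXTS) {
        isCx <- ctxRef == cx
        bg <- isCx & !inFeature
        if (!any(bg)) next
        deficit <- piOf[[cx]] * sum(isCx) - sum(rate[isCx])
        adj <- deficit / sum(bg)
        rate[bg] <- pmin(1, pmax(0, rate[bg] + adj))
    }
    stateA <- stats::rbinom(nRef, 1L, rate) == 1L
    levelA <- ifelse(stateA, stats::rbeta(nRef, p@betaShape1, p@betaShape2),
                     p@pErr)
    ## planted DMRs in gaps between features
    dmrs <- .placeDMRs(genome, features, p)
    ## sample B truth over the substituted genome's sites
    keyRef <- .siteKey(sitesRef)
    keyAlt <- .siteKey(sitesAlt)
    ctxAlt <- S4Vectors::mcols(sitesAlt)$context
    nAlt <- length(sitesAlt)
    mref <- match(keyAlt, keyRef)
    sameCtx <- !is.na(mref) & ctxRef[ifelse(is.na(mref), 1L, mref)] == ctxAlt
    stateB <- logical(nAlt)
    levelB <- numeric(nAlt)
    stateB[sameCtx] <- stateA[mref[sameCtx]]
    levelB[sameCtx] <- levelA[mref[sameCtx]]
    fresh <- !sameCtx
    if (any(fresh)) {
        fRate <- unname(piOf[ctxAlt[fresh]])
        fState <- stats::rbinom(sum(fresh), 1L, fRate) == 1L
        stateB[fresh] <- fState
        levelB[fresh] <- ifelse(fState,
                                stats::rbeta(sum(fresh), p@betaShape1,
                                             p@betaShape2), p@pErr)
    }
    if (length(dmrs)) {
        inD <- GenomicRanges::findOverlaps(sitesAlt, dmrs,
                                           ignore.strand = TRUE,
                                           select = "first")
        hit <- !is.na(inD)
        shift <- dmrs$shift[ifelse(is.na(inD), 1L, inD)]
        levelB[hit] <- pmin(1, pmax(0, levelB[hit] + shift[hit]))
        stateB[hit] <- levelB[hit] > 0.5
    }
    if (!is.null(geneClasses) && any(geneClasses$silenced)) {
        silGenes <- genes[geneClasses$silenced]
        silExons <- features[type == "exon" &
                             features$Parent %in% silGenes$ID]
        inSil <- IRanges::overlapsAny(sitesAlt, silExons,
                                            ignore.strand = TRUE)
        if (any(inSil)) {
            stateB[inSil] <- TRUE
            levelB[inSil] <- stats::rbeta(sum(inSil), 20, 2)
        }
    }
    draw <- function(sites, level) {
        depth <- stats::rpois(length(sites), p@meanDepth)
        nm <- stats::rbinom(length(sites), depth, level)
        MethylSiteCounts(GenomeInfoDb::seqnames(sites),
                         BiocGenerics::start(sites),
                         BiocGenerics::strand(sites),
                         S4Vectors::mcols(sites)$context,
                         S4Vectors::mcols(sites)$trinucleotide,
                         nm, depth - nm,
                         seqinfo = GenomeInfoDb::seqinfo(sites))
    }
    sampleA <- draw(sitesRef, levelA)
    sampleB <- draw(sitesAlt, levelB)
    sitesChl <- enumerateCytosines(chloroplast)
    controlA <- draw(sitesChl, rep(p@pErr, length(sitesChl)))
    controlB <- draw(sitesChl, rep(p@pErr, length(sitesChl)))
    ## ground-truth transition table by whole-genome re-enumeration diff
    onlyRef <- is.na(match(keyRef, keyAlt))
    changed <- which(!sameCtx & !is.na(mref))
    gained <- which(is.na(mref))
    onlyRefIdx <- which(onlyRef)
    transitions <- rbind(
        data.frame(chrom = as.character(GenomeInfoDb::seqnames(sitesRef))[onlyRefIdx],
                   pos = BiocGenerics::start(sitesRef)[onlyRefIdx],
                   strand = as.character(BiocGenerics::strand(sitesRef))[onlyRefIdx],
                   contextRef = ctxRef[onlyRefIdx],
                   contextAlt = rep("none", length(onlyRefIdx)),
                   stringsAsFactors = FALSE),
        data.frame(chrom = as.character(GenomeInfoDb::seqnames(sitesAlt))[changed],
                   pos = BiocGenerics::start(sitesAlt)[changed],
                   strand = as.character(BiocGenerics::strand(sitesAlt))[changed],
                   contextRef = ctxRef[mref[changed]],
                   contextAlt = ctxAlt[changed],
                   stringsAsFactors = FALSE),
        data.frame(chrom = as.character(GenomeInfoDb::seqnames(sitesAlt))[gained],
                   pos = BiocGenerics::start(sitesAlt)[gained],
                   strand = as.character(BiocGenerics::strand(sitesAlt))[gained],
                   contextRef = rep("none", length(gained)),
                   contextAlt = ctxAlt[gained],
                   stringsAsFactors = FALSE))
    truth <- list(
        siteA = data.frame(
            chrom = as.character(GenomeInfoDb::seqnames(sitesRef)),
            pos = BiocGenerics::start(sitesRef),
            strand = as.character(BiocGenerics::strand(sitesRef)),
            context = ctxRef, state = stateA, level = levelA,
            stringsAsFactors = FALSE),
        siteB = data.frame(
            chrom = as.character(GenomeInfoDb::seqnames(sitesAlt)),
            pos = BiocGenerics::start(sitesAlt),
            strand = as.character(BiocGenerics::strand(sitesAlt)),
            context = ctxAlt, state = stateB, level = levelB,
            contextChanged = !sameCtx, stringsAsFactors = FALSE),
        dmrs = dmrs, transitions = transitions, geneClasses = geneClasses)
    list(sampleA = sampleA, sampleB = sampleB, controlA = controlA,
         controlB = controlB, truth = truth)
}

## Place non-overlapping fixed-width DMR windows clear of genes and TEs.
.placeDMRs <- function(genome, features, p) {
    si <- GenomeInfoDb::Seqinfo(seqnames = names(genome),
                                seqlengths = BiocGenerics::width(genome))
    if (!p@nPlantedDMRs)
        return(GenomicRanges::GRanges(seqinfo = si))
    avoid <- GenomicRanges::reduce(features, ignore.strand = TRUE)
    placed <- GenomicRanges::GRanges(seqinfo = si)
    tries <- 0L
    while (length(placed) < p@nPlantedDMRs && tries < 50L * p@nPlantedDMRs) {
        tries <- tries + 1L
        ch <- sample(names(genome), 1L)
        L <- BiocGenerics::width(genome)[match(ch, names(genome))]
        s <- sample.int(L - p@dmrWidth, 1L)
        cand <- GenomicRanges::GRanges(ch,
                                       IRanges::IRanges(s,
                                                        width = p@dmrWidth),
                                       seqinfo = si)
        if (GenomicRanges::countOverlaps(cand, avoid,
                                         ignore.strand = TRUE) == 0L &&
            (!length(placed) ||
             GenomicRanges::countOverlaps(cand, placed,
                                          ignore.strand = TRUE) == 0L))
            placed <- c(placed, cand)
    }
    if (length(placed) < p@nPlantedDMRs)
        stop("configuration error: could not place ", p@nPlantedDMRs,
             " DMRs clear of features")
    placed$shift <- sample(c(-1, 1), length(placed),
                           replace = TRUE) * p@dmrDelta
    placed$id <- paste0("dmr", seq_along(placed))
    sort(placed, ignore.strand = TRUE)
}

#' Simulate replicate-level expression coupled to methylation
#'
#' Per gene and sample, the log mean expression is
#' `intercept - beta * L + N(0, sigma)` where `L` is the true exon CG
#' weighted level of the gene in that sample (mean of true site levels
#' over exon CG cytosines); replicate abundances are log-normal around
#' the mean. Planted silenced genes get abundance 0 in sample B. Paralog
#' pairs are disjoint random gene pairs; the negative coupling within
#' each sample induces the negative fold-change relationship between
#' pairs.
#'
#' The caller controls the RNG state (see [simulateDataset()]).
#'
#' @param features GRanges from [simulateGenome()].
#' @param truth the `truth` element of [simulateMethylomes()] output.
#' @param params a [MethylSimParams-class] object.
#' @return a list: `expression` (data.frame gene_id/sample/replicate/
#'   abundance, samples `"A"` and `"B"`), `paralogs` (data.frame
#'   gene_a/gene_b), `degs` (data.frame gene_id/lower_sample),
#'   `geneTruth` (data.frame with true exon levels and mean expressions).
#' @export
simulateExpression <- function(features, truth, params) {
    p <- params
    type <- S4Vectors::mcols(features)$type
    genes <- features[type == "gene"]
    exons <- features[type == "exon"]
    nGenes <- length(genes)
    if (!nGenes) {
        empty <- data.frame(gene_id = character(), sample = character(),
                            replicate = integer(), abundance = numeric(),
                            stringsAsFactors = FALSE)
        return(list(expression = empty,
                    paralogs = data.frame(gene_a = character(),
                                          gene_b = character(),
                                          stringsAsFactors = FALSE),
                    degs = data.frame(gene_id = character(),
                                      lower_sample = character(),
                                      stringsAsFactors = FALSE),
                    geneTruth = NULL))
    }
    exonLevelOf <- function(siteDf) {
        gr <- GenomicRanges::GRanges(siteDf$chrom,
                                     IRanges::IRanges(siteDf$pos,
                                                      width = 1L))
        sel <- siteDf$context == "CG"
        ov <- GenomicRanges::findOverlaps(gr[sel], exons,
                                          ignore.strand = TRUE,
                                          select = "first")
        gid <- exons$Parent[ov]
        lv <- tapply(siteDf$level[sel][!is.na(ov)], gid[!is.na(ov)], mean)
        out <- as.numeric(lv[match(genes$ID, names(lv))])
        ifelse(is.na(out), 0, out)
    }
    lA <- exonLevelOf(truth$siteA)
    lB <- exonLevelOf(truth$siteB)
    silenced <- if (!is.null(truth$geneClasses))
        truth$geneClasses$silenced else rep(FALSE, nGenes)
    logMeanA <- p@exprIntercept - p@exprBeta * lA +
        stats::rnorm(nGenes, 0, p@exprSigma)
    logMeanB <- p@exprIntercept - p@exprBeta * lB +
        stats::rnorm(nGenes, 0, p@exprSigma)
    meanA <- exp(logMeanA)
    meanB <- ifelse(silenced, 0, exp(logMeanB))
    reps <- function(mu) {
        muRep <- rep(mu, each = p@nReplicates)
        ab <- exp(log(pmax(muRep, .Machine$double.xmin)) +
                  stats::rnorm(length(muRep), 0, 0.2))
        ab[muRep == 0] <- 0
        ab
    }
    expression <- rbind(
        data.frame(gene_id = rep(genes$ID, each = p@nReplicates),
                   sample = rep("A", nGenes * p@nReplicates),
                   replicate = rep(seq_len(p@nReplicates), nGenes),
                   abundance = reps(meanA),
                   stringsAsFactors = FALSE),
        data.frame(gene_id = rep(genes$ID, each = p@nReplicates),
                   sample = rep("B", nGenes * p@nReplicates),
                   replicate = rep(seq_len(p@nReplicates), nGenes),
                   abundance = reps(meanB),
                   stringsAsFactors = FALSE))
    pick <- sample(nGenes, 2L * p@nParalogPairs)
    paralogs <- data.frame(
        gene_a = genes$ID[pick[seq_len(p@nParalogPairs)]],
        gene_b = genes$ID[pick[p@nParalogPairs + seq_len(p@nParalogPairs)]],
        stringsAsFactors = FALSE)
    degs <- data.frame(gene_id = genes$ID[silenced],
                       lower_sample = rep("B", sum(silenced)),
                       stringsAsFactors = FALSE)
    geneTruth <- data.frame(gene = genes$ID, exonLevelA = lA,
                            exonLevelB = lB, meanExprA = meanA,
                            meanExprB = meanB, silenced = silenced,
                            stringsAsFactors = FALSE)
    list(expression = expression, paralogs = paralogs, degs = degs,
         geneTruth = geneTruth)
}

#' Simulate a complete two-cultivar dataset
#'
#' Seeds the RNG once from `params@seed` (a single reproducible stream)
#' and runs [simulateGenome()], [simulateMethylomes()] and
#' [simulateExpression()]. Identical parameters give identical output.
#'
#' @param params a [MethylSimParams-class] object
#'   (default [simulationParams()]).
#' @return a list with elements `genome`, `chloroplast`, `altGenome`,
#'   `features`, `snps`, `sampleA`, `sampleB`, `controlA`, `controlB`,
#'   `expression`, `paralogs`, `degs`, `truth`, `params`.
#' @examples
#' \donttest{
#' sim <- simulateDataset(simulationParams(seed = 1, nChroms = 1,
#'                                         chromLength = 20000,
#'                                         nGenes = 5, nTEs = 2,
#'                                         nPlantedDMRs = 3, nSNPs = 20,
#'                                         chloroplastLength = 5000,
#'                                         nSilenced = 1,
#'                                         nParalogPairs = 2))
#' sim$sampleA
#' }
#' @export
simulateDataset <- function(params = simulationParams()) {
    set.seed(params@seed)
    g <- simulateGenome(params)
    m <- simulateMethylomes(g$genome, g$chloroplast, g$features, g$snps,
                            params, altGenome = g$altGenome)
    e <- simulateExpression(g$features, m$truth, params)
    m$truth$geneTruth <- e$geneTruth
    list(genome = g$genome, chloroplast = g$chloroplast,
         altGenome = g$altGenome, features = g$features, snps = g$snps,
         sampleA = m$sampleA, sampleB = m$sampleB,
         controlA = m$controlA, controlB = m$controlB,
         expression = e$expression, paralogs = e$paralogs, degs = e$degs,
         truth = m$truth, params = params)
}

#' Write a simulated dataset to disk
#'
#' Writes every external file of a simulated dataset: `genome.fa`,
#' `chloroplast.fa`, `features.gff3`, `snps.vcf`, per-sample CX reports
#' (`sampleA.CX.txt`, `sampleB.CX.txt`, `controlA.CX.txt`,
#' `controlB.CX.txt`), `expression.tsv`, `paralogs.tsv`, `degs.tsv`, and
#' ground-truth tables under `truth/`. Deterministic: identical datasets
#' give byte-identical files.
#'
#' @param sim output of [simulateDataset()].
#' @param outDir output directory (created if absent).
#' @return `outDir`, invisibly.
#' @export
writeSimulation <- function(sim, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    dir.create(file.path(outDir, "truth"), showWarnings = FALSE)
    Biostrings::writeXStringSet(sim$genome, file.path(outDir, "genome.fa"))
    Biostrings::writeXStringSet(sim$chloroplast,
                                file.path(outDir, "chloroplast.fa"))
    feat <- sim$features
    S4Vectors::mcols(feat)$type <- ifelse(feat$type == "TE",
                                          "transposable_element",
                                          feat$type)
    rtracklayer::export(feat, file.path(outDir, "features.gff3"),
                        format = "gff3")
    .writeMinimalVCF(sim$snps, sim$genome, file.path(outDir, "snps.vcf"))
    writeCXReport(sim$sampleA, file.path(outDir, "sampleA.CX.txt"))
    writeCXReport(sim$sampleB, file.path(outDir, "sampleB.CX.txt"))
    writeCXReport(sim$controlA, file.path(outDir, "controlA.CX.txt"))
    writeCXReport(sim$controlB, file.path(outDir, "controlB.CX.txt"))
    utils::write.table(sim$expression, file.path(outDir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$paralogs, file.path(outDir, "paralogs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$degs, file.path(outDir, "degs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth$siteA,
                       file.path(outDir, "truth", "siteA.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth$siteB,
                       file.path(outDir, "truth", "siteB.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(sim$truth$dmrs),
                       file.path(outDir, "truth", "dmrs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth$transitions,
                       file.path(outDir, "truth", "transitions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sim$truth$geneTruth))
        utils::write.table(sim$truth$geneTruth,
                           file.path(outDir, "truth", "genes.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(outDir)
}

.writeMinimalVCF <- function(snps, genome, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##fileformat=VCFv4.2", con)
    for (i in seq_along(genome))
        writeLines(sprintf("##contig=<ID=%s,length=%d>", names(genome)[i],
                           BiocGenerics::width(genome)[i]), con)
    writeLines(paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"), con)
    if (length(snps)) {
        rows <- paste(as.character(GenomeInfoDb::seqnames(snps)),
                      BiocGenerics::start(snps), ".", snps$ref, snps$alt,
                      ".", "PASS", ".", sep = "\t")
        writeLines(rows, con)
    }
    invisible(path)
}
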