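## Methylation-expression integration: per-gene summaries, rank
## correlation of gene-body methylation with expression, exon-vs-intron
## compartment effects, paralog fold-change comparison, and case reports
## for differentially expressed genes. Rank (Spearman) statistics are used
## throughout: expression scales are heavy-tailed and the associations of
## interest are monotone, not linear.

#' Per-gene methylation and expression summary
#'
#' Computes, for one sample: gene-body weighted levels per context,
#' exon/intron compartment pooled corrected counts and levels for one
#' context (default CG), and the mean expression over replicates.
#'
#' @param calls a [MethylCalls] object for the sample.
#' @param features a [GenomicRanges::GRanges] from [readGFFFeatures()]
#'   (types gene/exon/intron with `Parent` linking to gene IDs).
#' @param expression a data.frame as from [readExpressionTable()].
#' @param sample the sample label to take expression from; defaults to
#'   the single label present (error if ambiguous).
#' @param compartmentContext context for the exon/intron compartment
#'   counts (default `"CG"`).
#' @param counts `"corrected"` (default) or `"raw"`.
#' @return a data.frame keyed by `gene` with columns `levelCG`,
#'   `levelCHG`, `levelCHH`, `exonMeth`, `exonTotal`, `exonLevel`,
#'   `intronMeth`, `intronTotal`, `intronLevel`, `meanExpr`.
#' @export
summarizeGenes <- function(calls, features, expression, sample = NULL,
                           compartmentContext = "CG",
                           counts = c("corrected", "raw")) {
    counts <- match.arg(counts)
    type <- S4Vectors::mcols(features)$type
    genes <- features[type == "gene"]
    if (!length(genes)) stop("no gene features supplied")
    gid <- genes$ID
    wl <- weightedLevels(calls, genes, counts = counts)
    lev <- function(cx) wl$level[wl$context == cx][match(gid,
                                                    wl$region[wl$context == cx])]
    compart <- function(what) {
        sub <- features[type == what]
        if (!length(sub))
            return(data.frame(m = rep(0, length(gid)),
                              t = rep(0, length(gid))))
        w <- weightedLevels(calls, sub, contexts = compartmentContext,
                            counts = counts)
        m <- rowsum(w$numerator, sub$Parent)
        t <- rowsum(w$denominator, sub$Parent)
        i <- match(gid, rownames(m))
        data.frame(m = ifelse(is.na(i), 0, m[i, 1L]),
                   t = ifelse(is.na(i), 0, t[i, 1L]))
    }
    ex <- compart("exon")
    intr <- compart("intron")
    if (is.null(sample)) {
        ss <- unique(expression$sample)
        if (length(ss) != 1L)
            stop("expression has several samples; specify `sample`")
        sample <- ss
    }
    expr <- expression[expression$sample == sample, , drop = FALSE]
    me <- tapply(expr$abundance, expr$gene_id, mean)
    out <- data.frame(
        gene = gid,
        levelCG = lev("CG"), levelCHG = lev("CHG"), levelCHH = lev("CHH"),
        exonMeth = ex$m, exonTotal = ex$t,
        exonLevel = ifelse(ex$t > 0, ex$m / ex$t, NA_real_),
        intronMeth = intr$m, intronTotal = intr$t,
        intronLevel = ifelse(intr$t > 0, intr$m / intr$t, NA_real_),
        meanExpr = as.numeric(me[match(gid, names(me))]),
        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

.spearman <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                           exact = FALSE))
    list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Association between gene-body methylation and expression
#'
#' Spearman rank correlation between the gene-body weighted level of one
#' context and mean expression, plus a binned summary (median expression
#' per methylation-level bin) showing e.g. that highly methylated genes
#' are rarely expressed.
#'
#' @param geneSummaries output of [summarizeGenes()].
#' @param context context whose gene-body level to use (default `"CG"`).
#' @param binWidth width of the level bins (default 0.05).
#' @return a list with `rho`, `p`, `n`, and `bins` (data.frame with
#'   `binStart`, `binEnd`, `nGenes`, `medianExpr`).
#' @export
methylationExpressionAssociation <- function(geneSummaries, context = "CG",
                                             binWidth = 0.05) {
    lv <- geneSummaries[[paste0("level", context)]]
    ex <- geneSummaries$meanExpr
    ok <- !is.na(lv) & !is.na(ex)
    if (sum(ok) < 10L)
        stop("fewer than 10 genes with defined level and expression")
    st <- .spearman(lv, ex)
    edges <- seq(0, 1, by = binWidth)
    if (edges[length(edges)] < 1) edges <- c(edges, 1)
    bin <- cut(lv[ok], breaks = edges, include.lowest = TRUE, right = FALSE)
    bins <- data.frame(
        binStart = edges[-length(edges)], binEnd = edges[-1L],
        nGenes = as.integer(table(bin)),
        medianExpr = as.numeric(tapply(ex[ok], bin, stats::median)))
    list(rho = st$rho, p = st$p, n = st$n, bins = bins)
}

#' Exon-vs-intron compartment effect on expression
#'
#' Set E holds genes with zero corrected methylated reads in introns and
#' more than zero in exons; set I the converse. For each set the
#' methylation-expression association is evaluated on the respective
#' compartment level (exon level for E, intron level for I); the
#' difference of Spearman rho is the compartment effect contrast. A set
#' with fewer than 10 usable genes is reported as not evaluable rather
#' than an error.
#'
#' @param geneSummaries output of [summarizeGenes()].
#' @return a list with `nE`, `nI`, `rhoE`, `pE`, `rhoI`, `pI`,
#'   `deltaRho` (`rhoE - rhoI`), `evaluableE`, `evaluableI`.
#' @export
compartmentEffect <- function(geneSummaries) {
    gs <- geneSummaries
    inE <- gs$intronMeth == 0 & gs$exonMeth > 0 & gs$intronTotal > 0
    inI <- gs$exonMeth == 0 & gs$intronMeth > 0 & gs$exonTotal > 0
    evalSet <- function(sel, levelCol) {
        d <- gs[sel, , drop = FALSE]
        ok <- !is.na(d[[levelCol]]) & !is.na(d$meanExpr)
        if (sum(ok) < 10L)
            return(list(rho = NA_real_, p = NA_real_, n = sum(ok),
                        evaluable = FALSE))
        st <- .spearman(d[[levelCol]], d$meanExpr)
        c(st, list(evaluable = TRUE))
    }
    e <- evalSet(inE, "exonLevel")
    i <- evalSet(inI, "intronLevel")
    list(nE = sum(inE), nI = sum(inI),
         rhoE = e$rho, pE = e$p, rhoI = i$rho, pI = i$p,
         deltaRho = e$rho - i$rho,
         evaluableE = e$evaluable, evaluableI = i$evaluable)
}

#' Paralog methylation/expression fold changes
#'
#' For each paralog pair computes pseudocount-stabilised log2 fold changes
#' of gene-body methylation level and of mean expression, and their
#' Spearman correlation across pairs. Pairs with a member missing from
#' the summaries (or with undefined level) are skipped and counted.
#'
#' @param pairs a data.frame with columns `gene_a`, `gene_b`.
#' @param geneSummaries output of [summarizeGenes()].
#' @param context context whose gene-body level to use (default `"CG"`).
#' @param pseudocount stabiliser added to both levels and expressions
#'   before the ratio (default 0.01).
#' @return a data.frame with columns `gene_a`, `gene_b`, `levelA`,
#'   `levelB`, `exprA`, `exprB`, `methFC`, `exprFC`; attributes `rho`,
#'   `p`, `nSkipped`.
#' @export
paralogFoldChanges <- function(pairs, geneSummaries, context = "CG",
                               pseudocount = 0.01) {
    stopifnot(pseudocount > 0)
    lvCol <- paste0("level", context)
    ia <- match(pairs$gene_a, geneSummaries$gene)
    ib <- match(pairs$gene_b, geneSummaries$gene)
    wA <- geneSummaries[[lvCol]][ia]
    wB <- geneSummaries[[lvCol]][ib]
    eA <- geneSummaries$meanExpr[ia]
    eB <- geneSummaries$meanExpr[ib]
    ok <- !is.na(wA) & !is.na(wB) & !is.na(eA) & !is.na(eB)
    out <- data.frame(gene_a = pairs$gene_a[ok], gene_b = pairs$gene_b[ok],
                      levelA = wA[ok], levelB = wB[ok],
                      exprA = eA[ok], exprB = eB[ok],
                      methFC = log2((wA[ok] + pseudocount) /
                                    (wB[ok] + pseudocount)),
                      exprFC = log2((eA[ok] + pseudocount) /
                                    (eB[ok] + pseudocount)),
                      stringsAsFactors = FALSE)
    st <- if (nrow(out) >= 3L) .spearman(out$methFC, out$exprFC) else
        list(rho = NA_real_, p = NA_real_, n = nrow(out))
    attr(out, "rho") <- st$rho
    attr(out, "p") <- st$p
    attr(out, "nSkipped") <- sum(!ok)
    out
}

#' Flag candidate methylation-silencing cases among DEGs
#'
#' For each externally supplied differentially expressed gene (DEG),
#' reports the exon methylation level in both samples, whether a
#' significant DMR overlaps the gene's downstream window (strand-aware,
#' default 2 kb), and flags the gene when the lower-expressed sample has
#' the higher exon methylation or a downstream DMR hypermethylated in it.
#'
#' @param geneSummariesA,geneSummariesB outputs of [summarizeGenes()]
#'   for the two samples.
#' @param degs a data.frame with columns `gene_id` and `lower_sample`
#'   (`"A"` or `"B"`, the sample with lower expression).
#' @param features a [GenomicRanges::GRanges] with gene features (needed
#'   when `dmrs` is supplied).
#' @param dmrs optional [GenomicRanges::GRanges] from [dmrScan()].
#' @param downstreamBp downstream window size (default 2000).
#' @return a data.frame with one row per DEG: `gene_id`, `lower_sample`,
#'   `exonLevelA`, `exonLevelB`, `downstreamDMR`, `dmrHyperIn`,
#'   `flagged`.
#' @export
flagSilencingCases <- function(geneSummariesA, geneSummariesB, degs,
                               features = NULL, dmrs = NULL,
                               downstreamBp = 2000L) {
    cols <- c("gene_id", "lower_sample", "exonLevelA", "exonLevelB",
              "downstreamDMR", "dmrHyperIn", "flagged")
    if (is.null(degs) || !nrow(degs)) {
        out <- data.frame(gene_id = character(), lower_sample = character(),
                          exonLevelA = numeric(), exonLevelB = numeric(),
                          downstreamDMR = logical(),
                          dmrHyperIn = character(), flagged = logical(),
                          stringsAsFactors = FALSE)
        return(out[, cols])
    }
    ia <- match(degs$gene_id, geneSummariesA$gene)
    ib <- match(degs$gene_id, geneSummariesB$gene)
    exA <- geneSummariesA$exonLevel[ia]
    exB <- geneSummariesB$exonLevel[ib]
    dsDMR <- rep(FALSE, nrow(degs))
    hyperIn <- rep(NA_character_, nrow(degs))
    if (!is.null(dmrs) && length(dmrs) && !is.null(features)) {
        type <- S4Vectors::mcols(features)$type
        genes <- features[type == "gene"]
        gi <- match(degs$gene_id, genes$ID)
        known <- !is.na(gi)
        if (any(known)) {
            g <- genes[gi[known]]
            minus <- as.character(BiocGenerics::strand(g)) == "-"
            dsStart <- ifelse(minus,
                              pmax(BiocGenerics::start(g) - downstreamBp, 1L),
                              BiocGenerics::end(g) + 1L)
            dsEnd <- ifelse(minus, BiocGenerics::start(g) - 1L,
                            BiocGenerics::end(g) + downstreamBp)
            okWin <- dsEnd >= dsStart
            win <- GenomicRanges::GRanges(
                GenomeInfoDb::seqnames(g)[okWin],
                IRanges::IRanges(dsStart[okWin], dsEnd[okWin]))
            sig <- dmrs[!is.na(dmrs$significant) & dmrs$significant]
            hits <- GenomicRanges::findOverlaps(win, sig,
                                                ignore.strand = TRUE)
            hitIdx <- which(known)[which(okWin)][S4Vectors::queryHits(hits)]
            dsDMR[hitIdx] <- TRUE
            dir <- sig$direction[S4Vectors::subjectHits(hits)]
            hyperIn[hitIdx] <- ifelse(dir == "hyperA", "A",
                                      ifelse(dir == "hyperB", "B", NA))
        }
    }
    lower <- degs$lower_sample
    exLower <- ifelse(lower == "A", exA, exB)
    exOther <- ifelse(lower == "A", exB, exA)
    methHigher <- !is.na(exLower) & !is.na(exOther) & exLower > exOther
    dmrConcord <- dsDMR & !is.na(hyperIn) & hyperIn == lower
    data.frame(gene_id = degs$gene_id, lower_sample = lower,
               exonLevelA = exA, exonLevelB = exB,
               downstreamDMR = dsDMR, dmrHyperIn = hyperIn,
               flagged = methHigher | dmrConcord,
               stringsAsFactors = FALSE)
}
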