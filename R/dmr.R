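## Two-sample comparisons: per-site Fisher tests, sliding-window DMR
## detection (200 bp windows stepping 50 bp, candidate if a sample pools
## more than 5 corrected methylated reads, significant at Fisher p < 0.01),
## and gene-level differential methylation on pooled gene-body counts.

## Exact two-sided Fisher p for one 2x2 table (m1, u1 / m2, u2) at fixed
## margins: sum of hypergeometric probabilities <= the observed table's
## probability. relErr is the conventional tie band (cf. stats::fisher.test).
.fisher1 <- function(m1, u1, m2, u2, relErr = 1 + 1e-7) {
    r1 <- m1 + u1
    r2 <- m2 + u2
    c1 <- m1 + m2
    if (r1 + r2 == 0) stop("all-zero contingency table")
    if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == r1 + r2)
        return(1)    # degenerate margin: only one table possible
    kk <- max(0, c1 - r2):min(c1, r1)
    probs <- stats::dhyper(kk, r1, r2, c1)
    pObs <- probs[m1 - kk[1L] + 1L]
    min(1, sum(probs[probs <= pObs * relErr]))
}

#' Two-sided Fisher's exact test on a 2x2 count table
#'
#' Exact two-sided p-value for the table `rbind(c(m1, u1), c(m2, u2))`
#' at fixed margins, computed by summing all hypergeometric outcome
#' probabilities not exceeding the observed table's probability.
#' Vectorised over its arguments. Tables with a zero margin (but not all
#' zero) are degenerate — only one outcome is possible — and return 1.
#'
#' @param m1,u1 methylated/unmethylated counts in sample 1.
#' @param m2,u2 methylated/unmethylated counts in sample 2.
#' @return p-value(s) in `[0, 1]`.
#' @examples
#' fisherTwoSided(10, 0, 0, 10)   # 2 / choose(20, 10)
#' @export
fisherTwoSided <- function(m1, u1, m2, u2) {
    n <- max(length(m1), length(u1), length(m2), length(u2))
    m1 <- rep_len(as.numeric(m1), n); u1 <- rep_len(as.numeric(u1), n)
    m2 <- rep_len(as.numeric(m2), n); u2 <- rep_len(as.numeric(u2), n)
    if (any(c(m1, u1, m2, u2) < 0)) stop("counts must be non-negative")
    vapply(seq_len(n),
           function(i) .fisher1(m1[i], u1[i], m2[i], u2[i]),
           numeric(1L))
}

## Fisher p for many tables with de-duplication of identical count
## quadruples (site- and window-level data repeat tables heavily).
.fisherMany <- function(m1, u1, m2, u2) {
    key <- paste(m1, u1, m2, u2, sep = "_")
    uk <- !duplicated(key)
    pu <- vapply(which(uk), function(i) .fisher1(m1[i], u1[i], m2[i], u2[i]),
                 numeric(1L))
    unname(pu[match(key, key[uk])])
}

.siteKey <- function(x) {
    paste(GenomeInfoDb::seqnames(x), BiocGenerics::start(x),
          BiocGenerics::strand(x), sep = ":")
}

#' Per-site differential methylation between two samples
#'
#' Intersects the two call sets on sites with raw depth >= 1 in both
#' samples (the "commonly called" set), applies the two-sided Fisher test
#' to the corrected counts of each common site, and flags sites with
#' `p < pThreshold` (raw p-values; the per-site survey is reported
#' unadjusted).
#'
#' @param callsA,callsB [MethylCalls] objects on the same reference
#'   coordinates.
#' @param pThreshold significance threshold (default 0.01).
#' @param counts `"corrected"` (default) or `"raw"`.
#' @param adjust `"none"` (default, raw p-values as the survey statistic
#'   is conventionally reported) or `"BH"` to flag on
#'   Benjamini-Hochberg-adjusted p-values instead.
#' @return a [GenomicRanges::GRanges] of common sites with metadata
#'   columns `context`, `mA`, `uA`, `mB`, `uB`, `p`, `differential`;
#'   attributes `nCommon` and `nDifferential`.
#' @export
perSiteTests <- function(callsA, callsB, pThreshold = 0.01,
                         counts = c("corrected", "raw"),
                         adjust = c("none", "BH")) {
    adjust <- match.arg(adjust)
    cntA <- .countsOf(callsA, counts)
    cntB <- .countsOf(callsB, counts)
    covA <- siteDepth(callsA) >= 1L
    covB <- siteDepth(callsB) >= 1L
    keyA <- .siteKey(callsA)
    keyB <- .siteKey(callsB)
    idxB <- match(keyA, keyB)
    common <- covA & !is.na(idxB) & covB[ifelse(is.na(idxB), 1L, idxB)]
    if (!any(common)) stop("no site is covered in both samples")
    ia <- which(common)
    ib <- idxB[common]
    p <- .fisherMany(cntA[ia, "m"], cntA[ia, "u"],
                     cntB[ib, "m"], cntB[ib, "u"])
    pFlag <- if (adjust == "BH") stats::p.adjust(p, method = "BH") else p
    out <- GenomicRanges::granges(callsA[ia])
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        context = methContext(callsA)[ia],
        mA = cntA[ia, "m"], uA = cntA[ia, "u"],
        mB = cntB[ib, "m"], uB = cntB[ib, "u"],
        p = p, differential = pFlag < pThreshold)
    attr(out, "nCommon") <- length(out)
    attr(out, "nDifferential") <- sum(pFlag < pThreshold)
    out
}

#' Sliding-window DMR scan
#'
#' Slides fixed-width windows (default 200 bp, stepping 50 bp, i.e. 150 bp
#' overlap) along every chromosome — fully contained windows only — and
#' pools the corrected methylated/unmethylated counts of both samples in
#' each window (all contexts together by default). A window is a
#' candidate DMR iff its pooled methylated reads exceed `minMethReads`
#' (strictly) in at least one sample; a candidate is significant iff the
#' two-sided Fisher test on the pooled counts gives `p < pThreshold`.
#' Direction compares the window weighted levels.
#'
#' @param callsA,callsB [MethylCalls] objects on shared coordinates.
#' @param windowBp window width (default 200).
#' @param stepBp step between window starts (default 50).
#' @param minMethReads candidate threshold, strict (default 5, i.e. >= 6
#'   pooled methylated reads).
#' @param pThreshold significance threshold (default 0.01).
#' @param context optional single context to restrict the scan to
#'   (default `NULL`: all contexts pooled).
#' @param counts `"corrected"` (default) or `"raw"`.
#' @param adjust `"none"` (default) or `"BH"` to call significance on
#'   Benjamini-Hochberg-adjusted p-values across the candidate windows.
#' @return a [GenomicRanges::GRanges] of candidate windows with metadata
#'   columns `mA`, `uA`, `mB`, `uB`, `p`, `direction` (`"hyperA"` /
#'   `"hyperB"` / `"none"`), `significant`; attribute `nWindows` is the
#'   total number of windows scanned.
#' @export
dmrScan <- function(callsA, callsB, windowBp = 200L, stepBp = 50L,
                    minMethReads = 5L, pThreshold = 0.01,
                    context = NULL, counts = c("corrected", "raw"),
                    adjust = c("none", "BH")) {
    stopifnot(windowBp > stepBp, stepBp >= 1L)
    adjust <- match.arg(adjust)
    cntA <- .countsOf(callsA, counts)
    cntB <- .countsOf(callsB, counts)
    if (!is.null(context)) {
        selA <- methContext(callsA) == context
        selB <- methContext(callsB) == context
    } else {
        selA <- rep(TRUE, length(callsA))
        selB <- rep(TRUE, length(callsB))
    }
    seqlen <- GenomeInfoDb::seqlengths(callsA)
    if (any(is.na(seqlen)))
        stop("calls must carry seqlengths for a window scan")
    starts <- lapply(names(seqlen), function(ch) {
        L <- seqlen[[ch]]
        if (L < windowBp) {
            message("dmrScan: chromosome ", ch, " shorter than window; ",
                    "no windows")
            return(integer())
        }
        seq.int(1L, L - windowBp + 1L, by = stepBp)
    })
    nPer <- lengths(starts)
    windows <- GenomicRanges::GRanges(
        rep(names(seqlen), nPer),
        IRanges::IRanges(unlist(starts), width = windowBp),
        seqinfo = GenomeInfoDb::seqinfo(callsA))
    poolTo <- function(calls, cnt, sel, win) {
        m <- rep(0, length(win)); u <- rep(0, length(win))
        hits <- GenomicRanges::findOverlaps(calls[sel], win,
                                            ignore.strand = TRUE)
        qi <- which(sel)[S4Vectors::queryHits(hits)]
        si <- S4Vectors::subjectHits(hits)
        if (length(si)) {
            aggM <- rowsum(as.numeric(cnt[qi, "m"]), si)
            aggU <- rowsum(as.numeric(cnt[qi, "u"]), si)
            m[as.integer(rownames(aggM))] <- aggM[, 1L]
            u[as.integer(rownames(aggU))] <- aggU[, 1L]
        }
        cbind(m = m, u = u)
    }
    pa <- poolTo(callsA, cntA, selA, windows)
    pb <- poolTo(callsB, cntB, selB, windows)
    cand <- pa[, "m"] > minMethReads | pb[, "m"] > minMethReads
    out <- windows[cand]
    mA <- pa[cand, "m"]; uA <- pa[cand, "u"]
    mB <- pb[cand, "m"]; uB <- pb[cand, "u"]
    p <- if (length(out)) .fisherMany(mA, uA, mB, uB) else numeric()
    lvA <- ifelse(mA + uA > 0, mA / (mA + uA), NA_real_)
    lvB <- ifelse(mB + uB > 0, mB / (mB + uB), NA_real_)
    direction <- rep("none", length(out))
    direction[!is.na(lvA) & !is.na(lvB) & lvA > lvB] <- "hyperA"
    direction[!is.na(lvA) & !is.na(lvB) & lvA < lvB] <- "hyperB"
    pFlag <- if (adjust == "BH") stats::p.adjust(p, method = "BH") else p
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        mA = mA, uA = uA, mB = mB, uB = uB, p = p,
        direction = direction, significant = pFlag < pThreshold)
    attr(out, "nWindows") <- length(windows)
    attr(out, "nCandidates") <- length(out)
    out
}

#' Gene-level differential methylation
#'
#' Pools corrected counts of one context over each gene body in both
#' samples and applies the two-sided Fisher test. Genes with zero pooled
#' depth in either sample are excluded and counted.
#'
#' @param callsA,callsB [MethylCalls] objects on shared coordinates.
#' @param features a [GenomicRanges::GRanges] with a `type` column
#'   containing genes (or any GRanges of gene bodies).
#' @param context the context to test (default `"CG"`).
#' @param pThreshold significance threshold (default 0.01).
#' @param counts `"corrected"` (default) or `"raw"`.
#' @return a data.frame with columns `gene`, `mA`, `uA`, `mB`, `uB`, `p`,
#'   `significant`; attributes `nTested` and `nExcluded`.
#' @export
geneDifferential <- function(callsA, callsB, features, context = "CG",
                             pThreshold = 0.01,
                             counts = c("corrected", "raw")) {
    type <- S4Vectors::mcols(features)$type
    genes <- if (!is.null(type)) features[type == "gene"] else features
    if (!length(genes)) stop("no gene features supplied")
    wa <- weightedLevels(callsA, genes, contexts = context, counts = counts)
    wb <- weightedLevels(callsB, genes, contexts = context, counts = counts)
    mA <- wa$numerator; uA <- wa$denominator - wa$numerator
    mB <- wb$numerator; uB <- wb$denominator - wb$numerator
    tested <- wa$denominator > 0 & wb$denominator > 0
    p <- rep(NA_real_, length(tested))
    if (any(tested))
        p[tested] <- .fisherMany(mA[tested], uA[tested],
                                 mB[tested], uB[tested])
    out <- data.frame(gene = wa$region, mA = mA, uA = uA, mB = mB, uB = uB,
                      p = p,
                      significant = !is.na(p) & p < pThreshold,
                      stringsAsFactors = FALSE)
    out <- out[tested, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "nTested") <- sum(tested)
    attr(out, "nExcluded") <- sum(!tested)
    out
}
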