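## Binomial methylation calling against a bisulfite non-conversion rate
## estimated from an unmethylated control (the chloroplast genome in
## plants). Only an excess of methylated reads over the non-conversion
## rate is evidence of methylation, so the test is one-sided upper-tail.

#' Estimate the bisulfite non-conversion rate from an unmethylated control
#'
#' Pools all contexts over all control-sequence cytosines and returns
#' `pErr = sum(nMeth) / sum(nMeth + nUnmeth)` — the fraction of reads on a
#' genuinely unmethylated sequence that nevertheless report methylation
#' (conversion failures).
#'
#' @param controlCounts a [MethylSiteCounts] object from the control
#'   (chloroplast) sequence only.
#' @return a list with elements `pErr`, `nMethControl`, `nTotalControl`.
#' @examples
#' ctl <- MethylSiteCounts("chlr", 1:2, "+", "CHH", "CTT", c(0L, 1L),
#'                         c(500L, 499L))
#' estimateNonConversion(ctl)$pErr
#' @export
estimateNonConversion <- function(controlCounts) {
    stopifnot(methods::is(controlCounts, "MethylSiteCounts"))
    nm <- sum(as.numeric(nMeth(controlCounts)))
    nt <- nm + sum(as.numeric(nUnmeth(controlCounts)))
    if (nt <= 0)
        stop("cannot estimate non-conversion: zero total control depth")
    list(pErr = nm / nt, nMethControl = nm, nTotalControl = nt)
}

#' One-sided binomial p-value for methylation
#'
#' Upper-tail probability `P(X >= nMeth)` for
#' `X ~ Binomial(nTotal, pErr)`: the chance of seeing at least the
#' observed number of methylated reads if the site were unmethylated and
#' all apparent methylation came from conversion failure. Vectorised;
#' exact (no normal approximation).
#'
#' @param nMeth observed methylated read count(s).
#' @param nTotal total read count(s), `>= 1`.
#' @param pErr the non-conversion rate, in `[0, 1)`.
#' @return p-value(s) in `[0, 1]`.
#' @examples
#' binomialP(1, 10, 0.001114)   # 1 - (1 - 0.001114)^10
#' @export
binomialP <- function(nMeth, nTotal, pErr) {
    if (length(pErr) != 1L || pErr < 0 || pErr >= 1)
        stop("pErr must be a single value in [0, 1)")
    if (any(nTotal < 1L)) stop("nTotal must be >= 1")
    if (any(nMeth < 0L) || any(nMeth > nTotal))
        stop("nMeth must lie in [0, nTotal]")
    stats::pbinom(nMeth - 1, nTotal, pErr, lower.tail = FALSE)
}

## Storey-type q-values with a fixed lambda: pi0 is estimated from the
## fraction of p-values above lambda, then scales the BH adjustment.
.qvalueStorey <- function(p, lambda = 0.5) {
    pi0 <- min(1, mean(p > lambda) / (1 - lambda))
    pi0 <- max(pi0, .Machine$double.eps)
    pmin(1, pi0 * stats::p.adjust(p, method = "BH"))
}

#' Call per-site methylation status
#'
#' For every covered site (depth >= 1) computes the one-sided binomial
#' p-value against `pErr`, converts p-values to q-values across all tested
#' sites of the sample (all contexts jointly), and calls a site methylated
#' iff `q < qThreshold`. Counts are then corrected: significant sites keep
#' their raw counts; at non-significant sites all reads are regarded as
#' unmethylated (`cMeth = 0`, `cUnmeth = depth`), conserving total reads.
#' Zero-coverage sites are never tested: they pass through with
#' `p = q = 1`, status unmethylated and corrected counts (0, 0).
#'
#' @param sites a [MethylSiteCounts] object for one sample.
#' @param pErr the non-conversion rate (see [estimateNonConversion()]).
#' @param qThreshold significance threshold on the q-value (default 0.01).
#' @param fdr FDR procedure: `"BH"` (Benjamini-Hochberg, default) or
#'   `"storey"`.
#' @return a [MethylCalls] object.
#' @export
callSites <- function(sites, pErr, qThreshold = 0.01,
                      fdr = c("BH", "storey")) {
    stopifnot(methods::is(sites, "MethylSiteCounts"))
    if (!length(sites)) stop("no sites supplied")
    fdr <- match.arg(fdr)
    if (qThreshold <= 0 || qThreshold >= 1)
        stop("qThreshold must lie in (0, 1)")
    nm <- nMeth(sites)
    depth <- nm + nUnmeth(sites)
    covered <- depth >= 1L
    p <- rep(1, length(sites))
    q <- rep(1, length(sites))
    if (any(covered)) {
        p[covered] <- binomialP(nm[covered], depth[covered], pErr)
        q[covered] <- switch(fdr,
                             BH = stats::p.adjust(p[covered], method = "BH"),
                             storey = .qvalueStorey(p[covered]))
    }
    meth <- covered & q < qThreshold
    mc <- S4Vectors::mcols(sites)
    mc$p <- p
    mc$q <- q
    mc$status <- ifelse(meth, "methylated", "unmethylated")
    mc$cMeth <- ifelse(meth, nm, 0L)
    mc$cUnmeth <- ifelse(meth, depth - nm, depth)
    base <- sites
    S4Vectors::mcols(base) <- mc
    methods::new("MethylCalls", base, pErr = pErr,
                 qThreshold = qThreshold, fdrMethod = fdr)
}

#' Filter calls by depth and per-site level
#'
#' Retains sites whose raw depth is strictly greater than `minDepth` and
#' whose raw per-site level `nMeth / depth` is strictly greater than
#' `minLevel` (the reliability filter "level > 90% with supporting depth
#' > 10" at the defaults). Note both comparisons are strict: at
#' `minLevel = 0` every site with zero methylated reads is dropped.
#'
#' @param calls a [MethylSiteCounts] or [MethylCalls] object.
#' @param minDepth depth cutoff (strict; default 10).
#' @param minLevel level cutoff (strict; default 0.9).
#' @return the filtered object, same class as the input.
#' @export
filterSites <- function(calls, minDepth = 10L, minLevel = 0.9) {
    stopifnot(minDepth >= 0L, minLevel >= 0, minLevel <= 1)
    depth <- siteDepth(calls)
    lev <- ifelse(depth > 0L, nMeth(calls) / depth, NA_real_)
    keep <- depth > minDepth & !is.na(lev) & lev > minLevel
    calls[keep]
}
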