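## Accessors and show methods for the site-level classes.

#' @name accessors
#' @title Accessors for MethylSiteCounts and MethylCalls
#' @description Column accessors for the site-level containers: raw counts
#'   (`nMeth`, `nUnmeth`), `siteDepth` (their sum), `siteLevel`
#'   (`nMeth / depth`, `NaN` at zero depth), `methContext`,
#'   `trinucleotide`; and for [MethylCalls]: `methStatus`,
#'   `correctedCounts` (two-column matrix), `pErr`, `qThreshold`.
#' @param x a [MethylSiteCounts] or [MethylCalls] object.
#' @return vectors parallel to `x` (a 2-column integer matrix for
#'   `correctedCounts`; single numbers for `pErr` and `qThreshold`).
NULL

#' @rdname accessors
#' @export
setGeneric("nMeth", function(x) standardGeneric("nMeth"))
#' @rdname accessors
#' @export
setGeneric("nUnmeth", function(x) standardGeneric("nUnmeth"))
#' @rdname accessors
#' @export
setGeneric("siteDepth", function(x) standardGeneric("siteDepth"))
#' @rdname accessors
#' @export
setGeneric("siteLevel", function(x) standardGeneric("siteLevel"))
#' @rdname accessors
#' @export
setGeneric("methContext", function(x) standardGeneric("methContext"))
#' @rdname accessors
#' @export
setGeneric("trinucleotide", function(x) standardGeneric("trinucleotide"))
#' @rdname accessors
#' @export
setGeneric("methStatus", function(x) standardGeneric("methStatus"))
#' @rdname accessors
#' @export
setGeneric("correctedCounts", function(x) standardGeneric("correctedCounts"))
#' @rdname accessors
#' @export
setGeneric("pErr", function(x) standardGeneric("pErr"))
#' @rdname accessors
#' @export
setGeneric("qThreshold", function(x) standardGeneric("qThreshold"))

#' @rdname accessors
setMethod("nMeth", "MethylSiteCounts",
          function(x) S4Vectors::mcols(x)$nMeth)
#' @rdname accessors
setMethod("nUnmeth", "MethylSiteCounts",
          function(x) S4Vectors::mcols(x)$nUnmeth)
#' @rdname accessors
setMethod("siteDepth", "MethylSiteCounts",
          function(x) S4Vectors::mcols(x)$nMeth + S4Vectors::mcols(x)$nUnmeth)
#' @rdname accessors
setMethod("siteLevel", "MethylSiteCounts", function(x) {
    d <- siteDepth(x)
    S4Vectors::mcols(x)$nMeth / d
})
#' @rdname accessors
setMethod("methContext", "MethylSiteCounts",
          function(x) S4Vectors::mcols(x)$context)
#' @rdname accessors
setMethod("trinucleotide", "MethylSiteCounts",
          function(x) S4Vectors::mcols(x)$trinucleotide)
#' @rdname accessors
setMethod("methStatus", "MethylCalls",
          function(x) S4Vectors::mcols(x)$status)
#' @rdname accessors
setMethod("correctedCounts", "MethylCalls", function(x) {
    cbind(cMeth = S4Vectors::mcols(x)$cMeth,
          cUnmeth = S4Vectors::mcols(x)$cUnmeth)
})
#' @rdname accessors
setMethod("pErr", "MethylCalls", function(x) x@pErr)
#' @rdname accessors
setMethod("qThreshold", "MethylCalls", function(x) x@qThreshold)

setMethod("show", "MethylSiteCounts", function(object) {
    ctx <- table(factor(methContext(object), levels = .CONTEXTS))
    cat(class(object), "with", length(object), "cytosine sites",
        sprintf("(CG: %d, CHG: %d, CHH: %d)\n",
                ctx[["CG"]], ctx[["CHG"]], ctx[["CHH"]]))
    d <- siteDepth(object)
    cat("  mean depth:", format(mean(d), digits = 4),
        "| zero-coverage sites:", sum(d == 0L), "\n")
    if (methods::is(object, "MethylCalls")) {
        cat("  called methylated:",
            sum(methStatus(object) == "methylated"),
            sprintf("(pErr = %.6g, q < %g, %s)\n",
                    object@pErr, object@qThreshold, object@fdrMethod))
    }
    invisible(object)
})

setMethod("show", "MethylSimParams", function(object) {
    cat("MethylSimParams: ", object@nChroms, " x ",
        object@chromLength, " bp nuclear genome + ",
        object@chloroplastLength, " bp chloroplast\n", sep = "")
    cat(sprintf("  pi(CG/CHG/CHH) = %.3f/%.3f/%.3f, pErr = %.6g, depth = %g\n",
                object@piCG, object@piCHG, object@piCHH,
                object@pErr, object@meanDepth))
    cat(sprintf("  %d genes, %d TEs, %d DMRs (delta %.2f), %d SNPs, seed %d\n",
                object@nGenes, object@nTEs, object@nPlantedDMRs,
                object@dmrDelta, object@nSNPs, object@seed))
    invisible(object)
})
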