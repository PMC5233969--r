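## Central S4 containers. Both site-level classes extend GRanges so that the
## whole GenomicRanges toolkit (overlaps, subsetting, seqinfo) applies
## directly; validity methods pin down the required metadata columns.

.CONTEXTS <- c("CG", "CHG", "CHH")

#' Per-cytosine bisulfite counts
#'
#' `MethylSiteCounts` extends [GenomicRanges::GRanges] with one range per
#' cytosine (width 1, strand `+`/`-`) and required metadata columns:
#' \describe{
#'   \item{`context`}{cytosine context, one of `CG`, `CHG`, `CHH`.}
#'   \item{`trinucleotide`}{the 3-mer read 5'->3' on the cytosine's own
#'     strand (2 characters for a chromosome-terminal `CG`).}
#'   \item{`nMeth`, `nUnmeth`}{non-negative read counts supporting the
#'     methylated / unmethylated state.}
#' }
#' Minus-strand cytosines carry the plus-strand coordinate of the G on the
#' plus strand (the Bismark convention), so coordinates are shared with the
#' reference genome throughout.
#'
#' @slot .Data see [GenomicRanges::GRanges].
#' @seealso [readCXReport()], [callSites()]
#' @exportClass MethylSiteCounts
setClass("MethylSiteCounts", contains = "GRanges")

.validMethylSiteCounts <- function(object) {
    msg <- character()
    mc <- S4Vectors::mcols(object)
    need <- c("context", "trinucleotide", "nMeth", "nUnmeth")
    miss <- setdiff(need, colnames(mc))
    if (length(miss))
        return(paste("missing metadata column(s):",
                     paste(miss, collapse = ", ")))
    if (length(object)) {
        if (any(BiocGenerics::width(object) != 1L))
            msg <- c(msg, "all ranges must have width 1")
        if (any(as.character(BiocGenerics::strand(object)) == "*"))
            msg <- c(msg, "strand must be '+' or '-'")
        if (any(!as.character(mc$context) %in% .CONTEXTS))
            msg <- c(msg, "context must be one of CG, CHG, CHH")
        if (any(mc$nMeth < 0L) || any(mc$nUnmeth < 0L))
            msg <- c(msg, "read counts must be non-negative")
        tri <- as.character(mc$trinucleotide)
        if (any(substr(tri, 1L, 1L) != "C")) {
            msg <- c(msg, "trinucleotide must start with C")
        } else {
            ctx <- classifyContext(tri)
            bad <- which(is.na(ctx) | ctx != as.character(mc$context))
            if (length(bad))
                msg <- c(msg,
                         paste0("context inconsistent with trinucleotide at ",
                                length(bad), " site(s), first at index ",
                                bad[1L]))
        }
    }
    if (length(msg)) msg else TRUE
}

setValidity("MethylSiteCounts", .validMethylSiteCounts)

#' Construct a MethylSiteCounts object
#'
#' @param seqnames chromosome names (character or factor).
#' @param pos 1-based position of the cytosine, in plus-strand coordinates.
#' @param strand `"+"` or `"-"`.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param trinucleotide 3-mer on the cytosine's own strand.
#' @param nMeth,nUnmeth read counts.
#' @param seqinfo optional [GenomeInfoDb::Seqinfo] carrying chromosome
#'   lengths; when present, positions are checked against them.
#' @return a `MethylSiteCounts` object sorted by (chrom, pos, strand).
#' @examples
#' MethylSiteCounts("chr1", 2, "+", "CG", "CGT", 3, 1)
#' @export
MethylSiteCounts <- function(seqnames, pos, strand, context, trinucleotide,
                             nMeth, nUnmeth, seqinfo = NULL) {
    gr <- GenomicRanges::GRanges(
        seqnames = seqnames,
        ranges = IRanges::IRanges(start = as.integer(pos), width = 1L),
        strand = strand)
    if (!is.null(seqinfo))
        GenomeInfoDb::seqinfo(gr) <- seqinfo[GenomeInfoDb::seqlevels(gr)]
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        context = as.character(context),
        trinucleotide = as.character(trinucleotide),
        nMeth = as.integer(nMeth),
        nUnmeth = as.integer(nUnmeth))
    methods::new("MethylSiteCounts", sort(gr, ignore.strand = FALSE))
}

#' Per-cytosine methylation calls
#'
#' `MethylCalls` extends [MethylSiteCounts] with the results of binomial
#' methylation calling ([callSites()]): metadata columns `p` (one-sided
#' upper-tail binomial p-value against the non-conversion rate), `q`
#' (FDR-adjusted), `status` (`"methylated"`/`"unmethylated"`), and the
#' corrected counts `cMeth`/`cUnmeth` (raw counts for significant sites,
#' all reads reassigned to unmethylated otherwise; total reads conserved).
#'
#' @slot pErr the non-conversion rate the calls were made against.
#' @slot qThreshold the q-value significance threshold.
#' @slot fdrMethod the FDR procedure used (`"BH"` or `"storey"`).
#' @seealso [callSites()]
#' @exportClass MethylCalls
setClass("MethylCalls", contains = "MethylSiteCounts",
         representation(pErr = "numeric", qThreshold = "numeric",
                        fdrMethod = "character"))

.validMethylCalls <- function(object) {
    msg <- character()
    mc <- S4Vectors::mcols(object)
    need <- c("p", "q", "status", "cMeth", "cUnmeth")
    miss <- setdiff(need, colnames(mc))
    if (length(miss))
        return(paste("missing metadata column(s):",
                     paste(miss, collapse = ", ")))
    if (length(object)) {
        if (any(mc$p < 0 | mc$p > 1, na.rm = TRUE) ||
            any(mc$q < 0 | mc$q > 1, na.rm = TRUE))
            msg <- c(msg, "p and q must lie in [0, 1]")
        if (any(!as.character(mc$status) %in%
                c("methylated", "unmethylated")))
            msg <- c(msg, "status must be methylated or unmethylated")
        if (any(mc$cMeth + mc$cUnmeth != mc$nMeth + mc$nUnmeth))
            msg <- c(msg, "corrected counts must conserve total reads")
        meth <- as.character(mc$status) == "methylated"
        if (any(mc$cMeth[!meth] != 0L))
            msg <- c(msg, "unmethylated sites must have cMeth = 0")
        if (any(mc$cMeth[meth] != mc$nMeth[meth]))
            msg <- c(msg, "methylated sites must keep raw counts")
    }
    if (length(object) &&
        (length(object@pErr) != 1L || object@pErr < 0 || object@pErr >= 1))
        msg <- c(msg, "pErr must be a single value in [0, 1)")
    if (length(msg)) msg else TRUE
}

setValidity("MethylCalls", .validMethylCalls)

#' Synthetic-dataset parameters
#'
#' Holds every tunable of the synthetic two-cultivar WGBS generator. The
#' defaults describe the desk-scale study conditions used throughout the
#' test suite: a 2 x 500 kb nuclear genome plus a 50 kb unmethylated
#' chloroplast, mean depth 30, per-context methylated-site probabilities
#' pi(CG/CHG/CHH) = 0.589/0.515/0.179, Beta(8, 2) methylated-site levels,
#' non-conversion rate 0.001114, 50 planted 200 bp DMRs with level shift
#' 0.8, and 2000 SNPs. The chloroplast is 100 kb so the control pools
#' about a million reads at the default depth. See [simulationParams()].
#'
#' @name MethylSimParams-class
#' @exportClass MethylSimParams
setClass("MethylSimParams",
    representation(
        seed = "integer",
        nChroms = "integer", chromLength = "integer",
        gcFraction = "numeric", chloroplastLength = "integer",
        piCG = "numeric", piCHG = "numeric", piCHH = "numeric",
        betaShape1 = "numeric", betaShape2 = "numeric",
        pErr = "numeric", meanDepth = "numeric",
        nGenes = "integer", geneLengthMin = "integer",
        geneLengthMax = "integer", flankLength = "integer",
        nTEs = "integer", teLengthMin = "integer", teLengthMax = "integer",
        nPlantedDMRs = "integer", dmrWidth = "integer", dmrDelta = "numeric",
        nSNPs = "integer",
        exprBeta = "numeric", exprSigma = "numeric", exprIntercept = "numeric",
        nReplicates = "integer",
        nSilenced = "integer", nParalogPairs = "integer",
        highSiteRate = "numeric", lowSiteRate = "numeric",
        fracExonOnly = "numeric", fracIntronOnly = "numeric"),
    prototype(
        seed = 1L,
        nChroms = 2L, chromLength = 500000L,
        gcFraction = 0.35, chloroplastLength = 100000L,
        piCG = 0.589, piCHG = 0.515, piCHH = 0.179,
        betaShape1 = 8, betaShape2 = 2,
        pErr = 0.001114, meanDepth = 30,
        nGenes = 250L, geneLengthMin = 1000L, geneLengthMax = 3000L,
        flankLength = 2000L,
        nTEs = 40L, teLengthMin = 500L, teLengthMax = 2000L,
        nPlantedDMRs = 50L, dmrWidth = 200L, dmrDelta = 0.8,
        nSNPs = 2000L,
        exprBeta = 3, exprSigma = 0.5, exprIntercept = 5,
        nReplicates = 3L,
        nSilenced = 4L, nParalogPairs = 80L,
        highSiteRate = 0.95, lowSiteRate = 0.15,
        fracExonOnly = 0.12, fracIntronOnly = 0.12))

.validMethylSimParams <- function(object) {
    msg <- character()
    probs <- c(gcFraction = object@gcFraction, piCG = object@piCG,
               piCHG = object@piCHG, piCHH = object@piCHH,
               pErr = object@pErr,
               highSiteRate = object@highSiteRate,
               lowSiteRate = object@lowSiteRate,
               fracExonOnly = object@fracExonOnly,
               fracIntronOnly = object@fracIntronOnly)
    bad <- names(probs)[probs < 0 | probs > 1]
    if (length(bad))
        msg <- c(msg, paste("probabilities out of [0,1]:",
                            paste(bad, collapse = ", ")))
    if (object@gcFraction <= 0 || object@gcFraction > 1)
        msg <- c(msg, "gcFraction must lie in (0, 1]")
    if (object@meanDepth < 0) msg <- c(msg, "meanDepth must be >= 0")
    if (object@dmrDelta <= 0 || object@dmrDelta > 1)
        msg <- c(msg, "dmrDelta must lie in (0, 1]")
    if (object@fracExonOnly + object@fracIntronOnly > 1)
        msg <- c(msg, "compartment-pattern fractions exceed 1")
    if (object@geneLengthMin > object@geneLengthMax ||
        object@teLengthMin > object@teLengthMax)
        msg <- c(msg, "length ranges must have min <= max")
    if (object@nSilenced > object@nGenes)
        msg <- c(msg, "nSilenced exceeds nGenes")
    if (2L * object@nParalogPairs > object@nGenes)
        msg <- c(msg, "nParalogPairs requires 2*nParalogPairs <= nGenes")
    if (length(msg)) msg else TRUE
}

setValidity("MethylSimParams", .validMethylSimParams)
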