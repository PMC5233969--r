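## Weighted methylation levels and profiles. The weighted level of a
## region is sum(m) / sum(m + u) over all cytosines of a context in the
## region — depth-weighted, so deep sites count more than shallow ones.
## Corrected (post-calling) counts feed all levels by default; raw counts
## are available for diagnostics.

.countsOf <- function(calls, counts = c("corrected", "raw")) {
    counts <- match.arg(counts)
    if (counts == "corrected") {
        if (!methods::is(calls, "MethylCalls"))
            stop("corrected counts require a MethylCalls object; ",
                 "use counts = \"raw\" for uncalled sites")
        cbind(m = S4Vectors::mcols(calls)$cMeth,
              u = S4Vectors::mcols(calls)$cUnmeth)
    } else {
        cbind(m = nMeth(calls), u = nUnmeth(calls))
    }
}

#' Weighted methylation levels of regions
#'
#' For each region and context, sums the (corrected) methylated and total
#' read counts over all sites of that context with
#' `start(region) <= pos <= end(region)`, both strands, and returns
#' `level = numerator / denominator`. A region without covered sites has
#' an undefined level (`NA`), which is distinct from 0.
#'
#' @param calls a [MethylCalls] object (or [MethylSiteCounts] with
#'   `counts = "raw"`).
#' @param regions a [GenomicRanges::GRanges]; region ids are taken from
#'   `names(regions)`, else an `ID` metadata column, else generated.
#' @param contexts contexts to evaluate (default all three).
#' @param counts `"corrected"` (default) or `"raw"`.
#' @return a data.frame with columns `region`, `context`, `numerator`,
#'   `denominator`, `level` (rows: regions x contexts).
#' @export
weightedLevels <- function(calls, regions,
                           contexts = c("CG", "CHG", "CHH"),
                           counts = c("corrected", "raw")) {
    cnt <- .countsOf(calls, counts)
    ids <- names(regions)
    if (is.null(ids)) ids <- S4Vectors::mcols(regions)$ID
    if (is.null(ids)) ids <- paste0("region_", seq_along(regions))
    unknown <- setdiff(as.character(unique(GenomeInfoDb::seqnames(regions))),
                       GenomeInfoDb::seqlevels(calls))
    if (length(unknown))
        stop("region chromosome(s) absent from calls: ",
             paste(unknown, collapse = ", "))
    ctx <- factor(methContext(calls), levels = contexts)
    hits <- GenomicRanges::findOverlaps(calls, regions, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    keep <- !is.na(ctx[qi])
    qi <- qi[keep]; si <- si[keep]
    grp <- interaction(factor(si, levels = seq_along(regions)), ctx[qi],
                       drop = FALSE)
    num <- rowsum(as.numeric(cnt[qi, "m"]), grp)
    den <- rowsum(as.numeric(cnt[qi, "m"] + cnt[qi, "u"]), grp)
    full <- expand.grid(region = seq_along(regions), context = contexts,
                        stringsAsFactors = FALSE)
    key <- paste(full$region, full$context, sep = ".")
    numerator <- stats::setNames(rep(0, length(key)), key)
    denominator <- numerator
    numerator[rownames(num)] <- num[, 1L]
    denominator[rownames(den)] <- den[, 1L]
    data.frame(region = ids[full$region], context = full$context,
               numerator = unname(numerator),
               denominator = unname(denominator),
               level = ifelse(denominator > 0, numerator / denominator,
                              NA_real_),
               stringsAsFactors = FALSE)
}

## 5'->3' bin layout for one feature: upstream flank bins, body bins,
## downstream flank bins. Equal-width bins with the remainder bases in the
## final (most 3') bin of each zone; genomic coordinates returned.
.featureBins <- function(start, end, strand, flankBp, bodyBins, flankBins) {
    w <- end - start + 1L
    zones <- list()
    if (flankBins > 0L && flankBp > 0L) {
        fw <- flankBp %/% flankBins
        upS <- -flankBp + (seq_len(flankBins) - 1L) * fw
        upE <- c(upS[-1L] - 1L, -1L)
        zones$up <- cbind(upS, upE)
    }
    bw <- w %/% bodyBins
    bS <- (seq_len(bodyBins) - 1L) * bw
    bE <- c(bS[-1L] - 1L, w - 1L)
    zones$body <- cbind(bS, bE)
    if (flankBins > 0L && flankBp > 0L) {
        fw <- flankBp %/% flankBins
        dnS <- w + (seq_len(flankBins) - 1L) * fw
        dnE <- c(dnS[-1L] - 1L, w + flankBp - 1L)
        zones$down <- cbind(dnS, dnE)
    }
    off <- do.call(rbind, zones)
    if (strand == "-") {
        gs <- end - off[, 2L]
        ge <- end - off[, 1L]
    } else {
        gs <- start + off[, 1L]
        ge <- start + off[, 2L]
    }
    cbind(start = gs, end = ge)
}

#' Metagene (or meta-feature) methylation profile
#'
#' Splits each feature body into `bodyBins` equal-width intervals
#' (remainder bases in the final, most 3' bin) and each flank into
#' `flankBins` intervals, computes the per-feature weighted level of one
#' context in every bin (minus-strand features reversed so bins run
#' 5'->3'), and averages across features. Bins with no covered sites in a
#' feature are excluded from that bin's mean (absence of data is not
#' hypomethylation). Features shorter than `bodyBins` bases are skipped
#' and counted.
#'
#' @param calls a [MethylCalls] object.
#' @param features a [GenomicRanges::GRanges] of features of one type.
#' @param flankBp flank width in bases (default 2000).
#' @param bodyBins,flankBins bin counts (defaults 20 and 20).
#' @param context the context to profile (default `"CG"`).
#' @param counts `"corrected"` (default) or `"raw"`.
#' @param aggregate `"mean"` (default; per-feature mean of bin levels) or
#'   `"pooled"` (counts pooled across features per bin).
#' @return a data.frame with columns `bin`, `zone`
#'   (upstream/body/downstream), `level` and `nFeatures` (features with a
#'   defined level in that bin); attribute `nSkipped` counts features
#'   shorter than `bodyBins`.
#' @export
metageneProfile <- function(calls, features, flankBp = 2000L,
                            bodyBins = 20L, flankBins = 20L,
                            context = "CG",
                            counts = c("corrected", "raw"),
                            aggregate = c("mean", "pooled")) {
    if (!length(features)) stop("empty feature list")
    stopifnot(flankBp >= 0L, bodyBins >= 1L)
    aggregate <- match.arg(aggregate)
    cnt <- .countsOf(calls, counts)
    sel <- methContext(calls) == context
    calls <- calls[sel]
    cnt <- cnt[sel, , drop = FALSE]
    short <- BiocGenerics::width(features) < bodyBins
    nSkipped <- sum(short)
    features <- features[!short]
    if (!length(features)) stop("all features shorter than bodyBins")
    useFlank <- flankBp > 0L && flankBins > 0L
    nBins <- bodyBins + if (useFlank) 2L * flankBins else 0L
    binList <- lapply(seq_along(features), function(i) {
        .featureBins(BiocGenerics::start(features)[i],
                     BiocGenerics::end(features)[i],
                     as.character(BiocGenerics::strand(features))[i],
                     if (useFlank) flankBp else 0L, bodyBins,
                     if (useFlank) flankBins else 0L)
    })
    bins <- do.call(rbind, binList)
    featIdx <- rep(seq_along(features), each = nBins)
    binIdx <- rep(seq_len(nBins), length(features))
    ok <- bins[, "end"] >= 1L
    binStart <- pmax(bins[, "start"], 1L)
    grBins <- GenomicRanges::GRanges(
        as.character(GenomeInfoDb::seqnames(features))[featIdx][ok],
        IRanges::IRanges(binStart[ok], bins[ok, "end"]))
    hits <- GenomicRanges::findOverlaps(calls, grBins, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    slot <- (which(ok))[si]
    nSlots <- length(featIdx)
    num <- rep(0, nSlots)
    den <- rep(0, nSlots)
    if (length(slot)) {
        aggN <- rowsum(as.numeric(cnt[qi, "m"]), slot)
        aggD <- rowsum(as.numeric(cnt[qi, "m"] + cnt[qi, "u"]), slot)
        num[as.integer(rownames(aggN))] <- aggN[, 1L]
        den[as.integer(rownames(aggD))] <- aggD[, 1L]
    }
    zone <- rep(if (useFlank)
        c(rep("upstream", flankBins), rep("body", bodyBins),
          rep("downstream", flankBins)) else rep("body", bodyBins),
        length(features))
    if (aggregate == "mean") {
        lev <- ifelse(den > 0, num / den, NA_real_)
        res <- vapply(seq_len(nBins), function(b) {
            v <- lev[binIdx == b]
            v <- v[!is.na(v)]
            c(level = if (length(v)) mean(v) else NA_real_,
              nFeatures = length(v))
        }, c(level = 0, nFeatures = 0))
    } else {
        res <- vapply(seq_len(nBins), function(b) {
            i <- binIdx == b
            d <- sum(den[i])
            c(level = if (d > 0) sum(num[i]) / d else NA_real_,
              nFeatures = sum(den[i] > 0))
        }, c(level = 0, nFeatures = 0))
    }
    out <- data.frame(bin = seq_len(nBins),
                      zone = zone[seq_len(nBins)],
                      level = res["level", ],
                      nFeatures = as.integer(res["nFeatures", ]),
                      stringsAsFactors = FALSE)
    attr(out, "nSkipped") <- nSkipped
    attr(out, "context") <- context
    out
}

#' Methylated-cytosine counts in fixed genomic windows
#'
#' Tiles every chromosome into non-overlapping windows of `windowBp`
#' (the last window truncated at the chromosome end) and counts calls
#' with status methylated per context — the 50 kb "methylation landscape"
#' summary at the default width.
#'
#' @param calls a [MethylCalls] object.
#' @param seqlengths a named vector of chromosome lengths, or a
#'   [Biostrings::DNAStringSet]; defaults to the seqlengths of `calls`.
#' @param windowBp window width (default 50000).
#' @return a [GenomicRanges::GRanges] of windows with metadata columns
#'   `CG`, `CHG`, `CHH` (methylated-site counts) and `total`.
#' @export
windowCounts <- function(calls, seqlengths = NULL, windowBp = 50000L) {
    stopifnot(windowBp >= 1L)
    if (is.null(seqlengths)) {
        seqlengths <- GenomeInfoDb::seqlengths(calls)
        if (any(is.na(seqlengths)))
            stop("calls carry no seqlengths; supply them explicitly")
    } else if (methods::is(seqlengths, "DNAStringSet")) {
        seqlengths <- stats::setNames(BiocGenerics::width(seqlengths),
                                      names(seqlengths))
    }
    tiles <- GenomicRanges::tileGenome(seqlengths, tilewidth = windowBp,
                                       cut.last.tile.in.chrom = TRUE)
    meth <- calls[methStatus(calls) == "methylated"]
    for (cx in .CONTEXTS) {
        S4Vectors::mcols(tiles)[[cx]] <- GenomicRanges::countOverlaps(
            tiles, meth[methContext(meth) == cx], ignore.strand = TRUE)
    }
    tiles$total <- tiles$CG + tiles$CHG + tiles$CHH
    tiles
}

#' Assign methylated sites to genomic categories
#'
#' Each methylated call is assigned exactly one category by the precedence
#' UTR > CDS (exon minus UTR) > intron > upstream (within `upstreamBp` of
#' a gene start, strand-aware) > intergenic, and tallied per context.
#'
#' @param calls a [MethylCalls] object.
#' @param features a [GenomicRanges::GRanges] from [readGFFFeatures()]
#'   (types gene/exon/intron/UTR).
#' @param upstreamBp upstream window size (default 1000).
#' @return a contexts x categories integer matrix whose grand total equals
#'   the number of methylated calls.
#' @export
categorizeSites <- function(calls, features, upstreamBp = 1000L) {
    meth <- calls[methStatus(calls) == "methylated"]
    type <- S4Vectors::mcols(features)$type
    genes <- features[type == "gene"]
    upstream <- GenomicRanges::trim(suppressWarnings(
        GenomicRanges::promoters(genes, upstream = upstreamBp,
                                 downstream = 0L)))
    catRegions <- list(
        UTR = features[type %in% c("five_prime_UTR", "three_prime_UTR")],
        CDS = features[type == "exon"],
        intron = features[type == "intron"],
        upstream = upstream)
    category <- rep("intergenic", length(meth))
    for (nm in names(catRegions)) {
        hit <- IRanges::overlapsAny(meth, catRegions[[nm]],
                                          ignore.strand = TRUE)
        category[hit & category == "intergenic"] <- nm
    }
    tab <- table(factor(methContext(meth), levels = .CONTEXTS),
                 factor(category, levels = c("UTR", "CDS", "intron",
                                             "upstream", "intergenic")))
    m <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
    m
}
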