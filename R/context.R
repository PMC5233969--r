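## Cytosine-context arithmetic. Contexts follow the plant convention
## CG / CHG / CHH with H in {A, T, C}, decided from the two bases 3' of the
## cytosine on its own strand. A context is assigned iff it is decidable
## from the available bases: a chromosome-terminal "CG" is still CG (the
## third base is irrelevant), while a terminal "C" or "CH" is undecidable
## and excluded, as is any context needing an N.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Classify a cytosine trinucleotide into CG / CHG / CHH
#'
#' Vectorised. The input is the 1-3 bases starting at the cytosine, read
#' 5'->3' on the cytosine's own strand. Returns `NA` where the context is
#' undecidable (missing bases still needed, or an `N` at a decisive
#' position).
#'
#' @param trinucleotide character vector; each element 1-3 uppercase bases,
#'   the first of which must be `C`.
#' @return character vector of `"CG"`, `"CHG"`, `"CHH"` or `NA`.
#' @examples
#' classifyContext(c("CGT", "CTG", "CTT", "CG", "CT", "CNT"))
#' @export
classifyContext <- function(trinucleotide) {
    tn <- as.character(trinucleotide)
    if (any(nchar(tn) < 1L | substr(tn, 1L, 1L) != "C"))
        stop("every trinucleotide must start with 'C'")
    b2 <- substr(tn, 2L, 2L)
    b3 <- substr(tn, 3L, 3L)
    h <- c("A", "T", "C")
    ctx <- rep(NA_character_, length(tn))
    ctx[b2 == "G"] <- "CG"
    ctx[b2 %in% h & b3 == "G"] <- "CHG"
    ctx[b2 %in% h & b3 %in% h] <- "CHH"
    ctx
}

## Vectorised context of positions `pos` (own strand `strand`) on a
## chromosome given as a character vector of bases. Returns NA where the
## position does not hold a cytosine on that strand or the context is
## undecidable.
.contextAt <- function(chars, pos, strand) {
    n <- length(chars)
    out <- rep(NA_character_, length(pos))
    ok <- pos >= 1L & pos <= n
    plus <- ok & strand == "+"
    if (any(plus)) {
        p <- pos[plus]
        isC <- chars[p] == "C"
        b2 <- ifelse(p + 1L <= n, chars[pmin(p + 1L, n)], "")
        b3 <- ifelse(p + 2L <= n, chars[pmin(p + 2L, n)], "")
        tri <- paste0("C", b2, b3)
        res <- rep(NA_character_, length(p))
        res[isC] <- classifyContext(tri[isC])
        out[plus] <- res
    }
    minus <- ok & strand == "-"
    if (any(minus)) {
        p <- pos[minus]
        isC <- chars[p] == "G"
        b2 <- ifelse(p - 1L >= 1L, .COMPLEMENT[chars[pmax(p - 1L, 1L)]], "")
        b3 <- ifelse(p - 2L >= 1L, .COMPLEMENT[chars[pmax(p - 2L, 1L)]], "")
        tri <- paste0("C", b2, b3)
        res <- rep(NA_character_, length(p))
        res[isC] <- classifyContext(tri[isC])
        out[minus] <- res
    }
    out
}

## Enumerate context-decidable cytosines of one chromosome; returns a
## data.frame(pos, strand, context, trinucleotide).
.enumerateChrom <- function(chars) {
    n <- length(chars)
    res <- list()
    plusPos <- which(chars == "C")
    if (length(plusPos)) {
        b2 <- ifelse(plusPos + 1L <= n, chars[pmin(plusPos + 1L, n)], "")
        b3 <- ifelse(plusPos + 2L <= n, chars[pmin(plusPos + 2L, n)], "")
        tri <- paste0("C", b2, b3)
        ctx <- classifyContext(tri)
        keep <- !is.na(ctx)
        res$plus <- data.frame(pos = plusPos[keep], strand = "+",
                               context = ctx[keep],
                               trinucleotide = tri[keep],
                               stringsAsFactors = FALSE)
    }
    minusPos <- which(chars == "G")
    if (length(minusPos)) {
        b2 <- ifelse(minusPos - 1L >= 1L,
                     .COMPLEMENT[chars[pmax(minusPos - 1L, 1L)]], "")
        b3 <- ifelse(minusPos - 2L >= 1L,
                     .COMPLEMENT[chars[pmax(minusPos - 2L, 1L)]], "")
        tri <- paste0("C", b2, b3)
        ctx <- classifyContext(tri)
        keep <- !is.na(ctx)
        res$minus <- data.frame(pos = minusPos[keep], strand = "-",
                                context = ctx[keep],
                                trinucleotide = tri[keep],
                                stringsAsFactors = FALSE)
    }
    if (!length(res))
        return(data.frame(pos = integer(), strand = character(),
                          context = character(),
                          trinucleotide = character(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, res)
    out[order(out$pos, out$strand), , drop = FALSE]
}

#' Enumerate all context-decidable cytosines of a genome
#'
#' Scans both strands of every sequence and emits one site per cytosine
#' whose CG/CHG/CHH context is decidable (see [classifyContext()] for the
#' end-of-chromosome and N rules). Minus-strand cytosines (a `G` on the
#' plus strand) are reported at the plus-strand coordinate of that `G`,
#' with the trinucleotide read 5'->3' on the minus strand.
#'
#' @param genome a named [Biostrings::DNAStringSet] (see
#'   [readGenomeFasta()]).
#' @return a [GenomicRanges::GRanges], sorted by (chrom, pos, strand), with
#'   metadata columns `context` and `trinucleotide` and seqlengths set.
#' @examples
#' enumerateCytosines(Biostrings::DNAStringSet(c(chr1 = "ACGT")))
#' @export
enumerateCytosines <- function(genome) {
    stopifnot(methods::is(genome, "DNAStringSet"))
    if (is.null(names(genome)) || anyDuplicated(names(genome)))
        stop("genome sequences must carry unique names")
    per <- lapply(seq_along(genome), function(i) {
        chars <- strsplit(as.character(genome[[i]]), "", fixed = TRUE)[[1L]]
        df <- .enumerateChrom(chars)
        if (nrow(df)) df$chrom <- names(genome)[i]
        df
    })
    per <- per[vapply(per, nrow, 0L) > 0L]
    si <- GenomeInfoDb::Seqinfo(seqnames = names(genome),
                                seqlengths = BiocGenerics::width(genome))
    if (!length(per)) {
        gr <- GenomicRanges::GRanges(seqinfo = si)
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            context = character(), trinucleotide = character())
        return(gr)
    }
    df <- do.call(rbind, per)
    gr <- GenomicRanges::GRanges(
        seqnames = factor(df$chrom, levels = names(genome)),
        ranges = IRanges::IRanges(df$pos, width = 1L),
        strand = df$strand, seqinfo = si)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        context = df$context, trinucleotide = df$trinucleotide)
    sort(gr, ignore.strand = FALSE)
}

#' Flanking-base composition around cytosine sites
#'
#' Computes, per context, the frequency of A/C/G/T at each offset `-k..+k`
#' relative to the cytosine, on each site's own strand (minus-strand flanks
#' are reverse-complemented). Sites whose window overruns a sequence end
#' are skipped; the number skipped is reported as an attribute. This is the
#' composition matrix underlying a sequence-logo display of methylated-site
#' contexts.
#'
#' @param sites a [GenomicRanges::GRanges] (or [MethylSiteCounts]) with a
#'   `context` metadata column; typically the methylated calls of one
#'   context.
#' @param genome a named [Biostrings::DNAStringSet].
#' @param k flank width in bases (default 5).
#' @return a named list, one element per context present, each a 4 x
#'   (2k+1) matrix (rows A, C, G, T; columns offsets) whose columns sum to
#'   1, with attribute `nSkipped`.
#' @export
flankingComposition <- function(sites, genome, k = 5L) {
    stopifnot(k >= 1L)
    if (!length(sites)) stop("no sites supplied")
    ctxs <- unique(as.character(S4Vectors::mcols(sites)$context))
    if (!length(ctxs) || any(is.na(ctxs)))
        stop("sites must carry a 'context' metadata column")
    lens <- stats::setNames(BiocGenerics::width(genome), names(genome))
    out <- lapply(ctxs, function(cx) {
        s <- sites[S4Vectors::mcols(sites)$context == cx]
        chrom <- as.character(GenomeInfoDb::seqnames(s))
        pos <- BiocGenerics::start(s)
        ok <- pos - k >= 1L & pos + k <= lens[chrom]
        nSkip <- sum(!ok)
        s <- s[ok]; chrom <- chrom[ok]; pos <- pos[ok]
        if (!length(s))
            stop("no site has a full +/-", k, " bp window for context ", cx)
        win <- Biostrings::DNAStringSet(lapply(seq_along(s), function(i) {
            genome[[chrom[i]]][(pos[i] - k):(pos[i] + k)]
        }))
        minus <- as.character(BiocGenerics::strand(s)) == "-"
        if (any(minus))
            win[minus] <- Biostrings::reverseComplement(win[minus])
        m <- Biostrings::consensusMatrix(win, as.prob = TRUE,
                                         baseOnly = TRUE)[c("A", "C", "G",
                                                            "T"), ,
                                                          drop = FALSE]
        colnames(m) <- as.character(-k:k)
        attr(m, "nSkipped") <- nSkip
        attr(m, "nSites") <- length(s)
        m
    })
    stats::setNames(out, ctxs)
}
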