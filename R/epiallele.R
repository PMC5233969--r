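## SNP-induced cytosine-context transitions ("obligate epialleles"): a SNP
## within two bases of a cytosine can move it between CG, CHG and CHH, or
## create/destroy a context-decidable cytosine site altogether. Contexts
## are evaluated on the fully substituted alternate genome, so clustered
## SNPs compose correctly.

#' Substitute SNPs into a reference genome
#'
#' Pure single-base substitution: lengths and coordinates are unchanged,
#' so both genomes share a coordinate system. Every SNP's `ref` base must
#' match the reference.
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param snps a [GenomicRanges::GRanges] with `ref` and `alt` metadata
#'   columns (see [readSNPTable()]).
#' @return the alternate genome as a `DNAStringSet`.
#' @export
applySNPs <- function(genome, snps) {
    if (!length(snps)) return(genome)
    chrom <- as.character(GenomeInfoDb::seqnames(snps))
    pos <- BiocGenerics::start(snps)
    unknown <- setdiff(unique(chrom), names(genome))
    if (length(unknown))
        stop("SNP chromosome(s) absent from genome: ",
             paste(unknown, collapse = ", "))
    obs <- .refBaseAt(genome, chrom, pos)
    bad <- which(obs != snps$ref)
    if (length(bad))
        stop("SNP ref base mismatch at ",
             paste(utils::head(paste0(chrom[bad], ":", pos[bad]), 10L),
                   collapse = ", "))
    alt <- genome
    for (ch in unique(chrom)) {
        i <- chrom == ch
        alt[[ch]] <- Biostrings::replaceLetterAt(alt[[ch]], pos[i],
                                                 snps$alt[i])
    }
    alt
}

#' Classify SNP-induced cytosine context transitions
#'
#' For every SNP, examines all positions within two bases on both strands
#' (plus the SNP position itself) and emits one record per affected
#' cytosine per causal SNP wherever the decidable context differs between
#' the two genomes. A context-decidable cytosine site present in exactly
#' one genome is a gain (`none -> ctx`) or loss (`ctx -> none`); sites
#' with decidable contexts in both genomes yield one of the six directed
#' interchanges CG/CHG/CHH.
#'
#' @param refGenome a named [Biostrings::DNAStringSet].
#' @param snps a [GenomicRanges::GRanges] with `ref`/`alt` columns.
#' @param altGenome the SNP-substituted genome; computed with
#'   [applySNPs()] when `NULL`.
#' @return a data.frame with columns `chrom`, `pos`, `strand`, `snpPos`,
#'   `ref`, `alt`, `contextRef`, `contextAlt`, `class`
#'   (e.g. `"CG->CHH"`, `"none->CHG"`). Attributes: `classTotals`
#'   (table over unique affected cytosines), `nSNPsChangingContext`
#'   (distinct causal SNPs), `undirectedTotals` (the same totals with
#'   `X->Y` and `Y->X` folded together).
#' @export
classifyTransitions <- function(refGenome, snps, altGenome = NULL) {
    if (is.null(altGenome)) altGenome <- applySNPs(refGenome, snps)
    stopifnot(identical(names(refGenome), names(altGenome)),
              all(BiocGenerics::width(refGenome) ==
                  BiocGenerics::width(altGenome)))
    empty <- data.frame(chrom = character(), pos = integer(),
                        strand = character(), snpPos = integer(),
                        ref = character(), alt = character(),
                        contextRef = character(), contextAlt = character(),
                        class = character(), stringsAsFactors = FALSE)
    if (!length(snps)) {
        attr(empty, "classTotals") <- table(character())
        attr(empty, "nSNPsChangingContext") <- 0L
        return(empty)
    }
    chrom <- as.character(GenomeInfoDb::seqnames(snps))
    pos <- BiocGenerics::start(snps)
    res <- list()
    for (ch in unique(chrom)) {
        refChars <- strsplit(as.character(refGenome[[ch]]), "",
                             fixed = TRUE)[[1L]]
        altChars <- strsplit(as.character(altGenome[[ch]]), "",
                             fixed = TRUE)[[1L]]
        sp <- pos[chrom == ch]
        ## + strand sites read rightward: affected positions p with
        ## snp in [p, p+2]; - strand sites read leftward: snp in [p-2, p].
        candPos <- c(rep(sp, each = 3L) - (2:0),
                     rep(sp, each = 3L) + (0:2))
        candStrand <- rep(c("+", "-"), each = 3L * length(sp))
        candSnp <- c(rep(sp, each = 3L), rep(sp, each = 3L))
        ctxRef <- .contextAt(refChars, candPos, candStrand)
        ctxAlt <- .contextAt(altChars, candPos, candStrand)
        keep <- (!is.na(ctxRef) | !is.na(ctxAlt)) &
            (is.na(ctxRef) | is.na(ctxAlt) | ctxRef != ctxAlt)
        if (!any(keep)) next
        res[[ch]] <- data.frame(
            chrom = ch, pos = candPos[keep], strand = candStrand[keep],
            snpPos = candSnp[keep],
            contextRef = ifelse(is.na(ctxRef[keep]), "none", ctxRef[keep]),
            contextAlt = ifelse(is.na(ctxAlt[keep]), "none", ctxAlt[keep]),
            stringsAsFactors = FALSE)
    }
    if (!length(res)) {
        attr(empty, "classTotals") <- table(character())
        attr(empty, "nSNPsChangingContext") <- 0L
        return(empty)
    }
    out <- do.call(rbind, res)
    snpKey <- paste(chrom, pos)
    m <- match(paste(out$chrom, out$snpPos), snpKey)
    out$ref <- snps$ref[m]
    out$alt <- snps$alt[m]
    out$class <- paste0(out$contextRef, "->", out$contextAlt)
    out <- out[order(out$chrom, out$pos, out$strand, out$snpPos), ]
    rownames(out) <- NULL
    uniqSite <- !duplicated(paste(out$chrom, out$pos, out$strand))
    attr(out, "classTotals") <- table(out$class[uniqSite])
    attr(out, "nSNPsChangingContext") <-
        length(unique(paste(out$chrom, out$snpPos)))
    pair <- ifelse(out$contextRef < out$contextAlt,
                   paste(out$contextRef, out$contextAlt, sep = "<->"),
                   paste(out$contextAlt, out$contextRef, sep = "<->"))
    attr(out, "undirectedTotals") <- table(pair[uniqSite])
    out
}

#' Cross-tabulate methylation-state changes over context transitions
#'
#' For each context transition (unique affected cytosine), looks up the
#' called methylation status at that site in the reference-aligned sample
#' (A) and the alternate-genome-aligned sample (B) and tallies the
#' transition classes against the state changes M->M, M->U, U->M, U->U.
#' Sites absent or with zero raw depth in either sample are tallied as
#' uncovered.
#'
#' @param transitions output of [classifyTransitions()].
#' @param callsA [MethylCalls] for the reference sample.
#' @param callsB [MethylCalls] for the alternate sample (shared
#'   coordinates).
#' @return a data.frame with one row per transition class and columns
#'   `MM`, `MU`, `UM`, `UU`, `uncovered`, `total`.
#' @export
crosstabTransitions <- function(transitions, callsA, callsB) {
    tr <- transitions[!duplicated(paste(transitions$chrom, transitions$pos,
                                        transitions$strand)), , drop = FALSE]
    lookup <- function(calls, df) {
        key <- .siteKey(calls)
        idx <- match(paste(df$chrom, df$pos, df$strand, sep = ":"), key)
        status <- rep(NA_character_, nrow(df))
        ok <- !is.na(idx) & siteDepth(calls)[ifelse(is.na(idx), 1L, idx)] >= 1L
        status[ok] <- as.character(methStatus(calls))[idx[ok]]
        status
    }
    sA <- lookup(callsA, tr)
    sB <- lookup(callsB, tr)
    cell <- rep("uncovered", nrow(tr))
    known <- !is.na(sA) & !is.na(sB)
    cell[known] <- paste0(ifelse(sA[known] == "methylated", "M", "U"),
                          ifelse(sB[known] == "methylated", "M", "U"))
    tab <- table(class = tr$class,
                 cell = factor(cell, levels = c("MM", "MU", "UM", "UU",
                                                "uncovered")))
    out <- as.data.frame.matrix(tab)
    out$total <- rowSums(out)
    out
}
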