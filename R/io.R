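## Readers and writers for every external format the pipeline touches.
## All coordinates are 1-based inclusive at every external boundary
## (GFF3, VCF, Bismark CX reports all agree on this).

#' Read a genome FASTA
#'
#' Loads a FASTA file into a named [Biostrings::DNAStringSet], uppercases
#' the sequences, truncates header names at the first whitespace, and
#' validates the residue alphabet against `{A, C, G, T, N}`.
#'
#' @param path path to a FASTA file.
#' @return a named `DNAStringSet`.
#' @export
readGenomeFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    genome <- withCallingHandlers(
        tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                 error = function(e)
                     stop("FASTA format error in ", path, ": ",
                          conditionMessage(e))),
        warning = function(w) {
            if (grepl("invalid one-letter sequence codes",
                      conditionMessage(w))) {
                lines <- readLines(path, warn = FALSE)
                bad <- which(!startsWith(lines, ">") &
                             grepl("[^ACGTNacgtn]", lines))[1L]
                stop("illegal residue character in ", path, " at line ",
                     bad)
            }
            invokeRestart("muffleWarning")
        })
    if (!length(genome)) stop("FASTA file is empty: ", path)
    names(genome) <- sub("\\s.*$", "", names(genome))
    if (anyDuplicated(names(genome)))
        stop("duplicate sequence name(s): ",
             paste(unique(names(genome)[duplicated(names(genome))]),
                   collapse = ", "))
    genome <- Biostrings::DNAStringSet(toupper(genome))
    freq <- Biostrings::alphabetFrequency(genome, collapse = TRUE)
    bad <- freq[setdiff(names(freq), c("A", "C", "G", "T", "N"))]
    if (any(bad > 0))
        stop("illegal residue character(s) in ", path, ": ",
             paste(names(bad)[bad > 0], collapse = ", "))
    if (any(BiocGenerics::width(genome) < 1L))
        stop("zero-length sequence in ", path)
    genome
}

#' Read a Bismark-style CX report
#'
#' Parses the 7-column tab-separated per-cytosine report (chrom, pos,
#' strand, methylated count, unmethylated count, context, trinucleotide;
#' no header). Positions are 1-based; minus-strand cytosines carry the
#' plus-strand coordinate of the G (Bismark convention). Zero-coverage
#' rows are accepted and preserved; downstream operations filter them.
#'
#' @param path path to the report.
#' @param seqinfo optional [GenomeInfoDb::Seqinfo] with chromosome lengths,
#'   used to validate positions.
#' @return a [MethylSiteCounts] object.
#' @export
readCXReport <- function(path, seqinfo = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    nf <- utils::count.fields(path, sep = "\t", quote = "")
    if (is.null(nf) || !length(nf)) {
        return(MethylSiteCounts(character(), integer(), character(),
                                character(), character(), integer(),
                                integer(), seqinfo = seqinfo))
    }
    if (any(nf != 7L))
        stop("CX report ", path, ": expected 7 tab-separated columns, got ",
             nf[which(nf != 7L)[1L]], " at line ", which(nf != 7L)[1L])
    df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                            col.names = c("chrom", "pos", "strand", "nMeth",
                                          "nUnmeth", "context",
                                          "trinucleotide"),
                            colClasses = c("character", "integer",
                                           "character", "integer", "integer",
                                           "character", "character"))
    if (any(df$nMeth < 0L) || any(df$nUnmeth < 0L)) {
        bad <- which(df$nMeth < 0L | df$nUnmeth < 0L)[1L]
        stop("CX report ", path, ": negative read count at line ", bad)
    }
    if (any(!df$context %in% .CONTEXTS)) {
        bad <- which(!df$context %in% .CONTEXTS)[1L]
        stop("CX report ", path, ": unknown context token '",
             df$context[bad], "' at line ", bad)
    }
    if (any(!df$strand %in% c("+", "-"))) {
        bad <- which(!df$strand %in% c("+", "-"))[1L]
        stop("CX report ", path, ": bad strand at line ", bad)
    }
    MethylSiteCounts(df$chrom, df$pos, df$strand, df$context,
                     df$trinucleotide, df$nMeth, df$nUnmeth,
                     seqinfo = seqinfo)
}

#' Write a Bismark-style CX report
#'
#' Writes the 7-column tab-separated dialect read by [readCXReport()], one
#' record per line, no header, in the order given.
#'
#' @param sites a [MethylSiteCounts] object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCXReport <- function(sites, path) {
    stopifnot(methods::is(sites, "MethylSiteCounts"))
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(sites)),
                     pos = BiocGenerics::start(sites),
                     strand = as.character(BiocGenerics::strand(sites)),
                     nMeth = nMeth(sites), nUnmeth = nUnmeth(sites),
                     context = methContext(sites),
                     trinucleotide = trinucleotide(sites))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read gene/TE features from GFF3
#'
#' Imports a GFF3 annotation via [rtracklayer::import()], keeps the feature
#' types gene, exon, five_prime_UTR, three_prime_UTR and
#' transposable_element (mapped to `TE`), warns about and drops other
#' types, and synthesizes intron records as the gaps between consecutive
#' exons of the same parent gene when no introns are annotated.
#'
#' @param path path to a GFF3 file.
#' @return a [GenomicRanges::GRanges] with metadata columns `type`
#'   (gene/exon/intron/five_prime_UTR/three_prime_UTR/TE), `ID` and
#'   `Parent` (empty string for parentless features).
#' @export
readGFFFeatures <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    gff <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gff$type)
    type[type == "transposable_element"] <- "TE"
    keep <- c("gene", "exon", "intron", "five_prime_UTR", "three_prime_UTR",
              "TE")
    drop <- setdiff(unique(type), keep)
    if (length(drop))
        warning("ignoring feature type(s): ", paste(drop, collapse = ", "))
    gff <- gff[type %in% keep]
    type <- type[type %in% keep]
    parent <- vapply(seq_along(gff), function(i) {
        p <- gff$Parent[[i]]
        if (length(p)) as.character(p)[1L] else ""
    }, character(1L))
    id <- if (!is.null(gff$ID)) as.character(gff$ID) else
        rep(NA_character_, length(gff))
    id[is.na(id)] <- paste0(type[is.na(id)], "_", which(is.na(id)))
    if (any(type %in% c("exon", "five_prime_UTR", "three_prime_UTR") &
            parent == ""))
        stop("exon/UTR record without Parent attribute in ", path)
    out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gff),
                                  IRanges::ranges(gff),
                                  strand = BiocGenerics::strand(gff))
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(type = type, ID = id,
                                                  Parent = parent)
    if (!any(type == "intron"))
        out <- c(out, .synthesizeIntrons(out))
    sort(out, ignore.strand = TRUE)
}

## Introns = gaps between consecutive exons sharing a Parent.
.synthesizeIntrons <- function(features) {
    ex <- features[features$type == "exon"]
    empty <- GenomicRanges::GRanges()
    S4Vectors::mcols(empty) <- S4Vectors::DataFrame(type = character(),
                                                    ID = character(),
                                                    Parent = character())
    if (!length(ex)) return(empty)
    sp <- split(ex, ex$Parent)
    pieces <- lapply(names(sp), function(g) {
        e <- sort(sp[[g]], ignore.strand = TRUE)
        if (length(e) < 2L) return(NULL)
        s <- BiocGenerics::end(e)[-length(e)] + 1L
        t <- BiocGenerics::start(e)[-1L] - 1L
        ok <- s <= t
        if (!any(ok)) return(NULL)
        gr <- GenomicRanges::GRanges(
            GenomeInfoDb::seqnames(e)[1L],
            IRanges::IRanges(s[ok], t[ok]),
            strand = BiocGenerics::strand(e)[1L])
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            type = "intron",
            ID = paste0(g, ".intron", seq_along(gr)),
            Parent = g)
        gr
    })
    pieces <- pieces[!vapply(pieces, is.null, TRUE)]
    if (!length(pieces)) return(empty)
    do.call(c, pieces)
}

#' Read biallelic SNVs from a VCF
#'
#' Reads a VCF (via \pkg{vcfR}), splits multi-allelic rows, keeps only
#' single-nucleotide REF/ALT records, and skips indels and
#' multi-nucleotide records with a logged count (attribute `nSkipped` and
#' a message). When a genome is supplied, every REF base is validated
#' against it.
#'
#' @param path path to a VCF file.
#' @param genome optional named [Biostrings::DNAStringSet] for REF
#'   validation.
#' @return a [GenomicRanges::GRanges] of width-1 positions with metadata
#'   columns `ref` and `alt`, and attribute `nSkipped`.
#' @export
readSNPTable <- function(path, genome = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                         dimnames = list(NULL, names(fix)))
    chrom <- fix[, "CHROM"]
    pos <- as.integer(fix[, "POS"])
    ref <- toupper(fix[, "REF"])
    altRaw <- toupper(fix[, "ALT"])
    alts <- strsplit(altRaw, ",", fixed = TRUE)
    n <- lengths(alts)
    chrom <- rep(chrom, n); pos <- rep(pos, n); ref <- rep(ref, n)
    alt <- unlist(alts, use.names = FALSE)
    snv <- nchar(ref) == 1L & nchar(alt) == 1L &
        ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
        ref != alt
    nSkipped <- sum(!snv)
    if (nSkipped)
        message("readSNPTable: skipped ", nSkipped,
                " non-SNV allele record(s)")
    gr <- GenomicRanges::GRanges(chrom[snv],
                                 IRanges::IRanges(pos[snv], width = 1L))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(ref = ref[snv],
                                                 alt = alt[snv])
    if (!is.null(genome) && length(gr)) {
        obs <- .refBaseAt(genome, as.character(GenomeInfoDb::seqnames(gr)),
                          BiocGenerics::start(gr))
        bad <- which(obs != gr$ref)
        if (length(bad))
            stop("REF mismatch with genome at ",
                 paste(utils::head(paste0(GenomeInfoDb::seqnames(gr)[bad],
                                          ":", BiocGenerics::start(gr)[bad]),
                                   10L), collapse = ", "))
    }
    attr(gr, "nSkipped") <- nSkipped
    gr
}

.refBaseAt <- function(genome, chrom, pos) {
    vapply(seq_along(pos), function(i)
        as.character(genome[[chrom[i]]][pos[i]]), character(1L))
}

#' Read a replicate-level expression table
#'
#' Tab-separated with header `gene_id  sample  replicate  abundance`;
#' abundances are non-negative FPKM-like values.
#'
#' @param path path to the TSV.
#' @return a data.frame with those four columns.
#' @export
readExpressionTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                            stringsAsFactors = FALSE)
    need <- c("gene_id", "sample", "replicate", "abundance")
    if (!all(need %in% colnames(df)))
        stop("expression table must have columns: ",
             paste(need, collapse = ", "))
    if (any(df$abundance < 0)) stop("negative abundance value")
    if (anyDuplicated(df[, c("gene_id", "sample", "replicate")]))
        stop("duplicate (gene, sample, replicate) record")
    df
}

#' Read a paralog pair list
#'
#' Tab-separated, two columns `gene_a` and `gene_b` (header required).
#'
#' @param path path to the TSV.
#' @return a data.frame with columns `gene_a`, `gene_b`.
#' @export
readParalogPairs <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                            stringsAsFactors = FALSE)
    if (!all(c("gene_a", "gene_b") %in% colnames(df)))
        stop("paralog table must have columns gene_a, gene_b")
    df
}

#' Write DMR windows to BED6
#'
#' Emits `chrom, start-1, end, name, -log10(p) rounded to 3 decimals, "."`
#' for each window, converting the 1-based inclusive internal coordinates
#' to BED's 0-based half-open convention.
#'
#' @param dmrs a [GenomicRanges::GRanges] from [dmrScan()] (typically
#'   subset to significant windows) with a `p` metadata column.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeDMRBed <- function(dmrs, path) {
    score <- round(-log10(pmax(dmrs$p, .Machine$double.xmin)), 3L)
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(dmrs)),
                     start = BiocGenerics::start(dmrs) - 1L,
                     end = BiocGenerics::end(dmrs),
                     name = paste0("DMR_", seq_along(dmrs)),
                     score = score,
                     strand = ".")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
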