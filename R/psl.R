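#' Construct an IsoformSet from per-model vectors
#'
#' @param chrom,strand Character vectors, one entry per model.
#' @param exonStarts List of integer vectors: 0-based exon start coordinates
#'   (PSL `tStarts` convention).
#' @param exonSizes List of integer vectors: exon block sizes.
#' @param isoform_id Unique model identifiers.
#' @param source Cell or pool of origin per model.
#' @param support Read or cell count per model (default 1).
#' @param gene_id Gene per model (default `NA`).
#' @param targetSize Length of the target sequence (chromosome); kept so PSL
#'   round-trips are exact.  Defaults to the maximum end coordinate.
#' @return An [IsoformSet-class] object.
#' @examples
#' newIsoformSet("chr1", "+", list(c(0L, 200L)), list(c(100L, 100L)),
#'               "iso1", "cellA")
#' @export
newIsoformSet <- function(chrom, strand, exonStarts, exonSizes, isoform_id,
                          source, support = 1L, gene_id = NA_character_,
                          targetSize = NA_integer_) {
    n <- length(isoform_id)
    stopifnot(length(exonStarts) == n, length(exonSizes) == n)
    chrom <- rep_len(chrom, n); strand <- rep_len(strand, n)
    source <- rep_len(source, n); support <- rep_len(support, n)
    gene_id <- rep_len(gene_id, n)
    targetSize <- rep_len(as.integer(targetSize), n)
    exons <- IRanges::IRangesList(lapply(seq_len(n), function(i) {
        IRanges::IRanges(start = exonStarts[[i]] + 1L,
                         width = exonSizes[[i]])
    }))
    starts <- vapply(seq_len(n),
                     function(i) min(IRanges::start(exons[[i]])), integer(1))
    ends <- vapply(seq_len(n),
                   function(i) max(IRanges::end(exons[[i]])), integer(1))
    if (n && anyNA(targetSize)) targetSize[is.na(targetSize)] <- max(ends)
    anchors <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(starts, ends), strand = strand)
    S4Vectors::mcols(anchors) <- S4Vectors::DataFrame(
        isoform_id = isoform_id, source = source,
        support = as.numeric(support), gene_id = gene_id,
        target_size = targetSize)
    new("IsoformSet", anchors = anchors, exons = exons)
}

#' @describeIn IsoformSet Model identifiers.
#' @export
isoformIds <- function(x) S4Vectors::mcols(x@anchors)$isoform_id

#' @describeIn IsoformSet Cell or pool of origin per model.
#' @export
isoformSource <- function(x) S4Vectors::mcols(x@anchors)$source

#' @describeIn IsoformSet Support (read or cell count) per model.
#' @export
isoformSupport <- function(x) S4Vectors::mcols(x@anchors)$support

#' @describeIn IsoformSet Gene per model.
#' @export
geneIds <- function(x) S4Vectors::mcols(x@anchors)$gene_id

#' @describeIn IsoformSet Replace gene assignments.
#' @param value Character vector of gene ids.
#' @export
`geneIds<-` <- function(x, value) {
    S4Vectors::mcols(x@anchors)$gene_id <- rep_len(value, length(x))
    x
}

#' @describeIn IsoformSet Exon blocks as an `IRangesList` (1-based closed).
#' @export
exonBlocks <- function(x) x@exons

#' @describeIn IsoformSet Anchor ranges (whole-model spans) as `GRanges`.
#' @export
isoformAnchors <- function(x) x@anchors

#' Splice chains of an IsoformSet
#'
#' The splice chain of a model is the ordered list of its intron boundaries
#' in 0-based genomic coordinates: for each intron, the donor (end of the
#' upstream exon, 0-based exclusive) followed by the acceptor (start of the
#' downstream exon, 0-based).  Models with identical chains have identical
#' splicing structure.
#'
#' @param x An [IsoformSet-class].
#' @return An [IRanges::IntegerList], one (possibly empty) chain per model.
#' @export
spliceChains <- function(x) {
    IRanges::IntegerList(lapply(seq_along(x@exons), function(i) {
        ex <- x@exons[[i]]
        k <- length(ex)
        if (k < 2L) return(integer(0))
        as.integer(rbind(IRanges::end(ex)[-k], IRanges::start(ex)[-1L] - 1L))
    }))
}

#' Subset an IsoformSet
#' @param x An `IsoformSet`; `i` an index vector.
#' @param i,j,...,drop Standard subsetting arguments (`j` unused).
#' @export
setMethod("[", "IsoformSet", function(x, i, j, ..., drop = FALSE) {
    new("IsoformSet", anchors = x@anchors[i], exons = x@exons[i])
})

#' Combine IsoformSets
#' @param x,... `IsoformSet` objects.
#' @export
setMethod("c", "IsoformSet", function(x, ...) {
    rest <- list(...)
    anchors <- do.call(c, c(list(x@anchors), lapply(rest, function(y) y@anchors)))
    exons <- do.call(c, c(list(x@exons), lapply(rest, function(y) y@exons)))
    new("IsoformSet", anchors = anchors, exons = exons)
})

pslNumeric <- c(1:8, 11:13, 15:18)

#' Read transcript models from a PSL file
#'
#' Parses 21-column PSL (as emitted by BLAT-convention isoform callers) into
#' an [IsoformSet-class].  Only the fields the pipeline uses are retained:
#' target name/size, strand, block structure, and the query name as the
#' isoform id.  Coordinates are converted from PSL's 0-based half-open
#' convention.
#'
#' @param path PSL file path.
#' @param source Label for the cell or pool these models come from
#'   (default: file name without extension).
#' @param support Support value for all models, or `NULL` to parse a
#'   trailing `_<count>` from each query name.
#' @return An [IsoformSet-class].
#' @export
readPsl <- function(path, source = sub("\\.psl$", "", basename(path)),
                    support = 1L) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(newIsoformSet(character(0), character(0), list(), list(),
                             character(0), character(0)))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 21L)
    if (length(bad))
        stop("malformed PSL line ", bad[1L], " in ", path, ": expected 21 ",
             "columns, found ", lengths(fields)[bad[1L]])
    get <- function(k) vapply(fields, `[`, character(1), k)
    suppressWarnings({
        num <- lapply(pslNumeric, function(k) as.numeric(get(k)))
    })
    badNum <- which(vapply(num, anyNA, logical(1)))
    if (length(badNum))
        stop("malformed PSL numeric field in ", path)
    qName <- get(10L)
    strand <- get(9L)
    tName <- get(14L)
    tSize <- as.integer(get(15L))
    blockSizes <- lapply(strsplit(get(19L), ",", fixed = TRUE), as.integer)
    tStarts <- lapply(strsplit(get(21L), ",", fixed = TRUE), as.integer)
    nb <- as.integer(get(18L))
    okBlocks <- lengths(blockSizes) == nb & lengths(tStarts) == nb
    if (!all(okBlocks))
        stop("malformed PSL line ", which(!okBlocks)[1L], " in ", path,
             ": block count disagrees with block lists")
    if (is.null(support)) {
        support <- vapply(qName, function(q) {
            mm <- regmatches(q, regexpr("_[0-9]+$", q))
            if (length(mm) && nzchar(mm)) as.integer(sub("_", "", mm)) else 1L
        }, integer(1), USE.NAMES = FALSE)
    }
    newIsoformSet(tName, strand, tStarts, blockSizes, qName, source,
                  support = support, targetSize = tSize)
}

#' Write an IsoformSet as 21-column PSL
#'
#' Emits canonical PSL: block-derived match counts, zero mismatch/repeat
#' fields, query coordinates spanning the concatenated blocks, and
#' comma-terminated block lists.  `readPsl()` of the output reproduces the
#' in-scope fields exactly.
#'
#' @param x An [IsoformSet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePsl <- function(x, path) {
    n <- length(x)
    con <- file(path, "w")
    on.exit(close(con))
    mc <- S4Vectors::mcols(x@anchors)
    for (i in seq_len(n)) {
        ex <- x@exons[[i]]
        sizes <- IRanges::width(ex)
        t0 <- IRanges::start(ex) - 1L
        qsize <- sum(sizes)
        qstarts <- cumsum(c(0L, sizes[-length(sizes)]))
        introns <- if (length(ex) > 1L)
            sum(IRanges::start(ex)[-1L] - 1L - IRanges::end(ex)[-length(ex)])
            else 0L
        line <- paste(
            qsize, 0L, 0L, 0L, 0L, 0L,
            max(length(ex) - 1L, 0L), introns,
            as.character(GenomicRanges::strand(x@anchors)[i]),
            mc$isoform_id[i], qsize, 0L, qsize,
            as.character(GenomicRanges::seqnames(x@anchors)[i]),
            mc$target_size[i],
            GenomicRanges::start(x@anchors)[i] - 1L,
            GenomicRanges::end(x@anchors)[i],
            length(ex),
            paste0(paste(sizes, collapse = ","), ","),
            paste0(paste(qstarts, collapse = ","), ","),
            paste0(paste(t0, collapse = ","), ","),
            sep = "\t")
        writeLines(line, con)
    }
    invisible(path)
}
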