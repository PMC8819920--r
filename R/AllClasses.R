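#' Read-layout (chemistry) description
#'
#' Describes where the cell barcode and molecular identifiers sit within a
#' full-length cDNA consensus read.  The layout is
#' \code{[adapter][cell barcode][10X UMI][oligo-dT][transcript, reverse
#' complement]} with an optional splint-UMI cassette
#' (\code{[flank1][splint UMI][flank2]}) appended at the 3' end of the read,
#' standing in for the UMI carried on the circularization splint.
#'
#' The default adapter is the constant PCR priming site of the 10X oligo-dT
#' primer (the partial Illumina Read 1 primer).  Barcode and UMI lengths
#' default to the 10X Chromium 3' v2/v3 chemistry (16 nt and 10 nt).
#'
#' @param adapter Constant priming-site sequence 5' of the barcode.
#' @param barcodeLen Cell-barcode length in nt (default 16).
#' @param umiLen 10X-UMI length in nt (default 10).
#' @param polyALen Length of the oligo-dT stretch written by the simulator.
#' @param splintUmiLen Splint-UMI length in nt; 0 disables the cassette.
#' @param splintFlanks Character vector of length 2: the constant sequences
#'   flanking the splint UMI.  Extraction is anchored on these.
#'
#' @return A `ChemistryConfig` object.
#' @examples
#' ChemistryConfig()
#' @export ChemistryConfig
#' @exportClass ChemistryConfig
ChemistryConfig <- setClass("ChemistryConfig",
    slots = c(adapter = "character", barcodeLen = "integer",
              umiLen = "integer", polyALen = "integer",
              splintUmiLen = "integer", splintFlanks = "character"))

setValidity("ChemistryConfig", function(object) {
    msg <- NULL
    if (!nzchar(object@adapter)) msg <- c(msg, "'adapter' must be non-empty")
    if (object@barcodeLen <= 0L) msg <- c(msg, "'barcodeLen' must be > 0")
    if (object@umiLen <= 0L) msg <- c(msg, "'umiLen' must be > 0")
    if (object@splintUmiLen > 0L &&
        (length(object@splintFlanks) != 2L || !all(nzchar(object@splintFlanks))))
        msg <- c(msg, "two non-empty 'splintFlanks' required when splintUmiLen > 0")
    if (is.null(msg)) TRUE else msg
})

#' @export
setMethod("initialize", "ChemistryConfig", function(.Object,
        adapter = "CTACACGACGCTCTTCCGATCT",
        barcodeLen = 16L, umiLen = 10L, polyALen = 20L,
        splintUmiLen = 12L,
        splintFlanks = c("ACTTGCCTGTCG", "CGTAATGCTCTG"), ...) {
    callNextMethod(.Object, adapter = toupper(adapter),
                   barcodeLen = as.integer(barcodeLen),
                   umiLen = as.integer(umiLen),
                   polyALen = as.integer(polyALen),
                   splintUmiLen = as.integer(splintUmiLen),
                   splintFlanks = toupper(splintFlanks), ...)
})

setMethod("show", "ChemistryConfig", function(object) {
    cat("ChemistryConfig\n",
        "  adapter:      ", object@adapter, "\n",
        "  barcode/UMI:  ", object@barcodeLen, "nt /", object@umiLen, "nt\n",
        "  oligo-dT:     ", object@polyALen, "nt\n",
        "  splint UMI:   ", object@splintUmiLen, "nt between",
        object@splintFlanks[1], "/", object@splintFlanks[2], "\n")
})

#' Per-base sequencing error model
#'
#' Independent per-base substitution, insertion, and deletion probabilities
#' used by the simulator.  The defaults emulate consensus long reads at
#' roughly 98% accuracy (1% substitutions, 0.5% each indel class).
#'
#' @param subRate,insRate,delRate Per-base event probabilities, each in
#'   `[0, 1)` and summing to less than 1.
#' @return An `ErrorModel` object.
#' @examples
#' ErrorModel(subRate = 0, insRate = 0, delRate = 0)  # error-free
#' @export ErrorModel
#' @exportClass ErrorModel
ErrorModel <- setClass("ErrorModel",
    slots = c(subRate = "numeric", insRate = "numeric", delRate = "numeric"))

setValidity("ErrorModel", function(object) {
    r <- c(object@subRate, object@insRate, object@delRate)
    if (any(r < 0) || any(r >= 1)) return("rates must lie in [0, 1)")
    if (sum(r) >= 1) return("sub + ins + del rates must be < 1")
    TRUE
})

#' @export
setMethod("initialize", "ErrorModel", function(.Object,
        subRate = 0.01, insRate = 0.005, delRate = 0.005, ...) {
    callNextMethod(.Object, subRate = subRate, insRate = insRate,
                   delRate = delRate, ...)
})

setMethod("show", "ErrorModel", function(object) {
    cat(sprintf("ErrorModel: sub %.4g, ins %.4g, del %.4g\n",
                object@subRate, object@insRate, object@delRate))
})

#' Whitelist-construction parameters
#'
#' @param expectedCells Number of cells expected in the experiment; the
#'   whitelist keeps this many of the most frequent exact barcodes
#'   (default 1500, the per-replicate target of a typical Chromium run).
#' @param adapterMaxEdits Edit budget when locating the priming site;
#'   `NA` means 20% of the adapter length, rounded down.
#' @return A `WhitelistParams` object.
#' @export WhitelistParams
#' @exportClass WhitelistParams
WhitelistParams <- setClass("WhitelistParams",
    slots = c(expectedCells = "integer", adapterMaxEdits = "integer"))

setValidity("WhitelistParams", function(object) {
    if (object@expectedCells < 1L) return("'expectedCells' must be >= 1")
    TRUE
})

#' @export
setMethod("initialize", "WhitelistParams", function(.Object,
        expectedCells = 1500L, adapterMaxEdits = NA_integer_, ...) {
    callNextMethod(.Object, expectedCells = as.integer(expectedCells),
                   adapterMaxEdits = as.integer(adapterMaxEdits), ...)
})

#' UMI-merge parameters
#'
#' @param umiMaxEdits Two UMIs are "similar" (mergeable) when their
#'   Levenshtein distance is at most this value (default 1: at 10 nt and
#'   ~98% read accuracy most UMI errors are single events).
#' @param flankMaxEdits Edit budget when locating each splint-UMI flank;
#'   `NA` means 20% of the flank length.
#' @return A `UmiMergeParams` object.
#' @export UmiMergeParams
#' @exportClass UmiMergeParams
UmiMergeParams <- setClass("UmiMergeParams",
    slots = c(umiMaxEdits = "integer", flankMaxEdits = "integer"))

setValidity("UmiMergeParams", function(object) {
    if (object@umiMaxEdits < 0L) return("'umiMaxEdits' must be >= 0")
    TRUE
})

#' @export
setMethod("initialize", "UmiMergeParams", function(.Object,
        umiMaxEdits = 1L, flankMaxEdits = NA_integer_, ...) {
    callNextMethod(.Object, umiMaxEdits = as.integer(umiMaxEdits),
                   flankMaxEdits = as.integer(flankMaxEdits), ...)
})

#' Isoform-merge parameters
#'
#' Two isoform models are linked when their splice chains are equivalent and
#' both the start and the end coordinates differ by at most `endWindow` nt.
#' Splice-chain equivalence is base-accurate except that a single-base-pair
#' shift is tolerated when one of the two sites is much less abundant than
#' the other (support ratio at least `abundanceRatio`).
#'
#' @param endWindow Maximum distance in nt between start (and end) sites of
#'   linked isoforms (default 10).
#' @param spliceSlop Maximum tolerated per-site shift in nt, 0 or 1
#'   (default 1).
#' @param abundanceRatio Minimum majority:minority support ratio for a
#'   1-bp-shifted site to count as equivalent (default 5).
#' @return A `MergeParams` object.
#' @export MergeParams
#' @exportClass MergeParams
MergeParams <- setClass("MergeParams",
    slots = c(endWindow = "integer", spliceSlop = "integer",
              abundanceRatio = "numeric"))

setValidity("MergeParams", function(object) {
    if (object@endWindow < 0L) return("'endWindow' must be >= 0")
    if (!object@spliceSlop %in% c(0L, 1L)) return("'spliceSlop' must be 0 or 1")
    if (object@abundanceRatio < 1) return("'abundanceRatio' must be >= 1")
    TRUE
})

#' @export
setMethod("initialize", "MergeParams", function(.Object,
        endWindow = 10L, spliceSlop = 1L, abundanceRatio = 5, ...) {
    callNextMethod(.Object, endWindow = as.integer(endWindow),
                   spliceSlop = as.integer(spliceSlop),
                   abundanceRatio = abundanceRatio, ...)
})

#' Differential isoform-usage parameters
#'
#' @param alpha Significance level applied to the multiple-testing-corrected
#'   p-value (default 0.01).
#' @param minCellTypes Minimum number of cell types a gene must be expressed
#'   in to be tested (default 2).
#' @param correction Multiple-testing method, any value accepted by
#'   [stats::p.adjust()] (default `"BH"`).
#' @return A `DiffUsageParams` object.
#' @export DiffUsageParams
#' @exportClass DiffUsageParams
DiffUsageParams <- setClass("DiffUsageParams",
    slots = c(alpha = "numeric", minCellTypes = "integer",
              correction = "character"))

setValidity("DiffUsageParams", function(object) {
    if (object@alpha <= 0 || object@alpha >= 1) return("'alpha' must be in (0, 1)")
    if (object@minCellTypes < 2L) return("'minCellTypes' must be >= 2")
    TRUE
})

#' @export
setMethod("initialize", "DiffUsageParams", function(.Object,
        alpha = 0.01, minCellTypes = 2L, correction = "BH", ...) {
    callNextMethod(.Object, alpha = alpha,
                   minCellTypes = as.integer(minCellTypes),
                   correction = correction, ...)
})

#' V-segment filter parameters
#'
#' Reads (or consensus sequences) must align locally to some V-segment
#' reference with at least `minIdentity` identity over at least
#' `minAlignedLength` aligned columns to count as carrying a high-quality V
#' segment.
#'
#' @param minIdentity Minimum alignment identity fraction (default 0.80).
#' @param minAlignedLength Minimum alignment length in nt (default 100).
#' @return A `VFilterParams` object.
#' @export VFilterParams
#' @exportClass VFilterParams
VFilterParams <- setClass("VFilterParams",
    slots = c(minIdentity = "numeric", minAlignedLength = "integer"))

setValidity("VFilterParams", function(object) {
    if (object@minIdentity <= 0 || object@minIdentity > 1)
        return("'minIdentity' must be in (0, 1]")
    if (object@minAlignedLength < 1L) return("'minAlignedLength' must be >= 1")
    TRUE
})

#' @export
setMethod("initialize", "VFilterParams", function(.Object,
        minIdentity = 0.80, minAlignedLength = 100L, ...) {
    callNextMethod(.Object, minIdentity = minIdentity,
                   minAlignedLength = as.integer(minAlignedLength), ...)
})

#' Set of transcript isoform models
#'
#' A container for transcript models as produced by PSL-emitting isoform
#' callers: one genomic anchor range per model plus its exon block structure.
#' Coordinates are stored 1-based closed internally (the `GRanges`/`IRanges`
#' convention) and converted to PSL's 0-based half-open convention on
#' read/write.
#'
#' @slot anchors A [GenomicRanges::GRanges] with one range per isoform
#'   spanning the whole model; metadata columns `isoform_id`, `source`
#'   (cell or pool of origin), `support` (read or cell count), `gene_id`.
#' @slot exons A [IRanges::IRangesList] parallel to `anchors` holding the
#'   exon blocks of each model in genomic coordinates.
#'
#' @seealso [readPsl()], [writePsl()], [mergeIsoforms()], [spliceChains()]
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom IRanges CompressedIRangesList
#' @export
#' @exportClass IsoformSet
setClass("IsoformSet",
    slots = c(anchors = "GRanges", exons = "CompressedIRangesList"))

setValidity("IsoformSet", function(object) {
    msg <- NULL
    if (length(object@anchors) != length(object@exons))
        msg <- c(msg, "'anchors' and 'exons' must be parallel")
    req <- c("isoform_id", "source", "support", "gene_id")
    if (!all(req %in% colnames(S4Vectors::mcols(object@anchors))))
        msg <- c(msg, paste("anchors must carry mcols:",
                            paste(req, collapse = ", ")))
    else if (length(object@anchors) &&
             any(S4Vectors::mcols(object@anchors)$support < 1))
        msg <- c(msg, "'support' must be >= 1")
    if (length(object@exons)) {
        ok <- vapply(seq_along(object@exons), function(i) {
            s <- IRanges::start(object@exons[[i]]); e <- IRanges::end(object@exons[[i]])
            !is.unsorted(s, strictly = TRUE) && all(e >= s)
        }, logical(1))
        if (!all(ok)) msg <- c(msg, "exon blocks must be sorted and non-degenerate")
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "IsoformSet", function(object) {
    cat("IsoformSet with", length(object@anchors), "isoform models on",
        length(unique(as.character(GenomicRanges::seqnames(object@anchors)))),
        "sequence(s)\n")
    if (length(object@anchors)) {
        src <- unique(S4Vectors::mcols(object@anchors)$source)
        cat("  sources:", length(src), "| genes:",
            length(unique(S4Vectors::mcols(object@anchors)$gene_id)), "\n")
    }
})

#' @describeIn IsoformSet Number of isoform models in the set.
#' @param x An `IsoformSet`.
#' @export
setMethod("length", "IsoformSet", function(x) length(x@anchors))
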