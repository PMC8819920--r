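#' Are two splice chains equivalent?
#'
#' Chains are equivalent when they have the same number of sites and every
#' corresponding site is either identical or shifted by at most
#' `spliceSlop` (default 1) bp in a case where one of the two isoforms is
#' much less abundant than the other: the minority support times
#' `abundanceRatio` must not exceed the majority support.  Comparison is
#' base-accurate otherwise.
#'
#' @param chainA,chainB Integer vectors of splice-site coordinates (see
#'   [spliceChains()]).
#' @param supportA,supportB Support of the two isoforms carrying the chains.
#' @param params A [MergeParams].
#' @return `TRUE` or `FALSE`.
#' @examples
#' spliceSitesEquivalent(c(100L, 200L), c(100L, 201L), 100, 2)  # TRUE
#' spliceSitesEquivalent(c(100L, 200L), c(100L, 202L), 100, 2)  # FALSE
#' @export
spliceSitesEquivalent <- function(chainA, chainB, supportA = 1, supportB = 1,
                                  params = MergeParams()) {
    if (length(chainA) != length(chainB)) return(FALSE)
    if (!length(chainA)) return(TRUE)
    d <- abs(chainA - chainB)
    if (all(d == 0L)) return(TRUE)
    if (any(d > params@spliceSlop)) return(FALSE)
    # 1-bp shifts are only forgiven across a strong abundance imbalance
    min(supportA, supportB) * params@abundanceRatio <= max(supportA, supportB)
}

# minimal union-find used by mergeIsoforms
ufFind <- function(parent, i) {
    while (parent[i] != i) i <- parent[i]
    i
}

#' Merge isoform models from many cells
#'
#' Single-linkage (union-find) grouping of isoform models.  Two models link
#' iff they share chromosome and strand, their splice chains are equivalent
#' under [spliceSitesEquivalent()], and both their start and end coordinates
#' differ by at most `endWindow` nt.  Because grouping is iterative, two
#' members of one group can have ends further apart than `endWindow` when a
#' third member connects them.  The partition is independent of input order.
#'
#' @param x An [IsoformSet-class] carrying per-cell models (`source` = cell).
#' @param params A [MergeParams].
#' @return List with `groupOf` (integer group id per model, 1-based, ordered
#'   by first appearance) and `groups` (data.frame: `group`,
#'   `representative` model id — highest support, then longest, then
#'   smallest id —, `n_models`, `cell_count` distinct sources,
#'   `total_support`, `gene_id` of the representative).
#' @export
mergeIsoforms <- function(x, params = MergeParams()) {
    n <- length(x)
    if (n == 0L)
        return(list(groupOf = integer(0),
                    groups = data.frame(group = integer(0),
                                        representative = character(0),
                                        n_models = integer(0),
                                        cell_count = integer(0),
                                        total_support = numeric(0),
                                        gene_id = character(0))))
    chains <- spliceChains(x)
    chrom <- as.character(GenomicRanges::seqnames(x@anchors))
    strand <- as.character(GenomicRanges::strand(x@anchors))
    starts <- GenomicRanges::start(x@anchors)
    ends <- GenomicRanges::end(x@anchors)
    supp <- isoformSupport(x)
    ids <- isoformIds(x)

    parent <- seq_len(n)
    bucket <- split(seq_len(n),
                    paste(chrom, strand, lengths(chains), sep = "\r"))
    for (idx in bucket) {
        m <- length(idx)
        if (m < 2L) next
        chm <- if (length(chains[[idx[1L]]]))
            do.call(rbind, as.list(chains[idx])) else NULL
        for (a in seq_len(m - 1L)) {
            i <- idx[a]
            for (b in seq((a + 1L), m)) {
                j <- idx[b]
                ra <- ufFind(parent, i); rb <- ufFind(parent, j)
                if (ra == rb) next
                if (abs(starts[i] - starts[j]) > params@endWindow) next
                if (abs(ends[i] - ends[j]) > params@endWindow) next
                eq <- if (is.null(chm)) TRUE else
                    spliceSitesEquivalent(chm[a, ], chm[b, ],
                                          supp[i], supp[j], params)
                if (eq) parent[max(ra, rb)] <- min(ra, rb)
            }
        }
    }
    roots <- vapply(seq_len(n), function(i) ufFind(parent, i), integer(1))
    groupOf <- match(roots, unique(roots))
    idxByGroup <- split(seq_len(n), groupOf)
    lens <- ends - starts
    groups <- data.frame(
        group = as.integer(names(idxByGroup)),
        representative = vapply(idxByGroup, function(i) {
            o <- order(-supp[i], -lens[i], ids[i])
            ids[i][o[1L]]
        }, character(1)),
        n_models = lengths(idxByGroup),
        cell_count = vapply(idxByGroup, function(i)
            length(unique(isoformSource(x)[i])), integer(1)),
        total_support = vapply(idxByGroup, function(i) sum(supp[i]),
                               numeric(1)),
        gene_id = vapply(idxByGroup, function(i) {
            o <- order(-supp[i], -lens[i], ids[i])
            geneIds(x)[i][o[1L]]
        }, character(1)),
        stringsAsFactors = FALSE)
    rownames(groups) <- NULL
    groups <- groups[order(groups$group), ]
    list(groupOf = groupOf, groups = groups)
}

#' Per-gene isoform diversity statistics
#'
#' Contrasts the "merged single cell" isoform count of each gene (distinct
#' merged groups across cells) with the isoform count of a synthetic-bulk
#' call on the pooled reads.
#'
#' @param x The per-cell [IsoformSet-class] that was merged.
#' @param merged Result of [mergeIsoforms()] on `x`.
#' @param bulk Either an [IsoformSet-class] of synthetic-bulk models or a
#'   data.frame with columns `gene_id`, `bulk_isoforms`.
#' @return data.frame with one row per gene: `gene_id`, `cells_expressing`,
#'   `unique_merged_isoforms`, `multi_cell_isoforms` (groups seen in more
#'   than one cell), `bulk_isoforms`, `log10_ratio`
#'   (log10(merged/bulk); `NA` with `ratio_defined = FALSE` for genes absent
#'   from the bulk set).
#' @export
diversityStats <- function(x, merged, bulk) {
    gene <- geneIds(x)
    src <- isoformSource(x)
    grp <- merged$groupOf
    genes <- sort(unique(gene))
    bulkCount <- if (is.data.frame(bulk)) {
        setNames(bulk$bulk_isoforms, bulk$gene_id)
    } else {
        tab <- table(geneIds(bulk))
        setNames(as.integer(tab), names(tab))
    }
    rows <- lapply(genes, function(g) {
        i <- which(gene == g)
        perGroup <- split(src[i], grp[i])
        bi <- bulkCount[g]
        um <- length(unique(grp[i]))
        data.frame(gene_id = g,
                   cells_expressing = length(unique(src[i])),
                   unique_merged_isoforms = um,
                   multi_cell_isoforms = sum(vapply(perGroup, function(s)
                       length(unique(s)) > 1L, logical(1))),
                   bulk_isoforms = if (is.na(bi)) NA_integer_
                                   else as.integer(bi),
                   log10_ratio = if (is.na(bi) || bi == 0) NA_real_
                                 else log10(um / bi),
                   ratio_defined = !is.na(bi) && bi > 0,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Quantify isoform groups per cell type
#'
#' Sums per-cell isoform supports within each cell type, producing the long
#' count table feeding [diffIsoformUsage()].  Cells absent from the
#' cell-type table are dropped with one warning.
#'
#' @param x The per-cell [IsoformSet-class].
#' @param merged Result of [mergeIsoforms()] on `x`.
#' @param cellTypes data.frame with columns `cell_id`, `cell_type`.
#' @return data.frame with columns `gene_id`, `isoform` (merged group id),
#'   `cell_type`, `count`; attribute `dropped_cells` holds the number of
#'   cells without a cell-type assignment.
#' @export
quantifyByGroup <- function(x, merged, cellTypes) {
    stopifnot(all(c("cell_id", "cell_type") %in% colnames(cellTypes)))
    src <- isoformSource(x)
    ct <- cellTypes$cell_type[match(src, cellTypes$cell_id)]
    drop <- is.na(ct)
    nDropped <- length(unique(src[drop]))
    if (nDropped)
        warning(nDropped, " cell(s) missing from the cell-type table; ",
                "their models were excluded")
    keep <- !drop
    if (!any(keep)) {
        out <- data.frame(gene_id = character(0), isoform = integer(0),
                          cell_type = character(0), count = numeric(0))
        attr(out, "dropped_cells") <- nDropped
        return(out)
    }
    gid <- merged$groups$gene_id[match(merged$groupOf[keep],
                                       merged$groups$group)]
    agg <- stats::aggregate(
        list(count = isoformSupport(x)[keep]),
        by = list(gene_id = gid, isoform = merged$groupOf[keep],
                  cell_type = ct[keep]),
        FUN = sum)
    agg <- agg[order(agg$gene_id, agg$isoform, agg$cell_type), ]
    rownames(agg) <- NULL
    attr(agg, "dropped_cells") <- nDropped
    agg
}
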