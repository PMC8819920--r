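#' Extract the splint UMI from reads
#'
#' Locates the two constant flank sequences of the splint-UMI cassette by
#' semi-global alignment (edit budget: `flankMaxEdits`, default 20% of each
#' flank's length) and returns the intervening bases.  A read yields
#' `not_found` when either flank is missing, the flanks are out of order, or
#' the intervening length deviates from the configured splint-UMI length by
#' more than `umiMaxEdits`.
#'
#' @param reads Named [Biostrings::DNAStringSet] or character vector.
#' @param chemistry A [ChemistryConfig] (defines the flanks and UMI length).
#' @param params A [UmiMergeParams].
#' @param orientation Optional `+`/`-` vector (e.g. from [demultiplex()]);
#'   reads with `NA` or missing orientation are searched on both strands.
#' @return data.frame with columns `read_id`, `splint_umi` (`NA` when not
#'   found), `status` (`ok`/`not_found`).
#' @export
extractSplintUmi <- function(reads, chemistry = ChemistryConfig(),
                             params = UmiMergeParams(), orientation = NULL) {
    seqs <- if (is(reads, "XStringSet")) as.character(reads) else reads
    ids <- names(seqs)
    if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(seqs))
    n <- length(seqs)
    out <- data.frame(read_id = ids, splint_umi = NA_character_,
                      status = "not_found", stringsAsFactors = FALSE)
    if (n == 0L || chemistry@splintUmiLen == 0L) return(out)
    f1 <- chemistry@splintFlanks[1]; f2 <- chemistry@splintFlanks[2]
    budget <- function(f) {
        if (is.na(params@flankMaxEdits)) as.integer(floor(0.2 * nchar(f)))
        else params@flankMaxEdits
    }
    b1 <- budget(f1); b2 <- budget(f2)

    if (is.null(orientation)) orientation <- rep(NA_character_, n)
    rc <- revcomp(seqs)
    oriented <- ifelse(!is.na(orientation) & orientation == "-", rc, seqs)
    # unknown orientation: pick the strand where flank1 matches better
    unk <- is.na(orientation)
    if (any(unk)) {
        df <- cpp_infix_search(f1, seqs[unk])$dist
        dr <- cpp_infix_search(f1, rc[unk])$dist
        oriented[unk] <- ifelse(dr < df, rc[unk], seqs[unk])
    }
    h1 <- cpp_infix_search(f1, oriented)
    h2 <- cpp_infix_search(f2, oriented)
    ok <- h1$dist <= b1 & h2$dist <= b2 &
        !is.na(h1$end) & !is.na(h2$start) & h2$start > h1$end + 1L
    umi <- ifelse(ok, substr(oriented, h1$end + 1L, h2$start - 1L), NA)
    lenOk <- ok & abs(nchar(umi) - chemistry@splintUmiLen) <= params@umiMaxEdits
    out$splint_umi[lenOk] <- umi[lenOk]
    out$status[lenOk] <- "ok"
    out
}

selectRepresentative <- function(ids, subreads, lens) {
    o <- order(-subreads, -lens, ids)
    ids[o[1L]]
}

#' Merge reads whose UMIs are similar
#'
#' Single-linkage grouping (union-find) of reads whose UMIs lie within
#' `umiMaxEdits` Levenshtein distance of each other.  Reads with no
#' extractable UMI (`NA`) pass through as singletons.  The partition is
#' independent of input order; the representative of each group is the member
#' with the highest subread count, then the longest sequence, then the
#' lexicographically smallest read id.
#'
#' @param readIds Character vector of read ids.
#' @param umis Character vector of UMIs parallel to `readIds` (`NA` allowed).
#' @param params A [UmiMergeParams].
#' @param subreads Optional numeric vector of subread counts (default 1).
#' @param lens Optional numeric vector of read lengths (default 0).
#' @return List with `membership` (data.frame `read_id`, `group`) and
#'   `groups` (data.frame `group`, `representative`, `member_count`).
#' @export
mergeByUmi <- function(readIds, umis, params = UmiMergeParams(),
                       subreads = NULL, lens = NULL) {
    stopifnot(length(readIds) == length(umis))
    n <- length(readIds)
    if (is.null(subreads)) subreads <- rep(1, n)
    if (is.null(lens)) lens <- rep(0, n)
    grp <- cpp_umi_groups(as.character(umis), params@umiMaxEdits)
    membership <- data.frame(read_id = readIds, group = grp,
                             stringsAsFactors = FALSE)
    idx <- split(seq_len(n), grp)
    groups <- data.frame(
        group = as.integer(names(idx)),
        representative = vapply(idx, function(i)
            selectRepresentative(readIds[i], subreads[i], lens[i]),
            character(1)),
        member_count = lengths(idx),
        stringsAsFactors = FALSE)
    rownames(groups) <- NULL
    groups <- groups[order(groups$group), ]
    list(membership = membership, groups = groups)
}

#' Two-stage UMI merging: splint UMI, then 10X UMI
#'
#' Stage 1 groups reads sharing a similar splint UMI (same circularization
#' event); stage 2 regroups the stage-1 representatives by similar 10X UMI
#' (same RNA molecule).  Merging runs across all reads at once — before the
#' final per-cell demultiplexing — so groups that accidentally span cells can
#' arise and are handled by [discardCrossCellMerges()] afterwards, mirroring
#' the published processing order.
#'
#' @param assignments Assignment data.frame from [demultiplex()] (needs
#'   `read_id`, `observed_umi`, `orientation`, `assigned_barcode`).
#' @param reads Named [Biostrings::DNAStringSet] (for splint-UMI extraction
#'   and representative tie-breaking).
#' @param chemistry A [ChemistryConfig].
#' @param params A [UmiMergeParams].
#' @param subreads Optional named numeric vector of subread counts.
#' @return List with `merged` (data.frame: `group`, `representative`,
#'   `member_count`, `n_cells`, `cells` comma-separated distinct member
#'   cells), `members` (data.frame `read_id`, `group`), and `report`
#'   (per-stage input/output counts and merged fractions).
#' @export
sequentialMerge <- function(assignments, reads,
                            chemistry = ChemistryConfig(),
                            params = UmiMergeParams(), subreads = NULL) {
    ids <- assignments$read_id
    lens <- setNames(as.numeric(Biostrings::width(reads)), names(reads))[ids]
    lens[is.na(lens)] <- 0
    sub <- if (is.null(subreads)) rep(1, length(ids))
           else { s <- subreads[ids]; s[is.na(s)] <- 1; s }

    sp <- extractSplintUmi(reads[ids], chemistry, params,
                           orientation = assignments$orientation)
    st1 <- mergeByUmi(ids, sp$splint_umi, params, sub, lens)

    rep1 <- st1$groups$representative
    i1 <- match(rep1, ids)
    st2 <- mergeByUmi(rep1, assignments$observed_umi[i1], params,
                      sub[i1], lens[i1])

    # final group of each read: its stage-1 group's stage-2 group
    # (st2 membership rows are parallel to st1$groups rows)
    g2 <- st2$membership$group[match(st1$membership$group, st1$groups$group)]

    cellOf <- setNames(assignments$assigned_barcode, ids)
    idx <- split(seq_along(ids), g2)
    merged <- data.frame(
        group = as.integer(names(idx)),
        representative = vapply(idx, function(i)
            selectRepresentative(ids[i], sub[i], lens[i]), character(1)),
        member_count = lengths(idx),
        n_cells = vapply(idx, function(i)
            length(unique(stats::na.omit(cellOf[ids[i]]))), integer(1)),
        cells = vapply(idx, function(i)
            paste(sort(unique(stats::na.omit(cellOf[ids[i]]))), collapse = ","),
            character(1)),
        stringsAsFactors = FALSE)
    rownames(merged) <- NULL
    merged <- merged[order(merged$group), ]

    nReads <- length(ids); n1 <- nrow(st1$groups); n2 <- nrow(merged)
    report <- list(
        input_reads = nReads,
        splint_merged_reads = n1,
        splint_merge_fraction = if (nReads) 1 - n1 / nReads else 0,
        tenx_merged_reads = n2,
        tenx_merge_fraction = if (n1) 1 - n2 / n1 else 0,
        splint_umi_found = sum(sp$status == "ok"))
    list(merged = merged,
         members = data.frame(read_id = ids, group = g2,
                              stringsAsFactors = FALSE),
         report = report)
}

#' Discard merged reads spanning multiple cell assignments
#'
#' A merged consensus read generated by merging reads with different cell
#' assignments is discarded (unassigned members do not count as a cell).
#'
#' @param merged The `merged` data.frame from [sequentialMerge()] (needs
#'   `n_cells`).
#' @return List with `kept` and `discarded` subsets of `merged`.
#' @export
discardCrossCellMerges <- function(merged) {
    bad <- merged$n_cells > 1L
    list(kept = merged[!bad, , drop = FALSE],
         discarded = merged[bad, , drop = FALSE])
}

#' Exact barcode/UMI deduplication with a raw-coverage floor
#'
#' The short-read-style molecule counting: collapse identical (cell barcode,
#' UMI) pairs and keep only molecules whose raw read coverage exceeds
#' `minRawCoverage` (default 3, i.e. at least 4 reads).
#'
#' @param barcodes,umis Character vectors, parallel, one entry per raw read.
#' @param minRawCoverage Keep pairs with coverage strictly greater than this.
#' @return data.frame `barcode`, `umi`, `coverage` of surviving molecules.
#' @examples
#' illuminaDedup(rep("AAAA", 5), rep("CCCC", 5))  # coverage 5 > 3: kept
#' @export
illuminaDedup <- function(barcodes, umis, minRawCoverage = 3L) {
    stopifnot(length(barcodes) == length(umis), minRawCoverage >= 0)
    key <- paste(barcodes, umis, sep = "\t")
    tab <- table(key)
    keep <- tab > minRawCoverage
    parts <- strsplit(names(tab)[keep], "\t", fixed = TRUE)
    data.frame(barcode = vapply(parts, `[`, character(1), 1L),
               umi = vapply(parts, `[`, character(1), 2L),
               coverage = as.integer(tab[keep]),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare per-cell UMI sets between two datasets
#'
#' For each cell present in either dataset, reports the UMIs shared between
#' the two (exact string match) and those unique to each, plus the aggregate
#' shared fraction relative to dataset A.
#'
#' @param umisA,umisB Named lists of character vectors: UMIs per cell.
#' @return List with `perCell` (data.frame `cell`, `shared`, `a_only`,
#'   `b_only`) and `shared_fraction` (shared / total A UMIs).
#' @export
compareUmiSets <- function(umisA, umisB) {
    cells <- union(names(umisA), names(umisB))
    rows <- lapply(cells, function(cl) {
        a <- unique(umisA[[cl]]); b <- unique(umisB[[cl]])
        data.frame(cell = cl,
                   shared = length(intersect(a, b)),
                   a_only = length(setdiff(a, b)),
                   b_only = length(setdiff(b, a)),
                   stringsAsFactors = FALSE)
    })
    perCell <- do.call(rbind, rows)
    totA <- sum(perCell$shared) + sum(perCell$a_only)
    list(perCell = perCell,
         shared_fraction = if (totA) sum(perCell$shared) / totA else NA_real_)
}
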