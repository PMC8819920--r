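#' @import Biostrings
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

randomDna <- function(n, len) {
    vapply(seq_len(n), function(i)
        paste(sample(DNA_BASES4, len, replace = TRUE), collapse = ""),
        character(1))
}

#' Generate a barcode whitelist with a minimum pairwise distance
#'
#' Draws random barcodes of the requested length and keeps those at
#' Levenshtein distance at least `minDist` from every barcode already kept.
#' Real 10X whitelists are not distance-separated; enforcing a separation
#' makes simulated demultiplexing benchmarks interpretable, because assignment
#' errors can then be attributed to read errors rather than whitelist
#' collisions.
#'
#' @param n Number of barcodes.
#' @param length Barcode length in nt.
#' @param minDist Minimum pairwise Levenshtein distance (0 disables the check).
#' @param seed Optional integer seed.
#' @param maxAttempts Bound on candidate draws before giving up.
#' @return Character vector of `n` distinct barcodes.
#' @examples
#' makeBarcodeWhitelist(10, 16, minDist = 5, seed = 1)
#' @export
makeBarcodeWhitelist <- function(n, length = 16L, minDist = 0L, seed = NULL,
                                 maxAttempts = 1000L * n) {
    stopifnot(n >= 1, length >= 1, minDist >= 0)
    if (4^length < 4 * n)
        stop("barcode space 4^length too small for n barcodes")
    if (!is.null(seed)) set.seed(seed)
    kept <- character(0)
    attempts <- 0L
    while (base::length(kept) < n) {
        attempts <- attempts + 1L
        if (attempts > maxAttempts)
            stop("could not find ", n, " barcodes at minDist ", minDist,
                 " within ", maxAttempts, " attempts")
        cand <- randomDna(1L, length)
        if (base::length(kept) == 0L ||
            minDist == 0L && !cand %in% kept ||
            minDist > 0L && all(cpp_levenshtein_matrix(cand, kept) >= minDist))
            kept <- c(kept, cand)
    }
    kept
}

#' Apply a per-base error model to sequences
#'
#' Each base is independently deleted, substituted (with a different random
#' base), or kept; after each emitted position an insertion of a random base
#' occurs with the insertion rate.  With all rates zero the input is returned
#' unchanged.  Randomness comes from R's RNG, so `set.seed()` makes the
#' corruption reproducible.
#'
#' @param seqs Character vector or [Biostrings::DNAStringSet].
#' @param model An [ErrorModel].
#' @return Object of the same class as `seqs` with errors applied.
#' @examples
#' corruptSequence("ACGTACGT", ErrorModel(subRate = 0, insRate = 0, delRate = 0))
#' @export
corruptSequence <- function(seqs, model = ErrorModel()) {
    stopifnot(is(model, "ErrorModel"))
    wasXSS <- is(seqs, "XStringSet")
    x <- if (wasXSS) as.character(seqs) else seqs
    stopifnot(all(nchar(x) > 0))
    out <- cpp_corrupt(x, model@subRate, model@insRate, model@delRate)
    names(out) <- names(x)
    if (wasXSS) Biostrings::DNAStringSet(out) else out
}

revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# "separated" UMIs are pairwise Levenshtein distance >= 2 apart so that
# ground-truth molecule identity stays unambiguous under the default
# similar-UMI merge threshold of 1 edit; "unique" only guarantees
# distinctness (needed when the requested count exceeds what distance-2
# sphere packing allows, e.g. tens of thousands of 10-mers).
uniqueUmis <- function(n, len, mode = "separated") {
    if (n == 0L) return(character(0))
    if (mode == "separated")
        return(cpp_separated_umis(as.integer(n), as.integer(len)))
    umis <- randomDna(n, len)
    while (anyDuplicated(umis)) {
        dup <- which(duplicated(umis))
        umis[dup] <- randomDna(length(dup), len)
    }
    umis
}

#' Simulate barcoded full-length cDNA consensus reads with ground truth
#'
#' Emits reads laid out as
#' `[adapter][barcode][10X UMI][oligo-dT][revcomp(transcript)][splint cassette]`
#' and a truth table linking every read to its cell, RNA molecule, and
#' circularization event.  Each RNA molecule carries a globally unique 10X
#' UMI; with probability `tenxDupRate` a molecule is reverse-transcribed into
#' an additional read sharing that UMI (a PCR duplicate, independently
#' circularized); with probability `splintDupRate` a circularization event
#' emits a second read sharing its splint UMI.  Reads land on a random strand
#' and errors are applied last.
#'
#' @param whitelist Character vector of cell barcodes; the first `cells`
#'   entries become cells.
#' @param transcripts Named [Biostrings::DNAStringSet] of transcript bodies.
#' @param cells Number of cells to simulate (ignored when `transcriptCells`
#'   is given).
#' @param moleculesPerCell Either a single count (every cell gets exactly that
#'   many molecules) or a function of the number of cells returning a vector
#'   of counts.
#' @param splintDupRate,tenxDupRate Per-event duplication probabilities
#'   (one extra copy each time).
#' @param chemistry A [ChemistryConfig].
#' @param errors An [ErrorModel]; use all-zero rates for error-free reads.
#' @param transcriptCells Optional character vector parallel to
#'   `names(transcripts)` giving the cell label owning each transcript; when
#'   set, each cell's molecules are drawn only from its own transcripts (used
#'   for immune-receptor simulations where transcripts are cell-private).
#' @param transcriptInfo Optional data.frame keyed by `transcript_id` whose
#'   remaining columns (e.g. locus and segment identities) are joined onto
#'   the truth table.
#' @param umiMode `"separated"` (default) draws UMIs at pairwise Levenshtein
#'   distance of at least 2, so that merging with the default 1-edit
#'   threshold can recover molecule identity exactly; `"unique"` only
#'   guarantees distinct UMIs and must be used when the molecule count
#'   exceeds the distance-2 packing capacity of the UMI space.
#' @param seed Optional integer seed.
#' @return List with `reads` (named `DNAStringSet`) and `truth` (data.frame
#'   with columns `read_id`, `cell_barcode`, `molecule_id`,
#'   `splint_event_id`, `transcript_id`, `strand`, `umi`, `splint_umi`, plus
#'   any `transcriptInfo` columns).
#' @examples
#' wl <- makeBarcodeWhitelist(4, 16, minDist = 5, seed = 1)
#' tx <- Biostrings::DNAStringSet(setNames(
#'     c(paste(rep("ACGT", 50), collapse = ""),
#'       paste(rep("GGCA", 50), collapse = "")), c("t1", "t2")))
#' sim <- simulateReads(wl, tx, cells = 4, moleculesPerCell = 5, seed = 1,
#'                      errors = ErrorModel(0, 0, 0))
#' length(sim$reads)
#' @export
simulateReads <- function(whitelist, transcripts, cells = length(whitelist),
                          moleculesPerCell = 10,
                          splintDupRate = 0, tenxDupRate = 0,
                          chemistry = ChemistryConfig(),
                          errors = ErrorModel(0, 0, 0),
                          transcriptCells = NULL, transcriptInfo = NULL,
                          umiMode = c("separated", "unique"), seed = NULL) {
    umiMode <- match.arg(umiMode)
    stopifnot(length(whitelist) >= 1, length(transcripts) >= 1,
              !is.null(names(transcripts)))
    if (!is.null(seed)) set.seed(seed)
    txSeq <- as.character(transcripts)
    txIds <- names(transcripts)

    if (!is.null(transcriptCells)) {
        stopifnot(length(transcriptCells) == length(transcripts))
        cellLabels <- unique(transcriptCells)
        cells <- length(cellLabels)
        if (cells > length(whitelist))
            stop("whitelist smaller than the number of cells")
        txByCell <- split(seq_along(txIds), transcriptCells)[cellLabels]
    } else {
        cells <- as.integer(cells)
        if (cells > length(whitelist))
            stop("whitelist smaller than the number of cells")
        cellLabels <- whitelist[seq_len(cells)]
        txByCell <- rep(list(seq_along(txIds)), cells)
    }
    barcodes <- whitelist[seq_len(cells)]

    nMol <- if (is.function(moleculesPerCell)) {
        as.integer(moleculesPerCell(cells))
    } else rep(as.integer(moleculesPerCell), cells)
    stopifnot(length(nMol) == cells, all(nMol >= 0))

    totMol <- sum(nMol)
    molCell <- rep(seq_len(cells), nMol)
    molTx <- unlist(lapply(seq_len(cells), function(ci) {
        pool <- txByCell[[ci]]
        pool[sample.int(length(pool), nMol[ci], replace = TRUE)]
    }), use.names = FALSE)
    molUmi <- uniqueUmis(totMol, chemistry@umiLen, umiMode)
    molId <- sprintf("mol_%06d", seq_len(totMol))

    # circularization events: one per molecule copy
    nCopies <- 1L + (stats::runif(totMol) < tenxDupRate)
    circMol <- rep(seq_len(totMol), nCopies)
    nCirc <- length(circMol)
    circUmi <- uniqueUmis(nCirc, max(chemistry@splintUmiLen, 1L), umiMode)
    circId <- sprintf("circ_%06d", seq_len(nCirc))

    # reads: one per circularization event, plus splint duplicates
    nReads <- 1L + (stats::runif(nCirc) < splintDupRate)
    readCirc <- rep(seq_len(nCirc), nReads)
    n <- length(readCirc)

    mol <- circMol[readCirc]
    plus <- paste0(chemistry@adapter,
                   barcodes[molCell[mol]],
                   molUmi[mol],
                   strrep("T", chemistry@polyALen),
                   revcomp(txSeq[molTx[mol]]))
    if (chemistry@splintUmiLen > 0L)
        plus <- paste0(plus, chemistry@splintFlanks[1], circUmi[readCirc],
                       chemistry@splintFlanks[2])
    strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
    seqs <- ifelse(strand == "+", plus, revcomp(plus))
    seqs <- cpp_corrupt(seqs, errors@subRate, errors@insRate, errors@delRate)
    readIds <- sprintf("read_%06d", seq_len(n))
    names(seqs) <- readIds

    truth <- data.frame(
        read_id = readIds,
        cell_barcode = barcodes[molCell[mol]],
        cell = cellLabels[molCell[mol]],
        molecule_id = molId[mol],
        splint_event_id = circId[readCirc],
        transcript_id = txIds[molTx[mol]],
        strand = strand,
        umi = molUmi[mol],
        splint_umi = if (chemistry@splintUmiLen > 0L) circUmi[readCirc]
                     else NA_character_,
        stringsAsFactors = FALSE)
    if (!is.null(transcriptInfo)) {
        stopifnot("transcript_id" %in% colnames(transcriptInfo))
        extra <- transcriptInfo[, c("transcript_id",
            setdiff(colnames(transcriptInfo), colnames(truth))),
            drop = FALSE]
        truth <- merge(truth, extra, by = "transcript_id",
                       all.x = TRUE, sort = FALSE)
        truth <- truth[order(truth$read_id), ]
        rownames(truth) <- NULL
    }
    list(reads = Biostrings::DNAStringSet(seqs), truth = truth)
}

#' Synthetic V(D)J segment references
#'
#' Generates random (synthetic, not IMGT-derived) segment references for the
#' five adaptive-immune-receptor loci, with realistic lengths: V ~300 nt,
#' D ~16 nt, J ~50 nt, constant regions ~450 nt.  IGH constant regions are
#' emitted once per isotype.
#'
#' @param nV,nJ Segments per locus.
#' @param nD Segments for the D-bearing loci (IGH, TRB).
#' @param isotypes IGH isotype labels to emit constant regions for.
#' @param seed Optional integer seed.
#' @return Named list with elements `V`, `D`, `J`, `C`, each a list of
#'   [Biostrings::DNAStringSet] keyed by locus.
#' @export
simulateSegmentReferences <- function(nV = 8L, nD = 6L, nJ = 4L,
        isotypes = c("IGHM", "IGHD", "IGHG1", "IGHG2", "IGHA1"),
        seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    loci <- c("IGH", "IGK", "IGL", "TRA", "TRB")
    dLoci <- c("IGH", "TRB")
    mk <- function(ids, len) {
        Biostrings::DNAStringSet(setNames(randomDna(length(ids), len), ids))
    }
    V <- setNames(lapply(loci, function(l)
        mk(sprintf("%sV%d", l, seq_len(nV)), 300L)), loci)
    D <- setNames(lapply(dLoci, function(l)
        mk(sprintf("%sD%d", l, seq_len(nD)), 16L)), dLoci)
    J <- setNames(lapply(loci, function(l)
        mk(sprintf("%sJ%d", l, seq_len(nJ)), 50L)), loci)
    C <- setNames(lapply(loci, function(l) {
        if (l == "IGH") mk(isotypes, 450L)
        else mk(paste0(l, "C"), 450L)
    }), loci)
    list(V = V, D = D, J = J, C = C)
}

#' Simulate a per-cell adaptive immune receptor repertoire
#'
#' Each B cell receives one recombined IGH transcript (V-D-J plus a sampled
#' isotype constant region) and one light-chain transcript (IGK or IGL,
#' equal probability); each T cell receives one TRA (V-J-C) and one TRB
#' (V-D-J-C) transcript.  Junctions get 0-8 random nt insertions.  All
#' transcripts of a cell are labelled with the cell so the read simulator can
#' keep them cell-private.
#'
#' @param refs Segment references as returned by
#'   [simulateSegmentReferences()] (or user-supplied FASTA sets in the same
#'   list-of-loci layout).
#' @param nBcells,nTcells Cell counts.
#' @param extraIsotypeRate Probability that a B cell expresses a second IGH
#'   isotype from the same rearrangement (same V/D/J, different constant
#'   region), emulating alternative-splicing isotype products.
#' @param seed Optional integer seed.
#' @return List with `transcripts` (named `DNAStringSet`),
#'   `transcriptCells` (character vector parallel to the transcripts naming
#'   the owning cell), and `truth` (data.frame: `transcript_id`, `cell`,
#'   `cell_type`, `locus`, `v_id`, `d_id`, `j_id`, `c_id`, `isotype`).
#' @examples
#' refs <- simulateSegmentReferences(seed = 1)
#' rep <- simulateAirRepertoire(refs, nBcells = 2, nTcells = 2, seed = 1)
#' rep$truth[, c("cell", "locus", "v_id")]
#' @export
simulateAirRepertoire <- function(refs, nBcells, nTcells,
                                  extraIsotypeRate = 0, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    stopifnot(nBcells >= 0, nTcells >= 0)
    for (l in c("IGH", "IGK", "IGL", "TRA", "TRB"))
        if (!l %in% names(refs$V) || !l %in% names(refs$J) ||
            !l %in% names(refs$C))
            stop("missing V/J/C references for locus ", l)
    for (l in c("IGH", "TRB"))
        if (!l %in% names(refs$D)) stop("missing D references for locus ", l)

    junction <- function() {
        k <- sample.int(9L, 1L) - 1L
        if (k == 0L) "" else randomDna(1L, k)
    }
    pick <- function(set) {
        i <- sample.int(length(set), 1L)
        list(id = names(set)[i], seq = as.character(set[[i]]))
    }
    rows <- list(); seqs <- character(0); owners <- character(0)
    emit <- function(cell, cellType, locus, isotype = NA_character_,
                     fixed = NULL) {
        v <- if (is.null(fixed)) pick(refs$V[[locus]]) else fixed$v
        hasD <- locus %in% c("IGH", "TRB")
        d <- if (!hasD) NULL else if (is.null(fixed)) pick(refs$D[[locus]]) else fixed$d
        j <- if (is.null(fixed)) pick(refs$J[[locus]]) else fixed$j
        cset <- refs$C[[locus]]
        ci <- if (locus == "IGH") {
            if (is.na(isotype)) isotype <- sample(names(cset), 1L)
            which(names(cset) == isotype)
        } else 1L
        cid <- names(cset)[ci]
        body <- paste0(v$seq, junction(),
                       if (hasD) paste0(d$seq, junction()) else "",
                       j$seq, as.character(cset[[ci]]))
        txid <- sprintf("%s_%s%s", cell, locus,
                        if (locus == "IGH" && !is.na(isotype))
                            paste0("_", isotype) else "")
        rows[[length(rows) + 1L]] <<- data.frame(
            transcript_id = txid, cell = cell, cell_type = cellType,
            locus = locus, v_id = v$id,
            d_id = if (hasD) d$id else NA_character_,
            j_id = j$id, c_id = cid,
            isotype = if (locus == "IGH") cid else NA_character_,
            stringsAsFactors = FALSE)
        seqs[txid] <<- body
        owners[txid] <<- cell
        invisible(list(v = v, d = d, j = j))
    }

    for (b in seq_len(nBcells)) {
        cell <- sprintf("Bcell_%03d", b)
        fixed <- emit(cell, "B", "IGH")
        if (extraIsotypeRate > 0 && stats::runif(1) < extraIsotypeRate) {
            first <- rows[[length(rows)]]$isotype
            others <- setdiff(names(refs$C[["IGH"]]), first)
            if (length(others))
                emit(cell, "B", "IGH", isotype = sample(others, 1L),
                     fixed = fixed)
        }
        emit(cell, "B", sample(c("IGK", "IGL"), 1L))
    }
    for (t in seq_len(nTcells)) {
        cell <- sprintf("Tcell_%03d", t)
        emit(cell, "T", "TRA")
        emit(cell, "T", "TRB")
    }
    truth <- if (length(rows)) do.call(rbind, rows) else
        data.frame(transcript_id = character(0), cell = character(0),
                   cell_type = character(0), locus = character(0),
                   v_id = character(0), d_id = character(0),
                   j_id = character(0), c_id = character(0),
                   isotype = character(0), stringsAsFactors = FALSE)
    list(transcripts = Biostrings::DNAStringSet(seqs),
         transcriptCells = owners, truth = truth)
}

#' Write simulated reads as FASTQ with constant quality
#'
#' @param reads Named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @param quality Single Phred+33 quality character applied to every base.
#' @return `path`, invisibly.
#' @export
writeSimFastq <- function(reads, path, quality = "I") {
    q <- Biostrings::BStringSet(vapply(width(reads), function(w)
        strrep(quality, w), character(1)))
    qs <- Biostrings::QualityScaledDNAStringSet(
        reads, Biostrings::PhredQuality(q))
    Biostrings::writeQualityScaledXStringSet(qs, path)
    invisible(path)
}
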