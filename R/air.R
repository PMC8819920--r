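AIR_LOCI <- c("IGH", "IGK", "IGL", "TRA", "TRB")
D_LOCI <- c("IGH", "TRB")

#' Read locus definitions from a BED file
#'
#' BED intervals (0-based half-open) naming the receptor locus each interval
#' belongs to (name column in `IGH`, `IGK`, `IGL`, `TRA`, `TRB`).  A locus
#' may span several intervals (e.g. constant-region exon clusters).
#'
#' @param path BED3+ file with the locus in the name column.
#' @return A [GenomicRanges::GRanges] with metadata columns `locus` and
#'   `requires_D`.
#' @export
readLocusBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(gr$name) || any(is.na(gr$name)))
        stop("locus BED needs a name column naming the locus of each interval")
    bad <- setdiff(unique(gr$name), AIR_LOCI)
    if (length(bad))
        stop("unknown locus name(s) in BED: ", paste(bad, collapse = ", "))
    gr$locus <- gr$name
    gr$requires_D <- gr$locus %in% D_LOCI
    gr$name <- NULL
    gr
}

#' Extract receptor-locus reads from SAM alignments
#'
#' Selects reads whose primary alignment overlaps any interval of a locus by
#' at least one base; unmapped, secondary, and supplementary alignments are
#' ignored.  Cell identity comes either from a `CB` tag on each record or
#' from a one-file-per-cell layout (named `samPaths`); an unnamed multi-cell
#' SAM without `CB` tags is an error.
#'
#' @param samPaths Character vector of SAM/BAM paths.  Names, when present,
#'   are taken as the cell ids of the files.
#' @param loci Locus definitions from [readLocusBed()].
#' @return List with `table` (data.frame `read_id`, `cell`, `locus`) and
#'   `reads` (named [Biostrings::DNAStringSet] of the selected reads, as
#'   aligned, i.e. reverse-complemented records are already on the reference
#'   strand).
#' @export
extractLocusReads <- function(samPaths, loci) {
    perFile <- lapply(seq_along(samPaths), function(k) {
        path <- samPaths[k]
        bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
            dest <- tempfile(fileext = ".bam")
            Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                             overwrite = TRUE, indexDestination = TRUE)
        } else path
        flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                       isSecondaryAlignment = FALSE,
                                       isSupplementaryAlignment = FALSE)
        param <- Rsamtools::ScanBamParam(flag = flag, what = c("seq"),
                                         tag = "CB")
        aln <- GenomicAlignments::readGAlignments(bam, use.names = TRUE,
                                                  param = param)
        if (!length(aln)) return(NULL)
        cb <- S4Vectors::mcols(aln)$CB
        cell <- if (!is.null(names(samPaths)) && nzchar(names(samPaths)[k])) {
            rep(names(samPaths)[k], length(aln))
        } else if (!is.null(cb) && !all(is.na(cb))) {
            as.character(cb)
        } else {
            stop("no cell identity: supply named samPaths (one file per ",
                 "cell) or CB tags on the alignments")
        }
        hits <- GenomicRanges::findOverlaps(GenomicRanges::granges(aln),
                                            loci, minoverlap = 1L)
        if (!length(hits)) return(NULL)
        q <- S4Vectors::queryHits(hits)
        df <- data.frame(read_id = names(aln)[q], cell = cell[q],
                         locus = loci$locus[S4Vectors::subjectHits(hits)],
                         stringsAsFactors = FALSE)
        df <- df[!duplicated(df[, c("read_id", "locus")]), ]
        seqs <- S4Vectors::mcols(aln)$seq[match(unique(df$read_id),
                                                names(aln))]
        names(seqs) <- unique(df$read_id)
        list(table = df, reads = seqs)
    })
    perFile <- perFile[!vapply(perFile, is.null, logical(1))]
    if (!length(perFile))
        return(list(table = data.frame(read_id = character(0),
                                       cell = character(0),
                                       locus = character(0)),
                    reads = Biostrings::DNAStringSet()))
    tab <- do.call(rbind, lapply(perFile, `[[`, "table"))
    reads <- do.call(c, lapply(perFile, `[[`, "reads"))
    rownames(tab) <- NULL
    list(table = tab, reads = Biostrings::DNAStringSet(reads))
}

# screen all (reference, strand) combinations by semi-global edit distance,
# then score the single best candidate with a traceback Smith-Waterman.
# refs: named character vector.  Returns one row per read.
bestSegmentHit <- function(seqs, refs, scoring) {
    n <- length(seqs)
    rc <- revcomp(seqs)
    bestDist <- rep(Inf, n)
    bestRef <- rep(NA_character_, n)
    bestStrand <- rep(NA_character_, n)
    ord <- order(names(refs))          # deterministic tie-break: smaller id
    for (j in ord) {
        for (str in c("+", "-")) {
            d <- cpp_myers_search(unname(refs[j]),
                                  if (str == "+") seqs else rc)$dist
            upd <- d < bestDist
            bestDist[upd] <- d[upd]
            bestRef[upd] <- names(refs)[j]
            bestStrand[upd] <- str
        }
    }
    out <- data.frame(ref = bestRef, strand = bestStrand,
                      score = NA_real_, identity = NA_real_,
                      aligned_length = NA_integer_,
                      q_start = NA_integer_, q_end = NA_integer_,
                      stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
        if (is.na(bestRef[i])) next
        qs <- if (bestStrand[i] == "+") seqs[i] else rc[i]
        a <- cpp_local_align(qs, unname(refs[bestRef[i]]),
                             scoring["match"], scoring["mismatch"],
                             scoring["gapOpen"], scoring["gapExtend"])
        out$score[i] <- a$score
        out$identity[i] <- if (a$n_cols > 0) a$n_match / a$n_cols else 0
        out$aligned_length[i] <- a$n_cols
        out$q_start[i] <- a$q_start
        out$q_end[i] <- a$q_end
    }
    out
}

defaultAirScoring <- function() {
    c(match = 2, mismatch = -2, gapOpen = -4, gapExtend = -1)
}

#' Filter reads for a high-quality V-segment match
#'
#' Aligns every read locally against every V reference on both strands and
#' keeps reads whose best alignment reaches `minIdentity` identity over at
#' least `minAlignedLength` aligned columns.  Reads are reported reoriented
#' to the V-coding strand.
#'
#' @param reads Named [Biostrings::DNAStringSet] or character vector.
#' @param vRefs Either a [Biostrings::DNAStringSet] of V references for one
#'   locus, or a named list of such sets keyed by locus — in the latter case
#'   each read is also assigned the locus of its best V match.
#' @param params A [VFilterParams].
#' @param scoring Named numeric vector `match`, `mismatch`, `gapOpen`,
#'   `gapExtend`.
#' @return List with `table` (data.frame `read_id`, `locus` (`NA` when a
#'   single reference set was given), `v_id`, `identity`, `aligned_length`,
#'   `strand`, `pass`) and `oriented` (DNAStringSet of the passing reads on
#'   the V-coding strand).
#' @export
vFilter <- function(reads, vRefs, params = VFilterParams(),
                    scoring = defaultAirScoring()) {
    seqs <- if (is(reads, "XStringSet")) as.character(reads) else reads
    ids <- names(seqs)
    if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(seqs))
    byLocus <- is.list(vRefs) && !is(vRefs, "XStringSet")
    flat <- if (byLocus) {
        locusOf <- rep(names(vRefs), lengths(vRefs))
        refs <- unlist(lapply(vRefs, as.character), use.names = FALSE)
        names(refs) <- unlist(lapply(vRefs, names), use.names = FALSE)
        stopifnot(!anyDuplicated(names(refs)))
        attr(refs, "locus") <- setNames(locusOf, names(refs))
        refs
    } else setNames(as.character(vRefs), names(vRefs))
    hit <- bestSegmentHit(seqs, flat, scoring)
    pass <- !is.na(hit$identity) & hit$identity >= params@minIdentity &
        hit$aligned_length >= params@minAlignedLength
    tab <- data.frame(
        read_id = ids,
        locus = if (byLocus) unname(attr(flat, "locus")[hit$ref])
                else NA_character_,
        v_id = hit$ref, identity = hit$identity,
        aligned_length = hit$aligned_length, strand = hit$strand,
        pass = pass, stringsAsFactors = FALSE)
    oriented <- ifelse(hit$strand == "-", revcomp(seqs), seqs)
    names(oriented) <- ids
    list(table = tab,
         oriented = Biostrings::DNAStringSet(oriented[which(pass)]))
}

#' Assign IGH reads to isotypes by constant-region alignment
#'
#' Each read (already on the V-coding strand) is assigned the isotype of its
#' best-scoring constant-region reference; reads with no sufficient match
#' are set aside as unassigned.
#'
#' @param reads Named [Biostrings::DNAStringSet] of V-oriented IGH reads.
#' @param cRefs [Biostrings::DNAStringSet] of constant-region references
#'   named by isotype (e.g. `IGHM`, `IGHG1`); membrane/secreted forms can be
#'   distinguished by supplying form-specific references.
#' @param minIdentity,minAlignedLength Acceptance thresholds for the
#'   constant-region match (defaults 0.80 and 50 nt: constant regions are
#'   shorter targets than V segments).
#' @param scoring Alignment scoring, as in [vFilter()].
#' @return data.frame `read_id`, `isotype` (`NA` when unassigned),
#'   `identity`, `aligned_length`.
#' @export
splitIghByIsotype <- function(reads, cRefs, minIdentity = 0.80,
                              minAlignedLength = 50L,
                              scoring = defaultAirScoring()) {
    seqs <- if (is(reads, "XStringSet")) as.character(reads) else reads
    ids <- names(seqs)
    refs <- setNames(as.character(cRefs), names(cRefs))
    n <- length(seqs)
    out <- data.frame(read_id = ids, isotype = NA_character_,
                      identity = NA_real_, aligned_length = NA_integer_,
                      stringsAsFactors = FALSE)
    if (!n) return(out)
    # reads are already oriented: forward strand only
    bestScore <- rep(-Inf, n); bestRef <- rep(NA_character_, n)
    bestDist <- rep(Inf, n)
    for (j in order(names(refs))) {
        d <- cpp_myers_search(unname(refs[j]), seqs)$dist
        upd <- d < bestDist
        bestDist[upd] <- d[upd]
        bestRef[upd] <- names(refs)[j]
    }
    for (i in seq_len(n)) {
        a <- cpp_local_align(seqs[i], unname(refs[bestRef[i]]),
                             scoring["match"], scoring["mismatch"],
                             scoring["gapOpen"], scoring["gapExtend"])
        idf <- if (a$n_cols > 0) a$n_match / a$n_cols else 0
        if (idf >= minIdentity && a$n_cols >= minAlignedLength) {
            out$isotype[i] <- bestRef[i]
            out$identity[i] <- idf
            out$aligned_length[i] <- a$n_cols
        }
    }
    out
}

#' Build a consensus sequence from reads of one cell and locus
#'
#' A single read is returned verbatim.  For multiple reads the medoid (the
#' read with minimal summed edit distance to the others; ties broken by
#' smaller read id) is polished by per-column majority vote over global
#' alignments of every member to the medoid: a column keeps the majority
#' base, drops to nothing when the majority is a gap, and falls back to the
#' medoid base on ties.  Insertions relative to the medoid are kept when a
#' strict majority of members supports the identical inserted string at the
#' same junction — this is what lets the vote repair deletions the medoid
#' itself carries.  The result does not depend on read order.
#'
#' @param reads Named [Biostrings::DNAStringSet] or character vector.
#' @return List with `consensus` (character), `support` (number of reads),
#'   `medoid` (read id of the scaffold).
#' @export
buildConsensus <- function(reads) {
    seqs <- if (is(reads, "XStringSet")) as.character(reads) else reads
    stopifnot(length(seqs) >= 1)
    ids <- names(seqs)
    if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(seqs))
    o <- order(ids)
    seqs <- seqs[o]; ids <- ids[o]
    n <- length(seqs)
    if (n == 1L)
        return(list(consensus = unname(seqs), support = 1L, medoid = ids))
    dm <- cpp_levenshtein_matrix(seqs, seqs)
    med <- which.min(rowSums(dm))     # first index on ties = smallest id
    scaffold <- seqs[med]
    L <- nchar(scaffold)
    alphabet <- c("A", "C", "G", "T", "N", "-")
    votes <- matrix(0L, nrow = length(alphabet), ncol = L,
                    dimnames = list(alphabet, NULL))
    # insertions relative to the medoid, keyed "junction\rstring";
    # junction j = between medoid positions j and j+1 (0 = before the start)
    insVotes <- new.env(parent = emptyenv())
    for (i in seq_len(n)) {
        if (i == med) {
            ch <- strsplit(scaffold, "")[[1]]
            idx <- match(ch, alphabet); idx[is.na(idx)] <- 5L
            votes[cbind(idx, seq_len(L))] <- votes[cbind(idx, seq_len(L))] + 1L
            next
        }
        al <- cpp_global_align(scaffold, seqs[i], 1, -1, -1)
        ga <- strsplit(al$a, "")[[1]]
        gb <- strsplit(al$b, "")[[1]]
        keep <- ga != "-"             # columns that consume a scaffold base
        obs <- gb[keep]
        idx <- match(obs, alphabet); idx[is.na(idx)] <- 5L
        votes[cbind(idx, seq_len(L))] <- votes[cbind(idx, seq_len(L))] + 1L
        if (any(!keep)) {
            junc <- cumsum(keep)[!keep]        # medoid position before gap
            for (j in unique(junc)) {
                key <- paste0(j, "\r", paste(gb[!keep][junc == j],
                                             collapse = ""))
                insVotes[[key]] <- (if (is.null(insVotes[[key]])) 0L
                                    else insVotes[[key]]) + 1L
            }
        }
    }
    schars <- strsplit(scaffold, "")[[1]]
    best <- apply(votes, 2L, max)
    cons <- vapply(seq_len(L), function(p) {
        w <- which(votes[, p] == best[p])
        if (length(w) > 1L) schars[p]          # tie: keep the medoid base
        else alphabet[w]
    }, character(1))
    cons[cons == "-"] <- ""
    # splice in majority insertions (strict majority of all members)
    ins <- rep("", L + 1L)
    for (key in ls(insVotes)) {
        if (insVotes[[key]] * 2L > n) {
            parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
            j <- as.integer(parts[1])
            cand <- parts[2]
            # keep the lexicographically smallest on equal majority counts
            if (!nzchar(ins[j + 1L]) || cand < ins[j + 1L])
                ins[j + 1L] <- cand
        }
    }
    out <- paste0(paste0(ins[seq_len(L)], cons, collapse = ""), ins[L + 1L])
    list(consensus = out, support = n, medoid = ids[med])
}

segmentCall <- function(query, refs, scoring) {
    if (is.null(refs) || !length(refs)) return(NULL)
    hit <- bestSegmentHit(query, setNames(as.character(refs), names(refs)),
                          scoring)
    hit
}

#' Assign V, (D,) J, and constant segments to a consensus sequence
#'
#' Performs local alignment of the consensus against each reference class.
#' The consensus is first oriented by its best V match; calls must then be
#' positionally ordered V before (D before) J before C along the consensus —
#' a violating D or C call is dropped and flagged, and a consensus without
#' an acceptable V and J is reported unannotated.
#'
#' @param consensus A single sequence (character).
#' @param refs List with elements `V`, `J`, and optionally `D`, `C`:
#'   [Biostrings::DNAStringSet] references for one locus.
#' @param params A [VFilterParams] (applied to the V call).
#' @param minJAligned,minDAligned,minCAligned Minimum aligned lengths for
#'   the shorter segment classes (identity threshold is shared with V).
#' @param scoring Alignment scoring, as in [vFilter()].
#' @return List with elements `v`, `d`, `j`, `c` (each `NULL` or a list of
#'   `id`, `identity`, `aligned_length`, `q_start`, `q_end`), `status`
#'   (`ok`/`unannotated`), `flags` (character vector of dropped or missing
#'   calls), and `oriented` (the consensus on the V-coding strand).
#' @export
assignVdj <- function(consensus, refs, params = VFilterParams(),
                      minJAligned = 25L, minDAligned = 10L,
                      minCAligned = 50L, scoring = defaultAirScoring()) {
    stopifnot(length(consensus) == 1L)
    flags <- character(0)
    vhit <- bestSegmentHit(consensus,
                           setNames(as.character(refs$V), names(refs$V)),
                           scoring)
    if (is.na(vhit$identity) || vhit$identity < params@minIdentity ||
        vhit$aligned_length < params@minAlignedLength)
        return(list(v = NULL, d = NULL, j = NULL, c = NULL,
                    status = "unannotated", flags = "no_V",
                    oriented = consensus))
    oriented <- if (vhit$strand == "-") revcomp(consensus) else consensus
    asCall <- function(hit) list(id = hit$ref, identity = hit$identity,
                                 aligned_length = hit$aligned_length,
                                 q_start = hit$q_start, q_end = hit$q_end)
    # re-evaluate V on the oriented sequence so coordinates are comparable
    vhit <- bestSegmentHit(oriented,
                           setNames(as.character(refs$V), names(refs$V)),
                           scoring)
    v <- asCall(vhit)

    callClass <- function(set, minLen) {
        if (is.null(set) || !length(set)) return(NULL)
        hit <- bestSegmentHit(oriented,
                              setNames(as.character(set), names(set)),
                              scoring)
        if (is.na(hit$identity) || hit$identity < params@minIdentity ||
            hit$aligned_length < minLen) return(NULL)
        asCall(hit)
    }
    j <- callClass(refs$J, minJAligned)
    if (is.null(j))
        return(list(v = v, d = NULL, j = NULL, c = NULL,
                    status = "unannotated", flags = "no_J",
                    oriented = oriented))
    if (j$q_start <= v$q_start) {
        return(list(v = v, d = NULL, j = NULL, c = NULL,
                    status = "unannotated", flags = "J_before_V",
                    oriented = oriented))
    }
    d <- callClass(refs$D, minDAligned)
    if (!is.null(d) && !(d$q_start > v$q_start && d$q_start < j$q_end)) {
        d <- NULL
        flags <- c(flags, "D_out_of_order")
    }
    cc <- callClass(refs$C, minCAligned)
    if (!is.null(cc) && cc$q_start <= j$q_start) {
        cc <- NULL
        flags <- c(flags, "C_out_of_order")
    }
    list(v = v, d = d, j = j, c = cc, status = "ok", flags = flags,
         oriented = oriented)
}

#' Per-cell immune-receptor consensus and annotation
#'
#' Ties the per-read steps together: V-filter (and locus assignment when the
#' read-to-locus table does not provide one), isotype split for IGH,
#' per-cell/per-locus(/per-isotype) consensus, and V(D)J(C) assignment.
#'
#' @param reads Named [Biostrings::DNAStringSet] of candidate receptor reads.
#' @param cells Named character vector mapping read id to cell id.
#' @param refs Segment references: list with `V`, `D`, `J`, `C`, each a list
#'   of [Biostrings::DNAStringSet] keyed by locus (the layout of
#'   [simulateSegmentReferences()]).
#' @param params A [VFilterParams].
#' @param locusOf Optional named character vector mapping read id to locus
#'   (e.g. from [extractLocusReads()]); when absent the locus of the best V
#'   match is used.
#' @param scoring Alignment scoring, as in [vFilter()].
#' @return data.frame with one row per consensus: `cell`, `locus`,
#'   `isotype`, `support`, `consensus`, `v_id`, `v_identity`, `d_id`,
#'   `j_id`, `j_identity`, `c_id`, `status`, `flags`.
#' @export
airConsensus <- function(reads, cells, refs, params = VFilterParams(),
                         locusOf = NULL, scoring = defaultAirScoring()) {
    vf <- vFilter(reads, refs$V, params, scoring)
    tab <- vf$table[vf$table$pass, , drop = FALSE]
    if (!is.null(locusOf))
        tab$locus <- unname(locusOf[tab$read_id])
    tab$cell <- unname(cells[tab$read_id])
    tab <- tab[!is.na(tab$cell) & !is.na(tab$locus), , drop = FALSE]
    oriented <- vf$oriented

    tab$isotype <- NA_character_
    igh <- tab$locus == "IGH"
    if (any(igh) && "IGH" %in% names(refs$C)) {
        iso <- splitIghByIsotype(oriented[tab$read_id[igh]],
                                 refs$C[["IGH"]],
                                 minIdentity = params@minIdentity,
                                 scoring = scoring)
        tab$isotype[igh] <- iso$isotype[match(tab$read_id[igh], iso$read_id)]
    }
    tab <- tab[!(igh & is.na(tab$isotype)), , drop = FALSE]

    key <- paste(tab$cell, tab$locus,
                 ifelse(is.na(tab$isotype), "", tab$isotype), sep = "\r")
    groups <- split(seq_len(nrow(tab)), key)
    groups <- groups[order(names(groups))]
    rows <- lapply(groups, function(i) {
        locus <- tab$locus[i[1L]]
        cons <- buildConsensus(oriented[tab$read_id[i]])
        lrefs <- list(V = refs$V[[locus]], J = refs$J[[locus]],
                      D = refs$D[[locus]], C = refs$C[[locus]])
        call <- assignVdj(cons$consensus, lrefs, params, scoring = scoring)
        g <- function(cl, f) if (is.null(call[[cl]])) NA else call[[cl]][[f]]
        data.frame(cell = tab$cell[i[1L]], locus = locus,
                   isotype = tab$isotype[i[1L]],
                   support = cons$support, consensus = call$oriented,
                   v_id = g("v", "id"), v_identity = g("v", "identity"),
                   d_id = g("d", "id"),
                   j_id = g("j", "id"), j_identity = g("j", "identity"),
                   c_id = g("c", "id"),
                   status = call$status,
                   flags = paste(call$flags, collapse = ";"),
                   stringsAsFactors = FALSE)
    })
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(cell = character(0), locus = character(0),
                   isotype = character(0), support = integer(0),
                   consensus = character(0), v_id = character(0),
                   v_identity = numeric(0), d_id = character(0),
                   j_id = character(0), j_identity = numeric(0),
                   c_id = character(0), status = character(0),
                   flags = character(0), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Pair heavy/light and alpha/beta receptor chains per cell
#'
#' An IG pair is an annotated IGH consensus plus an annotated light chain
#' (IGK or IGL; when both are present the one with higher read support wins,
#' ties going to IGK then the smaller V id).  A TCR pair is TRA plus TRB.
#' Cells lacking a chain are reported unpaired together with which chains
#' were detected.  For cells with several IGH isotype consensuses,
#' `v_consistent` records whether all isotypes carry the same V call — the
#' signature of alternative splicing products of one rearrangement.
#'
#' @param consensusTable Output of [airConsensus()].
#' @return data.frame with one row per cell and receptor type: `cell`,
#'   `receptor_type` (`IG`/`TCR`), `paired`, `chain_a_locus`, `chain_a_v`,
#'   `chain_a_j`, `chain_b_locus`, `chain_b_v`, `chain_b_j`,
#'   `detected` (comma-separated annotated loci), `v_consistent` (IG only,
#'   `NA` when fewer than two isotypes).
#' @export
pairReceptors <- function(consensusTable) {
    ct <- consensusTable[consensusTable$status == "ok", , drop = FALSE]
    cellsAll <- unique(consensusTable$cell)
    rows <- list()
    for (cell in sort(cellsAll)) {
        cc <- ct[ct$cell == cell, , drop = FALSE]
        det <- sort(unique(cc$locus))
        if (!nrow(cc)) {
            # present in the input but with no annotated chain at all
            rows[[length(rows) + 1L]] <- data.frame(
                cell = cell, receptor_type = "none", paired = FALSE,
                chain_a_locus = NA, chain_a_v = NA, chain_a_j = NA,
                chain_b_locus = NA, chain_b_v = NA, chain_b_j = NA,
                detected = "", v_consistent = NA, stringsAsFactors = FALSE)
            next
        }
        # IG
        if (any(cc$locus %in% c("IGH", "IGK", "IGL")) ||
            !any(cc$locus %in% c("TRA", "TRB"))) {
            igh <- cc[cc$locus == "IGH", , drop = FALSE]
            light <- cc[cc$locus %in% c("IGK", "IGL"), , drop = FALSE]
            vcons <- if (nrow(igh) >= 2L) length(unique(igh$v_id)) == 1L
                     else NA
            if (nrow(igh) || nrow(light)) {
                hv <- if (nrow(igh)) {
                    o <- order(-igh$support, igh$isotype)
                    igh[o[1L], ]
                } else NULL
                lv <- if (nrow(light)) {
                    o <- order(-light$support, light$locus, light$v_id)
                    light[o[1L], ]
                } else NULL
                rows[[length(rows) + 1L]] <- data.frame(
                    cell = cell, receptor_type = "IG",
                    paired = !is.null(hv) && !is.null(lv),
                    chain_a_locus = if (is.null(hv)) NA else "IGH",
                    chain_a_v = if (is.null(hv)) NA else hv$v_id,
                    chain_a_j = if (is.null(hv)) NA else hv$j_id,
                    chain_b_locus = if (is.null(lv)) NA else lv$locus,
                    chain_b_v = if (is.null(lv)) NA else lv$v_id,
                    chain_b_j = if (is.null(lv)) NA else lv$j_id,
                    detected = paste(intersect(det, c("IGH", "IGK", "IGL")),
                                     collapse = ","),
                    v_consistent = vcons, stringsAsFactors = FALSE)
            }
        }
        # TCR
        if (any(cc$locus %in% c("TRA", "TRB"))) {
            tra <- cc[cc$locus == "TRA", , drop = FALSE]
            trb <- cc[cc$locus == "TRB", , drop = FALSE]
            pickOne <- function(x) {
                if (!nrow(x)) return(NULL)
                o <- order(-x$support, x$v_id)
                x[o[1L], ]
            }
            a <- pickOne(trb); b <- pickOne(tra)
            rows[[length(rows) + 1L]] <- data.frame(
                cell = cell, receptor_type = "TCR",
                paired = !is.null(a) && !is.null(b),
                chain_a_locus = if (is.null(a)) NA else "TRB",
                chain_a_v = if (is.null(a)) NA else a$v_id,
                chain_a_j = if (is.null(a)) NA else a$j_id,
                chain_b_locus = if (is.null(b)) NA else "TRA",
                chain_b_v = if (is.null(b)) NA else b$v_id,
                chain_b_j = if (is.null(b)) NA else b$j_id,
                detected = paste(intersect(det, c("TRA", "TRB")),
                                 collapse = ","),
                v_consistent = NA, stringsAsFactors = FALSE)
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(cell = character(0), receptor_type = character(0),
                   paired = logical(0), chain_a_locus = character(0),
                   chain_a_v = character(0), chain_a_j = character(0),
                   chain_b_locus = character(0), chain_b_v = character(0),
                   chain_b_j = character(0), detected = character(0),
                   v_consistent = logical(0), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}
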