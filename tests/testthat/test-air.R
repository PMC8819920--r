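rand_seq <- function(n, seed) {
    set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

writeSamFixture <- function(path, withCB = TRUE) {
    seq1 <- rand_seq(50, 80)
    lines <- c(
        "@HD\tVN:1.6\tSO:unsorted",
        "@SQ\tSN:chr14\tLN:10000",
        "@SQ\tSN:chr2\tLN:10000")
    rec <- function(qname, flag, rname, pos, cigar, cb) {
        paste(c(qname, flag, rname, pos, 60, cigar, "*", 0, 0, seq1, "*",
                if (withCB) paste0("CB:Z:", cb) else NULL),
              collapse = "\t")
    }
    lines <- c(lines,
        rec("inside", 0, "chr14", 120, "50M", "cellA"),      # fully inside
        rec("edge1", 0, "chr14", 92, "10M40S", "cellA"),     # 1-base overlap
        rec("edge0", 0, "chr14", 91, "10M40S", "cellA"),     # no overlap
        rec("otherchrom", 0, "chr2", 120, "50M", "cellA"),   # wrong chrom
        rec("secondary", 256, "chr14", 120, "50M", "cellB"), # secondary
        rec("unmapped", 4, "*", 0, "*", "cellB"))
    lines[length(lines)] <- sub("\tchr14\t", "\t*\t",
                                lines[length(lines)])  # unmapped: no rname
    writeLines(lines, path)
    path
}

test_that("locus read extraction respects half-open BED overlap and flags", {
    bed <- tempfile(fileext = ".bed")
    writeLines("chr14\t100\t200\tIGH", bed)   # 0-based [100,200)
    loci <- readLocusBed(bed)
    expect_equal(GenomicRanges::start(loci), 101L)
    expect_true(loci$requires_D)
    sam <- tempfile(fileext = ".sam")
    writeSamFixture(sam)
    ex <- extractLocusReads(sam, loci)
    expect_setequal(ex$table$read_id, c("inside", "edge1"))
    expect_equal(unique(ex$table$cell), "cellA")
    expect_equal(unique(ex$table$locus), "IGH")
    expect_equal(length(ex$reads), 2)
    # named path supplies cell identity when CB tags are absent
    sam2 <- tempfile(fileext = ".sam")
    writeSamFixture(sam2, withCB = FALSE)
    ex2 <- extractLocusReads(c(cellZ = sam2), loci)
    expect_equal(unique(ex2$table$cell), "cellZ")
    # no CB and no file naming: error names the missing convention
    expect_error(extractLocusReads(sam2, loci), "CB")
    # malformed locus name
    bedBad <- tempfile(fileext = ".bed")
    writeLines("chr14\t100\t200\tNOTALOCUS", bedBad)
    expect_error(readLocusBed(bedBad), "unknown locus")
})

test_that("V filtering keeps recombined transcripts and rejects noise", {
    refs <- simulateSegmentReferences(seed = 81)
    rep <- simulateAirRepertoire(refs, nBcells = 2, nTcells = 0, seed = 82)
    reads <- rep$transcripts
    vf <- vFilter(reads, refs$V)
    expect_true(all(vf$table$pass))
    tr <- rep$truth[match(vf$table$read_id, rep$truth$transcript_id), ]
    expect_identical(vf$table$v_id, tr$v_id)
    expect_identical(vf$table$locus, tr$locus)
    # reverse-complemented input is reoriented
    rc <- Biostrings::reverseComplement(reads)
    vfrc <- vFilter(rc, refs$V)
    expect_true(all(vfrc$table$strand == "-"))
    expect_identical(as.character(vfrc$oriented), as.character(reads))
    # random sequences of receptor length never pass
    set.seed(83)
    rand <- Biostrings::DNAStringSet(setNames(vapply(1:100, function(i)
        paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = ""),
        character(1)), sprintf("rnd%03d", 1:100)))
    vfr <- vFilter(rand, refs$V)
    expect_equal(sum(vfr$table$pass), 0)
    # 2% substitution errors still pass
    set.seed(84)
    err <- corruptSequence(rep(as.character(reads), 25),
                           ErrorModel(0.02, 0.005, 0.005))
    names(err) <- sprintf("e%03d", seq_along(err))
    vfe <- vFilter(err, refs$V)
    expect_gte(mean(vfe$table$pass), 0.99)
})

test_that("isotype assignment follows the best constant-region match", {
    refs <- simulateSegmentReferences(seed = 85)
    rep <- simulateAirRepertoire(refs, nBcells = 4, nTcells = 0,
                                 extraIsotypeRate = 1, seed = 86)
    igh <- rep$truth[rep$truth$locus == "IGH", ]
    reads <- rep$transcripts[igh$transcript_id]
    iso <- splitIghByIsotype(reads, refs$C[["IGH"]])
    expect_identical(iso$isotype, igh$isotype)
    # a read without any constant region stays unassigned
    vonly <- Biostrings::DNAStringSet(c(vr = as.character(
        refs$V[["IGH"]][[1]])))
    expect_true(is.na(splitIghByIsotype(vonly, refs$C[["IGH"]])$isotype))
})

test_that("consensus building is exact, robust, and order-independent", {
    s <- rand_seq(600, 87)
    five <- setNames(rep(s, 5), sprintf("r%d", 1:5))
    expect_equal(buildConsensus(five)$consensus, s)
    expect_equal(buildConsensus(c(one = s))$consensus, s)
    expect_equal(buildConsensus(c(one = s))$support, 1L)
    # 10 reads at 2% error: consensus within 0.1% of truth
    set.seed(88)
    noisy <- corruptSequence(rep(s, 10), ErrorModel(0.02, 0.005, 0.005))
    names(noisy) <- sprintf("n%02d", 1:10)
    cons <- buildConsensus(noisy)
    expect_gte(1 - levenshtein(cons$consensus, s) / nchar(s), 0.999)
    # shuffling the reads changes nothing
    cons2 <- buildConsensus(noisy[sample(10)])
    expect_identical(cons$consensus, cons2$consensus)
})

test_that("V(D)J assignment reproduces truth and flags broken structure", {
    refs <- simulateSegmentReferences(seed = 89)
    rep <- simulateAirRepertoire(refs, nBcells = 1, nTcells = 1, seed = 90)
    for (i in seq_len(nrow(rep$truth))) {
        t <- rep$truth[i, ]
        lrefs <- list(V = refs$V[[t$locus]], D = refs$D[[t$locus]],
                      J = refs$J[[t$locus]], C = refs$C[[t$locus]])
        call <- assignVdj(as.character(rep$transcripts[[t$transcript_id]]),
                          lrefs)
        expect_equal(call$status, "ok")
        expect_equal(call$v$id, t$v_id)
        expect_equal(call$j$id, t$j_id)
        expect_equal(call$c$id, t$c_id)
        if (t$locus %in% c("IGH", "TRB")) expect_equal(call$d$id, t$d_id)
    }
    # truncated fixture: V segment alone has no J -> unannotated
    vonly <- as.character(refs$V[["IGK"]][[1]])
    call <- assignVdj(vonly, list(V = refs$V[["IGK"]], J = refs$J[["IGK"]],
                                  C = refs$C[["IGK"]]))
    expect_equal(call$status, "unannotated")
    expect_equal(call$flags, "no_J")
})

test_that("receptor pairing applies the printed chain rules", {
    row <- function(cell, locus, isotype = NA, v = "V1", j = "J1",
                    support = 3)
        data.frame(cell = cell, locus = locus, isotype = isotype,
                   support = support, consensus = "ACGT", v_id = v,
                   v_identity = 1, d_id = NA, j_id = j, j_identity = 1,
                   c_id = NA, status = "ok", flags = "",
                   stringsAsFactors = FALSE)
    ct <- rbind(row("c1", "IGH"), row("c1", "IGK"),
                row("c2", "TRB"),
                row("c3", "IGH", isotype = "IGHM", v = "V7"),
                row("c3", "IGH", isotype = "IGHG1", v = "V7"),
                row("c3", "IGK"))
    pr <- pairReceptors(ct)
    expect_true(pr$paired[pr$cell == "c1"])
    expect_false(pr$paired[pr$cell == "c2"])
    expect_equal(pr$detected[pr$cell == "c2"], "TRB")
    # two isotypes from one rearrangement: consistent V
    expect_true(pr$v_consistent[pr$cell == "c3"])
    expect_true(pr$paired[pr$cell == "c3"])
    # inconsistent V across isotypes
    ct2 <- rbind(row("c4", "IGH", isotype = "IGHM", v = "V1"),
                 row("c4", "IGH", isotype = "IGHA1", v = "V2"))
    expect_false(pairReceptors(ct2)$v_consistent)
    # light-chain choice: higher support wins
    ct3 <- rbind(row("c5", "IGH"), row("c5", "IGK", support = 2),
                 row("c5", "IGL", support = 9))
    expect_equal(pairReceptors(ct3)$chain_b_locus, "IGL")
})
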