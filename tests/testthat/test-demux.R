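test_that("levenshtein matches textbook cases and a DP oracle", {
    expect_equal(levenshtein("ACGT", "ACGT"), 0L)
    expect_equal(levenshtein("", "ACG"), 3L)
    expect_equal(levenshtein("kitten", "sitting"), 3L)
    set.seed(20)
    for (i in 1:50) {
        a <- paste(sample(c("A", "C", "G", "T"), sample(0:20, 1), TRUE),
                   collapse = "")
        b <- paste(sample(c("A", "C", "G", "T"), sample(0:20, 1), TRUE),
                   collapse = "")
        expect_equal(levenshtein(a, b), bruteLevenshtein(a, b))
        expect_equal(levenshtein(a, b), levenshtein(b, a))  # symmetry
    }
})

test_that("bit-parallel adapter search equals the DP search it replaces", {
    set.seed(19)
    bases <- c("A", "C", "G", "T")
    for (i in 1:200) {
        m <- sample(4:150, 1)
        L <- sample(0:400, 1)
        pat <- paste(sample(bases, m, TRUE), collapse = "")
        txt <- if (L) paste(sample(bases, L, TRUE), collapse = "") else ""
        fast <- scLongReads:::cpp_myers_search(pat, txt)
        slow <- scLongReads:::cpp_infix_search(pat, txt)
        expect_equal(fast$dist, slow$dist)
        expect_equal(fast$end, slow$end)
    }
})

test_that("adapter location finds barcodes on either strand and rejects noise", {
    chem <- ChemistryConfig()
    read <- layoutRead("ACGTACGTACGTACGT", "AACCGGTTAA", "TTTGGGCCCAAATTTGGG")
    loc <- locateBarcode(setNames(read, "r1"), chem)
    expect_equal(loc$locate_status, "ok")
    expect_equal(loc$observed_barcode, "ACGTACGTACGTACGT")
    expect_equal(loc$observed_umi, "AACCGGTTAA")
    expect_equal(loc$orientation, "+")
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(read)))
    loc2 <- locateBarcode(setNames(rc, "r1"), chem)
    expect_equal(loc2$observed_barcode, "ACGTACGTACGTACGT")
    expect_equal(loc2$observed_umi, "AACCGGTTAA")
    expect_equal(loc2$orientation, "-")
    # false-location rate on adapter-free random sequence < 1%
    set.seed(21)
    rand <- vapply(1:1000, function(i)
        paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = ""),
        character(1))
    locr <- locateBarcode(setNames(rand, paste0("n", 1:1000)), chem)
    expect_lt(mean(locr$locate_status == "ok"), 0.01)
})

test_that("whitelist counting recovers the true barcodes", {
    wl <- makeBarcodeWhitelist(10, 16, minDist = 5, seed = 22)
    tx <- randomTranscripts(3, seed = 23)
    sim <- simulateReads(wl, tx, cells = 10, moleculesPerCell = 50,
                         errors = ErrorModel(0, 0, 0), seed = 24)
    bw <- buildWhitelist(sim$reads, params = WhitelistParams(expectedCells = 10))
    expect_setequal(bw$whitelist, wl)
    expect_false(bw$truncated)
    # asking for more cells than exist returns all, with a warning
    expect_warning(
        bw2 <- buildWhitelist(sim$reads,
                              params = WhitelistParams(expectedCells = 50)),
        "distinct barcodes")
    expect_setequal(bw2$whitelist, wl)
    expect_true(bw2$truncated)
})

test_that("the printed L1/L2 rules decide assignment", {
    # observed equals an entry, others far: assigned
    wl <- c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG")
    a <- assignBarcode("AAAAAAAA", wl)
    expect_equal(a$status, "assigned")
    expect_equal(a$L1, 0L)
    expect_equal(a$assigned_barcode, "AAAAAAAA")
    # distance tie (L1 == L2) fails rule 2 -> ambiguous
    a2 <- assignBarcode("AAAAAATT", c("AAAAAAAA", "AAAATTTT"))
    expect_equal(sort(c(a2$L1, a2$L2)), c(2, 2))
    expect_equal(a2$status, "ambiguous")
    # explicit L1=2, L2=3 and L1=2, L2=4 cases
    a3 <- assignBarcode("AACCAACC", c("AACCAATT", "AACCTTTT"))  # d=2, d=4
    expect_equal(a3$L1, 2L); expect_equal(a3$L2, 4)
    expect_equal(a3$status, "assigned")
    a4 <- assignBarcode("AACCAACC", c("AACCAATT", "AACCATTT"))  # d=2, d=3
    expect_equal(a4$L1, 2L); expect_equal(a4$L2, 3)
    expect_equal(a4$status, "ambiguous")
    # L1 >= 3: too distant even with distant L2
    a5 <- assignBarcode("TTTTTTTT", c("AAAAAAAA", "CCCCCCCC"))
    expect_equal(a5$status, "too_distant")
    # single-entry whitelist: L2 is +Inf
    a6 <- assignBarcode("AAAAAAAT", "AAAAAAAA")
    expect_equal(a6$L2, Inf)
    expect_equal(a6$status, "assigned")
})

test_that("assignment agrees with the brute-force rule oracle", {
    set.seed(25)
    for (trial in 1:200) {
        wl <- unique(vapply(1:6, function(i)
            paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = ""),
            character(1)))
        if (length(wl) < 2) next
        obs <- paste(sample(c("A", "C", "G", "T"), sample(6:10, 1), TRUE),
                     collapse = "")
        got <- assignBarcode(obs, wl)
        want <- bruteAssign(obs, wl)
        expect_equal(got$L1, as.numeric(want$L1))
        expect_equal(got$L2, as.numeric(want$L2))
        expect_equal(got$status, want$status)
        if (want$status == "assigned")
            expect_equal(got$assigned_barcode, want$assigned)
    }
})

test_that("demultiplexing partitions reads and is perfect without errors", {
    wl <- makeBarcodeWhitelist(10, 16, minDist = 5, seed = 26)
    tx <- randomTranscripts(3, seed = 27)
    sim <- simulateReads(wl, tx, cells = 10, moleculesPerCell = 30,
                         errors = ErrorModel(0, 0, 0), seed = 28)
    dm <- demultiplex(sim$reads, wl)
    expect_equal(dm$report$assigned_fraction, 1)
    expect_identical(dm$assignments$assigned_barcode, sim$truth$cell_barcode)
    # partition: statuses cover every read exactly once
    expect_equal(sum(dm$report$counts), length(sim$reads))
    expect_equal(length(unlist(dm$perCell)) + length(dm$unassigned),
                 length(sim$reads))
    # empty input
    dm0 <- demultiplex(Biostrings::DNAStringSet(), wl)
    expect_equal(nrow(dm0$assignments), 0)
    expect_equal(sum(dm0$report$counts), 0)
})

test_that("lower error rates never lower the assigned fraction", {
    wl <- makeBarcodeWhitelist(20, 16, minDist = 5, seed = 29)
    tx <- randomTranscripts(3, seed = 30)
    rates <- c(0, 0.01, 0.03)
    for (seed in 31:33) {
        fr <- vapply(rates, function(r) {
            sim <- simulateReads(wl, tx, cells = 20, moleculesPerCell = 25,
                                 errors = ErrorModel(subRate = r,
                                                     insRate = r / 2,
                                                     delRate = r / 2),
                                 seed = seed)
            demultiplex(sim$reads, wl)$report$assigned_fraction
        }, numeric(1))
        # within sampling noise of 500 reads: allow 2 percentage points
        expect_true(all(diff(fr) <= 0.02))
    }
})
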