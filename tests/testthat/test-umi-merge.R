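simSmallRun <- function(seed, cells = 5, mols = 40, splintDup = 0,
                        tenxDup = 0, errors = ErrorModel(0, 0, 0)) {
    wl <- makeBarcodeWhitelist(cells, 16, minDist = 5, seed = seed)
    tx <- randomTranscripts(3, seed = seed + 1)
    sim <- simulateReads(wl, tx, cells = cells, moleculesPerCell = mols,
                         splintDupRate = splintDup, tenxDupRate = tenxDup,
                         errors = errors, seed = seed + 2)
    dm <- demultiplex(sim$reads, wl)
    list(sim = sim, dm = dm, wl = wl)
}

test_that("splint UMIs are extracted exactly from clean reads", {
    chem <- ChemistryConfig()
    r <- simSmallRun(40, cells = 3, mols = 10)
    sp <- extractSplintUmi(r$sim$reads, chem,
                           orientation = r$dm$assignments$orientation)
    expect_true(all(sp$status == "ok"))
    expect_identical(sp$splint_umi, r$sim$truth$splint_umi)
    # unknown orientation: both strands are searched
    sp2 <- extractSplintUmi(r$sim$reads, chem)
    expect_identical(sp2$splint_umi, r$sim$truth$splint_umi)
    # reads without the cassette yield not_found
    bare <- Biostrings::DNAStringSet(setNames(
        layoutRead("ACGTACGTACGTACGT", "AACCGGTTAA",
                   as.character(randomTranscripts(1, seed = 41))), "b1"))
    expect_equal(extractSplintUmi(bare, chem)$status, "not_found")
})

test_that("splint-UMI extraction tolerates flank errors", {
    set.seed(42)
    chem <- ChemistryConfig()
    r <- simSmallRun(43, cells = 3, mols = 60,
                     errors = ErrorModel(subRate = 0.02, insRate = 0,
                                         delRate = 0))
    sp <- extractSplintUmi(r$sim$reads, chem)
    expect_gte(mean(sp$status == "ok"), 0.95)
})

test_that("UMI grouping merges by similarity and passes NA through", {
    m <- mergeByUmi(c("r1", "r2"), c("ACGTACGTAC", "ACGTACGTAC"))
    expect_equal(nrow(m$groups), 1)
    expect_equal(m$groups$member_count, 2)
    # distance 2 with maxEdits 1: separate groups
    m2 <- mergeByUmi(c("r1", "r2"), c("ACGTACGTAC", "ACGTACGTGG"))
    expect_equal(nrow(m2$groups), 2)
    # distance 1: merged
    m3 <- mergeByUmi(c("r1", "r2"), c("ACGTACGTAC", "ACGTACGTAG"))
    expect_equal(nrow(m3$groups), 1)
    # NA UMIs stay singletons
    m4 <- mergeByUmi(c("r1", "r2", "r3"), c(NA, NA, "ACGTACGTAC"))
    expect_equal(nrow(m4$groups), 3)
    # representative: highest subread count, then longest, then smallest id
    m5 <- mergeByUmi(c("b", "a"), c("ACGTACGTAC", "ACGTACGTAC"),
                     subreads = c(1, 1), lens = c(5, 5))
    expect_equal(m5$groups$representative, "a")
    m6 <- mergeByUmi(c("a", "b"), c("ACGTACGTAC", "ACGTACGTAC"),
                     subreads = c(1, 5), lens = c(5, 5))
    expect_equal(m6$groups$representative, "b")
})

test_that("grouping against a brute-force single-linkage oracle", {
    set.seed(44)
    for (trial in 1:20) {
        n <- 30
        umis <- vapply(seq_len(n), function(i)
            paste(sample(c("A", "C"), 6, TRUE), collapse = ""),
            character(1))
        got <- mergeByUmi(sprintf("r%02d", 1:n), umis)$membership$group
        link <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
            bruteLevenshtein(umis[i], umis[j]) <= 1))
        want <- bruteTransitiveGroups(link)
        expect_equal(canonPartition(got), canonPartition(want))
    }
})

test_that("two-stage merging recovers true molecules exactly", {
    r <- simSmallRun(45, cells = 5, mols = 40, splintDup = 0.4,
                     tenxDup = 0.4)
    sm <- sequentialMerge(r$dm$assignments, r$sim$reads)
    # conservation before discard
    expect_equal(sum(sm$merged$member_count), length(r$sim$reads))
    expect_equal(nrow(sm$merged),
                 length(unique(r$sim$truth$molecule_id)))
    dc <- discardCrossCellMerges(sm$merged)
    expect_equal(nrow(dc$discarded), 0)
    # no duplication: both stages merge nothing
    r0 <- simSmallRun(46)
    sm0 <- sequentialMerge(r0$dm$assignments, r0$sim$reads)
    expect_equal(sm0$report$splint_merge_fraction, 0)
    expect_equal(sm0$report$tenx_merge_fraction, 0)
    # splint duplication only: stage 1 merges, stage 2 does not
    r1 <- simSmallRun(47, splintDup = 0.5)
    sm1 <- sequentialMerge(r1$dm$assignments, r1$sim$reads)
    expect_gt(sm1$report$splint_merge_fraction, 0)
    expect_equal(sm1$report$tenx_merge_fraction, 0)
})

test_that("merging is idempotent and order-independent", {
    r <- simSmallRun(48, cells = 4, mols = 30, splintDup = 0.5,
                     tenxDup = 0.5)
    sm <- sequentialMerge(r$dm$assignments, r$sim$reads)
    # idempotence: representatives with distinct UMIs do not merge again
    reps <- sm$merged$representative
    umis <- r$sim$truth$umi[match(reps, r$sim$truth$read_id)]
    again <- mergeByUmi(reps, umis)
    expect_equal(nrow(again$groups), length(reps))
    # order independence: shuffle input, same partition of read ids
    set.seed(49)
    perm <- sample(nrow(r$dm$assignments))
    smP <- sequentialMerge(r$dm$assignments[perm, ], r$sim$reads)
    keyOf <- function(m) {
        members <- split(m$members$read_id, m$members$group)
        sort(vapply(members, function(x) paste(sort(x), collapse = "+"),
                    character(1)))
    }
    expect_identical(unname(keyOf(sm)), unname(keyOf(smP)))
})

test_that("cross-cell merges are discarded, exactly the colliding ones", {
    chem <- ChemistryConfig()
    tx <- as.character(randomTranscripts(1, len = 300, seed = 50))
    wl <- makeBarcodeWhitelist(2, 16, minDist = 5, seed = 51)
    # two cells deliberately given the same 10X UMI, plus one clean molecule
    reads <- Biostrings::DNAStringSet(c(
        rA = layoutRead(wl[1], "ACGTACGTAC", tx, splintUmi = "GGATCCGGATCC"),
        rB = layoutRead(wl[2], "ACGTACGTAC", tx, splintUmi = "TTGGCCAATTGG"),
        rC = layoutRead(wl[1], "CCCCGGGGTT", tx, splintUmi = "AACCGGTTAACC")))
    dm <- demultiplex(reads, wl, chem)
    sm <- sequentialMerge(dm$assignments, reads, chem)
    dc <- discardCrossCellMerges(sm$merged)
    expect_equal(nrow(dc$discarded), 1)
    expect_equal(dc$discarded$n_cells, 2)
    expect_equal(nrow(dc$kept), 1)
    expect_equal(dc$kept$representative, "rC")
    # all-same-cell groups are retained
    expect_true(all(dc$kept$n_cells == 1))
})

test_that("exact barcode/UMI dedup applies the raw-coverage floor", {
    d <- illuminaDedup(rep("AAAA", 5), rep("CCCC", 5))
    expect_equal(d$coverage, 5)
    expect_equal(nrow(illuminaDedup(rep("AAAA", 3), rep("CCCC", 3))), 0)
    # mixture of known multiplicities: survivors are exactly those >= 4
    bc <- rep("CELL1", 10)
    umi <- c(rep("U1", 5), rep("U2", 4), rep("U3", 1))
    d2 <- illuminaDedup(bc, umi)
    expect_setequal(d2$umi, c("U1", "U2"))
    expect_equal(d2$coverage[d2$umi == "U1"], 5)
})

test_that("UMI set comparison counts shared and unique molecules", {
    a <- list(c1 = c("U1", "U2", "U3"), c2 = c("U4"))
    expect_equal(compareUmiSets(a, a)$shared_fraction, 1)
    b <- list(c1 = c("U1", "U2", "U9"), c2 = character(0))
    cmp <- compareUmiSets(a, b)
    expect_equal(cmp$perCell$shared[cmp$perCell$cell == "c1"], 2)
    expect_equal(cmp$perCell$a_only[cmp$perCell$cell == "c2"], 1)
    disj <- compareUmiSets(list(c1 = "U1"), list(c1 = "U2"))
    expect_equal(disj$perCell$shared, 0)
    # constructed 2/3 overlap
    cmp23 <- compareUmiSets(list(c1 = c("U1", "U2", "U3")),
                            list(c1 = c("U1", "U2")))
    expect_equal(cmp23$shared_fraction, 2 / 3)
})
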