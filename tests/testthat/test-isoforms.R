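# helper: single-intron isoforms with controllable ends and splice sites
mkIso <- function(starts, intronA, intronB, ends, ids, sources,
                  support = 1, strand = "+", chrom = "chr1") {
    n <- length(ids)
    newIsoformSet(chrom, strand,
        exonStarts = lapply(seq_len(n), function(i)
            c(starts[i], intronB[i])),
        exonSizes = lapply(seq_len(n), function(i)
            c(intronA[i] - starts[i], ends[i] - intronB[i])),
        isoform_id = ids, source = sources, support = support,
        targetSize = 100000L)
}

test_that("splice-chain equivalence follows the 1-bp abundance rule", {
    p <- MergeParams()
    expect_true(spliceSitesEquivalent(c(100L, 200L), c(100L, 200L)))
    # 1 bp apart, strong imbalance (100 vs 2, ratio 50 >= 5): equivalent
    expect_true(spliceSitesEquivalent(c(100L, 200L), c(100L, 201L), 100, 2, p))
    # 1 bp apart, balanced supports: not equivalent
    expect_false(spliceSitesEquivalent(c(100L, 200L), c(100L, 201L), 10, 10, p))
    # 2 bp apart: never equivalent
    expect_false(spliceSitesEquivalent(c(100L, 200L), c(100L, 202L), 100, 1, p))
    # different chain lengths: never equivalent
    expect_false(spliceSitesEquivalent(c(100L, 200L), c(100L, 200L, 300L, 400L)))
})

test_that("isoform merging applies the 10nt end window and chains groups", {
    # same chain, ends 8 and 6 nt apart: one group
    iso <- mkIso(starts = c(100L, 108L), intronA = c(300L, 300L),
                 intronB = c(500L, 500L), ends = c(900L, 906L),
                 ids = c("A", "B"), sources = c("c1", "c2"))
    expect_equal(nrow(mergeIsoforms(iso)$groups), 1)
    # ends 11 nt apart, no connector: two groups
    iso11 <- mkIso(starts = c(100L, 111L), intronA = c(300L, 300L),
                   intronB = c(500L, 500L), ends = c(900L, 900L),
                   ids = c("A", "B"), sources = c("c1", "c2"))
    expect_equal(nrow(mergeIsoforms(iso11)$groups), 2)
    # chained: A-B 8nt, B-C 9nt, A-C 17nt -> one group of three
    ch <- mkIso(starts = c(100L, 108L, 117L), intronA = rep(300L, 3),
                intronB = rep(500L, 3), ends = rep(900L, 3),
                ids = c("A", "B", "C"), sources = c("c1", "c2", "c3"))
    mg <- mergeIsoforms(ch)
    expect_equal(nrow(mg$groups), 1)
    expect_equal(mg$groups$n_models, 3)
    expect_equal(mg$groups$cell_count, 3)
    # different strands never merge
    isoS <- newIsoformSet("chr1", c("+", "-"),
        exonStarts = list(c(100L, 500L), c(100L, 500L)),
        exonSizes = list(c(200L, 400L), c(200L, 400L)),
        isoform_id = c("A", "B"), source = c("c1", "c2"))
    expect_equal(nrow(mergeIsoforms(isoS)$groups), 2)
})

test_that("merging is a partition, invariant under shuffling, matching the oracle", {
    set.seed(60)
    p <- MergeParams()
    for (trial in 1:25) {
        n <- 30
        starts <- sample(seq(0L, 60L, by = 3L), n, TRUE)
        intronA <- sample(c(300L, 301L, 310L), n, TRUE)
        intronB <- sample(c(500L, 520L), n, TRUE)
        ends <- 900L + sample(seq(0L, 40L, by = 4L), n, TRUE)
        supp <- sample(c(1, 2, 20), n, TRUE)
        iso <- mkIso(starts, intronA, intronB, ends,
                     ids = sprintf("i%02d", 1:n),
                     sources = sprintf("c%d", sample(5, n, TRUE)),
                     support = supp)
        mg <- mergeIsoforms(iso, p)
        # partition: every model in exactly one group
        expect_equal(sum(mg$groups$n_models), n)
        expect_equal(sort(unique(mg$groupOf)), seq_len(nrow(mg$groups)))
        # brute-force transitive closure over the literal link rule
        ch <- as.list(spliceChains(iso))
        link <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
            abs(starts[i] - starts[j]) <= 10 &&
                abs(ends[i] - ends[j]) <= 10 &&
                length(ch[[i]]) == length(ch[[j]]) &&
                all(abs(ch[[i]] - ch[[j]]) == 0 |
                    (abs(ch[[i]] - ch[[j]]) == 1 &
                     min(supp[i], supp[j]) * 5 <= max(supp[i], supp[j])))
        }))
        want <- bruteTransitiveGroups(link)
        got <- mg$groupOf
        expect_equal(canonPartition(got), canonPartition(want))
        # shuffle invariance
        perm <- sample(n)
        mgP <- mergeIsoforms(iso[perm], p)
        back <- integer(n); back[perm] <- mgP$groupOf
        expect_equal(canonPartition(back), canonPartition(got))
    }
})

test_that("diversity statistics separate low- from high-diversity genes", {
    # gene L: 5 cells share one isoform; gene H: 5 cells, all distinct
    low <- mkIso(rep(100L, 5), rep(300L, 5), rep(500L, 5), rep(900L, 5),
                 ids = sprintf("L%d", 1:5), sources = sprintf("c%d", 1:5))
    geneIds(low) <- "RPL35like"
    high <- mkIso(seq(100L, 500L, 100L), rep(1300L, 5),
                  seq(2000L, 2400L, 100L), seq(2900L, 3300L, 100L),
                  ids = sprintf("H%d", 1:5), sources = sprintf("c%d", 1:5))
    geneIds(high) <- "LMNAlike"
    both <- c(low, high)
    mg <- mergeIsoforms(both)
    bulk <- data.frame(gene_id = c("RPL35like", "LMNAlike"),
                       bulk_isoforms = c(1L, 3L))
    ds <- diversityStats(both, mg, bulk)
    expect_equal(ds$cells_expressing, c(5, 5))
    expect_equal(ds$unique_merged_isoforms[ds$gene_id == "RPL35like"], 1)
    expect_equal(ds$unique_merged_isoforms[ds$gene_id == "LMNAlike"], 5)
    expect_gt(ds$log10_ratio[ds$gene_id == "LMNAlike"],
              ds$log10_ratio[ds$gene_id == "RPL35like"])
    expect_equal(ds$multi_cell_isoforms, c(0, 1))
    # gene absent from bulk: undefined ratio flagged
    ds2 <- diversityStats(both, mg,
                          data.frame(gene_id = "RPL35like",
                                     bulk_isoforms = 1L))
    expect_false(ds2$ratio_defined[ds2$gene_id == "LMNAlike"])
    expect_true(is.na(ds2$log10_ratio[ds2$gene_id == "LMNAlike"]))
})

test_that("per-cell-type quantification sums supports and warns on unmapped cells", {
    iso <- mkIso(rep(100L, 4), rep(300L, 4), rep(500L, 4), rep(900L, 4),
                 ids = sprintf("i%d", 1:4),
                 sources = c("c1", "c2", "c3", "c4"),
                 support = c(5, 3, 2, 7))
    geneIds(iso) <- "G1"
    mg <- mergeIsoforms(iso)
    ctab <- data.frame(cell_id = c("c1", "c2", "c3"),
                       cell_type = c("B", "B", "T"))
    expect_warning(q <- quantifyByGroup(iso, mg, ctab), "excluded")
    expect_equal(attr(q, "dropped_cells"), 1)
    # hand-summed: B = 5+3, T = 2; c4 dropped
    expect_equal(q$count[q$cell_type == "B"], 8)
    expect_equal(q$count[q$cell_type == "T"], 2)
    expect_equal(sum(q$count), 10)   # conservation over mapped cells
    # single cell type collapses to per-isoform totals
    q1 <- quantifyByGroup(iso, mg, data.frame(
        cell_id = sprintf("c%d", 1:4), cell_type = "B"))
    expect_equal(sum(q1$count), 17)
})
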