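# Independent brute-force oracles.  These deliberately avoid the package's
# own primitives: plain-R dynamic programming and set arithmetic only.

# full-DP unit-cost Levenshtein distance
bruteLevenshtein <- function(a, b) {
    sa <- strsplit(a, "")[[1]]
    sb <- strsplit(b, "")[[1]]
    m <- length(sa); n <- length(sb)
    d <- matrix(0L, m + 1, n + 1)
    d[, 1] <- 0:m
    d[1, ] <- 0:n
    for (i in seq_len(m))
        for (j in seq_len(n))
            d[i + 1, j + 1] <- min(d[i, j] + (sa[i] != sb[j]),
                                   d[i, j + 1] + 1L, d[i + 1, j] + 1L)
    d[m + 1, n + 1]
}

# literal application of the printed barcode-assignment rules over a full
# distance table
bruteAssign <- function(observed, whitelist) {
    d <- vapply(whitelist, function(w) bruteLevenshtein(observed, w),
                numeric(1))
    o <- order(d)
    L1 <- d[o[1]]
    L2 <- if (length(d) > 1) d[o[2]] else Inf
    assigned <- L1 < 3 && L1 < L2 - 1
    list(L1 = L1, L2 = L2,
         assigned = if (assigned) whitelist[o[1]] else NA_character_,
         status = if (assigned) "assigned"
                  else if (L1 >= 3) "too_distant" else "ambiguous")
}

# canonical labelling of a partition: labels become 1..k by first appearance,
# so two labelled partitions are equal iff their canonical forms are identical
canonPartition <- function(g) match(g, unique(g))

# transitive closure of a pairwise link relation (boolean matrix) by
# repeated squaring; returns a group id per element
bruteTransitiveGroups <- function(link) {
    n <- nrow(link)
    reach <- link | diag(TRUE, n)
    repeat {
        nxt <- (reach %*% reach) > 0
        if (identical(nxt, reach)) break
        reach <- nxt
    }
    match(apply(reach, 1, function(r) paste(which(r), collapse = ",")),
          unique(apply(reach, 1, function(r) paste(which(r), collapse = ","))))
}

randomTranscripts <- function(n, len = 400L, prefix = "tx", seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    seqs <- vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""), character(1))
    Biostrings::DNAStringSet(setNames(seqs, paste0(prefix, seq_len(n))))
}

# assemble an error-free read in the layout the chemistry describes
layoutRead <- function(barcode, umi, transcript, splintUmi = NULL,
                       chemistry = ChemistryConfig()) {
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(transcript)))
    s <- paste0(chemistry@adapter, barcode, umi,
                strrep("T", chemistry@polyALen), rc)
    if (!is.null(splintUmi))
        s <- paste0(s, chemistry@splintFlanks[1], splintUmi,
                    chemistry@splintFlanks[2])
    s
}
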