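#' Levenshtein (unit-cost edit) distance
#'
#' Vectorized over the longer argument, recycling the shorter.
#'
#' @param a,b Character vectors.
#' @return Integer vector of distances.
#' @examples
#' levenshtein("kitten", "sitting")  # 3
#' @export
levenshtein <- function(a, b) {
    cpp_levenshtein(as.character(a), as.character(b))
}

adapterBudget <- function(chemistry, maxEdits) {
    if (is.na(maxEdits)) as.integer(floor(0.2 * nchar(chemistry@adapter)))
    else as.integer(maxEdits)
}

#' Locate the priming site and extract barcode and UMI
#'
#' Searches both strands of each read for the adapter (constant PCR priming
#' site) by semi-global alignment, allowing up to `maxEdits` edits (default:
#' 20% of the adapter length).  On success the cell barcode is taken as the
#' `barcodeLen` bases immediately 3' of the adapter and the UMI as the
#' `umiLen` bases after those, reported in whitelist orientation together
#' with the detected strand.
#'
#' @param reads Named [Biostrings::DNAStringSet] or character vector.
#' @param chemistry A [ChemistryConfig].
#' @param maxEdits Adapter edit budget; `NA` for the default.
#' @return data.frame with columns `read_id`, `observed_barcode`,
#'   `observed_umi`, `orientation` (`+`/`-`), `adapter_dist`, and
#'   `locate_status` (`ok`, `no_adapter`, `ambiguous_adapter`).
#' @export
locateBarcode <- function(reads, chemistry = ChemistryConfig(),
                          maxEdits = NA_integer_) {
    seqs <- if (is(reads, "XStringSet")) as.character(reads) else reads
    ids <- names(seqs)
    if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(seqs))
    budget <- adapterBudget(chemistry, maxEdits)
    n <- length(seqs)
    out <- data.frame(read_id = ids,
                      observed_barcode = rep(NA_character_, n),
                      observed_umi = rep(NA_character_, n),
                      orientation = rep(NA_character_, n),
                      adapter_dist = rep(NA_integer_, n),
                      locate_status = rep("no_adapter", n),
                      stringsAsFactors = FALSE)
    if (n == 0L) return(out)
    rc <- revcomp(seqs)
    fwd <- cpp_myers_search(chemistry@adapter, seqs)
    rev <- cpp_myers_search(chemistry@adapter, rc)
    need <- chemistry@barcodeLen + chemistry@umiLen
    best <- pmin(fwd$dist, rev$dist)
    tie <- fwd$dist == rev$dist
    out$locate_status[best <= budget & tie] <- "ambiguous_adapter"
    useF <- fwd$dist < rev$dist
    s <- ifelse(useF, seqs, rc)
    e <- ifelse(useF, fwd$end, rev$end)
    ok <- best <= budget & !tie & !is.na(e) & nchar(s) >= e + need
    okw <- which(ok)
    out$observed_barcode[okw] <- substr(s[okw], e[okw] + 1L,
                                        e[okw] + chemistry@barcodeLen)
    out$observed_umi[okw] <- substr(s[okw],
                                    e[okw] + chemistry@barcodeLen + 1L,
                                    e[okw] + need)
    out$orientation[okw] <- ifelse(useF[okw], "+", "-")
    out$adapter_dist[okw] <- best[okw]
    out$locate_status[okw] <- "ok"
    out
}

#' Build a cell-barcode whitelist by exact counting
#'
#' Counts the exact observed barcodes across all reads with a locatable
#' adapter and keeps the `expectedCells` most frequent, breaking count ties
#' lexicographically.  No knee-point detection is attempted: errored barcode
#' variants are far rarer than any true barcode at realistic per-cell read
#' depth, so simple counting suffices.
#'
#' @param reads Named [Biostrings::DNAStringSet] or character vector, or a
#'   data.frame already produced by [locateBarcode()].
#' @param chemistry A [ChemistryConfig].
#' @param params A [WhitelistParams].
#' @return List with `whitelist` (character, ranked), `counts` (data.frame
#'   `barcode`, `count`, full table), and `truncated` (`TRUE` with a warning
#'   when fewer distinct barcodes exist than requested).
#' @export
buildWhitelist <- function(reads, chemistry = ChemistryConfig(),
                           params = WhitelistParams()) {
    loc <- if (is.data.frame(reads)) reads
           else locateBarcode(reads, chemistry, params@adapterMaxEdits)
    obs <- loc$observed_barcode[loc$locate_status == "ok"]
    obs <- obs[!is.na(obs) & nchar(obs) == chemistry@barcodeLen]
    if (!length(obs)) stop("no reads with a locatable adapter")
    tab <- table(obs)
    counts <- data.frame(barcode = names(tab), count = as.integer(tab),
                         stringsAsFactors = FALSE)
    counts <- counts[order(-counts$count, counts$barcode), ]
    rownames(counts) <- NULL
    truncated <- nrow(counts) < params@expectedCells
    if (truncated)
        warning("only ", nrow(counts), " distinct barcodes observed; ",
                "expected ", params@expectedCells)
    list(whitelist = utils::head(counts$barcode, params@expectedCells),
         counts = counts, truncated = truncated)
}

#' Assign observed barcodes to whitelist entries by the L1/L2 rules
#'
#' For each observed barcode, `L1` is the Levenshtein distance to the most
#' similar whitelist entry and `L2` the distance to the second most similar.
#' The barcode is assigned to the unique nearest entry iff both
#' `L1 < 3` and `L1 < L2 - 1`; otherwise the status records the failing
#' rule (`too_distant` when `L1 >= 3`, else `ambiguous`; a distance tie
#' between two entries gives `L2 == L1`, so rule 2 fails and the read is
#' ambiguous).  With a single-entry whitelist `L2` is `+Inf`.
#'
#' @param observed Character vector of observed barcodes (`NA` allowed;
#'   reported as `no_adapter`).
#' @param whitelist Character vector of whitelist barcodes.
#' @return data.frame with columns `observed_barcode`, `assigned_barcode`,
#'   `L1`, `L2`, `status`.
#' @examples
#' assignBarcode("AACC", c("AACC", "GGTT"))
#' @export
assignBarcode <- function(observed, whitelist) {
    stopifnot(length(whitelist) >= 1)
    nt <- cpp_nearest_two(as.character(observed), whitelist)
    L1 <- nt$L1
    L2 <- ifelse(is.na(nt$L2) & !is.na(L1), Inf, as.numeric(nt$L2))
    status <- ifelse(is.na(L1), "no_adapter",
              ifelse(L1 < 3 & L1 < L2 - 1, "assigned",
              ifelse(L1 >= 3, "too_distant", "ambiguous")))
    data.frame(observed_barcode = as.character(observed),
               assigned_barcode = ifelse(status == "assigned",
                                         whitelist[nt$index], NA_character_),
               L1 = L1, L2 = L2, status = status,
               stringsAsFactors = FALSE)
}

#' Demultiplex reads into per-cell sets
#'
#' Runs [locateBarcode()] and [assignBarcode()] and partitions the reads:
#' every read lands in exactly one cell's set or in the unassigned pool.
#'
#' @param reads Named [Biostrings::DNAStringSet].
#' @param whitelist Character vector of cell barcodes.
#' @param chemistry A [ChemistryConfig].
#' @param maxEdits Adapter edit budget; `NA` for the default.
#' @return List with `assignments` (data.frame: `read_id`,
#'   `observed_barcode`, `observed_umi`, `orientation`, `assigned_barcode`,
#'   `L1`, `L2`, `status`), `perCell` (list of read-id vectors keyed by
#'   barcode), `unassigned` (read ids), and `report` (per-status counts and
#'   the assigned fraction).
#' @export
demultiplex <- function(reads, whitelist, chemistry = ChemistryConfig(),
                        maxEdits = NA_integer_) {
    loc <- locateBarcode(reads, chemistry, maxEdits)
    asg <- assignBarcode(loc$observed_barcode, whitelist)
    assignments <- cbind(loc[, c("read_id", "observed_barcode",
                                 "observed_umi", "orientation")],
                         asg[, c("assigned_barcode", "L1", "L2", "status")])
    ok <- assignments$status == "assigned"
    perCell <- split(assignments$read_id[ok], assignments$assigned_barcode[ok])
    statuses <- c("assigned", "ambiguous", "too_distant", "no_adapter")
    counts <- vapply(statuses, function(s) sum(assignments$status == s),
                     integer(1))
    report <- list(counts = counts, total = nrow(assignments),
                   assigned_fraction = if (nrow(assignments))
                       unname(counts["assigned"]) / nrow(assignments) else 0)
    list(assignments = assignments, perCell = perCell,
         unassigned = assignments$read_id[!ok], report = report)
}
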