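pipelineConfigKeys <- c(
    "reads", "out_dir", "seed", "expected_cells", "adapter", "barcode_len",
    "umi_len", "polya_len", "splint_umi_len", "splint_flanks",
    "adapter_max_edits", "umi_max_edits", "log_level")

#' Read a pipeline configuration from JSON
#'
#' A flat JSON object holding the chemistry, whitelist, and UMI-merge
#' settings plus input/output paths and the global seed.  Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path JSON file.
#' @return Named list with classes resolved (`chemistry`,
#'   `whitelistParams`, `umiParams`, `seed`, `reads`, `out_dir`).
#' @export
readPipelineConfig <- function(path) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(cfg), pipelineConfigKeys)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    pick <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
    chemistry <- ChemistryConfig(
        adapter = pick("adapter", "CTACACGACGCTCTTCCGATCT"),
        barcodeLen = pick("barcode_len", 16L),
        umiLen = pick("umi_len", 10L),
        polyALen = pick("polya_len", 20L),
        splintUmiLen = pick("splint_umi_len", 12L),
        splintFlanks = pick("splint_flanks",
                            c("ACTTGCCTGTCG", "CGTAATGCTCTG")))
    list(reads = cfg$reads, out_dir = pick("out_dir", "."),
         seed = pick("seed", 1L),
         chemistry = chemistry,
         whitelistParams = WhitelistParams(
             expectedCells = pick("expected_cells", 1500L),
             adapterMaxEdits = pick("adapter_max_edits", NA_integer_)),
         umiParams = UmiMergeParams(
             umiMaxEdits = pick("umi_max_edits", 1L)))
}

#' Run the full read-processing pipeline
#'
#' Executes whitelist construction, demultiplexing, splint-UMI merging,
#' 10X-UMI merging, and the cross-cell discard rule, writing each stage's
#' outputs before the next begins: the assignment report, the merge report,
#' the merged-read table, and one FASTQ of merged representative reads per
#' cell (header carries `;members=N`).  The pipeline itself consumes no
#' randomness, so identical inputs give byte-identical outputs.
#'
#' @param reads Named [Biostrings::DNAStringSet] or a FASTQ/FASTA path.
#' @param outDir Output directory (created if missing).
#' @param chemistry A [ChemistryConfig].
#' @param whitelistParams A [WhitelistParams].
#' @param umiParams A [UmiMergeParams].
#' @param writePerCell Write per-cell FASTQ files (default TRUE).
#' @return A run report (list): per-stage counts and fractions
#'   (`consensus_reads`, `splint_merged_reads`, `tenx_merged_reads`,
#'    `demultiplexed_reads`, the corresponding fractions, and
#'    `discarded_cross_cell`), plus `n_cells` and the elapsed time per
#'    stage in seconds.  Written to `run_report.json` in `outDir` as well.
#' @export
runPipeline <- function(reads, outDir = ".",
                        chemistry = ChemistryConfig(),
                        whitelistParams = WhitelistParams(),
                        umiParams = UmiMergeParams(),
                        writePerCell = TRUE) {
    if (is.character(reads) && length(reads) == 1L) reads <- readReads(reads)
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    elapsed <- c()
    tic <- function() proc.time()[["elapsed"]]
    t0 <- tic()

    wl <- buildWhitelist(reads, chemistry, whitelistParams)
    writeTsv(wl$counts, file.path(outDir, "barcode_counts.tsv"))
    elapsed["whitelist"] <- tic() - t0; t0 <- tic()

    dm <- demultiplex(reads, wl$whitelist, chemistry,
                      whitelistParams@adapterMaxEdits)
    writeTsv(dm$assignments, file.path(outDir, "assignments.tsv"))
    elapsed["demux"] <- tic() - t0; t0 <- tic()

    sm <- sequentialMerge(dm$assignments, reads, chemistry, umiParams)
    writeTsv(sm$merged, file.path(outDir, "merged_reads.tsv"))
    elapsed["umi_merge"] <- tic() - t0; t0 <- tic()

    dc <- discardCrossCellMerges(sm$merged)
    writeTsv(dc$discarded, file.path(outDir, "discarded_groups.tsv"))
    kept <- dc$kept
    assigned <- kept[kept$n_cells == 1L, , drop = FALSE]

    if (writePerCell && nrow(assigned)) {
        cellDir <- file.path(outDir, "cells")
        if (!dir.exists(cellDir)) dir.create(cellDir)
        for (cell in sort(unique(assigned$cells))) {
            rows <- assigned[assigned$cells == cell, , drop = FALSE]
            seqs <- reads[rows$representative]
            names(seqs) <- sprintf("%s;members=%d", rows$representative,
                                   rows$member_count)
            writeSimFastq(seqs, file.path(cellDir, paste0(cell, ".fastq")))
        }
    }
    elapsed["write"] <- tic() - t0

    nReads <- length(reads)
    report <- list(
        consensus_reads = nReads,
        splint_merged_reads = sm$report$splint_merged_reads,
        splint_merge_fraction = sm$report$splint_merge_fraction,
        tenx_merged_reads = sm$report$tenx_merged_reads,
        tenx_merge_fraction = sm$report$tenx_merge_fraction,
        discarded_cross_cell = nrow(dc$discarded),
        demultiplexed_reads = nrow(assigned),
        demux_fraction = dm$report$assigned_fraction,
        n_cells = length(unique(assigned$cells)),
        status_counts = as.list(dm$report$counts),
        elapsed_s = as.list(round(elapsed, 3)),
        version = as.character(utils::packageVersion("scLongReads")))
    jsonlite::write_json(report, file.path(outDir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report
}
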