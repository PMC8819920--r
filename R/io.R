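#' Read sequences from FASTA or FASTQ
#'
#' Format is chosen by extension (`.fq`/`.fastq` vs anything else); quality
#' strings are not retained — downstream processing is sequence-only.
#'
#' @param path Input file.
#' @return Named [Biostrings::DNAStringSet].
#' @export
readReads <- function(path) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
        "fastq" else "fasta"
    Biostrings::readDNAStringSet(path, format = fmt)
}

#' Write a data.frame as a tab-separated table with header
#'
#' @param x data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read a tab-separated table written by [writeTsv()]
#' @param path Input path.
#' @return data.frame.
#' @export
readTsv <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, comment.char = "",
                      quote = "")
}

#' Does a BED-style half-open interval contain a position?
#'
#' Utility for half-open interval arithmetic: position `pos` (0-based) is
#' inside `[start, end)`.
#'
#' @param start,end 0-based half-open interval bounds.
#' @param pos 0-based position(s).
#' @return Logical vector.
#' @examples
#' bedContains(10, 20, 19)  # TRUE
#' bedContains(10, 20, 20)  # FALSE
#' @export
bedContains <- function(start, end, pos) {
    pos >= start & pos < end
}
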