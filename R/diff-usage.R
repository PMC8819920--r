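#' Pearson chi-square contingency test
#'
#' Computes the Pearson statistic \eqn{\sum (O - E)^2 / E} with expected
#' counts from the row/column marginals, degrees of freedom
#' \eqn{(r-1)(c-1)}, and the upper-tail chi-square p-value.  No continuity
#' correction is applied.  All-zero rows and columns are dropped before
#' testing; a table left with fewer than two rows or columns is reported
#' `not_testable` rather than raising an error.
#'
#' @param tab Numeric matrix of counts (isoforms x cell types, typically).
#' @return List with `chi2`, `df`, `p`, and `status` (`"ok"` or
#'   `"not_testable"`; the numeric fields are `NA` in the latter case).
#' @examples
#' chisqContingency(matrix(c(20, 5, 5, 20), 2))$chi2  # 18
#' @export
chisqContingency <- function(tab) {
    tab <- as.matrix(tab)
    stopifnot(all(tab >= 0), !anyNA(tab))
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2L || ncol(tab) < 2L)
        return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                    status = "not_testable"))
    total <- sum(tab)
    expected <- outer(rowSums(tab), colSums(tab)) / total
    chi2 <- sum((tab - expected)^2 / expected)
    df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
    list(chi2 = chi2, df = df,
         p = stats::pchisq(chi2, df, lower.tail = FALSE), status = "ok")
}

#' Test genes for differential isoform usage between cell types
#'
#' For each gene, builds the isoform-by-cell-type count table from
#' [quantifyByGroup()] output, restricts it to cell types where the gene is
#' expressed, skips genes expressed in fewer than `minCellTypes` cell types
#' or with fewer than two expressed isoforms, applies
#' [chisqContingency()], corrects the p-values across all tested genes
#' (default Benjamini-Hochberg), and flags genes with corrected p below
#' `alpha`.  Raw p-values are always reported alongside corrected ones.
#'
#' @param quant Long count table from [quantifyByGroup()].
#' @param params A [DiffUsageParams].
#' @return data.frame with one row per gene: `gene_id`, `n_isoforms`,
#'   `n_cell_types`, `chi2`, `df`, `p`, `corrected_p`, `significant`,
#'   `status` (`tested`, `too_few_cell_types`, `too_few_isoforms`).  The
#'   contingency tables of tested genes are attached as attribute
#'   `tables` (a named list).
#' @export
diffIsoformUsage <- function(quant, params = DiffUsageParams()) {
    genes <- sort(unique(quant$gene_id))
    tables <- list()
    rows <- lapply(genes, function(g) {
        q <- quant[quant$gene_id == g, ]
        tab <- stats::xtabs(count ~ isoform + cell_type, data = q)
        tab <- as.matrix(unclass(tab))
        tab <- tab[, colSums(tab) > 0, drop = FALSE]   # expressed cell types
        tab <- tab[rowSums(tab) > 0, , drop = FALSE]
        row <- data.frame(gene_id = g, n_isoforms = nrow(tab),
                          n_cell_types = ncol(tab),
                          chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                          corrected_p = NA_real_, significant = FALSE,
                          status = NA_character_, stringsAsFactors = FALSE)
        if (ncol(tab) < params@minCellTypes) {
            row$status <- "too_few_cell_types"
        } else if (nrow(tab) < 2L) {
            row$status <- "too_few_isoforms"
        } else {
            res <- chisqContingency(tab)
            if (res$status != "ok") {
                row$status <- "too_few_isoforms"
            } else {
                row$chi2 <- res$chi2; row$df <- res$df; row$p <- res$p
                row$status <- "tested"
                tables[[g]] <<- tab
            }
        }
        row
    })
    out <- do.call(rbind, rows)
    tested <- out$status == "tested"
    if (any(tested)) {
        out$corrected_p[tested] <- stats::p.adjust(out$p[tested],
                                                   method = params@correction)
        out$significant[tested] <- out$corrected_p[tested] < params@alpha
    }
    rownames(out) <- NULL
    attr(out, "tables") <- tables
    out
}
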