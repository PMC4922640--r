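## RNA-seq differential expression (two-group NB exact test with TMM
## normalisation) and inverse-direction integration with methylation calls.

#' Two-group RNA-seq differential expression
#'
#' Gene-level NB exact test via the same machinery as the methylation
#' branch, with TMM normalisation by default: common and tagwise
#' dispersion, exact test, BH q-values, and the `is_de` call under an FDR
#' and a fold-change cutoff. All-zero genes are dropped with a message.
#'
#' @param counts integer matrix genes x samples (rownames = gene ids).
#' @param groups two-level factor over samples (lower-dose level first);
#'   `NA` samples are ignored.
#' @param fdrCut FDR (q-value) cutoff for `is_de` (default 0.10).
#' @param fcCut linear fold-change cutoff for `is_de` (default 2).
#' @param config a [ramConfig()]; `normalization` and `prior_df` are used.
#' @param comparison optional label stored as an attribute and column.
#' @return `DataFrame` with `gene_id`, `log2FC`, `pvalue`, `qvalue`,
#'   `is_de` (and `comparison` when given). Setting `fdrCut = 1` and
#'   `fcCut = 1` marks every testable gene.
#' @export
rnaseqDE <- function(counts, groups, fdrCut = 0.10, fcCut = 2,
                     config = ramConfig(normalization = "tmm"),
                     comparison = NA_character_) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("gene%04d", seq_len(nrow(counts)))
    groups <- as.factor(groups)
    keep <- !is.na(groups)
    counts <- counts[, keep, drop = FALSE]
    groups <- .checkGroups(groups[keep], ncol(counts))
    allzero <- rowSums(counts) == 0
    if (any(allzero)) {
        message("rnaseqDE: dropping ", sum(allzero), " all-zero gene(s)")
        counts <- counts[!allzero, , drop = FALSE]
    }
    eff <- effectiveLibSizes(counts, config$normalization)
    y <- .pseudoCounts(counts, eff)
    phiT <- estimateTagwiseDispersion(counts, groups, effLibSizes = eff,
                                      priorDf = config$prior_df)
    A <- groups == levels(groups)[1L]
    B <- !A
    sA <- round(rowSums(y[, A, drop = FALSE]))
    sB <- round(rowSums(y[, B, drop = FALSE]))
    nA <- sum(A)
    nB <- sum(B)
    p <- vapply(seq_along(sA), function(i)
        .exactPvalSums(sA[i], sB[i], nA, nB, phiT[i],
                       config$two_sided_rule), numeric(1))
    q <- bhAdjust(p)
    lfc <- log2((sB + 0.5) / nB) - log2((sA + 0.5) / nA)
    out <- S4Vectors::DataFrame(
        gene_id = rownames(counts), log2FC = lfc, pvalue = p, qvalue = q,
        is_de = q < fdrCut & abs(lfc) >= log2(fcCut))
    if (!is.na(comparison)) out$comparison <- comparison
    attr(out, "comparison") <- comparison
    out
}

#' Integrate methylation calls with expression
#'
#' Emits (gene, RAM) pairs where a RAM lies within the TSS-proximity window
#' of the gene, the gene's expression changes nominally
#' (`pvalue < exprAlpha`), and the expression log2 fold-change has the
#' opposite sign to the methylation log2 fold-change ("inversely
#' correlated"). One candidate per gene and comparison, keeping the RAM
#' with the smallest p-value.
#'
#' @param rams annotated RAM `GRanges` (mcols `nearest_gene`, `within_5kb`,
#'   `direction`, `log2FC`, `pvalue`, `comparison`).
#' @param exprResults `DataFrame` from [rnaseqDE()].
#' @param comparison the comparison both inputs must belong to.
#' @param exprAlpha nominal expression p-value threshold (default 0.05).
#' @return `DataFrame` of integration candidates.
#' @export
integrateMethylationExpression <- function(rams, exprResults, comparison,
                                           exprAlpha = 0.05) {
    ramCmp <- unique(rams$comparison)
    if (length(ramCmp) && !identical(ramCmp, comparison))
        stop("comparison mismatch: RAMs are ",
             paste(ramCmp, collapse = ","), ", expected ", comparison)
    exprCmp <- attr(exprResults, "comparison")
    if (!is.null(exprCmp) && !is.na(exprCmp) &&
        !identical(exprCmp, comparison))
        stop("comparison mismatch: expression results are ", exprCmp,
             ", expected ", comparison)
    empty <- S4Vectors::DataFrame(
        gene_id = character(0), chrom = character(0), start = integer(0),
        end = integer(0), methylation_direction = character(0),
        expression_direction = character(0), methylation_p = numeric(0),
        expression_p = numeric(0), comparison = character(0))
    if (length(rams) == 0L || nrow(exprResults) == 0L) return(empty)
    keep <- !is.na(rams$nearest_gene) & rams$within_5kb
    rams <- rams[keep]
    if (length(rams) == 0L) return(empty)
    ei <- match(rams$nearest_gene, exprResults$gene_id)
    ok <- !is.na(ei) &
        exprResults$pvalue[ei] < exprAlpha &
        sign(exprResults$log2FC[ei]) == -sign(rams$log2FC) &
        sign(rams$log2FC) != 0
    rams <- rams[ok]
    ei <- ei[ok]
    if (length(rams) == 0L) return(empty)
    # strongest RAM (smallest p) per gene
    o <- order(rams$nearest_gene, rams$pvalue)
    first <- o[!duplicated(rams$nearest_gene[o])]
    rams <- rams[first]
    ei <- ei[first]
    S4Vectors::DataFrame(
        gene_id = rams$nearest_gene,
        chrom = as.character(GenomicRanges::seqnames(rams)),
        start = GenomicRanges::start(rams) - 1L,
        end = GenomicRanges::end(rams),
        methylation_direction = rams$direction,
        expression_direction = ifelse(exprResults$log2FC[ei] > 0,
                                      "up", "down"),
        methylation_p = rams$pvalue,
        expression_p = exprResults$pvalue[ei],
        comparison = rep(comparison, length(rams)))
}
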