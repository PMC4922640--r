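## RAM calling: significance thresholding plus the two post-processing
## filters (within-group consistency; flanking-window / stretch support).

#' Candidate differential windows
#'
#' Windows whose nominal p-value (or q-value, per the config) falls strictly
#' below the significance threshold, carrying their direction.
#'
#' @param results `GRanges` from [testWindows()].
#' @param config a [ramConfig()]; uses `alpha` and `use_q`.
#' @return Subset of `results`.
#' @export
callCandidates <- function(results, config = ramConfig()) {
    stat <- if (isTRUE(config$use_q)) results$qvalue else results$pvalue
    results[stat < config$alpha]
}

.cpmMatrix <- function(cm, config) {
    eff <- effectiveLibSizes(cm, config$normalization)
    sweep(SummarizedExperiment::assay(cm, "counts"), 2L, 1e6 / eff, `*`)
}

#' Within-group consistency filter
#'
#' For each candidate window, each sample's normalised count
#' (counts per million of the effective library size) is compared with the
#' median normalised count of the opposite group: a higher-group sample is
#' consistent when it lies on the direction's side of the lower-group
#' median, and a lower-group sample when it lies on the opposite side of
#' the higher-group median. A candidate is retained when the consistent
#' fraction reaches `min_fraction` in both groups.
#'
#' @param candidates `GRanges` of candidate windows (with `direction`).
#' @param cm the [WindowCounts-class] the candidates were tested on.
#' @param groups the same two-level factor passed to [testWindows()].
#' @param config a [ramConfig()].
#' @return Filtered candidates with a logical mcol `filter_consistency`.
#' @export
consistencyFilter <- function(candidates, cm, groups, config = ramConfig()) {
    if (length(candidates) == 0L) {
        candidates$filter_consistency <- logical(0)
        return(candidates)
    }
    groups <- as.factor(groups)
    keep <- !is.na(groups)
    cm <- cm[, keep]
    groups <- .checkGroups(groups[keep], ncol(cm))
    hit <- GenomicRanges::match(candidates, GenomicRanges::granges(
        SummarizedExperiment::rowRanges(cm)))
    if (anyNA(hit))
        stop("candidate window(s) missing from the count matrix")
    cpm <- .cpmMatrix(cm, config)[hit, , drop = FALSE]
    A <- groups == levels(groups)[1L]
    B <- !A
    mA <- apply(cpm[, A, drop = FALSE], 1L, stats::median)
    mB <- apply(cpm[, B, drop = FALSE], 1L, stats::median)
    hyper <- candidates$direction == "hyper"
    consB <- ifelse(hyper, 1, -1) * (cpm[, B, drop = FALSE] - mA) > 0
    consA <- ifelse(hyper, 1, -1) * (mB - cpm[, A, drop = FALSE]) > 0
    ok <- rowMeans(consB) >= config$min_fraction &
          rowMeans(consA) >= config$min_fraction
    out <- candidates[ok]
    out$filter_consistency <- rep(TRUE, length(out))
    out
}

#' Flanking-window support filter
#'
#' A candidate survives when (a) at least one of its two overlapping
#' neighbour windows (start +/- step) shows differential methylation in the
#' same direction at `flank_alpha`, or (b) at least one other candidate
#' window with the same direction starts within `stretch_bp`. Logical mcols
#' `filter_flank_a` / `filter_flank_b` record which branch fired.
#'
#' @param candidates `GRanges` of candidate windows.
#' @param allResults full `GRanges` from [testWindows()] (all windows).
#' @param config a [ramConfig()].
#' @return Filtered candidates.
#' @export
flankingFilter <- function(candidates, allResults, config = ramConfig()) {
    if (length(candidates) == 0L) {
        candidates$filter_flank_a <- logical(0)
        candidates$filter_flank_b <- logical(0)
        return(candidates)
    }
    key <- function(chrom, start) paste(chrom, start, sep = ":")
    allKey <- key(as.character(GenomicRanges::seqnames(allResults)),
                  GenomicRanges::start(allResults))
    candChrom <- as.character(GenomicRanges::seqnames(candidates))
    candStart <- GenomicRanges::start(candidates)
    candDir <- candidates$direction
    step <- config$step

    flankOk <- function(chrom, start, dir) {
        i <- match(key(chrom, start), allKey)
        !is.na(i) && allResults$pvalue[i] < config$flank_alpha &&
            allResults$direction[i] == dir
    }
    a <- vapply(seq_along(candidates), function(i)
        flankOk(candChrom[i], candStart[i] - step, candDir[i]) ||
        flankOk(candChrom[i], candStart[i] + step, candDir[i]),
        logical(1))

    b <- logical(length(candidates))
    grp <- paste(candChrom, candDir)
    for (g in unique(grp)) {
        i <- which(grp == g)
        if (length(i) < 2L) next
        s <- sort(candStart[i])
        near <- c(diff(s) <= config$stretch_bp, FALSE) |
                c(FALSE, diff(s) <= config$stretch_bp)
        b[i] <- near[match(candStart[i], s)]
    }

    out <- candidates[a | b]
    out$filter_flank_a <- a[a | b]
    out$filter_flank_b <- b[a | b]
    out
}

#' Call RAMs for one comparison
#'
#' The full calling branch: coverage filter, per-window NB test, candidate
#' thresholding, and the consistency and flanking post-filters (each
#' switchable in the config).
#'
#' @param cm a [WindowCounts-class] (pre- or post-coverage filter; the
#'   filter is idempotent).
#' @param groups two-level factor, lower-dose level first (see
#'   [comparisonGroups()]).
#' @param comparison label stored on the result (e.g. `"nd_vs_high"`).
#' @param config a [ramConfig()].
#' @return `GRanges` of RAM windows with test statistics, direction,
#'   comparison label and filter flags.
#' @export
callRams <- function(cm, groups, comparison = NA_character_,
                     config = ramConfig()) {
    cm <- coverageFilter(cm, config$min_samples, config$min_count)
    res <- testWindows(cm, groups, config)
    cand <- callCandidates(res, config)
    if (config$apply_consistency)
        cand <- consistencyFilter(cand, cm, groups, config)
    if (config$apply_flanking)
        cand <- flankingFilter(cand, res, config)
    if (length(cand)) cand$comparison <- comparison
    else cand$comparison <- character(0)
    S4Vectors::metadata(cand)$n_tested <- length(res)
    S4Vectors::metadata(cand)$phi_common <- S4Vectors::metadata(res)$phi_common
    cand
}

#' Merge overlapping RAM windows for reporting
#'
#' Overlapping 50 bp-shifted RAM windows are merged (per direction) into
#' maximal regions. Merging is for reporting only; all statistics remain at
#' window level.
#'
#' @param rams `GRanges` of RAM windows with `direction`.
#' @return Reduced `GRanges` with a `direction` mcol.
#' @export
mergeRams <- function(rams) {
    out <- lapply(c("hyper", "hypo"), function(d) {
        r <- GenomicRanges::reduce(rams[rams$direction == d])
        if (length(r)) r$direction <- d else r$direction <- character(0)
        r
    })
    GenomicRanges::sort(c(out[[1L]], out[[2L]]))
}
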