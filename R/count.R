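#' Build a WindowCounts container
#'
#' @param counts integer matrix, windows x samples.
#' @param windows [GenomicRanges::GRanges] parallel to the rows.
#' @param sampleData a data.frame/`DataFrame` of per-sample columns; must
#'   contain `lib_size` or it is filled with the column sums.
#' @return A [WindowCounts-class].
#' @export
WindowCounts <- function(counts, windows, sampleData = NULL) {
    counts <- as.matrix(counts)
    if (is.null(sampleData))
        sampleData <- S4Vectors::DataFrame(lib_size = colSums(counts))
    sampleData <- as(sampleData, "DataFrame")
    if (!"lib_size" %in% colnames(sampleData))
        sampleData$lib_size <- colSums(counts)
    rownames(sampleData) <- colnames(counts)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), rowRanges = windows,
        colData = sampleData)
    new("WindowCounts", se)
}

#' @describeIn WindowCounts total mapped reads per sample.
#' @param x a `WindowCounts`.
#' @export
setMethod("libSizes", "WindowCounts",
    function(x) setNames(SummarizedExperiment::colData(x)$lib_size,
                         colnames(x)))

.asReadGRanges <- function(reads) {
    if (is(reads, "GRanges")) return(reads)
    # BED-style data.frame: chrom, start (0-based), [end]
    stopifnot(is.data.frame(reads), ncol(reads) >= 2L)
    GenomicRanges::GRanges(seqnames = as.character(reads[[1L]]),
        ranges = IRanges::IRanges(start = reads[[2L]] + 1L, width = 1L))
}

#' Count reads per window per sample
#'
#' Each read is represented by its 5' start position only; a read whose
#' start lies inside a window increments that window. With a 50 bp step and
#' 100 bp windows every interior position falls in exactly two windows.
#' Reads on chromosomes absent from the window set are skipped with a
#' message; their tally is kept in `metadata(x)$skipped_reads`.
#'
#' @param windows tiling windows from [tileWindows()].
#' @param readStarts named list (one element per sample) of read start
#'   positions: either width-1 `GRanges` or BED-style data.frames
#'   (chrom, 0-based start, ...).
#' @param sampleData optional per-sample data.frame (sample sheet).
#' @return A [WindowCounts-class]; `lib_size` is the number of reads per
#'   sample on known chromosomes.
#' @export
countReads <- function(windows, readStarts, sampleData = NULL) {
    stopifnot(is(windows, "GRanges"), is.list(readStarts) ||
              is(readStarts, "GRangesList"))
    ids <- names(readStarts)
    if (is.null(ids)) ids <- paste0("S", seq_along(readStarts))
    known <- GenomeInfoDb::seqlevels(windows)
    counts <- matrix(0L, nrow = length(windows), ncol = length(readStarts),
                     dimnames = list(NULL, ids))
    lib <- integer(length(readStarts))
    skipped <- integer(length(readStarts))
    for (i in seq_along(readStarts)) {
        r <- .asReadGRanges(readStarts[[i]])
        bad <- !(as.character(GenomicRanges::seqnames(r)) %in% known)
        skipped[i] <- sum(bad)
        if (skipped[i] > 0L) {
            message("countReads: skipping ", skipped[i],
                    " read(s) on unknown chromosome(s) in sample ", ids[i])
            r <- r[!bad]
        }
        r <- GenomicRanges::GRanges(
            factor(as.character(GenomicRanges::seqnames(r)),
                   levels = known),
            IRanges::ranges(r),
            seqinfo = GenomeInfoDb::seqinfo(windows))
        counts[, i] <- GenomicRanges::countOverlaps(windows, r)
        lib[i] <- length(r)
    }
    if (is.null(sampleData))
        sampleData <- S4Vectors::DataFrame(lib_size = lib, row.names = ids)
    else {
        sampleData <- as(sampleData, "DataFrame")
        sampleData$lib_size <- lib
        rownames(sampleData) <- ids
    }
    cm <- WindowCounts(counts, windows, sampleData)
    S4Vectors::metadata(cm)$skipped_reads <- setNames(skipped, ids)
    cm
}

#' Coverage filter
#'
#' Retains windows in which strictly more than `minCount` reads are observed
#' in at least `minSamples` samples. Window order is preserved and the
#' operation is idempotent.
#'
#' @param cm a [WindowCounts-class].
#' @param minSamples minimum number of samples exceeding the count.
#' @param minCount per-sample read-count threshold (strict `>`).
#' @return The filtered `WindowCounts` (library sizes untouched).
#' @export
coverageFilter <- function(cm, minSamples = 3L, minCount = 20L) {
    stopifnot(is(cm, "WindowCounts"))
    if (minSamples > ncol(cm))
        stop("minSamples exceeds the number of samples")
    keep <- rowSums(SummarizedExperiment::assay(cm, "counts") > minCount) >=
        minSamples
    cm[keep, ]
}
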