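#' Construct a GenomeSpec
#'
#' @param chromNames character vector of unique chromosome names.
#' @param chromLengths integer-ish vector of positive lengths (bp), parallel
#'   to `chromNames`.
#' @param xChrom,yChrom optional name of the X-like / Y-like chromosome.
#' @return A [GenomeSpec-class] object.
#' @examples
#' gs <- GenomeSpec(c("chr1", "chrX", "chrY"), c(2e6, 1e6, 5e5),
#'                  xChrom = "chrX", yChrom = "chrY")
#' chromLengths(gs)
#' @export
GenomeSpec <- function(chromNames, chromLengths,
                       xChrom = character(), yChrom = character()) {
    si <- GenomeInfoDb::Seqinfo(seqnames = as.character(chromNames),
                                seqlengths = as.integer(chromLengths))
    new("GenomeSpec", seqinfo = si,
        xChrom = as.character(xChrom), yChrom = as.character(yChrom))
}

# canonical hg19 chromosome lengths (25 sequences: 1-22, X, Y, M)
.HG19_LENGTHS <- c(
    chr1 = 249250621L, chr2 = 243199373L, chr3 = 198022430L,
    chr4 = 191154276L, chr5 = 180915260L, chr6 = 171115067L,
    chr7 = 159138663L, chr8 = 146364022L, chr9 = 141213431L,
    chr10 = 135534747L, chr11 = 135006516L, chr12 = 133851895L,
    chr13 = 115169878L, chr14 = 107349540L, chr15 = 102531392L,
    chr16 = 90354753L, chr17 = 81195210L, chr18 = 78077248L,
    chr19 = 59128983L, chr20 = 63025520L, chr21 = 48129895L,
    chr22 = 51304566L, chrX = 155270560L, chrY = 59373566L,
    chrM = 16571L)

#' The 25 canonical hg19 chromosomes as a GenomeSpec
#'
#' Bundled constant table of hg19 chromosome lengths (autosomes 1-22, X, Y
#' and the mitochondrial genome) with the sex chromosomes flagged.
#'
#' @return A [GenomeSpec-class] for hg19.
#' @examples
#' countTiledWindows(hg19GenomeSpec())
#' @export
hg19GenomeSpec <- function() {
    GenomeSpec(names(.HG19_LENGTHS), .HG19_LENGTHS,
               xChrom = "chrX", yChrom = "chrY")
}

#' @describeIn GenomeSpec chromosome names.
#' @param x a `GenomeSpec`.
#' @export
setMethod("chromNames", "GenomeSpec",
    function(x) GenomeInfoDb::seqnames(x@seqinfo))

#' @describeIn GenomeSpec named chromosome lengths (bp).
#' @export
setMethod("chromLengths", "GenomeSpec",
    function(x) GenomeInfoDb::seqlengths(x@seqinfo))

#' @describeIn GenomeSpec named list with elements `x` and `y` (each length
#'   0 or 1).
#' @export
setMethod("sexChroms", "GenomeSpec",
    function(x) list(x = x@xChrom, y = x@yChrom))

#' @describeIn GenomeSpec chromosome names that are neither X- nor Y-like.
#' @export
setMethod("autosomes", "GenomeSpec",
    function(x) setdiff(chromNames(x), c(x@xChrom, x@yChrom)))

setMethod("show", "GenomeSpec", function(object) {
    n <- length(chromNames(object))
    cat("GenomeSpec with", n, "chromosome(s),",
        format(sum(as.numeric(chromLengths(object))), big.mark = ","), "bp\n")
    sx <- sexChroms(object)
    cat("  X-like:", if (length(sx$x)) sx$x else "<none>",
        " Y-like:", if (length(sx$y)) sx$y else "<none>", "\n")
})

.seqinfo <- function(genome) genome@seqinfo

#' Number of tiling windows, in closed form
#'
#' Counts the windows that [tileWindows()] would emit, without materialising
#' them: per chromosome of length `L >= windowSize` the count is
#' `floor((L - windowSize) / step) + 1`; shorter chromosomes contribute zero.
#'
#' @param genome a [GenomeSpec-class].
#' @param windowSize,step window width and shift (bp).
#' @return Total window count (numeric, may exceed `.Machine$integer.max`).
#' @examples
#' countTiledWindows(hg19GenomeSpec())  # > 61 million
#' @export
countTiledWindows <- function(genome, windowSize = 100L, step = 50L) {
    stopifnot(is(genome, "GenomeSpec"))
    .checkWindowParams(windowSize, step)
    L <- as.numeric(chromLengths(genome))
    sum(ifelse(L >= windowSize, floor((L - windowSize) / step) + 1, 0))
}

.checkWindowParams <- function(windowSize, step) {
    if (!(step > 0 && step <= windowSize))
        stop("step must satisfy 0 < step <= windowSize")
}

#' Tile a genome into overlapping constant-width windows
#'
#' Emits windows with starts `0, step, 2*step, ...` (0-based) per chromosome
#' while the full window fits; partial terminal windows are dropped so every
#' window has identical width. Chromosomes shorter than `windowSize` yield no
#' windows.
#'
#' @inheritParams countTiledWindows
#' @return A [GenomicRanges::GRanges] of windows (1-based closed, as usual
#'   for `GRanges`), sorted by chromosome then start, with mcols `window_id`
#'   (ordinal within chromosome).
#' @examples
#' gs <- GenomeSpec("chr1", 250)
#' tileWindows(gs)  # 4 windows, 0-based starts 0, 50, 100, 150
#' @export
tileWindows <- function(genome, windowSize = 100L, step = 50L) {
    stopifnot(is(genome, "GenomeSpec"))
    .checkWindowParams(windowSize, step)
    windowSize <- as.integer(windowSize)
    step <- as.integer(step)
    L <- chromLengths(genome)
    n <- ifelse(L >= windowSize, (L - windowSize) %/% step + 1L, 0L)
    if (sum(as.numeric(n)) > 5e7)
        stop("refusing to materialise > 50 million windows; ",
             "use countTiledWindows() for arithmetic at this scale")
    starts0 <- unlist(lapply(n, function(k) step * (seq_len(k) - 1L)),
                      use.names = FALSE)
    gr <- GenomicRanges::GRanges(
        seqnames = rep(names(L), n),
        ranges = IRanges::IRanges(start = starts0 + 1L, width = windowSize),
        seqinfo = .seqinfo(genome))
    gr$window_id <- unlist(lapply(n, seq_len), use.names = FALSE)
    gr
}
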