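## Genomic-context annotation: CGI island/shore/shelf, nearest TSS,
## promoter/TSR/exon/intron/intergenic/repeat classes, per-chromosome
## densities and cross-comparison set overlaps.

#' CpG-island context of windows
#'
#' `island` when a window overlaps a (merged) CGI; otherwise `shore` when
#' the gap to the nearest CGI edge is at most 2 kb, `shelf` when at most
#' 4 kb, else `open_sea`. Precedence island > shore > shelf.
#'
#' @param windows `GRanges`.
#' @param cgi `GRanges` of CpG islands (merged on use).
#' @param shoreBp,shelfBp outer shore/shelf limits (bp).
#' @return Character vector, one of `island`, `shore`, `shelf`, `open_sea`.
#' @export
classifyCgiContext <- function(windows, cgi, shoreBp = 2000L,
                               shelfBp = 4000L) {
    out <- rep("open_sea", length(windows))
    if (length(cgi) == 0L || length(windows) == 0L) return(out)
    cgi <- GenomicRanges::reduce(.stripMcols(cgi))
    hit <- GenomicRanges::distanceToNearest(windows, cgi,
                                            ignore.strand = TRUE)
    d <- rep(NA_real_, length(windows))
    d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
    out[!is.na(d) & d <= shelfBp] <- "shelf"
    out[!is.na(d) & d <= shoreBp] <- "shore"
    out[!is.na(d) & d == 0 &
        GenomicRanges::countOverlaps(windows, cgi) > 0] <- "island"
    out
}

.stripMcols <- function(gr) {
    S4Vectors::mcols(gr) <- NULL
    gr
}

# 0-based TSS of each gene: start-1 on +, end-1 on -
.tss0 <- function(genes) {
    ifelse(as.character(GenomicRanges::strand(genes)) == "+",
           GenomicRanges::start(genes) - 1L,
           GenomicRanges::end(genes) - 1L)
}

#' Nearest transcription start site
#'
#' Distance from each window's midpoint to the nearest gene TSS, signed by
#' the gene's strand (positive downstream of the TSS, negative upstream).
#' Ties are broken by the lower TSS coordinate, then the lexicographically
#' smaller gene id.
#'
#' @param windows `GRanges` of constant-width windows.
#' @param genes gene models: `GRanges` with strand and `gene_id` (e.g.
#'   [geneModels()] of an [AnnotationTracks-class]).
#' @param maxDistance flag distance for `within_flag` (bp, default 5000).
#' @return `DataFrame` with `nearest_gene`, `tss_distance`, `within_flag`.
#' @export
nearestTss <- function(windows, genes, maxDistance = 5000L) {
    if (length(genes) == 0L) stop("no gene models supplied")
    mid0 <- floor((GenomicRanges::start(windows) - 1 +
                   GenomicRanges::end(windows)) / 2)
    wchrom <- as.character(GenomicRanges::seqnames(windows))
    gchrom <- as.character(GenomicRanges::seqnames(genes))
    tss0 <- .tss0(genes)
    gid <- genes$gene_id
    gstrand <- as.character(GenomicRanges::strand(genes))

    nearest_gene <- rep(NA_character_, length(windows))
    tss_distance <- rep(NA_real_, length(windows))
    for (ch in unique(wchrom)) {
        gi <- which(gchrom == ch)
        wi <- which(wchrom == ch)
        if (length(gi) == 0L || length(wi) == 0L) next
        # order by coordinate then id; drop co-located duplicates so the
        # tie rule (lower coordinate, then smaller id) is automatic
        o <- gi[order(tss0[gi], gid[gi])]
        o <- o[!duplicated(tss0[o])]
        ts <- tss0[o]
        idx <- findInterval(mid0[wi], ts)
        left <- pmax(idx, 1L)
        right <- pmin(idx + 1L, length(ts))
        dl <- abs(mid0[wi] - ts[left])
        dr <- abs(mid0[wi] - ts[right])
        useLeft <- idx >= 1L & (idx >= length(ts) | dl <= dr)
        pick <- o[ifelse(useLeft, left, right)]
        nearest_gene[wi] <- gid[pick]
        raw <- mid0[wi] - tss0[pick]
        tss_distance[wi] <- ifelse(gstrand[pick] == "-", -raw, raw)
    }
    S4Vectors::DataFrame(nearest_gene = nearest_gene,
                         tss_distance = tss_distance,
                         within_flag = !is.na(tss_distance) &
                             abs(tss_distance) <= maxDistance)
}

# strand-aware promoter intervals, 0-based [tss-500, tss+100) on + and
# [tss-100, tss+500) on -, as 1-based GRanges (unclipped starts floored at 1)
.promoterRanges <- function(genes, up = 500L, down = 100L) {
    tss0 <- .tss0(genes)
    plus <- as.character(GenomicRanges::strand(genes)) == "+"
    s0 <- ifelse(plus, tss0 - up, tss0 - down)
    e0 <- ifelse(plus, tss0 + down, tss0 + up)
    GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
        IRanges::IRanges(start = pmax(s0 + 1L, 1L), end = e0))
}

.tsrRanges <- function(genes, halfWidth = 50L) {
    tss0 <- .tss0(genes)
    GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
        IRanges::IRanges(start = pmax(tss0 + 1L - halfWidth, 1L),
                         end = tss0 + 1L + halfWidth))
}

#' Feature classes of windows
#'
#' Overlap-based classification against gene models and a repeat track:
#' `tsr` (within `tsrHalfWidth` of a TSS), `promoter` (-500/+100 bp of the
#' TSS, strand-aware), `exon`, `intron` (gene minus exons), `gene_locus`
#' (full transcript extent), `intergenic` (none of the genic/promoter/TSR
#' classes) and the orthogonal `repeat_el` flag.
#'
#' @param windows `GRanges`.
#' @param tracks an [AnnotationTracks-class].
#' @param tsrHalfWidth half-width of the transcription start region (bp).
#' @return `DataFrame` of logical columns `tsr`, `promoter`, `exon`,
#'   `intron`, `gene_locus`, `intergenic`, `repeat_el`.
#' @export
classifyFeatures <- function(windows, tracks, tsrHalfWidth = 50L) {
    stopifnot(is(tracks, "AnnotationTracks"))
    genes <- geneModels(tracks)
    ov <- function(subject) {
        if (length(subject) == 0L) return(rep(FALSE, length(windows)))
        GenomicRanges::countOverlaps(windows, .stripMcols(subject),
                                     ignore.strand = TRUE) > 0
    }
    exAll <- unlist(exonModels(tracks), use.names = FALSE)
    intronic <- if (length(genes))
        GenomicRanges::setdiff(GenomicRanges::reduce(.stripMcols(genes),
                                                     ignore.strand = TRUE),
                               GenomicRanges::reduce(.stripMcols(exAll),
                                                     ignore.strand = TRUE),
                               ignore.strand = TRUE)
        else GenomicRanges::GRanges()
    gene_locus <- ov(genes)
    promoter <- if (length(genes)) ov(.promoterRanges(genes))
                else rep(FALSE, length(windows))
    tsr <- if (length(genes)) ov(.tsrRanges(genes, tsrHalfWidth))
           else rep(FALSE, length(windows))
    S4Vectors::DataFrame(
        tsr = tsr, promoter = promoter, exon = ov(exAll),
        intron = ov(intronic), gene_locus = gene_locus,
        intergenic = !(gene_locus | promoter | tsr),
        repeat_el = ov(repeatTrack(tracks)))
}

#' Annotate windows with full genomic context
#'
#' Convenience wrapper combining [classifyCgiContext()], [nearestTss()] and
#' [classifyFeatures()] into mcols on the input.
#'
#' @inheritParams classifyFeatures
#' @param maxDistance TSS proximity flag distance (bp).
#' @return `windows` with added mcols.
#' @export
annotateWindows <- function(windows, tracks, maxDistance = 5000L,
                            tsrHalfWidth = 50L) {
    stopifnot(is(tracks, "AnnotationTracks"))
    S4Vectors::mcols(windows)$cgi_context <-
        classifyCgiContext(windows, cgiTrack(tracks))
    nt <- nearestTss(windows, geneModels(tracks), maxDistance)
    S4Vectors::mcols(windows)$nearest_gene <- nt$nearest_gene
    S4Vectors::mcols(windows)$tss_distance <- nt$tss_distance
    S4Vectors::mcols(windows)$within_5kb <- nt$within_flag
    fc <- classifyFeatures(windows, tracks, tsrHalfWidth)
    for (nm in colnames(fc)) S4Vectors::mcols(windows)[[nm]] <- fc[[nm]]
    windows
}

#' Per-chromosome RAM density
#'
#' Hyper- and hypomethylated window counts per chromosome, scaled to counts
#' per megabase of chromosome length.
#'
#' @param rams `GRanges` of RAM windows with `direction`.
#' @param genome a [GenomeSpec-class].
#' @return data.frame with `chrom`, `length_bp`, `n_hyper`, `n_hypo`,
#'   `hyper_per_mb`, `hypo_per_mb`.
#' @export
chromDistribution <- function(rams, genome) {
    stopifnot(is(genome, "GenomeSpec"))
    L <- chromLengths(genome)
    ch <- as.character(GenomicRanges::seqnames(rams))
    if (length(rams) && !all(ch %in% names(L)))
        stop("RAM(s) on chromosome(s) absent from the genome: ",
             paste(unique(setdiff(ch, names(L))), collapse = ", "))
    nh <- table(factor(ch[rams$direction == "hyper"], levels = names(L)))
    nl <- table(factor(ch[rams$direction == "hypo"], levels = names(L)))
    data.frame(chrom = names(L), length_bp = as.numeric(L),
               n_hyper = as.integer(nh), n_hypo = as.integer(nl),
               hyper_per_mb = as.integer(nh) * 1e6 / as.numeric(L),
               hypo_per_mb = as.integer(nl) * 1e6 / as.numeric(L),
               row.names = NULL)
}

#' Set accounting across comparisons
#'
#' All intersection cells of the (up to 3-set) Venn of per-comparison window
#' sets, plus the union, per-set totals, the pooled total (sum of the set
#' sizes) and the number of windows found in exactly one set.
#'
#' @param sets named list of character vectors of window ids (e.g.
#'   `"chrom:start"` keys, see [ramWindowKeys()]).
#' @return A list with `per_set`, `pooled_total`, `union`, `exactly_one`,
#'   `cells` (exclusive Venn cells keyed like `"A"`, `"A&B"`) and
#'   `intersections` (plain pairwise/triple intersection sizes).
#' @export
overlapSets <- function(sets) {
    stopifnot(is.list(sets), length(sets) >= 2L, length(sets) <= 3L)
    if (is.null(names(sets))) names(sets) <- LETTERS[seq_along(sets)]
    sets <- lapply(sets, unique)
    ids <- unique(unlist(sets, use.names = FALSE))
    memb <- vapply(sets, function(s) ids %in% s,
                   logical(length(ids)))
    if (length(ids) == 1L) memb <- matrix(memb, nrow = 1L,
                                          dimnames = list(NULL, names(sets)))
    nm <- names(sets)
    cellKey <- apply(memb, 1L, function(r) paste(nm[r], collapse = "&"))
    cells <- table(cellKey)
    inter <- list()
    for (k in 2:length(sets)) {
        for (cmb in utils::combn(seq_along(sets), k, simplify = FALSE)) {
            key <- paste(nm[cmb], collapse = "&")
            inter[[key]] <- sum(rowSums(memb[, cmb, drop = FALSE]) == k)
        }
    }
    list(per_set = vapply(sets, length, integer(1)),
         pooled_total = sum(vapply(sets, length, integer(1))),
         union = length(ids),
         exactly_one = sum(rowSums(memb) == 1L),
         cells = as.list(cells),
         intersections = inter)
}

#' Window identity keys
#'
#' Windows are identified across comparisons by chromosome and 0-based
#' start.
#'
#' @param gr `GRanges`.
#' @return Character vector `"chrom:start0"`.
#' @export
ramWindowKeys <- function(gr) {
    paste(as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr) - 1L, sep = ":")
}

#' Repeat-overlap percentages by direction
#'
#' Percentage of hyper- and of hypomethylated RAM windows overlapping the
#' repeat track; the per-comparison values are data-dependent summaries.
#'
#' @param rams annotated RAM `GRanges` (mcols `direction`, `repeat_el`).
#' @return Named numeric: percent of hyper / hypo RAMs in repeats.
#' @export
repeatOverlapPercent <- function(rams) {
    pc <- function(d) {
        i <- rams$direction == d
        if (!any(i)) return(NA_real_)
        100 * mean(rams$repeat_el[i])
    }
    c(hyper = pc("hyper"), hypo = pc("hypo"))
}
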