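## Synthetic-data generators: miniature genomes with CGI/gene/repeat tracks,
## enrichment-sequencing read positions with known spiked effects, sample
## sheets under the BPA trichotomization, and expression counts with
## inverse methylation-expression coupling.

.checkParam <- function(ok, field, what) {
    if (!isTRUE(ok)) stop("invalid parameter '", field, "': ", what)
}

# place k non-overlapping intervals of the given widths uniformly on [0, L):
# sample starts in the gap space and add back cumulative widths, so the
# interval count keeps its sampled distribution exactly
.placeNonOverlapping <- function(k, widths, L) {
    if (k == 0L) return(data.frame(start = integer(0), end = integer(0)))
    widths <- rep_len(widths, k)
    free <- L - sum(widths)
    if (free < 0) {
        k <- max(which(cumsum(rep_len(widths, k)) <= L), 0L)
        if (k == 0L) return(data.frame(start = integer(0), end = integer(0)))
        widths <- widths[seq_len(k)]
        free <- L - sum(widths)
    }
    gaps <- sort(floor(stats::runif(k, 0, free + 1)))
    starts <- gaps + cumsum(c(0L, widths[-k]))
    data.frame(start = as.integer(starts),
               end = as.integer(starts + widths))
}

.gr0 <- function(chrom, start0, end0, seqinfo = NULL, ...) {
    if (length(start0) == 0L)
        return(GenomicRanges::GRanges(seqinfo = seqinfo))
    GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = start0 + 1L, end = end0),
        seqinfo = seqinfo, ...)
}

#' Simulate a miniature genome with annotation tracks
#'
#' Chromosome lengths are drawn around `meanLengthBp`; CpG islands and gene
#' models arrive as Poisson processes (`cgiDensity`, `geneDensity` per bp)
#' placed without overlap, repeats cover approximately `repeatFraction` of
#' each chromosome. When `includeSexChroms` is set, the last two chromosomes
#' are named `chrX`/`chrY` and flagged. Deterministic under a fixed seed.
#'
#' @param nChroms number of chromosomes.
#' @param meanLengthBp mean chromosome length (>= 10000 bp).
#' @param cgiDensity expected CpG islands per bp (e.g. 5e-5 gives 50 per Mb).
#' @param geneDensity expected genes per bp.
#' @param repeatFraction approximate fraction of each chromosome covered by
#'   repeats.
#' @param seed integer seed.
#' @param includeSexChroms flag the last two chromosomes as X/Y.
#' @param lengthJitter relative half-width of the uniform length
#'   distribution around `meanLengthBp` (0 gives constant lengths).
#' @return list with elements `genome` ([GenomeSpec-class]) and `tracks`
#'   ([AnnotationTracks-class]).
#' @export
simulateGenome <- function(nChroms = 4L, meanLengthBp = 1e6,
                           cgiDensity = 2e-5, geneDensity = 1e-5,
                           repeatFraction = 0.2, seed = 1L,
                           includeSexChroms = TRUE, lengthJitter = 0.3) {
    .checkParam(nChroms >= 1, "nChroms", "must be >= 1")
    .checkParam(meanLengthBp >= 10000, "meanLengthBp", "must be >= 10000")
    .checkParam(cgiDensity >= 0, "cgiDensity", "must be >= 0")
    .checkParam(geneDensity >= 0, "geneDensity", "must be >= 0")
    .checkParam(repeatFraction >= 0 && repeatFraction < 1, "repeatFraction",
                "must be in [0, 1)")
    .checkParam(lengthJitter >= 0 && lengthJitter < 1, "lengthJitter",
                "must be in [0, 1)")
    if (includeSexChroms && nChroms < 3L)
        .checkParam(FALSE, "nChroms", "need >= 3 chromosomes for X and Y")
    set.seed(as.integer(seed))
    nms <- if (includeSexChroms)
        c(paste0("chr", seq_len(nChroms - 2L)), "chrX", "chrY")
        else paste0("chr", seq_len(nChroms))
    L <- as.integer(round(meanLengthBp *
        stats::runif(nChroms, 1 - lengthJitter, 1 + lengthJitter)))
    genome <- GenomeSpec(nms, L,
        xChrom = if (includeSexChroms) "chrX" else character(),
        yChrom = if (includeSexChroms) "chrY" else character())
    si <- .seqinfo(genome)

    cgis <- list(); reps <- list(); genes <- list(); exons <- list()
    geneCounter <- 0L
    for (i in seq_along(nms)) {
        len <- L[i]
        # CpG islands: Poisson count, widths 200-2000 bp
        k <- stats::rpois(1L, len * cgiDensity)
        w <- as.integer(round(stats::runif(k, 200, 2000)))
        iv <- .placeNonOverlapping(k, w, len)
        cgis[[i]] <- .gr0(nms[i], iv$start, iv$end, si)
        # repeats: count chosen so expected coverage ~ repeatFraction
        meanRepW <- 300
        kr <- stats::rpois(1L, repeatFraction * len / meanRepW)
        wr <- as.integer(round(stats::runif(kr, 100, 500)))
        ivr <- .placeNonOverlapping(kr, wr, len)
        reps[[i]] <- .gr0(nms[i], ivr$start, ivr$end, si)
        # genes: Poisson count, widths 2-20 kb, random strand, 1-4 exons
        kg <- stats::rpois(1L, len * geneDensity)
        wg <- as.integer(round(stats::runif(kg, 2000, 20000)))
        ivg <- .placeNonOverlapping(kg, wg, len)
        kg <- nrow(ivg)
        if (kg > 0L) {
            ids <- sprintf("gene%04d", geneCounter + seq_len(kg))
            geneCounter <- geneCounter + kg
            str <- sample(c("+", "-"), kg, replace = TRUE)
            g <- .gr0(nms[i], ivg$start, ivg$end, si, strand = str,
                      gene_id = ids)
            genes[[i]] <- g
            exons[[i]] <- lapply(seq_len(kg), function(j) {
                gl <- ivg$end[j] - ivg$start[j]
                nex <- sample(1:4, 1L)
                if (nex == 1L)
                    return(.gr0(nms[i], ivg$start[j], ivg$end[j], si))
                # interior boundaries: alternate exon/intron, first and
                # last exon pinned to the gene ends
                cuts <- sort(sample(seq_len(gl - 1L), 2L * (nex - 1L)))
                s0 <- ivg$start[j] + c(0L, cuts[seq(2L, by = 2L,
                                                    length.out = nex - 1L)])
                e0 <- ivg$start[j] + c(cuts[seq(1L, by = 2L,
                                                length.out = nex - 1L)], gl)
                .gr0(nms[i], s0, e0, si)
            })
            names(exons[[i]]) <- ids
        }
    }
    catGr <- function(lst) {
        lst <- Filter(Negate(is.null), lst)
        lst <- Filter(length, lst)
        if (length(lst) == 0L) return(GenomicRanges::GRanges(seqinfo = si))
        do.call(c, unname(lst))
    }
    exFlat <- do.call(c, c(list(list()), Filter(Negate(is.null), exons)))
    exonList <- if (length(exFlat)) GenomicRanges::GRangesList(exFlat)
                else GenomicRanges::GRangesList()
    tracks <- new("AnnotationTracks",
        cgi = catGr(cgis), repeats = catGr(reps),
        genes = catGr(genes), exons = exonList)
    list(genome = genome, tracks = tracks)
}

#' @describeIn AnnotationTracks merged CpG-island intervals.
#' @param x an `AnnotationTracks`.
#' @export
setMethod("cgiTrack", "AnnotationTracks", function(x) x@cgi)

#' @describeIn AnnotationTracks repeat intervals.
#' @export
setMethod("repeatTrack", "AnnotationTracks", function(x) x@repeats)

#' @describeIn AnnotationTracks gene ranges with strand and `gene_id`.
#' @export
setMethod("geneModels", "AnnotationTracks", function(x) x@genes)

#' @describeIn AnnotationTracks per-gene exon `GRangesList`.
#' @export
setMethod("exonModels", "AnnotationTracks", function(x) x@exons)

setMethod("show", "AnnotationTracks", function(object) {
    cat("AnnotationTracks:", length(object@cgi), "CGI,",
        length(object@repeats), "repeat,",
        length(object@genes), "gene interval(s)\n")
})

#' Trichotomize BPA concentrations into exposure groups
#'
#' Liver BPA concentration (ng/g) to exposure group: `non_detect` up to
#' 0.83, `low` 3.50-5.79, `high` 35.44-96.76; concentrations falling in the
#' gaps between (or above) those ranges are `unassigned` and excluded from
#' comparisons. `NA` encodes a non-detect measurement.
#'
#' @param bpa numeric vector of concentrations (ng/g); `NA` = non-detect.
#' @return Character vector of groups.
#' @examples
#' trichotomizeBpa(c(0.5, 4.2, 50, 10, NA))
#' @export
trichotomizeBpa <- function(bpa) {
    if (any(bpa < 0, na.rm = TRUE))
        stop("BPA concentrations must be >= 0")
    out <- rep("unassigned", length(bpa))
    out[is.na(bpa) | bpa <= 0.83] <- "non_detect"
    out[!is.na(bpa) & bpa >= 3.50 & bpa <= 5.79] <- "low"
    out[!is.na(bpa) & bpa >= 35.44 & bpa <= 96.76] <- "high"
    out
}

#' Simulate a sample sheet
#'
#' Draws `nPerGroup` subjects per exposure group with concentrations
#' uniform within each group's range (non-detect subjects get `NA` with
#' probability 1/2, otherwise a value below 0.83 ng/g) and sexes split as
#' evenly as the group size allows. Groups are assigned through
#' [trichotomizeBpa()], so sheet and rule agree by construction.
#'
#' @param nPerGroup subjects per exposure group (default 6, the study
#'   design).
#' @param seed integer seed.
#' @return data.frame with columns `id`, `sex`, `bpa_ng_per_g`, `group`.
#' @export
simulateSampleSheet <- function(nPerGroup = 6L, seed = 1L) {
    .checkParam(nPerGroup >= 1, "nPerGroup", "must be >= 1")
    set.seed(as.integer(seed))
    ranges <- list(non_detect = c(0, 0.83), low = c(3.50, 5.79),
                   high = c(35.44, 96.76))
    rows <- lapply(names(ranges), function(g) {
        bpa <- stats::runif(nPerGroup, ranges[[g]][1], ranges[[g]][2])
        if (g == "non_detect")
            bpa[stats::runif(nPerGroup) < 0.5] <- NA
        sex <- rep(c("male", "female"), length.out = nPerGroup)
        data.frame(sex = sex, bpa_ng_per_g = bpa)
    })
    out <- do.call(rbind, rows)
    out$id <- sprintf("S%02d", seq_len(nrow(out)))
    out$group <- trichotomizeBpa(out$bpa_ng_per_g)
    out[, c("id", "sex", "bpa_ng_per_g", "group")]
}

#' Construct a TruthTable
#'
#' @param spikedWindows data.frame (`chrom`, `start`, `end`, `true_log2FC`,
#'   `comparison`), 0-based half-open coordinates.
#' @param deGenes data.frame (`gene_id`, `true_log2FC`, `comparison`).
#' @param coupling data.frame (`chrom`, `start`, `gene_id`).
#' @param genome optional [GenomeSpec-class]; when given, spiked windows are
#'   checked against chromosome bounds.
#' @return A [TruthTable-class].
#' @export
TruthTable <- function(spikedWindows = NULL, deGenes = NULL,
                       coupling = NULL, genome = NULL) {
    empty <- function(...) data.frame(...)
    if (is.null(spikedWindows))
        spikedWindows <- empty(chrom = character(0), start = integer(0),
            end = integer(0), true_log2FC = numeric(0),
            comparison = character(0))
    if (is.null(deGenes))
        deGenes <- empty(gene_id = character(0), true_log2FC = numeric(0),
            comparison = character(0))
    if (is.null(coupling))
        coupling <- empty(chrom = character(0), start = integer(0),
            gene_id = character(0))
    if (!is.null(genome) && nrow(spikedWindows)) {
        L <- chromLengths(genome)
        bad <- !(spikedWindows$chrom %in% names(L)) |
            spikedWindows$start < 0 |
            spikedWindows$end > L[spikedWindows$chrom]
        if (any(bad))
            stop("spiked window(s) outside genome bounds: row(s) ",
                 paste(which(bad), collapse = ", "))
    }
    new("TruthTable", spikedWindows = spikedWindows, deGenes = deGenes,
        coupling = coupling)
}

#' @describeIn TruthTable spiked-window table.
#' @param x a `TruthTable`.
#' @export
setMethod("spikedWindows", "TruthTable", function(x) x@spikedWindows)

#' @describeIn TruthTable differential-gene table.
#' @export
setMethod("deGenes", "TruthTable", function(x) x@deGenes)

#' @describeIn TruthTable window-to-gene inverse-coupling map.
#' @export
setMethod("couplingMap", "TruthTable", function(x) x@coupling)

setMethod("show", "TruthTable", function(object) {
    cat("TruthTable:", nrow(object@spikedWindows), "spiked window(s),",
        nrow(object@deGenes), "DE gene(s),",
        nrow(object@coupling), "coupled pair(s)\n")
})

#' Random spiked-window truth
#'
#' Places `nSpikes` runs of `runLength` consecutive 100 bp windows (50 bp
#' step) on the requested chromosomes, each run carrying one log2
#' fold-change for one comparison. Runs are kept at least `minGapBp` apart
#' so spikes do not interact through the flanking filter.
#'
#' @param genome a [GenomeSpec-class].
#' @param nSpikes number of spike runs.
#' @param log2FC effect size (sign = direction in the higher group);
#'   recycled.
#' @param comparison comparison label(s); recycled.
#' @param runLength consecutive windows per run (>= 1).
#' @param chroms chromosomes to use (default: autosomes).
#' @param seed integer seed.
#' @param windowSize,step tiling geometry.
#' @param minGapBp minimum distance between run starts.
#' @return A [TruthTable-class] whose `spikedWindows` lists every fully
#'   spiked window.
#' @export
randomSpikeTruth <- function(genome, nSpikes = 15L, log2FC = 2,
                             comparison = "nd_vs_high", runLength = 3L,
                             chroms = NULL, seed = 1L, windowSize = 100L,
                             step = 50L, minGapBp = 2000L) {
    stopifnot(is(genome, "GenomeSpec"), runLength >= 1L)
    set.seed(as.integer(seed))
    if (is.null(chroms)) chroms <- autosomes(genome)
    L <- chromLengths(genome)[chroms]
    spanBp <- windowSize + (runLength - 1L) * step
    # sample run anchor starts on the step lattice, spaced >= minGapBp
    prob <- as.numeric(L) / sum(as.numeric(L))
    rows <- list()
    tries <- 0L
    anchors <- data.frame(chrom = character(0), start = integer(0))
    while (nrow(anchors) < nSpikes && tries < 50L * nSpikes) {
        tries <- tries + 1L
        ch <- sample(chroms, 1L, prob = prob)
        maxStart <- L[[ch]] - spanBp - step
        if (maxStart < step) next
        s <- step * sample.int(maxStart %/% step, 1L)
        if (any(anchors$chrom == ch &
                abs(anchors$start - s) < minGapBp + spanBp)) next
        anchors <- rbind(anchors, data.frame(chrom = ch, start = s))
    }
    if (nrow(anchors) < nSpikes)
        warning("placed only ", nrow(anchors), " of ", nSpikes, " spikes")
    lfc <- rep_len(log2FC, nrow(anchors))
    cmp <- rep_len(comparison, nrow(anchors))
    sw <- do.call(rbind, lapply(seq_len(nrow(anchors)), function(j) {
        st <- anchors$start[j] + step * (seq_len(runLength) - 1L)
        data.frame(chrom = anchors$chrom[j], start = st,
                   end = st + windowSize, true_log2FC = lfc[j],
                   comparison = cmp[j])
    }))
    TruthTable(spikedWindows = sw, genome = genome)
}

# union of spiked bins (the 50 bp half-windows whose intensity is scaled);
# a tiling window is fully spiked iff both its bins are inside this span
spikeSpans <- function(truth, step = 50L) {
    sw <- spikedWindows(truth)
    if (nrow(sw) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(.gr0(sw$chrom, sw$start, sw$end))
}

.higherGroupOf <- function(comparison) {
    if (!comparison %in% names(.COMPARISONS))
        stop("unknown comparison: ", comparison)
    .COMPARISONS[[comparison]][2L]
}

.sampleStreamSeeds <- function(seed, n) {
    set.seed(as.integer(seed))
    sample.int(.Machine$integer.max, n)
}

#' Simulate methylation-enrichment read positions
#'
#' Per sample, 50 bp bins tile each chromosome; bin intensities start at 1,
#' are multiplied by `cgiEnrichmentFactor` inside CpG islands, by a sex
#' structure (Y-like bins get `yLeakage` in females, X-like bins
#' `xFemaleFactor` in females), and by `2^true_log2FC` inside spiked
#' windows for samples in the higher group of the spike's comparison.
#' Bin counts are drawn negative-binomially so that 100 bp window counts
#' aggregated from the reads are marginally NB with the requested
#' dispersion (`dispersion = 0` gives Poisson counts), and each read is a
#' uniform position within its bin. Per-sample PRNG streams are split from
#' the seed, so adding samples leaves existing ones unchanged.
#'
#' @param genome a [GenomeSpec-class].
#' @param tracks an [AnnotationTracks-class] (CGI track used).
#' @param sampleSheet data.frame with `id`, `sex`, `group`.
#' @param depthPerSample expected reads per sample.
#' @param cgiEnrichmentFactor intensity multiplier inside CpG islands.
#' @param truth a [TruthTable-class] (or `NULL` for no spikes).
#' @param dispersion NB dispersion of 100 bp window counts (>= 0).
#' @param seed integer seed.
#' @param xFemaleFactor X-like intensity multiplier in females (dosage).
#' @param yLeakage Y-like intensity multiplier in females (default 0).
#' @param binSize bin width (bp); half the tiling window size.
#' @return Named list (per sample) of width-1 `GRanges` read starts.
#' @export
simulateMethylationReads <- function(genome, tracks, sampleSheet,
                                     depthPerSample = 1e6,
                                     cgiEnrichmentFactor = 8,
                                     truth = NULL, dispersion = 0.1,
                                     seed = 1L, xFemaleFactor = 2,
                                     yLeakage = 0, binSize = 50L) {
    .checkParam(depthPerSample > 0, "depthPerSample", "must be > 0")
    .checkParam(dispersion >= 0, "dispersion", "must be >= 0")
    .checkParam(cgiEnrichmentFactor > 0, "cgiEnrichmentFactor",
                "must be > 0")
    stopifnot(is(genome, "GenomeSpec"), is(tracks, "AnnotationTracks"))
    if (is.null(truth)) truth <- TruthTable()
    sw <- spikedWindows(truth)
    if (nrow(sw)) {
        L <- chromLengths(genome)
        bad <- !(sw$chrom %in% names(L)) | sw$start < 0 |
            sw$end > L[sw$chrom]
        if (any(bad))
            stop("spiked window(s) outside genome bounds")
    }
    si <- .seqinfo(genome)
    L <- chromLengths(genome)
    nbin <- L %/% binSize
    bins <- GenomicRanges::GRanges(
        rep(names(L), nbin),
        IRanges::IRanges(
            start = unlist(lapply(nbin, function(k)
                binSize * (seq_len(k) - 1L) + 1L), use.names = FALSE),
            width = binSize),
        seqinfo = si)
    binChrom <- as.character(GenomicRanges::seqnames(bins))
    baseW <- rep(1, length(bins))
    inCgi <- GenomicRanges::countOverlaps(bins, cgiTrack(tracks)) > 0
    baseW[inCgi] <- baseW[inCgi] * cgiEnrichmentFactor
    sx <- sexChroms(genome)

    seeds <- .sampleStreamSeeds(seed, nrow(sampleSheet))
    out <- vector("list", nrow(sampleSheet))
    names(out) <- sampleSheet$id
    for (i in seq_len(nrow(sampleSheet))) {
        set.seed(seeds[i])
        w <- baseW
        if (sampleSheet$sex[i] == "female") {
            if (length(sx$y))
                w[binChrom == sx$y] <- w[binChrom == sx$y] * yLeakage
            if (length(sx$x))
                w[binChrom == sx$x] <- w[binChrom == sx$x] * xFemaleFactor
        }
        if (nrow(sw)) {
            # listed windows overlap (50 bp shifts); scale the union span of
            # each (comparison, effect) once so shared bins are not scaled
            # repeatedly
            for (key in unique(paste(sw$comparison, sw$true_log2FC))) {
                rows <- sw[paste(sw$comparison, sw$true_log2FC) == key, ]
                hi <- .higherGroupOf(rows$comparison[1L])
                inHigher <- (sampleSheet$group[i] == hi) ||
                    (hi %in% c("male", "female") &&
                     sampleSheet$sex[i] == hi)
                if (!inHigher) next
                span <- GenomicRanges::reduce(
                    .gr0(rows$chrom, rows$start, rows$end, si))
                within <- IRanges::overlapsAny(bins, span, type = "within")
                w[within] <- w[within] * 2^rows$true_log2FC[1L]
            }
        }
        mu <- depthPerSample * w / sum(w)
        cnt <- if (dispersion == 0) stats::rpois(length(mu), mu)
               else stats::rnbinom(length(mu), mu = mu,
                                   size = 1 / (2 * dispersion))
        tot <- sum(cnt)
        pos0 <- rep(GenomicRanges::start(bins) - 1L, cnt) +
            floor(stats::runif(tot) * binSize)
        out[[i]] <- GenomicRanges::GRanges(
            rep(binChrom, cnt),
            IRanges::IRanges(start = pos0 + 1L, width = 1L),
            seqinfo = si)
    }
    out
}

#' Simulate gene-level expression counts
#'
#' NB counts per gene and sample around `baselineMean`; genes listed in the
#' truth's `deGenes` are shifted by `2^true_log2FC` in samples belonging to
#' the higher group of the gene's comparison. Per-sample PRNG streams are
#' split from the seed.
#'
#' @param geneIds character vector of gene ids (e.g. from [geneModels()]).
#' @param sampleSheet data.frame with `id`, `sex`, `group`.
#' @param truth a [TruthTable-class] (or `NULL`).
#' @param baselineMean expected count per gene (> 0).
#' @param dispersion NB dispersion (>= 0 ; 0 gives Poisson).
#' @param seed integer seed.
#' @return Integer matrix genes x samples.
#' @export
simulateExpressionCounts <- function(geneIds, sampleSheet, truth = NULL,
                                     baselineMean = 100, dispersion = 0.1,
                                     seed = 1L) {
    .checkParam(baselineMean > 0, "baselineMean", "must be > 0")
    .checkParam(dispersion >= 0, "dispersion", "must be >= 0")
    if (is.null(truth)) truth <- TruthTable()
    dg <- deGenes(truth)
    if (nrow(dg) && !all(dg$gene_id %in% geneIds))
        stop("unknown gene id(s) in truth: ",
             paste(setdiff(dg$gene_id, geneIds), collapse = ", "))
    if (nrow(dg) && is.null(dg$comparison))
        stop("deGenes needs a 'comparison' column")
    G <- length(geneIds)
    seeds <- .sampleStreamSeeds(seed, nrow(sampleSheet))
    out <- matrix(0L, nrow = G, ncol = nrow(sampleSheet),
                  dimnames = list(geneIds, sampleSheet$id))
    for (i in seq_len(nrow(sampleSheet))) {
        set.seed(seeds[i])
        mu <- rep(baselineMean, G)
        if (nrow(dg)) {
            hi <- vapply(dg$comparison, .higherGroupOf, character(1))
            inHigher <- (sampleSheet$group[i] == hi) |
                (hi %in% c("male", "female") & sampleSheet$sex[i] == hi)
            idx <- match(dg$gene_id[inHigher], geneIds)
            mu[idx] <- mu[idx] * 2^dg$true_log2FC[inHigher]
        }
        out[, i] <- if (dispersion == 0) stats::rpois(G, mu)
                    else stats::rnbinom(G, mu = mu, size = 1 / dispersion)
    }
    out
}
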