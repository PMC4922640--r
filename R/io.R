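## Plain-text interchange: BED for intervals and read starts, TSV for
## sample sheets, gene models, count matrices, results and truth tables.
## BED is 0-based half-open on disk; GRanges are 1-based closed in memory
## (rtracklayer does the shift).

#' Read / write BED interval tracks
#'
#' @param path file path.
#' @return `readBedTrack`: a `GRanges`.
#' @export
readBedTrack <- function(path) {
    rtracklayer::import(path, format = "BED")
}

#' @rdname readBedTrack
#' @param gr a `GRanges`.
#' @export
writeBedTrack <- function(gr, path) {
    rtracklayer::export(.stripMcols(gr), path, format = "BED")
    invisible(path)
}

#' Export per-sample read starts as BED3 files
#'
#' @param reads named list of width-1 `GRanges`
#'   (from [simulateMethylationReads()]).
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
exportReadBeds <- function(reads, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(names(reads), function(id) {
        p <- file.path(dir, paste0(id, ".bed"))
        writeBedTrack(reads[[id]], p)
        p
    }, character(1))
    invisible(paths)
}

#' Export RAM windows as BED6
#'
#' name = comparison, score = -10*log10(p) (capped at 1000), strand ".".
#'
#' @param rams RAM `GRanges` with `comparison` and `pvalue`.
#' @param path output file.
#' @export
exportRamBed <- function(rams, path) {
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(rams)),
        start = GenomicRanges::start(rams) - 1L,
        end = GenomicRanges::end(rams),
        name = rams$comparison,
        score = pmin(round(-10 * log10(pmax(rams$pvalue, 1e-100))), 1000L),
        strand = ".")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read / write a sample sheet TSV
#'
#' Columns: `id`, `sex`, `bpa_ng_per_g` (empty = non-detect), `group`.
#'
#' @param path file path.
#' @export
readSampleSheet <- function(path) {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
}

#' @rdname readSampleSheet
#' @param sheet a sample-sheet data.frame.
#' @export
writeSampleSheet <- function(sheet, path) {
    utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write / read gene models as TSV
#'
#' Tab-delimited with columns `gene_id`, `chrom`, `strand`, `tss`
#' (0-based), `exon_starts`, `exon_ends` (comma-joined, 0-based half-open).
#'
#' @param tracks an [AnnotationTracks-class].
#' @param path file path.
#' @export
writeGeneModels <- function(tracks, path) {
    g <- geneModels(tracks)
    ex <- exonModels(tracks)
    join <- function(v) vapply(v, paste, character(1), collapse = ",")
    df <- data.frame(
        gene_id = g$gene_id,
        chrom = as.character(GenomicRanges::seqnames(g)),
        strand = as.character(GenomicRanges::strand(g)),
        tss = .tss0(g),
        exon_starts = join(lapply(g$gene_id, function(id)
            GenomicRanges::start(ex[[id]]) - 1L)),
        exon_ends = join(lapply(g$gene_id, function(id)
            GenomicRanges::end(ex[[id]]))))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeGeneModels
#' @param genome a [GenomeSpec-class] providing the coordinate frame.
#' @return `readGeneModels`: an [AnnotationTracks-class] with empty CGI and
#'   repeat tracks.
#' @export
readGeneModels <- function(path, genome) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    si <- .seqinfo(genome)
    split0 <- function(s) as.integer(strsplit(s, ",")[[1L]])
    exons <- GenomicRanges::GRangesList(lapply(seq_len(nrow(df)), function(i)
        .gr0(df$chrom[i], split0(df$exon_starts[i]),
             split0(df$exon_ends[i]), si)))
    names(exons) <- df$gene_id
    starts0 <- vapply(df$exon_starts, function(s) min(split0(s)), integer(1))
    ends0 <- vapply(df$exon_ends, function(s) max(split0(s)), integer(1))
    genes <- .gr0(df$chrom, starts0, ends0, si, strand = df$strand,
                  gene_id = df$gene_id)
    new("AnnotationTracks", cgi = GenomicRanges::GRanges(seqinfo = si),
        repeats = GenomicRanges::GRanges(seqinfo = si),
        genes = genes, exons = exons)
}

#' Export / import a TruthTable as TSVs
#'
#' Writes `spiked_windows.tsv`, `de_genes.tsv` and `coupling.tsv` under
#' `dir`; `importTruthTable` round-trips them.
#'
#' @param truth a [TruthTable-class].
#' @param dir directory.
#' @export
exportTruthTable <- function(truth, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, f) utils::write.table(df, file.path(dir, f),
        sep = "\t", quote = FALSE, row.names = FALSE)
    w(spikedWindows(truth), "spiked_windows.tsv")
    w(deGenes(truth), "de_genes.tsv")
    w(couplingMap(truth), "coupling.tsv")
    invisible(dir)
}

#' @rdname exportTruthTable
#' @export
importTruthTable <- function(dir) {
    r <- function(f) {
        p <- file.path(dir, f)
        df <- utils::read.table(p, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
        df
    }
    sw <- r("spiked_windows.tsv")
    dg <- r("de_genes.tsv")
    cp <- r("coupling.tsv")
    TruthTable(spikedWindows = if (nrow(sw)) sw else NULL,
               deGenes = if (nrow(dg)) dg else NULL,
               coupling = if (nrow(cp)) cp else NULL)
}

#' Export window test results / counts as TSV
#'
#' @param results `GRanges` from [testWindows()] or [callRams()].
#' @param path file path.
#' @export
exportResultsTsv <- function(results, path) {
    df <- as.data.frame(results)
    df$start <- df$start - 1L  # 0-based half-open on disk
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
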