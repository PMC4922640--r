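#' GenomeSpec: the coordinate frame of an analysis
#'
#' Chromosome names and lengths plus flags naming the X-like and Y-like
#' chromosome (if any). All window tiling, counting and annotation is done
#' relative to a GenomeSpec, and the sex-based empirical-FDR estimator needs
#' its sex-chromosome flags to decide which hits are autosomal.
#'
#' @slot seqinfo a [GenomeInfoDb::Seqinfo] with chromosome names and lengths.
#' @slot xChrom,yChrom character of length 0 or 1 naming the X-like / Y-like
#'   chromosome.
#' @export
setClass("GenomeSpec",
    slots = c(seqinfo = "Seqinfo", xChrom = "character", yChrom = "character"))

setValidity("GenomeSpec", function(object) {
    si <- object@seqinfo
    msg <- character()
    if (length(si) == 0L)
        msg <- c(msg, "genome must have at least one chromosome")
    len <- GenomeInfoDb::seqlengths(si)
    if (any(is.na(len)) || any(len <= 0))
        msg <- c(msg, "all chromosome lengths must be positive")
    if (anyDuplicated(GenomeInfoDb::seqnames(si)))
        msg <- c(msg, "chromosome names must be unique")
    if (length(object@xChrom) > 1L)
        msg <- c(msg, "at most one X-like chromosome")
    if (length(object@yChrom) > 1L)
        msg <- c(msg, "at most one Y-like chromosome")
    sex <- c(object@xChrom, object@yChrom)
    if (!all(sex %in% GenomeInfoDb::seqnames(si)))
        msg <- c(msg, "sex chromosomes must be among the chromosome names")
    if (length(sex) == 2L && sex[1] == sex[2])
        msg <- c(msg, "X-like and Y-like chromosomes must differ")
    if (length(msg)) msg else TRUE
})

#' WindowCounts: read counts per genomic window per sample
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are
#' constant-width tiling windows and whose single assay `"counts"` holds
#' non-negative read counts. `colData` carries at least `lib_size` (total
#' mapped reads per sample) and may carry the sample sheet columns
#' (`sex`, `bpa_ng_per_g`, `group`).
#'
#' @export
setClass("WindowCounts", contains = "RangedSummarizedExperiment")

setValidity("WindowCounts", function(object) {
    msg <- character()
    if (!"counts" %in% names(SummarizedExperiment::assays(object)))
        return("assay 'counts' is required")
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    cd <- SummarizedExperiment::colData(object)
    if (!"lib_size" %in% colnames(cd))
        return("colData must have a 'lib_size' column")
    if (any(cd$lib_size < 0)) msg <- c(msg, "lib_size must be non-negative")
    if (length(msg)) msg else TRUE
})

#' AnnotationTracks: CpG islands, repeats and gene models
#'
#' Interval annotation for a genome: merged CpG-island intervals, repeat
#' intervals, strand-annotated gene models (whose 5' end is the TSS) and
#' per-gene exon structure.
#'
#' @slot cgi,repeats [GenomicRanges::GRanges] interval sets.
#' @slot genes [GenomicRanges::GRanges] with mcols `gene_id`; strand + or -;
#'   the TSS is the 5' end of the range (start on +, end on -).
#' @slot exons [GenomicRanges::GRangesList] named by `gene_id`; exons lie
#'   within the gene extent.
#' @export
setClass("AnnotationTracks",
    slots = c(cgi = "GRanges", repeats = "GRanges",
              genes = "GRanges", exons = "GRangesList"))

setValidity("AnnotationTracks", function(object) {
    msg <- character()
    g <- object@genes
    if (length(g)) {
        if (is.null(g$gene_id) || anyDuplicated(g$gene_id))
            msg <- c(msg, "genes must carry unique mcols$gene_id")
        if (!all(as.character(GenomicRanges::strand(g)) %in% c("+", "-")))
            msg <- c(msg, "gene strand must be + or -")
    }
    ex <- object@exons
    if (length(ex)) {
        if (!all(names(ex) %in% g$gene_id))
            msg <- c(msg, "exon list names must be gene ids")
        for (nm in names(ex)) {
            gr <- g[g$gene_id == nm]
            if (any(GenomicRanges::start(ex[[nm]]) < GenomicRanges::start(gr)) ||
                any(GenomicRanges::end(ex[[nm]]) > GenomicRanges::end(gr))) {
                msg <- c(msg, "exons must lie within their gene extent")
                break
            }
        }
    }
    if (length(msg)) msg else TRUE
})

#' TruthTable: ground truth of a synthetic experiment
#'
#' Records which windows were spiked with a methylation effect, which genes
#' were given an expression effect, and which (window, gene) pairs are
#' inversely coupled, so recovery can be scored against known truth.
#'
#' @slot spikedWindows data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `true_log2FC`, `comparison`.
#' @slot deGenes data.frame with columns `gene_id`, `true_log2FC`,
#'   `comparison`.
#' @slot coupling data.frame with columns `chrom`, `start`, `gene_id` linking
#'   a spiked window to an inversely coupled gene.
#' @export
setClass("TruthTable",
    slots = c(spikedWindows = "data.frame", deGenes = "data.frame",
              coupling = "data.frame"))

setValidity("TruthTable", function(object) {
    msg <- character()
    sw <- object@spikedWindows
    need <- c("chrom", "start", "end", "true_log2FC", "comparison")
    if (nrow(sw) && !all(need %in% names(sw)))
        msg <- c(msg, paste("spikedWindows needs columns:",
                            paste(need, collapse = ", ")))
    dg <- object@deGenes
    if (nrow(dg) && !all(c("gene_id", "true_log2FC") %in% names(dg)))
        msg <- c(msg, "deGenes needs columns gene_id, true_log2FC")
    cp <- object@coupling
    if (nrow(cp)) {
        if (!all(c("chrom", "start", "gene_id") %in% names(cp)))
            msg <- c(msg, "coupling needs columns chrom, start, gene_id")
        else if (nrow(sw) && nrow(dg)) {
            key <- paste(sw$chrom, sw$start)
            mlfc <- sw$true_log2FC[match(paste(cp$chrom, cp$start), key)]
            elfc <- dg$true_log2FC[match(cp$gene_id, dg$gene_id)]
            ok <- !is.na(mlfc) & !is.na(elfc) & sign(mlfc) == -sign(elfc)
            if (!all(ok))
                msg <- c(msg, "coupled pairs must have opposite-signed effects")
        }
    }
    if (length(msg)) msg else TRUE
})

#' FdrEstimate: result of the sex-based empirical FDR estimator
#'
#' Per random male/female set, the number of significant windows, the number
#' of those on autosomes, and their ratio; the summary estimate is the mean
#' ratio over sets with at least one significant window.
#'
#' @slot perSetFraction numeric; autosomal fraction per set (NA when a set
#'   had no significant windows).
#' @slot nSignificant,nAutosomal integer per set.
#' @slot sets list of character vectors of subject ids per set.
#' @slot ramSets list of `GRanges`, the significant windows per set.
#' @slot seed integer seed used to draw the sets.
#' @export
setClass("FdrEstimate",
    slots = c(perSetFraction = "numeric", nSignificant = "integer",
              nAutosomal = "integer", sets = "list", ramSets = "list",
              seed = "integer"))

setValidity("FdrEstimate", function(object) {
    f <- object@perSetFraction
    if (any(!is.na(f) & (f < 0 | f > 1)))
        return("per-set fractions must lie in [0, 1]")
    TRUE
})
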