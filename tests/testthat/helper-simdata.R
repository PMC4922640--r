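# Shared fixture builders (all generated in code; no stored data).

# WindowCounts with NB counts and synthetic non-overlapping windows
quickCounts <- function(W, mu = 50, phi = 0.1, nA = 6, nB = 6, seed = 1,
                        muB = mu) {
  set.seed(seed)
  counts <- cbind(
    matrix(rnbinom(W * nA, mu = mu, size = if (phi > 0) 1 / phi else Inf),
           W, nA),
    matrix(rnbinom(W * nB, mu = muB, size = if (phi > 0) 1 / phi else Inf),
           W, nB))
  if (phi == 0) {
    counts <- cbind(matrix(rpois(W * nA, mu), W, nA),
                    matrix(rpois(W * nB, muB), W, nB))
  }
  colnames(counts) <- sprintf("S%02d", seq_len(nA + nB))
  gs <- GenomeSpec("chr1", W * 100 + 200)
  windows <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = (seq_len(W) - 1L) * 100L + 1L, width = 100L))
  # constant library sizes: these windows stand for a subset of a much
  # larger genome, so a spiked fixture must not perturb normalisation
  WindowCounts(counts, windows,
               S4Vectors::DataFrame(lib_size = rep(1e6, nA + nB)))
}

twoGroupFactor <- function(nA = 6, nB = 6)
  factor(rep(c("a", "b"), c(nA, nB)), levels = c("a", "b"))

# a small complete world: genome + tracks + sheet + truth + counts
miniWorld <- function(seed = 1, nChroms = 3, chromLen = 2e5,
                      includeSexChroms = FALSE, nSpikes = 10,
                      log2FC = 2, comparison = "nd_vs_high",
                      depth = 3e5, dispersion = 0.1,
                      cgiEnrichmentFactor = 1, cgiDensity = 0,
                      sheet = NULL, truth = NULL, xFemaleFactor = 2,
                      yLeakage = 0) {
  sim <- simulateGenome(nChroms = nChroms, meanLengthBp = chromLen,
                        cgiDensity = cgiDensity, geneDensity = 0,
                        repeatFraction = 0, seed = seed,
                        includeSexChroms = includeSexChroms,
                        lengthJitter = 0)
  if (is.null(sheet)) sheet <- simulateSampleSheet(6, seed = seed + 1)
  if (is.null(truth) && nSpikes > 0)
    truth <- randomSpikeTruth(sim$genome, nSpikes = nSpikes,
                              log2FC = log2FC, comparison = comparison,
                              seed = seed + 2,
                              chroms = if (includeSexChroms)
                                autosomes(sim$genome) else NULL)
  reads <- simulateMethylationReads(sim$genome, sim$tracks, sheet,
      depthPerSample = depth, cgiEnrichmentFactor = cgiEnrichmentFactor,
      truth = truth, dispersion = dispersion, seed = seed + 3,
      xFemaleFactor = xFemaleFactor, yLeakage = yLeakage)
  cm <- countReads(tileWindows(sim$genome), reads, sampleData = sheet)
  list(genome = sim$genome, tracks = sim$tracks, sheet = sheet,
       truth = truth, reads = reads, cm = cm)
}

spikeKeys <- function(truth) {
  sw <- spikedWindows(truth)
  paste(sw$chrom, sw$start, sep = ":")
}

# 0-based window constructor and plain data-frame -> AnnotationTracks
# builders shared by the annotation tests
.win0 <- function(chrom, start0, width = 100L)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L,
                                                 width = width))

.mkGenes <- function(df, si = NULL) {
  GenomicRanges::GRanges(df$chrom,
    IRanges::IRanges(df$start + 1L, df$end), strand = df$strand,
    gene_id = df$gene_id, seqinfo = si)
}

.mkTracks <- function(genes0, exons0, repeats0, cgis0 = NULL) {
  emptyGr <- GenomicRanges::GRanges()
  genes <- if (nrow(genes0)) .mkGenes(genes0) else emptyGr
  exons <- GenomicRanges::GRangesList(lapply(
    split(exons0, exons0$gene_id), function(d)
      GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L,
                                                       d$end))))
  reps <- if (nrow(repeats0))
    GenomicRanges::GRanges(repeats0$chrom,
      IRanges::IRanges(repeats0$start + 1L, repeats0$end)) else emptyGr
  cgi <- if (!is.null(cgis0) && nrow(cgis0))
    GenomicRanges::GRanges(cgis0$chrom,
      IRanges::IRanges(cgis0$start + 1L, cgis0$end)) else emptyGr
  new("AnnotationTracks", cgi = cgi, repeats = reps, genes = genes,
      exons = exons)
}
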