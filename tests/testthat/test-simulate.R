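test_that("genome simulation is deterministic and validates parameters", {
  s1 <- simulateGenome(nChroms = 3, meanLengthBp = 5e4, seed = 1)
  s2 <- simulateGenome(nChroms = 3, meanLengthBp = 5e4, seed = 1)
  expect_identical(chromLengths(s1$genome), chromLengths(s2$genome))
  expect_identical(as.data.frame(cgiTrack(s1$tracks)),
                   as.data.frame(cgiTrack(s2$tracks)))
  expect_identical(as.data.frame(geneModels(s1$tracks)),
                   as.data.frame(geneModels(s2$tracks)))
  # repeatFraction = 0 gives an empty repeat track
  s3 <- simulateGenome(nChroms = 3, meanLengthBp = 5e4,
                       repeatFraction = 0, seed = 2)
  expect_equal(length(repeatTrack(s3$tracks)), 0L)
  expect_error(simulateGenome(meanLengthBp = 500), "meanLengthBp")
  expect_error(simulateGenome(cgiDensity = -1), "cgiDensity")
  expect_error(simulateGenome(repeatFraction = 1.5), "repeatFraction")
})

test_that("simulated tracks respect their structural invariants", {
  s <- simulateGenome(nChroms = 4, meanLengthBp = 3e5, cgiDensity = 5e-5,
                      geneDensity = 2e-5, repeatFraction = 0.2, seed = 9)
  cgi <- cgiTrack(s$tracks)
  # CGIs non-overlapping per chromosome
  expect_equal(length(GenomicRanges::reduce(cgi)), length(cgi))
  L <- chromLengths(s$genome)
  expect_true(all(GenomicRanges::end(cgi) <=
    L[as.character(GenomicRanges::seqnames(cgi))]))
  g <- geneModels(s$tracks)
  ex <- exonModels(s$tracks)
  expect_setequal(names(ex), g$gene_id)
  # first/last exon pinned to the gene ends => transcript extent = gene
  for (id in head(g$gene_id, 10)) {
    gr <- g[g$gene_id == id]
    expect_equal(min(GenomicRanges::start(ex[[id]])),
                 GenomicRanges::start(gr))
    expect_equal(max(GenomicRanges::end(ex[[id]])),
                 GenomicRanges::end(gr))
  }
})

test_that("CGI counts follow the stated Poisson distribution", {
  # density 5e-5 on a fixed 1 Mb chromosome: expectation 50 per seed
  n <- vapply(1:200, function(s)
    length(cgiTrack(simulateGenome(nChroms = 1, meanLengthBp = 1e6,
        cgiDensity = 5e-5, geneDensity = 0, repeatFraction = 0,
        seed = s, includeSexChroms = FALSE, lengthJitter = 0)$tracks)),
    integer(1))
  # total of 200 Poisson(50) draws inside its two-sided 99% interval
  expect_gt(sum(n), qpois(0.005, 200 * 50))
  expect_lt(sum(n), qpois(0.995, 200 * 50))
})

test_that("BPA trichotomization maps ranges, gaps and non-detects", {
  expect_equal(trichotomizeBpa(0.5), "non_detect")
  expect_equal(trichotomizeBpa(4.2), "low")
  expect_equal(trichotomizeBpa(50), "high")
  expect_equal(trichotomizeBpa(10.0), "unassigned")  # inter-group gap
  expect_equal(trichotomizeBpa(c(NA, 0.83, 2, 3.50, 5.79, 35.44, 96.76,
                                 200)),
               c("non_detect", "non_detect", "unassigned", "low", "low",
                 "high", "high", "unassigned"))
  expect_error(trichotomizeBpa(-1), ">= 0")
})

test_that("sample sheets are consistent with the trichotomization rule", {
  sheet <- simulateSampleSheet(6, seed = 4)
  expect_equal(nrow(sheet), 18L)
  expect_false(anyDuplicated(sheet$id) > 0)
  expect_identical(sheet$group, trichotomizeBpa(sheet$bpa_ng_per_g))
  expect_equal(unname(table(sheet$group)[c("non_detect", "low", "high")]),
               rep(6L, 3), ignore_attr = TRUE)
  expect_true(all(table(sheet$sex) >= 6))
})

test_that("read simulation honours sex structure and seed splitting", {
  s <- simulateGenome(nChroms = 4, meanLengthBp = 5e4, seed = 3,
                      includeSexChroms = TRUE, lengthJitter = 0)
  sheet <- simulateSampleSheet(4, seed = 5)
  reads <- simulateMethylationReads(s$genome, s$tracks, sheet,
      depthPerSample = 5e4, dispersion = 0.1, seed = 6)
  isF <- sheet$sex == "female"
  yCount <- vapply(reads, function(r)
    sum(as.character(GenomicRanges::seqnames(r)) == "chrY"), integer(1))
  xFrac <- vapply(reads, function(r)
    mean(as.character(GenomicRanges::seqnames(r)) == "chrX"), numeric(1))
  # females: zero Y-like reads at default leakage; X dosage about 2x
  expect_true(all(yCount[isF] == 0))
  expect_true(all(yCount[!isF] > 0))
  expect_gt(mean(xFrac[isF]), 1.5 * mean(xFrac[!isF]))
  # same seed, same reads; extending the sheet preserves earlier streams
  r2 <- simulateMethylationReads(s$genome, s$tracks, sheet,
      depthPerSample = 5e4, dispersion = 0.1, seed = 6)
  expect_identical(lapply(reads, as.data.frame), lapply(r2, as.data.frame))
  r3 <- simulateMethylationReads(s$genome, s$tracks,
      rbind(sheet, sheet[1, ]), depthPerSample = 5e4, dispersion = 0.1,
      seed = 6)
  expect_identical(as.data.frame(reads[[2]]), as.data.frame(r3[[2]]))
})

test_that("window counts from reads have the requested NB moments", {
  s <- simulateGenome(nChroms = 1, meanLengthBp = 2.1e5, cgiDensity = 0,
                      geneDensity = 0, repeatFraction = 0, seed = 1,
                      includeSexChroms = FALSE, lengthJitter = 0)
  sheet <- data.frame(id = "S1", sex = "male", bpa_ng_per_g = 50,
                      group = "high")
  w <- tileWindows(s$genome)
  odd <- seq(1, length(w), 2)  # non-overlapping subset
  # dispersion 0: Poisson, index of dispersion near 1 over 2000+ windows
  r0 <- simulateMethylationReads(s$genome, s$tracks, sheet,
      depthPerSample = 2.1e5, cgiEnrichmentFactor = 1, dispersion = 0,
      seed = 4)
  c0 <- SummarizedExperiment::assay(countReads(w, r0), "counts")[odd, 1]
  expect_gt(length(c0), 2000)
  expect_gt(var(c0) / mean(c0), 0.9)
  expect_lt(var(c0) / mean(c0), 1.1)
  # dispersion 0.1: moment-implied phi near 0.1
  r1 <- simulateMethylationReads(s$genome, s$tracks, sheet,
      depthPerSample = 2.1e5, cgiEnrichmentFactor = 1, dispersion = 0.1,
      seed = 4)
  c1 <- SummarizedExperiment::assay(countReads(w, r1), "counts")[odd, 1]
  phiHat <- (var(c1) - mean(c1)) / mean(c1)^2
  expect_gt(phiHat, 0.06)
  expect_lt(phiHat, 0.14)
})

test_that("spiked windows shift group means by the requested fold change", {
  # log2FC = 2 between groups: group mean ratio in [3.2, 5] at depth
  # giving window means >= 50, averaged over replicates
  s <- simulateGenome(nChroms = 1, meanLengthBp = 1e5, cgiDensity = 0,
                      geneDensity = 0, repeatFraction = 0, seed = 1,
                      includeSexChroms = FALSE, lengthJitter = 0)
  sheet <- simulateSampleSheet(6, seed = 2)
  truth <- randomSpikeTruth(s$genome, nSpikes = 4, log2FC = 2,
                            comparison = "nd_vs_high", seed = 3,
                            chroms = "chr1")
  sw <- spikedWindows(truth)
  wGr <- GenomicRanges::GRanges(sw$chrom,
      IRanges::IRanges(sw$start + 1L, sw$end))
  ratios <- vapply(1:8, function(rep) {
    reads <- simulateMethylationReads(s$genome, s$tracks, sheet,
        depthPerSample = 1.2e5, cgiEnrichmentFactor = 1, truth = truth,
        dispersion = 0.1, seed = 100 + rep)
    cm <- countReads(tileWindows(s$genome), reads, sampleData = sheet)
    hit <- GenomicRanges::match(wGr, GenomicRanges::granges(
      SummarizedExperiment::rowRanges(cm)))
    cc <- SummarizedExperiment::assay(cm, "counts")[hit, ]
    mean(cc[, sheet$group == "high"]) /
      mean(cc[, sheet$group == "non_detect"])
  }, numeric(1))
  expect_gt(mean(ratios), 3.2)
  expect_lt(mean(ratios), 5.0)
  # spiking outside the genome is a bounds error
  badTruth <- data.frame(chrom = "chr1", start = 99950, end = 100150,
                         true_log2FC = 2, comparison = "nd_vs_high")
  expect_error(TruthTable(spikedWindows = badTruth, genome = s$genome),
               "bounds")
})

test_that("expression counts realise truth effects and stay null otherwise", {
  sheet <- simulateSampleSheet(6, seed = 11)
  genes <- sprintf("g%03d", 1:1000)
  # empty truth: group log2 ratios rarely exceed +/- 0.5 (low-dispersion
  # regime, where sampling noise alone cannot mimic an effect)
  x0 <- simulateExpressionCounts(genes, sheet, NULL, baselineMean = 100,
                                 dispersion = 0.02, seed = 12)
  hi <- rowMeans(x0[, sheet$group == "high"])
  lo <- rowMeans(x0[, sheet$group == "non_detect"])
  expect_lt(mean(abs(log2(hi / lo)) > 0.5), 0.01)
  # coupled pair: hyper RAM, negative expression effect => mean decreases
  truth <- TruthTable(
    spikedWindows = data.frame(chrom = "chr1", start = 0, end = 100,
        true_log2FC = 2, comparison = "nd_vs_high"),
    deGenes = data.frame(gene_id = "g001", true_log2FC = -1.5,
        comparison = "nd_vs_high"),
    coupling = data.frame(chrom = "chr1", start = 0, gene_id = "g001"))
  x1 <- simulateExpressionCounts(genes, sheet, truth, baselineMean = 100,
                                 dispersion = 0.1, seed = 13)
  expect_lt(mean(x1["g001", sheet$group == "high"]),
            mean(x1["g001", sheet$group == "non_detect"]))
  # seed determinism; unknown gene id errors
  x2 <- simulateExpressionCounts(genes, sheet, truth, baselineMean = 100,
                                 dispersion = 0.1, seed = 13)
  expect_identical(x1, x2)
  badTruth <- TruthTable(deGenes = data.frame(gene_id = "nope",
      true_log2FC = 1, comparison = "nd_vs_high"))
  expect_error(simulateExpressionCounts(genes, sheet, badTruth,
                                        seed = 1), "unknown gene")
})

test_that("coupling validity demands opposite-signed effects", {
  expect_error(TruthTable(
    spikedWindows = data.frame(chrom = "chr1", start = 0, end = 100,
        true_log2FC = 2, comparison = "nd_vs_high"),
    deGenes = data.frame(gene_id = "g1", true_log2FC = 1.5,
        comparison = "nd_vs_high"),
    coupling = data.frame(chrom = "chr1", start = 0, gene_id = "g1")),
    "opposite")
})

test_that("truth tables round-trip through their TSV form", {
  truth <- TruthTable(
    spikedWindows = data.frame(chrom = c("chr1", "chr2"),
        start = c(100, 500), end = c(200, 600),
        true_log2FC = c(2, -2),
        comparison = c("nd_vs_high", "low_vs_high")),
    deGenes = data.frame(gene_id = "g1", true_log2FC = -1,
        comparison = "nd_vs_high"),
    coupling = data.frame(chrom = "chr1", start = 100, gene_id = "g1"))
  dir <- withr::local_tempdir()
  exportTruthTable(truth, dir)
  back <- importTruthTable(dir)
  expect_equal(spikedWindows(back), spikedWindows(truth))
  expect_equal(deGenes(back), deGenes(truth))
  expect_equal(couplingMap(back), couplingMap(truth))
})
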