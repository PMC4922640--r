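test_that("CGI context follows the shore/shelf distance bands", {
  cgi <- .win0("chr1", 10000, 500)  # CGI [10000, 10500)
  expect_equal(classifyCgiContext(.win0("chr1", 10600), cgi), "shore")
  expect_equal(classifyCgiContext(.win0("chr1", 13000), cgi), "shelf")
  expect_equal(classifyCgiContext(.win0("chr1", 60000), cgi), "open_sea")
  expect_equal(classifyCgiContext(.win0("chr1", 10200), cgi), "island")
  # overlap beats distance; band edges are inclusive
  expect_equal(classifyCgiContext(.win0("chr1", 10450), cgi), "island")
  expect_equal(classifyCgiContext(.win0("chr1", 12500), cgi), "shore")
  expect_equal(classifyCgiContext(.win0("chr1", 12501), cgi), "shelf")
  expect_equal(classifyCgiContext(.win0("chr1", 14500), cgi), "shelf")
  expect_equal(classifyCgiContext(.win0("chr1", 14501), cgi), "open_sea")
  # no CGI at all
  expect_equal(classifyCgiContext(.win0("chr1", 0),
                                  GenomicRanges::GRanges()), "open_sea")
})

test_that("nearest TSS uses window midpoints, signs and tie rules", {
  genes <- .mkGenes(data.frame(chrom = "chr1", start = 5000, end = 9000,
                               strand = "+", gene_id = "gA"))
  # midpoint 9950, TSS at 5000 (+): distance +4950, within 5 kb
  nt <- nearestTss(.win0("chr1", 9900), genes)
  expect_equal(nt$nearest_gene, "gA")
  expect_equal(nt$tss_distance, 4950)
  expect_true(nt$within_flag)
  # 50 kb away: not within
  nt2 <- nearestTss(.win0("chr1", 55000), genes)
  expect_false(nt2$within_flag)
  # minus-strand gene: TSS at its end, downstream is leftward
  genesM <- .mkGenes(data.frame(chrom = "chr1", start = 5000, end = 9000,
                                strand = "-", gene_id = "gB"))
  ntM <- nearestTss(.win0("chr1", 8000), genesM)
  # midpoint 8050, TSS0 8999, raw -949, minus strand: +949 (downstream)
  expect_equal(ntM$tss_distance, 949)
  # equidistant TSSs: lower coordinate wins
  two <- .mkGenes(data.frame(chrom = "chr1", start = c(1000, 2000),
                             end = c(1900, 2900), strand = "+",
                             gene_id = c("gLo", "gHi")))
  ntT <- nearestTss(.win0("chr1", 1450), two)  # midpoint 1500
  expect_equal(ntT$nearest_gene, "gLo")
  # co-located TSSs: lexicographically smaller id wins
  dup <- .mkGenes(data.frame(chrom = "chr1", start = c(1000, 1000),
                             end = c(1900, 2900), strand = "+",
                             gene_id = c("gZ", "gA")))
  expect_equal(nearestTss(.win0("chr1", 1200), dup)$nearest_gene, "gA")
  expect_error(nearestTss(.win0("chr1", 0), GenomicRanges::GRanges()),
               "gene models")
})

test_that("feature classes follow the promoter/TSR/genic definitions", {
  genes0 <- data.frame(chrom = "chr1", start = 10000, end = 14000,
                       strand = "+", gene_id = "gA")
  exons0 <- data.frame(chrom = "chr1", gene_id = "gA",
                       start = c(10000, 13000), end = c(11000, 14000))
  reps0 <- data.frame(chrom = "chr1", start = 20000, end = 20400)
  tr <- .mkTracks(genes0, exons0, reps0)
  # window [9600, 9700) lies inside the + promoter [9500, 10100)
  fc <- classifyFeatures(.win0("chr1", 9600), tr)
  expect_true(fc$promoter)
  expect_false(fc$gene_locus)
  expect_false(fc$intergenic)
  # window inside the intron [11000, 13000): gene_locus + intron
  fc2 <- classifyFeatures(.win0("chr1", 12000), tr)
  expect_true(fc2$gene_locus && fc2$intron)
  expect_false(fc2$exon || fc2$intergenic)
  # intergenic window overlapping a repeat
  fc3 <- classifyFeatures(.win0("chr1", 20100), tr)
  expect_true(fc3$intergenic && fc3$repeat_el)
  expect_false(fc3$gene_locus)
  # TSR: within +/- 50 bp of the TSS
  fc4 <- classifyFeatures(.win0("chr1", 10040, width = 10L), tr)
  expect_true(fc4$tsr)
})

test_that("random-instance classifications equal the brute-force oracle", {
  set.seed(71)
  for (rep in 1:60) {
    L <- 5000L
    nG <- sample(0:2, 1)
    genes0 <- if (nG == 0) data.frame(chrom = character(0),
        start = integer(0), end = integer(0), strand = character(0),
        gene_id = character(0)) else {
      s <- sort(sample(0:(L - 1500L), nG))
      data.frame(chrom = "c", start = s,
                 end = s + sample(600:1400, nG, TRUE),
                 strand = sample(c("+", "-"), nG, TRUE),
                 gene_id = paste0("g", seq_len(nG)))
    }
    exons0 <- if (nG == 0) data.frame(chrom = character(0),
        gene_id = character(0), start = integer(0), end = integer(0))
      else do.call(rbind, lapply(seq_len(nG), function(i) {
        w <- genes0$end[i] - genes0$start[i]
        cut <- sort(sample(seq_len(w - 1L), 2L))
        data.frame(chrom = "c", gene_id = genes0$gene_id[i],
                   start = genes0$start[i] + c(0L, cut[2]),
                   end = genes0$start[i] + c(cut[1], w))
      }))
    nR <- sample(0:3, 1)
    reps0 <- if (nR == 0) data.frame(chrom = character(0),
        start = integer(0), end = integer(0)) else {
      s <- sample(0:(L - 300L), nR)
      data.frame(chrom = "c", start = s, end = s + 200L)
    }
    nC <- sample(0:2, 1)
    cgis0 <- if (nC == 0) NULL else {
      s <- sort(sample(seq(0, L - 400L, by = 400L), nC))
      data.frame(chrom = "c", start = s, end = s + 300L)
    }
    tr <- .mkTracks(genes0, exons0, reps0, cgis0)
    ws0 <- sample(0:(L - 100L), 8)
    w <- .win0("c", ws0)
    fc <- classifyFeatures(w, tr)
    cg <- classifyCgiContext(w, cgiTrack(tr))
    for (i in seq_along(ws0)) {
      orc <- oracleFeatures(ws0[i], ws0[i] + 100L, genes0, exons0, reps0)
      got <- unlist(as.data.frame(fc[i, ]))
      expect_identical(unname(got[names(orc)]), unname(orc),
        label = paste("features rep", rep, "window", ws0[i]))
      expect_identical(cg[i], oracleCgiContext(ws0[i], ws0[i] + 100L,
          if (is.null(cgis0)) data.frame(start = integer(0),
                                         end = integer(0)) else cgis0),
        label = paste("cgi rep", rep, "window", ws0[i]))
    }
    # structural invariants
    expect_true(all(!(fc$intron & !fc$gene_locus)))
    expect_true(all(!(fc$intergenic & (fc$gene_locus | fc$promoter))))
    expect_true(all(cg %in% c("island", "shore", "shelf", "open_sea")))
  }
})

test_that("annotateWindows combines context, TSS and feature calls", {
  s <- simulateGenome(nChroms = 2, meanLengthBp = 1e5, cgiDensity = 5e-5,
                      geneDensity = 3e-5, repeatFraction = 0.2, seed = 5,
                      includeSexChroms = FALSE)
  w <- tileWindows(s$genome)[seq(1, 3000, 7)]
  a <- annotateWindows(w, s$tracks)
  expect_true(all(c("cgi_context", "nearest_gene", "tss_distance",
                    "within_5kb", "promoter", "repeat_el") %in%
                  colnames(S4Vectors::mcols(a))))
  expect_true(all(a$within_5kb == (!is.na(a$tss_distance) &
                                   abs(a$tss_distance) <= 5000)))
})

test_that("chromosome distribution normalises by length", {
  gs <- GenomeSpec(c("chr1", "chr2"), c(2e6, 4e6))
  rams <- GenomicRanges::GRanges(rep("chr1", 10),
      IRanges::IRanges(seq(1, by = 5000, length.out = 10), width = 100))
  rams$direction <- rep("hyper", 10)
  d <- chromDistribution(rams, gs)
  expect_equal(d$hyper_per_mb[d$chrom == "chr1"], 5.0)
  expect_equal(d$hypo_per_mb, c(0, 0))
  # doubling the length halves the density
  gs2 <- GenomeSpec(c("chr1", "chr2"), c(4e6, 4e6))
  d2 <- chromDistribution(rams, gs2)
  expect_equal(d2$hyper_per_mb[1], d$hyper_per_mb[1] / 2)
  # empty input gives zeros; unknown chromosome errors
  d0 <- chromDistribution(rams[0], gs)
  expect_true(all(d0$hyper_per_mb == 0))
  ramsBad <- GenomicRanges::GRanges("chrZZ", IRanges::IRanges(1, 100))
  ramsBad$direction <- "hyper"
  expect_error(chromDistribution(ramsBad, gs), "chrZZ")
})

test_that("set accounting reproduces every Venn cell", {
  out <- overlapSets(list(A = c("w1", "w2"), B = c("w2", "w3"),
                          C = "w3"))
  expect_equal(out$pooled_total, 5L)
  expect_equal(out$union, 3L)
  expect_equal(out$exactly_one, 1L)
  expect_equal(out$intersections[["A&B"]], 1L)
  expect_equal(out$intersections[["B&C"]], 1L)
  expect_equal(out$intersections[["A&C"]], 0L)
  expect_equal(out$intersections[["A&B&C"]], 0L)
  # identical sets: nothing exclusive
  s <- c("a", "b", "c")
  expect_equal(overlapSets(list(s, s, s))$exactly_one, 0L)
  # disjoint sets: exactly-one = union = pooled total
  dis <- overlapSets(list(A = "x", B = "y", C = "z"))
  expect_equal(dis$exactly_one, 3L)
  expect_equal(dis$union, 3L)
  expect_equal(dis$pooled_total, 3L)
  # random agreement with the enumeration oracle
  set.seed(5)
  for (i in 1:20) {
    sets <- lapply(1:3, function(j)
      sample(paste0("w", 1:30), sample(5:20, 1)))
    mine <- overlapSets(sets)
    orc <- oracleVenn(lapply(sets, unique))
    expect_equal(mine$pooled_total, orc$pooled_total)
    expect_equal(mine$union, orc$union)
    expect_equal(mine$exactly_one, orc$exactly_one)
  }
})
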