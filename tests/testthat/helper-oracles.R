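# Independent brute-force oracles used to validate the fast implementations.
# All oracle coordinates are 0-based half-open, as in BED.

# interval-membership read counting: read with start p increments every
# window with start <= p < end
oracleCountReads <- function(windows0, positions0) {
  vapply(seq_len(nrow(windows0)), function(i) {
    sum(positions0$chrom == windows0$chrom[i] &
        positions0$pos >= windows0$start[i] &
        positions0$pos < windows0$end[i])
  }, numeric(1))
}

# gap (bp) between half-open intervals; 0 when they touch or overlap
.gap0 <- function(s1, e1, s2, e2) {
  if (e1 <= s2) return(s2 - e1)
  if (e2 <= s1) return(s1 - e2)
  0L
}

oracleCgiContext <- function(ws, we, cgis0) {
  if (nrow(cgis0) == 0L) return("open_sea")
  over <- any(cgis0$start < we & ws < cgis0$end)
  if (over) return("island")
  d <- min(vapply(seq_len(nrow(cgis0)), function(i)
    .gap0(ws, we, cgis0$start[i], cgis0$end[i]), numeric(1)))
  if (d <= 2000) "shore" else if (d <= 4000) "shelf" else "open_sea"
}

# feature classes for one window against plain data-frame tracks
oracleFeatures <- function(ws, we, genes0, exons0, repeats0) {
  overlaps <- function(df) nrow(df) > 0 &&
    any(df$start < we & ws < df$end)
  gene_locus <- overlaps(genes0)
  prom <- if (nrow(genes0) == 0L) genes0 else do.call(rbind,
    lapply(seq_len(nrow(genes0)), function(i) {
      tss <- if (genes0$strand[i] == "+") genes0$start[i] else
        genes0$end[i] - 1L
      if (genes0$strand[i] == "+")
        data.frame(start = tss - 500L, end = tss + 100L)
      else data.frame(start = tss - 100L, end = tss + 500L)
    }))
  tsr <- if (nrow(genes0) == 0L) genes0 else do.call(rbind,
    lapply(seq_len(nrow(genes0)), function(i) {
      tss <- if (genes0$strand[i] == "+") genes0$start[i] else
        genes0$end[i] - 1L
      data.frame(start = tss - 50L, end = tss + 51L)
    }))
  promoter <- overlaps(prom)
  tsrF <- overlaps(tsr)
  exon <- overlaps(exons0)
  # intronic space: per-base membership in a gene but not in an exon
  intron <- FALSE
  if (gene_locus) {
    for (b in ws:(we - 1L)) {
      inG <- any(genes0$start <= b & b < genes0$end)
      inE <- nrow(exons0) > 0 && any(exons0$start <= b & b < exons0$end)
      if (inG && !inE) { intron <- TRUE; break }
    }
  }
  c(tsr = tsrF, promoter = promoter, exon = exon, intron = intron,
    gene_locus = gene_locus,
    intergenic = !(gene_locus | promoter | tsrF),
    repeat_el = overlaps(repeats0))
}

# exact conditional NB test by direct enumeration with dnbinom at an
# arbitrary mean (the mean cancels in the conditional distribution)
oracleExactTest <- function(sA, sB, nA, nB, phi, rule = "doubling",
                            mu = 7.3) {
  t <- sA + sB
  if (t == 0) return(1)
  a <- 0:t
  if (phi == 0) {
    w <- dbinom(a, t, nA / (nA + nB))
  } else {
    w <- dnbinom(a, size = nA / phi, mu = nA * mu) *
         dnbinom(t - a, size = nB / phi, mu = nB * mu)
    w <- w / sum(w)
  }
  lower <- sum(w[a <= sA])
  upper <- sum(w[a >= sA])
  if (rule == "doubling") min(1, 2 * min(lower, upper))
  else min(1, sum(w[w <= w[sA + 1] * (1 + 1e-10)]))
}

oracleVenn <- function(sets) {
  ids <- unique(unlist(sets))
  memb <- sapply(sets, function(s) ids %in% s)
  if (length(ids) == 1L) memb <- matrix(memb, nrow = 1L)
  list(pooled_total = sum(lengths(lapply(sets, unique))),
       union = length(ids),
       exactly_one = sum(rowSums(memb) == 1L))
}
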