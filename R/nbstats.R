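## Negative-binomial two-group machinery: library-size normalisation,
## conditional-likelihood common dispersion, weighted-likelihood tagwise
## (moderated) dispersion, exact test, BH adjustment.

.DISP_RANGE <- c(1e-6, 10)

.countsOf <- function(x) {
    if (is(x, "WindowCounts")) SummarizedExperiment::assay(x, "counts")
    else as.matrix(x)
}

.libSizesOf <- function(x, libSizes = NULL) {
    if (!is.null(libSizes)) return(libSizes)
    if (is(x, "WindowCounts")) libSizes(x) else colSums(as.matrix(x))
}

#' Per-sample normalisation factors
#'
#' `libsize` returns unit factors so that effective library sizes equal the
#' raw library sizes; `tmm` computes trimmed-mean-of-M-values factors
#' (30% trim on M, 5% on A, reference sample chosen by upper quartile),
#' scaled to geometric mean 1. Effective library sizes are
#' `lib_size * factor`.
#'
#' @param x a [WindowCounts-class] or a count matrix.
#' @param method `"libsize"` or `"tmm"`.
#' @param libSizes optional library sizes when `x` is a bare matrix.
#' @return Named numeric vector of factors.
#' @export
normFactors <- function(x, method = c("libsize", "tmm"), libSizes = NULL) {
    method <- match.arg(method)
    counts <- .countsOf(x)
    ls <- .libSizesOf(x, libSizes)
    zero <- colSums(counts) == 0
    if (any(zero))
        stop("all-zero sample(s): ",
             paste(colnames(counts)[zero], collapse = ", "))
    f <- if (method == "libsize") rep(1, ncol(counts))
         else edgeR::calcNormFactors(counts, lib.size = ls, method = "TMM")
    setNames(f, colnames(counts))
}

#' Effective library sizes
#'
#' @inheritParams normFactors
#' @return `lib_size * normFactors(x, method)` per sample.
#' @export
effectiveLibSizes <- function(x, method = c("libsize", "tmm"),
                              libSizes = NULL) {
    .libSizesOf(x, libSizes) * normFactors(x, method, libSizes)
}

# linear equalisation of all samples to the geometric-mean effective size
.pseudoCounts <- function(counts, effLibSizes) {
    gm <- exp(mean(log(effLibSizes)))
    sweep(counts, 2L, gm / effLibSizes, `*`)
}

.checkGroups <- function(groups, n) {
    groups <- as.factor(groups)
    if (length(groups) != n)
        stop("groups must have one entry per sample")
    groups <- droplevels(groups)
    if (nlevels(groups) != 2L)
        stop("exactly two groups are required")
    groups
}

# per-window NB conditional log-likelihood on equalised counts;
# phi is a scalar or a per-window vector
.condLogLik <- function(y, groups, phi) {
    r <- 1 / phi
    ll <- numeric(nrow(y))
    for (g in levels(groups)) {
        idx <- which(groups == g)
        n <- length(idx)
        if (n < 2L) next  # singleton groups carry no conditional information
        yg <- y[, idx, drop = FALSE]
        s <- rowSums(yg)
        ll <- ll + rowSums(lgamma(yg + r)) - n * lgamma(r) +
            lgamma(n * r) - lgamma(s + n * r)
    }
    ll
}

.dispGrid <- function(n = 121L)
    exp(seq(log(.DISP_RANGE[1]), log(.DISP_RANGE[2]), length.out = n))

# spline of the mean (over windows) conditional log-likelihood on a dense
# log-phi grid; shared between the common and tagwise estimators so the
# infinite-shrinkage limit of the tagwise estimate is the common estimate
.meanCondLLSpline <- function(y, groups) {
    grid <- .dispGrid()
    mll <- vapply(grid, function(phi) mean(.condLogLik(y, groups, phi)),
                  numeric(1))
    stats::splinefun(log(grid), mll)
}

# vectorised golden-section maximisation on log-phi over .DISP_RANGE;
# fn takes a phi vector (length W) and returns objective values (length W)
.goldenMaxVec <- function(fn, W, iter = 60L) {
    gr <- (sqrt(5) - 1) / 2
    a <- rep(log(.DISP_RANGE[1]), W)
    b <- rep(log(.DISP_RANGE[2]), W)
    x1 <- b - gr * (b - a)
    x2 <- a + gr * (b - a)
    f1 <- fn(exp(x1))
    f2 <- fn(exp(x2))
    for (k in seq_len(iter)) {
        up <- f1 < f2  # maximum lies right of x1
        a[up] <- x1[up]; x1[up] <- x2[up]; f1[up] <- f2[up]
        x2[up] <- a[up] + gr * (b[up] - a[up])
        dn <- !up
        b[dn] <- x2[dn]; x2[dn] <- x1[dn]; f2[dn] <- f1[dn]
        x1[dn] <- b[dn] - gr * (b[dn] - a[dn])
        xnew <- ifelse(up, x2, x1)
        fnew <- fn(exp(xnew))
        f2[up] <- fnew[up]
        f1[dn] <- fnew[dn]
    }
    exp((a + b) / 2)
}

.requireReplication <- function(groups) {
    if (!any(table(groups) >= 2L))
        stop("no replication in any group: dispersion cannot be estimated; ",
             "run the exact test with a fixed phi instead")
}

#' Common NB dispersion by conditional maximum likelihood
#'
#' Counts are equalised to the geometric-mean effective library size and the
#' summed per-window conditional log-likelihood is maximised over
#' `phi` in `[1e-6, 10]` (golden-section search on log phi against a dense
#' spline of the likelihood profile).
#'
#' @param x a [WindowCounts-class] or count matrix.
#' @param groups two-level factor over samples (lower-dose level first).
#' @param effLibSizes effective library sizes; defaults to raw library sizes.
#' @return Scalar dispersion estimate.
#' @export
estimateCommonDispersion <- function(x, groups, effLibSizes = NULL) {
    counts <- .countsOf(x)
    groups <- .checkGroups(groups, ncol(counts))
    .requireReplication(groups)
    if (is.null(effLibSizes)) effLibSizes <- .libSizesOf(x)
    y <- .pseudoCounts(counts, effLibSizes)
    sp <- .meanCondLLSpline(y, groups)
    .goldenMaxVec(function(phi) sp(log(phi)), 1L)
}

#' Tagwise (moderated) NB dispersion
#'
#' Per-window weighted-likelihood estimate: each window's conditional
#' log-likelihood is augmented with `priorDf` times the mean per-window
#' log-likelihood of the whole data set, and maximised over the same
#' bounded range as the common estimator. As `priorDf` grows the estimates
#' shrink onto the common dispersion.
#'
#' @inheritParams estimateCommonDispersion
#' @param priorDf shrinkage weight (prior degrees of freedom), default 10.
#' @return Numeric vector of per-window dispersions.
#' @export
estimateTagwiseDispersion <- function(x, groups, effLibSizes = NULL,
                                      priorDf = 10) {
    stopifnot(priorDf > 0)
    counts <- .countsOf(x)
    groups <- .checkGroups(groups, ncol(counts))
    .requireReplication(groups)
    if (is.null(effLibSizes)) effLibSizes <- .libSizesOf(x)
    y <- .pseudoCounts(counts, effLibSizes)
    sp <- .meanCondLLSpline(y, groups)
    fn <- function(phi) .condLogLik(y, groups, phi) + priorDf * sp(log(phi))
    .goldenMaxVec(fn, nrow(y))
}

# exact conditional two-group NB test for one window, given integer group
# sums; the NB probability parameter cancels so only phi and the group
# sizes enter. Returns the two-sided p-value.
.exactPvalSums <- function(sA, sB, nA, nB, phi,
                           rule = c("doubling", "minlik")) {
    rule <- match.arg(rule)
    t <- sA + sB
    if (t == 0L) return(1)
    a <- 0:t
    if (phi < 1e-12) {
        lw <- stats::dbinom(a, t, nA / (nA + nB), log = TRUE)
    } else {
        rA <- nA / phi
        rB <- nB / phi
        lw <- lgamma(a + rA) - lgamma(a + 1) +
              lgamma(t - a + rB) - lgamma(t - a + 1)
    }
    w <- exp(lw - max(lw))
    w <- w / sum(w)
    cw <- cumsum(w)
    lowerP <- cw[sA + 1L]
    upperP <- if (sA == 0L) 1 else 1 - cw[sA]
    if (rule == "doubling") {
        min(1, 2 * min(lowerP, upperP))
    } else {
        min(1, sum(w[w <= w[sA + 1L] * (1 + 1e-10)]))
    }
}

.condWeights <- function(t, nA, nB, phi) {
    a <- 0:t
    if (phi < 1e-12) {
        lw <- stats::dbinom(a, t, nA / (nA + nB), log = TRUE)
    } else {
        rA <- nA / phi
        rB <- nB / phi
        lw <- lgamma(a + rA) - lgamma(a + 1) +
              lgamma(t - a + rB) - lgamma(t - a + 1)
    }
    w <- exp(lw - max(lw))
    w / sum(w)
}

# probability that the two-sided p-value (computed under phiTest, the
# dispersion the pipeline plugged into the test) falls below alpha, when
# the group split is truly distributed with dispersion phiTrue. Used for
# analytic false-positive expectations on null data.
.exactRejectionProb <- function(t, nA, nB, phiTest, alpha,
                                rule = c("doubling", "minlik"),
                                phiTrue = phiTest) {
    rule <- match.arg(rule)
    if (t == 0L) return(0)
    w <- .condWeights(t, nA, nB, phiTest)
    cw <- cumsum(w)
    lowerP <- cw
    upperP <- 1 - c(0, cw[-length(cw)])
    p <- if (rule == "doubling") pmin(1, 2 * pmin(lowerP, upperP))
         else vapply(seq_along(w),
                     function(i) min(1, sum(w[w <= w[i] * (1 + 1e-10)])),
                     numeric(1))
    wTrue <- if (phiTrue == phiTest) w else .condWeights(t, nA, nB, phiTrue)
    sum(wTrue[p < alpha])
}

#' Exact two-group negative-binomial test
#'
#' Counts are equalised to the geometric-mean effective library size, summed
#' within group and rounded; the p-value is the two-sided conditional
#' probability of group splits as or more extreme than observed given the
#' total, under NB dispersion `phi` (binomial when `phi = 0`). The default
#' two-sided rule doubles the smaller tail (capped at 1); `"minlik"` sums
#' the probabilities of splits no more likely than the observed one.
#'
#' @param countsA,countsB count vectors (one window) or matrices
#'   (windows x samples) for the two groups.
#' @param phi NB dispersion, scalar or per-window vector.
#' @param libSizesA,libSizesB effective library sizes per sample; default
#'   equal sizes (no equalisation).
#' @param rule two-sided rule, `"doubling"` (default) or `"minlik"`.
#' @return Vector of p-values in (0, 1].
#' @export
nbExactTest <- function(countsA, countsB, phi,
                        libSizesA = NULL, libSizesB = NULL,
                        rule = c("doubling", "minlik")) {
    rule <- match.arg(rule)
    if (is.vector(countsA)) countsA <- matrix(countsA, nrow = 1L)
    if (is.vector(countsB)) countsB <- matrix(countsB, nrow = 1L)
    if (any(countsA < 0) || any(countsB < 0))
        stop("counts must be non-negative")
    if (any(phi < 0)) stop("phi must be >= 0")
    nA <- ncol(countsA)
    nB <- ncol(countsB)
    if (!is.null(libSizesA) || !is.null(libSizesB)) {
        ls <- c(libSizesA, libSizesB)
        stopifnot(length(ls) == nA + nB, all(ls > 0))
        y <- .pseudoCounts(cbind(countsA, countsB), ls)
        countsA <- y[, seq_len(nA), drop = FALSE]
        countsB <- y[, nA + seq_len(nB), drop = FALSE]
    }
    sA <- round(rowSums(countsA))
    sB <- round(rowSums(countsB))
    phi <- rep_len(phi, length(sA))
    vapply(seq_along(sA), function(i)
        .exactPvalSums(sA[i], sB[i], nA, nB, phi[i], rule), numeric(1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH q-values with monotone enforcement; input order is preserved
#' and the result is stable under permutation of the input.
#'
#' @param p p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
bhAdjust <- function(p) {
    if (length(p) == 0L) return(numeric(0))
    if (any(!is.finite(p)) || any(p <= 0 | p > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Per-window two-group differential test
#'
#' The full testing branch for one comparison: normalisation factors,
#' common and tagwise dispersion, exact NB test, BH adjustment, log2
#' fold-change (higher-dose group over lower-dose group, 0.5 pseudo-count)
#' and hyper/hypo direction of the higher-dose group.
#'
#' @param cm a [WindowCounts-class].
#' @param groups two-level factor over the samples of `cm`; the FIRST level
#'   is the lower-dose group, the SECOND the higher-dose group. Samples with
#'   `NA` are ignored.
#' @param config a [ramConfig()] list (normalisation method, prior df,
#'   two-sided rule).
#' @return A `GRanges` parallel to the windows of `cm` with mcols `log2FC`,
#'   `pvalue`, `qvalue`, `direction` (`"hyper"`/`"hypo"`) and `phi`.
#' @export
testWindows <- function(cm, groups, config = ramConfig()) {
    stopifnot(is(cm, "WindowCounts"))
    groups <- as.factor(groups)
    keep <- !is.na(groups)
    cm <- cm[, keep]
    groups <- .checkGroups(groups[keep], ncol(cm))
    counts <- SummarizedExperiment::assay(cm, "counts")
    eff <- effectiveLibSizes(cm, config$normalization)
    y <- .pseudoCounts(counts, eff)
    phiC <- estimateCommonDispersion(cm, groups, effLibSizes = eff)
    phiT <- estimateTagwiseDispersion(cm, groups, effLibSizes = eff,
                                      priorDf = config$prior_df)
    A <- groups == levels(groups)[1L]
    B <- !A
    sA <- round(rowSums(y[, A, drop = FALSE]))
    sB <- round(rowSums(y[, B, drop = FALSE]))
    nA <- sum(A)
    nB <- sum(B)
    p <- vapply(seq_along(sA), function(i)
        .exactPvalSums(sA[i], sB[i], nA, nB, phiT[i],
                       config$two_sided_rule), numeric(1))
    res <- GenomicRanges::granges(SummarizedExperiment::rowRanges(cm))
    res$window_id <- SummarizedExperiment::rowRanges(cm)$window_id
    res$log2FC <- log2((sB + 0.5) / nB) - log2((sA + 0.5) / nA)
    res$pvalue <- p
    res$qvalue <- bhAdjust(p)
    res$direction <- ifelse(res$log2FC > 0, "hyper", "hypo")
    res$phi <- phiT
    S4Vectors::metadata(res)$phi_common <- phiC
    S4Vectors::metadata(res)$groups <- levels(groups)
    res
}
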