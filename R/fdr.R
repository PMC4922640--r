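## Sex-based empirical FDR: rerun the full calling pipeline on random
## male-versus-female subsets and treat autosomal hits as false positives.

#' Empirical FDR from male-versus-female contrasts
#'
#' Draws `nSets` random subsets of `nPerSide` males and `nPerSide` females
#' (without replacement within a set; sets are drawn independently), runs
#' the complete calling pipeline on each with the supplied configuration,
#' and records the fraction of significant windows that are autosomal.
#' Because X/Y methylation differs structurally between the sexes, X/Y hits
#' are presumed true and autosomal hits presumed false, so the mean fraction
#' is an upper bound on the pipeline's FDR (to the extent that no true
#' autosomal sex differences exist).
#'
#' @param cm a [WindowCounts-class] over all samples.
#' @param sampleSheet data.frame/`DataFrame` with columns `id` and `sex`
#'   matching the columns of `cm`.
#' @param genome the [GenomeSpec-class] with sex-chromosome flags.
#' @param nPerSide males and females per set (default 6).
#' @param nSets number of random sets (default 8).
#' @param seed integer seed; the same seed reproduces the same subject sets.
#' @param config the same [ramConfig()] used for the exposure contrasts.
#' @return A [FdrEstimate-class].
#' @export
sexBasedFdr <- function(cm, sampleSheet, genome, nPerSide = 6L, nSets = 8L,
                        seed = 1L, config = ramConfig()) {
    stopifnot(is(cm, "WindowCounts"), is(genome, "GenomeSpec"))
    sampleSheet <- as.data.frame(sampleSheet)
    ids <- if ("id" %in% names(sampleSheet)) sampleSheet$id
           else rownames(sampleSheet)
    males <- ids[sampleSheet$sex == "male"]
    females <- ids[sampleSheet$sex == "female"]
    if (length(males) < nPerSide || length(females) < nPerSide)
        stop("need at least ", nPerSide, " of each sex; have ",
             length(males), " male(s) and ", length(females), " female(s)")
    auto <- autosomes(genome)
    if (length(auto) == length(chromNames(genome)))
        stop("genome has no flagged sex chromosomes")

    set.seed(as.integer(seed))
    setSeeds <- sample.int(.Machine$integer.max, nSets)
    sets <- vector("list", nSets)
    ramSets <- vector("list", nSets)
    nSig <- integer(nSets)
    nAuto <- integer(nSets)
    for (k in seq_len(nSets)) {
        set.seed(setSeeds[k])
        subj <- c(sample(males, nPerSide), sample(females, nPerSide))
        sets[[k]] <- subj
        sub <- cm[, match(subj, colnames(cm))]
        sheet <- sampleSheet[match(subj, ids), , drop = FALSE]
        groups <- comparisonGroups(sheet, "female_vs_male")
        rams <- callRams(sub, groups, comparison = "female_vs_male", config)
        ramSets[[k]] <- rams
        nSig[k] <- length(rams)
        nAuto[k] <- sum(as.character(GenomicRanges::seqnames(rams)) %in% auto)
    }
    frac <- ifelse(nSig > 0L, nAuto / nSig, NA_real_)
    if (anyNA(frac))
        warning(sum(is.na(frac)),
                " set(s) had no significant windows and are excluded ",
                "from the mean")
    new("FdrEstimate", perSetFraction = frac, nSignificant = nSig,
        nAutosomal = nAuto, sets = sets, ramSets = ramSets,
        seed = as.integer(seed))
}

#' @describeIn FdrEstimate mean autosomal fraction over sets with at least
#'   one significant window.
#' @param x a `FdrEstimate`.
#' @export
setMethod("meanFdr", "FdrEstimate",
    function(x) mean(x@perSetFraction, na.rm = TRUE))

#' @describeIn FdrEstimate per-set autosomal fractions (NA when undefined).
#' @export
setMethod("perSetFractions", "FdrEstimate",
    function(x) x@perSetFraction)

setMethod("show", "FdrEstimate", function(object) {
    cat("FdrEstimate over", length(object@perSetFraction), "set(s)\n")
    cat("  significant per set:",
        paste(object@nSignificant, collapse = " "), "\n")
    cat("  autosomal per set:  ",
        paste(object@nAutosomal, collapse = " "), "\n")
    cat(sprintf("  mean autosomal fraction (empirical FDR bound): %.3f\n",
                meanFdr(object)))
})

#' Tabulate an FdrEstimate
#'
#' @param x a [FdrEstimate-class].
#' @return data.frame with one row per set: subjects, counts and fraction.
#' @export
fdrReport <- function(x) {
    stopifnot(is(x, "FdrEstimate"))
    data.frame(set_id = seq_along(x@perSetFraction),
               subjects = vapply(x@sets, paste, character(1), collapse = ","),
               n_significant = x@nSignificant,
               n_autosomal = x@nAutosomal,
               fraction = x@perSetFraction)
}
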