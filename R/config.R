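#' Pipeline configuration
#'
#' One object holding every tunable of the calling pipeline, so the same
#' settings used for the exposure contrasts are reused verbatim by the
#' sex-based empirical-FDR estimator.
#'
#' @param alpha significance threshold on the nominal p-value (or q-value
#'   when `use_q = TRUE`) for candidate windows.
#' @param use_q threshold on BH q-values instead of nominal p-values.
#' @param min_samples,min_count coverage filter: windows kept when more than
#'   `min_count` reads are seen in at least `min_samples` samples.
#' @param min_fraction consistency filter: required fraction of per-group
#'   samples whose normalised count moves with the group-level direction.
#' @param flank_alpha significance threshold for the flanking-window branch
#'   of the neighbourhood filter.
#' @param stretch_bp window starts within this distance count as "within a
#'   stretch" for the second branch of the neighbourhood filter.
#' @param step window shift size (bp) used to locate flanking windows.
#' @param normalization `"libsize"` (default for methylation windows) or
#'   `"tmm"` (default for RNA-seq).
#' @param prior_df shrinkage weight of the tagwise dispersion estimator.
#' @param two_sided_rule `"doubling"` or `"minlik"`.
#' @param apply_consistency,apply_flanking switch the two post-filters.
#' @return A named list of class `RamConfig`.
#' @export
ramConfig <- function(alpha = 0.001, use_q = FALSE,
                      min_samples = 3L, min_count = 20L,
                      min_fraction = 0.5, flank_alpha = 0.05,
                      stretch_bp = 500L, step = 50L,
                      normalization = c("libsize", "tmm"),
                      prior_df = 10, two_sided_rule = c("doubling", "minlik"),
                      apply_consistency = TRUE, apply_flanking = TRUE) {
    stopifnot(alpha > 0, alpha < 1, min_fraction >= 0, min_fraction <= 1,
              flank_alpha > 0, stretch_bp > 0, prior_df > 0)
    structure(list(alpha = alpha, use_q = use_q,
                   min_samples = as.integer(min_samples),
                   min_count = as.integer(min_count),
                   min_fraction = min_fraction, flank_alpha = flank_alpha,
                   stretch_bp = as.integer(stretch_bp),
                   step = as.integer(step),
                   normalization = match.arg(normalization),
                   prior_df = prior_df,
                   two_sided_rule = match.arg(two_sided_rule),
                   apply_consistency = isTRUE(apply_consistency),
                   apply_flanking = isTRUE(apply_flanking)),
              class = "RamConfig")
}

#' @export
print.RamConfig <- function(x, ...) {
    cat("RamConfig:\n")
    for (nm in names(x)) cat("  ", nm, "=", format(x[[nm]]), "\n")
    invisible(x)
}

.COMPARISONS <- list(
    nd_vs_low = c("non_detect", "low"),
    nd_vs_high = c("non_detect", "high"),
    low_vs_high = c("low", "high"),
    female_vs_male = c("female", "male"))

#' Group factor for a named comparison
#'
#' Maps a sample sheet onto the two-level factor expected by
#' [testWindows()]: the first level is the lower-dose group and the second
#' the higher-dose group. `female_vs_male` draws on the `sex` column and is
#' used by the sex-based FDR estimator.
#'
#' @param sampleSheet data.frame/`DataFrame` with columns `group` and `sex`.
#' @param comparison one of `"nd_vs_low"`, `"nd_vs_high"`, `"low_vs_high"`,
#'   `"female_vs_male"`.
#' @return Factor over samples with two ordered levels; samples outside the
#'   comparison are `NA`.
#' @export
comparisonGroups <- function(sampleSheet,
                             comparison = names(.COMPARISONS)) {
    comparison <- match.arg(comparison)
    lv <- .COMPARISONS[[comparison]]
    src <- if (comparison == "female_vs_male") sampleSheet$sex
           else sampleSheet$group
    factor(ifelse(src %in% lv, as.character(src), NA), levels = lv)
}
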