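#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

#' TrialCohort: genotypes, covariates and repeated phenotype measures
#'
#' `TrialCohort` extends [SummarizedExperiment::RangedSummarizedExperiment]
#' with one assay, `"dosage"` (variants in rows, subjects in columns, values
#' in \[0, 2\]), variant metadata on `rowRanges()` (`ref`, `alt`,
#' `imputation_r2`), subject covariates in `colData()` (at minimum
#' `baseline_age_years` and `sex`), and a long-format table of repeated
#' test scores in the `phenotypes` slot with columns `subject_id`,
#' `time_days`, `test_id` and `score`.
#'
#' Validity requires every dosage to lie in \[0, 2\] (missing allowed),
#' every phenotyped subject to be a column of the assay and to have a
#' baseline (`time_days == 0`) row, and `(subject_id, time_days, test_id)`
#' keys to be unique.
#'
#' @slot phenotypes A [S4Vectors::DataFrame] of long-format scores.
#'
#' @seealso [TrialCohort()] for construction, [simulateCohort()] to
#'   generate one, [dosages()], [covariates()], [phenotypes()],
#'   [variantMeta()].
#' @export
setClass("TrialCohort",
    contains = "RangedSummarizedExperiment",
    representation(phenotypes = "DataFrame")
)

setValidity("TrialCohort", function(object) {
    msg <- character()
    if (!"dosage" %in% assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- assay(object, "dosage")
        rng <- suppressWarnings(range(d, na.rm = TRUE))
        if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
            msg <- c(msg, "dosages must lie in [0, 2]")
    }
    ph <- object@phenotypes
    if (nrow(ph) > 0) {
        need <- c("subject_id", "time_days", "test_id", "score")
        if (!all(need %in% colnames(ph)))
            msg <- c(msg, paste("phenotypes must have columns",
                                paste(need, collapse = ", ")))
        else {
            if (any(ph$time_days < 0))
                msg <- c(msg, "phenotype time_days must be >= 0")
            bad <- setdiff(unique(ph$subject_id), colnames(object))
            if (length(bad))
                msg <- c(msg, paste0("phenotyped subjects absent from assay: ",
                                     paste(head(bad, 3L), collapse = ", ")))
            base <- unique(ph$subject_id[ph$time_days == 0])
            nob <- setdiff(unique(ph$subject_id), base)
            if (length(nob))
                msg <- c(msg, paste0("subjects without a baseline row: ",
                                     paste(head(nob, 3L), collapse = ", ")))
            key <- paste(ph$subject_id, ph$time_days, ph$test_id, sep = "\r")
            if (anyDuplicated(key))
                msg <- c(msg, "duplicated (subject, time, test) phenotype keys")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TrialCohort
#'
#' @param dosages Numeric matrix, variants x subjects, entries in \[0, 2\]
#'   (`NA` for missing calls). Row names are variant ids, column names
#'   subject ids.
#' @param variantMeta A `data.frame` with one row per variant and columns
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `imputation_r2`.
#' @param covariates A `data.frame` with one row per subject; must contain
#'   `baseline_age_years` and `sex` (0/1).
#' @param phenotypes Long-format `data.frame` with columns `subject_id`,
#'   `time_days`, `test_id`, `score`. May be empty.
#'
#' @return A [TrialCohort-class] object.
#' @examples
#' cohort <- simulateCohort(simulationConfig(n_candidates = 40,
#'                                           n_variants = 10, seed = 1))
#' cohort
#' @export
TrialCohort <- function(dosages, variantMeta, covariates,
                        phenotypes = data.frame()) {
    stopifnot(is.matrix(dosages),
              nrow(variantMeta) == nrow(dosages),
              nrow(covariates) == ncol(dosages))
    if (is.null(rownames(dosages)))
        rownames(dosages) <- sprintf("var%d", seq_len(nrow(dosages)))
    if (is.null(colnames(dosages)))
        colnames(dosages) <- sprintf("subj%d", seq_len(ncol(dosages)))
    rr <- GRanges(seqnames = as.character(variantMeta$chrom),
                  ranges = IRanges(start = variantMeta$pos, width = 1L))
    keep <- setdiff(colnames(variantMeta), c("chrom", "pos"))
    S4Vectors::mcols(rr) <- DataFrame(variantMeta[, keep, drop = FALSE])
    names(rr) <- rownames(dosages)
    se <- SummarizedExperiment(
        assays = SimpleList(dosage = dosages),
        rowRanges = rr,
        colData = DataFrame(covariates, row.names = colnames(dosages)))
    new("TrialCohort", se, phenotypes = DataFrame(phenotypes))
}

#' GEE fit for clustered Gaussian data
#'
#' Result of [fitGEE()]: coefficient vector, model-based ("naive") and
#' robust sandwich covariances, working-correlation estimate, dispersion
#' and a convergence record.
#'
#' @slot beta Named numeric coefficient vector.
#' @slot naiveCov,robustCov Symmetric covariance matrices of `beta`.
#' @slot corstr Working correlation structure used.
#' @slot corrParams Estimated working-correlation parameters (the
#'   exchangeable correlation, or the unstructured matrix).
#' @slot dispersion Estimated residual dispersion (scale).
#' @slot nClusters,nObs,nIter Integers.
#' @slot converged Logical.
#' @export
setClass("GEEFit", representation(
    beta = "numeric", naiveCov = "matrix", robustCov = "matrix",
    corstr = "character", corrParams = "ANY", dispersion = "numeric",
    nClusters = "integer", nObs = "integer", nIter = "integer",
    converged = "logical"))

setValidity("GEEFit", function(object) {
    p <- length(object@beta)
    if (!all(dim(object@robustCov) == p) || !all(dim(object@naiveCov) == p))
        return("covariance dimensions must match beta")
    if (max(abs(object@robustCov - t(object@robustCov))) > 1e-10)
        return("robustCov must be symmetric")
    if (object@dispersion <= 0) return("dispersion must be positive")
    TRUE
})

#' Linear mixed model fit (random intercept and slope)
#'
#' Thin container for the REML fit used in model exploration and PRS
#' testing; see [fitLMM()].
#'
#' @slot fixef Named fixed-effect estimates.
#' @slot fixefCov Covariance of the fixed effects.
#' @slot varcomp Named variance components: `var_intercept`, `var_slope`,
#'   `cov_int_slope`, `var_resid`.
#' @slot logLik REML log-likelihood.
#' @slot converged Logical.
#' @slot randomSlope Whether a random slope was retained.
#' @export
setClass("LMMFit", representation(
    fixef = "numeric", fixefCov = "matrix", varcomp = "numeric",
    logLik = "numeric", converged = "logical", randomSlope = "logical"))

#' Genome scan result
#'
#' Per-variant four-parameter association records plus scan-level
#' summaries. `records(x)` returns a `data.frame` with, per variant and
#' per trajectory parameter (`intercept`, `age`, `slope1`, `slope2`),
#' the estimate (`beta_*`, phenotype-SD units; slopes per year), robust
#' standard error (`se_*`) and two-sided Wald p-value (`p_*`).
#'
#' @slot records A [S4Vectors::DataFrame] of per-variant results.
#' @slot lambda Named numeric: genomic-inflation lambda per parameter.
#' @slot threshold Genome-wide significance threshold used.
#' @slot outcome Outcome name.
#' @slot nTested,nConverged,nSignificant Integers.
#' @export
setClass("ScanResult", representation(
    records = "DataFrame", lambda = "numeric", threshold = "numeric",
    outcome = "character", nTested = "integer", nConverged = "integer",
    nSignificant = "integer"))

#' Polygenic score model
#'
#' Variant weights aligned to a cohort's alt-allele dosages, the
#' per-subject standardized score, and an alignment ledger recording
#' dropped weights (reasons: `source_p`, `ambiguous`, `unmatched`,
#' `allele_mismatch`, `clumped`).
#'
#' @slot trait Trait name.
#' @slot weights Aligned weights table (one row per retained variant).
#' @slot score Named per-subject standardized score.
#' @slot ledger DataFrame of excluded weight rows and reasons.
#' @export
setClass("PRSModel", representation(
    trait = "character", weights = "DataFrame", score = "numeric",
    ledger = "DataFrame"))
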