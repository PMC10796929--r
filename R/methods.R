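#' Accessors for TrialCohort
#'
#' `dosages()` returns the variants x subjects dosage matrix;
#' `variantMeta()` the per-variant metadata as a `data.frame` (chrom, pos,
#' ref, alt, imputation_r2, ...); `covariates()` the subject covariate
#' table; `phenotypes()` the long-format score table.
#'
#' @param x A [TrialCohort-class].
#' @param ... Unused.
#' @param value Replacement long-format phenotype table.
#' @return See description.
#' @name TrialCohort-accessors
NULL

#' @rdname TrialCohort-accessors
#' @export
setMethod("dosages", "TrialCohort", function(x, ...) assay(x, "dosage"))

#' @rdname TrialCohort-accessors
#' @export
setMethod("variantMeta", "TrialCohort", function(x, ...) {
    rr <- rowRanges(x)
    data.frame(variant_id = names(rr),
               chrom = as.character(GenomicRanges::seqnames(rr)),
               pos = GenomicRanges::start(rr),
               as.data.frame(S4Vectors::mcols(rr)),
               row.names = names(rr))
})

#' @rdname TrialCohort-accessors
#' @export
setMethod("covariates", "TrialCohort", function(x, ...)
    as.data.frame(colData(x)))

#' @rdname TrialCohort-accessors
#' @export
setMethod("phenotypes", "TrialCohort", function(x, ...)
    as.data.frame(x@phenotypes))

#' @rdname TrialCohort-accessors
#' @export
setReplaceMethod("phenotypes", "TrialCohort", function(x, value) {
    x@phenotypes <- S4Vectors::DataFrame(value)
    validObject(x)
    x
})

setMethod("show", "TrialCohort", function(object) {
    cat("TrialCohort:", nrow(object), "variants x", ncol(object),
        "subjects\n")
    ph <- object@phenotypes
    if (nrow(ph))
        cat("  phenotypes:", nrow(ph), "rows,",
            length(unique(ph$test_id)), "tests,",
            length(unique(ph$subject_id)), "subjects\n")
    callNextMethod()
})

#' @param object A fitted object.
#' @rdname GEEFit-class
#' @export
setMethod("show", "GEEFit", function(object) {
    cat(sprintf(
        "GEEFit (%s working correlation): %d clusters, %d observations\n",
        object@corstr, object@nClusters, object@nObs))
    cat(sprintf("  converged: %s after %d iterations; dispersion %.4g\n",
                object@converged, object@nIter, object@dispersion))
    se <- sqrt(diag(object@robustCov))
    print(data.frame(beta = object@beta, robust_se = se,
                     z = object@beta / se,
                     p = 2 * stats::pnorm(-abs(object@beta / se))))
    invisible(object)
})

#' Extract GEE coefficients and covariances
#'
#' @param object A [GEEFit-class].
#' @param ... Unused.
#' @return `coef()` the coefficient vector; `vcov()` the robust sandwich
#'   covariance (set `robust = FALSE` for the model-based one).
#' @param robust Return the sandwich covariance (default) or model-based.
#' @rdname GEEFit-class
#' @export
setMethod("coef", "GEEFit", function(object, ...) object@beta)

#' @rdname GEEFit-class
#' @export
setMethod("vcov", "GEEFit", function(object, robust = TRUE, ...)
    if (robust) object@robustCov else object@naiveCov)

#' @rdname LMMFit-class
#' @export
setMethod("coef", "LMMFit", function(object, ...) object@fixef)

#' @rdname LMMFit-class
#' @export
setMethod("vcov", "LMMFit", function(object, ...) object@fixefCov)

setMethod("show", "LMMFit", function(object) {
    cat("LMMFit (REML): random intercept",
        if (object@randomSlope) "+ slope", "\n")
    print(object@varcomp)
    se <- sqrt(diag(object@fixefCov))
    print(data.frame(beta = object@fixef, se = se, z = object@fixef / se))
    invisible(object)
})

#' Accessors for ScanResult
#'
#' `records()` returns the per-variant association table; `lambdaGC()`
#' the per-parameter genomic-inflation estimates.
#'
#' @param x A [ScanResult-class].
#' @param ... Unused.
#' @name ScanResult-accessors
NULL

#' @rdname ScanResult-accessors
#' @export
setMethod("records", "ScanResult", function(x, ...) as.data.frame(x@records))

#' @rdname ScanResult-accessors
#' @export
setMethod("lambdaGC", "ScanResult", function(x, ...) x@lambda)

setMethod("show", "ScanResult", function(object) {
    cat(sprintf("ScanResult for outcome '%s': %d variants tested, %d converged\n",
                object@outcome, object@nTested, object@nConverged))
    cat(sprintf("  genome-wide threshold %.3g; %d significant record(s)\n",
                object@threshold, object@nSignificant))
    cat("  lambda:", paste(sprintf("%s=%.3f", names(object@lambda),
                                   object@lambda), collapse = ", "), "\n")
    invisible(object)
})

#' @rdname prs
#' @export
setMethod("prsScores", "PRSModel", function(x, ...) x@score)

setMethod("show", "PRSModel", function(object) {
    cat(sprintf("PRSModel '%s': %d variants retained, %d subjects scored\n",
                object@trait, nrow(object@weights), length(object@score)))
    if (nrow(object@ledger))
        print(table(object@ledger$reason))
    invisible(object)
})
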