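#' @rdname TrialCohort-accessors
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @rdname TrialCohort-accessors
#' @export
setGeneric("variantMeta", function(x, ...) standardGeneric("variantMeta"))

#' @rdname TrialCohort-accessors
#' @export
setGeneric("covariates", function(x, ...) standardGeneric("covariates"))

#' @rdname TrialCohort-accessors
#' @export
setGeneric("phenotypes", function(x, ...) standardGeneric("phenotypes"))

#' @rdname TrialCohort-accessors
#' @export
setGeneric("phenotypes<-", function(x, value) standardGeneric("phenotypes<-"))

#' @rdname ScanResult-accessors
#' @export
setGeneric("records", function(x, ...) standardGeneric("records"))

#' @rdname ScanResult-accessors
#' @export
setGeneric("lambdaGC", function(x, ...) standardGeneric("lambdaGC"))

#' @rdname prs
#' @export
setGeneric("prsScores", function(x, ...) standardGeneric("prsScores"))
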