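# Phenotype preparation: baseline z-standardisation of component tests,
# available-case domain and composite averaging, and the knot-point
# trajectory design.

#' Fit a baseline standardizer
#'
#' Computes per-test baseline mean and sample (n-1) SD from the
#' `time_days == 0` rows. Later visits are standardised with these
#' baseline parameters unchanged, so each test's z-scores have mean 0 and
#' SD 1 at baseline by construction.
#'
#' @param phenotypes Long-format `data.frame` with `subject_id`,
#'   `time_days`, `test_id`, `score`.
#' @return A `data.frame` of class `PhenotypeStandardizer` with columns
#'   `test_id`, `baseline_mean`, `baseline_sd`.
#' @examples
#' ph <- data.frame(subject_id = c("a", "b", "c"), time_days = 0,
#'                  test_id = "t1", score = c(1, 2, 3))
#' fitStandardizer(ph)   # mean 2, sd 1
#' @export
fitStandardizer <- function(phenotypes) {
    base <- phenotypes[phenotypes$time_days == 0 & !is.na(phenotypes$score), ]
    if (!nrow(base)) stop("no baseline (time_days == 0) rows")
    n <- tapply(base$score, base$test_id, length)
    if (any(n < 2))
        stop("fewer than 2 baseline values for test(s): ",
             paste(names(n)[n < 2], collapse = ", "))
    mu <- tapply(base$score, base$test_id, mean)
    sd_ <- tapply(base$score, base$test_id, stats::sd)
    if (any(sd_ <= 0 | !is.finite(sd_)))
        stop("constant baseline scores for test(s): ",
             paste(names(sd_)[sd_ <= 0 | !is.finite(sd_)], collapse = ", "))
    out <- data.frame(test_id = names(mu), baseline_mean = as.numeric(mu),
                      baseline_sd = as.numeric(sd_), row.names = names(mu))
    class(out) <- c("PhenotypeStandardizer", "data.frame")
    out
}

#' Apply a baseline standardizer
#'
#' @param standardizer From [fitStandardizer()].
#' @param phenotypes Long-format rows to standardise; tests unseen at fit
#'   time are an error.
#' @return The input with `score` replaced by
#'   `(score - baseline_mean) / baseline_sd`.
#' @export
applyStandardizer <- function(standardizer, phenotypes) {
    unseen <- setdiff(unique(phenotypes$test_id), standardizer$test_id)
    if (length(unseen))
        stop("no baseline parameters for test(s): ",
             paste(unseen, collapse = ", "))
    i <- match(phenotypes$test_id, standardizer$test_id)
    phenotypes$score <- (phenotypes$score - standardizer$baseline_mean[i]) /
        standardizer$baseline_sd[i]
    phenotypes
}

#' Domain scores from component z-scores
#'
#' The domain score at each (subject, time) is the unweighted mean of the
#' available (non-missing) component test z-scores. A (subject, time)
#' whose components are all missing is omitted and recorded in the
#' `"droppedRows"` attribute.
#'
#' @param zscores Standardised long-format rows ([applyStandardizer()]).
#' @param domainMap Named list mapping domain names to component test
#'   ids; see [defaultDomainMap()] and [readDomainMap()].
#' @return Long-format `data.frame` with `subject_id`, `time_days`,
#'   `test_id` (the domain name) and `score`.
#' @export
domainScores <- function(zscores, domainMap) {
    out <- vector("list", length(domainMap))
    dropped <- character()
    for (d in seq_along(domainMap)) {
        rows <- zscores[zscores$test_id %in% domainMap[[d]], ]
        if (!nrow(rows)) next
        key <- paste(rows$subject_id, rows$time_days, sep = "\r")
        ok <- !is.na(rows$score)
        m <- tapply(rows$score[ok], key[ok], mean)
        lost <- setdiff(unique(key), names(m))
        if (length(lost))
            dropped <- c(dropped,
                         paste(names(domainMap)[d], lost, sep = "\r"))
        parts <- do.call(rbind, strsplit(names(m), "\r", fixed = TRUE))
        out[[d]] <- data.frame(subject_id = parts[, 1],
                               time_days = as.numeric(parts[, 2]),
                               test_id = names(domainMap)[d],
                               score = as.numeric(m))
    }
    res <- do.call(rbind, out)
    res <- res[order(res$subject_id, res$time_days, res$test_id), ]
    rownames(res) <- NULL
    attr(res, "droppedRows") <- dropped
    res
}

#' Composite (global) score from domain scores
#'
#' Unweighted available-case mean of the domain scores at each
#' (subject, time).
#'
#' @param domainRows Output of [domainScores()].
#' @param name Test id to assign to the composite rows.
#' @return Long-format rows for the composite score.
#' @examples
#' d <- data.frame(subject_id = "s", time_days = 0,
#'                 test_id = paste0("dom", 1:5), score = rep(1, 5))
#' compositeScore(d)$score   # 1
#' @export
compositeScore <- function(domainRows, name = "global") {
    key <- paste(domainRows$subject_id, domainRows$time_days, sep = "\r")
    ok <- !is.na(domainRows$score)
    m <- tapply(domainRows$score[ok], key[ok], mean)
    parts <- do.call(rbind, strsplit(names(m), "\r", fixed = TRUE))
    out <- data.frame(subject_id = parts[, 1],
                      time_days = as.numeric(parts[, 2]),
                      test_id = name, score = as.numeric(m))
    out <- out[order(out$subject_id, out$time_days), ]
    rownames(out) <- NULL
    out
}

#' Build the knot-point trajectory design
#'
#' Encodes the piecewise-linear trajectory with one slope change: per row,
#' `intercept = 1`, `age_c = baseline_age - age_ref` (years),
#' `s1 = min(t, knot)/365` and `s2 = max(t - knot, 0)/365` (years of
#' follow-up before and after the knot). The identity
#' `365 * (s1 + s2) = t` holds for all `t >= 0`, so the two slope
#' coefficients read as change per year before and after the knot.
#'
#' @param time_days Non-negative visit times in days.
#' @param baseline_age Baseline age in years (recycled to length of
#'   `time_days`).
#' @param knot_days Slope-change point (default 365).
#' @param age_ref Centring age in years.
#' @return Numeric matrix with columns `intercept`, `age_c`, `s1`, `s2`.
#' @examples
#' buildTrajectoryBasis(c(0, 365, 730), baseline_age = 70, age_ref = 73.4)
#' @export
buildTrajectoryBasis <- function(time_days, baseline_age, knot_days = 365,
                                 age_ref = 73.4) {
    if (any(time_days < 0)) stop("negative visit times are not allowed")
    stopifnot(knot_days > 0)
    n <- length(time_days)
    cbind(intercept = rep(1, n),
          age_c = rep_len(baseline_age, n) - age_ref,
          s1 = pmin(time_days, knot_days) / 365,
          s2 = pmax(time_days - knot_days, 0) / 365)
}

#' Read or write a domain map as YAML
#'
#' @param path File path; the YAML is a mapping
#'   `{domain: [test_id, ...]}`.
#' @param domainMap Named list of character vectors.
#' @return `readDomainMap()` returns the named list.
#' @export
readDomainMap <- function(path) {
    m <- yaml::read_yaml(path)
    lapply(m, as.character)
}

#' @rdname readDomainMap
#' @export
writeDomainMap <- function(domainMap, path) {
    yaml::write_yaml(domainMap, path)
    invisible(path)
}

#' Prepare analysis outcomes from a cohort's raw phenotypes
#'
#' Standardises every component test to its baseline mean and SD, builds
#' the five domain scores and the global composite, and returns the long
#' outcome table used by the scan and PRS models.
#'
#' @param cohort A [TrialCohort-class].
#' @param domainMap Named list of component tests per domain.
#' @return `data.frame` of z-scored outcome rows (`test_id` is a domain
#'   name or `"global"`), with the fitted standardizer in the
#'   `"standardizer"` attribute.
#' @export
prepareOutcomes <- function(cohort, domainMap = defaultDomainMap()) {
    ph <- phenotypes(cohort)
    if (!nrow(ph)) stop("cohort has no phenotype rows")
    std <- fitStandardizer(ph)
    z <- applyStandardizer(std, ph)
    dom <- domainScores(z, domainMap)
    out <- rbind(dom, compositeScore(dom))
    attr(out, "standardizer") <- std
    out
}
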