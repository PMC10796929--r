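# Per-variant trajectory GWAS: one GEE fit per variant with the variant
# entering additively on the intercept and interacting with baseline age
# and both slopes; robust Wald tests per parameter, genomic-control
# lambda, greedy LD clumping and external-variant lookups.

.PARAMS <- c("intercept", "age", "slope1", "slope2")

# shared per-scan quantities: outcome vector, covariate-only design,
# cluster bookkeeping and the genotype interaction columns
.buildScanContext <- function(cohort, outcome, outcomeRows = NULL,
                              pcs = NULL, nPCs = 5, riskVariantIds = NULL,
                              knotDays = 365, ageRef = 73.4,
                              adjustLifestyle = FALSE,
                              domainMap = defaultDomainMap()) {
    if (is.null(outcomeRows))
        outcomeRows <- prepareOutcomes(cohort, domainMap)
    rows <- outcomeRows[outcomeRows$test_id == outcome &
                        !is.na(outcomeRows$score), ]
    if (!nrow(rows)) stop("no outcome rows for '", outcome, "'")
    subj <- intersect(colnames(cohort), unique(rows$subject_id))
    rows <- rows[rows$subject_id %in% subj, ]
    cov <- covariates(cohort)[subj, , drop = FALSE]
    if (is.null(riskVariantIds))
        riskVariantIds <- metadata(cohort)$riskVariantIds
    if (is.null(pcs)) {
        pca <- genotypePCA(cohort, k = nPCs)
        pcs <- pca$scores
    }
    pcs <- as.matrix(pcs)[subj, , drop = FALSE]
    si <- match(rows$subject_id, subj)
    basis <- buildTrajectoryBasis(rows$time_days,
                                  cov$baseline_age_years[si],
                                  knot_days = knotDays, age_ref = ageRef)
    Xbase <- cbind(basis, sex = cov$sex[si])
    if (length(riskVariantIds)) {
        Dr <- dosages(cohort)[riskVariantIds, subj, drop = FALSE]
        for (v in riskVariantIds) {
            d <- Dr[v, ]
            d[is.na(d)] <- mean(d, na.rm = TRUE)
            Xbase <- cbind(Xbase, d[si])
            colnames(Xbase)[ncol(Xbase)] <- paste0("risk_", v)
        }
    }
    Xbase <- cbind(Xbase, pcs[si, , drop = FALSE])
    if (adjustLifestyle) {
        extra <- as.matrix(cov[si, c("education_years", "alcohol",
                                     "smoking", "bmi")])
        Xbase <- cbind(Xbase, extra)
    }
    cl <- .clusterCodes(rows$subject_id)
    list(y = rows$score, Xbase = Xbase, code = cl$code, sizes = cl$sizes,
         nClusters = cl$m, subj = subj, si = si,
         age_c = basis[, "age_c"], s1 = basis[, "s1"], s2 = basis[, "s2"],
         riskVariantIds = riskVariantIds)
}

.emptyRecord <- function() {
    rec <- as.list(rep(NA_real_, 4 * length(.PARAMS)))
    names(rec) <- c(t(outer(c("beta_", "se_", "z_", "p_"), .PARAMS,
                            paste0)))
    rec
}

.scanOne <- function(ctx, g, corstr = "exchangeable", maxIter = 50L,
                     tol = 1e-8) {
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    if (stats::var(g) == 0)
        stop("variant is monomorphic in analysis sample")
    gobs <- g[ctx$si]
    X <- cbind(ctx$Xbase, g = gobs, g_age = gobs * ctx$age_c,
               g_s1 = gobs * ctx$s1, g_s2 = gobs * ctx$s2)
    fit <- .geeFitCore(ctx$y, X, ctx$code, ctx$sizes, corstr,
                       maxIter = maxIter, tol = tol)
    p <- ncol(X)
    idx <- (p - 3L):p
    beta <- fit$beta[idx]
    V <- fit$robustCov[idx, idx, drop = FALSE]
    se <- sqrt(diag(V))
    w <- waldTest(beta, se)
    rec <- .emptyRecord()
    rec[paste0("beta_", .PARAMS)] <- beta
    rec[paste0("se_", .PARAMS)] <- se
    rec[paste0("z_", .PARAMS)] <- w$z
    rec[paste0("p_", .PARAMS)] <- w$p
    stat <- drop(crossprod(beta, solve(V, beta)))
    rec$p_joint <- stats::pchisq(stat, df = 4, lower.tail = FALSE)
    rec$converged <- fit$converged
    rec
}

#' Four-parameter association test for one variant
#'
#' Fits one GEE to the outcome trajectory with fixed effects
#' {intercept, centred baseline age, slope 1, slope 2, sex, the two
#' risk-locus dosages, the top ancestry PCs} plus the variant dosage and
#' its interactions with the intercept column's companions: `g`,
#' `g x age_c`, `g x s1`, `g x s2`. Education, alcohol, smoking and BMI
#' are deliberately not adjusted (they are plausibly downstream of
#' genotype, so conditioning on them can induce collider bias); set
#' `adjustLifestyle = TRUE` to override. Robust Wald z/p per genetic term.
#'
#' @param cohort A [TrialCohort-class].
#' @param variantId Row name of the variant to test.
#' @param outcome Outcome name in the prepared outcome table (default
#'   `"global"`).
#' @param ... Passed to the scan context builder: `outcomeRows`, `pcs`,
#'   `nPCs`, `riskVariantIds`, `knotDays`, `ageRef`, `adjustLifestyle`,
#'   `domainMap`.
#' @param corstr Working correlation for the scan GEE.
#' @return One-row `data.frame`: per-parameter `beta_*`, `se_*`, `z_*`,
#'   `p_*` (parameters `intercept`, `age`, `slope1`, `slope2`), the
#'   4-df joint `p_joint`, and `converged`.
#' @export
scanVariant <- function(cohort, variantId, outcome = "global",
                        corstr = "exchangeable", ...) {
    ctx <- .buildScanContext(cohort, outcome, ...)
    g <- dosages(cohort)[variantId, ctx$subj]
    data.frame(variant_id = variantId,
               .scanOne(ctx, g, corstr = corstr))
}

#' Run the trajectory GWAS over all variants
#'
#' Applies the four-parameter GEE test of [scanVariant()] to every
#' variant (shared quantities are computed once), then summarises:
#' per-parameter genomic-inflation lambda, convergence and significance
#' counts. Per-variant failures (e.g. monomorphic in the analysis
#' sample) are recorded as missing rows, never aborting the scan.
#'
#' @inheritParams scanVariant
#' @param variants Variant ids to scan (default: all rows of the cohort,
#'   e.g. the kept set from [filterVariants()]).
#' @param threshold Genome-wide significance threshold (default 5e-8).
#' @param maxIter,tol Per-variant GEE convergence control.
#' @return A [ScanResult-class].
#' @examples
#' cohort <- simulateCohort(simulationConfig(n_candidates = 80,
#'                                           n_variants = 15, seed = 2))
#' scan <- runScan(cohort, nPCs = 2)
#' head(records(scan))
#' @export
runScan <- function(cohort, outcome = "global", variants = NULL,
                    corstr = "exchangeable", threshold = 5e-8,
                    maxIter = 50L, tol = 1e-8, ...) {
    ctx <- .buildScanContext(cohort, outcome, ...)
    D <- dosages(cohort)[, ctx$subj, drop = FALSE]
    if (is.null(variants)) variants <- rownames(D)
    meta <- variantMeta(cohort)[variants, , drop = FALSE]
    out <- vector("list", length(variants))
    failures <- character()
    for (i in seq_along(variants)) {
        rec <- tryCatch(
            .scanOne(ctx, D[variants[i], ], corstr = corstr,
                     maxIter = maxIter, tol = tol),
            error = function(e) {
                failures <<- c(failures, paste0(variants[i], ": ",
                                                conditionMessage(e)))
                c(.emptyRecord(), p_joint = NA_real_, converged = FALSE)
            })
        out[[i]] <- unlist(rec)
    }
    tab <- as.data.frame(do.call(rbind, out))
    tab$converged <- as.logical(tab$converged)
    af <- rowMeans(D[variants, , drop = FALSE], na.rm = TRUE) / 2
    rec <- data.frame(variant_id = variants, chrom = meta$chrom,
                      pos = meta$pos, effect_allele = meta$alt,
                      other_allele = meta$ref, eaf = af, tab,
                      row.names = variants)
    lambda <- vapply(.PARAMS, function(pp) {
        pv <- rec[[paste0("p_", pp)]]
        pv <- pv[!is.na(pv)]
        if (length(pv)) genomicLambda(pv) else NA_real_
    }, 0)
    psig <- as.matrix(rec[, paste0("p_", .PARAMS)])
    new("ScanResult", records = S4Vectors::DataFrame(rec),
        lambda = lambda, threshold = threshold, outcome = outcome,
        nTested = length(variants),
        nConverged = sum(rec$converged, na.rm = TRUE),
        nSignificant = sum(psig < threshold, na.rm = TRUE))
}

#' Genomic-control lambda
#'
#' `lambda = median(chi2) / 0.4549364`, the observed median 1-df
#' chi-square statistic over its null expectation. P-values are converted
#' to chi-square quantiles when supplied.
#'
#' @param p Vector of p-values, or `NULL` if `chisq` given.
#' @param chisq Vector of 1-df chi-square statistics.
#' @return Lambda (1 for perfectly calibrated tests).
#' @examples
#' genomicLambda(chisq = rep(qchisq(0.5, 1), 10))   # exactly 1
#' @export
genomicLambda <- function(p = NULL, chisq = NULL) {
    if (is.null(chisq)) {
        if (is.null(p) || !length(p)) stop("empty input")
        chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
    }
    if (!length(chisq)) stop("empty input")
    stats::median(chisq) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Greedy LD clumping of scan results
#'
#' Significant variants are sorted by ascending p-value (ties by
#' chromosome then position); the best unassigned variant becomes an
#' index, absorbing every unassigned variant on the same chromosome
#' within the window whose squared Pearson dosage correlation with the
#' index reaches `r2Threshold`. Repeats until all significant variants
#' are assigned.
#'
#' @param scan A [ScanResult-class] or its `records()` data.frame.
#' @param parameter One of `"intercept"`, `"age"`, `"slope1"`,
#'   `"slope2"`, or `"joint"`.
#' @param dosages Variants x subjects dosage matrix for LD computation.
#' @param pThreshold Significance threshold (default 5e-8).
#' @param r2Threshold LD threshold for absorption (default 0.1).
#' @param windowKb Maximum distance from the index, in kb (default 1000).
#' @return `data.frame` with `variant_id`, `index_variant`,
#'   `r2_with_index`, `p`; index variants are their own index.
#' @export
clumpVariants <- function(scan, parameter = "slope2", dosages,
                          pThreshold = 5e-8, r2Threshold = 0.1,
                          windowKb = 1000) {
    rec <- if (is(scan, "ScanResult")) records(scan) else scan
    pcol <- paste0("p_", parameter)
    stopifnot(pcol %in% colnames(rec))
    sig <- rec[!is.na(rec[[pcol]]) & rec[[pcol]] < pThreshold, ]
    if (!nrow(sig))
        return(data.frame(variant_id = character(),
                          index_variant = character(),
                          r2_with_index = numeric(), p = numeric()))
    sig <- sig[order(sig[[pcol]], sig$chrom, sig$pos), ]
    ids <- sig$variant_id
    assigned <- rep(NA_character_, length(ids))
    r2out <- rep(NA_real_, length(ids))
    for (i in seq_along(ids)) {
        if (!is.na(assigned[i])) next
        assigned[i] <- ids[i]
        r2out[i] <- 1
        open <- which(is.na(assigned))
        if (!length(open)) break
        near <- open[sig$chrom[open] == sig$chrom[i] &
                     abs(sig$pos[open] - sig$pos[i]) <= windowKb * 1000]
        if (!length(near)) next
        gi <- dosages[ids[i], ]
        for (j in near) {
            r2 <- suppressWarnings(
                stats::cor(gi, dosages[ids[j], ],
                           use = "pairwise.complete.obs"))^2
            if (!is.na(r2) && r2 >= r2Threshold) {
                assigned[j] <- ids[i]
                r2out[j] <- r2
            }
        }
    }
    data.frame(variant_id = ids, index_variant = assigned,
               r2_with_index = r2out, p = sig[[pcol]])
}

#' Look up externally reported variants in scan results
#'
#' Aligns an external variant list (id, effect allele, optionally the
#' published beta) to the scan: when the external effect allele equals
#' the scan's other (non-effect) allele, the reported scan betas are
#' negated and the effect-allele frequency flipped; unmatched ids are
#' returned with status `"not_tested"`, allele mismatches with
#' `"allele_mismatch"`. Survivors of a Bonferroni threshold of
#' `alpha / (n_variants x 4 parameters)` are flagged.
#'
#' @param scan A [ScanResult-class] or its records.
#' @param external `data.frame` with `variant_id`, `effect_allele`, and
#'   optionally `beta`.
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @return `data.frame`: one row per external variant with harmonised
#'   per-parameter betas and p-values, `status`, `bonferroni_threshold`
#'   and `significant`.
#' @export
lookupVariants <- function(scan, external, alpha = 0.05) {
    rec <- if (is(scan, "ScanResult")) records(scan) else scan
    thr <- alpha / (nrow(external) * 4)
    i <- match(external$variant_id, rec$variant_id)
    out <- data.frame(variant_id = external$variant_id,
                      status = "ok", stringsAsFactors = FALSE)
    bcols <- paste0("beta_", .PARAMS)
    pcols <- paste0("p_", .PARAMS)
    for (cn in c(bcols, pcols)) out[[cn]] <- rec[[cn]][i]
    out$eaf <- rec$eaf[i]
    flip <- !is.na(i) & external$effect_allele == rec$other_allele[i]
    match_ok <- !is.na(i) & (external$effect_allele == rec$effect_allele[i] |
                             flip)
    out[flip, bcols] <- -out[flip, bcols]
    out$eaf[flip] <- 1 - out$eaf[flip]
    out$status[is.na(i)] <- "not_tested"
    out$status[!is.na(i) & !match_ok] <- "allele_mismatch"
    out[out$status != "ok", c(bcols, pcols, "eaf")] <- NA
    out$bonferroni_threshold <- thr
    out$significant <- apply(out[, pcols] < thr, 1, any)
    out$significant[out$status != "ok"] <- NA
    out
}

#' Write scan summary statistics as TSV
#'
#' One row per variant with chrom, pos, alleles, frequency and the four
#' beta/se/p blocks (a GWAS-SSF-like layout).
#'
#' @param scan A [ScanResult-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeScanSummary <- function(scan, path) {
    utils::write.table(records(scan), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' QQ-plot data table
#'
#' Expected vs observed -log10 p for one parameter, ready for plotting.
#'
#' @param scan A [ScanResult-class] or records data.frame.
#' @param parameter Trajectory parameter name.
#' @return `data.frame` with `expected` and `observed` columns.
#' @export
qqData <- function(scan, parameter = "slope2") {
    rec <- if (is(scan, "ScanResult")) records(scan) else scan
    p <- sort(rec[[paste0("p_", parameter)]])
    p <- p[!is.na(p)]
    n <- length(p)
    data.frame(expected = -log10(stats::ppoints(n)),
               observed = -log10(p))
}
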