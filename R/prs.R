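# Polygenic scores: genome-wide-significant external weights are LD
# clumped against the cohort panel, aligned to the cohort's alt-allele
# dosages (strand-ambiguous variants dropped), summed into a per-subject
# score, standardized in-sample, and tested against the four trajectory
# parameters of each outcome.

.AMBIGUOUS <- c(A = "T", T = "A", C = "G", G = "C")

#' Select, clump and allele-align external GWAS weights
#'
#' Keeps weight rows with source `p < pThreshold` (default genome-wide,
#' 5e-8), drops strand-ambiguous (A/T, C/G) variants, matches the rest
#' to cohort variants by id, aligns the effect allele to the cohort's
#' alt allele (weight negated when the effect allele is the cohort ref;
#' other allele pairs are dropped as mismatches), and greedily LD-clumps
#' survivors against the cohort dosages so each signal contributes one
#' variant. Every dropped row lands in the ledger with a reason.
#'
#' @param weights `data.frame` with `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `p`.
#' @param cohort A [TrialCohort-class].
#' @param trait Trait label for the model.
#' @param pThreshold Source-GWAS inclusion threshold.
#' @param clump Clump against cohort LD (default TRUE).
#' @param r2Threshold,windowKb Clumping parameters.
#' @return A [PRSModel-class] (score empty until [computePRS()]).
#' @export
selectAndAlign <- function(weights, cohort, trait = "trait",
                           pThreshold = 5e-8, clump = TRUE,
                           r2Threshold = 0.1, windowKb = 1000) {
    need <- c("variant_id", "effect_allele", "other_allele", "beta", "p")
    stopifnot(all(need %in% colnames(weights)))
    w <- weights
    ledger <- data.frame(variant_id = character(), reason = character())
    drop_rows <- function(w, bad, why) {
        if (any(bad))
            ledger <<- rbind(ledger, data.frame(
                variant_id = w$variant_id[bad], reason = why))
        w[!bad, , drop = FALSE]
    }
    w <- drop_rows(w, !(w$p < pThreshold), "source_p")
    amb <- .AMBIGUOUS[w$effect_allele] == w$other_allele &
           !is.na(.AMBIGUOUS[w$effect_allele])
    w <- drop_rows(w, amb %in% TRUE, "ambiguous")
    meta <- variantMeta(cohort)
    i <- match(w$variant_id, meta$variant_id)
    w <- drop_rows(w, is.na(i), "unmatched")
    i <- i[!is.na(i)]
    same <- w$effect_allele == meta$alt[i] & w$other_allele == meta$ref[i]
    flip <- w$effect_allele == meta$ref[i] & w$other_allele == meta$alt[i]
    keep <- same | flip
    flip <- flip[keep]
    i <- i[keep]
    w <- drop_rows(w, !keep, "allele_mismatch")
    if (nrow(w)) {
        w$aligned_weight <- ifelse(flip, -w$beta, w$beta)
        w$chrom <- meta$chrom[i]
        w$pos <- meta$pos[i]
    }
    if (clump && nrow(w) > 1) {
        pseudo <- data.frame(variant_id = w$variant_id, chrom = w$chrom,
                             pos = w$pos, p_source = w$p)
        cl <- clumpVariants(pseudo, parameter = "source",
                            dosages = dosages(cohort),
                            pThreshold = 2, r2Threshold = r2Threshold,
                            windowKb = windowKb)
        absorbed <- cl$variant_id[cl$variant_id != cl$index_variant]
        w <- drop_rows(w, w$variant_id %in% absorbed, "clumped")
    }
    if (!nrow(w))
        stop("no variants survive selection and alignment")
    new("PRSModel", trait = trait, weights = S4Vectors::DataFrame(w),
        score = numeric(0), ledger = S4Vectors::DataFrame(ledger))
}

#' Compute a standardized polygenic score
#'
#' Raw score per subject is the aligned-weight-by-dosage sum over the
#' model's variants (missing dosages mean-imputed per variant), then
#' standardized to mean 0, SD 1 in the analysis sample — so downstream
#' trajectory betas read per SD of score. Doubling all weights therefore
#' leaves the standardized score unchanged.
#'
#' @param model A [PRSModel-class] from [selectAndAlign()].
#' @param cohort A [TrialCohort-class] (or variants x subjects dosage
#'   matrix covering the model's variants).
#' @return The model with its `score` slot filled (use [prsScores()]).
#' @export
computePRS <- function(model, cohort) {
    D <- if (is(cohort, "TrialCohort")) dosages(cohort) else cohort
    ids <- model@weights$variant_id
    miss <- setdiff(ids, rownames(D))
    if (length(miss))
        stop("dosages missing for: ", paste(head(miss, 3), collapse = ", "))
    Dm <- D[ids, , drop = FALSE]
    if (anyNA(Dm)) {
        mu <- rowMeans(Dm, na.rm = TRUE)
        allmiss <- !is.finite(mu)
        if (any(allmiss))
            stop("all dosages missing for: ",
                 paste(ids[allmiss], collapse = ", "))
        idx <- which(is.na(Dm), arr.ind = TRUE)
        Dm[idx] <- mu[idx[, 1]]
    }
    raw <- drop(crossprod(Dm, model@weights$aligned_weight))
    s <- stats::sd(raw)
    if (!is.finite(s) || s == 0)
        stop("polygenic score is constant; cannot standardize")
    score <- (raw - mean(raw)) / s
    names(score) <- colnames(Dm)
    attr(score, "raw") <- unname(raw)
    model@score <- score
    model
}

#' Test a polygenic score against outcome trajectories
#'
#' Longitudinal model of the outcome with fixed effects {trajectory
#' basis, sex, risk-locus dosages, ancestry PCs, score, score x age_c,
#' score x s1, score x s2}. The default family is the linear mixed model
#' (random intercept and slope); `family = "gee"` uses the exchangeable
#' GEE instead — for Gaussian outcomes the two give comparable estimates.
#'
#' @param cohort A [TrialCohort-class].
#' @param score Named standardized score per subject (from
#'   [computePRS()] / [prsScores()]) — or a [PRSModel-class].
#' @param outcome Outcome name (default `"global"`).
#' @param family `"lmm"` (default) or `"gee"`.
#' @param ... Scan-context options: `outcomeRows`, `pcs`, `nPCs`,
#'   `riskVariantIds`, `knotDays`, `ageRef`.
#' @return `data.frame` with one row per trajectory block (`intercept`,
#'   `age`, `slope1`, `slope2`): `beta` (per SD of score), `se`, `z`,
#'   `p`, plus the model family and convergence flag.
#' @export
testPRSTrajectory <- function(cohort, score, outcome = "global",
                              family = c("lmm", "gee"), ...) {
    family <- match.arg(family)
    if (is(score, "PRSModel")) score <- prsScores(score)
    ctx <- .buildScanContext(cohort, outcome, ...)
    if (is.null(names(score)))
        stop("score must be named by subject id")
    s <- score[ctx$subj]
    if (anyNA(s)) stop("score missing for some analysis subjects")
    sobs <- s[ctx$si]
    X <- cbind(ctx$Xbase, prs = sobs, prs_age = sobs * ctx$age_c,
               prs_s1 = sobs * ctx$s1, prs_s2 = sobs * ctx$s2)
    idx <- (ncol(X) - 3L):ncol(X)
    if (family == "lmm") {
        tot_years <- (ctx$s1 + ctx$s2)
        fit <- fitLMM(ctx$y, X, ctx$code, tot_years)
        beta <- coef(fit)[idx]
        V <- vcov(fit)[idx, idx]
        conv <- fit@converged
    } else {
        fit <- fitGEE(ctx$y, X, ctx$code, corstr = "exchangeable")
        beta <- coef(fit)[idx]
        V <- vcov(fit)[idx, idx]
        conv <- fit@converged
    }
    se <- sqrt(diag(V))
    w <- waldTest(beta, se)
    data.frame(parameter = .PARAMS, beta = unname(beta), se = unname(se),
               z = w$z, p = w$p, family = family, converged = conv)
}

#' Bonferroni threshold at the printed precision
#'
#' `alpha / n`, rounded to one significant figure as thresholds are
#' conventionally reported (6 models at alpha 0.05 gives 0.008; 72 gives
#' 7e-4).
#'
#' @param n_models Number of models in the family (>= 1).
#' @param alpha Family-wise error rate.
#' @return The presentation-rounded threshold.
#' @examples
#' bonferroniThreshold(6)    # 0.008
#' bonferroniThreshold(72)   # 7e-4
#' @export
bonferroniThreshold <- function(n_models, alpha = 0.05) {
    if (n_models < 1) stop("n_models must be >= 1")
    signif(alpha / n_models, 1)
}

#' Read a PRS weights file
#'
#' Tab-separated with columns `variant_id`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `beta`, `p`.
#'
#' @param path File path.
#' @param weights Weights `data.frame` (for writing).
#' @return `readWeights()` returns the `data.frame`.
#' @export
readWeights <- function(path) {
    w <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(variant_id = "character",
                                          effect_allele = "character",
                                          other_allele = "character"))
    if ("chrom" %in% colnames(w)) w$chrom <- as.character(w$chrom)
    w
}

#' @rdname readWeights
#' @export
writeWeights <- function(weights, path) {
    utils::write.table(weights, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
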