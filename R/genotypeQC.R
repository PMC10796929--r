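# Variant-level quality control: exact Hardy-Weinberg test, minor allele
# frequency, expected minor allele count (EMAC = 2 * N * MAF * r2),
# call-rate/threshold filtering with an exclusion ledger, and genotype
# principal components for ancestry adjustment.

#' Exact two-sided Hardy-Weinberg equilibrium test
#'
#' Conditional on the observed allele counts, sums the probabilities of
#' all heterozygote counts whose probability does not exceed that of the
#' observed count. Probabilities are accumulated by the standard
#' heterozygote recurrence in log space for numerical stability at large
#' sample sizes.
#'
#' @param n_hom_ref,n_het,n_hom_alt Non-negative integer genotype counts.
#' @return Exact two-sided p-value in (0, 1].
#' @examples
#' hweExactTest(25, 50, 25)
#' hweExactTest(100, 0, 0)   # monomorphic: p = 1
#' @export
hweExactTest <- function(n_hom_ref, n_het, n_hom_alt) {
    counts <- c(n_hom_ref, n_het, n_hom_alt)
    if (any(counts < 0) || any(counts != round(counts)))
        stop("genotype counts must be non-negative integers")
    n <- sum(counts)
    if (n < 1) stop("total genotype count must be >= 1")
    nA <- 2 * n_hom_ref + n_het           # ref allele count
    rare <- min(nA, 2 * n - nA)           # minor allele count
    if (rare == 0) return(1)
    hets <- seq(rare %% 2, rare, by = 2)  # attainable het counts
    # log P(h+2) - log P(h) = log[(R-h)(2n-R-h)] - log[(h+2)(h+1)]
    lp <- numeric(length(hets))
    if (length(hets) > 1) {
        h <- hets[-length(hets)]
        steps <- log(rare - h) + log(2 * n - rare - h) -
                 log(h + 2) - log(h + 1)
        lp <- c(0, cumsum(steps))
    }
    lp <- lp - max(lp)
    pr <- exp(lp)
    pr <- pr / sum(pr)
    p_obs <- pr[match(n_het, hets)]
    if (is.na(p_obs)) stop("heterozygote count inconsistent with totals")
    min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Allele frequency and minor allele frequency from dosages
#'
#' @param dosage Numeric dosages in \[0, 2\]; missing entries are dropped
#'   from the denominator.
#' @return List with `alt_freq` and `maf = min(alt_freq, 1 - alt_freq)`.
#' @examples
#' computeMAF(c(0, 0, 2))   # alt_freq 1/3
#' @export
computeMAF <- function(dosage) {
    d <- dosage[!is.na(dosage)]
    if (!length(d)) stop("all dosages missing")
    if (any(d < 0 | d > 2)) stop("dosages must lie in [0, 2]")
    af <- mean(d) / 2
    list(alt_freq = af, maf = min(af, 1 - af))
}

#' Expected minor allele count
#'
#' `EMAC = 2 * N * MAF * r2`: the expected number of minor alleles in the
#' analysis sample, discounted by imputation quality. A filter at
#' EMAC > 200 corresponds to a MAF of 4% at N = 2515 when the imputation
#' quality is 1.
#'
#' @param N Analysis sample size.
#' @param maf Minor allele frequency.
#' @param r2 Imputation quality.
#' @return The expected minor allele count (monotone in each argument).
#' @examples
#' emac(2515, 0.04, 1)   # 201.2
#' @export
emac <- function(N, maf, r2) {
    stopifnot(N >= 0, all(maf >= 0), all(maf <= 0.5),
              all(r2 >= 0), all(r2 <= 1))
    2 * N * maf * r2
}

#' Per-variant QC statistics for a cohort
#'
#' Computes call rate, alt/minor allele frequency, the exact
#' Hardy-Weinberg p-value (dosages rounded to hard genotypes; set
#' `hweOnDosages = FALSE` to skip the test for imputed dosages, recording
#' p = 1) and EMAC for every variant.
#'
#' @param cohort A [TrialCohort-class].
#' @param hweOnDosages Round dosages to genotypes and run the exact test
#'   (default); otherwise `hwe_p` is set to 1.
#' @return `data.frame`: `variant_id`, `chrom`, `pos`, `call_rate`,
#'   `alt_freq`, `maf`, `imputation_r2`, `hwe_p`, `emac`.
#' @export
variantQCStats <- function(cohort, hweOnDosages = TRUE) {
    D <- dosages(cohort)
    meta <- variantMeta(cohort)
    N <- ncol(D)
    call_rate <- rowMeans(!is.na(D))
    af <- rowMeans(D, na.rm = TRUE) / 2
    maf <- pmin(af, 1 - af)
    hwe_p <- rep(1, nrow(D))
    if (hweOnDosages) {
        G <- round(D)
        for (i in seq_len(nrow(D))) {
            g <- G[i, !is.na(G[i, ])]
            hwe_p[i] <- hweExactTest(sum(g == 0), sum(g == 1), sum(g == 2))
        }
    }
    data.frame(variant_id = rownames(D), chrom = meta$chrom,
               pos = meta$pos, call_rate = call_rate, alt_freq = af,
               maf = maf, imputation_r2 = meta$imputation_r2,
               hwe_p = hwe_p,
               emac = emac(N, maf, meta$imputation_r2),
               row.names = rownames(D))
}

#' Default variant QC thresholds
#'
#' Call rate at least 0.95, Hardy-Weinberg p at least 1e-8, MAF at least
#' 0.01, imputation r2 at least 0.7, EMAC strictly above 200.
#'
#' @return Named list of thresholds.
#' @export
defaultQCThresholds <- function() {
    list(call_rate = 0.95, hwe_p = 1e-8, maf = 0.01,
         imputation_r2 = 0.7, emac = 200)
}

#' Filter variants on QC thresholds with an exclusion ledger
#'
#' A variant is kept iff `call_rate >= 0.95` and `hwe_p >= 1e-8` and
#' `maf >= 0.01` and `imputation_r2 >= 0.7` and `emac > 200` (defaults;
#' all configurable). Each excluded variant is recorded once, under the
#' first rule it fails, in that order.
#'
#' @param stats Output of [variantQCStats()] (or any table with those
#'   columns).
#' @param thresholds Named list as [defaultQCThresholds()].
#' @return List with `kept` (variant ids) and `ledger`
#'   (`data.frame` of `variant_id`, `reason`).
#' @export
filterVariants <- function(stats, thresholds = defaultQCThresholds()) {
    th <- utils::modifyList(defaultQCThresholds(), thresholds)
    reason <- rep(NA_character_, nrow(stats))
    fail <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
    reason <- fail(stats$call_rate < th$call_rate, "call_rate")
    reason <- fail(stats$hwe_p < th$hwe_p, "hwe_p")
    reason <- fail(stats$maf < th$maf, "maf")
    reason <- fail(stats$imputation_r2 < th$imputation_r2, "imputation_r2")
    reason <- fail(stats$emac <= th$emac, "emac")
    excluded <- !is.na(reason)
    list(kept = stats$variant_id[!excluded],
         ledger = data.frame(variant_id = stats$variant_id[excluded],
                             reason = reason[excluded]))
}

#' Genotype principal components
#'
#' Standardises each variant's dosages as `(d - 2p) / sqrt(2 p (1 - p))`
#' (monomorphic variants dropped, missing dosages mean-imputed), then
#' takes the singular value decomposition over an optionally LD-thinned
#' variant subset. Subject scores are left singular vectors scaled by the
#' singular values, so score columns are mutually orthogonal.
#'
#' @param cohort A [TrialCohort-class] or a variants x subjects dosage
#'   matrix.
#' @param k Number of components (default 5).
#' @param thin Keep every `thin`-th variant (default 1 = all).
#' @return List with `scores` (subjects x k), `explained` (variance
#'   fractions) and `nVariantsUsed`.
#' @export
genotypePCA <- function(cohort, k = 5, thin = 1L) {
    D <- if (is(cohort, "TrialCohort")) dosages(cohort) else cohort
    if (thin > 1L)
        D <- D[seq(1L, nrow(D), by = as.integer(thin)), , drop = FALSE]
    if (ncol(D) < k + 1) stop("need at least k + 1 subjects")
    p <- rowMeans(D, na.rm = TRUE) / 2
    poly <- p > 0 & p < 1
    D <- D[poly, , drop = FALSE]
    p <- p[poly]
    if (!nrow(D)) stop("no polymorphic variants")
    Z <- (D - 2 * p) / sqrt(2 * p * (1 - p))
    Z[is.na(Z)] <- 0
    sv <- svd(t(Z), nu = k, nv = 0)
    scores <- sv$u * rep(sv$d[seq_len(k)], each = ncol(D))
    dimnames(scores) <- list(colnames(D), sprintf("PC%d", seq_len(k)))
    list(scores = scores, explained = sv$d[seq_len(k)]^2 / sum(sv$d^2),
         nVariantsUsed = nrow(D))
}
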