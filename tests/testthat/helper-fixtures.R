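# Shared test fixtures and independent oracles.

# Closed-form conditional genotype distribution given allele counts:
# P(het = h | n, nA) via the multinomial/hypergeometric identity,
# computed directly with lgamma (independent of the package's log-space
# recursion).
hweOracleDist <- function(n, nA) {
    nB <- 2 * n - nA
    rare <- min(nA, nB)
    hets <- seq(rare %% 2, rare, by = 2)
    a <- (nA - hets) / 2
    b <- (nB - hets) / 2
    lp <- lgamma(n + 1) - lgamma(a + 1) - lgamma(hets + 1) -
          lgamma(b + 1) + hets * log(2) +
          lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
    list(hets = hets, pr = exp(lp))
}

hweOracleP <- function(n_hom_ref, n_het, n_hom_alt) {
    n <- n_hom_ref + n_het + n_hom_alt
    nA <- 2 * n_hom_ref + n_het
    o <- hweOracleDist(n, nA)
    pobs <- o$pr[match(n_het, o$hets)]
    min(1, sum(o$pr[o$pr <= pobs * (1 + 1e-12)]))
}

# A small cohort with phenotypes, reused across files (cheap to build).
smallCohort <- function(seed = 42, n = 80, m = 24, ...) {
    simulateCohort(simulationConfig(n_candidates = n, n_variants = m,
                                    seed = seed, ...))
}

# Hand-built cohort from explicit pieces, for exact-value tests.
manualCohort <- function(dosages, phenotypes = data.frame(),
                         age = NULL, sex = NULL) {
    m <- nrow(dosages)
    ns <- ncol(dosages)
    meta <- data.frame(chrom = rep("1", m),
                       pos = seq_len(m) * 1000L,
                       ref = rep("A", m), alt = rep("G", m),
                       imputation_r2 = rep(0.99, m))
    cov <- data.frame(
        baseline_age_years = if (is.null(age)) rep(72, ns) else age,
        sex = if (is.null(sex)) rep(0:1, length.out = ns) else sex)
    TrialCohort(dosages, meta, cov, phenotypes)
}

# Clustered Gaussian data with exchangeable correlation, for GEE tests.
exchData <- function(nClusters, sizePerCluster, rho, beta = c(1, 0.5),
                     sd = 1) {
    id <- rep(seq_len(nClusters), each = sizePerCluster)
    nobs <- length(id)
    x <- rnorm(nobs)
    shared <- rnorm(nClusters)[id]
    e <- sd * (sqrt(rho) * shared + sqrt(1 - rho) * rnorm(nobs))
    X <- cbind(intercept = 1, x = x)
    list(y = drop(X %*% beta) + e, X = X, id = id)
}
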