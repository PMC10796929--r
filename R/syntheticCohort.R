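# Synthetic trial-cohort generator: HWE genotypes with optional LD blocks,
# risk-stratified age-dependent selection into the study, and piecewise-linear
# longitudinal phenotypes with additive variant effects on any of the four
# trajectory parameters (intercept, baseline-age gradient, slope 1, slope 2).

.substream <- function(seed, k) {
    as.integer((as.numeric(seed) + 104729 * k) %% 2147483647)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator. Defaults encode
#' the study design emulated throughout: screening ages 65--83 years,
#' 6-monthly visits (182.5 days) over 5 years (so between 1 and 11
#' measurement occasions per subject), a slope change at day 365, and
#' z-score-scale phenotypes.
#'
#' @param n_candidates Number of screened individuals (before selection).
#' @param n_variants Number of biallelic variants.
#' @param allele_freq_range Alt-allele frequency range, within (0, 1).
#' @param age_range_years Baseline-age range at screening.
#' @param visit_spacing_days Scheduled spacing of visits.
#' @param max_followup_days Last scheduled visit day.
#' @param knot_days Slope-change point of the trajectory model.
#' @param dropout_prob_per_visit Per-visit probability of monotone dropout
#'   after baseline (missing at random).
#' @param resid_sd Residual SD of the latent domain process, per occasion
#'   (0 gives a noise-free deterministic trajectory, useful for geometry
#'   checks).
#' @param random_intercept_sd,random_slope_sd Subject-level random-effect
#'   SDs (slope per year).
#' @param within_corr_structure Residual correlation across occasions:
#'   `"independence"`, `"exchangeable"` or `"ar1"`.
#' @param within_corr_rho Correlation parameter for non-independence
#'   structures.
#' @param test_resid_sd Test-specific measurement noise SD (latent scale).
#' @param ld_block_size Consecutive variants per LD block (1 = none).
#' @param ld_flip_prob Per-site probability that a block member is redrawn
#'   from Hardy-Weinberg instead of copied from the block seed variant.
#' @param missing_rate Per-entry probability of a missing dosage.
#' @param inclusion_base_rate Marginal inclusion probability when both
#'   selection coefficients are zero (1 keeps every candidate).
#' @param age_ref_years Centring age for the baseline-age covariate.
#' @param traj_means Population trajectory: named vector with elements
#'   `intercept`, `age` (per year of baseline age), `slope1` and `slope2`
#'   (per year of follow-up), all in phenotype-SD units.
#' @param domain_map Named list mapping domains to component test ids;
#'   see [defaultDomainMap()].
#' @param seed Integer seed; every stochastic operation derives its own
#'   substream from it.
#'
#' @return A list of class `SimulationConfig`.
#' @examples
#' cfg <- simulationConfig(n_candidates = 100, n_variants = 20, seed = 7)
#' @export
simulationConfig <- function(n_candidates = 1000L,
                             n_variants = 100L,
                             allele_freq_range = c(0.05, 0.95),
                             age_range_years = c(65, 83),
                             visit_spacing_days = 182.5,
                             max_followup_days = 1825,
                             knot_days = 365,
                             dropout_prob_per_visit = 0.05,
                             resid_sd = 0.55,
                             random_intercept_sd = 0.7,
                             random_slope_sd = 0.08,
                             within_corr_structure = c("independence",
                                                       "exchangeable", "ar1"),
                             within_corr_rho = 0.3,
                             test_resid_sd = 0.35,
                             ld_block_size = 1L,
                             ld_flip_prob = 0.05,
                             missing_rate = 0,
                             inclusion_base_rate = 1,
                             age_ref_years = 73.4,
                             traj_means = c(intercept = 0, age = -0.03,
                                            slope1 = 0.10, slope2 = 0.02),
                             domain_map = defaultDomainMap(),
                             seed = 1L) {
    within_corr_structure <- match.arg(within_corr_structure)
    stopifnot(n_candidates >= 1, n_variants >= 1,
              length(allele_freq_range) == 2,
              all(allele_freq_range > 0), all(allele_freq_range < 1),
              visit_spacing_days > 0, max_followup_days > 0, knot_days > 0,
              dropout_prob_per_visit >= 0, dropout_prob_per_visit < 1,
              resid_sd >= 0, random_intercept_sd >= 0, random_slope_sd >= 0,
              missing_rate >= 0, missing_rate < 1,
              inclusion_base_rate > 0, inclusion_base_rate <= 1,
              all(c("intercept", "age", "slope1", "slope2") %in%
                  names(traj_means)))
    cfg <- list(n_candidates = as.integer(n_candidates),
                n_variants = as.integer(n_variants),
                allele_freq_range = sort(allele_freq_range),
                age_range_years = sort(age_range_years),
                visit_spacing_days = visit_spacing_days,
                max_followup_days = max_followup_days,
                knot_days = knot_days,
                dropout_prob_per_visit = dropout_prob_per_visit,
                resid_sd = resid_sd,
                random_intercept_sd = random_intercept_sd,
                random_slope_sd = random_slope_sd,
                within_corr_structure = within_corr_structure,
                within_corr_rho = within_corr_rho,
                test_resid_sd = test_resid_sd,
                ld_block_size = as.integer(ld_block_size),
                ld_flip_prob = ld_flip_prob,
                missing_rate = missing_rate,
                inclusion_base_rate = inclusion_base_rate,
                age_ref_years = age_ref_years,
                traj_means = traj_means,
                domain_map = domain_map,
                seed = as.integer(seed))
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Read or write a simulation configuration as YAML
#'
#' @param path File path.
#' @param config A `SimulationConfig`.
#' @return `readSimulationConfig()` returns a `SimulationConfig`.
#' @export
readSimulationConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    if (!is.null(raw$traj_means)) raw$traj_means <- unlist(raw$traj_means)
    do.call(simulationConfig, raw)
}

#' @rdname readSimulationConfig
#' @export
writeSimulationConfig <- function(config, path) {
    out <- unclass(config)
    out$traj_means <- as.list(out$traj_means)
    yaml::write_yaml(out, path)
    invisible(path)
}

#' True genetic effects and selection coefficients
#'
#' Defines per-variant effects on the four trajectory parameters and the
#' logistic selection model that draws candidates into the study. The
#' all-zero default is the global null; zero selection coefficients give
#' unbiased sampling.
#'
#' @param n_variants Number of variants (rows of `gamma`).
#' @param gamma Matrix `n_variants x 4` with columns `intercept`, `age`,
#'   `slope1`, `slope2`: additive per-allele effects, phenotype-SD units
#'   (slopes per year).
#' @param risk_variant_ids Character ids (or integer indices) of the two
#'   selection-driving risk loci.
#' @param selection_age_coeff Log-odds of inclusion per year of baseline
#'   age (centred).
#' @param selection_risk_coeff Log-odds of inclusion per risk-allele
#'   dosage summed over the risk loci.
#'
#' @return A list of class `TrueEffects`.
#' @examples
#' eff <- trueEffects(50)                     # global null
#' g <- matrix(0, 50, 4, dimnames = list(NULL,
#'      c("intercept", "age", "slope1", "slope2")))
#' g[7, "slope2"] <- -0.08
#' eff <- trueEffects(50, gamma = g)
#' @export
trueEffects <- function(n_variants,
                        gamma = NULL,
                        risk_variant_ids = NULL,
                        selection_age_coeff = 0,
                        selection_risk_coeff = 0) {
    if (is.null(gamma))
        gamma <- matrix(0, n_variants, 4)
    gamma <- as.matrix(gamma)
    stopifnot(nrow(gamma) == n_variants, ncol(gamma) == 4)
    colnames(gamma) <- c("intercept", "age", "slope1", "slope2")
    eff <- list(gamma = gamma,
                risk_variant_ids = risk_variant_ids,
                selection_age_coeff = selection_age_coeff,
                selection_risk_coeff = selection_risk_coeff)
    class(eff) <- "TrueEffects"
    eff
}

#' Default domain-to-test map
#'
#' Five cognitive domains (attention, episodic memory, executive function,
#' language, learning), each scored from five synthetic component tests.
#' The composite averages the five domain scores.
#'
#' @return Named list of character vectors of test ids.
#' @export
defaultDomainMap <- function() {
    domains <- c("attention", "episodic_memory", "executive_function",
                 "language", "learning")
    out <- lapply(domains, function(d) sprintf("%s_test%d", d, 1:5))
    names(out) <- domains
    out
}

.visitGrid <- function(config) {
    seq(0, config$max_followup_days, by = config$visit_spacing_days)
}

.variantPositions <- function(n_variants) {
    # contiguous chunks over autosomes so LD blocks stay on one chromosome
    n_chrom <- min(22L, n_variants)
    chrom_of <- sort(rep_len(seq_len(n_chrom), n_variants))
    idx_within <- sequence(tabulate(chrom_of))
    data.frame(chrom = as.character(chrom_of),
               pos = 100000L + idx_within * 5000L)
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Draws per-variant alt-allele frequencies uniformly within
#' `allele_freq_range` and genotypes from Hardy-Weinberg proportions
#' (binomial(2, p)). When `ld_block_size > 1`, consecutive variants form
#' LD blocks: members copy the block's seed variant and are independently
#' redrawn from Hardy-Weinberg at each subject with probability
#' `ld_flip_prob` (zero gives pairwise r-squared of 1 within a block).
#' Imputation quality is sampled uniformly in (0.5, 1].
#'
#' @param config A [simulationConfig()].
#' @return A list with `dosages` (variants x subjects matrix),
#'   `variantMeta` (chrom, pos, ref, alt, imputation_r2, true_freq),
#'   and `freqs`.
#' @examples
#' g <- simulateGenotypes(simulationConfig(n_candidates = 50,
#'                                         n_variants = 10, seed = 3))
#' dim(g$dosages)
#' @export
simulateGenotypes <- function(config) {
    set.seed(.substream(config$seed, 1L))
    n <- config$n_candidates
    m <- config$n_variants
    fr <- config$allele_freq_range
    if (fr[1] <= 0 || fr[2] >= 1)
        stop("degenerate allele frequencies (0 or 1) are not allowed")
    freqs <- stats::runif(m, fr[1], fr[2])
    B <- max(1L, config$ld_block_size)
    block <- rep(seq_len(ceiling(m / B)), each = B, length.out = m)
    if (B > 1L)  # one frequency per block so copies are exchangeable
        freqs <- freqs[!duplicated(block)][block]
    G <- matrix(0L, m, n)
    for (b in unique(block)) {
        members <- which(block == b)
        seedvar <- stats::rbinom(n, 2L, freqs[members[1]])
        G[members[1], ] <- seedvar
        for (j in members[-1]) {
            flip <- stats::runif(n) < config$ld_flip_prob
            gj <- seedvar
            if (any(flip))
                gj[flip] <- stats::rbinom(sum(flip), 2L, freqs[j])
            G[j, ] <- gj
        }
    }
    D <- matrix(as.numeric(G), m, n)
    if (config$missing_rate > 0)
        D[stats::runif(m * n) < config$missing_rate] <- NA_real_
    pos <- .variantPositions(m)
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), "")
    meta <- data.frame(chrom = pos$chrom, pos = pos$pos,
                       ref = ref, alt = unname(alt),
                       imputation_r2 = 0.5 + stats::runif(m) * 0.5,
                       true_freq = freqs)
    rownames(D) <- sprintf("var%04d", seq_len(m))
    colnames(D) <- sprintf("subj%05d", seq_len(n))
    rownames(meta) <- rownames(D)
    list(dosages = D, variantMeta = meta, freqs = freqs)
}

.simulateCovariates <- function(config, n) {
    set.seed(.substream(config$seed, 2L))
    ar <- config$age_range_years
    data.frame(
        baseline_age_years = stats::runif(n, ar[1], ar[2]),
        sex = stats::rbinom(n, 1L, 0.5),
        education_years = pmin(20L, pmax(6L,
            round(stats::rnorm(n, 14, 3)))),
        alcohol = round(stats::rlnorm(n, log(5), 0.8), 1),
        smoking = round(stats::rexp(n, 1 / 10) *
                        stats::rbinom(n, 1L, 0.45), 1),
        bmi = pmin(45, pmax(16, stats::rnorm(n, 27.5, 4.5))))
}

.riskIds <- function(effects, meta) {
    ids <- effects$risk_variant_ids
    if (is.null(ids)) {
        on19 <- rownames(meta)[meta$chrom == "19"]
        ids <- if (length(on19) >= 2) on19[1:2] else rownames(meta)[1:2]
    }
    if (is.numeric(ids)) ids <- rownames(meta)[ids]
    miss <- setdiff(ids, rownames(meta))
    if (length(miss))
        stop("risk variants not present: ", paste(miss, collapse = ", "))
    ids
}

#' Apply genotype- and age-dependent selection into the study
#'
#' Inclusion of each screened candidate is Bernoulli with logistic
#' probability
#' `logit(P) = logit(base) + a * (age - age_ref) + r * (d1 + d2)`,
#' where `d1`, `d2` are dosages at the two risk loci. This emulates a
#' trial that enrols by a combination of age and two established risk
#' genotypes, the mechanism that induces collider (selection) bias
#' downstream. With both coefficients zero, inclusion is uniform at the
#' base rate. A `risk_stratum` covariate (`"high"` if any risk allele is
#' carried) is added to the output.
#'
#' @param candidates A [TrialCohort-class] of screened candidates.
#' @param effects A [trueEffects()] (supplies risk loci and coefficients).
#' @param config A [simulationConfig()].
#' @return The included [TrialCohort-class]; `metadata()$inclusionLog`
#'   holds a data.frame of per-candidate inclusion probabilities and
#'   indicators, and `metadata()$riskVariantIds` the resolved risk loci.
#' @export
applySelection <- function(candidates, effects, config) {
    set.seed(.substream(config$seed, 3L))
    meta <- variantMeta(candidates)
    ids <- .riskIds(effects, meta)
    D <- dosages(candidates)
    cov <- covariates(candidates)
    drisk <- colSums(D[ids, , drop = FALSE], na.rm = TRUE)
    eta <- effects$selection_age_coeff *
               (cov$baseline_age_years - config$age_ref_years) +
           effects$selection_risk_coeff * drisk
    if (config$inclusion_base_rate >= 1 && all(eta == 0)) {
        prob <- rep(1, ncol(D))
    } else {
        base <- min(config$inclusion_base_rate, 1 - 1e-12)
        prob <- stats::plogis(stats::qlogis(base) + eta)
    }
    incl <- stats::runif(ncol(D)) < prob
    if (!any(incl))
        stop("selection excluded every candidate; relax the coefficients")
    log <- data.frame(subject_id = colnames(D), prob = prob,
                      included = incl, risk_dosage = drisk)
    out <- candidates[, incl]
    colData(out)$risk_stratum <-
        ifelse(round(drisk[incl]) >= 1, "high", "low")
    metadata(out)$inclusionLog <- log
    metadata(out)$riskVariantIds <- ids
    out
}

# deterministic per-test calibration so raw scores differ across tests
.testAffine <- function(test_ids) {
    j <- seq_along(test_ids)
    data.frame(test_id = test_ids, mean = 20 + 7 * j,
               scale = 1 + 0.25 * (j %% 5), row.names = test_ids)
}

.residualDraw <- function(n_subj, n_occ, structure, rho, sd) {
    E <- matrix(stats::rnorm(n_subj * n_occ), n_subj, n_occ)
    if (structure == "exchangeable" && rho > 0) {
        shared <- stats::rnorm(n_subj)
        E <- sqrt(rho) * shared + sqrt(1 - rho) * E
    } else if (structure == "ar1" && rho != 0) {
        for (t in 2:n_occ)
            E[, t] <- rho * E[, t - 1] + sqrt(1 - rho^2) * E[, t]
    }
    E * sd
}

#' Simulate knot-point longitudinal phenotypes
#'
#' For subject `s` at visit day `t` the latent process of every domain is
#' `mu(t) = b0 + b_age (age_s - age_ref) + b_s1 s1(t) + b_s2 s2(t)
#'  + sum_v d_sv (g0 + g_age (age_s - age_ref) + g1 s1(t) + g2 s2(t))`
#' with `s1(t) = min(t, knot)/365` and `s2(t) = max(t - knot, 0)/365`
#' in years, plus a subject random intercept and slope and occasion
#' residuals with the configured correlation structure. Component test
#' raw scores are fixed affine transforms of the latent value plus
#' test-specific noise. Dropout is monotone: once a subject misses a
#' visit, no later visit occurs; every subject keeps the baseline visit
#' (so 1 to 11 occasions under the default grid).
#'
#' @param included A [TrialCohort-class] (selected subjects).
#' @param effects A [trueEffects()].
#' @param config A [simulationConfig()].
#' @return Long-format `data.frame` with `subject_id`, `time_days`,
#'   `test_id`, `score`.
#' @export
simulateTrajectories <- function(included, effects, config) {
    if (config$resid_sd < 0) stop("resid_sd must not be negative")
    set.seed(.substream(config$seed, 4L))
    grid <- .visitGrid(config)
    n_occ <- length(grid)
    cov <- covariates(included)
    n <- nrow(cov)
    subj <- colnames(included)
    # monotone dropout: number of observed occasions per subject
    n_vis <- rep(n_occ, n)
    if (config$dropout_prob_per_visit > 0) {
        drop_at <- apply(
            matrix(stats::runif(n * (n_occ - 1)) <
                   config$dropout_prob_per_visit, n, n_occ - 1),
            1, function(z) if (any(z)) which(z)[1] else n_occ)
        n_vis <- pmin(n_vis, drop_at)
    }
    age_c <- cov$baseline_age_years - config$age_ref_years
    s1 <- pmin(grid, config$knot_days) / 365
    s2 <- pmax(grid - config$knot_days, 0) / 365
    tm <- config$traj_means
    MU <- outer(rep(1, n), tm["intercept"] + tm["slope1"] * s1 +
                               tm["slope2"] * s2) + tm["age"] * age_c
    gm <- effects$gamma
    act <- which(rowSums(abs(gm)) > 0)
    if (length(act)) {
        Dv <- dosages(included)[act, , drop = FALSE]
        Dv[is.na(Dv)] <- 0
        gsum <- drop(crossprod(Dv, gm[act, "intercept", drop = FALSE]))
        gage <- drop(crossprod(Dv, gm[act, "age", drop = FALSE]))
        gs1 <- drop(crossprod(Dv, gm[act, "slope1", drop = FALSE]))
        gs2 <- drop(crossprod(Dv, gm[act, "slope2", drop = FALSE]))
        MU <- MU + gsum + gage * age_c +
              outer(gs1, s1) + outer(gs2, s2)
    }
    u0 <- stats::rnorm(n, 0, config$random_intercept_sd)
    u1 <- stats::rnorm(n, 0, config$random_slope_sd)
    L <- MU + u0 + outer(u1, grid / 365)
    dm <- config$domain_map
    tests <- unlist(dm, use.names = FALSE)
    aff <- .testAffine(tests)
    obs <- rep(seq_len(n), n_vis)              # subject index per kept row
    occ <- unlist(lapply(n_vis, seq_len))      # occasion index per kept row
    rows <- vector("list", length(dm))
    for (d in seq_along(dm)) {
        Ld <- L + .residualDraw(n, n_occ, config$within_corr_structure,
                                config$within_corr_rho, config$resid_sd)
        lat <- Ld[cbind(obs, occ)]
        dtests <- dm[[d]]
        k <- length(dtests)
        noise <- if (config$test_resid_sd > 0)
            matrix(stats::rnorm(length(lat) * k, 0, config$test_resid_sd),
                   length(lat), k) else matrix(0, length(lat), k)
        rows[[d]] <- data.frame(
            subject_id = rep(subj[obs], k),
            time_days = rep(grid[occ], k),
            test_id = rep(dtests, each = length(lat)),
            score = as.vector(
                t(aff[dtests, "mean"] + aff[dtests, "scale"] *
                  t(lat + noise))))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Simulate a complete trial cohort
#'
#' Convenience wrapper: [simulateGenotypes()] on screened candidates,
#' candidate covariates, [applySelection()], then
#' [simulateTrajectories()] on the included subjects. All randomness is
#' driven by deterministic substreams of `config$seed`, so repeated calls
#' are bit-identical.
#'
#' @param config A [simulationConfig()].
#' @param effects A [trueEffects()]; default is the global null with no
#'   selection.
#' @return A [TrialCohort-class]; `metadata()` holds `inclusionLog` and
#'   `riskVariantIds`.
#' @examples
#' cohort <- simulateCohort(simulationConfig(n_candidates = 60,
#'                                           n_variants = 12, seed = 11))
#' table(covariates(cohort)$risk_stratum)
#' @export
simulateCohort <- function(config, effects = trueEffects(config$n_variants)) {
    g <- simulateGenotypes(config)
    cov <- .simulateCovariates(config, config$n_candidates)
    candidates <- TrialCohort(g$dosages, g$variantMeta, cov)
    included <- applySelection(candidates, effects, config)
    ph <- simulateTrajectories(included, effects, config)
    phenotypes(included) <- ph
    included
}
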