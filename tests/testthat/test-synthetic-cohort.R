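test_that("genotypes follow Hardy-Weinberg at the requested frequency", {
    cfg <- simulationConfig(n_candidates = 10000, n_variants = 5,
                            allele_freq_range = c(0.5, 0.5), seed = 101)
    g <- simulateGenotypes(cfg)
    expect_true(all(abs(rowMeans(g$dosages) - 1) < 0.03))
    expect_true(all(g$dosages %in% 0:2))
    expect_true(all(g$variantMeta$imputation_r2 > 0.5 &
                    g$variantMeta$imputation_r2 <= 1))
})

test_that("marginal genotype draws pass the package's own HWE test", {
    cfg <- simulationConfig(n_candidates = 300, n_variants = 1000,
                            seed = 77)
    g <- simulateGenotypes(cfg)
    p <- vapply(seq_len(nrow(g$dosages)), function(i) {
        d <- g$dosages[i, ]
        hweExactTest(sum(d == 0), sum(d == 1), sum(d == 2))
    }, 0)
    expect_gte(mean(p >= 1e-8), 0.999)
})

test_that("zero flip probability makes LD-block members identical", {
    cfg <- simulationConfig(n_candidates = 100, n_variants = 12,
                            ld_block_size = 4, ld_flip_prob = 0,
                            seed = 5)
    g <- simulateGenotypes(cfg)
    for (b in list(1:4, 5:8, 9:12)) {
        block <- g$dosages[b, ]
        r2 <- cor(t(block))^2
        expect_true(all(abs(r2 - 1) < 1e-12))
    }
})

test_that("the generator is deterministic given the seed", {
    cfg <- simulationConfig(n_candidates = 50, n_variants = 10, seed = 9)
    expect_identical(simulateGenotypes(cfg)$dosages,
                     simulateGenotypes(cfg)$dosages)
    c1 <- simulateCohort(cfg)
    c2 <- simulateCohort(cfg)
    expect_identical(dosages(c1), dosages(c2))
    expect_identical(phenotypes(c1), phenotypes(c2))
})

test_that("degenerate allele frequencies are rejected", {
    expect_error(simulationConfig(allele_freq_range = c(0, 0.5)))
    expect_error(simulationConfig(allele_freq_range = c(0.1, 1)))
})

test_that("null selection leaves allele frequencies unbiased", {
    cfg <- simulationConfig(n_candidates = 4000, n_variants = 6,
                            inclusion_base_rate = 0.5, seed = 13)
    g <- simulateGenotypes(cfg)
    cand <- manualCohort(g$dosages)
    eff <- trueEffects(6, risk_variant_ids = c("var0001", "var0002"))
    incl <- applySelection(cand, eff, cfg)
    f_cand <- mean(g$dosages["var0001", ]) / 2
    f_incl <- mean(dosages(incl)["var0001", ]) / 2
    expect_lt(abs(f_incl - f_cand), 0.03)
    # roughly the base rate survives
    expect_gt(ncol(incl), 0.4 * 4000)
    expect_lt(ncol(incl), 0.6 * 4000)
})

test_that("inclusion probability one returns the input unchanged", {
    cfg <- simulationConfig(n_candidates = 60, n_variants = 8, seed = 3)
    g <- simulateGenotypes(cfg)
    cand <- manualCohort(g$dosages)
    eff <- trueEffects(8, risk_variant_ids = 1:2)
    incl <- applySelection(cand, eff, cfg)   # base rate 1, no coefficients
    expect_identical(dosages(incl), dosages(cand))
    expect_identical(colnames(incl), colnames(cand))
})

test_that("strong risk selection shifts the included allele frequency", {
    cfg <- simulationConfig(n_candidates = 5000, n_variants = 4,
                            inclusion_base_rate = 0.4, seed = 21)
    g <- simulateGenotypes(cfg)
    cand <- manualCohort(g$dosages)
    eff <- trueEffects(4, risk_variant_ids = c("var0001", "var0002"),
                       selection_risk_coeff = 1)
    incl <- applySelection(cand, eff, cfg)
    log <- S4Vectors::metadata(incl)$inclusionLog
    d <- g$dosages["var0001", ]
    in_alleles <- c(sum(d[log$included]), 2 * sum(log$included))
    out_alleles <- c(sum(d[!log$included]), 2 * sum(!log$included))
    tst <- prop.test(c(in_alleles[1], out_alleles[1]),
                     c(in_alleles[2], out_alleles[2]))
    expect_lt(tst$p.value, 0.001)
    expect_gt(in_alleles[1] / in_alleles[2],
              out_alleles[1] / out_alleles[2])
})

test_that("noise-free trajectories lie exactly on the two-slope curve", {
    cfg <- simulationConfig(n_candidates = 30, n_variants = 4,
                            resid_sd = 0, random_intercept_sd = 0,
                            random_slope_sd = 0, test_resid_sd = 0,
                            dropout_prob_per_visit = 0, seed = 8)
    co <- simulateCohort(cfg)
    ph <- phenotypes(co)
    cov <- covariates(co)
    tm <- cfg$traj_means
    basis <- buildTrajectoryBasis(
        ph$time_days, cov[ph$subject_id, "baseline_age_years"],
        knot_days = cfg$knot_days, age_ref = cfg$age_ref_years)
    mu <- drop(basis %*% tm[c("intercept", "age", "slope1", "slope2")])
    # every test is an exact affine image of the latent mean curve
    for (tid in unique(ph$test_id)) {
        i <- ph$test_id == tid
        fit <- lm(ph$score[i] ~ mu[i])
        expect_lt(max(abs(resid(fit))), 1e-9)
    }
})

test_that("a negative slope-2 effect separates genotypes only after the knot", {
    m <- 5
    gam <- matrix(0, m, 4)
    gam[3, 4] <- -0.3    # slope 2 of variant 3
    cfg <- simulationConfig(n_candidates = 40, n_variants = m,
                            resid_sd = 0, random_intercept_sd = 0,
                            random_slope_sd = 0, test_resid_sd = 0,
                            dropout_prob_per_visit = 0,
                            traj_means = c(intercept = 0, age = 0,
                                           slope1 = 0, slope2 = 0),
                            seed = 30)
    co <- simulateCohort(cfg, trueEffects(m, gamma = gam,
                                          risk_variant_ids = 1:2))
    ph <- phenotypes(co)
    ph <- ph[ph$test_id == ph$test_id[1], ]
    g <- dosages(co)[3, ph$subject_id]
    at_knot <- ph$score[ph$time_days == 365]
    expect_lt(diff(range(at_knot)), 1e-9)          # identical at the knot
    end <- ph[ph$time_days == 1825, ]
    gend <- dosages(co)[3, end$subject_id]
    means <- tapply(end$score, gend, mean)
    expect_true(length(means) >= 2)
    expect_true(all(diff(means[order(as.numeric(names(means)))]) < 0))
})

test_that("occasions per subject stay within 1 and 11 with baseline kept", {
    co <- smallCohort(seed = 55, n = 150, m = 5,
                      dropout_prob_per_visit = 0.25)
    ph <- phenotypes(co)
    occ <- tapply(ph$time_days, list(ph$subject_id, ph$test_id),
                  function(t) length(unique(t)))
    expect_true(all(occ >= 1 & occ <= 11, na.rm = TRUE))
    base <- tapply(ph$time_days, ph$subject_id, min)
    expect_true(all(base == 0))
    # dropout is monotone: observed visits are a prefix of the grid
    one <- ph[ph$test_id == ph$test_id[1], ]
    for (s in unique(one$subject_id)[1:20]) {
        tt <- sort(unique(one$time_days[one$subject_id == s]))
        expect_equal(tt, seq(0, by = 182.5, length.out = length(tt)))
    }
})

test_that("risk stratum reflects risk-locus dosages", {
    co <- smallCohort(seed = 91)
    ids <- S4Vectors::metadata(co)$riskVariantIds
    drisk <- colSums(dosages(co)[ids, ])
    expect_identical(covariates(co)$risk_stratum,
                     unname(ifelse(round(drisk) >= 1, "high", "low")))
})

test_that("simulation config round-trips through YAML", {
    cfg <- simulationConfig(n_candidates = 33, n_variants = 7,
                            within_corr_structure = "ar1", seed = 2)
    f <- tempfile(fileext = ".yaml")
    writeSimulationConfig(cfg, f)
    cfg2 <- readSimulationConfig(f)
    expect_equal(cfg2$n_candidates, 33L)
    expect_equal(cfg2$within_corr_structure, "ar1")
    expect_equal(cfg2$traj_means, cfg$traj_means)
    expect_identical(simulateGenotypes(cfg)$dosages,
                     simulateGenotypes(cfg2)$dosages)
})
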