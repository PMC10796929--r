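makeWeights <- function(ids, ea, oa, beta, p = 1e-9) {
    data.frame(variant_id = ids, effect_allele = ea, other_allele = oa,
               beta = beta, p = p)
}

test_that("weight selection filters, aligns and ledgers as specified", {
    D <- rbind(v1 = c(0, 1, 2, 1), v2 = c(2, 1, 0, 1),
               v3 = c(1, 1, 0, 2), v4 = c(0, 0, 1, 2))
    colnames(D) <- paste0("s", 1:4)
    meta <- data.frame(chrom = "1", pos = c(1e5, 2e6, 4e6, 6e6),
                       ref = c("A", "A", "A", "A"),
                       alt = c("G", "G", "T", "C"))
    meta$imputation_r2 <- 0.99
    co <- TrialCohort(D, meta, data.frame(baseline_age_years = rep(70, 4),
                                          sex = c(0, 1, 0, 1)))
    w <- makeWeights(c("v1", "v2", "v3", "v4", "v9"),
                     ea = c("G", "A", "A", "T", "G"),
                     oa = c("A", "G", "T", "G", "C"),
                     beta = c(0.1, 0.2, 0.3, 0.4, 0.5),
                     p = c(1e-9, 1e-9, 1e-9, 1e-9, 1e-3))
    m <- selectAndAlign(w, co, clump = FALSE)
    wt <- as.data.frame(m@weights)
    # v1: effect allele is the cohort alt, weight kept
    expect_equal(wt$aligned_weight[wt$variant_id == "v1"], 0.1)
    # v2: effect allele is the cohort ref, weight negated
    expect_equal(wt$aligned_weight[wt$variant_id == "v2"], -0.2)
    led <- as.data.frame(m@ledger)
    expect_identical(led$reason[led$variant_id == "v3"], "ambiguous")
    expect_identical(led$reason[led$variant_id == "v9"], "source_p")
    expect_identical(led$reason[led$variant_id == "v4"],
                     "allele_mismatch")
})

test_that("perfect-LD weight pairs collapse to one variant after clumping", {
    set.seed(71)
    g <- rbinom(300, 2, 0.4)
    D <- rbind(v1 = g, v2 = g, v3 = rbinom(300, 2, 0.4))
    colnames(D) <- paste0("s", 1:300)
    meta <- data.frame(chrom = "1", pos = c(1e5, 1.5e5, 9e6),
                       ref = "A", alt = "G", imputation_r2 = 0.99)
    co <- TrialCohort(D, meta,
                      data.frame(baseline_age_years = runif(300, 65, 83),
                                 sex = rbinom(300, 1, 0.5)))
    w <- makeWeights(c("v1", "v2", "v3"), "G", "A", c(0.2, 0.1, 0.3),
                     p = c(1e-10, 1e-9, 1e-9))
    m <- selectAndAlign(w, co)
    wt <- as.data.frame(m@weights)
    expect_setequal(wt$variant_id, c("v1", "v3"))   # v2 absorbed by v1
    led <- as.data.frame(m@ledger)
    expect_identical(led$reason[led$variant_id == "v2"], "clumped")
})

test_that("the raw score is the weighted dosage sum", {
    D <- rbind(v1 = c(0, 2, 1), v2 = c(1, 0, 2), v3 = c(2, 1, 0))
    colnames(D) <- paste0("s", 1:3)
    meta <- data.frame(chrom = "1", pos = c(1, 2, 3) * 1e5, ref = "A",
                       alt = "G", imputation_r2 = 1)
    co <- TrialCohort(D, meta, data.frame(baseline_age_years = rep(70, 3),
                                          sex = c(0, 1, 0)))
    w <- makeWeights(c("v1", "v2", "v3"), "G", "A", c(0.1, -0.2, 0.3))
    m <- computePRS(selectAndAlign(w, co, clump = FALSE), co)
    raw <- attr(prsScores(m), "raw")
    # subject s1: 0*0.1 + 1*(-0.2) + 2*0.3 = 0.4
    expect_equal(raw[1], 0.4)
    expect_equal(mean(prsScores(m)), 0, tolerance = 1e-12)
    expect_equal(sd(prsScores(m)), 1, tolerance = 1e-12)
    # doubling the weights leaves the standardized score unchanged
    w2 <- w; w2$beta <- 2 * w2$beta
    m2 <- computePRS(selectAndAlign(w2, co, clump = FALSE), co)
    expect_equal(as.numeric(prsScores(m2)), as.numeric(prsScores(m)),
                 tolerance = 1e-12)
})

test_that("score is invariant to variant order and simultaneous allele flips", {
    co <- smallCohort(seed = 72, n = 100, m = 10)
    meta <- variantMeta(co)
    ok <- !(paste0(meta$ref, meta$alt) %in% c("AT", "TA", "CG", "GC"))
    ids <- rownames(meta)[ok][1:5]
    w <- makeWeights(ids, meta[ids, "alt"], meta[ids, "ref"],
                     beta = seq(0.1, 0.5, by = 0.1))
    m1 <- computePRS(selectAndAlign(w, co, clump = FALSE), co)
    m2 <- computePRS(selectAndAlign(w[5:1, ], co, clump = FALSE), co)
    expect_equal(prsScores(m1), prsScores(m2), tolerance = 1e-12)
    wf <- w
    wf$effect_allele[2] <- meta[ids[2], "ref"]
    wf$other_allele[2] <- meta[ids[2], "alt"]
    wf$beta[2] <- -wf$beta[2]
    m3 <- computePRS(selectAndAlign(wf, co, clump = FALSE), co)
    expect_equal(prsScores(m3), prsScores(m1), tolerance = 1e-12)
})

test_that("degenerate weights are rejected", {
    co <- smallCohort(seed = 73, n = 30, m = 6)
    meta <- variantMeta(co)
    ok <- which(!(paste0(meta$ref, meta$alt) %in%
                  c("AT", "TA", "CG", "GC")))[1:2]
    w0 <- makeWeights(rownames(meta)[ok], meta$alt[ok], meta$ref[ok],
                      beta = c(0, 0))
    expect_error(computePRS(selectAndAlign(w0, co, clump = FALSE), co),
                 "constant")
    wnone <- makeWeights("nope", "A", "G", 0.5, p = 0.5)
    expect_error(selectAndAlign(wnone, co), "no variants")
})

test_that("a score acting on the baseline level is recovered", {
    set.seed(74)
    covered <- 0
    for (r in 1:10) {
        cfg <- simulationConfig(n_candidates = 500, n_variants = 20,
                                domain_map = list(gd = "gd_test1"),
                                traj_means = c(intercept = 0, age = 0,
                                               slope1 = 0.1,
                                               slope2 = 0.02),
                                seed = 7400 + r)
        gam <- matrix(0, 20, 4)
        gam[5, 1] <- 0.25                # intercept effect at one variant
        co <- simulateCohort(cfg, trueEffects(20, gamma = gam,
                                              risk_variant_ids = 1:2))
        # single-variant score built directly from the causal dosage
        raw <- 0.25 * dosages(co)["var0005", ]
        score <- (raw - mean(raw)) / sd(raw)
        # truth per SD of score on the z-scored outcome
        sdd <- sd(dosages(co)["var0005", ])
        s_base <- sqrt(cfg$random_intercept_sd^2 + cfg$resid_sd^2 +
                       cfg$test_resid_sd^2 + 0.25^2 * sdd^2)
        truth <- 0.25 * sdd / s_base
        assoc <- testPRSTrajectory(co, score, family = "gee", nPCs = 2,
                                   domainMap = list(gd = "gd_test1"))
        row <- assoc[assoc$parameter == "intercept", ]
        if (abs(row$beta - truth) < 2 * row$se) covered <- covered + 1
    }
    expect_gte(covered, 8)
})

test_that("a permuted score is null across the four parameters", {
    set.seed(75)
    co <- smallCohort(seed = 76, n = 250, m = 12,
                      domain_map = list(gd = "gd_test1"))
    oc <- prepareOutcomes(co, list(gd = "gd_test1"))
    rejections <- 0; total <- 0
    for (r in 1:30) {
        score <- rnorm(ncol(co))
        names(score) <- colnames(co)
        score <- (score - mean(score)) / sd(score)
        assoc <- testPRSTrajectory(co, score, family = "gee",
                                   outcomeRows = oc, nPCs = 2)
        rejections <- rejections + sum(assoc$p < 0.05)
        total <- total + 4
    }
    # 99% binomial band around 0.05 for 120 tests
    expect_lt(rejections / total, 0.05 + 2.576 * sqrt(0.05 * 0.95 / total))
})

test_that("an LMM-based PRS association runs and matches GEE closely", {
    co <- smallCohort(seed = 77, n = 150, m = 10,
                      domain_map = list(gd = "gd_test1"))
    oc <- prepareOutcomes(co, list(gd = "gd_test1"))
    set.seed(77)
    score <- rnorm(ncol(co)); names(score) <- colnames(co)
    a1 <- testPRSTrajectory(co, score, family = "lmm",
                            outcomeRows = oc, nPCs = 2)
    a2 <- testPRSTrajectory(co, score, family = "gee",
                            outcomeRows = oc, nPCs = 2)
    expect_equal(a1$beta, a2$beta, tolerance = 0.05)
    expect_identical(a1$parameter,
                     c("intercept", "age", "slope1", "slope2"))
})

test_that("Bonferroni thresholds reproduce conventional reporting", {
    expect_equal(bonferroniThreshold(6), 0.008)
    expect_equal(bonferroniThreshold(72), 7e-4)
    expect_equal(bonferroniThreshold(1), 0.05)
    expect_error(bonferroniThreshold(0), ">= 1")
})

test_that("weights tables round-trip through TSV", {
    w <- makeWeights(c("v1", "v2"), c("A", "C"), c("G", "T"),
                     c(0.12, -0.3), p = c(1e-9, 2e-10))
    w$chrom <- "3"; w$pos <- c(100L, 200L)
    f <- tempfile(fileext = ".tsv")
    writeWeights(w, f)
    expect_equal(readWeights(f), w)
})
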