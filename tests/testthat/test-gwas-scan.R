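test_that("scan records carry four calibrated parameter blocks", {
    co <- smallCohort(seed = 41, n = 120, m = 20)
    sc <- runScan(co, nPCs = 3)
    rec <- records(sc)
    expect_equal(nrow(rec), 20)
    for (pp in c("intercept", "age", "slope1", "slope2")) {
        p <- rec[[paste0("p_", pp)]]
        expect_true(all(p > 0 & p <= 1, na.rm = TRUE))
        expect_equal(rec[[paste0("z_", pp)]],
                     rec[[paste0("beta_", pp)]] / rec[[paste0("se_", pp)]])
    }
    expect_true(all(c("p_joint", "eaf", "effect_allele") %in%
                    colnames(rec)))
})

test_that("monomorphic variants error in scanVariant, are logged in runScan", {
    co <- smallCohort(seed = 42, n = 60, m = 10)
    D <- dosages(co)
    D["var0003", ] <- 2
    co2 <- TrialCohort(D, variantMeta(co), covariates(co),
                       phenotypes(co))
    S4Vectors::metadata(co2)$riskVariantIds <-
        S4Vectors::metadata(co)$riskVariantIds
    expect_error(scanVariant(co2, "var0003", nPCs = 2), "monomorphic")
    sc <- runScan(co2, nPCs = 2)
    rec <- records(sc)
    expect_true(is.na(rec["var0003", "p_slope2"]))
    expect_false(rec["var0003", "converged"])
    # the risk-locus covariates are collinear with themselves when
    # scanned, so only they and the monomorphic variant lack records
    other <- setdiff(rownames(rec),
                     c("var0003",
                       S4Vectors::metadata(co2)$riskVariantIds))
    expect_false(any(is.na(rec[other, "p_slope2"])))
})

test_that("duplicated variant columns give identical scan records", {
    co <- smallCohort(seed = 43, n = 80, m = 12)
    D <- dosages(co)
    D["var0006", ] <- D["var0005", ]
    co2 <- TrialCohort(D, variantMeta(co), covariates(co),
                       phenotypes(co))
    S4Vectors::metadata(co2)$riskVariantIds <- c("var0001", "var0002")
    rec <- records(runScan(co2, nPCs = 2))
    cols <- grep("^(beta|se|z|p)_", colnames(rec), value = TRUE)
    expect_equal(unlist(rec["var0005", cols]),
                 unlist(rec["var0006", cols]), tolerance = 1e-10)
})

test_that("permuted genotypes are null in all four parameters", {
    co <- smallCohort(seed = 44, n = 250, m = 10)
    set.seed(44)
    g <- dosages(co)["var0007", ]
    D <- t(vapply(1:100, function(i) sample(g), numeric(length(g))))
    rownames(D) <- sprintf("perm%03d", 1:100)
    colnames(D) <- colnames(co)
    meta <- data.frame(chrom = "2", pos = 1000L * (1:100), ref = "A",
                       alt = "G", imputation_r2 = 0.99)
    cols <- c("chrom", "pos", "ref", "alt", "imputation_r2")
    co2 <- TrialCohort(rbind(dosages(co), D),
                       rbind(variantMeta(co)[, cols], meta),
                       covariates(co), phenotypes(co))
    S4Vectors::metadata(co2)$riskVariantIds <- c("var0001", "var0002")
    rec <- records(runScan(co2, variants = rownames(D), nPCs = 2))
    z <- as.matrix(rec[, paste0("z_",
                                c("intercept", "age", "slope1", "slope2"))])
    expect_true(all(abs(z) < 4))
})

test_that("an injected slope effect is recovered with the right sign", {
    hits <- 0
    for (r in 1:20) {
        m <- 10
        gam <- matrix(0, m, 4)
        gam[5, 3] <- 0.15                 # slope-1 effect
        cfg <- simulationConfig(
            n_candidates = 2000, n_variants = m, seed = 4400 + r,
            domain_map = list(gd = "gd_test1"),
            traj_means = c(intercept = 0, age = -0.02, slope1 = 0.1,
                           slope2 = 0.02))
        co <- simulateCohort(cfg, trueEffects(m, gamma = gam,
                                              risk_variant_ids = 1:2))
        rec <- scanVariant(co, "var0005", nPCs = 2,
                           domainMap = list(gd = "gd_test1"))
        if (rec$beta_slope1 > 0) hits <- hits + 1
    }
    expect_gte(hits, 19)
})

test_that("a strong causal slope-2 variant is the minimum-p variant", {
    m <- 30
    gam <- matrix(0, m, 4)
    gam[17, 4] <- -0.25
    cfg <- simulationConfig(n_candidates = 600, n_variants = m,
                            seed = 46, domain_map = list(gd = "gd_test1"))
    co <- simulateCohort(cfg, trueEffects(m, gamma = gam,
                                          risk_variant_ids = 1:2))
    rec <- records(runScan(co, outcome = "global", nPCs = 3,
                           domainMap = list(gd = "gd_test1")))
    expect_identical(rownames(rec)[which.min(rec$p_slope2)], "var0017")
    expect_lt(rec["var0017", "beta_slope2"], 0)
})

test_that("scan results are invariant to subject ordering", {
    co <- smallCohort(seed = 47, n = 60, m = 8)
    set.seed(47)
    perm <- sample(ncol(co))
    co2 <- co[, perm]
    ph <- phenotypes(co)
    phenotypes(co2) <- ph[sample(nrow(ph)), ]
    r1 <- records(runScan(co, nPCs = 2))
    r2 <- records(runScan(co2, nPCs = 2))
    cols <- grep("^(beta|p)_", colnames(r1), value = TRUE)
    expect_equal(as.matrix(r1[rownames(r1), cols]),
                 as.matrix(r2[rownames(r1), cols]), tolerance = 1e-6)
})

test_that("genomic lambda follows the median chi-square definition", {
    med <- qchisq(0.5, 1)
    expect_equal(genomicLambda(chisq = rep(med, 11)), 1)
    expect_equal(genomicLambda(chisq = rep(2 * med, 11)), 2)
    set.seed(48)
    expect_lt(abs(genomicLambda(p = runif(1e5)) - 1), 0.01)
    expect_error(genomicLambda(), "empty")
    expect_error(genomicLambda(p = numeric(0)), "empty")
})

test_that("greedy clumping follows p-order, window and r2 rules", {
    set.seed(49)
    n <- 500
    z1 <- rnorm(n); z2 <- rnorm(n); z3 <- rnorm(n)
    D <- rbind(A = z1,
               B = sqrt(0.5) * z1 + sqrt(0.5) * z2,
               C = sqrt(0.5) * (sqrt(0.5) * z1 + sqrt(0.5) * z2) +
                   sqrt(0.5) * z3)
    # A-B and B-C correlated (~0.5 r2), A-C weak (~0.25 r2 via chain)
    C_indep <- rnorm(n)
    rec <- data.frame(variant_id = c("A", "B", "C"), chrom = "1",
                      pos = c(1e5, 2e5, 3e5),
                      p_slope2 = c(1e-10, 1e-9, 1e-8))
    # pair in strong LD: one clump, best p indexes it
    D2 <- rbind(A = z1, B = 0.9 * z1 + sqrt(1 - 0.81) * z2,
                C = C_indep)
    cl <- clumpVariants(rec, "slope2", D2, r2Threshold = 0.1)
    expect_identical(cl$index_variant[cl$variant_id == "A"], "A")
    expect_identical(cl$index_variant[cl$variant_id == "B"], "A")
    expect_identical(cl$index_variant[cl$variant_id == "C"], "C")
    # independent pair: two indexes
    D3 <- rbind(A = z1, B = z2, C = z3)
    cl3 <- clumpVariants(rec[1:2, ], "slope2", D3, r2Threshold = 0.1)
    expect_identical(cl3$index_variant, c("A", "B"))
    # chain: A absorbs B; C (weakly linked to A) indexes itself
    cl4 <- clumpVariants(rec, "slope2", D, r2Threshold = 0.4)
    expect_identical(cl4$index_variant[cl4$variant_id == "B"], "A")
    expect_identical(cl4$index_variant[cl4$variant_id == "C"], "C")
    # outside the window nothing is absorbed regardless of LD
    recw <- rec
    recw$pos <- c(1e5, 1e5 + 2e6, 3e6)
    clw <- clumpVariants(recw[1:2, ], "slope2", D2, r2Threshold = 0.1,
                         windowKb = 1000)
    expect_identical(clw$index_variant, c("A", "B"))
})

test_that("clump output satisfies its structural invariants", {
    co <- smallCohort(seed = 50, n = 100, m = 30, ld_block_size = 5,
                      ld_flip_prob = 0.05)
    sc <- runScan(co, nPCs = 2)
    rec <- records(sc)
    cl <- clumpVariants(sc, "slope1", dosages(co), pThreshold = 0.5,
                        r2Threshold = 0.2)
    expect_true(all(cl$variant_id[cl$variant_id == cl$index_variant]
                    %in% rec$variant_id))
    idx <- unique(cl$index_variant)
    D <- dosages(co)
    for (i in idx) for (j in idx) {
        if (i == j) next
        same_chr <- rec[i, "chrom"] == rec[j, "chrom"]
        close <- abs(rec[i, "pos"] - rec[j, "pos"]) <= 1e6
        if (same_chr && close)
            expect_lt(cor(D[i, ], D[j, ])^2, 0.2)
    }
    ab <- cl[cl$variant_id != cl$index_variant, ]
    if (nrow(ab))
        expect_true(all(ab$r2_with_index >= 0.2))
})

test_that("external lookups harmonise alleles and apply Bonferroni", {
    co <- smallCohort(seed = 51, n = 80, m = 12)
    sc <- runScan(co, nPCs = 2)
    rec <- records(sc)
    v <- rownames(rec)[3]
    ext <- data.frame(
        variant_id = c(v, v, "rs_absent"),
        effect_allele = c(rec[v, "effect_allele"],
                          rec[v, "other_allele"], "A"))
    # build a 166-variant family so the threshold matches 0.05/664
    ext <- rbind(ext, data.frame(
        variant_id = sprintf("rs%03d", 1:163), effect_allele = "A"))
    out <- lookupVariants(sc, ext)
    expect_equal(out$beta_slope2[1], rec[v, "beta_slope2"])
    expect_equal(out$beta_slope2[2], -rec[v, "beta_slope2"])
    expect_equal(out$eaf[2], 1 - rec[v, "eaf"])
    expect_identical(out$status[3], "not_tested")
    expect_true(all(is.na(out[3, c("beta_slope1", "p_slope1")])))
    expect_equal(out$bonferroni_threshold[1], 0.05 / (166 * 4))
    expect_equal(signif(out$bonferroni_threshold[1], 1), 8e-5)
})

test_that("qq data and summary TSV round out the scan outputs", {
    co <- smallCohort(seed = 52, n = 60, m = 10)
    sc <- runScan(co, nPCs = 2)
    qq <- qqData(sc, "intercept")
    expect_equal(nrow(qq), sum(!is.na(records(sc)$p_intercept)))
    expect_gte(nrow(qq), 8)
    expect_true(all(diff(qq$observed) <= 0 | diff(qq$observed) >= 0))
    f <- tempfile(fileext = ".tsv")
    writeScanSummary(sc, f)
    back <- read.delim(f)
    expect_equal(nrow(back), 10)
    expect_equal(back$p_slope2, records(sc)$p_slope2, tolerance = 1e-12)
})
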