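# Selection (collider) bias diagnostic: among included subjects, genetic
# variants should be independent of both age and sex; a variant that
# drives selection into the study becomes associated with them. We run a
# GWAS of baseline age (linear, robust SEs) and of sex (logistic) with
# one row per subject, flag genome-wide significant loci, and feed their
# dosages into the scan covariate set.

#' Logistic regression by Newton-Raphson with separation detection
#'
#' Maximum-likelihood logistic fit with step-halving. Complete separation
#' (the likelihood increasing along a diverging coefficient path) is
#' detected by coefficient magnitude and flagged rather than silently
#' returning huge estimates; flagged fits carry missing p-values.
#'
#' @param X Design matrix (include your own intercept column).
#' @param y 0/1 outcome.
#' @param maxIter,tol Convergence control on the score step.
#' @return List with `beta`, `cov` (inverse information), `se`, `z`, `p`,
#'   `converged`, `separation`.
#' @examples
#' fitLogistic(matrix(1, 100), rep(c(0, 1), c(75, 25)))$beta  # log(1/3)
#' @export
fitLogistic <- function(X, y, maxIter = 50L, tol = 1e-10) {
    X <- as.matrix(X)
    stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y))
    if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
    p <- ncol(X)
    beta <- numeric(p)
    dev_old <- Inf
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        eta <- drop(X %*% beta)
        mu <- stats::plogis(eta)
        W <- mu * (1 - mu)
        info <- crossprod(X, X * W)
        score <- crossprod(X, y - mu)
        step <- tryCatch(solve(info, score), error = function(e) NULL)
        if (is.null(step)) break
        dev <- function(b) {
            e <- drop(X %*% b)
            # stable log(1 + exp(e))
            lse <- pmax(e, 0) + log1p(exp(-abs(e)))
            -2 * sum(y * e - lse)
        }
        lambda <- 1
        repeat {  # step-halving
            cand <- beta + lambda * drop(step)
            if (dev(cand) <= dev_old + 1e-10 || lambda < 1e-4) break
            lambda <- lambda / 2
        }
        beta <- beta + lambda * drop(step)
        dev_old <- dev(beta)
        if (max(abs(lambda * step)) < tol) { converged <- TRUE; break }
    }
    separation <- max(abs(beta)) > 15
    eta <- drop(X %*% beta)
    W <- stats::plogis(eta) * (1 - stats::plogis(eta))
    cov <- tryCatch(solve(crossprod(X, X * W)),
                    error = function(e) matrix(NA_real_, p, p))
    se <- sqrt(diag(cov))
    z <- beta / se
    pval <- 2 * stats::pnorm(-abs(z))
    if (separation) pval <- rep(NA_real_, p)
    list(beta = drop(beta), cov = cov, se = se, z = drop(z),
         p = pval, converged = converged, separation = separation)
}

# vectorised per-variant simple linear regression with HC1 robust SEs
.bulkLinearScan <- function(G, y, adjust = NULL) {
    n <- length(y)
    if (!is.null(adjust)) {            # Frisch-Waugh residualisation
        A <- cbind(1, as.matrix(adjust))
        Q <- qr(A)
        y <- stats::lm.fit(A, y)$residuals
        G <- G - t(qr.fitted(Q, t(G)))
        dfad <- ncol(A)
    } else dfad <- 1L
    gc_ <- G - rowMeans(G)
    yc <- y - mean(y)
    Sxx <- rowSums(gc_^2)
    ok <- Sxx > 1e-12
    beta <- drop(gc_ %*% yc) / Sxx
    E <- matrix(yc, nrow(G), n, byrow = TRUE) - beta * gc_
    meat <- rowSums((gc_ * E)^2)
    se <- sqrt(meat * n / (n - dfad - 1)) / Sxx
    beta[!ok] <- se[!ok] <- NA_real_
    data.frame(beta = beta, se = se, z = beta / se,
               p = 2 * stats::pnorm(-abs(beta / se)),
               status = ifelse(ok, "ok", "monomorphic"))
}

# vectorised per-variant logistic regression (intercept + dosage), with an
# optional fixed offset from a covariate-only fit
.bulkLogisticScan <- function(G, y, offset = NULL, maxIter = 30L) {
    m <- nrow(G); n <- length(y)
    if (is.null(offset)) offset <- numeric(n)
    a <- rep(stats::qlogis(max(min(mean(y), 1 - 1e-6), 1e-6)), m)
    b <- numeric(m)
    Y <- matrix(y, m, n, byrow = TRUE)
    OFF <- matrix(offset, m, n, byrow = TRUE)
    for (it in seq_len(maxIter)) {
        MU <- stats::plogis(a + b * G + OFF)
        W <- MU * (1 - MU)
        R <- Y - MU
        U1 <- rowSums(R)
        U2 <- rowSums(G * R)
        I11 <- rowSums(W)
        I12 <- rowSums(W * G)
        I22 <- rowSums(W * G * G)
        det <- I11 * I22 - I12^2
        det[abs(det) < 1e-12] <- NA
        da <- (I22 * U1 - I12 * U2) / det
        db <- (I11 * U2 - I12 * U1) / det
        da[is.na(da)] <- 0; db[is.na(db)] <- 0
        da <- pmin(pmax(da, -5), 5); db <- pmin(pmax(db, -5), 5)
        a <- a + da; b <- b + db
        if (max(abs(da), abs(db)) < 1e-8) break
    }
    MU <- stats::plogis(a + b * G + OFF)
    W <- MU * (1 - MU)
    I11 <- rowSums(W); I12 <- rowSums(W * G); I22 <- rowSums(W * G * G)
    det <- I11 * I22 - I12^2
    se <- sqrt(I11 / det)
    sep <- abs(b) > 15 | !is.finite(se)
    mono <- .rowVars(G) < 1e-12
    beta <- b; beta[mono] <- NA
    se[mono | sep] <- NA
    p <- 2 * stats::pnorm(-abs(beta / se))
    data.frame(beta = beta, se = se, z = beta / se, p = p,
               status = ifelse(mono, "monomorphic",
                               ifelse(sep, "separation", "ok")))
}

# row variances without extra dependencies
.rowVars <- function(G) {
    rowSums((G - rowMeans(G))^2) / (ncol(G) - 1)
}

#' GWAS of a selection-sensitive covariate (age or sex)
#'
#' One row per subject: per variant, baseline age is regressed linearly
#' on dosage (robust HC1 standard errors) or sex is fitted by logistic
#' regression on dosage. Monomorphic variants are skipped with status
#' `"monomorphic"`; logistic separation is flagged. Supply `adjust`
#' (e.g. flagged risk-locus dosages) to condition the diagnostic:
#' linear models are exactly residualised, the logistic model uses the
#' covariate-only linear predictor as a fixed offset.
#'
#' @param cohort A [TrialCohort-class].
#' @param trait `"age"` or `"sex"`.
#' @param adjust Optional subjects x q matrix of adjustment covariates.
#' @return `data.frame` with `variant_id`, `beta`, `se`, `z`, `p`,
#'   `status`; attribute `"lambda"` holds the genomic-control lambda over
#'   the tested variants.
#' @export
scanCovariate <- function(cohort, trait = c("age", "sex"), adjust = NULL) {
    trait <- match.arg(trait)
    G <- dosages(cohort)
    if (anyNA(G)) {
        mu <- rowMeans(G, na.rm = TRUE)
        idx <- which(is.na(G), arr.ind = TRUE)
        G[idx] <- mu[idx[, 1]]
    }
    cov <- covariates(cohort)
    out <- if (trait == "age") {
        .bulkLinearScan(G, cov$baseline_age_years, adjust = adjust)
    } else {
        offset <- NULL
        if (!is.null(adjust)) {
            base <- fitLogistic(cbind(1, adjust), cov$sex)
            offset <- drop(as.matrix(adjust) %*% base$beta[-1])
        }
        .bulkLogisticScan(G, cov$sex, offset = offset)
    }
    out <- cbind(variant_id = rownames(G), out)
    rownames(out) <- NULL
    pv <- out$p[!is.na(out$p)]
    attr(out, "lambda") <- if (length(pv)) genomicLambda(pv) else NA_real_
    out
}

#' Selection-bias report over both traits
#'
#' Runs [scanCovariate()] for age and sex and collects flagged variants
#' (genome-wide significant association with either trait).
#'
#' @param cohort A [TrialCohort-class].
#' @param threshold Flagging threshold, matching the scan's genome-wide
#'   criterion (default 5e-8).
#' @return List with `report` (merged per-variant table), `flagged`
#'   (variant ids), `lambda_age`, `lambda_sex`, `threshold`.
#' @examples
#' cohort <- simulateCohort(simulationConfig(n_candidates = 60,
#'                                           n_variants = 10, seed = 5))
#' selectionReport(cohort)$flagged
#' @export
selectionReport <- function(cohort, threshold = 5e-8) {
    age <- scanCovariate(cohort, "age")
    sex <- scanCovariate(cohort, "sex")
    rep_ <- data.frame(variant_id = age$variant_id,
                       beta_age = age$beta, se_age = age$se, p_age = age$p,
                       beta_sex = sex$beta, se_sex = sex$se,
                       p_sex = sex$p)
    flagged <- rep_$variant_id[
        (!is.na(rep_$p_age) & rep_$p_age < threshold) |
        (!is.na(rep_$p_sex) & rep_$p_sex < threshold)]
    list(report = rep_, flagged = flagged,
         lambda_age = attr(age, "lambda"),
         lambda_sex = attr(sex, "lambda"), threshold = threshold)
}

#' Turn flagged selection loci into scan covariates
#'
#' Returns the dosage columns of the flagged variants (subjects x
#' n_flagged, mean-imputed), ready to append to the GWAS covariate set.
#' An empty flag set returns a zero-column matrix, leaving the covariate
#' set unchanged.
#'
#' @param report Output of [selectionReport()].
#' @param cohort The same [TrialCohort-class].
#' @return Numeric matrix, subjects x flagged variants.
#' @export
flagSelectionLoci <- function(report, cohort) {
    ids <- report$flagged
    G <- dosages(cohort)
    if (!length(ids))
        return(matrix(numeric(0), ncol(G), 0,
                      dimnames = list(colnames(G), NULL)))
    M <- t(G[ids, , drop = FALSE])
    for (j in seq_len(ncol(M))) {
        mj <- M[, j]
        mj[is.na(mj)] <- mean(mj, na.rm = TRUE)
        M[, j] <- mj
    }
    M
}
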