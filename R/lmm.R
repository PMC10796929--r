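# Gaussian linear mixed model (REML) with subject-level random intercept
# and slope, used for stage-1 model exploration, the GEE/MLM equivalence
# check and PRS trajectory testing. Estimation is delegated to lme4.

#' Fit a linear mixed model with random intercept and slope
#'
#' REML fit of `y ~ X + (1 + time | id)` via [lme4::lmer()]. When no
#' cluster has two or more observations the random slope is not
#' identifiable; the model drops to a random intercept with a warning
#' (`randomSlope = FALSE` forces that simpler model).
#'
#' @param y Outcome vector.
#' @param X Fixed-effect design matrix (include the intercept column).
#' @param id Subject identifier per row.
#' @param time Total follow-up time per row, in years, for the random
#'   slope.
#' @param randomSlope Include a random slope (default TRUE).
#' @return An [LMMFit-class] with fixed effects, their covariance,
#'   variance components (`var_intercept`, `var_slope`,
#'   `cov_int_slope`, `var_resid`) and the REML log-likelihood.
#' @examples
#' set.seed(2)
#' id <- rep(1:30, each = 4)
#' tt <- rep(0:3, 30) / 2
#' y <- 0.5 + rnorm(30)[id] + 0.2 * tt + rnorm(120, 0, 0.5)
#' fitLMM(y, cbind(intercept = 1, t = tt), id, tt)
#' @export
fitLMM <- function(y, X, id, time, randomSlope = TRUE) {
    X <- as.matrix(X)
    if (is.null(colnames(X)))
        colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
    stopifnot(length(y) == nrow(X), length(id) == nrow(X),
              length(time) == nrow(X))
    sizes <- table(id)
    if (max(sizes) < 2) {
        # no repeated measures at all: no random effect is identifiable,
        # fall back to the fixed-effect (OLS) fit
        warning("all clusters are singletons; random slope and intercept ",
                "are not identifiable - returning the fixed-effects fit")
        fit <- stats::lm.fit(X, y)
        s2 <- sum(fit$residuals^2) / (length(y) - ncol(X))
        fc <- s2 * solve(crossprod(X))
        dimnames(fc) <- list(colnames(X), colnames(X))
        beta <- fit$coefficients
        names(beta) <- colnames(X)
        ll <- -0.5 * length(y) * (log(2 * pi * s2) + 1)
        return(new("LMMFit", fixef = beta, fixefCov = fc,
                   varcomp = c(var_intercept = 0, var_slope = 0,
                               cov_int_slope = 0, var_resid = s2),
                   logLik = ll, converged = TRUE, randomSlope = FALSE))
    }
    if (randomSlope && sum(sizes >= 2) < 3) {
        warning("too few clusters with repeated measures; ",
                "dropping the random slope")
        randomSlope <- FALSE
    }
    dat <- data.frame(.y = y, .id = id, .t = time)
    dat$.X <- X
    form <- if (randomSlope)
        .y ~ 0 + .X + (1 + .t | .id) else .y ~ 0 + .X + (1 | .id)
    fit <- suppressMessages(lme4::lmer(form, data = dat, REML = TRUE,
        control = lme4::lmerControl(check.conv.singular = "ignore",
                                    calc.derivs = FALSE)))
    vc <- lme4::VarCorr(fit)
    v_id <- vc$.id
    varcomp <- c(var_intercept = unname(v_id[1, 1]),
                 var_slope = if (randomSlope) unname(v_id[2, 2]) else 0,
                 cov_int_slope = if (randomSlope) unname(v_id[1, 2]) else 0,
                 var_resid = stats::sigma(fit)^2)
    fe <- lme4::fixef(fit)
    names(fe) <- sub("^\\.X", "", names(fe))
    fc <- as.matrix(stats::vcov(fit))
    dimnames(fc) <- list(names(fe), names(fe))
    conv <- length(fit@optinfo$conv$lme4) == 0
    new("LMMFit", fixef = fe, fixefCov = fc, varcomp = varcomp,
        logLik = as.numeric(stats::logLik(fit)), converged = conv,
        randomSlope = randomSlope)
}
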