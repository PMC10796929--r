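# End-to-end pipeline: simulate (or load) -> phenotype preparation ->
# variant QC -> selection-bias check -> per-outcome trajectory GWAS ->
# clumping -> optional PRS associations, with a provenance record. All
# stochastic stages run off deterministic substreams of one seed, so a
# rerun with the same configuration reproduces every numeric output.

#' Pipeline run configuration
#'
#' @param simulation A [simulationConfig()] (or `NULL` when `paths` are
#'   supplied).
#' @param effects A [trueEffects()]; defaults to the global null.
#' @param paths Optional named list (`vcf`, `phenotypes`, `covariates`)
#'   to load a cohort instead of simulating.
#' @param outcomes Outcome names to scan; default the global composite
#'   plus the five domains.
#' @param thresholds QC thresholds, defaulting to
#'   [defaultQCThresholds()].
#' @param genomewideThreshold Genome-wide significance level (5e-8).
#' @param corstr Working correlation for the scan GEE.
#' @param nPCs Number of ancestry principal components.
#' @param clumpR2,clumpWindowKb Clumping parameters.
#' @param prsWeights Optional named list of weights tables (or file
#'   paths) for PRS association, one per trait.
#' @param domainMap Domain-to-test map.
#' @return A list of class `RunConfig`.
#' @export
runConfig <- function(simulation = simulationConfig(),
                      effects = NULL, paths = NULL,
                      outcomes = c("global", "attention",
                                   "episodic_memory", "executive_function",
                                   "language", "learning"),
                      thresholds = defaultQCThresholds(),
                      genomewideThreshold = 5e-8,
                      corstr = "exchangeable", nPCs = 5,
                      clumpR2 = 0.1, clumpWindowKb = 1000,
                      prsWeights = NULL,
                      domainMap = defaultDomainMap()) {
    thresholds <- utils::modifyList(defaultQCThresholds(), thresholds)
    cfg <- list(simulation = simulation, effects = effects, paths = paths,
                outcomes = outcomes, thresholds = thresholds,
                genomewideThreshold = genomewideThreshold,
                corstr = corstr, nPCs = nPCs, clumpR2 = clumpR2,
                clumpWindowKb = clumpWindowKb, prsWeights = prsWeights,
                domainMap = domainMap)
    class(cfg) <- "RunConfig"
    cfg
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: cohort acquisition (simulate or load), phenotype
#' preparation (baseline z-scores, domain and composite averages),
#' variant QC with an exclusion ledger, the age/sex selection-bias
#' diagnostic (flagged loci join the scan covariates), one trajectory
#' GWAS per outcome with summary TSV and per-parameter clump tables, and
#' optional PRS associations. A `provenance.json` records the
#' configuration hash, seed and package version.
#'
#' @param config A [runConfig()].
#' @param outDir Output directory for summaries, ledgers and provenance.
#' @return Invisible list: `cohort`, `qc`, `selection`, `scans` (one
#'   [ScanResult-class] per outcome), `clumps`, `prs`, `outDir`.
#' @examples
#' \donttest{
#' cfg <- runConfig(simulationConfig(n_candidates = 60, n_variants = 12,
#'                                   seed = 4),
#'                  thresholds = list(emac = 5), outcomes = "global")
#' res <- runPipeline(cfg, outDir = tempfile("run"))
#' }
#' @export
runPipeline <- function(config, outDir) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    cohort <- .stage("cohort", {
        if (!is.null(config$paths))
            readCohort(config$paths$vcf, config$paths$phenotypes,
                       config$paths$covariates)
        else {
            eff <- config$effects
            if (is.null(eff))
                eff <- trueEffects(config$simulation$n_variants)
            simulateCohort(config$simulation, eff)
        }
    })
    outcomeRows <- .stage("phenotypes",
                          prepareOutcomes(cohort, config$domainMap))
    qc <- .stage("qc", {
        st <- variantQCStats(cohort)
        fl <- filterVariants(st, config$thresholds)
        utils::write.table(fl$ledger,
                           file.path(outDir, "qc_exclusions.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        c(fl, list(stats = st))
    })
    if (!length(qc$kept))
        stop("pipeline stage 'qc' failed: no variants pass QC")
    selection <- .stage("selection", {
        rep_ <- selectionReport(cohort[qc$kept, ],
                                threshold = config$genomewideThreshold)
        utils::write.table(rep_$report,
                           file.path(outDir, "selection_report.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        rep_
    })
    riskIds <- union(metadata(cohort)$riskVariantIds, selection$flagged)
    pcs <- .stage("pca", genotypePCA(cohort[qc$kept, ],
                                     k = config$nPCs)$scores)
    scans <- list()
    clumps <- list()
    for (oc in config$outcomes) {
        scans[[oc]] <- .stage(paste0("scan:", oc),
            runScan(cohort, outcome = oc, variants = qc$kept,
                    corstr = config$corstr,
                    threshold = config$genomewideThreshold,
                    outcomeRows = outcomeRows, pcs = pcs,
                    riskVariantIds = riskIds))
        writeScanSummary(scans[[oc]],
                         file.path(outDir,
                                   sprintf("summary_%s.tsv", oc)))
        cl <- lapply(.PARAMS, function(pp)
            clumpVariants(scans[[oc]], pp, dosages(cohort),
                          pThreshold = config$genomewideThreshold,
                          r2Threshold = config$clumpR2,
                          windowKb = config$clumpWindowKb))
        cl <- do.call(rbind, Map(function(d, pp)
            if (nrow(d)) cbind(parameter = pp, d) else NULL,
            cl, .PARAMS))
        clumps[[oc]] <- cl
        if (!is.null(cl) && nrow(cl))
            utils::write.table(cl,
                file.path(outDir, sprintf("clumps_%s.tsv", oc)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    }
    prs <- NULL
    if (!is.null(config$prsWeights)) {
        prs <- .stage("prs", {
            out <- list()
            for (trait in names(config$prsWeights)) {
                w <- config$prsWeights[[trait]]
                if (is.character(w)) w <- readWeights(w)
                model <- computePRS(
                    selectAndAlign(w, cohort, trait = trait,
                                   r2Threshold = config$clumpR2,
                                   windowKb = config$clumpWindowKb),
                    cohort)
                assoc <- do.call(rbind, lapply(config$outcomes,
                    function(oc) cbind(trait = trait, outcome = oc,
                        testPRSTrajectory(cohort, model, outcome = oc,
                                          outcomeRows = outcomeRows,
                                          pcs = pcs,
                                          riskVariantIds = riskIds))))
                out[[trait]] <- assoc
            }
            tab <- do.call(rbind, out)
            utils::write.table(tab,
                file.path(outDir, "prs_associations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
            tab
        })
    }
    prov <- list(
        package = "TrajGEE",
        version = as.character(utils::packageVersion("TrajGEE")),
        seed = if (!is.null(config$simulation))
                   config$simulation$seed else NA,
        config_hash = .configHash(config),
        outcomes = config$outcomes,
        thresholds = config$thresholds,
        n_subjects = ncol(cohort), n_variants_kept = length(qc$kept))
    jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(cohort = cohort, qc = qc, selection = selection,
                   scans = scans, clumps = clumps, prs = prs,
                   outDir = outDir))
}

.configHash <- function(config) {
    f <- tempfile(fileext = ".yaml")
    on.exit(unlink(f))
    cfg <- config
    cfg$prsWeights <- NULL
    cfg$effects <- NULL
    yaml::write_yaml(lapply(unclass(cfg), function(x)
        if (is.list(x)) lapply(x, as.character) else as.character(x)), f)
    unname(tools::md5sum(f))
}

#' Compare coefficients between two fits of the same model
#'
#' Side-by-side comparison of, e.g., the full-cohort and
#' genotyped-subset fits of one outcome: absolute and SE-scaled
#' coefficient differences. Fits must share the same parameterisation
#' (identical coefficient names).
#'
#' @param fitFull,fitSub Two [GEEFit-class] or [LMMFit-class] objects.
#' @return `data.frame`: `term`, `beta_full`, `beta_sub`, `diff`,
#'   `se_full`, `diff_over_se`.
#' @export
sensitivityCompare <- function(fitFull, fitSub) {
    bf <- coef(fitFull)
    bs <- coef(fitSub)
    if (!identical(sort(names(bf)), sort(names(bs))))
        stop("mismatched parameterisation between the two fits")
    bs <- bs[names(bf)]
    se <- sqrt(diag(vcov(fitFull)))[names(bf)]
    data.frame(term = names(bf), beta_full = unname(bf),
               beta_sub = unname(bs), diff = unname(bs - bf),
               se_full = unname(se),
               diff_over_se = unname((bs - bf) / se))
}
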