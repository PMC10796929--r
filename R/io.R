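# Cohort serialisation: dosage VCF 4.2 (FORMAT/DS, 1-based positions,
# imputation quality in INFO/R2), long-format phenotype TSV and covariate
# TSV. Reading goes through the vcfR parser.

#' Write a cohort to disk
#'
#' Emits three files into `dir`: `genotypes.vcf` (VCF 4.2 with a single
#' FORMAT field `DS`, per-variant `INFO/R2` imputation quality and contig
#' header lines), `phenotypes.tsv` (`subject_id`, `time_days`, `test_id`,
#' `score`) and `covariates.tsv` (one row per subject). Dosages are
#' written with six decimals, so a write/read round trip reproduces the
#' matrix to 1e-6.
#'
#' @param cohort A [TrialCohort-class]; must carry phenotype rows.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    ph <- phenotypes(cohort)
    if (!nrow(ph)) stop("cohort has an empty phenotype table")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    vcf <- file.path(dir, "genotypes.vcf")
    meta <- variantMeta(cohort)
    D <- dosages(cohort)
    hdr <- c("##fileformat=VCFv4.2",
             paste0("##FORMAT=<ID=DS,Number=1,Type=Float,Description=",
                    "\"Estimated alternate allele dosage\">"),
             paste0("##INFO=<ID=R2,Number=1,Type=Float,Description=",
                    "\"Imputation quality\">"),
             sprintf("##contig=<ID=%s>", unique(meta$chrom)),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", colnames(D)),
                   collapse = "\t"))
    ds <- matrix(sprintf("%.6f", D), nrow(D), ncol(D))
    ds[is.na(D)] <- "."
    body <- paste(meta$chrom, meta$pos, meta$variant_id, meta$ref,
                  meta$alt, ".", "PASS",
                  sprintf("R2=%.4f", meta$imputation_r2), "DS",
                  apply(ds, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(c(hdr, body), vcf)
    phf <- file.path(dir, "phenotypes.tsv")
    utils::write.table(ph, phf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cvf <- file.path(dir, "covariates.tsv")
    cov <- cbind(subject_id = colnames(D), covariates(cohort))
    utils::write.table(cov, cvf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(vcf = vcf, phenotypes = phf, covariates = cvf))
}

#' Read a cohort from disk
#'
#' Parses the dosage VCF with vcfR and reassembles a
#' [TrialCohort-class] together with the phenotype and covariate TSVs
#' written by [writeCohort()] (or produced by any tool emitting the same
#' layout).
#'
#' @param vcfPath Dosage VCF (FORMAT/DS).
#' @param phenotypesPath Long-format phenotype TSV.
#' @param covariatesPath Covariate TSV with a `subject_id` column.
#' @return A [TrialCohort-class].
#' @export
readCohort <- function(vcfPath, phenotypesPath, covariatesPath) {
    for (f in c(vcfPath, phenotypesPath, covariatesPath))
        if (!file.exists(f)) stop("file not found: ", f)
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    fix <- vcfR::getFIX(v)
    r2 <- suppressWarnings(as.numeric(sub("^.*R2=([0-9.eE+-]+).*$", "\\1",
                                          v@fix[, "INFO"])))
    meta <- data.frame(chrom = fix[, "CHROM"],
                       pos = as.integer(fix[, "POS"]),
                       ref = fix[, "REF"], alt = fix[, "ALT"],
                       imputation_r2 = r2,
                       row.names = fix[, "ID"])
    rownames(ds) <- fix[, "ID"]
    ph <- utils::read.table(phenotypesPath, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = c(subject_id = "character",
                                           test_id = "character"))
    cov <- utils::read.table(covariatesPath, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = c(subject_id = "character"))
    rownames(cov) <- cov$subject_id
    cov <- cov[colnames(ds), setdiff(colnames(cov), "subject_id"),
               drop = FALSE]
    TrialCohort(ds, meta, cov, ph)
}
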