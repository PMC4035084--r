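#' Run the full analysis pipeline on a synthetic cohort
#'
#' Chains every stage under one configuration and seed: cohort simulation,
#' phenotype QC, the six GRSS methods, CNV consensus / filtering / catalog
#' matching / scores, the covariate + GRSS + CNV association models with the
#' interaction scan, and nested ROC prediction of the four obesity classes.
#' When `out_dir` is given, each stage's tables plus the resolved
#' configuration (seed included) are written there, so re-running the
#' emitted config reproduces the run exactly.
#'
#' @param config configuration list (see [default_config()]).
#' @param seed integer seed; overrides `config$seed` when given.
#' @param out_dir optional output directory.
#' @param verbose log stage counts.
#' @return list with `cohort`, `qc`, `scores`, `cnv` (consensus, matched,
#'   carrier matrix, region classes, scores, burden), `association` (fits,
#'   interaction scan, nested tests) and `prediction` (roc report).
#' @export
run_pipeline <- function(config = default_config(), seed = NULL,
                         out_dir = NULL, verbose = FALSE) {
  validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  th <- config$thresholds

  design <- simulation_design(
    n_subjects = config$cohort$n_subjects,
    variance_fractions = config$variance_fractions,
    imputation_quality = config$cohort$imputation_quality,
    proxy_r2 = config$cohort$proxy_r2,
    n_group_a = config$cohort$n_group_a
  )
  cohort <- simulate_cohort(design, seed = config$seed)

  # --- phenotype QC ---------------------------------------------------
  qc <- apply_exclusions(cohort$phenotypes)
  phen <- qc$retained
  stage_log("phenotype_qc", nrow(cohort$phenotypes), nrow(phen),
            verbose = verbose)
  phen$bodyweight <- classify_bodyweight(phen$bmi)
  phen <- cbind(phen, obesity_indicators(phen$bmi))

  # --- GRSS -----------------------------------------------------------
  scores <- grss_all_methods(cohort$genotypes, design$catalog,
                             proxy = cohort$proxy)
  phen <- merge(phen, scores, by = "subject_id", sort = FALSE)

  # --- CNV pipeline ---------------------------------------------------
  calls <- do.call(rbind, cohort$cnv$calls)
  kept <- filter_calls_by_confidence(calls, th$lbf_min, verbose = verbose)
  consensus <- merge_consensus(kept, threshold = th$reciprocal_overlap)
  consensus <- remove_excluded_regions(consensus, default_exclusion_regions(),
                                       verbose = verbose)
  catalog_cnv <- default_cnv_catalog()
  matched <- match_catalog(consensus, catalog_cnv, th$catalog_overlap)
  carriers <- carrier_matrix(matched, cohort$genotypes$samples,
                             catalog_cnv$region)
  region_class <- classify_frequency(carriers, design$n_subjects,
                                     th$common_freq)
  cnv_scores <- data.frame(
    subject_id = rownames(carriers),
    rare_grss = build_cnv_scores(matched, region_class, "rare",
                                 rownames(carriers)),
    common_grss = build_cnv_scores(matched, region_class, "common",
                                   rownames(carriers)),
    rare_grss_100kb = build_cnv_scores(matched, region_class, "rare",
                                       rownames(carriers),
                                       min_length = th$large_cnv_bp),
    burden = compute_burden(consensus, rownames(carriers), th$common_freq,
                            th$reciprocal_overlap),
    stringsAsFactors = FALSE
  )
  del_region <- design$cnv_loci$region[design$cnv_loci$effect != 0][1]
  phen$del_carrier <- carriers[match(phen$subject_id, rownames(carriers)),
                               del_region]

  # --- association ----------------------------------------------------
  centered <- center_predictors(
    phen, c("PC1", "PC4", "PC8", "age", "prob_weighted"))
  dat <- centered$data
  m_cov <- fit_linear(bmi ~ PC1 + PC4 + PC8 + sex + age + AD + ND +
                        PC1:sex + age:AD, dat)
  scan <- scan_interactions(
    bmi ~ PC1 + PC4 + PC8 + sex + age + AD + ND + PC1:sex + age:AD +
      prob_weighted + del_carrier,
    dat, candidates = c("sex:prob_weighted", "age:prob_weighted"),
    alpha = th$interaction_alpha)
  m_grss <- fit_linear(stats::update.formula(m_cov$formula,
                                             . ~ . + prob_weighted), dat)
  m_full <- fit_linear(stats::update.formula(m_grss$formula,
                                             . ~ . + del_carrier), dat)
  assoc <- list(
    covariates = m_cov, with_grss = m_grss, full = m_full,
    interaction_scan = scan,
    nested = nested_f_test(m_cov, m_full),
    delta_r2 = incremental_r2(list(m_cov, m_grss, m_full))
  )

  # --- prediction -----------------------------------------------------
  outcomes <- c("overweight", "obese_I", "obese_II", "obese_III")
  report <- list()
  for (oc in outcomes) {
    if (length(unique(dat[[oc]])) < 2 || sum(dat[[oc]]) < 2) next
    f1 <- stats::as.formula(paste(oc, "~ PC1 + PC4 + PC8 + sex + age +",
                                  "AD + ND + PC1:sex + age:AD"))
    l1 <- fit_logistic(f1, dat)
    l2 <- fit_logistic(stats::update.formula(f1, . ~ . + prob_weighted), dat)
    l3 <- fit_logistic(stats::update.formula(f1, . ~ . + prob_weighted +
                                               del_carrier), dat)
    rows <- rbind(
      roc_summary(l1$fitted_probabilities, dat[[oc]], oc, "covariates"),
      roc_summary(l2$fitted_probabilities, dat[[oc]], oc, "+GRSS"),
      roc_summary(l3$fitted_probabilities, dat[[oc]], oc, "+CNV"))
    rows$p_delta <- c(NA,
      paired_auc_test(l1$fitted_probabilities, l2$fitted_probabilities,
                      dat[[oc]])$p,
      paired_auc_test(l2$fitted_probabilities, l3$fitted_probabilities,
                      dat[[oc]])$p)
    report[[oc]] <- rows
  }
  roc_report <- delta_auc_report(do.call(rbind, report))

  result <- list(cohort = cohort, qc = qc, scores = scores,
                 phenotypes = phen,
                 cnv = list(consensus = consensus, matched = matched,
                            carriers = carriers,
                            region_class = region_class,
                            scores = cnv_scores),
                 association = assoc,
                 prediction = roc_report,
                 config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_config(config, file.path(out_dir, "run_config.yaml"))
    write_phenotypes(phen, file.path(out_dir, "phenotypes_qc.tsv"))
    utils::write.table(qc$log, file.path(out_dir, "exclusions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(scores, file.path(out_dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(consensus, file.path(out_dir, "consensus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cnv_scores, file.path(out_dir, "cnv_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(roc_report, file.path(out_dir, "roc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fits_json <- lapply(assoc[c("covariates", "with_grss", "full")],
                        function(m) list(coefficients = m$coefficients,
                                         r_squared = m$r_squared,
                                         n = m$n, seed = config$seed))
    jsonlite::write_json(fits_json, file.path(out_dir, "model_fits.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  result
}
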