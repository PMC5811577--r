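#' Pipeline configuration
#'
#' Analysis parameters for [run_pipeline()]. Unknown keys are rejected by R's
#' argument matching, so a typo in a config name fails before any stage runs.
#'
#' @param min_coverage minimum per-sample read coverage for site inclusion.
#' @param outlier_sd SD threshold for sample outlier removal.
#' @param alpha_evc ANOVA threshold for EVC status.
#' @param alpha_osc harmonic-regression threshold for oscillation calls.
#' @param alpha_aging Bonferroni-corrected threshold for age-modC calls.
#' @param period oscillation period in hours.
#' @param n_perm permutations for the mean-R^2 test.
#' @param seed RNG seed for all stochastic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_coverage = 30, outlier_sd = 3,
                            alpha_evc = 0.05, alpha_osc = 0.05,
                            alpha_aging = 0.05, period = 24,
                            n_perm = 1000, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full circadian-aging analysis pipeline
#'
#' Orchestrates: coverage QC and beta computation, sample outlier removal,
#' per-age-group EVC detection, replicate collapse, per-age-group harmonic
#' fits with oscillation calls and the mean-R^2 permutation test, aging
#' regression on the EVCs shared by all age groups, and the circadian-aging
#' association battery. When oxBS counts are supplied, hmC is estimated on
#' the union of modC/mC EVCs and the mC-vs-hmC antiphase test is run on
#' sites oscillating in both modalities. Every stage writes a TSV into
#' `out_dir` (when given) and appends to a log; stage outputs are pure
#' functions of (inputs, config, seed).
#'
#' @param bs [mod_counts()] of the bisulfite assay (or path to a counts TSV
#'   given together with `meta` and `sites` paths).
#' @param oxbs optional [mod_counts()] of the oxBS assay.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @param meta,sites paths used only when `bs`/`oxbs` are file paths.
#' @return A report list: per-stage site/sample counts, per-age-group EVC
#'   tables, harmonic fits, oscillation calls and permutation summaries,
#'   aging fits, and association results.
#' @export
run_pipeline <- function(bs, oxbs = NULL, config = pipeline_config(),
                         out_dir = NULL, meta = NULL, sites = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(bs)) {
    if (is.null(meta) || is.null(sites))
      stop("meta and sites paths are required when bs is a file path")
    bs <- read_counts(bs, meta, sites)
  }
  if (!is.null(oxbs) && is.character(oxbs))
    oxbs <- read_counts(oxbs, meta, sites)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  log_path <- if (!is.null(out_dir)) file.path(out_dir, "pipeline.log")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " | ", ...)
    message(line)
    if (!is.null(log_path)) cat(line, "\n", file = log_path, append = TRUE)
  }
  emit <- function(df, name) {
    if (!is.null(out_dir))
      write_table_commented(df, file.path(out_dir, paste0(name, ".tsv")),
                            list(seed = config$seed))
  }
  report <- list(config = config)

  ## -- stage: qc --------------------------------------------------------
  qc_one <- function(counts, label) {
    n0 <- nrow(counts$M)
    counts <- filter_min_coverage(counts, config$min_coverage)
    beta <- compute_beta(counts)
    out <- remove_outlier_samples(beta, config$outlier_sd)
    logf("qc[", label, "]: ", n0, " -> ", nrow(out$beta$beta),
         " sites (coverage >= ", config$min_coverage, "); removed ",
         length(out$removed), " outlier sample(s)")
    out$beta
  }
  beta_bs <- qc_one(bs, "BS")
  beta_ox <- if (!is.null(oxbs)) qc_one(oxbs, "oxBS")
  report$qc <- list(n_sites = nrow(beta_bs$beta),
                    n_samples = ncol(beta_bs$beta))

  ## -- stage: evc (per age group) ---------------------------------------
  ages <- sort(unique(beta_bs$samples$age_months))
  evc_by_age <- lapply(ages, function(a) {
    sub <- subset_mod(beta_bs, samples = beta_bs$samples$age_months == a)
    res <- detect_evc(sub, config$alpha_evc)
    logf("evc[age ", a, "]: ", sum(res$is_evc), " / ", nrow(res), " EVCs")
    emit(res, paste0("evc_age", a))
    res
  })
  names(evc_by_age) <- as.character(ages)
  report$evc <- evc_by_age

  ## -- stage: rhythm (per age group, on that group's EVCs) --------------
  collapsed <- collapse_replicates(beta_bs)
  rhythm <- lapply(ages, function(a) {
    evc_ids <- evc_by_age[[as.character(a)]]
    evc_ids <- evc_ids$site_id[evc_ids$is_evc]
    if (length(evc_ids) < 2) {
      logf("rhythm[age ", a, "]: <2 EVCs, skipped")
      return(NULL)
    }
    sub <- subset_mod(collapsed, sites = evc_ids,
                      samples = collapsed$samples$age_months == a)
    fits <- harmonic_fit_matrix(sub$beta, sub$samples$zt, config$period)
    fits$class <- as.character(classify_acrophase(fits$acrophase))
    osc <- call_osc(fits, config$alpha_osc)
    perm <- permute_mean_r2(sub, n_perm = config$n_perm,
                            seed = config$seed + a)
    logf("rhythm[age ", a, "]: ", length(osc$osc_ids), " / ", osc$n_tested,
         " oscillating (", round(100 * osc$fraction, 1), "%), perm p ",
         perm$p_label)
    emit(fits, paste0("harmonic_age", a))
    list(fits = fits, osc = osc, perm = perm)
  })
  names(rhythm) <- as.character(ages)
  report$rhythm <- rhythm

  ## -- stage: aging (EVCs in all age groups) ----------------------------
  if (length(ages) >= 2) {
    evc_all <- Reduce(intersect,
                      lapply(evc_by_age, function(r) r$site_id[r$is_evc]))
    report$evc_all_ages <- evc_all
    if (length(evc_all) >= 2 && length(ages) >= 3) {
      aging_beta <- subset_mod(collapsed, sites = evc_all)
      aging <- fit_aging(aging_beta, alpha = config$alpha_aging)
      logf("aging: ", sum(aging$is_age_modc), " / ", nrow(aging),
           " age-modCs (Bonferroni < ", config$alpha_aging, ")")
      emit(aging, "aging")
      report$aging <- aging

      ## -- stage: associate -----------------------------------------------
      young <- as.character(ages[1])
      fits_y <- rhythm[[young]]$fits
      if (!is.null(fits_y)) {
        osc_y <- fits_y$series_id[!is.na(fits_y$p) &
                                  fits_y$p < config$alpha_osc]
        universe <- intersect(evc_all, fits_y$series_id)
        assoc <- tryCatch(
          fisher_association(intersect(osc_y, universe),
                             aging$site_id[aging$is_age_modc], universe),
          error = function(e) structure(list(error = conditionMessage(e)),
                                        class = "osc_assoc_failed"))
        asym <- tryCatch(acrophase_direction_asymmetry(fits_y, aging,
                                                       config$alpha_osc),
                         error = function(e)
                           structure(list(error = conditionMessage(e)),
                                     class = "osc_assoc_failed"))
        ampcor <- tryCatch(amplitude_magnitude_correlation(
                             fits_y[fits_y$series_id %in% osc_y, ],
                             aging[aging$is_age_modc, ]),
                           error = function(e) NULL)
        osc_sets <- lapply(rhythm, function(r)
          if (is.null(r)) character(0) else r$osc$osc_ids)
        venn <- tryCatch(venn_binomial_enrichment(osc_sets, aging),
                         error = function(e) NULL)
        report$associations <- list(osc_vs_aging = assoc,
                                    acrophase_direction = asym,
                                    amplitude_magnitude = ampcor,
                                    venn = venn)
        if (!inherits(assoc, "osc_assoc_failed"))
          logf("associate: osc x aging OR = ",
               format(assoc$odds_ratio, digits = 3), ", p = ",
               format(assoc$p, digits = 3))
      }
    }
  }

  ## -- stage: hmC (optional) --------------------------------------------
  if (!is.null(beta_ox)) {
    young <- as.character(ages[1])
    sub_bs <- subset_mod(beta_bs, samples = beta_bs$samples$age_months == ages[1])
    sub_ox <- subset_mod(beta_ox, samples = beta_ox$samples$age_months == ages[1])
    common <- intersect(rownames(sub_bs$beta), rownames(sub_ox$beta))
    sub_bs <- subset_mod(sub_bs, sites = common)
    sub_ox <- subset_mod(sub_ox, sites = common)
    evc_mc <- detect_evc(sub_ox, config$alpha_evc)
    evc_union <- intersect(evc_union_for_hmc(evc_by_age[[young]], evc_mc),
                           common)
    if (length(evc_union) >= 2) {
      c_bs <- collapse_replicates(subset_mod(sub_bs, sites = evc_union))
      c_ox <- collapse_replicates(subset_mod(sub_ox, sites = evc_union))
      hmc <- estimate_hmc(c_bs, c_ox)
      fits_mc <- harmonic_fit_matrix(c_ox$beta, c_ox$samples$zt, config$period)
      fits_hmc <- harmonic_fit_matrix(hmc$beta, hmc$samples$zt, config$period)
      both <- !is.na(fits_mc$p) & fits_mc$p < config$alpha_osc &
              !is.na(fits_hmc$p) & fits_hmc$p < config$alpha_osc
      report$hmc <- list(evc_union = evc_union, fits_mc = fits_mc,
                         fits_hmc = fits_hmc)
      if (sum(both) >= 2) {
        anti <- median_acrophase_diff_test(fits_mc$acrophase[both],
                                           fits_hmc$acrophase[both],
                                           n_perm = config$n_perm,
                                           seed = config$seed,
                                           alternative = "greater")
        logf("hmC: median mC-hmC acrophase difference ",
             round(anti$observed_stat, 2), " h over ", sum(both),
             " sites, perm p ", anti$p_label)
        report$hmc$antiphase <- anti
      }
    }
  }
  logf("pipeline complete")
  report
}
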