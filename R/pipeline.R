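#' Validate and normalize a pipeline run configuration
#'
#' The configuration is a YAML file with exactly one of two data sources:
#' a `simulation` section (keys of [sim_config()]) or an `inputs` section
#' (`panel`, `genotypes`, `cohort` file paths). Optional sections: `qc`
#' (keys of [qc_thresholds()]), `adjustment` (`n_pcs`), `evaluation`
#' (`folds`, `seed`, `w_pos`, `w_neg`, `n_population_controls`), and
#' `output_dir`. Unknown keys are errors; defaults are filled in.
#'
#' @param path Path to a YAML configuration file, or a list with the same
#'   structure.
#' @return A normalized `run_config` list.
#' @export
validate_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  known <- c("simulation", "inputs", "qc", "adjustment", "evaluation",
             "output_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  has_sim <- !is.null(raw$simulation)
  has_inp <- !is.null(raw$inputs)
  if (has_sim && has_inp)
    stopf("configuration has both 'simulation' and 'inputs'; choose one mode")
  if (!has_sim && !has_inp)
    stopf("configuration needs a 'simulation' or an 'inputs' section")
  if (has_inp) {
    for (key in c("panel", "genotypes", "cohort")) {
      if (is.null(raw$inputs[[key]]))
        stopf("inputs mode requires the '%s' path", key)
      if (!file.exists(raw$inputs[[key]]))
        stopf("input file for '%s' does not exist: %s", key, raw$inputs[[key]])
    }
  }
  sim <- NULL
  if (has_sim) {
    sim_args <- raw$simulation
    bad <- setdiff(names(sim_args), names(formals(sim_config)))
    if (length(bad))
      stopf("unknown simulation key(s): %s", paste(bad, collapse = ", "))
    for (nm in c("category_prevalences", "fit_positive_prob"))
      if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
    for (nm in c("raf_range", "weight_range"))
      if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- as.numeric(unlist(sim_args[[nm]]))
    sim <- do.call(sim_config, sim_args)
  }
  qc_args <- raw$qc %||% list()
  bad <- setdiff(names(qc_args), names(formals(qc_thresholds)))
  if (length(bad)) stopf("unknown qc key(s): %s", paste(bad, collapse = ", "))
  ev <- raw$evaluation %||% list()
  bad <- setdiff(names(ev), c("folds", "seed", "w_pos", "w_neg",
                              "n_population_controls"))
  if (length(bad))
    stopf("unknown evaluation key(s): %s", paste(bad, collapse = ", "))
  structure(list(
    mode = if (has_sim) "simulation" else "inputs",
    simulation = sim,
    inputs = raw$inputs,
    qc = do.call(qc_thresholds, qc_args),
    n_pcs = (raw$adjustment %||% list())$n_pcs %||% 5,
    folds = ev$folds %||% 5,
    seed = as.integer(ev$seed %||% (if (has_sim) sim$seed else 1L)),
    w_pos = ev$w_pos %||% 0.06,
    w_neg = ev$w_neg %||% 0.94,
    n_population_controls = ev$n_population_controls %||% 1000,
    output_dir = raw$output_dir
  ), class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full evaluation pipeline
#'
#' From either real inputs or a simulated cohort, runs QC, scoring,
#' principal components, covariate adjustment, and every evaluation output:
#' seven-group summary with trend test, screening summary with FIT margins,
#' (cross-validated) ROC results overall and by FIT stratum,
#' predictive-value curves per stratum and population-weighted, the
#' control-decile odds-ratio table, the per-variant association scan, the
#' QC reports and a reproducibility manifest. With `output_dir` set in the
#' config, every table is also written as TSV (curves and manifest as JSON).
#'
#' @param config A [validate_config()] result (or a path / list accepted by
#'   it).
#' @return A `pipeline_result` list; see Details.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)

  if (config$mode == "simulation") {
    dat <- run_stage("simulate", {
      sim <- simulate_cohort(config$simulation)
      scr <- sample_screening(sim)
      # study set = screening subset + a draw of population controls +
      # the clinically diagnosed cancers (both outside the programme)
      rg <- as.character(sim$cohort$risk_group)
      pop <- which(rg == "population_control")
      set.seed(config$simulation$seed + 6L)
      pop <- sort(sample(pop, min(config$n_population_controls, length(pop))))
      clin <- which(rg == "clinical_CRC")
      idx <- sort(unique(c(scr$index, pop, clin)))
      cohort <- sim$cohort[idx, , drop = FALSE]
      class(cohort) <- class(sim$cohort)
      list(panel = sim$panel,
           geno = genotype_matrix(unclass(sim$geno)[idx, , drop = FALSE]),
           cohort = cohort, weights = scr$weights)
    })
  } else {
    dat <- run_stage("read_inputs", {
      panel <- read_panel(config$inputs$panel)
      list(panel = panel,
           geno = read_genotypes(config$inputs$genotypes, panel),
           cohort = read_cohort(config$inputs$cohort),
           weights = c(w_pos = config$w_pos, w_neg = config$w_neg))
    })
  }

  qcv <- run_stage("qc_variants",
                   qc_variants(dat$geno, dat$panel, config$qc))
  qcs <- run_stage("qc_samples",
                   qc_samples(qcv$geno, config$qc$sample_missing))
  geno <- qcs$geno
  cohort <- dat$cohort[match(rownames(geno), dat$cohort$sample_id), ,
                       drop = FALSE]
  if (anyNA(cohort$sample_id))
    stopf("pipeline stage 'qc_samples' failed: genotyped samples missing from cohort table")

  scores <- run_stage("score", compute_scores(geno, qcv$panel))
  pcs <- run_stage("pca", genotype_pca(geno, K = config$n_pcs))
  adj <- run_stage("adjust", adjust_prs(scores, cohort, pcs,
                                        n_pcs = config$n_pcs))
  aprs <- adj$adjusted_prs[match(cohort$sample_id, adj$sample_id)]

  group_summary <- run_stage("group_summary", {
    out <- do.call(rbind, lapply(risk_group_levels(), function(g) {
      v <- aprs[as.character(cohort$risk_group) == g]
      data.frame(risk_group = g, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1) sd(v) else NA_real_,
                 min = if (length(v)) min(v) else NA_real_,
                 max = if (length(v)) max(v) else NA_real_)
    }))
    out
  })
  trend <- run_stage("trend", {
    m <- group_summary$mean[!is.na(group_summary$mean)]
    mann_kendall_test(m)
  })

  scr_idx <- as.character(cohort$risk_group) %in% screening_levels()
  screening_summary <- run_stage("screening_summary", {
    sub <- cohort[scr_idx, ]
    out <- do.call(rbind, lapply(screening_levels(), function(g) {
      s <- sub[as.character(sub$risk_group) == g, ]
      data.frame(risk_group = g, n = nrow(s),
                 fit_negative = sum(s$fit_result == "negative"),
                 fit_positive = sum(s$fit_result == "positive"))
    }))
    rbind(out, data.frame(risk_group = "total", n = nrow(sub),
                          fit_negative = sum(sub$fit_result == "negative"),
                          fit_positive = sum(sub$fit_result == "positive")))
  })

  grouping <- run_stage("group_outcomes",
                        group_outcomes(cohort, "primary_screening"))
  x <- aprs[grouping$index]
  y <- grouping$label
  fit_res <- cohort$fit_result[grouping$index]

  roc <- run_stage("roc", {
    strata <- list(all = rep(TRUE, length(y)),
                   fit_positive = fit_res == "positive",
                   fit_negative = fit_res == "negative")
    lapply(strata, function(s) {
      if (sum(y[s]) >= config$folds && sum(!y[s]) >= config$folds)
        cv_auc(x[s], y[s], folds = config$folds, seed = config$seed)
      else roc_auc(x[s], y[s])
    })
  })

  curves <- run_stage("predictive_curves", {
    grid <- seq(floor(min(x)), ceiling(max(x)))
    pos <- fit_res == "positive"; neg <- fit_res == "negative"
    cp <- predictive_curve(x[pos], y[pos], grid, stratum = "fit_positive")
    cn <- predictive_curve(x[neg], y[neg], grid, stratum = "fit_negative")
    list(all = predictive_curve(x, y, grid, stratum = "all"),
         fit_positive = cp, fit_negative = cn,
         population_weighted = weight_curves(cp, cn,
                                             w_pos = dat$weights[["w_pos"]],
                                             w_neg = dat$weights[["w_neg"]]))
  })

  deciles <- run_stage("decile_or", decile_or(x, y))

  assoc <- run_stage("per_snp", {
    ov <- group_outcomes(cohort, "overall")
    covs <- data.frame(sex = factor(cohort$sex),
                       age = cohort$age,
                       array = factor(cohort$array),
                       family_history = factor(cohort$family_history))
    covs <- cbind(covs, pcs$scores[match(cohort$sample_id, rownames(geno)), ,
                                   drop = FALSE])
    covs <- droplevels(covs[ov$index, , drop = FALSE])
    covs <- covs[, vapply(covs, function(v)
      is.numeric(v) || nlevels(v) > 1, logical(1)), drop = FALSE]
    per_snp_logistic(genotype_matrix(unclass(geno)[ov$index, , drop = FALSE]),
                     ov$label, covariates = covs)
  })

  manifest <- list(
    package_version = as.character(packageVersion("prscreen")),
    mode = config$mode,
    seed = config$seed,
    folds = config$folds,
    qc_thresholds = config$qc,
    weights = as.list(dat$weights),
    n_samples = nrow(geno), n_variants = ncol(geno),
    config_hash = object_hash(unclass(config))
  )
  manifest$result_hash <- object_hash(list(group_summary, screening_summary,
                                           deciles$table))

  res <- structure(list(
    group_summary = group_summary, trend = trend,
    screening_summary = screening_summary,
    roc = roc, curves = curves, deciles = deciles, assoc = assoc,
    qc_variant_report = qcv$report, qc_sample_report = qcs$report,
    scores = scores, adjusted = adj, pcs = pcs, cohort = cohort,
    grouping = grouping, weights = dat$weights, manifest = manifest
  ), class = "pipeline_result")

  if (!is.null(config$output_dir)) write_pipeline_result(res, config$output_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("== screening PRS pipeline ==\n")
  cat(sprintf("samples: %d, variants: %d (mode: %s, seed: %d)\n",
              x$manifest$n_samples, x$manifest$n_variants,
              x$manifest$mode, x$manifest$seed))
  cat(sprintf("trend across 7 groups: S = %d, p = %.3g\n",
              x$trend$S, x$trend$p))
  cat(sprintf("primary grouping: %d cases / %d controls\n",
              x$grouping$n_case, x$grouping$n_control))
  cat(sprintf("cv aROC: %.3f (%.3f-%.3f)\n", x$roc$all$auc,
              x$roc$all$ci_low, x$roc$all$ci_high))
  cat(sprintf("OR D10 vs D1: %.2f (%.2f-%.2f)\n", x$deciles$table$or[10],
              x$deciles$table$or_low[10], x$deciles$table$or_high[10]))
  invisible(x)
}

write_pipeline_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(res$group_summary, "group_summary.tsv")
  wt(res$screening_summary, "screening_summary.tsv")
  wt(res$deciles$table, "decile_or.tsv")
  wt(res$assoc, "per_snp_association.tsv")
  wt(res$qc_variant_report, "qc_variants.tsv")
  wt(res$qc_sample_report, "qc_samples.tsv")
  for (nm in names(res$curves))
    wt(as.data.frame(res$curves[[nm]]), sprintf("predictive_curve_%s.tsv", nm))
  roc_json <- lapply(res$roc, function(r)
    list(auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high,
         n_case = r$n_case, n_control = r$n_control,
         cv_folds = r$cv_folds, seed = r$seed))
  jsonlite::write_json(roc_json, file.path(dir, "roc.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
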