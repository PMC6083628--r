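# End-to-end orchestration: exclusions, per-nutrient model fits, agreement
# statistics, stratified and sensitivity analyses, and plain-text outputs.

#' Configuration of a full validation analysis
#'
#' @param nutrients nutrient columns to validate against their references.
#' @param densities nutrients additionally analyzed as densities (g/MJ of
#'   energy; the reference density divides the biomarker value by TEE).
#' @param ci_method `"delta"` or `"bootstrap"` for attenuation/correlation
#'   intervals.
#' @param n_boot bootstrap replicates for ICC (and bootstrap CIs).
#' @param min_stratum smallest stratum refitted in stratified analyses.
#' @param seed seed for all resampling in the analysis.
#' @param tool_labels display labels for the two tools.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(nutrients = c("protein", "potassium", "sodium",
                                          "total_sugars", "energy"),
                            densities = c("protein", "potassium", "sodium",
                                          "total_sugars"),
                            ci_method = c("delta", "bootstrap"),
                            n_boot = 200L,
                            min_stratum = 30L,
                            seed = 1L,
                            tool_labels = c(A = "online", B = "interviewer")) {
  structure(list(nutrients = nutrients, densities = densities,
                 ci_method = match.arg(ci_method),
                 n_boot = as.integer(n_boot),
                 min_stratum = as.integer(min_stratum),
                 seed = as.integer(seed), tool_labels = tool_labels),
            class = "analysis_config")
}

check_dataset <- function(dataset, config) {
  need <- c("participant", "occasion", "instrument", config$nutrients)
  miss <- setdiff(need, names(dataset))
  if (length(miss))
    dv_config_error(paste0("dataset is missing required columns: ",
                           paste(miss, collapse = ", ")))
  invisible(dataset)
}

# one analysis variable = nutrient or nutrient density
analysis_variables <- function(config) {
  rbind(data.frame(nutrient = config$nutrients, density = FALSE,
                   stringsAsFactors = FALSE),
        if (length(config$densities))
          data.frame(nutrient = config$densities, density = TRUE,
                     stringsAsFactors = FALSE))
}

#' Attenuation, correlation and bias table for every tool and nutrient
#'
#' Fits the measurement-error model per analysis variable and reports, per
#' tool: attenuation factor, correlation with true intake and mean
#' percentage difference, each with its 95% interval.
#'
#' @param dataset a study dataset (exclusion flags applied beforehand).
#' @param config an [analysis_config()].
#' @param k administrations averaged for attenuation/correlation (default 1).
#' @return data.frame, one row per variable x tool.
#' @export
validation_table <- function(dataset, config = analysis_config(), k = 1) {
  vars <- analysis_variables(config)
  out <- lapply(seq_len(nrow(vars)), function(i) {
    nut <- vars$nutrient[i]
    dens <- vars$density[i]
    fit <- tryCatch(fit_mem(dataset, nut, density = dens),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("fit failed for ", nut, if (dens) " density", ": ",
              conditionMessage(fit))
      return(NULL)
    }
    do.call(rbind, lapply(fit$tools, function(tool) {
      lam <- derived_ci(fit, "attenuation", tool, k, config$ci_method,
                        dataset = dataset, nboot = config$n_boot,
                        seed = config$seed)
      rho <- derived_ci(fit, "correlation", tool, k, config$ci_method,
                        dataset = dataset, nboot = config$n_boot,
                        seed = config$seed)
      pd <- mean_pct_difference(dataset, tool, nut, dens)
      data.frame(variable = if (dens) paste0(nut, "_density") else nut,
                 tool = unname(config$tool_labels[tool]),
                 n = fit$n, k = k,
                 attenuation = lam$estimate,
                 attenuation_lo = lam$ci[1], attenuation_hi = lam$ci[2],
                 correlation = rho$estimate,
                 correlation_lo = rho$ci[1], correlation_hi = rho$ci[2],
                 pct_diff = pd$pct_diff,
                 pct_diff_lo = pd$ci[1], pct_diff_hi = pd$ci[2],
                 logLik = fit$logLik, converged = fit$convergence == 0,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, out)
}

#' Geometric means at the first clinic visit
#'
#' Per instrument and analysis variable: `exp` of the t-interval on the mean
#' log value among first-occasion records surviving the exclusions.
#'
#' @inheritParams validation_table
#' @param level confidence level.
#' @export
geometric_mean_table <- function(dataset, config = analysis_config(),
                                 level = 0.95) {
  vars <- analysis_variables(config)
  first <- dataset[dataset$occasion == min(dataset$occasion), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(vars))) {
    nut <- vars$nutrient[i]
    dens <- vars$density[i]
    dm <- mem_data_matrix(first, nut, dens)
    J <- dm$J
    cols <- list(biomarker = seq_len(J))
    for (t in seq_along(dm$tools))
      cols[[paste0("tool_", dm$tools[t])]] <- t * J + seq_len(J)
    for (inst in names(cols)) {
      lv <- as.vector(dm$Y[, cols[[inst]]])
      lv <- lv[is.finite(lv)]
      if (!length(lv)) next
      n <- length(lv)
      se <- if (n > 1L) stats::sd(lv) / sqrt(n) else 0
      tq <- if (n > 1L) stats::qt(1 - (1 - level) / 2, n - 1L) else 0
      out[[length(out) + 1L]] <- data.frame(
        variable = if (dens) paste0(nut, "_density") else nut,
        instrument = inst, n = n,
        geometric_mean = exp(mean(lv)),
        gm_lo = exp(mean(lv) - tq * se), gm_hi = exp(mean(lv) + tq * se),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Run the full main analysis
#'
#' Applies the main exclusion rules, then produces the geometric-mean table
#' (first visit), the validation table (attenuation, correlation, mean %
#' difference per tool and nutrient/density) and the between-tool agreement
#' table (ICC, % difference, limits of agreement per nutrient).
#'
#' @param dataset a study dataset.
#' @param config an [analysis_config()].
#' @return An object of class `dv_results`:
#'   `geometric_means`, `validation`, `agreement`, `exclusions`, `config`.
#' @export
run_main_analysis <- function(dataset, config = analysis_config()) {
  check_dataset(dataset, config)
  ds <- apply_exclusions(dataset, "main")
  agreement <- do.call(rbind, lapply(config$nutrients, function(nut)
    tryCatch(agreement_analysis(ds, nut, nboot = config$n_boot,
                                seed = config$seed),
             error = function(e) NULL)))
  structure(list(geometric_means = geometric_mean_table(ds, config),
                 validation = validation_table(ds, config),
                 agreement = agreement,
                 exclusions = attr(ds, "exclusion_log"),
                 config = config),
            class = "dv_results")
}

#' @export
print.dv_results <- function(x, ...) {
  cat("Validation analysis:", nrow(x$validation), "tool x variable fits,",
      nrow(x$exclusions), "exclusions/adjustments applied\n\n")
  v <- x$validation
  cat(sprintf("%-22s %-12s %6s %22s %22s\n", "variable", "tool", "n",
              "attenuation (95% CI)", "correlation (95% CI)"))
  for (i in seq_len(nrow(v)))
    cat(sprintf("%-22s %-12s %6d   %.2f (%.2f, %.2f)      %.2f (%.2f, %.2f)\n",
                v$variable[i], v$tool[i], v$n[i], v$attenuation[i],
                v$attenuation_lo[i], v$attenuation_hi[i], v$correlation[i],
                v$correlation_lo[i], v$correlation_hi[i]))
  invisible(x)
}

participant_covariates <- function(dataset) {
  idx <- !duplicated(dataset$participant)
  data.frame(participant = dataset$participant[idx],
             sex = dataset$sex[idx], age = dataset$age[idx],
             bmi = dataset$bmi[idx], stringsAsFactors = FALSE)
}

#' Stratified re-fits of the validation analysis
#'
#' Independent re-fits of the validation table per stratum of `sex`,
#' `age_group` (tertiles) or `bmi_group` (below 25 vs 25 and above).
#' Strata smaller than `config$min_stratum` are skipped with a warning.
#'
#' @inheritParams run_main_analysis
#' @param variable `"sex"`, `"age_group"` or `"bmi_group"`.
#' @return data.frame of per-stratum validation rows (column `stratum`).
#' @export
run_stratified <- function(dataset, config = analysis_config(),
                           variable = c("sex", "age_group", "bmi_group")) {
  variable <- match.arg(variable)
  check_dataset(dataset, config)
  cov <- participant_covariates(dataset)
  strata <- switch(variable,
    sex = stats::setNames(cov$sex, cov$participant),
    bmi_group = stats::setNames(ifelse(cov$bmi < 25, "bmi<25", "bmi>=25"),
                                cov$participant),
    age_group = {
      qs <- stats::quantile(cov$age, c(1 / 3, 2 / 3), na.rm = TRUE)
      stats::setNames(cut(cov$age, c(-Inf, qs, Inf),
                          labels = c("age_low", "age_mid", "age_high")),
                      cov$participant)
    })
  ds <- apply_exclusions(dataset, "main")
  out <- list()
  for (s in sort(unique(as.character(strata)))) {
    ids <- as.integer(names(strata)[strata == s])
    if (length(ids) < config$min_stratum) {
      warning("stratum ", s, " below minimum size (", length(ids),
              " < ", config$min_stratum, "); skipped")
      next
    }
    sub <- ds[ds$participant %in% ids, , drop = FALSE]
    attr(sub, "exclusion_log") <- attr(ds, "exclusion_log")
    tab <- validation_table(sub, config)
    if (!is.null(tab)) { tab$stratum <- s; out[[s]] <- tab }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Sensitivity re-runs under alternative exclusion regimes
#'
#' Re-runs the validation table after applying, on top of the main rules,
#' the chosen sensitivity regime: PABA completeness adjustment/exclusion,
#' armband wear-time exclusion, or exclusion of recalls within 24 h of a
#' biomarker collection.
#'
#' @inheritParams run_main_analysis
#' @param mode `"paba_sensitivity"`, `"wear_sensitivity"` or
#'   `"proximity_sensitivity"`.
#' @return list(validation, geometric_means, exclusions, mode).
#' @export
run_sensitivity <- function(dataset, config = analysis_config(),
                            mode = c("paba_sensitivity", "wear_sensitivity",
                                     "proximity_sensitivity")) {
  mode <- match.arg(mode)
  check_dataset(dataset, config)
  ds <- apply_exclusions(dataset, mode)
  list(validation = validation_table(ds, config),
       geometric_means = geometric_mean_table(ds, config),
       exclusions = attr(ds, "exclusion_log"),
       mode = mode)
}

#' Write an analysis result bundle as CSV files plus a YAML provenance header
#'
#' @param results a [run_main_analysis()] result.
#' @param dir output directory (created if needed).
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
  wr(results$geometric_means, "geometric_means")
  wr(results$validation, "validation")
  wr(results$agreement, "agreement")
  wr(results$exclusions, "exclusions")
  yaml::write_yaml(list(package = "dietvalid",
                        version = as.character(utils::packageVersion("dietvalid")),
                        config = unclass(results$config)),
                   file.path(dir, "provenance.yaml"))
  invisible(dir)
}
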