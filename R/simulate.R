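# Synthetic validation studies: log-normal usual intakes, biased self-reports
# with person-specific and intake-related error, unbiased reference
# biomarkers with within-person error, and raw biomarker signals constructed
# so that the derivation module reproduces the intended reference intakes.

#' Default per-nutrient simulation truth
#'
#' One row per nutrient with the generative parameters on the natural-log
#' scale.  The validity profile of each tool (single-administration
#' attenuation factor `lambda`, correlation with true intake `rho`, and mean
#' percentage difference against the reference) is the primary input; the
#' tool bias parameters are solved from it via [tool_params_from_validity()].
#' The defaults describe a protein-like primary scenario (online-tool
#' attenuation about 0.30) together with potassium-, sodium-, total-sugars-
#' and energy-like scenarios.  The geometric mean reference intakes and the
#' validity profiles follow the published scale of a 24-h recall biomarker
#' validation study; the between- and within-person log-scale variances are
#' realistic placeholders, not estimates from any study.
#'
#' @return data.frame with columns nutrient, gm_ref (geometric mean reference
#'   intake, nutrient units), sigma2_T, sigma2_u, and per tool (A = online,
#'   B = interviewer) lambda, rho, pct_diff.
#' @export
default_nutrient_truth <- function() {
  data.frame(
    nutrient = c("protein", "potassium", "sodium", "total_sugars", "energy"),
    gm_ref   = c(68.4, 2.1, 1.8, 128.3, 11.0),
    sigma2_T = c(0.04, 0.05, 0.06, 0.10, 0.03),
    sigma2_u = c(0.05, 0.09, 0.12, 0.20, 0.02),
    lambda_A = c(0.30, 0.31, 0.21, 0.15, 0.19),
    rho_A    = c(0.43, 0.40, 0.30, 0.24, 0.29),
    pct_A    = c(1, 26, 22, -45, -31),
    lambda_B = c(0.38, 0.35, 0.22, 0.25, 0.32),
    rho_B    = c(0.48, 0.38, 0.28, 0.31, 0.37),
    pct_B    = c(11, 48, 28, -30, -23),
    stringsAsFactors = FALSE)
}

#' Solve tool bias parameters from a validity profile
#'
#' Given a target single-administration attenuation factor `lambda`,
#' correlation with true intake `rho`, mean percentage difference against the
#' reference, and the between-person variance of true log intake, returns the
#' measurement-error parameters of a self-report tool:
#' intake-related bias slope `beta1 = rho^2 / lambda`, additive bias `beta0`
#' chosen to reproduce the percentage difference, and person-specific bias /
#' within-person error variances splitting the residual variance
#' `(rho/lambda)^2 * sigma2_T * (1 - rho^2)` in proportion `r_share`.
#'
#' @param lambda attenuation factor (single administration).
#' @param rho correlation with true intake.
#' @param pct_diff mean percentage difference against the reference.
#' @param mu_T,sigma2_T mean and variance of true log intake.
#' @param r_share share of the residual variance assigned to the
#'   person-specific bias (default 0.3).
#' @return list(beta0, beta1, sigma2_r, sigma2_eps).
#' @export
tool_params_from_validity <- function(lambda, rho, pct_diff, mu_T, sigma2_T,
                                      r_share = 0.3) {
  if (lambda <= 0 || rho <= 0 || rho >= 1)
    dv_config_error("need lambda > 0 and rho in (0, 1)")
  beta1 <- rho^2 / lambda
  var_q <- (rho / lambda)^2 * sigma2_T
  resid <- var_q * (1 - rho^2)
  list(beta0 = log(1 + pct_diff / 100) - (beta1 - 1) * mu_T,
       beta1 = beta1,
       sigma2_r = r_share * resid,
       sigma2_eps = (1 - r_share) * resid)
}

#' Configuration of a synthetic validation study
#'
#' Defines the generative model: per-nutrient true-intake distributions and
#' biomarker error, per-tool bias parameters (derived from validity profiles
#' unless supplied directly), cross-tool person-bias correlation,
#' missing-at-random probabilities per instrument, a demographics model and
#' the raw-signal parameters used to construct urine, calorimetry,
#' accelerometer and plasma measurements.
#'
#' @param n_participants number of participants.
#' @param n_occasions occasions per participant (default 3, two weeks apart).
#' @param truth per-nutrient truth table as in [default_nutrient_truth()].
#' @param r_share share of tool residual variance that is person-specific.
#' @param rho_bias correlation of the person-specific biases of the two
#'   tools (the biases of the two recalls are correlated).
#' @param missingness named probabilities of a record being missing, per
#'   instrument (`tool_A`, `tool_B`, `biomarker`).
#' @param demographics list: p_female, age_range, weight mean/sd by sex,
#'   bmi mean/sd, weight_drift_sd (relative per-visit drift).
#' @param raw list of raw-signal parameters: urine volume log-mean/log-sd,
#'   PABA recovery mean/sd, per-void miss probability, calorimetry
#'   multiplicative noise sd and respiratory quotient, AEE log-mean/log-sd,
#'   wear-time mean/sd, sucrose share of urinary sugars, plasma analyte
#'   log-scale parameters.
#' @param seed integer RNG seed; everything downstream is deterministic
#'   given it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 200L,
                              n_occasions = 3L,
                              truth = default_nutrient_truth(),
                              r_share = 0.3,
                              rho_bias = 0.5,
                              missingness = c(tool_A = 0.10, tool_B = 0.10,
                                              biomarker = 0.10),
                              demographics = list(
                                p_female = 0.60, age_range = c(18, 65),
                                weight_mean = c(M = 81, F = 67),
                                weight_sd = c(M = 13, F = 13),
                                bmi_mean = 25.5, bmi_sd = 4.5,
                                weight_drift_sd = 0.015),
                              raw = list(
                                urine_volume_meanlog = log(1.6),
                                urine_volume_sdlog = 0.25,
                                paba_mean = 96, paba_sd = 6,
                                missed_void_prob = 0.08,
                                calorimetry_noise_sd = 0.05, rq = 0.85,
                                aee_meanlog = log(2.7), aee_sdlog = 0.3,
                                wear_mean = 23.8, wear_sd = 0.6,
                                sucrose_share = 0.6,
                                plasma = list(
                                  beta_carotene = c(meanlog = log(0.59),
                                                    between = 0.35, within = 0.15),
                                  vitamin_C = c(meanlog = log(60),
                                                between = 0.12, within = 0.06),
                                  vitamin_E = c(meanlog = log(37),
                                                between = 0.06, within = 0.03))),
                              seed = 1L) {
  # tool parameters derived from the validity profiles
  tools <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    row <- truth[i, ]
    mu_T <- log(row$gm_ref)
    do.call(rbind, lapply(c("A", "B"), function(m) {
      pr <- tool_params_from_validity(row[[paste0("lambda_", m)]],
                                      row[[paste0("rho_", m)]],
                                      row[[paste0("pct_", m)]],
                                      mu_T, row$sigma2_T, r_share)
      data.frame(tool = m, nutrient = row$nutrient, beta0 = pr$beta0,
                 beta1 = pr$beta1, sigma2_r = pr$sigma2_r,
                 sigma2_eps = pr$sigma2_eps, stringsAsFactors = FALSE)
    }))
  }))
  nutrients <- data.frame(nutrient = truth$nutrient,
                          mu_T = log(truth$gm_ref),
                          sigma2_T = truth$sigma2_T,
                          sigma2_u = truth$sigma2_u,
                          stringsAsFactors = FALSE)
  cfg <- structure(list(n_participants = as.integer(n_participants),
                        n_occasions = as.integer(n_occasions),
                        nutrients = nutrients, tools = tools,
                        rho_bias = rho_bias, missingness = missingness,
                        demographics = demographics, raw = raw,
                        seed = as.integer(seed)),
                   class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

#' @rdname simulation_config
#' @param config object to validate.
#' @export
validate_simulation_config <- function(config) {
  if (config$n_participants < 1L) dv_config_error("n_participants must be >= 1")
  if (config$n_occasions < 1L) dv_config_error("n_occasions must be >= 1")
  nv <- config$nutrients
  if (any(nv$sigma2_T < 0) || any(nv$sigma2_u < 0))
    dv_config_error("nutrient variances must be non-negative")
  tl <- config$tools
  if (any(tl$sigma2_r < 0) || any(tl$sigma2_eps < 0))
    dv_config_error("tool variances must be non-negative")
  for (nut in nv$nutrient) {
    sr <- tl$sigma2_r[tl$nutrient == nut]
    if (length(sr) == 2L) {
      bound <- sqrt(prod(sr))
      if (abs(config$rho_bias) * bound > bound + 1e-12 ||
          abs(config$rho_bias) > 1)
        dv_config_error(paste0("person-bias covariance not admissible for ", nut))
    }
  }
  if (any(config$missingness < 0 | config$missingness > 1))
    dv_config_error("missingness probabilities must lie in [0, 1]")
  if (config$raw$missed_void_prob < 0 || config$raw$missed_void_prob > 1)
    dv_config_error("missed_void_prob must lie in [0, 1]")
  invisible(config)
}

#' Simulate a complete validation study
#'
#' Draws, per participant and nutrient, a true usual log intake
#' `T ~ N(mu_T, sigma2_T)`; biomarker log values `T + u` per occasion; and
#' per tool `beta0 + beta1*T + r + eps` with the two tools' person-specific
#' biases `(r_A, r_B)` bivariate normal.  Raw biomarker signals are then
#' attached so that [derive_reference_intakes()] reproduces the biomarker
#' values (exactly, for complete-recovery collections), and
#' missing-at-random deletion is applied per instrument.  Deterministic
#' given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param constants a [derivation_constants()] object used to invert the
#'   derivations when building raw signals.
#' @param raw_panels set `FALSE` to skip raw-signal generation (faster when
#'   only the modelled log values are needed).
#' @return A long-format `data.frame` (class `study_dataset`): one row per
#'   participant x occasion x instrument.
#' @export
generate_validation_study <- function(config,
                                      constants = derivation_constants(),
                                      raw_panels = TRUE) {
  validate_simulation_config(config)
  set.seed(config$seed)
  n <- config$n_participants
  J <- config$n_occasions
  nuts <- config$nutrients$nutrient

  dem <- config$demographics
  sex <- ifelse(stats::runif(n) < dem$p_female, "F", "M")
  age <- round(stats::runif(n, dem$age_range[1], dem$age_range[2]))
  weight0 <- stats::rnorm(n, dem$weight_mean[sex], dem$weight_sd[sex])
  weight0 <- pmax(weight0, 40)
  bmi <- pmax(pmin(stats::rnorm(n, dem$bmi_mean, dem$bmi_sd), 45), 17)
  # per-visit weights: multiplicative random drift around baseline
  drift <- matrix(stats::rnorm(n * J, 0, dem$weight_drift_sd), n, J)
  drift[, 1] <- 0
  weights <- weight0 * exp(t(apply(drift, 1, cumsum)))
  if (J == 1L) weights <- matrix(weight0, n, 1)

  # occasion (biomarker) dates ~14 +/- 2 days apart; recalls follow 1-3 and
  # then 2-4 days later, tool order randomized per participant
  start <- as.Date("2016-01-15") + sample.int(90, n, replace = TRUE)
  gaps <- matrix(pmax(round(stats::rnorm(n * J, 14, 2)), 7), n, J)
  gaps[, 1] <- 0
  bio_dates <- start + t(apply(gaps, 1, cumsum))
  if (J == 1L) bio_dates <- matrix(start, n, 1)
  first_tool <- sample(c("A", "B"), n, replace = TRUE)
  off1 <- matrix(sample(1:3, n * J, replace = TRUE), n, J)
  off2 <- off1 + matrix(sample(2:4, n * J, replace = TRUE), n, J)

  # latent true log intakes and measurement draws
  K <- length(nuts)
  TT <- matrix(NA_real_, n, K, dimnames = list(NULL, nuts))
  bio_vals <- array(NA_real_, c(n, J, K), dimnames = list(NULL, NULL, nuts))
  tool_vals <- list(A = array(NA_real_, c(n, J, K), dimnames = list(NULL, NULL, nuts)),
                    B = array(NA_real_, c(n, J, K), dimnames = list(NULL, NULL, nuts)))
  for (k in seq_len(K)) {
    nut <- nuts[k]
    nv <- config$nutrients[config$nutrients$nutrient == nut, ]
    TT[, k] <- stats::rnorm(n, nv$mu_T, sqrt(nv$sigma2_T))
    bio_vals[, , k] <- TT[, k] + matrix(stats::rnorm(n * J, 0, sqrt(nv$sigma2_u)), n, J)
    tlA <- config$tools[config$tools$nutrient == nut & config$tools$tool == "A", ]
    tlB <- config$tools[config$tools$nutrient == nut & config$tools$tool == "B", ]
    # bivariate person-specific biases via Cholesky of the 2x2 covariance
    sA <- sqrt(tlA$sigma2_r); sB <- sqrt(tlB$sigma2_r)
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    rA <- sA * z1
    rB <- sB * (config$rho_bias * z1 + sqrt(1 - config$rho_bias^2) * z2)
    for (m in c("A", "B")) {
      tl <- if (m == "A") tlA else tlB
      r <- if (m == "A") rA else rB
      eps <- matrix(stats::rnorm(n * J, 0, sqrt(tl$sigma2_eps)), n, J)
      tool_vals[[m]][, , k] <- tl$beta0 + tl$beta1 * TT[, k] + r + eps
    }
  }

  build <- function(instrument, vals, dates) {
    do.call(rbind, lapply(seq_len(J), function(j) {
      df <- data.frame(participant = seq_len(n), occasion = j,
                       instrument = instrument, date = dates[, j],
                       age = age, sex = sex, weight = weights[, j], bmi = bmi,
                       stringsAsFactors = FALSE)
      for (k in seq_len(K)) df[[nuts[k]]] <- exp(vals[, j, k])
      df
    }))
  }
  recall_dates <- function(m) {
    d <- bio_dates
    use1 <- first_tool == m
    d[use1, ] <- bio_dates[use1, , drop = FALSE] + off1[use1, , drop = FALSE]
    d[!use1, ] <- bio_dates[!use1, , drop = FALSE] + off2[!use1, , drop = FALSE]
    d
  }
  ds <- rbind(build("biomarker", bio_vals, bio_dates),
              build("tool_A", tool_vals$A, recall_dates("A")),
              build("tool_B", tool_vals$B, recall_dates("B")))
  ds <- ds[order(ds$participant, ds$occasion, ds$instrument), ]
  rownames(ds) <- NULL
  class(ds) <- c("study_dataset", "data.frame")

  if (raw_panels) ds <- generate_raw_panels(ds, config, constants)

  if (any(config$missingness > 0))
    ds <- apply_mar_missingness(ds, config$missingness,
                                seed = (config$seed + 1L) %% .Machine$integer.max)
  ds
}

#' Attach raw biomarker signals consistent with the planted reference values
#'
#' For each biomarker row, constructs urine volume, urinary analyte amounts,
#' PABA recovery, missed-void count, a 15-minute VO2/VCO2 calorimetry series,
#' accelerometer AEE and wear time, and plasma antioxidant concentrations,
#' such that running [derive_reference_intakes()] with the same constants
#' recovers the row's nutrient values exactly for complete-PABA-recovery
#' collections.  Collections with PABA recovery below 85% are treated as
#' physically incomplete: their urinary N/K/Na amounts are scaled by
#' `recovery/93`, which the PABA adjustment rule inverts exactly.
#'
#' @inheritParams generate_validation_study
#' @param dataset a study dataset containing biomarker rows.
#' @return The dataset with raw panel columns filled on biomarker rows.
#' @export
generate_raw_panels <- function(dataset, config,
                                constants = derivation_constants()) {
  bio <- which(dataset$instrument == "biomarker")
  if (!length(bio)) dv_input_error("dataset has no biomarker rows")
  nb <- length(bio)
  raw <- config$raw

  for (col in c("urine_volume", "urinary_nitrogen", "urinary_potassium",
                "urinary_sodium", "urinary_sucrose", "urinary_fructose",
                "paba_recovery", "missed_voids", "aee", "wear_time",
                "plasma_beta_carotene", "plasma_vitamin_C", "plasma_vitamin_E"))
    if (!col %in% names(dataset)) dataset[[col]] <- NA_real_
  if (!"vo2_series" %in% names(dataset)) {
    dataset$vo2_series <- vector("list", nrow(dataset))
    dataset$vco2_series <- vector("list", nrow(dataset))
  }

  dataset$urine_volume[bio] <- stats::rlnorm(nb, raw$urine_volume_meanlog,
                                             raw$urine_volume_sdlog)
  rec <- stats::rnorm(nb, raw$paba_mean, raw$paba_sd)
  dataset$paba_recovery[bio] <- pmin(pmax(rec, 40), 115)
  dataset$missed_voids[bio] <- stats::rbinom(nb, 3L, raw$missed_void_prob)

  # complete collections carry the full analyte amount; incomplete ones are
  # scaled by recovery/93 so the PABA adjustment inverts the loss exactly
  loss <- ifelse(dataset$paba_recovery[bio] < 85,
                 dataset$paba_recovery[bio] /
                   (100 * constants$paba_excretion_fraction), 1)
  dataset$urinary_nitrogen[bio] <- dataset$protein[bio] *
    constants$nitrogen_excretion_fraction / constants$nitrogen_to_protein_ratio * loss
  dataset$urinary_potassium[bio] <- dataset$potassium[bio] *
    constants$potassium_excretion_fraction * loss
  dataset$urinary_sodium[bio] <- dataset$sodium[bio] *
    constants$sodium_excretion_fraction * loss

  # invert the total-sugars calibration for the urinary sugar amounts
  cf <- constants$sugar_coef
  female <- as.numeric(toupper(substr(dataset$sex[bio], 1, 1)) == "F")
  total_mg <- exp((log(dataset$total_sugars[bio]) - cf[["a"]] -
                     cf[["c"]] * dataset$age[bio] - cf[["d"]] * female) / cf[["b"]])
  dataset$urinary_sucrose[bio] <- total_mg * raw$sucrose_share
  dataset$urinary_fructose[bio] <- total_mg * (1 - raw$sucrose_share)

  # energy: TEE is the planted value; AEE drawn, REE implied, calorimetry
  # series built so the Weir mean over the last 10 minutes is exact
  tee <- dataset$energy[bio]
  aee <- stats::rlnorm(nb, raw$aee_meanlog, raw$aee_sdlog)
  aee <- pmin(aee, 0.8 * (1 - constants$tef_fraction) * tee)
  ree <- (1 - constants$tef_fraction) * tee - aee
  dataset$aee[bio] <- aee
  dataset$wear_time[bio] <- stats::rnorm(nb, raw$wear_mean, raw$wear_sd)
  kcal_min <- ree / constants$kcal_to_mj / 1440
  vo2_target <- kcal_min / (constants$weir_vo2 + constants$weir_vco2 * raw$rq)
  vco2_target <- raw$rq * vo2_target
  noise <- matrix(exp(stats::rnorm(nb * 15, 0, raw$calorimetry_noise_sd)), nb, 15)
  settle <- matrix(stats::runif(nb * 5, 1.05, 1.25), nb, 5)
  for (i in seq_len(nb)) {
    w <- noise[i, 6:15] / mean(noise[i, 6:15])  # renormalize: exact last-10 mean
    vo2 <- c(vo2_target[i] * settle[i, ] * noise[i, 1:5], vo2_target[i] * w)
    vco2 <- c(vco2_target[i] * settle[i, ] * noise[i, 1:5], vco2_target[i] * w)
    dataset$vo2_series[[bio[i]]] <- vo2
    dataset$vco2_series[[bio[i]]] <- vco2
  }

  # plasma concentration biomarkers: person-level component plus occasion
  # noise, independent of the dietary nutrients (concentration biomarkers
  # support ranking only and are not converted to intakes)
  ids <- dataset$participant[bio]
  uid <- unique(ids)
  for (an in names(raw$plasma)) {
    pp <- raw$plasma[[an]]
    person <- stats::rnorm(length(uid), 0, sqrt(pp[["between"]]))
    names(person) <- as.character(uid)
    dataset[[paste0("plasma_", an)]][bio] <-
      exp(pp[["meanlog"]] + person[as.character(ids)] +
            stats::rnorm(nb, 0, sqrt(pp[["within"]])))
  }
  dataset
}

#' Delete records completely at random
#'
#' Each record (row) is deleted independently with the probability given for
#' its instrument, independently of all latent and observed values
#' (missing completely at random, a special case of missing at random).
#'
#' @param dataset a study dataset.
#' @param probs named per-instrument deletion probabilities.
#' @param seed integer seed making the deletion reproducible.
#' @return The dataset with rows removed.
#' @export
apply_mar_missingness <- function(dataset, probs, seed = 1L) {
  if (any(probs < 0 | probs > 1))
    dv_config_error("missingness probabilities must lie in [0, 1]")
  set.seed(seed)
  p <- probs[dataset$instrument]
  p[is.na(p)] <- 0
  drop <- stats::runif(nrow(dataset)) < p
  out <- dataset[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusion_log") <- attr(dataset, "exclusion_log")
  class(out) <- class(dataset)
  out
}
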