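# Conversion of raw biomarker measurements to reference intakes, and the
# study's completeness / inclusion rules.

#' Constants used to derive reference intakes from raw biomarker measurements
#'
#' Recovery biomarkers recover a fixed, known fraction of intake in 24-h
#' urine: 81% of dietary nitrogen, 80% of potassium and 86% of sodium, while
#' 93% of an administered PABA (para-aminobenzoic acid) dose is excreted
#' within 24 h when the collection is complete.  Total energy expenditure is
#' reconstructed from resting energy expenditure (indirect calorimetry via
#' the Weir equation), activity energy expenditure (accelerometry) and an
#' assumed thermic effect of food of 10% of total expenditure.  Urinary
#' sucrose plus fructose is a predictive biomarker of total sugars through a
#' log-linear calibration with age and sex terms; the default coefficients
#' are synthetic placeholders (the published calibration is not reproduced
#' here) and should be overridden when real coefficients are available.
#'
#' @param nitrogen_to_protein_ratio grams of protein per gram of nitrogen
#'   (default 6.25; food-source-specific ratios can also be supplied per
#'   record via a `nitrogen_ratio` column in the dataset).
#' @param nitrogen_excretion_fraction,potassium_excretion_fraction,sodium_excretion_fraction
#'   fraction of intake excreted in a complete 24-h urine collection.
#' @param paba_excretion_fraction fraction of the PABA dose excreted in 24 h.
#' @param tef_fraction thermic effect of food as a fraction of total energy
#'   expenditure.
#' @param weir_vo2,weir_vco2 Weir coefficients, kcal per litre of oxygen
#'   consumed / carbon dioxide produced per minute.
#' @param kcal_to_mj megajoules per kilocalorie.
#' @param sugar_coef named vector `c(a, b, c, d)` of the total-sugars
#'   calibration: predicted grams = exp(a + b*log(sucrose+fructose mg) +
#'   c*age + d*I[female]).
#' @return An object of class `derivation_constants`.
#' @export
derivation_constants <- function(nitrogen_to_protein_ratio = 6.25,
                                 nitrogen_excretion_fraction = 0.81,
                                 potassium_excretion_fraction = 0.80,
                                 sodium_excretion_fraction = 0.86,
                                 paba_excretion_fraction = 0.93,
                                 tef_fraction = 0.10,
                                 weir_vo2 = 3.941,
                                 weir_vco2 = 1.106,
                                 kcal_to_mj = 4.184e-3,
                                 sugar_coef = c(a = 2.5, b = 0.48,
                                                c = 0.008, d = -0.12)) {
  fr <- c(nitrogen_excretion_fraction, potassium_excretion_fraction,
          sodium_excretion_fraction, paba_excretion_fraction)
  if (any(fr <= 0 | fr > 1))
    dv_config_error("excretion fractions must lie in (0, 1]")
  if (nitrogen_to_protein_ratio <= 0)
    dv_config_error("nitrogen_to_protein_ratio must be positive")
  if (tef_fraction < 0 || tef_fraction >= 1)
    dv_config_error("tef_fraction must lie in [0, 1)")
  if (!all(c("a", "b", "c", "d") %in% names(sugar_coef)))
    dv_config_error("sugar_coef must have elements named a, b, c, d")
  structure(list(nitrogen_to_protein_ratio = nitrogen_to_protein_ratio,
                 nitrogen_excretion_fraction = nitrogen_excretion_fraction,
                 potassium_excretion_fraction = potassium_excretion_fraction,
                 sodium_excretion_fraction = sodium_excretion_fraction,
                 paba_excretion_fraction = paba_excretion_fraction,
                 tef_fraction = tef_fraction,
                 weir_vo2 = weir_vo2, weir_vco2 = weir_vco2,
                 kcal_to_mj = kcal_to_mj, sugar_coef = sugar_coef),
            class = "derivation_constants")
}

#' Classify 24-h urine collections by PABA recovery
#'
#' Recovery of 85--110% of the administered PABA dose indicates a complete
#' collection; 50 to below 85% is adjustable (analytes can be rescaled to the
#' expected 93% recovery); below 50% or above 110% the collection is excluded.
#' Boundaries are inclusive at 50, 85 and 110.
#'
#' @param recovery PABA recovery as a percentage of the administered dose.
#' @return Character vector in `c("complete", "adjustable", "excluded")`.
#' @export
classify_paba <- function(recovery) {
  if (any(recovery < 0, na.rm = TRUE))
    dv_input_error("PABA recovery cannot be negative")
  out <- rep(NA_character_, length(recovery))
  out[recovery >= 85 & recovery <= 110] <- "complete"
  out[recovery >= 50 & recovery < 85] <- "adjustable"
  out[recovery < 50 | recovery > 110] <- "excluded"
  out
}

#' Rescale a urinary analyte to the expected PABA recovery
#'
#' For adjustable collections (PABA recovery 50 to below 85%) the analyte
#' amount is multiplied by `target / recovery`, i.e. scaled up to what a
#' complete collection (93% recovery) would have contained.
#'
#' @param amount analyte amount, g/24 h.
#' @param recovery observed PABA recovery, %.
#' @param target recovery the analyte is rescaled to, % (default 93).
#' @export
paba_adjust <- function(amount, recovery, target = 93) {
  status <- classify_paba(recovery)
  if (any(status != "adjustable", na.rm = TRUE))
    dv_input_error("paba_adjust() is only defined for adjustable recoveries (50 to <85%)")
  amount * target / recovery
}

#' Protein intake from 24-h urinary nitrogen
#'
#' @param urinary_nitrogen g nitrogen per 24 h.
#' @param constants a [derivation_constants()] object.
#' @param ratio optional per-record nitrogen-to-protein ratio overriding the
#'   constant (food-source-specific ratios).
#' @return Protein intake, g/day.
#' @export
protein_from_nitrogen <- function(urinary_nitrogen,
                                  constants = derivation_constants(),
                                  ratio = NULL) {
  if (any(urinary_nitrogen < 0, na.rm = TRUE))
    dv_input_error("urinary nitrogen cannot be negative")
  if (is.null(ratio)) ratio <- constants$nitrogen_to_protein_ratio
  urinary_nitrogen / constants$nitrogen_excretion_fraction * ratio
}

#' Mineral intake from 24-h urinary excretion
#'
#' @param amount urinary amount, g/24 h.
#' @param excretion_fraction fraction of intake excreted, in (0, 1].
#' @return Intake, g/day.
#' @export
mineral_from_urine <- function(amount, excretion_fraction) {
  if (excretion_fraction <= 0 || excretion_fraction > 1)
    dv_input_error("excretion_fraction must lie in (0, 1]")
  if (any(amount < 0, na.rm = TRUE))
    dv_input_error("urinary amount cannot be negative")
  amount / excretion_fraction
}

#' Predicted total sugars intake from urinary sucrose and fructose
#'
#' Log-linear calibration with age and sex terms:
#' `exp(a + b*log(sucrose + fructose) + c*age + d*I[female])`.
#'
#' @param sucrose,fructose mg per 24 h.
#' @param age years.
#' @param sex `"F"`/`"M"` (or `"female"`/`"male"`).
#' @param constants a [derivation_constants()] object.
#' @return Predicted total sugars intake, g/day.
#' @export
predict_total_sugars <- function(sucrose, fructose, age, sex,
                                 constants = derivation_constants()) {
  total <- sucrose + fructose
  if (any(total <= 0, na.rm = TRUE))
    dv_input_error("total urinary sugars must be positive for prediction")
  cf <- constants$sugar_coef
  female <- as.numeric(toupper(substr(sex, 1, 1)) == "F")
  exp(cf[["a"]] + cf[["b"]] * log(total) + cf[["c"]] * age + cf[["d"]] * female)
}

#' Resting energy expenditure from indirect calorimetry (Weir equation)
#'
#' Uses the mean of the last 10 one-minute VO2 and VCO2 readings (the earlier
#' minutes are the stabilization period), converts to an energy rate with the
#' Weir linear combination and scales to MJ/day.
#'
#' @param vo2_series,vco2_series L/min readings, one per minute, length >= 10.
#' @param constants a [derivation_constants()] object.
#' @return REE, MJ/day.
#' @export
weir_ree <- function(vo2_series, vco2_series,
                     constants = derivation_constants()) {
  if (length(vo2_series) < 10 || length(vco2_series) < 10)
    dv_input_error("calorimetry series must have at least 10 readings")
  last10 <- function(x) mean(utils::tail(x, 10))
  kcal_min <- constants$weir_vo2 * last10(vo2_series) +
    constants$weir_vco2 * last10(vco2_series)
  kcal_min * 1440 * constants$kcal_to_mj
}

#' Total energy expenditure from REE and AEE
#'
#' `TEE = (REE + AEE) / (1 - tef_fraction)`; TEE serves as the reference for
#' total energy intake under the assumption of energy balance.
#'
#' @param ree,aee resting / activity energy expenditure, MJ/day.
#' @param constants a [derivation_constants()] object.
#' @export
total_energy_expenditure <- function(ree, aee,
                                     constants = derivation_constants()) {
  if (constants$tef_fraction >= 1)
    dv_config_error("tef_fraction must be below 1")
  if (any(ree < 0, na.rm = TRUE) || any(aee < 0, na.rm = TRUE))
    dv_input_error("ree and aee cannot be negative")
  (ree + aee) / (1 - constants$tef_fraction)
}

#' Recompute reference intakes from the raw biomarker panels
#'
#' Replaces the nutrient values on biomarker rows with values derived from
#' the raw panel columns: protein from urinary nitrogen, potassium and sodium
#' from urinary excretion, total sugars from the urinary sucrose + fructose
#' calibration, and energy from calorimetry + accelerometry (TEE).  Rows
#' whose urinary sugars are zero get `NA` sugars and a reason code in the
#' returned `sugar_status` column rather than a fabricated prediction.
#'
#' @param dataset a study dataset with raw panel columns on biomarker rows.
#' @param constants a [derivation_constants()] object.
#' @return The dataset with derived reference values.
#' @export
derive_reference_intakes <- function(dataset,
                                     constants = derivation_constants()) {
  bio <- which(dataset$instrument == "biomarker")
  if (!length(bio)) dv_input_error("dataset has no biomarker rows")
  ratio <- if ("nitrogen_ratio" %in% names(dataset))
    dataset$nitrogen_ratio[bio] else NULL
  dataset$protein[bio] <-
    protein_from_nitrogen(dataset$urinary_nitrogen[bio], constants, ratio)
  dataset$potassium[bio] <-
    mineral_from_urine(dataset$urinary_potassium[bio],
                       constants$potassium_excretion_fraction)
  dataset$sodium[bio] <-
    mineral_from_urine(dataset$urinary_sodium[bio],
                       constants$sodium_excretion_fraction)

  total <- dataset$urinary_sucrose[bio] + dataset$urinary_fructose[bio]
  dataset$sugar_status <- NA_character_
  ok <- !is.na(total) & total > 0
  dataset$sugar_status[bio] <- ifelse(ok, "included", "no_urinary_sugar")
  sug <- rep(NA_real_, length(bio))
  if (any(ok))
    sug[ok] <- predict_total_sugars(dataset$urinary_sucrose[bio][ok],
                                    dataset$urinary_fructose[bio][ok],
                                    dataset$age[bio][ok],
                                    dataset$sex[bio][ok], constants)
  dataset$total_sugars[bio] <- sug

  ree <- vapply(bio, function(i) {
    vo2 <- dataset$vo2_series[[i]]
    vco2 <- dataset$vco2_series[[i]]
    if (is.null(vo2) || length(vo2) < 10) return(NA_real_)
    weir_ree(vo2, vco2, constants)
  }, numeric(1))
  dataset$energy[bio] <-
    total_energy_expenditure(ree, dataset$aee[bio], constants)
  dataset
}

#' Apply the study's inclusion/exclusion rules
#'
#' The main rules always apply: urinary-derived values are excluded for
#' occasions with two or more missed urine voids, and TEE is excluded at
#' visits where body weight deviates by more than 5% from the first
#' appointment.  Sensitivity modes add, on top of the main rules:
#' \describe{
#'   \item{`paba_sensitivity`}{urinary nitrogen-, potassium- and
#'     sodium-derived values are rescaled to 93% PABA recovery where recovery
#'     was 50 to below 85%, and excluded outside 50--110%.}
#'   \item{`wear_sensitivity`}{TEE excluded where armband wear time was below
#'     23 h or above 25 h.}
#'   \item{`proximity_sensitivity`}{recall records collected within 24 h
#'     (calendar-date difference of at most one day) of a biomarker
#'     collection are excluded.}
#' }
#'
#' @param dataset a study dataset.
#' @param mode one of `"main"`, `"paba_sensitivity"`, `"wear_sensitivity"`,
#'   `"proximity_sensitivity"`.
#' @return The dataset with logical columns `use_urinary`, `use_tee`,
#'   `use_recall` and an `exclusion_log` attribute (one row per exclusion or
#'   adjustment, with the rule and detail).
#' @export
apply_exclusions <- function(dataset, mode = c("main", "paba_sensitivity",
                                               "wear_sensitivity",
                                               "proximity_sensitivity")) {
  modes <- eval(formals(apply_exclusions)$mode)
  mode <- mode[1L]
  if (!mode %in% modes)
    dv_input_error(paste0("unknown exclusion mode: ", mode))

  ds <- dataset
  ds$use_urinary <- TRUE
  ds$use_tee <- TRUE
  ds$use_recall <- TRUE
  log <- list()
  note <- function(rows, rule, detail) {
    if (!length(rows)) return(invisible())
    log[[length(log) + 1L]] <<- data.frame(
      participant = ds$participant[rows], occasion = ds$occasion[rows],
      instrument = ds$instrument[rows], rule = rule, detail = detail,
      stringsAsFactors = FALSE)
  }

  bio <- ds$instrument == "biomarker"

  # >= 2 missed voids: the urinary collection is unusable for that occasion
  mv <- which(bio & !is.na(ds$missed_voids) & ds$missed_voids >= 2)
  ds$use_urinary[mv] <- FALSE
  note(mv, "missed_voids", "two or more missed urine voids")

  # > 5% weight change from the first clinic appointment: TEE unreliable
  for (id in unique(ds$participant)) {
    rows <- which(ds$participant == id & bio)
    if (!length(rows)) next
    rows <- rows[order(ds$occasion[rows])]
    w0 <- ds$weight[rows[1L]]
    if (is.na(w0) || w0 <= 0) next
    bad <- rows[!is.na(ds$weight[rows]) & abs(ds$weight[rows] - w0) / w0 > 0.05]
    ds$use_tee[bad] <- FALSE
    note(bad, "weight_change", "more than 5% weight change from first appointment")
  }

  if (mode == "paba_sensitivity") {
    rec <- ds$paba_recovery
    status <- rep(NA_character_, nrow(ds))
    has <- bio & !is.na(rec)
    status[has] <- classify_paba(rec[has])
    adj <- which(status == "adjustable" & ds$use_urinary)
    for (i in adj) {
      f <- 100 * derivation_constants()$paba_excretion_fraction / rec[i]
      for (col in intersect(c("protein", "potassium", "sodium"), names(ds)))
        ds[[col]][i] <- ds[[col]][i] * f
    }
    note(adj, "paba_adjusted", "urinary N/K/Na rescaled to 93% PABA recovery")
    exc <- which(status == "excluded")
    ds$use_urinary[exc] <- FALSE
    note(exc, "paba_excluded", "PABA recovery outside 50-110%")
  }

  if (mode == "wear_sensitivity") {
    bad <- which(bio & !is.na(ds$wear_time) &
                   (ds$wear_time < 23 | ds$wear_time > 25))
    ds$use_tee[bad] <- FALSE
    note(bad, "wear_time", "armband worn < 23 h or > 25 h")
  }

  if (mode == "proximity_sensitivity") {
    recall <- which(ds$instrument %in% c("tool_A", "tool_B"))
    for (i in recall) {
      bdates <- ds$date[ds$participant == ds$participant[i] & bio]
      if (!length(bdates)) next
      if (any(abs(as.numeric(ds$date[i]) - as.numeric(bdates)) <= 1, na.rm = TRUE)) {
        ds$use_recall[i] <- FALSE
        note(i, "proximity", "recall within 24 h of a biomarker collection")
      }
    }
  }

  attr(ds, "exclusion_log") <- if (length(log)) do.call(rbind, log) else
    data.frame(participant = integer(), occasion = integer(),
               instrument = character(), rule = character(),
               detail = character(), stringsAsFactors = FALSE)
  ds
}
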