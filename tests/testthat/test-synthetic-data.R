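test_that("generated studies have the forced shape and are seed-deterministic", {
  cfg <- clean_config(n = 10, seed = 4)
  ds <- generate_validation_study(cfg)
  expect_equal(nrow(ds), 10 * 3 * 3)
  expect_equal(as.integer(table(ds$instrument)), rep(30L, 3))
  expect_true(all(!duplicated(ds[c("participant", "occasion", "instrument")])))
  expect_true(all(ds$protein > 0 & ds$energy > 0))
  # dates strictly increasing within participant for each instrument
  for (id in unique(ds$participant))
    for (inst in unique(ds$instrument)) {
      d <- ds$date[ds$participant == id & ds$instrument == inst]
      expect_true(all(diff(as.numeric(d)) > 0))
    }
  expect_identical(ds, generate_validation_study(cfg))
  cfg2 <- cfg; cfg2$seed <- 5L
  expect_false(identical(generate_validation_study(cfg2), ds))
})

test_that("single-occasion tool log variance matches its closed form", {
  # var(log Q) = beta1^2 sigma2_T + sigma2_r + sigma2_eps = 0.11
  cfg <- explicit_protein_config(n = 50000, seed = 8)
  cfg$n_occasions <- 1L
  ds <- generate_validation_study(cfg, raw_panels = FALSE)
  v <- var(log(ds$protein[ds$instrument == "tool_A"]))
  truth <- 1^2 * 0.04 + 0.02 + 0.05
  se3 <- 3 * truth * sqrt(2 / (50000 - 1))
  expect_lt(abs(v - truth), se3)
})

test_that("log-value moments converge to the configured model moments", {
  cfg <- explicit_protein_config(n = 20000, seed = 15)
  ds <- generate_validation_study(cfg, raw_panels = FALSE)
  logv <- function(inst, occ) {
    d <- ds[ds$instrument == inst & ds$occasion %in% occ, ]
    log(d$protein[order(d$participant, d$occasion)])
  }
  n <- cfg$n_participants
  mu_T <- cfg$nutrients$mu_T
  # biomarker mean and between/within decomposition
  expect_lt(abs(mean(logv("biomarker", 1)) - mu_T),
            3 * sqrt((0.04 + 0.05) / n))
  cov_b <- cov(logv("biomarker", 1), logv("biomarker", 2))
  expect_lt(abs(cov_b - 0.04), 3 * 0.1 / sqrt(n))
  # cross-instrument covariance beta1_A * beta1_B * sigma2_T + sigma_rAB
  cov_ab <- cov(logv("tool_A", 1), logv("tool_B", 2))
  truth_ab <- 1 * 1 * 0.04 + cfg$rho_bias * 0.02
  expect_lt(abs(cov_ab - truth_ab), 3 * 0.1 / sqrt(n))
  # tool-biomarker covariance identifies beta1 sigma2_T
  cov_am <- cov(logv("tool_A", 1), logv("biomarker", 2))
  expect_lt(abs(cov_am - 0.04), 3 * 0.1 / sqrt(n))
})

test_that("raw panels invert the derivations for complete collections", {
  cfg <- clean_config(n = 25, seed = 21)
  ds <- generate_validation_study(cfg)
  bio <- ds$instrument == "biomarker"
  # urinary nitrogen consistent with planted protein: N = protein*0.81/6.25
  expect_equal(ds$urinary_nitrogen[bio], ds$protein[bio] * 0.81 / 6.25,
               tolerance = 1e-12)
  # Weir REE from the series equals 0.9*TEE - AEE
  i <- which(bio)[1]
  expect_equal(weir_ree(ds$vo2_series[[i]], ds$vco2_series[[i]]),
               0.9 * ds$energy[i] - ds$aee[i], tolerance = 1e-9)
  expect_true(all(ds$missed_voids[bio] == 0))
  # full derivation round trip, relative error below 1e-9
  der <- derive_reference_intakes(ds)
  for (col in c("protein", "potassium", "sodium", "total_sugars", "energy"))
    expect_lt(max(abs(der[[col]][bio] - ds[[col]][bio]) / ds[[col]][bio]),
              1e-9)
})

test_that("incomplete collections lose analyte in proportion to PABA recovery", {
  cfg <- clean_config(n = 30, seed = 33)
  cfg$raw$paba_sd <- 18   # spread recoveries across the classes
  ds <- generate_validation_study(cfg)
  bio <- which(ds$instrument == "biomarker")
  rec <- ds$paba_recovery[bio]
  low <- rec < 85
  expect_true(any(low))  # the fixture must exercise the incomplete branch
  expect_equal(ds$urinary_nitrogen[bio][low],
               ds$protein[bio][low] * 0.81 / 6.25 * rec[low] / 93,
               tolerance = 1e-12)
})

test_that("missing-at-random deletion matches its probabilities", {
  cfg <- clean_config(n = 10, seed = 2)
  ds <- generate_validation_study(cfg)
  expect_identical(nrow(apply_mar_missingness(ds, c(tool_A = 0, tool_B = 0,
                                                    biomarker = 0))),
                   nrow(ds))
  gone <- apply_mar_missingness(ds, c(tool_B = 1))
  expect_false("tool_B" %in% gone$instrument)
  # binomial check at ~10,000 records
  cfg2 <- clean_config(n = 1112, seed = 6)
  big <- generate_validation_study(cfg2, raw_panels = FALSE)
  kept <- apply_mar_missingness(big, c(tool_A = 0.2, tool_B = 0.2,
                                       biomarker = 0.2), seed = 9)
  frac <- 1 - nrow(kept) / nrow(big)
  expect_lt(abs(frac - 0.2), 0.012)
  # seed-reproducible
  expect_identical(kept, apply_mar_missingness(big, c(tool_A = 0.2,
                                                      tool_B = 0.2,
                                                      biomarker = 0.2),
                                               seed = 9))
})

test_that("invalid configurations are rejected with configuration errors", {
  cfg <- clean_config()
  cfg$nutrients$sigma2_T[1] <- -1
  expect_error(validate_simulation_config(cfg), class = "dietvalid_config_error")
  cfg <- clean_config()
  cfg$missingness[1] <- 1.5
  expect_error(validate_simulation_config(cfg), class = "dietvalid_config_error")
  cfg <- clean_config()
  cfg$rho_bias <- 1.4
  expect_error(validate_simulation_config(cfg), class = "dietvalid_config_error")
  expect_error(simulation_config(n_participants = 0), class = "dietvalid_config_error")
})

test_that("datasets round-trip through CSV with the YAML sidecar", {
  cfg <- clean_config(n = 6, seed = 12)
  ds <- generate_validation_study(cfg)
  path <- file.path(withr::local_tempdir(), "study.csv")
  write_study_dataset(ds, path, config = cfg)
  back <- read_study_dataset(path)
  expect_equal(back$protein, ds$protein, tolerance = 1e-9)
  expect_equal(back$date, ds$date)
  expect_equal(back$vo2_series[[1]], ds$vo2_series[[1]], tolerance = 1e-9)
  cfg_back <- config_from_list(yaml::read_yaml(sub("csv$", "yaml", path)))
  expect_equal(cfg_back$nutrients, cfg$nutrients)
  expect_equal(cfg_back$seed, cfg$seed)
  # the sidecar parameters regenerate the identical study
  expect_equal(generate_validation_study(cfg_back)$protein, ds$protein)
})
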