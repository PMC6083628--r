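test_that("identical methods give unit ICC and zero method effects", {
  set.seed(3)
  b <- rnorm(50, 10, 1)
  dat <- do.call(rbind, lapply(c("m1", "m2"), function(m)
    data.frame(subject = 1:50, method = m, occasion = 1, value = b)))
  cp <- fit_two_way_mixed(dat)
  expect_lt(max(cp$sigma2_int, cp$sigma2_e), 1e-6)
  expect_lt(max(abs(cp$tau)), 1e-6)
  expect_gt(icc_absolute(cp)$icc, 1 - 1e-6)
})

test_that("a constant shift moves the method effect, not the variances", {
  dat <- simulate_two_way(150, sigma2_int = c(0.2, 0.2),
                          sigma2_e = c(0.5, 0.5), seed = 8)
  dat2 <- dat
  dat2$value[dat2$method == "m2"] <- dat2$value[dat2$method == "m2"] + 0.7
  cp1 <- fit_two_way_mixed(dat)
  cp2 <- fit_two_way_mixed(dat2)
  expect_equal(diff(cp2$tau) - diff(cp1$tau), 0.7, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(cp1$sigma2_subject, cp2$sigma2_subject, tolerance = 1e-6)
  expect_equal(cp1$sigma2_e, cp2$sigma2_e, tolerance = 1e-6)
  # absolute agreement: the offset must lower the ICC
  expect_lt(icc_absolute(cp2)$icc, icc_absolute(cp1)$icc)
})

test_that("maximum likelihood matches lme4 in the homogeneous special case", {
  dat <- simulate_two_way(250, sigma2_int = c(0.3, 0.3),
                          sigma2_e = c(0.8, 0.8), shift = 0.4, seed = 42)
  cp <- fit_two_way_mixed(dat, heterogeneous = FALSE)
  m <- lme4::lmer(value ~ method + (1 | subject) + (1 | subject:method),
                  data = dat, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(m))
  ref <- c(int = vc$vcov[vc$grp == "subject:method"],
           subj = vc$vcov[vc$grp == "subject"],
           res = vc$vcov[vc$grp == "Residual"])
  expect_equal(cp$sigma2_subject, ref[["subj"]], tolerance = 1e-3)
  expect_equal(unname(cp$sigma2_int[1]), ref[["int"]], tolerance = 1e-3)
  expect_equal(unname(cp$sigma2_e[1]), ref[["res"]], tolerance = 1e-3)
  expect_equal(cp$logLik, as.numeric(stats::logLik(m)), tolerance = 1e-6)
})

test_that("heterogeneous variance components are recovered", {
  dat <- simulate_two_way(2000, sigma2_subject = 1,
                          sigma2_int = c(0.1, 0.4), sigma2_e = c(0.6, 1.3),
                          shift = 0.3, seed = 7)
  cp <- fit_two_way_mixed(dat)
  se3 <- 3 / sqrt(2000)
  expect_lt(abs(cp$sigma2_subject - 1), se3 * 2)
  expect_lt(abs(cp$sigma2_int[["m1"]] - 0.1), se3 * 2)
  expect_lt(abs(cp$sigma2_int[["m2"]] - 0.4), se3 * 2)
  expect_lt(abs(cp$sigma2_e[["m1"]] - 0.6), se3 * 2)
  expect_lt(abs(cp$sigma2_e[["m2"]] - 1.3), se3 * 2)
  expect_equal(unname(diff(cp$tau)), 0.3, tolerance = 3 * 0.05)
})

test_that("the ICC denominator applies the absolute-agreement penalty", {
  cp <- structure(list(methods = c("m1", "m2"), sigma2_subject = 1,
                       sigma2_int = c(m1 = 0, m2 = 0),
                       sigma2_e = c(m1 = 1, m2 = 1),
                       tau = c(m1 = 0, m2 = 0), mu = 0,
                       heterogeneous = TRUE),
                  class = "mixed_components")
  expect_equal(icc_absolute(cp)$icc, 0.5)
  cp$sigma2_e <- c(m1 = 0, m2 = 0)
  cp$tau <- c(m1 = -0.5, m2 = 0.5)   # sum tau^2 / (M-1) = 0.5... scaled below
  cp$tau <- cp$tau * sqrt(2)         # now sum tau^2 = 1
  expect_equal(icc_absolute(cp)$icc, 0.5)
  cp$tau <- c(m1 = 0, m2 = 0)
  expect_error(
    icc_absolute(structure(list(methods = c("m1", "m2"), sigma2_subject = 0,
                                sigma2_int = c(0, 0), sigma2_e = c(0, 0),
                                tau = c(0, 0)), class = "mixed_components")),
    class = "dietvalid_input_error")
})

test_that("ICC is scale-invariant and the bootstrap CI is reproducible", {
  dat <- simulate_two_way(120, sigma2_int = c(0.2, 0.3),
                          sigma2_e = c(0.7, 1.0), shift = 0.2, seed = 12)
  cp <- fit_two_way_mixed(dat)
  dat2 <- dat; dat2$value <- dat2$value * 3.7
  cp2 <- fit_two_way_mixed(dat2)
  expect_equal(icc_absolute(cp2)$icc, icc_absolute(cp)$icc, tolerance = 1e-5)
  i1 <- icc_absolute(cp, data = dat, nboot = 20, seed = 4)
  i2 <- icc_absolute(cp, data = dat, nboot = 20, seed = 4)
  expect_identical(i1$ci, i2$ci)
  expect_true(i1$ci[1] < i1$icc && i1$icc < i1$ci[2])
})

test_that("log-scale Bland-Altman matches hand-computed oracles", {
  x <- exp(c(1, 1.5, 0.8)); y <- x
  ba <- bland_altman_log(x, y)
  expect_equal(ba$pct_diff, 0)
  expect_equal(ba$loa, c(0, 0))
  ba2 <- bland_altman_log(1.1 * y, y)
  expect_equal(ba2$pct_diff, 10, tolerance = 1e-9)
  expect_equal(ba2$loa, c(10, 10), tolerance = 1e-7)
  # fixed inputs constructed to have sample mean log(1.1) and sample sd 0.2
  z <- as.numeric(scale(1:5))
  d <- log(1.1) + 0.2 * z
  ba3 <- bland_altman_log(exp(d), rep(1, 5))
  expect_equal(ba3$loa, (exp(log(1.1) + c(-1, 1) * 1.96 * 0.2) - 1) * 100,
               tolerance = 1e-9)
  expect_error(bland_altman_log(c(1, -1), c(1, 1)),
               class = "dietvalid_input_error")
  expect_error(bland_altman_log(1, 1), class = "dietvalid_input_error")
})

test_that("Bland-Altman is antisymmetric in the two methods", {
  set.seed(31)
  x <- rlnorm(200, 4, 0.3); y <- rlnorm(200, 4.1, 0.25)
  ab <- bland_altman_log(x, y)
  ba <- bland_altman_log(y, x)
  flip <- function(p) (1 / (1 + p / 100) - 1) * 100
  expect_equal(ba$pct_diff, flip(ab$pct_diff), tolerance = 1e-9)
  expect_equal(sort(ba$loa), sort(flip(ab$loa)), tolerance = 1e-9)
})

test_that("agreement_analysis pairs occasion-level records of two instruments", {
  cfg <- clean_config(n = 50, seed = 41)
  ds <- generate_validation_study(cfg, raw_panels = FALSE)
  row <- agreement_analysis(ds, "protein", nboot = 10, seed = 2)
  expect_equal(row$n_pairs, 150)
  expect_true(row$icc > -1 && row$icc < 1)
  expect_true(row$loa_lo <= row$pct_diff && row$pct_diff <= row$loa_hi)
  # z-standardized comparison across incommensurable units still yields an ICC
  ds$plasma_like <- NA_real_
  bio <- ds$instrument == "biomarker"
  ds$plasma_like[bio] <- ds$protein[bio] / 50
  ds$plasma_like[!bio] <- ds$protein[!bio]
  std <- agreement_analysis(ds, "plasma_like",
                            methods = c("biomarker", "tool_A"),
                            standardize = TRUE)
  expect_true(is.finite(std$icc))
  expect_true(is.na(std$pct_diff))
})
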