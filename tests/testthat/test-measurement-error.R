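make_params <- function(beta1 = 1, sigma2_T = 1, sigma2_r = 0, sigma2_eps = 1,
                        mu_T = 4, sigma2_u = 0.05) {
  mem_params(mu_T, sigma2_T, sigma2_u,
             data.frame(tool = "A", beta0 = 0, beta1 = beta1,
                        sigma2_r = sigma2_r, sigma2_eps = sigma2_eps,
                        stringsAsFactors = FALSE))
}

test_that("attenuation and correlation follow their closed forms", {
  expect_equal(attenuation_factor(make_params()), 0.5)
  expect_equal(attenuation_factor(make_params(), k = Inf), 1.0)
  p <- make_params(beta1 = 0.6, sigma2_T = 0.25, sigma2_r = 0.05,
                   sigma2_eps = 0.20)
  expect_equal(attenuation_factor(p),
               0.6 * 0.25 / (0.36 * 0.25 + 0.05 + 0.20))
  expect_equal(correlation_with_truth(make_params(sigma2_eps = 0)), 1.0)
  expect_equal(correlation_with_truth(make_params()), 1 / sqrt(2))
  expect_equal(correlation_with_truth(p),
               0.6 * 0.5 / sqrt(0.36 * 0.25 + 0.05 + 0.20))
  expect_error(correlation_with_truth(make_params(sigma2_T = 0)),
               class = "dietvalid_input_error")
  expect_error(attenuation_factor(p, k = 0), class = "dietvalid_input_error")
})

test_that("attenuation increases with repeat administrations to its limit", {
  p <- make_params(beta1 = 0.8, sigma2_T = 0.04, sigma2_r = 0.01,
                   sigma2_eps = 0.05)
  ks <- c(1, 2, 4, 7)
  lam <- vapply(ks, function(k) attenuation_factor(p, k = k), numeric(1))
  expect_true(all(diff(lam) > 0))
  limit <- 0.8 * 0.04 / (0.64 * 0.04 + 0.01)
  expect_lt(abs(attenuation_factor(p, k = Inf) - limit), 1e-12)
  # classical reliability ratio when beta1 = 1 and no person bias
  q <- make_params(beta1 = 1, sigma2_T = 0.3, sigma2_r = 0, sigma2_eps = 0.2)
  expect_equal(attenuation_factor(q), 0.3 / 0.5)
  # identity rho = lambda * sd(Q) / sd(T)
  varQ <- 0.64 * 0.04 + 0.01 + 0.05
  expect_equal(correlation_with_truth(p),
               attenuation_factor(p) * sqrt(varQ) / sqrt(0.04))
})

test_that("the simulated-from solver reproduces the requested validity profile", {
  for (lam in c(0.15, 0.30, 0.43)) for (rho in c(0.24, 0.43)) {
    pr <- tool_params_from_validity(lam, rho, 10, mu_T = 4, sigma2_T = 0.04)
    p <- mem_params(4, 0.04, 0.05,
                    data.frame(tool = "A", beta0 = pr$beta0, beta1 = pr$beta1,
                               sigma2_r = pr$sigma2_r,
                               sigma2_eps = pr$sigma2_eps,
                               stringsAsFactors = FALSE))
    expect_equal(attenuation_factor(p), lam, tolerance = 1e-12)
    expect_equal(correlation_with_truth(p), rho, tolerance = 1e-12)
  }
})

test_that("the analytic likelihood gradient matches finite differences", {
  cfg <- clean_config(n = 30, seed = 9)
  ds <- generate_validation_study(cfg, raw_panels = FALSE)
  Y <- dietvalid:::mem_data_matrix(ds, "protein")$Y
  set.seed(1)
  Y[sample(length(Y), 25)] <- NA
  eta <- dietvalid:::mem_eta_from_params(dietvalid:::mem_moments(Y, 3)) + 0.04
  f <- dietvalid:::fit_structured_mvn(Y, dietvalid:::mem_builder(3), eta,
                                      maxit = 1)
  g_num <- dietvalid:::numeric_gradient(f$nll_fn, eta)
  expect_lt(max(abs(f$gr_fn(eta) - g_num)) / max(abs(g_num)), 1e-6)
})

test_that("simulation truth is recovered on balanced data", {
  cfg <- explicit_protein_config(n = 5000, seed = 13)
  ds <- generate_validation_study(cfg, raw_panels = FALSE)
  fit <- fit_mem(ds, "protein")
  expect_equal(fit$convergence, 0)
  p <- fit$params
  se3 <- 3 / sqrt(5000)    # loose Monte-Carlo scale for variance parameters
  expect_lt(abs(p$sigma2_T - 0.04), se3 * 0.1)
  expect_lt(abs(p$tools$beta1[1] - 1), se3)
  expect_lt(abs(p$tools$sigma2_r[1] - 0.02), se3 * 0.1)
  expect_lt(abs(p$tools$sigma2_eps[1] - 0.05), se3 * 0.1)
  expect_lt(abs(p$sigma_rAB - 0.5 * 0.02), se3 * 0.1)
})

test_that("a near-perfect instrument yields attenuation near one", {
  cfg <- explicit_protein_config(n = 2000, seed = 17, sigma2_r = 0,
                                 sigma2_eps = 1e-6)
  ds <- generate_validation_study(cfg, raw_panels = FALSE)
  fit <- fit_mem(ds, "protein")
  expect_lt(abs(attenuation_factor(fit, "A") - 1), 0.01)
})

test_that("fitting works with a single tool and flags identifiability problems", {
  cfg <- clean_config(n = 60, seed = 19)
  ds <- generate_validation_study(cfg, raw_panels = FALSE)
  one <- ds[ds$instrument != "tool_B", ]
  fit <- fit_mem(one, "protein")
  expect_equal(fit$tools, "A")
  expect_true(is.finite(attenuation_factor(fit, "A")))
  expect_error(fit_mem(ds[ds$instrument == "biomarker", ], "protein"),
               class = "dietvalid_input_error")
  bad <- ds; bad$protein[3] <- -1
  expect_error(fit_mem(bad, "protein"), class = "dietvalid_input_error")
})

test_that("mean percentage difference back-transforms mean log ratios", {
  cfg <- clean_config(n = 15, seed = 23)
  ds <- generate_validation_study(cfg, raw_panels = FALSE)
  # tool identical to reference
  ds2 <- ds
  for (j in 1:3) {
    src <- ds2$instrument == "biomarker" & ds2$occasion == j
    dst <- ds2$instrument == "tool_A" & ds2$occasion == j
    ds2$protein[dst] <- ds2$protein[src]
  }
  expect_equal(mean_pct_difference(ds2, "A", "protein")$pct_diff, 0)
  # constant multiplicative bias
  ds3 <- ds2
  ds3$protein[ds3$instrument == "tool_A"] <-
    1.1 * ds3$protein[ds3$instrument == "tool_A"]
  expect_equal(mean_pct_difference(ds3, "A", "protein")$pct_diff, 10,
               tolerance = 1e-9)
  ds4 <- ds2
  ds4$protein[ds4$instrument == "tool_A"] <-
    0.5 * ds4$protein[ds4$instrument == "tool_A"]
  expect_equal(mean_pct_difference(ds4, "A", "protein")$pct_diff, -50,
               tolerance = 1e-9)
  ci <- mean_pct_difference(ds3, "A", "protein")$ci
  expect_equal(ci, c(10, 10), tolerance = 1e-9)  # zero dispersion in d
})

test_that("bootstrap confidence intervals are seed-reproducible", {
  cfg <- clean_config(n = 40, seed = 29)
  ds <- generate_validation_study(cfg, raw_panels = FALSE)
  fit <- fit_mem(ds, "protein")
  b1 <- derived_ci(fit, "attenuation", "A", method = "bootstrap",
                   dataset = ds, nboot = 25, seed = 11)
  b2 <- derived_ci(fit, "attenuation", "A", method = "bootstrap",
                   dataset = ds, nboot = 25, seed = 11)
  expect_identical(b1$ci, b2$ci)
  expect_true(b1$ci[1] <= b1$estimate && b1$estimate <= b1$ci[2])
  d1 <- derived_ci(fit, "correlation", "A")
  expect_true(d1$ci[1] <= d1$estimate && d1$estimate <= d1$ci[2])
})

test_that("missingness leaves estimates nearly unbiased (MAR robustness)", {
  cfg <- explicit_protein_config(n = 4000, seed = 37)
  ds <- generate_validation_study(cfg, raw_panels = FALSE)
  full <- attenuation_factor(fit_mem(ds, "protein"), "A")
  thinned <- apply_mar_missingness(ds, c(tool_A = 0.2, tool_B = 0.2,
                                         biomarker = 0.2), seed = 5)
  thin <- attenuation_factor(fit_mem(thinned, "protein"), "A")
  expect_lt(abs(full - thin), 0.02)
})
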