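# Fixture builders shared across the suite.  Everything is generated in code;
# no data files.

# small study with no missingness and clean raw signals (complete PABA, no
# missed voids, stable weight, full wear) so tests can plant violations
clean_config <- function(n = 10L, seed = 1L, n_occasions = 3L) {
  cfg <- simulation_config(n_participants = n, n_occasions = n_occasions,
                           missingness = c(tool_A = 0, tool_B = 0, biomarker = 0),
                           seed = seed)
  cfg$demographics$weight_drift_sd <- 0
  cfg$raw$paba_mean <- 96
  cfg$raw$paba_sd <- 0
  cfg$raw$missed_void_prob <- 0
  cfg$raw$wear_mean <- 24
  cfg$raw$wear_sd <- 0
  cfg
}

# noise-free, bias-free study: every instrument reports exp(T) exactly
zero_noise_config <- function(n = 40L, seed = 1L) {
  cfg <- clean_config(n, seed)
  cfg$nutrients$sigma2_u <- 0
  cfg$tools$beta0 <- 0
  cfg$tools$beta1 <- 1
  cfg$tools$sigma2_r <- 0
  cfg$tools$sigma2_eps <- 0
  cfg$raw$calorimetry_noise_sd <- 0
  cfg
}

# protein-only truth table with explicit tool parameters (bypasses the
# validity-profile solver): beta1, sigma2_r, sigma2_eps set directly
explicit_protein_config <- function(n, seed, beta1 = 1, sigma2_T = 0.04,
                                    sigma2_r = 0.02, sigma2_eps = 0.05,
                                    sigma2_u = 0.05, missing = 0) {
  cfg <- simulation_config(
    n_participants = n, seed = seed,
    truth = default_nutrient_truth()[1, , drop = FALSE],
    missingness = c(tool_A = missing, tool_B = missing, biomarker = missing))
  cfg$nutrients$sigma2_T <- sigma2_T
  cfg$nutrients$sigma2_u <- sigma2_u
  cfg$tools$beta1 <- beta1
  cfg$tools$beta0 <- 0
  cfg$tools$sigma2_r <- sigma2_r
  cfg$tools$sigma2_eps <- sigma2_eps
  cfg
}

# flatten mem_params for comparisons
params_vector <- function(p) {
  c(mu_T = p$mu_T, sigma2_T = p$sigma2_T, sigma2_u = p$sigma2_u,
    beta0 = p$tools$beta0, beta1 = p$tools$beta1,
    sigma2_r = p$tools$sigma2_r, sigma2_eps = p$tools$sigma2_eps,
    sigma_rAB = p$sigma_rAB)
}

# long-format two-way data with known components
simulate_two_way <- function(n, J = 3, sigma2_subject = 1,
                             sigma2_int = c(0, 0), sigma2_e = c(1, 1),
                             shift = 0, seed = 1) {
  set.seed(seed)
  b <- rnorm(n, 0, sqrt(sigma2_subject))
  do.call(rbind, lapply(1:2, function(m) {
    ci <- rnorm(n, 0, sqrt(sigma2_int[m]))
    do.call(rbind, lapply(seq_len(J), function(j)
      data.frame(subject = seq_len(n), method = paste0("m", m), occasion = j,
                 value = (m - 1) * shift + b + ci +
                   rnorm(n, 0, sqrt(sigma2_e[m])))))
  }))
}
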