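# Latent-variable measurement-error model for validation of self-report
# dietary instruments against an unbiased reference.
#
# On the natural-log scale, for participant i, occasion j:
#   reference (biomarker / TEE):  M_ij = T_i + u_ij
#   tool m in {A, B}:             Q_ijm = beta0_m + beta1_m T_i + r_im + eps_ijm
# with T_i ~ N(mu_T, sigma2_T), u within-person reference error, r_im
# person-specific bias ((r_A, r_B) correlated across tools), eps within-person
# error.  The reference is anchored as unbiased for T (intercept 0, slope 1),
# which identifies the scale of T.  Fitting is by maximum likelihood on each
# participant's observed sub-vector (missing at random).

# ---- parameter containers ----------------------------------------------

#' Measurement-error model parameters
#'
#' @param mu_T,sigma2_T mean / between-person variance of true log intake.
#' @param sigma2_u within-person variance of the reference on the log scale.
#' @param tools data.frame with one row per tool: `tool`, `beta0` (constant
#'   bias), `beta1` (intake-related bias slope), `sigma2_r` (person-specific
#'   bias variance), `sigma2_eps` (within-person error variance).
#' @param sigma_rAB covariance of the two tools' person-specific biases.
#' @return An object of class `mem_params`.
#' @export
mem_params <- function(mu_T, sigma2_T, sigma2_u, tools, sigma_rAB = 0) {
  if (sigma2_T < 0 || sigma2_u < 0 || any(tools$sigma2_r < 0) ||
      any(tools$sigma2_eps < 0))
    dv_config_error("variances must be non-negative")
  if (nrow(tools) == 2L &&
      abs(sigma_rAB) > sqrt(prod(tools$sigma2_r)) + 1e-12)
    dv_config_error("person-bias covariance exceeds its admissible bound")
  structure(list(mu_T = mu_T, sigma2_T = sigma2_T, sigma2_u = sigma2_u,
                 tools = tools, sigma_rAB = sigma_rAB),
            class = "mem_params")
}

tool_row <- function(params, tool) {
  i <- match(tool, params$tools$tool)
  if (is.na(i)) dv_input_error(paste0("unknown tool: ", tool))
  params$tools[i, ]
}

# ---- eta <-> params -----------------------------------------------------

# eta layout (two tools):  mu_T, beta0_A, beta1_A, beta0_B, beta1_B,
#                          lT, lu, lrA, leA, lrB, leB, z
# one tool:                mu_T, beta0_A, beta1_A, lT, lu, lrA, leA
mem_eta_names <- function(tools) {
  if (length(tools) == 2L)
    c("mu_T", "beta0_A", "beta1_A", "beta0_B", "beta1_B",
      "lT", "lu", "lrA", "leA", "lrB", "leB", "z")
  else
    c("mu_T", paste0(c("beta0_", "beta1_"), tools), "lT", "lu", "lr", "le")
}

mem_params_from_eta <- function(eta, tools = c("A", "B")) {
  two <- length(tools) == 2L
  if (two) {
    srA <- var_from_log(eta[8]); srB <- var_from_log(eta[10])
    tl <- data.frame(tool = tools,
                     beta0 = c(eta[2], eta[4]), beta1 = c(eta[3], eta[5]),
                     sigma2_r = c(srA, srB),
                     sigma2_eps = c(var_from_log(eta[9]), var_from_log(eta[11])),
                     stringsAsFactors = FALSE)
    mem_params(eta[1], var_from_log(eta[6]), var_from_log(eta[7]), tl,
               tanh(eta[12]) * sqrt(srA * srB))
  } else {
    tl <- data.frame(tool = tools, beta0 = eta[2], beta1 = eta[3],
                     sigma2_r = var_from_log(eta[6]),
                     sigma2_eps = var_from_log(eta[7]),
                     stringsAsFactors = FALSE)
    mem_params(eta[1], var_from_log(eta[4]), var_from_log(eta[5]), tl, 0)
  }
}

mem_eta_from_params <- function(params) {
  tl <- params$tools
  if (nrow(tl) == 2L) {
    rho <- params$sigma_rAB / sqrt(prod(pmax(tl$sigma2_r, .dv_var_floor)))
    rho <- max(min(rho, 0.99), -0.99)
    stats::setNames(
      c(params$mu_T, tl$beta0[1], tl$beta1[1], tl$beta0[2], tl$beta1[2],
        log_from_var(params$sigma2_T), log_from_var(params$sigma2_u),
        log_from_var(tl$sigma2_r[1]), log_from_var(tl$sigma2_eps[1]),
        log_from_var(tl$sigma2_r[2]), log_from_var(tl$sigma2_eps[2]),
        atanh(rho)),
      mem_eta_names(tl$tool))
  } else {
    stats::setNames(
      c(params$mu_T, tl$beta0[1], tl$beta1[1],
        log_from_var(params$sigma2_T), log_from_var(params$sigma2_u),
        log_from_var(tl$sigma2_r[1]), log_from_var(tl$sigma2_eps[1])),
      mem_eta_names(tl$tool))
  }
}

# ---- model moments and builder -----------------------------------------

# Implied mean vector and covariance of the stacked (reference, tool A
# [, tool B]) x occasion log-value vector.
mem_moments_from_params <- function(params, J) {
  tl <- params$tools
  v <- c(1, tl$beta1)
  M <- length(v)
  R <- diag(c(0, tl$sigma2_r), M)
  if (M == 3L) R[2, 3] <- R[3, 2] <- params$sigma_rAB
  Wd <- diag(c(params$sigma2_u, tl$sigma2_eps), M)
  ones <- matrix(1, J, J)
  Sigma <- kronecker(params$sigma2_T * tcrossprod(v) + R, ones) +
    kronecker(Wd, diag(J))
  mu <- rep(c(params$mu_T, tl$beta0 + tl$beta1 * params$mu_T), each = J)
  list(mu = mu, Sigma = Sigma)
}

mem_builder <- function(J, tools = c("A", "B")) {
  two <- length(tools) == 2L
  M <- if (two) 3L else 2L
  ones <- matrix(1, J, J)
  IJ <- diag(J)
  basis <- function(i, j = i) {
    m <- matrix(0, M, M); m[i, j] <- 1; m
  }
  symb <- function(i, j) basis(i, j) + basis(j, i)
  BJ <- function(m) kronecker(m, ones)
  BI <- function(m) kronecker(m, IJ)
  per_inst <- function(x) rep(x, each = J)

  function(eta) {
    muT <- eta[1]; aA <- eta[2]; bA <- eta[3]
    if (two) { aB <- eta[4]; bB <- eta[5]; off <- 5L } else off <- 3L
    eT <- exp(eta[off + 1L]); eu <- exp(eta[off + 2L])
    erA <- exp(eta[off + 3L]); eeA <- exp(eta[off + 4L])
    sT <- .dv_var_floor + eT; su <- .dv_var_floor + eu
    srA <- .dv_var_floor + erA; seA <- .dv_var_floor + eeA
    if (two) {
      erB <- exp(eta[off + 5L]); eeB <- exp(eta[off + 6L])
      srB <- .dv_var_floor + erB; seB <- .dv_var_floor + eeB
      z <- eta[off + 7L]; rho <- tanh(z)
      srAB <- rho * sqrt(srA * srB)
    }
    v <- if (two) c(1, bA, bB) else c(1, bA)
    R <- diag(c(0, srA, if (two) srB), M)
    if (two) R[2, 3] <- R[3, 2] <- srAB
    Wd <- diag(c(su, seA, if (two) seB), M)
    Sigma <- BJ(sT * tcrossprod(v) + R) + BI(Wd)
    mu <- per_inst(c(muT, aA + bA * muT, if (two) aB + bB * muT))

    p <- length(eta)
    dmu <- matrix(0, M * J, p)
    dSigma <- vector("list", p)
    dmu[, 1] <- per_inst(v)
    dmu[, 2] <- per_inst(c(0, 1, if (two) 0))
    dmu[, 3] <- per_inst(c(0, muT, if (two) 0))
    e2 <- c(0, 1, if (two) 0)
    dSigma[[3]] <- BJ(sT * (outer(e2, v) + outer(v, e2)))
    if (two) {
      dmu[, 4] <- per_inst(c(0, 0, 1))
      dmu[, 5] <- per_inst(c(0, 0, muT))
      e3 <- c(0, 0, 1)
      dSigma[[5]] <- BJ(sT * (outer(e3, v) + outer(v, e3)))
    }
    dSigma[[off + 1L]] <- BJ(eT * tcrossprod(v))
    dSigma[[off + 2L]] <- BI(eu * basis(1))
    if (two) {
      S23 <- BJ(symb(2, 3))
      dSigma[[off + 3L]] <- BJ(erA * basis(2)) + (srAB * 0.5 * erA / srA) * S23
      dSigma[[off + 4L]] <- BI(eeA * basis(2))
      dSigma[[off + 5L]] <- BJ(erB * basis(3)) + (srAB * 0.5 * erB / srB) * S23
      dSigma[[off + 6L]] <- BI(eeB * basis(3))
      dSigma[[off + 7L]] <- ((1 - rho^2) * sqrt(srA * srB)) * S23
    } else {
      dSigma[[off + 3L]] <- BJ(erA * basis(2))
      dSigma[[off + 4L]] <- BI(eeA * basis(2))
    }
    list(mu = mu, Sigma = Sigma, dmu = dmu, dSigma = dSigma)
  }
}

# ---- data extraction ----------------------------------------------------

# Stack each participant's log values into a row of a (reference, tool A
# [, tool B]) x occasion matrix, honouring exclusion flags when present.
mem_data_matrix <- function(dataset, nutrient, density = FALSE,
                            tools = c("A", "B")) {
  if (!nutrient %in% names(dataset))
    dv_input_error(paste0("nutrient column not found: ", nutrient))
  ds <- dataset
  if (is.null(ds$use_urinary)) ds$use_urinary <- TRUE
  if (is.null(ds$use_tee)) ds$use_tee <- TRUE
  if (is.null(ds$use_recall)) ds$use_recall <- TRUE

  value_of <- function(rows) {
    val <- ds[[nutrient]][rows]
    if (density) val <- val / ds$energy[rows]
    val
  }
  usable_ref <- if (nutrient == "energy") ds$use_tee
  else if (density) ds$use_urinary & ds$use_tee
  else ds$use_urinary

  ids <- sort(unique(ds$participant))
  J <- max(ds$occasion)
  insts <- c("biomarker", paste0("tool_", tools))
  Y <- matrix(NA_real_, length(ids), length(insts) * J)
  bad <- character()
  for (ii in seq_along(insts)) {
    inst <- insts[ii]
    rows <- which(ds$instrument == inst &
                    (if (inst == "biomarker") usable_ref else ds$use_recall))
    val <- value_of(rows)
    nonpos <- !is.na(val) & val <= 0
    if (any(nonpos))
      bad <- c(bad, paste0(inst, " participant ",
                           ds$participant[rows][nonpos], " occasion ",
                           ds$occasion[rows][nonpos]))
    keep <- !is.na(val) & val > 0
    i <- match(ds$participant[rows][keep], ids)
    j <- ds$occasion[rows][keep]
    Y[cbind(i, (ii - 1L) * J + j)] <- log(val[keep])
  }
  if (length(bad))
    dv_input_error(paste0("non-positive values cannot be log-transformed: ",
                          paste(utils::head(bad, 5), collapse = "; ")))
  list(Y = Y, ids = ids, J = J, tools = tools)
}

# Model-implied method-of-moments estimator: per-instrument means, scatter
# about those means, entries averaged over the exchangeable occasion orbits.
# On complete balanced data this is exactly the maximum-likelihood estimate
# (the invariant covariance pattern forms a quadratic subspace).
mem_moments <- function(Y, J, tools = c("A", "B")) {
  two <- length(tools) == 2L
  M <- if (two) 3L else 2L
  blocks <- lapply(seq_len(M), function(m) (m - 1L) * J + seq_len(J))
  inst_mean <- vapply(blocks, function(b) mean(Y[, b], na.rm = TRUE), numeric(1))
  mu_fit <- rep(inst_mean, each = J)
  Yc <- sweep(Y, 2, mu_fit, "-")
  n <- nrow(Y)
  if (!anyNA(Y)) {
    S <- crossprod(Yc) / n
  } else {
    cnt <- crossprod(!is.na(Yc))
    Yc0 <- Yc; Yc0[is.na(Yc0)] <- 0
    S <- crossprod(Yc0) / pmax(cnt, 1L)
  }
  avg_off <- function(b1, b2 = b1) {
    Sb <- S[b1, b2, drop = FALSE]
    if (identical(b1, b2)) {
      if (J == 1L) return(0)
      mean(Sb[row(Sb) != col(Sb)])
    } else mean(Sb)
  }
  avg_diag <- function(b) mean(diag(S[b, b, drop = FALSE]))

  sT <- max(avg_off(blocks[[1]]), 1e-8)
  su <- avg_diag(blocks[[1]]) - sT
  b1 <- vapply(seq_len(M - 1L), function(m)
    avg_off(blocks[[1]], blocks[[m + 1L]]) / sT, numeric(1))
  sr <- vapply(seq_len(M - 1L), function(m)
    avg_off(blocks[[m + 1L]]) - b1[m]^2 * sT, numeric(1))
  se <- vapply(seq_len(M - 1L), function(m)
    avg_diag(blocks[[m + 1L]]) - b1[m]^2 * sT - sr[m], numeric(1))
  srAB <- if (two) avg_off(blocks[[2]], blocks[[3]]) - b1[1] * b1[2] * sT else 0
  clamp <- function(x) pmax(x, .dv_var_floor)
  sr <- clamp(sr); se <- clamp(se); su <- clamp(su)
  if (two) {
    bound <- sqrt(prod(sr))
    srAB <- max(min(srAB, 0.99 * bound), -0.99 * bound)
  }
  tl <- data.frame(tool = tools, beta0 = inst_mean[-1] - b1 * inst_mean[1],
                   beta1 = b1, sigma2_r = sr, sigma2_eps = se,
                   stringsAsFactors = FALSE)
  mem_params(inst_mean[1], sT, su, tl, srAB)
}

# ---- fitting ------------------------------------------------------------

#' Fit the measurement-error model by maximum likelihood
#'
#' Maximizes, over the structured multivariate normal implied by the model,
#' the sum across participants of the log density of each participant's
#' observed log-value sub-vector (up to `J` reference plus `J` per-tool
#' values), marginalizing missing entries (missing at random).  The
#' reference instrument is the biomarker value of `nutrient` (or TEE when
#' `nutrient = "energy"`); with `density = TRUE` all values are divided by
#' the same instrument's energy value first (g/MJ).  Starting values come
#' from the method-of-moments estimator; variances are optimized on the log
#' scale and the cross-tool bias correlation through `tanh`, keeping the
#' covariance admissible.
#'
#' @param dataset a study dataset (optionally carrying exclusion flags from
#'   [apply_exclusions()]).
#' @param nutrient nutrient column to analyze.
#' @param density analyze the nutrient density (nutrient per MJ energy)?
#' @param tools which self-report tools to include (default both).
#' @return An object of class `mem_fit`: `params` ([mem_params()]), `eta`,
#'   `vcov_eta` (inverse observed information), `logLik`, `convergence`
#'   (0 = converged), `n` (participants).
#' @export
fit_mem <- function(dataset, nutrient, density = FALSE,
                    tools = c("A", "B")) {
  have <- intersect(paste0("tool_", tools), unique(dataset$instrument))
  tools <- sub("tool_", "", have)
  if (length(tools) < 1L || !"biomarker" %in% dataset$instrument)
    dv_input_error("need the reference and at least one tool instrument")
  dm <- mem_data_matrix(dataset, nutrient, density, tools)
  if (max(dm$J) < 2L)
    warning("fewer than 2 occasions; within- and between-person variances are weakly identified")
  start <- mem_moments(dm$Y, dm$J, tools)
  eta0 <- mem_eta_from_params(start)
  fit <- fit_structured_mvn(dm$Y, mem_builder(dm$J, tools), eta0)
  vcov_eta <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  params <- mem_params_from_eta(fit$eta, tools)
  structure(list(params = params, eta = stats::setNames(fit$eta, names(eta0)),
                 vcov_eta = vcov_eta, logLik = fit$logLik,
                 convergence = fit$convergence, n = fit$n, J = dm$J,
                 tools = tools, nutrient = nutrient, density = density),
            class = "mem_fit")
}

#' @export
print.mem_fit <- function(x, ...) {
  cat("Measurement-error model fit:",
      if (x$density) paste0(x$nutrient, " density") else x$nutrient, "\n")
  cat("  participants:", x$n, " occasions:", x$J,
      " logLik:", format(x$logLik, digits = 6),
      " converged:", x$convergence == 0, "\n")
  for (tool in x$params$tools$tool)
    cat(sprintf("  tool %s: lambda = %.3f, rho = %.3f\n", tool,
                attenuation_factor(x, tool), correlation_with_truth(x, tool)))
  invisible(x)
}

# accept a fit or bare parameters
as_mem_params <- function(x) {
  if (inherits(x, "mem_fit")) x$params
  else if (inherits(x, "mem_params")) x
  else dv_input_error("expected a mem_fit or mem_params object")
}

#' Attenuation factor of a self-report tool
#'
#' The multiplier by which log relative risks estimated with the error-prone
#' tool are attenuated; equals the regression-calibration slope of true on
#' observed intake.  For the mean of `k` repeat administrations:
#' `lambda = beta1 sigma2_T / (beta1^2 sigma2_T + sigma2_r + sigma2_eps / k)`.
#'
#' @param params a [mem_params()] or `mem_fit` object.
#' @param tool tool label.
#' @param k number of repeat administrations averaged (default 1).
#' @export
attenuation_factor <- function(params, tool = "A", k = 1) {
  if (k < 1) dv_input_error("k must be >= 1")
  p <- as_mem_params(params)
  tl <- tool_row(p, tool)
  den <- tl$beta1^2 * p$sigma2_T + tl$sigma2_r + tl$sigma2_eps / k
  if (den == 0) dv_input_error("attenuation factor undefined: zero variance")
  tl$beta1 * p$sigma2_T / den
}

#' Correlation between a self-report tool and true usual intake
#'
#' `rho = beta1 sqrt(sigma2_T) / sqrt(beta1^2 sigma2_T + sigma2_r +
#' sigma2_eps / k)` for the mean of `k` administrations.
#'
#' @inheritParams attenuation_factor
#' @export
correlation_with_truth <- function(params, tool = "A", k = 1) {
  if (k < 1) dv_input_error("k must be >= 1")
  p <- as_mem_params(params)
  if (p$sigma2_T <= 0) dv_input_error("correlation undefined: sigma2_T is zero")
  tl <- tool_row(p, tool)
  den <- tl$beta1^2 * p$sigma2_T + tl$sigma2_r + tl$sigma2_eps / k
  tl$beta1 * sqrt(p$sigma2_T) / sqrt(den)
}

#' Mean percentage difference between a tool and the reference
#'
#' For each participant with at least one tool and one reference
#' observation, the difference of within-person means of log values is
#' formed; the average difference is back-transformed:
#' `(exp(mean d) - 1) * 100`, with a t-based confidence interval
#' back-transformed the same way.
#'
#' @inheritParams fit_mem
#' @param tool tool label.
#' @param level confidence level (default 0.95).
#' @return list(pct_diff, ci, n, mean_d, se_d).
#' @export
mean_pct_difference <- function(dataset, tool = "A", nutrient = "protein",
                                density = FALSE, level = 0.95) {
  dm <- mem_data_matrix(dataset, nutrient, density,
                        tools = sub("tool_", "",
                                    intersect(paste0("tool_", c("A", "B")),
                                              unique(dataset$instrument))))
  J <- dm$J
  ref <- dm$Y[, seq_len(J), drop = FALSE]
  ti <- match(tool, dm$tools)
  if (is.na(ti)) dv_input_error(paste0("tool not present in dataset: ", tool))
  tl <- dm$Y[, ti * J + seq_len(J), drop = FALSE]
  d <- rowMeans(tl, na.rm = TRUE) - rowMeans(ref, na.rm = TRUE)
  d <- d[is.finite(d)]
  n <- length(d)
  if (n == 0L) dv_input_error("no participants with both tool and reference observations")
  m <- mean(d)
  se <- stats::sd(d) / sqrt(n)
  if (n < 2L || !is.finite(se)) se <- 0
  tq <- if (n > 1L) stats::qt(1 - (1 - level) / 2, n - 1L) else 0
  list(pct_diff = (exp(m) - 1) * 100,
       ci = (exp(m + c(-1, 1) * tq * se) - 1) * 100,
       n = n, mean_d = m, se_d = se)
}

#' Confidence interval for an attenuation factor or correlation
#'
#' Delta method on the unconstrained parameterization (default), or a
#' participant-resampling percentile bootstrap.  If the observed information
#' is singular the delta method falls back to the bootstrap with a warning
#' (when the dataset is available) or returns a degenerate interval.
#'
#' @param fit a `mem_fit` object.
#' @param functional `"attenuation"` or `"correlation"`.
#' @param tool tool label.
#' @param k administrations averaged.
#' @param method `"delta"` or `"bootstrap"`.
#' @param dataset dataset to resample (bootstrap only).
#' @param nboot bootstrap replicates (default 1000).
#' @param seed seed for the bootstrap resampling.
#' @param level confidence level.
#' @return list(estimate, ci, method).
#' @export
derived_ci <- function(fit, functional = c("attenuation", "correlation"),
                       tool = "A", k = 1, method = c("delta", "bootstrap"),
                       dataset = NULL, nboot = 1000L, seed = 1L,
                       level = 0.95) {
  functional <- match.arg(functional)
  method <- match.arg(method)
  fun <- switch(functional, attenuation = attenuation_factor,
                correlation = correlation_with_truth)
  est <- fun(fit, tool, k)
  h <- function(eta) fun(mem_params_from_eta(eta, fit$tools), tool, k)

  if (method == "delta") {
    if (is.null(fit$vcov_eta)) {
      if (!is.null(dataset) && nboot >= 1L) {
        warning("singular information; falling back to bootstrap CI")
        return(derived_ci(fit, functional, tool, k, "bootstrap", dataset,
                          nboot, seed, level))
      }
      return(list(estimate = est, ci = c(est, est), method = "delta"))
    }
    g <- numeric_gradient(h, fit$eta)
    v <- drop(t(g) %*% fit$vcov_eta %*% g)
    if (!is.finite(v) || v < 0) v <- 0
    zq <- stats::qnorm(1 - (1 - level) / 2)
    return(list(estimate = est, ci = est + c(-1, 1) * zq * sqrt(v),
                method = "delta"))
  }

  if (is.null(dataset)) dv_input_error("bootstrap CI needs the dataset")
  set.seed(seed)
  ids <- unique(dataset$participant)
  stat <- vapply(seq_len(nboot), function(b) {
    take <- sample(ids, length(ids), replace = TRUE)
    rows <- unlist(lapply(seq_along(take), function(i) {
      which(dataset$participant == take[i])
    }))
    bd <- dataset[rows, , drop = FALSE]
    bd$participant <- rep(seq_along(take),
                          times = vapply(take, function(id)
                            sum(dataset$participant == id), integer(1)))
    out <- tryCatch(fun(fit_mem(bd, fit$nutrient, fit$density, fit$tools),
                        tool, k),
                    error = function(e) NA_real_)
    out
  }, numeric(1))
  qs <- stats::quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  list(estimate = est, ci = qs, method = "bootstrap")
}
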