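# Agreement between two measurement methods: intraclass correlation from a
# two-way mixed-effects model with method-specific variances, and
# Bland-Altman bias / limits of agreement on the log scale.

# Model, for subject i, method m, occasion j:
#   y_imj = mu + tau_m + b_i + c_im + e_imj
# with fixed method effects tau (sum-to-zero), subject effect b, a
# subject-by-method interaction c with method-specific variance, and
# method-specific residual variance.  Fit by maximum likelihood on each
# subject's observed sub-vector, like the measurement-error model.

two_way_builder <- function(J, M, heterogeneous = TRUE) {
  ones <- matrix(1, J, J)
  IJ <- diag(J)
  onesM <- matrix(1, M, M)
  basis <- function(i) { m <- matrix(0, M, M); m[i, i] <- 1; m }
  BJ <- function(m) kronecker(m, ones)
  BI <- function(m) kronecker(m, IJ)
  nint <- if (heterogeneous) M else 1L
  # eta: mu_1..mu_M, ls, li_(1..nint), le_(1..nint)
  function(eta) {
    mus <- eta[seq_len(M)]
    es <- exp(eta[M + 1L])
    ss <- .dv_var_floor + es
    ei <- exp(eta[M + 1L + seq_len(nint)])
    ee <- exp(eta[M + 1L + nint + seq_len(nint)])
    si <- .dv_var_floor + ei
    se <- .dv_var_floor + ee
    int_m <- if (heterogeneous) si else rep(si, M)
    e_m <- if (heterogeneous) se else rep(se, M)
    Sigma <- BJ(ss * onesM + diag(int_m, M)) + BI(diag(e_m, M))
    mu <- rep(mus, each = J)
    p <- length(eta)
    dmu <- matrix(0, M * J, p)
    dSigma <- vector("list", p)
    for (m in seq_len(M)) dmu[(m - 1L) * J + seq_len(J), m] <- 1
    dSigma[[M + 1L]] <- BJ(es * onesM)
    if (heterogeneous) {
      for (m in seq_len(M)) {
        dSigma[[M + 1L + m]] <- BJ(ei[m] * basis(m))
        dSigma[[M + 1L + nint + m]] <- BI(ee[m] * basis(m))
      }
    } else {
      dSigma[[M + 2L]] <- BJ(ei * diag(M))
      dSigma[[M + 3L]] <- BI(ee * diag(M))
    }
    list(mu = mu, Sigma = Sigma, dmu = dmu, dSigma = dSigma)
  }
}

two_way_matrix <- function(data) {
  need <- c("subject", "method", "occasion", "value")
  if (!all(need %in% names(data)))
    dv_input_error("data needs columns subject, method, occasion, value")
  methods <- sort(unique(as.character(data$method)))
  if (length(methods) < 2L) dv_input_error("need at least 2 methods")
  subjects <- sort(unique(data$subject))
  if (length(subjects) < 2L) dv_input_error("need at least 2 subjects")
  occ <- sort(unique(data$occasion))
  J <- length(occ)
  Y <- matrix(NA_real_, length(subjects), length(methods) * J)
  i <- match(data$subject, subjects)
  m <- match(as.character(data$method), methods)
  j <- match(data$occasion, occ)
  Y[cbind(i, (m - 1L) * J + j)] <- data$value
  list(Y = Y, methods = methods, subjects = subjects, J = J)
}

#' Fit a two-way mixed-effects agreement model
#'
#' Maximum-likelihood fit of `value = mu + tau_method + subject +
#' subject:method + error` on occasion-level records, with the method as a
#' fixed effect and, when `heterogeneous = TRUE` (the default), the
#' subject-by-method interaction variance and the residual variance allowed
#' to differ between methods.
#'
#' @param data data.frame with columns `subject`, `method`, `occasion`,
#'   `value` (at most one value per subject x method x occasion).
#' @param heterogeneous allow method-specific interaction and residual
#'   variances?
#' @return An object of class `mixed_components`: `sigma2_subject`,
#'   `sigma2_int` and `sigma2_e` (named per method), `tau` (sum-to-zero
#'   fixed method effects), `mu`, `logLik`, `convergence`, `n_subjects`.
#' @export
fit_two_way_mixed <- function(data, heterogeneous = TRUE) {
  tm <- two_way_matrix(data)
  M <- length(tm$methods)
  J <- tm$J
  # moment starting values
  blocks <- lapply(seq_len(M), function(m) (m - 1L) * J + seq_len(J))
  mus <- vapply(blocks, function(b) mean(tm$Y[, b], na.rm = TRUE), numeric(1))
  Yc <- sweep(tm$Y, 2, rep(mus, each = J), "-")
  cc <- stats::cov(Yc, use = "pairwise.complete.obs")
  cc[!is.finite(cc)] <- 0
  cross <- outer(seq_len(M), seq_len(M), Vectorize(function(a, b)
    if (a == b) NA_real_ else mean(cc[blocks[[a]], blocks[[b]]])))
  ss <- max(mean(cross, na.rm = TRUE), .dv_var_floor)
  si <- vapply(seq_len(M), function(m) {
    Sb <- cc[blocks[[m]], blocks[[m]], drop = FALSE]
    off <- if (J > 1L) mean(Sb[row(Sb) != col(Sb)]) else ss
    max(off - ss, .dv_var_floor)
  }, numeric(1))
  se <- vapply(seq_len(M), function(m) {
    Sb <- cc[blocks[[m]], blocks[[m]], drop = FALSE]
    max(mean(diag(Sb)) - ss - si[m], .dv_var_floor)
  }, numeric(1))
  if (!heterogeneous) { si <- mean(si); se <- mean(se) }
  eta0 <- c(mus, log_from_var(ss), log_from_var(si), log_from_var(se))

  fit <- fit_structured_mvn(tm$Y, two_way_builder(J, M, heterogeneous), eta0)
  nint <- if (heterogeneous) M else 1L
  s2s <- var_from_log(fit$eta[M + 1L])
  s2i <- var_from_log(fit$eta[M + 1L + seq_len(nint)])
  s2e <- var_from_log(fit$eta[M + 1L + nint + seq_len(nint)])
  if (!heterogeneous) { s2i <- rep(s2i, M); s2e <- rep(s2e, M) }
  mu_m <- fit$eta[seq_len(M)]
  structure(list(methods = tm$methods,
                 sigma2_subject = s2s,
                 sigma2_int = stats::setNames(s2i, tm$methods),
                 sigma2_e = stats::setNames(s2e, tm$methods),
                 tau = stats::setNames(mu_m - mean(mu_m), tm$methods),
                 mu = mean(mu_m), logLik = fit$logLik,
                 convergence = fit$convergence,
                 n_subjects = fit$n, J = J,
                 heterogeneous = heterogeneous),
            class = "mixed_components")
}

#' Intraclass correlation for absolute agreement
#'
#' Fixed-rater absolute-agreement ICC with heterogeneous variances combined
#' by arithmetic mean across methods and a penalty for systematic method
#' offsets:
#' `ICC = sigma2_subject / (sigma2_subject + mean(sigma2_int) +
#' mean(sigma2_e) + sum(tau^2)/(M - 1))`.
#' The confidence interval is a subject-resampling percentile bootstrap.
#'
#' @param components a [fit_two_way_mixed()] result.
#' @param data the occasion-level data (needed for the bootstrap CI).
#' @param nboot bootstrap replicates (default 1000; set 0 to skip the CI).
#' @param seed seed for resampling.
#' @param level confidence level.
#' @return list(icc, ci, components).
#' @export
icc_absolute <- function(components, data = NULL, nboot = 1000L, seed = 1L,
                         level = 0.95) {
  icc_of <- function(cp) {
    M <- length(cp$methods)
    den <- cp$sigma2_subject + mean(cp$sigma2_int) + mean(cp$sigma2_e) +
      sum(cp$tau^2) / (M - 1L)
    if (den <= .dv_var_floor * 4)
      dv_input_error("all variance components are zero; ICC undefined")
    cp$sigma2_subject / den
  }
  icc <- icc_of(components)
  ci <- c(NA_real_, NA_real_)
  if (!is.null(data) && nboot > 0L) {
    set.seed(seed)
    subjects <- unique(data$subject)
    stat <- vapply(seq_len(nboot), function(b) {
      take <- sample(subjects, length(subjects), replace = TRUE)
      pieces <- lapply(seq_along(take), function(i) {
        d <- data[data$subject == take[i], , drop = FALSE]
        d$subject <- i
        d
      })
      bd <- do.call(rbind, pieces)
      tryCatch(icc_of(fit_two_way_mixed(bd, components$heterogeneous)),
               error = function(e) NA_real_)
    }, numeric(1))
    ci <- stats::quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE, names = FALSE)
  }
  list(icc = icc, ci = ci, components = components)
}

#' Bland-Altman agreement on the log scale
#'
#' Per-pair differences of log values `d = log(x) - log(y)` give a relative
#' bias `(exp(mean d) - 1) * 100` (the ratio of geometric means as a
#' percentage), limits of agreement
#' `(exp(mean d +/- 1.96 sd(d)) - 1) * 100`, and a back-transformed
#' t-interval for the mean.
#'
#' @param x,y positive paired measurements (method 1, method 2).
#' @param level confidence level for the interval on the mean difference
#'   (the limits of agreement always use 1.96 standard deviations).
#' @return list(pct_diff, ci, loa, n, mean_d, sd_d).
#' @export
bland_altman_log <- function(x, y, level = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) dv_input_error("need at least 2 complete pairs")
  if (any(x <= 0) || any(y <= 0))
    dv_input_error(paste0("non-positive values at pairs: ",
                          paste(utils::head(which(x <= 0 | y <= 0), 5),
                                collapse = ", ")))
  d <- log(x) - log(y)
  m <- mean(d)
  s <- stats::sd(d)
  n <- length(d)
  tq <- stats::qt(1 - (1 - level) / 2, n - 1L)
  list(pct_diff = (exp(m) - 1) * 100,
       ci = (exp(m + c(-1, 1) * tq * s / sqrt(n)) - 1) * 100,
       loa = (exp(m + c(-1, 1) * 1.96 * s) - 1) * 100,
       n = n, mean_d = m, sd_d = s)
}

#' Agreement analysis between two instruments of a study dataset
#'
#' Builds occasion-level paired records for one nutrient (or a plasma
#' analyte) from two instruments, fits the two-way mixed model on the log
#' scale and computes the ICC, the mean percentage difference and the
#' Bland-Altman limits.  When the two series are in different units (for
#' instance a plasma concentration against an estimated intake), set
#' `standardize = TRUE` to z-standardize the log values within method before
#' the ICC fit; absolute agreement across incommensurable units is otherwise
#' undefined.  The percentage difference and limits are only reported for
#' unstandardized (same-unit) comparisons.
#'
#' @param dataset a study dataset.
#' @param nutrient value column to compare.
#' @param methods length-2 instrument labels (e.g. `c("tool_A", "tool_B")`).
#' @param standardize z-standardize log values within method before the ICC?
#' @param nboot,seed,level bootstrap settings for the ICC interval.
#' @return An agreement-result row: data.frame with icc, icc CI, % difference
#'   in means with CI, % limits of agreement, n pairs.
#' @export
agreement_analysis <- function(dataset, nutrient,
                               methods = c("tool_A", "tool_B"),
                               standardize = FALSE,
                               nboot = 0L, seed = 1L, level = 0.95) {
  if (length(methods) != 2L) dv_input_error("methods must have length 2")
  if (is.null(dataset$use_recall)) dataset$use_recall <- TRUE
  rows <- dataset$instrument %in% methods &
    (dataset$instrument == "biomarker" | dataset$use_recall)
  ds <- dataset[rows & !is.na(dataset[[nutrient]]), , drop = FALSE]
  if (any(ds[[nutrient]] <= 0))
    dv_input_error("non-positive values cannot be log-transformed")
  long <- data.frame(subject = ds$participant,
                     method = as.character(ds$instrument),
                     occasion = ds$occasion,
                     value = log(ds[[nutrient]]),
                     stringsAsFactors = FALSE)
  if (standardize)
    for (m in methods) {
      sel <- long$method == m
      long$value[sel] <- as.numeric(scale(long$value[sel]))
    }
  cp <- fit_two_way_mixed(long)
  icc <- icc_absolute(cp, data = if (nboot > 0L) long else NULL,
                      nboot = nboot, seed = seed, level = level)

  # paired occasion-level values for the Bland-Altman summary
  w <- stats::reshape(long, direction = "wide", idvar = c("subject", "occasion"),
                      timevar = "method")
  v1 <- w[[paste0("value.", methods[1])]]
  v2 <- w[[paste0("value.", methods[2])]]
  ok <- !is.na(v1) & !is.na(v2)
  ba <- if (!standardize && sum(ok) >= 2L)
    bland_altman_log(exp(v1[ok]), exp(v2[ok]), level) else NULL
  data.frame(variable = nutrient,
             method_1 = methods[1], method_2 = methods[2],
             n_pairs = sum(ok),
             icc = icc$icc, icc_lo = icc$ci[1], icc_hi = icc$ci[2],
             pct_diff = if (is.null(ba)) NA_real_ else ba$pct_diff,
             pct_diff_lo = if (is.null(ba)) NA_real_ else ba$ci[1],
             pct_diff_hi = if (is.null(ba)) NA_real_ else ba$ci[2],
             loa_lo = if (is.null(ba)) NA_real_ else ba$loa[1],
             loa_hi = if (is.null(ba)) NA_real_ else ba$loa[2],
             stringsAsFactors = FALSE)
}
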