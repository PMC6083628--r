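# Maximum likelihood for structured multivariate normal models with arbitrary
# missingness patterns.
#
# Both latent-variable models in this package (the measurement-error model and
# the two-way mixed-effects agreement model) imply, for each participant, a
# multivariate normal distribution over the stacked instrument-by-occasion
# vector whose mean and covariance are smooth functions of an unconstrained
# parameter vector eta (variances enter as floor + exp(log-variance),
# correlations through tanh).  A model supplies a builder mapping eta to the
# implied moments and their derivatives; participants contribute the marginal
# density of their observed sub-vector only, so missing-at-random entries are
# integrated out rather than imputed.

# builder(eta) must return list(mu, Sigma, dmu, dSigma):
#   mu     numeric(d), Sigma d x d
#   dmu    d x p matrix of mean derivatives
#   dSigma list of length p; each element a d x d matrix or NULL (zero)
fit_structured_mvn <- function(Y, builder, eta0, maxit = 500L, reltol = 1e-12) {
  stopifnot(is.matrix(Y))
  obs <- !is.na(Y)
  keep <- rowSums(obs) > 0L
  Y <- Y[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  if (nrow(Y) == 0L) dv_input_error("no rows with observed data")

  key <- apply(obs, 1L, function(r) paste(which(r), collapse = ","))
  # per-pattern sufficient statistics: the likelihood and its gradient only
  # need the count, column sums and uncentered scatter of each pattern
  patterns <- lapply(split(seq_len(nrow(Y)), key), function(rows) {
    idx <- which(obs[rows[1L], ])
    Yp <- Y[rows, idx, drop = FALSE]
    list(idx = idx, n = length(rows), cs = colSums(Yp), SS = crossprod(Yp))
  })
  p <- length(eta0)

  d <- ncol(Y)
  cache <- new.env(parent = emptyenv())
  evaluate <- function(eta) {
    if (!is.null(cache$eta) && identical(cache$eta, eta)) return(cache$res)
    ms <- builder(eta)
    # flatten derivative structures so each pattern contributes two
    # matrix-vector products instead of a per-parameter loop
    DS <- vapply(ms$dSigma, function(x)
      if (is.null(x)) numeric(d * d) else as.vector(x), numeric(d * d))
    nll <- 0
    gS <- numeric(d * d)   # accumulated d nll / d Sigma (full matrix, vec)
    gM <- numeric(d)       # accumulated d nll / d mu
    ok <- tryCatch({
      for (pt in patterns) {
        o <- pt$idx
        ch <- chol(ms$Sigma[o, o, drop = FALSE])
        W <- chol2inv(ch)
        mo <- ms$mu[o]
        Wm <- W %*% mo
        Wc <- W %*% pt$cs
        quad <- sum(W * pt$SS) - 2 * sum(Wm * pt$cs) + pt$n * sum(mo * Wm)
        nll <- nll +
          pt$n * (length(o) * log(2 * pi) + 2 * sum(log(diag(ch)))) / 2 +
          quad / 2
        WSW <- W %*% pt$SS %*% W - tcrossprod(Wc, Wm) - tcrossprod(Wm, Wc) +
          pt$n * tcrossprod(Wm)
        Gfull <- matrix(0, d, d)
        Gfull[o, o] <- (pt$n * W - WSW) / 2
        gS <- gS + as.vector(Gfull)
        gM[o] <- gM[o] - as.vector(Wc - pt$n * Wm)
      }
      TRUE
    }, error = function(e) FALSE)
    res <- if (ok)
      list(value = nll,
           gradient = as.vector(crossprod(DS, gS)) +
             as.vector(crossprod(ms$dmu, gM)))
    else list(value = 1e10, gradient = rep(0, p))
    cache$eta <- eta
    cache$res <- res
    res
  }
  fn <- function(eta) evaluate(eta)$value
  gr <- function(eta) evaluate(eta)$gradient

  opt <- stats::optim(eta0, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  hess <- stats::optimHess(opt$par, fn, gr)
  list(eta = opt$par, nll = opt$value, logLik = -opt$value,
       convergence = opt$convergence, hessian = hess,
       counts = opt$counts, n = nrow(Y), nll_fn = fn, gr_fn = gr)
}

# Finite-difference gradient used by tests to validate analytic gradients and
# by the delta method for scalar functionals of eta.
numeric_gradient <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(j) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Smallest admissible variance: keeps the implied covariance positive definite
# for degenerate (noise-free) data instead of letting the likelihood diverge.
.dv_var_floor <- 1e-10

# log-variance <-> variance transform used by every builder
var_from_log <- function(l) .dv_var_floor + exp(l)
log_from_var <- function(v) log(pmax(v - .dv_var_floor, .dv_var_floor))
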