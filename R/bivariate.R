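#' Seven-parameter censored selection model
#'
#' Parameter vector of the censored bivariate model underlying a selection
#' study: predictor mean/SD in applicants (`mu_a`, `sigma_a`), predictor
#' mean/SD in entrants (`mu_i`, `sigma_i`), outcome mean/SD in entrants
#' (`mu_y`, `sigma_y`; fixed at 0/1 when the outcome is ordinal or binary),
#' and the predictor-outcome correlation in entrants (`r_i`).
#'
#' @param mu_a,sigma_a Predictor mean and SD in applicants (points).
#' @param mu_i,sigma_i Predictor mean and SD in entrants (points).
#' @param mu_y,sigma_y Outcome mean and SD in entrants (outcome units).
#' @param r_i Predictor-outcome correlation in entrants, in (-1, 1).
#' @return Named numeric vector of class `seven_parameter_model`.
#' @export
seven_parameter_model <- function(mu_a, sigma_a, mu_i, sigma_i,
                                  mu_y = 0, sigma_y = 1, r_i = 0) {
  if (sigma_a <= 0 || sigma_i <= 0 || sigma_y <= 0)
    stop("all SDs must be positive")
  if (abs(r_i) >= 1) stop("|r_i| must be < 1")
  structure(c(mu_a = mu_a, sigma_a = sigma_a, mu_i = mu_i,
              sigma_i = sigma_i, mu_y = mu_y, sigma_y = sigma_y, r_i = r_i),
            class = "seven_parameter_model")
}

.par_names <- c("mu_a", "sigma_a", "mu_i", "sigma_i", "mu_y", "sigma_y", "r_i")

# bivariate standard-normal CDF P(X <= u, Y <= v); high-accuracy TVPACK
# with a GenzBretz fallback for the degenerate limits TVPACK rejects
.pbvn <- function(u, v, r) {
  if (u == -Inf || v == -Inf) return(0)
  if (u == Inf) return(pnorm(v))
  if (v == Inf) return(pnorm(u))
  p <- tryCatch(
    mvtnorm::pmvnorm(upper = c(u, v),
                     corr = matrix(c(1, r, r, 1), 2),
                     algorithm = mvtnorm::TVPACK(abseps = 1e-12)),
    error = function(e)
      mvtnorm::pmvnorm(upper = c(u, v),
                       corr = matrix(c(1, r, r, 1), 2),
                       algorithm = mvtnorm::GenzBretz(abseps = 1e-10)))
  min(max(as.numeric(p), 0), 1)
}

# P(X >= zc, a < Y <= b) for standard bivariate normal with correlation r
.rect_upper_x <- function(zc, a, b, r) {
  hi <- if (b == Inf) pnorm(zc, lower.tail = FALSE) else pnorm(b) - .pbvn(zc, b, r)
  lo <- if (a == -Inf) 0 else pnorm(a) - .pbvn(zc, a, r)
  max(hi - lo, 0)
}

# ---- model preparation -----------------------------------------------------

# Precomputes sufficient statistics / groupings so that repeated likelihood
# evaluation inside the optimizer and the MCMC chain is cheap.
.prep_entrants <- function(entrants, spec, ceiling) {
  stopifnot(is.data.frame(entrants),
            all(c("predictor", "outcome") %in% names(entrants)))
  x <- as.numeric(entrants$predictor)
  if (any(x > ceiling))
    stop("entrant predictor values exceed the ceiling")
  cens <- x >= ceiling
  if (spec$kind == "continuous") {
    y <- as.numeric(entrants$outcome)
    xu <- x[!cens]; yu <- y[!cens]
    list(kind = "continuous", ceiling = ceiling,
         n_u = length(xu), sx = sum(xu), sy = sum(yu),
         sxx = sum(xu^2), syy = sum(yu^2), sxy = sum(xu * yu),
         y_cens = y[cens], n_c = sum(cens))
  } else {
    k <- length(spec$thresholds) + 1L
    j <- entrants$outcome
    if (is.factor(j)) j <- as.integer(j)
    j <- as.integer(j)
    if (any(is.na(j)) || any(j < 1L) || any(j > k))
      stop("ordinal outcome column inconsistent with the outcome spec ",
           "(expected categories 1..", k, ")")
    tau <- c(-Inf, spec$thresholds, Inf)
    list(kind = "ordinal", ceiling = ceiling, k = k, tau = tau,
         x_u = x[!cens], j_u = j[!cens],
         cens_counts = tabulate(j[cens], nbins = k),
         n_u = sum(!cens), n_c = sum(cens))
  }
}

.entrant_loglik <- function(par, ep) {
  mu_i <- par[["mu_i"]]; s_i <- par[["sigma_i"]]
  mu_y <- par[["mu_y"]]; s_y <- par[["sigma_y"]]
  r <- par[["r_i"]]
  if (!all(is.finite(c(mu_i, s_i, mu_y, s_y, r)))) return(-Inf)
  if (s_i <= 0 || s_y <= 0 || abs(r) >= 1) return(-Inf)
  s2 <- 1 - r^2
  if (ep$kind == "continuous") {
    ll <- 0
    if (ep$n_u > 0) {
      sdx2 <- ep$sxx - 2 * mu_i * ep$sx + ep$n_u * mu_i^2
      sdy2 <- ep$syy - 2 * mu_y * ep$sy + ep$n_u * mu_y^2
      sdxy <- ep$sxy - mu_i * ep$sy - mu_y * ep$sx + ep$n_u * mu_i * mu_y
      q <- (sdx2 / s_i^2 - 2 * r * sdxy / (s_i * s_y) + sdy2 / s_y^2) / s2
      ll <- -ep$n_u * (log(s_i) + log(s_y) + log(2 * pi) + 0.5 * log(s2)) -
        q / 2
    }
    if (ep$n_c > 0) {
      zy <- (ep$y_cens - mu_y) / s_y
      zc <- (ep$ceiling - mu_i) / s_i
      ll <- ll + sum(dnorm(ep$y_cens, mu_y, s_y, log = TRUE)) +
        sum(pnorm((zc - r * zy) / sqrt(s2),
                  lower.tail = FALSE, log.p = TRUE))
    }
    ll
  } else {
    tau <- ep$tau
    ll <- 0
    if (ep$n_u > 0) {
      zx <- (ep$x_u - mu_i) / s_i
      s <- sqrt(s2)
      p <- pnorm((tau[ep$j_u + 1L] - r * zx) / s) -
        pnorm((tau[ep$j_u] - r * zx) / s)
      if (any(p <= 0)) return(-Inf)
      ll <- sum(dnorm(ep$x_u, mu_i, s_i, log = TRUE)) + sum(log(p))
    }
    if (ep$n_c > 0) {
      zc <- (ep$ceiling - mu_i) / s_i
      for (j in which(ep$cens_counts > 0)) {
        pj <- .rect_upper_x(zc, tau[j], tau[j + 1L], r)
        if (pj <= 0) return(-Inf)
        ll <- ll + ep$cens_counts[j] * log(pj)
      }
    }
    ll
  }
}

#' Log-likelihood of entrant predictor-outcome data under the censored model
#'
#' Each entrant pair contributes according to its censorship and outcome
#' type: with a continuous outcome, an uncensored pair contributes the
#' bivariate-normal density and a ceiling pair the outcome's marginal
#' density times the conditional upper tail of the predictor; with an
#' ordinal or binary outcome (latent standard normal, cut at the spec's
#' thresholds), pairs contribute interval probabilities, computed with
#' bivariate-normal rectangle probabilities when the predictor is censored.
#' Out-of-range correlations return `-Inf` rather than an error, so the
#' function is safe as an MCMC target.
#'
#' @param params A [seven_parameter_model()] or named vector with the same
#'   elements.
#' @param entrants Data frame with columns `predictor` and `outcome`
#'   (numeric outcome, or category index / factor for ordinal outcomes).
#' @param spec An [outcome_spec()].
#' @param ceiling Right-censoring point of the predictor (`Inf` for none).
#' @return Scalar log-likelihood (possibly `-Inf`).
#' @export
loglik_bivariate <- function(params, entrants,
                             spec = outcome_spec("continuous"),
                             ceiling = Inf) {
  ep <- .prep_entrants(entrants, spec, ceiling)
  .entrant_loglik(params, ep)
}

# ---- joint model ----------------------------------------------------------

# free-parameter transforms: sigmas on log scale, r on atanh scale
.free_index <- function(kind) {
  if (kind == "continuous") .par_names else
    c("mu_a", "sigma_a", "mu_i", "sigma_i", "r_i")
}
.to_free <- function(par, free) {
  th <- par[free]
  th[grep("^sigma", free)] <- log(th[grep("^sigma", free)])
  th["r_i"] <- atanh(par[["r_i"]])
  th
}
.to_full <- function(theta, free, kind) {
  par <- c(mu_a = NA_real_, sigma_a = NA_real_, mu_i = NA_real_,
           sigma_i = NA_real_, mu_y = 0, sigma_y = 1, r_i = NA_real_)
  th <- theta
  names(th) <- free
  th[grep("^sigma", free)] <- exp(th[grep("^sigma", free)])
  th["r_i"] <- tanh(th[["r_i"]])
  par[free] <- th
  par
}

.joint_loglik <- function(par, app_stats, ep) {
  .tobit_loglik(par[["mu_a"]], par[["sigma_a"]], app_stats) +
    .entrant_loglik(par, ep)
}

.moment_start <- function(applicants, entrants, spec) {
  fa <- fit_censored_normal(applicants)
  xs <- censored_sample(entrants$predictor, ceiling = applicants$ceiling)
  fi <- fit_censored_normal(xs)
  unc <- !xs$censored
  if (spec$kind == "continuous") {
    y <- as.numeric(entrants$outcome)
    r0 <- if (sum(unc) > 2) cor(entrants$predictor[unc], y[unc]) else 0
    seven_parameter_model(fa$params[["mu"]], fa$params[["sigma"]],
                          fi$params[["mu"]], fi$params[["sigma"]],
                          mean(y), max(sd(y), 1e-6),
                          max(min(r0, 0.9), -0.9))
  } else {
    j <- entrants$outcome
    if (is.factor(j)) j <- as.integer(j)
    r0 <- if (sum(unc) > 2) cor(entrants$predictor[unc], as.numeric(j)[unc]) else 0
    seven_parameter_model(fa$params[["mu"]], fa$params[["sigma"]],
                          fi$params[["mu"]], fi$params[["sigma"]],
                          0, 1, max(min(1.2 * r0, 0.9), -0.9))
  }
}

#' Joint maximum-likelihood fit of the seven-parameter selection model
#'
#' Maximizes the sum of the Tobit log-likelihood of the applicant predictor
#' scores and the censored bivariate log-likelihood of the entrant
#' predictor-outcome pairs.  Entrants are treated as a subset of applicants
#' drawn by indirect selection; no explicit selection term enters the
#' likelihood (the range-restriction correction is applied afterwards, per
#' draw or at the MLE).  Used as the deterministic initializer and oracle
#' for the MCMC chain.  When nothing is censored and the outcome is
#' continuous the fit reduces to closed-form sample moments and the Pearson
#' correlation.
#'
#' @param applicants A [censored_sample()] of applicant predictor scores.
#' @param entrants Data frame with columns `predictor` and `outcome`.
#' @param spec An [outcome_spec()].
#' @param ceiling Predictor ceiling for the entrants; defaults to the
#'   applicants' ceiling.
#' @return A `clpv_fit` whose `params` is a [seven_parameter_model()].
#'   Non-convergence is flagged in `converged`, not thrown.
#' @export
fit_seven_parameter_mle <- function(applicants, entrants,
                                    spec = outcome_spec("continuous"),
                                    ceiling = applicants$ceiling) {
  stopifnot(inherits(applicants, "censored_sample"))
  n_used <- length(applicants$values) + nrow(entrants)
  # closed-form path: no censoring anywhere, continuous outcome
  if (spec$kind == "continuous" && !any(applicants$censored) &&
      !any(entrants$predictor >= ceiling)) {
    x <- entrants$predictor; y <- as.numeric(entrants$outcome); n <- length(x)
    par <- seven_parameter_model(
      mean(applicants$values),
      sqrt(mean((applicants$values - mean(applicants$values))^2)),
      mean(x), sqrt(mean((x - mean(x))^2)),
      mean(y), sqrt(mean((y - mean(y))^2)),
      cor(x, y))
    ep <- .prep_entrants(entrants, spec, ceiling)
    return(structure(list(params = par,
                          loglik = .joint_loglik(par, .tobit_stats(applicants), ep),
                          converged = TRUE, n_used = n_used),
                     class = "clpv_fit"))
  }
  app_stats <- .tobit_stats(applicants)
  ep <- .prep_entrants(entrants, spec, ceiling)
  free <- .free_index(spec$kind)
  start <- .to_free(.moment_start(applicants, entrants, spec), free)
  negll <- function(theta) {
    ll <- .joint_loglik(.to_full(theta, free, spec$kind), app_stats, ep)
    if (!is.finite(ll)) 1e10 else -ll
  }
  o1 <- optim(start, negll, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-10))
  o2 <- optim(o1$par, negll, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-12))
  best <- if (o2$value <= o1$value) o2 else o1
  par <- .to_full(best$par, free, spec$kind)
  structure(list(params = structure(par, class = "seven_parameter_model"),
                 loglik = -best$value,
                 converged = o2$convergence == 0,
                 n_used = n_used),
            class = "clpv_fit")
}
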