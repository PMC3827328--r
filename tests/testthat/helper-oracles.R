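# Independent numerical oracles used across test files.  These never call
# the package's own likelihood decomposition: pair probabilities are
# computed by direct (numerical) integration of the joint latent density.

# joint density of (x, latent y) given seven parameters; latent y is the
# standardized outcome scale used for ordinal outcomes
.oracle_joint <- function(par, continuous = TRUE) {
  if (continuous) {
    mu <- c(par[["mu_i"]], par[["mu_y"]])
    Sig <- matrix(c(par[["sigma_i"]]^2,
                    par[["r_i"]] * par[["sigma_i"]] * par[["sigma_y"]],
                    par[["r_i"]] * par[["sigma_i"]] * par[["sigma_y"]],
                    par[["sigma_y"]]^2), 2)
  } else {
    mu <- c(par[["mu_i"]], 0)
    Sig <- matrix(c(par[["sigma_i"]]^2, par[["r_i"]] * par[["sigma_i"]],
                    par[["r_i"]] * par[["sigma_i"]], 1), 2)
  }
  function(x, y) mvtnorm::dmvnorm(cbind(x, y), mean = mu, sigma = Sig)
}

# brute-force log-likelihood of entrant pairs by quadrature
oracle_loglik_bivariate <- function(par, entrants, spec, ceiling) {
  dens_c <- .oracle_joint(par, continuous = spec$kind == "continuous")
  tau <- if (spec$kind != "continuous") c(-Inf, spec$thresholds, Inf)
  xhi <- par[["mu_i"]] + 12 * par[["sigma_i"]]   # effective +infinity
  ll <- 0
  for (i in seq_len(nrow(entrants))) {
    x <- entrants$predictor[i]
    cens <- x >= ceiling
    if (spec$kind == "continuous") {
      y <- entrants$outcome[i]
      p <- if (!cens) dens_c(x, y) else
        stats::integrate(function(t) dens_c(t, rep(y, length(t))),
                         ceiling, xhi, rel.tol = 1e-11)$value
    } else {
      j <- as.integer(entrants$outcome[i])
      lo <- max(tau[j], -12); hi <- min(tau[j + 1L], 12)
      p <- if (!cens) {
        stats::integrate(function(t) dens_c(rep(x, length(t)), t),
                         lo, hi, rel.tol = 1e-11)$value
      } else {
        pracma::integral2(function(u, v)
          matrix(dens_c(as.vector(u), as.vector(v)), nrow(u), ncol(u)),
          ceiling, xhi, lo, hi, reltol = 1e-10)$Q
      }
    }
    ll <- ll + log(p)
  }
  ll
}

# small deterministic entrant datasets for oracle comparisons
make_small_dataset <- function(seed) {
  set.seed(seed)
  n <- 4 + seed %% 3
  x <- round(rnorm(n, 25, 4), 2)
  ceiling <- round(quantile(x, 0.75), 2)
  x <- pmin(x, ceiling)
  y <- round(0.4 * x + rnorm(n, 0, 2), 2)
  list(entrants = data.frame(predictor = x, outcome = y), ceiling = ceiling)
}

# quick synthetic cohort for pipeline-level tests
small_cohort <- function(seed = 7, n = 4000, ...) {
  simulate_cohort(cohort_config(n_applicants = n, seed = seed, ...))
}

fit_small <- function(coh, seed = 1, length = 2000, use_last = 800) {
  clpv(outcome ~ predictor, data = coh$entrants,
       applicants = coh$applicants$values, ceiling = coh$ceiling,
       reliability = c(predictor = coh$config$r_XXa,
                       outcome = coh$truth$r_YYi),
       chain = chain_control(length = length, use_last = use_last,
                             seed = seed))
}
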