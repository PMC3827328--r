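#' Estimate construct-level predictive validity from selection data
#'
#' The main fitting function.  Fits the seven-parameter censored
#' bivariate-normal model — predictor mean/SD in applicants and entrants,
#' outcome mean/SD in entrants, and the entrant predictor-outcome
#' correlation — to applicant and entrant data by maximum likelihood, then
#' samples the posterior with a DRAM chain (flat priors on means, 1/sigma
#' on the SDs, uniform on the correlation) started at the MLE.  The
#' Hunter-Schmidt-Le indirect range-restriction correction is applied to
#' every retained draw, using that draw's selection ratio, giving the
#' construct-level predictive validity with a standard error, percentile
#' interval and equivalent sample size.
#'
#' When no applicant scores are available, supply `u` (e.g. a
#' [default_selection_ratio()]): the entrant-side model is then fitted
#' alone and the fixed ratio used for every draw.
#'
#' @param formula Model formula `outcome ~ predictor`, resolved in `data`.
#' @param data Data frame of entrants.
#' @param applicants Numeric vector of applicant predictor scores
#'   (censored at `ceiling`), or `NULL` when `u` is given.
#' @param ceiling Right-censoring point of the predictor (`Inf` = none).
#' @param outcome Outcome type: `"continuous"`, `"ordinal"` or
#'   `"binary"`.  For ordinal/binary, the outcome column must be a factor
#'   or small-integer codes; latent thresholds are fixed from the marginal
#'   category frequencies (two-step).
#' @param reliability Named vector `c(predictor = , outcome = )`; defaults
#'   to the field averages in [default_reliability()].
#' @param u Fixed selection ratio, only when `applicants` is `NULL`.
#' @param chain A [chain_control()].
#' @param seed Convenience override of `chain$seed`.
#' @param mle_only Skip the MCMC stage (estimate without uncertainty).
#' @return An object of class `clpv` with components `estimate` (a
#'   `clpv_estimate`), `mle`, `chain`, `chain_summary`, `outcome_spec`,
#'   `reliability`, and the matched call.  Methods: `print`, `summary`,
#'   `coef`, `confint`, `vcov`, `predict`, `plot`, `simulate`.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(cohort_config(n_applicants = 4000, seed = 7))
#' fit <- clpv(outcome ~ predictor, data = coh$entrants,
#'             applicants = coh$applicants$values, ceiling = coh$ceiling,
#'             reliability = c(predictor = 0.815,
#'                             outcome = coh$truth$r_YYi),
#'             chain = chain_control(length = 2000, use_last = 800, seed = 1))
#' fit
#' }
#' @export
clpv <- function(formula, data, applicants = NULL, ceiling = Inf,
                 outcome = c("continuous", "ordinal", "binary"),
                 reliability = default_reliability(), u = NULL,
                 chain = chain_control(), seed = NULL, mle_only = FALSE) {
  cl <- match.call()
  outcome <- match.arg(outcome)
  if (!is.null(seed)) chain$seed <- as.integer(seed)
  stopifnot(all(c("predictor", "outcome") %in% names(reliability)))
  vars <- all.vars(formula)
  if (length(vars) != 2L)
    stop("formula must be of the form outcome ~ predictor")
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("columns missing from data: ", paste(miss, collapse = ", "))
  entrants <- data.frame(outcome = data[[vars[1]]],
                         predictor = data[[vars[2]]])
  entrants <- entrants[complete.cases(entrants), ]

  ospec <- if (outcome == "continuous") outcome_spec("continuous") else {
    j <- entrants$outcome
    if (is.factor(j)) j <- as.integer(j) else j <- as.integer(j)
    counts <- tabulate(j, nbins = max(j))
    outcome_spec(outcome, thresholds = ordinal_thresholds(counts))
  }

  have_applicants <- !is.null(applicants)
  if (!have_applicants && is.null(u))
    stop("supply applicant scores or a fixed selection ratio u")

  if (have_applicants) {
    app <- censored_sample(applicants[!is.na(applicants)], ceiling = ceiling)
    mle <- fit_seven_parameter_mle(app, entrants, ospec, ceiling)
    app_stats <- .tobit_stats(app)
  } else {
    # entrant-only model: applicant parameters tied via the fixed ratio
    app <- NULL
    pseudo <- censored_sample(entrants$predictor, ceiling = ceiling)
    fi <- fit_censored_normal(pseudo)
    mle0 <- seven_parameter_model(
      fi$params[["mu"]], fi$params[["sigma"]] / u,
      fi$params[["mu"]], fi$params[["sigma"]],
      if (ospec$kind == "continuous") mean(entrants$outcome) else 0,
      if (ospec$kind == "continuous") max(sd(entrants$outcome), 1e-6) else 1,
      0)
    ep0 <- .prep_entrants(entrants, ospec, ceiling)
    # direct optimization over the entrant-side free parameters
    th0 <- .to_free(mle0, .free_index(ospec$kind))
    ent_free <- setdiff(names(th0), c("mu_a", "sigma_a"))
    obj <- function(th) {
      full <- .to_full(.merge_free(th0, th, ent_free), .free_index(ospec$kind),
                       ospec$kind)
      ll <- .entrant_loglik(full, ep0)
      if (!is.finite(ll)) 1e10 else -ll
    }
    o <- optim(th0[ent_free], obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
    o <- optim(o$par, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
    par <- .to_full(.merge_free(th0, o$par, ent_free),
                    .free_index(ospec$kind), ospec$kind)
    par[["sigma_a"]] <- par[["sigma_i"]] / u
    par[["mu_a"]] <- par[["mu_i"]]        # not identified; unused downstream
    mle <- structure(list(params = structure(par,
                                             class = "seven_parameter_model"),
                          loglik = -o$value, converged = o$convergence == 0,
                          n_used = nrow(entrants)),
                     class = "clpv_fit")
    app_stats <- NULL
  }

  ep <- .prep_entrants(entrants, ospec, ceiling)
  free <- if (have_applicants) .free_index(ospec$kind) else
    setdiff(.free_index(ospec$kind), c("mu_a", "sigma_a"))
  th_mle <- .to_free(mle$params, .free_index(ospec$kind))

  logpost <- function(th) {
    full <- .to_full(.merge_free(th_mle, th, free), .free_index(ospec$kind),
                     ospec$kind)
    if (!have_applicants) {
      full[["sigma_a"]] <- full[["sigma_i"]] / u
      full[["mu_a"]] <- full[["mu_i"]]
    }
    ll <- .entrant_loglik(full, ep)
    if (!is.finite(ll)) return(-Inf)
    if (have_applicants) {
      ll <- ll + .tobit_loglik(full[["mu_a"]], full[["sigma_a"]], app_stats)
      if (!is.finite(ll)) return(-Inf)
    }
    # priors: flat on means, 1/sigma on SDs, uniform on r; on the sampling
    # scale (log sigma, atanh r) the Jacobian makes log sigma flat and adds
    # log(1 - r^2) for the correlation
    ll + log1p(-full[["r_i"]]^2)
  }

  if (mle_only) {
    u_mle <- if (have_applicants)
      mle$params[["sigma_i"]] / mle$params[["sigma_a"]] else u
    rho <- hsl_case_iv(mle$params[["r_i"]], reliability[["predictor"]],
                       reliability[["outcome"]], u_mle)
    est <- structure(list(rho = rho, se = NA_real_,
                          ci = c(lower = NA_real_, upper = NA_real_),
                          equivalent_n = NA_real_, u = u_mle,
                          reliability = reliability,
                          n_draws = 0L, n_rejected = 0L, n_clipped = 0L,
                          unreliable = FALSE),
                     class = "clpv_estimate")
    out <- list(call = cl, estimate = est, mle = mle, chain = NULL,
                chain_summary = NULL, outcome_spec = ospec,
                reliability = reliability, fixed_u = if (have_applicants)
                  NULL else u, ceiling = ceiling)
    class(out) <- "clpv"
    return(out)
  }

  # proposal covariance from the curvature at the MLE where available
  prop <- tryCatch({
    H <- optimHess(th_mle[free], function(th) -logpost(th))
    V <- solve(H)
    if (any(!is.finite(V)) || any(diag(V) <= 0)) stop("bad hessian")
    (V + t(V)) / 2
  }, error = function(e) pmax(abs(th_mle[free]) * 0.02, 0.02))
  raw <- run_dram(logpost, th_mle[free], chain, proposal_sd = prop)

  # map sampled (transformed, free) draws back to the full parameter scale
  full_draws <- matrix(NA_real_, nrow(raw$draws), 7,
                       dimnames = list(NULL, .par_names))
  for (i in seq_len(nrow(raw$draws))) {
    full <- .to_full(.merge_free(th_mle, raw$draws[i, ], free),
                     .free_index(ospec$kind), ospec$kind)
    if (!have_applicants) {
      full[["sigma_a"]] <- full[["sigma_i"]] / u
      full[["mu_a"]] <- full[["mu_i"]]
    }
    full_draws[i, ] <- full
  }
  ch <- structure(list(draws = full_draws, logpost = raw$logpost,
                       acceptance = raw$acceptance,
                       acceptance_total = raw$acceptance_total,
                       config = chain),
                  class = "clpv_chain")
  smry <- withCallingHandlers(
    summarize_chain(ch, chain),
    warning = function(w) invokeRestart("muffleWarning"))
  est <- clpv_with_uncertainty(ch, reliability)

  out <- list(call = cl, estimate = est, mle = mle, chain = ch,
              chain_summary = smry, outcome_spec = ospec,
              reliability = reliability,
              fixed_u = if (have_applicants) NULL else u,
              ceiling = ceiling)
  class(out) <- "clpv"
  out
}

# overwrite the elements of the reference free vector named in `nm`
.merge_free <- function(ref, th, nm) {
  ref[nm] <- th
  ref[names(ref)]
}

#' @export
print.clpv <- function(x, ...) {
  cat("Construct-level predictive validity model\n")
  cat("Call: "); print(x$call)
  e <- x$estimate
  if (is.na(e$se)) {
    cat(sprintf("\n  rho = %s (MLE only, no uncertainty)\n", .fmt(e$rho)))
  } else {
    cat(sprintf("\n  rho = %s (SE %s), 95%% CI [%s, %s]\n",
                .fmt(e$rho), .fmt(e$se), .fmt(e$ci[1]), .fmt(e$ci[2])))
    cat(sprintf("  equivalent N = %s, acceptance rate %.2f\n",
                format(attr(e$equivalent_n, "rounded")), x$chain$acceptance))
  }
  cat(sprintf("  selection ratio u = %s%s, reliabilities: predictor %s, outcome %s\n",
              .fmt(e$u), if (!is.null(x$fixed_u)) " (fixed)" else "",
              .fmt(x$reliability[["predictor"]]),
              .fmt(x$reliability[["outcome"]])))
  invisible(x)
}

#' @export
summary.clpv <- function(object, ...) {
  structure(list(call = object$call, params = object$chain_summary,
                 estimate = object$estimate, mle = object$mle,
                 acceptance = if (!is.null(object$chain))
                   object$chain$acceptance else NA_real_),
            class = "summary.clpv")
}

#' @export
print.summary.clpv <- function(x, ...) {
  cat("Seven-parameter censored selection model (posterior summaries)\n\n")
  if (!is.null(x$params)) print(round(as.data.frame(x$params)[1:4], 4))
  cat("\n")
  print(x$estimate)
  invisible(x)
}

#' @export
coef.clpv <- function(object, ...) {
  if (!is.null(object$chain_summary))
    c(setNames(object$chain_summary$mean, rownames(object$chain_summary)),
      rho = object$estimate$rho)
  else c(unclass(object$mle$params), rho = object$estimate$rho)
}

#' @export
vcov.clpv <- function(object, ...) {
  if (is.null(object$chain)) stop("no chain: model fitted with mle_only = TRUE")
  keep <- tail(object$chain$draws, object$chain$config$use_last)
  cov(keep)
}

#' @export
confint.clpv <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$chain)) stop("no chain: model fitted with mle_only = TRUE")
  keep <- tail(object$chain$draws, object$chain$config$use_last)
  a <- (1 - level) / 2
  ci <- t(apply(keep, 2, quantile, probs = c(a, 1 - a)))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Predict out-of-range performance from a fitted validity model
#'
#' Uses the fitted decensored applicant moments and the corrected validity
#' to predict standardized performance and tail rates for arbitrary
#' grade-points totals, exactly as [predict_performance()] does for
#' hand-supplied inputs.
#'
#' @param object A fitted [clpv()] model.
#' @param points Numeric vector of predictor points (optionally named by
#'   grade profile).
#' @param base_rates Named baseline tail rates (proportions).
#' @param reliability Reliabilities used for attenuation; defaults to the
#'   model's.
#' @param ... Unused.
#' @return See [predict_performance()].
#' @export
predict.clpv <- function(object, points,
                         base_rates = c(fail = 0.03, retake = 0.15),
                         reliability = object$reliability, ...) {
  cf <- coef(object)
  predict_performance(points, pool_mean = cf[["mu_a"]],
                      pool_sd = cf[["sigma_a"]],
                      rho = object$estimate$rho,
                      r_XX = reliability[["predictor"]],
                      r_YY = reliability[["outcome"]],
                      base_rates = base_rates)
}

#' @export
plot.clpv <- function(x, ...) {
  if (is.null(x$chain)) stop("no chain to plot")
  draws <- x$chain$draws
  keep <- colnames(draws)[apply(draws, 2, sd) > 0]
  op <- par(mfrow = c(ceiling(length(keep) / 2), 2), mar = c(3, 4, 2, 1))
  on.exit(par(op))
  for (nm in keep) {
    plot(draws[, nm], type = "l", ylab = nm, xlab = "iteration", ...)
    abline(v = nrow(draws) - x$chain$config$use_last, col = 2, lty = 2)
  }
  invisible(x)
}

#' Simulate entrant data from a fitted model
#'
#' Draws predictor-outcome pairs from the fitted entrant-side bivariate
#' normal (posterior-mean parameters), censored at the model's ceiling —
#' useful for posterior-predictive checks.
#'
#' @param object A fitted [clpv()] model.
#' @param nsim Number of simulated datasets.
#' @param seed Optional seed.
#' @param n Rows per dataset (default: the entrant count used in fitting).
#' @param ... Unused.
#' @return A list of `nsim` data frames with columns `predictor`,
#'   `outcome`, `censored`.
#' @export
simulate.clpv <- function(object, nsim = 1, seed = NULL,
                          n = object$mle$n_used, ...) {
  if (!is.null(seed)) set.seed(seed)
  cf <- if (!is.null(object$chain_summary))
    setNames(object$chain_summary$mean, rownames(object$chain_summary))
  else unclass(object$mle$params)
  r <- cf[["r_i"]]
  lapply(seq_len(nsim), function(i) {
    x <- rnorm(n, cf[["mu_i"]], cf[["sigma_i"]])
    y <- cf[["mu_y"]] + cf[["sigma_y"]] *
      (r * (x - cf[["mu_i"]]) / cf[["sigma_i"]] +
         sqrt(1 - r^2) * rnorm(n))
    cens <- x >= object$ceiling
    data.frame(predictor = pmin(x, object$ceiling), outcome = y,
               censored = cens)
  })
}
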