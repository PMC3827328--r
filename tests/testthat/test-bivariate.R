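par_demo <- seven_parameter_model(mu_a = 24, sigma_a = 5, mu_i = 26,
                                  sigma_i = 4, mu_y = 0.3, sigma_y = 1.1,
                                  r_i = 0.4)

test_that("with r = 0 and no censoring the likelihood factorizes", {
  set.seed(41)
  d <- data.frame(predictor = rnorm(30, 26, 4), outcome = rnorm(30, 0.3, 1.1))
  par0 <- par_demo; par0[["r_i"]] <- 0
  ll <- loglik_bivariate(par0, d, outcome_spec("continuous"), ceiling = Inf)
  expect_equal(ll,
               sum(dnorm(d$predictor, 26, 4, log = TRUE)) +
                 sum(dnorm(d$outcome, 0.3, 1.1, log = TRUE)),
               tolerance = 1e-10)
})

test_that("likelihood matches the quadrature oracle on many small datasets", {
  spec <- outcome_spec("continuous")
  for (seed in 1:12) {
    ds <- make_small_dataset(seed)
    ll <- loglik_bivariate(par_demo, ds$entrants, spec, ds$ceiling)
    expect_equal(ll, oracle_loglik_bivariate(par_demo, ds$entrants, spec,
                                             ds$ceiling),
                 tolerance = 1e-6, label = paste("continuous seed", seed))
  }
  # ordinal outcomes, including pairs censored at the ceiling
  tau <- c(-1, 0, 1.2)
  spec4 <- outcome_spec("ordinal", thresholds = tau)
  for (seed in 1:8) {
    ds <- make_small_dataset(seed)
    set.seed(100 + seed)
    ds$entrants$outcome <- sample(1:4, nrow(ds$entrants), replace = TRUE)
    ll <- loglik_bivariate(par_demo, ds$entrants, spec4, ds$ceiling)
    expect_equal(ll, oracle_loglik_bivariate(par_demo, ds$entrants, spec4,
                                             ds$ceiling),
                 tolerance = 1e-6, label = paste("ordinal seed", seed))
  }
})

test_that("out-of-range correlations give -Inf, not an error", {
  d <- data.frame(predictor = c(1, 2), outcome = c(0, 1))
  bad <- par_demo; bad[["r_i"]] <- 1
  expect_identical(loglik_bivariate(bad, d, ceiling = Inf), -Inf)
})

test_that("the likelihood is invariant to affine rescaling of the outcome", {
  set.seed(42)
  d <- data.frame(predictor = pmin(rnorm(40, 26, 4), 29),
                  outcome = rnorm(40, 0.3, 1.1))
  ll1 <- loglik_bivariate(par_demo, d, ceiling = 29)
  d2 <- d; d2$outcome <- 10 + 3 * d$outcome
  par2 <- par_demo
  par2[["mu_y"]] <- 10 + 3 * par_demo[["mu_y"]]
  par2[["sigma_y"]] <- 3 * par_demo[["sigma_y"]]
  # density transforms by the Jacobian of the y rescaling
  expect_equal(loglik_bivariate(par2, d2, ceiling = 29),
               ll1 - nrow(d) * log(3), tolerance = 1e-8)
})

test_that("raising the ceiling never changes uncensored contributions", {
  set.seed(43)
  x <- rnorm(25, 26, 4)
  d <- data.frame(predictor = x, outcome = 0.4 * x + rnorm(25))
  c1 <- max(x) + 0.5
  expect_equal(loglik_bivariate(par_demo, d, ceiling = c1),
               loglik_bivariate(par_demo, d, ceiling = Inf),
               tolerance = 1e-12)
})

test_that("joint MLE reduces to sample moments without censoring", {
  set.seed(44)
  app <- censored_sample(rnorm(500, 24, 5), ceiling = Inf)
  x <- rnorm(300, 26, 4)
  d <- data.frame(predictor = x, outcome = 0.3 + 0.4 * x + rnorm(300))
  fit <- fit_seven_parameter_mle(app, d)
  expect_equal(fit$params[["mu_a"]], mean(app$values), tolerance = 1e-6)
  expect_equal(fit$params[["mu_i"]], mean(x), tolerance = 1e-6)
  expect_equal(fit$params[["r_i"]], cor(x, d$outcome), tolerance = 1e-6)
  expect_equal(fit$params[["sigma_i"]], sqrt(mean((x - mean(x))^2)),
               tolerance = 1e-6)
  # identical samples: applicant and entrant parameters agree
  app2 <- censored_sample(x, ceiling = Inf)
  fit2 <- fit_seven_parameter_mle(app2, d)
  expect_equal(fit2$params[["mu_a"]], fit2$params[["mu_i"]], tolerance = 1e-8)
  expect_equal(fit2$params[["sigma_a"]], fit2$params[["sigma_i"]],
               tolerance = 1e-8)
})

test_that("joint MLE recovers generative parameters on a synthetic cohort", {
  coh <- small_cohort(seed = 1, n = 6000)
  fit <- fit_seven_parameter_mle(coh$applicants, coh$entrants,
                                 coh$outcome_spec, coh$ceiling)
  expect_true(fit$converged)
  tr <- coh$truth
  # rough large-sample SEs; all parameters within 3 of them
  n_e <- nrow(coh$entrants); n_a <- length(coh$applicants$values)
  expect_lt(abs(fit$params[["mu_a"]] - tr$mu_a), 3 * tr$sigma_a / sqrt(n_a) + .02)
  expect_lt(abs(fit$params[["sigma_a"]] - tr$sigma_a), 3 * tr$sigma_a / sqrt(n_a) + .03)
  expect_lt(abs(fit$params[["mu_i"]] - tr$mu_i), 3 * tr$sigma_i / sqrt(n_e) + .02)
  expect_lt(abs(fit$params[["sigma_i"]] - tr$sigma_i), 3 * tr$sigma_i / sqrt(n_e) + .03)
  expect_lt(abs(fit$params[["r_i"]] - tr$r_i), 3 / sqrt(n_e) + .03)
})

test_that("heavy censoring still permits correlation recovery", {
  coh <- simulate_cohort(cohort_config(n_applicants = 20000, seed = 9,
                                       ceiling_quantile = 0.62))
  # ceiling at the applicants' 62nd percentile puts ~60% of entrants at it
  expect_gt(coh$truth$prop_censored_entrants, 0.5)
  fit <- fit_seven_parameter_mle(coh$applicants, coh$entrants,
                                 coh$outcome_spec, coh$ceiling)
  expect_lt(abs(fit$params[["r_i"]] - coh$truth$r_i), 0.05)
})

test_that("binary-outcome MLE agrees with a tetrachoric estimate", {
  set.seed(46)
  n <- 4000
  x <- rnorm(n); ylat <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  ybin <- as.integer(ylat > 0.3) + 1L
  tau <- ordinal_thresholds(tabulate(ybin, 2))
  d <- data.frame(predictor = x, outcome = ybin)
  app <- censored_sample(rnorm(2000), ceiling = Inf)
  spec <- outcome_spec("binary", thresholds = tau)
  fit <- fit_seven_parameter_mle(app, d, spec, ceiling = Inf)
  # independent oracle: tetrachoric correlation from the 2x2 table of
  # median-split x against the binary outcome, by direct 1-D ML search
  xbin <- x > median(x)
  tab <- table(xbin, ybin == 2)
  tx <- qnorm(mean(!xbin)); ty <- qnorm(mean(ybin == 1))
  nll <- function(r) {
    p11 <- mvtnorm::pmvnorm(upper = c(tx, ty),
                            corr = matrix(c(1, r, r, 1), 2))
    p1x <- pnorm(tx) - p11; px1 <- pnorm(ty) - p11
    p <- c(p11, px1, p1x, 1 - p11 - p1x - px1)
    -sum(as.numeric(tab) * log(pmax(p, 1e-12)))
  }
  tet <- optimize(nll, c(-0.95, 0.95))$minimum
  # biserial-style MLE on continuous x is more efficient than the
  # tetrachoric; agreement to a few hundredths is what the shared latent
  # model implies
  expect_lt(abs(fit$params[["r_i"]] - tet), 0.06)
  expect_lt(abs(fit$params[["r_i"]] - 0.5), 0.05)
})
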