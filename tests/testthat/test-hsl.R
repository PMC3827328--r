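test_that("selection ratio is the plain SD quotient with guard rails", {
  expect_equal(selection_ratio(4, 4), 1)
  expect_equal(selection_ratio(3.87, 5.89), 3.87 / 5.89, tolerance = 1e-12)
  expect_warning(selection_ratio(6, 5), "exceeds 1")
  expect_error(selection_ratio(0, 5), "positive")
  expect_equal(default_selection_ratio("A-levels"), 0.664)
  expect_equal(default_selection_ratio("GCSEs/O-levels"), 0.690)
  expect_equal(default_selection_ratio("aptitude"), 0.750)
})

test_that("restricted reliability follows constant-error-variance bookkeeping", {
  expect_equal(restrict_reliability(0.8, 1), 0.8, tolerance = 1e-12)
  expect_equal(restrict_reliability(0.8, 0.656), 1 - 0.2 / 0.656^2,
               tolerance = 1e-12)
  # independent variance bookkeeping: true variance u^2 - (1 - r), error (1 - r)
  u <- 0.656; r <- 0.8
  true_var <- u^2 - (1 - r); err_var <- 1 - r
  expect_equal(restrict_reliability(r, u), true_var / (true_var + err_var),
               tolerance = 1e-12)
  # boundary: still defined but near-degenerate, warns
  expect_warning(v <- restrict_reliability(0.6, 0.656), "near-degenerate")
  expect_equal(v, 1 - 0.4 / 0.656^2, tolerance = 1e-10)
  expect_error(restrict_reliability(0.5, 0.656), "would be <= 0")
})

test_that("the correction is the identity at perfect reliability and no selection", {
  for (r in seq(-0.9, 0.9, by = 0.1))
    expect_equal(hsl_case_iv(r, 1, 1, 1), r, tolerance = 1e-12)
})

test_that("worked correction example and stepwise hand evaluation agree", {
  # hand evaluation of the four-step sequence
  r_i <- 0.2; r_XXa <- 0.8; r_YYi <- 0.84; u <- 0.656
  r_XXi <- 1 - (1 - r_XXa) / u^2
  u_T <- sqrt((u^2 - (1 - r_XXa)) / r_XXa)
  r_TPi <- r_i / sqrt(r_XXi * r_YYi)
  rho_hand <- (r_TPi / u_T) / sqrt(1 + r_TPi^2 * (1 / u_T^2 - 1))
  expect_equal(hsl_case_iv(r_i, r_XXa, r_YYi, u), rho_hand, tolerance = 1e-12)
  expect_equal(rho_hand, 0.503, tolerance = 1e-3)
})

test_that("corrections only enlarge, and monotonically", {
  # output at least |r_i| for valid inputs with u <= 1
  set.seed(51)
  for (i in 1:50) {
    rel1 <- runif(1, 0.55, 1); rel2 <- runif(1, 0.55, 1)
    u <- runif(1, min(sqrt(1 - rel1) + 0.15, 1), 1)
    r_XXi <- 1 - (1 - rel1) / u^2
    r_i <- runif(1, 0.05, 0.85 * sqrt(r_XXi * rel2))
    rho <- suppressWarnings(hsl_case_iv(r_i, rel1, rel2, u))
    expect_gte(rho, r_i - 1e-12)
  }
  # strictly increasing in r_i
  grid <- seq(0.02, 0.5, by = 0.02)
  vals <- vapply(grid, hsl_case_iv, numeric(1),
                 r_XXa = 0.8, r_YYi = 0.84, u = 0.7)
  expect_true(all(diff(vals) > 0))
  # lower reliabilities and lower selection ratios never decrease rho
  rel_grid <- seq(0.6, 1, by = 0.05)
  v1 <- vapply(rel_grid, function(rel)
    hsl_case_iv(0.2, rel, 0.84, 0.85), numeric(1))
  expect_true(all(diff(v1) <= 1e-12))
  v2 <- vapply(rel_grid, function(rel)
    hsl_case_iv(0.2, 0.8, rel, 0.85), numeric(1))
  expect_true(all(diff(v2) <= 1e-12))
  u_grid <- seq(0.5, 1, by = 0.05)
  v3 <- vapply(u_grid, function(u)
    hsl_case_iv(0.2, 0.8, 0.84, u), numeric(1))
  expect_true(all(diff(v3) <= 1e-12))
})

test_that("inconsistent inputs are rejected, overshoot is clipped with warning", {
  expect_error(hsl_case_iv(0.95, 0.5, 0.5, 0.9), "inconsistent")
  expect_error(hsl_case_iv(0.2, 0.8, 0.84, 0.4), "correction undefined")
})

test_that("equivalent N inverts the correlation standard-error formula", {
  n <- equivalent_n(0.45, 0.06)
  expect_equal(as.numeric(n), ((1 - 0.45^2) / 0.06)^2 + 1, tolerance = 1e-12)
  expect_equal(as.numeric(n), 177.7, tolerance = 0.05)
  expect_equal(as.numeric(equivalent_n(0, 0.1)), 101, tolerance = 1e-12)
  # round trip n -> SE -> n
  for (n0 in c(25, 177.67, 1000)) {
    se <- (1 - 0.45^2) / sqrt(n0 - 1)
    expect_equal(as.numeric(equivalent_n(0.45, se)), n0, tolerance = 1e-9)
  }
  expect_true(attr(equivalent_n(0.9, 0.5), "flagged"))
})

test_that("per-draw propagation collapses correctly on a degenerate chain", {
  draws <- matrix(rep(c(5, 4, 0.2), each = 100), 100, 3,
                  dimnames = list(NULL, c("sigma_a", "sigma_i", "r_i")))
  est <- clpv_with_uncertainty(draws,
                               reliability = c(predictor = 0.8,
                                               outcome = 0.84))
  expect_equal(est$rho, hsl_case_iv(0.2, 0.8, 0.84, 0.8), tolerance = 1e-12)
  expect_equal(est$se, 0)
  expect_false(est$unreliable)
  # perfect reliabilities and no selection: rho equals the chain mean of r_i
  set.seed(52)
  draws2 <- cbind(sigma_a = rep(4, 500), sigma_i = rep(4, 500),
                  r_i = runif(500, 0.1, 0.3))
  est2 <- clpv_with_uncertainty(draws2,
                                reliability = c(predictor = 1, outcome = 1))
  expect_equal(est2$rho, mean(draws2[, "r_i"]), tolerance = 1e-12)
  # draws violating the preconditions are counted and flagged past 5%
  draws3 <- cbind(sigma_a = rep(4, 100),
                  sigma_i = c(rep(4 * 0.3, 10), rep(4 * 0.9, 90)),
                  r_i = rep(0.2, 100))
  est3 <- clpv_with_uncertainty(draws3,
                                reliability = c(predictor = 0.8,
                                                outcome = 0.84))
  expect_equal(est3$n_rejected, 10L)
  expect_true(est3$unreliable)
})
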