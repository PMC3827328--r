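# The six printed inputs that drive the out-of-range worked example:
# construct-level validities .625 (finals) and .744 (overall BMS),
# reliabilities .867 (A-levels), .905 (finals), .904 (BMS), and the
# decensored applicant A-level pool 29.01 (SD 5.89).
POOL_MEAN <- 29.01; POOL_SD <- 5.89
RHO_FINALS <- 0.625; RHO_BMS <- 0.744
REL_ALEVEL <- 0.867; REL_FINALS <- 0.905; REL_BMS <- 0.904
PTS <- c(BBB = 24, BBC = 22, BCC = 20, CCC = 18, DDD = 12, EEE = 6)

test_that("attenuation reproduces the printed observed-scale correlations", {
  expect_equal(round(attenuate(RHO_FINALS, REL_ALEVEL, REL_FINALS), 2), 0.55)
  expect_equal(attenuate(RHO_FINALS, REL_ALEVEL, REL_FINALS),
               0.625 * sqrt(0.867 * 0.905), tolerance = 1e-12)
  expect_equal(round(attenuate(RHO_BMS, REL_ALEVEL, REL_BMS), 3), 0.659)
  expect_equal(attenuate(0.5, 1, 1), 0.5)
})

test_that("predictor z-scores against the decensored pool match print", {
  z <- predictor_z(PTS, POOL_MEAN, POOL_SD)
  expect_equal(round(unname(z), 2),
               c(-0.85, -1.19, -1.53, -1.87, -2.89, -3.91))
  expect_equal(predictor_z(POOL_MEAN, POOL_MEAN, POOL_SD), 0)
})

test_that("expected outcome z-scores match print (2-dp z convention)", {
  # products are taken from the 2-dp printed z-scores, the convention the
  # worked example itself uses
  r_att <- attenuate(RHO_FINALS, REL_ALEVEL, REL_FINALS)
  z2 <- round(predictor_z(PTS, POOL_MEAN, POOL_SD), 2)
  expect_equal(round(unname(expected_outcome_z(z2, r_att)), 2),
               c(-0.47, -0.66, -0.85, -1.04, -1.60, -2.16))
  expect_equal(expected_outcome_z(0, r_att), 0)
  # CCC..BBB average ~ -.75, matching the external cohort's -.73
  expect_equal(round(mean(expected_outcome_z(z2[1:4], r_att)), 2), -0.75)
})

test_that("failure and retake rates match all twelve printed values", {
  r_att <- attenuate(RHO_BMS, REL_ALEVEL, REL_BMS)
  z <- predictor_z(PTS, POOL_MEAN, POOL_SD)
  fail <- 100 * tail_rate(0.03, z, r_att)
  retake <- 100 * tail_rate(0.15, z, r_att)
  expect_equal(round(unname(fail[1:4]), 1), c(9.3, 13.6, 19.1, 25.8))
  expect_equal(round(unname(fail[5:6])), c(51, 76))
  expect_equal(round(unname(retake[1:4]), 1), c(31.7, 40.0, 48.8, 57.7))
  expect_equal(round(unname(retake[5:6])), c(81, 94))
  expect_equal(round(mean(fail[1:4]), 1), 17.0)
  expect_equal(round(mean(retake[1:4]), 1), 44.6)
  # implied baseline cutoffs (-1.03 is printed truncated; exact is -1.036)
  expect_equal(round(qnorm(0.03), 2), -1.88)
  expect_equal(qnorm(0.15), -1.03, tolerance = 0.01)
  # identities and monotonicity
  expect_equal(tail_rate(0.03, 0, r_att), 0.03, tolerance = 1e-12)
  zz <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(tail_rate(0.1, zz, 0.5)) < 0))
})

test_that("grade-increment projections match the A* worked example", {
  r_bms <- attenuate(RHO_BMS, REL_ALEVEL, REL_BMS)
  r_fin <- attenuate(RHO_FINALS, REL_ALEVEL, REL_FINALS)
  expect_equal(round(grade_increment_effect(c(2, 4, 6), POOL_SD, r_bms), 2),
               c(0.22, 0.45, 0.67))
  expect_equal(round(grade_increment_effect(c(2, 4, 6), POOL_SD, r_fin), 2),
               c(0.19, 0.38, 0.56))
  expect_equal(grade_increment_effect(0, POOL_SD, r_bms), 0)
})

test_that("power-based sample sizes match the printed requirement", {
  expect_identical(as.integer(sample_size_for_power(0.171, 0.05, 0.90, 1)),
                   290L)
  n2 <- sample_size_for_power(0.211, 0.05, 0.90, 1)
  expect_lte(abs(as.integer(n2) - 189L), 1L)   # formula gives 189.6
  # monotone decreasing in r, approaching the +3 floor
  rs <- c(0.1, 0.3, 0.6, 0.9, 0.99)
  ns <- vapply(rs, function(r)
    as.integer(sample_size_for_power(r, 0.05, 0.9, 1)), integer(1))
  expect_true(all(diff(ns) < 0))
  expect_lte(ns[length(ns)], 4L)
})

test_that("the one-call prediction table assembles all pieces", {
  tab <- predict_performance(PTS, POOL_MEAN, POOL_SD, RHO_BMS,
                             REL_ALEVEL, REL_BMS,
                             base_rates = c(fail = 0.03, retake = 0.15))
  expect_equal(nrow(tab), 6)
  expect_equal(attr(tab, "r_att"), attenuate(RHO_BMS, REL_ALEVEL, REL_BMS))
  expect_equal(round(tab$fail_rate[4] * 100, 1), 25.8)
  expect_equal(tab$outcome_z, attr(tab, "r_att") * tab$z, tolerance = 1e-12)
})

test_that("full attenuation round trip matches the generative observed r", {
  # correcting an entrant correlation and then re-attenuating should land
  # on the unrestricted-pool observed-scale correlation
  set.seed(71)
  n <- 50000
  rho <- 0.65; rxx <- 0.815; ryy <- 0.834
  T_ <- rnorm(n); P_ <- rho * T_ + sqrt(1 - rho^2) * rnorm(n)
  X <- sqrt(rxx) * T_ + sqrt(1 - rxx) * rnorm(n)
  Y <- sqrt(ryy) * P_ + sqrt(1 - ryy) * rnorm(n)
  S <- T_                      # selection on the true score
  sel <- S > quantile(S, 0.6)
  r_i <- cor(X[sel], Y[sel])
  u <- sd(X[sel]) / sd(X)
  ryyi <- ryy * var(P_[sel]) / (ryy * var(P_[sel]) + (1 - ryy))
  rho_hat <- hsl_case_iv(r_i, rxx, ryyi, u)
  expect_lt(abs(attenuate(rho_hat, rxx, ryy) - rho * sqrt(rxx * ryy)), 0.02)
})
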