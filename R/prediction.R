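#' Attenuate a construct-level correlation back to the observed scale
#'
#' Multiplying the true-score correlation by the square root of the
#' product of the two reliabilities gives the correlation expected between
#' the observed (error-contaminated) measures in an unrestricted pool.
#'
#' @param rho Construct-level correlation, in (0, 1].
#' @param r_XX,r_YY Predictor and outcome reliabilities, in (0, 1].
#' @return `rho * sqrt(r_XX * r_YY)`.
#' @examples
#' attenuate(0.625, 0.867, 0.905)  # A-levels -> finals, ~.554
#' @export
attenuate <- function(rho, r_XX, r_YY) {
  stopifnot(rho > 0, rho <= 1, r_XX > 0, r_XX <= 1, r_YY > 0, r_YY <= 1)
  rho * sqrt(r_XX * r_YY)
}

#' Standardize a grade-points total against the applicant pool
#'
#' @param points Tariff points of a grade profile (e.g. CCC = 18).
#' @param pool_mean,pool_sd Decensored mean and SD of the predictor in the
#'   applicant pool.
#' @return z-score `(points - pool_mean) / pool_sd`.
#' @export
predictor_z <- function(points, pool_mean, pool_sd) {
  stopifnot(pool_sd > 0)
  (points - pool_mean) / pool_sd
}

#' Expected standardized outcome for a given predictor z-score
#'
#' Regression of the standardized outcome on the standardized predictor:
#' a student `z` SDs from the applicant mean on the predictor is expected
#' `r_att * z` SDs from the mean on the outcome.
#'
#' @param z Predictor z-score(s).
#' @param r_att Attenuated predictor-outcome correlation (|r_att| < 1).
#' @return Expected outcome z-score(s).
#' @export
expected_outcome_z <- function(z, r_att) {
  stopifnot(abs(r_att) < 1)
  r_att * z
}

#' Predicted tail rate (failure or retake) for out-of-range entrants
#'
#' A baseline tail rate in conventional students fixes a cut-off on the
#' standardized outcome scale (`z_cut = qnorm(base_rate)`).  A student at
#' predictor z-score `z` has outcome modeled as normal with mean
#' `r_att * z` and unit SD, so their predicted rate is
#' `pnorm(z_cut - r_att * z)`.  The unit residual SD is the convention
#' adopted throughout; set `conditional_sd = TRUE` for the
#' `sqrt(1 - r_att^2)` residual-SD variant.
#'
#' @param base_rate Baseline tail rate in conventional entrants, in (0, 1).
#' @param z Predictor z-score(s).
#' @param r_att Attenuated predictor-outcome correlation.
#' @param conditional_sd Use the conditional residual SD instead of unit
#'   SD.
#' @return Predicted tail rate(s), as proportions.
#' @examples
#' tail_rate(0.03, predictor_z(18, 29.01, 5.89), 0.659)  # ~.258
#' @export
tail_rate <- function(base_rate, z, r_att, conditional_sd = FALSE) {
  stopifnot(base_rate > 0, base_rate < 1, abs(r_att) < 1)
  z_cut <- qnorm(base_rate)
  s <- if (conditional_sd) sqrt(1 - r_att^2) else 1
  pnorm((z_cut - r_att * z) / s)
}

#' Expected outcome gain per grade-points increment
#'
#' How many outcome SDs a `delta_points` increase on the predictor is
#' worth: `r_att * delta_points / pool_sd`.  Used, e.g., to project the
#' advantage of A* profiles over AAA.
#'
#' @param delta_points Points difference between two grade profiles.
#' @param pool_sd Decensored applicant-pool SD of the predictor.
#' @param r_att Attenuated predictor-outcome correlation.
#' @return Expected gain in outcome SD units.
#' @export
grade_increment_effect <- function(delta_points, pool_sd, r_att) {
  stopifnot(pool_sd > 0)
  r_att * delta_points / pool_sd
}

#' Sample size needed to detect a correlation
#'
#' Fisher-z approximation:
#' `n = ((z_alpha + z_power) / atanh(r))^2 + 3`, with `z_alpha` one- or
#' two-tailed, rounded to the nearest integer.
#'
#' @param r Population correlation to detect, in (0, 1).
#' @param alpha Significance level.
#' @param power Desired power.
#' @param tails 1 or 2.
#' @return Required sample size (integer), with the unrounded value as
#'   attribute `"exact"`.
#' @examples
#' sample_size_for_power(0.171, alpha = 0.05, power = 0.90, tails = 1) # 290
#' @export
sample_size_for_power <- function(r, alpha = 0.05, power = 0.80, tails = 1) {
  stopifnot(r > 0, r < 1, alpha > 0, alpha < 1, power > 0, power < 1,
            tails %in% c(1, 2))
  n <- ((qnorm(1 - alpha / tails) + qnorm(power)) / atanh(r))^2 + 3
  structure(as.integer(round(n)), exact = n)
}

#' Performance predictions for grade profiles
#'
#' The closed-form downstream pipeline in one call: each grade-points
#' total is standardized against the (decensored) applicant pool, the
#' construct-level validity is attenuated by the two reliabilities, and
#' expected outcome z-scores plus tail rates against each baseline
#' cut-off are produced.
#'
#' @param points Named or unnamed numeric vector of tariff points (e.g.
#'   `c(BBB = 24, CCC = 18)`).
#' @param pool_mean,pool_sd Decensored applicant predictor moments.
#' @param rho Construct-level predictive validity.
#' @param r_XX,r_YY Predictor and outcome reliabilities.
#' @param base_rates Named vector of baseline tail rates (proportions),
#'   e.g. `c(fail = 0.03, retake = 0.15)`; may be empty.
#' @param conditional_sd Passed to [tail_rate()].
#' @return Data frame with one row per profile: `points`, `z`,
#'   `outcome_z`, and one rate column (proportion) per baseline.  The
#'   attenuated correlation is attached as attribute `"r_att"`.
#' @examples
#' predict_performance(c(BBB = 24, BBC = 22, BCC = 20, CCC = 18),
#'                     pool_mean = 29.01, pool_sd = 5.89,
#'                     rho = 0.744, r_XX = 0.867, r_YY = 0.904,
#'                     base_rates = c(fail = 0.03, retake = 0.15))
#' @export
predict_performance <- function(points, pool_mean, pool_sd, rho, r_XX, r_YY,
                                base_rates = c(fail = 0.03, retake = 0.15),
                                conditional_sd = FALSE) {
  r_att <- attenuate(rho, r_XX, r_YY)
  z <- predictor_z(points, pool_mean, pool_sd)
  out <- data.frame(profile = if (is.null(names(points)))
    as.character(points) else names(points),
    points = as.numeric(points),
    z = as.numeric(z),
    outcome_z = as.numeric(expected_outcome_z(z, r_att)),
    row.names = NULL)
  for (nm in names(base_rates))
    out[[paste0(nm, "_rate")]] <-
      as.numeric(tail_rate(base_rates[[nm]], z, r_att, conditional_sd))
  attr(out, "r_att") <- r_att
  out
}
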