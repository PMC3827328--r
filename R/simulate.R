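#' Configuration for synthetic selection cohorts
#'
#' Fixes the generative conditions of a simulated selection study: latent
#' true-score pairs with a stated construct correlation, observed scores
#' degraded by the stated reliabilities, indirect top-fraction selection,
#' and right-censorship at an applicant-pool quantile.  Defaults emulate
#' the geometry of large UK selection cohorts: 20,000 applicants, a
#' construct correlation of .65, predictor reliability .815, outcome
#' reliability .834, a quarter of applicants admitted, selection-composite
#' weight .8, and a ceiling at the applicants' 90th percentile.
#'
#' @param n_applicants Number of applicants.
#' @param rho_true Latent construct correlation to be recovered.
#' @param r_XXa Predictor reliability in the unrestricted pool.
#' @param r_YYa Outcome reliability in the unrestricted pool (the
#'   restricted value realized after selection is recorded in the cohort's
#'   `truth`).
#' @param selection_fraction Proportion of applicants admitted.
#' @param indirectness Weight `w` of the selection-relevant signal in the
#'   selection composite; the rest is independent noise.
#' @param ceiling_quantile Applicant-pool quantile at which the observed
#'   predictor is censored; 1 means no ceiling.
#' @param outcome_mode `"continuous"`, `"ordinal"` or `"binary"`.
#' @param cuts Quantile cut-points for binning the entrant outcome
#'   (ordinal/binary modes); defaults to `c(.03, .15, .90)` (four bands)
#'   and `.5` (median split).
#' @param selection_on What the composite's signal term is:
#'   `"true_score"` (default) selects on the predictor's latent true score
#'   plus noise, the indirect-selection structure assumed by the
#'   range-restriction correction; `"observed"` selects on the observed,
#'   error-contaminated predictor, whose `w = 1` limit is classical direct
#'   selection.
#' @param predictor_mean,predictor_sd Location/scale applied to the
#'   observed predictor (points units).
#' @param seed Integer seed; cohorts are bit-reproducible.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_applicants = 20000L, rho_true = 0.65,
                          r_XXa = 0.815, r_YYa = 0.834,
                          selection_fraction = 0.25, indirectness = 0.8,
                          ceiling_quantile = 0.9,
                          outcome_mode = c("continuous", "ordinal", "binary"),
                          cuts = NULL,
                          selection_on = c("true_score", "observed"),
                          predictor_mean = 0, predictor_sd = 1,
                          seed = 1L) {
  outcome_mode <- match.arg(outcome_mode)
  selection_on <- match.arg(selection_on)
  stopifnot(n_applicants >= 1, abs(rho_true) < 1,
            r_XXa > 0, r_XXa <= 1, r_YYa > 0, r_YYa <= 1,
            selection_fraction > 0, selection_fraction <= 1,
            indirectness >= 0, indirectness <= 1,
            ceiling_quantile > 0, ceiling_quantile <= 1,
            predictor_sd > 0)
  if (is.null(cuts))
    cuts <- switch(outcome_mode, continuous = NULL,
                   ordinal = c(0.03, 0.15, 0.90), binary = 0.5)
  if (outcome_mode == "binary" && length(cuts) != 1L)
    stop("binary outcome needs exactly one cut")
  structure(list(n_applicants = as.integer(n_applicants),
                 rho_true = rho_true, r_XXa = r_XXa, r_YYa = r_YYa,
                 selection_fraction = selection_fraction,
                 indirectness = indirectness,
                 ceiling_quantile = ceiling_quantile,
                 outcome_mode = outcome_mode, cuts = cuts,
                 selection_on = selection_on,
                 predictor_mean = predictor_mean,
                 predictor_sd = predictor_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate an applicant pool and a selected, censored entrant cohort
#'
#' Draws latent true-score pairs (T, P) from a bivariate normal with
#' correlation `rho_true`; forms observed scores
#' `X = sqrt(r_XXa) T + sqrt(1 - r_XXa) e` and
#' `Y = sqrt(r_YYa) P + sqrt(1 - r_YYa) e'`; admits the top
#' `selection_fraction` of applicants on the selection composite
#' `S = w * signal + sqrt(1 - w^2) * noise` (signal per `selection_on`);
#' censors the observed predictor at the `ceiling_quantile` point of the
#' applicant distribution; and bins the entrant outcome if requested.
#' The returned `truth` block records the generative values and the
#' realized (empirical) selection ratio, restricted reliabilities, and
#' entrant correlation, so recovery tests have exact targets.
#'
#' @param config A [cohort_config()].
#' @return An object of class `clpv_cohort`: `applicants` (a
#'   [censored_sample()]), `entrants` (data frame `predictor`, `outcome`,
#'   `censored`), `ceiling`, `outcome_spec`, `truth`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_applicants
  a <- sqrt(config$r_XXa); b <- sqrt(1 - config$r_XXa)
  g <- sqrt(config$r_YYa); h <- sqrt(1 - config$r_YYa)
  T_ <- rnorm(n)
  P_ <- config$rho_true * T_ + sqrt(1 - config$rho_true^2) * rnorm(n)
  X <- a * T_ + b * rnorm(n)
  Y <- g * P_ + h * rnorm(n)
  w <- config$indirectness
  signal <- if (config$selection_on == "true_score") T_ else X
  S <- w * signal + sqrt(1 - w^2) * rnorm(n)
  n_ent <- round(config$selection_fraction * n)
  if (n_ent < 50L)
    stop("selection fraction admits fewer than 50 entrants")
  sel <- order(S, decreasing = TRUE)[seq_len(n_ent)]

  # points scale, then ceiling at the applicant-pool quantile
  Xp <- config$predictor_mean + config$predictor_sd * X
  ceiling_pt <- if (config$ceiling_quantile >= 1) Inf else
    unname(quantile(Xp, config$ceiling_quantile))
  X_obs <- pmin(Xp, ceiling_pt)
  cens <- Xp >= ceiling_pt

  y_ent <- Y[sel]
  ospec <- outcome_spec("continuous")
  outcome <- y_ent
  if (config$outcome_mode != "continuous") {
    outcome <- bin_outcome(y_ent, config$cuts)
    ospec <- outcome_spec(if (config$outcome_mode == "binary") "binary"
                          else "ordinal",
                          thresholds = attr(outcome, "thresholds"))
  }

  truth <- list(
    rho_true = config$rho_true,
    mu_a = mean(Xp), sigma_a = sd(Xp),
    mu_i = mean(Xp[sel]), sigma_i = sd(Xp[sel]),
    mu_y = mean(y_ent), sigma_y = sd(y_ent),
    u = sd(Xp[sel]) / sd(Xp),                    # decensored (pre-ceiling) SDs
    r_XXi = cor(X[sel], T_[sel])^2,
    r_YYi = cor(y_ent, P_[sel])^2,
    r_i = cor(X[sel], y_ent),
    ceiling = ceiling_pt,
    prop_censored_entrants = mean(cens[sel]))

  structure(list(
    applicants = censored_sample(X_obs, ceiling = ceiling_pt),
    entrants = data.frame(predictor = X_obs[sel], outcome = outcome,
                          censored = cens[sel]),
    ceiling = ceiling_pt, outcome_spec = ospec,
    truth = truth, config = config),
    class = "clpv_cohort")
}

#' @export
print.clpv_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d applicants, %d entrants (%s outcome)\n",
              length(x$applicants$values), nrow(x$entrants),
              x$config$outcome_mode))
  cat(sprintf("  rho_true = %s, realized u = %s, ceiling = %s (%.0f%% of entrants at ceiling)\n",
              .fmt(x$truth$rho_true), .fmt(x$truth$u),
              if (is.finite(x$ceiling)) .fmt(x$ceiling, 2) else "none",
              100 * x$truth$prop_censored_entrants))
  invisible(x)
}

#' Bin a continuous outcome into ordinal categories by quantile cuts
#'
#' @param y Continuous outcome values.
#' @param cuts Strictly increasing quantile cut-points in (0, 1); a single
#'   cut of .5 gives a median split (binary).
#' @return Integer category labels (1 = lowest), with the latent
#'   standard-normal `"thresholds"` implied by the realized bin
#'   proportions as an attribute.
#' @export
bin_outcome <- function(y, cuts) {
  stopifnot(all(cuts > 0), all(cuts < 1))
  if (any(diff(cuts) <= 0)) stop("cuts must be strictly increasing")
  brk <- c(-Inf, unname(quantile(y, cuts)), Inf)
  if (any(duplicated(brk))) stop("quantile cuts produce an empty bin")
  j <- as.integer(cut(y, breaks = brk, labels = FALSE))
  counts <- tabulate(j, nbins = length(cuts) + 1L)
  if (any(counts == 0)) stop("empty outcome bin")
  structure(j, thresholds = ordinal_thresholds(counts))
}
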