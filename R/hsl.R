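#' Default reliabilities and selection ratios
#'
#' Field averages used when study-specific values are unavailable:
#' predictor reliability .815 in the applicant pool and outcome
#' reliability .834 in entrants; median selection ratios .664 for
#' A-levels, .690 for GCSEs/O-levels and .750 for aptitude tests.  Callers
#' should log whenever a default stands in for a measured value.
#'
#' @param predictor_class For `default_selection_ratio()`: one of
#'   `"A-levels"`, `"GCSEs/O-levels"`, `"aptitude"`.
#' @return `default_reliability()` returns a named vector
#'   (`predictor`, `outcome`); `default_selection_ratio()` a single ratio.
#' @export
default_reliability <- function() c(predictor = 0.815, outcome = 0.834)

#' @rdname default_reliability
#' @export
default_selection_ratio <- function(predictor_class = c("A-levels",
                                                        "GCSEs/O-levels",
                                                        "aptitude")) {
  predictor_class <- match.arg(predictor_class)
  c("A-levels" = 0.664, "GCSEs/O-levels" = 0.690,
    "aptitude" = 0.750)[[predictor_class]]
}

#' Selection ratio
#'
#' The SD of the predictor in entrants as a proportion of its SD in all
#' applicants; smaller values mean stronger selection.  When the predictor
#' is censored, both SDs must be the decensored (latent) SDs, since
#' censorship shrinks observed SDs.
#'
#' @param sd_entrants,sd_applicants Positive predictor SDs.
#' @return The ratio `u` (numeric).  Values above 1 are allowed but warn,
#'   since selection is expected to reduce spread.
#' @export
selection_ratio <- function(sd_entrants, sd_applicants) {
  if (!is.finite(sd_entrants) || sd_entrants <= 0 ||
      !is.finite(sd_applicants) || sd_applicants <= 0)
    stop("selection ratio needs positive SDs")
  u <- sd_entrants / sd_applicants
  if (u > 1)
    warning("selection ratio exceeds 1 (entrants more variable than applicants)")
  u
}

#' Reliability of the predictor within the restricted (entrant) group
#'
#' Range restriction lowers reliability: assuming constant error variance,
#' the entrant-group reliability is `1 - (1 - r_XXa) / u^2`.  Requires
#' `u^2 > 1 - r_XXa`, otherwise the implied true-score variance in
#' entrants is non-positive.
#'
#' @param r_XXa Predictor reliability in the unrestricted applicant pool,
#'   in (0, 1].
#' @param u Selection ratio.
#' @return Restricted reliability `r_XXi`; warns when the result is
#'   near-degenerate (below .1).
#' @export
restrict_reliability <- function(r_XXa, u) {
  stopifnot(r_XXa > 0, r_XXa <= 1, u > 0)
  if (u^2 <= 1 - r_XXa)
    stop("u^2 = ", signif(u^2, 4), " does not exceed 1 - r_XXa = ",
         signif(1 - r_XXa, 4),
         ": true-score variance in entrants would be <= 0")
  r <- 1 - (1 - r_XXa) / u^2
  if (r < 0.1)
    warning("restricted reliability ", signif(r, 3),
            " is near-degenerate; correction will be unstable")
  r
}

# vectorized correction core used for per-draw propagation; returns NA for
# draws violating preconditions and clips out-of-range outputs to (-1, 1)
.hsl_core <- function(r_i, r_XXa, r_YYi, u) {
  bad <- !is.finite(r_i) | abs(r_i) >= 1 | u <= 0 | u^2 <= (1 - r_XXa)
  u2 <- ifelse(bad, NA_real_, u^2)
  r_XXi <- 1 - (1 - r_XXa) / u2
  u_T <- sqrt((u2 - (1 - r_XXa)) / r_XXa)
  r_TPi <- r_i / sqrt(r_XXi * r_YYi)
  bad <- bad | !is.finite(r_TPi) | abs(r_TPi) >= 1
  r_TPi[bad] <- NA_real_
  rho <- (r_TPi / u_T) / sqrt(1 + r_TPi^2 * (1 / u_T^2 - 1))
  clipped <- !is.na(rho) & abs(rho) >= 1
  rho[clipped] <- sign(rho[clipped]) * (1 - 1e-12)
  list(rho = rho, rejected = bad, clipped = clipped)
}

#' Hunter-Schmidt-Le correction for indirect range restriction
#'
#' Converts the observed entrant predictor-outcome correlation into the
#' construct-level (true-score) correlation in the applicant pool, in four
#' steps: restrict the predictor reliability to the entrant group, derive
#' the true-score selection ratio
#' `u_T = sqrt((u^2 - (1 - r_XXa)) / r_XXa)`, disattenuate the entrant
#' correlation for both reliabilities, and reverse the range restriction
#' on the true score.  When both reliabilities and the selection ratio are
#' 1 the output equals the input correlation, and the correction can only
#' raise (never lower) the magnitude for valid inputs.
#'
#' @param r_i Observed predictor-outcome correlation in entrants
#'   (|r_i| < 1).
#' @param r_XXa Predictor reliability in applicants, in (0, 1].
#' @param r_YYi Outcome reliability in entrants, in (0, 1].
#' @param u Selection ratio (decensored SDs).
#' @return The construct-level predictive validity `rho`, clipped into
#'   (-1, 1) with a warning if the correction overshoots.
#' @examples
#' hsl_case_iv(0.2, 0.8, 0.84, 0.656)  # ~= .503
#' @export
hsl_case_iv <- function(r_i, r_XXa, r_YYi, u) {
  stopifnot(length(r_i) == 1L, r_XXa > 0, r_XXa <= 1, r_YYi > 0, r_YYi <= 1)
  if (abs(r_i) >= 1) stop("|r_i| must be < 1")
  if (u^2 <= 1 - r_XXa)
    stop("u^2 = ", signif(u^2, 4), " does not exceed 1 - r_XXa = ",
         signif(1 - r_XXa, 4), ": correction undefined")
  res <- .hsl_core(r_i, r_XXa, r_YYi, u)
  if (res$rejected)
    stop("disattenuated entrant correlation |r_TPi| >= 1: ",
         "inputs are mutually inconsistent")
  if (res$clipped)
    warning("corrected correlation fell outside (-1, 1); clipped")
  unname(res$rho)
}

#' Propagate the correction through a chain of posterior draws
#'
#' For every retained draw, the selection ratio is computed from that
#' draw's entrant and applicant (decensored) predictor SDs and the
#' Hunter-Schmidt-Le correction applied to that draw's entrant
#' correlation.  The mean of the per-draw corrected values is the
#' construct-level predictive validity, their SD its standard error, and
#' the 2.5th/97.5th percentiles its interval; the equivalent sample size
#' is back-calculated from the standard error.
#'
#' @param chain A `clpv_chain` with (at least) columns `sigma_a`,
#'   `sigma_i`, `r_i`, or a matrix of retained draws with those columns.
#' @param reliability Named vector with elements `predictor` (`r_XXa`) and
#'   `outcome` (`r_YYi`).
#' @param use_last Retained segment length; defaults to the chain config.
#' @return An object of class `clpv_estimate`: `rho`, `se`, `ci`,
#'   `equivalent_n`, draw diagnostics (`n_draws`, `n_rejected`,
#'   `n_clipped`), and `unreliable` (`TRUE` when more than 5\% of draws
#'   violated the correction's preconditions).
#' @export
clpv_with_uncertainty <- function(chain, reliability = default_reliability(),
                                  use_last = NULL) {
  draws <- if (inherits(chain, "clpv_chain")) {
    if (is.null(use_last)) use_last <- chain$config$use_last
    chain$draws
  } else as.matrix(chain)
  if (is.null(use_last)) use_last <- nrow(draws)
  need <- c("sigma_a", "sigma_i", "r_i")
  if (!all(need %in% colnames(draws)))
    stop("chain draws must have columns ", paste(need, collapse = ", "))
  keep <- draws[seq(nrow(draws) - use_last + 1L, nrow(draws)), , drop = FALSE]
  u <- keep[, "sigma_i"] / keep[, "sigma_a"]
  res <- .hsl_core(keep[, "r_i"], reliability[["predictor"]],
                   reliability[["outcome"]], u)
  rho <- res$rho[!res$rejected]
  n_rej <- sum(res$rejected)
  if (length(rho) == 0L) stop("every draw violated the correction preconditions")
  est <- mean(rho)
  se <- sd(rho)
  eq_n <- if (se > 0) equivalent_n(est, se) else
    structure(NA_real_, rounded = NA_real_, flagged = TRUE)
  structure(list(rho = est, se = se,
                 ci = c(lower = unname(quantile(rho, 0.025)),
                        upper = unname(quantile(rho, 0.975))),
                 equivalent_n = eq_n,
                 u = mean(u), reliability = reliability,
                 n_draws = length(res$rho), n_rejected = n_rej,
                 n_clipped = sum(res$clipped),
                 unreliable = n_rej / length(res$rho) > 0.05),
            class = "clpv_estimate")
}

#' @export
print.clpv_estimate <- function(x, ...) {
  cat("Construct-level predictive validity\n")
  cat(sprintf("  rho = %s (SE %s), 95%% CI [%s, %s]\n",
              .fmt(x$rho), .fmt(x$se), .fmt(x$ci[1]), .fmt(x$ci[2])))
  cat(sprintf("  equivalent N = %s, mean selection ratio u = %s\n",
              format(attr(x$equivalent_n, "rounded")), .fmt(x$u)))
  if (isTRUE(x$unreliable))
    cat("  WARNING: >5% of draws rejected by correction preconditions\n")
  invisible(x)
}

#' Equivalent sample size for a corrected correlation
#'
#' Inverts the standard error formula of a correlation,
#' `SE(r) = (1 - r^2) / sqrt(n - 1)`, to find the sample size that would
#' give a plain correlation the same standard error as the chain-derived
#' estimate: `n = ((1 - rho^2) / se)^2 + 1`.
#'
#' @param rho Corrected correlation (|rho| < 1).
#' @param se Its standard error (> 0).
#' @return The equivalent n (numeric), with attributes `"rounded"` and
#'   `"flagged"` (`TRUE` when the implied n falls below 4).
#' @examples
#' equivalent_n(0, 0.1)  # 101
#' @export
equivalent_n <- function(rho, se) {
  stopifnot(se > 0, abs(rho) < 1)
  n <- ((1 - rho^2) / se)^2 + 1
  structure(n, rounded = round(n), flagged = n < 4)
}
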