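#' Random-effects pooling of validity coefficients
#'
#' Pools correlation-type effects (observed correlations or corrected
#' construct-level validities) across studies.  The default route
#' transforms to Fisher z with within-study variance `1/(n - 3)` — for
#' corrected validities `n` is the equivalent N back-calculated from the
#' chain standard error — estimates the between-study variance by the
#' DerSimonian-Laird method-of-moments, and inverse-variance weights with
#' `1/(1/(n - 3) + tau^2)`; the pooled mean and CI are back-transformed to
#' the correlation scale.  Alternatively, study variances can be supplied
#' directly as z-scale standard errors (`sei`) or derived from printed
#' confidence intervals (`ci_lo`/`ci_hi`).  A bare-bones Hunter-Schmidt
#' raw-r mode (`method = "raw-r"`, n-weighted, no transform) is available
#' for sensitivity analysis.
#'
#' @param r Correlations, |r| < 1.
#' @param n Study sample sizes (actual or equivalent); each must exceed 3.
#' @param sei Optional Fisher-z scale standard errors (overrides `n`).
#' @param ci_lo,ci_hi Optional 95\% CI bounds on the r scale, converted to
#'   z-scale variances (override `n`).
#' @param labels Optional study labels for error messages.
#' @param method `"fisher-z"` (default) or `"raw-r"`.
#' @return An object of class `clpv_meta`: pooled estimate with CI on the
#'   r scale, `tau2`, residual heterogeneity `Q_E` with df and p, study
#'   count `k`, and the underlying [metafor::rma()] fit (Fisher-z route).
#' @export
pool_random_effects <- function(r, n = NULL, sei = NULL,
                                ci_lo = NULL, ci_hi = NULL,
                                labels = NULL,
                                method = c("fisher-z", "raw-r")) {
  method <- match.arg(method)
  k <- length(r)
  stopifnot(k >= 1, all(abs(r) < 1))
  if (is.null(labels)) labels <- paste0("study", seq_len(k))
  if (method == "raw-r") {
    stopifnot(!is.null(n))
    wm <- sum(n * r) / sum(n)
    var_obs <- sum(n * (r - wm)^2) / sum(n)
    var_err <- sum(n * ((1 - wm^2)^2 / (n - 1))) / sum(n)
    return(structure(list(estimate = wm, ci = c(NA_real_, NA_real_),
                          tau2 = max(var_obs - var_err, 0),
                          Q_E = NA_real_, df_E = NA_integer_,
                          p_E = NA_real_, k = k, method = method,
                          rma = NULL),
                     class = "clpv_meta"))
  }
  yi <- atanh(r)
  vi <- .meta_vi(r, n, sei, ci_lo, ci_hi, labels)
  if (k == 1L) {
    return(structure(list(estimate = r, ci = tanh(yi + c(-1, 1) * 1.96 * sqrt(vi)),
                          tau2 = 0, Q_E = 0, df_E = 0L, p_E = NA_real_,
                          k = 1L, method = method, rma = NULL),
                     class = "clpv_meta"))
  }
  fit <- metafor::rma(yi = yi, vi = vi, method = "DL")
  structure(list(estimate = tanh(as.numeric(fit$beta)),
                 ci = c(tanh(fit$ci.lb), tanh(fit$ci.ub)),
                 tau2 = fit$tau2,
                 Q_E = fit$QE, df_E = fit$k - fit$p, p_E = fit$QEp,
                 k = fit$k, method = method, rma = fit),
            class = "clpv_meta")
}

.meta_vi <- function(r, n, sei, ci_lo, ci_hi, labels) {
  if (!is.null(sei)) return(sei^2)
  if (!is.null(ci_lo) && !is.null(ci_hi))
    return(((atanh(ci_hi) - atanh(ci_lo)) / (2 * qnorm(0.975)))^2)
  if (is.null(n)) stop("supply n, sei, or ci_lo/ci_hi")
  if (any(n <= 3))
    stop("sample size must exceed 3; offending: ",
         paste(labels[n <= 3], collapse = ", "))
  1 / (n - 3)
}

#' Random-effects meta-regression of validities on moderators
#'
#' Weighted least squares of Fisher-z effects on study moderators with
#' random-effects (DerSimonian-Laird) weights.  Categorical moderators
#' (predictor class, outcome stage, cohort) enter as factors; continuous
#' moderators such as year of entry or year of training enter linearly;
#' interactions are supported through the formula.  `Q_B` is the chi-square
#' omnibus test that all non-intercept coefficients are zero (df = their
#' number); `Q_E` is residual heterogeneity.
#'
#' @param formula Moderator formula, e.g. `~ predictor_class +
#'   year_of_training`; `~ 1` reproduces [pool_random_effects()].
#' @param data Data frame with a correlation column `r`, a size column
#'   `n` (or `sei`, or `ci_lo`/`ci_hi`), and the moderators.
#' @param method Passed to [metafor::rma()]; default `"DL"`.
#' @return A `clpv_meta` with, additionally, the coefficient table
#'   (`coefficients`, z-scale), `Q_B`, `df_B` and `p_B`.
#' @export
meta_regress <- function(formula, data, method = "DL") {
  stopifnot("r" %in% names(data))
  labels <- if (!is.null(rownames(data))) rownames(data) else
    paste0("study", seq_len(nrow(data)))
  yi <- atanh(data$r)
  vi <- .meta_vi(data$r, data[["n"]], data[["sei"]],
                 data[["ci_lo"]], data[["ci_hi"]], labels)
  mm <- model.matrix(formula, data)
  if (qr(mm)$rank < ncol(mm)) {
    qrm <- qr(mm)
    aliased <- colnames(mm)[setdiff(seq_len(ncol(mm)),
                                    qrm$pivot[seq_len(qrm$rank)])]
    stop("moderator design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  fit <- metafor::rma(yi = yi, vi = vi, mods = formula, data = data,
                      method = method)
  cf <- data.frame(estimate = as.numeric(fit$beta), se = fit$se,
                   zval = fit$zval, pval = fit$pval,
                   row.names = rownames(fit$beta))
  intercept_only <- fit$int.only
  structure(list(estimate = if (intercept_only) tanh(as.numeric(fit$beta))
                 else NA_real_,
                 ci = if (intercept_only) c(tanh(fit$ci.lb[1]),
                                            tanh(fit$ci.ub[1]))
                 else c(NA_real_, NA_real_),
                 coefficients = cf,
                 tau2 = fit$tau2,
                 Q_B = if (intercept_only) NA_real_ else fit$QM,
                 df_B = if (intercept_only) NA_integer_ else fit$m,
                 p_B = if (intercept_only) NA_real_ else fit$QMp,
                 Q_E = fit$QE, df_E = fit$k - fit$p, p_E = fit$QEp,
                 k = fit$k, method = "fisher-z", rma = fit),
            class = "clpv_meta")
}

#' @export
print.clpv_meta <- function(x, ...) {
  cat("Random-effects pooling of validity coefficients",
      sprintf("(%s)\n", x$method))
  if (!is.na(x$estimate))
    cat(sprintf("  pooled r = %s, n = %d studies, CI [%s, %s]\n",
                .fmt(x$estimate), x$k,
                .fmt(x$ci[1]), .fmt(x$ci[2])))
  cat(sprintf("  tau^2 = %s", .fmt(x$tau2, 4)))
  if (!is.na(x$Q_E) && length(x$df_E) && !is.na(x$df_E))
    cat(sprintf(";  Q_E = %.2f (%d df)", x$Q_E, x$df_E))
  cat("\n")
  if (!is.null(x$Q_B) && !is.na(x$Q_B)) {
    cat(sprintf("  moderators: Q_B = %.2f (%d df), p = %.4g\n",
                x$Q_B, x$df_B, x$p_B))
    print(round(x$coefficients, 4))
  }
  invisible(x)
}

#' Standard coding of outcome stage as years of training
#'
#' Maps the named outcome stages onto a continuous year-of-training scale
#' (first-year basic medical sciences = 1, overall BMS = 2, finals = 5,
#' the three MRCP(UK) parts = 8, 9, 10, Specialist Register = 12).
#'
#' @param stage Character vector of stage labels: `"BMS1"`,
#'   `"BMSoverall"`, `"Finals"`, `"MRCP1"`, `"MRCP2"`, `"MRCPclinical"`,
#'   `"SpecialistRegister"`.
#' @return Numeric years of training.
#' @export
year_of_training <- function(stage) {
  map <- c(BMS1 = 1, BMSoverall = 2, Finals = 5, MRCP1 = 8, MRCP2 = 9,
           MRCPclinical = 10, SpecialistRegister = 12)
  bad <- setdiff(unique(stage), names(map))
  if (length(bad)) stop("unknown outcome stage(s): ",
                        paste(bad, collapse = ", "))
  unname(map[stage])
}
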