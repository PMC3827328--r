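#' Right-censored samples
#'
#' Container for scores observed with a known ceiling: values at the
#' ceiling are recorded as censored ("at least this much"), as happens when
#' grade inflation piles candidates up at the maximum attainable points.
#' Ties at the ceiling define censorship: any value `>= ceiling` is flagged
#' and stored as exactly the ceiling.
#'
#' @param values Numeric scores.
#' @param ceiling The censoring point `c` (same units as `values`); `Inf`
#'   means no censoring.
#' @param censored Optional logical flags; defaults to `values >= ceiling`.
#' @return An object of class `censored_sample` with elements `values`,
#'   `censored` and `ceiling`.
#' @export
censored_sample <- function(values, ceiling = Inf, censored = NULL) {
  stopifnot(is.numeric(values), length(ceiling) == 1L)
  if (any(values > ceiling))
    stop("values exceed the ceiling: data inconsistent with censoring at c = ",
         ceiling)
  if (is.null(censored)) censored <- values >= ceiling
  stopifnot(length(censored) == length(values))
  if (any(censored & values != ceiling))
    stop("every censored value must equal the ceiling")
  structure(list(values = as.numeric(values),
                 censored = as.logical(censored),
                 ceiling = as.numeric(ceiling)),
            class = "censored_sample")
}

#' @export
print.censored_sample <- function(x, ...) {
  cat(sprintf("Censored sample: n = %d, %d at ceiling (c = %g)\n",
              length(x$values), sum(x$censored), x$ceiling))
  invisible(x)
}

#' Log-likelihood of a right-censored normal (Tobit) sample
#'
#' Uncensored points contribute the normal density; points at the ceiling
#' contribute the upper-tail probability beyond `c`.
#'
#' @param mu,sigma Latent normal mean and SD (`sigma > 0`).
#' @param sample A [censored_sample()].
#' @return The exact Tobit log-likelihood (scalar).
#' @export
loglik_censored_normal <- function(mu, sigma, sample) {
  stopifnot(inherits(sample, "censored_sample"))
  if (!is.finite(mu) || !is.finite(sigma) || sigma <= 0) return(-Inf)
  x <- sample$values[!sample$censored]
  n_c <- sum(sample$censored)
  ll <- sum(dnorm(x, mu, sigma, log = TRUE))
  if (n_c > 0)
    ll <- ll + n_c * pnorm(sample$ceiling, mu, sigma,
                           lower.tail = FALSE, log.p = TRUE)
  ll
}

# sufficient statistics form, used by the samplers: same value as
# loglik_censored_normal but O(1) in the number of uncensored points
.tobit_stats <- function(sample) {
  x <- sample$values[!sample$censored]
  list(n_u = length(x), sx = sum(x), sxx = sum(x^2),
       n_c = sum(sample$censored), c = sample$ceiling)
}
.tobit_loglik <- function(mu, sigma, st) {
  if (!is.finite(sigma) || sigma <= 0) return(-Inf)
  ss <- st$sxx - 2 * mu * st$sx + st$n_u * mu^2
  ll <- -st$n_u * (log(sigma) + 0.5 * log(2 * pi)) - ss / (2 * sigma^2)
  if (st$n_c > 0)
    ll <- ll + st$n_c * pnorm(st$c, mu, sigma, lower.tail = FALSE, log.p = TRUE)
  ll
}

#' Maximum-likelihood fit of a right-censored normal
#'
#' Recovers the latent ("decensored") mean and SD that generated a sample
#' observed with a ceiling.  With no censored observations this reduces to
#' the closed-form normal MLE (mean and the n-divisor SD).
#'
#' @param sample A [censored_sample()] with at least 10 uncensored values
#'   and at most 95\% censored.
#' @return A list of class `clpv_fit` with `params` (named: `mu`, `sigma`),
#'   `loglik`, `converged` and `n_used`.
#' @export
fit_censored_normal <- function(sample) {
  stopifnot(inherits(sample, "censored_sample"))
  n <- length(sample$values)
  n_c <- sum(sample$censored)
  if (n - n_c < 10L)
    stop("need at least 10 uncensored observations")
  if (n_c / n > 0.95)
    stop("more than 95% of observations censored: latent parameters not identifiable")
  if (n_c == 0L) {
    mu <- mean(sample$values)
    sigma <- sqrt(mean((sample$values - mu)^2))
    return(structure(list(params = c(mu = mu, sigma = sigma),
                          loglik = loglik_censored_normal(mu, sigma, sample),
                          converged = TRUE, n_used = n),
                     class = "clpv_fit"))
  }
  st <- .tobit_stats(sample)
  x_u <- sample$values[!sample$censored]
  start <- c(mean(x_u), log(sd(x_u)))
  negll <- function(par) -.tobit_loglik(par[1], exp(par[2]), st)
  opt <- optim(start, negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  mu <- opt$par[1]; sigma <- exp(opt$par[2])
  structure(list(params = c(mu = mu, sigma = sigma),
                 loglik = -opt$value,
                 converged = opt$convergence == 0,
                 n_used = n),
            class = "clpv_fit")
}

#' @export
print.clpv_fit <- function(x, ...) {
  cat("Model fit", if (!x$converged) "(NOT converged)", "\n")
  print(round(x$params, 4))
  cat("log-likelihood:", format(x$loglik), " n =", x$n_used, "\n")
  invisible(x)
}

#' Latent thresholds for an ordinal outcome
#'
#' Fixes the cut-points of a latent standard-normal outcome from the
#' marginal category frequencies, as in two-step polychoric/tetrachoric
#' estimation: the j-th threshold is the standard-normal quantile of the
#' cumulative proportion through category j.
#'
#' @param category_counts Counts per ordered category (at least 2
#'   categories, all non-empty).
#' @return Numeric vector of `length(category_counts) - 1` strictly
#'   increasing thresholds.
#' @examples
#' ordinal_thresholds(c(25, 25, 25, 25)) # standard-normal quartiles
#' @export
ordinal_thresholds <- function(category_counts) {
  k <- length(category_counts)
  if (k < 2L) stop("need at least 2 categories")
  if (any(category_counts == 0))
    stop("empty category: thresholds not identifiable")
  p <- cumsum(category_counts) / sum(category_counts)
  qnorm(p[-k])
}

#' Outcome specification
#'
#' Describes the outcome scale of the entrant data: continuous, ordinal or
#' binary (binary is ordinal with two categories).  For ordinal/binary
#' outcomes the latent outcome is standard normal and `thresholds` are the
#' cut-points on that scale, usually from [ordinal_thresholds()].
#'
#' @param kind `"continuous"`, `"ordinal"` or `"binary"`.
#' @param categories Ordered category labels (ordinal/binary only).
#' @param thresholds Strictly increasing cut-points, one fewer than the
#'   number of categories.
#' @return An object of class `outcome_spec`.
#' @export
outcome_spec <- function(kind = c("continuous", "ordinal", "binary"),
                         categories = NULL, thresholds = NULL) {
  kind <- match.arg(kind)
  if (kind != "continuous") {
    if (is.null(thresholds))
      stop("ordinal/binary outcomes need thresholds")
    if (any(diff(thresholds) <= 0))
      stop("thresholds must be strictly increasing")
    if (is.null(categories))
      categories <- as.character(seq_len(length(thresholds) + 1L))
    if (length(categories) != length(thresholds) + 1L)
      stop("need one more category than thresholds")
    if (kind == "binary" && length(categories) != 2L)
      stop("binary outcome must have exactly 2 categories")
  }
  structure(list(kind = kind, categories = categories,
                 thresholds = thresholds),
            class = "outcome_spec")
}
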