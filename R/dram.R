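#' Chain configuration for the DRAM sampler
#'
#' Conventions follow common practice for this model family: chains of
#' 5,000 (or 10,000) iterations with summaries taken from the final 2,000;
#' burn-in is therefore `length - use_last` exactly, not a separate knob.
#'
#' @param length Total chain length (at least 1,000).
#' @param use_last Number of final iterations used for summaries
#'   (strictly less than `length`).
#' @param seed Integer seed; the chain is bit-reproducible given
#'   `seed` + config + data.
#' @param adapt_interval Iterations between proposal-covariance
#'   adaptations.
#' @param adapt_start First iteration at which adaptation may occur.
#' @param dr_shrink Proposal-SD shrink factor for the delayed-rejection
#'   second stage.
#' @param scale Proposal scaling applied to the empirical covariance;
#'   default is the standard 2.38^2/d random-walk optimum.
#' @return A list of class `chain_control`.
#' @export
chain_control <- function(length = 5000L, use_last = 2000L, seed = 1L,
                          adapt_interval = 100L, adapt_start = 200L,
                          dr_shrink = 5, scale = NULL) {
  stopifnot(length >= 1000L, use_last >= 1L, use_last < length,
            adapt_interval >= 1L, dr_shrink > 1)
  structure(list(length = as.integer(length), use_last = as.integer(use_last),
                 seed = as.integer(seed),
                 adapt_interval = as.integer(adapt_interval),
                 adapt_start = as.integer(adapt_start),
                 dr_shrink = dr_shrink, scale = scale),
            class = "chain_control")
}

#' Delayed-rejection adaptive Metropolis (DRAM) sampler
#'
#' Random-walk Metropolis with two DRAM ingredients: the proposal
#' covariance is re-estimated from the chain history every
#' `adapt_interval` iterations (adaptive Metropolis), and each rejected
#' first-stage proposal triggers one delayed-rejection retry from a
#' shrunken proposal, accepted with the two-stage probability that
#' preserves the target distribution.
#'
#' @param logpost Function taking a numeric parameter vector and returning
#'   the log posterior density (may return `-Inf`).
#' @param init Numeric start vector; `logpost(init)` must be finite (use
#'   the MLE initializer if it is not).
#' @param config A [chain_control()].
#' @param proposal_sd Optional vector of initial proposal SDs (one per
#'   parameter) or a full initial proposal covariance matrix; defaults to
#'   5\% of `max(|init|, 0.5)`.
#' @return An object of class `clpv_chain`: `draws` (length x d matrix),
#'   `logpost` per draw, `acceptance` (first-stage acceptance rate, the
#'   usual random-walk diagnostic), `acceptance_total` (including
#'   delayed-rejection accepts), and the `config`.
#' @examples
#' ch <- run_dram(function(th) -sum(th^2) / 2, c(0, 0),
#'                chain_control(length = 1000, use_last = 500, seed = 1))
#' colMeans(ch$draws)
#' @export
run_dram <- function(logpost, init, config = chain_control(),
                     proposal_sd = NULL) {
  stopifnot(inherits(config, "chain_control"))
  d <- length(init)
  lp0 <- logpost(init)
  if (!is.finite(lp0))
    stop("log posterior is not finite at the initial value; ",
         "initialize at the maximum-likelihood fit")
  set.seed(config$seed)
  sc <- if (is.null(config$scale)) 2.38^2 / d else config$scale
  if (is.null(proposal_sd)) proposal_sd <- 0.05 * pmax(abs(init), 0.5)
  cov_prop <- if (is.matrix(proposal_sd)) proposal_sd else
    diag(proposal_sd^2, d)
  L <- chol(cov_prop)                      # upper-triangular factor
  gam <- config$dr_shrink
  draws <- matrix(NA_real_, config$length, d)
  if (!is.null(names(init))) colnames(draws) <- names(init)
  lps <- numeric(config$length)
  x <- as.numeric(init); lpx <- lp0
  n_acc <- 0L; n_acc_dr <- 0L
  eps <- 1e-10
  qf <- function(dvec) {                   # d' C^{-1} d via the factor
    z <- backsolve(L, dvec, transpose = TRUE)
    sum(z^2)
  }
  for (i in seq_len(config$length)) {
    z1 <- rnorm(d)
    y1 <- x + drop(crossprod(L, z1))
    lpy1 <- logpost(y1)
    a1 <- if (is.finite(lpy1)) min(1, exp(lpy1 - lpx)) else 0
    if (runif(1) < a1) {
      x <- y1; lpx <- lpy1; n_acc <- n_acc + 1L
    } else {
      # delayed rejection: narrower proposal, two-stage acceptance
      z2 <- rnorm(d)
      y2 <- x + drop(crossprod(L, z2)) / gam
      lpy2 <- logpost(y2)
      if (is.finite(lpy2)) {
        a1_rev <- if (is.finite(lpy1)) min(1, exp(lpy1 - lpy2)) else 0
        if (a1_rev < 1 && a1 < 1) {
          log_num <- lpy2 - 0.5 * qf(y1 - y2) + log1p(-a1_rev)
          log_den <- lpx - 0.5 * qf(y1 - x) + log1p(-a1)
          if (log(runif(1)) < log_num - log_den) {
            x <- y2; lpx <- lpy2; n_acc_dr <- n_acc_dr + 1L
          }
        }
      }
    }
    draws[i, ] <- x
    lps[i] <- lpx
    if (i >= config$adapt_start && i %% config$adapt_interval == 0L) {
      ch_cov <- cov(draws[seq_len(i), , drop = FALSE])
      cov_prop <- sc * (ch_cov + eps * diag(d))
      Lnew <- tryCatch(chol(cov_prop), error = function(e) NULL)
      if (!is.null(Lnew)) L <- Lnew
    }
  }
  structure(list(draws = draws, logpost = lps,
                 acceptance = n_acc / config$length,
                 acceptance_total = (n_acc + n_acc_dr) / config$length,
                 config = config),
            class = "clpv_chain")
}

#' @export
print.clpv_chain <- function(x, ...) {
  cat(sprintf(
    "DRAM chain: %d draws x %d parameters, acceptance %.2f (%.2f with DR)\n",
    nrow(x$draws), ncol(x$draws), x$acceptance, x$acceptance_total))
  invisible(x)
}

#' Summarize the retained segment of a chain
#'
#' Summaries use exactly the final `use_last` draws (earlier draws are
#' burn-in): per-parameter posterior mean (the estimate), SD (the standard
#' error), and 2.5th/97.5th percentiles (the 95\% interval).  As an
#' automated stand-in for a visual equilibrium check, each retained
#' parameter trace is regressed on iteration number; a slope significant at
#' p < .01 flags the parameter as possibly non-equilibrated (with a
#' warning).
#'
#' @param chain A `clpv_chain` (or any matrix of draws).
#' @param config A [chain_control()]; defaults to the chain's own.
#' @return A data frame of class `clpv_chain_summary` with columns `mean`,
#'   `se`, `ci_lo`, `ci_hi`, `equilibrium`, plus attribute
#'   `"nonequilibrium"` naming flagged parameters.
#' @export
summarize_chain <- function(chain, config = NULL) {
  draws <- if (inherits(chain, "clpv_chain")) chain$draws else as.matrix(chain)
  if (is.null(config) && inherits(chain, "clpv_chain")) config <- chain$config
  if (is.null(config)) stop("a chain_control is required")
  if (config$use_last > nrow(draws))
    stop("use_last (", config$use_last, ") exceeds chain length (",
         nrow(draws), ")")
  keep <- draws[seq(nrow(draws) - config$use_last + 1L, nrow(draws)), ,
                drop = FALSE]
  if (is.null(colnames(keep)))
    colnames(keep) <- paste0("par", seq_len(ncol(keep)))
  idx <- seq_len(nrow(keep))
  stats <- lapply(seq_len(ncol(keep)), function(j) {
    v <- keep[, j]
    ok <- TRUE
    if (sd(v) > 0) {
      fit <- summary(lm(v ~ idx))$coefficients
      ok <- !(nrow(fit) > 1 && fit[2, 4] < 0.01)
    }
    c(mean = mean(v), se = sd(v),
      ci_lo = unname(quantile(v, 0.025)), ci_hi = unname(quantile(v, 0.975)),
      equilibrium = as.numeric(ok))
  })
  out <- as.data.frame(do.call(rbind, stats))
  rownames(out) <- colnames(keep)
  out$equilibrium <- out$equilibrium > 0
  bad <- rownames(out)[!out$equilibrium]
  if (length(bad))
    warning("possible non-equilibrium (trend test p < .01) for: ",
            paste(bad, collapse = ", "))
  attr(out, "nonequilibrium") <- bad
  class(out) <- c("clpv_chain_summary", "data.frame")
  out
}
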