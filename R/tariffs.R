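#' Grade tariff tables
#'
#' A tariff maps grade letters to points and fixes how many of a student's
#' best grades are summed.  Tariffs are data, not code: the shipped defaults
#' are the standard UK scorings (A-level/AS-level A = 10, B = 8, C = 6,
#' D = 4, E = 2; GCSE A* = 6 down to E = 1; SQA Highers A = 10 to D = 4;
#' `HighersPlus` band scoring A1 = 10 down to D8 = 3), and variants such as
#' an A* = 12 extension of the A-level tariff are additions loaded from
#' config, not edits to the defaults.
#'
#' @param qualification Character label for the qualification family.
#' @param mapping Named numeric vector, grade letter to points, given in
#'   grade-rank order (best first).  Points must be positive and strictly
#'   decreasing in rank.
#' @param k Number of best grades summed (at least 1).
#' @return An object of class `grade_tariff`.
#' @examples
#' tariff("A-level", c(A = 10, B = 8, C = 6, D = 4, E = 2), k = 3)
#' @export
tariff <- function(qualification, mapping, k) {
  stopifnot(is.character(qualification), length(qualification) == 1L)
  if (is.null(names(mapping)) || any(!nzchar(names(mapping))))
    stop("tariff mapping must be a named vector of grade letters")
  if (any(mapping <= 0))
    stop("tariff points must all be positive")
  if (any(diff(mapping) >= 0))
    stop("tariff mapping must be strictly decreasing in grade rank")
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("k must be a whole number >= 1")
  structure(list(qualification = qualification,
                 mapping = mapping, k = as.integer(k)),
            class = "grade_tariff")
}

#' @export
print.grade_tariff <- function(x, ...) {
  cat("Grade tariff:", x$qualification,
      sprintf("(best %d summed)\n", x$k))
  print(x$mapping)
  invisible(x)
}

#' Default grade tariffs
#'
#' Built-in tariff tables for the six UK qualification families, plus an
#' `"A-level-Astar"` variant extending the A-level tariff with A* = 12 for
#' post-2010 grade profiles.
#'
#' @param qualification Name of the tariff wanted; with no argument, the
#'   full named list is returned.
#' @return A `grade_tariff`, or a named list of them.
#' @export
default_tariff <- function(qualification = NULL) {
  hp <- c(A1 = 10, A2 = 9, B3 = 8, B4 = 7, C5 = 6, C6 = 5, D7 = 4, D8 = 3)
  defaults <- list(
    "A-level"        = tariff("A-level", c(A = 10, B = 8, C = 6, D = 4, E = 2), 3),
    "AS-level"       = tariff("AS-level", c(A = 10, B = 8, C = 6, D = 4, E = 2), 4),
    "GCSE"           = tariff("GCSE", c("A*" = 6, A = 5, B = 4, C = 3, D = 2, E = 1), 9),
    "Higher"         = tariff("Higher", c(A = 10, B = 8, C = 6, D = 4), 5),
    "HighersPlus"    = tariff("HighersPlus", hp, 5),
    "AdvancedHigher" = tariff("AdvancedHigher", hp, 1),
    "A-level-Astar"  = tariff("A-level-Astar",
                              c("A*" = 12, A = 10, B = 8, C = 6, D = 4, E = 2), 3))
  if (is.null(qualification)) return(defaults)
  if (!qualification %in% names(defaults))
    stop("no default tariff for qualification '", qualification, "'")
  defaults[[qualification]]
}

#' Read a tariff from a JSON or YAML file
#'
#' The file holds fields `qualification`, `mapping` (grade letter to points)
#' and `k`.
#'
#' @param path File path; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return A `grade_tariff`.
#' @export
read_tariff <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  tariff(spec$qualification, unlist(spec$mapping), spec$k)
}

#' Score a grade profile as the sum of the best k grades
#'
#' Maps each grade letter through the tariff and sums the `k` largest point
#' values (e.g. three best A-levels).  Profiles with fewer than `k` grades
#' are summed in full and flagged rather than rejected, since real cohorts
#' contain such students.
#'
#' @param grades Character vector of grade letters (order irrelevant).
#' @param tariff A `grade_tariff`.
#' @return A list of class `attainment_score` with `points` (integer sum),
#'   `n_graded` (number of grades actually summed) and `short` (`TRUE` when
#'   fewer than `k` grades were available).
#' @examples
#' score_best_k(c("A", "B", "C", "D"), default_tariff("A-level"))$points # 24
#' @export
score_best_k <- function(grades, tariff) {
  stopifnot(inherits(tariff, "grade_tariff"))
  if (length(grades) == 0L) stop("grade profile is empty")
  unknown <- setdiff(unique(grades), names(tariff$mapping))
  if (length(unknown))
    stop("unknown grade letter(s) for ", tariff$qualification, ": ",
         paste(unknown, collapse = ", "))
  pts <- sort(unname(tariff$mapping[grades]), decreasing = TRUE)
  n <- min(tariff$k, length(pts))
  structure(list(points = sum(pts[seq_len(n)]),
                 n_graded = n,
                 short = length(pts) < tariff$k),
            class = "attainment_score")
}

#' @export
print.attainment_score <- function(x, ...) {
  cat(x$points, "points from", x$n_graded, "grades",
      if (x$short) "(fewer than tariff k available)", "\n")
  invisible(x)
}

#' Standardize scores within groups
#'
#' Converts scores to z-scores separately within each group (for example,
#' by year of entry, so that marks are comparable across cohorts).  The
#' sample (n - 1) standard deviation is used.
#'
#' @param values Numeric scores.
#' @param groups Group labels, one per score.
#' @return Numeric vector of z-scores in input order: within each group the
#'   result has mean 0 and sample SD 1.
#' @export
zscore_by_group <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  out <- numeric(length(values))
  for (g in unique(groups)) {
    idx <- groups == g
    if (sum(idx) < 2L)
      stop("group '", g, "' has fewer than 2 members")
    s <- sd(values[idx])
    if (!is.finite(s) || s == 0)
      stop("group '", g, "' has zero variance")
    out[idx] <- (values[idx] - mean(values[idx])) / s
  }
  out
}

#' Composite attainment score via EM imputation and first principal component
#'
#' Builds a single attainment composite from several (partially missing)
#' qualification scores: columns are standardized, missing cells are
#' replaced under a multivariate-normal model fitted by
#' expectation-maximization, and the composite is the first principal
#' component of the completed, standardized table (principal components of
#' the correlation matrix, since the qualifications are on mixed scales).
#' The component's sign is fixed so that it correlates positively with the
#' row mean of the completed table.
#'
#' @param x Numeric matrix or data frame; rows are students, columns are
#'   qualification scores, `NA` for missing.  Each column needs at least
#'   50\% observed values.
#' @param tol EM convergence tolerance: iteration stops when the largest
#'   absolute change in any mean or covariance entry falls below `tol`.
#' @param max_iter Maximum EM iterations before rejection.
#' @return Numeric vector of composite scores (one per row), standardized
#'   to mean 0, SD 1, with attribute `"loadings"` giving the first
#'   principal-component loadings.
#' @export
composite_attainment <- function(x, tol = 1e-6, max_iter = 500L) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("score table must be numeric")
  n <- nrow(x); p <- ncol(x)
  obs_frac <- colMeans(!is.na(x))
  if (any(obs_frac < 0.5))
    stop("column(s) with more than 50% missing: ",
         paste(colnames(x)[obs_frac < 0.5], collapse = ", "))
  if (p == 1L) {
    if (anyNA(x)) stop("a single-column table must be complete")
    z <- drop(scale(x))
    attr(z, "loadings") <- stats::setNames(1, colnames(x))
    return(z)
  }
  # standardize on observed values; mixed-scale qualifications
  ctr <- colMeans(x, na.rm = TRUE)
  scl <- apply(x, 2, sd, na.rm = TRUE)
  if (any(scl == 0)) stop("constant column(s) in score table")
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")

  comp <- .em_mvnorm(z, tol = tol, max_iter = max_iter)
  zc <- scale(comp)                         # re-standardize completed table
  ev <- eigen(cor(zc), symmetric = TRUE)
  load <- ev$vectors[, 1]
  scores <- drop(zc %*% load)
  if (cor(scores, rowMeans(zc)) < 0) { scores <- -scores; load <- -load }
  scores <- drop(scale(scores))
  attr(scores, "loadings") <- stats::setNames(load, colnames(x))
  scores
}

# EM for a multivariate normal with data missing at random; returns the
# completed matrix (missing cells at their conditional means).
.em_mvnorm <- function(z, tol, max_iter) {
  n <- nrow(z); p <- ncol(z)
  miss <- is.na(z)
  if (!any(miss)) return(z)
  mu <- colMeans(z, na.rm = TRUE)
  sig <- cov(z, use = "pairwise.complete.obs")
  sig[!is.finite(sig)] <- 0
  diag(sig)[diag(sig) <= 0] <- 1
  pat <- apply(miss, 1, function(m) paste(which(m), collapse = ","))
  groups <- split(seq_len(n), pat)
  for (iter in seq_len(max_iter)) {
    t1 <- numeric(p); t2 <- matrix(0, p, p)
    for (rows in groups) {
      m <- miss[rows[1], ]
      zi <- z[rows, , drop = FALSE]
      if (!any(m)) {
        t1 <- t1 + colSums(zi)
        t2 <- t2 + crossprod(zi)
        next
      }
      o <- !m
      soo_inv <- solve(sig[o, o, drop = FALSE])
      smo <- sig[m, o, drop = FALSE]
      beta <- smo %*% soo_inv
      cond_cov <- sig[m, m, drop = FALSE] - beta %*% t(smo)
      dev <- sweep(zi[, o, drop = FALSE], 2, mu[o])
      zi[, m] <- matrix(mu[m], nrow(zi), sum(m), byrow = TRUE) +
        dev %*% t(beta)
      t1 <- t1 + colSums(zi)
      cp <- crossprod(zi)
      cp[m, m] <- cp[m, m] + length(rows) * cond_cov
      t2 <- t2 + cp
    }
    mu_new <- t1 / n
    sig_new <- t2 / n - tcrossprod(mu_new)
    delta <- max(abs(mu_new - mu), abs(sig_new - sig))
    mu <- mu_new; sig <- sig_new
    if (delta < tol) {
      # final imputation at converged parameters
      for (rows in groups) {
        m <- miss[rows[1], ]
        if (!any(m)) next
        o <- !m
        beta <- sig[m, o, drop = FALSE] %*% solve(sig[o, o, drop = FALSE])
        dev <- sweep(z[rows, o, drop = FALSE], 2, mu[o])
        z[rows, m] <- matrix(mu[m], length(rows), sum(m), byrow = TRUE) +
          dev %*% t(beta)
      }
      return(z)
    }
  }
  stop("EM imputation did not converge after ", max_iter, " iterations")
}
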