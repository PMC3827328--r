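#' Pipeline runners
#'
#' Thin orchestration layer over the package functions, mirroring the
#' stages of a full selection-validity analysis: simulate a cohort, fit
#' and correct a validity, pool validities across studies, predict
#' out-of-range performance, and score grade files.  Each runner takes a
#' config (a named list, or a path to a YAML file with the same fields),
#' writes plain-text/JSON outputs into `out_dir` when one is given, and
#' returns its result invisibly.  All outputs are deterministic given the
#' config seed (no timestamps), and existing files are never overwritten
#' unless `overwrite = TRUE`.  Defaults that stand in for missing inputs
#' (reliabilities, selection ratios) are recorded in the output's
#' `warnings` array.
#'
#' @param config Named list or YAML file path.
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param overwrite Allow replacing existing output files.
#' @return `run_simulate()` the cohort; `run_estimate()` a one-row data
#'   frame (the validity record); `run_meta()` a `clpv_meta`;
#'   `run_predict()` the prediction table; `run_score()` the scored table.
#' @name pipeline
NULL

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    stopifnot(file.exists(config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

# rolling polynomial hash of the deparsed config, for run identification
.config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.out_path <- function(out_dir, file, overwrite) {
  if (is.null(out_dir)) return(NULL)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- file.path(out_dir, file)
  if (file.exists(path) && !overwrite)
    stop("output file exists (use overwrite = TRUE): ", path)
  path
}

.write_tsv <- function(df, path) {
  if (is.null(path)) return(invisible(NULL))
  # full-precision round trip: default formatting truncates to 7 digits,
  # which would detach ceiling values from the ceiling on re-read
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_json <- function(x, path) {
  if (is.null(path)) return(invisible(NULL))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

#' @rdname pipeline
#' @export
run_simulate <- function(config = list(), out_dir = NULL, overwrite = FALSE) {
  config <- .load_config(config)
  cc <- do.call(cohort_config, config)
  coh <- simulate_cohort(cc)
  .write_tsv(data.frame(predictor = coh$applicants$values,
                        censored = coh$applicants$censored),
             .out_path(out_dir, "applicants.tsv", overwrite))
  .write_tsv(coh$entrants, .out_path(out_dir, "entrants.tsv", overwrite))
  .write_json(c(coh$truth, list(config_hash = .config_hash(config),
                                package_version =
                                  as.character(packageVersion("clpv")))),
              .out_path(out_dir, "truth.json", overwrite))
  invisible(coh)
}

.read_table_checked <- function(path, required, what) {
  stopifnot(file.exists(path))
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' @rdname pipeline
#' @export
run_estimate <- function(config, out_dir = NULL, overwrite = FALSE) {
  config <- .load_config(config)
  warnings_out <- character()
  entrants <- .read_table_checked(config$entrants,
                                  c("predictor", "outcome"), "entrants")
  ceiling <- if (is.null(config$ceiling)) Inf else config$ceiling
  # a censored flag column, when present, pins those values to the ceiling
  if (!is.null(entrants$censored))
    entrants$predictor[as.logical(entrants$censored)] <- ceiling
  outcome <- if (is.null(config$outcome)) "continuous" else config$outcome
  rel <- default_reliability()
  if (!is.null(config$reliability_predictor))
    rel[["predictor"]] <- config$reliability_predictor
  else warnings_out <- c(warnings_out,
                         "default predictor reliability .815 used")
  if (!is.null(config$reliability_outcome))
    rel[["outcome"]] <- config$reliability_outcome
  else warnings_out <- c(warnings_out, "default outcome reliability .834 used")

  applicants <- NULL; u_fixed <- NULL
  if (!is.null(config$applicants) && file.exists(config$applicants)) {
    app_tab <- .read_table_checked(config$applicants, "predictor",
                                   "applicants")
    applicants <- app_tab$predictor
    if (!is.null(app_tab$censored))
      applicants[as.logical(app_tab$censored)] <- ceiling
  } else {
    cls <- if (is.null(config$predictor_class)) "A-levels" else
      config$predictor_class
    u_fixed <- default_selection_ratio(cls)
    warnings_out <- c(warnings_out,
                      sprintf("no applicant file: default selection ratio %.3f for %s used",
                              u_fixed, cls))
  }
  ch_args <- config$chain
  ch <- if (is.null(ch_args)) chain_control() else
    do.call(chain_control, ch_args)
  if (!is.null(config$seed)) ch$seed <- as.integer(config$seed)

  fit <- clpv(outcome ~ predictor, data = entrants, applicants = applicants,
              ceiling = ceiling, outcome = outcome, reliability = rel,
              u = u_fixed, chain = ch)
  warnings_out <- c(warnings_out,
                    if (isTRUE(fit$estimate$unreliable))
                      ">5% of draws rejected by correction preconditions",
                    if (fit$estimate$n_clipped > 0)
                      sprintf("%d draws clipped at |rho| = 1",
                              fit$estimate$n_clipped),
                    if (length(attr(fit$chain_summary, "nonequilibrium")))
                      paste("non-equilibrium trend flagged for:",
                            paste(attr(fit$chain_summary, "nonequilibrium"),
                                  collapse = ", ")))

  keep <- as.data.frame(tail(fit$chain$draws, ch$use_last))
  .write_tsv(round(keep, 8), .out_path(out_dir, "chain.tsv", overwrite))
  e <- fit$estimate
  .write_json(list(
    estimate = list(rho = e$rho, se = e$se, ci = unname(e$ci),
                    equivalent_n = as.numeric(e$equivalent_n),
                    equivalent_n_rounded = attr(e$equivalent_n, "rounded"),
                    u = e$u),
    parameters = cbind(parameter = rownames(fit$chain_summary),
                       as.data.frame(fit$chain_summary)[1:4]),
    acceptance = fit$chain$acceptance,
    reliability = as.list(rel),
    warnings = as.list(warnings_out),
    config_hash = .config_hash(config),
    package_version = as.character(packageVersion("clpv"))),
    .out_path(out_dir, "summary.json", overwrite))
  record <- data.frame(
    r = e$rho,
    n = if (is.na(e$se)) NA_real_ else as.numeric(attr(e$equivalent_n, "rounded")),
    se = e$se,
    predictor_class = if (is.null(config$predictor_class)) NA_character_
    else config$predictor_class,
    outcome_stage = if (is.null(config$outcome_stage)) NA_character_
    else config$outcome_stage,
    cohort = if (is.null(config$cohort)) NA_character_ else config$cohort,
    year_of_entry = if (is.null(config$year_of_entry)) NA_real_
    else config$year_of_entry,
    stringsAsFactors = FALSE)
  .write_tsv(record, .out_path(out_dir, "clpv_record.tsv", overwrite))
  for (w in warnings_out) message("note: ", w)
  invisible(record)
}

#' @rdname pipeline
#' @export
run_meta <- function(config, out_dir = NULL, overwrite = FALSE) {
  config <- .load_config(config)
  tab <- .read_table_checked(config$effects, c("r"), "effects")
  res <- if (!is.null(config$moderators)) {
    meta_regress(as.formula(config$moderators), tab)
  } else {
    pool_random_effects(tab$r, n = tab[["n"]], sei = tab[["sei"]],
                        ci_lo = tab[["ci_lo"]], ci_hi = tab[["ci_hi"]])
  }
  .write_json(list(
    estimate = res$estimate, ci = unname(res$ci), tau2 = res$tau2,
    k = res$k,
    Q_B = res$Q_B, df_B = res$df_B, p_B = res$p_B,
    Q_E = res$Q_E, df_E = res$df_E, p_E = res$p_E,
    coefficients = if (!is.null(res$coefficients))
      cbind(term = rownames(res$coefficients), res$coefficients),
    config_hash = .config_hash(config),
    package_version = as.character(packageVersion("clpv"))),
    .out_path(out_dir, "meta.json", overwrite))
  path <- .out_path(out_dir, "meta.txt", overwrite)
  if (!is.null(path)) {
    con <- file(path, "w"); sink(con); print(res); sink(); close(con)
  }
  invisible(res)
}

#' @rdname pipeline
#' @export
run_predict <- function(config, out_dir = NULL, overwrite = FALSE) {
  config <- .load_config(config)
  if (is.character(config$scenario))
    config <- modifyList(config,
                         jsonlite::read_json(config$scenario,
                                             simplifyVector = TRUE))
  profiles <- config$profiles
  pts <- if (is.null(profiles)) numeric(0) else
    setNames(as.numeric(unlist(profiles)), names(unlist(profiles)))
  base_rates <- if (is.null(config$base_rates))
    c(fail = 0.03, retake = 0.15) else unlist(config$base_rates)
  tab <- if (length(pts) == 0L) {
    data.frame(profile = character(), points = numeric(), z = numeric(),
               outcome_z = numeric())
  } else {
    predict_performance(pts, pool_mean = config$pool_mean,
                        pool_sd = config$pool_sd, rho = config$rho,
                        r_XX = config$r_XX, r_YY = config$r_YY,
                        base_rates = base_rates)
  }
  .write_tsv(tab, .out_path(out_dir, "predictions.tsv", overwrite))
  invisible(tab)
}

#' @rdname pipeline
#' @export
run_score <- function(config, out_dir = NULL, overwrite = FALSE) {
  config <- .load_config(config)
  grades <- .read_table_checked(config$grades, character(), "grades")
  trf <- if (is.character(config$tariff)) {
    if (file.exists(config$tariff)) read_tariff(config$tariff) else
      default_tariff(config$tariff)
  } else do.call(tariff, config$tariff)
  grade_cols <- setdiff(names(grades), config$group_column)
  scored <- t(apply(grades[grade_cols], 1, function(row) {
    row <- row[!is.na(row) & nzchar(row)]
    s <- score_best_k(as.character(row), trf)
    c(points = s$points, n_graded = s$n_graded)
  }))
  out <- cbind(grades, as.data.frame(scored))
  if (!is.null(config$group_column)) {
    out$z <- zscore_by_group(out$points, grades[[config$group_column]])
  } else {
    out$z <- drop(scale(out$points))
  }
  .write_tsv(out, .out_path(out_dir, "scored.tsv", overwrite))
  invisible(out)
}
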