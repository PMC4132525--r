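# Orchestration: read or simulate a household table, then run
# scalability -> item selection -> model checks -> scores -> PCA contrast
# -> reliability -> expenditure comparison as one seeded, reproducible
# pipeline.

#' Pipeline configuration
#'
#' Either `input` (a delimited household table) or `synthetic` (a generator
#' block) supplies the data; everything else tunes the stages. All tuning
#' constants live here so a replication run on real survey data is a config
#' change, not a code change.
#'
#' @param input path to a comma-separated household table with a header row
#'   (or `NULL` to simulate).
#' @param synthetic list for the generator when `input` is `NULL`: either
#'   `list(preset = "whs_like", n = ..., seed = ...)` or a full
#'   [latent_config()] specification (`n`, `items`, `expenditure`).
#' @param items item column names (default: every column except the
#'   expenditure and `theta` columns).
#' @param expenditure_column name of the expenditure column.
#' @param dichotomise named list of thresholds for numeric columns: value
#'   `>= threshold` codes 1 (e.g. a car count with threshold 1 becomes
#'   ownership).
#' @param selection arguments for [selection_config()].
#' @param checks arguments for [check_config()].
#' @param n_boot bootstrap replicates for item-`H` standard errors (0 skips
#'   them).
#' @param out_dir directory for serialised outputs (`NULL`: none written).
#' @param seed integer master seed for every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL,
                            synthetic = list(preset = "whs_like", n = 3810),
                            items = NULL,
                            expenditure_column = "expenditure",
                            dichotomise = list(),
                            selection = list(),
                            checks = list(),
                            n_boot = 500,
                            out_dir = NULL,
                            seed = 1) {
  if (!is.null(items) && length(items) == 0L) {
    stop("item column list must be non-empty")
  }
  if (length(dichotomise) && !all(is.finite(unlist(dichotomise)))) {
    stop("dichotomisation thresholds must be finite")
  }
  structure(list(input = input, synthetic = synthetic, items = items,
                 expenditure_column = expenditure_column,
                 dichotomise = dichotomise,
                 selection = selection, checks = checks,
                 n_boot = n_boot, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys match [pipeline_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  # YAML 1.1 would coerce the bare keys y/n to booleans; keep them literal
  # (the generator block uses `n` for the household count)
  handlers <- list(
    "bool#yes" = function(x) if (x %in% c("y", "Y")) x else TRUE,
    "bool#no" = function(x) if (x %in% c("n", "N")) x else FALSE)
  do.call(pipeline_config, yaml::read_yaml(path, handlers = handlers))
}

#' Read a household table with complete-case exclusion
#'
#' Numeric columns named in the dichotomisation rules are recoded to
#' ownership indicators; households missing any item value are excluded
#' (complete-case analysis) and counted. Households with missing or
#' non-positive expenditure are kept for scaling and merely flagged so the
#' expenditure comparison can drop them.
#'
#' @param path comma-separated file with a header row.
#' @param config a [pipeline_config()].
#' @return list with `responses` (a `response_matrix`), `expenditure`
#'   (numeric, `NA` where unusable), and `exclusion_log` (rows in/used/
#'   excluded and the exclusion percentage).
#' @export
read_households <- function(path, config = pipeline_config(input = path)) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  exp_col <- config$expenditure_column
  items <- config$items
  if (is.null(items)) items <- setdiff(names(df), c(exp_col, "theta"))
  missing_cols <- setdiff(c(items,
                            if (exp_col %in% names(df)) exp_col), names(df))
  if (length(missing_cols)) {
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in names(config$dichotomise)) {
    if (!col %in% items) stop("unknown column in dichotomise rules: ", col)
    df[[col]] <- as.integer(df[[col]] >= config$dichotomise[[col]])
  }
  item_mat <- as.matrix(df[, items, drop = FALSE])
  complete <- stats::complete.cases(item_mat)
  n_in <- nrow(df)
  n_used <- sum(complete)
  if (n_used == 0L) stop("all households excluded: no complete cases")
  expenditure <- if (exp_col %in% names(df)) df[[exp_col]][complete] else
    rep(NA_real_, n_used)
  expenditure[!is.na(expenditure) & expenditure <= 0] <- NA_real_
  list(responses = as_response_matrix(item_mat[complete, , drop = FALSE]),
       expenditure = expenditure,
       exclusion_log = list(rows_in = n_in, rows_used = n_used,
                            rows_excluded = n_in - n_used,
                            pct_excluded = 100 * (n_in - n_used) / n_in,
                            expenditure_unusable = sum(is.na(expenditure))))
}

.acquire_data <- function(config) {
  if (!is.null(config$input)) {
    hh <- read_households(config$input, config)
    list(responses = hh$responses, expenditure = hh$expenditure,
         exclusion_log = hh$exclusion_log, theta = NULL)
  } else {
    syn <- config$synthetic
    seed <- if (!is.null(syn$seed)) syn$seed else config$seed
    ds <- if (identical(syn$preset, "whs_like") || is.null(syn$items)) {
      simulate_whs_like(n = if (!is.null(syn$n)) syn$n else 3810, seed = seed)
    } else {
      cfg <- latent_config(syn$n, as.data.frame(do.call(rbind, lapply(
        syn$items, as.data.frame))),
        expenditure = if (!is.null(syn$expenditure)) syn$expenditure else
          list(mu = 7, lambda = 0.525, sigma = 0.7),
        seed = seed)
      simulate_responses(cfg)
    }
    n_in <- length(ds$theta)
    list(responses = ds$responses, expenditure = ds$expenditure,
         exclusion_log = list(rows_in = n_in, rows_used = n_in,
                              rows_excluded = 0L, pct_excluded = 0,
                              expenditure_unusable = 0L),
         theta = ds$theta)
  }
}

#' Run the full SEP measurement pipeline
#'
#' Executes, in order: Loevinger scalability (with bootstrap standard
#' errors), the automated item selection procedure, the monotonicity check
#' on the first scale, the invariant-item-ordering check with iterative
#' removal, the Mokken sum score with quintiles, polychoric PCA indices on
#' the full pool and on the retained items, four weighted Cronbach's alphas
#' (unit- and PCA-weighted, full pool and retained pool), and the
#' comparison of all indices against log expenditure. Every stochastic
#' stage is seeded from `config$seed`, so identical configurations give
#' identical reports (timestamps aside).
#'
#' @param config a [pipeline_config()].
#' @return object of class `run_report`; if `config$out_dir` is set the
#'   report and its main tables are also written there (JSON + CSV). If a
#'   stage fails, the partial report is written with a `failed_stage`
#'   marker before the error propagates.
#' @export
run_full_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(provenance = list(
    config_hash = .config_hash(config), seed = config$seed,
    version = as.character(utils::packageVersion("mokkensep")),
    timestamp = format(Sys.time(), tz = "UTC")))
  class(report) <- "run_report"

  finish <- function(rep_) {
    if (!is.null(config$out_dir)) write_run_report(rep_, config$out_dir)
    rep_
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$failed_stage <<- name
      finish(report)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  dat <- stage("data", .acquire_data(config))
  report$exclusion_log <- dat$exclusion_log
  x <- dat$responses

  sel_cfg <- do.call(selection_config,
                     utils::modifyList(list(seed = config$seed),
                                       config$selection))
  chk_cfg <- do.call(check_config, config$checks)

  report$scalability <- stage("scalability", compute_scalability(
    x, se = config$n_boot > 0, n_boot = max(config$n_boot, 200),
    seed = config$seed))
  report$partition <- stage("aisp", aisp(x, sel_cfg))
  if (length(report$partition$scales) == 0L) {
    report$failed_stage <- "aisp (no scale formed)"
    return(finish(report))
  }
  scale1 <- report$partition$scales[[1L]]

  report$monotonicity <- stage("monotonicity",
                               check_monotonicity(x, scale1, chk_cfg))
  iio <- stage("iio", iterative_iio_removal(x, scale1, chk_cfg))
  report$iio_report <- iio$final_report
  report$removal_log <- iio$removal_log
  report$retained_items <- iio$retained

  report$mokken_index <- stage("mokken_score",
                               mokken_score(x, iio$retained))
  report$pca_full <- stage("pca_full", {
    R <- polychoric_matrix(x)
    pc <- pca_first_component(R)
    list(pca = pc, index = pca_scores(x, pc))
  })
  xr <- as_response_matrix(unclass(x)[, iio$retained, drop = FALSE])
  report$pca_reduced <- stage("pca_reduced", {
    R <- polychoric_matrix(xr)
    pc <- pca_first_component(R)
    list(pca = pc, index = pca_scores(xr, pc))
  })

  report$reliability <- stage("reliability", list(
    unit_full = weighted_alpha(x),
    pca_full = weighted_alpha(x, report$pca_full$pca$loadings),
    unit_mokken = weighted_alpha(xr),
    pca_reduced = weighted_alpha(xr, report$pca_reduced$pca$loadings)))

  report$comparison <- stage("comparison", {
    ok <- !is.na(dat$expenditure)
    sub_index <- function(w) {
      w$score <- w$score[ok]
      w$quintile <- w$quintile[ok]
      w
    }
    compare_indices(sub_index(report$mokken_index),
                    sub_index(report$pca_full$index),
                    sub_index(report$pca_reduced$index),
                    dat$expenditure[ok])
  })
  if (!is.null(dat$theta)) {
    report$theta_recovery <- list(
      spearman_mokken_theta = stats::cor(report$mokken_index$score,
                                         dat$theta, method = "spearman"))
  }
  finish(report)
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.run_report <- function(x, ...) {
  cat("SEP pipeline run (seed ", x$provenance$seed, ", config ",
      substr(x$provenance$config_hash, 1, 8), ")\n", sep = "")
  if (!is.null(x$failed_stage)) {
    cat("FAILED at stage:", x$failed_stage, "\n")
    return(invisible(x))
  }
  cat(" ", x$exclusion_log$rows_used, "households used (",
      sprintf("%.1f", x$exclusion_log$pct_excluded), "% excluded )\n")
  print(x$partition)
  cat("  retained after IIO removal:",
      paste(x$partition$item_labels[x$retained_items], collapse = ", "), "\n")
  cat(sprintf("  alphas: unit/full %.3f, pca/full %.3f, unit/scale %.3f, pca/reduced %.3f\n",
              x$reliability$unit_full$alpha, x$reliability$pca_full$alpha,
              x$reliability$unit_mokken$alpha,
              x$reliability$pca_reduced$alpha))
  cat(sprintf("  r(mokken, pca_full) = %.3f; r(mokken, log expenditure) = %.3f\n",
              x$comparison$pearson["mokken", "pca_full"],
              x$comparison$pearson["mokken", "log_expenditure"]))
  invisible(x)
}

#' Serialise a run report to JSON and delimited text tables
#'
#' Writes `run_report.json` plus `item_table.csv` (label, popularity, scale,
#' H_i, SE), `pair_table.csv`, `wealth_index.csv` (household, method, score,
#' quintile for each index) and `quintile_summary.csv` into `dir`.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(provenance = report$provenance,
               failed_stage = report$failed_stage,
               exclusion_log = report$exclusion_log)
  if (!is.null(report$scalability)) {
    json$scalability <- list(scale_H = report$scalability$scale_H,
                             transposed_H = report$scalability$transposed_H,
                             item = report$scalability$item)
    utils::write.csv(report$scalability$pairs,
                     file.path(dir, "pair_table.csv"), row.names = FALSE)
  }
  if (!is.null(report$partition)) {
    json$partition <- list(scales = report$partition$scales,
                           unscalable = report$partition$unscalable,
                           log = report$partition$selection_log)
  }
  if (!is.null(report$removal_log)) json$removal_log <- report$removal_log
  if (!is.null(report$retained_items)) {
    json$retained_items <- report$retained_items
  }
  if (!is.null(report$reliability)) {
    json$reliability <- lapply(report$reliability, function(r)
      list(alpha = r$alpha, ci_low = r$ci_low, ci_high = r$ci_high))
  }
  if (!is.null(report$comparison)) {
    json$comparison <- list(pearson = report$comparison$pearson,
                            spearman = report$comparison$spearman)
    utils::write.csv(report$comparison$quintile_summary,
                     file.path(dir, "quintile_summary.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$pca_full)) {
    json$pca_full <- list(
      loadings = report$pca_full$pca$loadings,
      eigenvalues = report$pca_full$pca$eigenvalues,
      variance_proportions = report$pca_full$pca$variance_proportions)
  }
  if (!is.null(report$pca_reduced)) {
    json$pca_reduced <- list(
      loadings = report$pca_reduced$pca$loadings,
      eigenvalues = report$pca_reduced$pca$eigenvalues,
      variance_proportions = report$pca_reduced$pca$variance_proportions)
  }
  jsonlite::write_json(json, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (!is.null(report$scalability) && !is.null(report$partition)) {
    it <- report$scalability$item
    scale_of <- rep(NA_integer_, nrow(it))
    for (s in seq_along(report$partition$scales)) {
      scale_of[report$partition$scales[[s]]] <- s
    }
    it$scale <- scale_of
    utils::write.csv(it, file.path(dir, "item_table.csv"), row.names = FALSE)
  }
  if (!is.null(report$mokken_index)) {
    wi <- do.call(rbind, lapply(
      list(report$mokken_index, report$pca_full$index,
           report$pca_reduced$index),
      function(w) data.frame(household = w$household_ids, method = w$method,
                             items = length(w$items), score = w$score,
                             quintile = w$quintile)))
    utils::write.csv(wi, file.path(dir, "wealth_index.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
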