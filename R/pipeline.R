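#' Build and validate an analysis configuration
#'
#' One flat key-value configuration drives the whole pipeline; every
#' published-analysis threshold is a default here, never hard-coded
#' downstream. Inputs may be file paths or `"fixture:<name>"` references to
#' the packaged tables.
#'
#' @param exposure,outcome summary-statistic sources: a path, a
#'   `"fixture:<name>"` string, or an in-memory `summary_stats` table.
#' @param exposure_n,outcome_n study sample sizes; auto-filled from the
#'   packaged metadata when the corresponding input is a fixture reference.
#' @param p_threshold instrument selection p-value cutoff (default 5e-6).
#' @param ld_r2_threshold clumping r-squared cutoff (default 0.001).
#' @param clump_window_bp clumping window (default 10 Mb).
#' @param ld LD source (path to a 3-column TSV, a matrix, or a function);
#'   `NULL` skips clumping (instruments assumed pre-clumped).
#' @param annotations,blocklist local trait-annotation table (path or data
#'   frame) and trait substrings for confounder screening; `NULL` skips.
#' @param palindromic_eaf_window see [harmonize()].
#' @param model `"auto_by_q"` (random effects when Cochran's Q p < 0.05,
#'   else fixed — the published rule), `"fixed"`, or `"random"`.
#' @param presso_n_sim,presso_outlier_alpha MR-PRESSO settings.
#' @param n_boot weighted-median bootstrap replicates.
#' @param seed integer seed for every stochastic step (required).
#' @param out_dir optional output directory for [write_analysis_report()].
#' @return A validated `analysis_config` list.
#' @export
analysis_config <- function(exposure, outcome, exposure_n = NULL,
                            outcome_n = NULL, p_threshold = 5e-6,
                            ld_r2_threshold = 0.001, clump_window_bp = 1e7,
                            ld = NULL, annotations = NULL, blocklist = NULL,
                            palindromic_eaf_window = 0.08,
                            model = c("auto_by_q", "fixed", "random"),
                            presso_n_sim = 1000, presso_outlier_alpha = 0.05,
                            n_boot = 1000, seed, out_dir = NULL) {
  model <- match.arg(model)
  if (missing(seed) || is.null(seed)) {
    stop_mr("analysis_config: seed is required (weighted median and MR-PRESSO are stochastic)",
            class = "mrpipe_config_error")
  }
  stopifnot(p_threshold > 0, p_threshold <= 1,
            ld_r2_threshold >= 0, ld_r2_threshold <= 1,
            palindromic_eaf_window >= 0, palindromic_eaf_window < 0.5,
            presso_n_sim >= 1, presso_outlier_alpha > 0,
            presso_outlier_alpha < 1, n_boot >= 1)
  structure(list(exposure = exposure, outcome = outcome,
                 exposure_n = exposure_n, outcome_n = outcome_n,
                 p_threshold = p_threshold,
                 ld_r2_threshold = ld_r2_threshold,
                 clump_window_bp = clump_window_bp, ld = ld,
                 annotations = annotations, blocklist = blocklist,
                 palindromic_eaf_window = palindromic_eaf_window,
                 model = model, presso_n_sim = presso_n_sim,
                 presso_outlier_alpha = presso_outlier_alpha,
                 n_boot = n_boot, seed = as.integer(seed), out_dir = out_dir),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path config file; keys are the arguments of [analysis_config()].
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(formals(analysis_config)))
  if (length(unknown)) {
    stop_mr("unknown config key(s): %s", paste(unknown, collapse = ", "),
            class = "mrpipe_config_error")
  }
  do.call(analysis_config, raw)
}

fixture_n_lookup <- c(bph_instruments = "Benign prostatic hyperplasia",
                      prostatitis_instruments = "Inflammatory diseases of prostate (prostatitis)")

resolve_stats_source <- function(src, what) {
  if (inherits(src, "summary_stats") || is.data.frame(src)) {
    return(list(records = as_summary_stats(as.data.frame(src)), n = NULL,
                label = sprintf("<in-memory %s>", what)))
  }
  if (is.character(src) && startsWith(src, "fixture:")) {
    name <- sub("^fixture:", "", src)
    records <- load_fixture(name)
    meta <- load_fixture("study_meta")
    n <- if (name %in% names(fixture_n_lookup))
      meta$n[match(fixture_n_lookup[[name]], meta$trait_label)] else NULL
    return(list(records = records, n = n, label = src))
  }
  list(records = read_summary_stats(src), n = NULL, label = src)
}

#' Run the full two-sample MR analysis
#'
#' Stages run in a fixed order: p-value selection, LD clumping (when an LD
#' source is configured), confounder screening (when annotations are
#' configured), harmonization, estimation (fixed and random IVW, MR-Egger and
#' weighted median where enough instruments remain), and the sensitivity
#' suite (Cochran's Q, Egger intercept, MR-PRESSO, leave-one-out, plot
#' data). The reporting IVW model follows the configured rule; `auto_by_q`
#' picks random effects exactly when the Q test p-value is below 0.05.
#'
#' @param config an `analysis_config`.
#' @return An `analysis_report` list; every number in it is reconstructable
#'   from inputs + config + seed.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- "resolve_inputs"
  report <- list(config = config[setdiff(names(config), c("ld", "annotations"))],
                 package_version = as.character(utils::packageVersion("mrpipe")))
  tryCatch({
    exp_src <- resolve_stats_source(config$exposure, "exposure")
    out_src <- resolve_stats_source(config$outcome, "outcome")
    n_x <- config$exposure_n %||% exp_src$n
    n_y <- config$outcome_n %||% out_src$n
    if (is.null(n_x)) {
      stop_mr("exposure_n not given and not inferable from the input",
              class = "mrpipe_config_error")
    }

    stage <- "select_instruments"
    iv <- select_instruments(exp_src$records, config$p_threshold)

    stage <- "clump"
    if (!is.null(config$ld)) {
      ld <- config$ld
      if (is.character(ld)) ld <- utils::read.table(ld, header = TRUE,
                                                    sep = "\t",
                                                    stringsAsFactors = FALSE)
      iv <- clump(iv, ld, config$ld_r2_threshold, config$clump_window_bp)
    } else {
      iv$provenance <- add_step(iv$provenance, iv$records, "clump", 0,
                                "skipped (no LD source configured)")
    }

    stage <- "screen_confounders"
    if (!is.null(config$annotations)) {
      ann <- config$annotations
      if (is.character(ann)) ann <- utils::read.table(ann, header = TRUE,
                                                      sep = "\t",
                                                      stringsAsFactors = FALSE)
      iv <- screen_confounders(iv, ann, config$blocklist %||% character(0))
    } else {
      iv$provenance <- add_step(iv$provenance, iv$records, "screen_confounders",
                                0, "skipped (no annotation table configured)")
    }

    stage <- "instrument_strength"
    report$strength <- instrument_strength(iv, n = n_x)
    report$strength_summary <- strength_summary(iv, n = n_x)

    stage <- "harmonize"
    hs <- harmonize(iv, out_src$records,
                    palindromic_eaf_window = config$palindromic_eaf_window)
    report$harmonization <- harmonization_report(hs)
    iv$provenance <- add_step(iv$provenance, iv$records, "harmonize",
                              nrow(hs$dropped),
                              sprintf("%d pair(s) retained", nrow(hs$pairs)))
    report$provenance <- iv$provenance
    k <- nrow(hs$pairs)
    if (k < 1) stop_mr("no pairs survived harmonization")

    stage <- "heterogeneity"
    q <- if (k >= 2) cochran_q(hs) else NULL
    report$q_test <- if (is.null(q)) NULL else unclass(q)
    model <- switch(config$model,
                    fixed = "fixed", random = "random",
                    auto_by_q = if (!is.null(q) && q$pvalue < 0.05) "random"
                      else "fixed")
    report$model <- list(rule = config$model, chosen = model,
                         q_pvalue = if (is.null(q)) NA_real_ else q$pvalue)

    stage <- "estimation"
    estimates <- list(main = mr_ivw(hs, model), ivw_fixed = mr_ivw(hs, "fixed"),
                      ivw_random = mr_ivw(hs, "random"))
    if (k >= 3) {
      estimates$egger <- mr_egger(hs)
      estimates$weighted_median <- mr_weighted_median(hs, config$n_boot,
                                                      seed = config$seed)
    }
    report$estimates <- mr_estimates_table(estimates)
    report$estimates$role <- names(estimates)

    stage <- "diagnostics"
    if (k >= 3) report$egger_intercept <- egger_intercept_test(hs)
    if (k >= 4) {
      pr <- mr_presso(hs, n_sim = config$presso_n_sim, seed = config$seed,
                      outlier_alpha = config$presso_outlier_alpha)
      report$presso <- unclass(pr)
    }
    if (k >= 2) {
      loo <- leave_one_out(hs, model = model)
      report$loo <- loo
      report$loo_sign_consistency <- attr(loo, "sign_consistency")
    }
    report$plot_data <- funnel_and_forest_data(
      hs, estimates = estimates[setdiff(names(estimates), "main")])
    report$run_info <- list(timestamp = format(Sys.time(), tz = "UTC"),
                            r_version = R.version.string)
    structure(report, class = "analysis_report")
  }, mrpipe_error = function(e) {
    prov <- tryCatch(report$provenance, error = function(...) NULL)
    stop_mr("analysis aborted at stage '%s': %s", stage, conditionMessage(e),
            class = "mrpipe_stage_error")
  })
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> mrpipe %s\n", x$package_version))
  print(x$provenance, row.names = FALSE)
  cat(sprintf("model: %s (rule %s, Q p = %.3g)\n", x$model$chosen,
              x$model$rule, x$model$q_pvalue))
  print(x$estimates[, c("role", "method", "nsnp", "beta", "se", "ci_low",
                        "ci_high", "pvalue", "or_point")], row.names = FALSE)
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits `report.json` (timestamps quarantined under `run_info` so the rest
#' is diffable) plus TSV tables: estimates, harmonization, provenance,
#' leave-one-out, and the forest/funnel/scatter plot data.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  validate_report(report)
  json <- report
  json$loo <- as.data.frame(json$loo)
  jsonlite::write_json(json, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE, pretty = TRUE)
  wt <- function(df, name) {
    if (!is.null(df)) utils::write.table(df, file.path(dir, name), sep = "\t",
                                         quote = FALSE, row.names = FALSE)
  }
  wt(report$estimates, "estimates.tsv")
  wt(report$harmonization, "harmonization.tsv")
  wt(report$provenance, "provenance.tsv")
  wt(report$loo, "loo.tsv")
  wt(report$plot_data$forest, "forest.tsv")
  wt(report$plot_data$funnel, "funnel.tsv")
  wt(report$plot_data$scatter, "scatter.tsv")
  invisible(dir)
}

#' Validate a report against the shipped JSON schema
#'
#' Checks the presence and JSON type of every required top-level field named
#' in `inst/schema/report_schema.json`.
#'
#' @param report an `analysis_report` (or a list parsed from report.json).
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_report <- function(report) {
  schema_path <- system.file("schema", "report_schema.json",
                             package = "mrpipe", mustWork = TRUE)
  schema <- jsonlite::read_json(schema_path)
  required <- unlist(schema$required)
  missing <- setdiff(required, names(report))
  if (length(missing)) {
    stop_mr("report missing required field(s): %s",
            paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
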