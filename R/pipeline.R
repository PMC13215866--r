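# End-to-end pipeline: simulate-or-read -> FGLS vulnerability -> distribution
# -> VIF / OLS / quantiles / Wald / subgroup / interactions -> composites ->
# path fit -> effect decomposition -> fit indices. Fully determined by
# (config, master seed); the master seed expands to per-stage substreams so
# disabling one stage never changes another's results.

default_quantile_covariates <- function() {
  c("educational_level", "health_status", "labor_force", "migrant_workers",
    "agri_machines", "durable_products", "building_material", "tap_water",
    "latrines_type", "cultivated_area", "sep_housing_kitchen",
    "cash_gift_log", "outpatient", "outpatient_oop_log", "inpatient",
    "inpatient_oop_log", "physical_examination", "self_treatment")
}

#' Pipeline configuration
#'
#' Exactly one of `input_csv` / `synthetic` must be provided.
#'
#' @param input_csv path to a survey CSV, or NULL.
#' @param synthetic a [synthetic_config()], or NULL.
#' @param income_spec an [income_model_spec()] for the FGLS stage.
#' @param income_col income column name.
#' @param poverty_line relative poverty line.
#' @param threshold vulnerability classification threshold.
#' @param bin_edges distribution bin edges.
#' @param quantile_covariates covariates of the heterogeneity analysis.
#' @param taus quantile levels.
#' @param run_quantiles,run_paths stage switches.
#' @param group_col binary grouping column for the subgroup stage (skipped if
#'   absent from the table).
#' @param interaction_pairs list of covariate pairs for the interaction model.
#' @param constructs a [construct_spec()].
#' @param diagram a [path_diagram()].
#' @param bootstrap_reps bootstrap replications shared by the bootstrap
#'   stages.
#' @param seed master seed.
#' @param out_dir output directory (NULL = no files written).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_csv = NULL, synthetic = NULL,
                            income_spec = income_model_spec(
                              c("household_size", "dependency_ratio",
                                "health_status", "medical_insurance",
                                "medical_debt"),
                              c("dependency_ratio", "health_status",
                                "medical_debt")),
                            income_col = "income",
                            poverty_line = 9202, threshold = 0.5,
                            bin_edges = c(0, 0.25, 0.5, 0.75, 1),
                            quantile_covariates = default_quantile_covariates(),
                            taus = c(0.25, 0.5, 0.75),
                            run_quantiles = TRUE, run_paths = TRUE,
                            group_col = "farming",
                            interaction_pairs = list(
                              c("labor_force", "farming"),
                              c("migrant_workers", "farming")),
                            constructs = default_construct_spec(),
                            diagram = default_path_diagram(),
                            bootstrap_reps = 500, seed = 1L,
                            out_dir = NULL) {
  if (is.null(input_csv) == is.null(synthetic)) {
    abort("exactly one of input_csv / synthetic must be set")
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  structure(list(input_csv = input_csv, synthetic = synthetic,
                 income_spec = income_spec, income_col = income_col,
                 poverty_line = poverty_line, threshold = threshold,
                 bin_edges = bin_edges,
                 quantile_covariates = quantile_covariates, taus = taus,
                 run_quantiles = isTRUE(run_quantiles),
                 run_paths = isTRUE(run_paths), group_col = group_col,
                 interaction_pairs = interaction_pairs,
                 constructs = constructs, diagram = diagram,
                 bootstrap_reps = bootstrap_reps, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

run_stage <- function(stage, report, expr) {
  tryCatch(expr, error = function(e) {
    abort("stage '%s' failed: %s (completed stages: %s)", stage,
          conditionMessage(e),
          paste(names(report), collapse = ", "))
  })
}

#' Run the full analysis pipeline
#'
#' @param config a [pipeline_config()].
#' @return object of class `run_report` with one element per executed stage;
#'   artifacts are written under `config$out_dir` when set (per-household
#'   CSV, table twins, and a machine-readable `summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list()

  table <- run_stage("input", report, {
    if (!is.null(config$input_csv)) {
      read_survey(config$input_csv)
    } else {
      generate_survey(config$synthetic)$table
    }
  })
  report$input <- list(n = nrow(table), columns = names(table),
                       source = if (is.null(config$input_csv)) "synthetic"
                                else config$input_csv)

  # VEP-FGLS and the vulnerability distribution
  vep <- run_stage("vep_fgls", report, {
    fit <- fit_income_fgls(table, config$income_spec,
                           income_col = config$income_col)
    pred <- predict_mean_variance(fit, table)
    v <- vulnerability_index(pred$mu, pred$sigma2, config$poverty_line)
    dist <- classify_and_summarize(v, config$threshold, config$bin_edges)
    list(fit = fit, index = v, distribution = dist)
  })
  table$vulnerability <- vep$index
  report$vep_fgls <- list(
    beta_hat = vep$fit$beta_hat, theta_hat = vep$fit$theta_hat,
    n = vep$fit$n, floored_rows = length(vep$fit$floored_rows),
    excluded_rows = vep$fit$excluded_rows,
    poverty_line = config$poverty_line, threshold = config$threshold,
    distribution = list(bins = vep$distribution$bin_labels,
                        counts = vep$distribution$counts,
                        percents = vep$distribution$percents,
                        bin_means = vep$distribution$bin_means,
                        bin_sds = vep$distribution$bin_sds,
                        headcount = vep$distribution$headcount_ge_threshold,
                        headcount_percent = vep$distribution$headcount_percent))

  if (config$run_quantiles) {
    q <- run_stage("quantiles", report, {
      covs <- intersect(config$quantile_covariates, names(table))
      constant <- covs[vapply(table[covs],
                              function(x) stats::sd(as.numeric(x)) == 0,
                              logical(1))]
      if (length(constant) > 0) {
        message("dropping constant covariate(s) from the quantile stage: ",
                paste(constant, collapse = ", "))
        covs <- setdiff(covs, constant)
      }
      X <- design_matrix(table, covs)
      y <- table$vulnerability
      vif <- compute_vif(X[, -1, drop = FALSE])
      ols <- fit_ols(X, y)
      cq <- cross_quantile_tests(
        X, y, taus = config$taus,
        bootstrap_reps = config$bootstrap_reps,
        seed = substream_seed(config$seed, "quantile-bootstrap"))
      subgroup <- NULL
      if (!is.null(config$group_col) && config$group_col %in% names(table)) {
        subgroup <- subgroup_equality(table, "vulnerability", covs,
                                      config$group_col)
      }
      interactions <- NULL
      pairs_ok <- Filter(function(p) all(p %in% names(table)),
                         config$interaction_pairs)
      if (length(pairs_ok) > 0) {
        interactions <- fit_interactions(
          table, "vulnerability",
          unique(c(covs, config$group_col)), pairs_ok)
      }
      list(vif = vif, ols = ols, cross_quantile = cq, subgroup = subgroup,
           interactions = interactions)
    })
    report$quantiles <- list(
      vif = q$vif$vif, max_vif = q$vif$max_vif,
      ols = data.frame(variable = names(q$ols$coefficients),
                       estimate = as.numeric(q$ols$coefficients),
                       se = as.numeric(q$ols$se),
                       p_value = as.numeric(q$ols$p_value)),
      cross_quantile = q$cross_quantile$table,
      subgroup = if (!is.null(q$subgroup)) q$subgroup$table,
      interactions = if (!is.null(q$interactions)) {
        data.frame(variable = names(q$interactions$coefficients),
                   estimate = as.numeric(q$interactions$coefficients),
                   se = as.numeric(q$interactions$se),
                   p_value = as.numeric(q$interactions$p_value))
      })
  }

  if (config$run_paths) {
    pth <- run_stage("path_model", report, {
      composites <- build_composites(table, config$constructs)
      fit <- fit_path_model(composites, config$diagram,
                            bootstrap_reps = config$bootstrap_reps,
                            seed = substream_seed(config$seed,
                                                  "path-bootstrap"))
      effects <- decompose_effects(fit)
      Sigma <- implied_covariance(fit)
      idx <- fit_indices(fit$S, Sigma, path_model_df(config$diagram),
                         n = fit$n)
      list(fit = fit, effects = effects, fit_indices = idx)
    })
    report$path_model <- list(
      edges = significance_report(pth$fit),
      effects = as.data.frame(pth$effects),
      fit_indices = list(chi_square = pth$fit_indices$chi_square,
                         df = pth$fit_indices$df,
                         GFI = pth$fit_indices$GFI,
                         AGFI = pth$fit_indices$AGFI,
                         PGFI = pth$fit_indices$PGFI,
                         IFI = pth$fit_indices$IFI,
                         CFI = pth$fit_indices$CFI,
                         SRMR = pth$fit_indices$SRMR,
                         RMSEA = pth$fit_indices$RMSEA))
  }

  report$config_echo <- list(seed = config$seed,
                             poverty_line = config$poverty_line,
                             threshold = config$threshold,
                             taus = config$taus,
                             bootstrap_reps = config$bootstrap_reps,
                             run_quantiles = config$run_quantiles,
                             run_paths = config$run_paths)
  report$versions <- list(
    vepvuln = as.character(utils::packageVersion("vepvuln")),
    R = paste(R.version$major, R.version$minor, sep = "."))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_survey(data.frame(household = seq_len(nrow(table)),
                            index = vep$index,
                            vulnerable = as.integer(
                              vep$index >= config$threshold)),
                 file.path(config$out_dir, "vulnerability.csv"))
    if (config$run_quantiles) {
      write_survey(report$quantiles$cross_quantile,
                   file.path(config$out_dir, "cross_quantile_tests.csv"))
      write_survey(report$quantiles$ols,
                   file.path(config$out_dir, "ols.csv"))
    }
    if (config$run_paths) {
      write_survey(report$path_model$edges,
                   file.path(config$out_dir, "path_coefficients.csv"))
      write_survey(report$path_model$effects,
                   file.path(config$out_dir, "effects.csv"))
    }
    jsonlite::write_json(report, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null", force = TRUE)
  }
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report; stages:",
      paste(setdiff(names(x), c("config_echo", "versions")),
            collapse = ", "), "\n")
  cat(sprintf("  n = %d; vulnerable share %.2f%%\n", x$input$n,
              x$vep_fgls$distribution$headcount_percent))
  invisible(x)
}
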